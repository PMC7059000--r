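id	gender	age	lesion	we_fmt	history
001	F	65	Right IC, CR	94	HD, HL
002	M	62	Right IC	100	HD, HL
003	F	63	Right CR, IC, LN	98	HBP
004	F	52	Right CR, IC, LN	99	None
005	M	53	Right CR, IC, LN	95	HBP, HL
006	M	65	Right CR	98	HD, HL
007	M	59	Left CR, IC, LN	98	HD, HL
008	M	49	Left CR, IC, LN	98	HD, HD
009	M	60	Left CR	100	HD, HL
010	F	72	Right CR, IC, LN	98	HD
011	F	55	Left Th	100	HD
012	M	49	Right CR, IC, LN	100	HD
013	M	42	Left Th	100	HD, DM, TIA, HL
014	M	50	Left CR, IC	100	HD, TIA, HL
015	M	52	Left CR, IC	100	HL
016	M	58	Left IC	100	HBP
017	M	65	Right CR, IC, LN	99	HBP, HD
018	F	63	Right Th	100	HD
019	M	55	Left IC, LN	100	HBP, HL
020	M	47	Left CR	100	HBP, DM, HL
021	M	58	Right CR, Cau, IC	100	HD
022	M	63	Left CR, IC	100	TIA, HL, DM
023	M	45	Right CR	100	HD, DM, HL
024	M	49	Right CR, IC	96	HD, HL
025	F	53	Left CR, IC, LN	99	HBP
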
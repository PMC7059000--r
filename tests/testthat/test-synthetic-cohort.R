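# Synthetic cohort generator: reproducibility, generative model structure,
# planted group effects, metadata, and on-disk datasets.

test_that("spec validation names the offending field", {
  expect_error(cohort_spec(n_patients = 0), "n_patients")
  expect_error(cohort_spec(n_volumes = 5), "n_volumes")
  expect_error(cohort_spec(grid_shape = c(10, 10)), "grid_shape")
  expect_error(cohort_spec(band = c(0.1, 0.05)), "band")
  expect_error(cohort_spec(group_effects = list(
    list(pair = c("sma_proper", "nowhere"), delta = 0.1))), "nowhere")
})

test_that("identical spec and seed reproduce identical data", {
  spec <- tiny_spec(rng_seed = 11)
  truth <- make_ground_truth(spec)
  a <- synthesize_bold(truth, "patient", rng_seed = 42)
  b <- synthesize_bold(truth, "patient", rng_seed = 42)
  expect_identical(a$img$data, b$img$data)
  expect_identical(a$motion, b$motion)
  d <- synthesize_bold(truth, "patient", rng_seed = 43)
  expect_false(identical(a$img$data, d$img$data))
})

test_that("images have the requested geometry and volume count", {
  spec <- cohort_spec(n_patients = 1, n_controls = 1,
                      grid_shape = c(14, 14, 12), n_volumes = 180,
                      rng_seed = 3)
  truth <- make_ground_truth(spec)
  sub <- synthesize_bold(truth, "control", 1)
  expect_equal(dim(sub$img$data), c(14, 14, 12, 180))
  expect_equal(nrow(sub$motion), 180)
  expect_equal(sub$img$tr_s, 2.0)
})

test_that("seed subregions tile the seed mask on different grids", {
  for (g in list(c(24, 28, 24), c(14, 14, 12), c(16, 18, 14))) {
    masks <- parcelfc:::default_region_layout(g)
    expect_gt(sum(masks$seed), 0)
    expect_equal(masks$sma_proper + masks$presma, masks$seed)
    expect_equal(sum(masks$sma_proper * masks$presma), 0)
    # all regions sit inside the brain, disjoint from one another
    for (r in c("target_motor", "target_prefrontal", "target_shared")) {
      expect_gt(sum(masks[[r]]), 0)
      expect_true(all(masks$brain[masks[[r]] > 0] == 1))
      expect_equal(sum(masks[[r]] * masks$seed), 0)
    }
    # x-mirror symmetry so that left-right flips are structure-preserving
    for (r in c("seed", "brain", "gm", "target_motor", "target_shared"))
      expect_equal(flip3d(masks[[r]]), masks[[r]])
  }
})

test_that("latent courses are band-limited", {
  set.seed(12)
  for (i in 1:5) {
    cs <- parcelfc:::band_limited_courses(3, 170, 2, c(0.01, 0.08))
    co <- abs(mvfft(cs))^2
    freqs <- pmin(seq(0, 169), 170 - seq(0, 169)) / (170 * 2)
    inband <- freqs >= 0.01 & freqs <= 0.08
    expect_gt(sum(co[inband, ]) / sum(co), 0.9)
    expect_equal(apply(cs, 2, sd), rep(1, 3), tolerance = 1e-6)
  }
})

test_that("noiseless shared source gives perfect correlation", {
  spec <- tiny_spec(noise_sd = 0, global_sd = 0, drift_slope_sd = 0,
                    motion_artifact_sd = 0, coupling_jitter_sd = 0,
                    rng_seed = 5)
  truth <- make_ground_truth(spec)
  # make both regions load a single shared course
  truth$coupling_control["sma_proper", ] <- c(1, 0, 0)
  truth$coupling_control["target_motor", ] <- c(1, 0, 0)
  sub <- synthesize_bold(truth, "control", 4)
  m <- img_matrix(sub$img)
  a <- rowMeans(m[, which(truth$region_masks$sma_proper > 0)])
  b <- rowMeans(m[, which(truth$region_masks$target_motor > 0)])
  expect_equal(cor(a, b), 1.0, tolerance = 1e-10)
})

test_that("within-region voxel correlation matches the closed form", {
  # loading 1 against unit noise: expected r = a^2/(a^2+1) = 0.5
  spec <- tiny_spec(global_sd = 0, drift_slope_sd = 0,
                    motion_artifact_sd = 0, coupling_jitter_sd = 0,
                    n_volumes = 170, rng_seed = 6)
  truth <- make_ground_truth(spec)
  truth$coupling_control["target_motor", ] <- c(1, 0, 0)
  idx <- which(truth$region_masks$target_motor > 0)[1:2]
  rs <- vapply(1:100, function(i) {
    sub <- synthesize_bold(truth, "control", 1000 + i)
    m <- matrix(sub$img$data, prod(dim(sub$img$data)[1:3]), 170)
    cor(m[idx[1], ], m[idx[2], ])
  }, numeric(1))
  expect_equal(mean(rs), 0.5, tolerance = 0.1)
})

test_that("all-zero loadings leave voxel correlations centred on zero", {
  spec <- tiny_spec(global_sd = 0, drift_slope_sd = 0,
                    motion_artifact_sd = 0, rng_seed = 13)
  truth <- make_ground_truth(spec)
  truth$coupling_control[] <- 0
  sub <- synthesize_bold(truth, "control", 2)
  m <- img_matrix(sub$img)
  idx <- which(truth$region_masks$target_motor > 0)
  cc <- cor(m[, idx[1:6]])
  expect_lt(abs(mean(cc[upper.tri(cc)])), 0.1)
})

test_that("planted effects shift patient coupling only, in the right direction", {
  spec <- tiny_spec(group_effects = NULL, rng_seed = 17)
  truth <- make_ground_truth(spec)
  # delta = 0 leaves the generative model untouched
  t0 <- plant_group_effect(truth, c("sma_proper", "target_motor"), 0)
  expect_equal(t0$coupling_patient, truth$coupling_patient)
  expect_error(plant_group_effect(truth, c("sma_proper", "atlantis"), 0.1),
               "unknown region")
  # two effects on disjoint pairs are recorded independently
  t2 <- plant_group_effect(truth, c("sma_proper", "target_motor"), 0.3)
  t2 <- plant_group_effect(t2, c("presma", "target_shared"), -0.3)
  expect_equal(length(t2$planted_group_deltas), 2)
  expect_equal(t2$coupling_patient["sma_proper", "net_motor"], 1.3)
  expect_equal(t2$coupling_patient["presma", "net_salience"], 0.2)
  expect_equal(t2$coupling_control, truth$coupling_control)
})

test_that("negative planted delta lowers patient-minus-control connectivity", {
  diffs <- vapply(1:8, function(c_i) {
    spec <- tiny_spec(n_patients = 6, n_controls = 6, n_volumes = 100,
                      rng_seed = 400 + c_i,
                      group_effects = list(list(
                        pair = c("presma", "target_shared"), delta = -0.4)))
    co <- simulate_cohort(spec)
    z <- vapply(seq_len(nrow(co$meta)), function(i)
      roi_pair_fc(co$subjects[[i]]$img, co$truth$region_masks$presma,
                  co$truth$region_masks$target_shared), numeric(1))
    pat <- co$meta$group == "patient"
    mean(z[pat]) - mean(z[!pat])
  }, numeric(1))
  expect_lt(mean(diffs), 0)
  expect_gte(mean(diffs < 0), 0.85)
})

test_that("positive planted delta raises connectivity in nearly all cohorts", {
  diffs <- vapply(1:20, function(c_i) {
    spec <- cohort_spec(n_patients = 25, n_controls = 22,
                        grid_shape = c(14, 14, 12), n_volumes = 100,
                        rng_seed = 600 + c_i,
                        group_effects = list(list(
                          pair = c("sma_proper", "target_motor"),
                          delta = 0.4)))
    co <- simulate_cohort(spec)
    z <- vapply(seq_len(nrow(co$meta)), function(i)
      roi_pair_fc(co$subjects[[i]]$img, co$truth$region_masks$sma_proper,
                  co$truth$region_masks$target_motor), numeric(1))
    pat <- co$meta$group == "patient"
    mean(z[pat]) - mean(z[!pat])
  }, numeric(1))
  expect_gte(mean(diffs > 0), 0.95)
})

test_that("subject metadata matches the emulated cohort structure", {
  spec <- cohort_spec(rng_seed = 23)
  meta <- subject_table(spec)
  expect_equal(nrow(meta), 47)
  expect_equal(sum(meta$group == "patient"), 25)
  expect_equal(sum(meta$sex[meta$group == "patient"] == "F"), 7)
  expect_equal(sum(meta$sex[meta$group == "control"] == "F"), 11)
  expect_true(all(meta$age >= 42 & meta$age <= 74))
  expect_equal(unique(meta$lesion_side[meta$group == "control"]), "none")
  expect_setequal(unique(meta$lesion_side[meta$group == "patient"]),
                  c("left", "right"))
  expect_true(all(meta$we_fmt[meta$group == "patient"] > 90))
  expect_true(all(is.na(meta$we_fmt[meta$group == "control"])))
  # deterministic given the seed
  expect_identical(meta, subject_table(spec))
})

test_that("on-disk datasets are complete and byte-reproducible", {
  spec <- tiny_spec(n_patients = 1, n_controls = 1, n_volumes = 30,
                    rng_seed = 11)
  d1 <- file.path(tempdir(), "cohort_a")
  d2 <- file.path(tempdir(), "cohort_b")
  generate_cohort(spec, d1)
  generate_cohort(spec, d2)
  expect_true(file.exists(file.path(d1, "participants.tsv")))
  expect_true(file.exists(file.path(d1, "provenance.json")))
  expect_true(file.exists(file.path(d1, "masks", "seed.nii.gz")))
  imgs <- list.files(d1, pattern = "bold", full.names = TRUE)
  expect_length(imgs, 2)
  a <- read_image(file.path(d1, "sub-001_bold.nii.gz"), "4d")
  b <- read_image(file.path(d2, "sub-001_bold.nii.gz"), "4d")
  expect_identical(a$data, b$data)
  expect_equal(dim(a$data)[4], 30)
  prov <- jsonlite::read_json(file.path(d1, "provenance.json"))
  expect_equal(prov$spec$rng_seed, 11)
  unlink(c(d1, d2), recursive = TRUE)
})
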
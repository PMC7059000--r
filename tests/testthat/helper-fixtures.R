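# Shared fixtures: small synthetic cohorts and masks built in code.

# A small cohort spec that keeps unit tests fast.
tiny_spec <- function(n_patients = 3, n_controls = 3, n_volumes = 60,
                      rng_seed = 7, ...) {
  cohort_spec(n_patients = n_patients, n_controls = n_controls,
              grid_shape = c(14, 14, 12), n_volumes = n_volumes,
              rng_seed = rng_seed, ...)
}

# One preprocessed control subject of the tiny cohort plus its truth.
tiny_subject <- function(rng_seed = 7, fwhm_mm = 0) {
  spec <- tiny_spec(rng_seed = rng_seed)
  truth <- make_ground_truth(spec)
  sub <- synthesize_bold(truth, "control", rng_seed = rng_seed)
  pp <- preprocess_subject(sub$img, sub$motion, truth$masks,
                           fwhm_mm = fwhm_mm)
  list(spec = spec, truth = truth, raw = sub, img = pp$img, qc = pp$qc)
}

# Ground-truth subregion labels (1 = anterior, 2 = posterior) on the
# seed-mask voxel order.
truth_labels <- function(truth) {
  seed_idx <- which(truth$masks$seed > 0)
  ifelse(truth$region_masks$presma[seed_idx] > 0, 1L, 2L)
}

# Adjusted Rand index between two labelings (independent implementation
# used as a clustering oracle).
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(as.vector(tab))
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  maxi <- (si + sj) / 2
  if (maxi == expected) return(1)
  (sij - expected) / (maxi - expected)
}

# Reverse a 3D array along x (reference flip used as an oracle).
flip3d <- function(v) v[dim(v)[1]:1, , , drop = FALSE]

# Gaussian white-noise z-maps (3D) for group-statistics tests.
noise_maps <- function(n, dims = c(8, 8, 6), sd = 1, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) array(rnorm(prod(dims), sd = sd), dims))
}
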
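# Seed-based FC maps, one-sample FDR maps, group GLM contrasts,
# Monte-Carlo cluster-extent correction, ROI-wise tests.

test_that("seed FC maps equal direct voxel correlations", {
  sub <- tiny_subject(rng_seed = 14)
  brain <- sub$truth$masks$brain
  roi <- sub$truth$region_masks$sma_proper
  zmap <- seed_fc_map(sub$img, roi, brain)
  # single-voxel ROI equals the plain correlation map at that voxel
  one <- array(0L, dim(roi)); one[which(roi > 0)[1]] <- 1L
  zmap1 <- seed_fc_map(sub$img, one, brain)
  M <- img_matrix(sub$img)
  ref <- atanh(pmin(pmax(cor(M[, which(one > 0)], M[, which(brain > 0)]),
                         -1 + 1e-7), 1 - 1e-7))
  expect_equal(zmap1[which(brain > 0)], as.vector(ref), tolerance = 1e-12)
  # the seed voxel itself correlates perfectly -> capped z
  expect_equal(zmap1[which(one > 0)], atanh(1 - 1e-7))
  # a pure-noise voxel sits near zero
  far <- which(brain > 0 & sub$truth$region_masks$target_prefrontal == 0 &
                 sub$truth$region_masks$target_motor == 0 &
                 sub$truth$region_masks$target_shared == 0 &
                 sub$truth$masks$seed == 0)[1]
  expect_lt(abs(zmap[far]), 0.5)
  expect_error(seed_fc_map(sub$img, roi * 0L, brain), "empty")
})

test_that("one-sample FDR maps threshold and cluster correctly", {
  dims <- c(10, 10, 8)
  mask <- array(1L, dims)
  # all-zero maps: nothing survives, no error
  zeros <- lapply(1:5, function(i) array(0, dims))
  res <- one_sample_t_fdr(zeros, mask, min_cluster = 5)
  expect_equal(sum(res$thresholded != 0), 0)
  # constant nonzero maps are degenerate
  consts <- lapply(1:5, function(i) array(2, dims))
  expect_error(one_sample_t_fdr(consts, mask), "zero variance")
  # a strong planted block survives; small blocks are extent-filtered
  set.seed(15)
  maps <- lapply(1:8, function(i) {
    m <- array(rnorm(prod(dims), sd = 0.1), dims)
    m[2:6, 2:6, 2:5] <- m[2:6, 2:6, 2:5] + 1   # 100-voxel block
    m[9, 9, 7] <- m[9, 9, 7] + 1               # single voxel
    m
  })
  res <- one_sample_t_fdr(maps, mask, q = 0.05, min_cluster = 30)
  surv <- res$thresholded != 0
  expect_true(all(surv[2:6, 2:6, 2:5]))
  expect_false(surv[9, 9, 7])                  # extent filter removed it
  expect_gt(min(res$clusters$size), 30)        # strict extent rule
})

test_that("FDR discovery rate is controlled under the global null", {
  set.seed(16)
  n_sim <- 500
  any_disc <- vapply(seq_len(n_sim), function(i) {
    maps <- lapply(1:6, function(j) array(rnorm(150), c(10, 15, 1)))
    res <- one_sample_t_fdr(maps, array(1L, c(10, 15, 1)), q = 0.05,
                            min_cluster = 0)
    sum(res$thresholded != 0) > 0
  }, logical(1))
  mc_err <- sqrt(0.05 * 0.95 / n_sim)
  expect_lte(mean(any_disc), 0.05 + 2 * mc_err)
})

test_that("group GLM matches lm() per voxel and calibrates type I error", {
  dims <- c(6, 5, 4)
  mask <- array(1L, dims)
  set.seed(17)
  n <- 20
  design <- data.frame(group = rep(c(1, 0), each = 10),
                       age = rnorm(n, 60, 8), sex = rep(0:1, 10))
  maps <- lapply(1:n, function(i) array(rnorm(prod(dims)), dims))
  res <- two_sample_glm(maps, design, mask)
  expect_equal(res$df, n - 4)
  # independent oracle: base lm at a handful of voxels
  for (v in c(1, 37, 100)) {
    y <- vapply(maps, function(m) m[v], numeric(1))
    fit <- summary(lm(y ~ group + age + sex, data = design))
    expect_equal(res$stat[v], fit$coefficients["group", "t value"],
                 tolerance = 1e-10)
    expect_equal(res$p[v], fit$coefficients["group", "Pr(>|t|)"],
                 tolerance = 1e-10)
  }
  # planted shift concentrates positive t in the region
  shift <- maps
  block <- array(FALSE, dims); block[1:3, 1:3, 1:2] <- TRUE
  for (i in which(design$group == 1))
    shift[[i]][block] <- shift[[i]][block] + 1.5
  res2 <- two_sample_glm(shift, design, mask)
  expect_gt(mean(res2$stat[block]), 2)
  expect_lt(mean(abs(res2$stat[!block])), 1.5)
  # constant covariate is rank deficient
  bad <- design; bad$age <- 60
  expect_error(two_sample_glm(maps, bad, mask), "rank-deficient")
  # type-I calibration at voxel p < 0.01 under label exchange
  set.seed(18)
  rate <- mean(vapply(1:40, function(i) {
    m2 <- lapply(1:n, function(j) array(rnorm(prod(dims)), dims))
    mean(two_sample_glm(m2, design, mask)$p[mask > 0] < 0.01)
  }, numeric(1)))
  expect_gt(rate, 0.005); expect_lt(rate, 0.015)
})

test_that("Monte-Carlo cluster threshold matches an independent oracle", {
  mask <- array(1L, c(10, 10, 10))
  mc <- alphasim_threshold(mask, voxel_p = 0.01, fwhm_mm = 0,
                           n_iter = 1000, rng_seed = 5)
  # second implementation: igraph components over a distance graph
  skip_if_not_installed("igraph")
  set.seed(999)
  thr <- qnorm(1 - 0.01 / 2)
  maxs <- replicate(1000, {
    z <- array(rnorm(1000), c(10, 10, 10))
    sup <- which(abs(z) > thr)
    if (!length(sup)) return(0)
    co <- arrayInd(sup, c(10, 10, 10))
    adj <- as.matrix(dist(co)) < 1.8 & as.matrix(dist(co)) > 0
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    max(igraph::components(g)$csize)
  })
  k_oracle <- 1
  while (mean(maxs >= k_oracle) > 0.05) k_oracle <- k_oracle + 1
  expect_lte(abs(mc$k_min - k_oracle), 1)
  # alpha = 1 accepts single voxels
  expect_equal(alphasim_threshold(mask, n_iter = 100, alpha = 1,
                                  rng_seed = 1)$k_min, 1)
  # reproducible given the seed
  mc2 <- alphasim_threshold(mask, voxel_p = 0.01, fwhm_mm = 0,
                            n_iter = 1000, rng_seed = 5)
  expect_identical(mc$max_sizes, mc2$max_sizes)
  # smoothing enlarges null clusters: k* is non-decreasing in fwhm
  mc_sm <- alphasim_threshold(mask, voxel_p = 0.01, fwhm_mm = 6,
                              voxel_mm = 3, n_iter = 300, rng_seed = 7)
  expect_gte(mc_sm$k_min, alphasim_threshold(mask, voxel_p = 0.01,
                                             fwhm_mm = 0, n_iter = 300,
                                             rng_seed = 7)$k_min)
})

test_that("cluster-extent thresholding keeps sizes consistent", {
  dims <- c(12, 12, 6)
  mask <- array(1L, dims)
  set.seed(19)
  maps <- lapply(1:14, function(i) {
    m <- array(rnorm(prod(dims), sd = 0.3), dims)
    m[2:4, 2:4, 2:3] <- m[2:4, 2:4, 2:3] + (i <= 7) * 1.2  # group block
    m
  })
  design <- data.frame(group = rep(c(1, 0), each = 7),
                       age = rnorm(14, 60), sex = rep(0:1, 7))
  glm <- two_sample_glm(maps, design, mask, voxel_p = 0.01)
  st <- apply_cluster_threshold(glm, k_min = 3)
  expect_equal(st$correction, "MC-cluster")
  expect_equal(sum(st$thresholded != 0), sum(st$clusters$size))
  # an 18-voxel cluster dies under a larger extent threshold
  st2 <- apply_cluster_threshold(glm, k_min = 1000)
  expect_equal(nrow(st2$clusters), 0)
  expect_equal(sum(st2$thresholded != 0), 0)
})

test_that("ROI-pair connectivity and ROI-wise group tests are consistent", {
  sub <- tiny_subject(rng_seed = 20)
  roi <- sub$truth$region_masks$sma_proper
  # identical ROIs give the capped z
  expect_equal(roi_pair_fc(sub$img, roi, roi), atanh(1 - 1e-7))
  expect_error(roi_pair_fc(sub$img, roi, roi * 0L), "empty")
  # single-voxel ROIs agree with the seed FC map
  one_a <- array(0L, dim(roi)); one_a[which(roi > 0)[1]] <- 1L
  one_b <- array(0L, dim(roi))
  one_b[which(sub$truth$region_masks$target_motor > 0)[1]] <- 1L
  zmap <- seed_fc_map(sub$img, one_a, sub$truth$masks$brain)
  expect_equal(roi_pair_fc(sub$img, one_a, one_b),
               zmap[which(one_b > 0)], tolerance = 1e-12)
  # identical values in both groups: t = 0
  design <- data.frame(group = rep(c(1, 0), each = 5),
                       age = rnorm(10, 60), sex = rep(0:1, 5))
  expect_equal(roiwise_group_test(rep(0.4, 10), design)$t, 0)
  # equivalence with the voxel-wise GLM at a single voxel
  set.seed(21)
  vals <- rnorm(10)
  maps <- lapply(vals, function(v) array(v, c(1, 1, 1)))
  glm <- two_sample_glm(maps, design, array(1L, c(1, 1, 1)))
  rt <- roiwise_group_test(vals, design)
  expect_equal(rt$t, glm$stat[1], tolerance = 1e-10)
  expect_equal(rt$p, glm$p[1], tolerance = 1e-10)
})

test_that("planted lesion-side effects keep a consistent direction", {
  # the planted coupling increase shows the same sign in left- and
  # right-lesion patient subgroups against controls (unflipped analysis)
  spec <- tiny_spec(n_patients = 8, n_controls = 8, n_volumes = 100,
                    rng_seed = 77,
                    group_effects = list(list(
                      pair = c("sma_proper", "target_motor"), delta = 0.5)))
  co <- simulate_cohort(spec)
  z <- vapply(seq_len(nrow(co$meta)), function(i)
    roi_pair_fc(co$subjects[[i]]$img, co$truth$region_masks$sma_proper,
                co$truth$region_masks$target_motor), numeric(1))
  design <- data.frame(group = as.integer(co$meta$group == "patient"),
                       age = co$meta$age,
                       sex = as.integer(co$meta$sex == "M"))
  ts <- vapply(c("left", "right"), function(side) {
    sel <- co$meta$group == "control" | co$meta$lesion_side == side
    roiwise_group_test(z[sel], design[sel, ])$t
  }, numeric(1))
  expect_true(all(ts > 0))
})

test_that("smoothness estimation tracks the applied kernel", {
  mask <- array(1L, c(16, 16, 12))
  set.seed(22)
  # white maps: near-zero estimated smoothness
  white <- lapply(1:6, function(i) array(rnorm(prod(dim(mask))), dim(mask)))
  expect_lt(estimate_fwhm(white, mask, voxel_mm = 3), 2)
  # smoothed maps: estimate within 30% of the applied 8-mm kernel
  sm <- lapply(white, function(m) smooth_gaussian(m, 8, 3))
  est <- estimate_fwhm(sm, mask, voxel_mm = 3)
  expect_gt(est, 8 * 0.7); expect_lt(est, 8 * 1.3)
})
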
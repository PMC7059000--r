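# Seed-based group functional connectivity: per-subject seed FC z-maps,
# one-sample t maps with FDR + extent filtering, two-sample GLM contrasts
# with age/sex covariates, Monte-Carlo cluster-extent (AlphaSim-style)
# correction, ROI-wise validation tests and clinical partial correlation.

#' Seed-based functional connectivity z-map
#'
#' Pearson correlation between the mean time series of an ROI and every
#' voxel of the brain mask, Fisher r-to-z transformed.
#'
#' @param img a preprocessed [bold_image].
#' @param roi_mask 3D ROI mask (nonempty, non-constant mean series).
#' @param brain_mask 3D mask over which the map is computed.
#' @return 3D array of z values (0 outside the brain mask).
#' @export
seed_fc_map <- function(img, roi_mask, brain_mask) {
  if (sum(roi_mask > 0) == 0) stop("empty ROI mask")
  roi_ts <- rowMeans(img_matrix(img, roi_mask))
  if (stats::sd(roi_ts) == 0) stop("constant ROI mean time series")
  Y <- img_matrix(img, brain_mask)
  sds <- apply(Y, 2, stats::sd)
  z <- numeric(ncol(Y))
  ok <- sds > 0
  z[ok] <- atanh(clip_r(as.vector(stats::cor(roi_ts, Y[, ok, drop = FALSE]))))
  unmask(z, brain_mask)
}

# Stack a list of 3D z-maps into a voxel x subject matrix on a mask.
stack_maps <- function(zmaps, mask) {
  idx <- which(mask > 0)
  matrix(vapply(zmaps, function(m) m[idx], numeric(length(idx))),
         nrow = length(idx))
}

new_stat_map <- function(stat, p, df, mask, correction, threshold = NULL,
                         min_cluster = NULL, connectivity = NULL,
                         excluded = integer(0)) {
  structure(list(stat = stat, p = p, df = df, mask = mask,
                 correction = correction, threshold = threshold,
                 min_cluster = min_cluster, connectivity = connectivity,
                 excluded_voxels = excluded,
                 thresholded = NULL, clusters = NULL),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("<stat_map> df = %d, correction: %s\n", x$df, x$correction))
  if (!is.null(x$clusters)) {
    cat(sprintf("  %d surviving cluster(s)\n", nrow(x$clusters)))
    if (nrow(x$clusters)) print(x$clusters)
  }
  invisible(x)
}

#' One-sample t map with FDR and cluster-extent filtering
#'
#' Voxel-wise one-sample t-test of subject z-maps against zero, two-sided,
#' with Benjamini-Hochberg FDR over in-mask voxels at rate `q`.  Surviving
#' voxels are grouped into connected components and only components larger
#' than `min_cluster` voxels are retained (strict inequality).
#'
#' @param zmaps list of 3D z-maps (one per subject).
#' @param mask 3D analysis mask.
#' @param q FDR rate (default 0.05).
#' @param min_cluster extent filter: clusters must exceed this size
#'   (default 30).
#' @param connectivity cluster connectivity (6, 18 or 26; default 18).
#' @return a `stat_map` with `thresholded` t image and a cluster table.
#' @export
one_sample_t_fdr <- function(zmaps, mask, q = 0.05, min_cluster = 30,
                             connectivity = 18) {
  n <- length(zmaps)
  if (n < 3) stop("need at least 3 subject maps")
  Z <- stack_maps(zmaps, mask)
  mu <- rowMeans(Z)
  s <- apply(Z, 1, stats::sd)
  zero_var <- which(s == 0)
  degenerate <- which(s == 0 & mu != 0)
  if (length(degenerate))
    stop("zero variance with nonzero mean (degenerate constant maps) at ",
         length(degenerate), " voxel(s)")
  tval <- rep(NA_real_, length(mu))
  ok <- s > 0
  tval[ok] <- mu[ok] / (s[ok] / sqrt(n))
  df <- n - 1
  p <- 2 * stats::pt(-abs(tval), df = df)
  padj <- rep(NA_real_, length(p))
  padj[ok] <- stats::p.adjust(p[ok], method = "BH")
  sig <- !is.na(padj) & padj < q
  sig_img <- unmask(as.integer(sig), mask)
  lab <- label_clusters(sig_img, connectivity)
  keep <- which(cluster_sizes(lab) > min_cluster)
  surviving <- array(lab %in% keep, dim(mask))
  out <- new_stat_map(unmask(tval, mask), unmask(p, mask), df, mask,
                      correction = "FDR", threshold = q,
                      min_cluster = min_cluster, connectivity = connectivity,
                      excluded = zero_var)
  timg <- unmask(tval, mask)
  timg[is.na(timg)] <- 0
  out$thresholded <- timg * surviving
  out$clusters <- cluster_table(timg, surviving, connectivity, mask)
  out
}

# Tabulate surviving clusters: id, size, peak statistic, peak location.
cluster_table <- function(stat_img, surviving, connectivity, mask,
                          affine = NULL) {
  lab <- label_clusters(array(surviving > 0, dim(mask)), connectivity)
  ids <- setdiff(unique(as.vector(lab)), 0L)
  if (!length(ids))
    return(data.frame(cluster = integer(0), size = integer(0),
                      peak_stat = numeric(0), peak_x = numeric(0),
                      peak_y = numeric(0), peak_z = numeric(0)))
  rows <- lapply(ids, function(id) {
    vox <- which(lab == id)
    pk <- vox[which.max(abs(stat_img[vox]))]
    ijk <- arrayInd(pk, dim(mask)) - 1L
    xyz <- if (is.null(affine)) ijk else voxel_to_world(ijk, affine)
    data.frame(cluster = id, size = length(vox),
               peak_stat = stat_img[pk],
               peak_x = xyz[1], peak_y = xyz[2], peak_z = xyz[3])
  })
  out <- do.call(rbind, rows)
  out[order(-out$size), , drop = FALSE]
}

#' Two-sample group contrast GLM on z-maps
#'
#' Per voxel, ordinary least squares of the subject z values on
#' `[1, group, age, sex]`; returns the t statistic for the group
#' coefficient (patient = 1, control = 0, so positive t means
#' patient > control) with `n - 4` degrees of freedom and two-sided p.
#'
#' @param zmaps list of 3D z-maps, one per subject.
#' @param design data.frame with columns `group` (0/1), `age`, `sex` (0/1).
#' @param mask 3D analysis mask.
#' @param voxel_p voxel-wise threshold recorded for later cluster
#'   correction (default 0.01).
#' @return a `stat_map` (uncorrected; see [alphasim_threshold()] and
#'   [apply_cluster_threshold()]), with residual maps attached for
#'   smoothness estimation.
#' @export
two_sample_glm <- function(zmaps, design, mask, voxel_p = 0.01) {
  n <- length(zmaps)
  if (nrow(design) != n) stop("design rows must match number of maps")
  if (sum(design$group == 1) < 2 || sum(design$group == 0) < 2)
    stop("each group needs at least 2 subjects")
  X <- cbind(1, design$group, design$age, design$sex)
  colnames(X) <- c("intercept", "group", "age", "sex")
  qx <- qr(X)
  if (qx$rank < ncol(X))
    stop("rank-deficient design (constant covariate?)")
  Z <- stack_maps(zmaps, mask)          # voxel x subject
  Yt <- t(Z)                            # subject x voxel
  coefs <- qr.coef(qx, Yt)
  resid <- qr.resid(qx, Yt)
  df <- n - ncol(X)
  sigma2 <- colSums(resid^2) / df
  XtXinv <- solve(crossprod(X))
  se <- sqrt(sigma2 * XtXinv["group", "group"])
  tval <- coefs["group", ] / se
  tval[se == 0] <- NA_real_
  p <- 2 * stats::pt(-abs(tval), df = df)
  out <- new_stat_map(unmask(tval, mask), unmask(p, mask), df, mask,
                      correction = "none", threshold = voxel_p)
  out$residuals <- resid
  out
}

#' Estimate map smoothness from residual maps
#'
#' Gaussian-equivalent full width at half maximum estimated from the mean
#' lag-1 spatial autocorrelation of residual maps along each axis
#' (`sigma^2 = -1 / (4 log rho)` voxel units for Gaussian-smoothed white
#' noise), averaged over axes and maps.
#'
#' @param resid matrix (subject x in-mask voxel) of residual maps, or a
#'   list of 3D residual images.
#' @param mask 3D analysis mask.
#' @param voxel_mm voxel size in mm.
#' @return estimated FWHM in mm (0 when no positive autocorrelation).
#' @export
estimate_fwhm <- function(resid, mask, voxel_mm = 3) {
  d <- dim(mask)
  idx <- which(mask > 0)
  if (is.list(resid)) resid <- t(stack_maps(resid, mask))
  coords <- arrayInd(idx, d)
  pos <- integer(prod(d)); pos[idx] <- seq_along(idx)
  rho_axes <- vapply(1:3, function(a) {
    nb <- coords
    nb[, a] <- nb[, a] + 1L
    ok <- nb[, a] <= d[a]
    nb_lin <- nb[ok, 1] + (nb[ok, 2] - 1L) * d[1] +
      (nb[ok, 3] - 1L) * d[1] * d[2]
    pair <- pos[nb_lin]
    src <- which(ok)[pair > 0]
    dst <- pair[pair > 0]
    if (length(src) < 3) return(NA_real_)
    a_vals <- as.vector(resid[, src, drop = FALSE])
    b_vals <- as.vector(resid[, dst, drop = FALSE])
    stats::cor(a_vals, b_vals)
  }, numeric(1))
  rho <- mean(rho_axes, na.rm = TRUE)
  if (!is.finite(rho) || rho <= 0) return(0)
  rho <- min(rho, 0.99)
  sigma_vox <- sqrt(-1 / (4 * log(rho)))
  2 * sqrt(2 * log(2)) * sigma_vox * voxel_mm
}

#' Monte-Carlo cluster-extent threshold (AlphaSim-style)
#'
#' Simulates Gaussian white noise in the mask, smooths it to the target
#' FWHM, standardizes, applies a two-sided voxel threshold at `voxel_p`,
#' and records the maximum suprathreshold cluster size per iteration.
#' Returns the smallest extent `k*` such that the fraction of iterations
#' whose maximum cluster reaches `k*` is at most `alpha`.
#'
#' @param mask 3D analysis mask.
#' @param voxel_p two-sided voxel-wise p threshold (default 0.01).
#' @param fwhm_mm assumed spatial smoothness of the maps (mm; 0 = white).
#' @param voxel_mm voxel size in mm.
#' @param n_iter Monte-Carlo iterations (default 1000, minimum 100).
#' @param alpha corrected cluster-level alpha (default 0.05).
#' @param connectivity cluster connectivity (default 18).
#' @param rng_seed integer seed; results are reproducible given the seed.
#' @return list with `k_min` (minimum surviving extent), `max_sizes`
#'   (per-iteration maxima) and the parameters used.
#' @export
alphasim_threshold <- function(mask, voxel_p = 0.01, fwhm_mm = 0,
                               voxel_mm = 3, n_iter = 1000, alpha = 0.05,
                               connectivity = 18, rng_seed = 1) {
  if (sum(mask > 0) == 0) stop("empty mask")
  if (n_iter < 100) stop("need at least 100 iterations")
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  d <- dim(mask)
  idx <- which(mask > 0)
  thr <- stats::qnorm(1 - voxel_p / 2)
  max_sizes <- with_seed(rng_seed, {
    vapply(seq_len(n_iter), function(it) {
      noise <- array(stats::rnorm(prod(d)), d)
      if (fwhm_mm > 0)
        noise <- smooth_gaussian(noise, fwhm_mm, voxel_mm)
      vals <- noise[idx]
      vals <- (vals - mean(vals)) / stats::sd(vals)
      sup <- array(0L, d)
      sup[idx[abs(vals) > thr]] <- 1L
      if (!any(sup > 0)) return(0L)
      lab <- label_clusters(sup, connectivity)
      max(cluster_sizes(lab))
    }, numeric(1))
  })
  k <- 1L
  while (mean(max_sizes >= k) > alpha) k <- k + 1L
  list(k_min = as.integer(k), max_sizes = as.integer(max_sizes),
       voxel_p = voxel_p, fwhm_mm = fwhm_mm, alpha = alpha,
       connectivity = connectivity, n_iter = n_iter)
}

#' Apply a cluster-extent threshold to a statistic map
#'
#' Keeps connected components of voxels with `p < voxel_p` (recorded in the
#' map) whose size is at least `k_min`, and tabulates each surviving
#' cluster's size, peak statistic and peak coordinate.
#'
#' @param stat a `stat_map` from [two_sample_glm()] (or compatible).
#' @param k_min minimum cluster extent (e.g. from [alphasim_threshold()]).
#' @param connectivity cluster connectivity (default 18).
#' @param affine optional affine for peak world coordinates.
#' @return the `stat_map` with `thresholded` image and `clusters` table.
#' @export
apply_cluster_threshold <- function(stat, k_min, connectivity = 18,
                                    affine = NULL) {
  if (is.null(stat$p)) stop("stat map carries no p-values")
  voxel_p <- stat$threshold
  sup <- array(0L, dim(stat$mask))
  inmask <- which(stat$mask > 0)
  sup[inmask] <- as.integer(!is.na(stat$p[inmask]) &
                              stat$p[inmask] < voxel_p)
  lab <- label_clusters(sup, connectivity)
  keep <- which(cluster_sizes(lab) >= k_min)
  surviving <- array(lab %in% keep, dim(stat$mask))
  simg <- stat$stat
  simg[is.na(simg)] <- 0
  stat$thresholded <- simg * surviving
  stat$correction <- "MC-cluster"
  stat$min_cluster <- k_min
  stat$connectivity <- connectivity
  stat$clusters <- cluster_table(simg, surviving, connectivity,
                                 stat$mask, affine)
  stat
}

#' Functional connectivity between two ROIs
#'
#' Fisher z of the Pearson correlation between the two ROI mean time
#' series.
#'
#' @param img a preprocessed [bold_image].
#' @param roi_a,roi_b 3D ROI masks.
#' @return scalar z value.
#' @export
roi_pair_fc <- function(img, roi_a, roi_b) {
  if (sum(roi_a > 0) == 0 || sum(roi_b > 0) == 0) stop("empty ROI")
  a <- rowMeans(img_matrix(img, roi_a))
  b <- rowMeans(img_matrix(img, roi_b))
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("constant ROI mean time series")
  atanh(clip_r(stats::cor(a, b)))
}

#' ROI-wise group test with age and sex covariates
#'
#' Scalar general linear model of per-subject connectivity values on
#' `[1, group, age, sex]`, reported uncorrected; used for the unflipped
#' lesion-side subgroup validation.
#'
#' @param values per-subject connectivity z values.
#' @param design data.frame with `group`, `age`, `sex` for those subjects.
#' @return list with `t`, `p`, `df` for the group coefficient.
#' @export
roiwise_group_test <- function(values, design) {
  n <- length(values)
  if (nrow(design) != n) stop("design rows must match values")
  if (sum(design$group == 1) < 2 || sum(design$group == 0) < 2)
    stop("each group needs at least 2 subjects")
  X <- cbind(1, design$group, design$age, design$sex)
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("rank-deficient design")
  beta <- qr.coef(qx, values)
  resid <- qr.resid(qx, values)
  df <- n - ncol(X)
  sigma2 <- sum(resid^2) / df
  XtXinv <- solve(crossprod(X))
  se <- sqrt(sigma2 * XtXinv[2, 2])
  # a perfectly fit (constant) response has se 0 up to round-off: t = 0
  tol <- 1e-10 * (stats::sd(values) + abs(mean(values)) + 1)
  tval <- if (se <= tol) 0 else beta[2] / se
  list(t = as.numeric(tval), p = 2 * stats::pt(-abs(tval), df = df),
       df = df)
}
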
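# Resting-state preprocessing chain for already-registered volumetric data:
# volume discard, motion screening, framewise displacement, Gaussian
# smoothing, nuisance regression, band-pass filtering and left-right flips.
#
# The fixed stage order applied by preprocess_subject() is:
#   discard -> motion screen -> flip -> smooth -> nuisance regression ->
#   band-pass.

#' Discard initial volumes
#'
#' Drops the first `n_discard` volumes of a BOLD series (signal-equilibrium
#' volumes), trimming the motion trace identically when supplied.
#'
#' @param img a [bold_image].
#' @param n_discard number of leading volumes to drop.
#' @param motion optional motion-parameter matrix (one row per volume).
#' @return The trimmed `bold_image`, or `list(img, motion)` when a motion
#'   trace is supplied.
#' @export
discard_initial_volumes <- function(img, n_discard = 10, motion = NULL) {
  nt <- dim(img$data)[4]
  if (n_discard < 0 || n_discard >= nt)
    stop(sprintf("n_discard (%d) must be in [0, %d)", n_discard, nt))
  keep <- (n_discard + 1):nt
  img$data <- img$data[, , , keep, drop = FALSE]
  if (is.null(motion)) return(img)
  if (nrow(motion) != nt)
    stop("motion trace rows must match the original volume count")
  list(img = img, motion = motion[keep, , drop = FALSE])
}

#' Screen a motion trace against displacement/rotation limits
#'
#' A subject fails when any translation magnitude exceeds `max_disp_mm`
#' or any rotation magnitude exceeds `max_rot_deg` (strict inequalities:
#' maxima exactly at the limit pass).
#'
#' @param motion matrix with 6 columns: 3 translations (mm) then
#'   3 rotations (degrees).
#' @param max_disp_mm translation limit in mm.
#' @param max_rot_deg rotation limit in degrees.
#' @return list with `pass`, `max_translation_mm`, `max_rotation_deg`.
#' @export
motion_screen <- function(motion, max_disp_mm = 2.0, max_rot_deg = 2.0) {
  motion <- as.matrix(motion)
  if (nrow(motion) == 0) stop("empty motion trace")
  if (ncol(motion) != 6) stop("motion trace must have 6 columns")
  if (any(!is.finite(motion))) stop("non-finite motion parameters")
  max_t <- max(abs(motion[, 1:3]))
  max_r <- max(abs(motion[, 4:6]))
  list(pass = !(max_t > max_disp_mm || max_r > max_rot_deg),
       max_translation_mm = max_t, max_rotation_deg = max_r)
}

#' Framewise displacement
#'
#' Power-style FD: per volume, the sum of absolute backward differences of
#' the three translations (mm) plus the absolute rotation differences
#' converted from degrees to radians and projected on a 50-mm sphere.
#' The first frame has FD 0.
#'
#' @param motion 6-column motion matrix (translations mm, rotations deg).
#' @param sphere_radius_mm projection radius for rotations.
#' @return list with per-volume `fd` (mm) and `mean_fd`.
#' @export
compute_fd <- function(motion, sphere_radius_mm = 50) {
  motion <- as.matrix(motion)
  if (nrow(motion) < 2) stop("need at least 2 volumes for FD")
  if (any(!is.finite(motion))) stop("non-finite motion parameters")
  dt <- abs(diff(motion[, 1:3, drop = FALSE]))
  dr <- abs(diff(motion[, 4:6, drop = FALSE])) * pi / 180
  fd <- c(0, rowSums(dt) + sphere_radius_mm * rowSums(dr))
  list(fd = fd, mean_fd = mean(fd))
}

#' Regress nuisance signals out of a BOLD series
#'
#' Per-voxel ordinary least squares of the time series on an intercept plus
#' the nuisance columns; returns the residual image.  Residuals are
#' orthogonal to every regressor.
#'
#' @param img a [bold_image].
#' @param nuisance numeric matrix, one row per volume (e.g. 6 motion
#'   parameters, linear drift, ventricular/white-matter/whole-brain means).
#' @param brain_mask optional 3D mask restricting the regression; voxels
#'   outside keep their original values.
#' @return The residual `bold_image`.
#' @export
regress_nuisance <- function(img, nuisance, brain_mask = NULL) {
  nuisance <- as.matrix(nuisance)
  nt <- dim(img$data)[4]
  if (nrow(nuisance) != nt)
    stop("nuisance rows must match the volume count")
  X <- cbind(intercept = 1, nuisance)
  cn <- colnames(X)
  cn[cn == "" | is.na(cn)] <- paste0("nuisance", which(cn == "" | is.na(cn)))
  colnames(X) <- cn
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- setdiff(cn, cn[qx$pivot[seq_len(qx$rank)]])
    stop("rank-deficient nuisance design; collinear columns: ",
         paste(dropped, collapse = ", "))
  }
  d <- dim(img$data)
  Y <- matrix(img$data, prod(d[1:3]), nt)
  idx <- if (is.null(brain_mask)) seq_len(nrow(Y)) else which(brain_mask > 0)
  res <- qr.resid(qx, t(Y[idx, , drop = FALSE]))
  Y[idx, ] <- t(res)
  img$data <- array(Y, d)
  img
}

# Assemble the standard nuisance set: 6 motion parameters, a linear drift
# column, and mean signals within the ventricular, white-matter and
# whole-brain masks.
build_nuisance <- function(img, motion, vent_mask = NULL, wm_mask = NULL,
                           brain_mask = NULL) {
  nt <- dim(img$data)[4]
  motion <- as.matrix(motion)
  if (nrow(motion) != nt) stop("motion rows must match volume count")
  cols <- list(motion = motion, drift = seq_len(nt) / nt)
  mean_series <- function(mask) rowMeans(img_matrix(img, mask))
  if (!is.null(vent_mask)) cols$ventricle <- mean_series(vent_mask)
  if (!is.null(wm_mask)) cols$white_matter <- mean_series(wm_mask)
  if (!is.null(brain_mask)) cols$global <- mean_series(brain_mask)
  X <- do.call(cbind, cols)
  colnames(X) <- c(paste0("motion", 1:6), "drift",
                   names(cols)[-(1:2)])
  X
}

#' Ideal band-pass filter
#'
#' Frequency-domain ideal filter applied per voxel: discrete Fourier
#' coefficients with frequency outside `[low, high]` Hz are zeroed (both
#' tails, including DC, so the mean is removed) and the series is inverse
#' transformed.
#'
#' @param img a [bold_image].
#' @param low,high passband edges in Hz (defaults 0.01-0.08).
#' @param brain_mask optional mask restricting the filtering.
#' @return The filtered `bold_image`.
#' @export
bandpass <- function(img, low = 0.01, high = 0.08, brain_mask = NULL) {
  tr <- img$tr_s
  nyq <- 1 / (2 * tr)
  if (low < 0 || low >= high) stop("need 0 <= low < high")
  if (high >= nyq) stop(sprintf("high (%g Hz) must be below Nyquist (%g Hz)",
                                high, nyq))
  d <- dim(img$data)
  nt <- d[4]
  freqs <- seq(0, nt - 1) / (nt * tr)
  freqs <- pmin(freqs, 1 / tr - freqs)        # fold to [0, Nyquist]
  keep <- freqs >= low & freqs <= high
  Y <- matrix(img$data, prod(d[1:3]), nt)
  idx <- if (is.null(brain_mask)) seq_len(nrow(Y)) else which(brain_mask > 0)
  co <- stats::mvfft(t(Y[idx, , drop = FALSE]))
  co[!keep, ] <- 0
  Y[idx, ] <- t(Re(stats::mvfft(co, inverse = TRUE)) / nt)
  img$data <- array(Y, d)
  img
}

#' Gaussian spatial smoothing
#'
#' Separable 3D Gaussian convolution with a kernel of the given full width
#' at half maximum (`sigma = fwhm / 2.3548` per axis, converted to voxel
#' units via the affine).  Zero padding at the edges; the image sum is
#' conserved for interior signal.  Works on 3D arrays and 4D
#' [bold_image]s (volume by volume).
#'
#' @param img a [bold_image] or 3D array.
#' @param fwhm_mm kernel full width at half maximum in mm (0 = identity).
#' @param voxel_mm voxel sizes for plain arrays (taken from the affine for
#'   `bold_image`s).
#' @return The smoothed image, same type as the input.
#' @export
smooth_gaussian <- function(img, fwhm_mm = 8, voxel_mm = NULL) {
  if (fwhm_mm < 0) stop("fwhm must be non-negative")
  if (fwhm_mm == 0) return(img)
  is_bold <- inherits(img, "bold_image")
  if (is_bold) {
    vs <- voxel_sizes(img$affine)
    arr <- img$data
  } else {
    vs <- rep_len(if (is.null(voxel_mm)) 1 else voxel_mm, 3)
    arr <- unclass(img)
  }
  d <- dim(arr)
  sig <- (fwhm_mm / (2 * sqrt(2 * log(2)))) / vs[1:3]
  Ks <- lapply(1:3, function(a) {
    n <- d[a]
    if (sig[a] <= 0) return(diag(n))
    idx <- seq_len(n)
    K <- exp(-outer(idx, idx, "-")^2 / (2 * sig[a]^2))
    K / sum(exp(-(seq(-4 * ceiling(sig[a] + 1), 4 * ceiling(sig[a] + 1)))^2 /
                  (2 * sig[a]^2)))
  })
  nt <- if (length(d) == 4) d[4] else 1L
  flat <- array(arr, c(d[1], d[2], d[3], nt))
  # axis 1
  m <- matrix(flat, d[1], d[2] * d[3] * nt)
  flat <- array(Ks[[1]] %*% m, c(d[1], d[2], d[3], nt))
  # axis 2
  p <- aperm(flat, c(2, 1, 3, 4))
  m <- matrix(p, d[2], d[1] * d[3] * nt)
  p <- array(Ks[[2]] %*% m, c(d[2], d[1], d[3], nt))
  flat <- aperm(p, c(2, 1, 3, 4))
  # axis 3
  p <- aperm(flat, c(3, 1, 2, 4))
  m <- matrix(p, d[3], d[1] * d[2] * nt)
  p <- array(Ks[[3]] %*% m, c(d[3], d[1], d[2], nt))
  flat <- aperm(p, c(2, 3, 1, 4))
  out <- array(flat, d)
  if (is_bold) {
    img$data <- out
    img
  } else {
    attrs <- attributes(img)
    out <- structure(out, affine = attrs$affine)
    out
  }
}

#' Flip an image left-right for left-lesion subjects
#'
#' Reverses the x-axis voxel order when `lesion_side` is `"left"`, so that
#' the lesioned hemisphere lies on a common side across patients; identity
#' for `"right"`, `"none"` or `NA` (controls).  The flip is an involution.
#'
#' @param img a [bold_image] or 3D array.
#' @param lesion_side `"left"`, `"right"`, `"none"` or `NA`.
#' @return The (possibly flipped) image.
#' @export
flip_lr <- function(img, lesion_side) {
  if (length(lesion_side) != 1) stop("lesion_side must be a single value")
  if (is.na(lesion_side)) lesion_side <- "none"
  side <- tolower(as.character(lesion_side))
  if (!side %in% c("left", "right", "none"))
    stop("unknown lesion_side: ", lesion_side)
  if (side != "left") return(img)
  if (inherits(img, "bold_image")) {
    nx <- dim(img$data)[1]
    img$data <- img$data[nx:1, , , , drop = FALSE]
    img
  } else {
    nx <- dim(img)[1]
    d <- length(dim(img))
    if (d == 3) {
      out <- img[nx:1, , , drop = FALSE]
    } else stop("flip_lr expects a 3D array or bold_image")
    attributes(out)$affine <- attr(img, "affine")
    out
  }
}

#' Run the full preprocessing chain on one subject
#'
#' Applies, in order: initial volume discard, motion screening, left-right
#' flip (left-lesion patients), Gaussian smoothing, nuisance regression
#' (motion, drift, ventricular / white-matter / global means), and ideal
#' band-pass filtering.
#'
#' @param img a [bold_image].
#' @param motion 6-column motion trace (one row per acquired volume).
#' @param masks list with `brain`, and optionally `ventricle`, `white_matter`
#'   (all 3D masks on the image grid).
#' @param lesion_side `"left"`, `"right"` or `"none"`.
#' @param n_discard initial volumes to drop (default 10).
#' @param fwhm_mm smoothing kernel FWHM in mm (default 8; 0 disables).
#' @param band passband in Hz (default `c(0.01, 0.08)`).
#' @param max_disp_mm,max_rot_deg motion screening limits.
#' @return list with the preprocessed `img` and a `qc` list (motion maxima,
#'   mean FD, screening pass flag, volumes retained).
#' @export
preprocess_subject <- function(img, motion, masks, lesion_side = "none",
                               n_discard = 10, fwhm_mm = 8,
                               band = c(0.01, 0.08),
                               max_disp_mm = 2.0, max_rot_deg = 2.0) {
  trimmed <- discard_initial_volumes(img, n_discard, motion)
  img <- trimmed$img; motion <- trimmed$motion
  screen <- motion_screen(motion, max_disp_mm, max_rot_deg)
  fd <- compute_fd(motion)
  img <- flip_lr(img, lesion_side)
  if (fwhm_mm > 0) img <- smooth_gaussian(img, fwhm_mm)
  nuis <- build_nuisance(img, motion,
                         vent_mask = masks$ventricle,
                         wm_mask = masks$white_matter,
                         brain_mask = masks$brain)
  img <- regress_nuisance(img, nuis, masks$brain)
  img <- bandpass(img, band[1], band[2], masks$brain)
  list(img = img,
       qc = list(pass = screen$pass,
                 max_translation_mm = screen$max_translation_mm,
                 max_rotation_deg = screen$max_rotation_deg,
                 mean_fd = fd$mean_fd,
                 volumes_retained = dim(img$data)[4]))
}
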
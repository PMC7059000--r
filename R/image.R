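# The `bold_image` container: a 4D BOLD time series (x, y, z, t) with its
# voxel-to-world affine and repetition time, plus NIfTI-1 input/output.

#' Construct a 4D BOLD time-series image
#'
#' @param data numeric 4D array (x, y, z, t).
#' @param tr_s repetition time in seconds.
#' @param voxel_mm voxel edge length in mm (ignored when `affine` is given).
#' @param affine optional 4x4 voxel-to-world affine; defaults to a diagonal
#'   affine built from `voxel_mm`.
#' @return An object of class `bold_image`.
#' @export
bold_image <- function(data, tr_s = 2, voxel_mm = 3, affine = NULL) {
  if (length(dim(data)) != 4L)
    stop("`data` must be a 4D array (x, y, z, t)")
  if (!is.numeric(tr_s) || tr_s <= 0) stop("`tr_s` must be positive")
  if (is.null(affine)) affine <- grid_affine(voxel_mm)
  structure(list(data = data, tr_s = tr_s, affine = affine),
            class = "bold_image")
}

#' @export
dim.bold_image <- function(x) dim(x$data)

#' @export
print.bold_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold_image> %d x %d x %d voxels, %d volumes, TR = %g s\n",
              d[1], d[2], d[3], d[4], x$tr_s))
  cat(sprintf("  voxel size: %s mm\n",
              paste(signif(diag(x$affine)[1:3], 4), collapse = " x ")))
  invisible(x)
}

# Voxel edge lengths implied by the affine (mm per axis).
voxel_sizes <- function(affine) {
  sqrt(colSums(affine[1:3, 1:3]^2))
}

# Time x voxel matrix view of the image, optionally restricted to a mask.
img_matrix <- function(img, mask = NULL) {
  d <- dim(img$data)
  m <- matrix(img$data, prod(d[1:3]), d[4])
  if (!is.null(mask)) m <- m[which(mask > 0), , drop = FALSE]
  t(m)
}

# Rebuild a 3D array from per-voxel values on a mask (fill elsewhere).
unmask <- function(values, mask, fill = 0) {
  out <- array(fill, dim(mask))
  out[which(mask > 0)] <- values
  out
}

#' Read a NIfTI-1 image
#'
#' Reads a 4D BOLD series as a [bold_image], or a 3D volume (e.g. a mask)
#' as a plain array with an `affine` attribute.
#'
#' @param path NIfTI file path.
#' @param expect `"4d"`, `"3d"` or `"any"`; a mismatch raises an error.
#' @return A `bold_image` or a 3D array.
#' @export
read_image <- function(path, expect = c("any", "4d", "3d")) {
  expect <- match.arg(expect)
  if (!file.exists(path)) stop("file not found: ", path)
  nii <- RNifti::readNifti(path)
  nd <- length(dim(nii))
  if (expect == "4d" && nd != 4L)
    stop(sprintf("expected a 4D image, got %dD: %s", nd, path))
  if (expect == "3d" && nd != 3L)
    stop(sprintf("expected a 3D image, got %dD: %s", nd, path))
  aff <- structure(RNifti::xform(nii), class = "matrix")
  aff <- matrix(as.numeric(aff), 4, 4)
  if (nd == 4L) {
    tr <- RNifti::pixdim(nii)[4]
    if (!is.finite(tr) || tr <= 0) tr <- 1
    bold_image(array(as.numeric(nii), dim(nii)), tr_s = tr, affine = aff)
  } else {
    structure(array(as.numeric(nii), dim(nii)), affine = aff)
  }
}

#' Write an image to NIfTI-1
#'
#' @param img a [bold_image] or a 3D array (optionally with an `affine`
#'   attribute).
#' @param path output file path (`.nii` or `.nii.gz`).
#' @param affine affine override for plain arrays.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path, affine = NULL) {
  if (inherits(img, "bold_image")) {
    arr <- img$data
    aff <- img$affine
    pd <- c(voxel_sizes(aff), img$tr_s)
  } else {
    arr <- unclass(img)
    aff <- if (!is.null(affine)) affine else attr(img, "affine")
    if (is.null(aff)) aff <- grid_affine(1)
    pd <- voxel_sizes(aff)
  }
  nii <- RNifti::asNifti(arr)
  RNifti::pixdim(nii) <- pd          # before sform: sets grid + TR spacing
  nii <- RNifti::`sform<-`(nii, structure(aff, code = 2L))
  RNifti::writeNifti(nii, path)
  invisible(path)
}
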
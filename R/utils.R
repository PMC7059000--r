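# Internal helpers shared across the package: seeded RNG scoping, voxel/world
# coordinate conversion, and connected-component labelling on voxel grids.

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the random number generator seeded at `seed`, then
#' restores the caller's RNG state, so that seeded internals never perturb
#' the global random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a deterministic sub-seed from a master seed and stream indices.
# Keeps results inside the 32-bit signed range required by set.seed().
derive_seed <- function(seed, ...) {
  idx <- c(...)
  m <- 2147483629                        # prime below 2^31
  s <- as.double(seed) %% m
  for (i in idx) s <- (s * 48271 + as.double(i) + 1) %% m
  as.integer(s)
}

#' Build a diagonal voxel-to-world affine
#'
#' @param voxel_mm voxel edge length(s) in mm (scalar or length 3).
#' @param origin_mm world coordinate of voxel (0,0,0).
#' @return 4x4 affine matrix mapping 0-based voxel indices to mm.
#' @export
grid_affine <- function(voxel_mm = 3, origin_mm = c(0, 0, 0)) {
  v <- rep_len(voxel_mm, 3)
  a <- diag(c(v, 1))
  a[1:3, 4] <- origin_mm
  a
}

#' Convert 0-based voxel indices to world coordinates
#'
#' @param ijk integer matrix (n x 3) of 0-based voxel indices.
#' @param affine 4x4 voxel-to-world affine.
#' @return n x 3 matrix of mm coordinates.
#' @export
voxel_to_world <- function(ijk, affine) {
  ijk <- matrix(as.numeric(ijk), ncol = 3)
  xyz1 <- cbind(ijk, 1) %*% t(affine)
  xyz1[, 1:3, drop = FALSE]
}

# 0-based (i,j,k) coordinates of the TRUE voxels of a 3D mask, in the order
# given by which(); this fixed order defines the voxel order of profile
# matrices and label vectors throughout.
mask_coords <- function(mask) {
  d <- dim(mask)
  lin <- which(mask > 0)
  arr <- arrayInd(lin, d) - 1L
  storage.mode(arr) <- "integer"
  arr
}

# Neighbourhood offsets for a given connectivity scheme (6 faces,
# 18 faces+edges, 26 full cube).
neighbour_offsets <- function(connectivity = 18) {
  if (!connectivity %in% c(6, 18, 26))
    stop("connectivity must be 6, 18 or 26")
  g <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  nz <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
    "6"  = nz == 1,
    "18" = nz >= 1 & nz <= 2,
    "26" = nz >= 1)
  g[keep, , drop = FALSE]
}

#' Label connected components of a binary 3D mask
#'
#' Union-find labelling of the TRUE voxels of `mask` under face (6),
#' face+edge (18, default) or full-cube (26) connectivity.
#'
#' @param mask logical/0-1 3D array.
#' @param connectivity 6, 18 or 26.
#' @return integer 3D array: 0 outside the mask, component id (1..n) inside.
#' @export
label_clusters <- function(mask, connectivity = 18) {
  d <- dim(mask)
  if (length(d) != 3L) stop("mask must be a 3D array")
  lin <- which(mask > 0)
  out <- array(0L, d)
  n <- length(lin)
  if (n == 0L) return(out)
  coords <- arrayInd(lin, d)                      # 1-based
  id_of <- integer(prod(d)); id_of[lin] <- seq_len(n)
  offs <- neighbour_offsets(connectivity)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (o in seq_len(nrow(offs))) {
    nb <- coords + matrix(offs[o, ], n, 3, byrow = TRUE)
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] &
          nb[, 2] >= 1 & nb[, 2] <= d[2] &
          nb[, 3] >= 1 & nb[, 3] <= d[3]
    if (!any(ok)) next
    nb_lin <- nb[ok, 1] + (nb[ok, 2] - 1L) * d[1] +
      (nb[ok, 3] - 1L) * d[1] * d[2]
    nb_id <- id_of[nb_lin]
    src <- which(ok)[nb_id > 0]
    dst <- nb_id[nb_id > 0]
    for (e in seq_along(src)) {
      a <- find(src[e]); b <- find(dst[e])
      if (a != b) parent[b] <- a
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  out[lin] <- match(root, unique(root))
  out
}

# Sizes of labelled components, as a named integer vector (label -> size).
cluster_sizes <- function(labels) {
  tab <- tabulate(labels[labels > 0])
  stats::setNames(tab, seq_along(tab))
}

# Clip correlations strictly inside (-1, 1) before atanh.
clip_r <- function(r, eps = 1e-7) pmin(pmax(r, -1 + eps), 1 - eps)
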
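# Connectivity-based parcellation of a seed mask: whole-brain connectivity
# profiles per seed voxel, profile cross-correlation, spectral clustering
# into K subregions, canonical anterior/posterior label alignment, and
# group-level maximum probability maps with centroid ROIs.

#' Whole-brain connectivity profiles of the seed voxels
#'
#' For every voxel of the seed mask, Pearson correlations with the time
#' series of every other in-brain voxel (brain mask minus seed), converted
#' to Fisher z.  Zero-variance target voxels are excluded and reported;
#' a zero-variance seed voxel is an error.
#'
#' @param img a preprocessed [bold_image].
#' @param seed_mask,brain_mask 3D masks on the image grid; the seed must be
#'   contained in the brain mask.
#' @return list of class `fc_profiles`: `z` (seed x target Fisher-z matrix),
#'   `seed_coords` (0-based voxel indices), `target_index` (linear indices),
#'   `dropped_targets`, and the `affine`.
#' @export
compute_fc_profiles <- function(img, seed_mask, brain_mask) {
  if (sum(seed_mask > 0) == 0 || sum(brain_mask > 0) == 0)
    stop("empty mask")
  if (any(seed_mask > 0 & !(brain_mask > 0)))
    stop("seed mask must be contained in the brain mask")
  nt <- dim(img$data)[4]
  if (nt < 30) stop("need at least 30 time points for profiles")
  seed_idx <- which(seed_mask > 0)
  targ_idx <- setdiff(which(brain_mask > 0), seed_idx)
  if (length(targ_idx) < 2) stop("fewer than 2 target voxels")
  M <- img_matrix(img)
  Ys <- M[, seed_idx, drop = FALSE]
  Yt <- M[, targ_idx, drop = FALSE]
  rm(M)
  vs <- apply(Ys, 2, stats::sd)
  if (any(vs == 0))
    stop("constant seed voxel time series at seed indices: ",
         paste(which(vs == 0), collapse = ", "))
  vt <- apply(Yt, 2, stats::sd)
  dropped <- targ_idx[vt == 0]
  if (length(dropped)) {
    Yt <- Yt[, vt > 0, drop = FALSE]
    targ_idx <- targ_idx[vt > 0]
  }
  z <- atanh(clip_r(stats::cor(Ys, Yt)))
  structure(list(z = z,
                 seed_coords = mask_coords(seed_mask),
                 target_index = targ_idx,
                 dropped_targets = dropped,
                 affine = img$affine),
            class = "fc_profiles")
}

#' Cross-correlation of connectivity profiles
#'
#' Pearson correlation across the target dimension for every pair of seed
#' voxels; the matrix fed to the clustering step.
#'
#' @param profiles an `fc_profiles` object (or a seed x target matrix).
#' @return symmetric seed x seed similarity matrix with unit diagonal.
#' @export
profile_similarity <- function(profiles) {
  z <- if (inherits(profiles, "fc_profiles")) profiles$z else profiles
  if (nrow(z) < 2) stop("need at least 2 seed voxels")
  if (ncol(z) < 2) stop("need at least 2 target voxels")
  rv <- apply(z, 1, stats::sd)
  if (any(rv == 0))
    stop("zero-variance profile row(s): ",
         paste(which(rv == 0), collapse = ", "))
  s <- stats::cor(t(z))
  (s + t(s)) / 2
}

#' Spectral clustering of a profile similarity matrix
#'
#' Builds a non-negative affinity `W = max(sim, 0)` with zero diagonal,
#' embeds the seed voxels with the top-K eigenvectors of the symmetric
#' normalized affinity `D^(-1/2) W D^(-1/2)` (rows unit-normalized), and
#' partitions the embedding with restarted centroid-based assignment
#' (k-means), keeping the best of `n_restarts` restarts.  Deterministic
#' given `rng_seed`.
#'
#' @param sim symmetric similarity matrix.
#' @param K number of clusters (default 2).
#' @param n_restarts k-means restarts.
#' @param rng_seed integer seed for the restarts.
#' @return integer vector of cluster labels in `1..K`.
#' @export
spectral_cluster <- function(sim, K = 2, n_restarts = 20, rng_seed = 1) {
  n <- nrow(sim)
  if (K < 1 || K > n) stop("K must be in [1, n]")
  if (K == 1) return(rep(1L, n))
  W <- pmax(sim, 0)
  diag(W) <- 0
  comp <- label_graph_components(W > 0)
  if (max(comp) > K)
    stop(sprintf("affinity graph has %d connected components (> K = %d)",
                 max(comp), K))
  deg <- rowSums(W)
  if (any(deg == 0))
    stop("isolated seed voxel(s) in the affinity graph: ",
         paste(which(deg == 0), collapse = ", "))
  Dh <- 1 / sqrt(deg)
  L <- W * outer(Dh, Dh)
  ev <- eigen((L + t(L)) / 2, symmetric = TRUE)
  U <- ev$vectors[, seq_len(K), drop = FALSE]
  nrm <- sqrt(rowSums(U^2))
  nrm[nrm == 0] <- 1
  U <- U / nrm
  km <- with_seed(rng_seed,
                  stats::kmeans(U, centers = K, nstart = n_restarts,
                                iter.max = 100))
  as.integer(km$cluster)
}

# Connected components of an undirected adjacency (logical matrix) by
# label propagation; small n only (seed voxels).
label_graph_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0) next
    cur <- cur + 1L
    frontier <- s
    comp[s] <- cur
    while (length(frontier)) {
      nb <- which(colSums(adj[frontier, , drop = FALSE]) > 0)
      nb <- nb[comp[nb] == 0]
      comp[nb] <- cur
      frontier <- nb
    }
  }
  comp
}

#' Canonical anterior/posterior alignment of two cluster labels
#'
#' Relabels a K = 2 parcellation so that the cluster with the larger mean
#' anterior-posterior (world y) coordinate gets label 1 (the anterior
#' subregion) and the other label 2 (the posterior subregion).  Idempotent;
#' required before per-subject label maps can be pooled.
#'
#' @param labels integer labels (values 1, 2), one per seed voxel.
#' @param seed_coords 0-based voxel index matrix matching `labels`.
#' @param affine voxel-to-world affine.
#' @return relabelled integer vector.
#' @export
align_cluster_labels <- function(labels, seed_coords, affine) {
  if (!all(sort(unique(labels)) == c(1L, 2L)))
    stop("expected exactly labels 1 and 2")
  y <- voxel_to_world(seed_coords, affine)[, 2]
  m1 <- mean(y[labels == 1L]); m2 <- mean(y[labels == 2L])
  if (isTRUE(all.equal(m1, m2)))
    stop("degenerate geometry: clusters have equal mean y coordinate")
  if (m1 > m2) as.integer(labels) else as.integer(3L - labels)
}

#' Maximum probability map across subjects
#'
#' Per seed voxel, the label assigned by the largest number of subjects,
#' with its probability (count / n subjects).  Ties are broken toward the
#' lower label index and flagged.
#'
#' @param label_list list of canonical per-subject label vectors on the
#'   same seed mask (identical voxel order).
#' @return list of class `mpm`: `labels`, `prob`, `tie`, `n_subjects`.
#' @export
compute_mpm <- function(label_list) {
  if (length(label_list) < 1) stop("need at least one subject")
  lens <- vapply(label_list, length, integer(1))
  if (length(unique(lens)) != 1)
    stop("inconsistent seed masks: label vectors differ in length")
  M <- do.call(cbind, label_list)
  K <- max(M)
  counts <- vapply(seq_len(K), function(k) rowSums(M == k),
                   numeric(nrow(M)))
  counts <- matrix(counts, nrow = nrow(M))
  win <- max.col(counts, ties.method = "first")
  best <- counts[cbind(seq_len(nrow(M)), win)]
  tie <- rowSums(counts == best) > 1
  structure(list(labels = as.integer(win),
                 prob = best / length(label_list),
                 tie = tie,
                 n_subjects = length(label_list)),
            class = "mpm")
}

#' Cluster centroids in world coordinates
#'
#' Unweighted mean world (mm) coordinate of the member voxels of each
#' cluster label.
#'
#' @param labels integer label vector (one per seed voxel).
#' @param seed_coords 0-based voxel index matrix matching `labels`.
#' @param affine voxel-to-world affine.
#' @return K x 3 matrix of centroids (row k = cluster k).
#' @export
compute_centroid <- function(labels, seed_coords, affine) {
  xyz <- voxel_to_world(seed_coords, affine)
  K <- max(labels)
  out <- t(vapply(seq_len(K), function(k) {
    sel <- labels == k
    if (!any(sel)) stop("empty cluster: ", k)
    colMeans(xyz[sel, , drop = FALSE])
  }, numeric(3)))
  colnames(out) <- c("x", "y", "z")
  out
}

#' Cohort-average centroids
#'
#' @param centroid_list list of per-subject K x 3 centroid matrices.
#' @return K x 3 matrix: mean of the per-subject centroids.
#' @export
cohort_centroid <- function(centroid_list) {
  Reduce(`+`, centroid_list) / length(centroid_list)
}

#' Spherical ROI restricted to gray matter
#'
#' Marks voxels whose center lies within `radius_mm` of `center_mm`
#' (center-to-center Euclidean distance), then intersects with the gray
#' matter mask.
#'
#' @param center_mm length-3 world coordinate of the sphere center.
#' @param gm_mask 3D gray-matter mask.
#' @param affine voxel-to-world affine.
#' @param radius_mm sphere radius (default 6; the 8-mm variant is supported
#'   by passing `radius_mm = 8`).
#' @return binary 3D ROI mask.
#' @export
make_sphere_roi <- function(center_mm, gm_mask, affine, radius_mm = 6) {
  if (radius_mm <= 0) stop("radius must be positive")
  d <- dim(gm_mask)
  ijk <- as.matrix(expand.grid(i = 0:(d[1] - 1), j = 0:(d[2] - 1),
                               k = 0:(d[3] - 1)))
  xyz <- voxel_to_world(ijk, affine)
  dist2 <- colSums((t(xyz) - center_mm)^2)
  sph <- array(as.integer(dist2 <= radius_mm^2), d)
  roi <- sph * (gm_mask > 0)
  if (sum(roi) == 0)
    stop("sphere ROI does not intersect the gray matter mask")
  roi
}

#' Parcellate a cohort of preprocessed images
#'
#' Runs the per-subject parcellation (connectivity profiles, profile
#' similarity, spectral clustering, anterior/posterior alignment) for every
#' image and aggregates the canonical label maps into a maximum probability
#' map with per-subject and cohort-average centroids.
#'
#' @param imgs list of preprocessed [bold_image]s on a common grid.
#' @param seed_mask,brain_mask 3D masks.
#' @param K number of subregions (default 2).
#' @param n_restarts k-means restarts per subject.
#' @param rng_seed master seed; each subject gets a derived sub-seed.
#' @return object of class `parcellation`: per-subject `labels` matrix
#'   (seed voxel x subject), `mpm`, `centroids` (per subject),
#'   `cohort_centroids`, `seed_coords`, `affine`, `K`.
#' @export
parcellate_cohort <- function(imgs, seed_mask, brain_mask, K = 2,
                              n_restarts = 20, rng_seed = 1) {
  stopifnot(length(imgs) >= 1)
  coords <- mask_coords(seed_mask)
  labs <- list(); cents <- list()
  for (i in seq_along(imgs)) {
    prof <- compute_fc_profiles(imgs[[i]], seed_mask, brain_mask)
    sim <- profile_similarity(prof)
    lab <- spectral_cluster(sim, K = K, n_restarts = n_restarts,
                            rng_seed = derive_seed(rng_seed, i))
    if (K == 2)
      lab <- align_cluster_labels(lab, coords, imgs[[i]]$affine)
    labs[[i]] <- lab
    cents[[i]] <- compute_centroid(lab, coords, imgs[[i]]$affine)
  }
  mpm <- compute_mpm(labs)
  structure(list(labels = do.call(cbind, labs),
                 mpm = mpm,
                 centroids = cents,
                 cohort_centroids = cohort_centroid(cents),
                 seed_coords = coords,
                 affine = imgs[[1]]$affine,
                 K = K,
                 n_subjects = length(imgs)),
            class = "parcellation")
}

#' @export
print.parcellation <- function(x, ...) {
  cat(sprintf("<parcellation> K = %d, %d seed voxels, %d subjects\n",
              x$K, nrow(x$seed_coords), x$n_subjects))
  cat("cohort centroids (mm):\n")
  print(round(x$cohort_centroids, 1))
  invisible(x)
}

#' @export
summary.parcellation <- function(object, ...) {
  sizes <- tabulate(object$mpm$labels, object$K)
  cat(sprintf("Parcellation of %d seed voxels into %d subregions ",
              nrow(object$seed_coords), object$K))
  cat(sprintf("(%d subjects)\n", object$n_subjects))
  for (k in seq_len(object$K))
    cat(sprintf("  subregion %d: %d voxels (MPM), mean probability %.2f\n",
                k, sizes[k],
                mean(object$mpm$prob[object$mpm$labels == k])))
  cat(sprintf("  voxels with tied votes: %d\n", sum(object$mpm$tie)))
  invisible(object)
}
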
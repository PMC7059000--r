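# End-to-end orchestration: simulate (or load) a cohort, preprocess every
# subject, parcellate the control group, build subregion ROIs from the
# maximum probability map, and run the within- and between-group seed-based
# connectivity statistics.  Subjects are processed one at a time so memory
# stays bounded at one 4D image.

#' Pipeline configuration
#'
#' @param spec a [cohort_spec()] describing the synthetic cohort.
#' @param out_dir output directory (`NULL` = no files written, results
#'   returned in memory only).
#' @param n_discard initial volumes to drop.
#' @param fwhm_mm spatial smoothing FWHM (mm; 0 disables).
#' @param band temporal passband (Hz).
#' @param K number of seed subregions.
#' @param n_restarts clustering restarts.
#' @param parcellation_subjects how many control subjects to parcellate
#'   (`NULL` = all controls).
#' @param radius_mm ROI sphere radius (6 or 8).
#' @param fdr_q FDR rate for the one-sample maps.
#' @param min_cluster extent filter for the one-sample maps.
#' @param voxel_p voxel threshold for the group contrast.
#' @param alpha corrected cluster-level alpha.
#' @param n_iter Monte-Carlo iterations for the cluster-extent threshold.
#' @param connectivity cluster connectivity (6/18/26).
#' @param roi_validation run the unflipped ROI-wise lesion-side validation
#'   and the motor-score partial correlation.
#' @param rng_seed master seed for clustering restarts and Monte Carlo.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(spec = cohort_spec(), out_dir = NULL,
                            n_discard = 10, fwhm_mm = 8,
                            band = c(0.01, 0.08), K = 2, n_restarts = 20,
                            parcellation_subjects = NULL, radius_mm = 6,
                            fdr_q = 0.05, min_cluster = 30, voxel_p = 0.01,
                            alpha = 0.05, n_iter = 1000, connectivity = 18,
                            roi_validation = FALSE, rng_seed = 1) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!radius_mm %in% c(6, 8))
    stop("radius_mm must be 6 or 8")
  structure(as.list(environment()), class = "pipeline_config")
}

# Preprocess one subject of a simulated cohort (streaming helper).
preprocess_one <- function(truth, meta_row, spec, config) {
  sub <- synthesize_bold(truth, meta_row$group,
                         derive_seed(spec$rng_seed, meta_row$index))
  preprocess_subject(sub$img, sub$motion, truth$masks,
                     lesion_side = meta_row$lesion_side,
                     n_discard = config$n_discard,
                     fwhm_mm = config$fwhm_mm, band = config$band)
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Stages, in order: cohort simulation, per-subject preprocessing
#' (discard, motion screen, flip, smooth, nuisance regression, band-pass),
#' connectivity-based parcellation of the control group into K subregions
#' with a maximum probability map, sphere ROIs at the per-hemisphere
#' cohort centroids, per-subject seed FC z-maps, one-sample t maps
#' (FDR + extent) and patient-vs-control GLM contrasts with Monte-Carlo
#' cluster-extent correction.
#'
#' @param config a [pipeline_config()].
#' @param force rerun even when outputs for the same configuration exist.
#' @return list of class `pipeline_result` with `parcellation`, `rois`,
#'   `one_sample` and `two_sample` stat maps per ROI, `qc` table, `meta`,
#'   `k_min`, and the `config`.
#' @export
run_pipeline <- function(config, force = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  spec <- config$spec
  out_dir <- config$out_dir
  cfg_hash <- config_hash(config)
  if (!is.null(out_dir) && !force) {
    prov_path <- file.path(out_dir, "provenance.json")
    if (file.exists(prov_path)) {
      prov <- jsonlite::read_json(prov_path)
      if (identical(prov$config_hash, cfg_hash)) {
        message("outputs up to date for this configuration; skipping ",
                "(use force = TRUE to rerun)")
        return(invisible(NULL))
      }
    }
  }
  truth <- make_ground_truth(spec)
  meta <- subject_table(spec)
  meta$index <- seq_len(nrow(meta))
  gm <- truth$masks$gm
  brain <- truth$masks$brain
  seed_mask <- truth$masks$seed

  # ---- pass 1: preprocess + parcellate the controls -------------------
  ctrl <- meta[meta$group == "control", , drop = FALSE]
  if (!is.null(config$parcellation_subjects))
    ctrl <- ctrl[seq_len(min(nrow(ctrl), config$parcellation_subjects)), ,
                 drop = FALSE]
  coords <- mask_coords(seed_mask)
  labs <- list(); cents <- list(); qc_rows <- list()
  for (i in seq_len(nrow(ctrl))) {
    message(sprintf("[parcellate] %s (%d/%d)", ctrl$id[i], i, nrow(ctrl)))
    pp <- preprocess_one(truth, ctrl[i, ], spec, config)
    if (!pp$qc$pass)
      warning("subject ", ctrl$id[i], " fails motion screening")
    prof <- compute_fc_profiles(pp$img, seed_mask, brain)
    sim <- profile_similarity(prof)
    lab <- spectral_cluster(sim, K = config$K,
                            n_restarts = config$n_restarts,
                            rng_seed = derive_seed(config$rng_seed,
                                                   ctrl$index[i]))
    if (config$K == 2)
      lab <- align_cluster_labels(lab, coords, truth$affine)
    labs[[i]] <- lab
    cents[[i]] <- compute_centroid(lab, coords, truth$affine)
    qc_rows[[ctrl$id[i]]] <- pp$qc
  }
  mpm <- compute_mpm(labs)
  parc <- structure(list(labels = do.call(cbind, labs), mpm = mpm,
                         centroids = cents,
                         cohort_centroids = cohort_centroid(cents),
                         seed_coords = coords, affine = truth$affine,
                         K = config$K, n_subjects = length(labs)),
                    class = "parcellation")

  # ---- subregion x hemisphere ROIs from the MPM -----------------------
  rois <- mpm_hemisphere_rois(parc, seed_mask, gm, truth$affine,
                              config$radius_mm)

  # ---- pass 2: seed FC z-maps for every subject -----------------------
  zmaps <- lapply(rois, function(r) vector("list", nrow(meta)))
  for (i in seq_len(nrow(meta))) {
    message(sprintf("[fcmap] %s (%d/%d)", meta$id[i], i, nrow(meta)))
    pp <- preprocess_one(truth, meta[i, ], spec, config)
    qc_rows[[meta$id[i]]] <- pp$qc
    for (rn in names(rois))
      zmaps[[rn]][[i]] <- seed_fc_map(pp$img, rois[[rn]]$mask, brain)
  }

  # ---- group statistics ----------------------------------------------
  design <- data.frame(group = as.integer(meta$group == "patient"),
                       age = meta$age,
                       sex = as.integer(meta$sex == "M"))
  is_ctrl <- meta$group == "control"
  one_sample <- list(); two_sample <- list()
  k_min <- NULL
  for (rn in names(rois)) {
    one_sample[[rn]] <- one_sample_t_fdr(zmaps[[rn]][is_ctrl], brain,
                                         q = config$fdr_q,
                                         min_cluster = config$min_cluster,
                                         connectivity = config$connectivity)
    glm <- two_sample_glm(zmaps[[rn]], design, brain,
                          voxel_p = config$voxel_p)
    if (is.null(k_min)) {
      fwhm_est <- estimate_fwhm(glm$residuals, brain, spec$voxel_mm)
      mc <- alphasim_threshold(brain, voxel_p = config$voxel_p,
                               fwhm_mm = fwhm_est,
                               voxel_mm = spec$voxel_mm,
                               n_iter = config$n_iter,
                               alpha = config$alpha,
                               connectivity = config$connectivity,
                               rng_seed = derive_seed(config$rng_seed, 9999))
      k_min <- mc$k_min
    }
    two_sample[[rn]] <- apply_cluster_threshold(glm, k_min,
                                                config$connectivity,
                                                truth$affine)
  }

  qc <- do.call(rbind, lapply(names(qc_rows), function(id)
    data.frame(id = id, as.data.frame(qc_rows[[id]]))))

  result <- structure(list(parcellation = parc, rois = rois,
                           one_sample = one_sample,
                           two_sample = two_sample,
                           qc = qc, meta = meta, k_min = k_min,
                           truth = truth, config = config),
                      class = "pipeline_result")
  if (isTRUE(config$roi_validation))
    result$roi_validation <- roi_validation_pass(result)
  if (!is.null(out_dir)) write_pipeline_outputs(result, cfg_hash)
  result
}

# Split each MPM subregion at the midplane (world x of the seed-mask
# center) and place a sphere ROI at each hemisphere centroid.
mpm_hemisphere_rois <- function(parc, seed_mask, gm, affine, radius_mm) {
  xyz <- voxel_to_world(parc$seed_coords, affine)
  mid <- mean(range(xyz[, 1]))
  rois <- list()
  for (k in seq_len(parc$K)) {
    for (h in c("left", "right")) {
      sel <- parc$mpm$labels == k &
        (if (h == "left") xyz[, 1] < mid else xyz[, 1] >= mid)
      if (!any(sel)) next
      ctr <- colMeans(xyz[sel, , drop = FALSE])
      name <- paste0("subregion", k, "_", h)
      rois[[name]] <- list(center_mm = ctr, label = k, hemisphere = h,
                           mask = make_sphere_roi(ctr, gm, affine,
                                                  radius_mm))
    }
  }
  rois
}

# Unflipped ROI-wise lesion-side validation and motor-score partial
# correlation, based on the surviving group-contrast clusters.
roi_validation_pass <- function(result) {
  config <- result$config; spec <- config$spec
  truth <- result$truth; meta <- result$meta
  gm <- truth$masks$gm
  targets <- list()
  for (rn in names(result$two_sample)) {
    cl <- result$two_sample[[rn]]$clusters
    if (is.null(cl) || nrow(cl) == 0) next
    for (ci in seq_len(nrow(cl)))
      targets[[paste0(rn, "_cluster", cl$cluster[ci])]] <-
        list(seed_roi = rn,
             mask = make_sphere_roi(as.numeric(cl[ci, c("peak_x", "peak_y",
                                                        "peak_z")]),
                                    gm, truth$affine, config$radius_mm))
  }
  if (!length(targets)) return(list())
  vals <- matrix(NA_real_, nrow(meta), length(targets),
                 dimnames = list(meta$id, names(targets)))
  cfg_unflipped <- config
  for (i in seq_len(nrow(meta))) {
    row <- meta[i, ]; row$lesion_side <- "none"   # unflipped pass
    pp <- preprocess_one(truth, row, spec, cfg_unflipped)
    for (tn in names(targets))
      vals[i, tn] <- roi_pair_fc(pp$img,
                                 result$rois[[targets[[tn]]$seed_roi]]$mask,
                                 targets[[tn]]$mask)
  }
  design <- data.frame(group = as.integer(meta$group == "patient"),
                       age = meta$age, sex = as.integer(meta$sex == "M"))
  out <- list()
  for (tn in names(targets)) {
    res <- list()
    for (side in c("left", "right")) {
      sel <- meta$group == "control" | meta$lesion_side == side
      if (sum(meta$lesion_side == side) >= 2)
        res[[paste0(side, "_lesion_vs_controls")]] <-
          roiwise_group_test(vals[sel, tn], design[sel, , drop = FALSE])
    }
    pat <- meta$group == "patient"
    res$fmt_partial_corr <- tryCatch(
      partial_corr(vals[pat, tn], meta$we_fmt[pat], meta$age[pat],
                   as.integer(meta$sex[pat] == "M")),
      error = function(e) conditionMessage(e))
    out[[tn]] <- res
  }
  out
}

# Cheap deterministic fingerprint of a configuration (content sum over the
# deparsed object; collisions are harmless, only used for the no-op check).
config_hash <- function(config) {
  plain <- unclass(config)
  plain$out_dir <- NULL
  txt <- paste(deparse(plain), collapse = "")
  raw <- utf8ToInt(txt)
  sprintf("%d-%.0f-%.0f", nchar(txt), sum(raw),
          sum(raw * seq_along(raw)) %% 1e9)
}

write_pipeline_outputs <- function(result, cfg_hash) {
  out_dir <- result$config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  aff <- result$truth$affine
  seed_mask <- result$truth$masks$seed
  mpm_img <- unmask(result$parcellation$mpm$labels, seed_mask)
  write_image(mpm_img, file.path(out_dir, "mpm.nii.gz"), affine = aff)
  cents <- result$parcellation$cohort_centroids
  utils::write.table(data.frame(subregion = seq_len(nrow(cents)), cents),
                     file.path(out_dir, "centroids.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(result$qc, file.path(out_dir, "qc.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (rn in names(result$one_sample)) {
    write_image(result$one_sample[[rn]]$thresholded,
                file.path(out_dir, paste0(rn, "_one_sample_t.nii.gz")),
                affine = aff)
    write_image(result$two_sample[[rn]]$thresholded,
                file.path(out_dir, paste0(rn, "_group_contrast_t.nii.gz")),
                affine = aff)
    cl <- result$two_sample[[rn]]$clusters
    utils::write.table(cl, file.path(out_dir,
                                     paste0(rn, "_clusters.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  prov <- list(config_hash = cfg_hash,
               config = rapply(unclass(result$config),
                               function(x) x, how = "replace"),
               k_min = result$k_min,
               package = "parcelfc",
               version = as.character(utils::packageVersion("parcelfc")),
               timestamp = format(Sys.time(), tz = "UTC"))
  prov$config$spec <- unclass(prov$config$spec)
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$parcellation)
  cat(sprintf("  ROIs: %s\n", paste(names(x$rois), collapse = ", ")))
  cat(sprintf("  cluster-extent threshold k* = %d voxels\n", x$k_min))
  for (rn in names(x$two_sample)) {
    cl <- x$two_sample[[rn]]$clusters
    cat(sprintf("  %s: %d surviving group-contrast cluster(s)\n",
                rn, if (is.null(cl)) 0L else nrow(cl)))
  }
  invisible(x)
}
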
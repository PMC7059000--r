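# Simulation experiments packaged as reusable functions: parcellation
# recovery on the full-size default cohort, and calibration / sensitivity
# of the group inference on scaled-down cohorts.  These implement the
# package's validation studies; the methods vignette documents the chosen
# problem sizes.

#' Scaled-down cohort specification for calibration studies
#'
#' The reduced study conditions used for the Monte-Carlo calibration of
#' the group inference: 16 patients vs 16 controls on a 14 x 14 x 12 grid
#' with 130 acquired volumes, all other generative parameters at their
#' defaults.
#'
#' @param rng_seed integer seed.
#' @param group_effects planted effects (default: the package defaults;
#'   `NULL` for the global null).
#' @return a [cohort_spec()].
#' @export
scaled_cohort_spec <- function(rng_seed, group_effects = default_group_effects()) {
  cohort_spec(n_patients = 16, n_controls = 16, grid_shape = c(14, 14, 12),
              n_volumes = 130, group_effects = group_effects,
              rng_seed = rng_seed)
}

# Preprocess one subject of a simulated cohort and return its seed-FC
# z-maps for the requested seed regions (no smoothing in the scaled-down
# studies: the maps are analysed at acquisition resolution).
scaled_subject_maps <- function(truth, meta_row, spec, seed_regions,
                                fwhm_mm = 0) {
  sub <- synthesize_bold(truth, meta_row$group,
                         derive_seed(spec$rng_seed, meta_row$index))
  pp <- preprocess_subject(sub$img, sub$motion, truth$masks,
                           lesion_side = meta_row$lesion_side,
                           fwhm_mm = fwhm_mm)
  lapply(seed_regions, function(r)
    seed_fc_map(pp$img, truth$region_masks[[r]], truth$masks$brain))
}

# Shared driver: simulate one scaled-down cohort, fit the group GLM for
# each requested seed region, and apply the Monte-Carlo cluster-extent
# threshold (smoothness estimated from the GLM residual maps).
scaled_cohort_group_maps <- function(spec, seed_regions, voxel_p = 0.01,
                                     alpha = 0.05, n_iter = 1000,
                                     connectivity = 18) {
  truth <- make_ground_truth(spec)
  meta <- subject_table(spec)
  meta$index <- seq_len(nrow(meta))
  zmaps <- lapply(seed_regions, function(r) vector("list", nrow(meta)))
  names(zmaps) <- seed_regions
  for (i in seq_len(nrow(meta))) {
    maps <- scaled_subject_maps(truth, meta[i, ], spec, seed_regions)
    for (r in seq_along(seed_regions))
      zmaps[[r]][[i]] <- maps[[r]]
  }
  design <- data.frame(group = as.integer(meta$group == "patient"),
                       age = meta$age, sex = as.integer(meta$sex == "M"))
  out <- list()
  k_min <- NULL
  for (r in seed_regions) {
    glm <- two_sample_glm(zmaps[[r]], design, truth$masks$brain, voxel_p)
    if (is.null(k_min)) {
      fw <- estimate_fwhm(glm$residuals, truth$masks$brain, spec$voxel_mm)
      mc <- alphasim_threshold(truth$masks$brain, voxel_p, fw,
                               spec$voxel_mm, n_iter = n_iter,
                               alpha = alpha, connectivity = connectivity,
                               rng_seed = derive_seed(spec$rng_seed, 777))
      k_min <- mc$k_min
    }
    out[[r]] <- apply_cluster_threshold(glm, k_min, connectivity)
  }
  list(maps = out, truth = truth, k_min = k_min)
}

#' Null calibration of the corrected group inference
#'
#' Simulates `n_cohorts` scaled-down cohorts under the no-effect
#' generative model (latent network structure present, no planted group
#' differences), runs the full seed-FC group pipeline on each, and
#' reports the fraction of cohorts in which any Monte-Carlo-corrected
#' cluster survives.  Under a calibrated procedure this fraction should
#' not exceed the cluster-level alpha (up to Monte-Carlo error).
#'
#' @param n_cohorts number of simulated cohorts (default 200).
#' @param rng_seed master seed.
#' @param voxel_p,alpha,n_iter inference parameters.
#' @return list with `false_positive_rate`, per-cohort `any_cluster`,
#'   and `n_cohorts`.
#' @export
group_null_calibration <- function(n_cohorts = 200, rng_seed = 1,
                                   voxel_p = 0.01, alpha = 0.05,
                                   n_iter = 1000) {
  any_cluster <- logical(n_cohorts)
  for (c_i in seq_len(n_cohorts)) {
    spec <- scaled_cohort_spec(derive_seed(rng_seed, 10, c_i),
                               group_effects = NULL)
    res <- scaled_cohort_group_maps(spec, "sma_proper", voxel_p, alpha,
                                    n_iter)
    any_cluster[c_i] <- nrow(res$maps$sma_proper$clusters) > 0
  }
  list(false_positive_rate = mean(any_cluster), any_cluster = any_cluster,
       n_cohorts = n_cohorts)
}

#' Sign recovery of planted group effects
#'
#' Simulates scaled-down cohorts with the default planted coupling shifts
#' and, for each planted effect, asks whether the corrected group-contrast
#' map of the corresponding seed subregion detects the effect inside the
#' true target region with the planted sign (and no opposite-sign
#' survivors there).  Reports the success rate pooled over planted
#' effects and cohorts.
#'
#' @param n_cohorts number of simulated cohorts (default 40).
#' @param rng_seed master seed.
#' @param voxel_p,alpha,n_iter inference parameters.
#' @return list with `sign_match_rate`, a cohort x effect success matrix,
#'   and the effect descriptors.
#' @export
group_sign_recovery <- function(n_cohorts = 40, rng_seed = 1,
                                voxel_p = 0.01, alpha = 0.05,
                                n_iter = 1000) {
  effects <- default_group_effects()
  seed_regions <- vapply(effects, function(e) e$pair[1], character(1))
  ok <- matrix(NA, n_cohorts, length(effects),
               dimnames = list(NULL, vapply(effects, function(e)
                 paste(e$pair, collapse = "-"), character(1))))
  for (c_i in seq_len(n_cohorts)) {
    spec <- scaled_cohort_spec(derive_seed(rng_seed, 20, c_i))
    res <- scaled_cohort_group_maps(spec, unique(seed_regions), voxel_p,
                                    alpha, n_iter)
    for (e_i in seq_along(effects)) {
      eff <- effects[[e_i]]
      thr <- res$maps[[eff$pair[1]]]$thresholded
      target <- res$truth$region_masks[[eff$pair[2]]] > 0
      vals <- thr[target]
      ok[c_i, e_i] <- if (eff$delta > 0)
        any(vals > 0) && all(vals >= 0)
      else
        any(vals < 0) && all(vals <= 0)
    }
  }
  list(sign_match_rate = mean(ok), success = ok, effects = effects)
}

#' Parcellation recovery on the default cohort
#'
#' Generates the default full-size synthetic cohort, preprocesses and
#' parcellates the control subjects, and compares (i) the control-group
#' maximum probability map against the ground-truth subregion labels and
#' (ii) the MPM of a random 9-subject subsample against the full
#' control-group MPM.
#'
#' @param spec cohort specification (default [cohort_spec()]).
#' @param n_subsample subjects in the stability subsample (default 9).
#' @param rng_seed seed for clustering restarts and the subsample draw.
#' @return list with `mpm_truth_agreement`, `subsample_agreement`,
#'   the `parcellation` object and the subsample indices.
#' @export
parcellation_recovery <- function(spec = cohort_spec(), n_subsample = 9,
                                  rng_seed = 1) {
  config <- pipeline_config(spec = spec, rng_seed = rng_seed)
  truth <- make_ground_truth(spec)
  meta <- subject_table(spec)
  meta$index <- seq_len(nrow(meta))
  ctrl <- meta[meta$group == "control", , drop = FALSE]
  coords <- mask_coords(truth$masks$seed)
  labs <- vector("list", nrow(ctrl))
  cents <- vector("list", nrow(ctrl))
  for (i in seq_len(nrow(ctrl))) {
    pp <- preprocess_one(truth, ctrl[i, ], spec, config)
    prof <- compute_fc_profiles(pp$img, truth$masks$seed,
                                truth$masks$brain)
    lab <- spectral_cluster(profile_similarity(prof), K = 2,
                            n_restarts = config$n_restarts,
                            rng_seed = derive_seed(rng_seed,
                                                   ctrl$index[i]))
    labs[[i]] <- align_cluster_labels(lab, coords, truth$affine)
    cents[[i]] <- compute_centroid(labs[[i]], coords, truth$affine)
  }
  mpm_full <- compute_mpm(labs)
  seed_idx <- which(truth$masks$seed > 0)
  truth_lab <- ifelse(truth$region_masks$presma[seed_idx] > 0, 1L, 2L)
  sub_idx <- with_seed(derive_seed(rng_seed, 999),
                       sample(length(labs), min(n_subsample, length(labs))))
  mpm_sub <- compute_mpm(labs[sub_idx])
  parc <- structure(list(labels = do.call(cbind, labs), mpm = mpm_full,
                         centroids = cents,
                         cohort_centroids = cohort_centroid(cents),
                         seed_coords = coords, affine = truth$affine,
                         K = 2, n_subjects = length(labs)),
                    class = "parcellation")
  list(mpm_truth_agreement = mean(mpm_full$labels == truth_lab),
       subsample_agreement = mean(mpm_sub$labels == mpm_full$labels),
       parcellation = parc, subsample = sub_idx)
}
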
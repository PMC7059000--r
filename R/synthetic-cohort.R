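# Synthetic BOLD cohort generator.  Produces a fully self-contained cohort
# (4D BOLD images, masks, motion traces, metadata) whose ground truth embeds
# the structure the downstream pipeline assumes: a seed mask split into two
# contiguous anterior/posterior subregions along the y axis, each coupled to
# a distinct set of distal target networks with one shared target, bounded
# inter-subject coupling variability, planted group-level coupling
# differences, and motion/drift/global nuisance components on top of
# band-limited neural signal.

#' Specification of a synthetic cohort
#'
#' Defaults describe the study conditions emulated throughout the package:
#' 25 patients vs 22 controls, 180 volumes at TR = 2 s, a 24 x 28 x 24 grid
#' of 3-mm voxels, three latent networks, unit-variance neural loading
#' against unit-variance white noise, and planted group coupling shifts of
#' +0.3 / -0.3 loading units (about +/-0.2 Fisher-z at this signal-to-noise
#' ratio).
#'
#' @param n_patients,n_controls group sizes.
#' @param grid_shape 3 integers, the voxel grid.
#' @param voxel_mm voxel edge length (mm).
#' @param tr_s repetition time (s).
#' @param n_volumes acquired volumes per subject.
#' @param noise_sd white-noise standard deviation (signal units).
#' @param coupling_jitter_sd per-subject loading jitter (bounded at
#'   +/- 2.5 sd).
#' @param global_sd global (whole-brain) nuisance signal sd.
#' @param drift_slope_sd linear drift slope sd (signal units per volume).
#' @param motion_amplitude_mm peak amplitude of the simulated motion
#'   random walk (mm and degrees); small enough that screening passes.
#' @param motion_artifact_sd amplitude of the motion-coupled artifact
#'   loaded onto brain-edge voxels.
#' @param band passband of the latent neural courses (Hz).
#' @param group_effects list of planted effects, each
#'   `list(pair = c(region1, region2), delta = <loading shift>)`; applied
#'   to patients only.  `NULL` disables all effects.
#' @param rng_seed master integer seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 25, n_controls = 22,
                        grid_shape = c(24, 28, 24), voxel_mm = 3,
                        tr_s = 2.0, n_volumes = 180,
                        noise_sd = 1.0, coupling_jitter_sd = 0.05,
                        global_sd = 0.3, drift_slope_sd = 0.005,
                        motion_amplitude_mm = 0.3,
                        motion_artifact_sd = 0.3,
                        band = c(0.01, 0.08),
                        group_effects = default_group_effects(),
                        rng_seed = 1) {
  spec <- list(n_patients = as.integer(n_patients),
               n_controls = as.integer(n_controls),
               grid_shape = as.integer(grid_shape), voxel_mm = voxel_mm,
               tr_s = tr_s, n_volumes = as.integer(n_volumes),
               noise_sd = noise_sd, coupling_jitter_sd = coupling_jitter_sd,
               global_sd = global_sd, drift_slope_sd = drift_slope_sd,
               motion_amplitude_mm = motion_amplitude_mm,
               motion_artifact_sd = motion_artifact_sd,
               band = band, group_effects = group_effects,
               rng_seed = as.integer(rng_seed))
  class(spec) <- "cohort_spec"
  validate_cohort_spec(spec)
  spec
}

#' Default planted group effects
#'
#' One coupling increase between the posterior seed subregion and the
#' distal motor target, and one decrease between the anterior subregion
#' and the shared (salience-like) target; shifts of +/-0.3 loading units,
#' about +/-0.2 Fisher-z at the default signal-to-noise ratio.
#'
#' @return list of effect descriptors.
#' @export
default_group_effects <- function() {
  list(list(pair = c("sma_proper", "target_motor"), delta = 0.3),
       list(pair = c("presma", "target_shared"), delta = -0.3))
}

validate_cohort_spec <- function(spec) {
  if (spec$n_patients <= 0) stop("invalid spec: n_patients must be > 0")
  if (spec$n_controls <= 0) stop("invalid spec: n_controls must be > 0")
  if (length(spec$grid_shape) != 3 || any(spec$grid_shape < 8))
    stop("invalid spec: grid_shape must be 3 integers >= 8")
  if (spec$n_volumes < 20) stop("invalid spec: n_volumes must be >= 20")
  if (spec$tr_s <= 0) stop("invalid spec: tr_s must be positive")
  if (spec$noise_sd < 0) stop("invalid spec: noise_sd must be >= 0")
  if (spec$band[1] < 0 || spec$band[1] >= spec$band[2] ||
      spec$band[2] >= 1 / (2 * spec$tr_s))
    stop("invalid spec: band must satisfy 0 <= low < high < Nyquist")
  regions <- rownames(default_coupling())
  for (eff in spec$group_effects) {
    if (length(eff$pair) != 2 || eff$pair[1] == eff$pair[2])
      stop("invalid spec: group_effects pair must name two distinct regions")
    unknown <- setdiff(eff$pair, regions)
    if (length(unknown))
      stop("invalid spec: unknown region in group_effects: ",
           paste(unknown, collapse = ", "))
  }
  invisible(spec)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("<cohort_spec> %d patients vs %d controls\n",
              x$n_patients, x$n_controls))
  cat(sprintf("  grid %s at %g mm, %d volumes, TR = %g s, seed %d\n",
              paste(x$grid_shape, collapse = "x"), x$voxel_mm,
              x$n_volumes, x$tr_s, x$rng_seed))
  cat(sprintf("  %d planted group effect(s)\n", length(x$group_effects)))
  invisible(x)
}

# Ground-truth coupling of each region on each latent network
# (rows: regions, columns: networks).  The two seed subregions load on
# distinct networks plus a shared salience-like network; each distal
# target tracks one network.
default_coupling <- function() {
  m <- rbind(
    sma_proper        = c(1.0, 0.0, 0.5),
    presma            = c(0.0, 1.0, 0.5),
    target_motor      = c(1.0, 0.0, 0.0),
    target_prefrontal = c(0.0, 1.0, 0.0),
    target_shared     = c(0.0, 0.0, 1.0))
  colnames(m) <- c("net_motor", "net_cognitive", "net_salience")
  m
}

# Symmetric (about the x midplane) anatomical layout scaled to any grid:
# ellipsoidal brain, inner white-matter ellipsoid, central ventricle box,
# a dorsal-medial seed slab split into anterior/posterior halves along y,
# and three distal targets (posterior "motor", anterior "prefrontal",
# bilateral "shared").
default_region_layout <- function(grid_shape) {
  d <- as.integer(grid_shape)
  ctr <- (d - 1) / 2
  ax <- expand.grid(i = 0:(d[1] - 1), j = 0:(d[2] - 1), k = 0:(d[3] - 1))
  ellipse <- function(semi) {
    v <- ((ax$i - ctr[1]) / semi[1])^2 + ((ax$j - ctr[2]) / semi[2])^2 +
      ((ax$k - ctr[3]) / semi[3])^2
    array(as.integer(v <= 1), d)
  }
  brain <- ellipse(0.44 * d)
  wm <- ellipse(0.14 * d)
  vent <- array(0L, d)
  hw <- pmax(0.06 * d, 1)
  vent[abs(ax$i - ctr[1]) <= hw[1] & abs(ax$j - ctr[2]) <= hw[2] &
         abs(ax$k - ctr[3]) <= hw[3]] <- 1L
  vent <- vent * brain
  wm <- wm * brain * (1L - vent)
  gm <- brain * (1L - wm) * (1L - vent)

  box <- function(xi, yj, zk) {
    m <- array(0L, d)
    m[xi + 1, yj + 1, zk + 1] <- 1L
    m * gm
  }
  sym_x <- function(hw_frac) {
    which(abs(0:(d[1] - 1) - ctr[1]) <= hw_frac * d[1]) - 1L
  }
  yr <- function(lo, hi) seq(round(lo * d[2]), round(hi * d[2]) - 1)
  zr <- function(lo, hi) seq(round(lo * d[3]), round(hi * d[3]) - 1)

  seed_x <- sym_x(0.08)
  seed_y <- yr(0.29, 0.71)
  seed_z <- zr(0.625, 0.875)
  seed <- box(seed_x, seed_y, seed_z)
  y_split <- floor(mean(range(seed_y)))
  ys <- seq(min(seed_y), y_split)
  ya <- seq(y_split + 1, max(seed_y))
  sma_proper <- box(seed_x, ys, seed_z)        # posterior (lower y)
  presma <- box(seed_x, ya, seed_z)            # anterior (higher y)

  target_motor <- box(sym_x(0.14), yr(0.11, 0.25), zr(0.42, 0.58))
  target_prefrontal <- box(sym_x(0.14), yr(0.75, 0.89), zr(0.33, 0.50))
  off <- abs(0:(d[1] - 1) - ctr[1])
  shared_x <- which(off >= 0.27 * d[1] & off <= 0.38 * d[1]) - 1L
  target_shared <- box(shared_x, yr(0.43, 0.57), zr(0.33, 0.50))

  masks <- list(brain = brain, gm = gm, white_matter = wm,
                ventricle = vent, seed = seed,
                sma_proper = sma_proper, presma = presma,
                target_motor = target_motor,
                target_prefrontal = target_prefrontal,
                target_shared = target_shared)
  empty <- names(masks)[vapply(masks, function(m) sum(m) == 0, logical(1))]
  if (length(empty))
    stop("region layout produced empty mask(s) on this grid: ",
         paste(empty, collapse = ", "))
  if (any(sma_proper * presma > 0) ||
      !all((sma_proper + presma) == seed))
    stop("seed subregions must be disjoint and tile the seed mask")
  masks
}

#' Build the generative ground truth for a cohort
#'
#' Assembles the region layout, the control coupling matrix, and the
#' patient coupling matrix with all planted group effects applied.
#'
#' @param spec a [cohort_spec()].
#' @return object of class `ground_truth`: `region_masks`, `masks`
#'   (anatomical masks), `coupling_control`, `coupling_patient`,
#'   `planted_group_deltas`, `affine`, and the `spec`.
#' @export
make_ground_truth <- function(spec) {
  validate_cohort_spec(spec)
  masks <- default_region_layout(spec$grid_shape)
  regions <- c("sma_proper", "presma", "target_motor",
               "target_prefrontal", "target_shared")
  truth <- structure(list(
    region_masks = masks[regions],
    masks = masks[c("brain", "gm", "white_matter", "ventricle", "seed")],
    coupling_control = default_coupling(),
    coupling_patient = default_coupling(),
    planted_group_deltas = list(),
    affine = grid_affine(spec$voxel_mm),
    spec = spec), class = "ground_truth")
  for (eff in spec$group_effects)
    truth <- plant_group_effect(truth, eff$pair, eff$delta)
  truth
}

#' Plant a group coupling effect
#'
#' Shifts the patients' loading of both named regions on their shared
#' latent network by `delta` (controls untouched), and records the effect.
#' Positive `delta` increases the patient-vs-control connectivity between
#' the pair; negative decreases it.
#'
#' @param truth a `ground_truth` object.
#' @param pair character vector of two distinct region names.
#' @param delta coupling shift in loading units.
#' @return the updated `ground_truth`.
#' @export
plant_group_effect <- function(truth, pair, delta) {
  cp <- truth$coupling_patient
  unknown <- setdiff(pair, rownames(cp))
  if (length(unknown))
    stop("unknown region name: ", paste(unknown, collapse = ", "))
  if (length(pair) != 2 || pair[1] == pair[2])
    stop("pair must name two distinct regions")
  share <- abs(cp[pair[1], ] * cp[pair[2], ])
  k <- if (any(share > 0)) which.max(share) else which.max(abs(cp[pair[2], ]))
  cp[pair[1], k] <- cp[pair[1], k] + delta
  cp[pair[2], k] <- cp[pair[2], k] + delta
  if (any(!is.finite(cp))) stop("planted effect produced non-finite loading")
  truth$coupling_patient <- cp
  truth$planted_group_deltas <- c(truth$planted_group_deltas,
                                  list(list(pair = pair, delta = delta,
                                            network = colnames(cp)[k])))
  truth
}

# Band-limited unit-variance latent courses: white Gaussian series,
# ideal-filtered to the analysis band, then variance-normalized.
band_limited_courses <- function(n_courses, n_volumes, tr_s, band) {
  x <- matrix(stats::rnorm(n_volumes * n_courses), n_volumes, n_courses)
  freqs <- seq(0, n_volumes - 1) / (n_volumes * tr_s)
  freqs <- pmin(freqs, 1 / tr_s - freqs)
  keep <- freqs >= band[1] & freqs <= band[2]
  co <- stats::mvfft(x)
  co[!keep, ] <- 0
  y <- Re(stats::mvfft(co, inverse = TRUE)) / n_volumes
  scale(y)[, , drop = FALSE]
}

# Smooth small-amplitude motion random walk: 3 translations (mm) and
# 3 rotations (deg), each a cumulative sum rescaled to a peak drawn in
# [0.5, 1] x amplitude.
simulate_motion <- function(n_volumes, amplitude) {
  w <- apply(matrix(stats::rnorm(n_volumes * 6), n_volumes, 6), 2, cumsum)
  w <- sweep(w, 2, w[1, ])
  peak <- apply(abs(w), 2, max)
  peak[peak == 0] <- 1
  target <- amplitude * stats::runif(6, 0.5, 1)
  w <- sweep(w, 2, target / peak, `*`)
  colnames(w) <- c("dx_mm", "dy_mm", "dz_mm",
                   "rot_x_deg", "rot_y_deg", "rot_z_deg")
  w
}

#' Synthesize one subject's BOLD image
#'
#' Voxel model: for a voxel in ground-truth region r,
#' `sum_k loading(r, k) * course_k(t)` plus linear drift, global signal,
#' a motion-coupled artifact on brain-edge voxels, and white noise;
#' voxels outside all regions carry only noise and nuisance terms.
#'
#' @param truth a `ground_truth`.
#' @param group `"patient"` or `"control"`.
#' @param rng_seed integer seed for this subject.
#' @return list with `img` (a [bold_image]), `motion` (volumes x 6 matrix)
#'   and the subject `loadings` actually used.
#' @export
synthesize_bold <- function(truth, group = c("control", "patient"),
                            rng_seed = 1) {
  group <- match.arg(group)
  spec <- truth$spec
  d <- spec$grid_shape
  nt <- spec$n_volumes
  coup <- if (group == "patient") truth$coupling_patient
          else truth$coupling_control
  with_seed(rng_seed, {
    courses <- band_limited_courses(ncol(coup), nt, spec$tr_s, spec$band)
    jit <- matrix(stats::rnorm(length(coup), sd = spec$coupling_jitter_sd),
                  nrow(coup), ncol(coup))
    jit <- pmin(pmax(jit, -2.5 * spec$coupling_jitter_sd),
                2.5 * spec$coupling_jitter_sd)
    load <- coup + jit * (coup != 0)
    motion <- simulate_motion(nt, spec$motion_amplitude_mm)
    drift_slope <- stats::rnorm(1, sd = spec$drift_slope_sd)
    drift <- drift_slope * (seq_len(nt) - nt / 2)
    global <- stats::rnorm(nt, sd = spec$global_sd)
    arr <- array(stats::rnorm(prod(d) * nt, sd = spec$noise_sd),
                 c(prod(d), nt))
    brain_idx <- which(truth$masks$brain > 0)
    nuis <- drift + global
    arr[brain_idx, ] <- arr[brain_idx, ] +
      matrix(nuis, length(brain_idx), nt, byrow = TRUE)
    edge_idx <- brain_edge_voxels(truth$masks$brain)
    if (length(edge_idx) && spec$motion_artifact_sd > 0) {
      mseries <- rowSums(motion[, 1:3])
      if (stats::sd(mseries) > 0) {
        mseries <- as.numeric(scale(mseries)) * spec$motion_artifact_sd
        arr[edge_idx, ] <- arr[edge_idx, ] +
          matrix(mseries, length(edge_idx), nt, byrow = TRUE)
      }
    }
    for (r in rownames(coup)) {
      ridx <- which(truth$region_masks[[r]] > 0)
      if (!length(ridx)) next
      sig <- courses %*% load[r, ]
      arr[ridx, ] <- arr[ridx, ] +
        matrix(sig, length(ridx), nt, byrow = TRUE)
    }
    list(img = bold_image(array(arr, c(d, nt)), tr_s = spec$tr_s,
                          affine = truth$affine),
         motion = motion, loadings = load)
  })
}

# Brain voxels with at least one 6-neighbour outside the brain mask.
brain_edge_voxels <- function(brain) {
  d <- dim(brain)
  idx <- which(brain > 0)
  coords <- arrayInd(idx, d)
  offs <- neighbour_offsets(6)
  edge <- rep(FALSE, length(idx))
  for (o in seq_len(nrow(offs))) {
    nb <- coords + matrix(offs[o, ], length(idx), 3, byrow = TRUE)
    outside <- nb[, 1] < 1 | nb[, 1] > d[1] | nb[, 2] < 1 | nb[, 2] > d[2] |
      nb[, 3] < 1 | nb[, 3] > d[3]
    nb_lin <- rep(NA_integer_, length(idx))
    nb_lin[!outside] <- nb[!outside, 1] + (nb[!outside, 2] - 1L) * d[1] +
      (nb[!outside, 3] - 1L) * d[1] * d[2]
    edge <- edge | outside | (brain[ifelse(is.na(nb_lin), 1L, nb_lin)] == 0 &
                                !is.na(nb_lin))
  }
  idx[edge]
}

#' Subject metadata table for a cohort
#'
#' Deterministically (given the spec seed) assigns ages uniform on 42-74,
#' sex in proportions matching the emulated cohort (7/25 female patients,
#' 11/22 female controls), alternating left/right lesion sides for
#' patients, and near-ceiling whole-extremity motor scores (94-100,
#' patients only).
#'
#' @param spec a [cohort_spec()].
#' @return data.frame with columns `id`, `group`, `age`, `sex`,
#'   `lesion_side`, `we_fmt`.
#' @export
subject_table <- function(spec) {
  n <- spec$n_patients + spec$n_controls
  grp <- c(rep("patient", spec$n_patients), rep("control", spec$n_controls))
  with_seed(derive_seed(spec$rng_seed, 0), {
    age <- round(stats::runif(n, 42, 74))
    nfp <- round(spec$n_patients * 7 / 25)
    nfc <- round(spec$n_controls * 11 / 22)
    sex <- c(sample(c(rep("F", nfp), rep("M", spec$n_patients - nfp))),
             sample(c(rep("F", nfc), rep("M", spec$n_controls - nfc))))
    lesion <- c(rep(c("left", "right"), length.out = spec$n_patients),
                rep("none", spec$n_controls))
    we_fmt <- c(sample(94:100, spec$n_patients, replace = TRUE),
                rep(NA_integer_, spec$n_controls))
    data.frame(id = sprintf("sub-%03d", seq_len(n)), group = grp,
               age = age, sex = sex, lesion_side = lesion,
               we_fmt = we_fmt, stringsAsFactors = FALSE)
  })
}

#' Simulate a full cohort in memory
#'
#' @param spec a [cohort_spec()].
#' @return list with `truth`, `meta` (subject table) and `subjects`
#'   (list of `synthesize_bold()` results, in table order).
#' @export
simulate_cohort <- function(spec) {
  truth <- make_ground_truth(spec)
  meta <- subject_table(spec)
  subjects <- lapply(seq_len(nrow(meta)), function(i)
    synthesize_bold(truth, meta$group[i], derive_seed(spec$rng_seed, i)))
  list(truth = truth, meta = meta, subjects = subjects)
}

#' Generate a cohort dataset on disk
#'
#' Writes per-subject 4D BOLD NIfTI images and whitespace-delimited motion
#' traces, the metadata TSV, all ground-truth masks, and a provenance JSON
#' capturing the full spec and seed.  Identical spec and seed reproduce
#' byte-identical arrays.
#'
#' @param spec a [cohort_spec()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
generate_cohort <- function(spec, dir) {
  validate_cohort_spec(spec)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("output directory is not writable: ", dir)
  truth <- make_ground_truth(spec)
  meta <- subject_table(spec)
  utils::write.table(meta, file.path(dir, "participants.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  mask_dir <- file.path(dir, "masks")
  dir.create(mask_dir, showWarnings = FALSE)
  for (nm in names(truth$masks))
    write_image(truth$masks[[nm]], file.path(mask_dir, paste0(nm, ".nii.gz")),
                affine = truth$affine)
  for (nm in names(truth$region_masks))
    write_image(truth$region_masks[[nm]],
                file.path(mask_dir, paste0(nm, ".nii.gz")),
                affine = truth$affine)
  for (i in seq_len(nrow(meta))) {
    sub <- synthesize_bold(truth, meta$group[i],
                           derive_seed(spec$rng_seed, i))
    write_image(sub$img, file.path(dir, paste0(meta$id[i], "_bold.nii.gz")))
    utils::write.table(format(sub$motion, digits = 8),
                       file.path(dir, paste0(meta$id[i], "_motion.txt")),
                       sep = " ", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  prov <- list(spec = unclass(spec),
               planted_group_deltas = truth$planted_group_deltas,
               package = "parcelfc",
               version = as.character(utils::packageVersion("parcelfc")))
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
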
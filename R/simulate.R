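# Synthetic matched-cohort generator.
#
# Emulates the statistical structure the downstream analysis assumes:
# FA-valued volumes in [0, 1] with spatially smooth noise, one-to-one
# matched patient/control pairs, planted focal FA differences of
# configurable sign/extent/effect size, an optional bimodal subgroup
# structure in one region, and symptom scores whose trait-anxiety
# component separates by latent subgroup while the depression measures
# are drawn from a distribution shared across subgroups.

#' Describe a planted focal FA difference
#'
#' @param region Either a logical 3-D array on the simulation grid or a
#'   list `list(lo = c(i, j, k), hi = c(i, j, k))` of inclusive 1-based
#'   voxel index bounds of a box.
#' @param direction `"increase"` (patients elevated) or `"decrease"`.
#' @param effect_size Cohen's d of the patient-minus-control shift, in
#'   units of the voxelwise noise standard deviation, applied when the
#'   whole cohort carries the effect (`subgroup_fraction = 1`).
#' @param subgroup_fraction Fraction of patients carrying the effect;
#'   values below 1 plant a bimodal subgroup structure.
#' @param separation For bimodal plants, the standardized distance between
#'   the carrier and non-carrier patient means in the region.
#' @return A `planted_effect` description.
#' @export
planted_effect <- function(region, direction = c("increase", "decrease"),
                           effect_size = 1, subgroup_fraction = 1,
                           separation = 0) {
  direction <- match.arg(direction)
  stopifnot(effect_size >= 0, separation >= 0,
            subgroup_fraction > 0, subgroup_fraction <= 1)
  structure(list(region = region, direction = direction,
                 effect_size = effect_size,
                 subgroup_fraction = subgroup_fraction,
                 separation = separation),
            class = "planted_effect")
}

#' Simulation configuration
#'
#' Defaults describe the study conditions the package is validated under:
#' 22 matched pairs, a 32 x 32 x 32 grid at 2 mm, baseline FA 0.45 with
#' voxelwise noise s.d. 0.05 smoothed by an isotropic Gaussian kernel of
#' FWHM 2 voxels (the minimal realistic spatial-correlation structure of
#' registered FA maps), and trait-anxiety scores drawn per latent subgroup
#' (abnormal 61.80 +/- 7.32, normal 51.27 +/- 8.96, controls 35 +/- 8)
#' with depression measures shared across subgroups.
#'
#' @param grid_shape Integer length-3 grid dimensions.
#' @param voxel_size_mm Isotropic voxel edge length in mm.
#' @param n_pairs Number of matched patient/control pairs (>= 2).
#' @param fa_mean Baseline FA level.
#' @param fa_sd Voxelwise noise standard deviation (after smoothing).
#' @param smooth_fwhm_vox FWHM of the smoothing kernel, in voxels.
#' @param effects List of [planted_effect()]s.
#' @param symptoms List of `c(mean, sd)` pairs: `control_stai`,
#'   `normal_stai`, `abnormal_stai`, `ids_total`, `ids_anhedonia`,
#'   `ids_sadness`, `ids_psychomotor`.
#' @param seed Integer seed; generation is bit-reproducible for a fixed
#'   seed.
#' @return A `sim_config` object.
#' @export
sim_config <- function(grid_shape = c(32L, 32L, 32L),
                       voxel_size_mm = 2,
                       n_pairs = 22L,
                       fa_mean = 0.45,
                       fa_sd = 0.05,
                       smooth_fwhm_vox = 2,
                       effects = list(),
                       symptoms = list(
                         control_stai   = c(mean = 35,    sd = 8),
                         normal_stai    = c(mean = 51.27, sd = 8.96),
                         abnormal_stai  = c(mean = 61.80, sd = 7.32),
                         ids_total      = c(mean = 36,    sd = 9.6),
                         ids_anhedonia  = c(mean = 1.3,   sd = 0.8),
                         ids_sadness    = c(mean = 2.1,   sd = 0.9),
                         ids_psychomotor = c(mean = 1.1,  sd = 1.0)),
                       seed = 1L) {
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 4), n_pairs >= 2,
            fa_mean > 0, fa_mean < 1, fa_sd > 0, smooth_fwhm_vox >= 0)
  if (length(effects) && inherits(effects, "planted_effect"))
    effects <- list(effects)
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_size_mm = voxel_size_mm, n_pairs = as.integer(n_pairs),
                 fa_mean = fa_mean, fa_sd = fa_sd,
                 smooth_fwhm_vox = smooth_fwhm_vox, effects = effects,
                 symptoms = symptoms, seed = as.integer(seed)),
            class = "sim_config")
}

# Separable Gaussian smoothing with edge renormalisation.
gaussian_smooth3d <- function(arr, fwhm_vox) {
  if (fwhm_vox <= 0) return(arr)
  sigma <- fwhm_vox / (2 * sqrt(2 * log(2)))
  r <- max(1L, ceiling(2.5 * sigma))
  kern <- dnorm(seq(-r, r), sd = sigma)
  kern <- kern / sum(kern)
  wts <- array(1, dim = dim(arr))
  for (axis in 1:3) {
    arr <- .conv_axis(arr, kern, axis)
    wts <- .conv_axis(wts, kern, axis)
  }
  arr / wts
}

.conv_axis <- function(arr, kern, axis) {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  m <- matrix(aperm(arr, perm), nrow = d[axis])
  L <- d[axis]
  r <- (length(kern) - 1L) / 2L
  out <- matrix(0, nrow = L, ncol = ncol(m))
  for (o in seq(-r, r)) {
    w <- kern[o + r + 1L]
    tgt <- max(1L, 1L - o):min(L, L - o)
    out[tgt, ] <- out[tgt, ] + w * m[tgt + o, ]
  }
  aperm(array(out, dim = d[perm]), order(perm))
}

.resolve_region <- function(region, grid_shape) {
  if (is.array(region)) {
    if (!identical(dim(region), as.integer(grid_shape)) &&
        !identical(dim(region), grid_shape))
      stop("planted region mask does not match the simulation grid")
    return(which(region != 0))
  }
  lo <- region$lo; hi <- region$hi
  if (is.null(lo) || is.null(hi))
    stop("box regions need `lo` and `hi` index triples")
  if (any(lo < 1) || any(hi > grid_shape) || any(lo > hi))
    stop("planted region lies outside the simulation grid")
  idx <- as.matrix(expand.grid(lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]))
  idx[, 1] + (idx[, 2] - 1L) * grid_shape[1] +
    (idx[, 3] - 1L) * grid_shape[1] * grid_shape[2]
}

.box_around <- function(lin, grid_shape, margin = 1L) {
  co <- arrayInd(lin, grid_shape)
  lo <- pmax(apply(co, 2, min) - margin, 1L)
  hi <- pmin(apply(co, 2, max) + margin, grid_shape)
  mask <- array(FALSE, dim = grid_shape)
  mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  mask
}

#' Generate a synthetic matched FA cohort
#'
#' Draws one smooth FA volume per subject, applies the planted effects to
#' the carrier patients, builds an AOE set (a primary mask covering each
#' planted region, a disjoint secondary mask, and a whole-brain tier), and
#' generates the matched-pair cohort table with symptom scores. The truth
#' record lists each patient's latent subgroup and each planted region's
#' voxel set.
#'
#' Latent subgroups: if any effect has `subgroup_fraction < 1`, a single
#' carrier subset of `round(fraction * n_pairs)` patients is drawn (shared
#' by all sub-cohort effects, which must agree on the fraction) and
#' labelled `abnormal`; effects with `subgroup_fraction = 1` apply to all
#' patients. Carrier patients are shifted in the region by
#' `separation * fa_sd` for sub-cohort effects and `effect_size * fa_sd`
#' for whole-cohort effects, signed by `direction`.
#'
#' @param config A [sim_config()].
#' @return A list with `patients` and `controls` (lists of [fa_volume]),
#'   `aoes` (list of [aoe_tier]), `cohort` (data.frame), `truth`
#'   (latent subgroups and planted voxel sets) and `affine`.
#' @export
generate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  gs <- config$grid_shape
  n <- config$n_pairs
  affine <- diag(c(rep(config$voxel_size_mm, 3), 1))
  affine[1:3, 4] <- -(gs / 2) * config$voxel_size_mm

  regions <- lapply(config$effects, function(e) .resolve_region(e$region, gs))

  sub_idx <- which(vapply(config$effects, function(e) e$subgroup_fraction < 1,
                          logical(1)))
  if (length(sub_idx)) {
    fr <- vapply(config$effects[sub_idx], `[[`, numeric(1), "subgroup_fraction")
    if (length(unique(fr)) > 1L)
      stop("all sub-cohort effects must share the same subgroup_fraction")
    n_abn <- round(fr[1] * n)
    carriers <- sort(sample.int(n, n_abn))
  } else {
    carriers <- integer(0)
  }
  subgroup <- ifelse(seq_len(n) %in% carriers, "abnormal", "normal")

  draw_vol <- function(id) {
    z <- gaussian_smooth3d(array(rnorm(prod(gs)), dim = gs), config$smooth_fwhm_vox)
    z <- (z - mean(z)) / sd(z)
    fa_volume(pmin(pmax(config$fa_mean + config$fa_sd * z, 0), 1),
              affine, subject_id = id, space = "synthetic")
  }

  patients <- lapply(seq_len(n), function(i) {
    v <- draw_vol(sprintf("P%02d", i))
    for (j in seq_along(config$effects)) {
      e <- config$effects[[j]]
      applies <- if (e$subgroup_fraction < 1) i %in% carriers else TRUE
      if (!applies) next
      shift <- (if (e$subgroup_fraction < 1) e$separation else e$effect_size) *
        config$fa_sd * (if (e$direction == "increase") 1 else -1)
      v$data[regions[[j]]] <- pmin(pmax(v$data[regions[[j]]] + shift, 0), 1)
    }
    v
  })
  controls <- lapply(seq_len(n), function(i) draw_vol(sprintf("C%02d", i)))

  # AOE set: primary covers every planted region (or a central default box),
  # secondary is a disjoint slab, the whole-brain tier spans the grid.
  if (length(regions)) {
    primary_mask <- array(FALSE, dim = gs)
    for (lin in regions) primary_mask <- primary_mask | .box_around(lin, gs)
  } else {
    c0 <- round(gs / 2)
    primary_mask <- array(FALSE, dim = gs)
    primary_mask[(c0[1] - 2):(c0[1] + 3), (c0[2] - 3):(c0[2] + 3),
                 (c0[3] - 4):(c0[3] + 5)] <- TRUE
  }
  secondary_mask <- array(FALSE, dim = gs)
  secondary_mask[3:10, 3:(gs[2] - 2), 3:(gs[3] - 2)] <- TRUE
  secondary_mask[primary_mask] <- FALSE
  aoes <- list(
    aoe_tier("planted_primary", primary_mask, "primary"),
    aoe_tier("secondary_slab", secondary_mask, "secondary"),
    aoe_tier("whole_brain", array(TRUE, dim = gs), "whole_brain")
  )

  sym <- config$symptoms
  draw <- function(par, m) round(rnorm(m, par["mean"], par["sd"]))
  stai_p <- ifelse(subgroup == "abnormal",
                   draw(sym$abnormal_stai, n), draw(sym$normal_stai, n))
  item <- function(par) pmin(pmax(draw(par, n), 0), 3)
  ages <- round(runif(n, 20, 60))
  edu <- round(runif(n, 12, 20))
  cohort <- rbind(
    data.frame(subject_id = sprintf("P%02d", seq_len(n)), group = "patient",
               pair_id = sprintf("S%02d", seq_len(n)),
               age = ages, education = edu,
               sex = rep_len(c("F", "M"), n),
               handedness = rep_len(c(rep("R", 9), "L"), n),
               IDS_total = pmin(pmax(draw(sym$ids_total, n), 0), 84),
               IDS_anhedonia = item(sym$ids_anhedonia),
               IDS_sadness = item(sym$ids_sadness),
               IDS_psychomotor = item(sym$ids_psychomotor),
               STAI_T = pmax(stai_p, 20)),
    data.frame(subject_id = sprintf("C%02d", seq_len(n)), group = "control",
               pair_id = sprintf("S%02d", seq_len(n)),
               age = pmin(pmax(ages + sample(-3:3, n, replace = TRUE), 18), 65),
               education = pmin(pmax(edu + sample(-2:2, n, replace = TRUE), 10), 22),
               sex = rep_len(c("F", "M"), n),
               handedness = rep_len(c(rep("R", 9), "L"), n),
               IDS_total = pmin(pmax(round(rnorm(n, 4, 3)), 0), 84),
               IDS_anhedonia = pmin(pmax(round(rnorm(n, 0.2, 0.4)), 0), 3),
               IDS_sadness = pmin(pmax(round(rnorm(n, 0.3, 0.5)), 0), 3),
               IDS_psychomotor = pmin(pmax(round(rnorm(n, 0.2, 0.4)), 0), 3),
               STAI_T = pmax(draw(sym$control_stai, n), 20))
  )
  validate_cohort_table(cohort)

  truth <- list(
    subgroup = setNames(subgroup, sprintf("P%02d", seq_len(n))),
    carriers = sprintf("P%02d", carriers),
    effects = lapply(seq_along(config$effects), function(j)
      list(voxels = regions[[j]],
           direction = config$effects[[j]]$direction,
           subgroup_fraction = config$effects[[j]]$subgroup_fraction))
  )

  list(patients = patients, controls = controls, aoes = aoes,
       cohort = cohort, truth = truth, affine = affine, config = config)
}

#' The 22 published per-subject VTA/SN cluster-mean FA values
#'
#' Returns the packaged fixture of 22 per-subject mean FA values from the
#' midbrain (VTA/SN) cluster of the published whole-cohort contrast,
#' together with each subject's printed subgroup section label and the two
#' printed antidepressant columns (treatment history and status at the
#' time of scanning).
#'
#' @return A data.frame with 22 rows and columns `fa`, `subgroup`
#'   (`"normal"`/`"abnormal"`), `antidepressant_history`,
#'   `antidepressant_current` (logical).
#' @export
table1_fixture <- function() {
  path <- system.file("extdata", "table1_vta_sn_fa.tsv", package = "fagap",
                      mustWork = TRUE)
  tbl <- utils::read.delim(path, stringsAsFactors = FALSE)
  tbl$antidepressant_history <- tbl$antidepressant_history == "Yes"
  tbl$antidepressant_current <- tbl$antidepressant_current == "Yes"
  tbl
}
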
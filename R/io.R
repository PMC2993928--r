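# Volume, table and configuration I/O.

#' Read and write FA volumes as NIfTI
#'
#' Volumes are stored as 3-D NIfTI scalar images; data are written in double
#' precision so that a write/read round trip preserves finite values
#' bit-exactly. `NaN` voxels are preserved and treated as missing
#' downstream.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param subject_id Identifier to attach; defaults to the file name.
#' @param reference Optional `fa_volume` (or list with `data` and `affine`)
#'   declaring the expected grid; a shape or affine mismatch is an error.
#' @param space Space label to attach to the volume.
#' @return `read_fa_volume` returns an [fa_volume]; `write_fa_volume`
#'   returns `path` invisibly.
#' @export
read_fa_volume <- function(path, subject_id = NULL, reference = NULL,
                           space = "MNI-ICBM152") {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  nd <- length(dim(arr))
  if (nd != 3L)
    stop("expected a 3-D NIfTI volume but '", basename(path),
         "' has ", nd, " dimensions")
  affine <- unclass(RNifti::xform(img))
  attributes(affine) <- list(dim = c(4L, 4L))
  vol <- fa_volume(arr, affine,
                   subject_id = subject_id %||% sub("\\.nii(\\.gz)?$", "", basename(path)),
                   space = space)
  if (!is.null(reference)) .check_shared_grid(list(vol), reference)
  vol
}

#' @param volume An [fa_volume].
#' @rdname read_fa_volume
#' @export
write_fa_volume <- function(volume, path) {
  stopifnot(inherits(volume, "fa_volume"))
  img <- RNifti::asNifti(volume$data)
  RNifti::sform(img) <- structure(volume$affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read and write binary AOE masks as NIfTI
#'
#' @inheritParams read_fa_volume
#' @param name,tier Passed to [aoe_tier()].
#' @return An [aoe_tier] for `read_aoe_mask`.
#' @export
read_aoe_mask <- function(path, name, tier, reference = NULL) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L)
    stop("expected a 3-D mask but '", basename(path), "' has ",
         length(dim(arr)), " dimensions")
  if (!is.null(reference) && !identical(dim(arr), dim(reference$data)))
    stop("grid mismatch: mask '", basename(path), "' does not match the reference grid")
  aoe_tier(name, arr != 0, tier)
}

#' @param aoe An [aoe_tier].
#' @rdname read_aoe_mask
#' @export
write_aoe_mask <- function(aoe, path, affine = diag(4)) {
  img <- RNifti::asNifti(array(as.integer(aoe$mask), dim = dim(aoe$mask)))
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

# ---------------------------------------------------------------------------
# Cohort table
# ---------------------------------------------------------------------------

.cohort_columns <- c("subject_id", "group", "pair_id", "age", "education",
                     "sex", "handedness", "IDS_total", "IDS_anhedonia",
                     "IDS_sadness", "IDS_psychomotor", "STAI_T")

#' Read, validate and write the cohort table
#'
#' The cohort table is tab-delimited text with one row per subject and the
#' columns `subject_id`, `group` (`patient`/`control`), `pair_id`, `age`,
#' `education`, `sex`, `handedness`, and the symptom measures `IDS_total`,
#' `IDS_anhedonia`, `IDS_sadness`, `IDS_psychomotor`, `STAI_T` (symptom
#' fields may be missing). Validation checks the one-to-one matching: each
#' `pair_id` occurs exactly once per group and, when `matched = TRUE`,
#' members of a pair differ by at most 5 years of age and 5 years of
#' education.
#'
#' @param path Path to a tab-delimited file with a header row.
#' @param matched Enforce the within-pair age/education bounds.
#' @return A validated `data.frame`.
#' @export
read_cohort_table <- function(path, matched = TRUE) {
  classes <- c(subject_id = "character", group = "character",
               pair_id = "character", sex = "character",
               handedness = "character", age = "numeric",
               education = "numeric", IDS_total = "numeric",
               IDS_anhedonia = "numeric", IDS_sadness = "numeric",
               IDS_psychomotor = "numeric", STAI_T = "numeric")
  tbl <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = classes)
  validate_cohort_table(tbl, matched = matched)
}

#' @param table A cohort `data.frame`.
#' @rdname read_cohort_table
#' @export
write_cohort_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_cohort_table
#' @export
validate_cohort_table <- function(table, matched = TRUE) {
  missing_cols <- setdiff(.cohort_columns, names(table))
  if (length(missing_cols))
    stop("cohort table is missing column(s): ", paste(missing_cols, collapse = ", "))
  if (!all(table$group %in% c("patient", "control")))
    stop("`group` must be 'patient' or 'control'")
  for (g in c("patient", "control")) {
    ids <- table$pair_id[table$group == g]
    if (anyDuplicated(ids))
      stop("pair_id values must be unique within the ", g, " group")
  }
  pat <- table[table$group == "patient", ]
  ctl <- table[table$group == "control", ]
  if (!setequal(pat$pair_id, ctl$pair_id))
    stop("patients and controls do not form one-to-one pairs")
  if (matched) {
    ctl <- ctl[match(pat$pair_id, ctl$pair_id), ]
    if (any(abs(pat$age - ctl$age) > 5, na.rm = TRUE))
      stop("matched design violated: a pair differs by more than 5 years of age")
    if (any(abs(pat$education - ctl$education) > 5, na.rm = TRUE))
      stop("matched design violated: a pair differs by more than 5 years of education")
  }
  table
}

# ---------------------------------------------------------------------------
# Tier configuration
# ---------------------------------------------------------------------------

#' Tiered cluster/correction configuration
#'
#' Holds the per-voxel inclusion threshold, the per-tier minimum cluster
#' extents, the base alpha of the tiered Bonferroni correction, the
#' trend rule, and the contiguity rule. Defaults reproduce the published
#' tiers: voxelwise p < 0.05, cluster extents of 9 / 27 / 81 contiguous
#' voxels for the primary / secondary / whole-brain tiers, trends within one
#' order of magnitude of the corrected threshold, and 18-neighbourhood
#' contiguity (voxels sharing a face or an edge, never only a corner).
#'
#' @param alpha Base significance level of the Bonferroni correction.
#' @param voxel_p_threshold Per-voxel two-tailed p for cluster membership.
#' @param k_cluster Named vector of minimum cluster extents per tier.
#' @param trend_factor Order-of-magnitude multiplier of the trend rule.
#' @param connectivity 6, 18 or 26 (face; face+edge; face+edge+corner).
#' @param n_search_whole_brain Optional fixed search-volume size for the
#'   whole-brain tier (e.g. the 200,000-voxel compatibility constant);
#'   by default the evaluated-voxel count of the search mask is used.
#' @return A `tier_config` object.
#' @export
tier_config <- function(alpha = 0.05,
                        voxel_p_threshold = 0.05,
                        k_cluster = c(primary = 9, secondary = 27, whole_brain = 81),
                        trend_factor = 10,
                        connectivity = 18,
                        n_search_whole_brain = NULL) {
  stopifnot(alpha > 0, alpha < 1, voxel_p_threshold > 0, voxel_p_threshold <= 1,
            trend_factor >= 1)
  if (!all(c("primary", "secondary", "whole_brain") %in% names(k_cluster)))
    stop("`k_cluster` must name tiers primary, secondary and whole_brain")
  if (!connectivity %in% c(6, 18, 26))
    stop("`connectivity` must be 6, 18 or 26")
  structure(list(alpha = alpha, voxel_p_threshold = voxel_p_threshold,
                 k_cluster = k_cluster, trend_factor = trend_factor,
                 connectivity = as.integer(connectivity),
                 n_search_whole_brain = n_search_whole_brain),
            class = "tier_config")
}

#' Read a tier configuration from YAML or JSON
#'
#' @param path File ending in `.yaml`/`.yml` or `.json`; keys are the
#'   arguments of [tier_config()].
#' @return A `tier_config`.
#' @export
read_tier_config <- function(path) {
  x <- .read_config_file(path)
  if (!is.null(x$k_cluster)) x$k_cluster <- unlist(x$k_cluster)
  do.call(tier_config, x)
}

.read_config_file <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    stop("configuration file must be YAML or JSON: ", path)
  }
}
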
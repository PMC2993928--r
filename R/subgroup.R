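# Per-subject cluster means, subgroup re-contrasts, symptom comparisons.

#' Mean FA over a cluster for each subject
#'
#' @param cluster An `fa_cluster`, a vector of linear voxel indices, or a
#'   logical mask on the volumes' grid.
#' @param volumes List of [fa_volume] on a shared grid.
#' @return Named numeric vector, one arithmetic mean per subject; missing
#'   voxels are excluded per subject. A subject with no valid voxel in the
#'   cluster is an error.
#' @export
extract_cluster_means <- function(cluster, volumes) {
  vox <- if (inherits(cluster, "fa_cluster")) cluster$voxels
         else if (is.array(cluster)) which(cluster != 0)
         else as.integer(cluster)
  if (!length(vox)) stop("cluster is empty")
  .check_shared_grid(volumes)
  out <- vapply(volumes, function(v) {
    vals <- v$data[vox]
    vals <- vals[is.finite(vals)]
    if (!length(vals))
      stop("cluster is empty after missing-data exclusion for subject ",
           v$subject_id)
    mean(vals)
  }, numeric(1))
  names(out) <- vapply(volumes, `[[`, character(1), "subject_id")
  out
}

#' Pair patients with their matched controls and subgroup labels
#'
#' @param cohort A validated cohort table (see [read_cohort_table()]).
#' @param labels Character vector of subgroup labels, named by patient
#'   `subject_id` (or unnamed, aligned with the patients in cohort order).
#' @return A data.frame with one row per patient: `patient_id`,
#'   `control_id`, `pair_id`, `subgroup`.
#' @export
subgroup_design <- function(cohort, labels) {
  validate_cohort_table(cohort, matched = FALSE)
  pat <- cohort[cohort$group == "patient", ]
  ctl <- cohort[cohort$group == "control", ]
  if (is.null(names(labels))) {
    if (length(labels) != nrow(pat))
      stop("`labels` must have one entry per patient")
    names(labels) <- pat$subject_id
  }
  miss <- setdiff(pat$subject_id, names(labels))
  if (length(miss))
    stop("missing subgroup labels for patient(s): ", paste(miss, collapse = ", "))
  ctl_of <- ctl$subject_id[match(pat$pair_id, ctl$pair_id)]
  if (anyNA(ctl_of))
    stop("unmatched patient(s): no control shares pair_id ",
         paste(pat$pair_id[is.na(ctl_of)], collapse = ", "))
  data.frame(patient_id = pat$subject_id, control_id = ctl_of,
             pair_id = pat$pair_id,
             subgroup = unname(labels[pat$subject_id]))
}

#' Voxel-based contrast of one subgroup versus its matched controls
#'
#' Re-runs the voxel-based contrast for the patients carrying a given
#' subgroup label against their individually matched controls only, and
#' identifies and corrects clusters with exactly the same tier
#' configuration as the full-cohort contrast.
#'
#' @param patients,controls Lists of [fa_volume]; `subject_id`s must match
#'   the cohort table.
#' @param design Output of [subgroup_design()].
#' @param subgroup Label selecting the subgroup to contrast.
#' @param aoes List of [aoe_tier].
#' @param config A [tier_config()]; reused verbatim, including search
#'   sizes.
#' @param mask,variance Passed to [fa_contrast()].
#' @return As [detect_clusters()], plus `statmap` and `group_sizes`.
#' @export
subgroup_contrast <- function(patients, controls, design, subgroup, aoes,
                              config = tier_config(), mask = NULL,
                              variance = c("pooled", "welch")) {
  sel <- design[design$subgroup == subgroup, , drop = FALSE]
  if (!nrow(sel)) stop("subgroup '", subgroup, "' has no patients")
  if (nrow(sel) < 2)
    stop("subgroup '", subgroup, "' has a single subject; cannot form a t statistic")
  pid <- vapply(patients, `[[`, character(1), "subject_id")
  cid <- vapply(controls, `[[`, character(1), "subject_id")
  ip <- match(sel$patient_id, pid)
  ic <- match(sel$control_id, cid)
  if (anyNA(ip) || anyNA(ic))
    stop("volumes missing for some subjects of subgroup '", subgroup, "'")
  sm <- fa_contrast(patients[ip], controls[ic], mask = mask,
                    variance = variance)
  out <- detect_clusters(sm, aoes, config)
  out$statmap <- sm
  out$group_sizes <- sm$group_sizes
  out
}

#' Compare symptom measures between patient subgroups
#'
#' Two-tailed pooled-variance t tests of each symptom measure between the
#' two patient subgroups, with available-case handling per measure (each
#' measure's df reflects its own non-missing sample sizes) and a
#' Bonferroni significance flag at `alpha / n_corrections` (0.05/5 = 0.01
#' under the defaults).
#'
#' @param cohort Cohort table with the symptom columns.
#' @param labels Subgroup labels as in [subgroup_design()].
#' @param measures Character vector of symptom column names.
#' @param alpha Base level of the Bonferroni rule.
#' @param n_corrections Number of comparisons corrected for; defaults to
#'   `length(measures)`.
#' @return A data.frame with one row per measure: group means, s.d.s and
#'   ns, `t`, `df`, `p`, the Bonferroni `threshold` and `significant`
#'   flag. A measure with fewer than two non-missing values in either
#'   subgroup is reported with `NA` statistics rather than failing the
#'   batch.
#' @export
symptom_compare <- function(cohort, labels,
                            measures = c("IDS_total", "IDS_anhedonia",
                                         "IDS_sadness", "IDS_psychomotor",
                                         "STAI_T"),
                            alpha = 0.05, n_corrections = length(measures)) {
  design <- subgroup_design(cohort, labels)
  groups <- sort(unique(design$subgroup))
  if (length(groups) != 2)
    stop("symptom comparison needs exactly two subgroups, got ",
         length(groups))
  pat <- cohort[cohort$group == "patient", ]
  lab <- design$subgroup[match(pat$subject_id, design$patient_id)]
  thr <- alpha / n_corrections
  rows <- lapply(measures, function(ms) {
    if (!ms %in% names(pat)) stop("unknown symptom measure: ", ms)
    x <- pat[[ms]][lab == groups[1]]; x <- x[!is.na(x)]
    y <- pat[[ms]][lab == groups[2]]; y <- y[!is.na(y)]
    base <- data.frame(measure = ms, group_1 = groups[1], group_2 = groups[2],
                       mean_1 = mean(x), sd_1 = sd(x), n_1 = length(x),
                       mean_2 = mean(y), sd_2 = sd(y), n_2 = length(y))
    if (length(x) < 2 || length(y) < 2)
      return(cbind(base, t = NA_real_, df = NA_real_, p = NA_real_,
                   threshold = thr, significant = NA))
    tt <- .t2_pooled(x, y)
    cbind(base, t = tt$t, df = tt$df, p = tt$p, threshold = thr,
          significant = tt$p < thr)
  })
  do.call(rbind, rows)
}
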
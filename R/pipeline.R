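# End-to-end pipeline: simulate/load -> contrast -> clusters -> cluster
# means -> gapping -> subgroup contrasts -> symptom comparisons, with
# stage caching and a run manifest.

.stage_names <- c("data", "contrast", "clusters", "means", "gap",
                  "subgroups", "symptoms")

#' Run the full analysis pipeline
#'
#' Executes every stage in order, feeding each stage's output to the next:
#' cohort acquisition (synthetic generation, or volumes/tables read from
#' the paths in `config$inputs`), the whole-cohort voxel contrast, cluster
#' detection with tiered correction, per-subject mean extraction for every
#' primary-tier cluster meeting its extent requirement (including
#' clusters that missed the corrected peak threshold, so that cohort
#' heterogeneity can be probed), the gapping analysis of each candidate
#' cluster (the cluster with the smallest null p drives the subgrouping),
#' the per-subgroup re-contrasts against matched controls, and the
#' subgroup symptom comparison.
#'
#' Stage outputs are cached as files under `out_dir/cache`; re-running
#' with the same directory resumes from the cached stages (delete a
#' stage's cache file to recompute it and everything downstream). All
#' randomness flows from `config$seed`, expanded deterministically into
#' one sub-seed per stage, so two runs with identical configuration
#' produce identical outputs.
#'
#' @param config A list (or YAML/JSON path) with fields `seed`, one of
#'   `simulate` (arguments of [sim_config()], `effects` given as lists of
#'   [planted_effect()] arguments) or `inputs` (paths: `patients`,
#'   `controls`, `cohort`, and `aoes` as a list of
#'   `list(path, name, tier)`), and optionally `tier` ([tier_config()]
#'   arguments), `gap` (`n_sims`, `df_t`, `calibration`), `variance`.
#' @param out_dir Output directory; created if needed.
#' @param overwrite Recompute all stages, ignoring caches.
#' @return Invisibly, a list with all stage outputs and the `manifest`.
#' @export
run_pipeline <- function(config, out_dir, overwrite = FALSE) {
  if (is.character(config) && length(config) == 1L)
    config <- .read_config_file(config)
  .validate_pipeline_config(config)
  dir.create(file.path(out_dir, "cache"), recursive = TRUE, showWarnings = FALSE)

  set.seed(config$seed)
  stage_seeds <- setNames(sample.int(2^31 - 2, length(.stage_names)),
                          .stage_names)
  tier_cfg <- do.call(tier_config, config$tier %||% list())
  gap_cfg <- utils::modifyList(
    list(n_sims = 10000, df_t = 4, calibration = "standardized_gap"),
    config$gap %||% list())
  variance <- config$variance %||% "pooled"

  timings <- list()
  results <- list()
  run_stage <- function(name, fun) {
    cache <- file.path(out_dir, "cache", paste0(name, ".rds"))
    t0 <- proc.time()[["elapsed"]]
    if (!overwrite && file.exists(cache)) {
      out <- readRDS(cache)
      timings[[name]] <<- list(seconds = proc.time()[["elapsed"]] - t0,
                               cached = TRUE)
    } else {
      out <- fun()
      saveRDS(out, cache)
      timings[[name]] <<- list(seconds = proc.time()[["elapsed"]] - t0,
                               cached = FALSE)
    }
    results[[name]] <<- out
    out
  }

  dat <- run_stage("data", function() {
    if (!is.null(config$simulate)) {
      sim_args <- config$simulate
      if (!is.null(sim_args$effects))
        sim_args$effects <- lapply(sim_args$effects, function(e)
          do.call(planted_effect, e))
      sim_args$seed <- sim_args$seed %||% stage_seeds[["data"]]
      generate_cohort(do.call(sim_config, sim_args))
    } else {
      .load_inputs(config$inputs)
    }
  })

  sm <- run_stage("contrast", function()
    fa_contrast(dat$patients, dat$controls, variance = variance))

  det <- run_stage("clusters", function()
    detect_clusters(sm, dat$aoes, tier_cfg))

  means <- run_stage("means", function() {
    k_primary <- tier_cfg$k_cluster[["primary"]]
    cand <- Filter(function(x) x$tier == "primary" && x$size >= k_primary,
                   det$clusters)
    lapply(cand, function(cl) list(
      cluster = cl,
      patients = extract_cluster_means(cl, dat$patients),
      controls = extract_cluster_means(cl, dat$controls)))
  })

  gap <- run_stage("gap", function() {
    if (!length(means)) return(NULL)
    fits <- lapply(seq_along(means), function(i)
      gap_analysis(means[[i]]$patients,
                   n_sims = gap_cfg$n_sims, df_t = gap_cfg$df_t,
                   seed = stage_seeds[["gap"]] %% (2^31 - 10) + 2L * i,
                   type = gap_cfg$calibration))
    best <- which.min(vapply(fits, `[[`, numeric(1), "p_gaussian"))
    list(fits = fits, selected = best, result = fits[[best]],
         labels = setNames(fits[[best]]$labels,
                           names(means[[best]]$patients)))
  })

  subgroups <- run_stage("subgroups", function() {
    if (is.null(gap)) return(NULL)
    design <- subgroup_design(dat$cohort, gap$labels)
    labs <- unique(design$subgroup)
    out <- lapply(labs, function(lb) {
      if (sum(design$subgroup == lb) < 2) return(NULL)
      subgroup_contrast(dat$patients, dat$controls, design, lb,
                        dat$aoes, tier_cfg, variance = variance)
    })
    setNames(out, labs)
  })

  symptoms <- run_stage("symptoms", function() {
    if (is.null(gap) || length(unique(gap$labels)) != 2) return(NULL)
    symptom_compare(dat$cohort, gap$labels)
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("fagap")),
    seed = config$seed,
    stage_seeds = as.list(stage_seeds),
    tier_config = unclass(tier_cfg),
    gap_config = gap_cfg,
    variance = variance,
    input_hashes = .input_hashes(config$inputs),
    timings = timings,
    outputs = .write_stage_tables(out_dir, det, means, gap, subgroups,
                                  symptoms)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  results$manifest <- manifest
  invisible(results)
}

.validate_pipeline_config <- function(config) {
  if (!is.list(config)) stop("pipeline config must be a list")
  if (is.null(config$seed)) stop("pipeline config is missing key: seed")
  if (is.null(config$simulate) && is.null(config$inputs))
    stop("pipeline config needs either key 'simulate' or key 'inputs'")
  known <- c("seed", "simulate", "inputs", "tier", "gap", "variance")
  bad <- setdiff(names(config), known)
  if (length(bad))
    stop("unknown pipeline config key(s): ", paste(bad, collapse = ", "))
  invisible(TRUE)
}

.load_inputs <- function(inputs) {
  for (p in c(inputs$patients, inputs$controls, inputs$cohort,
              vapply(inputs$aoes, `[[`, character(1), "path")))
    if (!file.exists(p)) stop("missing input file: ", p)
  patients <- lapply(inputs$patients, read_fa_volume)
  ref <- patients[[1]]
  controls <- lapply(inputs$controls, read_fa_volume, reference = ref)
  aoes <- lapply(inputs$aoes, function(a)
    read_aoe_mask(a$path, a$name, a$tier, reference = ref))
  cohort <- read_cohort_table(inputs$cohort)
  list(patients = patients, controls = controls, aoes = aoes,
       cohort = cohort, affine = ref$affine)
}

.input_hashes <- function(inputs) {
  if (is.null(inputs)) return(NULL)
  files <- c(inputs$patients, inputs$controls, inputs$cohort,
             vapply(inputs$aoes, `[[`, character(1), "path"))
  as.list(tools::md5sum(files))
}

.write_stage_tables <- function(out_dir, det, means, gap, subgroups,
                                symptoms) {
  paths <- list()
  w <- function(tbl, file) {
    p <- file.path(out_dir, file)
    utils::write.table(tbl, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  paths$cluster_table <- w(det$table, "cluster_table.tsv")
  if (length(means)) {
    mt <- do.call(rbind, lapply(seq_along(means), function(i)
      data.frame(cluster = i, aoe = means[[i]]$cluster$aoe_name,
                 subject_id = c(names(means[[i]]$patients),
                                names(means[[i]]$controls)),
                 group = rep(c("patient", "control"),
                             c(length(means[[i]]$patients),
                               length(means[[i]]$controls))),
                 mean_fa = c(means[[i]]$patients, means[[i]]$controls))))
    paths$cluster_means <- w(mt, "cluster_means.tsv")
  }
  if (!is.null(gap)) {
    g <- gap$result
    paths$gap_result <- file.path(out_dir, "gap_result.json")
    jsonlite::write_json(
      list(aoe = means[[gap$selected]]$cluster$aoe_name,
           max_ratio = g$max_ratio, standardized_gap = g$standardized_gap,
           boundary = g$boundary_values, n_below = g$n_below,
           n_above = g$n_above, p_gaussian = g$p_gaussian, p_t = g$p_t,
           df_t = g$df_t, n_sims = g$n_sims, calibration = g$calibration),
      paths$gap_result, auto_unbox = TRUE, digits = NA)
    paths$subgroup_labels <- w(
      data.frame(subject_id = names(gap$labels), subgroup = gap$labels),
      "subgroup_labels.tsv")
  }
  if (!is.null(subgroups))
    for (lb in names(subgroups))
      if (!is.null(subgroups[[lb]]))
        paths[[paste0("clusters_", lb)]] <-
          w(subgroups[[lb]]$table, sprintf("cluster_table_%s.tsv", lb))
  if (!is.null(symptoms)) paths$symptoms <- w(symptoms, "symptom_table.tsv")
  paths
}

#' Render a human-readable report of a pipeline run
#'
#' Formats the whole-cohort cluster table, the gap summary, the
#' per-subgroup cluster tables and the symptom table. Rendering is a pure
#' function of the stage outputs: regenerating the report from the same
#' run is idempotent.
#'
#' @param run A [run_pipeline()] result, or the `out_dir` of a previous
#'   run (its cached stages are read back).
#' @param path Optional file to write the report to.
#' @return The report, invisibly, as a character vector of lines.
#' @export
render_report <- function(run, path = NULL) {
  if (is.character(run) && length(run) == 1L) {
    cache <- file.path(run, "cache")
    run <- setNames(
      lapply(.stage_names, function(s) {
        f <- file.path(cache, paste0(s, ".rds"))
        if (file.exists(f)) readRDS(f) else NULL
      }), .stage_names)
  }
  if (all(vapply(run[.stage_names], is.null, logical(1))))
    stop("no stage outputs found")

  fmt_tbl <- function(tbl) {
    if (is.null(tbl) || !nrow(tbl)) return("  no clusters met threshold")
    num <- vapply(tbl, is.numeric, logical(1))
    tbl[num] <- lapply(tbl[num], function(x) signif(x, 4))
    paste0("  ", utils::capture.output(print(tbl, row.names = FALSE)))
  }
  lines <- c("FA group-contrast report", "========================", "")
  if (!is.null(run$contrast))
    lines <- c(lines, sprintf(
      "Whole-cohort contrast: %d vs %d subjects, %d evaluated voxels (%s variance)",
      run$contrast$group_sizes[1], run$contrast$group_sizes[2],
      sum(run$contrast$search_mask), run$contrast$variance), "")
  lines <- c(lines, "Whole-cohort clusters:", fmt_tbl(run$clusters$table), "")
  if (!is.null(run$gap)) {
    g <- run$gap$result
    lines <- c(lines, "Gapping analysis of per-subject cluster means:",
               sprintf("  maximal middle-gap ratio %.3f between %.6g and %.6g",
                       g$max_ratio, g$boundary_values[1], g$boundary_values[2]),
               sprintf("  %d subjects below the gap, %d above", g$n_below,
                       g$n_above),
               sprintf("  Monte-Carlo p: %.4g (Gaussian), %.4g (t, df = %d); %d sims, %s statistic",
                       g$p_gaussian, g$p_t, g$df_t, g$n_sims, g$calibration),
               "")
  } else {
    lines <- c(lines, "Gapping analysis: no primary-tier cluster met the extent requirement",
               "")
  }
  if (!is.null(run$subgroups))
    for (lb in names(run$subgroups)) {
      sg <- run$subgroups[[lb]]
      if (is.null(sg)) next
      lines <- c(lines, sprintf("Subgroup '%s' contrast (%d vs %d):", lb,
                                sg$group_sizes[1], sg$group_sizes[2]),
                 fmt_tbl(sg$table), "")
    }
  if (!is.null(run$symptoms))
    lines <- c(lines, "Symptom comparison between subgroups:",
               fmt_tbl(run$symptoms), "")
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
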
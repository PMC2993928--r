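# Cluster-mean extraction, subgroup re-contrasts, symptom comparisons.

test_that("cluster means are per-subject arithmetic means", {
  d <- c(5, 5, 5)
  vols <- make_cohort_vols(c(0.2, 0.5), dim = d)
  vox1 <- 1L
  expect_equal(unname(extract_cluster_means(vox1, vols)), c(0.2, 0.5))
  # constant volume -> mean c for any cluster
  mask <- array(FALSE, dim = d); mask[2:4, 2, 2] <- TRUE
  expect_equal(unname(extract_cluster_means(mask, vols)), c(0.2, 0.5))
  # two-voxel cluster averaging 0.2 and 0.4
  v <- make_vol(0.3, dim = d); v$data[1, 1, 1] <- 0.2; v$data[2, 1, 1] <- 0.4
  expect_equal(unname(extract_cluster_means(c(1L, 2L), list(v))), 0.3)
})

test_that("cluster means are linear in the volumes and skip missing voxels", {
  set.seed(14)
  d <- c(5, 5, 5)
  vols <- make_cohort_vols(runif(3, 0.2, 0.4), dim = d, jitter = 0.02,
                           seed = 15)
  vox <- sample(prod(d), 10)
  m1 <- extract_cluster_means(vox, vols)
  scaled <- lapply(vols, function(v) { v$data <- v$data * 0.5; v })
  expect_equal(extract_cluster_means(vox, scaled), 0.5 * m1, tolerance = 1e-12)

  vols[[2]]$data[vox[1]] <- NaN
  m2 <- extract_cluster_means(vox, vols)
  expect_equal(m2[[2]], mean(vols[[2]]$data[vox[-1]]))
  vols[[2]]$data[vox] <- NaN
  expect_error(extract_cluster_means(vox, vols), "missing-data exclusion")
  expect_error(extract_cluster_means(integer(0), vols), "empty")
})

test_that("the subgroup design pairs each patient with its own control", {
  tbl <- make_cohort_table(4)
  labels <- setNames(c("a", "a", "b", "b"), sprintf("P%02d", 1:4))
  des <- subgroup_design(tbl, labels)
  expect_equal(des$control_id, sprintf("C%02d", 1:4))
  expect_equal(des$subgroup, c("a", "a", "b", "b"))
  bad <- tbl[tbl$subject_id != "C03", ]
  expect_error(subgroup_design(bad, labels), "one-to-one")
  expect_error(subgroup_design(tbl, labels[-1]), "missing subgroup labels")
})

test_that("a subgroup equal to the full cohort reproduces the contrast", {
  sim <- generate_cohort(sim_config(grid_shape = c(12, 12, 12), n_pairs = 5,
                                    seed = 9))
  cfg <- tier_config()
  full <- detect_clusters(fa_contrast(sim$patients, sim$controls),
                          sim$aoes, cfg)
  des <- subgroup_design(sim$cohort,
                         setNames(rep("all", 5), sprintf("P%02d", 1:5)))
  sub <- subgroup_contrast(sim$patients, sim$controls, des, "all",
                           sim$aoes, cfg)
  expect_equal(sub$table, full$table)
  expect_equal(sub$group_sizes, c(n_patients = 5L, n_controls = 5L))

  one <- des; one$subgroup[1] <- "solo"
  expect_error(subgroup_contrast(sim$patients, sim$controls, one, "solo",
                                 sim$aoes, cfg), "single subject")
  expect_error(subgroup_contrast(sim$patients, sim$controls, des, "nope",
                                 sim$aoes, cfg), "no patients")
})

test_that("symptom comparison matches the hand-computed pooled t", {
  tbl <- make_cohort_table(6, stai_p = c(1, 2, 3, 4, 5, 6))
  labels <- setNames(rep(c("g1", "g2"), each = 3), sprintf("P%02d", 1:6))
  res <- symptom_compare(tbl, labels, measures = "STAI_T",
                         n_corrections = 5)
  expect_equal(res$t, -3.674, tolerance = 1e-3)
  expect_equal(res$df, 4)
  expect_equal(res$p, 0.0213, tolerance = 1e-3)
  expect_equal(res$threshold, 0.01)
  expect_false(res$significant)
  expect_equal(res$mean_1, 2)   # g1 = {1,2,3}
  expect_equal(res$mean_2, 5)
})

test_that("identical symptom distributions give t = 0 and p = 1", {
  tbl <- make_cohort_table(6, stai_p = rep(c(40, 50, 60), 2))
  labels <- setNames(rep(c("g1", "g2"), 3), sprintf("P%02d", 1:6))
  res <- symptom_compare(tbl, labels)
  expect_true(all(res$t[res$measure == "STAI_T"] == 0))
  expect_true(all(res$p[res$measure == "STAI_T"] == 1))
  expect_equal(unique(res$threshold), 0.01)
})

test_that("a measure missing in one subgroup is reported, not fatal", {
  tbl <- make_cohort_table(6, stai_p = c(60, 62, 64, 50, 52, 54))
  tbl$IDS_total[tbl$subject_id %in% sprintf("P%02d", 1:3)] <- NA
  labels <- setNames(rep(c("g1", "g2"), each = 3), sprintf("P%02d", 1:6))
  res <- symptom_compare(tbl, labels)
  row <- res[res$measure == "IDS_total", ]
  expect_true(is.na(row$t))
  expect_equal(row$n_1, 0)
  expect_false(anyNA(res[res$measure == "STAI_T", "p"]))
  # dfs reflect per-measure available cases
  tbl2 <- make_cohort_table(6, stai_p = c(60, 62, 64, 50, 52, 54))
  tbl2$IDS_sadness[tbl2$subject_id == "P01"] <- NA
  res2 <- symptom_compare(tbl2, labels)
  expect_equal(res2$df[res2$measure == "IDS_sadness"], 3)
  expect_equal(res2$df[res2$measure == "STAI_T"], 4)
})

test_that("STAI separates subgroups far more often than the IDS measures", {
  # at the planted symptom effect sizes the theoretical power of the
  # STAI comparison at the Bonferroni level is ~0.6 for 11-per-group
  # cohorts, so we check rates, not certainty: STAI must be flagged in a
  # clear majority of replicates and the (shared-distribution) IDS
  # measures at most rarely
  eff <- planted_effect(list(lo = c(6, 6, 6), hi = c(9, 9, 9)),
                        subgroup_fraction = 0.5, separation = 4)
  n_rep <- 40
  stai_hits <- 0; ids_hits <- 0
  for (i in seq_len(n_rep)) {
    # true latent labels drawn by the symptom model drive the comparison
    sim2 <- generate_cohort(sim_config(grid_shape = c(12, 12, 12),
                                       n_pairs = 22,
                                       effects = list(eff), seed = 300 + i))
    res <- symptom_compare(sim2$cohort,
                           setNames(sim2$truth$subgroup,
                                    names(sim2$truth$subgroup)))
    stai_hits <- stai_hits + isTRUE(res$significant[res$measure == "STAI_T"])
    ids_hits <- ids_hits +
      sum(res$significant[grepl("^IDS", res$measure)], na.rm = TRUE)
  }
  expect_gt(stai_hits / n_rep, 0.3)
  expect_lt(ids_hits / (3 * n_rep), 0.1)
})
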
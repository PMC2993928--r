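# Cluster detection, tier assignment and tiered Bonferroni correction.

test_that("corrected_threshold reproduces the tier thresholds exactly", {
  expect_equal(corrected_threshold(418, 9, 0.05), 0.05 * 9 / 418)
  expect_equal(round(corrected_threshold(418, 9, 0.05), 5), 0.00108)
  expect_equal(corrected_threshold(9308, 27, 0.05), 1.45e-4, tolerance = 1e-3)
  expect_equal(corrected_threshold(200000, 81, 0.05), 2.03e-5, tolerance = 3e-3)
})

test_that("corrected_threshold is homogeneous in alpha and N_search", {
  base <- corrected_threshold(1000, 10, 0.04)
  expect_equal(corrected_threshold(1000, 10, 0.08), 2 * base)
  expect_equal(corrected_threshold(2000, 10, 0.04), base / 2)
  expect_error(corrected_threshold(5, 9, 0.05), "exceeds")
  expect_error(corrected_threshold(10, 0, 0.05))
})

test_that("contiguity follows the edge-sharing rule, not corners", {
  d <- c(8, 8, 8)
  m <- array(FALSE, dim = d)
  m[2, 2, 2] <- TRUE
  cl <- find_clusters(make_statmap(m), tier_config())
  expect_length(cl, 1)
  expect_equal(cl[[1]]$size, 1)

  m2 <- array(FALSE, dim = d); m2[3:5, 3:5, 4] <- TRUE
  cl2 <- find_clusters(make_statmap(m2), tier_config())
  expect_length(cl2, 1)
  expect_equal(cl2[[1]]$size, 9)

  # corner contact only: two clusters under the default rule
  m3 <- array(FALSE, dim = d); m3[2, 2, 2] <- TRUE; m3[3, 3, 3] <- TRUE
  expect_length(find_clusters(make_statmap(m3), tier_config()), 2)
  expect_length(find_clusters(make_statmap(m3),
                              tier_config(connectivity = 26)), 1)

  # edge contact: one cluster at 18, two at 6
  m4 <- array(FALSE, dim = d); m4[2, 2, 2] <- TRUE; m4[3, 3, 2] <- TRUE
  expect_length(find_clusters(make_statmap(m4), tier_config()), 1)
  expect_length(find_clusters(make_statmap(m4),
                              tier_config(connectivity = 6)), 2)
})

test_that("opposite-sign voxels never join a cluster", {
  d <- c(6, 6, 6)
  m <- array(FALSE, dim = d); m[2:4, 3, 3] <- TRUE
  signs <- array(1, dim = d); signs[3, 3, 3] <- -1
  cl <- find_clusters(make_statmap(m, signs), tier_config())
  expect_length(cl, 3)
  expect_setequal(vapply(cl, `[[`, numeric(1), "sign"), c(1, 1, -1))
})

test_that("find_clusters agrees with a flood-fill oracle on random fields", {
  set.seed(77)
  for (conn in c(6, 18, 26)) {
    for (rep in 1:12) {
      d <- c(16, 16, 16)
      m <- array(runif(prod(d)) < 0.22, dim = d)
      cl <- find_clusters(make_statmap(m), tier_config(connectivity = conn))
      oracle <- flood_components(m, conn)
      oracle_sets <- component_sets(split(which(oracle > 0), oracle[oracle > 0]))
      got_sets <- component_sets(lapply(cl, `[[`, "voxels"))
      expect_identical(got_sets, oracle_sets)
    }
  }
})

test_that("clusters partition the suprathreshold set", {
  set.seed(88)
  d <- c(12, 12, 12)
  m <- array(runif(prod(d)) < 0.3, dim = d)
  signs <- array(sample(c(-1, 1), prod(d), replace = TRUE), dim = d)
  cl <- find_clusters(make_statmap(m, signs), tier_config())
  vox <- unlist(lapply(cl, `[[`, "voxels"))
  expect_equal(sort(vox), which(m))       # union equals the set
  expect_false(anyDuplicated(vox) > 0)    # pairwise disjoint
})

test_that("peak metadata identifies the most significant member voxel", {
  d <- c(6, 6, 6)
  m <- array(FALSE, dim = d); m[2:4, 2, 2] <- TRUE
  sm <- make_statmap(m)
  sm$p[3, 2, 2] <- 1e-5; sm$t[3, 2, 2] <- 6
  aff <- diag(c(2, 2, 2, 1)); aff[1:3, 4] <- c(-10, -10, -10)
  sm$affine <- aff
  cl <- find_clusters(sm, tier_config())[[1]]
  expect_equal(cl$peak_p, 1e-5)
  expect_equal(cl$peak_t, 6)
  expect_equal(cl$peak_vox, c(2, 1, 1))      # 0-based
  expect_equal(cl$peak_mm, c(-6, -8, -8))    # voxel centers through the affine
})

test_that("tier assignment needs a strict voxel majority inside the AOE", {
  d <- c(8, 8, 8)
  m <- array(FALSE, dim = d); m[2:5, 2, 2] <- TRUE   # 4-voxel cluster
  cl <- find_clusters(make_statmap(m), tier_config())[[1]]

  inside <- function(n_in, tier = "primary") {
    mask <- array(FALSE, dim = d)
    if (n_in > 0) mask[2:(1 + n_in), 2, 2] <- TRUE
    aoe_tier("roi", mask, tier)
  }
  expect_equal(assign_tier(cl, list(inside(4)))$tier, "primary")
  expect_equal(assign_tier(cl, list(inside(3)))$tier, "primary")     # 75%
  expect_equal(assign_tier(cl, list(inside(2)))$tier, "whole_brain") # exactly 50%
  expect_equal(assign_tier(cl, list(inside(1)))$tier, "whole_brain") # 25%
  # most lenient tier wins among multiple qualifying AOEs
  got <- assign_tier(cl, list(inside(3, "secondary"), inside(4, "primary")))
  expect_equal(got$tier, "primary")
  got2 <- assign_tier(cl, list(inside(3, "secondary")))
  expect_equal(got2$tier, "secondary")
  expect_equal(got2$aoe_name, "roi")
})

test_that("significance classes reproduce the tiered decision rule", {
  mk <- function(size, peak_p) structure(
    list(voxels = seq_len(size), size = size, sign = 1,
         peak_vox = c(0, 0, 0), peak_mm = c(0, 0, 0), peak_t = 3.5,
         peak_p = peak_p, tier = "primary", aoe_name = "roi"),
    class = "fa_cluster")
  cfg <- tier_config()
  expect_equal(classify_significance(mk(17, 0.000929), 418, cfg)$status,
               "significant")
  expect_equal(classify_significance(mk(9, 0.00264), 418, cfg)$status,
               "trend")
  expect_equal(classify_significance(mk(17, 0.5), 418, cfg)$status,
               "not_significant")
  expect_equal(classify_significance(mk(8, 0.000929), 418, cfg)$status,
               "not_significant")   # extent not met
})
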
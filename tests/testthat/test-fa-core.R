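# Core data model: FA formula, coordinates, containers, file round trips.

test_that("compute_fa matches the closed form and its limits", {
  expect_equal(compute_fa(1, 1, 1), 0)
  expect_equal(compute_fa(0.3, 0.3, 0.3), 0)
  expect_equal(compute_fa(1, 0, 0), 1)
  expect_equal(compute_fa(1, 0.5, 0.5), 0.408248, tolerance = 1e-6)
  # matrix input
  expect_equal(compute_fa(rbind(c(1, 1, 1), c(1, 0, 0))), c(0, 1))
})

test_that("compute_fa is scale- and permutation-invariant", {
  set.seed(11)
  for (i in 1:25) {
    l <- runif(3, 0.01, 3)
    c_ <- runif(1, 0.1, 10)
    expect_equal(compute_fa(c_ * l[1], c_ * l[2], c_ * l[3]),
                 compute_fa(l[1], l[2], l[3]), tolerance = 1e-12)
    p <- sample(3)
    expect_equal(compute_fa(l[p[1]], l[p[2]], l[p[3]]),
                 compute_fa(l[1], l[2], l[3]), tolerance = 1e-12)
  }
})

test_that("compute_fa rejects invalid eigenvalues", {
  expect_error(compute_fa(0, 0, 0), "undefined")
  expect_error(compute_fa(-1, 1, 1), "non-negative")
})

test_that("voxel/mm conversion applies the affine and round-trips", {
  expect_equal(voxel_to_mm(c(3, 4, 5), diag(4)), c(3, 4, 5))
  aff <- diag(c(-1, 1, 1, 1)); aff[1:3, 4] <- c(90, -126, -72)
  expect_equal(voxel_to_mm(c(0, 0, 0), aff), c(90, -126, -72))
  expect_equal(voxel_to_mm(c(10, 20, 30), aff), c(80, -106, -42))
  set.seed(2)
  aff2 <- diag(c(2, 2, 2, 1)); aff2[1:3, 4] <- rnorm(3); aff2[1, 2] <- 0.3
  pts <- matrix(runif(15, 0, 20), ncol = 3)
  expect_equal(mm_to_voxel(voxel_to_mm(pts, aff2), aff2), pts,
               tolerance = 1e-10)
  expect_error(voxel_to_mm(c(0, 0, 0), matrix(0, 4, 4)), "invertible")
})

test_that("fa_volume enforces the FA range with a clamping tolerance", {
  a <- array(0.5, dim = c(3, 3, 3))
  expect_s3_class(fa_volume(a), "fa_volume")
  a[1] <- 1 + 1e-8
  expect_warning(v <- fa_volume(a), "clamping")
  expect_equal(max(v$data), 1)
  a[1] <- 1.01
  expect_error(fa_volume(a), "outside")
  expect_error(fa_volume(array(0.5, dim = c(3, 3))), "3-dimensional")
})

test_that("volume round trips are lossless and reject bad shapes", {
  set.seed(4)
  aff <- diag(c(-2, 2, 2, 1)); aff[1:3, 4] <- c(20, -30, -10)
  a <- array(runif(64), dim = c(4, 4, 4))
  a[2, 3, 1] <- NaN
  v <- fa_volume(a, aff, subject_id = "T01")
  f <- tempfile(fileext = ".nii.gz")
  write_fa_volume(v, f)
  v2 <- read_fa_volume(f, subject_id = "T01")
  expect_identical(v2$data[!is.nan(a)], v$data[!is.nan(a)])
  expect_true(is.nan(v2$data[2, 3, 1]))
  expect_equal(v2$affine, aff, tolerance = 1e-6)

  # constant 4x4x4 volume of 0.5 survives exactly
  f2 <- tempfile(fileext = ".nii")
  write_fa_volume(make_vol(0.5, dim = c(4, 4, 4)), f2)
  expect_identical(as.vector(read_fa_volume(f2)$data), rep(0.5, 64))

  # a 4-D file is refused with the offending dimensionality named
  f3 <- tempfile(fileext = ".nii")
  RNifti::writeNifti(RNifti::asNifti(array(0, dim = c(3, 3, 3, 2))), f3)
  expect_error(read_fa_volume(f3), "4 dimensions")

  # declared reference grid is enforced
  expect_error(read_fa_volume(f, reference = make_vol(0.5, dim = c(5, 5, 5))),
               "grid mismatch")
})

test_that("cohort tables round-trip and matching is validated", {
  tbl <- make_cohort_table(4)
  f <- tempfile(fileext = ".tsv")
  write_cohort_table(tbl, f)
  tbl2 <- read_cohort_table(f)
  expect_equal(nrow(tbl2), nrow(tbl))
  expect_identical(vapply(tbl2, class, character(1)),
                   vapply(tbl, class, character(1)))

  bad <- tbl; bad$pair_id[2] <- "S01"
  expect_error(validate_cohort_table(bad), "unique")
  bad2 <- tbl; bad2$age[1] <- bad2$age[5] + 9
  expect_error(validate_cohort_table(bad2), "5 years of age")
  expect_silent(validate_cohort_table(bad2, matched = FALSE))
  expect_error(validate_cohort_table(tbl[-1, ]), "one-to-one")
})

test_that("tier configuration validates and loads from YAML and JSON", {
  cfg <- tier_config()
  expect_equal(cfg$k_cluster[["primary"]], 9)
  expect_equal(cfg$k_cluster[["secondary"]], 27)
  expect_equal(cfg$k_cluster[["whole_brain"]], 81)
  expect_equal(cfg$alpha, 0.05)
  expect_equal(cfg$trend_factor, 10)
  expect_error(tier_config(connectivity = 10), "6, 18 or 26")

  fy <- tempfile(fileext = ".yaml")
  writeLines(c("alpha: 0.01", "connectivity: 6",
               "k_cluster: {primary: 5, secondary: 10, whole_brain: 20}"), fy)
  cy <- read_tier_config(fy)
  expect_equal(cy$alpha, 0.01)
  expect_equal(cy$connectivity, 6L)
  expect_equal(cy$k_cluster[["secondary"]], 10)

  fj <- tempfile(fileext = ".json")
  writeLines('{"alpha": 0.02, "n_search_whole_brain": 200000}', fj)
  cj <- read_tier_config(fj)
  expect_equal(cj$alpha, 0.02)
  expect_equal(cj$n_search_whole_brain, 200000)
})
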
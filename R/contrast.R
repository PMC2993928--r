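# Mass-univariate two-sample t contrast between FA cohorts.

#' Voxel-based two-sample t contrast of FA maps
#'
#' Computes, at every evaluated voxel, the two-tailed two-sample t test of
#' patients versus controls. Positive t means the patient mean exceeds the
#' control mean at that voxel. The default is the classic pooled-variance
#' (Student) test with `df = n1 + n2 - 2`; Welch's unequal-variance test is
#' available behind the `variance` flag and recorded in the result.
#'
#' Voxels that are missing (`NaN`) in any subject, outside `mask`, or with
#' zero pooled variance are excluded from the search set; their t and p are
#' `NA`.
#'
#' @param patients,controls Lists of [fa_volume] on an identical grid, at
#'   least two subjects per group.
#' @param mask Optional logical array restricting the evaluated voxels.
#' @param variance `"pooled"` (default) or `"welch"`.
#' @return An object of class `fa_statmap` with fields `t`, `p` (arrays),
#'   `df` (scalar for pooled, array for Welch), `search_mask`,
#'   `group_sizes`, `variance`, `affine` and `dim`.
#' @export
fa_contrast <- function(patients, controls, mask = NULL,
                        variance = c("pooled", "welch")) {
  variance <- match.arg(variance)
  n1 <- length(patients); n2 <- length(controls)
  if (n1 < 2 || n2 < 2)
    stop("need at least two subjects per group (got ", n1, " vs ", n2, ")")
  .check_shared_grid(c(patients, controls))
  d <- dim(patients[[1]]$data)
  nv <- prod(d)
  if (!is.null(mask) && !identical(dim(mask), d))
    stop("grid mismatch: `mask` does not match the volumes")

  X <- vapply(patients, function(v) as.vector(v$data), numeric(nv))
  Y <- vapply(controls, function(v) as.vector(v$data), numeric(nv))
  m1 <- rowMeans(X); m2 <- rowMeans(Y)
  v1 <- rowSums((X - m1)^2) / (n1 - 1)
  v2 <- rowSums((Y - m2)^2) / (n2 - 1)
  ok <- rowSums(!is.finite(X)) == 0 & rowSums(!is.finite(Y)) == 0
  if (!is.null(mask)) ok <- ok & as.vector(mask)

  if (variance == "pooled") {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
    ok <- ok & is.finite(sp2) & sp2 > 0
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    tval <- (m1 - m2) / se
    pval <- 2 * pt(abs(tval), df, lower.tail = FALSE)
    dfout <- df
  } else {
    ok <- ok & is.finite(v1 + v2) & (v1 + v2) > 0
    se2 <- v1 / n1 + v2 / n2
    tval <- (m1 - m2) / sqrt(se2)
    dfv <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    pval <- 2 * pt(abs(tval), dfv, lower.tail = FALSE)
    dfv[!ok] <- NA_real_
    dfout <- array(dfv, dim = d)
  }
  tval[!ok] <- NA_real_
  pval[!ok] <- NA_real_

  structure(list(t = array(tval, dim = d), p = array(pval, dim = d),
                 df = dfout, search_mask = array(ok, dim = d),
                 group_sizes = c(n_patients = n1, n_controls = n2),
                 variance = variance,
                 affine = patients[[1]]$affine, dim = d),
            class = "fa_statmap")
}

#' @export
print.fa_statmap <- function(x, ...) {
  cat(sprintf(
    "<fa_statmap> %s grid, %d evaluated voxels, %d vs %d subjects (%s variance)\n",
    paste(x$dim, collapse = "x"), sum(x$search_mask),
    x$group_sizes[1], x$group_sizes[2], x$variance))
  invisible(x)
}
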
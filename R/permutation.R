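# Permutation validation of cluster-mean group differences, and the
# laterality comparison.

#' Permutation test of a group difference in cluster-mean values
#'
#' Tests the absolute difference of group means under unrestricted
#' relabelling of the subjects. When the number of distinct label
#' assignments `choose(n, n1)` does not exceed `n_perms` the test is
#' exhaustive; otherwise `n_perms - 1` random relabellings are drawn and
#' the identity labelling is included in both the numerator and the
#' denominator, so the reported p can never be zero.
#'
#' @param values Numeric vector of per-subject cluster means.
#' @param labels Vector with exactly two distinct values, one per subject.
#' @param n_perms Number of permutations (>= 1).
#' @param seed Optional seed for the Monte-Carlo branch.
#' @return List with `p`, `observed` (absolute mean difference),
#'   `n_perms_used` and `exhaustive`.
#' @export
permutation_validate <- function(values, labels, n_perms = 10000, seed = NULL) {
  if (n_perms < 1) stop("`n_perms` must be at least 1")
  stopifnot(length(values) == length(labels))
  groups <- unique(labels)
  if (length(groups) != 2) stop("`labels` must contain exactly two groups")
  g1 <- labels == groups[1]
  n <- length(values); n1 <- sum(g1)
  if (n1 < 2 || n - n1 < 2) stop("need at least two subjects per group")

  tot <- sum(values)
  absdiff <- function(idx1) {
    s1 <- sum(values[idx1])
    abs(s1 / n1 - (tot - s1) / (n - n1))
  }
  obs <- absdiff(which(g1))
  eps <- 1e-12 * (abs(obs) + 1)

  n_comb <- choose(n, n1)
  if (n_comb <= n_perms) {
    stats <- combn(n, n1, absdiff)
    p <- mean(stats >= obs - eps)
    list(p = p, observed = obs, n_perms_used = n_comb, exhaustive = TRUE)
  } else {
    if (!is.null(seed)) set.seed(seed)
    hits <- 1L  # the identity labelling
    for (i in seq_len(n_perms - 1L))
      if (absdiff(sample.int(n, n1)) >= obs - eps) hits <- hits + 1L
    list(p = hits / n_perms, observed = obs, n_perms_used = n_perms,
         exhaustive = FALSE)
  }
}

# t tests that tolerate zero-variance inputs (constructed or degenerate
# volumes give exactly identical region means).
.t1 <- function(x) {
  n <- length(x); m <- mean(x); s <- sd(x)
  if (s == 0) {
    t <- if (m == 0) 0 else sign(m) * Inf
  } else t <- m / (s / sqrt(n))
  p <- if (is.infinite(t)) 0 else 2 * pt(abs(t), n - 1, lower.tail = FALSE)
  list(t = t, df = n - 1, p = p)
}

.t2_pooled <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / df
  dm <- mean(x) - mean(y)
  if (sp2 == 0) {
    t <- if (dm == 0) 0 else sign(dm) * Inf
  } else t <- dm / sqrt(sp2 * (1 / n1 + 1 / n2))
  p <- if (is.infinite(t)) 0 else 2 * pt(abs(t), df, lower.tail = FALSE)
  list(t = t, df = df, p = p)
}

#' Laterality of regional FA in each group
#'
#' Computes, for every subject, the laterality index `(R - L) / (R + L)`
#' of the mean FA over a homologous pair of region masks, then tests the
#' index against zero within each group (two-tailed one-sample t) and
#' compares the indices between groups (two-tailed pooled two-sample t).
#' Positive indices indicate right-lateralised FA; swapping the masks
#' negates every index.
#'
#' @param patients,controls Lists of [fa_volume] on a shared grid.
#' @param left_mask,right_mask Logical arrays (or [aoe_tier]) selecting the
#'   homologous left and right regions; both must be non-empty.
#' @return List with per-subject `index_patients`, `index_controls`, a
#'   `within` data.frame (per-group test of index != 0), and `between`
#'   (test of the group difference in indices).
#' @export
laterality_compare <- function(patients, controls, left_mask, right_mask) {
  lm <- if (inherits(left_mask, "aoe_tier")) left_mask$mask else left_mask
  rm_ <- if (inherits(right_mask, "aoe_tier")) right_mask$mask else right_mask
  if (!sum(lm) || !sum(rm_)) stop("laterality masks must be non-empty")
  .check_shared_grid(c(patients, controls))

  idx <- function(vols) vapply(vols, function(v) {
    L <- mean(v$data[lm], na.rm = TRUE)
    R <- mean(v$data[rm_], na.rm = TRUE)
    (R - L) / (R + L)
  }, numeric(1))
  ip <- idx(patients); ic <- idx(controls)
  wp <- .t1(ip); wc <- .t1(ic)
  bt <- .t2_pooled(ip, ic)
  list(index_patients = ip, index_controls = ic,
       within = data.frame(group = c("patients", "controls"),
                           mean_index = c(mean(ip), mean(ic)),
                           t = c(wp$t, wc$t), df = c(wp$df, wc$df),
                           p = c(wp$p, wc$p)),
       between = bt)
}
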
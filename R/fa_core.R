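#' fagap: voxel-based FA group analysis with gap-based subgrouping
#'
#' Tools for comparing fractional anisotropy (FA) maps between two matched
#' cohorts voxel by voxel, detecting clusters of contiguous suprathreshold
#' voxels, correcting peak p-values with a tiered Bonferroni rule over
#' a priori areas of evaluation (AOEs), testing the distribution of
#' per-subject cluster-mean FA values for a gap that splits the patient
#' cohort into subgroups, re-contrasting each subgroup against its own
#' matched controls, and comparing symptom measures across subgroups.
#'
#' @importFrom stats pt rnorm rt runif sd dnorm setNames
#' @importFrom utils combn
#' @keywords internal
"_PACKAGE"

# ---------------------------------------------------------------------------
# Fractional anisotropy
# ---------------------------------------------------------------------------

#' Fractional anisotropy from diffusion-tensor eigenvalues
#'
#' Computes the standard fractional anisotropy
#' \deqn{FA = \sqrt{3/2}\,\sqrt{\sum_i(\lambda_i - \bar\lambda)^2 / \sum_i \lambda_i^2}}
#' from the three eigenvalues of a diffusion tensor. FA is 0 for an
#' isotropic tensor and 1 in the fully anisotropic limit.
#'
#' @param l1,l2,l3 Non-negative eigenvalues. Each may be a vector; they are
#'   recycled to a common length. Alternatively `l1` may be a length-3
#'   vector or an n-by-3 matrix, with `l2`, `l3` omitted.
#' @return FA value(s) in `[0, 1]`.
#' @examples
#' compute_fa(1, 1, 1)        # 0: isotropic
#' compute_fa(1, 0, 0)        # 1: a single non-zero eigenvalue
#' compute_fa(1, 0.5, 0.5)    # 0.408248
#' @export
compute_fa <- function(l1, l2, l3) {
  if (missing(l2) && missing(l3)) {
    m <- if (is.matrix(l1)) l1 else matrix(l1, nrow = 1L)
    if (ncol(m) != 3L) stop("eigenvalue input must have three columns")
    l1 <- m[, 1L]; l2 <- m[, 2L]; l3 <- m[, 3L]
  }
  n <- max(length(l1), length(l2), length(l3))
  l1 <- rep_len(l1, n); l2 <- rep_len(l2, n); l3 <- rep_len(l3, n)
  if (any(l1 < 0 | l2 < 0 | l3 < 0, na.rm = TRUE))
    stop("eigenvalues must be non-negative")
  ssq <- l1^2 + l2^2 + l3^2
  if (any(ssq == 0, na.rm = TRUE))
    stop("undefined input: all three eigenvalues are zero")
  lb <- (l1 + l2 + l3) / 3
  fa <- sqrt(1.5 * ((l1 - lb)^2 + (l2 - lb)^2 + (l3 - lb)^2) / ssq)
  # numerical noise can push the fully anisotropic limit fractionally past 1
  pmin(pmax(fa, 0), 1)
}

# ---------------------------------------------------------------------------
# FA volume container
# ---------------------------------------------------------------------------

#' FA volume on a shared grid
#'
#' A lightweight container for a 3-D scalar field of FA values together with
#' the 4x4 voxel-to-mm affine of its grid. All volumes entering one contrast
#' must share the same grid shape and affine. Values must lie in `[0, 1]`;
#' `NA`/`NaN` marks voxels without valid FA (e.g. outside the brain).
#' Out-of-range values caused by numerical noise (less than `1e-6` beyond a
#' bound) are clamped with a warning; larger violations are an error.
#'
#' @param data 3-D numeric array of FA values.
#' @param affine 4x4 matrix mapping 0-based voxel indices to mm coordinates.
#' @param subject_id Identifier carried through per-subject extraction.
#' @param space Free-text label of the stereotaxic space.
#' @return An object of class `fa_volume`.
#' @export
fa_volume <- function(data, affine = diag(4), subject_id = NA_character_,
                      space = "MNI-ICBM152") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-dimensional array, got ",
         length(dim(data)) %||% 1L, " dimension(s)")
  if (!is.matrix(affine) || !all(dim(affine) == c(4L, 4L)))
    stop("`affine` must be a 4x4 matrix")
  storage.mode(data) <- "double"
  finite <- is.finite(data)
  lo <- data < 0 & finite
  hi <- data > 1 & finite
  if (any(lo) || any(hi)) {
    worst <- max(c(-data[lo], data[hi] - 1), 0)
    if (worst >= 1e-6)
      stop(sprintf("FA values outside [0, 1] by up to %.3g", worst))
    warning("clamping FA values outside [0, 1] by < 1e-6 (numerical noise)")
    data[lo] <- 0
    data[hi] <- 1
  }
  structure(
    list(data = data, affine = affine, subject_id = subject_id, space = space),
    class = "fa_volume"
  )
}

#' @export
print.fa_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<fa_volume> subject %s, %d x %d x %d grid (%s), %d missing voxels\n",
              x$subject_id, d[1], d[2], d[3], x$space, sum(!is.finite(x$data))))
  invisible(x)
}

#' Area-of-evaluation mask with its hypothesis tier
#'
#' @param name Name of the anatomical region the mask covers.
#' @param mask Logical 3-D array on the shared grid.
#' @param tier One of `"primary"`, `"secondary"`, `"whole_brain"`.
#' @return An `aoe_tier` object; `n_voxels` is the count of TRUE voxels.
#' @export
aoe_tier <- function(name, mask, tier = c("primary", "secondary", "whole_brain")) {
  tier <- match.arg(tier)
  if (!is.array(mask) || length(dim(mask)) != 3L)
    stop("`mask` must be a 3-dimensional array")
  mask <- array(as.logical(mask), dim = dim(mask))
  if (anyNA(mask)) stop("`mask` must not contain NA")
  structure(list(name = name, mask = mask, tier = tier,
                 n_voxels = sum(mask)),
            class = "aoe_tier")
}

#' @export
print.aoe_tier <- function(x, ...) {
  cat(sprintf("<aoe_tier> %s (%s tier), %d voxels\n", x$name, x$tier, x$n_voxels))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Coordinates
# ---------------------------------------------------------------------------

#' Convert voxel indices to mm coordinates (and back)
#'
#' Voxel indices are 0-based, following the NIfTI convention used by the
#' stored affines. `voxel_to_mm` returns the mm coordinates of voxel
#' centers; `mm_to_voxel` applies the inverse affine.
#'
#' @param vox,mm Length-3 vector or n-by-3 matrix of coordinates.
#' @param affine 4x4 voxel-to-mm matrix; must be invertible.
#' @return Matrix (or vector, for a single point) of converted coordinates.
#' @export
voxel_to_mm <- function(vox, affine) {
  .check_affine(affine)
  v <- if (is.matrix(vox)) vox else matrix(vox, nrow = 1L)
  out <- cbind(v, 1) %*% t(affine)
  out <- out[, 1:3, drop = FALSE]
  if (!is.matrix(vox)) out <- drop(out)
  out
}

#' @rdname voxel_to_mm
#' @export
mm_to_voxel <- function(mm, affine) {
  .check_affine(affine)
  voxel_to_mm(mm, solve(affine))
}

.check_affine <- function(affine) {
  if (!is.matrix(affine) || !all(dim(affine) == c(4L, 4L)))
    stop("`affine` must be a 4x4 matrix")
  if (abs(det(affine)) < .Machine$double.eps * 64)
    stop("`affine` is not invertible")
  invisible(TRUE)
}

# shared-grid check used by every multi-subject operation
.check_shared_grid <- function(volumes, reference = NULL) {
  stopifnot(length(volumes) >= 1L)
  ref <- reference %||% volumes[[1L]]
  for (v in volumes) {
    if (!identical(dim(v$data), dim(ref$data)))
      stop("grid mismatch: volume '", v$subject_id, "' has shape ",
           paste(dim(v$data), collapse = "x"), ", expected ",
           paste(dim(ref$data), collapse = "x"))
    if (max(abs(v$affine - ref$affine)) > 1e-6)
      stop("grid mismatch: volume '", v$subject_id,
           "' has a different affine than the reference grid")
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
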
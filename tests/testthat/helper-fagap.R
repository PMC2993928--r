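# Shared fixtures and independent oracles, built in code.

# Quick fa_volume from an array (or a constant) on a default grid.
make_vol <- function(x, dim = c(6, 6, 6), affine = diag(4), id = "S01") {
  if (length(x) == 1L) x <- array(x, dim = dim)
  fa_volume(x, affine, subject_id = id)
}

# A list of volumes holding the given per-subject values at every voxel,
# plus independent per-voxel jitter so variances are non-degenerate.
make_cohort_vols <- function(values, dim = c(5, 5, 5), jitter = 0,
                             prefix = "S", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_along(values), function(i) {
    a <- array(values[i], dim = dim)
    if (jitter > 0) a <- a + array(rnorm(prod(dim), 0, jitter), dim = dim)
    make_vol(pmin(pmax(a, 0), 1), dim = dim, id = sprintf("%s%02d", prefix, i))
  })
}

# Hand-built stat map: p small inside `mask`, with t signs from `signs`
# (an array, defaulting to +1 everywhere).
make_statmap <- function(mask, signs = NULL, p_in = 0.01, p_out = 0.9,
                         affine = diag(4)) {
  d <- dim(mask)
  if (is.null(signs)) signs <- array(1, dim = d)
  p <- array(p_out, dim = d); p[mask] <- p_in
  t <- array(0.1, dim = d); t[mask] <- 3
  t <- t * signs
  structure(list(t = t, p = p, df = 42, search_mask = array(TRUE, dim = d),
                 group_sizes = c(n_patients = 22, n_controls = 22),
                 variance = "pooled", affine = affine, dim = d),
            class = "fa_statmap")
}

# Independent flood-fill oracle for connected components of a logical
# array: breadth-first search from scratch, no shared code with
# find_clusters().
flood_components <- function(mask, connectivity) {
  d <- dim(mask)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0 &
                 rowSums(abs(offs)) <= c("6" = 1, "18" = 2, "26" = 3)[[as.character(connectivity)]], ,
               drop = FALSE]
  comp <- array(0L, dim = d)
  cur <- 0L
  for (start in which(mask)) {
    if (comp[start] > 0L) next
    cur <- cur + 1L
    queue <- matrix(arrayInd(start, d), ncol = 3)
    comp[start] <- cur
    while (nrow(queue)) {
      v <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
      for (r in seq_len(nrow(offs))) {
        nb <- v + offs[r, ]
        if (any(nb < 1) || any(nb > d)) next
        lin <- nb[1] + (nb[2] - 1L) * d[1] + (nb[3] - 1L) * d[1] * d[2]
        if (mask[lin] && comp[lin] == 0L) {
          comp[lin] <- cur
          queue <- rbind(queue, nb)
        }
      }
    }
  }
  comp
}

# Canonical form of a component labelling: sorted list of sorted voxel sets.
component_sets <- function(voxel_list) {
  sets <- unname(lapply(voxel_list, function(v) as.integer(sort(v))))
  sets[order(vapply(sets, min, numeric(1)))]
}

# Minimal matched cohort table for n pairs with optional symptom values.
make_cohort_table <- function(n, stai_p = NULL, ids = NULL) {
  base <- function(prefix, group) data.frame(
    subject_id = sprintf("%s%02d", prefix, seq_len(n)), group = group,
    pair_id = sprintf("S%02d", seq_len(n)), age = 30 + seq_len(n),
    education = 14, sex = "F", handedness = "R",
    IDS_total = if (is.null(ids)) 30 else ids,
    IDS_anhedonia = 1, IDS_sadness = 2, IDS_psychomotor = 1,
    STAI_T = if (is.null(stai_p) || group == "control") 35 else stai_p)
  rbind(base("P", "patient"), base("C", "control"))
}

# Exhaustive permutation oracle via bitmask enumeration (independent of
# utils::combn used by the implementation).
perm_oracle <- function(values, n1) {
  n <- length(values)
  stats <- c()
  for (b in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(b))[1:n]
    if (sum(bits) != n1) next
    g1 <- values[bits == 1]; g2 <- values[bits == 0]
    stats <- c(stats, abs(mean(g1) - mean(g2)))
  }
  stats
}
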
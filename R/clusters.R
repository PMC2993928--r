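# Cluster detection, tier assignment and tiered Bonferroni inference.

#' Tiered Bonferroni corrected threshold
#'
#' The corrected peak-voxel threshold for a search area of `n_search`
#' voxels and a required cluster extent of `k` contiguous voxels is
#' `alpha / (n_search / k) = alpha * k / n_search`: the Bonferroni
#' correction counts the number of non-overlapping clusters of size `k`
#' that fit in the search volume. With the default tiers this gives
#' 0.05/(418/9) = 0.00108 (primary), 0.05/(9308/27) = 1.45e-4 (secondary)
#' and 0.05/(200000/81) = 2.03e-5 (whole brain).
#'
#' @param n_search Total voxels in the tier's search area.
#' @param k Required cluster extent for the tier.
#' @param alpha Base significance level.
#' @return The corrected peak-voxel p threshold.
#' @export
corrected_threshold <- function(n_search, k, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1, k >= 1, n_search >= 1)
  if (k > n_search)
    stop("required cluster size k exceeds the search volume")
  alpha * k / n_search
}

# Neighbourhood offsets for the contiguity rule. 18-connectivity (voxels
# sharing a face or an edge, never only a corner) is the default reading of
# the edge-sharing rule in 3-D.
connectivity_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  lim <- switch(as.character(connectivity),
                "6" = 1L, "18" = 2L, "26" = 3L,
                stop("`connectivity` must be 6, 18 or 26"))
  g[rowSums(abs(g)) <= lim, , drop = FALSE]
}

#' Find clusters of contiguous suprathreshold voxels
#'
#' Builds the maximal connected components of same-sign voxels with
#' uncorrected `p < voxel_p_threshold` inside the search mask, under the
#' configured contiguity rule (18-neighbourhood by default: voxels sharing
#' a face or an edge count as contiguous, voxels touching only at a corner
#' do not). Positive and negative differences form separate clusters.
#' Components smaller than every tier's extent requirement are still
#' returned; [classify_significance()] flags them.
#'
#' @param statmap An [fa_contrast()] result.
#' @param config A [tier_config()].
#' @return A list of `fa_cluster` objects, each with `voxels` (linear
#'   indices), `size`, `sign`, `peak_vox` (0-based index triple),
#'   `peak_mm`, `peak_t`, `peak_p`.
#' @export
find_clusters <- function(statmap, config = tier_config()) {
  stopifnot(inherits(statmap, "fa_statmap"))
  d <- statmap$dim
  supra <- statmap$search_mask & !is.na(statmap$p) &
    statmap$p < config$voxel_p_threshold
  offs <- connectivity_offsets(config$connectivity)
  # half-neighbourhood: each undirected adjacency counted once
  offs <- offs[offs[, 1] + 3 * offs[, 2] + 9 * offs[, 3] > 0, , drop = FALSE]

  clusters <- list()
  for (sgn in c(1, -1)) {
    sel <- which(supra & sign(statmap$t) == sgn)
    if (!length(sel)) next
    ids <- array(0L, dim = d)
    ids[sel] <- seq_along(sel)
    co <- arrayInd(sel, d)
    edges <- integer(0)
    for (r in seq_len(nrow(offs))) {
      nb <- co + rep(offs[r, ], each = nrow(co))
      inside <- nb[, 1] >= 1 & nb[, 1] <= d[1] &
                nb[, 2] >= 1 & nb[, 2] <= d[2] &
                nb[, 3] >= 1 & nb[, 3] <= d[3]
      if (!any(inside)) next
      nlin <- nb[inside, 1] + (nb[inside, 2] - 1L) * d[1] +
        (nb[inside, 3] - 1L) * d[1] * d[2]
      nid <- ids[nlin]
      hit <- nid > 0L
      if (any(hit))
        edges <- c(edges, rbind(which(inside)[hit], nid[hit]))
    }
    gr <- igraph::make_empty_graph(n = length(sel), directed = FALSE)
    if (length(edges)) gr <- igraph::add_edges(gr, edges)
    comp <- igraph::components(gr)
    for (ci in seq_len(comp$no)) {
      members <- sel[comp$membership == ci]
      pv <- statmap$p[members]
      tv <- statmap$t[members]
      best <- which(pv == min(pv))
      if (length(best) > 1) best <- best[which.max(abs(tv[best]))]
      peak_lin <- members[best]
      peak_ijk0 <- arrayInd(peak_lin, d) - 1L
      clusters[[length(clusters) + 1L]] <- structure(
        list(voxels = members, size = length(members), sign = sgn,
             peak_vox = drop(peak_ijk0),
             peak_mm = drop(voxel_to_mm(peak_ijk0, statmap$affine)),
             peak_t = tv[best], peak_p = pv[best]),
        class = "fa_cluster")
    }
  }
  clusters[order(-vapply(clusters, `[[`, integer(1), "size"))]
}

#' Assign a cluster to an area of evaluation and its tier
#'
#' A cluster belongs to an AOE if and only if strictly more than 50% of its
#' voxels fall inside that AOE's mask. If several AOEs qualify, the most
#' lenient tier wins (primary over secondary over whole-brain); exactly 50%
#' does not qualify, and a cluster qualifying for no AOE is evaluated at
#' the whole-brain tier.
#'
#' @param cluster An `fa_cluster`.
#' @param aoes List of [aoe_tier] masks on the cluster's grid.
#' @return The cluster with `tier` and `aoe_name` fields set.
#' @export
assign_tier <- function(cluster, aoes) {
  stopifnot(inherits(cluster, "fa_cluster"))
  rank <- c(primary = 1L, secondary = 2L, whole_brain = 3L)
  best_rank <- rank[["whole_brain"]]
  best_name <- "whole_brain"
  best_frac <- 0
  for (a in aoes) {
    frac <- mean(a$mask[cluster$voxels])
    if (frac > 0.5) {
      r <- rank[[a$tier]]
      if (r < best_rank || (r == best_rank && frac > best_frac)) {
        best_rank <- r; best_name <- a$name; best_frac <- frac
      }
    }
  }
  cluster$tier <- names(rank)[best_rank]
  cluster$aoe_name <- best_name
  cluster
}

# Search-volume sizes per tier: the total voxel count over that tier's AOE
# masks; the whole-brain tier defaults to the evaluated-voxel count of the
# search mask unless the configuration fixes a constant.
tier_search_sizes <- function(aoes, search_mask, config) {
  sizes <- c(primary = 0, secondary = 0, whole_brain = 0)
  for (a in aoes)
    if (a$tier %in% c("primary", "secondary"))
      sizes[[a$tier]] <- sizes[[a$tier]] + a$n_voxels
  sizes[["whole_brain"]] <- config$n_search_whole_brain %||% sum(search_mask)
  sizes
}

#' Classify a cluster as significant, trend, or not significant
#'
#' A cluster is `significant` when its extent meets the tier's cluster
#' requirement and its peak uncorrected p falls below the tier's corrected
#' threshold; a `trend` when the peak p misses the corrected threshold by
#' less than one order of magnitude (factor `trend_factor`); otherwise
#' `not_significant`.
#'
#' @param cluster An `fa_cluster` with a tier assigned.
#' @param n_search Search-volume size of the cluster's tier.
#' @param config A [tier_config()].
#' @return The cluster with `status` and `corrected_threshold` set.
#' @export
classify_significance <- function(cluster, n_search, config = tier_config()) {
  stopifnot(inherits(cluster, "fa_cluster"), !is.null(cluster$tier))
  k <- config$k_cluster[[cluster$tier]]
  thr <- corrected_threshold(n_search, k, config$alpha)
  cluster$corrected_threshold <- thr
  cluster$status <-
    if (cluster$size < k) "not_significant"
    else if (cluster$peak_p < thr) "significant"
    else if (cluster$peak_p < config$trend_factor * thr) "trend"
    else "not_significant"
  cluster
}

#' Detect, tier and classify all clusters of a contrast
#'
#' Convenience wrapper chaining [find_clusters()], [assign_tier()] and
#' [classify_significance()] and tabulating the result in the layout of a
#' published cluster table: region, peak mm coordinates, peak t and
#' uncorrected p, extent, tier and significance class.
#'
#' @inheritParams find_clusters
#' @param aoes List of [aoe_tier].
#' @return A list with `clusters` (list of classified `fa_cluster`) and
#'   `table` (data.frame, one row per cluster, ordered by tier then peak p).
#' @export
detect_clusters <- function(statmap, aoes, config = tier_config()) {
  cl <- find_clusters(statmap, config)
  sizes <- tier_search_sizes(aoes, statmap$search_mask, config)
  cl <- lapply(cl, function(x) {
    x <- assign_tier(x, aoes)
    classify_significance(x, sizes[[x$tier]], config)
  })
  tbl <- cluster_table(cl)
  list(clusters = cl, table = tbl, n_search = sizes)
}

#' @rdname detect_clusters
#' @param clusters List of classified `fa_cluster` objects.
#' @export
cluster_table <- function(clusters) {
  if (!length(clusters))
    return(data.frame(aoe = character(), tier = character(),
                      peak_x_mm = numeric(), peak_y_mm = numeric(),
                      peak_z_mm = numeric(), peak_t = numeric(),
                      peak_p = numeric(), size = integer(),
                      corrected_threshold = numeric(), status = character()))
  tbl <- do.call(rbind, lapply(clusters, function(x)
    data.frame(aoe = x$aoe_name %||% NA_character_,
               tier = x$tier %||% NA_character_,
               peak_x_mm = x$peak_mm[1], peak_y_mm = x$peak_mm[2],
               peak_z_mm = x$peak_mm[3],
               peak_t = x$peak_t, peak_p = x$peak_p, size = x$size,
               corrected_threshold = x$corrected_threshold %||% NA_real_,
               status = x$status %||% NA_character_)))
  tier_rank <- match(tbl$tier, c("primary", "secondary", "whole_brain"))
  tbl[order(tier_rank, tbl$peak_p), , drop = FALSE]
}
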
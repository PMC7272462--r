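#' Hub identification by ranked betweenness centrality
#'
#' For each subject group, per-node betweenness centrality is averaged over
#' the group's subjects, every node is ranked 1..n (n = highest betweenness),
#' and the top 10% of ranks (9 of 90 nodes on a 90-region parcellation) are
#' classified as network hubs. Hub sets are then compared across groups.
#'
#' @name hubs
NULL

#' Group mean betweenness
#'
#' Arithmetic mean of per-subject betweenness vectors, node by node.
#'
#' @param b matrix (subjects x nodes) or list of equal-length named vectors.
#' @return named numeric vector of per-node means.
#' @export
group_mean_betweenness <- function(b) {
  if (is.list(b)) {
    if (length(b) == 0) stop("empty group: no betweenness vectors")
    labs <- names(b[[1]])
    for (v in b)
      if (length(v) != length(b[[1]]) || !identical(names(v), labs))
        stop("betweenness vectors must share the same parcellation")
    b <- do.call(rbind, b)
  }
  if (!is.matrix(b) || nrow(b) == 0) stop("empty group: no betweenness vectors")
  colMeans(b)
}

#' Rank nodes by a measure
#'
#' Ascending ranks 1..n: the node with the highest value receives rank n.
#' Ties are broken by node index (lower index gets the lower rank), so the
#' ranking is fully deterministic.
#'
#' @param values per-node numeric vector.
#' @return integer vector of ranks, a permutation of `1..n`.
#' @export
rank_nodes <- function(values) {
  if (length(values) < 1) stop("empty value vector")
  if (anyNA(values) || any(!is.finite(values)))
    stop("values must be finite to be ranked")
  r <- rank(values, ties.method = "first")
  storage.mode(r) <- "integer"
  names(r) <- names(values)
  r
}

#' Identify hub nodes from a ranking
#'
#' The `floor(fraction * n)` nodes with the highest ranks are classified as
#' hubs (9 nodes for the default 10% rule on 90 regions).
#'
#' @param ranks integer ranks from [rank_nodes()].
#' @param fraction top fraction classified as hubs, in (0, 1).
#' @return indices (or names, if `ranks` is named) of the hub nodes, in
#'   decreasing rank order.
#' @export
identify_hubs <- function(ranks, fraction = 0.10) {
  n <- length(ranks)
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  k <- floor(fraction * n)
  if (k < 1)
    stop("hub fraction ", fraction, " selects no nodes for n = ", n)
  sel <- which(ranks > n - k)
  sel <- sel[order(ranks[sel], decreasing = TRUE)]
  if (!is.null(names(ranks))) names(ranks)[sel] else sel
}

#' Per-group hub ranking table
#'
#' @param betweenness matrix (subjects x nodes) of betweenness vectors for
#'   one group, or a list of vectors.
#' @param group group label recorded in the output.
#' @param fraction hub fraction, see [identify_hubs()].
#' @return data.frame: group, node, mean_betweenness, rank, is_hub.
#' @export
hub_ranking <- function(betweenness, group = "group", fraction = 0.10) {
  mb <- group_mean_betweenness(betweenness)
  r <- rank_nodes(mb)
  identify_hubs(r, fraction = fraction)  # validates the fraction/n combination
  k <- floor(fraction * length(mb))
  node <- if (!is.null(names(mb))) names(mb) else as.character(seq_along(mb))
  data.frame(group = group, node = node, mean_betweenness = unname(mb),
             rank = unname(r), is_hub = unname(r) > length(mb) - k,
             row.names = NULL)
}

#' Hub-set overlap across groups
#'
#' @param hub_sets named list of per-group hub node sets.
#' @return list with `shared` (nodes that are hubs in every group), `unique`
#'   (per group, hubs found in no other group), `union` (hubs in any group),
#'   and `union_size`.
#' @export
hub_overlap <- function(hub_sets) {
  if (length(hub_sets) < 2) stop("need at least two groups to compare hubs")
  shared <- Reduce(intersect, hub_sets)
  uni <- Reduce(union, hub_sets)
  uniq <- lapply(seq_along(hub_sets), function(i) {
    others <- Reduce(union, hub_sets[-i])
    setdiff(hub_sets[[i]], others)
  })
  names(uniq) <- names(hub_sets)
  list(shared = shared, unique = uniq, union = uni, union_size = length(uni))
}

#' Per-group hub sets of a cohort of count matrices
#'
#' Builds each subject's weighted network, computes betweenness centrality,
#' and returns the per-group hub rankings and hub sets. A lighter-weight
#' alternative to [run_pipeline()] when only hubs are needed.
#'
#' @param matrices named list of streamline-count matrices.
#' @param groups character vector of group labels aligned with `matrices`.
#' @param which_groups groups to process (default: all present).
#' @param fraction hub fraction.
#' @param min_streamlines noise threshold for network construction.
#' @return list with `rankings` (per-group data.frames from [hub_ranking()])
#'   and `hub_sets` (per-group node index vectors).
#' @export
cohort_hub_sets <- function(matrices, groups, which_groups = NULL,
                            fraction = 0.10, min_streamlines = 10) {
  stopifnot(length(matrices) == length(groups))
  if (is.null(which_groups)) which_groups <- sort(unique(groups))
  rankings <- lapply(which_groups, function(g) {
    idx <- which(groups == g)
    b <- t(vapply(idx, function(i) {
      net <- build_network(matrices[[i]], min_streamlines = min_streamlines)
      unname(betweenness_centrality(net))
    }, numeric(nrow(matrices[[1]]))))
    hub_ranking(b, group = g, fraction = fraction)
  })
  names(rankings) <- which_groups
  hub_sets <- lapply(rankings, function(r) which(r$is_hub))
  list(rankings = rankings, hub_sets = hub_sets)
}
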
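#' Weighted graph-theory measures
#'
#' The measures used throughout the analysis, computed on weighted undirected
#' networks: strength (centrality), global efficiency and characteristic path
#' length (integration), clustering coefficient and local efficiency
#' (segregation), and betweenness centrality (the basis for hub
#' identification). Shortest paths are computed over edge lengths
#' `l_ij = 1 / w_ij` (strong connections are short), the convention of the
#' standard brain-connectivity toolboxes; `-log(w)` is available as an
#' alternative mapping.
#'
#' @name graph-measures
NULL

# Accept either a weighted_network or a plain weight matrix.
.as_weights <- function(x) {
  if (inherits(x, "weighted_network")) return(x$weights)
  validate_count_matrix(x, what = "weight matrix")
  if (max(abs(x - t(x))) > 1e-9 * max(abs(x), 1))
    stop("weight matrix must be symmetric")
  x
}

#' Map edge weights to edge lengths
#'
#' @param W symmetric nonnegative weight matrix.
#' @param map `"inverse"` for `1/w` or `"neglog"` for `-log(w)` (requires all
#'   weights in (0, 1]).
#' @return length matrix with `Inf` where no edge exists and 0 on the diagonal.
#' @keywords internal
weight_to_length <- function(W, map = c("inverse", "neglog")) {
  map <- match.arg(map)
  L <- matrix(Inf, nrow(W), ncol(W))
  pos <- W > 0
  if (map == "inverse") {
    L[pos] <- 1 / W[pos]
  } else {
    if (any(W[pos] > 1))
      stop("neglog length mapping requires weights in (0, 1]")
    L[pos] <- -log(W[pos])
  }
  diag(L) <- 0
  L
}

# Single-source Dijkstra over a length matrix (Inf = no edge).
.dijkstra_row <- function(L, s) {
  n <- nrow(L)
  dist <- rep(Inf, n)
  dist[s] <- 0
  done <- logical(n)
  for (i in seq_len(n)) {
    cand <- dist
    cand[done] <- Inf
    u <- which.min(cand)
    if (!is.finite(cand[u])) break
    done[u] <- TRUE
    nd <- dist[u] + L[u, ]
    upd <- !done & nd < dist
    dist[upd] <- nd[upd]
  }
  dist
}

.all_pairs_dist <- function(L) {
  n <- nrow(L)
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) D[s, ] <- .dijkstra_row(L, s)
  D
}

#' All-pairs shortest path lengths
#'
#' Dijkstra's algorithm from every source over edge lengths `1/w` (or
#' `-log w`). Unreachable pairs are `Inf`; the diagonal is 0.
#'
#' @param x a `weighted_network` or symmetric weight matrix.
#' @param map weight-to-length mapping, see [weight_to_length()].
#' @return symmetric numeric matrix of shortest-path lengths.
#' @export
shortest_paths <- function(x, map = c("inverse", "neglog")) {
  W <- .as_weights(x)
  .all_pairs_dist(weight_to_length(W, match.arg(map)))
}

#' Node strength
#'
#' Sum of the weights of all edges incident to each node. With `raw = TRUE`
#' the strength is reported in raw streamline counts
#' (pre-normalization), which is the scale on which group comparisons of
#' strength are usually reported.
#'
#' @param x a `weighted_network` or weight matrix.
#' @param raw if `TRUE` and `x` is a `weighted_network`, use raw counts.
#' @return named numeric vector of per-node strengths.
#' @export
node_strength <- function(x, raw = FALSE) {
  W <- if (raw && inherits(x, "weighted_network")) raw_counts(x) else .as_weights(x)
  rowSums(W)
}

.geff_from_dist <- function(D) {
  n <- nrow(D)
  if (n < 2) return(0)
  inv <- 1 / D
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0  # unreachable pairs contribute 0
  sum(inv) / (n * (n - 1))
}

#' Global efficiency
#'
#' Average inverse shortest-path length over ordered node pairs; pairs of
#' disconnected nodes (infinitely long paths) contribute 0, so the measure is
#' defined for fragmented networks as well.
#'
#' @param x a `weighted_network` or weight matrix.
#' @param D optional precomputed distance matrix from [shortest_paths()].
#' @inheritParams shortest_paths
#' @return scalar efficiency.
#' @export
global_efficiency <- function(x, D = NULL, map = "inverse") {
  if (is.null(D)) D <- shortest_paths(x, map = map)
  .geff_from_dist(D)
}

#' Characteristic path length
#'
#' Mean shortest-path length over reachable ordered node pairs; unreachable
#' pairs are excluded (rather than entering as infinite lengths).
#'
#' @inheritParams global_efficiency
#' @return scalar path length.
#' @export
characteristic_path_length <- function(x, D = NULL, map = "inverse") {
  if (is.null(D)) D <- shortest_paths(x, map = map)
  off <- D[row(D) != col(D)]
  fin <- off[is.finite(off)]
  if (length(fin) == 0)
    stop("characteristic path length undefined: no reachable node pair")
  mean(fin)
}

#' Nodal efficiency
#'
#' Per-node average inverse shortest-path length to every other node
#' (unreachable pairs contribute 0): how efficiently a single region reaches
#' the rest of the network. The mean of nodal efficiency over nodes equals
#' global efficiency.
#'
#' @inheritParams global_efficiency
#' @param nodes optional integer or character subset of nodes to evaluate
#'   (only the needed single-source problems are solved).
#' @return named numeric vector.
#' @export
nodal_efficiency <- function(x, nodes = NULL, D = NULL, map = "inverse") {
  W <- .as_weights(x)
  n <- nrow(W)
  labels <- rownames(W)
  if (is.null(nodes)) nodes <- seq_len(n)
  if (is.character(nodes)) nodes <- match(nodes, labels)
  if (anyNA(nodes) || any(nodes < 1 | nodes > n)) stop("unknown node selection")
  if (is.null(D)) {
    L <- weight_to_length(W, map)
    rows <- lapply(nodes, function(s) .dijkstra_row(L, s))
  } else {
    rows <- lapply(nodes, function(s) D[s, ])
  }
  out <- vapply(seq_along(nodes), function(i) {
    d <- rows[[i]][-nodes[i]]
    inv <- 1 / d
    inv[!is.finite(inv)] <- 0
    mean(inv)
  }, numeric(1))
  names(out) <- labels[nodes]
  out
}

#' Weighted clustering coefficient
#'
#' Geometric-mean (Onnela-type) weighted clustering: with weights scaled to
#' `[0, 1]` by the network maximum, `C_i = sum_{j,h} (w_ij w_ih w_jh)^(1/3) /
#' (k_i (k_i - 1))`, where `k_i` is the binary degree. Nodes with fewer than
#' two neighbors have `C_i = 0`. This is the weighted-undirected clustering
#' used by the standard brain-connectivity toolbox.
#'
#' @param x a `weighted_network` or weight matrix.
#' @return named numeric vector of per-node coefficients in `[0, 1]`.
#' @export
clustering_coefficient <- function(x) {
  W <- .as_weights(x)
  n <- nrow(W)
  mx <- max(W)
  C <- numeric(n)
  names(C) <- rownames(W)
  if (mx <= 0) return(C)
  A <- (W / mx)^(1 / 3)
  k <- rowSums(W > 0)
  cyc <- diag(A %*% A %*% A)
  idx <- k >= 2
  C[idx] <- cyc[idx] / (k[idx] * (k[idx] - 1))
  C
}

#' Local efficiency
#'
#' For each node, the global efficiency of the subgraph induced by its
#' neighbors (nodes it connects to with positive weight); 0 for nodes with
#' fewer than two neighbors. Measures the fault tolerance of each node's
#' neighborhood.
#'
#' @inheritParams clustering_coefficient
#' @inheritParams shortest_paths
#' @return named numeric vector.
#' @export
local_efficiency <- function(x, map = "inverse") {
  W <- .as_weights(x)
  n <- nrow(W)
  out <- numeric(n)
  names(out) <- rownames(W)
  for (i in seq_len(n)) {
    nb <- which(W[i, ] > 0)
    if (length(nb) < 2) next
    sub <- W[nb, nb, drop = FALSE]
    out[i] <- .geff_from_dist(.all_pairs_dist(weight_to_length(sub, map)))
  }
  out
}

# Brandes betweenness over a length matrix; equal-length path multiplicities
# are shared, endpoints excluded, undirected double counting halved.
.brandes <- function(L, tol = 1e-12) {
  n <- nrow(L)
  bc <- numeric(n)
  for (s in seq_len(n)) {
    dist <- .dijkstra_row(L, s)
    reach <- which(is.finite(dist))
    ord <- reach[order(dist[reach])]
    sigma <- numeric(n)
    sigma[s] <- 1
    preds <- vector("list", n)
    for (v in ord) {
      if (v == s) next
      du <- dist + L[, v]
      p <- which(is.finite(du) &
                   abs(du - dist[v]) <= tol * pmax(1, abs(dist[v])) &
                   dist < dist[v])
      preds[[v]] <- p
      sigma[v] <- sum(sigma[p])
    }
    delta <- numeric(n)
    for (v in rev(ord)) {
      if (v == s) next
      p <- preds[[v]]
      if (length(p))
        delta[p] <- delta[p] + sigma[p] / sigma[v] * (1 + delta[v])
    }
    delta[s] <- 0
    bc <- bc + delta
  }
  bc / 2
}

#' Betweenness centrality
#'
#' Brandes' algorithm on shortest paths under edge lengths `1/w`: for each
#' node, the number of all-pairs shortest paths that pass through it
#' (endpoints excluded), with equal-length shortest paths sharing their
#' multiplicity. High-betweenness nodes carry a large share of the network's
#' shortest routes and are the basis of hub identification.
#'
#' @inheritParams shortest_paths
#' @param tol relative tolerance for comparing floating-point path lengths.
#' @return named numeric vector of per-node betweenness.
#' @export
betweenness_centrality <- function(x, map = "inverse", tol = 1e-12) {
  W <- .as_weights(x)
  bc <- .brandes(weight_to_length(W, map), tol = tol)
  names(bc) <- rownames(W)
  bc
}

#' All measures for a single network
#'
#' @param net a `weighted_network`.
#' @param regional_efficiency which per-node efficiency to tabulate under the
#'   measure name `"efficiency"`: neighborhood `"local"` efficiency (default)
#'   or single-node `"nodal"` efficiency.
#' @param map weight-to-length mapping.
#' @return list with `global` (named numeric vector: `strength_raw`,
#'   `strength`, `global_efficiency`, `clustering`, `cpl`) and `nodal`
#'   (data.frame: node, strength_raw, strength, betweenness, clustering,
#'   efficiency).
#' @export
network_measures <- function(net, regional_efficiency = c("local", "nodal"),
                             map = "inverse") {
  regional_efficiency <- match.arg(regional_efficiency)
  D <- shortest_paths(net, map = map)
  s_raw <- node_strength(net, raw = TRUE)
  s_norm <- node_strength(net)
  cc <- clustering_coefficient(net)
  bc <- betweenness_centrality(net, map = map)
  eff <- switch(regional_efficiency,
                local = local_efficiency(net, map = map),
                nodal = nodal_efficiency(net, D = D))
  list(
    global = c(strength_raw = mean(s_raw),
               strength = mean(s_norm),
               global_efficiency = .geff_from_dist(D),
               clustering = mean(cc),
               cpl = characteristic_path_length(net, D = D)),
    nodal = data.frame(node = net$labels,
                       strength_raw = unname(s_raw),
                       strength = unname(s_norm),
                       betweenness = unname(bc),
                       clustering = unname(cc),
                       efficiency = unname(eff),
                       row.names = NULL)
  )
}

#' Long-format measure table for a cohort of networks
#'
#' @param networks named list of `weighted_network` objects (names are
#'   subject ids); all networks must share the same parcellation.
#' @inheritParams network_measures
#' @return data.frame with columns `subject_id`, `scope` ("global" or
#'   "node"), `node` (`NA` for global rows), `measure`, `value`.
#' @export
measure_table <- function(networks, regional_efficiency = c("local", "nodal"),
                          map = "inverse") {
  stopifnot(length(networks) >= 1)
  ids <- names(networks)
  if (is.null(ids)) ids <- sprintf("sub%03d", seq_along(networks))
  labels <- networks[[1]]$labels
  for (net in networks)
    if (!identical(net$labels, labels))
      stop("all networks must share the same parcellation labels")
  rows <- lapply(seq_along(networks), function(i) {
    m <- network_measures(networks[[i]], regional_efficiency, map)
    gl <- data.frame(subject_id = ids[i], scope = "global", node = NA_character_,
                     measure = names(m$global), value = unname(m$global),
                     row.names = NULL)
    nd <- m$nodal
    long <- do.call(rbind, lapply(setdiff(names(nd), "node"), function(ms) {
      data.frame(subject_id = ids[i], scope = "node", node = nd$node,
                 measure = ms, value = nd[[ms]], row.names = NULL)
    }))
    rbind(gl, long)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Min-max normalization of a measure table
#'
#' Linearly rescales each measure (within its scope) to `[0, 1]` across the
#' whole cohort, so measures on very different native scales can be examined
#' together. The affine mapping parameters are recorded in the `"scaling"`
#' attribute. A constant measure is mapped to 0, with a warning.
#' One-way ANOVA F statistics and Pearson correlations are invariant under
#' this per-measure affine map, so group statistics are unchanged by it.
#'
#' @param table a measure table from [measure_table()].
#' @return the table with `value` rescaled; attribute `"scaling"` holds a
#'   data.frame of (scope, measure, min, max).
#' @export
normalize_measures <- function(table) {
  stopifnot(all(c("scope", "measure", "value") %in% names(table)))
  key <- interaction(table$scope, table$measure, drop = TRUE)
  parts <- split(seq_len(nrow(table)), key)
  sc <- data.frame(scope = character(0), measure = character(0),
                   min = numeric(0), max = numeric(0))
  for (idx in parts) {
    v <- table$value[idx]
    lo <- min(v); hi <- max(v)
    if (hi > lo) {
      table$value[idx] <- (v - lo) / (hi - lo)
    } else {
      warning("measure '", table$measure[idx[1]], "' (", table$scope[idx[1]],
              ") is constant across the cohort; scaled to 0")
      table$value[idx] <- 0
    }
    sc <- rbind(sc, data.frame(scope = table$scope[idx[1]],
                               measure = table$measure[idx[1]],
                               min = lo, max = hi))
  }
  attr(table, "scaling") <- sc
  table
}
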
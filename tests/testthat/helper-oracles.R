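# Independent brute-force oracles for the weighted graph measures.
# Deliberately naive: Floyd-Warshall for distances, triple loops for
# clustering, explicit subgraphs for local efficiency, exhaustive simple-path
# enumeration for betweenness. Only usable on tiny graphs.

rand_graph <- function(n, density = 0.6, wmax = 1) {
  W <- matrix(0, n, n)
  ut <- upper.tri(W)
  on <- stats::runif(sum(ut)) < density
  w <- stats::runif(sum(ut), min = 0.05, max = wmax)
  W[ut] <- on * w
  W + t(W)
}

oracle_lengths <- function(W) {
  L <- matrix(Inf, nrow(W), ncol(W))
  L[W > 0] <- 1 / W[W > 0]
  diag(L) <- 0
  L
}

oracle_floyd <- function(W) {
  D <- oracle_lengths(W)
  n <- nrow(D)
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

oracle_geff <- function(W) {
  D <- oracle_floyd(W)
  n <- nrow(D)
  tot <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (is.finite(D[i, j])) tot <- tot + 1 / D[i, j]
  }
  tot / (n * (n - 1))
}

oracle_cpl <- function(W) {
  D <- oracle_floyd(W)
  vals <- D[row(D) != col(D)]
  mean(vals[is.finite(vals)])
}

oracle_clustering <- function(W) {
  n <- nrow(W)
  Wh <- W / max(W)
  C <- numeric(n)
  for (i in seq_len(n)) {
    k <- sum(W[i, ] > 0)
    if (k < 2) next
    tot <- 0
    for (j in seq_len(n)) for (h in seq_len(n)) {
      if (j == i || h == i || j == h) next
      tot <- tot + (Wh[i, j] * Wh[i, h] * Wh[j, h])^(1 / 3)
    }
    C[i] <- tot / (k * (k - 1))
  }
  C
}

oracle_local_eff <- function(W) {
  n <- nrow(W)
  out <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(W[i, ] > 0)
    if (length(nb) < 2) next
    out[i] <- oracle_geff(W[nb, nb, drop = FALSE])
  }
  out
}

# exhaustive enumeration of simple paths between every unordered pair;
# equal-length shortest paths share multiplicity, endpoints excluded
oracle_betweenness <- function(W, tol = 1e-9) {
  n <- nrow(W)
  L <- oracle_lengths(W)
  adj <- lapply(seq_len(n), function(i) which(W[i, ] > 0))
  b <- numeric(n)
  for (s in seq_len(n - 1)) for (t in seq(s + 1, n)) {
    paths <- list()
    lens <- numeric(0)
    walk <- function(v, visited, len) {
      if (v == t) {
        paths[[length(paths) + 1]] <<- visited
        lens[length(lens) + 1] <<- len
        return(invisible())
      }
      for (u in adj[[v]]) {
        if (u %in% visited) next
        walk(u, c(visited, u), len + L[v, u])
      }
    }
    walk(s, s, 0)
    if (!length(lens)) next
    dmin <- min(lens)
    sel <- which(lens <= dmin + tol * max(1, dmin))
    for (k in sel) {
      interior <- setdiff(paths[[k]], c(s, t))
      b[interior] <- b[interior] + 1 / length(sel)
    }
  }
  b
}

# small convenience: per-subject global measure vectors for a cohort
cohort_global_measures <- function(coh, what = c("strength_raw"),
                                   threshold = 10) {
  out <- lapply(names(coh$matrices), function(id) {
    net <- build_network(coh$matrices[[id]], min_streamlines = threshold)
    vals <- c()
    if ("strength_raw" %in% what)
      vals["strength_raw"] <- mean(node_strength(net, raw = TRUE))
    if ("global_efficiency" %in% what)
      vals["global_efficiency"] <- global_efficiency(net)
    if ("clustering" %in% what)
      vals["clustering"] <- mean(clustering_coefficient(net))
    vals
  })
  m <- do.call(rbind, out)
  data.frame(subject_id = names(coh$matrices),
             group = coh$metadata$group, m, row.names = NULL)
}
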
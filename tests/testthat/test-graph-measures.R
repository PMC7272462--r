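# Small named builders used across blocks
triangle <- function(w = 1) {
  m <- matrix(w, 3, 3); diag(m) <- 0; m
}
chain3 <- function() {
  m <- matrix(0, 3, 3); m[1, 2] <- m[2, 1] <- 1; m[2, 3] <- m[3, 2] <- 1; m
}

test_that("node strength sums incident weights", {
  expect_equal(unname(node_strength(triangle())), c(2, 2, 2))
  m <- matrix(0, 3, 3)
  m[1, 2] <- m[2, 1] <- 2
  m[1, 3] <- m[3, 1] <- 3
  expect_equal(unname(node_strength(m)), c(5, 2, 3))
  set.seed(21)
  W <- rand_graph(6)
  expect_equal(node_strength(W), rowSums(W))
})

test_that("shortest paths use the inverse-weight length convention", {
  D <- shortest_paths(chain3())
  expect_equal(D[1, 3], 2)        # two unit-length hops
  e <- matrix(0, 2, 2); e[1, 2] <- e[2, 1] <- 2
  expect_equal(shortest_paths(e)[1, 2], 0.5)   # l = 1/w
  set.seed(22)
  for (rep in 1:25) {
    W <- rand_graph(sample(4:8, 1), density = stats::runif(1, 0.3, 0.9))
    expect_equal(shortest_paths(W), oracle_floyd(W), tolerance = 1e-12)
  }
})

test_that("global efficiency and CPL match definitions and oracles", {
  expect_equal(global_efficiency(triangle()), 1)       # all distances 1
  expect_equal(global_efficiency(matrix(0, 4, 4)), 0)  # edgeless
  expect_equal(characteristic_path_length(triangle()), 1)
  expect_equal(characteristic_path_length(chain3()), 4 / 3)
  expect_error(characteristic_path_length(matrix(0, 3, 3)), "no reachable")
  set.seed(23)
  for (rep in 1:20) {
    W <- rand_graph(sample(4:8, 1), density = stats::runif(1, 0.3, 0.9))
    if (sum(W) == 0) next
    expect_equal(global_efficiency(W), oracle_geff(W), tolerance = 1e-10)
    expect_equal(characteristic_path_length(W), oracle_cpl(W),
                 tolerance = 1e-10)
  }
})

test_that("nodal efficiency averages to global efficiency", {
  set.seed(24)
  W <- rand_graph(7, density = 0.7)
  ne <- nodal_efficiency(W)
  expect_equal(mean(ne), global_efficiency(W), tolerance = 1e-12)
  # subsetted computation agrees with the full one
  expect_equal(nodal_efficiency(W, nodes = c(2, 5)), ne[c(2, 5)])
})

test_that("weighted clustering matches the geometric-mean form", {
  expect_equal(unname(clustering_coefficient(triangle())), c(1, 1, 1))
  star <- matrix(0, 5, 5)
  star[1, 2:5] <- star[2:5, 1] <- 1
  expect_equal(unname(clustering_coefficient(star)), rep(0, 5))  # no triangles
  set.seed(25)
  for (rep in 1:20) {
    W <- rand_graph(7, density = stats::runif(1, 0.4, 0.9))
    if (sum(W) == 0) next
    expect_equal(unname(clustering_coefficient(W)), oracle_clustering(W),
                 tolerance = 1e-10)
  }
})

test_that("local efficiency is the neighborhood subgraph efficiency", {
  expect_equal(unname(local_efficiency(triangle())), c(1, 1, 1))
  expect_equal(unname(local_efficiency(chain3()))[2], 0)  # A, C unconnected
  set.seed(26)
  for (rep in 1:15) {
    W <- rand_graph(sample(5:8, 1), density = stats::runif(1, 0.4, 0.9))
    expect_equal(unname(local_efficiency(W)), oracle_local_eff(W),
                 tolerance = 1e-10)
  }
})

test_that("betweenness follows Brandes accumulation with shared ties", {
  expect_equal(unname(betweenness_centrality(chain3())), c(0, 1, 0))
  star <- matrix(0, 5, 5)
  star[1, 2:5] <- star[2:5, 1] <- 1
  expect_equal(unname(betweenness_centrality(star)), c(6, 0, 0, 0, 0))
  # two equal-length routes share the multiplicity
  sq <- matrix(0, 4, 4)
  sq[1, 2] <- sq[2, 1] <- 1; sq[2, 3] <- sq[3, 2] <- 1
  sq[1, 4] <- sq[4, 1] <- 1; sq[4, 3] <- sq[3, 4] <- 1
  expect_equal(unname(betweenness_centrality(sq)), rep(0.5, 4))
  set.seed(27)
  for (rep in 1:20) {
    W <- rand_graph(sample(4:7, 1), density = stats::runif(1, 0.4, 0.9))
    expect_equal(unname(betweenness_centrality(W)), oracle_betweenness(W),
                 tolerance = 1e-9)
  }
})

test_that("path-based measures agree with an independent graph library", {
  set.seed(28)
  for (rep in 1:10) {
    W <- rand_graph(8, density = 0.6)
    if (sum(W) == 0) next
    g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
    len <- 1 / igraph::E(g)$weight
    expect_equal(unname(shortest_paths(W)),
                 unname(igraph::distances(g, weights = len)),
                 tolerance = 1e-10)
    expect_equal(unname(betweenness_centrality(W)),
                 unname(igraph::betweenness(g, weights = len)),
                 tolerance = 1e-8)
  }
})

test_that("measures are permutation-equivariant and scale as expected", {
  set.seed(29)
  W <- rand_graph(8, density = 0.6)
  p <- sample(8)
  Wp <- W[p, p]
  expect_equal(unname(node_strength(Wp)), unname(node_strength(W))[p])
  expect_equal(unname(betweenness_centrality(Wp)),
               unname(betweenness_centrality(W))[p], tolerance = 1e-9)
  expect_equal(unname(clustering_coefficient(Wp)),
               unname(clustering_coefficient(W))[p], tolerance = 1e-12)
  expect_equal(global_efficiency(Wp), global_efficiency(W), tolerance = 1e-12)
  # uniform scaling: strength scales, max-scaled clustering and betweenness
  # (an ordering property) are invariant
  c_ <- 3.7
  expect_equal(node_strength(W * c_), node_strength(W) * c_)
  expect_equal(clustering_coefficient(W * c_), clustering_coefficient(W),
               tolerance = 1e-12)
  expect_equal(betweenness_centrality(W * c_), betweenness_centrality(W),
               tolerance = 1e-9)
})

test_that("adding an edge never decreases global efficiency", {
  set.seed(30)
  for (rep in 1:10) {
    W <- rand_graph(7, density = 0.4)
    absent <- which(W == 0 & upper.tri(W), arr.ind = TRUE)
    if (nrow(absent) == 0) next
    pick <- absent[sample(nrow(absent), 1), ]
    W2 <- W
    W2[pick[1], pick[2]] <- W2[pick[2], pick[1]] <- stats::runif(1, 0.1, 1)
    expect_gte(global_efficiency(W2), global_efficiency(W) - 1e-12)
  }
})

test_that("measure table is long-format, consistent and serializable", {
  set.seed(31)
  tpl <- generate_template(n_nodes = 12, edge_density = 0.6, mean_count = 200,
                           seed = 5)
  net <- build_network(tpl)
  tab <- measure_table(list(a = net, b = net, c = net))
  expect_equal(sort(unique(tab$subject_id)), c("a", "b", "c"))
  # identical networks give identical rows per subject
  va <- tab$value[tab$subject_id == "a"]
  vb <- tab$value[tab$subject_id == "b"]
  expect_equal(va, vb)
  # 5 global + 5 nodal measures x 12 nodes per subject
  expect_equal(nrow(tab), 3 * (5 + 5 * 12))
  f <- tempfile(fileext = ".csv")
  utils::write.csv(tab, f, row.names = FALSE)
  back <- utils::read.csv(f, stringsAsFactors = FALSE)
  expect_equal(back$value, tab$value, tolerance = 1e-12)
  expect_equal(back$measure, tab$measure)
  # label mismatch across subjects is an error
  net2 <- build_network(tpl, labels = sprintf("x%02d", 1:12))
  expect_error(measure_table(list(a = net, b = net2)), "parcellation")
})

test_that("min-max normalization is idempotent and F-invariant", {
  tab <- data.frame(subject_id = rep(c("a", "b", "c", "d"), 2),
                    scope = "global", node = NA_character_,
                    measure = rep(c("m1", "m2"), each = 4),
                    value = c(2, 3, 4, 2.5, 10, 10, 10, 10))
  expect_warning(norm <- normalize_measures(tab), "constant")
  expect_equal(norm$value[1:4], c(0, 0.5, 1, 0.25))
  expect_equal(norm$value[5:8], rep(0, 4))
  norm2 <- suppressWarnings(normalize_measures(norm))
  expect_equal(norm2$value, norm$value)  # idempotent
  # ANOVA F unchanged by the affine rescaling
  set.seed(32)
  vals <- rnorm(30)
  groups <- rep(c("a", "b", "c"), each = 10)
  scaled <- (vals - min(vals)) / (max(vals) - min(vals))
  f1 <- anova_oneway(split(vals, groups))
  f2 <- anova_oneway(split(scaled, groups))
  expect_equal(f1$F, f2$F, tolerance = 1e-10)
  expect_equal(f1$p, f2$p, tolerance = 1e-10)
})
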
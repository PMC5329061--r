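# Nodal measures: closed-form fixtures, brute-force oracle agreement on
# random graphs, and structural invariants. The exhaustive oracle sweep
# over every non-isomorphic small graph lives in test-acceptance.R.

star4 <- function() {
  m <- matrix(0, 4, 4); m[1, 2:4] <- m[2:4, 1] <- 1
  build_graph(connectivity_matrix(m))
}
k4 <- function() build_graph(connectivity_matrix(matrix(1, 4, 4) - diag(4)))
path3 <- function() {
  m <- matrix(0, 3, 3); m[1, 2] <- m[2, 1] <- 1; m[2, 3] <- m[3, 2] <- 1
  build_graph(connectivity_matrix(m))
}
cycle4 <- function() {
  m <- matrix(0, 4, 4)
  for (e in list(c(1, 2), c(2, 3), c(3, 4), c(4, 1))) {
    m[e[1], e[2]] <- m[e[2], e[1]] <- 1
  }
  build_graph(connectivity_matrix(m))
}

test_that("closed-form fixture values are reproduced", {
  expect_equal(unname(node_closeness(star4())), c(1, 0.6, 0.6, 0.6))
  expect_equal(unname(node_closeness(k4())), rep(1, 4))
  expect_equal(unname(node_betweenness(star4())), c(3, 0, 0, 0))
  expect_equal(unname(node_betweenness(path3())), c(0, 1, 0))
  ev <- unname(node_eigenvector(star4()))
  expect_equal(ev, c(sqrt(3), 1, 1, 1) / sqrt(6))
  expect_equal(sum(ev^2), 1)
  expect_equal(unname(node_eigenvector(
    build_graph(connectivity_matrix(matrix(c(0, 1, 1, 0), 2))))),
    rep(1 / sqrt(2), 2))
  tri <- matrix(2, 3, 3) - diag(2, 3)
  expect_equal(unname(node_eigenvector(build_graph(connectivity_matrix(tri)))),
               rep(1 / sqrt(3), 3))
  expect_equal(unname(node_hits(star4())),
               c(sqrt(3), 1, 1, 1) / (sqrt(3) + 3))
  expect_equal(unname(node_hits(k4())), rep(0.25, 4))
  expect_equal(unname(node_degree(k4())), rep(1, 4))
  expect_equal(unname(node_degree(star4())), c(1, 1 / 3, 1 / 3, 1 / 3))
  expect_equal(unname(node_clustering(k4())), rep(1, 4))
  expect_equal(unname(node_clustering(star4())), rep(0, 4))
  expect_equal(unname(node_efficiency(path3())), c(0.75, 1, 0.75))
  expect_equal(unname(node_efficiency(k4())), rep(1, 4))
  expect_equal(unname(node_pagerank(k4())), rep(0.25, 4))
  expect_equal(unname(node_load(star4())), c(6, 0, 0, 0))
  expect_equal(unname(node_load(path3())), c(0, 2, 0))
  expect_equal(unname(node_redundancy(cycle4())), rep(1, 4))
  expect_equal(unname(node_redundancy(star4())), rep(0, 4))
  expect_equal(unname(node_redundancy(k4())), rep(1, 4))
})

test_that("Katz closed form matches hand computation and series limit", {
  k2 <- build_graph(connectivity_matrix(matrix(c(0, 1, 1, 0), 2)))
  # (I - A/2)^{-1} = [[4/3, 2/3], [2/3, 4/3]]; row sums - 1 = 1
  expect_equal(unname(node_katz(k2, alpha = 0.5)), c(1, 1))
  expect_error(node_katz(k2, alpha = 1), "diverges")
  # alpha -> 0: leading term alpha * weighted degree
  set.seed(11)
  m <- random_weight_matrix(6, 0.6)
  g <- graph_from_matrix(m)
  a <- 1e-6
  expect_equal(unname(node_katz(g, alpha = a)), a * rowSums(m),
               tolerance = 1e-4)
  # truncated-series oracle on random graphs
  for (seed in 1:5) {
    set.seed(seed)
    m <- random_weight_matrix(6, 0.5)
    if (all(m == 0)) next
    g <- graph_from_matrix(m)
    lmax <- max(eigen(m, symmetric = TRUE, only.values = TRUE)$values)
    alpha <- 0.5 / lmax
    expect_equal(unname(node_katz(g, alpha = alpha)),
                 oracle_katz(m, alpha), tolerance = 1e-8)
  }
})

test_that("measures agree with brute-force oracles on random graphs", {
  for (seed in 1:8) {
    set.seed(seed)
    m <- random_weight_matrix(7, 0.45)
    g <- graph_from_matrix(m)
    expect_equal(unname(node_closeness(g)), oracle_closeness(m),
                 tolerance = 1e-10)
    expect_equal(unname(node_betweenness(g)), oracle_betweenness(m),
                 tolerance = 1e-10)
    expect_equal(unname(node_load(g)), oracle_load(m), tolerance = 1e-10)
    expect_equal(unname(node_efficiency(g)), oracle_efficiency(m),
                 tolerance = 1e-10)
    expect_equal(unname(node_clustering(g)), oracle_clustering(m),
                 tolerance = 1e-10)
    expect_equal(unname(node_redundancy(g)), oracle_redundancy(m),
                 tolerance = 1e-10)
    expect_equal(unname(node_pagerank(g)), oracle_pagerank(m),
                 tolerance = 1e-8)
    if (any(m > 0)) {
      expect_equal(unname(node_eigenvector(g)), oracle_eigenvector(m),
                   tolerance = 1e-8)
      expect_equal(unname(node_hits(g)), oracle_hits(m), tolerance = 1e-8)
    }
  }
})

test_that("inverse-weight distances drive all shortest-path measures", {
  cfg <- measure_config(edge_length = "inverse_weight",
                        expected_nodes = NULL)
  set.seed(21)
  for (seed in 1:4) {
    set.seed(seed)
    m <- random_weight_matrix(6, 0.6)
    g <- graph_from_matrix(m)
    expect_equal(unname(node_closeness(g, cfg)),
                 oracle_closeness(m, "inverse_weight"), tolerance = 1e-9)
    expect_equal(unname(node_betweenness(g, cfg)),
                 oracle_betweenness(m, "inverse_weight"), tolerance = 1e-9)
    expect_equal(unname(node_efficiency(g, cfg)),
                 oracle_efficiency(m, "inverse_weight"), tolerance = 1e-9)
    expect_equal(unname(node_load(g, cfg)),
                 oracle_load(m, "inverse_weight"), tolerance = 1e-9)
  }
})

test_that("load equals twice betweenness on trees", {
  # unique shortest paths => ordered-pair flow = 2 x unordered-pair count
  set.seed(5)
  for (i in 1:5) {
    n <- 8
    m <- matrix(0, n, n)
    for (v in 2:n) {
      u <- sample(v - 1, 1)
      m[u, v] <- m[v, u] <- 1
    }
    g <- graph_from_matrix(m)
    expect_equal(unname(node_load(g)), 2 * unname(node_betweenness(g)))
  }
})

test_that("PageRank is a probability vector and matches igraph", {
  for (seed in 1:5) {
    set.seed(seed)
    m <- random_weight_matrix(9, 0.4)
    g <- graph_from_matrix(m)
    pr <- node_pagerank(g)
    expect_equal(sum(pr), 1, tolerance = 1e-10)
    if (igraph::ecount(g) > 0 && all(igraph::degree(g) > 0)) {
      expect_equal(unname(pr),
                   igraph::page_rank(g, damping = 0.85)$vector,
                   ignore_attr = TRUE, tolerance = 1e-6)
    }
  }
})

test_that("degenerate graphs follow the finite-value conventions", {
  empty <- build_graph(connectivity_matrix(matrix(0, 5, 5)))
  expect_equal(unname(node_closeness(empty)), rep(0, 5))
  expect_equal(unname(node_efficiency(empty)), rep(0, 5))
  expect_equal(unname(node_pagerank(empty)), rep(0.2, 5))
  expect_equal(unname(node_eigenvector(empty)), rep(0, 5))
  cfg_err <- measure_config(on_degenerate = "error")
  expect_error(node_eigenvector(empty, cfg_err), "eigenvector undefined")
  expect_error(node_hits(empty, cfg_err), "no edges")
  # isolated node in an otherwise connected graph
  m <- matrix(0, 4, 4); m[1, 2] <- m[2, 1] <- 1; m[2, 3] <- m[3, 2] <- 1
  g <- graph_from_matrix(m)
  expect_equal(unname(node_closeness(g))[4], 0)
  expect_equal(unname(node_efficiency(g))[4], 0)
  expect_equal(unname(node_eigenvector(g))[4], 0)
})

test_that("adding an edge never decreases endpoint degree; bounded measures stay in [0,1]", {
  set.seed(33)
  for (i in 1:10) {
    m <- random_weight_matrix(8, 0.4)
    g <- graph_from_matrix(m)
    zero <- which(m == 0 & upper.tri(m), arr.ind = TRUE)
    if (nrow(zero) == 0) next
    pick <- zero[sample(nrow(zero), 1), ]
    m2 <- m
    m2[pick[1], pick[2]] <- m2[pick[2], pick[1]] <- 3
    g2 <- graph_from_matrix(m2)
    expect_true(all(node_degree(g2)[c(pick)] >= node_degree(g)[c(pick)]))
    for (f in list(node_degree, node_clustering, node_redundancy)) {
      expect_true(all(f(g2) >= 0 & f(g2) <= 1))
    }
  }
})

test_that("feature vector has fixed length, order and label-keyed layout", {
  cfg <- measure_config()
  set.seed(8)
  m <- random_weight_matrix(41, 0.3)
  cm <- connectivity_matrix(m, subject_id = "fv")
  fv <- feature_vector(build_graph(cm), cfg)
  expect_length(fv, 451)
  expect_true(all(is.finite(fv)))
  expect_true(startsWith(names(fv)[1], "closeness_"))
  expect_true(startsWith(names(fv)[451], "redundancy_"))
  expect_equal(unique(sub("_.*", "", names(fv))), measure_names())

  # permuting node order (labels attached) leaves the vector unchanged
  perm <- sample(41)
  cm2 <- connectivity_matrix(m[perm, perm],
                             node_labels = cm$node_labels[perm],
                             subject_id = "fv")
  fv2 <- feature_vector(build_graph(cm2), cfg)
  expect_equal(fv2[names(fv)], fv[names(fv)])

  expect_error(feature_vector(star4(), cfg), "expected 41")

  # empty graph: every feature finite, shortest-path measures zero
  fv0 <- feature_vector(build_graph(connectivity_matrix(matrix(0, 41, 41))))
  expect_true(all(is.finite(fv0)))
  expect_true(all(fv0[grep("^(closeness|betweenness|load|efficiency|eigenvector|hits)_",
                           names(fv0))] == 0))
})

test_that("feature vectors are deterministic across repeated computation", {
  set.seed(13)
  m <- random_weight_matrix(41, 0.3)
  g <- graph_from_matrix(m)
  expect_identical(feature_vector(g), feature_vector(g))
})

test_that("cohort feature table carries ids, groups and 451 columns", {
  co <- generate_cohort(synthetic_cohort_config(n_per_class = 2, seed = 2))
  ft <- cohort_features(co)
  expect_equal(dim(ft), c(6, 453))
  expect_equal(ft$group, co$subjects$group)
  expect_false(anyNA(ft))
})
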
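# Eleven nodal network measures on weighted undirected brain graphs, and
# their assembly into the per-subject feature vector (41 nodes x 11
# measures = 451 entries, measure-major order).
#
# Distance convention: fiber counts are similarities, not costs, so all
# shortest-path measures (closeness, betweenness, efficiency, load) use
# binary hop distances by default; `edge_length = "inverse_weight"` maps
# each edge to length 1/W_ij instead. Spectral measures (eigenvector,
# Katz, HITS, PageRank) always act on the weighted adjacency matrix.

#' Configuration for nodal graph measures
#'
#' @param edge_length Length convention for shortest-path measures:
#'   `"hop"` (every edge has length 1, the default — fiber counts are
#'   similarities) or `"inverse_weight"` (length `1/W_ij`).
#' @param katz_alpha Katz attenuation factor; `NULL` (default) sets
#'   `katz_alpha_factor / lambda_max` per graph, which keeps the series
#'   convergent on every input.
#' @param katz_alpha_factor Fraction of `1/lambda_max` used when
#'   `katz_alpha` is `NULL`.
#' @param pagerank_damping PageRank damping factor (canonical 0.85).
#' @param hits_tol L1 convergence tolerance of the HITS iteration.
#' @param hits_max_iter Maximum HITS iterations before an error.
#' @param expected_nodes Node count enforced by [feature_vector()]
#'   (41 in the reference design); `NULL` disables the check.
#' @param on_degenerate What spectral measures do on an edgeless graph:
#'   `"zero"` (return all zeros, the feature-vector default, keeping every
#'   feature finite) or `"error"`.
#' @return A list of class `measure_config`.
#' @export
measure_config <- function(edge_length = c("hop", "inverse_weight"),
                           katz_alpha = NULL, katz_alpha_factor = 0.85,
                           pagerank_damping = 0.85,
                           hits_tol = 1e-12, hits_max_iter = 100000L,
                           expected_nodes = 41L,
                           on_degenerate = c("zero", "error")) {
  structure(
    list(edge_length = match.arg(edge_length),
         katz_alpha = katz_alpha, katz_alpha_factor = katz_alpha_factor,
         pagerank_damping = pagerank_damping,
         hits_tol = hits_tol, hits_max_iter = as.integer(hits_max_iter),
         expected_nodes = expected_nodes,
         on_degenerate = match.arg(on_degenerate)),
    class = "measure_config"
  )
}

# Dense weighted adjacency of an igraph graph (symmetric, zero diagonal).
.adjacency <- function(graph) {
  w <- igraph::as_adjacency_matrix(graph, attr = .weight_attr(graph),
                                   sparse = FALSE)
  unname(w)
}

.weight_attr <- function(graph) {
  if ("weight" %in% igraph::edge_attr_names(graph)) "weight" else NULL
}

# Edge lengths for igraph shortest-path routines under the configured
# convention: NA means "ignore weights" (hop lengths) in igraph.
.edge_lengths <- function(graph, config) {
  if (config$edge_length == "hop") return(NA)
  w <- igraph::E(graph)$weight
  1 / w
}

# All-pairs shortest-path length matrix under the configured convention.
.graph_distances <- function(graph, config) {
  wts <- .edge_lengths(graph, config)
  igraph::distances(graph, weights = wts)
}

.named <- function(values, graph) {
  stats::setNames(as.numeric(values), igraph::V(graph)$name)
}

#' Closeness centrality
#'
#' `C_v = (n-1) / sum_u d(v,u)`, computed over the reachable set and
#' scaled by `r/(n-1)` where `r` is the number of nodes reachable from
#' `v`, so disconnected graphs give finite values and isolated nodes 0.
#' On connected graphs this is exactly `(n-1)/sum d(v,u)` and lies in
#' `[0, 1]` under hop distances.
#'
#' @param graph An igraph brain graph.
#' @param config A [measure_config()].
#' @return Named numeric vector of per-node values.
#' @export
node_closeness <- function(graph, config = measure_config()) {
  n <- igraph::vcount(graph)
  if (n <= 1) return(.named(rep(0, n), graph))
  d <- .graph_distances(graph, config)
  diag(d) <- Inf
  vals <- vapply(seq_len(n), function(v) {
    dv <- d[v, ]
    reach <- is.finite(dv)
    r <- sum(reach)
    s <- sum(dv[reach])
    if (r == 0 || s == 0) return(0)
    (r / s) * (r / (n - 1))
  }, numeric(1))
  .named(vals, graph)
}

#' Betweenness centrality
#'
#' `C_B(v) = sum_{s != t != v} sigma_v(s,t) / sigma(s,t)` over unordered
#' pairs, endpoints excluded, unnormalized.
#'
#' @inheritParams node_closeness
#' @return Named numeric vector of per-node values.
#' @export
node_betweenness <- function(graph, config = measure_config()) {
  wts <- .edge_lengths(graph, config)
  .named(igraph::betweenness(graph, directed = FALSE, weights = wts,
                             normalized = FALSE), graph)
}

#' Eigenvector centrality
#'
#' Entries of the leading eigenvector of the weighted adjacency matrix,
#' oriented nonnegative and normalized to unit Euclidean norm. When the
#' leading eigenvalue is degenerate (equally dominant components), the
#' projection of the uniform vector onto the leading eigenspace is used,
#' which is deterministic and agrees with the limit of power iteration
#' from a uniform start. Nodes outside dominant components get 0.
#'
#' @inheritParams node_closeness
#' @return Named numeric vector of per-node values.
#' @export
node_eigenvector <- function(graph, config = measure_config()) {
  n <- igraph::vcount(graph)
  if (igraph::ecount(graph) == 0) {
    if (config$on_degenerate == "error") {
      stop("eigenvector undefined on a graph with no edges", call. = FALSE)
    }
    return(.named(rep(0, n), graph))
  }
  a <- .adjacency(graph)
  e <- eigen(a, symmetric = TRUE)
  lmax <- e$values[1]
  lead <- which(e$values > lmax - 1e-9 * max(1, abs(lmax)))
  u <- e$vectors[, lead, drop = FALSE]
  v <- u %*% crossprod(u, rep(1, n))  # projection of the uniform vector
  v <- as.numeric(v)
  i <- which.max(abs(v))
  if (v[i] < 0) v <- -v
  v[v < 0] <- 0  # numerical noise; the Perron limit is nonnegative
  v <- v / sqrt(sum(v^2))
  .named(v, graph)
}

#' Katz centrality
#'
#' `C_k(v) = sum_{k>=1} sum_u alpha^k (A^k)_{uv}`, evaluated in closed
#' form as the row sums of `(I - alpha A)^{-1} - I` on the weighted
#' adjacency. Requires `0 < alpha < 1/lambda_max`; the default attenuation
#' is `0.85 / lambda_max`, recomputed per graph.
#'
#' @inheritParams node_closeness
#' @param alpha Attenuation factor; `NULL` uses the config default.
#' @return Named numeric vector of per-node values.
#' @export
node_katz <- function(graph, config = measure_config(), alpha = NULL) {
  n <- igraph::vcount(graph)
  a <- .adjacency(graph)
  if (igraph::ecount(graph) == 0) return(.named(rep(0, n), graph))
  lmax <- max(eigen(a, symmetric = TRUE, only.values = TRUE)$values)
  alpha <- alpha %||% config$katz_alpha %||% (config$katz_alpha_factor / lmax)
  if (lmax > 0 && alpha >= 1 / lmax) {
    stop(sprintf("series diverges: alpha = %g >= 1/lambda_max = %g",
                 alpha, 1 / lmax), call. = FALSE)
  }
  if (alpha <= 0) stop("alpha must be positive", call. = FALSE)
  m <- diag(n) - alpha * a
  vals <- rowSums(solve(m)) - 1
  .named(vals, graph)
}

#' HITS centrality
#'
#' Iterates the authority/hub update rules with L1 normalization until the
#' L1 change falls below `tol`. On undirected graphs hub and authority
#' scores coincide, so one value per node is returned: the L1-normalized
#' Perron vector of the adjacency matrix. A positive diagonal shift is
#' applied inside the iteration so that it also converges on bipartite
#' components (where the unshifted authority iteration is degenerate);
#' the shift leaves the Perron limit unchanged.
#'
#' @inheritParams node_closeness
#' @param tol L1 convergence tolerance (overrides the config).
#' @param max_iter Iteration cap (overrides the config).
#' @return Named numeric vector of per-node authority (= hub) scores,
#'   summing to 1.
#' @export
node_hits <- function(graph, config = measure_config(),
                      tol = NULL, max_iter = NULL) {
  n <- igraph::vcount(graph)
  if (igraph::ecount(graph) == 0) {
    if (config$on_degenerate == "error") {
      stop("HITS undefined on a graph with no edges", call. = FALSE)
    }
    return(.named(rep(0, n), graph))
  }
  tol <- tol %||% config$hits_tol
  max_iter <- max_iter %||% config$hits_max_iter
  a <- .adjacency(graph)
  shift <- max(rowSums(a)) * 0.1  # bipartite-safe; same Perron limit
  as_ <- a + diag(shift, n)
  auth <- rep(1 / n, n)
  for (it in seq_len(max_iter)) {
    hub <- as.numeric(as_ %*% auth)
    hub <- hub / sum(hub)
    auth_new <- as.numeric(as_ %*% hub)
    auth_new <- auth_new / sum(auth_new)
    delta <- sum(abs(auth_new - auth))
    auth <- auth_new
    if (delta < tol) return(.named(auth, graph))
  }
  stop(sprintf("HITS did not converge in %d iterations (residual %g)",
               max_iter, delta), call. = FALSE)
}

#' Degree centrality
#'
#' `C_D(v) = deg(v) / (n - 1)` using binary edge counts (weights ignored).
#'
#' @inheritParams node_closeness
#' @return Named numeric vector of per-node values in `[0, 1]`.
#' @export
node_degree <- function(graph, config = measure_config()) {
  n <- igraph::vcount(graph)
  if (n <= 1) return(.named(rep(0, n), graph))
  .named(igraph::degree(graph) / (n - 1), graph)
}

#' Clustering coefficient
#'
#' `C_v = 2e / (k (k - 1))` on the binarized graph, where `k` is the
#' number of neighbors of `v` and `e` the number of edges among them;
#' nodes with fewer than two neighbors get 0.
#'
#' @inheritParams node_closeness
#' @return Named numeric vector of per-node values in `[0, 1]`.
#' @export
node_clustering <- function(graph, config = measure_config()) {
  vals <- igraph::transitivity(graph, type = "local", isolates = "zero",
                               weights = NA)
  .named(vals, graph)
}

#' Nodal efficiency
#'
#' `E(v) = (1/(n-1)) sum_{u != v} 1/d(v,u)`, the inverse harmonic mean of
#' the distances to the other nodes, with `1/Inf = 0` for unreachable
#' pairs (isolated nodes therefore score 0).
#'
#' @inheritParams node_closeness
#' @return Named numeric vector of per-node values.
#' @export
node_efficiency <- function(graph, config = measure_config()) {
  n <- igraph::vcount(graph)
  if (n <= 1) return(.named(rep(0, n), graph))
  d <- .graph_distances(graph, config)
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  .named(rowSums(inv) / (n - 1), graph)
}

#' PageRank
#'
#' Stationary vector of the damped, column-normalized weighted adjacency:
#' `x = (1-d)/n + d P x`, where dangling (isolated) nodes distribute their
#' mass uniformly. Solved exactly as a dense linear system; values sum
#' to 1.
#'
#' @inheritParams node_closeness
#' @param damping Damping factor (overrides the config).
#' @return Named numeric vector of per-node values summing to 1.
#' @export
node_pagerank <- function(graph, config = measure_config(), damping = NULL) {
  d <- damping %||% config$pagerank_damping
  n <- igraph::vcount(graph)
  a <- .adjacency(graph)
  cs <- colSums(a)
  p <- matrix(1 / n, n, n)
  ok <- cs > 0
  p[, ok] <- sweep(a[, ok, drop = FALSE], 2, cs[ok], "/")
  x <- solve(diag(n) - d * p, rep((1 - d) / n, n))
  .named(x, graph)
}

#' Load centrality
#'
#' Commodity-flow betweenness: every ordered pair `(s, t)` with `s != t`
#' sends one unit of commodity from `s` toward `t`; at each node the unit
#' is forwarded to the neighbors strictly closer to `t`, split equally
#' among ties. `L(v)` is the total commodity transiting `v`, endpoints
#' excluded. Unreachable pairs send nothing.
#'
#' @inheritParams node_closeness
#' @return Named numeric vector of per-node values.
#' @export
node_load <- function(graph, config = measure_config()) {
  n <- igraph::vcount(graph)
  load <- rep(0, n)
  if (n <= 2 || igraph::ecount(graph) == 0) return(.named(load, graph))
  a <- .adjacency(graph)
  len <- a
  len[a > 0] <- if (config$edge_length == "hop") 1 else 1 / a[a > 0]
  d <- .graph_distances(graph, config)
  eps <- 1e-10
  nbrs <- lapply(seq_len(n), function(v) which(a[v, ] > 0))
  for (t in seq_len(n)) {
    dt <- d[, t]
    senders <- which(is.finite(dt) & seq_len(n) != t)
    if (length(senders) == 0) next
    inflow <- rep(0, n)
    for (v in senders[order(dt[senders], decreasing = TRUE)]) {
      amount <- 1 + inflow[v]
      succ <- nbrs[[v]]
      succ <- succ[abs(dt[succ] + len[v, succ] - dt[v]) < eps]
      inflow[succ] <- inflow[succ] + amount / length(succ)
    }
    trans <- inflow
    trans[t] <- 0
    load <- load + trans
  }
  .named(load, graph)
}

#' Node redundancy coefficient
#'
#' Fraction of neighbor pairs `{j, k}` of node `i` that share another
#' common neighbor `i' != i`: parallel pathways that would keep `j` and
#' `k` indirectly linked if `i` were removed. Nodes with fewer than two
#' neighbors get 0.
#'
#' @inheritParams node_closeness
#' @return Named numeric vector of per-node values in `[0, 1]`.
#' @export
node_redundancy <- function(graph, config = measure_config()) {
  n <- igraph::vcount(graph)
  a <- .adjacency(graph)
  b <- (a > 0) * 1
  common <- b %*% b  # common-neighbor counts; includes i for pairs in N(i)
  vals <- vapply(seq_len(n), function(i) {
    nb <- which(b[i, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    cc <- common[nb, nb, drop = FALSE]
    covered <- sum(cc[upper.tri(cc)] >= 2)  # >= 2: some i' beyond i itself
    covered / (k * (k - 1) / 2)
  }, numeric(1))
  .named(vals, graph)
}

#' All eleven nodal measures as a node-by-measure table
#'
#' @inheritParams node_closeness
#' @return Numeric matrix with one row per node and one column per measure
#'   in canonical order (see [measure_names()]).
#' @export
nodal_measures <- function(graph, config = measure_config()) {
  funs <- list(
    closeness = node_closeness, betweenness = node_betweenness,
    eigenvector = node_eigenvector, katz = node_katz, hits = node_hits,
    degree = node_degree, clustering = node_clustering,
    efficiency = node_efficiency, pagerank = node_pagerank,
    load = node_load, redundancy = node_redundancy
  )
  vals <- vapply(MEASURE_ORDER, function(m) funs[[m]](graph, config),
                 numeric(igraph::vcount(graph)))
  rownames(vals) <- igraph::V(graph)$name
  vals
}

#' Per-subject feature vector
#'
#' Concatenates the eleven nodal measures in measure-major order
#' (41 closeness values, then 41 betweenness values, ...), giving the
#' 451-entry vector `<measure>_<node_label>` for a 41-node graph. Values
#' are deterministic given the graph and config, and keyed by node label
#' (permuting node input order with labels attached leaves the vector
#' unchanged).
#'
#' @inheritParams node_closeness
#' @return Named numeric vector of length `11 * n_nodes` with attribute
#'   `subject_id`.
#' @export
feature_vector <- function(graph, config = measure_config()) {
  n <- igraph::vcount(graph)
  if (!is.null(config$expected_nodes) && n != config$expected_nodes) {
    stop(sprintf("graph has %d nodes; expected %d (set expected_nodes = NULL to override)",
                 n, config$expected_nodes), call. = FALSE)
  }
  ord <- order(igraph::V(graph)$name)  # label-keyed layout
  vals <- nodal_measures(graph, config)[ord, , drop = FALSE]
  out <- as.numeric(vals)
  names(out) <- as.vector(outer(rownames(vals), colnames(vals),
                                function(node, m) paste(m, node, sep = "_")))
  attr(out, "subject_id") <- igraph::graph_attr(graph, "subject_id")
  out
}

#' Feature table for a whole cohort
#'
#' @param cohort A `cohort` (see [read_cohort_manifest()] or
#'   [generate_cohort()]).
#' @param config A [measure_config()].
#' @param threshold Edge-existence threshold passed to [build_graph()].
#' @return Data frame with columns `subject_id`, `group` and one column
#'   per feature (`<measure>_<node_label>`).
#' @export
cohort_features <- function(cohort, config = measure_config(),
                            threshold = 0) {
  stopifnot(inherits(cohort, "cohort"))
  feats <- lapply(cohort$subjects$subject_id, function(id) {
    feature_vector(build_graph(cohort$matrices[[id]], threshold = threshold),
                   config)
  })
  x <- do.call(rbind, feats)
  data.frame(subject_id = cohort$subjects$subject_id,
             group = cohort$subjects$group,
             x, check.names = FALSE, stringsAsFactors = FALSE)
}
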
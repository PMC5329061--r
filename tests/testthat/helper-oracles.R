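# Independent brute-force oracles for the eleven nodal measures. These
# deliberately avoid igraph and every code path of the package: distances
# by Floyd-Warshall, betweenness/load by explicit path enumeration and
# per-pair flow recursion, spectral measures by power iteration /
# truncated series / dense eigendecomposition of the Google matrix.

# adjacency helpers -----------------------------------------------------

mat_from_graph <- function(g) {
  igraph::as_adjacency_matrix(
    g, attr = if ("weight" %in% igraph::edge_attr_names(g)) "weight" else NULL,
    sparse = FALSE)
}

# matrix of edge lengths (Inf where no edge) under a convention
oracle_lengths <- function(a, edge_length = "hop") {
  len <- matrix(Inf, nrow(a), ncol(a))
  if (edge_length == "hop") len[a > 0] <- 1 else len[a > 0] <- 1 / a[a > 0]
  diag(len) <- 0
  len
}

oracle_distances <- function(a, edge_length = "hop") {
  d <- oracle_lengths(a, edge_length)
  n <- nrow(a)
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

oracle_closeness <- function(a, edge_length = "hop") {
  n <- nrow(a)
  if (n <= 1) return(rep(0, n))
  d <- oracle_distances(a, edge_length)
  sapply(seq_len(n), function(v) {
    dv <- d[v, -v]
    r <- sum(is.finite(dv))
    s <- sum(dv[is.finite(dv)])
    if (r == 0 || s == 0) 0 else (r / s) * (r / (n - 1))
  })
}

oracle_efficiency <- function(a, edge_length = "hop") {
  n <- nrow(a)
  if (n <= 1) return(rep(0, n))
  d <- oracle_distances(a, edge_length)
  sapply(seq_len(n), function(v) {
    dv <- d[v, -v]
    sum(1 / dv[is.finite(dv) & dv > 0]) / (n - 1)
  })
}

# enumerate all shortest simple paths between every ordered pair by DFS
oracle_all_shortest_paths <- function(a, edge_length = "hop") {
  n <- nrow(a)
  len <- oracle_lengths(a, edge_length)
  d <- oracle_distances(a, edge_length)
  eps <- 1e-9
  paths <- vector("list", n * n)
  dfs <- function(v, t, cur, curlen) {
    if (v == t) return(list(cur))
    out <- list()
    for (u in which(a[v, ] > 0)) {
      if (!(u %in% cur) &&
          curlen + len[v, u] + d[u, t] <= d[cur[1], t] + eps) {
        out <- c(out, dfs(u, t, c(cur, u), curlen + len[v, u]))
      }
    }
    out
  }
  for (s in seq_len(n)) {
    for (t in seq_len(n)) {
      if (s != t && is.finite(d[s, t])) {
        paths[[(s - 1) * n + t]] <- dfs(s, t, s, 0)
      }
    }
  }
  paths
}

oracle_betweenness <- function(a, edge_length = "hop") {
  n <- nrow(a)
  paths <- oracle_all_shortest_paths(a, edge_length)
  bw <- rep(0, n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      ps <- paths[[(s - 1) * n + t]]
      if (is.null(ps) || length(ps) == 0) next
      for (v in setdiff(seq_len(n), c(s, t))) {
        through <- sum(vapply(ps, function(p) v %in% p, logical(1)))
        bw[v] <- bw[v] + through / length(ps)
      }
    }
  }
  bw
}

# per-ordered-pair recursive commodity splitting
oracle_load <- function(a, edge_length = "hop") {
  n <- nrow(a)
  len <- oracle_lengths(a, edge_length)
  d <- oracle_distances(a, edge_length)
  eps <- 1e-9
  load <- rep(0, n)
  push <- function(v, t, amount) {
    if (v == t) return(invisible())
    succ <- which(a[v, ] > 0)
    succ <- succ[abs(d[succ, t] + len[v, succ] - d[v, t]) < eps]
    for (u in succ) {
      if (u != t) load[u] <<- load[u] + amount / length(succ)
      push(u, t, amount / length(succ))
    }
  }
  for (s in seq_len(n)) {
    for (t in seq_len(n)) {
      if (s != t && is.finite(d[s, t])) push(s, t, 1)
    }
  }
  load
}

oracle_degree <- function(a) {
  n <- nrow(a)
  if (n <= 1) return(rep(0, n))
  rowSums(a > 0) / (n - 1)
}

oracle_clustering <- function(a) {
  b <- a > 0
  n <- nrow(a)
  sapply(seq_len(n), function(v) {
    nb <- which(b[v, ])
    k <- length(nb)
    if (k < 2) return(0)
    e <- 0
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) if (b[nb[i], nb[j]]) e <- e + 1
    }
    2 * e / (k * (k - 1))
  })
}

oracle_redundancy <- function(a) {
  b <- a > 0
  n <- nrow(a)
  sapply(seq_len(n), function(i) {
    nb <- which(b[i, ])
    k <- length(nb)
    if (k < 2) return(0)
    covered <- 0
    for (x in seq_len(k - 1)) {
      for (y in (x + 1):k) {
        j <- nb[x]; kk <- nb[y]
        others <- setdiff(seq_len(n), i)
        if (any(b[others, j] & b[others, kk])) covered <- covered + 1
      }
    }
    covered / (k * (k - 1) / 2)
  })
}

# leading-eigenspace vector via power iteration on the shifted matrix
# (converges for bipartite components too; same limit as the package's
# eigendecomposition route)
oracle_eigenvector <- function(a, iters = 200000, tol = 1e-14) {
  n <- nrow(a)
  if (all(a == 0)) return(rep(0, n))
  m <- a + diag(0.05 * max(rowSums(a)), n)
  v <- rep(1 / sqrt(n), n)
  for (i in seq_len(iters)) {
    w <- as.numeric(m %*% v)
    w <- w / sqrt(sum(w^2))
    if (sum(abs(w - v)) < tol) break
    v <- w
  }
  v <- pmax(w, 0)
  v / sqrt(sum(v^2))
}

oracle_hits <- function(a, iters = 200000, tol = 1e-14) {
  v <- oracle_eigenvector(a, iters, tol)
  if (sum(v) == 0) return(v)
  v / sum(v)
}

oracle_katz <- function(a, alpha, terms = NULL) {
  n <- nrow(a)
  if (all(a == 0)) return(rep(0, n))
  lmax <- max(eigen(a, symmetric = TRUE, only.values = TRUE)$values)
  # enough terms that the geometric tail is < 1e-12
  terms <- terms %||% max(50, ceiling(log(1e-13) / log(alpha * lmax + 1e-12)))
  out <- rep(0, n)
  ak <- diag(1, n)
  for (k in seq_len(terms)) {
    ak <- ak %*% (alpha * a)
    out <- out + colSums(ak)
  }
  out
}

# dense eigendecomposition of the Google matrix
oracle_pagerank <- function(a, damping = 0.85) {
  n <- nrow(a)
  cs <- colSums(a)
  p <- matrix(1 / n, n, n)
  ok <- cs > 0
  p[, ok] <- sweep(a[, ok, drop = FALSE], 2, cs[ok], "/")
  g <- damping * p + (1 - damping) / n
  e <- eigen(g)
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v <- v / sum(v)
  if (any(v < -1e-8)) stop("oracle pagerank: negative stationary vector")
  pmax(v, 0) / sum(pmax(v, 0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random test graphs ----------------------------------------------------

random_weight_matrix <- function(n, density = 0.5, weighted = TRUE) {
  m <- matrix(0, n, n)
  up <- upper.tri(m)
  present <- runif(sum(up)) < density
  w <- ifelse(present,
              if (weighted) round(runif(sum(up), 1, 20)) else 1, 0)
  m[up] <- w
  m + t(m)
}

graph_from_matrix <- function(m) {
  build_graph(connectivity_matrix(m))
}

# all non-isomorphic simple graphs with n nodes, as adjacency matrices
all_graphs_up_to_iso <- function(n) {
  np <- n * (n - 1) / 2
  seen <- new.env(hash = TRUE)
  out <- list()
  for (code in 0:(2^np - 1)) {
    bits <- as.integer(intToBits(code))[seq_len(np)]
    m <- matrix(0, n, n)
    m[upper.tri(m)] <- bits
    m <- m + t(m)
    g <- igraph::graph_from_adjacency_matrix(m, mode = "undirected")
    cp <- igraph::canonical_permutation(g)$labeling
    cg <- igraph::permute(g, cp)
    key <- paste0("k", paste(
      as.integer(igraph::as_adjacency_matrix(cg, sparse = FALSE)
                 [upper.tri(m)]), collapse = ""))
    if (is.null(seen[[key]])) {
      seen[[key]] <- TRUE
      out[[length(out) + 1]] <- m
    }
  }
  out
}
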
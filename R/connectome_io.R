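# Reading, validating and graphing structural connectivity matrices.
#
# A connectivity matrix is a square, symmetric, nonnegative matrix of
# fiber counts between brain regions (41 Brodmann areas in the reference
# design), zero on the diagonal. The brain graph derived from it has an
# edge wherever at least one fiber connects two regions.

#' Construct and validate a connectivity matrix
#'
#' Validates squareness, finiteness, nonnegativity, symmetry (within
#' `tol`, then symmetrized as `(W + t(W))/2`) and a zero diagonal.
#' Validation errors name the offending cell.
#'
#' @param weights Square numeric matrix of nonnegative fiber-count weights.
#' @param node_labels Character vector of region labels, one per row.
#'   Defaults to `"BA1" ... "BA<n>"`.
#' @param subject_id Subject identifier.
#' @param tol Absolute tolerance for symmetry and diagonal checks.
#' @return An object of class `connectivity_matrix`: a list with elements
#'   `subject_id`, `node_labels` and `weights`.
#' @examples
#' w <- matrix(0, 3, 3); w[1, 2] <- w[2, 1] <- 5
#' cm <- connectivity_matrix(w, subject_id = "s1")
#' @export
connectivity_matrix <- function(weights, node_labels = NULL,
                                subject_id = NA_character_, tol = 1e-9) {
  if (!is.matrix(weights) || !is.numeric(weights)) {
    stop("`weights` must be a numeric matrix", call. = FALSE)
  }
  n <- nrow(weights)
  if (ncol(weights) != n) {
    stop(sprintf("connectivity matrix is not square: %d x %d",
                 n, ncol(weights)), call. = FALSE)
  }
  if (is.null(node_labels)) node_labels <- paste0("BA", seq_len(n))
  if (length(node_labels) != n) {
    stop(sprintf("dimension %d does not match label count %d",
                 n, length(node_labels)), call. = FALSE)
  }
  first_bad <- function(cond) {
    idx <- which(cond, arr.ind = TRUE)
    idx[order(idx[, 1], idx[, 2])[1], , drop = FALSE]  # row-major first
  }
  if (any(!is.finite(weights))) {
    bad <- first_bad(!is.finite(weights))
    stop(sprintf("non-finite entry at (%d, %d)", bad[1, 1], bad[1, 2]),
         call. = FALSE)
  }
  if (any(weights < 0)) {
    bad <- first_bad(weights < 0)
    stop(sprintf("negative entry %g at (%d, %d)",
                 weights[bad], bad[1, 1], bad[1, 2]), call. = FALSE)
  }
  asym <- abs(weights - t(weights))
  if (any(asym > tol)) {
    bad <- first_bad(asym > tol)
    stop(sprintf("asymmetry %g beyond tolerance at (%d, %d)",
                 asym[bad], bad[1, 1], bad[1, 2]), call. = FALSE)
  }
  weights <- (weights + t(weights)) / 2
  d <- which(abs(diag(weights)) > tol)
  if (length(d) > 0) {
    stop(sprintf("nonzero diagonal entry at (%d, %d)", d[1], d[1]),
         call. = FALSE)
  }
  diag(weights) <- 0
  dimnames(weights) <- list(node_labels, node_labels)
  structure(
    list(subject_id = subject_id, node_labels = node_labels,
         weights = weights),
    class = "connectivity_matrix"
  )
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> subject %s: %d nodes, %d edges\n",
              x$subject_id, length(x$node_labels),
              sum(x$weights[upper.tri(x$weights)] > 0)))
  invisible(x)
}

# Heuristic: a CSV token vector is "numeric" if every non-empty token
# parses as a number.
.all_numeric <- function(x) {
  x <- trimws(x)
  x <- x[nzchar(x)]
  length(x) > 0 && !anyNA(suppressWarnings(as.numeric(x)))
}

#' Read a connectivity matrix from a dense CSV file
#'
#' Accepts a plain dense numeric CSV, optionally with a header row and/or a
#' first column of region labels (auto-detected). The matrix is validated
#' as in [connectivity_matrix()].
#'
#' @param path Path to the CSV file.
#' @param labels Optional expected label vector; overrides labels found in
#'   the file and fixes the expected dimension.
#' @param subject_id Subject identifier; defaults to the file name without
#'   extension.
#' @param tol Symmetry tolerance passed to [connectivity_matrix()].
#' @return A `connectivity_matrix`.
#' @export
read_connectivity_matrix <- function(path, labels = NULL,
                                     subject_id = NULL, tol = 1e-9) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(subject_id)) {
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  }
  raw <- utils::read.csv(path, header = FALSE, colClasses = "character",
                         check.names = FALSE)
  raw <- as.matrix(raw)
  has_header <- nrow(raw) > 1 && !.all_numeric(raw[1, -1])
  if (has_header) raw <- raw[-1, , drop = FALSE]
  has_rowlab <- ncol(raw) > 1 && !.all_numeric(raw[, 1])
  file_labels <- NULL
  if (has_rowlab) {
    file_labels <- trimws(raw[, 1])
    raw <- raw[, -1, drop = FALSE]
  }
  w <- suppressWarnings(apply(raw, c(1, 2), as.numeric))
  bad <- which(is.na(w), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-numeric entry at (%d, %d) in %s",
                 bad[1, 1], bad[1, 2], path), call. = FALSE)
  }
  node_labels <- labels %||% file_labels
  if (!is.null(labels) && nrow(w) != length(labels)) {
    stop(sprintf("matrix dimension %d does not match expected label count %d",
                 nrow(w), length(labels)), call. = FALSE)
  }
  connectivity_matrix(unname(w), node_labels = node_labels,
                      subject_id = subject_id, tol = tol)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a connectivity matrix to CSV
#'
#' Writes a dense CSV with a header row and label column, at 15 significant
#' digits so that a write/read round trip reproduces weights exactly for
#' values representable at that precision.
#'
#' @param x A `connectivity_matrix`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_connectivity_matrix <- function(x, path) {
  stopifnot(inherits(x, "connectivity_matrix"))
  w <- x$weights
  txt <- apply(w, c(1, 2), function(v) format(v, digits = 15))
  df <- data.frame(node = x$node_labels, txt, check.names = FALSE)
  names(df) <- c("node", x$node_labels)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cohort manifest and its per-subject matrices
#'
#' The manifest CSV must have columns `subject_id, group, age, education,
#' sex` with `group` in `CT`, `MCI`, `AD`. One matrix file
#' `<subject_id>.csv` per subject is expected in `matrix_dir`. All matrices
#' must share identical node labels in identical order.
#'
#' @param path Manifest CSV path.
#' @param matrix_dir Directory containing one matrix CSV per subject.
#' @param labels Optional node labels forwarded to
#'   [read_connectivity_matrix()].
#' @return An object of class `cohort`: a list with `subjects` (data frame)
#'   and `matrices` (named list of `connectivity_matrix`).
#' @export
read_cohort_manifest <- function(path, matrix_dir, labels = NULL) {
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("subject_id", "group", "age", "education", "sex")
  missing_cols <- setdiff(required, names(man))
  if (length(missing_cols) > 0) {
    stop("manifest is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(man) == 0) stop("empty cohort", call. = FALSE)
  man$subject_id <- as.character(man$subject_id)
  dup <- man$subject_id[duplicated(man$subject_id)]
  if (length(dup) > 0) {
    stop("duplicate subject_id: ", dup[1], call. = FALSE)
  }
  bad_group <- setdiff(unique(man$group), GROUP_LEVELS)
  if (length(bad_group) > 0) {
    stop(sprintf("unknown group label '%s'; allowed: %s", bad_group[1],
                 paste(GROUP_LEVELS, collapse = ", ")), call. = FALSE)
  }
  if (any(!is.finite(man$age) | man$age <= 0)) {
    stop("age must be a positive number for every subject", call. = FALSE)
  }
  matrices <- lapply(man$subject_id, function(id) {
    f <- file.path(matrix_dir, paste0(id, ".csv"))
    if (!file.exists(f)) {
      stop("missing matrix file for subject ", id, ": ", f, call. = FALSE)
    }
    read_connectivity_matrix(f, labels = labels, subject_id = id)
  })
  names(matrices) <- man$subject_id
  lab0 <- matrices[[1]]$node_labels
  for (m in matrices) {
    if (!identical(m$node_labels, lab0)) {
      stop("node labels differ between subjects (", m$subject_id, ")",
           call. = FALSE)
    }
  }
  new_cohort(man, matrices)
}

new_cohort <- function(subjects, matrices) {
  structure(list(subjects = subjects, matrices = matrices),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  tab <- table(factor(x$subjects$group, levels = GROUP_LEVELS))
  cat(sprintf("<cohort> %d subjects (%s), %d-node connectomes\n",
              nrow(x$subjects),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
              length(x$matrices[[1]]$node_labels)))
  invisible(x)
}

#' Write a cohort (manifest plus matrices) to a directory
#'
#' Writes `manifest.csv`, one `<subject_id>.csv` per matrix, and, when the
#' cohort carries planted ground truth (see [generate_cohort()]),
#' `ground_truth.json`.
#'
#' @param cohort A `cohort`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$subjects, file.path(dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  for (m in cohort$matrices) {
    write_connectivity_matrix(m, file.path(dir, paste0(m$subject_id, ".csv")))
  }
  gt <- attr(cohort, "ground_truth")
  if (!is.null(gt)) {
    jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Build a weighted undirected brain graph from a connectivity matrix
#'
#' An edge joins regions i and j iff `W_ij > threshold` (default 0: at
#' least one fiber). Isolated nodes are kept, so every graph has the full
#' node set.
#'
#' @param matrix A `connectivity_matrix`.
#' @param threshold Edge-existence threshold on the weight; edges require
#'   `W_ij > threshold`.
#' @return An [igraph][igraph::igraph-package] graph with vertex names set
#'   to the node labels, edge attribute `weight`, and graph attribute
#'   `subject_id`.
#' @examples
#' w <- matrix(0, 3, 3); w[1, 2] <- w[2, 1] <- 2
#' g <- build_graph(connectivity_matrix(w))
#' igraph::ecount(g)  # 1
#' @export
build_graph <- function(matrix, threshold = 0) {
  stopifnot(inherits(matrix, "connectivity_matrix"))
  w <- matrix$weights
  w[w <= threshold] <- 0
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::V(g)$name <- matrix$node_labels
  g <- igraph::set_graph_attr(g, "subject_id", matrix$subject_id)
  g
}

#' Export a brain graph as GraphML
#'
#' @param graph An igraph graph as returned by [build_graph()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_graphml <- function(graph, path) {
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}
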
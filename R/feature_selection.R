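# Univariate ANOVA-F feature ranking and top-K selection for two-class
# labeled datasets, plus the accuracy-vs-K sweep used to pick K.

#' Assemble a two-class labeled dataset from a cohort feature table
#'
#' Encodes the clinically more severe class as +1 (AD in `AD-CT` and
#' `AD-MCI`; MCI in `MCI-CT`) and the other as -1.
#'
#' @param features Data frame from [cohort_features()].
#' @param task One of `"AD-CT"`, `"AD-MCI"`, `"MCI-CT"`.
#' @return A list of class `labeled_dataset` with elements `X` (numeric
#'   matrix), `y` (+1/-1 vector), `feature_names`, `subject_id`, `task`.
#' @export
labeled_dataset <- function(features, task = c("AD-CT", "AD-MCI", "MCI-CT")) {
  task <- match.arg(task)
  classes <- strsplit(task, "-", fixed = TRUE)[[1]]
  pos <- classes[1]
  neg <- classes[2]
  keep <- features$group %in% classes
  sub <- features[keep, , drop = FALSE]
  if (!all(classes %in% sub$group)) {
    stop("both classes of task ", task, " must be present", call. = FALSE)
  }
  feat_cols <- setdiff(names(sub), c("subject_id", "group"))
  x <- as.matrix(sub[, feat_cols, drop = FALSE])
  if (anyNA(x)) stop("feature matrix contains NA", call. = FALSE)
  y <- ifelse(sub$group == pos, 1, -1)
  structure(list(X = x, y = y, feature_names = feat_cols,
                 subject_id = sub$subject_id, task = task,
                 positive_class = pos, negative_class = neg),
            class = "labeled_dataset")
}

#' ANOVA F-scores for every feature of a two-class dataset
#'
#' One-way two-group ANOVA per feature: `F = SSB / (SSW / (n - 2))` with
#' p-value from the F distribution on `(1, n-2)` degrees of freedom. A
#' feature that is constant overall (zero between- and within-group
#' variance) gets `F = 0`; perfect separation with zero within-group
#' variance gives `F = Inf`, `p = 0`. For two groups `F` equals the
#' squared pooled two-sample t statistic.
#'
#' @param X Numeric matrix (subjects x features) or a `labeled_dataset`.
#' @param y +1/-1 labels (ignored when `X` is a `labeled_dataset`).
#' @return A list of class `feature_ranking`: `f_scores`, `p_values`,
#'   `order` (feature indices by descending F, ties broken by ascending
#'   index), `feature_names`.
#' @export
anova_f_scores <- function(X, y = NULL) {
  if (inherits(X, "labeled_dataset")) {
    y <- X$y
    feature_names <- X$feature_names
    X <- X$X
  } else {
    feature_names <- colnames(X) %||% paste0("f", seq_len(ncol(X)))
  }
  stopifnot(length(y) == nrow(X))
  g1 <- y > 0
  n1 <- sum(g1); n2 <- sum(!g1); n <- n1 + n2
  if (n1 < 2 || n2 < 2) stop("need at least 2 samples per class", call. = FALSE)
  m1 <- colMeans(X[g1, , drop = FALSE])
  m2 <- colMeans(X[!g1, , drop = FALSE])
  gm <- (n1 * m1 + n2 * m2) / n
  ssb <- n1 * (m1 - gm)^2 + n2 * (m2 - gm)^2
  ssw <- colSums(sweep(X[g1, , drop = FALSE], 2, m1)^2) +
    colSums(sweep(X[!g1, , drop = FALSE], 2, m2)^2)
  msw <- ssw / (n - 2)
  f <- ifelse(msw > 0, ssb / msw, ifelse(ssb > 0, Inf, 0))
  p <- stats::pf(f, 1, n - 2, lower.tail = FALSE)
  structure(list(f_scores = unname(f), p_values = unname(p),
                 order = order(-f, seq_along(f)),
                 feature_names = feature_names),
            class = "feature_ranking")
}

#' @export
print.feature_ranking <- function(x, n = 5, ...) {
  cat(sprintf("<feature_ranking> %d features; top %d:\n",
              length(x$f_scores), n))
  top <- x$order[seq_len(min(n, length(x$order)))]
  print(data.frame(feature = x$feature_names[top],
                   F = signif(x$f_scores[top], 4),
                   p = signif(x$p_values[top], 3)))
  invisible(x)
}

#' Ranking as a data frame (feature, F, p, rank)
#'
#' @param ranking A `feature_ranking`.
#' @return Data frame ordered by rank.
#' @export
ranking_table <- function(ranking) {
  stopifnot(inherits(ranking, "feature_ranking"))
  idx <- ranking$order
  data.frame(feature = ranking$feature_names[idx],
             F = ranking$f_scores[idx], p = ranking$p_values[idx],
             rank = seq_along(idx), stringsAsFactors = FALSE)
}

#' Select the top K features of a ranking
#'
#' @param ranking A `feature_ranking`.
#' @param k Number of features to keep, `1 <= k <= n_features`.
#' @return Integer vector of the first `k` feature indices in rank order.
#' @export
select_k_best <- function(ranking, k) {
  stopifnot(inherits(ranking, "feature_ranking"))
  nf <- length(ranking$f_scores)
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k > nf) {
    stop(sprintf("k must be in [1, %d]", nf), call. = FALSE)
  }
  ranking$order[seq_len(as.integer(k))]
}

#' Default K grid for the accuracy-vs-K sweep
#'
#' @param reduced If `TRUE`, a three-point grid for repeated-run studies.
#' @return Integer vector of candidate K values.
#' @export
default_k_grid <- function(reduced = FALSE) {
  if (reduced) c(50L, 230L, 451L)
  else c(10L, 30L, 50L, 110L, 150L, 230L, 310L, 390L, 430L, 451L)
}

#' Cross-validated accuracy as a function of the number of selected
#' features
#'
#' For each candidate `k`, runs stratified cross-validation in which the
#' ANOVA-F ranking and top-`k` selection are refit on every training fold
#' (no selection leakage), the five base learners are trained with the
#' supplied hyperparameters, and the uniform-weight voting ensemble
#' predicts the held-out fold.
#'
#' @param dataset A `labeled_dataset`.
#' @param k_grid Candidate feature counts.
#' @param specs Base-learner specifications, see [default_learner_specs()].
#' @param n_folds Number of stratified CV folds.
#' @param seed Integer seed controlling fold assignment and stochastic
#'   learners.
#' @return A list of class `k_sweep`: `curve` (data frame `k`,
#'   `accuracy`), `best_k` (argmax accuracy, ties to the smallest `k`),
#'   and `predictions` (per-k list of per-learner held-out prediction
#'   matrices, used internally by [nested_cv()]).
#' @export
sweep_k <- function(dataset, k_grid = default_k_grid(),
                    specs = default_learner_specs(), n_folds = 5,
                    seed = 1) {
  stopifnot(inherits(dataset, "labeled_dataset"), length(k_grid) > 0)
  x <- dataset$X
  y <- dataset$y
  k_grid <- as.integer(k_grid)
  folds <- stratified_folds(y, n_folds, seed)
  rankings <- lapply(seq_len(n_folds), function(g) {
    anova_f_scores(x[folds != g, , drop = FALSE], y[folds != g])
  })
  kinds <- vapply(specs, `[[`, character(1), "kind")
  preds <- lapply(k_grid, function(k) {
    p <- matrix(NA_real_, length(specs), length(y),
                dimnames = list(kinds, NULL))
    for (g in seq_len(n_folds)) {
      tr <- folds != g
      idx <- select_k_best(rankings[[g]], min(k, ncol(x)))
      for (s in seq_along(specs)) {
        fit <- fit_base(specs[[s]], x[tr, idx, drop = FALSE], y[tr],
                        params = specs[[s]]$params,
                        seed = seed + 97L * g + s)
        p[s, !tr] <- predict(fit, x[!tr, idx, drop = FALSE])
      }
    }
    p
  })
  acc <- vapply(preds, function(p) {
    votes <- colSums(p)
    mean(ifelse(votes > 0, 1, -1) == y)
  }, numeric(1))
  best_k <- k_grid[order(-acc, k_grid)][1]
  names(preds) <- as.character(k_grid)
  structure(list(curve = data.frame(k = k_grid, accuracy = acc),
                 best_k = best_k, predictions = preds),
            class = "k_sweep")
}
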
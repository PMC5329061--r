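# Diversity-weighted voting ensemble over the five base classifiers:
# pairwise Q-statistic diversity diagnostics, signed weighted voting
# C(x) = sign(sum_i w_i BC_i(x)), and grid-search weight refinement on
# inner-CV predictions.

#' Q statistic of a classifier pair
#'
#' `Q = (N11 N00 - N01 N10) / (N11 N00 + N01 N10)`, where `Nij` counts
#' samples classified correctly (`i = 1`) or incorrectly (`i = 0`) by the
#' first classifier and likewise (`j`) by the second. Lies in `[-1, 1]`;
#' lower means more diverse. Undefined (denominator 0) is reported as
#' `NA`, not 0.
#'
#' @param n11,n10,n01,n00 Nonnegative joint outcome counts. Alternatively
#'   pass a single list/vector with those names as `n11`.
#' @return The Q value, or `NA` when undefined.
#' @examples
#' q_statistic(5, 1, 1, 3)  # 0.875
#' @export
q_statistic <- function(n11, n10 = NULL, n01 = NULL, n00 = NULL) {
  if (is.list(n11) || length(n11) == 4) {
    cnt <- unlist(n11)
    n10 <- cnt[["n10"]]; n01 <- cnt[["n01"]]; n00 <- cnt[["n00"]]
    n11 <- cnt[["n11"]]
  }
  stopifnot(n11 >= 0, n10 >= 0, n01 >= 0, n00 >= 0)
  num <- n11 * n00 - n01 * n10
  den <- n11 * n00 + n01 * n10
  if (den == 0) return(NA_real_)
  num / den
}

#' Joint correct/incorrect counts for a classifier pair
#'
#' @param pred1,pred2 +/-1 prediction vectors.
#' @param truth +/-1 true labels.
#' @return Named list `n11`, `n10`, `n01`, `n00` summing to the sample
#'   count.
#' @export
q_outcome <- function(pred1, pred2, truth) {
  stopifnot(length(pred1) == length(truth), length(pred2) == length(truth))
  c1 <- pred1 == truth
  c2 <- pred2 == truth
  list(n11 = sum(c1 & c2), n10 = sum(c1 & !c2),
       n01 = sum(!c1 & c2), n00 = sum(!c1 & !c2))
}

#' Pairwise Q-statistic diversity matrix
#'
#' @param predictions Matrix of +/-1 predictions, one row per classifier
#'   (rownames become dimnames), one column per sample.
#' @param truth +/-1 true labels.
#' @return Symmetric matrix of Q values with 1 on the diagonal (by
#'   convention) and `NA` where Q is undefined.
#' @export
pairwise_diversity <- function(predictions, truth) {
  predictions <- as.matrix(predictions)
  if (ncol(predictions) != length(truth)) {
    stop("prediction and truth lengths differ", call. = FALSE)
  }
  k <- nrow(predictions)
  q <- diag(1, k)
  dimnames(q) <- list(rownames(predictions), rownames(predictions))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      q[i, j] <- q[j, i] <-
        q_statistic(q_outcome(predictions[i, ], predictions[j, ], truth))
    }
  }
  q
}

#' Default voting-weight candidate grid
#'
#' All 5-tuples over \{0, 0.5, 1, 2\} except the all-zero tuple, in
#' ascending lexicographic order (w1 most significant).
#'
#' @param values Candidate weight values per classifier.
#' @param n_classifiers Tuple length.
#' @return Numeric matrix, one candidate tuple per row.
#' @export
default_weight_grid <- function(values = c(0, 0.5, 1, 2),
                                n_classifiers = 5) {
  g <- as.matrix(expand.grid(rep(list(values), n_classifiers)))
  dimnames(g) <- NULL
  g <- g[rowSums(g != 0) > 0, , drop = FALSE]
  g[do.call(order, as.data.frame(g)), , drop = FALSE]
}

#' Refine voting weights on held-out base predictions
#'
#' Picks the weight tuple maximizing voting accuracy of
#' `sign(sum_i w_i BC_i)` on the supplied (inner-CV) predictions, with
#' ties broken toward the tuple closest to uniform (minimum variance) and
#' then by lexicographic order.
#'
#' @param predictions Matrix of +/-1 base-classifier predictions
#'   (classifiers x samples).
#' @param truth +/-1 labels.
#' @param grid Candidate weight matrix, see [default_weight_grid()].
#' @param tie_label Label assigned when the weighted vote sums to exactly
#'   0 (default -1, the less severe class).
#' @return The selected weight vector, with attribute `accuracy`.
#' @export
refine_weights <- function(predictions, truth, grid = default_weight_grid(),
                           tie_label = -1) {
  predictions <- as.matrix(predictions)
  stopifnot(nrow(grid) >= 1, ncol(grid) == nrow(predictions))
  votes <- grid %*% predictions
  pred <- ifelse(votes > 0, 1, ifelse(votes < 0, -1, tie_label))
  acc <- rowMeans(pred == matrix(truth, nrow(grid), length(truth),
                                 byrow = TRUE))
  best <- which(acc == max(acc))
  if (length(best) > 1) {
    v <- apply(grid[best, , drop = FALSE], 1, stats::var)
    best <- best[v == min(v)]  # grid rows are lexicographically ordered
  }
  w <- grid[best[1], ]
  attr(w, "accuracy") <- acc[best[1]]
  w
}

#' Fit the five-classifier voting ensemble
#'
#' @param X Full training feature matrix.
#' @param y +/-1 training labels.
#' @param specs Base-learner specifications ([default_learner_specs()]).
#' @param params Per-learner hyperparameter sets (named by kind); `NULL`
#'   uses each spec's default.
#' @param weights Voting weight vector (one per learner), nonnegative and
#'   not all zero.
#' @param feature_idx Indices of the selected features; `NULL` keeps all.
#' @param tie_label Label for an exactly-zero weighted vote.
#' @param seed Integer seed; each learner receives a seed derived from
#'   `(seed, learner index)`.
#' @return An object of class `ensemble_model`.
#' @export
fit_ensemble <- function(X, y, specs = default_learner_specs(),
                         params = NULL, weights = rep(1, length(specs)),
                         feature_idx = NULL, tie_label = -1, seed = 1) {
  X <- as.matrix(X)
  stopifnot(length(weights) == length(specs), all(weights >= 0),
            any(weights > 0))
  feature_idx <- feature_idx %||% seq_len(ncol(X))
  xs <- X[, feature_idx, drop = FALSE]
  base <- lapply(seq_along(specs), function(s) {
    p <- params[[specs[[s]]$kind]] %||% specs[[s]]$params
    fit_base(specs[[s]], xs, y, params = p, seed = seed + s)
  })
  names(base) <- vapply(specs, `[[`, character(1), "kind")
  structure(list(base = base, weights = weights,
                 feature_idx = feature_idx, tie_label = tie_label),
            class = "ensemble_model")
}

.base_matrix <- function(model, X, type) {
  xs <- as.matrix(X)[, model$feature_idx, drop = FALSE]
  t(vapply(model$base, function(b) predict(b, xs, type = type),
           numeric(nrow(xs))))
}

#' Ensemble vote
#'
#' `C(x) = sign(sum_i w_i BC_i(x))` with `BC_i(x)` in \{+1, -1\}; an
#' exactly-zero sum yields the configured tie label.
#'
#' @param model An `ensemble_model`.
#' @param X Feature matrix (full feature set; the model applies its own
#'   selection).
#' @return +/-1 label vector.
#' @export
vote <- function(model, X) {
  stopifnot(inherits(model, "ensemble_model"))
  s <- as.numeric(model$weights %*% .base_matrix(model, X, "label"))
  ifelse(s > 0, 1, ifelse(s < 0, -1, model$tie_label))
}

#' Continuous ensemble decision score
#'
#' `sum_i w_i score_i(x)` with each base score in `[-1, 1]`; used for ROC
#' AUC.
#'
#' @inheritParams vote
#' @return Numeric score vector (larger = more +1-like).
#' @export
decision_score <- function(model, X) {
  stopifnot(inherits(model, "ensemble_model"))
  as.numeric(model$weights %*% .base_matrix(model, X, "score"))
}
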
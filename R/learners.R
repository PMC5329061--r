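# The five base learners of the voting ensemble: regularized logistic
# regression, Gaussian naive Bayes, SVM, random forest and 1-nearest
# neighbor. Each exposes a +/-1 label prediction and a continuous score
# in [-1, 1] (larger = more +1-like), and is deterministic given a seed.
#
# Features are standardized inside each fitted learner using training-fold
# statistics (constant columns map to 0), so measures on very different
# scales (betweenness in the hundreds, clustering in [0, 1]) are
# comparable for the distance- and margin-based learners.

LEARNER_KINDS <- c("logistic_regression", "gaussian_naive_bayes", "svm",
                   "random_forest", "knn1")

#' Base-learner specification
#'
#' @param kind One of `"logistic_regression"`, `"gaussian_naive_bayes"`,
#'   `"svm"`, `"random_forest"`, `"knn1"`.
#' @param grid List of candidate hyperparameter sets (named lists), used
#'   by the inner-CV grid search; the first entry is the default.
#' @return A list of class `learner_spec` with elements `kind`, `grid`,
#'   `params` (the default parameter set).
#' @export
learner_spec <- function(kind, grid = list(list())) {
  kind <- match.arg(kind, LEARNER_KINDS)
  stopifnot(length(grid) >= 1)
  structure(list(kind = kind, grid = grid, params = grid[[1]]),
            class = "learner_spec")
}

#' Default specifications for the five base learners
#'
#' Full grids: logistic regression ridge penalty
#' `lambda` in \{0.01, 0.1, 1, 10\}; SVM kernel \{linear, radial\} x cost
#' \{0.1, 1, 10\}; random forest 100 trees, depth \{unlimited, 5\};
#' naive Bayes and 1-NN have nothing to tune. The reduced grids (single
#' candidate per learner) are intended for repeated-run studies where the
#' grid search would dominate runtime.
#'
#' @param reduced If `TRUE`, collapse every grid to one candidate.
#' @return Named list of five [learner_spec()] objects.
#' @export
default_learner_specs <- function(reduced = FALSE) {
  if (reduced) {
    specs <- list(
      learner_spec("logistic_regression", list(list(lambda = 1))),
      learner_spec("gaussian_naive_bayes"),
      learner_spec("svm", list(list(kernel = "linear", cost = 1))),
      learner_spec("random_forest",
                   list(list(num_trees = 100L, max_depth = 0L))),
      learner_spec("knn1")
    )
  } else {
    specs <- list(
      learner_spec("logistic_regression",
                   lapply(c(0.01, 0.1, 1, 10), function(l) list(lambda = l))),
      learner_spec("gaussian_naive_bayes"),
      learner_spec("svm", {
        g <- expand.grid(kernel = c("linear", "radial"),
                         cost = c(0.1, 1, 10), stringsAsFactors = FALSE)
        lapply(seq_len(nrow(g)),
               function(i) list(kernel = g$kernel[i], cost = g$cost[i]))
      }),
      learner_spec("random_forest",
                   list(list(num_trees = 100L, max_depth = 0L),
                        list(num_trees = 100L, max_depth = 5L))),
      learner_spec("knn1")
    )
  }
  names(specs) <- vapply(specs, `[[`, character(1), "kind")
  specs
}

.standardize_fit <- function(x) {
  n <- nrow(x)
  mu <- colMeans(x)
  s <- sqrt(pmax(colSums(x^2) - n * mu^2, 0) / (n - 1))
  s[!is.finite(s) | s < 1e-12] <- 1
  list(mu = mu, s = s)
}

.standardize_apply <- function(x, st) {
  sweep(sweep(x, 2, st$mu), 2, st$s, "/")
}

#' Fit one base classifier
#'
#' @param spec A [learner_spec()] (or a kind string).
#' @param X Training feature matrix (already restricted to the selected
#'   features).
#' @param y +1/-1 training labels; both classes must be present.
#' @param params Hyperparameter set (defaults to the spec's default).
#' @param seed Integer seed for stochastic learners (random forest,
#'   1-NN distance-tie breaking).
#' @return An object of class `base_classifier` supporting
#'   `predict(object, X)` (+1/-1 labels) and
#'   `predict(object, X, type = "score")` (scores in `[-1, 1]`).
#' @export
fit_base <- function(spec, X, y, params = NULL, seed = 1) {
  if (is.character(spec)) spec <- learner_spec(spec)
  stopifnot(inherits(spec, "learner_spec"))
  params <- params %||% spec$params
  X <- as.matrix(X)
  if (length(unique(y)) < 2) {
    stop("training labels contain a single class", call. = FALSE)
  }
  st <- .standardize_fit(X)
  xs <- .standardize_apply(X, st)
  colnames(xs) <- paste0("x", seq_len(ncol(xs)))  # positional names
  kind <- spec$kind
  fit <- switch(
    kind,
    logistic_regression = {
      # glmnet needs >= 2 columns; pad with a zero column when k = 1
      xg <- if (ncol(xs) == 1) cbind(xs, 0) else xs
      glmnet::glmnet(xg, factor(y, levels = c(-1, 1)), family = "binomial",
                     alpha = 0, lambda = params$lambda %||% 1,
                     standardize = FALSE)
    },
    gaussian_naive_bayes = .fit_gnb(xs, y, params),
    svm = e1071::svm(xs, factor(y, levels = c(-1, 1)),
                     kernel = params$kernel %||% "linear",
                     cost = params$cost %||% 1, scale = FALSE),
    random_forest = {
      depth <- params$max_depth %||% 0L
      ranger::ranger(y = factor(y, levels = c(-1, 1)),
                     x = as.data.frame(xs),
                     num.trees = params$num_trees %||% 100L,
                     max.depth = if (depth > 0) depth else NULL,
                     probability = TRUE, seed = seed, num.threads = 1)
    },
    knn1 = list(train = xs, y = y)
  )
  structure(list(kind = kind, fit = fit, standardize = st,
                 params = params, seed = seed),
            class = "base_classifier")
}

# Gaussian naive Bayes with variance smoothing: per-class per-feature
# normal likelihoods, variances floored at 1e-9 x the largest overall
# feature variance so zero-variance features (common after nodal-measure
# selection) stay well-defined.
.fit_gnb <- function(xs, y, params) {
  colvar <- function(m) {
    n <- nrow(m)
    pmax(colSums(m^2) - n * colMeans(m)^2, 0) / max(n - 1, 1)
  }
  eps <- (params$var_smoothing %||% 1e-9) * max(colvar(xs), 1e-12)
  classes <- c(-1, 1)
  stats_by_class <- lapply(classes, function(cl) {
    xc <- xs[y == cl, , drop = FALSE]
    list(mu = colMeans(xc),
         var = colvar(xc) + eps,
         logprior = log(nrow(xc) / length(y)))
  })
  names(stats_by_class) <- as.character(classes)
  stats_by_class
}

.predict_gnb_score <- function(fit, xs) {
  loglik <- vapply(fit, function(cl) {
    centered <- sweep(xs, 2, cl$mu)
    -0.5 * (centered^2 %*% (1 / cl$var))[, 1] -
      0.5 * sum(log(2 * pi * cl$var)) + cl$logprior
  }, numeric(nrow(xs)))
  if (nrow(xs) == 1) loglik <- matrix(loglik, nrow = 1)
  # posterior P(+1) via log-sum-exp
  m <- pmax(loglik[, 1], loglik[, 2])
  p1 <- exp(loglik[, 2] - m) /
    (exp(loglik[, 1] - m) + exp(loglik[, 2] - m))
  2 * p1 - 1
}

#' Predict labels or scores from a fitted base classifier
#'
#' Scores are squashed through `tanh` to `[-1, 1]` for comparability
#' across learner kinds; labels are `sign(score)` with ties (score
#' exactly 0) mapped to +1 for all kinds except 1-NN, whose score is its
#' own +/-1 vote.
#'
#' @param object A `base_classifier`.
#' @param newdata Feature matrix with the same columns as at fit time.
#' @param type `"label"` (+1/-1) or `"score"` (numeric in `[-1, 1]`).
#' @param ... Unused.
#' @return Numeric vector of labels or scores.
#' @export
predict.base_classifier <- function(object, newdata,
                                    type = c("label", "score"), ...) {
  type <- match.arg(type)
  xs <- .standardize_apply(as.matrix(newdata), object$standardize)
  colnames(xs) <- paste0("x", seq_len(ncol(xs)))
  raw <- switch(
    object$kind,
    logistic_regression = {
      xg <- if (ncol(xs) == 1) cbind(xs, 0) else xs
      p <- stats::predict(object$fit, xg, type = "response")[, 1]
      2 * p - 1
    },
    gaussian_naive_bayes = .predict_gnb_score(object$fit, xs),
    svm = {
      pr <- stats::predict(object$fit, xs, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      # orient the margin so positive means class +1
      if (grepl("^-1", colnames(dv)[1])) -dv[, 1] else dv[, 1]
    },
    random_forest = {
      p <- stats::predict(object$fit, data = as.data.frame(xs),
                          num.threads = 1)$predictions
      2 * p[, "1"] - 1
    },
    knn1 = {
      set.seed(object$seed)  # class::knn breaks exact distance ties randomly
      cl <- class::knn(object$fit$train, xs,
                       factor(object$fit$y, levels = c(-1, 1)), k = 1)
      as.numeric(as.character(cl))
    }
  )
  score <- tanh(as.numeric(raw))
  if (type == "score") return(score)
  if (object$kind == "knn1") return(sign(score))
  ifelse(score >= 0, 1, -1)
}
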
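# Nested stratified five-fold cross-validation with in-fold grid search,
# feature selection and weight refinement; performance metrics; repeated-
# run median confidence intervals.
#
# Inner tuning order (one pass, grid product pruned to keep the search
# tractable): per-learner hyperparameters first (on the full feature
# set), then the feature count K via the accuracy-vs-K sweep, then the
# voting weights on the cached inner-CV base predictions at the chosen K.

#' Stratified fold assignment
#'
#' Shuffles each class independently and deals its members round-robin
#' into `k` folds, so fold class proportions match the cohort's (exact
#' for the 15 + 15 design: five folds of 3 + 3).
#'
#' @param y Class label vector.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold ids in `1..k`, aligned with `y`.
#' @export
stratified_folds <- function(y, k, seed = 1) {
  counts <- table(y)
  if (any(counts < k)) {
    stop(sprintf("class too small for %d folds (min class size %d)",
                 k, min(counts)), call. = FALSE)
  }
  set.seed(seed)
  folds <- integer(length(y))
  for (cl in names(counts)) {
    idx <- sample(which(y == cl))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Nested cross-validation configuration
#'
#' @param outer_folds,inner_folds Fold counts (default 5 and 5).
#' @param k_grid Candidate feature counts, see [default_k_grid()].
#' @param specs Base-learner specifications with hyperparameter grids.
#' @param weight_grid Voting-weight candidates, see
#'   [default_weight_grid()].
#' @param tie_label Label for an exactly-zero weighted vote (default -1).
#' @param seed Global integer seed; fold assignments and every stochastic
#'   learner derive their seeds from it.
#' @param reduced Convenience switch: use the reduced learner grids and K
#'   grid intended for repeated-run studies.
#' @return A list of class `nested_cv_config`.
#' @export
nested_cv_config <- function(outer_folds = 5, inner_folds = 5,
                             k_grid = NULL, specs = NULL,
                             weight_grid = default_weight_grid(),
                             tie_label = -1, seed = 1, reduced = FALSE) {
  structure(
    list(outer_folds = outer_folds, inner_folds = inner_folds,
         k_grid = k_grid %||% default_k_grid(reduced),
         specs = specs %||% default_learner_specs(reduced),
         weight_grid = weight_grid, tie_label = tie_label, seed = seed),
    class = "nested_cv_config"
  )
}

# Inner-CV accuracy of a single learner for one hyperparameter set.
.inner_learner_accuracy <- function(spec, params, x, y, folds, seed) {
  pred <- numeric(length(y))
  for (g in sort(unique(folds))) {
    tr <- folds != g
    fit <- fit_base(spec, x[tr, , drop = FALSE], y[tr], params = params,
                    seed = seed + g)
    pred[!tr] <- predict(fit, x[!tr, , drop = FALSE])
  }
  mean(pred == y)
}

# Grid-search each learner's hyperparameters by inner-CV accuracy on the
# full feature set; ties go to the earlier grid entry.
.tune_hyperparams <- function(specs, x, y, folds, seed) {
  chosen <- lapply(seq_along(specs), function(s) {
    spec <- specs[[s]]
    if (length(spec$grid) == 1) return(spec$grid[[1]])
    acc <- vapply(spec$grid, function(p) {
      .inner_learner_accuracy(spec, p, x, y, folds, seed + 1000L * s)
    }, numeric(1))
    spec$grid[[which.max(acc)]]
  })
  names(chosen) <- vapply(specs, `[[`, character(1), "kind")
  chosen
}

#' Nested cross-validated evaluation of the ensemble pipeline
#'
#' Stratified outer folds estimate generalization; within each outer
#' training set an inner stratified CV tunes per-learner hyperparameters,
#' the feature count K (ANOVA-F top-K, refit on every inner training
#' fold) and the voting weights. The tuned ensemble is refit on the full
#' outer training set and predicts the held-out fold, so every subject is
#' predicted exactly once and no selection step ever sees its test data.
#'
#' @param dataset A `labeled_dataset` (see [labeled_dataset()]).
#' @param config A [nested_cv_config()].
#' @return Object of class `evaluation_result`: `predictions` (data frame
#'   with `subject_id`, `truth`, `fold`, `pred`, `score`), `confusion`,
#'   `metrics` (see [compute_metrics()]), and `folds` (per-outer-fold
#'   chosen hyperparameters, `k`, weights, inner accuracy and pairwise Q
#'   diversity matrix).
#' @export
nested_cv <- function(dataset, config = nested_cv_config()) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  x <- dataset$X
  y <- dataset$y
  outer <- stratified_folds(y, config$outer_folds, config$seed)
  pred <- numeric(length(y))
  score <- numeric(length(y))
  fold_info <- vector("list", config$outer_folds)
  for (f in seq_len(config$outer_folds)) {
    tr <- outer != f
    xtr <- x[tr, , drop = FALSE]
    ytr <- y[tr]
    seed_f <- config$seed + 10000L * f
    inner <- stratified_folds(ytr, config$inner_folds, seed_f)
    params <- .tune_hyperparams(config$specs, xtr, ytr, inner, seed_f)
    specs_tuned <- lapply(seq_along(config$specs), function(s) {
      sp <- config$specs[[s]]
      sp$params <- params[[sp$kind]]
      sp
    })
    names(specs_tuned) <- names(params)
    k_grid <- unique(pmin(config$k_grid, ncol(x)))
    sub <- dataset
    sub$X <- xtr
    sub$y <- ytr
    sub$subject_id <- dataset$subject_id[tr]
    sw <- sweep_k(sub, k_grid, specs_tuned, config$inner_folds, seed_f)
    inner_pred <- sw$predictions[[as.character(sw$best_k)]]
    w <- refine_weights(inner_pred, ytr, config$weight_grid,
                        config$tie_label)
    ranking <- anova_f_scores(xtr, ytr)
    idx <- select_k_best(ranking, sw$best_k)
    model <- fit_ensemble(xtr, ytr, specs_tuned, params = params,
                          weights = as.numeric(w), feature_idx = idx,
                          tie_label = config$tie_label, seed = seed_f)
    pred[!tr] <- vote(model, x[!tr, , drop = FALSE])
    score[!tr] <- decision_score(model, x[!tr, , drop = FALSE])
    fold_info[[f]] <- list(
      fold = f, k = sw$best_k, weights = as.numeric(w),
      hyperparams = params, inner_accuracy = attr(w, "accuracy"),
      sweep = sw$curve, q_matrix = pairwise_diversity(inner_pred, ytr),
      selected_features = dataset$feature_names[idx]
    )
  }
  metrics <- compute_metrics(pred, score, y)
  structure(
    list(predictions = data.frame(subject_id = dataset$subject_id,
                                  truth = y, fold = outer,
                                  pred = pred, score = score,
                                  stringsAsFactors = FALSE),
         confusion = attr(metrics, "confusion"), metrics = metrics,
         folds = fold_info, task = dataset$task, config = config),
    class = "evaluation_result"
  )
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf("<evaluation_result> task %s, %d subjects\n",
              x$task %||% "?", nrow(x$predictions)))
  print(round(unlist(x$metrics), 3))
  invisible(x)
}

#' Classification performance metrics
#'
#' Accuracy, recall (sensitivity) `TP/(TP+FN)`, precision `TP/(TP+FP)`,
#' specificity `TN/(TN+FP)`, F1 (harmonic mean of precision and recall)
#' and ROC AUC from the continuous decision scores (rank/trapezoidal
#' form, tied scores averaged). The positive class is +1. Any metric with
#' a zero denominator is reported as `NA`.
#'
#' @param predictions +/-1 predicted labels.
#' @param scores Continuous decision scores (`NULL` omits AUC).
#' @param truth +/-1 true labels; both classes must be present.
#' @return Named list of metrics with attribute `confusion` (named vector
#'   `TP`, `FP`, `TN`, `FN`).
#' @export
compute_metrics <- function(predictions, scores = NULL, truth) {
  stopifnot(length(predictions) == length(truth))
  if (length(unique(truth)) < 2) {
    stop("truth must contain both classes", call. = FALSE)
  }
  tp <- sum(predictions == 1 & truth == 1)
  fp <- sum(predictions == 1 & truth == -1)
  tn <- sum(predictions == -1 & truth == -1)
  fn <- sum(predictions == -1 & truth == 1)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  recall <- ratio(tp, tp + fn)
  precision <- ratio(tp, tp + fp)
  f1 <- if (is.na(recall) || is.na(precision) || recall + precision == 0) {
    NA_real_
  } else 2 * precision * recall / (precision + recall)
  auc <- if (is.null(scores)) NA_real_ else roc_auc(scores, truth)
  out <- list(accuracy = (tp + tn) / length(truth), recall = recall,
              precision = precision, specificity = ratio(tn, tn + fp),
              f1 = f1, auc = auc)
  attr(out, "confusion") <- c(TP = tp, FP = fp, TN = tn, FN = fn)
  out
}

#' ROC AUC from continuous scores
#'
#' Rank (Mann-Whitney) form, equivalent to the trapezoidal area with tied
#' scores averaged; invariant under strictly monotone score transforms.
#'
#' @param scores Continuous decision scores.
#' @param truth +/-1 labels.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, truth) {
  np <- sum(truth == 1)
  nn <- sum(truth == -1)
  if (np == 0 || nn == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[truth == 1]) - np * (np + 1) / 2) / (np * nn)
}

#' Distribution-free confidence interval for the median
#'
#' Binomial order-statistic interval: for a sample of size `n` the
#' interval runs from the `floor((n - z sqrt(n))/2)`-th to the
#' `ceiling(1 + (n + z sqrt(n))/2)`-th order statistic
#' (`z = qnorm(0.975)` for 95%), clamped to `[1, n]`.
#'
#' @param x Numeric sample.
#' @param conf Confidence level.
#' @return Named vector `median`, `lower`, `upper`.
#' @export
median_ci <- function(x, conf = 0.95) {
  n <- length(x)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  lo <- max(1L, floor((n - z * sqrt(n)) / 2))
  hi <- min(n, ceiling(1 + (n + z * sqrt(n)) / 2))
  s <- sort(x)
  c(median = stats::median(x), lower = s[lo], upper = s[hi])
}

#' Repeated-run median confidence intervals for the nested-CV metrics
#'
#' Repeats [nested_cv()] with distinct fold-assignment seeds, tests each
#' metric's sample for normality (Shapiro-Wilk) and reports the median
#' with a 95% distribution-free order-statistic interval.
#'
#' @param dataset A `labeled_dataset`.
#' @param config A [nested_cv_config()]; repeat `r` uses seed
#'   `config$seed + r`.
#' @param n_repeats Number of repeats (at least 20).
#' @return A list with `summary` (data frame: metric, median, lower,
#'   upper, shapiro_p) and `samples` (repeats x metrics matrix).
#' @export
repeated_run_ci <- function(dataset, config = nested_cv_config(),
                            n_repeats = 100) {
  stopifnot(n_repeats >= 20)
  metric_names <- c("accuracy", "recall", "specificity", "f1", "auc")
  samples <- matrix(NA_real_, n_repeats, length(metric_names),
                    dimnames = list(NULL, metric_names))
  for (r in seq_len(n_repeats)) {
    cfg <- config
    cfg$seed <- config$seed + r
    res <- nested_cv(dataset, cfg)
    samples[r, ] <- unlist(res$metrics[metric_names])
  }
  summary <- do.call(rbind, lapply(metric_names, function(m) {
    v <- samples[, m]
    v <- v[!is.na(v)]
    ci <- median_ci(v)
    sw <- if (length(unique(v)) > 2 && length(v) >= 3) {
      tryCatch(stats::shapiro.test(v)$p.value, error = function(e) NA_real_)
    } else NA_real_
    data.frame(metric = m, median = ci[["median"]], lower = ci[["lower"]],
               upper = ci[["upper"]], shapiro_p = sw,
               stringsAsFactors = FALSE)
  }))
  list(summary = summary, samples = samples)
}

#' Pooled two-sample t-test
#'
#' Equal-variance two-tailed t-test (the variant that reproduces the
#' reference cohort's reported age p-values from its raw roster). Two
#' identical constant groups give `t = 0`, `p = 1`.
#'
#' @param a,b Numeric vectors (each of length at least 2).
#' @return Named list `t`, `p`, `df`.
#' @export
two_sample_t_test <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  df <- length(a) + length(b) - 2
  sp2 <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) / df
  se <- sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  if (se == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, p = 1, df = df))
    return(list(t = sign(mean(a) - mean(b)) * Inf, p = 0, df = df))
  }
  t <- (mean(a) - mean(b)) / se
  list(t = t, p = 2 * stats::pt(-abs(t), df), df = df)
}

#' Per-group demographic summary
#'
#' Sample mean and SD (n-1 denominator) of age and education, and sex
#' proportions, per group. SD of a single-subject group is `NA`.
#'
#' @param subjects Data frame with columns `group`, `age`, `education`,
#'   `sex`, or a `cohort`.
#' @return Data frame, one row per group.
#' @export
group_summary <- function(subjects) {
  if (inherits(subjects, "cohort")) subjects <- subjects$subjects
  groups <- intersect(GROUP_LEVELS, unique(subjects$group))
  do.call(rbind, lapply(groups, function(g) {
    s <- subjects[subjects$group == g, , drop = FALSE]
    sdna <- function(x) if (length(x) < 2) NA_real_ else stats::sd(x)
    data.frame(group = g, n = nrow(s),
               age_mean = mean(s$age), age_sd = sdna(s$age),
               education_mean = mean(s$education),
               education_sd = sdna(s$education),
               prop_female = mean(s$sex == "F"),
               stringsAsFactors = FALSE)
  }))
}
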
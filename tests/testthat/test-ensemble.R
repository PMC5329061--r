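# Base learners, Q-statistic diversity, weighted voting and weight
# refinement.

blobs <- function(n_per_class = 20, gap = 6, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(2 * n_per_class), ncol = 2) + gap / 2,
             matrix(rnorm(2 * n_per_class), ncol = 2) - gap / 2)
  colnames(x) <- c("u", "v")
  list(X = x, y = rep(c(1, -1), each = n_per_class))
}

test_that("Q statistic follows its closed form and range", {
  expect_equal(q_statistic(5, 1, 1, 3), 14 / 16)
  expect_equal(q_statistic(0, 3, 2, 0), -1)
  # identical predictions with >= 1 correct and >= 1 error -> Q = 1
  truth <- c(1, 1, -1, -1)
  p <- c(1, -1, -1, -1)
  expect_equal(q_statistic(q_outcome(p, p, truth)), 1)
  # all-correct pair: denominator 0 -> missing, not 0
  expect_true(is.na(q_statistic(q_outcome(truth, truth, truth))))
  expect_error(q_statistic(-1, 0, 0, 2))
})

test_that("pairwise diversity matrix is symmetric with unit diagonal", {
  set.seed(2)
  truth <- sample(c(1, -1), 30, replace = TRUE)
  p <- rbind(a = truth * sample(c(1, -1), 30, TRUE, prob = c(0.8, 0.2)),
             b = truth * sample(c(1, -1), 30, TRUE, prob = c(0.7, 0.3)),
             c = sample(c(1, -1), 30, TRUE))
  q <- pairwise_diversity(p, truth)
  expect_equal(q, t(q))
  expect_equal(diag(q), c(a = 1, b = 1, c = 1))
  expect_true(all(q[!is.na(q)] >= -1 & q[!is.na(q)] <= 1))
  expect_error(pairwise_diversity(p[, 1:10], truth), "lengths differ")
})

test_that("independent classifiers have near-zero mean Q", {
  set.seed(7)
  n <- 10000
  truth <- sample(c(1, -1), n, replace = TRUE)
  p <- matrix(sample(c(1, -1), 5 * n, replace = TRUE), 5, n)
  q <- pairwise_diversity(p, truth)
  expect_lt(abs(mean(q[upper.tri(q)])), 0.05)
})

test_that("all five learner kinds separate linearly separable blobs", {
  d <- blobs(seed = 3)
  for (spec in default_learner_specs()) {
    fit <- fit_base(spec, d$X, d$y, seed = 5)
    expect_equal(predict(fit, d$X), d$y,
                 info = spec$kind)
    sc <- predict(fit, d$X, type = "score")
    expect_true(all(abs(sc) <= 1), info = spec$kind)
    expect_equal(sign(sc), d$y, info = spec$kind)
  }
})

test_that("1-NN predicts its own training labels", {
  set.seed(4)
  x <- matrix(rnorm(40), 20, 2)
  y <- rep(c(1, -1), 10)
  fit <- fit_base("knn1", x, y)
  expect_equal(predict(fit, x), y)
})

test_that("Gaussian NB boundary sits midway between symmetric classes", {
  set.seed(6)
  x <- cbind(c(rnorm(50, -2, 1), rnorm(50, 2, 1)), rnorm(100))
  y <- rep(c(-1, 1), each = 50)
  fit <- fit_base("gaussian_naive_bayes", x, y, seed = 1)
  grid <- cbind(seq(-4, 4, by = 0.25), 0)
  sc <- predict(fit, grid, type = "score")
  crossing <- grid[which.min(abs(sc)), 1]
  expect_lt(abs(crossing), 0.5)
  expect_true(all(diff(sc) >= -1e-12))  # monotone along the axis
})

test_that("in-package Gaussian NB agrees with e1071 on clean data", {
  skip_if_not_installed("e1071")
  set.seed(8)
  x <- matrix(rnorm(200, sd = 2), 50, 4)
  y <- rep(c(1, -1), 25)
  x[y == 1, 1] <- x[y == 1, 1] + 1.5
  fit <- fit_base("gaussian_naive_bayes", x, y, seed = 1)
  ref <- e1071::naiveBayes(x, factor(y))
  p_ref <- predict(ref, x, type = "raw")[, "1"]
  sc <- predict(fit, x, type = "score")
  expect_equal(sc, tanh(2 * p_ref - 1), tolerance = 1e-6)
})

test_that("learners with a zero-variance feature still fit and predict", {
  d <- blobs(seed = 9)
  x <- cbind(d$X, const = 1)
  for (spec in default_learner_specs()) {
    fit <- fit_base(spec, x, d$y, seed = 2)
    expect_true(all(predict(fit, x) %in% c(-1, 1)), info = spec$kind)
  }
})

test_that("single-class training labels are rejected", {
  expect_error(fit_base("svm", matrix(rnorm(10), 5), rep(1, 5)),
               "single class")
})

test_that("voting follows Eq. sign(sum w_i BC_i) with the stated tie rule", {
  votes <- c(1, 1, -1, -1, 1)
  expect_equal(sign(sum(rep(1, 5) * votes)), 1)
  d <- blobs(seed = 10)
  model <- fit_ensemble(d$X, d$y, weights = rep(1, 5), seed = 3)
  expect_true(all(vote(model, d$X) %in% c(-1, 1)))

  # degenerate weights reproduce the single weighted classifier exactly
  for (s in 1:5) {
    w <- rep(0, 5); w[s] <- 1
    m1 <- fit_ensemble(d$X, d$y, weights = w, seed = 3)
    expect_equal(vote(m1, d$X), predict(m1$base[[s]], d$X),
                 info = names(m1$base)[s])
  }

  # exact zero vote -> configured tie label
  x <- matrix(0, 1, 2)
  fake <- fit_ensemble(d$X, d$y, weights = c(1, 1, 1, 1, 0), seed = 3)
  lab <- matrix(c(1, 1, -1, -1, 1), 5, 1)
  s <- as.numeric(c(1, 1, 1, 1, 0) %*% lab)
  expect_equal(ifelse(s > 0, 1, ifelse(s < 0, -1, fake$tie_label)), -1)
})

test_that("prediction is invariant to uniform positive weight rescaling", {
  d <- blobs(n_per_class = 15, gap = 2, seed = 12)
  m1 <- fit_ensemble(d$X, d$y, weights = c(1, 0.5, 2, 1, 1), seed = 4)
  m2 <- fit_ensemble(d$X, d$y, weights = 10 * c(1, 0.5, 2, 1, 1), seed = 4)
  set.seed(99)
  xnew <- matrix(rnorm(40), 20, 2)
  expect_equal(vote(m1, xnew), vote(m2, xnew))
  expect_equal(decision_score(m2, xnew), 10 * decision_score(m1, xnew))
})

test_that("decision score is consistent with votes and separability", {
  d <- blobs(seed = 14)
  model <- fit_ensemble(d$X, d$y, weights = rep(1, 5), seed = 5)
  sc <- decision_score(model, d$X)
  expect_equal(roc_auc(sc, d$y), 1)
  v <- vote(model, d$X)
  agree <- sign(sc) != 0 & sign(sc) == v
  expect_true(all(agree[abs(sc) > 1e-8]))
  # antisymmetry under class swap: flipping labels flips the score
  model2 <- fit_ensemble(d$X, -d$y, weights = rep(1, 5), seed = 5)
  sc2 <- decision_score(model2, d$X)
  expect_equal(sign(sc2[abs(sc2) > 1e-8]), -sign(sc[abs(sc2) > 1e-8]))
})

test_that("weight refinement concentrates on a planted perfect classifier", {
  hits <- vapply(1:10, function(seed) {
    set.seed(seed)
    n <- 40
    truth <- sample(c(1, -1), n, replace = TRUE)
    p <- rbind(truth,
               matrix(sample(c(1, -1), 4 * n, replace = TRUE), 4, n))
    w <- refine_weights(p, truth)
    w[1] == max(w) && attr(w, "accuracy") == 1
  }, logical(1))
  expect_true(all(hits))
})

test_that("weight refinement tie rules pick the uniform tuple", {
  truth <- c(1, -1, 1, -1, 1, 1)
  p <- matrix(rep(c(1, -1, 1, 1, -1, 1), each = 5), 5)
  w <- refine_weights(p, truth)  # identical classifiers: all tuples tie
  expect_equal(var(as.numeric(w)), 0)
  g1 <- matrix(c(1, 1, 1, 1, 1), 1)
  expect_equal(as.numeric(refine_weights(p, truth, grid = g1)), rep(1, 5))
})
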
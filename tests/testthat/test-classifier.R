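test_that("preprocessing drops correlated copies and standardizes", {
  set.seed(21)
  x <- data.frame(a = rnorm(100), b = rnorm(100))
  x$a_copy <- 2 * x$a + 1                 # |r| = 1 with a
  x$c <- rnorm(100)
  out <- preprocess_features(x, correlation_threshold = 0.9)
  expect_setequal(names(out), c("a", "b", "c"))
  expect_identical(attr(out, "dropped"), "a_copy")
  expect_true(all(abs(vapply(out, mean, numeric(1))) < 1e-12))
  expect_equal(unname(vapply(out, sd, numeric(1))), rep(1, 3))

  # boundary: threshold 1 keeps imperfect correlations
  x$near <- x$a + rnorm(100, 0, 1e-3)
  out1 <- preprocess_features(x, correlation_threshold = 1)
  expect_true("near" %in% names(out1))

  x$flat <- 5
  expect_warning(out2 <- preprocess_features(x), "zero-variance")
  expect_false("flat" %in% names(out2))
})

test_that("stratified folds contain every class", {
  labels <- factor(rep(c("a", "b", "c"), times = c(40, 25, 10)))
  fold <- stratified_folds(labels, k = 5, seed = 3)
  expect_true(all(table(fold, labels) > 0))
  expect_equal(sort(unique(fold)), 1:5)
  # deterministic under a fixed seed
  expect_identical(fold, stratified_folds(labels, k = 5, seed = 3))
})

test_that("a perfectly separable dataset is learned by tree models", {
  set.seed(31)
  n <- 300
  x <- data.frame(x1 = runif(n), x2 = rnorm(n))
  y <- cut(x$x1, breaks = c(-Inf, 0.3, 0.6, Inf), labels = c("g1", "g2", "g3"))
  perf <- train_evaluate(x, y, models = c("decision_tree", "random_forest"),
                         grid_size = 5, seed = 2)
  expect_true(all(perf$accuracy_mean > 0.9))
  expect_true(all(perf$auroc_mean > 0.95))
})

test_that("shuffled labels score at the stratified-null level", {
  set.seed(32)
  n <- 300
  x <- data.frame(x1 = runif(n), x2 = rnorm(n), x3 = runif(n))
  # balanced classes, so no majority-class shortcut is available
  y <- factor(sample(c("g1", "g2", "g3"), n, replace = TRUE))
  perf <- train_evaluate(x, y, models = "random_forest", grid_size = 5,
                         seed = 2)
  null <- null_accuracy_distribution(rep(1 / 3, 3), n_items = n / 5,
                                     n_samples = 2e4, seed = 5)
  expect_lt(abs(perf$accuracy_mean - null$mean), 2 * null$sd)
})

test_that("null accuracy matches the closed form sum of squared proportions", {
  one <- null_accuracy_distribution(1, n_items = 50, n_samples = 100, seed = 1)
  expect_equal(one$mean, 1)
  expect_equal(one$sd, 0)

  five <- null_accuracy_distribution(rep(0.2, 5), n_items = 76,
                                     n_samples = 2e4, seed = 1)
  expect_equal(five$mean, 0.2, tolerance = 0.01)

  p <- c(0.45, 0.3, 0.15, 0.1)
  null <- null_accuracy_distribution(p, n_items = 80, n_samples = 2e4,
                                     seed = 2)
  se <- null$sd / sqrt(null$n_samples)
  expect_lt(abs(null$mean - sum(p^2)), 3 * se + 1e-9)
  expect_equal(null$p_value_for(1.01), 0)
  expect_equal(null$p_value_for(0), 1)
})

test_that("variable importance singles out the informative feature", {
  set.seed(33)
  n <- 400
  x <- data.frame(signal = runif(n), noise1 = rnorm(n), noise2 = runif(n))
  y <- factor(ifelse(x$signal > 0.5, "hi", "lo"))
  rf <- fit_random_forest(x, y, seed = 7)
  imp <- variable_importance(rf)
  expect_identical(names(imp)[1], "signal")
  expect_true(all(imp >= 0))
  expect_error(variable_importance(list()), "ranger")
})

test_that("evaluation is reproducible under a fixed seed", {
  set.seed(34)
  n <- 150
  x <- data.frame(x1 = runif(n), x2 = rnorm(n))
  y <- factor(ifelse(x$x1 + 0.3 * rnorm(n) > 0.5, "a", "b"))
  p1 <- train_evaluate(x, y, models = "decision_tree", grid_size = 3,
                       seed = 9)
  p2 <- train_evaluate(x, y, models = "decision_tree", grid_size = 3,
                       seed = 9)
  expect_identical(p1, p2)
})

test_that("all five model families run end to end on a small problem", {
  set.seed(35)
  n <- 120
  x <- data.frame(x1 = runif(n), x2 = rnorm(n))
  y <- factor(ifelse(x$x1 > 0.5, "a", "b"))
  perf <- train_evaluate(x, y,
                         models = c("knn", "decision_tree", "bagging",
                                    "random_forest", "boosted_trees"),
                         grid_size = 2, seed = 4)
  expect_identical(nrow(perf), 5L)
  expect_true(all(perf$accuracy_mean >= 0 & perf$accuracy_mean <= 1))
  expect_true(all(perf$auroc_mean >= 0 & perf$auroc_mean <= 1))
  expect_true(all(perf$accuracy_sd >= 0))
})
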
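#' @title Predicting the Arrhenius group from genetic-code features
#'
#' @description
#' Multiclass classification of the 380 ordered substitution pairs: the
#' response is the pre-exponential group (one of five Arrhenius levels) and
#' the predictors are the ten genetic-code features. Models are tuned with
#' random hyperparameter grids on macro AUROC and evaluated by stratified
#' 5-fold cross-validation; observed accuracies are judged against a
#' stratified random-guessing null.
#'
#' @name code_classifier
NULL

#' Correlation-filter and standardize a feature table
#'
#' Zero-variance features are dropped with a warning. Then, scanning
#' feature pairs in canonical column order, the later member of any pair
#' with absolute Pearson correlation above `correlation_threshold` is
#' dropped. Survivors are centered to mean 0 and scaled to sd 1.
#'
#' @param features Numeric data frame or matrix (rows = pairs).
#' @param correlation_threshold Absolute-correlation cutoff (default 0.9).
#' @return Standardized data frame; dropped column names are recorded in
#'   attribute `"dropped"`.
#' @export
preprocess_features <- function(features, correlation_threshold = 0.9) {
  x <- as.data.frame(features)
  stopifnot(ncol(x) >= 2L)
  sds <- vapply(x, stats::sd, numeric(1))
  if (any(sds == 0)) {
    warning("dropping zero-variance feature(s): ",
            paste(names(x)[sds == 0], collapse = ", "))
  }
  dropped <- names(x)[sds == 0]
  x <- x[, sds > 0, drop = FALSE]
  keep <- logical(ncol(x))
  for (j in seq_len(ncol(x))) {
    earlier <- which(keep)
    high <- length(earlier) > 0 &&
      any(abs(stats::cor(x[[j]], x[, earlier, drop = FALSE])) >
            correlation_threshold)
    keep[j] <- !high
  }
  dropped <- c(dropped, names(x)[!keep])
  x <- x[, keep, drop = FALSE]
  x[] <- lapply(x, function(col) as.numeric(scale(col)))
  attr(x, "dropped") <- dropped
  x
}

#' Stratified cross-validation folds
#'
#' Assigns each row to one of `k` folds, stratifying by label so every fold
#' contains every class whenever class sizes allow. If a fold misses a
#' class, the assignment is redrawn with an incremented seed (reported).
#'
#' @param labels Factor (or coercible) of class labels.
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @return Integer vector of fold ids in `1:k`.
#' @export
stratified_folds <- function(labels, k = 5, seed = 1) {
  labels <- as.factor(labels)
  n <- length(labels)
  for (attempt in 0:20) {
    set.seed(seed + attempt)
    fold <- integer(n)
    for (cls in levels(labels)) {
      idx <- which(labels == cls)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    complete <- all(table(fold, labels) > 0) ||
      any(table(labels) < k)   # a class smaller than k can never fill all folds
    if (complete) {
      if (attempt > 0) message("folds re-stratified with seed offset ", attempt)
      return(fold)
    }
  }
  stop("could not stratify folds", call. = FALSE)
}

# ---- model engines -------------------------------------------------------
# Each engine takes (train_x, train_y, test_x, params) and returns an
# n_test x nlevels matrix of class probabilities.

engine_knn <- function(train_x, train_y, test_x, params) {
  k <- params$k
  d <- as.matrix(stats::dist(rbind(as.matrix(test_x), as.matrix(train_x))))
  nte <- nrow(test_x)
  d <- d[seq_len(nte), -seq_len(nte), drop = FALSE]
  lev <- levels(train_y)
  probs <- t(apply(d, 1, function(row) {
    nb <- train_y[order(row)[seq_len(k)]]
    as.numeric(table(factor(nb, levels = lev))) / k
  }))
  colnames(probs) <- lev
  probs
}

engine_decision_tree <- function(train_x, train_y, test_x, params) {
  df <- data.frame(train_x, .y = train_y)
  fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                      control = rpart::rpart.control(
                        cp = params$cp, minsplit = params$minsplit,
                        maxdepth = params$maxdepth, xval = 0))
  stats::predict(fit, newdata = data.frame(test_x), type = "prob")
}

engine_ranger <- function(train_x, train_y, test_x, params, bagging = FALSE) {
  mtry <- if (bagging) ncol(train_x) else min(params$mtry, ncol(train_x))
  fit <- ranger::ranger(x = as.matrix(train_x), y = train_y,
                        num.trees = params$num_trees, mtry = mtry,
                        min.node.size = params$min_node_size,
                        probability = TRUE, seed = params$seed,
                        num.threads = 1)
  stats::predict(fit, data = as.matrix(test_x),
                 num.threads = 1)$predictions
}

engine_xgboost <- function(train_x, train_y, test_x, params) {
  lev <- levels(train_y)
  dtrain <- xgboost::xgb.DMatrix(as.matrix(train_x),
                                 label = as.integer(train_y) - 1L)
  fit <- xgboost::xgb.train(
    params = list(objective = "multi:softprob", num_class = length(lev),
                  eta = params$eta, max_depth = params$max_depth,
                  nthread = 1),
    data = dtrain, nrounds = params$nrounds, verbose = 0)
  probs <- stats::predict(fit, as.matrix(test_x))
  if (!is.matrix(probs))   # older xgboost returns a flat row-major vector
    probs <- matrix(probs, ncol = length(lev), byrow = TRUE)
  colnames(probs) <- lev
  probs
}

# Random hyperparameter draws for one model family.
random_grid <- function(model, grid_size) {
  switch(model,
    knn = data.frame(k = sample(1:15, grid_size, replace = TRUE)),
    decision_tree = data.frame(
      cp = 10^stats::runif(grid_size, -4, -1),
      minsplit = sample(2:40, grid_size, replace = TRUE),
      maxdepth = sample(2:30, grid_size, replace = TRUE)),
    bagging = data.frame(
      num_trees = sample(100:800, grid_size, replace = TRUE),
      min_node_size = sample(1:15, grid_size, replace = TRUE)),
    random_forest = data.frame(
      mtry = sample(1:10, grid_size, replace = TRUE),
      num_trees = sample(100:800, grid_size, replace = TRUE),
      min_node_size = sample(1:15, grid_size, replace = TRUE)),
    boosted_trees = data.frame(
      eta = 10^stats::runif(grid_size, -1.5, -0.4),
      max_depth = sample(1:8, grid_size, replace = TRUE),
      nrounds = sample(50:300, grid_size, replace = TRUE)),
    stop("unknown model: ", model, call. = FALSE))
}

predict_probs <- function(model, train_x, train_y, test_x, params) {
  switch(model,
    knn = engine_knn(train_x, train_y, test_x, params),
    decision_tree = engine_decision_tree(train_x, train_y, test_x, params),
    bagging = engine_ranger(train_x, train_y, test_x, params, bagging = TRUE),
    random_forest = engine_ranger(train_x, train_y, test_x, params),
    boosted_trees = engine_xgboost(train_x, train_y, test_x, params))
}

# Macro (one-vs-rest) multiclass metrics from a probability matrix.
fold_metrics <- function(probs, truth) {
  lev <- levels(truth)
  pred <- factor(lev[max.col(probs, ties.method = "first")], levels = lev)
  acc <- mean(pred == truth)
  sens <- spec <- auc <- numeric(0)
  for (cls in lev) {
    is_pos <- truth == cls
    if (any(is_pos)) sens <- c(sens, mean(pred[is_pos] == cls))
    if (any(!is_pos)) spec <- c(spec, mean(pred[!is_pos] != cls))
    if (any(is_pos) && any(!is_pos)) {
      roc <- pROC::roc(response = is_pos, predictor = probs[, cls],
                       levels = c(FALSE, TRUE), direction = "<",
                       quiet = TRUE)
      auc <- c(auc, as.numeric(pROC::auc(roc)))
    }
  }
  c(accuracy = acc, sensitivity = mean(sens), specificity = mean(spec),
    auroc = mean(auc))
}

#' Tune and cross-validate multiclass classifiers
#'
#' For each requested model family, `grid_size` random hyperparameter
#' configurations are evaluated on the same stratified `folds`-fold
#' cross-validation split; the configuration with the best mean macro AUROC
#' is selected and its per-fold accuracy, macro sensitivity, macro
#' specificity and macro AUROC are reported as mean and sd over the held-out
#' folds.
#'
#' @param features Numeric feature table (typically from
#'   [preprocess_features()]).
#' @param labels Class labels (factor or coercible).
#' @param models Character vector among `"knn"`, `"decision_tree"`,
#'   `"bagging"`, `"random_forest"`, `"boosted_trees"`.
#' @param folds Number of CV folds (default 5).
#' @param grid_size Random-grid size per family (default 27).
#' @param seed Integer seed controlling folds, grids and stochastic fits.
#' @return Data frame with one row per model: metric means and sds plus the
#'   selected hyperparameters (as a compact string).
#' @export
train_evaluate <- function(features,
                           labels,
                           models = c("knn", "decision_tree", "bagging",
                                      "random_forest", "boosted_trees"),
                           folds = 5,
                           grid_size = 27,
                           seed = 1) {
  models <- match.arg(models, several.ok = TRUE)
  x <- as.data.frame(features)
  y <- droplevels(as.factor(labels))
  stopifnot(nrow(x) == length(y))
  fold_id <- stratified_folds(y, k = folds, seed = seed)

  out <- lapply(models, function(model) {
    set.seed(seed + match(model, models))
    grid <- random_grid(model, grid_size)
    results <- lapply(seq_len(nrow(grid)), function(g) {
      params <- as.list(grid[g, , drop = FALSE])
      params$seed <- seed + g
      per_fold <- vapply(seq_len(folds), function(f) {
        tr <- fold_id != f
        probs <- predict_probs(model, x[tr, , drop = FALSE], y[tr],
                               x[!tr, , drop = FALSE], params)
        fold_metrics(probs, y[!tr])
      }, numeric(4))
      per_fold   # 4 x folds
    })
    tuning <- vapply(results, function(m) mean(m["auroc", ]), numeric(1))
    best <- which.max(tuning)
    m <- results[[best]]
    stats <- c(apply(m, 1, mean), apply(m, 1, stats::sd))
    names(stats) <- c(paste0(rownames(m), "_mean"), paste0(rownames(m), "_sd"))
    params <- grid[best, , drop = FALSE]
    data.frame(model = model, t(stats),
               params = paste(names(params), signif(unlist(params), 3),
                              sep = "=", collapse = ", "),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Accuracy distribution of a stratified random classifier
#'
#' Simulates `n_samples` test sets of `n_items` labels with the given class
#' strata; predictions are drawn independently from the same proportions.
#' The expected accuracy is the sum of squared class proportions.
#'
#' @param class_proportions Named or unnamed proportions summing to 1.
#' @param n_items Test-set size.
#' @param n_samples Monte-Carlo replicates (default 1e5).
#' @param seed Integer seed.
#' @return List with `mean`, `sd`, `n_samples`, `accuracies`, and
#'   `p_value_for(observed)` giving the fraction of null samples at or above
#'   the observed accuracy.
#' @export
null_accuracy_distribution <- function(class_proportions, n_items,
                                       n_samples = 1e5, seed = 1) {
  p <- class_proportions / sum(class_proportions)
  stopifnot(n_items >= 1)
  k <- length(p)
  # fixed strata: class counts proportional to p (largest remainder)
  counts <- floor(p * n_items)
  rem <- n_items - sum(counts)
  if (rem > 0) {
    extra <- order(p * n_items - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  labels <- rep(seq_len(k), counts)
  set.seed(seed)
  guesses <- matrix(sample.int(k, n_items * n_samples, replace = TRUE,
                               prob = p),
                    nrow = n_items)
  acc <- colMeans(guesses == labels)
  list(mean = mean(acc), sd = stats::sd(acc), n_samples = n_samples,
       accuracies = acc,
       p_value_for = function(observed) mean(acc >= observed))
}

#' Fit a probability random forest for importance analysis
#'
#' @param features Feature table.
#' @param labels Class labels.
#' @param num_trees,mtry,min_node_size Forest hyperparameters; `mtry`
#'   defaults to the square root of the feature count.
#' @param seed Integer seed.
#' @return A `ranger` fit with impurity (Gini) importance.
#' @export
fit_random_forest <- function(features, labels, num_trees = 500,
                              mtry = NULL, min_node_size = 1, seed = 1) {
  x <- as.matrix(as.data.frame(features))
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
  ranger::ranger(x = x, y = droplevels(as.factor(labels)),
                 num.trees = num_trees, mtry = mtry,
                 min.node.size = min_node_size, importance = "impurity",
                 seed = seed, num.threads = 1)
}

#' Gini variable importance, ranked
#'
#' @param fit A `ranger` fit with impurity importance (see
#'   [fit_random_forest()]).
#' @return Named numeric vector, decreasing mean decrease in node impurity.
#' @export
variable_importance <- function(fit) {
  if (!inherits(fit, "ranger") || is.null(fit$variable.importance) ||
      length(fit$variable.importance) == 0)
    stop("need a fitted ranger model with impurity importance", call. = FALSE)
  sort(fit$variable.importance, decreasing = TRUE)
}
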
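# The four-model menu: gradient-boosted trees, extra trees, multinomial
# logistic regression, and a small feed-forward ReLU network, plus a
# majority-vote baseline. All models consume z-scored activity feature rows
# with a Class factor.

.model_kinds <- c("logistic_regression", "extra_trees",
                  "gradient_boosted_trees", "feedforward_network",
                  "majority_baseline")

#' Default model specification for a classifier kind
#'
#' Returns the default hyperparameters for each model family. The extra
#' trees ensemble uses 42 trees, entropy splitting, up to 8717 leaf nodes
#' per tree, and 100% of the features considered at each split. The
#' feed-forward network uses 3 hidden layers of sizes (8, 5, 8) with ReLU
#' activation. Logistic regression is the multinomial baseline with no
#' added penalty. Gradient boosting defaults to leaf-wise growth with at
#' most 127 leaves, learning rate 0.1, and up to 200 boosting rounds with
#' early stopping on an inner validation slice, so the fitted ensemble ends
#' up with a tree count and leaf count of the same order as the
#' cross-validated consensus model this pipeline selects.
#'
#' @param kind One of `"logistic_regression"`, `"extra_trees"`,
#'   `"gradient_boosted_trees"`, `"feedforward_network"`,
#'   `"majority_baseline"`.
#' @param seed Integer seed stored in the spec.
#' @return An object of class `model_spec`: list with `kind`, `hyperparams`,
#'   `seed`.
#' @export
default_spec <- function(kind, seed = 1L) {
  if (!is.character(kind) || length(kind) != 1 || !(kind %in% .model_kinds))
    stop("unknown model kind: ", paste(kind, collapse = ", "))
  hp <- switch(kind,
    logistic_regression = list(objective = "multinomial", maxit = 200),
    extra_trees = list(n_trees = 42, max_leaf_nodes = 8717,
                       criterion = "entropy", features_per_split = 1.0,
                       min_node_size = 1),
    gradient_boosted_trees = list(nrounds = 200, learning_rate = 0.1,
                                  max_leaves = 127,
                                  early_stopping_rounds = 20,
                                  validation_frac = 0.15),
    feedforward_network = list(hidden = c(8, 5, 8), activation = "relu",
                               learning_rate = 0.01, batch_size = 32,
                               epochs = 200),
    majority_baseline = list()
  )
  structure(list(kind = kind, hyperparams = hp, seed = as.integer(seed)),
            class = "model_spec")
}

.model_matrix <- function(rows, features) {
  missing <- setdiff(features, names(rows))
  if (length(missing) > 0)
    stop("missing feature column(s): ", paste(missing, collapse = ", "))
  as.matrix(rows[, features, drop = FALSE])
}

#' Train a severity classifier
#'
#' Fits the model described by `spec` on normalized, labeled activity rows.
#' Tree models are deterministic given the spec seed. The fitted object
#' records training metadata: row count, classes seen, and a structural
#' summary (tree count and maximum leaf count) for the tree ensembles.
#'
#' @param spec A [default_spec()] (possibly with edited hyperparameters).
#' @param rows data.frame with feature columns and a `Class` factor; at
#'   least 2 classes must be present.
#' @param features Feature columns (default [rehab_feature_names()]).
#' @return An object of class `severity_model`.
#' @export
train_model <- function(spec, rows, features = rehab_feature_names()) {
  stopifnot(inherits(spec, "model_spec"))
  if (is.null(rows) || nrow(rows) == 0) stop("empty training set")
  if (!"Class" %in% names(rows)) stop("rows must carry a Class column")
  y <- droplevels(factor(rows$Class))
  if (nlevels(y) < 2 && spec$kind != "majority_baseline")
    stop("training set contains a single class")
  x <- .model_matrix(rows, features)
  hp <- spec$hyperparams
  set.seed(spec$seed)

  fit <- switch(spec$kind,
    logistic_regression = {
      df <- as.data.frame(x)
      df$.class <- y
      nnet::multinom(.class ~ ., data = df, trace = FALSE,
                     maxit = hp$maxit, MaxNWts = 5000)
    },
    extra_trees = {
      ranger::ranger(
        x = as.data.frame(x), y = y,
        num.trees = hp$n_trees,
        mtry = max(1, floor(hp$features_per_split * ncol(x))),
        splitrule = "extratrees", num.random.splits = 1,
        replace = FALSE, sample.fraction = 1,
        min.node.size = hp$min_node_size,
        seed = spec$seed, num.threads = 1
      )
    },
    gradient_boosted_trees = .fit_gbt(x, y, hp, spec$seed),
    feedforward_network = mlp_fit(
      x, as.integer(y), k = nlevels(y),
      hidden = hp$hidden, learning_rate = hp$learning_rate,
      batch_size = hp$batch_size, epochs = hp$epochs, seed = spec$seed
    ),
    majority_baseline = {
      tab <- table(y)
      list(mode = names(tab)[which.max(tab)])
    }
  )

  meta <- list(n_rows = nrow(rows), classes = levels(y))
  if (spec$kind == "extra_trees") {
    leaves <- vapply(seq_len(fit$num.trees), function(t) {
      sum(ranger::treeInfo(fit, t)$terminal)
    }, numeric(1))
    meta$structure <- list(n_trees = fit$num.trees,
                           max_leaves = max(leaves))
  } else if (spec$kind == "gradient_boosted_trees") {
    meta$structure <- fit$structure
  } else if (spec$kind == "feedforward_network") {
    meta$structure <- list(hidden = hp$hidden, activation = hp$activation)
  }

  structure(
    list(spec = spec, fit = fit, features = features,
         classes = levels(y), metadata = meta),
    class = "severity_model"
  )
}

# xgboost with leaf-wise growth and early stopping on an inner validation
# slice carved from the training rows (never from the holdout set).
.fit_gbt <- function(x, y, hp, seed) {
  k <- nlevels(y)
  lab <- as.integer(y) - 1L
  n <- nrow(x)
  n_val <- floor(hp$validation_frac * n)
  params <- list(
    objective = "multi:softprob", num_class = k,
    eta = hp$learning_rate, max_leaves = hp$max_leaves,
    grow_policy = "lossguide", max_depth = 0, tree_method = "hist",
    nthread = 1, seed = seed
  )
  if (n_val >= 10) {
    val_idx <- sample(n, n_val)
    dtrain <- xgboost::xgb.DMatrix(x[-val_idx, , drop = FALSE],
                                   label = lab[-val_idx])
    dval <- xgboost::xgb.DMatrix(x[val_idx, , drop = FALSE],
                                 label = lab[val_idx])
    bst <- xgboost::xgb.train(params, dtrain, nrounds = hp$nrounds,
                              evals = list(val = dval),
                              early_stopping_rounds = hp$early_stopping_rounds,
                              verbose = 0)
  } else {
    dtrain <- xgboost::xgb.DMatrix(x, label = lab)
    bst <- xgboost::xgb.train(params, dtrain, nrounds = hp$nrounds,
                              verbose = 0)
  }
  dump <- xgboost::xgb.model.dt.tree(model = bst)
  leaves_per_tree <- tapply(dump$Feature == "Leaf", dump$Tree, sum)
  list(booster = bst, k = k,
       structure = list(n_trees = length(leaves_per_tree),
                        max_leaves = max(leaves_per_tree)))
}

#' Predict severity classes for new rows
#'
#' @param object A [train_model()] fit.
#' @param newdata data.frame of rows normalized with the training
#'   normalizer.
#' @param ... Unused.
#' @return Factor of predicted classes (levels = classes seen in training).
#' @export
predict.severity_model <- function(object, newdata, ...) {
  if (is.null(newdata) || nrow(newdata) == 0)
    return(factor(character(0), levels = object$classes))
  x <- .model_matrix(newdata, object$features)
  pred <- switch(object$spec$kind,
    logistic_regression = {
      as.character(stats::predict(object$fit, newdata = as.data.frame(x)))
    },
    extra_trees = {
      as.character(stats::predict(object$fit,
                                  data = as.data.frame(x))$predictions)
    },
    gradient_boosted_trees = {
      probs <- stats::predict(object$fit$booster, xgboost::xgb.DMatrix(x))
      if (is.null(dim(probs)))
        probs <- matrix(probs, ncol = object$fit$k, byrow = TRUE)
      object$classes[max.col(probs, ties.method = "first")]
    },
    feedforward_network = {
      probs <- mlp_predict_prob(object$fit, x)
      object$classes[max.col(probs, ties.method = "first")]
    },
    majority_baseline = rep(object$fit$mode, nrow(x))
  )
  factor(pred, levels = object$classes)
}

#' Stratified k-fold cross-validation accuracy
#'
#' Splits the training rows into `k` stratified folds, holds each fold out
#' once, trains on the remainder, and records the held-out accuracy. Folds
#' partition the rows: no row appears in two held-out folds.
#'
#' @param spec A [default_spec()].
#' @param rows Labeled, normalized training rows.
#' @param k Number of folds (>= 2, and `nrow(rows) >= k`).
#' @param seed Integer seed governing fold assignment and per-fold model
#'   seeds.
#' @param features Feature columns.
#' @return An object of class `cv_result`: list with `k`, `fold_accuracy`,
#'   `mean_accuracy`, `sd_accuracy`, `fold_id` (per-row held-out fold).
#' @export
cross_validate <- function(spec, rows, k = 10, seed = 1L,
                           features = rehab_feature_names()) {
  stopifnot(inherits(spec, "model_spec"))
  n <- nrow(rows)
  if (k < 2) stop("k must be >= 2")
  if (n < k) stop("need at least k rows for k folds")
  set.seed(as.integer(seed))
  cls <- as.character(rows$Class)
  fold_id <- integer(n)
  for (cl in unique(cls)) {
    members <- which(cls == cl)
    # remainder rows land in randomly chosen folds so fold sizes stay even
    fold_id[members] <- sample(rep(sample(k), length.out = length(members)))
  }
  acc <- vapply(seq_len(k), function(fold) {
    hold <- fold_id == fold
    fold_spec <- spec
    fold_spec$seed <- as.integer(seed) + fold
    fit <- train_model(fold_spec, rows[!hold, , drop = FALSE], features)
    pred <- predict(fit, rows[hold, , drop = FALSE])
    mean(as.character(pred) == cls[hold])
  }, numeric(1))
  structure(
    list(k = k, fold_accuracy = acc, mean_accuracy = mean(acc),
         sd_accuracy = stats::sd(acc), fold_id = fold_id),
    class = "cv_result"
  )
}

#' Grid-search the feed-forward network hyperparameters
#'
#' Evaluates every grid point (hidden-layer sizes, learning rate, batch
#' size, epochs) by inner stratified cross-validation and returns the point
#' with the highest mean accuracy; ties go to the smaller network (fewer
#' hidden units). The tuning log records every evaluated point.
#'
#' @param rows Labeled, normalized training rows.
#' @param grid List of candidate hyperparameter lists, each with elements
#'   `hidden`, `learning_rate`, `batch_size`, `epochs`.
#' @param k Inner CV folds (default 3).
#' @param seed Integer seed.
#' @param features Feature columns.
#' @return List with `best` (the winning hyperparameter list), `log`
#'   (data.frame of all evaluated points with mean/SD accuracy).
#' @export
tune_network <- function(rows, grid, k = 3, seed = 1L,
                         features = rehab_feature_names()) {
  if (length(grid) == 0) stop("hyperparameter grid is empty")
  results <- lapply(seq_along(grid), function(i) {
    hp <- grid[[i]]
    spec <- default_spec("feedforward_network", seed = seed)
    spec$hyperparams[names(hp)] <- hp
    cv <- cross_validate(spec, rows, k = k, seed = seed, features = features)
    data.frame(
      point = i,
      hidden = paste(spec$hyperparams$hidden, collapse = "-"),
      learning_rate = spec$hyperparams$learning_rate,
      batch_size = spec$hyperparams$batch_size,
      epochs = spec$hyperparams$epochs,
      n_hidden_units = sum(spec$hyperparams$hidden),
      mean_accuracy = cv$mean_accuracy,
      sd_accuracy = cv$sd_accuracy,
      stringsAsFactors = FALSE
    )
  })
  log <- do.call(rbind, results)
  best_idx <- order(-log$mean_accuracy, log$n_hidden_units)[1]
  list(best = grid[[best_idx]], best_point = log$point[best_idx], log = log)
}
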
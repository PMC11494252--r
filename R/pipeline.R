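# End-to-end experiment driver used by the worked examples and the
# reproduction script.

#' Run the full severity-classification experiment
#'
#' Simulates a cohort directly to feature rows, attaches the clinician
#' labels, drops low-activity games, splits 80:20 (stratified), fits the
#' z-score normalizer on the training partition only, cross-validates and
#' trains each requested model, evaluates on the holdout set, and builds
#' the comparison tables.
#'
#' @param config A [simulation_config()].
#' @param params A [cleaning_params()].
#' @param models Character vector of model kinds (see [default_spec()]).
#' @param train_fraction Train share of the split (default 0.8).
#' @param cv_folds Cross-validation folds (default 10).
#' @param min_movements Activity filter threshold (default 3).
#' @param seed Experiment seed governing split, folds, and model seeds.
#' @param features Feature columns used for modeling.
#' @return List with `features` (labeled, filtered rows), `split`,
#'   `normalizer`, per-model `results` (each with `cv`, `model`, `metrics`,
#'   `confusion`), and `comparison` tables.
#' @export
run_experiment <- function(config = simulation_config(),
                           params = cleaning_params(),
                           models = c("gradient_boosted_trees", "extra_trees",
                                      "feedforward_network",
                                      "logistic_regression"),
                           train_fraction = 0.8, cv_folds = 10,
                           min_movements = 3, seed = 1L,
                           features = rehab_feature_names()) {
  sim <- simulate_features(config, params)
  rows <- attach_labels(sim$features, sim$assessments)
  rows <- filter_low_activity(rows, min_movements)

  split <- split_dataset(rows, train_fraction = train_fraction, seed = seed,
                         stratified = TRUE)
  normalizer <- fit_normalizer(split$train, features)
  train_z <- apply_normalizer(normalizer, split$train)
  test_z <- apply_normalizer(normalizer, split$test)

  results <- list()
  for (kind in models) {
    spec <- default_spec(kind, seed = seed)
    cv <- cross_validate(spec, train_z, k = cv_folds, seed = seed,
                         features = features)
    fit <- train_model(spec, train_z, features)
    ev <- evaluate_holdout(fit, test_z)
    results[[kind]] <- list(cv = cv, model = fit, metrics = ev$metrics,
                            confusion = ev$confusion)
  }

  comparison <- compare_models(results)
  list(features = rows, split = split, normalizer = normalizer,
       results = results, comparison = comparison)
}
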
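# Dataset assembly: activity filter, label attachment, train/test split,
# and leakage-safe z-score normalization.

#' Drop activities with too little movement
#'
#' Removes every activity row whose movement count is below
#' `min_movements`: with fewer than 3 direction changes no meaningful
#' therapeutic exercise took place. Original row order is preserved.
#'
#' @param rows data.frame with an `N_mov` column.
#' @param min_movements Minimum movement count to keep (default 3).
#' @return The retained rows.
#' @export
filter_low_activity <- function(rows, min_movements = 3) {
  if (is.null(rows) || nrow(rows) == 0) return(rows)
  if (!"N_mov" %in% names(rows)) stop("rows must carry an N_mov column")
  rows[rows$N_mov >= min_movements, , drop = FALSE]
}

#' Attach clinician severity labels to activity rows
#'
#' Joins each activity row to its patient's assessment and adds a `Class`
#' factor with levels `no < low < high` (integer encoding 0/1/2 via
#' `as.integer(Class) - 1`). Every patient must have exactly one
#' assessment.
#'
#' @param rows data.frame of activity feature rows with a `patient` column.
#' @param assessments data.frame with `patient` and `label` columns (see
#'   [simulate_assessment()]).
#' @return `rows` with an added `Class` factor column.
#' @export
attach_labels <- function(rows, assessments) {
  if (is.null(rows) || nrow(rows) == 0) {
    if (!is.null(rows)) rows$Class <- factor(character(0), levels = class_levels())
    return(rows)
  }
  dup <- unique(assessments$patient[duplicated(assessments$patient)])
  if (length(dup) > 0)
    stop("duplicate assessment for patient(s): ", paste(dup, collapse = ", "))
  idx <- match(rows$patient, assessments$patient)
  if (anyNA(idx)) {
    missing <- unique(rows$patient[is.na(idx)])
    stop("no assessment for patient(s): ", paste(missing, collapse = ", "))
  }
  rows$Class <- factor(assessments$label[idx], levels = class_levels())
  rows
}

#' Split activity rows into train and holdout test sets
#'
#' Partitions the rows at `train_fraction` (default 80%:20%). With
#' `stratified = TRUE` (default) each class contributes its share of
#' training rows to within one row, via largest-remainder rounding so the
#' total training size is exactly `round(train_fraction * n)`. With
#' `group_by_patient = TRUE` whole patients are assigned to one side, which
#' removes within-patient leakage at the cost of a less exact fraction
#' (activity-level splitting is the default).
#'
#' @param rows data.frame of (labeled) activity rows.
#' @param train_fraction Fraction in `(0, 1]`; 1 yields an empty test set.
#' @param seed Integer seed; identical seeds give identical splits.
#' @param stratified Stratify on `Class` (requires the column).
#' @param group_by_patient Split at the patient level instead of the
#'   activity level.
#' @return An object of class `split_dataset`: list with `train`, `test`,
#'   and `meta` (fraction, seed, flags).
#' @export
split_dataset <- function(rows, train_fraction = 0.8, seed = 1L,
                          stratified = TRUE, group_by_patient = FALSE) {
  if (!(train_fraction > 0 && train_fraction <= 1))
    stop("train_fraction must be in (0, 1]")
  n <- nrow(rows)
  set.seed(as.integer(seed))
  if (group_by_patient) {
    pats <- sample(unique(rows$patient))
    target <- round(train_fraction * n)
    sizes <- cumsum(vapply(pats, function(p) sum(rows$patient == p), numeric(1)))
    k <- which.min(abs(sizes - target))
    train_idx <- which(rows$patient %in% pats[seq_len(k)])
  } else if (stratified && "Class" %in% names(rows)) {
    target <- round(train_fraction * n)
    cls <- as.character(rows$Class)
    counts <- table(cls)
    exact <- as.numeric(counts) * train_fraction
    take <- floor(exact)
    rem <- target - sum(take)
    if (rem > 0) {
      extra <- order(exact - take, decreasing = TRUE)[seq_len(rem)]
      take[extra] <- take[extra] + 1
    }
    take <- pmin(take, as.numeric(counts))
    train_idx <- unlist(lapply(seq_along(counts), function(i) {
      members <- which(cls == names(counts)[i])
      sample(members, take[i])
    }), use.names = FALSE)
  } else {
    train_idx <- sample(n, round(train_fraction * n))
  }
  structure(
    list(
      train = rows[sort(train_idx), , drop = FALSE],
      test = rows[setdiff(seq_len(n), train_idx), , drop = FALSE],
      meta = list(train_fraction = train_fraction, seed = as.integer(seed),
                  stratified = stratified, group_by_patient = group_by_patient)
    ),
    class = "split_dataset"
  )
}

#' Fit per-feature z-score normalization on the training rows
#'
#' Computes per-feature mean and SD on the training set only. Features with
#' zero variance get an SD fallback of 1 (so they transform to 0 on the
#' training set) and are flagged.
#'
#' @param train_rows Nonempty data.frame of training rows.
#' @param features Feature columns to normalize (default
#'   [rehab_feature_names()]).
#' @return An object of class `feature_normalizer`: list with `features`,
#'   `mean`, `sd`, `zero_variance`.
#' @export
fit_normalizer <- function(train_rows, features = rehab_feature_names()) {
  if (is.null(train_rows) || nrow(train_rows) == 0)
    stop("cannot fit a normalizer on an empty training set")
  missing <- setdiff(features, names(train_rows))
  if (length(missing) > 0)
    stop("missing feature column(s): ", paste(missing, collapse = ", "))
  x <- as.matrix(train_rows[, features, drop = FALSE])
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  if (nrow(x) == 1) sd[] <- 0
  zero_var <- !is.finite(sd) | sd == 0
  sd[zero_var] <- 1
  structure(
    list(features = features, mean = mu, sd = sd, zero_variance = zero_var),
    class = "feature_normalizer"
  )
}

#' Apply a train-fitted normalizer to rows
#'
#' Transforms each feature to `z = (x - mean_train) / sd_train` using only
#' parameters fitted on the training set, preventing leakage of test-set
#' statistics.
#'
#' @param params A [fit_normalizer()] result.
#' @param rows data.frame containing the normalizer's feature columns.
#' @return `rows` with the feature columns replaced by z-scores.
#' @export
apply_normalizer <- function(params, rows) {
  stopifnot(inherits(params, "feature_normalizer"))
  if (is.null(rows) || nrow(rows) == 0) return(rows)
  for (f in params$features) {
    rows[[f]] <- (rows[[f]] - params$mean[[f]]) / params$sd[[f]]
  }
  rows
}
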
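# Feature-redundancy diagnostics (correlation matrix with a |r| > 0.9
# exclusion rule) and PCA explained-variance profile.

#' Pairwise Pearson correlations of the feature set
#'
#' Computes the symmetric Pearson correlation matrix of the chosen features
#' and flags every pair whose absolute correlation strictly exceeds
#' `threshold`. Correlations involving a zero-variance feature are undefined
#' and reported as 0 with a warning flag.
#'
#' @param rows data.frame with at least 2 rows.
#' @param features Feature columns (default [rehab_feature_names()]).
#' @param threshold Flagging threshold on `|r|` (default 0.9).
#' @return An object of class `correlation_report`: list with `features`,
#'   `matrix`, `flagged_pairs` (data.frame `a`, `b`, `r`),
#'   `zero_variance`, `threshold`, plus empty `dropped` / `kept_overrides`
#'   slots filled by [redundancy_filter()].
#' @export
correlation_matrix <- function(rows, features = rehab_feature_names(),
                               threshold = 0.9) {
  if (is.null(rows) || nrow(rows) < 2)
    stop("need at least 2 rows to compute correlations")
  x <- as.matrix(rows[, features, drop = FALSE])
  sds <- apply(x, 2, stats::sd)
  zero_var <- features[!is.finite(sds) | sds == 0]
  cm <- suppressWarnings(stats::cor(x))
  if (length(zero_var) > 0) {
    warning("zero-variance feature(s), correlations reported as 0: ",
            paste(zero_var, collapse = ", "))
    cm[is.na(cm)] <- 0
  }
  diag(cm) <- 1
  pairs <- which(upper.tri(cm) & abs(cm) > threshold, arr.ind = TRUE)
  flagged <- data.frame(
    a = features[pairs[, 1]],
    b = features[pairs[, 2]],
    r = cm[pairs],
    stringsAsFactors = FALSE
  )
  structure(
    list(features = features, matrix = cm, flagged_pairs = flagged,
         zero_variance = zero_var, threshold = threshold,
         dropped = character(0),
         kept_overrides = flagged[0, , drop = FALSE]),
    class = "correlation_report"
  )
}

#' Default redundancy keep-overrides
#'
#' The directional force pair `F_flex`/`F_ext` is strongly negatively
#' correlated (around -0.9) yet both members are kept: flexion and
#' extension strength recover along distinct neuromotor paths after stroke,
#' so neither is redundant clinically even when statistically coupled.
#'
#' @return List of length-2 character vectors (feature pairs to keep).
#' @export
default_keep_overrides <- function() list(c("F_flex", "F_ext"))

#' Apply the high-correlation exclusion rule
#'
#' For every pair with `|r|` strictly above `threshold` and not covered by a
#' keep-override, one member is dropped: deterministically the feature that
#' comes later in the canonical data-dictionary order. Pairs at exactly the
#' threshold are retained. Overridden pairs are recorded in
#' `kept_overrides`. Raising the threshold can only shrink the dropped set.
#'
#' @param report A [correlation_matrix()] report.
#' @param threshold Exclusion threshold (defaults to the report's).
#' @param keep_overrides List of feature pairs exempt from exclusion
#'   (default [default_keep_overrides()]).
#' @return The report with `dropped` and `kept_overrides` filled in.
#' @export
redundancy_filter <- function(report, threshold = report$threshold,
                              keep_overrides = default_keep_overrides()) {
  stopifnot(inherits(report, "correlation_report"))
  cm <- report$matrix
  features <- report$features
  pairs <- which(upper.tri(cm) & abs(cm) > threshold, arr.ind = TRUE)
  if (nrow(pairs) > 0) {
    # canonical order: by first then second member's dictionary position
    ord <- order(pairs[, 1], pairs[, 2])
    pairs <- pairs[ord, , drop = FALSE]
  }
  overridden <- function(a, b) {
    any(vapply(keep_overrides,
               function(p) setequal(p, c(a, b)), logical(1)))
  }
  dropped <- character(0)
  kept <- data.frame(a = character(0), b = character(0), r = numeric(0),
                     stringsAsFactors = FALSE)
  for (k in seq_len(nrow(pairs))) {
    a <- features[pairs[k, 1]]
    b <- features[pairs[k, 2]]
    if (a %in% dropped || b %in% dropped) next
    if (overridden(a, b)) {
      kept <- rbind(kept, data.frame(a = a, b = b, r = cm[a, b],
                                     stringsAsFactors = FALSE))
    } else {
      dropped <- c(dropped, b)  # drop the later feature in canonical order
    }
  }
  report$dropped <- dropped
  report$kept_overrides <- kept
  report$threshold <- threshold
  report
}

#' PCA explained-variance ratios
#'
#' Principal-component decomposition of the (already z-scored) feature
#' rows; returns the fraction of total variance attributable to each
#' component. Ratios are nonnegative, nonincreasing, and sum to 1.
#'
#' @param rows data.frame of z-scored rows, `nrow(rows) > 1`.
#' @param features Feature columns (default [rehab_feature_names()]).
#' @return Numeric vector of explained-variance ratios.
#' @export
pca_explained_variance <- function(rows, features = rehab_feature_names()) {
  if (is.null(rows) || nrow(rows) <= 1)
    stop("need more than 1 row for a principal-component decomposition")
  x <- as.matrix(rows[, features, drop = FALSE])
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  v <- pc$sdev^2
  v / sum(v)
}
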
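## Classification metrics: confusion matrices in the true-class-rows
## convention, per-class accuracy (recall) and precision, class-size-weighted
## averages, one-vs-rest ROC areas, and nested stratified cross-validation.

#' Build a confusion matrix
#'
#' @param true_labels,predicted_labels equal-length vectors of class labels.
#' @param class_names ordered class set; both label vectors must draw from it.
#' @return object of class \code{ConfusionMatrix}: integer K x K matrix,
#'   rows = true class, columns = predicted class.
#' @export
confusion_matrix <- function(true_labels, predicted_labels, class_names) {
  true_labels <- as.character(true_labels)
  predicted_labels <- as.character(predicted_labels)
  if (length(true_labels) != length(predicted_labels)) {
    stop_format("label vectors differ in length")
  }
  bad <- setdiff(unique(c(true_labels, predicted_labels)), class_names)
  if (length(bad) > 0) {
    stop_format("unknown label(s): %s", paste(bad, collapse = ", "))
  }
  counts <- table(factor(true_labels, levels = class_names),
                  factor(predicted_labels, levels = class_names))
  cm <- matrix(as.integer(counts), length(class_names),
               dimnames = list(true = class_names, predicted = class_names))
  structure(cm, class = c("ConfusionMatrix", "matrix"))
}

#' Wrap an existing count matrix as a ConfusionMatrix
#' @param counts square numeric matrix with matching dimnames (true rows,
#'   predicted columns).
#' @return a \code{ConfusionMatrix}.
#' @export
as_confusion_matrix <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == ncol(counts), !is.null(rownames(counts)))
  if (any(counts < 0)) stop_format("confusion counts must be nonnegative")
  structure(counts, class = c("ConfusionMatrix", "matrix"))
}

#' Per-class accuracy (recall)
#'
#' accuracy_i = 100 * counts[i, i] / (true size of class i). Classes with no
#' samples are reported as NA with a warning.
#'
#' @param cm a \code{ConfusionMatrix}.
#' @return named numeric vector of percentages.
#' @export
per_class_accuracy <- function(cm) {
  rs <- rowSums(cm)
  if (any(rs == 0)) warning("empty true class: accuracy undefined")
  out <- 100 * diag(cm) / rs
  out[rs == 0] <- NA_real_
  out
}

#' Per-class precision
#'
#' precision_j = 100 * counts[j, j] / (number of samples classified as j).
#'
#' @param cm a \code{ConfusionMatrix}.
#' @return named numeric vector of percentages (NA for empty predicted class).
#' @export
per_class_precision <- function(cm) {
  cs <- colSums(cm)
  if (any(cs == 0)) warning("empty predicted class: precision undefined")
  out <- 100 * diag(cm) / cs
  out[cs == 0] <- NA_real_
  out
}

#' Class-size-weighted average of per-class values
#'
#' Weights are TRUE class sizes; applied to per-class accuracies this equals
#' 100 * trace / total. NA values are excluded (with their weights).
#'
#' @param per_class_values numeric vector.
#' @param class_sizes nonnegative weights of equal length.
#' @return the weighted mean.
#' @export
weighted_average <- function(per_class_values, class_sizes) {
  if (length(per_class_values) != length(class_sizes)) {
    stop_format("values and sizes differ in length")
  }
  keep <- !is.na(per_class_values)
  if (sum(class_sizes[keep]) == 0) stop_format("all class sizes zero")
  sum(per_class_values[keep] * class_sizes[keep]) / sum(class_sizes[keep])
}

#' Metric report from a confusion matrix
#'
#' @param cm a \code{ConfusionMatrix}.
#' @param roc per-class ROC areas (optional named vector).
#' @return list of class \code{MetricReport}: per-class accuracy/precision (%),
#'   weighted averages, class sizes, and ROC areas when given.
#' @export
metric_report <- function(cm, roc = NULL) {
  acc <- per_class_accuracy(cm)
  prec <- per_class_precision(cm)
  sizes <- rowSums(cm)
  rep <- list(class_sizes = sizes,
              accuracy = acc, precision = prec,
              weighted_accuracy = weighted_average(acc, sizes),
              weighted_precision = weighted_average(prec, sizes))
  if (!is.null(roc)) {
    rep$roc_area <- roc
    rep$weighted_roc_area <- weighted_average(roc, sizes)
  }
  structure(rep, class = "MetricReport")
}

#' @export
print.MetricReport <- function(x, ...) {
  cat("MetricReport\n")
  for (cl in names(x$accuracy)) {
    cat(sprintf("  %s (%d): accuracy %.1f%%, precision %.1f%%%s\n", cl,
                x$class_sizes[cl], round_half_up(x$accuracy[cl]),
                round_half_up(x$precision[cl]),
                if (!is.null(x$roc_area)) sprintf(", ROC %.3f", x$roc_area[cl])
                else ""))
  }
  cat(sprintf("  weighted average (%d): accuracy %.1f%%, precision %.1f%%%s\n",
              sum(x$class_sizes), round_half_up(x$weighted_accuracy),
              round_half_up(x$weighted_precision),
              if (!is.null(x$weighted_roc_area))
                sprintf(", ROC %.3f", x$weighted_roc_area) else ""))
  invisible(x)
}

## midrank (tie-corrected) AUROC of scores against a binary indicator
auc_rank <- function(scores, positive) {
  n_pos <- sum(positive); n_neg <- sum(!positive)
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' One-vs-rest ROC areas and their class-size-weighted mean
#'
#' @param class_scores numeric matrix, one column of scores per class
#'   (pairwise-vote counts, decision margins or class probabilities), one row
#'   per sample; column names are the class names.
#' @param true_labels vector of true classes.
#' @return list: \code{per_class} named areas, \code{weighted} (weights = true
#'   class sizes; classes absent from the truth are NA and excluded).
#' @export
roc_area_weighted <- function(class_scores, true_labels) {
  class_scores <- as.matrix(class_scores)
  if (is.null(colnames(class_scores))) {
    stop_format("class_scores must carry class names as colnames")
  }
  true_labels <- as.character(true_labels)
  per <- vapply(colnames(class_scores), function(cl) {
    auc_rank(class_scores[, cl], true_labels == cl)
  }, 0)
  sizes <- vapply(colnames(class_scores), function(cl) sum(true_labels == cl), 0)
  list(per_class = per,
       weighted = weighted_average(per, sizes))
}

#' Nested stratified cross-validation
#'
#' The outer loop provides unbiased performance estimates: every
#' data-dependent choice (filtering, gene selection, ranking, refinement,
#' model fitting, any inner-loop tuning) is re-run inside each outer training
#' set by \code{pipeline_spec}; outer-test predictions are pooled into one
#' confusion matrix.
#'
#' @param m \code{ExpressionMatrix}.
#' @param labels class labels, one per sample.
#' @param pipeline_spec function(m_train, labels_train, inner_folds, seed)
#'   returning a prediction function(m_test) -> character labels.
#' @param outer_folds,inner_folds fold counts (default 10); outer folds are
#'   reduced (with a warning) when the smallest class has fewer samples.
#' @param seed integer seed.
#' @return list of class \code{NestedCVResult}: \code{confusion},
#'   \code{report}, \code{fold} assignment, \code{predictions}.
#' @export
nested_cv <- function(m, labels, pipeline_spec, outer_folds = 10,
                      inner_folds = 10, seed = 1L) {
  labels <- as.character(labels)
  n <- length(labels)
  if (n < outer_folds) stop_format("fewer samples than outer folds")
  classes <- sort(unique(labels))
  smallest <- min(table(labels))
  if (smallest < outer_folds) {
    warning(sprintf("smallest class has %d samples; reducing outer folds", smallest))
    outer_folds <- max(2, smallest)
  }
  fold <- stratified_folds(labels, outer_folds, derive_seed(seed, "outer"),
                           ids = sample_ids(m))
  pred <- character(n)
  for (f in sort(unique(fold))) {
    tr <- fold != f
    model <- pipeline_spec(em_subset(m, samples = which(tr)), labels[tr],
                           inner_folds, derive_seed(seed, "outerfold", f))
    pred[!tr] <- model(em_subset(m, samples = which(!tr)))
  }
  cmat <- confusion_matrix(labels, pred, classes)
  structure(list(confusion = cmat, report = metric_report(cmat),
                 fold = fold, predictions = pred),
            class = "NestedCVResult")
}

#' Pearson correlation of model accuracy against ROC area
#'
#' @param model_summaries data.frame with columns \code{accuracy} and
#'   \code{roc_area} (one row per model), or a list of \code{TreeModel}s.
#' @return Pearson correlation coefficient.
#' @export
correlate_model_metrics <- function(model_summaries) {
  if (!is.data.frame(model_summaries)) {
    model_summaries <- data.frame(
      accuracy = vapply(model_summaries, `[[`, 0, "accuracy"),
      roc_area = vapply(model_summaries, `[[`, 0, "roc_area")
    )
  }
  if (nrow(model_summaries) < 3) stop_format("need >= 3 models")
  if (stats::sd(model_summaries$accuracy) == 0 ||
      stats::sd(model_summaries$roc_area) == 0) {
    warning("zero variance in a metric: correlation undefined")
    return(NA_real_)
  }
  stats::cor(model_summaries$accuracy, model_summaries$roc_area)
}
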
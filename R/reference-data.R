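## Bundled reference results from a published three-class exposure study
## (248 samples: 32 control, 120 RDX, 96 TNT): the per-model classification
## summary of a 12-model tree suite and the confusion matrices of the
## SVM-optimized (39-gene), clustering-optimized (30-gene) and combined
## (58-gene) classifier sets. Used to validate the metric layer: recomputing
## accuracy, precision and weighted averages from these counts must reproduce
## the printed percentages.

#' Bundled reference confusion matrices
#'
#' @return named list of \code{ConfusionMatrix} objects: \code{svm39},
#'   \code{clust30}, \code{svm58}, \code{clust58}.
#' @export
reference_confusions <- function() {
  load1 <- function(name) {
    path <- system.file("extdata", paste0("confusion_", name, ".tsv"),
                        package = "isml", mustWork = TRUE)
    df <- utils::read.delim(path, check.names = FALSE)
    m <- as.matrix(df[, -1])
    rownames(m) <- df$true_class
    as_confusion_matrix(m)
  }
  list(svm39 = load1("svm39"), clust30 = load1("clust30"),
       svm58 = load1("svm58"), clust58 = load1("clust58"))
}

#' Bundled reference per-model summary (12 tree models)
#'
#' @return data.frame with columns \code{ensemble}, \code{algorithm},
#'   \code{accuracy_pct}, \code{roc_area}; also provides \code{accuracy} on
#'   the [0,1] scale.
#' @export
reference_model_summary <- function() {
  path <- system.file("extdata", "model_summary_reference.tsv",
                      package = "isml", mustWork = TRUE)
  df <- utils::read.delim(path, check.names = FALSE)
  df$accuracy <- df$accuracy_pct / 100
  df
}

#' Bundled reference ROC areas for the SVM confusion matrices
#'
#' @return named list of per-class ROC-area vectors for \code{svm39} and
#'   \code{svm58} (clustering has no scores, hence no ROC).
#' @export
reference_roc_areas <- function() {
  list(
    svm39 = c(control = 0.938, RDX = 0.887, TNT = 0.913),
    svm58 = c(control = 0.936, RDX = 0.856, TNT = 0.913)
  )
}
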
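## Weight-of-significance ranking of classifier genes.
##
## Within a tree, a gene's weight reflects its node position: the root gene
## gets the largest weight (1), deeper decision nodes smaller ones, normalized
## to the longest leaf-to-root path. Across models, per-model weights are
## combined into an overall weight by scaling each with that model's
## cross-validated accuracy and summing.

## decision-node count of the longest root-to-leaf path; with binary heap
## numbering a leaf at depth d sits below exactly d decision nodes
tree_longest_path <- function(tree) {
  max(tree$depth[tree$is_leaf])
}

#' Extract per-gene path weights from a tree model
#'
#' For a single tree, a gene at a decision node of depth d (root = 0) weighs
#' (L - d) / L under the default linear decay, where L is the number of
#' decision levels on the longest root-to-leaf path; a gene occurring at
#' several nodes takes the maximum. For an ensemble the member weights are
#' averaged (a member not using the gene contributes 0), which keeps every
#' weight in (0, 1]. Models carrying externally supplied per-gene weights
#' (e.g. from a logistic-model learner) return those untouched.
#'
#' @param model a \code{TreeModel} (or a bare \code{tree_structure}).
#' @param decay weight-versus-depth policy: function(depth, L) -> weight in
#'   (0, 1]; default linear \code{(L - depth) / L}.
#' @return named numeric vector gene_id -> weight in (0, 1]; empty for models
#'   with no decision node.
#' @export
extract_path_weights <- function(model,
                                 decay = function(depth, L) (L - depth) / L) {
  if (inherits(model, "tree_structure")) {
    trees <- list(model)
    external <- NULL
  } else {
    trees <- model$trees
    external <- model$external_weights
  }
  if (!is.null(external)) return(external)
  per_tree <- lapply(trees, function(tr) {
    dn <- tr[!tr$is_leaf, , drop = FALSE]
    if (nrow(dn) == 0) return(numeric(0))
    L <- tree_longest_path(tr)
    w <- decay(dn$depth, L)
    tapply(w, dn$gene_id, max)
  })
  genes <- unique(unlist(lapply(per_tree, names), use.names = FALSE))
  if (length(genes) == 0) return(stats::setNames(numeric(0), character(0)))
  acc <- stats::setNames(numeric(length(genes)), genes)
  for (wt in per_tree) acc[names(wt)] <- acc[names(wt)] + wt
  acc / length(trees)
}

#' Combine per-model weights into overall weights and ranks
#'
#' Overall weight W(g) = sum over models m of A_m * w(g, m), where A_m is the
#' model's cross-validated accuracy on the [0,1] scale and w(g, m) the path
#' weight from \code{\link{extract_path_weights}} (0 when g is absent from m).
#' Genes are ranked by W descending; ties break by gene id ascending.
#'
#' @param models list of \code{TreeModel}s.
#' @param decay passed to \code{\link{extract_path_weights}}.
#' @return object of class \code{GeneWeightTable}: \code{table} (data.frame
#'   gene_id, overall_weight, rank, sorted by rank), \code{per_model} (weight
#'   matrix genes x models), \code{accuracies}.
#' @export
overall_weights <- function(models, decay = NULL) {
  if (length(models) == 0) stop_format("empty model list")
  args <- if (is.null(decay)) list() else list(decay = decay)
  wlist <- lapply(models, function(mo) do.call(extract_path_weights,
                                               c(list(mo), args)))
  genes <- sort(unique(unlist(lapply(wlist, names), use.names = FALSE)))
  W <- matrix(0, length(genes), length(models),
              dimnames = list(genes, vapply(models, `[[`, "", "model_id")))
  for (i in seq_along(wlist)) W[names(wlist[[i]]), i] <- wlist[[i]]
  acc <- vapply(models, `[[`, 0, "accuracy")
  overall <- as.vector(W %*% acc)
  ord <- order(-overall, genes)
  table <- data.frame(gene_id = genes[ord], overall_weight = overall[ord],
                      rank = seq_along(genes), stringsAsFactors = FALSE)
  structure(list(table = table, per_model = W, accuracies = acc),
            class = "GeneWeightTable")
}

#' @export
print.GeneWeightTable <- function(x, ...) {
  cat(sprintf("GeneWeightTable: %d genes x %d models; top weight %.4g\n",
              nrow(x$table), ncol(x$per_model),
              if (nrow(x$table)) x$table$overall_weight[1] else NA))
  invisible(x)
}

#' Ranked gene ids of a weight table
#' @param wt a \code{GeneWeightTable}.
#' @return character vector, best-ranked first.
#' @export
ranked_genes <- function(wt) wt$table$gene_id

#' Pool classifier genes from a model list
#'
#' The classifier-gene set is the union of all genes appearing at any decision
#' node of any model; genes never used to split are discarded.
#'
#' @param models list of \code{TreeModel}s.
#' @return character vector of gene ids.
#' @export
select_classifier_genes <- function(models) {
  sort(unique(unlist(lapply(models, function(mo) {
    unlist(lapply(mo$trees, function(tr) tr$gene_id[!tr$is_leaf]),
           use.names = FALSE)
  }), use.names = FALSE)))
}
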
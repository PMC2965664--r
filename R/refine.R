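## Iterative backward-elimination refinement of the ranked classifier genes
## under two pluggable evaluators: a pairwise (one-vs-one) multi-class SVM
## and k-means clustering with optimal cluster-to-class matching.

#' Impute masked values by per-gene medians
#'
#' Classifier training needs complete data; masked cells are replaced by the
#' gene's median over its usable measurements. Genes with no usable value at
#' all are rejected.
#'
#' @param m an \code{ExpressionMatrix}.
#' @return an \code{ExpressionMatrix} with a full mask.
#' @export
impute_missing <- function(m) {
  v <- m$values
  for (i in seq_len(nrow(v))) {
    bad <- !m$mask[i, ]
    if (all(bad)) stop_format("gene %s has no usable value", rownames(v)[i])
    if (any(bad)) v[i, bad] <- stats::median(v[i, !bad])
  }
  expression_matrix(v, spikein_ids = m$spikein_ids)
}

## samples x genes numeric matrix for classifier input
classifier_input <- function(m, genes) {
  if (inherits(m, "ExpressionMatrix")) {
    missing <- setdiff(genes, gene_ids(m))
    if (length(missing) > 0) {
      stop_format("gene(s) absent from matrix: %s",
                  paste(utils::head(missing, 5), collapse = ", "))
    }
    v <- m$values[genes, , drop = FALSE]
    if (!all(m$mask[genes, ])) v <- impute_missing(em_subset(m, genes))$values
  } else {
    v <- as.matrix(m)[genes, , drop = FALSE]
  }
  t(v)
}

#' Train a multi-class SVM on a gene subset
#'
#' One binary soft-margin SVM per unordered class pair (linear kernel by
#' default), solved by an SMO-type decomposition method, combined by pairwise
#' voting; features are standardized with training statistics.
#'
#' @param m \code{ExpressionMatrix} or genes-x-samples matrix.
#' @param genes gene ids to use as features.
#' @param labels class labels, one per sample.
#' @param cost soft-margin cost C (default 1).
#' @param kernel \code{"linear"} (default) or \code{"radial"}.
#' @return list of class \code{McSvm} with a \code{predict} function
#'   (matrix/ExpressionMatrix of the same genes -> character labels).
#' @export
train_mc_svm <- function(m, genes, labels, cost = 1, kernel = "linear") {
  labels <- factor(as.character(labels))
  if (nlevels(labels) < 2) stop_format("need >= 2 classes")
  if (min(table(labels)) < 2) stop_format("every class needs >= 2 samples")
  x <- classifier_input(m, genes)
  constant <- apply(x, 2, function(col) stats::sd(col) == 0)
  fit <- e1071::svm(x, labels, type = "C-classification", kernel = kernel,
                    cost = cost, scale = !constant)
  structure(list(
    fit = fit, genes = genes, classes = levels(labels),
    predict = function(newdata) {
      nx <- classifier_input(newdata, genes)
      as.character(stats::predict(fit, nx))
    }
  ), class = "McSvm")
}

## ---- k-means with cluster-to-class matching ------------------------------

kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  d2 <- rowSums((x - matrix(centers[1, ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1)) {
    if (sum(d2) == 0) {
      idx <- sample.int(n, 1)
    } else {
      idx <- sample.int(n, 1, prob = d2)
    }
    centers[j + 1, ] <- x[idx, ]
    nd <- rowSums((x - matrix(centers[j + 1, ], n, ncol(x), byrow = TRUE))^2)
    d2 <- pmin(d2, nd)
  }
  centers
}

## all permutations of 1..k (k is the class count, so small)
permutations <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- permutations(k - 1)
  out <- NULL
  for (i in seq_len(k)) {
    out <- rbind(out, cbind(i, sub + (sub >= i)))
  }
  unname(out)
}

## one-to-one cluster->class assignment maximizing matched samples
best_assignment <- function(contingency) {
  k <- nrow(contingency)
  perms <- permutations(k)
  scores <- apply(perms, 1, function(p) {
    sum(contingency[cbind(seq_len(k), p)])
  })
  perms[which.max(scores), ]
}

#' Cluster samples and match clusters to classes
#'
#' K-means (Euclidean, k-means++ seeding, best within-cluster sum of squares
#' over restarts) on the samples restricted to a gene subset; the resulting
#' clusters are matched one-to-one to the true classes by the assignment that
#' maximizes the number of matched samples, and the class-by-matched-class
#' confusion matrix is returned.
#'
#' @param m \code{ExpressionMatrix} or genes-x-samples matrix.
#' @param genes gene subset.
#' @param labels true class labels.
#' @param k number of clusters; must equal the number of classes.
#' @param seed integer seed.
#' @param restarts k-means restarts (default 50 when p small, else 20).
#' @return a \code{ConfusionMatrix} (true class rows, matched-cluster columns).
#' @export
kmeans_match <- function(m, genes, labels, k = NULL, seed = 1L,
                         restarts = 25) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (is.null(k)) k <- length(classes)
  if (k != length(classes)) stop_format("k must equal the number of classes")
  x <- classifier_input(m, genes)
  if (k > nrow(x)) stop_format("more clusters than samples")
  set.seed(derive_seed(seed, "kmeans"))
  best <- NULL
  for (r in seq_len(restarts)) {
    centers <- kmeanspp_centers(x, k)
    dup <- duplicated(centers)
    if (any(dup)) { # degenerate data: perturb to keep centers distinct
      centers[dup, ] <- centers[dup, , drop = FALSE] +
        stats::rnorm(sum(dup) * ncol(centers), sd = 1e-8 + 1e-8 * mean(abs(x)))
    }
    km <- suppressWarnings(stats::kmeans(x, centers = centers, iter.max = 50))
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  contingency <- table(factor(labels, levels = classes),
                       factor(best$cluster, levels = seq_len(k)))
  assign <- best_assignment(t(contingency)) # cluster -> class index
  matched <- classes[assign[best$cluster]]
  confusion_matrix(labels, matched, classes)
}

## ---- accuracy curves and pruning ----------------------------------------

#' Accuracy curve over nested prefixes of a gene ranking
#'
#' Starting from the top-ranked gene and adding one gene of immediately lower
#' rank at a time, evaluates every prefix: the SVM evaluator pools
#' stratified cross-validation testing-fold predictions; the clustering
#' evaluator matches full-data k-means clusters to classes. Reports per-class
#' accuracy and the class-size-weighted average, in percent.
#'
#' @param ranked_genes character vector, best-ranked first.
#' @param m \code{ExpressionMatrix} or genes-x-samples matrix.
#' @param labels class labels.
#' @param evaluator \code{"svm"} or \code{"clustering"}.
#' @param cv_folds CV folds for the SVM evaluator (default 10).
#' @param seed integer seed.
#' @param cost SVM cost parameter.
#' @return data.frame of class \code{AccuracyCurve}: columns \code{k},
#'   \code{gene_id} (the gene added), one accuracy column per class, and
#'   \code{weighted}; one row per prefix size.
#' @export
accuracy_curve <- function(ranked_genes, m, labels,
                           evaluator = c("svm", "clustering"),
                           cv_folds = 10, seed = 1L, cost = 1) {
  evaluator <- match.arg(evaluator)
  if (length(ranked_genes) == 0) stop_format("empty ranking")
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  rows <- vector("list", length(ranked_genes))
  fold <- stratified_folds(labels, cv_folds, derive_seed(seed, "curve"))
  for (k in seq_along(ranked_genes)) {
    genes <- ranked_genes[seq_len(k)]
    if (evaluator == "svm") {
      pred <- character(length(labels))
      for (f in sort(unique(fold))) {
        tr <- fold != f
        cls <- train_mc_svm(em_or_mat_subset(m, genes, which(tr)), genes,
                            labels[tr], cost = cost)
        pred[!tr] <- cls$predict(em_or_mat_subset(m, genes, which(!tr)))
      }
      cmat <- confusion_matrix(labels, pred, classes)
    } else {
      cmat <- kmeans_match(m, genes, labels, seed = derive_seed(seed, "ck", k))
    }
    acc <- per_class_accuracy(cmat)
    rows[[k]] <- c(list(k = k, gene_id = ranked_genes[k]),
                   as.list(acc),
                   list(weighted = weighted_average(acc, rowSums(cmat))))
  }
  out <- do.call(rbind, lapply(rows, as.data.frame, stringsAsFactors = FALSE))
  attr(out, "classes") <- classes
  attr(out, "evaluator") <- evaluator
  class(out) <- c("AccuracyCurve", class(out))
  out
}

em_or_mat_subset <- function(m, genes, samples) {
  if (inherits(m, "ExpressionMatrix")) {
    em_subset(m, genes = genes, samples = samples)
  } else {
    as.matrix(m)[genes, samples, drop = FALSE]
  }
}

#' One backward-elimination pruning pass
#'
#' For each gene at rank position k >= 2 the four deltas between curve rows k
#' and k-1 (one per class plus the weighted average) measure the effect of
#' adding that gene; scanning from the bottom of the ranking upward, every
#' gene whose deltas are all strictly negative is removed. The top-ranked gene
#' is never removed and kept genes preserve their relative order.
#'
#' @param ranked_genes the ranking the curve was computed on.
#' @param curve the matching \code{AccuracyCurve}.
#' @return list: \code{kept}, \code{removed} (ordered bottom-up as scanned).
#' @export
prune_pass <- function(ranked_genes, curve) {
  if (nrow(curve) != length(ranked_genes) ||
      !identical(curve$gene_id, as.character(ranked_genes))) {
    stop_format("curve does not match the ranking")
  }
  classes <- attr(curve, "classes")
  series <- as.matrix(curve[, c(classes, "weighted")])
  removed <- character(0)
  if (nrow(series) >= 2) {
    deltas <- series[-1, , drop = FALSE] - series[-nrow(series), , drop = FALSE]
    drop_idx <- which(apply(deltas < 0, 1, all)) + 1L
    removed <- ranked_genes[rev(drop_idx)] # bottom of the ranking first
  }
  list(kept = setdiff(ranked_genes, removed), removed = removed)
}

#' Iterate accuracy-curve pruning to a fixed point
#'
#' Alternates \code{\link{accuracy_curve}} and \code{\link{prune_pass}} until
#' a pass removes no gene. The gene set strictly shrinks each earlier
#' iteration, so termination is guaranteed.
#'
#' @inheritParams accuracy_curve
#' @return list of class \code{RefinementTrace}: \code{final_set} (a
#'   \code{ClassifierGeneSet}), \code{iterations} (each with \code{genes},
#'   \code{removed}, \code{curve}), \code{evaluator}.
#' @export
iterate_refinement <- function(ranked_genes, m, labels,
                               evaluator = c("svm", "clustering"),
                               cv_folds = 10, seed = 1L, cost = 1) {
  evaluator <- match.arg(evaluator)
  current <- as.character(ranked_genes)
  iterations <- list()
  repeat {
    # seed keyed to the set size: re-running on the final set reproduces the
    # terminating pass exactly, making the output a true fixed point
    curve <- accuracy_curve(current, m, labels, evaluator, cv_folds,
                            seed = derive_seed(seed, "iter", length(current)),
                            cost = cost)
    pass <- prune_pass(current, curve)
    iterations[[length(iterations) + 1]] <-
      list(genes = current, removed = pass$removed, curve = curve)
    if (length(pass$removed) == 0) break
    current <- pass$kept
  }
  provenance <- if (evaluator == "svm") "svm_optimized" else "clustering_optimized"
  structure(list(
    final_set = classifier_gene_set(current, provenance),
    iterations = iterations, evaluator = evaluator
  ), class = "RefinementTrace")
}

#' @export
print.RefinementTrace <- function(x, ...) {
  sizes <- vapply(x$iterations, function(it) length(it$genes), 0L)
  cat(sprintf("RefinementTrace (%s): %s -> %d genes in %d pass(es)\n",
              x$evaluator, sizes[1], length(x$final_set$genes),
              length(x$iterations)))
  invisible(x)
}

#' Construct a ClassifierGeneSet
#' @param genes ordered unique gene ids.
#' @param provenance one of \code{"svm_optimized"},
#'   \code{"clustering_optimized"}, \code{"combined_union"},
#'   \code{"common_intersection"}.
#' @return a \code{ClassifierGeneSet}.
#' @export
classifier_gene_set <- function(genes, provenance) {
  provenance <- match.arg(provenance, c("svm_optimized", "clustering_optimized",
                                        "combined_union", "common_intersection"))
  genes <- as.character(genes)
  check_unique(genes, "gene id")
  structure(list(genes = genes, provenance = provenance),
            class = "ClassifierGeneSet")
}

#' @export
print.ClassifierGeneSet <- function(x, ...) {
  cat(sprintf("ClassifierGeneSet [%s]: %d genes\n", x$provenance,
              length(x$genes)))
  invisible(x)
}

#' Combine the SVM- and clustering-optimized gene sets
#'
#' @param svm_set,clust_set \code{ClassifierGeneSet}s (or plain vectors).
#' @return list: \code{union} (\code{combined_union}; order: svm set then new
#'   clustering genes) and \code{intersection} (\code{common_intersection}).
#' @export
combine_gene_sets <- function(svm_set, clust_set) {
  a <- if (inherits(svm_set, "ClassifierGeneSet")) svm_set$genes else svm_set
  b <- if (inherits(clust_set, "ClassifierGeneSet")) clust_set$genes else clust_set
  list(union = classifier_gene_set(union(a, b), "combined_union"),
       intersection = classifier_gene_set(intersect(a, b), "common_intersection"))
}
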
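## End-to-end driver: preprocess -> class comparison -> tree selection ->
## ranking -> refinement (svm and clustering) -> combination -> evaluation,
## with a run manifest recording seeds, stage gene counts and timings.

#' Assemble a pipeline configuration
#'
#' @param class_names ordered class labels; the first is the reference
#'   (control) class.
#' @param linear_range c(low, high) flagging bounds; NULL to skip.
#' @param presence_fraction presence filter threshold (default 0.5).
#' @param n_permutations,confidence,max_false_positives permutation-filter
#'   settings (reference settings: 10000, 0.99, 10).
#' @param suite learner suite (default \code{\link{default_learner_suite}()}).
#' @param cv_folds cross-validation folds (default 10).
#' @param svm_cost SVM cost parameter.
#' @param seed master seed.
#' @return a \code{PipelineConfig} list.
#' @export
pipeline_config <- function(class_names = c("control", "TNT", "RDX"),
                            linear_range = NULL,
                            presence_fraction = 0.5,
                            n_permutations = 10000,
                            confidence = 0.99,
                            max_false_positives = 10,
                            suite = default_learner_suite(),
                            cv_folds = 10,
                            svm_cost = 1,
                            seed = 1L) {
  if (presence_fraction <= 0 || presence_fraction > 1) {
    stop_format("presence_fraction must be in (0, 1]")
  }
  if (confidence <= 0 || confidence >= 1) stop_format("confidence must be in (0, 1)")
  if (max_false_positives < 0) stop_format("max_false_positives must be >= 0")
  if (n_permutations < 1) stop_format("n_permutations must be >= 1")
  structure(list(class_names = class_names, linear_range = linear_range,
                 presence_fraction = presence_fraction,
                 n_permutations = n_permutations, confidence = confidence,
                 max_false_positives = max_false_positives, suite = suite,
                 cv_folds = cv_folds, svm_cost = svm_cost,
                 seed = as.integer(seed)),
            class = "PipelineConfig")
}

#' Build the class-comparison suite from a sample annotation
#'
#' One two-class comparison per compound (pooled controls vs that compound's
#' pooled treatments) plus one multi-class comparison per compound and
#' experiment block (control samples of the block and the compound's
#' concentration groups in it), mirroring the pooled-plus-per-condition
#' design of multi-compound exposure studies.
#'
#' @param annotation sample annotation data.frame.
#' @param control_class reference class label (default \code{"control"}).
#' @return named list of comparisons (\code{samples}, \code{labels}).
#' @export
comparison_suite_from_annotation <- function(annotation,
                                             control_class = "control") {
  ann <- annotation
  compounds <- setdiff(unique(ann$class_label), control_class)
  suite <- list()
  ctl <- ann$sample_id[ann$class_label == control_class]
  for (cp in compounds) {
    trt <- ann$sample_id[ann$class_label == cp]
    suite[[paste0(cp, "-vs-", control_class)]] <- list(
      samples = c(ctl, trt),
      labels = c(rep(control_class, length(ctl)), rep(cp, length(trt)))
    )
    for (blk in unique(ann$experiment_block[ann$class_label == cp])) {
      in_blk <- ann$experiment_block == blk
      ctl_b <- ann$sample_id[in_blk & ann$class_label == control_class]
      rows <- which(in_blk & ann$class_label == cp)
      if (length(ctl_b) == 0 || length(rows) == 0) next
      conc <- ann$concentration_mg_per_kg[rows]
      suite[[paste0(cp, "-", blk)]] <- list(
        samples = c(ctl_b, ann$sample_id[rows]),
        labels = c(rep(control_class, length(ctl_b)),
                   paste0(cp, "_", conc))
      )
    }
  }
  suite
}

stage_digest <- function(x) {
  raw <- as.double(serialize(x, NULL, version = 2))
  # rolling polynomial checksum in double precision (exact below 2^53)
  h <- 0
  for (block in split(raw, ceiling(seq_along(raw) / 4096))) {
    h <- (h * 31 + sum(block * (seq_along(block) %% 97 + 1))) %% 2147483629
  }
  sprintf("%08x", as.integer(h))
}

#' Run the full pipeline
#'
#' @param m raw \code{ExpressionMatrix}.
#' @param annotation sample annotation data.frame (\code{sample_id},
#'   \code{class_label}, optional treatment columns).
#' @param config a \code{\link{pipeline_config}}.
#' @param spikes optional spike-in table for intensity conversion.
#' @param extra_flags optional logical flag matrix for pre-processing.
#' @param verbose print one line per stage.
#' @return list of class \code{PipelineResult}: \code{weights}
#'   (\code{GeneWeightTable}), \code{svm_trace}, \code{clustering_trace},
#'   \code{combined}, \code{reports} (final SVM/clustering metric reports on
#'   the combined set), \code{suite_result}, \code{models}, and
#'   \code{manifest} (stage gene counts, timings, digests, seed).
#' @export
run_pipeline <- function(m, annotation, config = pipeline_config(),
                         spikes = NULL, extra_flags = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "PipelineConfig"))
  seed <- config$seed
  labels <- annotation$class_label[match(sample_ids(m), annotation$sample_id)]
  if (anyNA(labels)) stop_format("samples lack annotation")
  manifest <- list(seed = seed, stages = list())
  note <- function(stage, count, obj) {
    manifest$stages[[stage]] <<- list(
      genes = count, digest = stage_digest(obj),
      time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
    )
    if (verbose) message(sprintf("[%s] %d genes (%s)", stage, count,
                                 manifest$stages[[stage]]$digest))
  }
  note("input", nrow(m$values) - length(m$spikein_ids), m$values)

  pre <- preprocess_pipeline(m, spikes = spikes,
                             linear_range = config$linear_range,
                             extra_flags = extra_flags,
                             presence_fraction = config$presence_fraction)
  note("preprocess", nrow(pre$values), pre$values)

  suite_cmp <- comparison_suite_from_annotation(annotation,
                                                config$class_names[1])
  suite_result <- run_comparison_suite(
    pre, suite_cmp, n_permutations = config$n_permutations,
    confidence = config$confidence,
    max_false_positives = config$max_false_positives,
    seed = derive_seed(seed, "compare")
  )
  sig_genes <- suite_result$union
  note("class_comparison", length(sig_genes), sig_genes)
  if (length(sig_genes) < 2) {
    stop_format("class comparison retained %d gene(s); nothing to select from",
                length(sig_genes))
  }

  sig <- impute_missing(em_subset(pre, genes = sig_genes))
  models <- train_model_suite(sig, labels, config$suite,
                              seed = derive_seed(seed, "trees"),
                              cv_folds = config$cv_folds)
  classifier_genes <- select_classifier_genes(models)
  note("tree_selection", length(classifier_genes), classifier_genes)

  weights <- overall_weights(models)
  ranking <- ranked_genes(weights)

  svm_trace <- iterate_refinement(ranking, sig, labels, "svm",
                                  cv_folds = config$cv_folds,
                                  seed = derive_seed(seed, "refine_svm"),
                                  cost = config$svm_cost)
  note("refine_svm", length(svm_trace$final_set$genes),
       svm_trace$final_set$genes)
  clust_trace <- iterate_refinement(ranking, sig, labels, "clustering",
                                    seed = derive_seed(seed, "refine_clust"))
  note("refine_clustering", length(clust_trace$final_set$genes),
       clust_trace$final_set$genes)

  combined <- combine_gene_sets(svm_trace$final_set, clust_trace$final_set)
  note("combined", length(combined$union$genes), combined$union$genes)

  # final evaluation of the combined set under both evaluators
  classes <- sort(unique(labels))
  fold <- stratified_folds(labels, config$cv_folds,
                           derive_seed(seed, "final_eval"))
  pred <- character(length(labels))
  for (f in sort(unique(fold))) {
    tr <- fold != f
    cls <- train_mc_svm(em_subset(sig, genes = combined$union$genes,
                                  samples = which(tr)),
                        combined$union$genes, labels[tr],
                        cost = config$svm_cost)
    pred[!tr] <- cls$predict(em_subset(sig, genes = combined$union$genes,
                                       samples = which(!tr)))
  }
  svm_cm <- confusion_matrix(labels, pred, classes)
  clust_cm <- kmeans_match(sig, combined$union$genes, labels,
                           seed = derive_seed(seed, "final_clust"))
  reports <- list(svm = metric_report(svm_cm),
                  clustering = metric_report(clust_cm))

  structure(list(weights = weights, models = models,
                 suite_result = suite_result,
                 svm_trace = svm_trace, clustering_trace = clust_trace,
                 combined = combined, reports = reports,
                 confusions = list(svm = svm_cm, clustering = clust_cm),
                 manifest = manifest),
            class = "PipelineResult")
}

#' @export
print.PipelineResult <- function(x, ...) {
  cat("PipelineResult\n")
  for (nm in names(x$manifest$stages)) {
    cat(sprintf("  %-18s %6d genes\n", nm, x$manifest$stages[[nm]]$genes))
  }
  invisible(x)
}

#' Write pipeline artifacts to a directory
#'
#' Emits the ranked-gene table, per-model summary, final gene sets and a
#' machine-readable run summary (JSON). Files are written to a temporary name
#' and renamed, so an aborted run leaves no partial final artifact.
#'
#' @param result a \code{PipelineResult}.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_pipeline_artifacts <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  emit <- function(name, writer) {
    tmp <- file.path(dir, paste0(".", name, ".tmp"))
    writer(tmp)
    file.rename(tmp, file.path(dir, name))
  }
  emit("ranked_genes.tsv", function(p) write_ranked_genes(result$weights, p))
  emit("model_summary.tsv", function(p) {
    df <- data.frame(
      model_id = vapply(result$models, `[[`, "", "model_id"),
      learner = vapply(result$models, `[[`, "", "learner_name"),
      ensemble = vapply(result$models, `[[`, "", "ensemble_mode"),
      accuracy_pct = round_half_up(100 * vapply(result$models, `[[`, 0, "accuracy")),
      roc_area = round(vapply(result$models, `[[`, 0, "roc_area"), 3)
    )
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  })
  for (nm in c("svm", "clustering")) {
    trace <- result[[paste0(if (nm == "svm") "svm" else "clustering", "_trace")]]
    emit(paste0(nm, "_genes.tsv"), function(p) {
      writeLines(c("gene_id", trace$final_set$genes), p)
    })
  }
  emit("combined_genes.tsv", function(p) {
    writeLines(c("gene_id", result$combined$union$genes), p)
  })
  emit("run_summary.json", function(p) {
    jsonlite::write_json(result$manifest, p, auto_unbox = TRUE, pretty = TRUE)
  })
  invisible(dir)
}
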
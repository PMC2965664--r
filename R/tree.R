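## Decision-tree learner suite and classifier-gene extraction.
##
## A configurable CART-family learner (rpart) stands behind the surface: the
## suite varies split criterion, pruning, depth and leaf-size limits, and is
## wrapped by bagging or AdaBoost.M1. The bespoke content — extracting
## classifier genes from tree structure and ranking them by weight of
## significance — is learner-agnostic.

## ---- internal tree structure -------------------------------------------
## A tree is a data.frame: node_id (binary heap numbering: children of v are
## 2v and 2v+1), depth (edges from root), is_leaf, gene_id (decision nodes),
## class_label (leaves), threshold (optional).

#' Build a tree-structure table
#'
#' @param node_id integer node ids in binary-heap numbering (root = 1,
#'   children of v are 2v and 2v+1).
#' @param is_leaf logical.
#' @param gene_id gene at each decision node (NA for leaves).
#' @param class_label leaf class (NA for decision nodes).
#' @param threshold optional split threshold.
#' @return data.frame of class \code{tree_structure} with a \code{depth} column.
#' @export
tree_structure <- function(node_id, is_leaf, gene_id, class_label,
                           threshold = NA_real_) {
  node_id <- as.integer(node_id)
  if (!1L %in% node_id) stop_format("tree must contain a root (node 1)")
  check_unique(node_id, "node id")
  df <- data.frame(node_id = node_id,
                   depth = floor(log2(node_id)),
                   is_leaf = as.logical(is_leaf),
                   gene_id = as.character(gene_id),
                   class_label = as.character(class_label),
                   threshold = as.numeric(threshold),
                   stringsAsFactors = FALSE)
  if (any(df$is_leaf & !is.na(df$gene_id))) {
    stop_format("leaves must not carry genes")
  }
  if (any(!df$is_leaf & is.na(df$gene_id))) {
    stop_format("decision nodes must carry genes")
  }
  class(df) <- c("tree_structure", class(df))
  df
}

tree_from_rpart <- function(fit, gene_map) {
  fr <- fit$frame
  nodes <- as.integer(rownames(fr))
  leaf <- fr$var == "<leaf>"
  ylv <- attr(fit, "ylevels")
  genes <- ifelse(leaf, NA_character_,
                  unname(gene_map[as.character(fr$var)]))
  labs <- ifelse(leaf, ylv[fr$yval], NA_character_)
  tree_structure(nodes, leaf, genes, labs)
}

## ---- learner configuration ---------------------------------------------

#' Describe a tree learner configuration
#'
#' @param name short label for reports.
#' @param split split criterion: \code{"gini"} or \code{"information"}.
#' @param prune \code{"none"} or \code{"cost_complexity"} (prune at the cp
#'   minimizing the internal cross-validated error).
#' @param maxdepth maximum tree depth.
#' @param minbucket minimum samples per leaf.
#' @param cp complexity parameter used while growing (default 0: grow full,
#'   prune afterwards if requested).
#' @return a \code{learner_config} list.
#' @export
learner_config <- function(name, split = c("gini", "information"),
                           prune = c("none", "cost_complexity"),
                           maxdepth = 30, minbucket = 5, cp = 0) {
  split <- match.arg(split)
  prune <- match.arg(prune)
  structure(list(name = name, split = split, prune = prune,
                 maxdepth = maxdepth, minbucket = minbucket, cp = cp),
            class = "learner_config")
}

#' Default learner suite: 3 configurations x 2 ensemble modes
#'
#' The grid spans the design axes the classic tree learners differ on (split
#' criterion, pruning, tree size) wrapped in bagging and AdaBoost.M1, giving
#' six tree models; set \code{n_members} or add configs for a larger grid.
#'
#' @param n_members ensemble size (default 10).
#' @return list of suite entries (config + ensemble mode + n_members).
#' @export
default_learner_suite <- function(n_members = 10) {
  cfgs <- list(
    learner_config("gini_deep", split = "gini", prune = "none"),
    learner_config("info_deep", split = "information", prune = "none"),
    learner_config("gini_pruned", split = "gini", prune = "cost_complexity",
                   minbucket = 3)
  )
  out <- list()
  for (cfg in cfgs) {
    for (mode in c("bagging", "adaboost_m1")) {
      out[[paste(cfg$name, mode, sep = ".")]] <-
        list(config = cfg, mode = mode, n_members = n_members)
    }
  }
  out
}

## ---- data marshalling ---------------------------------------------------

## samples x genes data.frame with syntactic names; mapping kept as attribute
em_to_frame <- function(m, genes = NULL) {
  if (inherits(m, "ExpressionMatrix")) {
    v <- masked_values(drop_spikeins(m))
  } else {
    v <- as.matrix(m)
  }
  if (!is.null(genes)) v <- v[genes, , drop = FALSE]
  safe <- paste0("g", seq_len(nrow(v)))
  map <- stats::setNames(rownames(v), safe)
  df <- as.data.frame(t(v))
  colnames(df) <- safe
  attr(df, "gene_map") <- map
  df
}

fit_rpart <- function(df, labels, config, weights = NULL) {
  dat <- df
  dat$.class <- factor(labels)
  ctl <- rpart::rpart.control(cp = config$cp, maxdepth = config$maxdepth,
                              minbucket = config$minbucket,
                              minsplit = max(2 * config$minbucket, 4),
                              xval = if (config$prune == "cost_complexity") 10 else 0,
                              maxsurrogate = 0, maxcompete = 0)
  fit <- rpart::rpart(.class ~ ., data = dat, method = "class",
                      parms = list(split = config$split), control = ctl,
                      weights = weights)
  if (config$prune == "cost_complexity" && nrow(fit$cptable) > 1) {
    best <- fit$cptable[which.min(fit$cptable[, "xerror"]), "CP"]
    fit <- rpart::prune(fit, cp = best)
  }
  fit
}

## ---- single tree and ensembles ------------------------------------------

new_tree_model <- function(model_id, learner_name, ensemble_mode, trees,
                           predict_fun, accuracy = NA_real_,
                           roc_area = NA_real_, external_weights = NULL) {
  structure(list(model_id = model_id, learner_name = learner_name,
                 ensemble_mode = ensemble_mode, trees = trees,
                 predict_fun = predict_fun, accuracy = accuracy,
                 roc_area = roc_area, external_weights = external_weights),
            class = "TreeModel")
}

#' @export
print.TreeModel <- function(x, ...) {
  cat(sprintf("TreeModel %s [%s/%s]: %d tree(s), CV accuracy %.3f, ROC %.3f\n",
              x$model_id, x$learner_name, x$ensemble_mode, length(x$trees),
              x$accuracy, x$roc_area))
  invisible(x)
}

## majority vote with ties broken by training prevalence then class name
vote <- function(vote_matrix, prevalence) {
  classes <- colnames(vote_matrix)
  ord <- order(-prevalence[classes], classes)
  pr <- vote_matrix[, ord, drop = FALSE]
  colnames(pr)[max.col(pr, ties.method = "first")]
}

train_tree_core <- function(df, labels, config, seed) {
  set.seed(derive_seed(seed, "tree"))
  fit <- fit_rpart(df, labels, config)
  gene_map <- attr(df, "gene_map")
  lv <- levels(factor(labels))
  predict_fun <- function(newdf) {
    list(class = as.character(stats::predict(fit, newdf, type = "class")),
         prob = stats::predict(fit, newdf, type = "prob")[, lv, drop = FALSE])
  }
  list(tree = tree_from_rpart(fit, gene_map), predict_fun = predict_fun)
}

train_ensemble_core <- function(df, labels, config, mode, n_members, seed) {
  n <- nrow(df)
  labels <- as.character(labels)
  lv <- sort(unique(labels))
  prevalence <- table(factor(labels, levels = lv)) / n
  gene_map <- attr(df, "gene_map")
  members <- list(); trees <- list(); alphas <- numeric(0)
  if (mode == "bagging") {
    for (bimember in seq_len(n_members)) {
      set.seed(derive_seed(seed, "bag", bimember))
      idx <- if (n_members == 1) seq_len(n) else sample(n, n, replace = TRUE)
      fit <- fit_rpart(df[idx, , drop = FALSE], labels[idx], config)
      members[[bimember]] <- fit
      trees[[bimember]] <- tree_from_rpart(fit, gene_map)
      alphas[bimember] <- 1
    }
  } else if (mode == "adaboost_m1") {
    w <- rep(1 / n, n)
    for (t in seq_len(n_members)) {
      set.seed(derive_seed(seed, "boost", t))
      fit <- fit_rpart(df, labels, config, weights = w * n)
      pred <- as.character(stats::predict(fit, df, type = "class"))
      miss <- pred != labels
      raw_err <- sum(w[miss])
      if (raw_err >= 0.5 && length(members) > 0) break
      err <- min(max(raw_err, 1e-10), 0.5 - 1e-10)
      alpha <- log((1 - err) / err)
      members[[length(members) + 1]] <- fit
      trees[[length(trees) + 1]] <- tree_from_rpart(fit, gene_map)
      alphas[length(alphas) + 1] <- alpha
      if (raw_err == 0) break # perfect member: early stop
      w <- w * exp(alpha * miss)
      w <- w / sum(w)
    }
  } else stop_format("unknown ensemble mode '%s'", mode)
  predict_fun <- function(newdf) {
    votes <- matrix(0, nrow(newdf), length(lv), dimnames = list(NULL, lv))
    for (i in seq_along(members)) {
      p <- as.character(stats::predict(members[[i]], newdf, type = "class"))
      votes[cbind(seq_len(nrow(newdf)), match(p, lv))] <-
        votes[cbind(seq_len(nrow(newdf)), match(p, lv))] + alphas[i]
    }
    prob <- votes / pmax(rowSums(votes), .Machine$double.eps)
    list(class = vote(votes, prevalence), prob = prob)
  }
  list(trees = trees, predict_fun = predict_fun, n_members = length(members))
}

## stratified 10-fold CV accuracy + pooled one-vs-rest ROC for any trainer
cv_model <- function(df, labels, trainer, folds = 10, seed = 1L) {
  labels <- as.character(labels)
  lv <- sort(unique(labels))
  fold <- stratified_folds(labels, folds, derive_seed(seed, "cv"))
  pred <- character(length(labels))
  prob <- matrix(NA_real_, length(labels), length(lv),
                 dimnames = list(NULL, lv))
  for (f in sort(unique(fold))) {
    tr <- fold != f
    fitted <- trainer(df[tr, , drop = FALSE], labels[tr],
                      derive_seed(seed, "cvfold", f))
    out <- fitted(df[!tr, , drop = FALSE])
    pred[!tr] <- out$class
    prob[!tr, colnames(out$prob)] <- out$prob
  }
  acc <- mean(pred == labels)
  roc <- tryCatch(roc_area_weighted(prob, labels)$weighted,
                  error = function(e) NA_real_)
  list(accuracy = acc, roc_area = roc, predictions = pred, prob = prob)
}

#' Train a single decision tree model
#'
#' Fits a CART-family tree under the given configuration and estimates its
#' accuracy and one-vs-rest ROC area by stratified 10-fold cross-validation on
#' the training data.
#'
#' @param m \code{ExpressionMatrix} or genes-x-samples matrix.
#' @param labels class labels, one per sample.
#' @param config a \code{\link{learner_config}}.
#' @param seed integer seed (drives fold assignment and any learner RNG).
#' @param cv_folds folds for the accuracy estimate (default 10).
#' @return a \code{TreeModel}.
#' @export
train_tree <- function(m, labels, config = learner_config("gini_deep"),
                       seed = 1L, cv_folds = 10) {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2) stop_format("need >= 2 classes")
  df <- em_to_frame(m)
  core <- train_tree_core(df, labels, config, seed)
  cv <- cv_model(df, labels,
                 function(d, l, s) train_tree_core(d, l, config, s)$predict_fun,
                 folds = cv_folds, seed = seed)
  new_tree_model(config$name, config$name, "none", list(core$tree),
                 core$predict_fun, cv$accuracy, cv$roc_area)
}

#' Train a bagged or boosted tree ensemble
#'
#' Bagging fits members on bootstrap resamples and votes by majority (ties to
#' the more prevalent training class, then lexicographic); AdaBoost.M1 fits
#' reweighted members with weighted vote, stopping early when a member's
#' weighted error reaches 0.5 or 0. Accuracy and ROC area are estimated by
#' stratified cross-validation, refitting the whole ensemble in each fold.
#'
#' @inheritParams train_tree
#' @param mode \code{"bagging"} or \code{"adaboost_m1"}.
#' @param n_members ensemble size (>= 1).
#' @return a \code{TreeModel}.
#' @export
train_ensemble <- function(m, labels, config = learner_config("gini_deep"),
                           mode = c("bagging", "adaboost_m1"), n_members = 10,
                           seed = 1L, cv_folds = 10) {
  mode <- match.arg(mode)
  if (n_members < 1) stop_format("n_members must be >= 1")
  labels <- as.character(labels)
  if (length(unique(labels)) < 2) stop_format("need >= 2 classes")
  df <- em_to_frame(m)
  core <- train_ensemble_core(df, labels, config, mode, n_members, seed)
  cv <- cv_model(df, labels, function(d, l, s) {
    train_ensemble_core(d, l, config, mode, n_members, s)$predict_fun
  }, folds = cv_folds, seed = seed)
  new_tree_model(paste(config$name, mode, sep = "."), config$name, mode,
                 core$trees, core$predict_fun, cv$accuracy, cv$roc_area)
}

#' Train the full model suite
#'
#' @param m \code{ExpressionMatrix} or genes-x-samples matrix.
#' @param labels class labels.
#' @param suite list from \code{\link{default_learner_suite}} (or the same
#'   shape); entries with \code{mode = "none"} train plain trees.
#' @param seed integer seed.
#' @param cv_folds CV folds for per-model accuracy.
#' @return list of \code{TreeModel}s.
#' @export
train_model_suite <- function(m, labels, suite = default_learner_suite(),
                              seed = 1L, cv_folds = 10) {
  models <- list()
  for (nm in names(suite)) {
    entry <- suite[[nm]]
    s <- derive_seed(seed, "suite", nm)
    if (identical(entry$mode, "none")) {
      models[[nm]] <- train_tree(m, labels, entry$config, seed = s,
                                 cv_folds = cv_folds)
    } else {
      models[[nm]] <- train_ensemble(m, labels, entry$config, entry$mode,
                                     entry$n_members, seed = s,
                                     cv_folds = cv_folds)
    }
    models[[nm]]$model_id <- nm
  }
  models
}
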
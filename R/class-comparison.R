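## Feature filtering by univariate statistics: random-variance (moderated)
## t/F tests with an inverse-gamma prior on per-gene variances, and the
## multivariate permutation procedure bounding the number of false-positive
## genes at a stated confidence.

#' Fit the inverse-gamma variance prior by marginal maximum likelihood
#'
#' Hierarchical model: per-gene precision 1/sigma^2 ~ Gamma(shape a, scale b),
#' and the observed residual variance satisfies df * s^2 / sigma^2 ~ chi^2_df.
#' Marginally a*b*s^2 ~ F(df, 2a); (a, b) maximize that marginal likelihood.
#'
#' @param residual_variances positive per-gene residual variances s^2.
#' @param dfs residual degrees of freedom, recycled to match.
#' @return list of class \code{VariancePrior}: \code{a} (shape), \code{b}
#'   (scale, inverse-variance units), \code{fallback} (TRUE when the input was
#'   degenerate and a diffuse prior was returned).
#' @export
fit_variance_prior <- function(residual_variances, dfs) {
  s2 <- as.double(residual_variances)
  dfs <- rep_len(as.double(dfs), length(s2))
  keep <- is.finite(s2) & s2 > 0 & dfs >= 1
  s2 <- s2[keep]; dfs <- dfs[keep]
  if (length(s2) < 10) {
    stop_format("variance prior needs >= 10 genes with df >= 1 (got %d)",
                length(s2))
  }
  if (stats::sd(log(s2)) < 1e-10) {
    warning("all residual variances identical; returning diffuse prior")
    return(structure(list(a = 1e-3, b = 1e6, fallback = TRUE),
                     class = "VariancePrior"))
  }
  nll <- function(par) {
    a <- exp(par[1]); b <- exp(par[2])
    x <- a * b * s2
    -sum(stats::df(x, dfs, 2 * a, log = TRUE) + log(a * b))
  }
  # moment-based start: E[s2] ~ 1/(b(a-1)) and heavy-tail spread set a
  start <- c(log(2), log(1 / mean(s2)))
  opt <- stats::optim(start, nll, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
  structure(list(a = exp(opt$par[1]), b = exp(opt$par[2]), fallback = FALSE),
            class = "VariancePrior")
}

#' @export
print.VariancePrior <- function(x, ...) {
  cat(sprintf("VariancePrior: a = %.4g, b = %.4g%s\n", x$a, x$b,
              if (isTRUE(x$fallback)) " (diffuse fallback)" else ""))
  invisible(x)
}

## Vectorized per-gene class statistics under a mask.
## Returns per-gene counts, within/between mean squares and residual df.
gene_class_stats <- function(values, mask, labels) {
  labels <- as.factor(labels)
  k <- nlevels(labels)
  Z <- stats::model.matrix(~ labels - 1) # n x k indicator
  values[!mask | is.na(values)] <- 0
  U <- mask * 1
  X <- values * U
  n_gc <- U %*% Z                      # genes x k usable counts
  sum_gc <- X %*% Z
  sumsq_gc <- (values^2 * U) %*% Z
  testable <- rowSums(n_gc >= 2) == k
  n_g <- rowSums(n_gc)
  mean_gc <- sum_gc / pmax(n_gc, 1)
  ssw <- rowSums(sumsq_gc - n_gc * mean_gc^2)
  nu <- n_g - k
  grand <- rowSums(sum_gc) / n_g
  ssb <- rowSums(n_gc * (mean_gc - grand)^2)
  list(k = k, n_gc = n_gc, mean_gc = mean_gc, testable = testable,
       nu = nu, s2 = ifelse(nu > 0, ssw / pmax(nu, 1), NA_real_),
       msb = ssb / (k - 1), levels = levels(labels))
}

#' Random-variance (moderated) t/F test per gene
#'
#' Pooled within-class variance s^2 with df nu is shrunk towards the prior:
#' s_tilde^2 = (nu*s^2 + 2/b) / (nu + 2a); the F statistic uses s_tilde^2 in
#' the denominator with denominator df nu + 2a. With two classes the statistic
#' reduces to the squared moderated t (the signed t is also reported).
#'
#' @param m an \code{ExpressionMatrix} (or plain values matrix).
#' @param labels class assignment, one per sample/column.
#' @param prior a \code{VariancePrior}; when NULL, fitted on this matrix's
#'   residual variances.
#' @return data.frame of class \code{GeneTestResult}: gene_id, statistic
#'   (moderated F), t (two-class only), p_value, testable flag, per-class
#'   means in columns \code{mean.<class>}.
#' @export
random_variance_test <- function(m, labels, prior = NULL) {
  if (inherits(m, "ExpressionMatrix")) {
    values <- m$values; mask <- m$mask; ids <- gene_ids(m)
  } else {
    values <- as.matrix(m); mask <- !is.na(values); ids <- rownames(values)
    values[!mask] <- 0
  }
  if (length(labels) != ncol(values)) {
    stop_format("labels length (%d) != sample count (%d)", length(labels),
                ncol(values))
  }
  st <- gene_class_stats(values, mask, labels)
  if (st$k < 2) stop_format("need >= 2 classes")
  if (is.null(prior)) {
    ok <- st$testable & st$nu >= 1
    prior <- fit_variance_prior(st$s2[ok], st$nu[ok])
  }
  a <- prior$a; b <- prior$b
  s2_shrunk <- (st$nu * st$s2 + 2 / b) / (st$nu + 2 * a)
  Fstat <- st$msb / s2_shrunk
  df1 <- st$k - 1
  df2 <- st$nu + 2 * a
  p <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
  p[Fstat == 0] <- 1
  Fstat[!st$testable] <- NA_real_
  p[!st$testable] <- NA_real_
  out <- data.frame(gene_id = ids, statistic = Fstat, p_value = p,
                    testable = st$testable, stringsAsFactors = FALSE)
  if (st$k == 2) {
    out$t <- sign(st$mean_gc[, 1] - st$mean_gc[, 2]) * sqrt(Fstat)
  }
  mg <- st$mean_gc
  colnames(mg) <- paste0("mean.", st$levels)
  out <- cbind(out, as.data.frame(mg))
  attr(out, "prior") <- prior
  attr(out, "df") <- c(df1 = df1)
  class(out) <- c("GeneTestResult", class(out))
  rownames(out) <- NULL
  out
}

## Distinct assignments of a label multiset: n! / prod(n_c!)
count_label_assignments <- function(labels) {
  tb <- table(labels)
  exp(lgamma(sum(tb) + 1) - sum(lgamma(tb + 1)))
}

## All distinct permutations of a label vector (multiset permutations),
## as a matrix with one assignment per column. Only called when the count
## is below the enumeration threshold.
enumerate_label_assignments <- function(labels) {
  labels <- as.character(labels)
  rec <- function(pool) {
    if (length(pool) == 1) return(matrix(pool, 1, 1))
    out <- NULL
    for (u in unique(pool)) {
      rest <- pool[-match(u, pool)]
      sub <- rec(rest)
      out <- cbind(out, rbind(u, sub))
    }
    out
  }
  unname(rec(labels))
}

#' Multivariate permutation filter controlling false-positive gene count
#'
#' Chooses the largest p-value cutoff alpha such that, over random
#' permutations of the class labels, the \code{confidence}-quantile of the
#' number of genes with permuted p <= alpha stays at or below
#' \code{max_false_positives}; returns the genes whose observed p-value is at
#' or below that cutoff, ordered by ascending p. When the label multiset has
#' fewer distinct permutations than requested (and below
#' \code{enumeration_threshold}), all of them are enumerated instead of
#' sampled. Genes untestable under the observed labeling are excluded from
#' both observed and permuted counts.
#'
#' @param m \code{ExpressionMatrix} or values matrix.
#' @param labels class labels, one per sample.
#' @param n_permutations number of label permutations (>= 100).
#' @param confidence confidence level of the false-discovery assessment,
#'   in (0, 1) (0.99 in the reference settings).
#' @param max_false_positives allowed number of false-positive genes (>= 0).
#' @param prior optional \code{VariancePrior}; fitted on the observed data
#'   when NULL and then reused for every permutation.
#' @param seed integer seed for the permutation draw.
#' @param comparison_name label stored with the result.
#' @param enumeration_threshold enumerate all distinct assignments when their
#'   number is below this (default 20000).
#' @return list of class \code{SignificantGeneList}: \code{comparison_name},
#'   \code{gene_ids} (ascending p), \code{p_values}, \code{cutoff} (alpha),
#'   \code{settings}, \code{n_tested}.
#' @export
multivariate_permutation_filter <- function(m, labels,
                                            n_permutations = 10000,
                                            confidence = 0.99,
                                            max_false_positives = 10,
                                            prior = NULL, seed = 1L,
                                            comparison_name = "comparison",
                                            enumeration_threshold = 20000) {
  if (confidence <= 0 || confidence >= 1) {
    stop_format("confidence must be in (0, 1)")
  }
  if (max_false_positives < 0) stop_format("max_false_positives must be >= 0")
  if (n_permutations < 100) {
    stop_format("need >= 100 permutations for meaningful quantiles")
  }
  labels <- as.character(labels)
  obs <- random_variance_test(m, labels, prior = prior)
  prior <- attr(obs, "prior")
  testable <- obs$testable
  p_obs <- obs$p_value[testable]
  ids <- obs$gene_id[testable]

  n_distinct <- count_label_assignments(labels)
  enumerate <- n_distinct <= min(n_permutations, enumeration_threshold)
  if (enumerate) {
    perms <- enumerate_label_assignments(labels)
  } else {
    set.seed(derive_seed(seed, "mvp"))
    perms <- replicate(n_permutations, sample(labels))
  }
  n_perm <- ncol(perms)

  # candidate cutoffs: observed p-values (and 0 meaning "select nothing")
  cand <- sort(unique(p_obs[is.finite(p_obs)]))
  if (length(cand) == 0) cand <- numeric(0)
  counts <- matrix(0L, nrow = length(cand), ncol = n_perm)
  for (i in seq_len(n_perm)) {
    pp <- random_variance_test(m, perms[, i], prior = prior)$p_value[testable]
    counts[, i] <- findInterval(cand, sort(pp[is.finite(pp)]))
  }
  # conservative empirical quantile: smallest value with ecdf >= confidence
  qidx <- min(n_perm, ceiling(confidence * n_perm))
  qcounts <- apply(counts, 1, function(x) sort(x)[qidx])
  ok <- which(qcounts <= max_false_positives)
  cutoff <- if (length(ok) > 0) cand[max(ok)] else 0
  sel <- which(p_obs <= cutoff)
  ord <- sel[order(p_obs[sel])]
  structure(list(
    comparison_name = comparison_name,
    gene_ids = ids[ord],
    p_values = p_obs[ord],
    cutoff = cutoff,
    settings = list(n_permutations = n_perm, confidence = confidence,
                    max_false_positives = max_false_positives,
                    enumerated = enumerate),
    n_tested = length(p_obs)
  ), class = "SignificantGeneList")
}

#' @export
print.SignificantGeneList <- function(x, ...) {
  cat(sprintf("SignificantGeneList '%s': %d genes (cutoff p <= %.3g, %d tested)\n",
              x$comparison_name, length(x$gene_ids), x$cutoff, x$n_tested))
  invisible(x)
}

#' Run a suite of class comparisons and take the union
#'
#' Each comparison names a sample subset and a label partition (e.g. pooled
#' controls vs one compound; or control plus the concentration groups of one
#' compound at one exposure duration). Labels are permuted within each
#' comparison's subset only. The result is the de-duplicated union with
#' per-comparison membership recorded, enabling overlap summaries.
#'
#' @param m \code{ExpressionMatrix}.
#' @param comparisons named list; each element is a list with \code{samples}
#'   (sample ids) and \code{labels} (vector of class labels, one per sample in
#'   \code{samples}).
#' @param n_permutations,confidence,max_false_positives filter settings shared
#'   by all comparisons.
#' @param seed integer seed.
#' @return list of class \code{ComparisonSuiteResult}: \code{union} (gene ids),
#'   \code{membership} (logical matrix genes x comparisons), \code{lists}
#'   (per-comparison \code{SignificantGeneList}), \code{skipped}.
#' @export
run_comparison_suite <- function(m, comparisons, n_permutations = 10000,
                                 confidence = 0.99, max_false_positives = 10,
                                 seed = 1L) {
  lists <- list()
  skipped <- character()
  for (nm in names(comparisons)) {
    cmp <- comparisons[[nm]]
    labs <- as.character(cmp$labels)
    if (length(unique(labs)) < 2 || min(table(labs)) < 2) {
      warning(sprintf("comparison '%s' skipped: empty or singleton class", nm))
      skipped <- c(skipped, nm)
      next
    }
    sub <- em_subset(m, samples = cmp$samples)
    lists[[nm]] <- multivariate_permutation_filter(
      sub, labs, n_permutations = n_permutations, confidence = confidence,
      max_false_positives = max_false_positives,
      seed = derive_seed(seed, "suite", nm), comparison_name = nm
    )
  }
  union_ids <- unique(unlist(lapply(lists, `[[`, "gene_ids"), use.names = FALSE))
  membership <- vapply(lists, function(l) union_ids %in% l$gene_ids,
                       logical(length(union_ids)))
  if (length(union_ids) == 0) {
    membership <- matrix(FALSE, 0, length(lists),
                         dimnames = list(NULL, names(lists)))
  } else {
    membership <- matrix(membership, nrow = length(union_ids),
                         dimnames = list(union_ids, names(lists)))
  }
  structure(list(union = union_ids, membership = membership, lists = lists,
                 skipped = skipped),
            class = "ComparisonSuiteResult")
}
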
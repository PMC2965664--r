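# Fixtures are generated in code; nothing is read from disk except the
# bundled reference tables.

# scaled-down planted-signal dataset used across modules
small_dataset <- function(seed = 7, n_genes = 300, n_disc = 10,
                          effect_size = 1.5, missing_rate = 0.02) {
  d <- default_design(seed = seed, n_genes = n_genes,
                      n_discriminative = c(TNT = n_disc, RDX = n_disc),
                      effect_size = effect_size, missing_rate = missing_rate)
  generate_dataset(d)
}

# random toy tree in binary-heap numbering, <= max_levels decision levels
random_toy_tree <- function(seed, max_levels = 6, genes = sprintf("g%02d", 1:12),
                            classes = c("A", "B", "C")) {
  set.seed(seed)
  node_id <- 1L
  open <- c(1L)
  internal <- integer(0)
  while (length(open) > 0) {
    v <- open[1]
    open <- open[-1]
    depth <- floor(log2(v))
    split_p <- if (depth == 0) 1 else if (depth >= max_levels) 0 else 0.55
    if (stats::runif(1) < split_p) {
      internal <- c(internal, v)
      open <- c(open, 2L * v, 2L * v + 1L)
    }
  }
  all_nodes <- sort(unique(c(1L, internal, 2L * internal, 2L * internal + 1L)))
  is_leaf <- !(all_nodes %in% internal)
  tree_structure(
    all_nodes, is_leaf,
    gene_id = ifelse(is_leaf, NA, sample(genes, length(all_nodes), replace = TRUE)),
    class_label = ifelse(is_leaf, sample(classes, length(all_nodes), replace = TRUE), NA)
  )
}

# independent brute-force oracle: enumerate all root-to-leaf paths, compute
# L as the max decision-node count over paths, weight = max over a gene's
# occurrences of (L - depth)/L
brute_force_path_weights <- function(tree) {
  leaves <- tree$node_id[tree$is_leaf]
  paths <- lapply(leaves, function(v) {
    anc <- integer(0)
    while (v >= 1) {
      anc <- c(anc, v)
      if (v == 1) break
      v <- v %/% 2
    }
    anc
  })
  decision <- tree$node_id[!tree$is_leaf]
  path_dn <- lapply(paths, function(p) intersect(p, decision))
  L <- max(lengths(path_dn))
  w <- list()
  for (p in path_dn) {
    for (v in p) {
      g <- tree$gene_id[tree$node_id == v]
      d <- floor(log2(v))
      cand <- (L - d) / L
      if (is.null(w[[g]]) || cand > w[[g]]) w[[g]] <- cand
    }
  }
  unlist(w)
}

# brute-force SVM dual solver (projected gradient on the box, with the
# equality constraint handled by projecting the gradient), independent of the
# SMO-type solver under test
qp_svm_dual <- function(K, y, C, iters = 200000, lr = 1e-3) {
  n <- length(y)
  Q <- (y %o% y) * K
  a <- rep(0, n)
  for (i in seq_len(iters)) {
    g <- 1 - Q %*% a          # gradient of sum(a) - a'Qa/2
    g <- g - y * sum(g * y) / n # project onto sum(a*y) = 0
    a_new <- pmin(pmax(a + lr * g, 0), C)
    # re-project equality after clipping (small correction loop)
    err <- sum(a_new * y)
    free <- a_new > 1e-12 & a_new < C - 1e-12
    if (any(free)) a_new[free] <- a_new[free] - y[free] * err / sum(free)
    a_new <- pmin(pmax(a_new, 0), C)
    if (max(abs(a_new - a)) < 1e-12) { a <- a_new; break }
    a <- a_new
  }
  obj <- sum(a) - 0.5 * drop(t(a) %*% Q %*% a)
  list(alpha = a, objective = obj)
}

svm_dual_objective <- function(alpha_signed, K) {
  # alpha_signed = alpha_i * y_i as returned by the fitted binary SVM
  a <- abs(alpha_signed)
  y <- sign(alpha_signed)
  Q <- (y %o% y) * K
  sum(a) - 0.5 * drop(t(a) %*% Q %*% a)
}

# hand-built accuracy curve for prune-rule tests
fake_curve <- function(series, classes = c("c1", "c2", "c3")) {
  stopifnot(ncol(series) == length(classes) + 1)
  df <- data.frame(k = seq_len(nrow(series)),
                   gene_id = sprintf("G%02d", seq_len(nrow(series))))
  df <- cbind(df, as.data.frame(series))
  colnames(df)[-(1:2)] <- c(classes, "weighted")
  attr(df, "classes") <- classes
  class(df) <- c("AccuracyCurve", class(df))
  df
}
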
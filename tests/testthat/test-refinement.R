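blob_data <- function(n_per = 20, sep = 6, p = 4, sd = 0.5, seed = 3) {
  set.seed(seed)
  classes <- c("a", "b", "c")
  centers <- rbind(rep(0, p), rep(sep, p), c(rep(0, p / 2), rep(sep, p / 2)))
  v <- do.call(cbind, lapply(1:3, function(k) {
    matrix(rnorm(p * n_per, centers[k, ], sd), p, n_per)
  }))
  dimnames(v) <- list(sprintf("g%02d", 1:p), sprintf("s%03d", 1:(3 * n_per)))
  list(m = v, labels = rep(classes, each = n_per))
}

test_that("the pairwise SVM separates separable problems", {
  # 2-class, 1-gene toy
  v <- matrix(c(0, 1, 10, 11), 1, 4,
              dimnames = list("g1", paste0("s", 1:4)))
  fit <- train_mc_svm(v, "g1", c("lo", "lo", "hi", "hi"))
  expect_identical(fit$predict(v), c("lo", "lo", "hi", "hi"))
  # 3 pairwise-separable classes
  bl <- blob_data()
  fit3 <- train_mc_svm(bl$m, rownames(bl$m), bl$labels)
  expect_identical(fit3$predict(bl$m), bl$labels)
  expect_error(train_mc_svm(v, "g1", c("lo", "lo", "hi", "x")), ">= 2")
})

test_that("the SMO-type dual solution matches a brute-force QP solver", {
  set.seed(11)
  n <- 20
  x <- matrix(rnorm(n * 2), n, 2)
  y <- ifelse(x[, 1] + 0.5 * x[, 2] + rnorm(n, sd = 0.7) > 0, 1, -1)
  C <- 1
  fit <- e1071::svm(x, factor(y), type = "C-classification", kernel = "linear",
                    cost = C, scale = FALSE, tolerance = 1e-6)
  K <- x %*% t(x)
  # e1071 returns alpha_i * y_i for the support vectors
  alpha_signed <- rep(0, n)
  alpha_signed[fit$index] <- fit$coefs[, 1]
  obj_smo <- svm_dual_objective(alpha_signed, K)
  oracle <- qp_svm_dual(K, y, C)
  expect_equal(obj_smo, oracle$objective, tolerance = 1e-4)
  # KKT: box constraints hold
  a <- abs(alpha_signed)
  expect_true(all(a >= -1e-8 & a <= C + 1e-8))
  expect_lt(abs(sum(alpha_signed)), 1e-6) # equality constraint
})

test_that("k-means matching produces a diagonal matrix on separated blobs", {
  bl <- blob_data(sep = 8)
  cm <- kmeans_match(bl$m, rownames(bl$m), bl$labels, seed = 1)
  expect_equal(unname(diag(cm)), rep(20, 3))
  expect_equal(rowSums(cm), c(a = 20, b = 20, c = 20)) # row sums = class sizes
  # matching is invariant to cluster numbering: different seeds, same matrix
  cm2 <- kmeans_match(bl$m, rownames(bl$m), bl$labels, seed = 99)
  expect_identical(unclass(cm), unclass(cm2))
  expect_error(kmeans_match(bl$m, rownames(bl$m), bl$labels, k = 2), "classes")
})

test_that("optimal cluster-to-class assignment equals brute force", {
  set.seed(21)
  for (i in 1:20) {
    tab <- matrix(rpois(9, 20), 3, 3)
    got <- isml:::best_assignment(tab)
    perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                  c(3, 1, 2), c(3, 2, 1))
    scores <- vapply(perms, function(p) sum(tab[cbind(1:3, p)]), 0)
    expect_equal(sum(tab[cbind(1:3, got)]), max(scores))
  }
})

test_that("accuracy curves are prefix-consistent", {
  bl <- blob_data(n_per = 15)
  genes <- rownames(bl$m)
  curve <- accuracy_curve(genes, bl$m, bl$labels, "svm", cv_folds = 5, seed = 2)
  expect_equal(nrow(curve), length(genes))
  expect_identical(curve$gene_id, genes)
  expect_true(all(curve$weighted >= 0 & curve$weighted <= 100))
  # the last row equals evaluating the full set directly
  fold <- stratified_folds(bl$labels, 5, derive_seed(2, "curve"))
  pred <- character(length(bl$labels))
  for (f in 1:5) {
    tr <- fold != f
    cls <- train_mc_svm(bl$m[, tr, drop = FALSE], genes, bl$labels[tr])
    pred[!tr] <- cls$predict(bl$m[, !tr, drop = FALSE])
  }
  cm <- confusion_matrix(bl$labels, pred, c("a", "b", "c"))
  expect_equal(curve$weighted[length(genes)],
               weighted_average(per_class_accuracy(cm), rowSums(cm)))
  # single-gene curve has exactly one row
  one <- accuracy_curve(genes[1], bl$m, bl$labels, "svm", cv_folds = 5, seed = 2)
  expect_equal(nrow(one), 1)
})

test_that("the prune rule removes exactly the all-four-declines genes", {
  series <- rbind(
    c(50, 50, 50, 50),      # gene 1 (never removed)
    c(49, 48, 49.5, 48.8),  # all four decline -> removed
    c(48, 46, 50.0, 47.6),  # one series ties -> kept (strict declines only)
    c(49, 47, 49.0, 48.2),  # mixed: one improves -> kept? no: compare row 4 vs 3
    c(49, 47, 49.0, 48.2)   # zero deltas -> kept
  )
  # row 4 vs row 3: deltas (+1, +1, -1, +0.6): kept
  curve <- fake_curve(series)
  out <- prune_pass(curve$gene_id, curve)
  expect_identical(out$removed, "G02")
  expect_identical(out$kept, c("G01", "G03", "G04", "G05"))
  # deltas like (-1, -2, +0.5, -1.2) keep the gene
  mixed <- fake_curve(rbind(c(50, 50, 50, 50), c(49, 48, 50.5, 48.8)))
  expect_length(prune_pass(mixed$gene_id, mixed)$removed, 0)
  # all-negative deltas remove it
  allneg <- fake_curve(rbind(c(50, 50, 50, 50), c(49, 48, 49.5, 48.8)))
  expect_identical(prune_pass(allneg$gene_id, allneg)$removed, "G02")
  expect_error(prune_pass(c("A", "B"), allneg), "match")
})

test_that("iterative refinement shrinks to a fixed point and keeps signal", {
  # moderate effect so accuracies stay off the ceiling: the prune rule only
  # fires on strict declines in all four series, so plateaus are kept
  set.seed(31)
  n <- 90
  labels <- rep(c("a", "b", "c"), each = n / 3)
  p_sig <- 10; p_null <- 90
  v <- matrix(rnorm((p_sig + p_null) * n, sd = 1), p_sig + p_null, n,
              dimnames = list(c(sprintf("sig%02d", 1:p_sig),
                                sprintf("nul%02d", 1:p_null)),
                              sprintf("s%03d", 1:n)))
  for (i in 1:p_sig) {
    cl <- c("b", "c")[i %% 2 + 1]
    v[i, labels == cl] <- v[i, labels == cl] + 0.8
  }
  ranking <- c(sprintf("sig%02d", 1:p_sig), sprintf("nul%02d", 1:p_null))
  res <- iterate_refinement(ranking, v, labels, "svm", cv_folds = 5, seed = 3)
  final <- res$final_set$genes
  # subsequence of the input ranking
  expect_identical(final, ranking[ranking %in% final])
  # strictly decreasing sizes until the final iteration
  sizes <- vapply(res$iterations, function(it) length(it$genes), 0L)
  expect_true(all(diff(sizes) < 0))
  expect_length(res$iterations[[length(res$iterations)]]$removed, 0)
  expect_lt(length(final), length(ranking)) # something was pruned
  expect_gte(length(intersect(final, sprintf("sig%02d", 1:p_sig))), 8)
  # re-running refinement on its own output is a fixed point
  again <- iterate_refinement(final, v, labels, "svm", cv_folds = 5, seed = 3)
  expect_identical(again$final_set$genes, final)
})

test_that("set combination mirrors the union/intersection arithmetic", {
  a <- classifier_gene_set(sprintf("s%02d", 1:39), "svm_optimized")
  b <- classifier_gene_set(c(sprintf("s%02d", 1:11), sprintf("c%02d", 1:19)),
                           "clustering_optimized")
  comb <- combine_gene_sets(a, b)
  expect_length(comb$union$genes, 58) # 39 + 30 - 11
  expect_length(comb$intersection$genes, 11)
  expect_identical(comb$union$provenance, "combined_union")
  expect_identical(comb$intersection$provenance, "common_intersection")

  d <- combine_gene_sets(letters[1:5], letters[6:8])
  expect_length(d$union$genes, 8)
  expect_length(d$intersection$genes, 0)

  e <- combine_gene_sets(letters[1:4], letters[1:4])
  expect_identical(e$union$genes, letters[1:4])
  expect_identical(e$intersection$genes, letters[1:4])
})
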
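test_that("variance prior is recovered from inverse-gamma simulated variances", {
  set.seed(13)
  a_true <- 3; b_true <- 1 # sigma^2 ~ InvGamma(shape 3, scale 1)
  n <- 5000; df <- 10
  sigma2 <- 1 / rgamma(n, shape = a_true, rate = b_true)
  s2 <- sigma2 * rchisq(n, df) / df
  prior <- fit_variance_prior(s2, df)
  expect_gt(prior$a, 2.4)
  expect_lt(prior$a, 3.6)
  # prior 'b' is the Gamma scale of the precision = 1 / (inverse-gamma scale)
  expect_lt(abs(prior$b - 1 / b_true) / (1 / b_true), 0.2)
  expect_false(prior$fallback)
})

test_that("degenerate prior inputs fall back or error", {
  expect_error(fit_variance_prior(c(1, 2), c(5, 5)), ">= 10")
  expect_warning(p <- fit_variance_prior(rep(2, 50), 10), "diffuse")
  expect_true(p$fallback)
})

test_that("moderated F matches the ordinary F in the concentrated-prior limit", {
  v <- matrix(c(1.2, 0.8, 1.1, 2.3, 2.0, 2.4), 1, 6,
              dimnames = list("g1", paste0("s", 1:6)))
  m <- expression_matrix(v)
  labels <- rep(c("a", "b"), each = 3)
  # ordinary one-way F
  fit <- stats::oneway.test(as.vector(v) ~ labels, var.equal = TRUE)
  a_big <- 1e10
  s2 <- summary(stats::lm(as.vector(v) ~ labels))$sigma^2
  prior <- structure(list(a = a_big, b = 1 / (s2 * (a_big - 1)), fallback = FALSE),
                     class = "VariancePrior")
  res <- random_variance_test(m, labels, prior = prior)
  expect_equal(res$statistic, unname(fit$statistic), tolerance = 1e-9)
  # two-class statistic is a squared moderated t
  expect_equal(res$t^2, res$statistic, tolerance = 1e-12)
})

test_that("a constant gene scores zero with p = 1", {
  set.seed(2)
  v <- rbind(g1 = rep(5, 8), g2 = rnorm(8))
  colnames(v) <- paste0("s", 1:8)
  prior <- structure(list(a = 2, b = 1, fallback = FALSE),
                     class = "VariancePrior")
  res <- random_variance_test(expression_matrix(v), rep(c("a", "b"), 4),
                              prior = prior)
  expect_equal(res$statistic[1], 0)
  expect_equal(res$p_value[1], 1)
})

test_that("null p-values are calibrated", {
  d <- default_design(seed = 17, n_genes = 2000, effect_size = 0,
                      missing_rate = 0, n_discriminative = c(TNT = 0, RDX = 0))
  ds <- generate_dataset(d)
  res <- random_variance_test(drop_spikeins(ds$matrix),
                              ds$annotation$class_label)
  frac <- mean(res$p_value < 0.05, na.rm = TRUE)
  expect_gte(frac, 0.035)
  expect_lte(frac, 0.065)
})

test_that("genes with too few usable values are untestable, not errors", {
  v <- rbind(g1 = rnorm(6), g2 = rnorm(6))
  colnames(v) <- paste0("s", 1:6)
  mask <- matrix(TRUE, 2, 6, dimnames = dimnames(v))
  mask["g1", 1:2] <- FALSE # class 'a' has 1 usable value left
  res <- random_variance_test(expression_matrix(v, mask),
                              rep(c("a", "b"), each = 3),
                              prior = structure(list(a = 2, b = 1),
                                                class = "VariancePrior"))
  expect_false(res$testable[1])
  expect_true(is.na(res$p_value[1]))
  expect_true(res$testable[2])
})

test_that("permutation filter respects its cutoff and monotonicity contracts", {
  ds <- small_dataset(seed = 23, n_genes = 150, n_disc = 8)
  m <- drop_spikeins(ds$matrix)
  labels <- ds$annotation$class_label
  base <- multivariate_permutation_filter(m, labels, n_permutations = 200,
                                          confidence = 0.95,
                                          max_false_positives = 5, seed = 1)
  expect_true(all(base$p_values <= base$cutoff))
  # looser false-positive allowance never shrinks the list
  looser <- multivariate_permutation_filter(m, labels, n_permutations = 200,
                                            confidence = 0.95,
                                            max_false_positives = 20, seed = 1)
  expect_true(all(base$gene_ids %in% looser$gene_ids))
  # higher confidence never grows it
  stricter <- multivariate_permutation_filter(m, labels, n_permutations = 200,
                                              confidence = 0.999,
                                              max_false_positives = 5, seed = 1)
  expect_true(all(stricter$gene_ids %in% base$gene_ids))
  expect_error(
    multivariate_permutation_filter(m, labels, confidence = 1.2),
    "confidence"
  )
})

test_that("permutation filter recovers planted genes with few extras", {
  # effect 1.5 on log scale ~ >2 prior SD (prior mean variance 0.5)
  d <- default_design(seed = 29, n_genes = 1000, effect_size = 1.5,
                      missing_rate = 0,
                      n_discriminative = c(TNT = 25, RDX = 25))
  ds <- generate_dataset(d)
  res <- multivariate_permutation_filter(
    drop_spikeins(ds$matrix), ds$annotation$class_label,
    n_permutations = 500, confidence = 0.99, max_false_positives = 10,
    seed = 2
  )
  planted <- unlist(ds$truth$discriminative_genes, use.names = FALSE)
  expect_true(all(planted %in% res$gene_ids))
  expect_lte(length(setdiff(res$gene_ids, planted)), 10)
})

test_that("small label sets are enumerated exactly", {
  v <- matrix(rnorm(80), 10, 8,
              dimnames = list(sprintf("g%02d", 1:10), sprintf("s%d", 1:8)))
  labels <- rep(c("a", "b"), each = 4) # choose(8,4) = 70 distinct assignments
  res <- multivariate_permutation_filter(expression_matrix(v), labels,
                                         n_permutations = 100,
                                         confidence = 0.9,
                                         max_false_positives = 1, seed = 1)
  expect_true(res$settings$enumerated)
  expect_equal(res$settings$n_permutations, 70)
})

test_that("comparison suites union their lists with membership flags", {
  ds <- small_dataset(seed = 37, n_genes = 200, n_disc = 10)
  pre <- preprocess_pipeline(ds$matrix, spikes = ds$spikeins)
  suite <- comparison_suite_from_annotation(ds$annotation)
  expect_length(suite, 6) # 2 two-class + 2 blocks x 2 compounds
  res <- run_comparison_suite(pre, suite, n_permutations = 150,
                              confidence = 0.95, max_false_positives = 5,
                              seed = 4)
  expect_setequal(res$union,
                  unique(unlist(lapply(res$lists, `[[`, "gene_ids"))))
  expect_identical(rownames(res$membership), res$union)
  for (nm in names(res$lists)) {
    expect_setequal(res$union[res$membership[, nm]], res$lists[[nm]]$gene_ids)
  }
  # per-compound comparisons are enriched for that compound's planted genes
  tnt_list <- res$lists[["TNT-vs-control"]]$gene_ids
  tnt_planted <- ds$truth$discriminative_genes$TNT
  expect_gte(length(intersect(tnt_list, tnt_planted)) /
               max(length(tnt_planted), 1), 0.8)

  # empty suite and skipped comparisons
  empty <- run_comparison_suite(pre, list(), n_permutations = 150)
  expect_length(empty$union, 0)
  expect_warning(
    sk <- run_comparison_suite(
      pre, list(bad = list(samples = sample_ids(pre)[1:4],
                           labels = c("a", "a", "a", "a"))),
      n_permutations = 150),
    "skipped"
  )
  expect_identical(sk$skipped, "bad")
})
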
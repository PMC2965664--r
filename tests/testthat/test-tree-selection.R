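sep_toy <- function(n = 30) {
  # one gene separating two classes perfectly at a threshold
  v <- matrix(c(rnorm(n, 0, 0.1), rnorm(n, 5, 0.1)), 1, 2 * n,
              dimnames = list("gSig", sprintf("s%03d", 1:(2 * n))))
  list(m = v, labels = rep(c("lo", "hi"), each = n))
}

test_that("a separable one-gene problem yields a single split with CV accuracy 1", {
  toy <- sep_toy()
  mod <- train_tree(toy$m, toy$labels, seed = 1)
  tr <- mod$trees[[1]]
  expect_equal(sum(!tr$is_leaf), 1)
  expect_equal(tr$gene_id[!tr$is_leaf], "gSig")
  expect_equal(mod$accuracy, 1)
  w <- extract_path_weights(mod)
  expect_equal(unname(w["gSig"]), 1) # root gene weighs 1
})

test_that("trees on label-permuted data score near chance", {
  set.seed(4)
  v <- matrix(rnorm(40 * 200), 40, 200,
              dimnames = list(sprintf("g%02d", 1:40), sprintf("s%03d", 1:200)))
  labels <- sample(rep(c("a", "b", "c"), length.out = 200))
  mod <- train_tree(v, labels, learner_config("gini_pruned", prune = "cost_complexity"),
                    seed = 3)
  expect_gte(mod$accuracy, 0.23)
  expect_lte(mod$accuracy, 0.45)
})

test_that("planted informative genes occupy the top decision levels", {
  set.seed(23)
  n <- 120
  labels <- rep(c("a", "b", "c"), each = n / 3)
  v <- matrix(rnorm(23 * n, sd = 0.3), 23, n,
              dimnames = list(c(sprintf("sig%d", 1:3), sprintf("n%02d", 1:20)),
                              sprintf("s%03d", 1:n)))
  v["sig1", labels != "a"] <- v["sig1", labels != "a"] + 3
  v["sig2", labels == "b"] <- v["sig2", labels == "b"] + 3
  v["sig3", labels == "c"] <- v["sig3", labels == "c"] + 3
  mod <- train_tree(v, labels, seed = 5)
  tr <- mod$trees[[1]]
  top <- tr$gene_id[!tr$is_leaf & tr$depth <= 2]
  expect_setequal(intersect(top, c("sig1", "sig2", "sig3")), top)
  expect_gte(length(unique(top)), 2)
})

test_that("path weights follow linear depth decay with max-over-occurrences", {
  # 3-level chain: gA at depth 0, gB at 1, gC at 2; L = 3
  chain <- tree_structure(
    node_id = c(1L, 2L, 3L, 6L, 7L, 14L, 15L),
    is_leaf = c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, TRUE),
    gene_id = c("gA", NA, "gB", NA, "gC", NA, NA),
    class_label = c(NA, "x", NA, "y", NA, "x", "z")
  )
  w <- extract_path_weights(chain)
  expect_equal(w[c("gA", "gB", "gC")], c(gA = 1, gB = 2 / 3, gC = 1 / 3))
  expect_equal(w, brute_force_path_weights(chain)[names(w)])

  # same gene at depths 0 and 2 takes the max: weight 1
  dup <- tree_structure(
    node_id = c(1L, 2L, 3L, 6L, 7L, 14L, 15L),
    is_leaf = c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, TRUE),
    gene_id = c("gA", NA, "gB", NA, "gA", NA, NA),
    class_label = c(NA, "x", NA, "y", NA, "x", "z")
  )
  expect_equal(unname(extract_path_weights(dup)["gA"]), 1)

  # single-leaf tree has no decision node: empty map
  leaf_only <- tree_structure(1L, TRUE, NA, "x")
  expect_length(extract_path_weights(leaf_only), 0)
})

test_that("weight extraction agrees with the brute-force path enumerator", {
  for (seed in 1:100) {
    tr <- random_toy_tree(seed)
    got <- extract_path_weights(tr)
    want <- brute_force_path_weights(tr)
    expect_equal(got[sort(names(got))], want[sort(names(want))],
                 tolerance = 1e-12)
    expect_true(all(got > 0 & got <= 1))
    expect_equal(unname(got[tr$gene_id[tr$node_id == 1]]), 1) # root weighs 1
  }
})

test_that("overall weights combine accuracy-scaled model weights", {
  mk_model <- function(id, tree, acc) {
    structure(list(model_id = id, learner_name = id, ensemble_mode = "none",
                   trees = list(tree), accuracy = acc, roc_area = NA,
                   external_weights = NULL, predict_fun = NULL),
              class = "TreeModel")
  }
  root_tree <- function(g) tree_structure(
    c(1L, 2L, 3L), c(FALSE, TRUE, TRUE), c(g, NA, NA), c(NA, "x", "y"))
  one <- overall_weights(list(mk_model("m1", root_tree("gA"), 0.8)))
  expect_equal(one$table$overall_weight, 0.8) # single term A * w = 0.8 * 1

  # a gene at the root of all 12 reference models attains W = sum of accuracies
  ref <- reference_model_summary()
  models <- lapply(seq_len(nrow(ref)), function(i) {
    mk_model(paste0("m", i), root_tree("gRoot"), ref$accuracy[i])
  })
  wt <- overall_weights(models)
  expect_equal(wt$table$overall_weight[1], sum(ref$accuracy), tolerance = 1e-12)
  expect_equal(round(sum(ref$accuracy), 2), 9.42)
  expect_gte(sum(ref$accuracy), 8.70) # consistency with the largest observed W

  # ties break by gene id, deterministically, and ranking ignores model order
  two <- list(mk_model("m1", root_tree("gB"), 0.5),
              mk_model("m2", root_tree("gA"), 0.5))
  t1 <- overall_weights(two)$table
  t2 <- overall_weights(rev(two))$table
  expect_identical(t1$gene_id, c("gA", "gB"))
  expect_identical(t1, t2)
  expect_error(overall_weights(list()), "empty")
})

test_that("W(g) never exceeds the sum of model accuracies", {
  ds <- small_dataset(seed = 41, n_genes = 60, n_disc = 6)
  m <- impute_missing(drop_spikeins(ds$matrix))
  models <- train_model_suite(m, ds$annotation$class_label,
                              default_learner_suite(n_members = 3), seed = 7,
                              cv_folds = 5)
  wt <- overall_weights(models)
  bound <- sum(vapply(models, `[[`, 0, "accuracy"))
  expect_true(all(wt$table$overall_weight <= bound + 1e-12))
  expect_true(all(wt$per_model >= 0 & wt$per_model <= 1))
  # classifier genes are exactly the union of decision-node genes
  expect_setequal(rownames(wt$per_model), select_classifier_genes(models))
})

test_that("degenerate ensembles behave like their base cases", {
  toy <- sep_toy()
  # bagging with one member uses the identity sample: equals the plain tree
  plain <- train_tree(toy$m, toy$labels, seed = 2)
  bag1 <- train_ensemble(toy$m, toy$labels, mode = "bagging", n_members = 1,
                         seed = 2)
  df <- as.data.frame(t(toy$m)); colnames(df) <- "g1"
  expect_identical(bag1$predict_fun(df)$class, plain$predict_fun(df)$class)
  # AdaBoost.M1 stops after one perfect member
  boost <- train_ensemble(toy$m, toy$labels, mode = "adaboost_m1",
                          n_members = 10, seed = 2)
  expect_length(boost$trees, 1)
  # an all-leaf model contributes no classifier genes
  leafy <- structure(list(model_id = "leaf", learner_name = "leaf",
                          ensemble_mode = "none",
                          trees = list(tree_structure(1L, TRUE, NA, "x")),
                          accuracy = 0.5, roc_area = NA,
                          external_weights = NULL, predict_fun = NULL),
                     class = "TreeModel")
  expect_length(select_classifier_genes(list(leafy)), 0)
})

test_that("bagging does not lose accuracy on noisy data", {
  accs <- vapply(1:5, function(s) {
    set.seed(100 + s)
    n <- 90
    labels <- rep(c("a", "b", "c"), each = n / 3)
    v <- matrix(rnorm(10 * n, sd = 1.2), 10, n,
                dimnames = list(sprintf("g%02d", 1:10), sprintf("s%03d", 1:n)))
    v["g01", labels == "b"] <- v["g01", labels == "b"] + 2
    v["g02", labels == "c"] <- v["g02", labels == "c"] + 2
    plain <- train_tree(v, labels, seed = s, cv_folds = 5)
    bag <- train_ensemble(v, labels, mode = "bagging", n_members = 25,
                          seed = s, cv_folds = 5)
    bag$accuracy - plain$accuracy
  }, 0)
  expect_gte(mean(accs), -0.02)
})
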
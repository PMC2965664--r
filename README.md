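# isml — integrated statistical and machine-learning selection of classifier genes

`isml` identifies, ranks and iteratively refines small sets of **classifier
genes** from multi-class gene-expression matrices — the kind of problem a
toxicogenomic study faces when a few hundred arrays (e.g. earthworms exposed
to the explosives TNT or RDX, plus untreated controls) must be separated into
treatment classes using a handful of marker genes rather than thousands.

The pipeline has four stages:

1. **Pre-processing** — linear-range flagging, spike-in standard-curve
   conversion of intensities to relative RNA concentrations, per-array median
   normalization, and a presence filter (a gene must be usable on at least
   `ceiling(fraction × n_arrays)` arrays).
2. **Class comparison** — a random-variance (moderated) t/F test per gene,
   with per-gene variances shrunk via an inverse-gamma prior fitted by
   marginal maximum likelihood:
   s̃²g = (νg s²g + 2/b) / (νg + 2a), F with denominator df νg + 2a.
   Significance is controlled by a **multivariate permutation filter** that
   picks the largest p-value cutoff α\* such that, with stated confidence
   (99%), the number of false-positive genes stays at or below a stated bound
   (10). A suite of two-class and multi-class comparisons is run and unioned.
3. **Tree-based selection and ranking** — a suite of CART-family tree models
   (plain, bagged, boosted) selects genes appearing at decision nodes and
   ranks them by **weight of significance**: within a tree a gene at depth d
   weighs (L − d)/L (root = 1, normalized to the longest root-to-leaf path,
   max over occurrences), and across the N models
   W(g) = Σₘ Aₘ · w(g, m), with Aₘ the model's cross-validated accuracy.
4. **Refinement** — starting from the top-ranked gene, accuracy curves over
   ranking prefixes are computed under two evaluators (pairwise multi-class
   SVM with SMO-type training; k-means with optimal cluster-to-class
   matching), and a backward-elimination pass removes every gene whose
   addition strictly decreased *all four* accuracy series (each class plus
   the weighted average), iterating to a fixed point. The SVM- and
   clustering-optimized sets are combined (union = refined set,
   intersection = core biomarker candidates).

Evaluation follows the field's conventions: confusion matrices with true
classes in rows, per-class accuracy (recall) and precision, class-size
weighted averages, one-vs-rest ROC areas with midrank ties, and nested
stratified 10-fold cross-validation in which all data-dependent selection is
re-run inside each outer training fold.

A synthetic-data generator (`generate_dataset()`) produces fixture datasets
with the structure the pipeline assumes — inverse-gamma per-gene variances,
planted class-discriminative genes, spike-in probes on a known log-log curve,
missing spots — plus the planted truth, so every stage is testable without
downloads.

## Worked example

```r
library(isml)

ds  <- generate_dataset(default_design(seed = 3, n_genes = 500,
                                       n_discriminative = c(TNT = 15, RDX = 15)))
cfg <- pipeline_config(n_permutations = 500, confidence = 0.99,
                       max_false_positives = 10,
                       suite = default_learner_suite(n_members = 5),
                       cv_folds = 10, seed = 42)
res <- run_pipeline(ds$matrix, ds$annotation, cfg, spikes = ds$spikeins)
print(res)
```

```
PipelineResult
  input                 500 genes
  preprocess            500 genes
  class_comparison       63 genes
  tree_selection         16 genes
  refine_svm             16 genes
  refine_clustering      16 genes
  combined               16 genes
```

Of 500 simulated genes (30 of them planted as class-discriminative), the
permutation filter retains 63 significant genes, the tree suite selects 16
classifier genes, and refinement keeps all 16 (on clean synthetic data the
accuracy curves plateau, and the conservative prune rule removes only genes
that strictly hurt every class). The ranking and the final SVM evaluation:

```r
head(res$weights$table)
#>   gene_id overall_weight rank
#> 1  G00029      2.5434028    1
#> 2  G00011      2.0052083    2
#> 3  G00024      1.0524306    3
#> 4  G00012      0.7756944    4
#> 5  G00027      0.6836806    5
#> 6  G00021      0.5520833    6

res$reports$svm
#> MetricReport
#>   control (16): accuracy 100.0%, precision 94.1%
#>   RDX (32): accuracy 100.0%, precision 100.0%
#>   TNT (48): accuracy 97.9%, precision 100.0%
#>   weighted average (96): accuracy 99.0%, precision 99.0%

recovery_score(res$combined$union$genes, ds$truth,
               length(res$combined$union$genes))
#> [1] 1
```

Every gene in the final 16-gene set is planted signal (`recovery = 1`); the
overall weight `W(g)` sums each model's accuracy-scaled path weight, so the
top gene (W ≈ 2.54) sat at or near the root of several of the six tree
models. A command-line wrapper with `simulate`, `preprocess` and `run-all`
subcommands ships in `inst/cli/isml.R`.

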
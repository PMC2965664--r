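---
title: "Classifier-gene selection with isml: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifier-gene selection with isml}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isml)
```

# The problem

Toxicogenomic classification studies profile thousands of genes over a few
hundred arrays and ask for a *small* set of classifier genes that separates
samples into treatment classes — for example earthworms exposed to the
explosives TNT or RDX versus untreated controls. Two obstacles dominate:
the dimensionality (genes far outnumber samples) and the combinatorial cost
of searching gene subsets. `isml` implements a staged pipeline that attacks
both: univariate statistical filtering shrinks the gene universe with an
explicit false-positive guarantee, decision-tree ensembles extract and rank
candidate classifier genes, and a backward-elimination loop under two
independent evaluators (a multi-class SVM and k-means clustering) refines
the ranked list into compact SVM- and clustering-optimized subsets whose
union is the final classifier set.

# Pre-processing

Four steps, in fixed order:

1. **Feature flagging.** Spots outside a configured linear intensity range
   are masked. Non-uniform-spot calls belong to the scanner software and
   cannot be recomputed from a value matrix, so they enter as an externally
   supplied flag matrix.
2. **Spike-in conversion.** Per array, ordinary least squares of
   log(known concentration) on log(observed spike-in intensity) converts
   every usable value to a relative RNA concentration. An array with fewer
   than two usable spike-ins is an error, not a silent skip.
3. **Median normalization.** Each array is divided by its median usable
   value, fixing the per-array median at exactly 1. Even-length medians are
   the mean of the two central values.
4. **Presence filtering.** A gene is kept if it is usable on at least
   `ceiling(min_fraction * n_arrays)` arrays, so a 50% threshold over 248
   arrays means at least 124 — the convention the ceiling reproduces.

The presence filter reads only the mask, so it commutes with normalization;
`preprocess_pipeline()` therefore normalizes on the filtered support, which
makes re-running the normalize/filter tail on its own output an exact no-op.
No background subtraction, between-array quantile normalization or log
transformation is applied.

# Statistical filtering: the random-variance model

Per-gene F-tests at a few samples per class are unstable because each gene's
variance is estimated from tiny counts. The random-variance model pools
information across genes: precisions $1/\sigma^2_g$ are modeled as
$\mathrm{Gamma}(a, b)$ (equivalently $\sigma^2_g \sim$ inverse-gamma), which
gives the shrunken variance estimate

$$\tilde{s}^2_g = \frac{\nu_g s^2_g + 2/b}{\nu_g + 2a}$$

and a moderated F statistic with denominator degrees of freedom
$\nu_g + 2a$; the two-class case reduces to a squared moderated t. The prior
$(a, b)$ is fitted by marginal maximum likelihood using the fact that
$a\,b\,s^2_g \sim F(\nu_g, 2a)$ marginally; degenerate inputs (all variances
equal) fall back to a diffuse prior with a warning. The simulator states its
variance prior on the inverse-gamma (shape, scale) scale; internally the
Gamma scale of the precision is its reciprocal.

**Multivariate permutation filter.** Rather than controlling a false
discovery *rate*, the filter bounds the *number* of false-positive genes:
it selects the largest p-value cutoff $\alpha^*$ such that, across random
permutations of the class labels, the `confidence`-quantile (conservative
empirical quantile) of the count of genes with permuted $p \le \alpha^*$
stays at or below `max_false_positives`. Reference settings are 10,000
permutations, 99% confidence, at most 10 false positives. When the label
multiset has fewer distinct assignments than requested (below a 20,000
threshold) all assignments are enumerated instead of sampled. Genes
untestable under the observed labeling (fewer than two usable values in
some class) are excluded from both observed and permuted counts so the
bound stays interpretable. The variance prior is fitted once on the
observed labeling and reused across permutations.

A study with two compounds is analyzed as a suite of comparisons — pooled
controls versus each compound, plus one multi-class comparison per compound
and exposure block over its concentration groups — and the de-duplicated
union (with per-comparison membership) feeds the next stage. Labels are
permuted within each comparison's sample subset only.

# Tree-based selection and the weight-of-significance ranking

A configurable CART-family learner (backed by `rpart`) spans the design
axes classic tree learners differ on: split criterion (Gini impurity or
information gain), pruning (none, or cost-complexity at the internally
cross-validated optimum), maximum depth and minimum leaf size. The default
suite crosses three configurations with two ensemble modes — bagging
(bootstrap members, majority vote; ties go to the more prevalent training
class, then lexicographic) and AdaBoost.M1 (reweighted members, weighted
vote, early stop at member error 0 or $\ge 0.5$) — for six tree models;
the grid is configurable to twelve or more. Gain-ratio splits and
reduced-error/best-first growth are not exposed by `rpart`; the depth and
leaf-size axes take their place. The downstream ranking is deliberately
learner-agnostic, which is also why multiple learners are used at all: no
single algorithm's bias decides the gene list. Each model's accuracy $A_m$
and one-vs-rest ROC area come from stratified 10-fold cross-validation.

**Path weights.** Within a tree, the genes at decision nodes carry
information in proportion to their height: the root split is the most
informative. With $L$ the number of decision levels on the longest
root-to-leaf path and $d(v)$ a decision node's depth (root $= 0$), a gene's
weight in one tree is

$$w(g, m) = \max_{v \,:\, \mathrm{gene}(v) = g} \frac{L - d(v)}{L},$$

so the root gene weighs 1 and the deepest decision node $1/L$. The linear
decay with max-over-occurrences is the simplest policy satisfying the
constraints the ranking needs (root largest and normalized to 1, deeper
strictly smaller, normalization by the longest path); the decay function is
a pluggable argument so alternatives can be swapped without touching
callers. Ensemble members are averaged (a member not using the gene
contributes 0), which keeps $w \in (0, 1]$; boosted members are not
reweighted inside $w$ because model quality already enters through $A_m$.
Models whose member weights come from elsewhere (e.g. logistic-model
trees) can supply `external_weights` verbatim.

**Overall weight and rank.** Across the $N$ models,

$$W(g) = \sum_{m=1}^{N} A_m \, w(g, m),$$

so $W(g) \le \sum_m A_m$, with equality only for a gene at the root of
every model. Genes are ranked by $W$ descending, ties broken by gene
identifier so the ranking is deterministic and invariant to model order.
The classifier-gene set is the union of genes at any decision node of any
model; genes never used to split are discarded.

# Refinement by backward elimination

Starting from the top-ranked gene, prefixes of the ranking are evaluated by
one of two evaluators:

- **MC-SVM**: one soft-margin binary SVM per unordered class pair (linear
  kernel, cost $C = 1$ by default), solved by an SMO-type decomposition
  method (`e1071`/libsvm), combined by pairwise voting; features are
  standardized with training-fold statistics. Accuracy comes from pooled
  stratified 10-fold testing-fold predictions.
- **k-means**: clusters (k = number of classes, k-means++ seeding, best
  within-cluster sum of squares over restarts) are matched one-to-one to
  classes by the assignment maximizing matched samples, on the full data —
  an unsupervised evaluator has no meaningful train/test split.

For each prefix size the per-class accuracies and the class-size-weighted
average are recorded. A pruning pass then scans from the bottom of the
ranking upward and removes every gene whose addition *strictly decreased
all four* series (each class and the weighted average); zero changes keep
the gene, deliberately conservative so that genes helping one class at
another's expense survive. The curve is recomputed and the pass repeated
until nothing is removed; the set shrinks strictly each earlier pass, so
termination is guaranteed. Each pass's evaluation seed is derived from the
current set size, so re-running refinement on its own output reproduces the
terminating pass and is a true fixed point.

Because the rule requires strict declines in *all four* series, pruning is
conservative wherever accuracy plateaus: adding a weak gene to an already
saturated classifier often changes no pooled prediction, every delta is 0,
and the gene is kept. On easy (high-effect) data the refined set therefore
stays close to the tree-selected set; pruning bites when accuracies sit
away from the ceiling. This is a property of the stated rule, not an
implementation choice.

The SVM- and clustering-optimized sets are finally combined: their union is
the refined classifier set and their intersection the core biomarker
candidates.

# Evaluation conventions

Confusion matrices put true classes in rows. Per-class accuracy (recall) is
$100 \cdot c_{ii} / \sum_j c_{ij}$; per-class precision is
$100 \cdot c_{jj} / \sum_i c_{ij}$. Weighted averages weight by *true*
class sizes — this convention is pinned by the bundled reference tables,
where the weighted precision matches true-class-size weighting — and the
weighted accuracy then equals the overall fraction correct. ROC areas are
one-vs-rest, computed by the rank statistic with midrank tie handling, and
class-size weighted for a single summary; the clustering evaluator produces
no scores, hence no ROC. Report percentages are rounded half-up to one
decimal. One bundled reference table prints a weighted ROC area that is not
the class-size-weighted mean of its own per-class areas; the package
reports the recomputed value under the stated convention.

Nested stratified cross-validation provides unbiased estimates: every
data-dependent choice (filtering, selection, ranking, refinement, tuning)
is re-run inside each outer training fold and outer-test predictions are
pooled. Fold assignment sorts samples by (class, seed-keyed hash of the
sample identifier) and deals round-robin — deterministic, seed-controlled,
and proportional within one sample per class.

# The synthetic-data generator

`generate_dataset()` emulates the statistical structure the pipeline
assumes: log-normal intensities (so median normalization and fold-change
semantics behave like real intensity data), per-gene log-scale variances
from an inverse-gamma prior (the random-variance assumption, default shape
3, scale 1), class-specific mean shifts of `effect_size` (default 1.5 log
units, roughly two prior standard deviations) for planted discriminative
genes, spike-in probes on a log-log standard curve over a doubling dilution
series, and independent missingness (default 5%). A single master seed
drives one RNG substream per gene, so extending a design with more genes
never changes earlier genes' draws. The default design scales the shape of
a concentration-by-duration exposure study down to 3 classes, 12 groups of
8 replicates (96 samples), 2,000 genes and 60 planted genes so that
full-pipeline tests run in minutes.

The generator deliberately omits probe-sequence effects, dye chemistry,
spatial artifacts, correlated gene modules and batch structure. Passing
tests on synthetic data therefore demonstrate the pipeline's statistical
contracts (calibration, false-positive control, recovery of planted
signal, absence of selection bias), not performance on real arrays — real
data carry correlation and confounding this generator does not model, and
synthetic classes separate more cleanly than real exposure groups.

# Numerical choices and problem sizes

- Prior fitting optimizes the marginal F likelihood over $(\log a, \log b)$
  by Nelder–Mead; at least 10 genes with positive variance are required.
- A constant gene has zero between- and within-class variance; its
  statistic is 0 and p-value 1 by convention.
- Permutation p-value cutoffs are searched over the observed p-values; the
  confidence quantile is the conservative (ceiling) empirical quantile.
- k-means centers drawn by k-means++ are perturbed by a tiny jitter if
  duplicated (degenerate data), keeping `stats::kmeans` happy.
- Masked values entering a classifier are imputed by the gene's median of
  usable values; preprocessing and filtering happen upstream of that.
- Test and acceptance runs use scaled-down sizes chosen as a deliberate
  compromise — 150–500 label permutations, ensembles of 3–10 members,
  5–10-fold cross-validation, 60–248 samples, up to 2,000 genes — the
  contracts they check are size-free.

# Known limitations

- The learner suite is CART-family only; functional-tree and
  logistic-model-tree internals (and multi-way splits) are out of scope,
  though external per-gene weights can stand in for such models.
- The permutation filter's guarantee is approximate at small permutation
  counts; the reference setting of 10,000 permutations is recommended for
  production runs.
- The clustering evaluator's accuracy depends on the scale of the input;
  values are used as-is (relative concentrations), matching the pipeline's
  no-log-transform convention, which can understate cluster separation for
  strongly skewed intensities.
- With `max_false_positives = 0` the cutoff often collapses to selecting
  nothing at modest permutation counts — the bound is on a count, and the
  smallest achievable quantile is grainy.
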
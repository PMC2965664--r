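## Synthetic multi-class expression data with planted discriminative genes.
##
## The generator emulates the statistical structure the pipeline assumes:
## log-normal intensities with per-gene variances drawn from an inverse-gamma
## prior (the random-variance model), class-specific mean shifts for planted
## discriminative genes, spike-in control probes on a log-log standard curve,
## and independently missing/flagged spots.

#' Describe a simulation design
#'
#' @param groups data.frame with columns \code{class_label}, \code{compound},
#'   \code{concentration}, \code{duration_days}, \code{experiment_block},
#'   \code{n_replicates}: one row per treatment group.
#' @param n_genes number of non-spike-in genes.
#' @param n_discriminative named integer vector: planted discriminative genes
#'   per non-reference class (names = class labels).
#' @param effect_size mean log-expression shift in the affected class(es).
#' @param variance_prior c(a, b): shape and scale of the inverse-gamma
#'   distribution of per-gene variances on the log scale.
#' @param baseline_log_mean grand mean of log expression (default 6, i.e.
#'   median raw intensity around exp(6) ~ 400).
#' @param missing_rate probability in [0,1) that any cell is flagged/missing.
#' @param n_spikeins number of spike-in control probes.
#' @param spikein_slope,spikein_intercept log-log standard curve of expected
#'   spike-in intensity against known concentration.
#' @param spikein_noise_sd log-scale noise of spike-in intensities.
#' @param reference_class class receiving no shift (default first group's class).
#' @param seed integer master seed.
#' @return a \code{SimulationDesign} list.
#' @export
simulation_design <- function(groups,
                              n_genes = 2000,
                              n_discriminative = NULL,
                              effect_size = 1.5,
                              variance_prior = c(a = 3, b = 1),
                              baseline_log_mean = 6,
                              missing_rate = 0.05,
                              n_spikeins = 10,
                              spikein_slope = 1.2,
                              spikein_intercept = 2,
                              spikein_noise_sd = 0.05,
                              reference_class = NULL,
                              seed = 1L) {
  stopifnot(is.data.frame(groups),
            all(c("class_label", "n_replicates") %in% names(groups)))
  for (col in c("compound", "experiment_block")) {
    if (is.null(groups[[col]])) groups[[col]] <- "none"
  }
  if (is.null(groups$concentration)) groups$concentration <- 0
  if (is.null(groups$duration_days)) groups$duration_days <- 0
  classes <- unique(groups$class_label)
  if (is.null(reference_class)) reference_class <- classes[1]
  if (is.null(n_discriminative)) {
    nd <- rep(30L, length(setdiff(classes, reference_class)))
    names(nd) <- setdiff(classes, reference_class)
    n_discriminative <- nd
  }
  if (sum(n_discriminative) > n_genes) {
    stop_format("design infeasible: %d discriminative genes > %d genes",
                sum(n_discriminative), n_genes)
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    stop_format("missing_rate must be in [0, 1)")
  }
  structure(list(
    groups = groups, classes = classes, reference_class = reference_class,
    n_genes = as.integer(n_genes), n_discriminative = n_discriminative,
    effect_size = effect_size,
    variance_prior = c(a = unname(variance_prior[1]), b = unname(variance_prior[2])),
    baseline_log_mean = baseline_log_mean,
    missing_rate = missing_rate, n_spikeins = as.integer(n_spikeins),
    spikein_slope = spikein_slope, spikein_intercept = spikein_intercept,
    spikein_noise_sd = spikein_noise_sd, seed = as.integer(seed)
  ), class = "SimulationDesign")
}

#' Default scaled-down three-class design
#'
#' Mirrors the shape of a concentration-by-duration toxicogenomic exposure
#' study scaled down so that full-pipeline tests run in minutes: 3 classes
#' (control and two compounds), 12 treatment groups of 8 replicates
#' (96 samples), 2,000 genes of which 30 respond to each compound.
#'
#' @param seed integer master seed.
#' @param ... overrides passed to \code{\link{simulation_design}}.
#' @return a \code{SimulationDesign}.
#' @export
default_design <- function(seed = 1L, ...) {
  groups <- rbind(
    data.frame(class_label = "control", compound = "none",
               concentration = 0, duration_days = c(4, 14),
               experiment_block = c("D4", "D14"), n_replicates = 8L),
    data.frame(class_label = "TNT", compound = "TNT",
               concentration = rep(c(6, 12, 24), 2),
               duration_days = rep(c(4, 14), each = 3),
               experiment_block = rep(c("D4", "D14"), each = 3),
               n_replicates = 8L),
    data.frame(class_label = "RDX", compound = "RDX",
               concentration = rep(c(8, 16), 2),
               duration_days = rep(c(4, 14), each = 2),
               experiment_block = rep(c("D4", "D14"), each = 2),
               n_replicates = 8L)
  )
  simulation_design(groups, seed = seed, ...)
}

inv_gamma_draw <- function(n, a, b) {
  # sigma^2 ~ InvGamma(shape a, scale b): 1/sigma^2 ~ Gamma(shape a, rate b)
  1 / stats::rgamma(n, shape = a, rate = b)
}

#' Generate a synthetic dataset
#'
#' Per gene g a variance sigma^2_g is drawn from the configured inverse-gamma
#' prior; null genes have log-expression Normal(mu0, sigma^2_g) in every
#' sample, discriminative genes are mean-shifted by \code{effect_size} in
#' their target class. Values are exponentiated to the intensity scale.
#' Spike-in probes follow the configured log-log standard curve against their
#' known concentrations. Mask entries are set FALSE independently with the
#' configured missing rate. One RNG substream per gene (derived from the
#' master seed) makes draws independent of how many genes the design holds.
#'
#' @param design a \code{SimulationDesign}.
#' @return list with elements \code{matrix} (\code{ExpressionMatrix}),
#'   \code{annotation} (data.frame), \code{spikeins} (data.frame), and
#'   \code{truth} (list: \code{discriminative_genes} map class -> gene ids,
#'   \code{null_genes}).
#' @export
generate_dataset <- function(design) {
  stopifnot(inherits(design, "SimulationDesign"))
  g <- design$groups
  n_samples <- sum(g$n_replicates)
  ann <- do.call(rbind, lapply(seq_len(nrow(g)), function(i) {
    data.frame(
      sample_id = sprintf("S%03d_%s_%s_r%d",
                          sum(g$n_replicates[seq_len(i - 1)]) + seq_len(g$n_replicates[i]),
                          g$class_label[i], g$experiment_block[i],
                          seq_len(g$n_replicates[i])),
      class_label = g$class_label[i],
      compound = g$compound[i],
      concentration_mg_per_kg = g$concentration[i],
      duration_days = g$duration_days[i],
      experiment_block = g$experiment_block[i],
      replicate = seq_len(g$n_replicates[i]),
      stringsAsFactors = FALSE
    )
  }))
  cls <- ann$class_label

  gene_names <- sprintf("G%05d", seq_len(design$n_genes))
  # assign planted genes to classes, disjointly, from the front
  truth_map <- list()
  offset <- 0L
  for (cl in names(design$n_discriminative)) {
    k <- design$n_discriminative[[cl]]
    truth_map[[cl]] <- gene_names[offset + seq_len(k)]
    offset <- offset + k
  }
  planted <- unlist(truth_map, use.names = FALSE)
  null_genes <- setdiff(gene_names, planted)

  a <- design$variance_prior["a"]; b <- design$variance_prior["b"]
  mu0 <- design$baseline_log_mean

  values <- matrix(NA_real_, design$n_genes, n_samples,
                   dimnames = list(gene_names, ann$sample_id))
  shift_class <- rep(NA_character_, design$n_genes)
  names(shift_class) <- gene_names
  for (cl in names(truth_map)) shift_class[truth_map[[cl]]] <- cl

  for (i in seq_len(design$n_genes)) {
    set.seed(derive_seed(design$seed, "gene", i))
    s2 <- inv_gamma_draw(1, a, b)
    mu <- rep(mu0, n_samples)
    if (!is.na(shift_class[i])) {
      mu[cls == shift_class[i]] <- mu0 + design$effect_size
    }
    values[i, ] <- exp(stats::rnorm(n_samples, mean = mu, sd = sqrt(s2)))
  }

  # spike-in probes: expected log intensity = intercept + slope * log(conc)
  spike_names <- sprintf("SPIKE%02d", seq_len(design$n_spikeins))
  conc <- 2^seq(0, design$n_spikeins - 1) # doubling dilution series
  spikes <- data.frame(probe_id = spike_names, known_concentration = conc,
                       stringsAsFactors = FALSE)
  spike_vals <- matrix(NA_real_, design$n_spikeins, n_samples,
                       dimnames = list(spike_names, ann$sample_id))
  for (i in seq_len(design$n_spikeins)) {
    set.seed(derive_seed(design$seed, "spike", i))
    mu <- design$spikein_intercept + design$spikein_slope * log(conc[i])
    spike_vals[i, ] <- exp(stats::rnorm(n_samples, mu, design$spikein_noise_sd))
  }

  all_values <- rbind(values, spike_vals)
  set.seed(derive_seed(design$seed, "mask"))
  mask <- matrix(stats::runif(length(all_values)) >= design$missing_rate,
                 nrow(all_values), ncol(all_values))
  dimnames(mask) <- dimnames(all_values)
  mask[spike_names, ] <- TRUE # control probes always usable

  list(
    matrix = expression_matrix(all_values, mask, spikein_ids = spike_names),
    annotation = ann,
    spikeins = spikes,
    truth = list(discriminative_genes = truth_map, null_genes = null_genes)
  )
}

#' Fraction of planted genes recovered in the top of a ranking
#'
#' @param ranked_genes character vector of gene ids, best first.
#' @param truth planted-truth list from \code{\link{generate_dataset}}.
#' @param top_k how many top-ranked genes to score.
#' @return |top-k intersect planted| / k, in [0, 1].
#' @export
recovery_score <- function(ranked_genes, truth, top_k) {
  if (top_k <= 0) stop_format("top_k must be positive")
  if (top_k > length(ranked_genes)) {
    stop_format("top_k (%d) exceeds ranking length (%d)", top_k,
                length(ranked_genes))
  }
  planted <- unlist(truth$discriminative_genes, use.names = FALSE)
  length(intersect(ranked_genes[seq_len(top_k)], planted)) / top_k
}
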
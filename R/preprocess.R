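## Pre-processing: flag -> spike-in conversion -> median normalize -> filter.
## Order is fixed; no operation ever flips a masked entry back to usable.

#' Flag features outside the scanner's linear range
#'
#' @param m an \code{ExpressionMatrix}.
#' @param low,high bounds of the linear signal-intensity range; values strictly
#'   below \code{low} or above \code{high} are masked.
#' @param extra_flags optional logical matrix (same shape), TRUE = flagged
#'   (models the scanner's non-uniform-spot call, which cannot be recomputed
#'   from a value matrix).
#' @return the matrix with its mask restricted.
#' @export
flag_features <- function(m, low, high, extra_flags = NULL) {
  stopifnot(inherits(m, "ExpressionMatrix"), low < high)
  bad <- m$values < low | m$values > high
  bad[is.na(bad)] <- TRUE
  if (!is.null(extra_flags)) {
    extra_flags <- as.matrix(extra_flags)
    if (!identical(dim(extra_flags), dim(m$values))) {
      stop_format("extra_flags shape mismatch")
    }
    bad <- bad | extra_flags
  }
  expression_matrix(m$values, m$mask & !bad, spikein_ids = m$spikein_ids)
}

#' Convert intensities to relative RNA concentrations via spike-in curve
#'
#' Per array, ordinary least squares of log(known concentration) on
#' log(observed spike-in intensity) is fitted on that array's usable,
#' positive spike-in measurements; every usable value x on the array is then
#' transformed to exp(intercept + slope * log x). Spike-in rows are retained
#' (still labeled as controls).
#'
#' @param m an \code{ExpressionMatrix} whose spike-in rows are labeled.
#' @param spikes data.frame \code{probe_id}, \code{known_concentration}.
#' @return converted \code{ExpressionMatrix}; per-array fitted coefficients in
#'   attribute \code{"spikein_fit"} (data.frame sample_id, intercept, slope).
#' @export
spike_in_convert <- function(m, spikes) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  probe_ids <- intersect(spikes$probe_id, gene_ids(m))
  if (length(probe_ids) < 2) {
    stop_format("fewer than 2 spike-in probes present in the matrix")
  }
  conc <- spikes$known_concentration[match(probe_ids, spikes$probe_id)]
  v <- m$values
  out <- v
  fits <- data.frame(sample_id = sample_ids(m), intercept = NA_real_,
                     slope = NA_real_, stringsAsFactors = FALSE)
  for (j in seq_len(ncol(v))) {
    x <- v[probe_ids, j]
    usable <- m$mask[probe_ids, j] & !is.na(x) & x > 0
    if (sum(usable) < 2 || length(unique(conc[usable])) < 2) {
      stop_format("array %s has fewer than 2 usable spike-ins", colnames(v)[j])
    }
    fit <- stats::lm.fit(cbind(1, log(x[usable])), log(conc[usable]))
    b0 <- fit$coefficients[1]; b1 <- fit$coefficients[2]
    fits$intercept[j] <- b0; fits$slope[j] <- b1
    ok <- m$mask[, j] & v[, j] > 0
    out[ok, j] <- exp(b0 + b1 * log(v[ok, j]))
  }
  res <- expression_matrix(out, m$mask & (v > 0), spikein_ids = m$spikein_ids)
  attr(res, "spikein_fit") <- fits
  res
}

#' Normalize each array to its median
#'
#' Divides each array's usable values by that array's median of usable values,
#' so the per-array median is exactly 1 afterwards (even-length medians are the
#' mean of the two central values).
#'
#' @param m an \code{ExpressionMatrix}.
#' @return normalized matrix.
#' @export
median_normalize <- function(m) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  v <- m$values
  out <- v
  for (j in seq_len(ncol(v))) {
    use <- m$mask[, j]
    if (!any(use)) stop_format("array %s has no usable values", colnames(v)[j])
    med <- stats::median(v[use, j])
    out[, j] <- v[, j] / med
  }
  expression_matrix(out, m$mask, spikein_ids = m$spikein_ids)
}

#' Filter genes by presence across arrays
#'
#' Keeps gene g iff its number of usable measurements is at least
#' \code{ceiling(min_fraction * n_samples)} (so 50% presence over 248 arrays
#' means at least 124 arrays). Spike-in rows are always dropped here: they are
#' controls, not candidate genes. Row order is preserved.
#'
#' @param m an \code{ExpressionMatrix}.
#' @param min_fraction required presence fraction in (0, 1].
#' @return filtered matrix.
#' @export
filter_genes_by_presence <- function(m, min_fraction = 0.5) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (min_fraction <= 0 || min_fraction > 1) {
    stop_format("min_fraction must be in (0, 1]")
  }
  thr <- ceiling(min_fraction * ncol(m$values))
  present <- rowSums(m$mask) >= thr
  keep <- gene_ids(m)[present & !(gene_ids(m) %in% m$spikein_ids)]
  em_subset(m, genes = keep)
}

#' Run the full pre-processing chain
#'
#' flag -> spike-in conversion -> median normalization -> presence filter.
#' The presence filter reads only the mask, so it commutes with
#' normalization; the chain normalizes each array to the median of the
#' values that survive the filter, which makes re-running the
#' normalize/filter tail on its own output an exact no-op.
#' Conversion is skipped when no spike-in table is given.
#'
#' @param m raw \code{ExpressionMatrix}.
#' @param spikes optional spike-in table.
#' @param linear_range length-2 numeric c(low, high); NULL skips flagging.
#' @param extra_flags optional logical flag matrix.
#' @param presence_fraction presence threshold (default 0.5).
#' @return pre-processed \code{ExpressionMatrix} (spike-in rows removed).
#' @export
preprocess_pipeline <- function(m, spikes = NULL, linear_range = NULL,
                                extra_flags = NULL, presence_fraction = 0.5) {
  if (!is.null(linear_range)) {
    m <- flag_features(m, linear_range[1], linear_range[2], extra_flags)
  } else if (!is.null(extra_flags)) {
    m <- flag_features(m, -Inf, Inf, extra_flags)
  }
  if (!is.null(spikes)) m <- spike_in_convert(m, spikes)
  m <- filter_genes_by_presence(m, presence_fraction)
  median_normalize(m)
}
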
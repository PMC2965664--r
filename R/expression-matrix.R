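## ExpressionMatrix: genes x samples values plus a usability mask -----------

#' Construct an ExpressionMatrix
#'
#' The pipeline's core container: a genes-by-samples numeric matrix of signal
#' intensities (or relative RNA concentrations after spike-in conversion)
#' together with a logical mask of the same shape, TRUE where the measurement
#' is usable and FALSE where the spot was flagged or missing.
#'
#' @param values numeric matrix, genes in rows, samples in columns; rownames
#'   are gene identifiers, colnames sample identifiers.
#' @param mask logical matrix of the same shape; defaults to \code{!is.na(values)}.
#' @param spikein_ids optional character vector of rows that are spike-in
#'   control probes rather than genes.
#' @return an object of class \code{ExpressionMatrix}.
#' @export
expression_matrix <- function(values, mask = NULL, spikein_ids = character()) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) {
    stop_format("values must carry gene identifiers as rownames")
  }
  if (is.null(colnames(values))) {
    stop_format("values must carry sample identifiers as colnames")
  }
  check_unique(rownames(values), "gene id")
  check_unique(colnames(values), "sample id")
  if (is.null(mask)) mask <- !is.na(values)
  mask <- as.matrix(mask)
  if (!identical(dim(mask), dim(values))) {
    stop_format("mask and values must share shape")
  }
  mask <- mask & !is.na(values)
  dimnames(mask) <- dimnames(values)
  storage.mode(mask) <- "logical"
  spikein_ids <- intersect(spikein_ids, rownames(values))
  structure(
    list(values = values, mask = mask, spikein_ids = spikein_ids),
    class = "ExpressionMatrix"
  )
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf(
    "ExpressionMatrix: %d genes x %d samples (%d spike-ins, %.1f%% masked)\n",
    nrow(x$values), ncol(x$values), length(x$spikein_ids),
    100 * mean(!x$mask)
  ))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Gene identifiers of an ExpressionMatrix
#' @param m an \code{ExpressionMatrix}.
#' @return character vector of row (gene) identifiers.
#' @export
gene_ids <- function(m) rownames(m$values)

#' Sample identifiers of an ExpressionMatrix
#' @param m an \code{ExpressionMatrix}.
#' @return character vector of column (sample) identifiers.
#' @export
sample_ids <- function(m) colnames(m$values)

#' Subset an ExpressionMatrix by genes and/or samples
#'
#' @param m an \code{ExpressionMatrix}.
#' @param genes character or index vector of rows to keep (default all).
#' @param samples character or index vector of columns to keep (default all).
#' @return the subsetted \code{ExpressionMatrix}.
#' @export
em_subset <- function(m, genes = NULL, samples = NULL) {
  if (is.null(genes)) genes <- seq_len(nrow(m$values))
  if (is.null(samples)) samples <- seq_len(ncol(m$values))
  v <- m$values[genes, samples, drop = FALSE]
  mk <- m$mask[genes, samples, drop = FALSE]
  expression_matrix(v, mk, spikein_ids = intersect(m$spikein_ids, rownames(v)))
}

#' Values with masked entries set to NA
#' @param m an \code{ExpressionMatrix}.
#' @return numeric matrix with NA where the mask is FALSE.
#' @export
masked_values <- function(m) {
  v <- m$values
  v[!m$mask] <- NA_real_
  v
}

#' Drop spike-in control rows
#' @param m an \code{ExpressionMatrix}.
#' @return the matrix restricted to non-spike-in genes.
#' @export
drop_spikeins <- function(m) {
  keep <- setdiff(gene_ids(m), m$spikein_ids)
  em_subset(m, genes = keep)
}
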
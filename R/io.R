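## Readers/writers for the flat tab-delimited formats the pipeline touches.
## Dialect: TSV, UTF-8, header row of sample ids, first column gene_id,
## missing values encoded as the empty string.

#' Read a gene-expression table
#'
#' @param path TSV file: first column gene identifiers, header row sample
#'   identifiers, one row per gene. Empty cells (or \code{na_string}) denote
#'   missing/flagged measurements and become masked entries.
#' @param transpose logical; set TRUE when the file stores samples in rows.
#' @param spikein_prefix rows whose id starts with this prefix are labeled as
#'   spike-in control probes (default \code{"SPIKE"}).
#' @param na_string additional sentinel for missing values (default \code{"NA"}).
#' @return an \code{ExpressionMatrix}.
#' @export
read_expression_table <- function(path, transpose = FALSE,
                                  spikein_prefix = "SPIKE",
                                  na_string = "NA") {
  if (!file.exists(path)) stop_format("file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 1) stop_format("empty expression table: %s", path)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1]]
  ncol_expected <- length(header)
  sample_names <- header[-1]
  check_unique(sample_names, "sample id")
  body <- cells[-1]
  widths <- lengths(body)
  bad <- which(widths > ncol_expected)
  if (length(bad) > 0) {
    stop_format("ragged row at line %d: %d fields, expected %d",
                bad[1] + 1L, widths[bad[1]], ncol_expected)
  }
  # trailing empty cells are dropped by strsplit; pad them back
  body <- lapply(body, function(r) c(r, rep("", ncol_expected - length(r))))
  ids <- vapply(body, `[[`, "", 1L)
  check_unique(ids, "gene id")
  raw <- vapply(body, function(r) r[-1], character(ncol_expected - 1L))
  raw <- matrix(raw, nrow = ncol_expected - 1L) # columns = genes here
  missing <- raw == "" | raw == na_string
  vals <- suppressWarnings(as.numeric(raw))
  vals[missing] <- NA_real_
  values <- t(matrix(vals, nrow = ncol_expected - 1L,
                     dimnames = list(sample_names, ids)))
  if (transpose) {
    values <- t(values)
    check_unique(rownames(values), "gene id")
  }
  spikes <- grep(paste0("^", spikein_prefix), rownames(values), value = TRUE)
  expression_matrix(values, spikein_ids = spikes)
}

#' Write a gene-expression table
#'
#' Inverse of \code{\link{read_expression_table}}: masked entries are written
#' as empty cells so a write-then-read round trip reproduces values and mask.
#'
#' @param m an \code{ExpressionMatrix}.
#' @param path output file path.
#' @export
write_expression_table <- function(m, path) {
  v <- m$values
  txt <- matrix(sprintf("%.15g", v), nrow = nrow(v))
  txt[!m$mask] <- ""
  lines <- c(
    paste(c("gene_id", colnames(v)), collapse = "\t"),
    vapply(seq_len(nrow(v)), function(i) {
      paste(c(rownames(v)[i], txt[i, ]), collapse = "\t")
    }, "")
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a sample-annotation table
#'
#' @param path TSV with required columns \code{sample_id} and
#'   \code{class_label}; optional \code{compound},
#'   \code{concentration_mg_per_kg}, \code{duration_days},
#'   \code{experiment_block}, \code{replicate}.
#' @param class_names allowed class labels; every \code{class_label} must be
#'   one of these.
#' @return data.frame with one row per sample.
#' @export
read_sample_annotation <- function(path, class_names) {
  if (!file.exists(path)) stop_format("file not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("sample_id", "class_label")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0) {
    stop_format("annotation lacks required column(s): %s",
                paste(miss, collapse = ", "))
  }
  if (nrow(df) == 0) return(df)
  check_unique(df$sample_id, "sample id")
  bad <- setdiff(unique(df$class_label), class_names)
  if (length(bad) > 0) {
    stop_format("unknown class label(s) %s; allowed: %s",
                paste(bad, collapse = ", "), paste(class_names, collapse = ", "))
  }
  df
}

#' Write a sample-annotation table
#' @param ann annotation data.frame.
#' @param path output file path.
#' @export
write_sample_annotation <- function(ann, path) {
  utils::write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a spike-in control table
#'
#' @param path TSV with columns \code{probe_id} and \code{known_concentration}.
#' @return data.frame with unique probe ids and positive concentrations.
#' @export
read_spikein_table <- function(path) {
  if (!file.exists(path)) stop_format("file not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("probe_id", "known_concentration")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0) {
    stop_format("spike-in table lacks column(s): %s", paste(miss, collapse = ", "))
  }
  check_unique(df$probe_id, "probe id")
  if (any(df$known_concentration <= 0)) {
    stop_format("spike-in concentrations must be positive")
  }
  if (length(unique(df$known_concentration)) < 2) {
    stop_format("need at least 2 distinct spike-in concentrations to fit a line")
  }
  df
}

#' Write a spike-in control table
#' @param spikes spike-in data.frame (\code{probe_id}, \code{known_concentration}).
#' @param path output file path.
#' @export
write_spikein_table <- function(spikes, path) {
  utils::write.table(spikes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a ranked classifier-gene table
#'
#' Tab-delimited columns \code{gene_id}, \code{overall_weight}, \code{rank},
#' sorted by rank ascending; output is byte-identical for identical input.
#' Weights are printed with 6 significant digits.
#'
#' @param table a \code{GeneWeightTable} (see \code{\link{overall_weights}})
#'   or any data.frame with those three columns.
#' @param path output file path.
#' @export
write_ranked_genes <- function(table, path) {
  if (inherits(table, "GeneWeightTable")) table <- table$table
  stopifnot(all(c("gene_id", "overall_weight", "rank") %in% names(table)))
  table <- table[order(table$rank), , drop = FALSE]
  lines <- c(
    "gene_id\toverall_weight\trank",
    sprintf("%s\t%.6g\t%d", table$gene_id, table$overall_weight,
            as.integer(table$rank))
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}
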
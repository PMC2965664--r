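#' @keywords internal
"_PACKAGE"

## Seed derivation -------------------------------------------------------

#' Derive a reproducible sub-seed from a master seed
#'
#' A single integer seed drives every stochastic stage; per-stage and
#' per-stream seeds are derived by a fixed integer hash so stages (and, in the
#' simulator, individual genes) can be re-run in isolation without disturbing
#' each other's draws.
#'
#' @param seed master integer seed.
#' @param ... further integer or character stream identifiers.
#' @return an integer in [1, 2^31 - 2].
#' @export
derive_seed <- function(seed, ...) {
  ids <- list(...)
  h <- as.double(seed) %% 2147483647
  for (id in ids) {
    if (is.character(id)) {
      id <- sum(utf8ToInt(id) * seq_along(utf8ToInt(id)))
    }
    for (v in as.double(id)) {
      h <- (h * 48271 + v + 1) %% 2147483647
    }
  }
  as.integer(h %% 2147483645) + 1L
}

## Validation helpers ----------------------------------------------------

stop_format <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_unique <- function(x, what) {
  d <- unique(x[duplicated(x)])
  if (length(d) > 0) {
    stop_format("duplicate %s: %s", what, paste(d, collapse = ", "))
  }
  invisible(x)
}

## Stratified cross-validation folds -------------------------------------

#' Deterministic stratified fold assignment
#'
#' Samples are ordered by (class, seed-keyed hash of their identifier) and
#' dealt round-robin into folds, so the assignment is reproducible from the
#' seed alone and every fold's class proportions are within one sample of the
#' global proportions.
#'
#' @param labels factor or character vector of class labels.
#' @param k number of folds.
#' @param seed integer seed.
#' @param ids optional sample identifiers used for hashing; defaults to
#'   positional indices.
#' @return integer vector of fold ids in 1..k, one per sample.
#' @export
stratified_folds <- function(labels, k, seed, ids = NULL) {
  labels <- as.character(labels)
  n <- length(labels)
  if (k < 2) stop_format("need at least 2 folds")
  if (is.null(ids)) ids <- as.character(seq_len(n))
  key <- vapply(seq_len(n), function(i) derive_seed(seed, "fold", ids[i]), 1L)
  ord <- order(labels, key)
  fold <- integer(n)
  fold[ord] <- (seq_len(n) - 1L) %% k + 1L
  fold
}

## Small numeric helpers --------------------------------------------------

round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}
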
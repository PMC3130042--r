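# Shared helpers: classed errors, sample-column bookkeeping, small numerics.

abort_class <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "metapqtl_error"), ...)
}

stop_invalid_config <- function(message) abort_class(message, "metapqtl_invalid_config")
stop_parse <- function(message) abort_class(message, "metapqtl_parse_error")
stop_schema <- function(message) abort_class(message, "metapqtl_schema_error")
stop_dimension <- function(message) abort_class(message, "metapqtl_dimension_error")
stop_numeric <- function(message) abort_class(message, "metapqtl_numeric_error")

#' Metadata column names of an isotope-group table
#'
#' An isotope-group table carries a fixed set of identification columns; every
#' other column is a per-sample log2 intensity column.
#'
#' @return Character vector of reserved metadata column names.
#' @export
isotope_meta_cols <- function() {
  c("feature_id", "peptide_label", "protein_id", "monoisotopic_mz",
    "charge_state", "peak_centroid_times", "peak_time_scores")
}

#' Sample columns of an isotope-group table
#'
#' @param table An isotope-group tibble.
#' @return Character vector of sample-id columns, in table order.
#' @export
isotope_sample_cols <- function(table) {
  setdiff(names(table), isotope_meta_cols())
}

#' Extract the samples-by-features intensity matrix
#'
#' @param table An isotope-group tibble.
#' @return Numeric matrix, rows = samples (named by sample id), columns =
#'   features (named by `feature_id`). Missing intensities are `NA`.
#' @export
intensity_matrix <- function(table) {
  samples <- isotope_sample_cols(table)
  if (length(samples) == 0L) {
    stop_schema("isotope-group table has no sample columns")
  }
  m <- t(as.matrix(as.data.frame(table[samples])))
  colnames(m) <- table$feature_id
  rownames(m) <- samples
  storage.mode(m) <- "double"
  m
}

# Standardize to mean 0, sd 1 (population-consistent with `sd`, i.e. n-1).
standardize <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop_numeric("cannot standardize a constant vector")
  (x - mean(x)) / s
}

# Deterministic sub-seed per purpose so e.g. changing the missing rate leaves
# genotypes untouched. Streams are split by a fixed offset table.
stream_seed <- function(seed, purpose) {
  offsets <- c(genotype = 1L, covariates = 2L, outcome = 3L, scores = 4L,
               loadings = 5L, membership = 6L, noise = 7L, masking = 8L,
               metadata = 9L)
  off <- offsets[[purpose]]
  (as.integer(seed) * 97L + off * 1003L) %% 2147483587L
}

with_stream <- function(seed, purpose, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(stream_seed(seed, purpose))
  force(expr)
}
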
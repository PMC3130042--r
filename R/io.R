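# Readers/writers for the pipeline's tabular interchange formats.
#
# TSV is the canonical dialect (comma available via `dialect = "csv"`).
# Multi-valued cells (several peak centroid times per isotope group) are
# comma-joined inside one tab-delimited field. All writers prepend a
# `#`-prefixed provenance header; readers treat `#` lines as comments.

provenance_header <- function(extra = character()) {
  ver <- tryCatch(as.character(utils::packageVersion("metapqtl")),
                  error = function(e) "dev")
  c(sprintf("# metapqtl %s", ver), sprintf("# %s", extra))
}

write_with_header <- function(table, path, delim, extra = character()) {
  writeLines(provenance_header(extra), path)
  readr::write_delim(table, path, delim = delim, na = "NA", append = TRUE,
                     col_names = TRUE)
  invisible(path)
}

split_numeric_cell <- function(x) {
  lapply(strsplit(as.character(x), ","), function(v) as.numeric(trimws(v)))
}

join_numeric_cell <- function(x) {
  vapply(x, function(v) paste(format(v, trim = TRUE, scientific = FALSE,
                                     digits = 15), collapse = ","), character(1))
}

#' Read an isotope-group quantitation table
#'
#' @param path Path to a delimited file with one row per isotope group. The
#'   columns named by [isotope_meta_cols()] are identification metadata; every
#'   remaining column is a per-sample log2 intensity. Empty or `NA` intensity
#'   cells become missing values; multi-valued `peak_centroid_times` and
#'   `peak_time_scores` cells are split on commas into numeric list-columns.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @param log2 If `TRUE`, intensities are log2-transformed on read; zero or
#'   negative raw values become missing.
#' @return An isotope-group tibble, row order preserved.
#' @export
read_isotope_table <- function(path, dialect = c("tsv", "csv"), log2 = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_parse(sprintf("file not found: %s", path))
  delim <- if (dialect == "tsv") "\t" else ","
  tab <- suppressWarnings(
    readr::read_delim(path, delim = delim, comment = "#", na = c("", "NA"),
                      show_col_types = FALSE, progress = FALSE,
                      col_types = readr::cols(.default = readr::col_guess())))
  probs <- readr::problems(tab)
  if (nrow(probs) > 0) {
    stop_parse(sprintf("malformed rows at line(s) %s of %s",
                       paste(unique(probs$row), collapse = ", "), path))
  }
  required <- c("feature_id", "protein_id")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0) {
    stop_schema(paste0("missing required column(s): ",
                       paste(missing_cols, collapse = ", ")))
  }
  samples <- setdiff(names(tab), isotope_meta_cols())
  if (length(samples) == 0) stop_schema("no sample columns found")

  tab$feature_id <- as.character(tab$feature_id)
  tab$protein_id <- as.character(tab$protein_id)
  if (!"peptide_label" %in% names(tab)) tab$peptide_label <- tab$protein_id
  if ("charge_state" %in% names(tab)) {
    tab$charge_state <- as.integer(tab$charge_state)
    if (any(stats::na.omit(tab$charge_state) < 1)) {
      stop_schema("charge_state must be >= 1")
    }
  }
  for (col in c("peak_centroid_times", "peak_time_scores")) {
    if (col %in% names(tab)) tab[[col]] <- split_numeric_cell(tab[[col]])
  }
  if ("peak_time_scores" %in% names(tab)) {
    sc <- unlist(tab$peak_time_scores)
    if (any(stats::na.omit(sc) < 0 | stats::na.omit(sc) > 1)) {
      stop_schema("peak_time_scores must lie in [0, 1]")
    }
  }
  for (s in samples) {
    v <- as.numeric(tab[[s]])
    if (log2) {
      v[!is.na(v) & v <= 0] <- NA_real_
      v <- base::log2(v)
    }
    tab[[s]] <- v
  }
  meta <- intersect(isotope_meta_cols(), names(tab))
  tab[c(meta, samples)]
}

#' Write an isotope-group table
#'
#' Inverse of [read_isotope_table()]: list-columns are comma-joined, missing
#' intensities become `NA`, and a provenance header is prepended.
#'
#' @param table An isotope-group tibble.
#' @param path Output path.
#' @param dialect `"tsv"` or `"csv"`.
#' @param provenance Optional character lines for the `#` header.
#' @return The path, invisibly.
#' @export
write_isotope_table <- function(table, path, dialect = c("tsv", "csv"),
                                provenance = character()) {
  dialect <- match.arg(dialect)
  out <- table
  for (col in c("peak_centroid_times", "peak_time_scores")) {
    if (col %in% names(out) && is.list(out[[col]])) {
      out[[col]] <- join_numeric_cell(out[[col]])
    }
  }
  write_with_header(out, path, if (dialect == "tsv") "\t" else ",", provenance)
}

GENOTYPE_LEVELS <- c(CC = 2L, CT = 1L, TC = 1L, TT = 0L)

#' Read a cohort table
#'
#' @param path Delimited file with columns `sample_id`, `genotype`, `sex`,
#'   `race`, and optionally `outcome`. Genotype strings are normalized
#'   case-insensitively; the unphased heterozygotes `TC` and `CT` are the same
#'   genotype and both get allele count 1 (count of C alleles).
#' @param dialect `"tsv"` or `"csv"`.
#' @return A cohort tibble with an added integer `allele_count` column and
#'   genotype labels normalized to `CC`/`CT`/`TT`.
#' @export
read_cohort_table <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_parse(sprintf("file not found: %s", path))
  delim <- if (dialect == "tsv") "\t" else ","
  tab <- readr::read_delim(path, delim = delim, comment = "#", na = c("", "NA"),
                           show_col_types = FALSE, progress = FALSE)
  required <- c("sample_id", "genotype", "sex", "race")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0) {
    stop_schema(paste0("missing required column(s): ",
                       paste(missing_cols, collapse = ", ")))
  }
  tab$sample_id <- as.character(tab$sample_id)
  if (anyDuplicated(tab$sample_id)) stop_schema("duplicate sample_id values")
  g <- toupper(trimws(as.character(tab$genotype)))
  unknown <- which(!g %in% names(GENOTYPE_LEVELS))
  if (length(unknown) > 0) {
    abort_class(sprintf("unknown genotype value(s) %s at row(s) %s",
                        paste(unique(g[unknown]), collapse = ", "),
                        paste(unknown, collapse = ", ")),
                "metapqtl_validation_error")
  }
  count <- unname(GENOTYPE_LEVELS[g])
  out <- tibble::tibble(
    sample_id = tab$sample_id,
    genotype = c("TT", "CT", "CC")[count + 1L],
    allele_count = count,
    sex = as.character(tab$sex),
    race = as.character(tab$race)
  )
  out$outcome <- if ("outcome" %in% names(tab)) as.character(tab$outcome) else NA_character_
  out
}

#' Write a cohort table
#'
#' @param cohort A cohort tibble.
#' @param path Output path.
#' @param dialect `"tsv"` or `"csv"`.
#' @param provenance Optional character lines for the `#` header.
#' @return The path, invisibly.
#' @export
write_cohort_table <- function(cohort, path, dialect = c("tsv", "csv"),
                               provenance = character()) {
  dialect <- match.arg(dialect)
  write_with_header(cohort, path, if (dialect == "tsv") "\t" else ",", provenance)
}

#' Read a protein identification-frequency table
#'
#' One row per identified protein with the number of distinct isotope groups
#' identified for it.
#'
#' @param path Delimited file with columns `protein_id`, `protein_name`,
#'   `n_isotope_groups`.
#' @param dialect `"tsv"` or `"csv"`.
#' @return A tibble.
#' @export
read_protein_frequency <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  delim <- if (dialect == "tsv") "\t" else ","
  tab <- readr::read_delim(path, delim = delim, comment = "#", na = c("", "NA"),
                           show_col_types = FALSE, progress = FALSE)
  required <- c("protein_id", "n_isotope_groups")
  if (length(setdiff(required, names(tab))) > 0) {
    stop_schema("protein frequency table needs protein_id and n_isotope_groups")
  }
  if (anyDuplicated(tab$protein_id)) stop_schema("duplicate protein_id values")
  if (any(tab$n_isotope_groups < 1)) stop_schema("n_isotope_groups must be >= 1")
  tab
}
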
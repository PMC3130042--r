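# Minimal MATLAB v5 (Level 5 MAT-file) reader/writer.
#
# Supports the subset the workspace contract needs: little-endian files,
# numeric arrays (stored or convertible to double), character arrays, and
# zlib-compressed (miCOMPRESSED) elements. Cell/struct/sparse classes are
# skipped with a warning. The writer emits uncompressed double matrices and
# character arrays (one string per row, space-padded, UINT16 code units),
# which MATLAB, Octave and scipy.io.loadmat all read back.

MI_TYPES <- c(miINT8 = 1L, miUINT8 = 2L, miINT16 = 3L, miUINT16 = 4L,
              miINT32 = 5L, miUINT32 = 6L, miSINGLE = 7L, miDOUBLE = 9L,
              miINT64 = 12L, miUINT64 = 13L, miMATRIX = 14L,
              miCOMPRESSED = 15L, miUTF8 = 16L, miUTF16 = 17L)

mat5_read_numeric <- function(raw, type, n) {
  switch(as.character(type),
    "1" = as.numeric(readBin(raw, integer(), n, size = 1L, signed = TRUE, endian = "little")),
    "2" = as.numeric(readBin(raw, integer(), n, size = 1L, signed = FALSE, endian = "little")),
    "3" = as.numeric(readBin(raw, integer(), n, size = 2L, signed = TRUE, endian = "little")),
    "4" = as.numeric(readBin(raw, integer(), n, size = 2L, signed = FALSE, endian = "little")),
    "17" = as.numeric(readBin(raw, integer(), n, size = 2L, signed = FALSE, endian = "little")),
    "5" = as.numeric(readBin(raw, integer(), n, size = 4L, endian = "little")),
    "6" = {  # miUINT32: R lacks unsigned 32-bit, wrap negatives
      v <- as.numeric(readBin(raw, integer(), n, size = 4L, endian = "little"))
      ifelse(v < 0, v + 4294967296, v)
    },
    "7" = as.numeric(readBin(raw, numeric(), n, size = 4L, endian = "little")),
    "9" = readBin(raw, numeric(), n, size = 8L, endian = "little"),
    stop_parse(sprintf("unsupported MAT data type %s", type))
  )
}

# One tagged data element starting at offset `pos` (1-based) in raw vector.
# Returns list(type, bytes = raw payload, next_pos).
mat5_element <- function(buf, pos) {
  tag <- readBin(buf[pos:(pos + 3L)], integer(), 1L, size = 4L, endian = "little")
  small_n <- bitwAnd(bitwShiftR(tag, 16L), 0xFFFFL)
  if (small_n > 0L) {
    type <- bitwAnd(tag, 0xFFFFL)
    nbytes <- small_n
    data <- buf[(pos + 4L):(pos + 3L + nbytes)]
    nxt <- pos + 8L
  } else {
    type <- tag
    nbytes <- readBin(buf[(pos + 4L):(pos + 7L)], integer(), 1L, size = 4L, endian = "little")
    data <- if (nbytes > 0L) buf[(pos + 8L):(pos + 7L + nbytes)] else raw(0)
    pad <- (8L - nbytes %% 8L) %% 8L
    if (type == MI_TYPES[["miCOMPRESSED"]]) pad <- 0L  # compressed data is not padded
    nxt <- pos + 8L + nbytes + pad
  }
  list(type = type, bytes = data, next_pos = nxt)
}

mat5_parse_matrix <- function(bytes) {
  pos <- 1L
  flags_el <- mat5_element(bytes, pos); pos <- flags_el$next_pos
  flags_word <- readBin(flags_el$bytes[1:4], integer(), 1L, size = 4L, endian = "little")
  klass <- bitwAnd(flags_word, 0xFFL)
  dims_el <- mat5_element(bytes, pos); pos <- dims_el$next_pos
  dims <- readBin(dims_el$bytes, integer(), length(dims_el$bytes) %/% 4L,
                  size = 4L, endian = "little")
  name_el <- mat5_element(bytes, pos); pos <- name_el$next_pos
  name <- rawToChar(name_el$bytes)
  n <- prod(dims)

  value <- NULL
  if (klass %in% c(6L, 7L, 8L, 9L, 10L, 11L, 12L, 13L)) {  # numeric classes
    data_el <- mat5_element(bytes, pos)
    value <- mat5_read_numeric(data_el$bytes, data_el$type, n)
    value <- array(value, dim = dims)
    if (length(dims) == 2L) value <- matrix(value, dims[1], dims[2])
  } else if (klass == 4L) {  # mxCHAR
    data_el <- mat5_element(bytes, pos)
    codes <- switch(as.character(data_el$type),
      "16" = as.integer(data_el$bytes),  # miUTF8, ASCII assumed
      "1" = , "2" = as.integer(data_el$bytes),
      "3" = , "4" = , "17" = readBin(data_el$bytes, integer(),
                                     length(data_el$bytes) %/% 2L,
                                     size = 2L, signed = FALSE, endian = "little"),
      stop_parse(sprintf("unsupported MAT char encoding %s", data_el$type)))
    cm <- matrix(codes, nrow = dims[1], ncol = dims[2])
    value <- apply(cm, 1, function(r) {
      sub(" +$", "", intToUtf8(r[r > 0L]))
    })
    if (dims[1] == 0L) value <- character(0)
  } else {
    return(list(name = name, value = NULL, skipped = TRUE))
  }
  list(name = name, value = value, skipped = FALSE)
}

#' Read a MATLAB v5 MAT-file into a named list
#'
#' @param path Path to a little-endian Level 5 MAT-file.
#' @return Named list: numeric arrays become matrices/arrays of doubles;
#'   character arrays become character vectors (one element per row).
#'   Unsupported classes (cell, struct, sparse, objects) are skipped with a
#'   warning naming the variable.
#' @export
read_mat <- function(path) {
  if (!file.exists(path)) stop_parse(sprintf("file not found: %s", path))
  buf <- readBin(path, raw(), file.info(path)$size)
  if (length(buf) < 128L) stop_parse("not a MAT v5 file (truncated header)")
  version <- readBin(buf[125:126], integer(), 1L, size = 2L, endian = "little")
  endian <- rawToChar(buf[127:128])
  if (endian != "IM") stop_parse("unsupported MAT file (big-endian or not v5)")
  if (version != 0x0100) stop_parse(sprintf("unsupported MAT version 0x%04x", version))

  out <- list()
  pos <- 129L
  while (pos + 7L <= length(buf)) {
    el <- mat5_element(buf, pos)
    pos <- el$next_pos
    if (el$type == MI_TYPES[["miCOMPRESSED"]]) {
      inner <- memDecompress(el$bytes, type = "gzip")
      el <- mat5_element(inner, 1L)
    }
    if (el$type != MI_TYPES[["miMATRIX"]]) next
    parsed <- mat5_parse_matrix(el$bytes)
    if (parsed$skipped) {
      warning(sprintf("skipping unsupported MAT variable '%s'", parsed$name))
    } else {
      out[[parsed$name]] <- parsed$value
    }
  }
  out
}

pad8 <- function(bytes) {
  pad <- (8L - length(bytes) %% 8L) %% 8L
  c(bytes, raw(pad))
}

mat5_tag <- function(type, nbytes) {
  c(writeBin(as.integer(type), raw(), size = 4L, endian = "little"),
    writeBin(as.integer(nbytes), raw(), size = 4L, endian = "little"))
}

mat5_encode_matrix <- function(name, value) {
  if (is.character(value)) {
    nr <- length(value)
    nc <- if (nr > 0) max(nchar(value)) else 0L
    padded <- formatC(value, width = -nc)  # right-pad with spaces
    codes <- matrix(32L, nrow = nr, ncol = nc)
    for (i in seq_len(nr)) {
      u <- utf8ToInt(padded[i])
      if (length(u) > 0) codes[i, seq_along(u)] <- u
    }
    klass <- 4L
    data_bytes <- writeBin(as.integer(as.vector(codes)), raw(), size = 2L,
                           endian = "little")
    data_type <- MI_TYPES[["miUINT16"]]
    dims <- c(nr, nc)
  } else {
    value <- as.matrix(value)
    storage.mode(value) <- "double"
    klass <- 6L
    data_bytes <- writeBin(as.vector(value), raw(), size = 8L, endian = "little")
    data_type <- MI_TYPES[["miDOUBLE"]]
    dims <- dim(value)
  }
  flags <- c(mat5_tag(MI_TYPES[["miUINT32"]], 8L),
             writeBin(as.integer(klass), raw(), size = 4L, endian = "little"),
             writeBin(0L, raw(), size = 4L, endian = "little"))
  dims_b <- pad8(c(mat5_tag(MI_TYPES[["miINT32"]], 4L * length(dims)),
                   writeBin(as.integer(dims), raw(), size = 4L, endian = "little")))
  name_raw <- charToRaw(name)
  name_b <- pad8(c(mat5_tag(MI_TYPES[["miINT8"]], length(name_raw)), name_raw))
  data_b <- pad8(c(mat5_tag(data_type, length(data_bytes)), data_bytes))
  body <- c(flags, dims_b, name_b, data_b)
  c(mat5_tag(MI_TYPES[["miMATRIX"]], length(body)), body)
}

#' Write a named list as a MATLAB v5 MAT-file
#'
#' Numeric vectors/matrices are written as double arrays (vectors as 1-row
#' matrices); character vectors as char arrays with one string per row.
#'
#' @param vars Named list of numeric matrices/vectors and character vectors.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_mat <- function(vars, path) {
  if (is.null(names(vars)) || any(names(vars) == "")) {
    stop_invalid_config("all MAT variables must be named")
  }
  header <- charToRaw(sprintf("MATLAB 5.0 MAT-file, written by metapqtl on %s",
                              format(Sys.time(), "%Y-%m-%d")))
  header <- c(header[seq_len(min(116L, length(header)))],
              raw(max(0L, 116L - length(header))))
  header[header == as.raw(0)] <- as.raw(32L)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(header, con)
  writeBin(raw(8), con)  # no subsystem data
  writeBin(c(writeBin(256L, raw(), size = 2L, endian = "little"), charToRaw("IM")), con)
  for (nm in names(vars)) {
    vec <- vars[[nm]]
    if (is.numeric(vec) && is.null(dim(vec))) vec <- matrix(vec, nrow = 1L)
    writeBin(mat5_encode_matrix(nm, vec), con)
  }
  invisible(path)
}

#' Read an analysis workspace from a MAT-file
#'
#' Maps workspace variables onto the pipeline's in-memory tables. The
#' `variable_map` names which variables play which role; anything not mapped
#' is ignored with a message. Required roles: `intensities` (features x
#' samples numeric matrix), `protein_id` (character, one entry per feature;
#' empty string = unidentified), `genotype` (per-sample C-allele counts 0/1/2,
#' or genotype strings), `sex`, `race`. Optional roles: `feature_id`,
#' `sample_id`, `outcome`, `monoisotopic_mz`, `charge_state`, `scores`
#' (samples x factors precomputed metaprotein scores), `score_names`.
#' Numeric codings accepted: sex 1 = male, race 1 = Caucasian, outcome
#' 1 = SVR.
#'
#' @param path Path to the MAT-file.
#' @param variable_map Named list/character vector: role -> workspace
#'   variable name.
#' @return A list with `peptides` (isotope-group tibble), `cohort` (cohort
#'   tibble) and `scores` (tibble of precomputed scores, or `NULL`).
#' @export
read_mat_workspace <- function(path, variable_map) {
  vars <- read_mat(path)
  variable_map <- as.list(variable_map)
  get_var <- function(role, required = TRUE) {
    nm <- variable_map[[role]]
    if (is.null(nm)) {
      if (required) stop_schema(sprintf("variable_map is missing required role '%s'", role))
      return(NULL)
    }
    if (!nm %in% names(vars)) {
      stop_schema(sprintf("mapped variable '%s' (role '%s') not found in workspace", nm, role))
    }
    vars[[nm]]
  }
  unmapped <- setdiff(names(vars), unlist(variable_map))
  if (length(unmapped) > 0) {
    message("ignoring unmapped workspace variable(s): ",
            paste(unmapped, collapse = ", "))
  }

  x <- get_var("intensities")
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  n_feat <- nrow(x); n_samp <- ncol(x)
  protein <- as.character(get_var("protein_id"))
  if (length(protein) != n_feat) {
    stop_dimension("protein_id length does not match intensity rows")
  }
  protein[protein == ""] <- NA_character_
  fid <- get_var("feature_id", required = FALSE)
  fid <- if (is.null(fid)) sprintf("F%04d", seq_len(n_feat)) else as.character(fid)
  sid <- get_var("sample_id", required = FALSE)
  sid <- if (is.null(sid)) sprintf("S%03d", seq_len(n_samp)) else as.character(sid)

  decode_geno <- function(g) {
    if (is.character(g)) unname(GENOTYPE_LEVELS[toupper(trimws(g))]) else as.integer(round(g))
  }
  decode_binary <- function(v, one, zero) {
    if (is.null(v)) return(NULL)
    if (is.character(v)) as.character(v) else ifelse(as.numeric(v) == 1, one, zero)
  }
  count <- decode_geno(as.vector(get_var("genotype")))
  if (length(count) != n_samp) stop_dimension("genotype length does not match samples")
  if (any(!count %in% 0:2)) stop_schema("genotype values must code 0/1/2 C alleles")
  sex <- decode_binary(as.vector(get_var("sex")), "male", "female")
  race <- decode_binary(as.vector(get_var("race")), "Caucasian", "African American")
  outcome <- decode_binary(as.vector(get_var("outcome", required = FALSE)), "SVR", "NR")
  if (is.null(outcome)) outcome <- NA_character_

  cohort <- tibble::tibble(
    sample_id = sid,
    genotype = c("TT", "CT", "CC")[count + 1L],
    allele_count = as.integer(count),
    sex = sex, race = race, outcome = outcome
  )

  mz <- get_var("monoisotopic_mz", required = FALSE)
  charge <- get_var("charge_state", required = FALSE)
  peptides <- tibble::tibble(
    feature_id = fid,
    peptide_label = ifelse(is.na(protein), "unidentified", protein),
    protein_id = protein,
    monoisotopic_mz = if (is.null(mz)) NA_real_ else as.vector(mz),
    charge_state = if (is.null(charge)) NA_integer_ else as.integer(as.vector(charge)),
    peak_centroid_times = replicate(n_feat, NA_real_, simplify = FALSE),
    peak_time_scores = replicate(n_feat, NA_real_, simplify = FALSE)
  )
  intens <- tibble::as_tibble(as.data.frame(x))
  names(intens) <- sid
  peptides <- dplyr::bind_cols(peptides, intens)

  scores <- get_var("scores", required = FALSE)
  scores_tbl <- NULL
  if (!is.null(scores)) {
    if (!is.matrix(scores)) scores <- matrix(scores, ncol = 1L)
    if (nrow(scores) != n_samp) stop_dimension("scores rows do not match samples")
    snames <- get_var("score_names", required = FALSE)
    colnames(scores) <- if (is.null(snames)) {
      sprintf("factor%02d", seq_len(ncol(scores)))
    } else {
      as.character(snames)
    }
    scores_tbl <- dplyr::bind_cols(tibble::tibble(sample_id = sid),
                                   tibble::as_tibble(as.data.frame(scores)))
  }
  list(peptides = peptides, cohort = cohort, scores = scores_tbl)
}
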
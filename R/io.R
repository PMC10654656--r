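#' File formats
#'
#' All tabular formats are plain text, UTF-8, LF line endings, with a header
#' row and `.` as decimal separator:
#' \describe{
#'   \item{readout.csv}{`sample_id,antibody_id,color_id,mfi` -- one row per
#'     bead set; the reserved `antibody_id` values `EMPTY_BEAD` and
#'     `SECONDARY_ONLY` mark control incubations, keyed either to a specific
#'     `sample_id` or to the wildcard `*` (one control set per run).}
#'   \item{beadmap.csv}{`color_id,fraction_index` -- a bijection between the
#'     96 bead color IDs and the 96 MW fractions (0 = top of gel, highest MW).}
#'   \item{ladder.csv}{`fraction_index,mw_kda` -- calibration anchors,
#'     strictly MW-decreasing with index.}
#'   \item{panel.json}{JSON list of `{antibody_id, marker, expected_mw_kda,
#'     valid_species}` objects.}
#'   \item{samples.csv}{`sample_id,species,source,protein_input_ug`.}
#'   \item{peaks.tsv / calls.tsv / matrix.tsv}{tab-separated result tables.}
#' }
#' Readers reject exactly the inputs that violate a type invariant, naming
#' the offending field (and line, where applicable); every writer's output
#' re-reads equal.
#'
#' @name digiwest-formats
NULL

# ---- readout ---------------------------------------------------------------

#' Read / write a bead readout table
#'
#' @param path Path to a `readout.csv` file (see [digiwest-formats]).
#' @return `read_readout()`: a data.frame with columns `sample_id`,
#'   `antibody_id`, `color_id` (character) and `mfi` (numeric, finite, >= 0),
#'   unique on the first three columns.
#' @export
read_readout <- function(path) {
  req <- c("sample_id", "antibody_id", "color_id", "mfi")
  df <- read_table_checked(path, req)
  df <- df[req]
  df$mfi <- parse_num_col(df$mfi, "mfi", path)
  bad <- which(!is.finite(df$mfi) | df$mfi < 0)
  if (length(bad)) {
    stop(sprintf("%s: mfi must be finite and >= 0; violated at line(s) %s",
                 path, paste(bad + 1L, collapse = ", ")), call. = FALSE)
  }
  key <- paste(df$sample_id, df$antibody_id, df$color_id, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup)) {
    stop(sprintf("%s: duplicate (sample_id, antibody_id, color_id) at line(s) %s",
                 path, paste(dup + 1L, collapse = ", ")), call. = FALSE)
  }
  rownames(df) <- NULL
  df
}

#' @rdname read_readout
#' @param readout A readout data.frame as returned by [read_readout()] or
#'   found in a simulated dataset.
#' @export
write_readout <- function(readout, path) {
  stopifnot(all(c("sample_id", "antibody_id", "color_id", "mfi") %in% names(readout)))
  write_table_file(readout[c("sample_id", "antibody_id", "color_id", "mfi")], path)
}

# ---- bead map --------------------------------------------------------------

#' Read / write the bead map
#'
#' The bead map is the bijection between bead color IDs and the 96 MW
#' fractions; fraction index 0 is the top of the gel (highest MW).
#'
#' @param path Path to a `beadmap.csv` file.
#' @return `read_beadmap()`: data.frame with columns `color_id` (character)
#'   and `fraction_index` (integer 0-95).
#' @export
read_beadmap <- function(path) {
  df <- read_table_checked(path, c("color_id", "fraction_index"))
  df <- df[c("color_id", "fraction_index")]
  idx <- parse_num_col(df$fraction_index, "fraction_index", path)
  if (any(is.na(idx)) || any(idx != floor(idx))) {
    stop(sprintf("%s: fraction_index must be integer", path), call. = FALSE)
  }
  df$fraction_index <- as.integer(idx)
  if (nrow(df) != N_FRACTIONS ||
      !identical(sort(df$fraction_index), 0:(N_FRACTIONS - 1L)) ||
      anyDuplicated(df$color_id)) {
    stop(sprintf(paste0("%s: bead map must be a bijection between color IDs and ",
                        "fraction indices 0-95: expected %d fractions, got %d distinct"),
                 path, N_FRACTIONS, length(unique(df$fraction_index))), call. = FALSE)
  }
  rownames(df) <- NULL
  df
}

#' @rdname read_beadmap
#' @param beadmap A bead-map data.frame.
#' @export
write_beadmap <- function(beadmap, path) {
  stopifnot(all(c("color_id", "fraction_index") %in% names(beadmap)))
  df <- beadmap[c("color_id", "fraction_index")]
  df$fraction_index <- as.integer(df$fraction_index)
  write_table_file(df, path)
}

# ---- ladder ----------------------------------------------------------------

#' Read / write ladder anchors
#'
#' @param path Path to a `ladder.csv` file.
#' @return `read_ladder()`: data.frame with columns `fraction_index`,
#'   `mw_kda`, validated as calibration anchors (>= 2 rows, strictly
#'   MW-decreasing with increasing index).
#' @export
read_ladder <- function(path) {
  df <- read_table_checked(path, c("fraction_index", "mw_kda"))
  df <- df[c("fraction_index", "mw_kda")]
  df$fraction_index <- parse_num_col(df$fraction_index, "fraction_index", path)
  df$mw_kda <- parse_num_col(df$mw_kda, "mw_kda", path)
  # fit_calibration performs the full anchor validation
  cal <- tryCatch(fit_calibration(df), error = function(e) {
    stop(sprintf("%s: %s", path, conditionMessage(e)), call. = FALSE)
  })
  cal$anchors
}

#' @rdname read_ladder
#' @param ladder Ladder anchor data.frame.
#' @export
write_ladder <- function(ladder, path) {
  stopifnot(all(c("fraction_index", "mw_kda") %in% names(ladder)))
  write_table_file(ladder[c("fraction_index", "mw_kda")], path)
}

# ---- panel -----------------------------------------------------------------

validate_panel <- function(panel, where = "panel") {
  req <- c("antibody_id", "marker", "expected_mw_kda", "valid_species")
  missing <- setdiff(req, names(panel))
  if (length(missing)) {
    stop(sprintf("%s: missing field(s): %s", where, paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  if (anyDuplicated(panel$antibody_id)) {
    stop(sprintf("%s: duplicate antibody_id", where), call. = FALSE)
  }
  panel$expected_mw_kda <- lapply(seq_len(nrow(panel)), function(i) {
    mws <- as.numeric(unlist(panel$expected_mw_kda[[i]]))
    if (!length(mws) || any(!is.finite(mws)) || any(mws <= 0)) {
      stop(sprintf("%s: antibody '%s': expected_mw_kda must be a nonempty list of positive kDa values",
                   where, panel$antibody_id[i]), call. = FALSE)
    }
    if (anyDuplicated(mws)) {
      stop(sprintf("%s: antibody '%s': expected_mw_kda values must be distinct",
                   where, panel$antibody_id[i]), call. = FALSE)
    }
    sort(mws)
  })
  panel$valid_species <- lapply(panel$valid_species, function(x) as.character(unlist(x)))
  panel
}

#' Read / write an antibody panel definition
#'
#' The panel lists, per antibody, the marker it detects, the expected
#' molecular weight(s) of the specific band(s) in kDa (normalized to sorted
#' ascending order on read), and the species the antibody is validated for.
#'
#' @param path Path to a `panel.json` file.
#' @return `read_panel()`: data.frame with character columns `antibody_id`,
#'   `marker` and list-columns `expected_mw_kda`, `valid_species`.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  entries <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!length(entries)) {
    panel <- data.frame(antibody_id = character(), marker = character())
    panel$expected_mw_kda <- list()
    panel$valid_species <- list()
    return(panel)
  }
  panel <- data.frame(
    antibody_id = vapply(entries, function(e) as.character(e$antibody_id %||% NA_character_), ""),
    marker = vapply(entries, function(e) as.character(e$marker %||% NA_character_), ""),
    stringsAsFactors = FALSE
  )
  panel$expected_mw_kda <- lapply(entries, function(e) e$expected_mw_kda)
  panel$valid_species <- lapply(entries, function(e) e$valid_species)
  validate_panel(panel, where = path)
}

#' @rdname read_panel
#' @param panel A panel data.frame.
#' @export
write_panel <- function(panel, path) {
  panel <- validate_panel(panel)
  entries <- lapply(seq_len(nrow(panel)), function(i) {
    list(antibody_id = jsonlite::unbox(panel$antibody_id[i]),
         marker = jsonlite::unbox(panel$marker[i]),
         expected_mw_kda = as.numeric(panel$expected_mw_kda[[i]]),
         valid_species = as.character(panel$valid_species[[i]]))
  })
  jsonlite::write_json(entries, path, digits = NA, pretty = TRUE)
  invisible(path)
}

# ---- samples ---------------------------------------------------------------

#' Read / write sample metadata
#'
#' @param path Path to a `samples.csv` file.
#' @return `read_samples()`: data.frame with columns `sample_id`, `species`,
#'   `source` and optionally `protein_input_ug`.
#' @export
read_samples <- function(path) {
  df <- read_table_checked(path, c("sample_id", "species", "source"))
  if ("protein_input_ug" %in% names(df)) {
    df$protein_input_ug <- parse_num_col(df$protein_input_ug, "protein_input_ug", path)
  }
  if (anyDuplicated(df$sample_id)) {
    stop(sprintf("%s: duplicate sample_id", path), call. = FALSE)
  }
  rownames(df) <- NULL
  df
}

#' @rdname read_samples
#' @param samples Sample metadata data.frame.
#' @export
write_samples <- function(samples, path) {
  stopifnot(all(c("sample_id", "species", "source") %in% names(samples)))
  write_table_file(samples, path)
}

# ---- result tables ---------------------------------------------------------

PEAK_COLS <- c("sample_id", "antibody_id", "apex_fraction", "apex_mw_kda",
               "height", "left", "right", "afi",
               "matched_expected_mw_kda", "mw_shift_kda")

#' Read / write a peak table
#'
#' @param path Path to a `peaks.tsv` file.
#' @return `read_peaks()`: data.frame with one row per detected peak; see
#'   [detect_peaks()] for the column semantics.
#' @export
read_peaks <- function(path) {
  df <- read_table_checked(path, PEAK_COLS, sep = "\t")
  df <- df[PEAK_COLS]
  for (col in setdiff(PEAK_COLS, c("sample_id", "antibody_id"))) {
    df[[col]] <- parse_num_col(df[[col]], col, path)
  }
  for (col in c("apex_fraction", "left", "right")) df[[col]] <- as.integer(df[[col]])
  rownames(df) <- NULL
  df
}

#' @rdname read_peaks
#' @param peaks Peak table data.frame.
#' @export
write_peaks <- function(peaks, path) {
  stopifnot(all(PEAK_COLS %in% names(peaks)))
  write_table_file(peaks[PEAK_COLS], path, sep = "\t")
}

CALL_COLS <- c("sample_id", "species", "source", "antibody_id", "marker",
               "status", "reasons", "afi", "height", "apex_mw_kda",
               "matched_expected_mw_kda", "mw_shift_kda")

#' Read / write a marker-call table
#'
#' @param path Path to a `calls.tsv` file.
#' @return `read_calls()`: data.frame with one row per sample x antibody cell.
#' @export
read_calls <- function(path) {
  df <- read_table_checked(path, CALL_COLS, sep = "\t")
  df <- df[CALL_COLS]
  for (col in c("afi", "height", "apex_mw_kda", "matched_expected_mw_kda", "mw_shift_kda")) {
    df[[col]] <- parse_num_col(df[[col]], col, path)
  }
  rownames(df) <- NULL
  df
}

#' @rdname read_calls
#' @param calls Call table data.frame.
#' @export
write_calls <- function(calls, path) {
  stopifnot(all(CALL_COLS %in% names(calls)))
  write_table_file(calls[CALL_COLS], path, sep = "\t")
}

# Detection matrix: markers x samples grid of status glyphs
# ("+" detected, "-" not detected, "." not applicable).
#' Read / write a detection matrix table
#'
#' @param path Path to a `matrix.tsv` file (rows = markers, columns =
#'   samples, cells `+` / `-` / `.`; first column `marker`).
#' @return `read_matrix_tsv()`: character matrix with marker rownames.
#' @export
read_matrix_tsv <- function(path) {
  df <- read_table_checked(path, "marker", sep = "\t")
  m <- as.matrix(df[setdiff(names(df), "marker")])
  rownames(m) <- df$marker
  m
}

#' @rdname read_matrix_tsv
#' @param m Character status matrix (markers x samples).
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(marker = rownames(m), stringsAsFactors = FALSE)
  for (j in seq_len(ncol(m))) df[[colnames(m)[j]]] <- m[, j]
  write_table_file(df, path, sep = "\t")
}
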
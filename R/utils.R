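# Internal constants and helpers shared across the package.

N_FRACTIONS <- 96L
EMPTY_BEAD <- "EMPTY_BEAD"
SECONDARY_ONLY <- "SECONDARY_ONLY"
CONTROL_IDS <- c(EMPTY_BEAD, SECONDARY_ONLY)
CONTROL_WILDCARD <- "*"
MW_CLAMP <- c(1, 500) # kDa; extrapolated calibrations never leave this range

# Canonical numeric rendering for all text outputs: 15 significant digits
# round-trips every value the simulator emits (MFI is rounded to 4 decimals
# at generation) and keeps files human-readable.
fmt_num <- function(x) {
  out <- sprintf("%.15g", x)
  out[is.na(x)] <- "NA"
  out
}

# read.csv wrapper that reads everything as character and checks the header.
read_table_checked <- function(path, required, sep = ",") {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  df <- utils::read.table(path, header = TRUE, sep = sep, colClasses = "character",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "", comment.char = "")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing required column(s): %s",
                 path, paste(missing, collapse = ", ")), call. = FALSE)
  }
  df
}

# Convert a character column to numeric, reporting 1-based file line numbers
# (header is line 1) for unparseable entries.
parse_num_col <- function(x, column, path) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !(x %in% c("NA", "")))
  if (length(bad)) {
    stop(sprintf("%s: column '%s' not numeric at line(s) %s",
                 path, column, paste(bad + 1L, collapse = ", ")), call. = FALSE)
  }
  out[x %in% c("NA", "")] <- NA_real_
  out
}

# Write lines with LF endings regardless of platform.
write_lines_lf <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con = con, sep = "\n")
  invisible(path)
}

# Render a data.frame to delimited text using the canonical numeric format.
format_table <- function(df, sep = ",") {
  cols <- lapply(df, function(col) {
    if (is.numeric(col)) fmt_num(col) else {
      out <- as.character(col)
      out[is.na(out)] <- "NA"
      out
    }
  })
  body <- do.call(paste, c(cols, sep = sep))
  c(paste(names(df), collapse = sep), body)
}

write_table_file <- function(df, path, sep = ",") {
  write_lines_lf(format_table(df, sep = sep), path)
}

# Seed handling: set the RNG for the duration of the call, restoring the
# caller's generator state afterwards.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
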
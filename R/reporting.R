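#' Render a Western-blot mimic from net lane profiles
#'
#' Produces the digital analogue of a blot photograph: one vertical grayscale
#' band column per lane, the pixel row mapping linearly to the fraction index
#' (fraction 0 / highest MW at the top) and the pixel darkness proportional
#' to the net fluorescence. Intensities are normalized per lane by default
#' because band intensities of this assay cannot be compared directly across
#' samples; `normalize = "figure"` scales all lanes by the common maximum
#' instead. Rendering is a pure function of its inputs: identical profiles
#' yield identical pixels.
#'
#' @param profiles Numeric matrix (96 x n lanes) of net profiles, or a list
#'   of length-96 vectors; column/list names label the lanes.
#' @param cal An `mw_calibration` (used for the MW axis ticks).
#' @param normalize `"lane"` (default) or `"figure"`.
#' @param scale Vertical pixels per fraction (nearest-neighbour upsampling).
#' @param lane_width,gap Lane and inter-lane gap width in pixels.
#' @param blur_sigma Optional Gaussian blur (in fractions) applied along the
#'   MW axis for visual smoothness; 0 disables it. The unblurred profiles are
#'   kept in the returned object so pixel math stays testable.
#' @param mw_ticks MW axis tick values in kDa.
#' @return Object of class `wb_mimic`: `pixels` (grayscale matrix in
#'   \[0, 1\], 0 = black), `ticks` (data.frame `mw_kda`, `row`), `lanes`,
#'   plus the rendering parameters.
#' @export
render_mimic <- function(profiles, cal, normalize = c("lane", "figure"),
                         scale = 4L, lane_width = 24L, gap = 10L,
                         blur_sigma = 0, mw_ticks = c(250, 150, 100, 75, 50,
                                                      37, 25, 20, 15, 10)) {
  normalize <- match.arg(normalize)
  if (is.list(profiles) && !is.data.frame(profiles)) {
    profiles <- do.call(cbind, profiles)
  }
  profiles <- as.matrix(profiles)
  if (!ncol(profiles)) stop("mimic needs at least one lane")
  if (nrow(profiles) != N_FRACTIONS) {
    stop(sprintf("profiles must have %d fractions per lane", N_FRACTIONS))
  }
  shown <- profiles
  if (blur_sigma > 0) {
    half <- max(1L, ceiling(3 * blur_sigma))
    kern <- stats::dnorm(-half:half, sd = blur_sigma)
    kern <- kern / sum(kern)
    shown <- apply(profiles, 2, function(v) {
      padded <- c(rep(v[1], half), v, rep(v[N_FRACTIONS], half))
      stats::filter(padded, kern, sides = 2)[(half + 1):(half + N_FRACTIONS)]
    })
  }
  norm <- switch(normalize,
                 lane = apply(shown, 2, max),
                 figure = rep(max(shown), ncol(shown)))
  norm[norm <= 0] <- 1
  intensity <- 1 - sweep(shown, 2, norm, "/") # 0 = saturated band

  nrow_px <- N_FRACTIONS * scale
  ncol_px <- ncol(profiles) * (lane_width + gap)
  pixels <- matrix(1, nrow_px, ncol_px)
  for (l in seq_len(ncol(profiles))) {
    col0 <- (l - 1L) * (lane_width + gap)
    lane_px <- intensity[rep(seq_len(N_FRACTIONS), each = scale), l]
    pixels[, col0 + seq_len(lane_width)] <- lane_px
  }

  tick_frac <- mw_to_fraction(cal, mw_ticks)
  in_span <- tick_frac >= 0 & tick_frac <= N_FRACTIONS - 1L
  ticks <- data.frame(mw_kda = mw_ticks[in_span],
                      row = round(tick_frac[in_span]) * scale + 1L)

  structure(list(pixels = pixels, ticks = ticks,
                 lanes = colnames(profiles) %||% paste0("lane", seq_len(ncol(profiles))),
                 profiles = profiles, normalize = normalize, scale = scale,
                 lane_width = lane_width, gap = gap, blur_sigma = blur_sigma),
            class = "wb_mimic")
}

#' Write a Western-blot mimic to a PNG file
#'
#' @param mimic A `wb_mimic` from [render_mimic()].
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_mimic_png <- function(mimic, path) {
  stopifnot(inherits(mimic, "wb_mimic"))
  png::writePNG(mimic$pixels, path)
  invisible(path)
}

#' Build the marker x fraction-set AFI heat-map matrix
#'
#' For each marker and sample (e.g. pooled SEC fraction set), the AFI of the
#' accepted peak, taken verbatim from the call table (which carries the
#' chosen peak of the peak table -- no re-computation). Cells where the
#' marker was too low for peak detection are a distinct sentinel (`NA` plus
#' `detected = FALSE`), never AFI 0: the "X-mark" state.
#'
#' @param dm A `detection_matrix` from [call_markers()].
#' @param markers Markers (rows) to include; default all panel markers with
#'   at least one detection.
#' @param samples Sample/fraction-set columns; default all, in sample-sheet
#'   order.
#' @return Object of class `afi_heatmap`: `afi` (numeric matrix, NA = not
#'   detected), `detected` (logical matrix), `markers`, `samples`.
#' @export
heatmap_afi <- function(dm, markers = NULL, samples = NULL) {
  stopifnot(inherits(dm, "detection_matrix"))
  calls <- dm$calls
  if (is.null(samples)) samples <- dm$samples$sample_id
  if (is.null(markers)) {
    det <- calls$marker[calls$status == "detected"]
    markers <- dm$panel$marker[dm$panel$marker %in% det]
  }
  if (!length(markers)) stop("heat map needs at least one marker")
  afi <- matrix(NA_real_, length(markers), length(samples),
                dimnames = list(markers, samples))
  detected <- matrix(FALSE, length(markers), length(samples),
                     dimnames = list(markers, samples))
  for (k in seq_len(nrow(calls))) {
    mk <- calls$marker[k]; s <- calls$sample_id[k]
    if (!(mk %in% markers) || !(s %in% samples)) next
    if (calls$status[k] == "detected") {
      afi[mk, s] <- calls$afi[k]
      detected[mk, s] <- TRUE
    }
  }
  structure(list(afi = afi, detected = detected, markers = markers,
                 samples = samples),
            class = "afi_heatmap")
}

#' Write / read an AFI heat-map matrix as TSV
#'
#' Not-detected cells are written as the sentinel `X` (the heat map's X-mark
#' state), distinguishing them from a true-zero AFI.
#'
#' @param hm An `afi_heatmap`.
#' @param path TSV path.
#' @return `write_afi_matrix()`: `path` invisibly; `read_afi_matrix()`: an
#'   `afi_heatmap`.
#' @export
write_afi_matrix <- function(hm, path) {
  stopifnot(inherits(hm, "afi_heatmap"))
  df <- data.frame(marker = hm$markers, stringsAsFactors = FALSE)
  for (j in seq_along(hm$samples)) {
    cells <- fmt_num(hm$afi[, j])
    cells[!hm$detected[, j]] <- "X"
    df[[hm$samples[j]]] <- cells
  }
  write_table_file(df, path, sep = "\t")
}

#' @rdname write_afi_matrix
#' @export
read_afi_matrix <- function(path) {
  df <- read_table_checked(path, "marker", sep = "\t")
  samples <- setdiff(names(df), "marker")
  markers <- df$marker
  afi <- matrix(NA_real_, length(markers), length(samples),
                dimnames = list(markers, samples))
  detected <- matrix(FALSE, length(markers), length(samples),
                     dimnames = list(markers, samples))
  for (j in seq_along(samples)) {
    cells <- df[[samples[j]]]
    is_x <- cells == "X"
    afi[!is_x, j] <- parse_num_col(cells[!is_x], samples[j], path)
    detected[, j] <- !is_x
  }
  structure(list(afi = afi, detected = detected, markers = markers,
                 samples = samples),
            class = "afi_heatmap")
}

#' Write an AFI heat map as a PNG image
#'
#' One cell block per marker x fraction set; cell darkness scales with AFI
#' relative to the matrix maximum; X-mark (not detected) cells are rendered
#' as light gray. Deterministic for fixed input.
#'
#' @param hm An `afi_heatmap`.
#' @param path Output PNG path.
#' @param cell Cell block size in pixels.
#' @return `path`, invisibly.
#' @export
write_heatmap_png <- function(hm, path, cell = 24L) {
  stopifnot(inherits(hm, "afi_heatmap"))
  maxv <- suppressWarnings(max(hm$afi, na.rm = TRUE))
  if (!is.finite(maxv) || maxv <= 0) maxv <- 1
  shade <- 1 - hm$afi / maxv
  shade[!hm$detected] <- 0.92
  px <- shade[rep(seq_along(hm$markers), each = cell),
              rep(seq_along(hm$samples), each = cell), drop = FALSE]
  png::writePNG(px, path)
  invisible(path)
}

#' Concordance between detected markers and a reference marker list
#'
#' Partitions, per sample group, the union of the markers detected by the
#' assay and a reference list (e.g. published mass-spectrometry results) into
#' `both`, `digiwest_only` and `reference_only`.
#'
#' @param detected Named list of character vectors (group -> detected
#'   markers), or a single character vector (group `"all"`).
#' @param reference Reference marker lists, same shape as `detected`.
#' @param vocabulary Optional known-marker vocabulary; reference markers
#'   outside it trigger a warning and stay in `reference_only`.
#' @return data.frame (`group`, `marker`, `status`) of class
#'   `concordance_table`, with a `counts` attribute (per group x status).
#' @export
concordance_table <- function(detected, reference, vocabulary = NULL) {
  as_groups <- function(x) {
    if (is.character(x)) list(all = x) else x
  }
  detected <- as_groups(detected)
  reference <- as_groups(reference)
  groups <- union(names(detected), names(reference))
  rows <- lapply(groups, function(g) {
    d <- unique(detected[[g]] %||% character())
    r <- unique(reference[[g]] %||% character())
    if (!is.null(vocabulary)) {
      unk <- setdiff(r, vocabulary)
      if (length(unk)) {
        warning(sprintf("group '%s': reference marker(s) not in vocabulary: %s",
                        g, paste(unk, collapse = ", ")))
      }
    }
    u <- union(d, r)
    if (!length(u)) return(NULL)
    status <- ifelse(u %in% d & u %in% r, "both",
                     ifelse(u %in% d, "digiwest_only", "reference_only"))
    data.frame(group = g, marker = sort(u),
               status = status[order(u)], stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  out <- if (length(rows)) {
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  } else {
    data.frame(group = character(), marker = character(),
               status = character(), stringsAsFactors = FALSE)
  }
  counts <- as.data.frame(table(group = out$group, status = out$status),
                          stringsAsFactors = FALSE)
  attr(out, "counts") <- counts
  class(out) <- c("concordance_table", class(out))
  out
}

#' Extract per-group detected marker sets from a detection matrix
#'
#' @param dm A `detection_matrix`.
#' @param by Grouping: `"sample"`, `"species"` or `"source"`.
#' @return Named list group -> character vector of detected markers.
#' @export
detected_marker_sets <- function(dm, by = c("sample", "species", "source")) {
  by <- match.arg(by)
  col <- switch(by, sample = "sample_id", species = "species", source = "source")
  det <- dm$calls[dm$calls$status == "detected", ]
  split(det$marker, det[[col]]) |> lapply(unique)
}

#' Export result tables
#'
#' Writes `peaks.tsv`, `calls.tsv` and `matrix.tsv` with a deterministic
#' column order; all three round-trip through their readers.
#'
#' @param peaks Peak table (or `NULL` to skip).
#' @param dm Detection matrix (or `NULL` to skip calls/matrix).
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
export_tables <- function(peaks = NULL, dm = NULL, out_dir = ".") {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok) stop(sprintf("cannot create output directory: %s", out_dir))
  paths <- character()
  if (!is.null(peaks)) {
    p <- file.path(out_dir, "peaks.tsv")
    write_peaks(peaks, p)
    paths <- c(paths, peaks = p)
  }
  if (!is.null(dm)) {
    p1 <- file.path(out_dir, "calls.tsv")
    write_calls(dm$calls, p1)
    p2 <- file.path(out_dir, "matrix.tsv")
    write_matrix_tsv(as.matrix(dm), p2)
    paths <- c(paths, calls = p1, matrix = p2)
  }
  invisible(paths)
}
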
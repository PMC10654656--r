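#' Apply the peak-acceptance thresholds
#'
#' A peak is acceptable when its baseline-subtracted height is at least
#' `min_height` AND its AFI is at least `min_afi` (both inclusive).
#'
#' @param height Peak height in AU.
#' @param afi Accumulated fluorescence intensity in AU.
#' @param min_height Minimum acceptable peak height (default 50 AU).
#' @param min_afi Minimum acceptable AFI (default 100 AU).
#' @return `list(pass = logical, reasons = character())` where `reasons` is a
#'   subset of `below_min_height`, `below_min_afi`.
#' @export
apply_thresholds <- function(height, afi, min_height = 50, min_afi = 100) {
  reasons <- character()
  if (height < min_height) reasons <- c(reasons, "below_min_height")
  if (afi < min_afi) reasons <- c(reasons, "below_min_afi")
  list(pass = length(reasons) == 0L, reasons = reasons)
}

#' Match a peak's apex MW against the antibody's expected MWs
#'
#' The matched expected MW is the one minimizing the absolute distance to the
#' apex MW; the match succeeds iff that distance is at most `tol_kda`
#' (inclusive). Equal distances resolve toward the lower expected MW.
#'
#' @param apex_mw_kda Apex molecular weight in kDa.
#' @param expected_mw_kda Numeric vector of expected MWs.
#' @param tol_kda Matching tolerance in kDa (default 10).
#' @return `list(matched = kDa or NA, shift = signed kDa or NA)`.
#' @export
match_mw <- function(apex_mw_kda, expected_mw_kda, tol_kda = 10) {
  expected <- sort(as.numeric(expected_mw_kda))
  d <- abs(apex_mw_kda - expected)
  best <- which(d == min(d))[1] # sorted ascending: ties resolve to lower MW
  if (d[best] <= tol_kda) {
    list(matched = expected[best], shift = apex_mw_kda - expected[best])
  } else {
    list(matched = NA_real_, shift = NA_real_)
  }
}

#' Check cross-sample shift consistency for one antibody
#'
#' An antibody's signal is specific only when the MW shift of its
#' threshold-passing peaks is consistent across samples: every passing peak
#' must match an expected MW within `tol_kda`, and the spread of the signed
#' shifts (max - min) must not exceed `spread_kda`. With no passing peaks the
#' antibody is vacuously consistent (and yields no detections).
#'
#' @param shifts Signed MW shifts (kDa) of the threshold-passing peaks; `NA`
#'   marks a passing peak that matched no expected MW.
#' @param tol_kda Per-peak match tolerance in kDa.
#' @param spread_kda Maximum allowed shift spread across samples (default 5).
#' @return Logical: consistent or not.
#' @export
check_consistency <- function(shifts, tol_kda = 10, spread_kda = 5) {
  if (!length(shifts)) return(TRUE)
  if (any(is.na(shifts))) return(FALSE)
  if (any(abs(shifts) > tol_kda)) return(FALSE)
  (max(shifts) - min(shifts)) <= spread_kda
}

#' Call markers per sample from a peak table
#'
#' Applies the full acceptance logic cell by cell: a marker is detected in a
#' sample iff a peak exists for its antibody, passes the height and AFI
#' thresholds, matches an expected MW within `mw_tol_kda`, and the antibody's
#' shift is consistent across samples. Cells whose sample species is not in
#' the antibody's `valid_species` are marked not-applicable rather than
#' not-detected. Every not-detected cell carries at least one
#' machine-readable reason (`no_peak`, `below_min_height`, `below_min_afi`,
#' `no_mw_match`, `inconsistent_shift`); for lanes with several candidate
#' peaks the reasons of the most nearly passing peak (fewest failures, then
#' highest AFI, then lowest apex fraction) are reported.
#'
#' @param peaks Peak table from [quantify_run()].
#' @param panel Antibody panel covering every antibody in `peaks`.
#' @param samples Sample metadata (`sample_id`, `species`, `source`).
#' @param min_height,min_afi Acceptance thresholds ([apply_thresholds()]).
#' @param mw_tol_kda MW match tolerance in kDa.
#' @param spread_kda Cross-sample shift-spread tolerance in kDa.
#' @return An object of class `detection_matrix`: list with the per-cell
#'   `calls` data.frame, `samples`, `panel` and the thresholds used.
#' @export
call_markers <- function(peaks, panel, samples, min_height = 50, min_afi = 100,
                         mw_tol_kda = 10, spread_kda = 5) {
  panel <- validate_panel(panel)
  unknown <- setdiff(unique(peaks$antibody_id), panel$antibody_id)
  if (length(unknown)) {
    stop(sprintf("antibody(ies) in peak table but not in panel: %s",
                 paste(unknown, collapse = ", ")))
  }

  # Per-peak evaluation against thresholds and expected MWs.
  n <- nrow(peaks)
  pass <- logical(n); matched <- numeric(n); shift <- numeric(n)
  thr_reasons <- vector("list", n)
  for (i in seq_len(n)) {
    thr <- apply_thresholds(peaks$height[i], peaks$afi[i], min_height, min_afi)
    pass[i] <- thr$pass
    thr_reasons[[i]] <- thr$reasons
    exp_i <- panel$expected_mw_kda[[match(peaks$antibody_id[i], panel$antibody_id)]]
    m <- match_mw(peaks$apex_mw_kda[i], exp_i, tol_kda = mw_tol_kda)
    matched[i] <- m$matched
    shift[i] <- m$shift
  }

  consistent <- vapply(panel$antibody_id, function(a) {
    check_consistency(shift[pass & peaks$antibody_id == a],
                      tol_kda = mw_tol_kda, spread_kda = spread_kda)
  }, logical(1))
  names(consistent) <- panel$antibody_id

  cells <- expand.grid(sample_i = seq_len(nrow(samples)),
                       ab_i = seq_len(nrow(panel)))
  calls <- lapply(seq_len(nrow(cells)), function(k) {
    si <- cells$sample_i[k]; ai <- cells$ab_i[k]
    s <- samples$sample_id[si]; a <- panel$antibody_id[ai]
    base <- data.frame(sample_id = s, species = samples$species[si],
                       source = samples$source[si], antibody_id = a,
                       marker = panel$marker[ai], status = NA_character_,
                       reasons = "", afi = NA_real_, height = NA_real_,
                       apex_mw_kda = NA_real_,
                       matched_expected_mw_kda = NA_real_,
                       mw_shift_kda = NA_real_, stringsAsFactors = FALSE)
    if (!(samples$species[si] %in% panel$valid_species[[ai]])) {
      base$status <- "not_applicable"
      return(base)
    }
    at <- which(peaks$sample_id == s & peaks$antibody_id == a)
    if (!length(at)) {
      base$status <- "not_detected"
      base$reasons <- "no_peak"
      return(base)
    }
    reason_sets <- lapply(at, function(i) {
      r <- thr_reasons[[i]]
      if (is.na(matched[i])) r <- c(r, "no_mw_match")
      if (pass[i] && !is.na(matched[i]) && !consistent[[a]]) {
        r <- c(r, "inconsistent_shift")
      }
      r
    })
    n_fail <- lengths(reason_sets)
    ok <- which(n_fail == 0L)
    pick <- if (length(ok)) {
      ok[order(-peaks$afi[at[ok]], peaks$apex_fraction[at[ok]])][1]
    } else {
      order(n_fail, -peaks$afi[at], peaks$apex_fraction[at])[1]
    }
    i <- at[pick]
    base$status <- if (length(ok)) "detected" else "not_detected"
    base$reasons <- paste(sort(unique(reason_sets[[pick]])), collapse = ";")
    base$afi <- peaks$afi[i]
    base$height <- peaks$height[i]
    base$apex_mw_kda <- peaks$apex_mw_kda[i]
    base$matched_expected_mw_kda <- matched[i]
    base$mw_shift_kda <- shift[i]
    base
  })
  calls <- do.call(rbind, c(calls, list(make.row.names = FALSE)))

  structure(list(calls = calls, samples = samples, panel = panel,
                 thresholds = list(min_height = min_height, min_afi = min_afi,
                                   mw_tol_kda = mw_tol_kda,
                                   spread_kda = spread_kda),
                 consistent = consistent),
            class = "detection_matrix")
}

#' Coerce a detection matrix to a markers x samples status grid
#'
#' @param x A `detection_matrix`.
#' @param ... Unused.
#' @return Character matrix with cells `+` (detected), `-` (not detected),
#'   `.` (not applicable), markers as rownames and sample IDs as colnames.
#' @export
as.matrix.detection_matrix <- function(x, ...) {
  glyph <- c(detected = "+", not_detected = "-", not_applicable = ".")
  m <- matrix("-", nrow(x$panel), nrow(x$samples),
              dimnames = list(x$panel$marker, x$samples$sample_id))
  for (k in seq_len(nrow(x$calls))) {
    m[x$calls$marker[k], x$calls$sample_id[k]] <- glyph[[x$calls$status[k]]]
  }
  m
}

#' @export
print.detection_matrix <- function(x, ...) {
  cat(sprintf("Detection matrix: %d markers x %d samples (height >= %g, AFI >= %g, |shift| <= %g kDa, spread <= %g kDa)\n",
              nrow(x$panel), nrow(x$samples), x$thresholds$min_height,
              x$thresholds$min_afi, x$thresholds$mw_tol_kda, x$thresholds$spread_kda))
  print(as.matrix(x))
  invisible(x)
}
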
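#' Reconstruct a virtual gel lane from bead readout rows
#'
#' Reassigns bead color IDs to molecular-weight fractions, recovering the
#' original lane as an ordered vector of 96 fluorescence values (fraction 0
#' first, i.e. highest MW at the top of the gel). The operation is a pure
#' permutation: the multiset of MFI values is preserved.
#'
#' @param rows Readout rows for one sample x antibody: data.frame with
#'   columns `color_id` and `mfi` (96 rows covering every fraction once).
#' @param beadmap Bead map data.frame ([read_beadmap()]).
#' @return Numeric vector of length 96 with attributes `sample_id` and
#'   `antibody_id` when present in `rows`.
#' @export
reconstruct_lane <- function(rows, beadmap) {
  idx <- beadmap$fraction_index[match(rows$color_id, beadmap$color_id)]
  unknown <- which(is.na(idx))
  if (length(unknown)) {
    stop(sprintf("unknown color_id(s): %s",
                 paste(unique(rows$color_id[unknown]), collapse = ", ")))
  }
  all_frac <- 0:(N_FRACTIONS - 1L)
  missing <- setdiff(all_frac, idx)
  dups <- unique(idx[duplicated(idx)])
  if (length(missing) || length(dups) || length(idx) != N_FRACTIONS) {
    stop(sprintf("lane must cover all 96 fractions exactly once; missing: {%s}; duplicated: {%s}",
                 paste(missing, collapse = ", "), paste(dups, collapse = ", ")))
  }
  v <- numeric(N_FRACTIONS)
  v[idx + 1L] <- rows$mfi
  if ("sample_id" %in% names(rows)) attr(v, "sample_id") <- rows$sample_id[1]
  if ("antibody_id" %in% names(rows)) attr(v, "antibody_id") <- rows$antibody_id[1]
  v
}

#' Estimate the assay baseline from control lanes
#'
#' The baseline combines the bead background (empty beads) and the
#' secondary-antibody-only signal: the elementwise maximum of the two control
#' profiles (a conservative, order-independent combination) smoothed with a
#' running median of window 3 (the window shrinks at the lane edges).
#'
#' @param empty_bead Empty-bead control profile (numeric, length 96), or
#'   `NULL` if unavailable.
#' @param secondary_only Secondary-antibody-only control profile, or `NULL`.
#' @return Numeric baseline of length 96 with attribute `provenance`.
#' @export
estimate_baseline <- function(empty_bead, secondary_only = NULL) {
  if (is.null(empty_bead) && is.null(secondary_only)) {
    stop("no control lanes: need at least one of empty-bead or secondary-only")
  }
  used <- c()
  if (!is.null(empty_bead)) {
    stopifnot(length(empty_bead) == N_FRACTIONS)
    used <- c(used, "empty_bead")
  }
  if (!is.null(secondary_only)) {
    stopifnot(length(secondary_only) == N_FRACTIONS)
    used <- c(used, "secondary_only")
  }
  raw <- if (length(used) == 2) pmax(empty_bead, secondary_only)
         else if (is.null(secondary_only)) as.numeric(empty_bead)
         else as.numeric(secondary_only)
  sm <- vapply(seq_len(N_FRACTIONS), function(i) {
    stats::median(raw[max(1L, i - 1L):min(N_FRACTIONS, i + 1L)])
  }, numeric(1))
  attr(sm, "provenance") <- used
  sm
}

#' Subtract the baseline from a lane profile
#'
#' Net values are clipped at zero; the number of clipped fractions is
#' attached as attribute `n_clipped`.
#'
#' @param profile Lane profile (numeric, length 96).
#' @param baseline Baseline (numeric, length 96).
#' @return Net profile of length 96, all values >= 0.
#' @export
subtract_background <- function(profile, baseline) {
  if (length(profile) != length(baseline)) {
    stop(sprintf("length mismatch: profile has %d values, baseline %d",
                 length(profile), length(baseline)))
  }
  net <- pmax(0, as.numeric(profile) - as.numeric(baseline))
  attr(net, "n_clipped") <- sum(profile < baseline)
  attr(net, "sample_id") <- attr(profile, "sample_id")
  attr(net, "antibody_id") <- attr(profile, "antibody_id")
  net
}

# Extract the expected-MW vector from a panel row / list / numeric vector.
expected_mws <- function(spec) {
  if (is.numeric(spec)) return(sort(unique(spec)))
  if (is.data.frame(spec)) return(sort(unique(as.numeric(unlist(spec$expected_mw_kda)))))
  if (is.list(spec) && !is.null(spec$expected_mw_kda)) {
    return(sort(unique(as.numeric(unlist(spec$expected_mw_kda)))))
  }
  stop("spec must be a numeric vector of expected MWs or a panel row")
}

# Walk from the apex in direction d (-1 left / +1 right) until the peak
# closes. The boundary is placed on the first fraction at or below tau
# (capturing the shoulder mass down to the threshold level), or at the lane
# edge. A local minimum below half the apex height out of which the signal
# rises again marks a split with an adjacent peak: the valley fraction is
# assigned to the taller of the two peaks (ties: to the peak on the
# lower-fraction side).
walk_boundary <- function(net, apex, d, tau, apex_height) {
  j <- apex
  repeat {
    nxt <- j + d
    if (nxt < 0L || nxt > N_FRACTIONS - 1L) return(j)
    vn <- net[nxt + 1L]
    vj <- net[j + 1L]
    if (vn <= tau) return(nxt)
    if (vn > vj && vj < 0.5 * apex_height) {
      adj <- adjacent_peak_height(net, nxt, d, tau)
      take_valley <- apex_height > adj || (apex_height == adj && d > 0L)
      return(if (take_valley) j else j - d)
    }
    j <- nxt
  }
}

# Height of the adjacent peak beyond a valley: maximum net value scanning in
# direction d until the signal drops to tau or the lane ends.
adjacent_peak_height <- function(net, start, d, tau) {
  m <- 0
  k <- start
  while (k >= 0L && k <= N_FRACTIONS - 1L && net[k + 1L] > tau) {
    m <- max(m, net[k + 1L])
    k <- k + d
  }
  m
}

#' Detect antibody-specific peaks in a net lane profile
#'
#' For each expected molecular weight `m` of the antibody, the fractions
#' whose MW lies within `m +/- mw_window_kda` are searched for the local
#' maximum (>= both neighbours) with the largest net value (apex ties resolve
#' to the fraction whose MW is closest to `m`, then to the lower index).
#' Integration boundaries extend outward from the apex while the net signal
#' stays above `tau = max(5% of apex height, 10 AU)`; the boundary is placed
#' on the first fraction at or below `tau`. A local minimum below 50% of the
#' apex height splits adjacent peaks, the valley going to the taller peak.
#' Two expected MWs may only yield two peaks when such a split separates
#' them; otherwise the candidate closer to its expected MW (same apex) or the
#' taller candidate (unsplit distinct apexes) is kept. Each peak is
#' integrated into its accumulated fluorescence intensity (AFI), the sum of
#' net values over the inclusive boundary window.
#'
#' @param net Net (baseline-subtracted) profile, length 96, values >= 0.
#' @param spec Panel row for the antibody, or a numeric vector of expected
#'   MWs in kDa.
#' @param cal An `mw_calibration`.
#' @param mw_window_kda Half-width of the MW search window around each
#'   expected MW (default 10 kDa, the assay's MW tolerance).
#' @return data.frame with columns `apex_fraction`, `apex_mw_kda`, `height`,
#'   `left`, `right`, `afi`, `matched_expected_mw_kda`, `mw_shift_kda`
#'   (zero rows when no peak is found).
#' @export
detect_peaks <- function(net, spec, cal, mw_window_kda = 10) {
  stopifnot(length(net) == N_FRACTIONS)
  if (any(net < 0)) stop("net profile must be >= 0 (baseline-subtracted, clipped)")
  expected <- expected_mws(spec)
  frac_mw <- fraction_to_mw(cal, 0:(N_FRACTIONS - 1L))
  n <- N_FRACTIONS
  is_local_max <- (net >= c(-Inf, net[-n])) & (net >= c(net[-1], -Inf))

  # Elect the best local maximum inside the MW window of expected MW m,
  # skipping apexes already claimed by another expected MW and maxima below
  # min_height (used to keep re-elections at isoform-band significance).
  elect <- function(m, excluded, min_height = 0) {
    win <- which(frac_mw >= m - mw_window_kda & frac_mw <= m + mw_window_kda) - 1L
    ok <- win[is_local_max[win + 1L] & net[win + 1L] > 0 &
                net[win + 1L] >= min_height & !(win %in% excluded)]
    if (!length(ok)) return(NA_integer_)
    vals <- net[ok + 1L]
    best <- ok[vals == max(vals)]
    if (length(best) > 1) {
      dist <- abs(frac_mw[best + 1L] - m)
      best <- best[dist == min(dist)]
      best <- min(best)
    }
    best
  }

  apexes <- vapply(expected, elect, integer(1), excluded = integer())
  # Overlapping windows may elect the same apex: it belongs to the closest
  # expected MW (ties: lower MW); the other windows re-elect among the
  # remaining local maxima. A re-elected secondary apex must reach at least
  # half the height of the claimed primary apex -- the same significance
  # level the valley rule uses -- so that shoulders and background bumps next
  # to a dominant band are not promoted to isoform peaks. Whether a
  # re-elected neighbour survives as a separate peak is then decided by the
  # valley-split rule below.
  for (pass in seq_along(expected)) {
    dup <- unique(apexes[!is.na(apexes) & duplicated(apexes)])
    if (!length(dup)) break
    for (ap in dup) {
      at <- which(!is.na(apexes) & apexes == ap)
      dist <- abs(frac_mw[ap + 1L] - expected[at])
      winner <- at[which.min(dist)] # expected sorted: ties go to lower MW
      for (i in setdiff(at, winner)) {
        apexes[i] <- elect(expected[i], excluded = apexes[!is.na(apexes)],
                           min_height = 0.5 * net[ap + 1L])
      }
    }
  }

  cand <- list()
  for (i in seq_along(expected)) {
    apex <- apexes[i]
    if (is.na(apex)) next
    height <- net[apex + 1L]
    tau <- max(0.05 * height, 10)
    left <- walk_boundary(net, apex, -1L, tau, height)
    right <- walk_boundary(net, apex, +1L, tau, height)
    cand[[length(cand) + 1L]] <- list(expected = expected[i], apex = apex,
                                      height = height, left = left,
                                      right = right,
                                      afi = sum(net[(left:right) + 1L]))
  }
  if (!length(cand)) return(empty_peak_frame())

  # Distinct apexes must be separated by a sub-half-height valley; unsplit
  # neighbours merge into the taller candidate.
  if (length(cand) > 1) {
    ord <- order(vapply(cand, `[[`, 0L, "apex"))
    cand <- cand[ord]
    keep <- rep(TRUE, length(cand))
    for (i in seq_len(length(cand) - 1L)) {
      a <- cand[[i]]; b <- cand[[i + 1L]]
      between <- if (b$apex - a$apex > 1L) net[(a$apex + 1L):(b$apex - 1L) + 1L] else numeric()
      split_ok <- length(between) && any(between < 0.5 * min(a$height, b$height))
      if (!split_ok) {
        drop <- if (a$height > b$height) i + 1L
                else if (b$height > a$height) i
                else i + 1L # equal heights: keep the lower-fraction apex
        keep[drop] <- FALSE
      }
    }
    cand <- cand[keep]
  }

  out <- do.call(rbind, lapply(cand, function(p) {
    apex_mw <- frac_mw[p$apex + 1L]
    m <- match_mw(apex_mw, expected, tol_kda = mw_window_kda)
    data.frame(apex_fraction = p$apex, apex_mw_kda = apex_mw, height = p$height,
               left = p$left, right = p$right, afi = p$afi,
               matched_expected_mw_kda = m$matched, mw_shift_kda = m$shift)
  }))
  rownames(out) <- NULL
  out
}

empty_peak_frame <- function() {
  data.frame(apex_fraction = integer(), apex_mw_kda = numeric(),
             height = numeric(), left = integer(), right = integer(),
             afi = numeric(), matched_expected_mw_kda = numeric(),
             mw_shift_kda = numeric())
}

#' Integrate a peak into its accumulated fluorescence intensity (AFI)
#'
#' AFI is the sum of the net (baseline-subtracted) values over the inclusive
#' boundary window.
#'
#' @param net Net profile, length 96.
#' @param left,right Integration boundaries (fraction indices, 0-95,
#'   `left <= right`).
#' @return The AFI in AU.
#' @export
integrate_peak <- function(net, left, right) {
  stopifnot(length(net) == N_FRACTIONS)
  if (left > right) stop(sprintf("inverted boundaries: left %d > right %d", left, right))
  if (left < 0 || right > N_FRACTIONS - 1L) {
    stop(sprintf("boundaries [%d, %d] outside fractions 0-%d", left, right, N_FRACTIONS - 1L))
  }
  sum(net[(left:right) + 1L])
}

# Locate the control lanes for a sample: exact sample_id match preferred,
# wildcard '*' controls otherwise.
control_profiles <- function(readout, beadmap, sample_id) {
  get_ctrl <- function(ab) {
    rows <- readout[readout$antibody_id == ab & readout$sample_id == sample_id, ]
    if (!nrow(rows)) {
      rows <- readout[readout$antibody_id == ab & readout$sample_id == CONTROL_WILDCARD, ]
    }
    if (!nrow(rows)) return(NULL)
    reconstruct_lane(rows, beadmap)
  }
  list(empty_bead = get_ctrl(EMPTY_BEAD), secondary_only = get_ctrl(SECONDARY_ONLY))
}

#' Quantify one sample x antibody lane
#'
#' Composition of lane reconstruction, baseline estimation from the controls,
#' background subtraction, peak detection and integration.
#'
#' @param readout Full readout table (assay rows plus control rows).
#' @param beadmap Bead map.
#' @param sample_id,antibody_id The lane to quantify.
#' @param panel Antibody panel.
#' @param cal An `mw_calibration`.
#' @param mw_window_kda MW search half-window in kDa.
#' @return Peak table for the lane, with `sample_id` / `antibody_id` columns.
#' @export
quantify_lane <- function(readout, beadmap, sample_id, antibody_id, panel, cal,
                          mw_window_kda = 10) {
  spec_row <- which(panel$antibody_id == antibody_id)
  if (!length(spec_row)) stop(sprintf("antibody '%s' not in panel", antibody_id))
  rows <- readout[readout$sample_id == sample_id & readout$antibody_id == antibody_id, ]
  res <- tryCatch({
    lane <- reconstruct_lane(rows, beadmap)
    ctrl <- control_profiles(readout, beadmap, sample_id)
    baseline <- estimate_baseline(ctrl$empty_bead, ctrl$secondary_only)
    net <- subtract_background(lane, baseline)
    detect_peaks(net, panel[spec_row, ], cal, mw_window_kda = mw_window_kda)
  }, error = function(e) {
    stop(sprintf("sample %s, antibody %s: %s", sample_id, antibody_id,
                 conditionMessage(e)), call. = FALSE)
  })
  if (nrow(res)) {
    res <- cbind(data.frame(sample_id = sample_id, antibody_id = antibody_id,
                            stringsAsFactors = FALSE), res)
  } else {
    res <- cbind(data.frame(sample_id = character(), antibody_id = character()),
                 res)
  }
  res
}

#' Quantify every lane of a readout table
#'
#' Runs [quantify_lane()] for every non-control sample x antibody combination
#' present in the readout. Deterministic for fixed input.
#'
#' @inheritParams quantify_lane
#' @return Peak table (`sample_id`, `antibody_id`, `apex_fraction`,
#'   `apex_mw_kda`, `height`, `left`, `right`, `afi`,
#'   `matched_expected_mw_kda`, `mw_shift_kda`).
#' @export
quantify_run <- function(readout, beadmap, panel, cal, mw_window_kda = 10) {
  assay <- readout[!(readout$antibody_id %in% CONTROL_IDS), ]
  combos <- unique(assay[c("sample_id", "antibody_id")])
  unknown <- setdiff(unique(combos$antibody_id), panel$antibody_id)
  if (length(unknown)) {
    stop(sprintf("antibody(ies) in readout but not in panel: %s",
                 paste(unknown, collapse = ", ")))
  }
  out <- lapply(seq_len(nrow(combos)), function(i) {
    quantify_lane(readout, beadmap, combos$sample_id[i], combos$antibody_id[i],
                  panel, cal, mw_window_kda = mw_window_kda)
  })
  out <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  if (is.null(out) || !nrow(out)) {
    out <- cbind(data.frame(sample_id = character(), antibody_id = character()),
                 empty_peak_frame())
  }
  out
}
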
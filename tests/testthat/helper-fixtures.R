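# Shared fixture builders. Everything is generated in code; no data files.

# Two-anchor log-linear calibration spanning the whole lane.
two_point_cal <- function() {
  fit_calibration(data.frame(fraction_index = c(0, 95), mw_kda = c(250, 10)))
}

# A noiseless Gaussian band in fraction space.
gauss_lane <- function(center, amp, sigma) {
  amp * exp(-((0:95) - center)^2 / (2 * sigma^2))
}

# MW span of the fraction neighbouring `f` (recovery tolerance for apex MW).
mw_span_at <- function(cal, f) {
  lo <- max(0, f - 1)
  hi <- min(95, f + 1)
  max(abs(diff(fraction_to_mw(cal, c(lo, f, hi)))))
}

# Minimal single-sample configuration: two antibodies, one with an isoform
# doublet spec, noiseless by default.
tiny_config <- function(noise_sd = 0, seed = 1L, amplitude = 500,
                        width_fractions = 1.2, bands = NULL, presence = NULL,
                        mw_shift_kda = 0, secondary_bump = NULL) {
  samples <- data.frame(sample_id = "s1", species = "human", source = "EV",
                        protein_input_ug = 5, stringsAsFactors = FALSE)
  panel <- data.frame(antibody_id = c("mkA", "mkB"),
                      marker = c("mkA", "mkB"), stringsAsFactors = FALSE)
  panel$expected_mw_kda <- list(46, c(21, 24))
  panel$valid_species <- list("human", "human")
  if (is.null(presence)) {
    presence <- matrix(TRUE, 1, 2, dimnames = list("s1", c("mkA", "mkB")))
  }
  sim_config(samples = samples, panel = panel, bands = bands,
             presence = presence, amplitude = amplitude,
             width_fractions = width_fractions, mw_shift_kda = mw_shift_kda,
             baseline_level = 100, secondary_bump = secondary_bump,
             noise_sd = noise_sd, seed = seed)
}

# Randomized multi-antibody configuration for property-style sweeps.
random_config <- function(seed, n_ab = 10, n_samples = 1, noise_range = c(0, 30)) {
  set.seed(seed)
  ab <- sprintf("ab%02d", seq_len(n_ab))
  panel <- data.frame(antibody_id = ab, marker = ab, stringsAsFactors = FALSE)
  panel$expected_mw_kda <- lapply(seq_len(n_ab), function(i) round(runif(1, 12, 240), 1))
  panel$valid_species <- rep(list("human"), n_ab)
  samples <- data.frame(sample_id = sprintf("s%d", seq_len(n_samples)),
                        species = "human", source = "EV",
                        protein_input_ug = 5, stringsAsFactors = FALSE)
  presence <- matrix(TRUE, n_samples, n_ab,
                     dimnames = list(samples$sample_id, ab))
  amp <- stats::setNames(round(runif(n_ab, 100, 2000)), ab)
  wid <- stats::setNames(round(runif(n_ab, 0.8, 3), 2), ab)
  noise <- round(runif(1, noise_range[1], noise_range[2]), 1)
  sim_config(samples = samples, panel = panel, presence = presence,
             amplitude = amp, width_fractions = wid, noise_sd = noise,
             seed = seed)
}

# Quantify a dataset end to end, returning peaks and the calibration.
quantify_dataset <- function(ds, mw_window_kda = 10) {
  cal <- fit_calibration(ds$ladder)
  list(peaks = quantify_run(ds$readout, ds$beadmap, ds$panel, cal,
                            mw_window_kda = mw_window_kda),
       cal = cal)
}

# Independent brute-force AFI oracle: re-reconstruct the net lane and sum
# the boundary window directly from the raw tables.
brute_force_afi <- function(ds, peak_row) {
  cal <- fit_calibration(ds$ladder)
  rows <- ds$readout[ds$readout$sample_id == peak_row$sample_id &
                       ds$readout$antibody_id == peak_row$antibody_id, ]
  lane <- reconstruct_lane(rows, ds$beadmap)
  ctrl_rows <- function(ab) {
    r <- ds$readout[ds$readout$antibody_id == ab & ds$readout$sample_id == "*", ]
    if (nrow(r)) reconstruct_lane(r, ds$beadmap) else NULL
  }
  baseline <- estimate_baseline(ctrl_rows("EMPTY_BEAD"), ctrl_rows("SECONDARY_ONLY"))
  net <- pmax(0, lane - baseline)
  sum(net[(peak_row$left:peak_row$right) + 1])
}
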
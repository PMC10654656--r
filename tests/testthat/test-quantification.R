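test_that("lane reconstruction is the inverse permutation of the bead map", {
  mfi <- round(runif(96, 0, 1000), 1)
  rows <- data.frame(sample_id = "s", antibody_id = "a",
                     color_id = sprintf("B%03d", 1:96), mfi = mfi)

  identity_map <- data.frame(color_id = sprintf("B%03d", 1:96),
                             fraction_index = 0:95)
  expect_equal(as.numeric(reconstruct_lane(rows, identity_map)), mfi)

  reversed_map <- data.frame(color_id = sprintf("B%03d", 1:96),
                             fraction_index = 95:0)
  expect_equal(as.numeric(reconstruct_lane(rows, reversed_map)), rev(mfi))

  # arbitrary permutation conserves the value multiset
  set.seed(8)
  perm_map <- data.frame(color_id = sprintf("B%03d", 1:96),
                         fraction_index = sample(0:95))
  expect_equal(sort(as.numeric(reconstruct_lane(rows, perm_map))), sort(mfi))
})

test_that("incomplete or unknown bead assignments are rejected", {
  identity_map <- data.frame(color_id = sprintf("B%03d", 1:96),
                             fraction_index = 0:95)
  rows <- data.frame(color_id = sprintf("B%03d", 1:96), mfi = 1:96)
  expect_error(reconstruct_lane(rows[1:95, ], identity_map), "missing: \\{95\\}")
  rows_dup <- rows
  rows_dup$color_id[2] <- "B001"
  expect_error(reconstruct_lane(rows_dup, identity_map), "duplicated: \\{0\\}")
  rows_unk <- rows
  rows_unk$color_id[1] <- "ZZZ"
  expect_error(reconstruct_lane(rows_unk, identity_map), "unknown color_id.*ZZZ")
})

test_that("baseline combines controls by elementwise max with median-3 smoothing", {
  expect_equal(as.numeric(estimate_baseline(rep(0, 96), rep(0, 96))), rep(0, 96))

  # isolated one-fraction excursion in the secondary control is removed by
  # the running median; a two-fraction excursion survives at its plateau
  empty <- rep(100, 96)
  sec1 <- rep(100, 96); sec1[12] <- 150
  expect_equal(as.numeric(estimate_baseline(empty, sec1)), rep(100, 96))

  sec2 <- rep(100, 96); sec2[12:13] <- 150
  expected <- rep(100, 96); expected[12:13] <- 150
  expect_equal(as.numeric(estimate_baseline(empty, sec2)), expected)

  # single-control fallback
  eb <- rep(80, 96)
  b <- estimate_baseline(eb, NULL)
  expect_equal(as.numeric(b), eb)
  expect_identical(attr(b, "provenance"), "empty_bead")
  expect_error(estimate_baseline(NULL, NULL), "no control lanes")
})

test_that("background subtraction clips at zero and preserves constructed peaks", {
  base <- rep(100, 96)
  expect_equal(as.numeric(subtract_background(base, base)), rep(0, 96))

  peak <- gauss_lane(40, 500, 2)
  net <- subtract_background(base + peak, base)
  expect_equal(as.numeric(net), peak)

  dipped <- base; dipped[10] <- 60
  net2 <- subtract_background(dipped, base)
  expect_true(all(net2 >= 0))
  expect_equal(attr(net2, "n_clipped"), 1L)
  expect_error(subtract_background(rep(0, 95), base), "length mismatch")
})

test_that("peak detection finds a single Gaussian at its expected MW", {
  cal <- two_point_cal()
  expect_equal(nrow(detect_peaks(rep(0, 96), 46, cal)), 0)

  center <- mw_to_fraction(cal, 46)
  net <- gauss_lane(center, 800, 1.5)
  pk <- detect_peaks(net, 46, cal)
  expect_equal(nrow(pk), 1)
  expect_lte(abs(pk$apex_mw_kda - 46), mw_span_at(cal, pk$apex_fraction))
  expect_equal(pk$matched_expected_mw_kda, 46)
  expect_gte(pk$afi, pk$height)
  expect_true(pk$left <= pk$apex_fraction && pk$apex_fraction <= pk$right)
})

test_that("an isoform doublet splits at the sub-half-height valley", {
  cal <- fit_calibration(default_ladder())
  f21 <- mw_to_fraction(cal, 21)
  f24 <- mw_to_fraction(cal, 24)
  # 21 and 24 kDa sit ~3.8 fractions apart on the default ladder: at
  # sigma = 1 the inter-band valley drops below half height and must split
  net <- gauss_lane(f21, 500, 1) + gauss_lane(f24, 500, 1)
  pk <- detect_peaks(net, c(21, 24), cal)
  expect_equal(nrow(pk), 2)
  expect_setequal(pk$matched_expected_mw_kda, c(21, 24))
  # integration windows must not overlap across the split
  pk <- pk[order(pk$apex_fraction), ]
  expect_lt(pk$right[1], pk$left[2])

  # at sigma = 1.2 the same doublet has no sub-half valley: one merged band
  wide <- gauss_lane(f21, 500, 1.2) + gauss_lane(f24, 500, 1.2)
  expect_equal(nrow(detect_peaks(wide, c(21, 24), cal)), 1)
})

test_that("a single isoform band yields exactly one peak matched to its MW", {
  cal <- fit_calibration(default_ladder())
  for (mw in c(21, 24)) {
    net <- gauss_lane(mw_to_fraction(cal, mw), 500, 1.2)
    pk <- detect_peaks(net, c(21, 24), cal)
    expect_equal(nrow(pk), 1)
    expect_equal(pk$matched_expected_mw_kda, mw)
  }
})

test_that("integration is the inclusive sum over the boundary window", {
  net <- c(0, 10, 60, 100, 60, 10, 0, rep(0, 89))
  expect_equal(integrate_peak(net, 1, 5), 240)
  expect_equal(integrate_peak(net, 0, 95), sum(net))
  expect_equal(integrate_peak(rep(0, 96), 10, 20), 0)
  expect_error(integrate_peak(net, 5, 1), "inverted")
  expect_error(integrate_peak(net, -1, 5), "outside")
})

test_that("AFI equals the brute-force oracle on every detected peak", {
  for (s in 1:5) {
    ds <- simulate_dataset(random_config(s, n_ab = 6, noise_range = c(5, 40)))
    q <- quantify_dataset(ds)
    for (i in seq_len(nrow(q$peaks))) {
      expect_identical(q$peaks$afi[i], brute_force_afi(ds, q$peaks[i, ]))
    }
  }
})

test_that("noiseless quantification recovers the analytic AFI within 1%", {
  for (sigma in c(1.2, 2, 3)) {
    cfg <- tiny_config(noise_sd = 0, amplitude = 1000, width_fractions = sigma)
    ds <- simulate_dataset(cfg)
    q <- quantify_dataset(ds)
    pk <- q$peaks[q$peaks$antibody_id == "mkA", ]
    truth <- ds$truth[ds$truth$antibody_id == "mkA", ]
    expect_equal(nrow(pk), 1)
    expect_lt(abs(pk$afi - truth$true_afi) / truth$true_afi, 0.01)
  }
})

test_that("AFI is monotone non-decreasing in simulated amplitude", {
  afis <- vapply(c(200, 400, 800, 1600), function(a) {
    ds <- simulate_dataset(tiny_config(noise_sd = 0, amplitude = a))
    q <- quantify_dataset(ds)
    q$peaks$afi[q$peaks$antibody_id == "mkA"]
  }, numeric(1))
  expect_true(all(diff(afis) > 0))
})

test_that("apex MW is recovered within one fraction span for >=95% of noisy peaks", {
  hits <- 0L; total <- 0L
  for (s in 1:25) {
    cfg <- random_config(100 + s, n_ab = 8, noise_range = c(0, 0))
    # amplitude/noise = 20 exactly: stress at the documented noise ceiling
    cfg$noise_sd <- min(cfg$amplitude) / 20
    ds <- simulate_dataset(cfg)
    q <- quantify_dataset(ds)
    cal <- q$cal
    for (i in seq_len(nrow(ds$truth))) {
      tr <- ds$truth[i, ]
      pk <- q$peaks[q$peaks$sample_id == tr$sample_id &
                      q$peaks$antibody_id == tr$antibody_id, ]
      if (!nrow(pk)) next
      total <- total + 1L
      span <- mw_span_at(cal, pk$apex_fraction[1])
      if (abs(pk$apex_mw_kda[1] - tr$true_center_mw_kda) <= span) hits <- hits + 1L
    }
  }
  expect_gt(total, 150)
  expect_gte(hits / total, 0.95)
})

test_that("quantification is deterministic and annotates errors with the lane", {
  ds <- simulate_dataset(tiny_config(seed = 31, noise_sd = 20))
  q1 <- quantify_dataset(ds)
  q2 <- quantify_dataset(ds)
  expect_identical(q1$peaks, q2$peaks)

  broken <- ds$readout[-5, ] # drop one bead of some lane
  expect_error(
    quantify_run(broken, ds$beadmap, ds$panel, fit_calibration(ds$ladder)),
    "sample s1, antibody")
})

test_that("a lane with nothing above baseline yields an empty peak list", {
  cfg <- tiny_config(noise_sd = 0,
                     presence = matrix(FALSE, 1, 2,
                                       dimnames = list("s1", c("mkA", "mkB"))))
  ds <- simulate_dataset(cfg)
  q <- quantify_dataset(ds)
  expect_equal(nrow(q$peaks), 0)
})
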
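test_that("mimic rendering maps fractions to rows and darkness to signal", {
  cal <- fit_calibration(default_ladder())
  center <- round(mw_to_fraction(cal, 46))
  net <- gauss_lane(center, 800, 1.5)
  m <- render_mimic(cbind(lane1 = net), cal, scale = 4L)
  # darkest pixel row maps back to a fraction whose MW is within one span of 46
  darkest_row <- which.min(m$pixels[, 1])
  frac <- (darkest_row - 1) %/% 4
  expect_lte(abs(fraction_to_mw(cal, frac) - 46), mw_span_at(cal, frac))
  expect_equal(dim(m$pixels), c(96 * 4, 1 * (24 + 10)))
  expect_true(all(m$pixels >= 0 & m$pixels <= 1))
})

test_that("an all-zero profile renders a uniform background column", {
  cal <- two_point_cal()
  m <- render_mimic(cbind(empty = rep(0, 96)), cal)
  expect_true(all(m$pixels == 1))
})

test_that("mimic rendering is a pure function: identical input, identical bytes", {
  cal <- two_point_cal()
  net <- cbind(a = gauss_lane(30, 500, 2), b = gauss_lane(60, 900, 1.5))
  p1 <- withr::local_tempfile(fileext = ".png")
  p2 <- withr::local_tempfile(fileext = ".png")
  write_mimic_png(render_mimic(net, cal), p1)
  write_mimic_png(render_mimic(net, cal), p2)
  expect_identical(readBin(p1, "raw", 1e7), readBin(p2, "raw", 1e7))
  expect_error(render_mimic(matrix(numeric(), 96, 0), cal), "at least one lane")
})

test_that("per-lane and per-figure normalization differ as documented", {
  cal <- two_point_cal()
  net <- cbind(weak = gauss_lane(30, 100, 2), strong = gauss_lane(30, 1000, 2))
  lane_norm <- render_mimic(net, cal, normalize = "lane")
  fig_norm <- render_mimic(net, cal, normalize = "figure")
  # per-lane: both lanes reach full black; per-figure: only the strong one
  expect_equal(min(lane_norm$pixels[, 1:24]), 0)
  expect_equal(min(lane_norm$pixels[, 35:58]), 0)
  expect_gt(min(fig_norm$pixels[, 1:24]), 0.8)
  expect_equal(min(fig_norm$pixels[, 35:58]), 0)
})

make_sec_heatmap <- function(seed = 5, noise_sd = 25) {
  base <- sim_config(samples = default_samples()[2, ], seed = seed,
                     noise_sd = noise_sd)
  ds <- simulate_sec_series(base)
  q <- quantify_dataset(ds)
  dm <- call_markers(q$peaks, ds$panel, ds$samples)
  list(ds = ds, peaks = q$peaks, dm = dm, hm = heatmap_afi(dm))
}

test_that("SEC heat-map argmax columns sit at the simulated enrichment centers", {
  x <- make_sec_heatmap()
  w <- x$ds$enrichment_weights
  for (marker in c("CD9", "TSG101", "GAPDH", "flotillin-1", "caveolin-1", "RPS6")) {
    best_set <- x$hm$samples[which.max(x$hm$afi[marker, ])]
    centers <- colnames(w)[w[marker, ] == max(w[marker, ])]
    expect_true(best_set %in% centers, label = marker)
  }
})

test_that("heat-map cells equal the call-table AFIs and X-marks are distinct from zero", {
  x <- make_sec_heatmap()
  calls <- x$dm$calls
  for (i in seq_along(x$hm$markers)) {
    for (j in seq_along(x$hm$samples)) {
      cell <- calls[calls$marker == x$hm$markers[i] &
                      calls$sample_id == x$hm$samples[j], ]
      if (cell$status == "detected") {
        expect_identical(x$hm$afi[i, j], cell$afi)
        expect_true(x$hm$detected[i, j])
      } else {
        expect_true(is.na(x$hm$afi[i, j])) # sentinel, never 0
        expect_false(x$hm$detected[i, j])
      }
    }
  }
  # markers below detection everywhere do not appear as default rows
  expect_false("keratin-8" %in% x$hm$markers)
})

test_that("the AFI matrix round-trips through its TSV form", {
  x <- make_sec_heatmap()
  p <- withr::local_tempfile(fileext = ".tsv")
  write_afi_matrix(x$hm, p)
  back <- read_afi_matrix(p)
  expect_equal(back$afi, x$hm$afi) # numeric equality at 15 significant digits
  expect_identical(back$detected, x$hm$detected)
  p2 <- withr::local_tempfile(fileext = ".png")
  write_heatmap_png(x$hm, p2)
  expect_true(file.exists(p2))
})

test_that("concordance tables partition the marker union", {
  tab <- concordance_table(list(milk = c("A", "B", "C")),
                           list(milk = c("A", "B")))
  expect_identical(tab$status[tab$marker == "C"], "digiwest_only")
  expect_setequal(tab$marker[tab$status == "both"], c("A", "B"))
  expect_false("reference_only" %in% tab$status)

  tab2 <- concordance_table(character(), c("X", "Y"))
  expect_true(all(tab2$status == "reference_only"))
  expect_equal(nrow(tab2), 2)
})

test_that("random concordance partitions are disjoint and covering", {
  set.seed(31)
  pool <- paste0("m", 1:30)
  for (rep in 1:20) {
    d <- sample(pool, sample(0:15, 1))
    r <- sample(pool, sample(0:15, 1))
    tab <- concordance_table(d, r)
    expect_equal(nrow(tab), length(union(d, r)))
    expect_equal(anyDuplicated(tab$marker), 0)
    expect_setequal(tab$marker[tab$status != "reference_only"], d)
    expect_setequal(tab$marker[tab$status != "digiwest_only"], r)
  }
})

test_that("unknown reference markers warn and stay reference_only", {
  expect_warning(
    tab <- concordance_table(c("A"), c("A", "mystery"), vocabulary = c("A", "B")),
    "mystery")
  expect_identical(tab$status[tab$marker == "mystery"], "reference_only")
})

test_that("detected marker sets group by sample and species", {
  ds <- simulate_dataset(sim_config(seed = 9, noise_sd = 0))
  q <- quantify_dataset(ds)
  dm <- call_markers(q$peaks, ds$panel, ds$samples)
  by_sample <- detected_marker_sets(dm, by = "sample")
  expect_setequal(names(by_sample), ds$samples$sample_id)
  expect_setequal(by_sample$human_MSC_EV,
                  c("flotillin-1", "TSG101", "caveolin-1", "HSP70", "HSPA8",
                    "annexin-A2", "GAPDH", "fibronectin", "enolase-1"))
  expect_true(all(c("CD9", "SHH", "ITGB1") %in% by_sample$pig_NC_EV))
})

test_that("empty results export header-only tables", {
  dir <- withr::local_tempdir()
  empty_peaks <- read_peaks(withr::local_tempfile(
    lines = paste(c("sample_id", "antibody_id", "apex_fraction", "apex_mw_kda",
                    "height", "left", "right", "afi", "matched_expected_mw_kda",
                    "mw_shift_kda"), collapse = "\t")))
  paths <- export_tables(peaks = empty_peaks, out_dir = dir)
  expect_equal(length(readLines(paths[["peaks"]])), 1)
  expect_equal(nrow(read_peaks(paths[["peaks"]])), 0)
})
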
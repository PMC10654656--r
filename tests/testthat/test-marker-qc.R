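test_that("height and AFI thresholds are inclusive at the boundary", {
  grid <- expand.grid(height = c(49, 50, 51), afi = c(99, 100, 101))
  for (i in seq_len(nrow(grid))) {
    res <- apply_thresholds(grid$height[i], grid$afi[i])
    should_pass <- grid$height[i] >= 50 && grid$afi[i] >= 100
    expect_identical(res$pass, should_pass)
    if (grid$height[i] < 50) expect_true("below_min_height" %in% res$reasons)
    if (grid$afi[i] < 100) expect_true("below_min_afi" %in% res$reasons)
  }
  expect_setequal(apply_thresholds(0, 0)$reasons,
                  c("below_min_height", "below_min_afi"))
  expect_identical(apply_thresholds(49, 500)$reasons, "below_min_height")
})

test_that("MW matching honours the 10 kDa shift rule inclusively", {
  expect_equal(match_mw(31, 21), list(matched = 21, shift = 10))
  expect_equal(match_mw(32, 21), list(matched = NA_real_, shift = NA_real_))
  expect_equal(match_mw(30, 21)$shift, 9)
  expect_equal(match_mw(11, 21)$shift, -10)
  # equidistant between isoforms: lower expected MW wins
  m <- match_mw(22.5, c(21, 24))
  expect_equal(m$matched, 21)
  expect_equal(m$shift, 1.5)
})

test_that("cross-sample consistency bounds the shift spread", {
  expect_true(check_consistency(c(9, 9, 8)))
  expect_false(check_consistency(c(10, -10))) # spread 20 > 5
  expect_true(check_consistency(6))            # single sample: no spread
  expect_true(check_consistency(numeric()))    # vacuous
  expect_false(check_consistency(c(2, NA)))    # unmatched passing peak
  expect_false(check_consistency(c(11, 11)))   # beyond the match tolerance
  expect_true(check_consistency(c(-2, 3)))     # spread 5 inclusive
})

test_that("the noiseless detection matrix reproduces the presence map exactly", {
  ds <- simulate_dataset(sim_config(seed = 12, noise_sd = 0))
  q <- quantify_dataset(ds)
  dm <- call_markers(q$peaks, ds$panel, ds$samples)
  truth <- ds$config$presence
  got <- as.matrix(dm)
  for (s in rownames(truth)) {
    for (a in colnames(truth)) {
      marker <- ds$panel$marker[ds$panel$antibody_id == a]
      expect_identical(got[marker, s] == "+", unname(truth[s, a]),
                       label = sprintf("%s x %s", s, a))
    }
  }
  # detected cells carry no reasons; undetected cells carry at least one
  expect_true(all(dm$calls$reasons[dm$calls$status == "detected"] == ""))
  expect_true(all(nchar(dm$calls$reasons[dm$calls$status == "not_detected"]) > 0))
})

test_that("a marker absent from every lane is reported as no_peak", {
  ds <- simulate_dataset(sim_config(seed = 13, noise_sd = 0))
  q <- quantify_dataset(ds)
  dm <- call_markers(q$peaks, ds$panel, ds$samples)
  k8 <- dm$calls[dm$calls$marker == "keratin-8", ]
  expect_true(all(k8$status == "not_detected"))
  expect_true(all(k8$reasons == "no_peak"))
})

test_that("peaks failing one acceptance rule are rejected with that reason", {
  panel <- data.frame(antibody_id = "ab", marker = "m", stringsAsFactors = FALSE)
  panel$expected_mw_kda <- list(46)
  panel$valid_species <- list("human")
  samples <- data.frame(sample_id = "s1", species = "human", source = "EV",
                        stringsAsFactors = FALSE)
  peak <- data.frame(sample_id = "s1", antibody_id = "ab", apex_fraction = 40L,
                     apex_mw_kda = 46, height = 200, left = 38L, right = 42L,
                     afi = 99, matched_expected_mw_kda = 46, mw_shift_kda = 0)
  dm <- call_markers(peak, panel, samples)
  expect_identical(dm$calls$status, "not_detected")
  expect_identical(dm$calls$reasons, "below_min_afi")

  peak$afi <- 500
  peak$apex_mw_kda <- 58 # 12 kDa off: no match
  dm2 <- call_markers(peak, panel, samples)
  expect_identical(dm2$calls$reasons, "no_mw_match")
})

test_that("an inconsistent shift flags every call of the antibody", {
  panel <- data.frame(antibody_id = "ab", marker = "m", stringsAsFactors = FALSE)
  panel$expected_mw_kda <- list(46)
  panel$valid_species <- list("human")
  samples <- data.frame(sample_id = c("s1", "s2"), species = "human",
                        source = "EV", stringsAsFactors = FALSE)
  peaks <- data.frame(sample_id = c("s1", "s2"), antibody_id = "ab",
                      apex_fraction = c(38L, 44L),
                      apex_mw_kda = c(56, 36), # shifts +10 / -10: spread 20
                      height = 500, left = c(36L, 42L), right = c(40L, 46L),
                      afi = 1500, matched_expected_mw_kda = 46,
                      mw_shift_kda = c(10, -10))
  dm <- call_markers(peaks, panel, samples)
  expect_true(all(dm$calls$status == "not_detected"))
  expect_true(all(dm$calls$reasons == "inconsistent_shift"))

  # a consistent +9/+8 shift is accepted
  peaks$apex_mw_kda <- c(55, 54)
  dm2 <- call_markers(peaks, panel, samples)
  expect_true(all(dm2$calls$status == "detected"))
})

test_that("species-invalid cells are not-applicable, not not-detected", {
  ds <- simulate_dataset(sim_config(seed = 14, noise_sd = 0))
  panel <- ds$panel
  panel$valid_species[[which(panel$antibody_id == "SHH")]] <- c("pig", "dog")
  q <- quantify_dataset(ds)
  dm <- call_markers(q$peaks, panel, ds$samples)
  shh <- dm$calls[dm$calls$marker == "SHH", ]
  expect_identical(shh$status[shh$species == "human"], "not_applicable")
  expect_true(all(shh$status[shh$species != "human"] == "detected"))
  expect_identical(as.matrix(dm)["SHH", "human_MSC_EV"], ".")
})

test_that("an antibody present in peaks but missing from the panel errors", {
  ds <- simulate_dataset(tiny_config(seed = 2, noise_sd = 0))
  q <- quantify_dataset(ds)
  expect_error(call_markers(q$peaks, ds$panel[1, ], ds$samples),
               "not in panel")
})

test_that("raising thresholds never turns an undetected cell into detected", {
  ds <- simulate_dataset(sim_config(seed = 21, noise_sd = 25))
  q <- quantify_dataset(ds)
  base <- call_markers(q$peaks, ds$panel, ds$samples)
  # restrict to antibodies whose shifts are consistent at the base thresholds,
  # where detection is monotone by construction
  ok_ab <- names(base$consistent)[base$consistent]
  for (mh in c(50, 100, 400)) {
    for (ma in c(100, 500, 1200)) {
      dm <- call_markers(q$peaks, ds$panel, ds$samples,
                         min_height = mh, min_afi = ma)
      for (a in ok_ab) {
        m <- ds$panel$marker[ds$panel$antibody_id == a]
        was <- base$calls$status[base$calls$marker == m] == "detected"
        now <- dm$calls$status[dm$calls$marker == m] == "detected"
        expect_true(all(now <= was))
      }
    }
  }
})
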
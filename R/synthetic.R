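#' Default ladder anchors
#'
#' Eight anchors from 250 kDa (fraction 2) to 10 kDa (fraction 93), spaced
#' log-linearly -- qualitatively mirroring migration on a 4-12% Bis-Tris
#' gradient gel.
#'
#' @return data.frame with columns `fraction_index`, `mw_kda`.
#' @export
default_ladder <- function() {
  idx <- round(seq(2, 93, length.out = 8))
  mw <- round(10^seq(log10(250), 1, length.out = 8), 1)
  data.frame(fraction_index = idx, mw_kda = mw)
}

#' Default antibody panel
#'
#' A 15-antibody extracellular-vesicle characterization panel: nine general
#' EV markers (membrane and luminal cargo), three source/species-restricted
#' markers (CD9, SHH, ITGB1) and three coisolation indicators (keratin-8,
#' keratin-18, ribosomal protein S6). Expected molecular weights are
#' field-standard values for these proteins; caveolin-1 carries the 21 and
#' 24 kDa isoform doublet.
#'
#' @return Panel data.frame (see [read_panel()] for the columns).
#' @export
default_panel <- function() {
  species <- c("human", "pig", "dog")
  spec <- list(
    "flotillin-1" = 49, "TSG101" = 44, "caveolin-1" = c(21, 24),
    "HSP70" = 70, "HSPA8" = 71, "annexin-A2" = 36, "GAPDH" = 36,
    "fibronectin" = 230, "enolase-1" = 47, "CD9" = 25, "SHH" = 19,
    "ITGB1" = 130, "keratin-8" = 54, "keratin-18" = 48, "RPS6" = 32
  )
  panel <- data.frame(antibody_id = names(spec), marker = names(spec),
                      stringsAsFactors = FALSE)
  panel$expected_mw_kda <- unname(lapply(spec, as.numeric))
  panel$valid_species <- rep(list(species), nrow(panel))
  panel
}

#' Default sample sheet: one EV preparation per species
#'
#' @return Sample metadata data.frame.
#' @export
default_samples <- function() {
  data.frame(sample_id = c("human_MSC_EV", "pig_NC_EV", "dog_NC_EV"),
             species = c("human", "pig", "dog"),
             source = c("MSC", "NC", "NC"),
             protein_input_ug = c(10, 9, 8),
             stringsAsFactors = FALSE)
}

GENERAL_EV_MARKERS <- c("flotillin-1", "TSG101", "caveolin-1", "HSP70", "HSPA8",
                        "annexin-A2", "GAPDH", "fibronectin", "enolase-1")

# Presence map emulating the cross-species experiment: the nine general
# markers in every sample; CD9/SHH/ITGB1 absent from the human MSC
# preparation; coisolation markers absent from all EV preparations.
default_presence <- function(samples, panel) {
  m <- matrix(FALSE, nrow(samples), nrow(panel),
              dimnames = list(samples$sample_id, panel$antibody_id))
  m[, GENERAL_EV_MARKERS] <- TRUE
  nc <- samples$sample_id[samples$source == "NC"]
  m[nc, c("CD9", "SHH", "ITGB1")] <- TRUE
  m
}

#' Build a simulation configuration
#'
#' Describes a complete synthetic DigiWest run: sample sheet, antibody panel,
#' the true band(s) each antibody produces when its marker is present, a
#' presence map, per-lane signal model (flat bead background, optional broad
#' low secondary-antibody bump, Gaussian peaks in fraction space) and
#' additive Gaussian noise clipped at zero.
#'
#' Defaults emulate a three-species EV characterization run: bead background
#' 100 AU, marker amplitude 500 AU, noise 25 AU (5% of amplitude), band
#' width 1.2 fractions, and a consistent -8 kDa shift of the CD9 band below
#' its expected weight.
#'
#' @param samples Sample sheet ([default_samples()]).
#' @param panel Antibody panel ([default_panel()]).
#' @param bands data.frame `antibody_id`, `mw_kda`: the band(s) emitted when
#'   the marker is present. Default: the lowest expected MW per antibody
#'   (caveolin-1 emits the 21 kDa isoform only).
#' @param presence Logical samples x antibodies matrix; default
#'   emulates the cross-species panel outcome.
#' @param amplitude Peak amplitude in AU: scalar, per-antibody named vector,
#'   or samples x antibodies matrix.
#' @param width_fractions Gaussian band width (sigma, in fractions): scalar
#'   or per-antibody named vector.
#' @param mw_shift_kda True MW shift applied to emitted bands: scalar,
#'   per-antibody named vector, or samples x antibodies matrix. Default 0
#'   except CD9 at -8 kDa.
#' @param baseline_level Flat bead background in AU.
#' @param secondary_bump `list(center_fraction, amplitude, width_fractions)`
#'   for the broad nonspecific secondary-antibody signal, or `NULL` for none.
#' @param noise_sd Standard deviation of the additive Gaussian noise (AU).
#' @param seed Integer RNG seed; identical configs with identical seeds
#'   reproduce byte-identical fixture files.
#' @param shuffle_beadmap Randomly permute the color-ID/fraction assignment
#'   (TRUE, as on a real plate) or use the identity map.
#' @return A validated object of class `sim_config`.
#' @export
sim_config <- function(samples = default_samples(),
                       panel = default_panel(),
                       bands = NULL,
                       presence = NULL,
                       amplitude = 500,
                       width_fractions = 1.2,
                       mw_shift_kda = NULL,
                       baseline_level = 100,
                       secondary_bump = list(center_fraction = 78, amplitude = 40,
                                             width_fractions = 6),
                       noise_sd = 25,
                       seed = 1L,
                       shuffle_beadmap = TRUE) {
  panel <- validate_panel(panel)
  ab <- panel$antibody_id
  sm <- samples$sample_id
  if (is.null(bands)) {
    bands <- data.frame(
      antibody_id = ab,
      mw_kda = vapply(panel$expected_mw_kda, function(x) x[[1]], 0),
      stringsAsFactors = FALSE
    )
  }
  if (is.null(presence)) presence <- default_presence(samples, panel)
  as_sa_matrix <- function(x, what, default = 0) {
    m <- matrix(default, length(sm), length(ab), dimnames = list(sm, ab))
    if (is.matrix(x)) {
      m[rownames(x), colnames(x)] <- x
    } else if (!is.null(names(x))) {
      for (a in names(x)) m[, a] <- x[[a]]
    } else if (!is.null(x)) {
      m[, ] <- x
    }
    m
  }
  amplitude <- as_sa_matrix(amplitude, "amplitude")
  if (is.null(mw_shift_kda)) {
    mw_shift_kda <- if ("CD9" %in% ab) c(CD9 = -8) else 0
  }
  mw_shift_kda <- as_sa_matrix(mw_shift_kda, "mw_shift_kda")
  wf <- stats::setNames(rep(1.2, length(ab)), ab)
  if (!is.null(names(width_fractions))) {
    wf[names(width_fractions)] <- width_fractions
  } else {
    wf[] <- width_fractions
  }
  cfg <- structure(list(samples = samples, panel = panel, bands = bands,
                        presence = presence, amplitude = amplitude,
                        width_fractions = wf, mw_shift_kda = mw_shift_kda,
                        baseline_level = baseline_level,
                        secondary_bump = secondary_bump,
                        noise_sd = noise_sd, seed = as.integer(seed),
                        shuffle_beadmap = isTRUE(shuffle_beadmap),
                        ladder = default_ladder()),
                   class = "sim_config")
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (nrow(cfg$samples) < 1) stop("config needs at least one sample")
  if (any(cfg$amplitude < 0)) {
    bad <- colnames(cfg$amplitude)[apply(cfg$amplitude < 0, 2, any)]
    stop(sprintf("negative amplitude for antibody '%s'", bad[1]))
  }
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0")
  if (any(cfg$width_fractions <= 0)) stop("width_fractions must be > 0")
  if (cfg$baseline_level < 0) stop("baseline_level must be >= 0")
  cal <- fit_calibration(cfg$ladder)
  for (i in seq_len(nrow(cfg$bands))) {
    a <- cfg$bands$antibody_id[i]
    mws <- cfg$bands$mw_kda[i] + cfg$mw_shift_kda[, a]
    ok <- mws >= MW_CLAMP[1] & mws <= MW_CLAMP[2]
    if (!all(ok)) {
      stop(sprintf("band for marker '%s' at %s kDa lies outside the calibration range [%g, %g] kDa",
                   cfg$panel$marker[match(a, cfg$panel$antibody_id)],
                   fmt_num(mws[!ok][1]), MW_CLAMP[1], MW_CLAMP[2]))
    }
  }
  bad_exp <- vapply(cfg$panel$expected_mw_kda,
                    function(x) any(x < MW_CLAMP[1] | x > MW_CLAMP[2]), TRUE)
  if (any(bad_exp)) {
    stop(sprintf("expected MW for marker '%s' outside the calibration range [%g, %g] kDa",
                 cfg$panel$marker[bad_exp][1], MW_CLAMP[1], MW_CLAMP[2]))
  }
  cfg
}

gaussian_profile <- function(frac, center, amplitude, sigma) {
  amplitude * exp(-(frac - center)^2 / (2 * sigma^2))
}

#' Simulate a complete DigiWest dataset with known ground truth
#'
#' Generates per-bead readouts, a bead map, ladder anchors, control lanes and
#' the matching ground truth. Every sample x antibody lane is
#' `baseline + secondary bump + Gaussian marker bands + N(0, noise_sd)`,
#' clipped at zero and rounded to 4 decimals (instrument granularity);
#' control lanes contain the bead background (`EMPTY_BEAD`) and
#' background + bump (`SECONDARY_ONLY`), with the same noise model, keyed to
#' the wildcard sample `*`.
#'
#' @param config A [sim_config()].
#' @return A list of class `digiwest_dataset` with elements `readout`,
#'   `beadmap`, `ladder`, `panel`, `samples`, `truth` (one row per present
#'   band: true center MW, amplitude, width, analytic AFI
#'   `amplitude * sigma * sqrt(2*pi)`) and `config`.
#' @export
simulate_dataset <- function(config) {
  config <- validate_sim_config(config)
  cal <- fit_calibration(config$ladder)
  frac <- 0:(N_FRACTIONS - 1L)
  with_seed(config$seed, {
    colors <- sprintf("B%03d", seq_len(N_FRACTIONS))
    perm <- if (config$shuffle_beadmap) sample(frac) else frac
    beadmap <- data.frame(color_id = colors, fraction_index = as.integer(perm),
                          stringsAsFactors = FALSE)
    color_of <- colors[order(perm)] # color_of[f + 1] = color carrying fraction f

    bump <- if (!is.null(config$secondary_bump)) {
      b <- config$secondary_bump
      gaussian_profile(frac, b$center_fraction, b$amplitude, b$width_fractions)
    } else {
      rep(0, N_FRACTIONS)
    }
    base <- config$baseline_level + bump

    lanes <- list()
    truth <- list()
    for (s in config$samples$sample_id) {
      for (a in config$panel$antibody_id) {
        v <- base
        if (isTRUE(config$presence[s, a])) {
          rows <- which(config$bands$antibody_id == a)
          for (i in rows) {
            mw_true <- config$bands$mw_kda[i] + config$mw_shift_kda[s, a]
            center <- mw_to_fraction(cal, mw_true)
            amp <- config$amplitude[s, a]
            sigma <- config$width_fractions[[a]]
            v <- v + gaussian_profile(frac, center, amp, sigma)
            truth[[length(truth) + 1L]] <- data.frame(
              sample_id = s, antibody_id = a,
              marker = config$panel$marker[match(a, config$panel$antibody_id)],
              true_center_mw_kda = mw_true,
              true_center_fraction = center,
              true_amplitude = amp,
              true_width_fractions = sigma,
              true_afi = amp * sigma * sqrt(2 * pi),
              stringsAsFactors = FALSE
            )
          }
        }
        v <- v + stats::rnorm(N_FRACTIONS, 0, config$noise_sd)
        lanes[[paste(s, a, sep = "\r")]] <-
          list(sample_id = s, antibody_id = a, values = round(pmax(v, 0), 4))
      }
    }
    lanes[[paste(CONTROL_WILDCARD, EMPTY_BEAD, sep = "\r")]] <- list(
      sample_id = CONTROL_WILDCARD, antibody_id = EMPTY_BEAD,
      values = round(pmax(config$baseline_level +
                            stats::rnorm(N_FRACTIONS, 0, config$noise_sd), 0), 4))
    if (!is.null(config$secondary_bump)) {
      lanes[[paste(CONTROL_WILDCARD, SECONDARY_ONLY, sep = "\r")]] <- list(
        sample_id = CONTROL_WILDCARD, antibody_id = SECONDARY_ONLY,
        values = round(pmax(base + stats::rnorm(N_FRACTIONS, 0, config$noise_sd), 0), 4))
    }

    readout <- do.call(rbind, lapply(lanes, function(l) {
      data.frame(sample_id = l$sample_id, antibody_id = l$antibody_id,
                 color_id = color_of, mfi = l$values, stringsAsFactors = FALSE)
    }))
    rownames(readout) <- NULL

    truth <- if (length(truth)) do.call(rbind, truth) else data.frame(
      sample_id = character(), antibody_id = character(), marker = character(),
      true_center_mw_kda = numeric(), true_center_fraction = numeric(),
      true_amplitude = numeric(), true_width_fractions = numeric(),
      true_afi = numeric(), stringsAsFactors = FALSE)
    rownames(truth) <- NULL

    structure(list(readout = readout, beadmap = beadmap, ladder = config$ladder,
                   panel = config$panel, samples = config$samples,
                   truth = truth, config = config),
              class = "digiwest_dataset")
  })
}

#' Default SEC enrichment weights
#'
#' Per-antibody amplitude multipliers across the pooled size-exclusion
#' fraction sets, emulating EV enrichment centered on sets 8-10 and 11-13
#' with a coisolated ribosomal marker restricted to those sets.
#'
#' @param sets Pooled-fraction set labels.
#' @return Numeric matrix antibodies x sets.
#' @export
default_sec_weights <- function(sets = c("5-7", "8-10", "11-13", "14-16",
                                         "17-19", "20-22")) {
  peak_early <- c(0.1, 1, 0.8, 0.25, 0.1, 0.05)  # centered on 8-10
  peak_late <- c(0.1, 0.8, 1, 0.3, 0.1, 0.05)    # centered on 11-13
  w <- rbind(
    "CD9" = peak_early, "TSG101" = peak_early, "GAPDH" = peak_early,
    "flotillin-1" = peak_late, "caveolin-1" = peak_late,
    "HSP70" = peak_early, "HSPA8" = peak_early, "annexin-A2" = peak_early,
    "enolase-1" = peak_early, "fibronectin" = peak_early,
    "SHH" = peak_early, "ITGB1" = peak_early,
    "RPS6" = c(0, 1, 1, 0, 0, 0),
    "keratin-8" = rep(0, 6), "keratin-18" = rep(0, 6)
  )
  colnames(w) <- sets
  w
}

#' Simulate a pooled SEC-fraction dilution series
#'
#' Derives one virtual lane set per pooled size-exclusion fraction set from a
#' base configuration, scaling each antibody's amplitude by the given
#' enrichment weights. The base sample defaults to the first sample of
#' `base_config`; for the default configuration this pig NC preparation
#' additionally carries the coisolated RPS6 marker, mirroring ribosomal
#' contamination of crude SEC fractions.
#'
#' @param base_config A [sim_config()]; its first sample provides species,
#'   presence and amplitude baseline.
#' @param enrichment_weights Numeric vector (one weight per set, applied to
#'   all present antibodies) or antibodies x sets matrix; all weights >= 0,
#'   at least one > 0.
#' @param sets Pooled-fraction set labels (become sample IDs).
#' @param base_sample Sample ID in `base_config` to derive from.
#' @param include_rps6 Make the coisolated RPS6 marker available in the
#'   series (default TRUE, matching the default weights).
#' @return A `digiwest_dataset` whose samples are the fraction sets, with an
#'   additional `sets` element and the per-set truth table.
#' @export
simulate_sec_series <- function(base_config = sim_config(),
                                enrichment_weights = NULL,
                                sets = c("5-7", "8-10", "11-13", "14-16",
                                         "17-19", "20-22"),
                                base_sample = NULL,
                                include_rps6 = TRUE) {
  stopifnot(inherits(base_config, "sim_config"))
  if (is.null(enrichment_weights)) enrichment_weights <- default_sec_weights(sets)
  if (!length(enrichment_weights)) stop("enrichment_weights must not be empty")
  if (any(enrichment_weights < 0)) stop("enrichment_weights must be >= 0")
  if (!any(enrichment_weights > 0)) stop("at least one enrichment weight must be > 0")
  ab <- base_config$panel$antibody_id
  if (is.matrix(enrichment_weights)) {
    if (is.null(colnames(enrichment_weights))) colnames(enrichment_weights) <- sets
    sets <- colnames(enrichment_weights)
    w <- matrix(0, length(ab), length(sets), dimnames = list(ab, sets))
    common <- intersect(rownames(enrichment_weights), ab)
    w[common, ] <- enrichment_weights[common, ]
  } else {
    if (length(enrichment_weights) != length(sets)) {
      stop("enrichment_weights must have one weight per fraction set")
    }
    w <- matrix(rep(enrichment_weights, each = length(ab)), length(ab),
                dimnames = list(ab, sets))
  }
  base_sample <- base_sample %||% base_config$samples$sample_id[1]
  base_row <- match(base_sample, base_config$samples$sample_id)
  if (is.na(base_row)) stop(sprintf("unknown base_sample '%s'", base_sample))

  samples <- data.frame(sample_id = sets,
                        species = base_config$samples$species[base_row],
                        source = paste0("SEC_", sets),
                        protein_input_ug = NA_real_,
                        stringsAsFactors = FALSE)
  base_presence <- base_config$presence[base_sample, ]
  if (include_rps6 && "RPS6" %in% ab) base_presence[["RPS6"]] <- TRUE
  presence <- t(vapply(sets, function(set) base_presence & w[, set] > 0,
                       logical(length(ab))))
  dimnames(presence) <- list(sets, ab)
  amplitude <- t(vapply(sets, function(set) base_config$amplitude[base_sample, ] * w[, set],
                        numeric(length(ab))))
  dimnames(amplitude) <- list(sets, ab)
  shift <- matrix(rep(base_config$mw_shift_kda[base_sample, ], each = length(sets)),
                  length(sets), length(ab), dimnames = list(sets, ab))

  cfg <- sim_config(samples = samples, panel = base_config$panel,
                    bands = base_config$bands, presence = presence,
                    amplitude = amplitude,
                    width_fractions = base_config$width_fractions,
                    mw_shift_kda = shift,
                    baseline_level = base_config$baseline_level,
                    secondary_bump = base_config$secondary_bump,
                    noise_sd = base_config$noise_sd,
                    seed = base_config$seed,
                    shuffle_beadmap = base_config$shuffle_beadmap)
  ds <- simulate_dataset(cfg)
  ds$sets <- sets
  ds$enrichment_weights <- w
  ds
}

#' Write a simulated dataset to fixture files
#'
#' Emits `readout.csv`, `beadmap.csv`, `ladder.csv`, `panel.json`,
#' `samples.csv` and `truth.csv` into `out_dir`; the files round-trip
#' losslessly through [read_dataset()].
#'
#' @param dataset A `digiwest_dataset` from [simulate_dataset()].
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_fixture_files <- function(dataset, out_dir) {
  stopifnot(inherits(dataset, "digiwest_dataset") || is.list(dataset))
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok) stop(sprintf("cannot create output directory: %s", out_dir))
  paths <- c(readout = file.path(out_dir, "readout.csv"),
             beadmap = file.path(out_dir, "beadmap.csv"),
             ladder = file.path(out_dir, "ladder.csv"),
             panel = file.path(out_dir, "panel.json"),
             samples = file.path(out_dir, "samples.csv"),
             truth = file.path(out_dir, "truth.csv"))
  write_readout(dataset$readout, paths[["readout"]])
  write_beadmap(dataset$beadmap, paths[["beadmap"]])
  write_ladder(dataset$ladder, paths[["ladder"]])
  write_panel(dataset$panel, paths[["panel"]])
  write_samples(dataset$samples, paths[["samples"]])
  write_table_file(dataset$truth, paths[["truth"]])
  invisible(paths)
}

#' Read a fixture directory back into a dataset
#'
#' @param dir Directory written by [write_fixture_files()] (truth.csv is
#'   optional: real datasets have none).
#' @return A `digiwest_dataset` (without the generating `config`).
#' @export
read_dataset <- function(dir) {
  truth_path <- file.path(dir, "truth.csv")
  truth <- NULL
  if (file.exists(truth_path)) {
    truth <- read_table_checked(truth_path, c("sample_id", "antibody_id", "marker"))
    for (col in setdiff(names(truth), c("sample_id", "antibody_id", "marker"))) {
      truth[[col]] <- parse_num_col(truth[[col]], col, truth_path)
    }
  }
  structure(list(readout = read_readout(file.path(dir, "readout.csv")),
                 beadmap = read_beadmap(file.path(dir, "beadmap.csv")),
                 ladder = read_ladder(file.path(dir, "ladder.csv")),
                 panel = read_panel(file.path(dir, "panel.json")),
                 samples = read_samples(file.path(dir, "samples.csv")),
                 truth = truth),
            class = "digiwest_dataset")
}

#' @export
print.digiwest_dataset <- function(x, ...) {
  cat(sprintf("DigiWest dataset: %d samples x %d antibodies, %d readout rows, %d truth bands\n",
              nrow(x$samples), nrow(x$panel), nrow(x$readout),
              if (is.null(x$truth)) 0L else nrow(x$truth)))
  invisible(x)
}
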
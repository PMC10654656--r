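#' Run the full DigiWest analysis pipeline
#'
#' Chains simulate (or load) -> calibrate -> quantify -> call -> report,
#' writing all artifacts into an output directory and logging one structured
#' line per stage (input/output row counts). Identical configuration and seed
#' reproduce byte-identical artifact files. On any stage failure the error
#' names the stage, and files written by the failed run are removed.
#'
#' @param config A run configuration: a named list or the path of a YAML file
#'   with keys
#'   \describe{
#'     \item{seed}{integer RNG seed (default 1).}
#'     \item{out}{output directory.}
#'     \item{simulate}{either `TRUE` / a list of [sim_config()] overrides
#'       (`noise_sd`, `seed`, ...), with optional `preset: "sec"` for the
#'       pooled SEC-fraction series; omitted when `inputs` is given.}
#'     \item{inputs}{directory of fixture files to load instead of
#'       simulating ([read_dataset()]).}
#'     \item{thresholds}{`min_height`, `min_afi`, `mw_tol_kda`, `spread_kda`.}
#'     \item{report}{logical flags `mimic`, `heatmap` (default both TRUE).}
#'   }
#' @param out_dir Output directory; overrides `config$out`.
#' @param quiet Suppress per-stage log lines.
#' @return Invisibly, a list with the written `paths` and the in-memory
#'   `dataset`, `cal`, `peaks`, `dm` (detection matrix) and `heatmap`.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL, quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out_dir <- out_dir %||% config$out %||% stop("run_pipeline: no output directory given")
  seed <- as.integer(config$seed %||% 1L)
  thr <- config$thresholds %||% list()
  min_height <- thr$min_height %||% 50
  min_afi <- thr$min_afi %||% 100
  mw_tol <- thr$mw_tol_kda %||% 10
  spread <- thr$spread_kda %||% 5
  report_cfg <- config$report %||% list()
  do_mimic <- report_cfg$mimic %||% TRUE
  do_heatmap <- report_cfg$heatmap %||% TRUE

  log_line <- function(stage, ...) {
    if (!quiet) message(sprintf("[%s] %s", stage, sprintf(...)))
  }
  written <- character()
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok) stop(sprintf("run: cannot create output directory %s", out_dir))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      stop(sprintf("%s: %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  # -- simulate / load -------------------------------------------------------
  dataset <- if (!is.null(config$inputs)) {
    stage("load", {
      ds <- read_dataset(config$inputs)
      log_line("load", "dir=%s readout_rows=%d", config$inputs, nrow(ds$readout))
      ds
    })
  } else {
    stage("simulate", {
      sim <- config$simulate
      if (isTRUE(sim) || is.null(sim)) sim <- list()
      preset <- sim$preset %||% "cross_species"
      sim$preset <- NULL
      sim$seed <- sim$seed %||% seed
      ds <- if (identical(preset, "sec")) {
        simulate_sec_series(base_config = do.call(sim_config, sim))
      } else {
        simulate_dataset(do.call(sim_config, sim))
      }
      fx <- write_fixture_files(ds, file.path(out_dir, "fixtures"))
      written <- c(written, fx)
      log_line("simulate", "preset=%s seed=%d readout_rows=%d truth_bands=%d",
               preset, sim$seed, nrow(ds$readout), nrow(ds$truth))
      ds
    })
  }

  # -- calibrate -------------------------------------------------------------
  cal <- stage("calibrate", {
    cal <- fit_calibration(dataset$ladder)
    log_line("calibrate", "anchors=%d span=%.1f-%.1f kDa", nrow(cal$anchors),
             fraction_to_mw(cal, cal$valid_range[2]),
             fraction_to_mw(cal, cal$valid_range[1]))
    cal
  })

  # -- quantify --------------------------------------------------------------
  peaks <- stage("quantify", {
    if (is.null(dataset$readout)) stop("input missing: no readout table")
    pk <- quantify_run(dataset$readout, dataset$beadmap, dataset$panel, cal,
                       mw_window_kda = mw_tol)
    p <- file.path(out_dir, "peaks.tsv")
    write_peaks(pk, p)
    written <- c(written, p)
    log_line("quantify", "lanes=%d peaks=%d",
             nrow(unique(dataset$readout[
               !(dataset$readout$antibody_id %in% CONTROL_IDS),
               c("sample_id", "antibody_id")])), nrow(pk))
    pk
  })

  # -- call ------------------------------------------------------------------
  dm <- stage("call", {
    dm <- call_markers(peaks, dataset$panel, dataset$samples,
                       min_height = min_height, min_afi = min_afi,
                       mw_tol_kda = mw_tol, spread_kda = spread)
    paths <- export_tables(dm = dm, out_dir = out_dir)
    written <- c(written, paths)
    log_line("call", "cells=%d detected=%d", nrow(dm$calls),
             sum(dm$calls$status == "detected"))
    dm
  })

  # -- report ----------------------------------------------------------------
  hm <- stage("report", {
    hm <- NULL
    if (isTRUE(do_mimic)) {
      ctrl <- control_profiles(dataset$readout, dataset$beadmap,
                               dataset$samples$sample_id[1])
      baseline <- estimate_baseline(ctrl$empty_bead, ctrl$secondary_only)
      assay <- dataset$readout[!(dataset$readout$antibody_id %in% CONTROL_IDS), ]
      combos <- unique(assay[c("sample_id", "antibody_id")])
      profiles <- vapply(seq_len(nrow(combos)), function(i) {
        rows <- assay[assay$sample_id == combos$sample_id[i] &
                        assay$antibody_id == combos$antibody_id[i], ]
        subtract_background(reconstruct_lane(rows, dataset$beadmap), baseline)
      }, numeric(N_FRACTIONS))
      colnames(profiles) <- paste(combos$sample_id, combos$antibody_id, sep = ":")
      mimic <- render_mimic(profiles, cal)
      p <- file.path(out_dir, "mimic.png")
      write_mimic_png(mimic, p)
      written <- c(written, p)
      log_line("report", "mimic lanes=%d", ncol(profiles))
    }
    if (isTRUE(do_heatmap) && any(dm$calls$status == "detected")) {
      hm <- heatmap_afi(dm)
      write_afi_matrix(hm, file.path(out_dir, "afi_matrix.tsv"))
      write_heatmap_png(hm, file.path(out_dir, "heatmap.png"))
      written <- c(written, file.path(out_dir, c("afi_matrix.tsv", "heatmap.png")))
      log_line("report", "heatmap markers=%d columns=%d",
               length(hm$markers), length(hm$samples))
    }
    hm
  })

  invisible(list(paths = written, dataset = dataset, cal = cal, peaks = peaks,
                 dm = dm, heatmap = hm, out_dir = out_dir))
}
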
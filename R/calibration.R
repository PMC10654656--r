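#' Fit a molecular-weight calibration from ladder anchors
#'
#' Builds the monotone mapping between gel fraction index (0-based; fraction 0
#' is the top of the gel, i.e. the highest molecular weight) and molecular
#' weight in kDa. The mapping is piecewise linear in `log10(MW)` versus
#' fraction index between anchors -- the standard model for protein migration
#' on SDS-PAGE gradient gels -- with linear extrapolation beyond the outermost
#' anchors, clamped so that no extrapolated MW leaves \[1, 500\] kDa.
#'
#' @param anchors A data.frame (or coercible) with columns `fraction_index`
#'   and `mw_kda`: at least two rows, fraction indices strictly increasing and
#'   molecular weights strictly decreasing.
#' @return An object of class `mw_calibration`.
#' @examples
#' cal <- fit_calibration(data.frame(fraction_index = c(0, 95),
#'                                   mw_kda = c(250, 10)))
#' fraction_to_mw(cal, 47.5) # 50 kDa: sqrt(250 * 10) under log-linearity
#' @seealso [fraction_to_mw()], [mw_to_fraction()], [read_ladder()]
#' @export
fit_calibration <- function(anchors) {
  anchors <- as.data.frame(anchors)
  req <- c("fraction_index", "mw_kda")
  if (!all(req %in% names(anchors))) {
    if (ncol(anchors) >= 2) {
      names(anchors)[1:2] <- req
    } else {
      stop("anchors must have columns 'fraction_index' and 'mw_kda'")
    }
  }
  anchors <- anchors[order(anchors$fraction_index), req, drop = FALSE]
  rownames(anchors) <- NULL
  if (nrow(anchors) < 2) {
    stop("calibration needs at least 2 ladder anchors")
  }
  if (any(!is.finite(anchors$fraction_index)) || any(!is.finite(anchors$mw_kda)) ||
      any(anchors$mw_kda <= 0)) {
    stop("ladder anchors must have finite fraction_index and positive mw_kda")
  }
  if (any(diff(anchors$fraction_index) <= 0)) {
    stop("ladder anchor fraction indices must be strictly increasing")
  }
  if (any(diff(anchors$mw_kda) >= 0)) {
    stop("ladder anchors must be strictly MW-decreasing with increasing fraction index")
  }
  structure(list(anchors = anchors,
                 index = anchors$fraction_index,
                 log_mw = log10(anchors$mw_kda),
                 valid_range = range(anchors$fraction_index)),
            class = "mw_calibration")
}

# Piecewise-linear interpolation with linear extrapolation from the end
# segments. x must be strictly increasing.
interp_extrap <- function(x, y, xout) {
  n <- length(x)
  res <- stats::approx(x, y, xout = xout, rule = 2, ties = "ordered")$y
  lo <- which(xout < x[1])
  hi <- which(xout > x[n])
  if (length(lo)) {
    res[lo] <- y[1] + (xout[lo] - x[1]) * (y[2] - y[1]) / (x[2] - x[1])
  }
  if (length(hi)) {
    res[hi] <- y[n] + (xout[hi] - x[n]) * (y[n] - y[n - 1]) / (x[n] - x[n - 1])
  }
  res
}

#' Convert fraction index to molecular weight
#'
#' @param cal An `mw_calibration` from [fit_calibration()].
#' @param index Numeric vector of (possibly fractional) fraction indices.
#' @return Molecular weights in kDa, clamped to \[1, 500\].
#' @export
fraction_to_mw <- function(cal, index) {
  stopifnot(inherits(cal, "mw_calibration"))
  if (any(!is.finite(index))) stop("fraction index must be finite")
  mw <- 10^interp_extrap(cal$index, cal$log_mw, index)
  pmin(pmax(mw, MW_CLAMP[1]), MW_CLAMP[2])
}

#' Convert molecular weight to fraction index
#'
#' Inverse of [fraction_to_mw()] within the anchor span (exactly, since the
#' inverse of a piecewise-linear map is piecewise linear).
#'
#' @param cal An `mw_calibration`.
#' @param mw_kda Molecular weights in kDa; must lie inside the supported
#'   \[1, 500\] kDa range.
#' @return Real-valued fraction indices.
#' @export
mw_to_fraction <- function(cal, mw_kda) {
  stopifnot(inherits(cal, "mw_calibration"))
  if (any(!is.finite(mw_kda)) || any(mw_kda <= 0)) {
    stop("molecular weight must be finite and positive")
  }
  out_of_range <- mw_kda < MW_CLAMP[1] | mw_kda > MW_CLAMP[2]
  if (any(out_of_range)) {
    stop(sprintf("molecular weight %s kDa outside the supported range [%g, %g] kDa",
                 paste(fmt_num(mw_kda[out_of_range]), collapse = ", "),
                 MW_CLAMP[1], MW_CLAMP[2]))
  }
  # log_mw decreases with index; reverse both to get an increasing abscissa.
  interp_extrap(rev(cal$log_mw), rev(cal$index), log10(mw_kda))
}

#' Tabulate the fitted calibration over the 96 fractions
#'
#' @param cal An `mw_calibration`.
#' @param fractions Integer fraction indices to tabulate (default all 96).
#' @return data.frame with columns `fraction_index`, `mw_kda`.
#' @export
calibration_table <- function(cal, fractions = 0:(N_FRACTIONS - 1L)) {
  data.frame(fraction_index = as.integer(fractions),
             mw_kda = fraction_to_mw(cal, fractions))
}

#' @export
print.mw_calibration <- function(x, ...) {
  rng <- fraction_to_mw(x, x$valid_range)
  cat(sprintf("MW calibration: %d anchors, fractions %g-%g (%.1f-%.1f kDa), log-linear\n",
              nrow(x$anchors), x$valid_range[1], x$valid_range[2], rng[1], rng[2]))
  invisible(x)
}
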
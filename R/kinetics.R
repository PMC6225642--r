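#' Smooth a fermentation curve by local polynomial regression
#'
#' Fits a degree-2 local polynomial (tricube weights, neighbourhood spanning
#' the `span` fraction of points) to cumulative CO2 versus time and returns
#' fitted values at the input times. The default span of 0.45 is the standard
#' setting for small-vessel CO2 weight-loss series.
#'
#' @param curve data.frame with columns `time_h` and `co2_g_per_l`
#'   (one sample; times strictly increasing).
#' @param span Smoothing span in (0, 1].
#' @return The input data.frame with `co2_g_per_l` replaced by fitted values.
#' @export
smooth_curve <- function(curve, span = 0.45) {
  stopifnot(
    is.data.frame(curve), all(c("time_h", "co2_g_per_l") %in% names(curve)),
    span > 0, span <= 1
  )
  if (nrow(curve) < 10) stop("need >= 10 points to smooth a curve")
  if (any(diff(curve$time_h) <= 0)) stop("times must be strictly increasing")
  if (stats::var(curve$co2_g_per_l) == 0) {
    return(curve) # constant curve is its own fit
  }
  fit <- stats::loess(
    co2_g_per_l ~ time_h, data = curve,
    span = span, degree = 2, family = "gaussian",
    control = stats::loess.control(surface = "direct")
  )
  out <- curve
  out$co2_g_per_l <- as.numeric(stats::predict(fit, curve$time_h))
  out
}

# first time at which `value` crosses `threshold` from below, by linear
# interpolation between grid points; NA if never reached
.first_crossing <- function(time, value, threshold) {
  if (value[1] >= threshold) return(time[1])
  above <- which(value >= threshold)
  if (!length(above)) return(NA_real_)
  i <- above[1]
  t0 <- time[i - 1]; t1 <- time[i]
  v0 <- value[i - 1]; v1 <- value[i]
  if (v1 == v0) return(t1)
  t0 + (threshold - v0) / (v1 - v0) * (t1 - t0)
}

#' Extract kinetic traits from a (smoothed) fermentation curve
#'
#' Computes the seven kinetic parameters of an alcoholic fermentation from a
#' cumulative CO2 curve:
#' \describe{
#'   \item{lp}{lag phase (h): first time CO2 release reaches 2 g/L;}
#'   \item{t35g, t50g, t80g}{time (h, minus `lp`) until 35, 50 and 80 g/L of
#'     CO2 have been released;}
#'   \item{V15_50, V50_80}{average rate (g/L/h) between the times at which 15%
#'     and 50% (resp. 50% and 80%) of the total CO2 has been released,
#'     multiplied by `sugar_factor` to express it as sugar consumption;}
#'   \item{co2max}{maximum CO2 released (g/L).}
#' }
#' Threshold crossings use linear interpolation on the grid; the first
#' crossing wins. A threshold never reached yields `NA` for that trait, and a
#' curve never reaching 2 g/L yields `NA` for `lp` and all `t*g` traits.
#'
#' @param curve data.frame with `time_h`, `co2_g_per_l`, normally the output
#'   of [smooth_curve()].
#' @param sugar_factor Stoichiometric sugar-per-CO2 factor applied to the
#'   phase rates. The default 2.045 converts the CO2 release rate to glucose
#'   consumption (180 g glucose -> 88 g CO2); use 1 for the CO2-native rate.
#' @param lag_threshold CO2 amount defining the lag phase (g/L, default 2).
#' @return One-row data.frame: `lp, t35g, t50g, t80g, V15_50, V50_80, co2max`.
#' @export
extract_traits <- function(curve, sugar_factor = 2.045, lag_threshold = 2) {
  stopifnot(all(c("time_h", "co2_g_per_l") %in% names(curve)),
            sugar_factor > 0)
  tm <- curve$time_h
  co2 <- curve$co2_g_per_l
  co2max <- max(co2)
  lp <- .first_crossing(tm, co2, lag_threshold)
  tg <- function(x) {
    if (is.na(lp)) return(NA_real_)
    tt <- .first_crossing(tm, co2, x)
    if (is.na(tt)) NA_real_ else tt - lp
  }
  phase_rate <- function(f0, f1) {
    ta <- .first_crossing(tm, co2, f0 * co2max)
    tb <- .first_crossing(tm, co2, f1 * co2max)
    if (is.na(ta) || is.na(tb) || tb <= ta) return(NA_real_)
    sugar_factor * (f1 - f0) * co2max / (tb - ta)
  }
  data.frame(
    lp = lp, t35g = tg(35), t50g = tg(50), t80g = tg(80),
    V15_50 = phase_rate(0.15, 0.50), V50_80 = phase_rate(0.50, 0.80),
    co2max = co2max
  )
}

#' Fit fermentation kinetics for a set of curves
#'
#' Smooths each sample's CO2 time series ([smooth_curve()]) and extracts the
#' seven kinetic traits ([extract_traits()]).
#'
#' @param curves data.frame with columns `sample_id`, `time_h`, `co2_g_per_l`
#'   (multiple samples stacked).
#' @param span Smoothing span (default 0.45).
#' @param sugar_factor See [extract_traits()].
#' @return A `kinetics_fit`: data.frame with one row per sample
#'   (`sample_id` + the seven traits), carrying the smoothed curves in
#'   attribute `"smoothed"`.
#' @export
fit_kinetics <- function(curves, span = 0.45, sugar_factor = 2.045) {
  stopifnot(all(c("sample_id", "time_h", "co2_g_per_l") %in% names(curves)))
  ids <- unique(curves$sample_id)
  sm <- vector("list", length(ids))
  rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    cv <- curves[curves$sample_id == ids[i], , drop = FALSE]
    cv <- cv[order(cv$time_h), , drop = FALSE]
    s <- smooth_curve(cv[, c("time_h", "co2_g_per_l")], span = span)
    s$sample_id <- ids[i]
    sm[[i]] <- s
    rows[[i]] <- cbind(
      data.frame(sample_id = ids[i], stringsAsFactors = FALSE),
      extract_traits(s, sugar_factor = sugar_factor)
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "smoothed") <- do.call(rbind, sm)
  attr(out, "span") <- span
  class(out) <- c("kinetics_fit", "data.frame")
  out
}

#' @export
print.kinetics_fit <- function(x, ...) {
  cat("Kinetic traits for", nrow(x), "fermentation(s), span =",
      attr(x, "span"), "\n")
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' @param x A `kinetics_fit`.
#' @param sample Sample ID to plot (default: first).
#' @param ... Passed to [graphics::plot()].
#' @rdname fit_kinetics
#' @export
plot.kinetics_fit <- function(x, sample = x$sample_id[1], ...) {
  sm <- attr(x, "smoothed")
  s <- sm[sm$sample_id == sample, ]
  graphics::plot(s$time_h, s$co2_g_per_l,
    type = "l", xlab = "time (h)",
    ylab = expression(CO[2] ~ "released (g/L)"), main = sample, ...
  )
  tr <- x[x$sample_id == sample, ]
  graphics::abline(h = 2, lty = 3)
  if (!is.na(tr$lp)) graphics::abline(v = tr$lp, lty = 2)
  invisible(x)
}
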
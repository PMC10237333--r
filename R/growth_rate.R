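## Specific growth rate from plate-reader OD600 curves: moving-average
## smoothing, sliding-window log-linear regression, and the tenth-fastest
## slope selection rule.

#' Construct a growth curve
#'
#' @param time_h measurement times, hours (strictly increasing).
#' @param od optical density readings (OD600).
#' @param blank medium blank OD; if `NULL`, estimated downstream as the
#'   minimum of the first three readings.
#' @param well optional well/condition identifier.
#' @return object of class `growth_curve`.
#' @export
growth_curve <- function(time_h, od, blank = NULL, well = NA_character_) {
  stopifnot(length(time_h) == length(od), all(diff(time_h) > 0),
            all(od >= 0))
  structure(list(time_h = time_h, od = od, blank = blank, well = well),
            class = "growth_curve")
}

#' @keywords internal
#' @noRd
resolve_blank <- function(curve) {
  curve$blank %||% min(curve$od[seq_len(min(3, length(curve$od)))])
}

#' Moving-average smoothing of a growth curve
#'
#' Centered moving average of the OD series; edges use shrunken (partial)
#' windows so the series length is preserved.
#'
#' @param curve a [growth_curve()].
#' @param window window length in points; odd, >= 1.
#' @return the smoothed [growth_curve()].
#' @export
smooth_curve <- function(curve, window = 5) {
  if (window < 1 || window %% 2 != 1) {
    stop("smoothing window must be an odd positive number of points")
  }
  if (window > length(curve$od)) stop("window longer than the series")
  curve$od <- zoo::rollapply(curve$od, window, mean, partial = TRUE)
  curve
}

#' Sliding-window specific growth rates
#'
#' For every contiguous window of `window` points, the least-squares slope
#' of `ln(OD - blank)` against time in hours: the specific growth rate over
#' that window. Points with non-positive blank-corrected OD are excluded
#' before windowing.
#'
#' @param curve a [growth_curve()].
#' @param window window length in points (>= 3).
#' @return data frame (t_start, t_mid, slope) of class `window_slopes`.
#' @export
window_slopes <- function(curve, window = 19) {
  stopifnot(window >= 3)
  blank <- resolve_blank(curve)
  odc <- curve$od - blank
  keep <- odc > 0
  t <- curve$time_h[keep]
  y <- log(odc[keep])
  if (length(y) < window) stop("fewer usable points than one full window")
  slopes <- window_ls_slopes(t, y, window)
  starts <- t[seq_along(slopes)]
  mids <- (t[seq_along(slopes)] + t[seq_along(slopes) + window - 1]) / 2
  structure(data.frame(t_start = starts, t_mid = mids, slope = slopes),
            class = c("window_slopes", "data.frame"))
}

#' Tenth-fastest-slope growth rate selection
#'
#' The determined growth rate is the tenth largest sliding-window slope, a
#' rank rule that suppresses outlier windows. With fewer than `rank`
#' windows, the smallest slope is returned with a warning.
#'
#' @param slopes numeric slopes or a `window_slopes` data frame.
#' @param rank rank of the selected slope (default 10).
#' @return selected specific growth rate, per hour.
#' @export
select_growth_rate <- function(slopes, rank = 10) {
  if (is.data.frame(slopes)) slopes <- slopes$slope
  if (length(slopes) == 0) stop("no slopes supplied")
  if (length(slopes) < rank) {
    warning("fewer than ", rank, " windows; selecting the slowest slope")
    rank <- length(slopes)
  }
  sort(slopes, decreasing = TRUE)[rank]
}

#' Full growth-rate estimation pipeline
#'
#' Moving-average smoothing, sliding-window log-linear regression, and
#' tenth-fastest-slope selection. The regression window length trades bias
#' against variance: a window much longer than the doubling time climbs the
#' logistic curve and biases the specific rate downward, while a short
#' window on a slow, low-density culture is dominated by read noise. With
#' `regression_window_min = NULL` (default) the window is therefore set
#' adaptively to about one doubling time (`ln 2` divided by a pilot rate
#' estimated with a 90-minute window, refined once, clamped to 90-300
#' minutes). A numeric value fixes the window instead. `log_od = FALSE`
#' switches the window regressions to plain blank-corrected OD for
#' comparison; rates are then not specific growth rates.
#'
#' @param curve a [growth_curve()].
#' @param smooth_window smoothing window, points.
#' @param regression_window_min regression window length in minutes, or
#'   `NULL` for the adaptive one-doubling window.
#' @param rank selection rank.
#' @param log_od regress on `ln(OD - blank)` (default) or plain OD.
#' @return object of class `growth_rate_result`: `rate` (per hour),
#'   `slopes`, `smooth_window`, `regression_window` (points), `blank`.
#' @export
estimate_growth_rate <- function(curve, smooth_window = 5,
                                 regression_window_min = NULL, rank = 10,
                                 log_od = TRUE) {
  dt_min <- stats::median(diff(curve$time_h)) * 60
  if (is.null(regression_window_min)) {
    regression_window_min <- 90
    for (pass in 1:2) {
      w <- max(3, round(regression_window_min / dt_min) + 1)
      pilot <- select_growth_rate(
        window_slopes(smooth_curve(curve, smooth_window), w)$slope, rank)
      if (pilot <= 0) break
      regression_window_min <- min(300, max(90, 60 * log(2) / pilot))
    }
  }
  window <- max(3, round(regression_window_min / dt_min) + 1)
  smoothed <- smooth_curve(curve, smooth_window)
  sl <- if (log_od) {
    window_slopes(smoothed, window)
  } else {
    blank <- resolve_blank(smoothed)
    odc <- smoothed$od - blank
    slopes <- window_ls_slopes(smoothed$time_h, odc, window)
    data.frame(t_start = smoothed$time_h[seq_along(slopes)],
               t_mid = NA_real_, slope = slopes)
  }
  structure(list(rate = select_growth_rate(sl$slope, rank), slopes = sl,
                 smooth_window = smooth_window, regression_window = window,
                 blank = resolve_blank(curve), well = curve$well,
                 log_od = log_od),
            class = "growth_rate_result")
}

#' @export
print.growth_rate_result <- function(x, ...) {
  cat(sprintf("Growth rate: %.4g %s (rank-10 of %d windows of %d points)\n",
              x$rate, if (x$log_od) "h^-1" else "OD/h",
              nrow(x$slopes), x$regression_window))
  invisible(x)
}
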
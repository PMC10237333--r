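## Ratiometric quantification of donor/acceptor fluorescence trace tables:
## background subtraction, spectral bleedthrough correction, FRET ratios,
## baseline normalization and the per-cell response features.

#' Subtract per-frame background from a trace table
#'
#' If `background_donor` / `background_acceptor` columns are present they are
#' subtracted from the matching channel; otherwise the table is returned
#' unchanged with a notice. Negative corrected intensities are permitted and
#' counted in the `n_negative` attribute.
#'
#' @param table a fluorescence trace table (see [read_trace_table()]).
#' @return the corrected table (background columns dropped).
#' @export
subtract_background <- function(table) {
  has_bg <- all(c("background_donor", "background_acceptor") %in% names(table))
  if (!has_bg) {
    message("no background columns present; table passed through unchanged")
    return(table)
  }
  table$donor <- table$donor - table$background_donor
  table$acceptor <- table$acceptor - table$background_acceptor
  n_neg <- sum(table$donor < 0) + sum(table$acceptor < 0)
  if (n_neg > 0) {
    message(n_neg, " channel values negative after background subtraction")
  }
  table$background_donor <- NULL
  table$background_acceptor <- NULL
  attr(table, "n_negative") <- n_neg
  table
}

#' Correct donor bleedthrough into the acceptor channel
#'
#' A fixed fraction `beta` of the donor emission is detected in the acceptor
#' channel; the corrected acceptor signal is `acceptor - beta * donor`. The
#' default of 0.40 matches the microscope filter set this analysis was
#' developed for.
#'
#' @param donor,acceptor channel intensities, arbitrary units (vectorized).
#' @param beta spillover fraction in `[0, 1)`.
#' @return corrected acceptor intensities.
#' @export
correct_bleedthrough <- function(donor, acceptor, beta = 0.40) {
  if (!is.numeric(beta) || length(beta) != 1 || beta < 0 || beta >= 1) {
    stop("beta must be a single value in [0, 1)")
  }
  acceptor - beta * donor
}

#' Compute per-cell FRET ratio traces
#'
#' The FRET ratio is the bleedthrough-corrected acceptor emission divided by
#' the donor emission, per frame. Frames with non-positive donor signal are
#' dropped and counted; cells losing all frames are excluded and reported.
#'
#' @param table trace table after background subtraction.
#' @param beta bleedthrough fraction passed to [correct_bleedthrough()].
#' @return a data frame (cell_id, time_min, ratio) of class `ratio_traces`,
#'   with attributes `qc` (dropped-frame and dropped-cell counts) and
#'   `dropped_cells`.
#' @export
compute_ratio <- function(table, beta = 0.40) {
  corrected <- correct_bleedthrough(table$donor, table$acceptor, beta)
  keep <- table$donor > 0
  n_dropped <- sum(!keep)
  out <- data.frame(cell_id = table$cell_id[keep],
                    time_min = table$time_min[keep],
                    ratio = corrected[keep] / table$donor[keep],
                    stringsAsFactors = FALSE)
  dropped_cells <- setdiff(unique(table$cell_id), unique(out$cell_id))
  if (length(dropped_cells) > 0) {
    warning(length(dropped_cells),
            " cell(s) lost all frames (donor <= 0) and were excluded")
  }
  attr(out, "qc") <- list(n_frames_dropped = n_dropped,
                          n_cells_dropped = length(dropped_cells))
  attr(out, "dropped_cells") <- dropped_cells
  class(out) <- c("ratio_traces", "data.frame")
  out
}

#' Baseline-normalize FRET ratio traces
#'
#' Each cell's ratio trace is divided by its mean ratio over the baseline
#' window, so 1 corresponds to the resting state. The default window is all
#' pre-perturbation frames (`time_min < 0`).
#'
#' @param traces a `ratio_traces` data frame from [compute_ratio()].
#' @param baseline_window `c(t_start, t_end)` in minutes (frames with
#'   `t_start <= time_min < t_end` are baseline), or `NULL` for all
#'   `time_min < 0`.
#' @return data frame (cell_id, time_min, normalized_ratio) of class
#'   `normalized_traces`, with a `baseline` attribute giving each cell's
#'   baseline mean ratio (the basal, non-normalized FRET level).
#' @export
normalize_baseline <- function(traces, baseline_window = NULL) {
  if (is.null(baseline_window)) baseline_window <- c(-Inf, 0)
  in_base <- traces$time_min >= baseline_window[1] &
    traces$time_min < baseline_window[2]
  if (!any(in_base)) stop("no frames fall inside the baseline window")
  base_mean <- tapply(traces$ratio[in_base], traces$cell_id[in_base], mean)
  bad <- setdiff(unique(traces$cell_id), names(base_mean))
  if (length(bad) > 0) {
    stop("cell(s) without baseline frames: ", paste(bad, collapse = ", "))
  }
  out <- data.frame(cell_id = traces$cell_id,
                    time_min = traces$time_min,
                    normalized_ratio =
                      traces$ratio / unname(base_mean[traces$cell_id]),
                    stringsAsFactors = FALSE)
  attr(out, "baseline") <- data.frame(cell_id = names(base_mean),
                                      baseline_mean = as.numeric(base_mean),
                                      stringsAsFactors = FALSE)
  attr(out, "baseline_window") <- baseline_window
  class(out) <- c("normalized_traces", "data.frame")
  out
}

#' Final FRET level of a trace
#'
#' The mean of the last three normalized values of the trace.
#'
#' @param values normalized ratio values in time order.
#' @return the mean of the final three values.
#' @export
final_fret <- function(values) {
  n <- length(values)
  if (n < 3) stop("final_fret requires at least 3 frames")
  mean(values[(n - 2):n])
}

#' Change in normalized FRET at an evaluation time
#'
#' The normalized ratio at the frame nearest `t_eval` (no interpolation),
#' minus 1. `t_eval = "end"` evaluates at the last recorded frame; a numeric
#' `t_eval` beyond the trace is clipped to the last frame with a notice.
#'
#' @param times frame times, minutes.
#' @param values normalized ratios.
#' @param t_eval evaluation time in minutes, or `"end"`.
#' @return delta normalized FRET (0 for a resting cell).
#' @export
delta_normalized_fret <- function(times, values, t_eval = 50) {
  if (identical(t_eval, "end")) {
    return(values[length(values)] - 1)
  }
  if (t_eval > max(times)) {
    message("t_eval beyond trace end; clipped to last frame")
    t_eval <- max(times)
  }
  values[which.min(abs(times - t_eval))] - 1
}

#' Maximal windowed slope of a normalized trace
#'
#' The maximum over all contiguous windows of `window` frames of the
#' least-squares slope of normalized ratio against time (per minute).
#' Evaluated on post-perturbation frames (`time_min >= 0`) only, since the
#' baseline is flat by construction.
#'
#' @param times frame times, minutes.
#' @param values normalized ratios.
#' @param window window length in frames (>= 2).
#' @param post_only restrict to `times >= 0` (default).
#' @return maximal slope, normalized FRET per minute.
#' @export
max_slope <- function(times, values, window = 3, post_only = TRUE) {
  if (window < 2) stop("window must be at least 2 frames")
  if (post_only) {
    keep <- times >= 0
    times <- times[keep]; values <- values[keep]
  }
  if (length(values) < window) {
    stop("fewer frames (", length(values), ") than the slope window")
  }
  max_slope_vector(times, values, window)
}

## Vectorized all-windows least-squares slopes; internal workhorse shared
## with the simulator's rise-rate calibration.
#' @keywords internal
#' @noRd
window_ls_slopes <- function(times, values, window) {
  tm <- stats::embed(times, window)[, window:1, drop = FALSE]
  ym <- stats::embed(values, window)[, window:1, drop = FALSE]
  tc <- tm - rowMeans(tm)
  rowSums(tc * ym) / rowSums(tc^2)
}

#' @keywords internal
#' @noRd
max_slope_vector <- function(times, values, window) {
  max(window_ls_slopes(times, values, window))
}

#' Sensor expression proxy
#'
#' Mean over baseline frames of donor plus bleedthrough-corrected acceptor
#' emission; with the simulator's emission partition this equals the cell's
#' expression level exactly in the noise-free case.
#'
#' @param donor,corrected_acceptor baseline-frame intensities.
#' @return expression proxy, arbitrary units.
#' @export
expression_proxy <- function(donor, corrected_acceptor) {
  if (length(donor) == 0) stop("at least one baseline frame required")
  mean(donor + corrected_acceptor)
}

#' pHluorin excitation ratio
#'
#' Ratio of emission under 380-420 nm excitation over emission under
#' 460-500 nm excitation (vectorized).
#'
#' @param f_405band fluorescence at 380-420 nm excitation.
#' @param f_488band fluorescence at 460-500 nm excitation.
#' @return the excitation ratio.
#' @export
phluorin_ratio <- function(f_405band, f_488band) {
  if (any(f_488band == 0)) stop("zero denominator in pHluorin ratio")
  f_405band / f_488band
}

#' Run the full ratiometric pipeline on a trace table
#'
#' Background subtraction, bleedthrough correction, per-cell FRET ratios,
#' baseline normalization, and per-cell response features: basal (raw) FRET
#' level, final normalized FRET (mean of last 3 frames), delta normalized
#' FRET at `t_eval`, maximal windowed slope, and the expression proxy.
#'
#' @param table fluorescence trace table.
#' @param beta bleedthrough fraction.
#' @param baseline_window see [normalize_baseline()].
#' @param t_eval evaluation time for [delta_normalized_fret()] (minutes or
#'   `"end"`).
#' @param slope_window window for [max_slope()], frames.
#' @return list of class `fret_pipeline` with `ratios`, `normalized`,
#'   `features` (one row per cell) and `qc`.
#' @export
fret_pipeline <- function(table, beta = 0.40, baseline_window = NULL,
                          t_eval = 50, slope_window = 3) {
  corrected <- suppressMessages(subtract_background(table))
  ratios <- compute_ratio(corrected, beta = beta)
  normalized <- normalize_baseline(ratios, baseline_window)
  baseline <- attr(normalized, "baseline")
  bw <- attr(normalized, "baseline_window")

  corr_acc <- correct_bleedthrough(corrected$donor, corrected$acceptor, beta)
  in_base <- corrected$time_min >= bw[1] & corrected$time_min < bw[2] &
    corrected$donor > 0
  expr <- tapply((corrected$donor + corr_acc)[in_base],
                 corrected$cell_id[in_base], mean)

  split_norm <- split(normalized[c("time_min", "normalized_ratio")],
                      normalized$cell_id)
  feats <- lapply(names(split_norm), function(id) {
    tr <- split_norm[[id]]
    data.frame(
      cell_id = id,
      basal_fret = baseline$baseline_mean[match(id, baseline$cell_id)],
      final_fret = final_fret(tr$normalized_ratio),
      delta_norm_fret = delta_normalized_fret(tr$time_min,
                                              tr$normalized_ratio, t_eval),
      max_slope = max_slope(tr$time_min, tr$normalized_ratio, slope_window),
      expression_proxy = unname(expr[id]),
      stringsAsFactors = FALSE
    )
  })
  features <- do.call(rbind, feats)
  rownames(features) <- NULL
  structure(list(ratios = ratios, normalized = normalized,
                 features = features, qc = attr(ratios, "qc")),
            class = "fret_pipeline")
}
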
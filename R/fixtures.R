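## Reference simulation designs: the three-class mannose-transition fixture
## and the grower/non-grower fixture. Class means are set to the published
## cluster and group summaries this pipeline is validated against; rise
## rates are calibrated so the designed maximal-slope features come out at
## their target values on the design's acquisition grid (see
## calibrate_rise_rate).

#' Three-class mannose-transition trace design
#'
#' Emulates the heterogeneous single-cell response to a mannose pulse:
#' an initial dip in FRET followed by three discrete outcomes. Class design
#' values (final normalized FRET): sustained switchers 1.25, weak responders
#' 1.08, decliners 0.90; the weak-responder rise rate is calibrated so the
#' class's expected maximal-slope feature is 0.26 normalized FRET per
#' minute. Grower probabilities per class follow the observed pattern that
#' cells reaching higher FRET states tend to resume growth.
#'
#' @param n_cells number of cells (default 200).
#' @param seed integer seed.
#' @param frame_interval acquisition interval, minutes.
#' @param slope_window slope-feature window (frames) the design is
#'   calibrated for.
#' @return a [trace_design()].
#' @export
mannose_design <- function(n_cells = 200, seed = 1L, frame_interval = 0.5,
                           slope_window = 3) {
  mcv <- 0.02

  ## amplitudes solved so the designed end-of-timelapse (50 min) normalized
  ## value is exact: end = 1 + A * (1 - exp(-k_rise * (50 - delay))) for the
  ## sustained classes
  switcher <- response_class("switcher", r0 = 1.00,
                             amplitude = 0.25 / (1 - exp(-0.15 * 45)),
                             rise_rate = 0.15, delay = 5,
                             sustained_fraction = 1, dip_depth = 0.08,
                             dip_rate = 0.25, cv_r0 = 0.08,
                             cv_amplitude = 0.12, grower_prob = 0.8)
  responder <- response_class("responder", r0 = 0.95, amplitude = 0.45,
                              rise_rate = 1, delay = 2,
                              sustained_fraction = 0.08 / 0.45,
                              decay_rate = 0.15, dip_depth = 0.08,
                              dip_rate = 0.25, cv_r0 = 0.08,
                              cv_amplitude = 0.12, grower_prob = 0.9)
  decliner <- response_class("decliner", r0 = 0.88,
                             amplitude = -0.10 / (1 - exp(-0.08 * 50)),
                             rise_rate = 0.08, delay = 0,
                             sustained_fraction = 1, dip_depth = 0.05,
                             dip_rate = 0.25, cv_r0 = 0.08,
                             cv_amplitude = 0.12, grower_prob = 0.1)
  responder$rise_rate <- calibrate_rise_rate(
    0.26, responder, frame_interval = frame_interval, window = slope_window,
    horizon = 50, channel_cv = mcv, beta = 0.40,
    baseline_frames = round(10 / frame_interval))

  trace_design(list(switcher, responder, decliner),
               proportions = c(0.35, 0.35, 0.30), n_cells = n_cells,
               frame_interval = frame_interval, baseline_duration = 10,
               total_duration = 60, multiplicative_noise_cv = mcv,
               allocation = "exact", seed = seed)
}

#' Grower / non-grower trace design
#'
#' Emulates the growth-linked response heterogeneity after a mannose
#' transition followed for two hours: growing cells have a lower basal FRET
#' ratio (0.84 +/- 0.16 vs 0.94 +/- 0.16), a larger normalized FRET change
#' at the end of the time lapse (0.20 +/- 0.09 vs 0.07 +/- 0.20) and a
#' faster maximal slope (designed 0.12 vs 0.09 per minute, set by rise-rate
#' calibration on the design's acquisition grid).
#'
#' @param n_per_group cells per group (default 50).
#' @param seed integer seed.
#' @param frame_interval acquisition interval, minutes.
#' @param slope_window slope-feature window (frames).
#' @return a [trace_design()].
#' @export
grower_design <- function(n_per_group = 50, seed = 1L, frame_interval = 0.75,
                          slope_window = 3) {
  mcv <- 0.02

  grower <- response_class("grower", r0 = 0.84, amplitude = 0.30,
                           rise_rate = 1, delay = 2,
                           sustained_fraction = 0.20 / 0.30,
                           decay_rate = 0.08, cv_r0 = 0.16 / 0.84,
                           cv_amplitude = 0.45, grower_prob = 1)
  nongrower <- response_class("nongrower", r0 = 0.94, amplitude = 0.07,
                              rise_rate = 1, delay = 2,
                              sustained_fraction = 1,
                              cv_r0 = 0.16 / 0.94,
                              cv_amplitude = 0.20 / 0.07, grower_prob = 0)
  grower$rise_rate <- calibrate_rise_rate(
    0.12, grower, frame_interval = frame_interval, window = slope_window,
    horizon = 120, channel_cv = mcv, beta = 0.40,
    baseline_frames = round(10 / frame_interval))

  ## the non-grower slope is largely noise-limited, so its calibrated rise
  ## rate is slow and the response need not saturate within the time lapse;
  ## amplitude and rise rate are solved jointly so the designed end-of-lapse
  ## delta (0.07) and the designed slope (0.09) both hold
  for (i in 1:3) {
    nongrower$rise_rate <- calibrate_rise_rate(
      0.09, nongrower, frame_interval = frame_interval, window = slope_window,
      horizon = 120, channel_cv = mcv, beta = 0.40,
      baseline_frames = round(10 / frame_interval))
    reached <- 1 - exp(-nongrower$rise_rate * (120 - nongrower$delay))
    nongrower$amplitude <- 0.07 / reached
    nongrower$cv_amplitude <- 0.20 / 0.07
  }

  trace_design(list(grower, nongrower), proportions = c(0.5, 0.5),
               n_cells = 2 * n_per_group, frame_interval = frame_interval,
               baseline_duration = 10, total_duration = 130,
               multiplicative_noise_cv = mcv, allocation = "exact",
               seed = seed)
}
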
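## Simulators for the non-microscopy inputs: dose-response end points,
## plate-reader growth curves, and flow-cytometry experiments.

#' Simulate per-cell final FRET responses across a dose series
#'
#' Final normalized FRET per cell follows the single-site saturation curve
#' `1 + max_response * c / (K05 + c)` plus Gaussian noise.
#'
#' @param K05 half-saturation concentration, mM (> 0).
#' @param max_response maximal change in normalized FRET.
#' @param concentrations dose series, mM (>= 0).
#' @param n_per_conc cells per concentration.
#' @param noise_sd per-cell Gaussian noise SD.
#' @param seed integer seed.
#' @return data frame (concentration, final_norm_fret).
#' @export
simulate_dose_response <- function(K05 = 0.24, max_response = 0.24,
                                   concentrations = c(0, 0.1, 0.25, 1, 5, 25, 100),
                                   n_per_conc = 20, noise_sd = 0.02,
                                   seed = 1L) {
  stopifnot(K05 > 0)
  if (any(concentrations < 0)) stop("concentrations must be non-negative")
  set.seed(seed)
  conc <- rep(concentrations, each = n_per_conc)
  resp <- 1 + max_response * conc / (K05 + conc) +
    stats::rnorm(length(conc), 0, noise_sd)
  data.frame(concentration = conc, final_norm_fret = resp)
}

#' Simulate a plate-reader growth curve
#'
#' Blank plus logistic growth starting from `od0` after a lag, with Gaussian
#' optical-density noise. In the early phase (`od << carrying_capacity`) the
#' blank-corrected curve is exponential with specific rate `mu`.
#'
#' @param mu specific growth rate, per hour (> 0).
#' @param od0 inoculum optical density.
#' @param carrying_capacity logistic ceiling, OD units.
#' @param lag lag time before growth starts, hours.
#' @param blank medium blank OD.
#' @param noise_sd OD noise SD.
#' @param interval sampling interval, minutes.
#' @param duration total assay length, hours.
#' @param seed integer seed.
#' @return a [growth_curve()] with the true blank attached.
#' @export
simulate_growth_curve <- function(mu = 0.36, od0 = 0.04,
                                  carrying_capacity = 1.4, lag = 1.5,
                                  blank = 0.04, noise_sd = 0.005,
                                  interval = 5, duration = 24, seed = 1L) {
  stopifnot(mu > 0, od0 < carrying_capacity, duration > 0)
  set.seed(seed)
  time_h <- seq(0, duration, by = interval / 60)
  t_eff <- pmax(time_h - lag, 0)
  K <- carrying_capacity
  od_true <- K * od0 * exp(mu * t_eff) / (K + od0 * (exp(mu * t_eff) - 1))
  od <- blank + od_true + stats::rnorm(length(time_h), 0, noise_sd)
  growth_curve(time_h, od, blank = blank)
}

#' Define a flow-cytometry simulation design
#'
#' Per-strain event models share the trace simulator's emission partition:
#' for a sensor-bearing strain with true FRET ratio `R` and expression `S`,
#' the noise-free donor channel is `S / (1 + R)` and the FRET channel is
#' `S * R / (1 + R) + beta * donor`. The direct-acceptor channel (acceptor
#' excited directly) is proportional to expression. Empty-plasmid events
#' carry background only; donor-only events carry donor signal whose only
#' FRET-channel content is bleedthrough. A stated fraction of events
#' saturates the scatter channels.
#'
#' @param conditions condition (carbon source) names.
#' @param true_ratio named per-condition kinase-dependent (activity) ratio
#'   of the sensor.
#' @param nr_ratio named per-condition kinase-independent artifact ratio:
#'   the non-responsive sensor reads `nr_ratio` and the responsive sensor
#'   reads `true_ratio * nr_ratio`, so dividing condition-matched medians
#'   removes the artifact.
#' @param n_events events per strain x condition.
#' @param expression_mean,expression_cv log-normal expression of
#'   sensor-bearing strains, arbitrary units.
#' @param da_scale direct-acceptor channel counts per expression unit.
#' @param background_mean,background_cv log-normal per-channel background
#'   (cellular autofluorescence), applied to every strain.
#' @param beta donor bleedthrough fraction into the FRET channel.
#' @param noise_cv multiplicative channel noise CV.
#' @param saturating_fraction fraction of events with saturating scatter.
#' @param saturation_value scatter saturation level (instrument full scale).
#' @param seed integer seed.
#' @return an object of class `flow_design`.
#' @export
flow_design <- function(conditions = c("ethanol", "galactose", "glucose", "mannose"),
                        true_ratio = c(ethanol = 1.0, galactose = 1.0,
                                       glucose = 1.0, mannose = 1.0),
                        nr_ratio = c(ethanol = 0.95, galactose = 1.05,
                                     glucose = 1.10, mannose = 1.05),
                        n_events = 10000, expression_mean = 20000,
                        expression_cv = 0.6, da_scale = 0.5,
                        background_mean = 300, background_cv = 0.4,
                        beta = 0.40, noise_cv = 0.05,
                        saturating_fraction = 0.05,
                        saturation_value = 2^24 - 1, seed = 1L) {
  stopifnot(all(conditions %in% names(true_ratio)),
            all(conditions %in% names(nr_ratio)),
            beta >= 0, beta < 1,
            saturating_fraction >= 0, saturating_fraction < 1)
  structure(list(conditions = conditions, true_ratio = true_ratio,
                 nr_ratio = nr_ratio, n_events = as.integer(n_events),
                 expression_mean = expression_mean,
                 expression_cv = expression_cv, da_scale = da_scale,
                 background_mean = background_mean,
                 background_cv = background_cv, beta = beta,
                 noise_cv = noise_cv,
                 saturating_fraction = saturating_fraction,
                 saturation_value = saturation_value,
                 seed = as.integer(seed)),
            class = "flow_design")
}

#' Simulate a flow-cytometry FRET experiment
#'
#' Generates events for the sensor strain, the non-responsive control, the
#' empty-plasmid background strain and the donor-only (eCFP) strain used for
#' bleedthrough estimation.
#'
#' @param design a [flow_design()].
#' @return data frame of events (fsc, ssc, donor_ch, fret_ch,
#'   direct_acceptor_ch, strain, condition) of class `flow_events`.
#' @export
simulate_flow_experiment <- function(design) {
  stopifnot(inherits(design, "flow_design"))
  set.seed(design$seed)

  bg <- function(n) rlnorm_mean_cv(n, design$background_mean,
                                   design$background_cv)
  noisy <- function(x) x * (1 + design$noise_cv * stats::rnorm(length(x)))

  make_strain <- function(strain, condition, ratio, has_sensor, donor_only) {
    n <- design$n_events
    fsc <- rlnorm_mean_cv(n, 5e5, 0.4)
    ssc <- rlnorm_mean_cv(n, 3e5, 0.5)
    sat <- stats::runif(n) < design$saturating_fraction
    fsc[sat] <- design$saturation_value
    donor <- bg(n); fret <- bg(n); da <- bg(n)
    if (has_sensor || donor_only) {
      S <- rlnorm_mean_cv(n, design$expression_mean, design$expression_cv)
      if (donor_only) {
        D <- S; Y <- 0; da_sig <- 0
      } else {
        D <- S / (1 + ratio); Y <- S * ratio / (1 + ratio)
        da_sig <- design$da_scale * S
      }
      donor <- donor + noisy(D)
      fret <- fret + noisy(Y) + design$beta * D
      da <- da + noisy(da_sig)
    }
    data.frame(fsc = fsc, ssc = ssc, donor_ch = donor, fret_ch = fret,
               direct_acceptor_ch = da, strain = strain,
               condition = condition, stringsAsFactors = FALSE)
  }

  out <- list()
  for (cond in design$conditions) {
    out[[length(out) + 1]] <-
      make_strain("sensor", cond,
                  design$true_ratio[[cond]] * design$nr_ratio[[cond]],
                  TRUE, FALSE)
    out[[length(out) + 1]] <-
      make_strain("sensor_NR", cond, design$nr_ratio[[cond]], TRUE, FALSE)
  }
  out[[length(out) + 1]] <- make_strain("empty", "none", NA, FALSE, FALSE)
  out[[length(out) + 1]] <- make_strain("donor_only", "none", NA, FALSE, TRUE)
  events <- do.call(rbind, out)
  rownames(events) <- NULL
  class(events) <- c("flow_events", "data.frame")
  attr(events, "design") <- design
  events
}
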
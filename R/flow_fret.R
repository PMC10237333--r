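## Population FRET levels from flow-cytometry event tables: scatter
## saturation filter, empty-plasmid median subtraction, donor-only
## bleedthrough estimation, minimum-acceptor gate, per-condition median
## ratios, and non-responsive-sensor correction with reference
## normalization.

FLUOR_CHANNELS <- c("donor_ch", "fret_ch", "direct_acceptor_ch")

#' Remove events with saturating scatter
#'
#' @param events flow event table.
#' @param saturation_value instrument full-scale value; events with forward
#'   or side scatter at or above it are removed.
#' @return filtered events with an `n_removed` attribute.
#' @export
filter_saturating <- function(events, saturation_value) {
  stopifnot(saturation_value > 0)
  keep <- events$fsc < saturation_value & events$ssc < saturation_value
  out <- events[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Subtract empty-plasmid control medians
#'
#' Per fluorescence channel, the median of the empty-plasmid (background)
#' strain is subtracted from every event.
#'
#' @param events flow event table (all strains).
#' @param empty_events empty-plasmid events (defaults to the
#'   `strain == "empty"` rows of `events`).
#' @return corrected events with a `control_medians` attribute.
#' @export
subtract_control_median <- function(events, empty_events = NULL) {
  empty_events <- empty_events %||% events[events$strain == "empty", ,
                                           drop = FALSE]
  if (nrow(empty_events) == 0) stop("empty-plasmid control events missing")
  med <- vapply(FLUOR_CHANNELS, function(ch) stats::median(empty_events[[ch]]),
                numeric(1))
  for (ch in FLUOR_CHANNELS) events[[ch]] <- events[[ch]] - med[[ch]]
  attr(events, "control_medians") <- med
  events
}

#' Estimate donor bleedthrough from the donor-only strain
#'
#' The bleedthrough fraction is the median over donor-only (eCFP) events of
#' the FRET-channel to donor-channel ratio, computed after control
#' subtraction.
#'
#' @param donor_only_events donor-only events after control subtraction.
#' @param min_events minimum usable events (donor > 0).
#' @return bleedthrough fraction beta.
#' @export
estimate_bleedthrough_flow <- function(donor_only_events, min_events = 100) {
  ok <- donor_only_events$donor_ch > 0
  if (sum(ok) < min_events) {
    stop("need >= ", min_events, " donor-only events with positive donor")
  }
  stats::median(donor_only_events$fret_ch[ok] /
                  donor_only_events$donor_ch[ok])
}

#' Minimum acceptor-fluorescence gate
#'
#' Keeps events whose direct-acceptor fluorescence is at least `threshold`
#' (inclusive), removing cells with too little sensor to quantify.
#'
#' @param events flow event table.
#' @param threshold gate level, arbitrary units.
#' @return gated events with an `n_removed` attribute.
#' @export
gate_min_acceptor <- function(events, threshold = 2500) {
  stopifnot(threshold >= 0)
  keep <- events$direct_acceptor_ch >= threshold
  out <- events[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Per-condition median FRET ratios
#'
#' Per event, ratio = (fret - beta * donor) / donor; per strain x condition,
#' the median over events. Events with non-positive donor are dropped.
#'
#' @param events gated, control-subtracted events.
#' @param beta bleedthrough fraction.
#' @return data frame (strain, condition, median_ratio, n).
#' @export
condition_ratios <- function(events, beta) {
  ok <- events$donor_ch > 0
  events <- events[ok, , drop = FALSE]
  ratio <- (events$fret_ch - beta * events$donor_ch) / events$donor_ch
  key <- interaction(events$strain, events$condition, drop = TRUE)
  med <- tapply(ratio, key, stats::median)
  n <- tapply(ratio, key, length)
  parts <- do.call(rbind, strsplit(names(med), ".", fixed = TRUE))
  out <- data.frame(strain = parts[, 1], condition = parts[, 2],
                    median_ratio = as.numeric(med), n = as.integer(n),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Non-responsive-sensor correction and reference normalization
#'
#' Corrects each condition's sensor median ratio for kinase-independent
#' signal using the matched non-responsive sensor, then normalizes to a
#' reference condition. The default correction divides the sensor median by
#' the NR median (preserving the ratio scale); a subtraction variant is
#' available.
#'
#' @param ratios data frame from [condition_ratios()] containing `sensor`
#'   and `sensor_NR` rows for every condition.
#' @param reference_condition condition whose normalized level is 1.
#' @param variant `"divide"` (default) or `"subtract"`.
#' @return data frame (condition, sensor_median, nr_median, corrected,
#'   normalized) of class `flow_fret_result`.
#' @export
nr_correct_and_normalize <- function(ratios, reference_condition,
                                     variant = c("divide", "subtract")) {
  variant <- match.arg(variant)
  sens <- ratios[ratios$strain == "sensor", , drop = FALSE]
  nr <- ratios[ratios$strain == "sensor_NR", , drop = FALSE]
  conditions <- sens$condition
  if (!all(conditions %in% nr$condition)) {
    stop("non-responsive sensor missing for condition(s): ",
         paste(setdiff(conditions, nr$condition), collapse = ", "))
  }
  if (!reference_condition %in% conditions) {
    stop("reference condition not measured: ", reference_condition)
  }
  nr_med <- nr$median_ratio[match(conditions, nr$condition)]
  corrected <- if (variant == "divide") {
    sens$median_ratio / nr_med
  } else {
    sens$median_ratio - nr_med
  }
  ref <- corrected[conditions == reference_condition]
  normalized <- if (variant == "divide") corrected / ref else corrected - ref + 1
  out <- data.frame(condition = conditions, sensor_median = sens$median_ratio,
                    nr_median = nr_med, corrected = corrected,
                    normalized = normalized, stringsAsFactors = FALSE)
  class(out) <- c("flow_fret_result", "data.frame")
  attr(out, "variant") <- variant
  attr(out, "reference_condition") <- reference_condition
  out
}

#' Full flow-cytometry FRET pipeline
#'
#' Scatter saturation filter, empty-plasmid median subtraction, donor-only
#' bleedthrough estimation, minimum-acceptor gate, per-condition median
#' ratios, NR correction and reference normalization. Event counts surviving
#' each gate are recorded.
#'
#' @param events flow event table with strain/condition columns (must
#'   include `empty` and `donor_only` strains).
#' @param saturation_value scatter full-scale value.
#' @param acceptor_gate minimum direct-acceptor fluorescence.
#' @param reference_condition condition normalized to 1.
#' @param variant NR-correction variant, see [nr_correct_and_normalize()].
#' @return list of class `flow_pipeline`: `result`, `ratios`, `beta`,
#'   `gate_counts` (events surviving each step), `control_medians`.
#' @export
flow_pipeline <- function(events, saturation_value, acceptor_gate = 2500,
                          reference_condition = "glucose",
                          variant = c("divide", "subtract")) {
  required <- c("empty", "donor_only")
  missing_strains <- setdiff(required, unique(events$strain))
  if (length(missing_strains) > 0) {
    stop("control strain(s) missing: ", paste(missing_strains, collapse = ", "))
  }
  counts <- c(input = nrow(events))
  ev <- filter_saturating(events, saturation_value)
  if (nrow(ev) == 0) stop("all events removed by the saturation filter")
  counts["after_saturation"] <- nrow(ev)
  ev <- subtract_control_median(ev)
  control_medians <- attr(ev, "control_medians")
  beta <- estimate_bleedthrough_flow(ev[ev$strain == "donor_only", ,
                                        drop = FALSE])
  sensors <- ev[ev$strain %in% c("sensor", "sensor_NR"), , drop = FALSE]
  counts["sensor_strains"] <- nrow(sensors)
  gated <- gate_min_acceptor(sensors, acceptor_gate)
  counts["after_acceptor_gate"] <- nrow(gated)
  ratios <- condition_ratios(gated, beta)
  result <- nr_correct_and_normalize(ratios, reference_condition, variant)
  structure(list(result = result, ratios = ratios, beta = beta,
                 gate_counts = counts, control_medians = control_medians),
            class = "flow_pipeline")
}
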
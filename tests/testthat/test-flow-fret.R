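noise_free_flow <- function(true_ratio = 1.0, n = 2000, background = 0,
                            seed = 1) {
  flow_design(conditions = "glucose",
              true_ratio = c(glucose = true_ratio),
              nr_ratio = c(glucose = 1.0),
              n_events = n, expression_cv = 0.3,
              background_mean = max(background, 1e-9), background_cv = 0,
              noise_cv = 0, saturating_fraction = 0, seed = seed)
}

test_that("the saturation filter removes the simulated saturating fraction", {
  des <- flow_design(n_events = 10000, saturating_fraction = 0.05, seed = 3)
  ev <- simulate_flow_experiment(des)
  kept <- filter_saturating(ev, des$saturation_value)
  frac <- attr(kept, "n_removed") / nrow(ev)
  se <- sqrt(0.05 * 0.95 / nrow(ev))
  expect_lt(abs(frac - 0.05), 3 * se)
  # no saturating events: identity
  clean <- simulate_flow_experiment(
    flow_design(n_events = 500, saturating_fraction = 0, seed = 1))
  expect_equal(nrow(filter_saturating(clean, 2^24 - 1)), nrow(clean))
})

test_that("control-median subtraction shifts channels by the empty medians", {
  ev <- data.frame(fsc = 1, ssc = 1, donor_ch = c(1000, 100),
                   fret_ch = c(500, 50), direct_acceptor_ch = c(800, 80),
                   strain = c("sensor", "empty"), condition = "c1")
  out <- subtract_control_median(ev)
  expect_equal(out$donor_ch, c(900, 0))
  expect_equal(out$fret_ch, c(450, 0))
  expect_error(subtract_control_median(ev[1, ]), "control events missing")
  # zero-median control: identity
  ev0 <- ev; ev0[ev0$strain == "empty", 3:5] <- 0
  expect_equal(subtract_control_median(ev0)$donor_ch[1], 1000)
})

test_that("donor-only events recover the bleedthrough fraction exactly at zero noise", {
  ev <- simulate_flow_experiment(noise_free_flow(background = 200))
  ev <- subtract_control_median(ev)
  d <- ev[ev$strain == "donor_only", ]
  expect_equal(estimate_bleedthrough_flow(d), 0.40, tolerance = 1e-12)
  # fret channel identically zero gives beta 0
  d0 <- d; d0$fret_ch <- 0
  expect_equal(estimate_bleedthrough_flow(d0), 0)
  expect_error(estimate_bleedthrough_flow(d[1:10, ]), ">= 100")
})

test_that("noisy bleedthrough estimation stays within 0.01 of truth", {
  des <- flow_design(n_events = 10000, noise_cv = 0.05, seed = 11)
  ev <- subtract_control_median(simulate_flow_experiment(des))
  b <- estimate_bleedthrough_flow(ev[ev$strain == "donor_only", ])
  expect_lt(abs(b - 0.40), 0.01)
})

test_that("the acceptor gate is inclusive and matches the analytic tail", {
  ev <- data.frame(fsc = 1, ssc = 1, donor_ch = 1, fret_ch = 1,
                   direct_acceptor_ch = c(2499, 2500, 2501),
                   strain = "sensor", condition = "c")
  kept <- gate_min_acceptor(ev, 2500)
  expect_equal(kept$direct_acceptor_ch, c(2500, 2501))
  expect_equal(nrow(gate_min_acceptor(ev, 0)), 3)
  # analytic log-normal tail for the simulated expression distribution
  des <- noise_free_flow(n = 20000, seed = 5)
  evs <- simulate_flow_experiment(des)
  sens <- evs[evs$strain == "sensor", ]
  gated <- gate_min_acceptor(sens, 2500)
  sdlog <- sqrt(log(1 + des$expression_cv^2))
  meanlog <- log(des$expression_mean) - sdlog^2 / 2
  p_keep <- stats::plnorm(2500 / des$da_scale, meanlog, sdlog,
                          lower.tail = FALSE)
  se <- sqrt(p_keep * (1 - p_keep) / nrow(sens))
  expect_lt(abs(nrow(gated) / nrow(sens) - p_keep), 3 * se + 1e-9)
})

test_that("condition ratios are exact for noise-free populations and order invariant", {
  ev <- simulate_flow_experiment(noise_free_flow(true_ratio = 1.3,
                                                 background = 150))
  ev <- subtract_control_median(ev)
  sens <- ev[ev$strain == "sensor", ]
  cr <- condition_ratios(sens, beta = 0.40)
  expect_equal(cr$median_ratio, 1.3, tolerance = 1e-12)
  set.seed(2)
  cr2 <- condition_ratios(sens[sample(nrow(sens)), ], beta = 0.40)
  expect_equal(cr2$median_ratio, cr$median_ratio, tolerance = 1e-12)
  # single-event arithmetic
  one <- data.frame(fsc = 1, ssc = 1, donor_ch = 100, fret_ch = 140,
                    direct_acceptor_ch = 5000, strain = "sensor",
                    condition = "x")
  expect_equal(condition_ratios(one, 0.4)$median_ratio, 1.0)
})

test_that("NR correction divides condition-matched medians and normalizes the reference to 1", {
  ratios <- data.frame(
    strain = rep(c("sensor", "sensor_NR"), each = 3),
    condition = rep(c("ethanol", "glucose", "mannose"), 2),
    median_ratio = c(1.2, 1.1, 0.99, 1.0, 1.1, 0.9),
    n = 100)
  res <- nr_correct_and_normalize(ratios, "glucose")
  expect_equal(res$corrected, c(1.2, 1.0, 1.1))
  expect_equal(res$normalized[res$condition == "glucose"], 1)
  # sensor identical to NR: corrected level 1 everywhere
  same <- ratios; same$median_ratio <- rep(c(1.2, 1.1, 0.99), 2)
  expect_equal(nr_correct_and_normalize(same, "glucose")$corrected,
               rep(1, 3))
  expect_error(nr_correct_and_normalize(ratios, "sucrose"), "reference")
  expect_error(nr_correct_and_normalize(ratios[-4, ], "glucose"), "missing")
})

test_that("the full flow pipeline recovers true ratios and keeps gate counts monotone", {
  des <- flow_design(seed = 13, n_events = 5000)
  ev <- simulate_flow_experiment(des)
  fp <- flow_pipeline(ev, saturation_value = des$saturation_value,
                      reference_condition = "glucose")
  expect_lt(abs(fp$beta - 0.40), 0.01)
  sens <- fp$ratios[fp$ratios$strain == "sensor", ]
  expected <- des$true_ratio[sens$condition] * des$nr_ratio[sens$condition]
  expect_true(all(abs(sens$median_ratio - expected) < 0.05))
  expect_true(all(diff(fp$gate_counts) <= 0))
  expect_equal(fp$result$normalized[fp$result$condition == "glucose"], 1)
  # NR artifacts divide out: corrected levels equal across conditions
  expect_lt(max(fp$result$corrected) / min(fp$result$corrected) - 1, 0.06)
  expect_error(flow_pipeline(ev[ev$strain != "empty", ], 2^24 - 1),
               "control strain")
})
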
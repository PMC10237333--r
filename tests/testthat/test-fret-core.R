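test_that("background subtraction is per-frame arithmetic with identity fallback", {
  tab <- data.frame(cell_id = "a", frame = 0:1, time_min = c(-1, 0),
                    donor = c(110, 120), acceptor = c(210, 220),
                    background_donor = 10, background_acceptor = 20)
  out <- subtract_background(tab)
  expect_equal(out$donor, c(100, 110))
  expect_equal(out$acceptor, c(190, 200))
  no_bg <- tab[, 1:5]
  expect_message(out2 <- subtract_background(no_bg), "passed through")
  expect_identical(out2, no_bg)
})

test_that("bleedthrough correction subtracts a fixed donor fraction", {
  expect_equal(correct_bleedthrough(100, 140, 0.40), 100)
  expect_equal(correct_bleedthrough(0, 55, 0.40), 55)
  expect_error(correct_bleedthrough(1, 1, beta = 1), "beta")
  expect_error(correct_bleedthrough(1, 1, beta = -0.1), "beta")
})

test_that("ratio computation divides corrected acceptor by donor and drops bad frames", {
  tab <- data.frame(cell_id = c("a", "a", "b", "c"), frame = c(0, 1, 0, 0),
                    time_min = c(-1, 0, -1, -1),
                    donor = c(100, 0, 50, -2), acceptor = c(160, 80, 95, 10))
  expect_warning(rt <- compute_ratio(tab, beta = 0.4), "lost all frames")
  expect_equal(rt$ratio[rt$cell_id == "a"], (160 - 40) / 100)
  expect_equal(attr(rt, "qc")$n_frames_dropped, 2)
  expect_equal(attr(rt, "qc")$n_cells_dropped, 1)
  expect_equal(attr(rt, "dropped_cells"), "c")
  # cell b survives: 95 - 20 = 75; 75/50 = 1.5
  expect_equal(rt$ratio[rt$cell_id == "b"], 1.5)
})

test_that("noise-free simulated ratios invert the forward model exactly", {
  tab <- tiny_trace_table(beta = 0.4, background = 30)
  pp <- fret_pipeline(tab, beta = 0.4)
  a <- pp$ratios[pp$ratios$cell_id == "a", ]
  expect_equal(a$ratio, c(1, 1, 1, 1.2, 1.5), tolerance = 1e-12)
  b <- pp$ratios[pp$ratios$cell_id == "b", ]
  expect_equal(b$ratio, rep(0.9, 5), tolerance = 1e-12)
  # expression proxy equals S exactly after corrections
  expect_equal(sort(pp$features$expression_proxy), c(800, 1000),
               tolerance = 1e-9)
})

test_that("baseline normalization divides by the baseline mean", {
  tr <- structure(data.frame(cell_id = "a", time_min = c(-2, -1, 5),
                             ratio = c(1.0, 1.2, 1.65)),
                  class = c("ratio_traces", "data.frame"))
  nt <- normalize_baseline(tr)
  expect_equal(nt$normalized_ratio[3], 1.5)
  expect_equal(attr(nt, "baseline")$baseline_mean, 1.1)
  const <- structure(data.frame(cell_id = "a", time_min = c(-1, 0, 1),
                                ratio = 0.9),
                     class = c("ratio_traces", "data.frame"))
  ntc <- normalize_baseline(const)
  expect_equal(ntc$normalized_ratio, rep(1, 3))
  expect_error(normalize_baseline(tr, baseline_window = c(-10, -5)),
               "baseline window")
})

test_that("normalizing an already-normalized trace is a no-op", {
  tab <- tiny_trace_table()
  rt <- compute_ratio(subtract_background(tab), beta = 0.4)
  n1 <- normalize_baseline(rt)
  renorm <- structure(data.frame(cell_id = n1$cell_id, time_min = n1$time_min,
                                 ratio = n1$normalized_ratio),
                      class = c("ratio_traces", "data.frame"))
  n2 <- normalize_baseline(renorm)
  expect_equal(n2$normalized_ratio, n1$normalized_ratio, tolerance = 1e-12)
})

test_that("final FRET is the mean of the last three frames", {
  expect_equal(final_fret(c(1, 1.2, 1.3, 1.4)), 1.3)
  expect_equal(final_fret(rep(0.97, 5)), 0.97)
  expect_error(final_fret(c(1, 2)), "at least 3")
})

test_that("delta normalized FRET reads the nearest frame minus one", {
  times <- c(-5, 0, 10, 20, 30)
  expect_equal(delta_normalized_fret(times, rep(1, 5), 20), 0)
  expect_equal(delta_normalized_fret(times, c(1, 1, 1.1, 1.25, 1.2), 21), 0.25)
  expect_equal(delta_normalized_fret(times, c(1, 1, 1.1, 1.25, 1.2), "end"), 0.2)
  expect_message(d <- delta_normalized_fret(times, c(1, 1, 1.1, 1.25, 1.3), 50),
                 "clipped")
  expect_equal(d, 0.3)
})

test_that("max slope is exact on lines, zero on constants, and matches the brute-force oracle", {
  times <- 0:10
  expect_equal(max_slope(times, 1 + 0.26 * times, window = 3), 0.26,
               tolerance = 1e-12)
  expect_equal(max_slope(times, 1 + 0.26 * times, window = 5), 0.26,
               tolerance = 1e-12)
  expect_equal(max_slope(times, rep(2, 11), window = 3), 0)
  set.seed(42)
  for (rep in 1:10) {
    n <- sample(6:15, 1)
    tt <- sort(stats::runif(n, 0, 30))
    vv <- stats::rnorm(n, 1, 0.3)
    for (w in c(3, 4)) {
      expect_equal(max_slope(tt, vv, window = w, post_only = FALSE),
                   oracle_max_slope(tt, vv, w), tolerance = 1e-10)
    }
  }
  expect_error(max_slope(0:1, c(1, 2), window = 5), "fewer frames")
  expect_error(max_slope(0:5, rep(1, 6), window = 1), "at least 2")
})

test_that("expression proxy averages donor plus corrected acceptor over baseline", {
  expect_equal(expression_proxy(100, 120), 220)
  expect_equal(expression_proxy(c(100, 105), c(120, 125)), 225)
  expect_error(expression_proxy(numeric(0), numeric(0)), "baseline frame")
})

test_that("pHluorin ratio divides the two excitation bands", {
  expect_equal(phluorin_ratio(50, 100), 0.5)
  expect_equal(phluorin_ratio(7, 7), 1)
  expect_equal(phluorin_ratio(c(50, 100), c(100, 100)), c(0.5, 1))
  expect_error(phluorin_ratio(1, 0), "denominator")
})

test_that("all ratio features except the expression proxy are scale invariant", {
  tab <- tiny_trace_table(background = 0)
  scaled <- tab
  scaled$donor <- scaled$donor * 3.7
  scaled$acceptor <- scaled$acceptor * 3.7
  p1 <- fret_pipeline(tab, t_eval = 1)
  p2 <- fret_pipeline(scaled, t_eval = 1)
  expect_equal(p2$ratios$ratio, p1$ratios$ratio, tolerance = 1e-12)
  expect_equal(p2$normalized$normalized_ratio, p1$normalized$normalized_ratio,
               tolerance = 1e-12)
  keep <- setdiff(names(p1$features), "expression_proxy")
  expect_equal(p2$features[keep], p1$features[keep], tolerance = 1e-12)
  expect_equal(p2$features$expression_proxy,
               3.7 * p1$features$expression_proxy, tolerance = 1e-12)
})
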
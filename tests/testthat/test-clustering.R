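# Shared two-class fixture: well-separated sustained plateaus.
two_class_design <- function(n = 60, seed = 4L) {
  up <- response_class("up", r0 = 1, amplitude = 0.25, rise_rate = 0.4,
                       sustained_fraction = 1, cv_r0 = 0.05,
                       cv_amplitude = 0.05, grower_prob = 1)
  down <- response_class("down", r0 = 1, amplitude = -0.10, rise_rate = 0.4,
                         sustained_fraction = 1, cv_r0 = 0.05,
                         cv_amplitude = 0.05, grower_prob = 0)
  trace_design(list(up, down), proportions = c(0.5, 0.5), n_cells = n,
               frame_interval = 1, baseline_duration = 5,
               total_duration = 40, allocation = "exact", seed = seed)
}

test_that("trace resampling interpolates linearly and passes grids through", {
  nt <- structure(data.frame(cell_id = rep("a", 2), time_min = c(0, 10),
                             normalized_ratio = c(1, 2)),
                  class = c("normalized_traces", "data.frame"))
  m <- resample_traces(nt, grid = c(0, 5, 10))
  expect_equal(as.numeric(m), c(1, 1.5, 2))
  m2 <- resample_traces(nt, grid = c(0, 10))
  expect_equal(as.numeric(m2), c(1, 2))
})

test_that("traces covering too little of the grid are excluded", {
  nt <- structure(data.frame(
    cell_id = c(rep("full", 5), rep("short", 2)),
    time_min = c(0, 10, 20, 30, 40, 0, 5),
    normalized_ratio = c(1, 1, 1, 1, 1, 2, 2)),
    class = c("normalized_traces", "data.frame"))
  expect_message(m <- resample_traces(nt, grid = seq(0, 40, 10)), "excluded")
  expect_equal(rownames(m), "full")
  expect_equal(attr(m, "excluded"), "short")
})

test_that("k = 1 returns the mean trace as centroid", {
  sim <- simulate_trace_set(two_class_design(n = 12))
  pp <- fret_pipeline(sim$table, t_eval = "end")
  m <- resample_traces(pp$normalized)
  cl <- cluster_traces(m, k = 1, seed = 1)
  expect_equal(unique(cl$labels), 1L)
  expect_equal(as.numeric(cl$centroids), unname(colMeans(m)),
               tolerance = 1e-12)
})

test_that("well-separated classes are recovered perfectly and labels are order invariant", {
  sim <- simulate_trace_set(two_class_design(n = 60))
  pp <- fret_pipeline(sim$table, t_eval = "end")
  m <- resample_traces(pp$normalized)
  cl <- cluster_traces(m, k = 2, seed = 1)
  truth <- sim$truth$class[match(names(cl$labels), sim$truth$cell_id)]
  expect_equal(mclust::adjustedRandIndex(cl$labels, truth), 1.0)
  # canonical order: cluster 1 has the higher final plateau
  expect_true(all(cl$labels[truth == "up"] == 1))
  expect_gt(cl$cluster_final[1], cl$cluster_final[2])
  # permuting input rows leaves per-cell labels unchanged
  perm <- sample(nrow(m))
  cl2 <- cluster_traces(m[perm, ], k = 2, seed = 1)
  expect_equal(cl2$labels[names(cl$labels)], cl$labels)
})

test_that("canonical labels are stable across clustering seeds", {
  des <- mannose_design(n_cells = 120, seed = 8L)
  pp <- fret_pipeline(simulate_trace_set(des)$table, t_eval = 50)
  m <- resample_traces(pp$normalized)
  ref <- cluster_traces(m, k = 3, seed = 1)
  for (s in 2:6) {
    cl <- cluster_traces(m, k = 3, seed = s)
    expect_gte(mclust::adjustedRandIndex(cl$labels, ref$labels), 0.95)
  }
})

test_that("the chosen restart has minimal inertia among restarts", {
  sim <- simulate_trace_set(two_class_design(n = 40, seed = 9L))
  pp <- fret_pipeline(sim$table, t_eval = "end")
  m <- resample_traces(pp$normalized)
  multi <- cluster_traces(m, k = 3, seed = 3, n_restarts = 25)
  singles <- vapply(1:8, function(s) {
    cluster_traces(m, k = 3, seed = s, n_restarts = 1)$inertia
  }, numeric(1))
  expect_true(all(multi$inertia <= singles + 1e-8))
})

test_that("cluster summaries reduce to per-cell features and are permutation invariant", {
  sim <- simulate_trace_set(two_class_design(n = 10))
  pp <- fret_pipeline(sim$table, t_eval = "end")
  m <- resample_traces(pp$normalized)
  cl <- cluster_traces(m, k = 2, seed = 1)
  su <- summarize_clusters(cl, pp$features)
  expect_equal(nrow(su), 2)
  expect_equal(sum(su$n), 10)
  su2 <- summarize_clusters(cl, pp$features[sample(nrow(pp$features)), ])
  expect_equal(su, su2)
  # single-cell cluster equals that cell's features
  one <- cluster_traces(m[1:3, ], k = 3, seed = 1)
  su1 <- summarize_clusters(one, pp$features)
  i <- match(names(one$labels)[one$labels == 1], pp$features$cell_id)
  expect_equal(su1$final_fret_mean[1], pp$features$final_fret[i])
})

test_that("composition histograms report grower fractions per cluster", {
  labels <- c(a = 1L, b = 1L, c = 2L, d = 2L)
  cl <- structure(list(labels = labels, k = 3L), class = "cluster_result")
  comp <- composition_histogram(cl, c(a = TRUE, b = TRUE, c = TRUE, d = FALSE))
  expect_equal(comp$grower_fraction[1:2], c(1, 0.5))
  expect_true(is.na(comp$grower_fraction[3]))   # empty cluster
  all_g <- composition_histogram(cl, c(a = TRUE, b = TRUE, c = TRUE, d = TRUE))
  expect_equal(all_g$grower_fraction[1:2], c(1, 1))
  expect_error(composition_histogram(cl, c(a = TRUE)), "missing")
})

test_that("designed grower probabilities are recovered within binomial error", {
  des <- mannose_design(n_cells = 200, seed = 23L)
  sim <- simulate_trace_set(des)
  pp <- fret_pipeline(sim$table, t_eval = 50)
  m <- resample_traces(pp$normalized)
  cl <- cluster_traces(m, k = 3, seed = 1)
  comp <- composition_histogram(
    cl, stats::setNames(sim$truth$grower, sim$truth$cell_id))
  design_p <- c(0.8, 0.9, 0.1)   # canonical clusters 1..3
  for (j in 1:3) {
    se <- sqrt(design_p[j] * (1 - design_p[j]) / comp$n[j])
    expect_lt(abs(comp$grower_fraction[j] - design_p[j]), 3 * se + 1e-9)
  }
})

test_that("group contrasts match the pooled-variance closed form", {
  x <- c(1.2, 1.4, 1.1, 1.5)
  y <- c(0.9, 1.0, 0.8)
  ct <- compare_groups(c(x, y), rep(c("g1", "g2"), c(4, 3)))
  sp2 <- (3 * stats::var(x) + 2 * stats::var(y)) / 5
  t_hand <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 4 + 1 / 3))
  expect_equal(abs(ct$t), abs(t_hand), tolerance = 1e-12)
  expect_equal(ct$p_value, 2 * stats::pt(-abs(t_hand), 5), tolerance = 1e-12)
  # identical groups: t = 0, p = 1
  same <- compare_groups(rep(c(1, 2), 4), rep(c("a", "b"), each = 4))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  expect_error(compare_groups(1:4, rep("a", 4)), "two groups")
  expect_error(compare_groups(1:3, c("a", "a", "b")), ">= 2")
})

test_that("cluster diagnostics report decreasing inertia in k", {
  sim <- simulate_trace_set(two_class_design(n = 30))
  pp <- fret_pipeline(sim$table, t_eval = "end")
  m <- resample_traces(pp$normalized)
  di <- cluster_diagnostics(m, k_range = 1:4, seed = 1)
  expect_true(all(diff(di$inertia) <= 1e-8))
})
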
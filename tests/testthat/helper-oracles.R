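# Independent oracles used across test files.

# Brute-force maximal windowed slope: one lm() per contiguous window.
oracle_max_slope <- function(times, values, window) {
  n <- length(values)
  slopes <- vapply(seq_len(n - window + 1), function(i) {
    idx <- i:(i + window - 1)
    unname(stats::coef(stats::lm(values[idx] ~ times[idx]))[2])
  }, numeric(1))
  max(slopes)
}

# Dense grid search minimizing the saturation-curve RSS, refined by zooming
# twice around the best grid point.
oracle_grid_fit <- function(conc, y, max_range = c(0.01, 1),
                            K_range = c(0.01, 10), n_grid = 121) {
  best <- list(max = NA, K = NA, rss = Inf)
  mr <- max_range; Kr <- K_range
  for (stage in 1:3) {
    ms <- seq(mr[1], mr[2], length.out = n_grid)
    Ks <- exp(seq(log(Kr[1]), log(Kr[2]), length.out = n_grid))
    for (m in ms) {
      r <- vapply(Ks, function(K) sum((y - 1 - m * conc / (K + conc))^2),
                  numeric(1))
      j <- which.min(r)
      if (r[j] < best$rss) best <- list(max = m, K = Ks[j], rss = r[j])
    }
    dm <- diff(mr) / (n_grid - 1); dK <- diff(log(Kr)) / (n_grid - 1)
    mr <- best$max + c(-2, 2) * dm
    Kr <- exp(log(best$K) + c(-2, 2) * dK)
  }
  best
}

# Small noise-free trace table built by hand (2 cells, known ratios), using
# the donor/acceptor partition donor = S/(1+R), acceptor = S*R/(1+R) + beta*donor.
tiny_trace_table <- function(beta = 0.4, background = 0) {
  grid <- data.frame(time_min = c(-2, -1, 0, 1, 2), frame = 0:4)
  build <- function(cell_id, S, R) {
    D <- S / (1 + R); Y <- S * R / (1 + R)
    data.frame(cell_id = cell_id, frame = grid$frame, time_min = grid$time_min,
               donor = D + background, acceptor = Y + beta * D + background,
               background_donor = background, background_acceptor = background)
  }
  rbind(build("a", 1000, c(1, 1, 1, 1.2, 1.5)),
        build("b", 800, c(0.9, 0.9, 0.9, 0.9, 0.9)))
}
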
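#!/usr/bin/env Rscript
# Stage 6 — specific growth rates from the simulated plate-reader curves:
# moving-average smoothing, sliding-window regression of ln(OD - blank),
# tenth-fastest-slope selection; per-well and per-condition summaries.

suppressPackageStartupMessages(library(fretlapse))
curves <- read_growth_table("results/data/growth_curves.csv", blank = 0.04)

res <- do.call(rbind, lapply(curves, function(cv) {
  r <- estimate_growth_rate(cv)
  data.frame(well = cv$well, rate = r$rate,
             windows = nrow(r$slopes),
             window_points = r$regression_window)
}))
res$condition <- sub("_[0-9]+$", "", res$well)
write_table_csv(res, "results/growth_rates_per_well.csv")

agg <- aggregate(rate ~ condition, res, function(x) c(mean = mean(x), sd = sd(x)))
agg <- data.frame(condition = agg$condition, mean_rate = agg$rate[, "mean"],
                  sd_rate = agg$rate[, "sd"])
write_table_csv(agg, "results/growth_rates_by_condition.csv")
for (i in seq_len(nrow(agg))) {
  cat(sprintf("%s: %.3f +/- %.3f h^-1\n", agg$condition[i],
              agg$mean_rate[i], agg$sd_rate[i]))
}
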
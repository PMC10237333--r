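#!/usr/bin/env Rscript
# Stage 5 — grower versus non-grower feature contrasts on the two-hour
# mannose follow-up: basal FRET, end-of-lapse delta normalized FRET, and
# maximal slope, with pooled-variance t-tests.

suppressPackageStartupMessages(library(fretlapse))
features <- utils::read.csv("results/grower_features.csv")
truth <- utils::read.csv("results/data/grower_truth.csv")
grower <- truth$grower[match(features$cell_id, truth$cell_id)]

rows <- list()
for (feat in c("basal_fret", "delta_norm_fret", "max_slope")) {
  ct <- compare_groups(features[[feat]],
                       ifelse(grower, "grower", "nongrower"))
  cat(sprintf("%s: grower %.3f +/- %.3f vs non-grower %.3f +/- %.3f, p = %.3g\n",
              feat, ct$mean[["grower"]], ct$sd[["grower"]],
              ct$mean[["nongrower"]], ct$sd[["nongrower"]], ct$p_value))
  rows[[feat]] <- data.frame(feature = feat,
                             grower_mean = ct$mean[["grower"]],
                             grower_sd = ct$sd[["grower"]],
                             nongrower_mean = ct$mean[["nongrower"]],
                             nongrower_sd = ct$sd[["nongrower"]],
                             t = ct$t, p_value = ct$p_value)
}
write_table_csv(do.call(rbind, rows), "results/grower_contrasts.csv")
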
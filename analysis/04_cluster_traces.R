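#!/usr/bin/env Rscript
# Stage 4 — k-means clustering of the mannose-transition trajectories
# (k = 3, canonical ordering by final normalized FRET), per-cluster feature
# summaries, and cluster composition against the ground-truth growth labels.

suppressPackageStartupMessages(library(fretlapse))
norm <- utils::read.csv("results/mannose_normalized.csv")
class(norm) <- c("normalized_traces", "data.frame")
features <- utils::read.csv("results/mannose_features.csv")
truth <- utils::read.csv("results/data/mannose_truth.csv")

mat <- resample_traces(norm)
diag_tab <- cluster_diagnostics(mat, k_range = 1:6, seed = 1)
write_table_csv(diag_tab, "results/cluster_elbow.csv")

cl <- cluster_traces(mat, k = 3, seed = 1)
su <- summarize_clusters(cl, features)
write_table_csv(su, "results/cluster_summary.csv")
write_table_csv(data.frame(cell_id = names(cl$labels), cluster = cl$labels),
                "results/cluster_labels.csv")

comp <- composition_histogram(cl, stats::setNames(truth$grower, truth$cell_id))
write_table_csv(comp, "results/cluster_composition.csv")

cat("cluster plateaus (final normalized FRET):",
    sprintf("%.3f", su$final_fret_mean), "\n")
cat("weak-responder cluster slope:",
    sprintf("%.3f per minute", su$max_slope_mean[2]), "\n")
cat("grower fraction per cluster:",
    sprintf("%.2f", comp$grower_fraction), "\n")
agree <- mean(cl$labels == c(switcher = 1, responder = 2,
                             decliner = 3)[truth$class[match(names(cl$labels),
                                                             truth$cell_id)]])
cat(sprintf("agreement with ground-truth classes: %.1f%%\n", 100 * agree))
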
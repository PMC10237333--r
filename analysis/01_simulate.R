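#!/usr/bin/env Rscript
# Stage 1 — simulate the study's input data with known ground truth:
# the three-class mannose-transition trace set, the grower/non-grower trace
# set, a glucose dose-response experiment, plate-reader growth curves at the
# four studied rates, and a flow-cytometry experiment. All outputs are
# delimited text under results/data/, each accompanied by its config.

suppressPackageStartupMessages(library(fretlapse))
seed <- 1L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

## mannose transition, 200 cells
des <- mannose_design(n_cells = 200, seed = seed)
sim <- simulate_trace_set(des)
write_table_csv(sim$table, file.path(out, "mannose_traces.csv"))
write_table_csv(sim$truth, file.path(out, "mannose_truth.csv"))
write_config(des, file.path(out, "mannose_design.yaml"))
cat("mannose trace set:", length(unique(sim$table$cell_id)), "cells,",
    nrow(sim$table), "rows\n")

## grower / non-grower transition, 50 + 50 cells, 2 h follow-up
gdes <- grower_design(n_per_group = 50, seed = seed + 1L)
gsim <- simulate_trace_set(gdes)
write_table_csv(gsim$table, file.path(out, "grower_traces.csv"))
write_table_csv(gsim$truth, file.path(out, "grower_truth.csv"))
write_config(gdes, file.path(out, "grower_design.yaml"))
cat("grower trace set:", length(unique(gsim$table$cell_id)), "cells\n")

## glucose dose-response end points (7 concentrations, 20 cells each)
dr <- simulate_dose_response(K05 = 0.24, max_response = 0.24,
                             n_per_conc = 20, noise_sd = 0.02,
                             seed = seed + 2L)
write_table_csv(dr, file.path(out, "dose_response.csv"))
cat("dose-response:", nrow(dr), "cells over",
    length(unique(dr$concentration)), "concentrations\n")

## growth curves: 6 wells per carbon source (ethanol/galactose/mannose/glucose)
mus <- c(ethanol = 0.16, galactose = 0.25, mannose = 0.34, glucose = 0.36)
rows <- list()
for (cs in names(mus)) {
  for (w in 1:6) {
    g <- simulate_growth_curve(mu = mus[[cs]], noise_sd = 0.005,
                               seed = seed * 100L + match(cs, names(mus)) * 10L + w)
    rows[[length(rows) + 1]] <- data.frame(
      time_h = g$time_h, od = g$od, well = sprintf("%s_%d", cs, w),
      blank = g$blank)
  }
}
write_table_csv(do.call(rbind, rows), file.path(out, "growth_curves.csv"))
cat("growth curves: 6 wells x", length(mus), "carbon sources\n")

## flow-cytometry experiment (sensor, NR, empty, donor-only strains)
fdes <- flow_design(seed = seed + 3L)
ev <- simulate_flow_experiment(fdes)
write_table_csv(ev, file.path(out, "flow_events.csv"))
write_config(fdes, file.path(out, "flow_design.yaml"))
cat("flow events:", nrow(ev), "across", length(unique(ev$strain)), "strains\n")
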
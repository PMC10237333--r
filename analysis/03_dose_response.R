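#!/usr/bin/env Rscript
# Stage 3 — saturation-kinetics fit of the glucose dose response:
# response - 1 = max * [glucose] / (K05 + [glucose]), fitted to
# per-concentration mean final normalized FRET.

suppressPackageStartupMessages(library(fretlapse))
pts <- utils::read.csv("results/data/dose_response.csv")

fit <- fit_dose_response(pts, on = "means")
print(fit)
agg <- fit$summary
agg$predicted <- predict_response(fit, agg$concentration)
write_table_csv(agg, "results/dose_response_summary.csv")
write_table_csv(data.frame(max_response = fit$max_response, K05 = fit$K05,
                           rss = fit$rss, n = fit$n),
                "results/dose_response_fit.csv")
cat(sprintf("Saturating response: K0.5 = %.3f mM, maximal normalized FRET = %.3f\n",
            fit$K05, 1 + fit$max_response))
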
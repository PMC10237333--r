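# fretlapse

Single-cell analysis of intramolecular FRET biosensor experiments in
budding yeast — the kind performed with the AKAR3-EV kinase activity
reporter to follow TORC1-Sch9/cAMP-PKA-dependent phosphorylation through
nutrient transitions. The package is for experimentalists who have per-cell
fluorescence tables (microscopy time lapses downstream of segmentation),
flow-cytometry event tables, or plate-reader OD₆₀₀ curves, and want the
complete quantification chain as tested, reusable functions.

## What it computes

**Ratiometric core.** Donor emission leaks into the acceptor channel, so the
FRET ratio is bleedthrough-corrected:

    R = (acceptor − β·donor) / donor,        β = 0.40 by default

Time-lapse traces are baseline-normalized (divided by each cell's mean
pre-perturbation ratio), and per-cell features are extracted: basal FRET
ratio, final normalized FRET (mean of the last 3 frames), Δ normalized FRET
at an evaluation time, maximal windowed slope, and an expression proxy
(donor + corrected acceptor).

**Dose response.** Final responses across glucose concentrations follow
single-site saturation kinetics,

    response − 1 = max·[glucose] / (K₀.₅ + [glucose])

fitted by nonlinear least squares.

**Trajectory clustering.** k-means over normalized post-perturbation trace
vectors with canonical cluster ordering (descending final FRET), cluster
summaries, grower/non-grower composition and pooled-variance t-contrasts.

**Growth rate.** Moving-average smoothing, sliding-window regression of
ln(OD − blank), and the tenth-fastest-slope rule.

**Flow cytometry.** Scatter-saturation filter → empty-plasmid median
subtraction → donor-only bleedthrough estimation → acceptor ≥ 2500 gate →
per-condition median ratios → non-responsive-sensor correction and
reference normalization.

**Forward simulator.** Every stage is validated against simulated
microscopy, cytometry and plate-reader data with known ground truth; the
emission partition (donor = S/(1+R), acceptor = S·R/(1+R) + β·donor) makes
each correction step exactly invertible in the noise-free limit.

## Worked example

Simulate the three-class mannose-transition experiment, quantify it, and
cluster the trajectories:

```r
library(fretlapse)

design <- mannose_design(n_cells = 200, seed = 1)
sim <- simulate_trace_set(design)
pp  <- fret_pipeline(sim$table, beta = 0.40, t_eval = 50)
mat <- resample_traces(pp$normalized)
cl  <- cluster_traces(mat, k = 3, seed = 1)
su  <- summarize_clusters(cl, pp$features)
round(su$final_fret_mean, 3)
#> [1] 1.249 1.085 0.899
round(su$max_slope_mean[2], 3)
#> [1] 0.262
```

Cluster 1 holds sustained switchers plateauing near 1.25, cluster 2 the
weak responders ending near 1.08 with the fastest FRET rise (~0.26 per
minute), cluster 3 the cells declining to ~0.90 — the three discrete
fates observed after a mannose pulse.

Fit the glucose dose response and estimate a growth rate:

```r
pts <- simulate_dose_response(K05 = 0.24, max_response = 0.24,
                              n_per_conc = 20, noise_sd = 0.02, seed = 3)
fit_dose_response(pts)
#> Saturation dose-response fit (response - 1 = max*c/(K05 + c))
#>   max_response: 0.24
#>   K05:          0.2387 mM
#>   RSS:          8.859e-05 (on means, n = 7)

g <- simulate_growth_curve(mu = 0.36, seed = 101)
estimate_growth_rate(g)
#> Growth rate: 0.348 h^-1 (rank-10 of 265 windows of 25 points)
```

A high-affinity saturating response (K₀.₅ ≈ 0.24 mM, maximal normalized
FRET ≈ 1.24) and a glucose-like specific growth rate near 0.36 h⁻¹.

## The analysis workflow

Numbered drivers under `analysis/` run the full study on simulated data and
write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R          # trace sets, dose series, growth curves, flow events
Rscript analysis/02_timelapse_features.R
Rscript analysis/03_dose_response.R
Rscript analysis/04_cluster_traces.R
Rscript analysis/05_grower_contrast.R
Rscript analysis/06_growth_rates.R
Rscript analysis/07_flow_fret.R
```

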
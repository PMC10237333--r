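---
title: "Quantifying single-cell FRET biosensor responses: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying single-cell FRET biosensor responses: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fretlapse)
```

# The measurement model

An intramolecular FRET biosensor such as the AKAR3-EV kinase activity
reporter changes conformation upon phosphorylation of its RRxT substrate
motif, increasing energy transfer from its donor (CFP-class) to its
acceptor (YFP-class) fluorophore. The observable is the ratio of acceptor
to donor emission; because a fraction of donor emission leaks through the
acceptor filter, the acceptor channel must first be corrected for
*bleedthrough*:

corrected acceptor = acceptor − β · donor,  FRET ratio R = corrected acceptor / donor.

β defaults to 0.40, the spillover of the CFP/YFP filter set this analysis
targets; it is a parameter everywhere. For time-lapse data each cell's
ratio trace is divided by its mean pre-perturbation ratio (*baseline
normalization*), so 1 is the resting state and responses are comparable
across cells with different absolute ratios.

Per cell the pipeline reports: the basal (non-normalized) FRET ratio; the
final normalized FRET (mean of the last three frames); the change in
normalized FRET at an evaluation time (nearest frame, default 50 min, with
an `"end"` sentinel); the maximal windowed slope (max over contiguous
3-frame windows of the least-squares slope of normalized ratio versus
time, post-perturbation frames only); and an expression proxy (baseline
mean of donor + corrected acceptor emission).

# The forward simulator

The package is validated against simulated data with known ground truth,
because only a forward model makes every correction step falsifiable. The
emission partition is chosen so that the true ratio is exactly recoverable
after perfect corrections: with expression level S and true ratio R,

donor = S / (1 + R),  acceptor = S·R / (1 + R) + β·donor,

so donor + corrected acceptor = S and corrected acceptor / donor = R
identically. Measured channels add a constant background (echoed in
background columns so tabular subtraction can be checked), multiplicative
Gaussian noise (CV 0.02 per channel by default) and an additive floor
(SD 1 a.u.).

Each cell draws a response class. A class's normalized trajectory after
the perturbation at t = 0 is a delayed saturating rise times an
exponential decay, minus an exponential dip:

g(s) = 1 − d·exp(−k_dip·s) + A·(1 − exp(−k_rise·(s − t₀)))·(f + (1 − f)·exp(−k_dec·(s − t₀)))

with the rise clamped to zero before the onset delay t₀. This is the
minimal family reproducing the observed phenomenology: sustained
"switchers" (f = 1), transient responders (f < 1), decliners (A < 0), and
the early dip seen after mannose (d > 0). Basal ratio and amplitude vary
log-normally across cells with class-specific CVs; growth (grower /
non-grower) labels are drawn per class with stated probabilities,
replacing the manual bud-volume annotation used on real images.

What the simulator does *not* emulate: pixel-level effects (segmentation
error, focus drift, photobleaching), temporal noise correlation, cell
division and lineage effects, and any mechanistic model of the
TORC1-Sch9/cAMP-PKA cascade. Passing tests therefore demonstrate that the
*analysis* recovers what the *measurement model* encodes — they do not
validate segmentation or upstream image processing.

## Reference designs

Two frozen designs encode the studied conditions.

The **mannose design** (`mannose_design()`): 200 cells, three classes
(35% switchers, 35% weak responders, 30% decliners), 0.5-min frames,
10 min baseline, 50 min follow-up. Class end-of-lapse normalized FRET is
designed to be exactly 1.25, 1.08 and 0.90 (amplitudes solved from the
rise kinetics), and the weak-responder class is calibrated so its
*measured* maximal-slope feature is 0.26 min⁻¹ (below). Grower
probabilities per canonical cluster are 0.8 / 0.9 / 0.1.

The **grower design** (`grower_design()`): 50 growers (basal ratio
0.84 ± 0.16, end-of-lapse Δ 0.20 ± 0.09, designed slope 0.12 min⁻¹) and
50 non-growers (0.94 ± 0.16, 0.07 ± 0.20, 0.09 min⁻¹), 0.75-min frames,
2 h follow-up. The non-grower Δ spread (CV ≈ 2.9 on a log-normal
amplitude) encodes that most non-growers barely respond while a few do.

## Calibrating designed slope features

The maximal-slope feature depends on the acquisition grid, the window
length and — through the maximum over windows — the noise level, so a
designed slope value does not map directly onto a rise rate.
`calibrate_rise_rate()` solves for the rise rate whose *expected measured
feature* equals the design value, by Monte-Carlo over cells using the
exact ratio-noise form: because the bleedthrough correction subtracts the
*measured* donor, donor noise enters the corrected ratio twice and the
per-frame noise is

ρ = R·(1 + cv·z_a)/(1 + cv·z_d) − β·cv·z_d/(1 + cv·z_d),

followed by baseline normalization over the design's baseline frames. A
Gaussian approximation of this noise underestimates the tails and leaves
the calibrated feature several percent high; the exact form recovers the
design values to ~2%. For the non-grower class the slope target makes the
calibrated rise rate slow enough that the response does not saturate
within the time lapse, so amplitude and rise rate are solved jointly to
honor both the designed end-of-lapse Δ and the designed slope.

# Dose-response fitting

Final normalized FRET (mean of last three frames) across glucose
concentrations follows single-site saturation kinetics,

response − 1 = max · [glucose] / (K₀.₅ + [glucose]),

fitted by nonlinear least squares (`stats::nls`) on per-concentration
means by default (per-cell points optional). Parameters are constrained
positive via a log parameterization; an unconstrained variant exists for
oracle comparisons. Starting values are max₀ = max(mean response) − 1 and
K₀ = median positive concentration; `scaleOffset = 1` with a tight
tolerance handles the zero-residual fixtures used to verify near-exact
(≤ 1e-6) recovery. Tests require the fit to match a dense two-dimensional
grid search of the same objective.

# Trajectory clustering

Cells are clustered on their baseline-normalized, post-perturbation trace
vectors (linearly interpolated onto a common grid; traces covering less
than half the grid are excluded with a QC record). k-means with Euclidean
distance runs with 25 random restarts (300 iteration cap), keeping the
restart with minimal inertia; k defaults to 3 but is always a user choice,
assisted by an inertia-versus-k report that never auto-selects. Cluster
identities are made reproducible by *canonical ordering*: clusters are
relabeled in descending order of mean final normalized FRET, so cluster 1
is always the highest plateau. Group contrasts use the classical
pooled-variance two-sample t-test (Welch optional).

# Growth-rate estimation

Specific growth rate is estimated from blank-corrected OD₆₀₀ curves by
moving-average smoothing (5 points), sliding-window least squares of
ln(OD − blank) versus time, and selection of the *tenth-fastest* window
slope, a rank rule that rejects up to nine outlier windows. The blank is
taken from the curve when known, else the minimum of the first three
readings.

The regression window length is the estimator's critical choice. The
downward bias from climbing the logistic curve scales with the OD
fold-change *within* a window (μ·T), while the variance from read noise at
low OD scales as T^(−3/2) — so slow growers need long windows and fast
growers short ones. The default is therefore adaptive: a 90-minute pilot
pass estimates the rate, and the final window is one doubling time
(clamped to 90-300 min). A fixed window (in minutes) can be supplied
instead. On noise-free exponential data the estimator returns μ exactly
for any smoothing and window choice.

One honest limitation: a contiguous artifact spanning several readings
(e.g. a doubled 5-point stretch from a bubble) corrupts roughly
2 × window/interval overlapping windows — more than the ten the rank rule
can reject at 5-minute sampling — so it shifts the estimate, though far
less than taking the single fastest window would. The rule's guarantee is
insensitivity to fewer than ten corrupted windows, and that is what the
tests assert.

# Flow-cytometry FRET

Event tables pass a fixed gate chain: removal of events saturating
forward or side scatter (instrument-dependent saturation value, a required
parameter); per-channel subtraction of the empty-plasmid strain's median
fluorescence; bleedthrough estimation as the median FRET/donor ratio of
the donor-only (eCFP) strain — estimated per experiment rather than fixed
at 0.40, since cytometer filters differ from the microscope's; an
inclusive minimum gate (default 2500 a.u.) on the *direct-excitation*
acceptor channel; and per-condition median ratios
(fret − β·donor)/donor. Kinase-independent signal is removed by dividing
each condition's sensor median by the matched non-responsive-sensor
median (a subtraction variant is provided behind a flag; division
preserves the ratio scale), then normalizing to a reference condition.
In the simulator the NR artifact multiplies both sensors, so the division
correction provably restores a condition-independent level when the true
activity is constant — the property the tests check.

# Numerical and degenerate-input choices

* Order of corrections is fixed: background → bleedthrough → ratio.
* Frames with non-positive donor after correction are dropped (never
  imputed) and counted; cells losing all frames are excluded and listed.
* Nearest-frame lookup (no interpolation) for the Δ evaluation time;
  times beyond the trace clip to the last frame with a notice.
* Baseline window defaults to all frames with time < 0.
* Identical seeds give bit-identical simulator output; k-means is
  deterministic given its seed, and canonical ordering makes labels stable
  across seeds on separated data.
* Degenerate inputs error early with named messages: empty class lists,
  non-positive frame intervals, all-zero concentration designs, fewer
  usable OD points than one window, missing control strains.

# Problem sizes

The shipped analyses and tests run at the studied scale: 200 cells for
the three-class experiment, 50 + 50 for the growth contrast, 20 cells at
each of 7 concentrations (100 replicates for the recovery statistics),
six replicate wells per carbon source at 5-minute sampling over 24 h, and
10⁴ cytometry events per strain and condition. All complete in a few
minutes on one CPU.
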
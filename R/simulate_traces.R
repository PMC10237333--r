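## Forward simulator for single-cell FRET biosensor time lapses.
##
## The simulator works at the per-cell table level (downstream of
## segmentation): each cell contributes donor and acceptor emissions per
## frame, built from a ground-truth FRET ratio trajectory, an expression
## level, donor-to-acceptor spectral bleedthrough, background, and
## additive plus multiplicative channel noise.

#' Define a response class for the trace simulator
#'
#' A response class describes the ground-truth normalized FRET trajectory of
#' one phenotypic subpopulation after a nutrient perturbation. The trajectory
#' (relative to the basal ratio, so 1 = resting state) is
#'
#' \deqn{g(s) = 1 - d\,e^{-k_{dip} s} +
#'   A\,(1 - e^{-k_{rise}(s - t_0)})\,(f + (1-f)\,e^{-k_{dec}(s - t_0)})}
#'
#' for time \eqn{s \ge 0} minutes after the perturbation (the rise term is
#' clamped to zero for \eqn{s < t_0}), and \eqn{g(s) = 1} during the
#' baseline. `sustained_fraction = 1` gives a sustained plateau at
#' \eqn{1 + A}; values below 1 give a transient that decays toward
#' \eqn{1 + fA}. A positive `dip_depth` produces the transient initial
#' decline seen for some sugars before the response develops.
#'
#' @param label class name.
#' @param r0 basal (pre-perturbation) FRET ratio; must be positive.
#' @param amplitude asymptotic fractional change `A` of the normalized ratio
#'   (may be negative for declining classes).
#' @param rise_rate rate of the saturating rise, per minute; positive.
#' @param delay lag `t0` between perturbation and response onset, minutes.
#' @param sustained_fraction fraction `f` in `[0, 1]` of the peak response
#'   retained at steady state.
#' @param decay_rate decay rate of the transient component, per minute.
#' @param dip_depth depth `d >= 0` of the initial dip (fraction of basal).
#' @param dip_rate recovery rate of the dip, per minute.
#' @param cv_r0,cv_amplitude cell-to-cell coefficients of variation of the
#'   basal ratio and the amplitude (log-normal across cells).
#' @param grower_prob probability that a cell of this class is a grower
#'   (ground-truth growth label).
#' @return an object of class `response_class`.
#' @export
response_class <- function(label, r0 = 1, amplitude = 0, rise_rate = 0.2,
                           delay = 0, sustained_fraction = 1,
                           decay_rate = 0.1, dip_depth = 0, dip_rate = 0.3,
                           cv_r0 = 0, cv_amplitude = 0, grower_prob = 0.5) {
  stopifnot(r0 > 0, rise_rate > 0,
            sustained_fraction >= 0, sustained_fraction <= 1,
            dip_depth >= 0, decay_rate >= 0, dip_rate >= 0,
            cv_r0 >= 0, cv_amplitude >= 0,
            grower_prob >= 0, grower_prob <= 1)
  structure(list(label = label, r0 = r0, amplitude = amplitude,
                 rise_rate = rise_rate, delay = delay,
                 sustained_fraction = sustained_fraction,
                 decay_rate = decay_rate, dip_depth = dip_depth,
                 dip_rate = dip_rate, cv_r0 = cv_r0,
                 cv_amplitude = cv_amplitude, grower_prob = grower_prob),
            class = "response_class")
}

#' Ground-truth normalized trajectory of a response class
#'
#' @param class a [response_class()].
#' @param s time after perturbation in minutes (vectorized); negative values
#'   return the baseline value 1.
#' @param amplitude optional realized amplitude overriding the class mean.
#' @return normalized ratio `g(s)` (multiply by the cell's basal ratio to get
#'   the true FRET ratio).
#' @export
true_trajectory <- function(class, s, amplitude = NULL) {
  A <- amplitude %||% class$amplitude
  f <- class$sustained_fraction
  sr <- pmax(s - class$delay, 0)
  rise <- A * (1 - exp(-class$rise_rate * sr)) *
    (f + (1 - f) * exp(-class$decay_rate * sr))
  dip <- class$dip_depth * exp(-class$dip_rate * pmax(s, 0))
  out <- 1 - dip + rise
  out[s < 0] <- 1
  out
}

#' Define a trace-set simulation design
#'
#' Bundles the response classes, their mixing proportions, the acquisition
#' grid and the measurement model of a simulated time-lapse experiment.
#' Time is in minutes with t = 0 at the perturbation; frames run from
#' `-baseline_duration` to `total_duration - baseline_duration`.
#'
#' @param classes list of [response_class()] objects.
#' @param proportions mixing proportions, summing to 1.
#' @param n_cells number of cells.
#' @param frame_interval minutes between frames.
#' @param baseline_duration minutes of baseline recorded before perturbation.
#' @param total_duration total minutes recorded.
#' @param bleedthrough_beta donor-into-acceptor-channel spillover fraction in
#'   `[0, 1)`.
#' @param expression_mean,expression_cv log-normal sensor expression level
#'   (arbitrary units) across cells.
#' @param additive_noise_sd additive channel noise SD, arbitrary units.
#' @param multiplicative_noise_cv multiplicative channel noise CV.
#' @param background_level constant background added to both channels.
#' @param allocation `"random"` draws each cell's class from the mixing
#'   proportions; `"exact"` assigns deterministic class counts.
#' @param seed integer seed; identical seeds give identical tables.
#' @return an object of class `trace_design`.
#' @export
trace_design <- function(classes, proportions = NULL, n_cells = 200,
                         frame_interval = 0.5, baseline_duration = 10,
                         total_duration = 60, bleedthrough_beta = 0.40,
                         expression_mean = 1000, expression_cv = 0.30,
                         additive_noise_sd = 1, multiplicative_noise_cv = 0.02,
                         background_level = 50,
                         allocation = c("random", "exact"), seed = 1L) {
  if (length(classes) == 0) stop("at least one response class is required")
  if (inherits(classes, "response_class")) classes <- list(classes)
  proportions <- proportions %||% rep(1 / length(classes), length(classes))
  stopifnot(length(proportions) == length(classes),
            abs(sum(proportions) - 1) < 1e-8,
            frame_interval > 0, baseline_duration < total_duration,
            bleedthrough_beta >= 0, bleedthrough_beta < 1,
            expression_mean > 0, additive_noise_sd >= 0,
            multiplicative_noise_cv >= 0, background_level >= 0)
  structure(list(classes = classes, proportions = proportions,
                 n_cells = as.integer(n_cells),
                 frame_interval = frame_interval,
                 baseline_duration = baseline_duration,
                 total_duration = total_duration,
                 bleedthrough_beta = bleedthrough_beta,
                 expression_mean = expression_mean,
                 expression_cv = expression_cv,
                 additive_noise_sd = additive_noise_sd,
                 multiplicative_noise_cv = multiplicative_noise_cv,
                 background_level = background_level,
                 allocation = match.arg(allocation),
                 seed = as.integer(seed)),
            class = "trace_design")
}

#' Simulate a single-cell fluorescence trace set
#'
#' Draws per-cell ground truth (class, basal ratio, amplitude, expression,
#' grower flag) and emits measured donor/acceptor emissions per frame. The
#' emission partition is chosen so that the true ratio is exactly recoverable
#' after perfect corrections: with expression `S` and true ratio `R`, the
#' noise-free donor is `S / (1 + R)` and the noise-free acceptor is
#' `S * R / (1 + R)`, so donor + acceptor is conserved at `S` and
#' acceptor / donor = `R`. Measured channels add multiplicative noise,
#' donor bleedthrough into the acceptor channel (`beta * donor`), additive
#' noise and a constant background; the background level is reported in
#' `background_donor` / `background_acceptor` columns so tabular background
#' subtraction can be validated.
#'
#' @param design a [trace_design()].
#' @return a list of class `trace_simulation` with elements
#'   `table` (data frame: cell_id, frame, time_min, donor, acceptor,
#'   background_donor, background_acceptor), `truth` (per-cell ground truth)
#'   and `design`.
#' @export
simulate_trace_set <- function(design) {
  stopifnot(inherits(design, "trace_design"))
  set.seed(design$seed)
  n <- design$n_cells
  k <- length(design$classes)

  if (design$allocation == "exact") {
    counts <- floor(design$proportions * n)
    rem <- n - sum(counts)
    if (rem > 0) {
      extra <- order(design$proportions * n - counts, decreasing = TRUE)[seq_len(rem)]
      counts[extra] <- counts[extra] + 1
    }
    class_idx <- rep(seq_len(k), counts)
  } else {
    class_idx <- sample.int(k, n, replace = TRUE, prob = design$proportions)
  }

  cls <- design$classes
  r0 <- numeric(n); A <- numeric(n); grower <- logical(n)
  for (j in seq_len(k)) {
    sel <- class_idx == j
    nj <- sum(sel)
    if (nj == 0) next
    cj <- cls[[j]]
    r0[sel] <- rlnorm_mean_cv(nj, cj$r0, cj$cv_r0)
    if (cj$amplitude == 0) {
      A[sel] <- 0
    } else {
      ## amplitudes drawn log-normally on their magnitude; sign preserved
      A[sel] <- sign(cj$amplitude) *
        rlnorm_mean_cv(nj, abs(cj$amplitude), cj$cv_amplitude)
    }
    grower[sel] <- stats::runif(nj) < cj$grower_prob
  }
  S <- rlnorm_mean_cv(n, design$expression_mean, design$expression_cv)

  time_min <- seq(-design$baseline_duration,
                  design$total_duration - design$baseline_duration,
                  by = design$frame_interval)
  nf <- length(time_min)
  cell_ids <- sprintf("cell_%04d", seq_len(n))

  ## ground-truth ratio per cell x frame
  R <- matrix(0, n, nf)
  for (j in seq_len(k)) {
    sel <- which(class_idx == j)
    for (i in sel) {
      R[i, ] <- r0[i] * true_trajectory(cls[[j]], time_min, amplitude = A[i])
    }
  }

  D <- S / (1 + R)           # true donor, n x nf (S recycled down columns)
  Y <- S * R / (1 + R)       # true acceptor

  cv <- design$multiplicative_noise_cv
  asd <- design$additive_noise_sd
  bg <- design$background_level
  beta <- design$bleedthrough_beta
  eta <- function() matrix(stats::rnorm(n * nf, 0, 1), n, nf)
  donor_meas <- D * (1 + cv * eta()) + asd * eta() + bg
  acceptor_meas <- Y * (1 + cv * eta()) + beta * D + asd * eta() + bg

  table <- data.frame(
    cell_id = rep(cell_ids, each = nf),
    frame = rep(seq_len(nf) - 1L, n),
    time_min = rep(time_min, n),
    donor = as.vector(t(donor_meas)),
    acceptor = as.vector(t(acceptor_meas)),
    background_donor = bg,
    background_acceptor = bg,
    stringsAsFactors = FALSE
  )
  truth <- data.frame(
    cell_id = cell_ids,
    class = vapply(cls, `[[`, character(1), "label")[class_idx],
    r0 = r0, amplitude = A, expression = S, grower = grower,
    stringsAsFactors = FALSE
  )
  structure(list(table = table, truth = truth, design = design),
            class = "trace_simulation")
}

#' Per-frame noise SD of the corrected FRET ratio
#'
#' With independent multiplicative channel noise of CV `cv`, the
#' bleedthrough-corrected ratio `(acceptor - beta * donor) / donor` carries
#' the donor noise twice (once in the denominator and once through the
#' correction term), giving a relative SD of approximately
#' `cv * sqrt(1 + (1 + beta / R)^2)` at true ratio `R`. Used to propagate
#' the design's channel noise into trajectory-level calibrations.
#'
#' @param cv multiplicative channel noise CV.
#' @param beta bleedthrough fraction.
#' @param r0 typical true ratio.
#' @return approximate per-frame SD of the normalized ratio.
#' @export
ratio_noise_sd <- function(cv, beta = 0.40, r0 = 1) {
  cv * sqrt(1 + (1 + beta / r0)^2)
}

#' Calibrate a class rise rate to a designed maximal-slope feature
#'
#' The maximal-slope feature is a windowed least-squares slope evaluated on a
#' discrete frame grid, so for a given designed slope value the underlying
#' exponential rise rate depends on the acquisition interval, the window
#' length, and (through the maximum over windows) the measurement noise.
#' This solves for the rise rate whose trajectory, sampled at the design's
#' frame interval, attains a given expected maximal windowed slope. With
#' `noise_sd = 0` the calibration is against the noise-free discretized
#' trajectory; with `noise_sd > 0` it targets the Monte-Carlo expectation of
#' the feature under per-frame Gaussian ratio noise and the class's
#' cell-to-cell amplitude variability, which is how designed slope values
#' for measured-feature fixtures are set.
#'
#' @param target designed maximal slope, normalized FRET per minute.
#' @param class a [response_class()] template (its `rise_rate` is ignored).
#' @param frame_interval acquisition interval, minutes.
#' @param window slope window length, frames.
#' @param horizon minutes after perturbation to evaluate over.
#' @param channel_cv multiplicative channel noise CV (0 = noise-free
#'   calibration).
#' @param beta bleedthrough fraction used in the measurement model.
#' @param baseline_frames number of baseline frames entering the
#'   normalization when noise is simulated.
#' @param n_sim Monte-Carlo cells when `channel_cv > 0`.
#' @return rise rate, per minute.
#' @export
calibrate_rise_rate <- function(target, class, frame_interval = 0.5,
                                window = 3, horizon = 50,
                                channel_cv = 0, beta = 0.40,
                                baseline_frames = 20, n_sim = 400) {
  stopifnot(target > 0)
  s <- seq(0, horizon, by = frame_interval)
  nf <- length(s)

  if (channel_cv > 0) {
    ## fixed draws shared across uniroot evaluations keep the objective
    ## deterministic and smooth in the rise rate
    old_seed <- if (exists(".Random.seed", .GlobalEnv)) {
      get(".Random.seed", .GlobalEnv)
    }
    set.seed(20260919L)
    ntot <- nf + baseline_frames
    za <- matrix(stats::rnorm(n_sim * ntot), n_sim, ntot)
    zd <- matrix(stats::rnorm(n_sim * ntot), n_sim, ntot)
    amps <- if (class$amplitude == 0 || class$cv_amplitude == 0) {
      rep(class$amplitude, n_sim)
    } else {
      sign(class$amplitude) *
        rlnorm_mean_cv(n_sim, abs(class$amplitude), class$cv_amplitude)
    }
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)

    ## measured ratio given true ratio R and per-frame channel noise:
    ## acceptor and donor each carry multiplicative noise and the
    ## bleedthrough correction subtracts the *measured* donor, so
    ## rho = R (1 + cv za) / (1 + cv zd) - beta cv zd / (1 + cv zd)
    measured_ratio <- function(R, i) {
      den <- 1 + channel_cv * zd[i, ]
      (R * (1 + channel_cv * za[i, ]) - beta * channel_cv * zd[i, ]) / den
    }
  }

  measured <- function(k) {
    cl <- class; cl$rise_rate <- k
    if (channel_cv == 0) {
      return(max_slope_vector(s, true_trajectory(cl, s), window))
    }
    mean(vapply(seq_len(n_sim), function(i) {
      R <- cl$r0 * c(rep(1, baseline_frames),
                     true_trajectory(cl, s, amplitude = amps[i]))
      rho <- measured_ratio(R, i)
      y <- rho / mean(rho[seq_len(baseline_frames)])
      max_slope_vector(s, y[-seq_len(baseline_frames)], window)
    }, numeric(1)))
  }
  cap <- measured(1e4)  # instantaneous-jump limit of the discretized slope
  if (target >= cap) {
    stop(sprintf(paste("designed slope %.3g exceeds the maximum %.3g",
                       "attainable at frame interval %.3g with window %d"),
                 target, cap, frame_interval, window))
  }
  stats::uniroot(function(k) measured(k) - target,
                 lower = 1e-4, upper = 1e4, tol = 1e-6)$root
}
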
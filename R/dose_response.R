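## Saturation-kinetics dose-response fitting of final normalized FRET
## levels: response - 1 = max * c / (K05 + c).

#' Per-concentration summary of final FRET responses
#'
#' @param points data frame with `concentration` and `final_norm_fret`.
#' @return data frame (concentration, mean, sd, n), ordered by
#'   concentration; `sd` is `NA` where n = 1.
#' @export
aggregate_final <- function(points) {
  if (nrow(points) == 0) stop("no dose-response points supplied")
  sp <- split(points$final_norm_fret, points$concentration)
  out <- data.frame(
    concentration = as.numeric(names(sp)),
    mean = vapply(sp, mean, numeric(1)),
    sd = vapply(sp, function(x) if (length(x) > 1) stats::sd(x) else NA_real_,
                numeric(1)),
    n = vapply(sp, length, integer(1))
  )
  out <- out[order(out$concentration), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fit the saturation dose-response curve
#'
#' Least-squares fit of `response - 1 = max * c / (K05 + c)` via
#' [stats::nls()]. By default the fit is on per-concentration mean responses;
#' `on = "cells"` fits all per-cell points. Parameters are constrained
#' positive through a log parameterization (`transform = "log"`); the plain
#' unconstrained parameterization is available for cross-checks.
#'
#' Starting values, unless supplied: `max0 = max(mean response) - 1`,
#' `K05_0 =` median of the positive concentrations.
#'
#' @param points data frame with `concentration` and `final_norm_fret`.
#' @param on fit per-concentration `"means"` (default) or per-cell
#'   `"cells"`.
#' @param transform `"log"` (positive-constrained) or `"identity"`.
#' @param start optional list with `max_response` and `K05`.
#' @return object of class `dose_response_fit`: `max_response`, `K05`,
#'   `rss`, `summary` (per-concentration table), `n`, `fit` (the nls
#'   object).
#' @export
fit_dose_response <- function(points, on = c("means", "cells"),
                              transform = c("log", "identity"),
                              start = NULL) {
  on <- match.arg(on)
  transform <- match.arg(transform)
  summary_tab <- aggregate_final(points)
  if (nrow(summary_tab) < 3 || all(summary_tab$concentration == 0)) {
    stop("need >= 3 distinct concentrations with at least one positive")
  }
  d <- if (on == "means") {
    data.frame(conc = summary_tab$concentration, y = summary_tab$mean)
  } else {
    data.frame(conc = points$concentration, y = points$final_norm_fret)
  }
  max0 <- max(summary_tab$mean) - 1
  if (max0 <= 0) max0 <- 1e-3   # flat/declining data: start near zero response
  K0 <- stats::median(summary_tab$concentration[summary_tab$concentration > 0])
  start <- start %||% list(max_response = max0, K05 = K0)

  fit <- if (transform == "log") {
    stats::nls(y - 1 ~ exp(lmax) * conc / (exp(lK) + conc), data = d,
               start = list(lmax = log(start$max_response),
                            lK = log(start$K05)),
               control = stats::nls.control(maxiter = 500, tol = 1e-9, minFactor = 1e-12, scaleOffset = 1))
  } else {
    stats::nls(y - 1 ~ max_response * conc / (K05 + conc), data = d,
               start = start,
               control = stats::nls.control(maxiter = 500, tol = 1e-9, minFactor = 1e-12, scaleOffset = 1))
  }
  cf <- stats::coef(fit)
  max_response <- if (transform == "log") exp(cf[["lmax"]]) else cf[["max_response"]]
  K05 <- if (transform == "log") exp(cf[["lK"]]) else cf[["K05"]]
  structure(list(max_response = max_response, K05 = K05,
                 rss = sum(stats::resid(fit)^2), summary = summary_tab,
                 n = nrow(d), on = on, transform = transform, fit = fit),
            class = "dose_response_fit")
}

#' Predicted normalized FRET response at a concentration
#'
#' @param result a `dose_response_fit`, or a list with `max_response` and
#'   `K05`.
#' @param concentration mM (vectorized, >= 0).
#' @return predicted normalized FRET response, `1 + max * c / (K05 + c)`.
#' @export
predict_response <- function(result, concentration) {
  if (any(concentration < 0)) stop("concentration must be non-negative")
  1 + result$max_response * concentration / (result$K05 + concentration)
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat("Saturation dose-response fit (response - 1 = max*c/(K05 + c))\n")
  cat(sprintf("  max_response: %.4g\n  K05:          %.4g mM\n  RSS:          %.4g (on %s, n = %d)\n",
              x$max_response, x$K05, x$rss, x$on, x$n))
  invisible(x)
}
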
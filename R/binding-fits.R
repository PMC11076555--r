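# Binding and exchange-kinetics fits.
#
# Two measurement models: (i) single-exponential decay of Mant-GDP
# fluorescence during GEF-catalysed nucleotide exchange, yielding the
# exchange rate k and relative GEF activities; (ii) 1:1 binding isotherms of
# titration series (e.g. microscale thermophoresis dilution series), yielding
# the dissociation constant K_d via the exact quadratic mass balance.

#' Construct an exchange trace
#' @param time Seconds, strictly increasing, length >= 5.
#' @param signal Fluorescence, arbitrary units.
#' @return Object of class `exchange_trace`.
#' @export
exchange_trace <- function(time, signal) {
  if (length(time) < 5L) stopf("trace needs at least 5 points")
  if (length(time) != length(signal)) stopf("time/signal length mismatch")
  if (any(diff(time) <= 0)) stopf("times must be strictly increasing")
  structure(list(time = as.numeric(time), signal = as.numeric(signal)),
            class = "exchange_trace")
}

#' Construct a titration series
#' @param conc Ligand concentrations, molar, all positive, length >= 6.
#' @param response Normalized signal.
#' @param receptor Labelled receptor concentration, molar (default 50 nM).
#' @return Object of class `titration_series`.
#' @export
titration_series <- function(conc, response, receptor = 50e-9) {
  if (length(conc) < 6L) stopf("titration needs at least 6 points")
  if (length(conc) != length(response)) stopf("conc/response length mismatch")
  if (any(conc <= 0)) stopf("concentrations must be positive")
  structure(list(conc = as.numeric(conc), response = as.numeric(response),
                 receptor = as.numeric(receptor)),
            class = "titration_series")
}

#' Serial dilution series
#'
#' @param start Starting concentration (molar), > 0.
#' @param factor Dilution factor per step, > 1 (1:2 dilution = 2).
#' @param n Number of concentrations, >= 1.
#' @return Numeric vector `start, start/factor, ...` of length `n`.
#' @export
dilution_series <- function(start, factor = 2, n = 16L) {
  if (start <= 0) stopf("start must be positive")
  if (factor <= 1) stopf("factor must exceed 1")
  if (n < 1L) stopf("n must be at least 1")
  start / factor^(seq_len(n) - 1L)
}

#' Exact 1:1 bound fraction with receptor depletion
#'
#' Fraction of receptor bound at total ligand `L`, total receptor `R` and
#' dissociation constant `kd`, from the quadratic mass balance. Reduces to
#' the hyperbola `L / (kd + L)` in the limit `R -> 0`.
#'
#' @param L Total ligand concentration(s), molar.
#' @param kd Dissociation constant, molar.
#' @param R Total receptor concentration, molar.
#' @return Bound fraction(s) in \[0, 1\].
#' @export
fraction_bound <- function(L, kd, R = 0) {
  if (R <= 0) return(L / (kd + L))
  b <- L + R + kd
  # numerically stable smaller root: 2LR / (b + sqrt(b^2 - 4LR)) avoids the
  # cancellation of b - sqrt(...) when R << L + kd
  RL <- 2 * L * R / (b + sqrt(pmax(b^2 - 4 * L * R, 0)))
  RL / R
}

new_fit_result <- function(parameters, se, rss, converged, flags = character()) {
  structure(list(parameters = parameters, se = se, rss = rss,
                 converged = converged, flags = flags),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result>", if (x$converged) "converged" else "NOT converged", "\n")
  for (nm in names(x$parameters))
    cat(sprintf("  %-9s %.6g (se %.3g)\n", nm, x$parameters[[nm]],
                x$se[[nm]] %||% NA))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Fit a single-exponential decay to an exchange trace
#'
#' Least-squares fit of `y(t) = y_inf + (y_0 - y_inf) exp(-k t)`. Starting
#' values come from a log-linearized fit; the rate is refined by multi-start
#' Levenberg-Marquardt (5 log-spaced `k` starts around the log-linear
#' estimate) with `k` parameterized on the log scale to enforce positivity.
#' Failure to converge yields a flagged result, not an exception.
#'
#' @param trace An `exchange_trace` (overall-decreasing signal).
#' @return A `fit_result` with parameters `k` (1/s), `y0`, `yinf`, standard
#'   errors from the Jacobian, residual sum of squares and a convergence
#'   flag.
#' @export
fit_exponential <- function(trace) {
  stopifnot(inherits(trace, "exchange_trace"))
  t <- trace$time; y <- trace$signal
  failed <- new_fit_result(c(k = NA_real_, y0 = NA_real_, yinf = NA_real_),
                           c(k = NA_real_, y0 = NA_real_, yinf = NA_real_),
                           NA_real_, FALSE, "non-convergence")
  if (stats::sd(y) == 0) return(failed)
  yinf0 <- min(y) - 0.05 * diff(range(y))
  amp <- y - yinf0
  ok <- amp > 0
  k0 <- tryCatch(max(-stats::coef(stats::lm(log(amp[ok]) ~ t[ok]))[2], 1e-8),
                 error = function(e) 1 / max(t))
  starts <- k0 * c(0.1, 0.316, 1, 3.16, 10)
  best <- NULL
  for (ks in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ yinf + (y0 - yinf) * exp(-exp(lk) * t),
                        start = list(yinf = yinf0, y0 = y[1], lk = log(ks)),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) return(failed)
  cf <- stats::coef(best$fit)
  se <- tryCatch(summary(best$fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 3))
  k <- exp(cf[["lk"]])
  k_se <- k * se[["lk"]]
  amp_fit <- abs(cf[["y0"]] - cf[["yinf"]])
  flags <- character()
  conv <- TRUE
  if (!is.finite(k_se) || amp_fit < 1e-6 * max(abs(y), 1) ||
      k_se > 10 * k) {
    conv <- FALSE
    flags <- "poorly-determined"
  }
  new_fit_result(c(k = k, y0 = cf[["y0"]], yinf = cf[["yinf"]]),
                 c(k = k_se, y0 = se[["y0"]], yinf = se[["yinf"]]),
                 best$rss, conv, flags)
}

#' Relative GEF activity from two exchange rates
#'
#' The ratio `k_variant / k_reference`, as used to normalize variant
#' activities against the wild type. Standard errors are propagated in
#' quadrature from the relative errors.
#'
#' @param k_variant,k_reference Positive exchange rates (1/s).
#' @param se_variant,se_reference Optional standard errors.
#' @return List with `ratio` and `se`.
#' @export
relative_activity <- function(k_variant, k_reference,
                              se_variant = 0, se_reference = 0) {
  if (k_variant <= 0 || k_reference <= 0)
    stopf("rates must be positive")
  ratio <- k_variant / k_reference
  se <- ratio * sqrt((se_variant / k_variant)^2 +
                     (se_reference / k_reference)^2)
  list(ratio = ratio, se = se)
}

#' Fit a 1:1 dissociation constant to a titration series
#'
#' Fits `response = U + (B - U) * fb(L; K_d, R)` with `fb` the exact 1:1
#' bound fraction from the quadratic mass balance (receptor depletion
#' handled; reduces to `L / (K_d + L)` when `R << K_d`). `U` (unbound
#' plateau), `B` (bound plateau) and `K_d` are fitted by multi-start
#' Levenberg-Marquardt least squares with `K_d` on the log scale (5
#' log-spaced starts spanning the concentration range).
#'
#' @param series A `titration_series` whose ligand range spans at least two
#'   orders of magnitude.
#' @return A `fit_result` with parameters `kd` (molar), `unbound`, `bound`;
#'   flagged `poorly-determined` when the optimum lies outside
#'   \[min conc / 100, max conc * 100\].
#' @export
fit_kd <- function(series) {
  stopifnot(inherits(series, "titration_series"))
  L <- series$conc; y <- series$response; R <- series$receptor
  if (max(L) / min(L) < 100)
    stopf("ligand range must span at least 2 orders of magnitude")
  starts <- exp(seq(log(min(L)), log(max(L)), length.out = 5))
  best <- NULL
  for (kd0 in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ U + (B - U) * fraction_bound(L, exp(lkd), R),
                        start = list(U = min(y), B = max(y), lkd = log(kd0)),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    return(new_fit_result(c(kd = NA_real_, unbound = NA_real_,
                            bound = NA_real_),
                          c(kd = NA_real_, unbound = NA_real_,
                            bound = NA_real_),
                          NA_real_, FALSE, "non-convergence"))
  cf <- stats::coef(best$fit)
  se <- tryCatch(summary(best$fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 3))
  kd <- exp(cf[["lkd"]])
  flags <- character()
  if (kd < min(L) / 100 || kd > max(L) * 100) flags <- "poorly-determined"
  new_fit_result(c(kd = kd, unbound = cf[["U"]], bound = cf[["B"]]),
                 c(kd = kd * se[["lkd"]], unbound = se[["U"]],
                   bound = se[["B"]]),
                 best$rss, TRUE, flags)
}
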
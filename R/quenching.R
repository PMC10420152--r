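# Stern-Volmer quenching analysis and double-logarithm binding fits.

# Limiting diffusion-controlled quenching rate constant; Kq above this
# indicates a static (complex-forming) component.
KQ_STATIC_THRESHOLD <- 2.0e10

#' Inner-filter effect correction
#'
#' Corrects an observed fluorescence signal for attenuation of the
#' excitation and emission beams by sample absorbance:
#' `F_cor = F_obs * exp((A_ex + A_em) / 2)`.
#'
#' @param F_obs Observed fluorescence signal(s).
#' @param A_ex Absorbance at the excitation wavelength (>= 0).
#' @param A_em Absorbance at the emission wavelength (>= 0).
#' @return Corrected signal, always >= `F_obs`.
#' @export
ife_correct <- function(F_obs, A_ex, A_em) {
  if (any(!is.finite(A_ex)) || any(!is.finite(A_em)) ||
      any(A_ex < 0) || any(A_em < 0)) {
    stop("absorbances must be finite and non-negative", call. = FALSE)
  }
  F_obs * exp((A_ex + A_em) / 2)
}

#' Stern-Volmer fit of a quenching titration
#'
#' Fits `F0/F = 1 + Ksv * [Q]` by ordinary least squares with a free
#' intercept; `Ksv` is the slope and `Kq = Ksv / tau0`.  The intercept is
#' not forced to 1: a fitted intercept deviating from 1 by more than 5 %
#' flags likely inner-filter under-correction instead of silently forcing
#' the model through it.
#'
#' @param concentrations_M Quencher concentrations in mol/L, including 0.
#' @param F0F Peak ratios F0/F, same length; the zero-concentration entry
#'   is 1 by construction.
#' @param tau0_s Unquenched fluorophore lifetime in seconds (default 1e-8,
#'   the accepted order of magnitude for tryptophan in serum albumin).
#' @param temperature_K Temperature recorded on the result.
#' @return An object of class `"quenching_result"` with fields
#'   `Ksv_per_M`, `Ksv_se`, `Kq_per_M_s`, `r_squared`, `tau0_s`,
#'   `F0F_ratios`, `mechanism` (single-temperature, low-confidence call
#'   from the Kq magnitude alone), and warning flags.
#' @export
stern_volmer_fit <- function(concentrations_M, F0F, tau0_s = 1e-8,
                             temperature_K = NA_real_) {
  q <- as.numeric(concentrations_M)
  y <- as.numeric(F0F)
  if (length(q) != length(y)) stop("length mismatch", call. = FALSE)
  if (length(q) < 3L) {
    stop("insufficient data: Stern-Volmer fit needs >= 3 concentrations",
         call. = FALSE)
  }
  if (tau0_s <= 0) stop("tau0_s must be positive", call. = FALSE)
  # replicate concentrations are averaged before fitting
  if (anyDuplicated(q)) {
    y <- as.numeric(tapply(y, q, mean))
    q <- sort(unique(q))
  }
  fit <- stats::lm(y ~ q)
  co <- summary(fit)$coefficients
  ksv <- unname(co["q", "Estimate"])
  negative_ksv <- ksv < 0
  if (negative_ksv) {
    warning("fitted Ksv is negative; reporting as-is", call. = FALSE)
  }
  intercept <- unname(co["(Intercept)", "Estimate"])
  intercept_warning <- abs(intercept - 1) > 0.05
  if (intercept_warning) {
    warning(sprintf(
      "Stern-Volmer intercept %.4f deviates from 1 by > 5%%; check inner-filter correction",
      intercept), call. = FALSE)
  }
  r2 <- summary(fit)$r.squared
  # a perfectly flat trace has zero total variance; the (constant) model
  # explains all of it
  if (is.nan(r2)) r2 <- 1
  kq <- ksv / tau0_s
  structure(
    list(temperature_K = temperature_K,
         Ksv_per_M = ksv,
         Ksv_se = unname(co["q", "Std. Error"]),
         intercept = intercept,
         Kq_per_M_s = kq,
         r_squared = r2,
         tau0_s = tau0_s,
         F0F_ratios = stats::setNames(y, q),
         mechanism = if (kq > KQ_STATIC_THRESHOLD) "static" else "dynamic",
         mechanism_low_confidence = TRUE,
         negative_ksv = negative_ksv,
         intercept_warning = intercept_warning),
    class = "quenching_result"
  )
}

#' @export
print.quenching_result <- function(x, ...) {
  cat(sprintf(
    "<quenching_result> T = %s K: Ksv = %.4g +/- %.2g /M (r2 = %.4f), Kq = %.4g /(M s)\n",
    format(x$temperature_K), x$Ksv_per_M, x$Ksv_se, x$r_squared, x$Kq_per_M_s))
  invisible(x)
}

#' Classify the quenching mechanism across temperatures
#'
#' Rule table: a static component is evidenced by every quenching rate
#' constant Kq exceeding the diffusion limit 2.0e10 L/(mol s); a dynamic
#' component by Ksv strictly increasing with temperature.  Both kinds of
#' evidence together give "mixed".
#'
#' @param results_by_T List of [stern_volmer_fit()] results at distinct
#'   temperatures.  A single result is classified from its Kq alone and the
#'   call is flagged low-confidence.
#' @return Character scalar `"dynamic"`, `"static"` or `"mixed"`, with
#'   attribute `low_confidence` when only one temperature was supplied.
#' @export
classify_mechanism <- function(results_by_T) {
  stopifnot(is.list(results_by_T), length(results_by_T) >= 1L,
            all(vapply(results_by_T, inherits, logical(1L),
                       "quenching_result")))
  if (length(results_by_T) == 1L) {
    out <- results_by_T[[1L]]$mechanism
    attr(out, "low_confidence") <- TRUE
    return(out)
  }
  tt <- vapply(results_by_T, `[[`, numeric(1L), "temperature_K")
  ord <- order(tt)
  ksv <- vapply(results_by_T, `[[`, numeric(1L), "Ksv_per_M")[ord]
  kq <- vapply(results_by_T, `[[`, numeric(1L), "Kq_per_M_s")[ord]
  static_evidence <- all(kq > KQ_STATIC_THRESHOLD)
  dynamic_evidence <- all(diff(ksv) > 0)
  if (static_evidence && dynamic_evidence) "mixed"
  else if (static_evidence) "static"
  else "dynamic"
}

#' Double-logarithm binding fit
#'
#' Fits the binding isotherm `log10((F0 - F)/F) = log10(Ka) + n * log10(Q)`
#' by ordinary least squares.  `Ka` is the association constant (1/M under
#' the convention that concentrations are in mol/L) and `n` the Hill-type
#' number of binding sites.  Points with `Q = 0` or `F >= F0` carry no
#' binding signal and are excluded and counted.
#'
#' @param concentrations_M Quencher concentrations in mol/L.
#' @param F0 Unquenched intensity: a scalar, or a vector matching `F`
#'   (e.g. when intensities are already expressed as ratios, pass
#'   `F0 = 1` and `F = F/F0`).
#' @param F Quenched intensities at each concentration.
#' @param temperature_K Temperature recorded on the result.
#' @return An object of class `"binding_result"` with `Ka_per_M`, `Ka_se`,
#'   `n_sites`, `n_se`, `r_squared`, `n_used`, `n_excluded`.
#' @export
double_log_fit <- function(concentrations_M, F0, F,
                           temperature_K = NA_real_) {
  q <- as.numeric(concentrations_M)
  f <- as.numeric(F)
  f0 <- as.numeric(F0)
  if (length(f0) == 1L) f0 <- rep(f0, length(f))
  if (length(q) != length(f) || length(f) != length(f0)) {
    stop("length mismatch", call. = FALSE)
  }
  nonzero <- q > 0
  usable <- nonzero & f < f0 & f > 0
  n_excluded <- sum(nonzero) - sum(usable)
  if (sum(usable) < 3L) {
    stop("insufficient data: double-log fit needs >= 3 usable points",
         call. = FALSE)
  }
  x <- log10(q[usable])
  y <- log10((f0[usable] - f[usable]) / f[usable])
  # replicate concentrations are averaged before fitting
  if (anyDuplicated(x)) {
    y <- as.numeric(tapply(y, x, mean))
    x <- sort(unique(x))
  }
  fit <- stats::lm(y ~ x)
  co <- summary(fit)$coefficients
  log_ka <- unname(co["(Intercept)", "Estimate"])
  log_ka_se <- unname(co["(Intercept)", "Std. Error"])
  ka <- 10^log_ka
  structure(
    list(temperature_K = temperature_K,
         Ka_per_M = ka,
         Ka_se = ka * log(10) * log_ka_se,  # delta method
         n_sites = unname(co["x", "Estimate"]),
         n_se = unname(co["x", "Std. Error"]),
         r_squared = summary(fit)$r.squared,
         n_used = sum(usable),
         n_excluded = n_excluded),
    class = "binding_result"
  )
}

#' @export
print.binding_result <- function(x, ...) {
  cat(sprintf(
    "<binding_result> T = %s K: Ka = %.4g /M, n = %.3f +/- %.3f (r2 = %.4f, %d points, %d excluded)\n",
    format(x$temperature_K), x$Ka_per_M, x$n_sites, x$n_se, x$r_squared,
    x$n_used, x$n_excluded))
  invisible(x)
}

#' Full quenching analysis of one titration series
#'
#' Convenience wrapper: extracts peak ratios at the ligand-free emission
#' maximum (after optional inner-filter correction from ligand molar
#' absorptivities) and runs both [stern_volmer_fit()] and
#' [double_log_fit()].
#'
#' @param series A [titration_series()].
#' @param tau0_s Unquenched lifetime for Kq (default 1e-8 s).
#' @param eps_ex,eps_em Ligand molar absorptivities at excitation and
#'   emission, L/(mol cm); when non-zero the observed intensities are
#'   inner-filter corrected with `A = eps * Q * path_cm` before fitting.
#' @param path_cm Cell path length in cm (default 1).
#' @return List with elements `quenching` and `binding`.
#' @export
analyze_titration <- function(series, tau0_s = 1e-8, eps_ex = 0, eps_em = 0,
                              path_cm = 1) {
  stopifnot(inherits(series, "titration_series"))
  rat <- quench_ratios(series)
  q <- rat$concentration_M
  f <- ife_correct(rat$F, eps_ex * q * path_cm, eps_em * q * path_cm)
  list(
    quenching = stern_volmer_fit(q, f[1L] / f, tau0_s = tau0_s,
                                 temperature_K = series$temperature_K),
    binding = double_log_fit(q, f[1L], f,
                             temperature_K = series$temperature_K)
  )
}
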
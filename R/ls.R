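#' Normalize a light-scattering intensity decay
#'
#' Maps the raw LS intensity onto
#' `dI(t) = (I(t) - I_final) / (I_initial - I_final)`, where `I_initial` and
#' `I_final` are the means of the first and last `edge_n` samples (windowed
#' means are robust to endpoint noise). A single-exponential decay
#' `dI ~ A exp(-r t) + offset` is fitted alongside and stored.
#'
#' @param trace An `ls_trace` (or tibble with `time_s`, `intensity`).
#' @param edge_n Samples averaged at each end (default 3).
#' @return A tibble of class `normalized_decay` with columns `time_s`,
#'   `dI`; attributes `fit` (list: `amplitude`, `rate`, `offset`) and the
#'   trace metadata.
#' @export
normalize_intensity <- function(trace, edge_n = 3) {
  if (nrow(trace) < 10) {
    abort("at least 10 samples are required", class = "ejectkin_insufficient_data")
  }
  I0 <- mean(head(trace$intensity, edge_n))
  I1 <- mean(tail(trace$intensity, edge_n))
  if (I0 == I1) {
    abort("flat trace: initial and final intensities are equal", class = "ejectkin_flat_trace")
  }
  dI <- (trace$intensity - I1) / (I0 - I1)
  tt <- trace$time_s
  # single-exponential fit with offset
  r0 <- 1 / max(tt[which.min(abs(dI - exp(-1)))], tt[2])
  res_fn <- function(p) p[1] * exp(-p[2] * tt) + p[3] - dI
  fit <- minpack.lm::nls.lm(
    par = c(1, r0, 0), fn = res_fn,
    lower = c(0, 1e-8, -0.5), upper = c(10, 10, 0.5),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  out <- tibble(time_s = tt, dI = dI)
  attr(out, "fit") <- list(
    amplitude = fit$par[1], rate = fit$par[2], offset = fit$par[3],
    rms = sqrt(mean(fit$fvec^2))
  )
  attr(out, "metadata") <- attr(trace, "metadata")
  class(out) <- c("normalized_decay", class(out))
  out
}

#' Differentiate a normalized LS decay
#'
#' `-d(dI)/dt` is the instantaneous rate of ejection events. The default
#' `"fit"` method differentiates the stored single-exponential fit
#' analytically; `"numeric"` applies central differences to a
#' Savitzky-Golay smoothed series (window 11, order 3).
#'
#' @param norm A `normalized_decay` from [normalize_intensity()].
#' @param method `"fit"` or `"numeric"`.
#' @return A tibble `time_s`, `ddI_dt` (1/s, the raw signed derivative).
#' @export
differentiate_decay <- function(norm, method = c("fit", "numeric")) {
  method <- match.arg(method)
  tt <- norm$time_s
  if (method == "fit") {
    f <- attr(norm, "fit")
    ddI <- -f$amplitude * f$rate * exp(-f$rate * tt)
  } else {
    y <- norm$dI
    if (length(y) >= 15) y <- signal::sgolayfilt(y, p = 3, n = 11)
    n <- length(y)
    ddI <- numeric(n)
    ddI[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (tt[3:n] - tt[1:(n - 2)])
    ddI[1] <- (y[2] - y[1]) / (tt[2] - tt[1])
    ddI[n] <- (y[n] - y[n - 1]) / (tt[n] - tt[n - 1])
  }
  out <- tibble(time_s = tt, ddI_dt = ddI)
  attr(out, "metadata") <- attr(norm, "metadata")
  out
}

#' Scale an LS derivative into ITC heat-flow units
#'
#' Multiplies `-d(dI)/dt` by the phage count and the heat released per
#' virion, converting J/s to ucal/s, so the LS-derived event rate can be
#' overlaid on a DP titration curve.
#'
#' @param deriv Output of [differentiate_decay()].
#' @param n_phage Number of phage in the matched ITC titration.
#' @param dH_per_virion_J Heat released per ejection, J.
#' @return A tibble of class `derived_heat_flow`: `time_s`,
#'   `power_ucal_s`.
#' @export
scale_to_itc <- function(deriv, n_phage, dH_per_virion_J) {
  if (missing(n_phage) || missing(dH_per_virion_J) ||
    is.null(n_phage) || is.null(dH_per_virion_J) ||
    n_phage <= 0 || dH_per_virion_J <= 0) {
    abort("positive n_phage and dH_per_virion_J are required", class = "ejectkin_unit_error")
  }
  out <- tibble(
    time_s = deriv$time_s,
    power_ucal_s = -deriv$ddI_dt * n_phage * dH_per_virion_J * UCAL_PER_J
  )
  attr(out, "metadata") <- c(
    attr(deriv, "metadata") %||% list(),
    list(n_phage = n_phage, dH_per_virion_J = dH_per_virion_J)
  )
  class(out) <- c("derived_heat_flow", class(out))
  out
}
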
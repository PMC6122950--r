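#' Decompose a SAXS frame background into component profiles
#'
#' Fits a non-negative linear combination of measured component profiles
#' (TM buffer, oPOE detergent, LamB receptor) to a frame, over a fit region
#' that excludes the DNA diffraction peak window (default flanks
#' `[0.10, 0.17]` and `[0.33, 0.40]` 1/Angstrom). A free constant offset is
#' included so the fit-region residual is zero-mean. Components not on the
#' frame's q-grid are linearly resampled.
#'
#' @param frame A tibble with columns `q_invA`, `intensity` (one frame).
#' @param components A tibble with `q_invA` and one column per component.
#' @param peak_window DNA-peak window excluded from the fit, 1/Angstrom.
#' @param fit_region Two flanking intervals (list of length-2 vectors) used
#'   for the fit.
#' @return A list of class `background_model`: `coefficients` (named,
#'   non-negative), `offset`, `background` (tibble on the frame grid) and
#'   `rank_deficient` flag.
#' @export
construct_background <- function(frame, components,
                                 peak_window = c(0.18, 0.32),
                                 fit_region = list(c(0.10, 0.17), c(0.33, 0.40))) {
  q <- frame$q_invA
  comp_names <- setdiff(names(components), "q_invA")
  B <- vapply(comp_names, function(nm) {
    approx(components$q_invA, components[[nm]], xout = q, rule = 2)$y
  }, numeric(length(q)))
  in_fit <- Reduce(`|`, lapply(fit_region, function(r) q >= r[1] & q <= r[2]))
  if (sum(in_fit) < length(comp_names) + 1) {
    abort("fit region holds too few points", class = "ejectkin_insufficient_data")
  }
  A <- cbind(B[in_fit, , drop = FALSE], offset_pos = 1, offset_neg = -1)
  rank_def <- qr(A)$rank < ncol(A) - 1 # the +/- offset pair is intentional
  if (rank_def) warn("component profiles are rank deficient; minimum-norm NNLS solution")
  sol <- pracma::lsqnonneg(A, frame$intensity[in_fit])
  x <- sol$x
  coefs <- setNames(x[seq_along(comp_names)], comp_names)
  offset <- x[length(comp_names) + 1] - x[length(comp_names) + 2]
  bg <- as.numeric(B %*% coefs) + offset
  structure(
    list(
      coefficients = coefs,
      offset = offset,
      background = tibble(q_invA = q, intensity = bg),
      rank_deficient = rank_def,
      fit_region_residual_mean = mean(frame$intensity[in_fit] - bg[in_fit])
    ),
    class = "background_model"
  )
}

#' Subtract a fitted background model from a frame
#'
#' @param frame A tibble with `q_invA`, `intensity`.
#' @param bg A `background_model` from [construct_background()].
#' @return The frame with background removed.
#' @export
subtract_saxs_background <- function(frame, bg) {
  out <- frame
  out$intensity <- frame$intensity - bg$background$intensity
  out
}

#' Fit the DNA diffraction peak of a background-subtracted frame
#'
#' Least-squares Gaussian-plus-line fit over the DNA peak window (default
#' `[0.18, 0.32]` 1/Angstrom); the peak area is computed analytically as
#' `amplitude * width * sqrt(2 pi)`. When the fitted amplitude falls below
#' `2 sigma` of the fit residuals the peak is flagged absent and the area
#' set to zero.
#'
#' @param frame Background-subtracted frame (`q_invA`, `intensity`).
#' @param window Fit window, 1/Angstrom.
#' @return A one-row tibble: `area`, `center_invA`, `width_invA`,
#'   `baseline_slope`, `baseline_intercept`, `peak_absent`, `time_s` (when
#'   the frame carries it).
#' @export
fit_dna_peak <- function(frame, window = c(0.18, 0.32)) {
  sel <- frame$q_invA >= window[1] & frame$q_invA <= window[2]
  if (sum(sel) < 8) {
    abort("peak window coverage is insufficient", class = "ejectkin_insufficient_data")
  }
  q <- frame$q_invA[sel]
  y <- frame$intensity[sel]
  line0 <- lm(y ~ q)
  resid0 <- y - predict(line0)
  amp0 <- max(resid0)
  q0 <- q[which.max(resid0)]
  res_fn <- function(par) {
    par[1] * exp(-(q - par[2])^2 / (2 * par[3]^2)) + par[4] + par[5] * q - y
  }
  fit <- minpack.lm::nls.lm(
    par = c(max(amp0, 1e-12), q0, 0.02, coef(line0)[1], coef(line0)[2]),
    fn = res_fn,
    lower = c(0, window[1], 1e-4, -Inf, -Inf),
    upper = c(Inf, window[2], 0.2, Inf, Inf),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  p <- unname(fit$par)
  sigma_res <- sqrt(sum(fit$fvec^2) / max(length(q) - 5, 1))
  # absent when the amplitude is within noise, or negligible next to the
  # overall intensity scale (an exactly featureless window fits with both
  # amplitude and residual near machine zero)
  absent <- p[1] < max(2 * sigma_res, 1e-8 * max(abs(y)))
  area <- if (absent) 0 else p[1] * p[3] * sqrt(2 * pi)
  tibble(
    area = area,
    center_invA = p[2],
    width_invA = p[3],
    baseline_slope = p[5],
    baseline_intercept = p[4],
    peak_absent = absent,
    time_s = if ("time_s" %in% names(frame)) frame$time_s[1] else NA_real_
  )
}

#' Reduce a SAXS frame series to a DNA-peak-area time series
#'
#' For every frame: fit the component background on the peak flanks,
#' subtract it, and fit the DNA peak. Component backgrounds default to the
#' profiles attached to a synthetic series.
#'
#' @param series A `saxs_series` (long tibble `time_s`, `q_invA`,
#'   `intensity`).
#' @param components Component background profiles; defaults to
#'   `attr(series, "backgrounds")`.
#' @param ... Passed to [fit_dna_peak()].
#' @return A tibble of class `peak_area_series`: `time_s`, `area`,
#'   `peak_absent`, `center_invA`; temperature metadata propagated.
#' @export
peak_area_series <- function(series, components = NULL, ...) {
  components <- components %||% attr(series, "backgrounds")
  if (is.null(components)) {
    abort("component background profiles are required", class = "ejectkin_invalid_argument")
  }
  out <- series %>%
    group_by(.data$time_s) %>%
    dplyr::group_map(function(fr, key) {
      fr$time_s <- key$time_s
      bg <- construct_background(fr, components)
      fit_dna_peak(subtract_saxs_background(fr, bg), ...)
    }) %>%
    bind_rows() %>%
    arrange(.data$time_s)
  attr(out, "metadata") <- attr(series, "metadata")
  class(out) <- c("peak_area_series", class(out))
  out
}

#' Ejection rate constants from a peak-area decay
#'
#' The DNA-peak area tracks the number of still-filled capsids, so its
#' log-linear decay rate is the ejection-event rate. Rates are extracted
#' separately for the fast regime (`t < t_split`, synchronized events) and
#' the slow regime (`t > t_split`, desynchronized events) as minus the OLS
#' slope of `ln(area)` versus time. Peak-absent or non-positive areas are
#' excluded; a regime with fewer than 3 usable points yields `NA`.
#'
#' @param areas A `peak_area_series` (or tibble with `time_s`, `area`).
#' @param t_split_s Regime split time, s (default 20).
#' @return A one-row tibble: `k_fast`, `k_slow` (1/s), `r2_fast`,
#'   `r2_slow`, `n_fast`, `n_slow`, plus `temperature_C` when known.
#' @export
ejection_rates <- function(areas, t_split_s = 20) {
  absent <- if ("peak_absent" %in% names(areas)) areas$peak_absent else FALSE
  usable <- areas$area > 0 & !absent
  df <- areas[usable, ]
  one_regime <- function(sel) {
    if (sum(sel) < 3) {
      return(list(k = NA_real_, r2 = NA_real_, n = sum(sel)))
    }
    fit <- lm(log(area) ~ time_s, data = df[sel, ])
    list(
      k = -unname(coef(fit)[2]),
      r2 = summary(fit)$r.squared,
      n = sum(sel)
    )
  }
  fast <- one_regime(df$time_s < t_split_s)
  slow <- one_regime(df$time_s > t_split_s)
  tibble(
    k_fast = fast$k, k_slow = slow$k,
    r2_fast = fast$r2, r2_slow = slow$r2,
    n_fast = fast$n, n_slow = slow$n,
    temperature_C = (attr(areas, "metadata") %||% list())$temperature_C %||% NA_real_
  )
}

#' Arrhenius fit of ejection rate constants
#'
#' Least squares of `ln k` on inverse absolute temperature:
#' `ln k = ln A - Ea / (kB T)`. The activation energy is
#' `Ea = -slope * kB` (J/virion) and is also reported in units of thermal
#' energy at a reference temperature, `Ea / (kB T_ref)`.
#'
#' @param k_by_T A data frame with columns `temperature_C` and `k` (1/s).
#'   Non-positive rates are excluded with a warning.
#' @param t_ref_C Reference temperature for the `kT` conversion, degrees C.
#' @return An object of class `arrhenius_fit` with fields `Ea_J`,
#'   `ln_prefactor`, `Ea_in_kT`, `t_ref_C` and the points used. Methods
#'   [tidy()], [glance()], [autoplot()].
#' @export
arrhenius_fit <- function(k_by_T, t_ref_C = 25) {
  keep <- is.finite(k_by_T$k) & k_by_T$k > 0
  if (any(!keep)) warn("non-positive rate constants excluded from Arrhenius fit")
  pts <- k_by_T[keep, ]
  if (nrow(pts) < 2) {
    abort("at least two positive rates are required", class = "ejectkin_insufficient_data")
  }
  inv_T <- 1 / celsius_to_kelvin(pts$temperature_C)
  fit <- lm(log(pts$k) ~ inv_T)
  slope <- unname(coef(fit)[2])
  Ea <- -slope * KB
  structure(
    list(
      Ea_J = Ea,
      ln_prefactor = unname(coef(fit)[1]),
      Ea_in_kT = ea_in_kt(Ea, t_ref_C),
      t_ref_C = t_ref_C,
      points = tibble(
        temperature_C = pts$temperature_C, k = pts$k, inv_T_K = inv_T
      ),
      r2 = if (nrow(pts) > 2) summary(fit)$r.squared else NA_real_
    ),
    class = "arrhenius_fit"
  )
}

#' Express an activation energy in units of thermal energy
#'
#' @param Ea_J Activation energy, J.
#' @param t_ref_C Reference temperature, degrees C.
#' @return `Ea / (kB T_ref)`, dimensionless.
#' @examples
#' ea_in_kt(1.2e-19, 25) # ~29 kT
#' @export
ea_in_kt <- function(Ea_J, t_ref_C = 25) {
  Ea_J / (KB * celsius_to_kelvin(t_ref_C))
}

#' @exportS3Method generics::tidy
tidy.arrhenius_fit <- function(x, ...) {
  tibble(
    term = c("Ea_J", "ln_prefactor", "Ea_in_kT"),
    estimate = c(x$Ea_J, x$ln_prefactor, x$Ea_in_kT)
  )
}

#' @exportS3Method generics::glance
glance.arrhenius_fit <- function(x, ...) {
  tibble(
    Ea_J = x$Ea_J, Ea_in_kT = x$Ea_in_kT, ln_prefactor = x$ln_prefactor,
    t_ref_C = x$t_ref_C, n = nrow(x$points), r2 = x$r2
  )
}

#' @export
print.arrhenius_fit <- function(x, ...) {
  cat(sprintf(
    "<arrhenius_fit> Ea = %.3g J/virion (%.1f kT at %g C), ln A = %.2f\n",
    x$Ea_J, x$Ea_in_kT, x$t_ref_C, x$ln_prefactor
  ))
  invisible(x)
}

#' @exportS3Method ggplot2::autoplot
autoplot.arrhenius_fit <- function(object, ...) {
  ggplot2::ggplot(
    object$points,
    ggplot2::aes(.data$inv_T_K, log(.data$k))
  ) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(
      intercept = object$ln_prefactor,
      slope = -object$Ea_J / KB, linetype = "dashed"
    ) +
    ggplot2::labs(x = "1 / T (1/K)", y = "ln k")
}
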
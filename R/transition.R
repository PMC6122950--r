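wls_line <- function(x, y, w) {
  # weighted least squares line; returns slope, intercept, sse, slope t-stat
  W <- sum(w)
  xb <- sum(w * x) / W
  yb <- sum(w * y) / W
  sxx <- sum(w * (x - xb)^2)
  if (sxx == 0) {
    return(list(slope = 0, intercept = yb, sse = sum(w * (y - yb)^2), tstat = 0))
  }
  slope <- sum(w * (x - xb) * (y - yb)) / sxx
  intercept <- yb - slope * xb
  resid <- y - intercept - slope * x
  sse <- sum(w * resid^2)
  n <- length(x)
  tstat <- if (n > 2 && sse > 0) {
    se <- sqrt((sse / (n - 2)) / sxx)
    slope / se
  } else if (sse == 0 && slope != 0) {
    Inf
  } else {
    0
  }
  list(slope = slope, intercept = intercept, sse = sse, tstat = tstat)
}

#' Two-segment breakpoint fit of an enthalpy-versus-temperature series
#'
#' Detects the intracapsid solid-to-fluid DNA transition temperature `T*`
#' as the breakpoint of `dH_ej(T)`. For every candidate breakpoint on a
#' 0.1 degree grid between the 2nd and (n-1)th temperature, two independent
#' lines are fitted by (weighted) least squares to the points at or below
#' and above the candidate; the breakpoint minimizing total SSE wins. The
#' segments are not constrained to meet (the transition appears as a
#' discontinuity); a connected hinge variant is available. Ties (plateaus
#' of equal SSE, the rule on noise-free data) resolve to the plateau
#' midpoint. The transition is flagged significant when the segment slopes
#' have opposite signs and each slope's |t| exceeds 2.
#'
#' @param series A data frame with columns `temperature_C`, `dH_ej_J` and
#'   optionally `se_J` (weights `1/se^2` are used when all SEs are
#'   positive), e.g. from [synthesize_enthalpy_series()].
#' @param grid_step_C Breakpoint search resolution, degrees C.
#' @param connected Fit a continuous hinge instead of two free lines.
#' @return An object of class `transition_fit` with fields `t_star_C`,
#'   `slope_below`, `slope_above` (J/virion/degree C, specific-heat
#'   proxies), `sse`, `inversion`, `significant`. Methods [tidy()],
#'   [glance()], [autoplot()].
#' @export
fit_two_segment <- function(series, grid_step_C = 0.1, connected = FALSE) {
  temps <- series$temperature_C
  dH <- series$dH_ej_J
  n <- length(temps)
  if (n < 5) {
    abort("at least 5 temperatures are required", class = "ejectkin_insufficient_data")
  }
  stopifnot(all(diff(temps) > 0))
  se <- if ("se_J" %in% names(series)) series$se_J else rep(0, n)
  w <- if (all(se > 0)) 1 / se^2 else rep(1, n)
  grid <- seq(temps[2], temps[n - 1], by = grid_step_C)
  # drop candidates leaving fewer than 2 points on a side
  ok <- vapply(
    grid,
    function(bp) sum(temps <= bp) >= 2 && sum(temps > bp) >= 2,
    logical(1)
  )
  grid <- grid[ok]
  eval_bp <- function(bp) {
    lo <- temps <= bp
    if (!connected) {
      f1 <- wls_line(temps[lo], dH[lo], w[lo])
      f2 <- wls_line(temps[!lo], dH[!lo], w[!lo])
      list(sse = f1$sse + f2$sse, below = f1, above = f2)
    } else {
      # hinge: dH = b0 + b1 (T - bp) + b2 max(T - bp, 0)
      x1 <- temps - bp
      x2 <- pmax(temps - bp, 0)
      fit <- lm(dH ~ x1 + x2, weights = w)
      cf <- coef(fit)
      sm <- summary(fit)$coefficients
      list(
        sse = sum(w * fit$residuals^2),
        below = list(
          slope = cf[["x1"]],
          tstat = sm["x1", "t value"]
        ),
        above = list(
          slope = cf[["x1"]] + cf[["x2"]],
          tstat = sm["x1", "t value"]
        )
      )
    }
  }
  sses <- vapply(grid, function(bp) eval_bp(bp)$sse, numeric(1))
  best_sse <- min(sses)
  tol <- max(best_sse * 1e-9, 1e-300)
  plateau <- which(sses <= best_sse + tol)
  # the SSE is piecewise constant between sampled temperatures, so the
  # optimum is a plateau [first, last + step); report its midpoint
  bp <- (grid[min(plateau)] + grid[max(plateau)] + grid_step_C) / 2
  best <- eval_bp(bp)
  inversion <- sign(best$below$slope) != sign(best$above$slope)
  significant <- inversion &&
    abs(best$below$tstat) > 2 && abs(best$above$tstat) > 2
  structure(
    list(
      t_star_C = bp,
      slope_below = best$below$slope,
      slope_above = best$above$slope,
      sse = best$sse,
      inversion = inversion,
      significant = significant,
      connected = connected,
      grid_step_C = grid_step_C,
      series = as_tibble(series[, intersect(
        c("temperature_C", "dH_ej_J", "se_J"), names(series)
      )])
    ),
    class = "transition_fit"
  )
}

#' @exportS3Method generics::tidy
tidy.transition_fit <- function(x, ...) {
  tibble(
    term = c("slope_below", "slope_above"),
    estimate = c(x$slope_below, x$slope_above)
  )
}

#' @exportS3Method generics::glance
glance.transition_fit <- function(x, ...) {
  tibble(
    t_star_C = x$t_star_C, slope_below = x$slope_below,
    slope_above = x$slope_above, sse = x$sse,
    inversion = x$inversion, significant = x$significant
  )
}

#' @export
print.transition_fit <- function(x, ...) {
  cat(sprintf(
    "<transition_fit> T* = %.1f C (%s, %s)\n", x$t_star_C,
    if (x$inversion) "slope inversion" else "no inversion",
    if (x$significant) "significant" else "not significant"
  ))
  invisible(x)
}

#' @exportS3Method ggplot2::autoplot
autoplot.transition_fit <- function(object, ...) {
  s <- object$series
  bp <- object$t_star_C
  seg <- bind_rows(
    tibble(
      temperature_C = s$temperature_C[s$temperature_C <= bp],
      side = "below"
    ),
    tibble(
      temperature_C = s$temperature_C[s$temperature_C > bp],
      side = "above"
    )
  )
  ggplot2::ggplot(s, ggplot2::aes(.data$temperature_C, .data$dH_ej_J)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = bp, linetype = "dashed") +
    ggplot2::labs(x = "temperature (C)", y = "dH_ej per virion (J)")
}

#' Transition temperature as a function of Mg concentration
#'
#' Applies [fit_two_segment()] to each enthalpy series and assembles the
#' `T*` map; the `saturated` flag marks concentrations at which `T*`
#' differs from the previous (lower) concentration by less than 1 degree C
#' (counter-ion saturation of the DNA helices).
#'
#' @param series_list A list of enthalpy series (each carrying an `mg_mM`
#'   attribute or column).
#' @param ... Passed to [fit_two_segment()].
#' @return A tibble sorted by `mg_mM` with columns `mg_mM`, `t_star_C`,
#'   `inversion`, `significant`, `saturated`. Per-series fit failures
#'   propagate as absent entries.
#' @export
tstar_vs_mg <- function(series_list, ...) {
  rows <- purrr::map(series_list, function(s) {
    mg <- attr(s, "mg_mM") %||% s$mg_mM[1]
    fit <- tryCatch(fit_two_segment(s, ...), error = function(e) NULL)
    if (is.null(fit)) {
      return(NULL)
    }
    tibble(
      mg_mM = mg, t_star_C = fit$t_star_C,
      inversion = fit$inversion, significant = fit$significant
    )
  })
  out <- bind_rows(purrr::compact(rows)) %>% arrange(.data$mg_mM)
  out$saturated <- c(
    NA,
    abs(diff(out$t_star_C)) < 1
  )[seq_len(nrow(out))]
  out
}
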
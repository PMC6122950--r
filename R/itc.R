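#' Construct a differential-power (DP) trace
#'
#' A DP trace is the heat-flow readout of an ITC instrument: power (ucal/s)
#' versus time (s), with the injection at `injection_time` (default 0) and
#' run metadata attached as attributes. Exothermic deflections are stored as
#' positive released heat flow after background subtraction; the raw
#' instrument polarity, if different, should be recorded in `metadata`.
#'
#' @param time_s Strictly increasing time grid, seconds.
#' @param power_ucal_s Heat flow, microcalories per second.
#' @param metadata Named list; recognised fields include `temperature_C`,
#'   `mg_mM`, `titrant_uL`, `titer_pfu_per_mL`, `injection_time_s`, `seed`.
#' @return A tibble of class `dp_trace` with columns `time_s`,
#'   `power_ucal_s` and the metadata as attribute `"metadata"`.
#' @export
dp_trace <- function(time_s, power_ucal_s, metadata = list()) {
  if (length(time_s) != length(power_ucal_s)) {
    abort("time and power must have equal length", class = "ejectkin_invalid_argument")
  }
  if (length(time_s) > 1 && any(diff(time_s) <= 0)) {
    abort("time grid must be strictly increasing", class = "ejectkin_invalid_argument")
  }
  if (any(!is.finite(power_ucal_s))) {
    abort("power values must be finite", class = "ejectkin_invalid_argument")
  }
  metadata$injection_time_s <- metadata$injection_time_s %||% 0
  out <- tibble(time_s = as.numeric(time_s), power_ucal_s = as.numeric(power_ucal_s))
  attr(out, "metadata") <- metadata
  class(out) <- c("dp_trace", class(out))
  out
}

#' Metadata attached to a trace
#'
#' @param x A `dp_trace`, `ls_trace` or other trace object.
#' @return The metadata list (possibly empty).
#' @export
trace_metadata <- function(x) attr(x, "metadata") %||% list()

#' Write / read a DP trace as CSV with a key=value sidecar
#'
#' The CSV dialect is `time_s,power_ucal_per_s` (UTF-8, '.' decimal, full
#' precision). Metadata are written to `<path>.meta` as `key=value` lines.
#'
#' @param trace A `dp_trace`.
#' @param path Output CSV path.
#' @return `path`, invisibly (write) or a `dp_trace` (read).
#' @export
write_dp_trace <- function(trace, path) {
  df <- data.frame(
    time_s = format(trace$time_s, digits = 17, trim = TRUE, scientific = FALSE),
    power_ucal_per_s = format(trace$power_ucal_s, digits = 17, trim = TRUE)
  )
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- trace_metadata(trace)
  meta_lines <- vapply(
    names(meta),
    function(k) paste0(k, "=", format(meta[[k]], digits = 17)),
    character(1)
  )
  writeLines(meta_lines, paste0(path, ".meta"))
  invisible(path)
}

#' @rdname write_dp_trace
#' @export
read_dp_trace <- function(path) {
  df <- read.csv(path)
  meta <- list()
  meta_path <- paste0(path, ".meta")
  if (file.exists(meta_path)) {
    for (line in readLines(meta_path)) {
      kv <- strsplit(line, "=", fixed = TRUE)[[1]]
      if (length(kv) == 2) {
        val <- suppressWarnings(as.numeric(kv[2]))
        meta[[kv[1]]] <- if (is.na(val)) kv[2] else val
      }
    }
  }
  dp_trace(df$time_s, df$power_ucal_per_s, metadata = meta)
}

resample_onto <- function(trace, time_s) {
  # linear interpolation; constant (baseline) extrapolation outside the span
  approx(trace$time_s, trace$power_ucal_s,
    xout = time_s, rule = 2
  )$y
}

#' Subtract control titrations from a sample DP trace
#'
#' Removes mixing-enthalpy and pressure-volume backgrounds measured in
#' separate control titrations: returns
#' `sample - (phage_into_buffer + buffer_into_lamb - buffer_into_buffer)`.
#' Controls are linearly resampled onto the sample's time grid (constant
#' extrapolation by their edge values); sample metadata are propagated.
#'
#' @param sample A `dp_trace` of the phage-into-LamB titration.
#' @param phage_into_buffer,buffer_into_lamb,buffer_into_buffer Control
#'   `dp_trace`s. The buffer-into-buffer heat is counted in both other
#'   controls, hence added back once.
#' @return A background-subtracted `dp_trace`.
#' @export
subtract_backgrounds <- function(sample, phage_into_buffer, buffer_into_lamb,
                                 buffer_into_buffer) {
  controls <- list(phage_into_buffer, buffer_into_lamb, buffer_into_buffer)
  t_sample <- trace_metadata(sample)$temperature_C
  for (ctrl in controls) {
    t_ctrl <- trace_metadata(ctrl)$temperature_C
    if (!is.null(t_sample) && !is.null(t_ctrl) &&
      abs(t_sample - t_ctrl) > 1e-9) {
      abort(
        "control and sample temperatures differ",
        class = "ejectkin_condition_mismatch"
      )
    }
  }
  bg <- resample_onto(phage_into_buffer, sample$time_s) +
    resample_onto(buffer_into_lamb, sample$time_s) -
    resample_onto(buffer_into_buffer, sample$time_s)
  dp_trace(sample$time_s, sample$power_ucal_s - bg,
    metadata = c(trace_metadata(sample), list(background_subtracted = TRUE))
  )
}

baseline_stats <- function(trace, window_s = 20) {
  # robust baseline and noise sigma from the pre-injection window
  t0 <- trace_metadata(trace)$injection_time_s %||% 0
  pre <- trace$power_ucal_s[trace$time_s < t0 & trace$time_s >= t0 - window_s]
  if (length(pre) < 3) {
    list(baseline = 0, sigma = 0, n = length(pre))
  } else {
    list(baseline = median(pre), sigma = mad(pre), n = length(pre))
  }
}

#' Detect return to baseline (equilibration time)
#'
#' Finds the earliest time after the trace's global extremum at which the
#' absolute deviation from baseline stays below `noise_k * sigma`
#' continuously for `hold_window` seconds. The baseline and noise sigma
#' default to the median and MAD of the 20 s of samples before the
#' injection; both can be overridden, e.g. to apply the detector to a
#' noise-free fitted component curve using the parent trace's noise level.
#'
#' @param trace A background-subtracted `dp_trace`.
#' @param noise_k Threshold multiplier on the noise sigma (default 2).
#' @param hold_window Time the signal must stay within the band, s
#'   (default 10).
#' @param baseline,sigma Optional overrides of the pre-injection estimates.
#' @return Equilibration time in seconds, with attributes `censored`
#'   (TRUE when the trace never settles; the end-of-trace time is returned),
#'   `baseline` and `sigma`.
#' @export
detect_equilibration <- function(trace, noise_k = 2, hold_window = 10,
                                 baseline = NULL, sigma = NULL) {
  bs <- baseline_stats(trace)
  baseline <- baseline %||% bs$baseline
  sigma <- sigma %||% bs$sigma
  dev <- abs(trace$power_ucal_s - baseline)
  i_peak <- which.max(dev)
  thr <- noise_k * sigma
  tt <- trace$time_s
  n <- length(tt)
  inside <- dev <= thr
  t_eq <- NA_real_
  i <- i_peak
  while (i <= n) {
    if (inside[i]) {
      j <- i
      while (j < n && inside[j + 1]) j <- j + 1
      if (tt[j] - tt[i] >= hold_window || j == n) {
        t_eq <- tt[i]
        break
      }
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  censored <- is.na(t_eq)
  if (censored) t_eq <- tt[n]
  structure(t_eq, censored = censored, baseline = baseline, sigma = sigma)
}

virion_count <- function(meta) {
  vol <- meta$titrant_uL
  titer <- meta$titer_pfu_per_mL
  if (is.null(vol) || is.null(titer)) {
    abort(
      "titrant volume and titer metadata are required to count virions",
      class = "ejectkin_unit_error"
    )
  }
  vol * 1e-3 * titer # uL -> mL
}

#' Integrate the ejection enthalpy of a DP trace
#'
#' Trapezoidal integral of the background-subtracted exothermic DP curve,
#' converted from ucal to joules (1 cal = 4.184 J), divided by the number of
#' titrated virions (`titrant_uL * titer_pfu_per_mL`) to give the enthalpy
#' of ejection per virion.
#'
#' @param trace A background-subtracted `dp_trace` with `titrant_uL` and
#'   `titer_pfu_per_mL` metadata.
#' @return A one-row tibble: `total_heat_J`, `dH_ej_J` (per virion),
#'   `n_virions`, `temperature_C`, `mg_mM`.
#' @examples
#' tr <- dp_trace(seq(-20, 40, 0.5),
#'   ifelse(seq(-20, 40, 0.5) >= 0 & seq(-20, 40, 0.5) < 10, 1, 0),
#'   metadata = list(titrant_uL = 2.69, titer_pfu_per_mL = 1e12)
#' )
#' integrate_ejection_enthalpy(tr)
#' @export
integrate_ejection_enthalpy <- function(trace) {
  meta <- trace_metadata(trace)
  n_vir <- virion_count(meta)
  total_ucal <- trapz_integral(trace$time_s, trace$power_ucal_s)
  total_J <- total_ucal / UCAL_PER_J
  tibble(
    total_heat_J = total_J,
    dH_ej_J = total_J / n_vir,
    n_virions = n_vir,
    temperature_C = meta$temperature_C %||% NA_real_,
    mg_mM = meta$mg_mM %||% NA_real_
  )
}

trapz_integral <- function(x, y) {
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}
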
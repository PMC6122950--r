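#' Default intracapsid DNA transition temperatures vs Mg concentration
#'
#' Transition temperature `T*` of the packaged genome's solid-to-fluid
#' transition as a function of MgCl2 concentration: T* rises steeply with
#' the first increase in Mg and saturates at 20 mM and above, where Mg ions
#' saturate the DNA helices.
#'
#' @return A tibble with columns `mg_mM`, `t_star_C`.
#' @export
default_tstar_map <- function() {
  tibble(mg_mM = c(5, 10, 20, 50), t_star_C = c(23, 33, 37, 37))
}

tstar_for_mg <- function(mg_mM, tstar_map = default_tstar_map()) {
  # piecewise-constant-from-the-right lookup with linear interpolation
  approx(tstar_map$mg_mM, tstar_map$t_star_C, xout = mg_mM, rule = 2)$y
}

#' Default per-condition calibration of the ITC scenario generator
#'
#' For ITC scenarios the simulator draws the desynchronized (solid-state)
#' ejection delays from an exponential law whose mean is specified directly
#' per (temperature, Mg) condition, together with the fluid-state share
#' `phi_fast`. The table is the package's calibration of the instrument
#' landmarks it emulates (fast median ~10 s at all temperatures; slow
#' medians ~30/45/55 s at 22 C, 32 C and 37 C / 20 mM; fast fraction 100%
#' at 5 mM and ~10% at >= 20 mM at 37 C; fast/slow baseline returns ~20 s
#' and ~250 s at 22 C). See the methods vignette for how each entry was
#' fixed.
#'
#' @return A tibble with columns `temperature_C`, `mg_mM`, `phi_fast`,
#'   `slow_mean_delay_s`.
#' @export
condition_defaults <- function() {
  tibble::tribble(
    ~temperature_C, ~mg_mM, ~phi_fast, ~slow_mean_delay_s,
    22, 10, 0.12, 54,
    32, 10, 0.12, 97,
    37, 10, 0.99, 6,
    42, 10, 0.995, 5,
    37, 5, 1.00, NA,
    37, 20, 0.10, 126,
    37, 50, 0.08, 130
  )
}

default_prefactor <- function(activation_energy = 1.2e-19, k_ref = 0.01,
                              t_ref_C = 25) {
  # chosen so that k(25 C) = 0.01 1/s; Ea recovery is independent of A
  k_ref * exp(activation_energy / (KB * celsius_to_kelvin(t_ref_C)))
}

#' Simulation configuration for the ejection-kinetics generator
#'
#' Bundles every generator parameter with validation and defaults. Two
#' modes set the desynchronized (solid-state) delay distribution:
#' `"table"` (default for ITC scenarios) takes the exponential mean delay
#' and fluid share `phi_fast` from [condition_defaults()];
#' `"arrhenius"` (default for SAXS scenarios) uses rate
#' `k(T) = A exp(-Ea / kB T)`.
#'
#' @param n_virions Number of virions titrated (simulated events).
#' @param temperature_C Bath temperature, degrees C.
#' @param mg_mM MgCl2 concentration, mM.
#' @param mode `"table"` or `"arrhenius"` (see above).
#' @param phi_fast Fluid-like (synchronized) share in `[0,1]`; `NULL` uses
#'   the condition table (table mode) or the transition map (arrhenius
#'   mode: 1 above `T*`, 0 below).
#' @param slow_mean_delay_s Mean solid-state initiation delay, s; `NULL`
#'   defers to the mode.
#' @param arrhenius_prefactor Arrhenius `A`, 1/s.
#' @param activation_energy Arrhenius `Ea`, J/virion.
#' @param translocation_duration_s Per-virion DNA translocation time, s.
#' @param pulse_shape Beta shape parameters `c(alpha, beta)` of the
#'   rise-then-fall translocation speed profile over the window.
#' @param jitter_max_s Upper bound of the uniform start jitter of
#'   fluid-state virions (mixing plus portal opening), s.
#' @param dH_per_virion_J Heat released per ejection, J.
#' @param irf_tau_s ITC instrument response time constant, s.
#' @param sampling_dt_s DP sampling interval, s.
#' @param noise_sd_ucal_s Additive Gaussian noise sigma on DP traces.
#' @param t_max_s End of the rendered trace, s; `NULL` extends adaptively
#'   past the last event so that all released heat is captured.
#' @param t_pre_s Pre-injection baseline span, s.
#' @param ls_relax_tau_s Diffusive relaxation time of ejected-DNA
#'   condensates in the light-scattering signal, s.
#' @param ls_condensate_weight Relative LS weight `w` of an unrelaxed
#'   condensate (in `[0,1]`).
#' @param ls_noise_sd Additive noise sigma on LS traces (intensity units).
#' @param titrant_uL Injected phage volume, uL.
#' @param titer_pfu_per_mL Phage titer of the titrant. The titration
#'   contains `titer x volume` virions; the `n_virions` simulated events
#'   are a statistical sample of them, so each rendered event carries the
#'   heat of `titer x volume / n_virions` virions and trace amplitudes are
#'   on the instrument's real scale.
#' @param tstar_map Transition-temperature map, as [default_tstar_map()].
#' @param seed Integer RNG seed; identical config + seed gives
#'   bit-identical outputs.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_virions = 100000,
                              temperature_C = 37,
                              mg_mM = 10,
                              mode = c("table", "arrhenius"),
                              phi_fast = NULL,
                              slow_mean_delay_s = NULL,
                              arrhenius_prefactor = NULL,
                              activation_energy = 1.2e-19,
                              translocation_duration_s = 10,
                              pulse_shape = c(8, 4),
                              jitter_max_s = 2,
                              dH_per_virion_J = 1e-15,
                              irf_tau_s = 3.5,
                              sampling_dt_s = 0.25,
                              noise_sd_ucal_s = 1e-4,
                              t_max_s = NULL,
                              t_pre_s = 30,
                              ls_relax_tau_s = 250,
                              ls_condensate_weight = 0.5,
                              ls_noise_sd = 0,
                              titrant_uL = 2.69,
                              titer_pfu_per_mL = 1e12,
                              tstar_map = default_tstar_map(),
                              seed = 1L) {
  mode <- match.arg(mode)
  if (n_virions < 0) abort("n_virions must be >= 0", class = "ejectkin_invalid_argument")
  if (temperature_C <= -273.15) {
    abort("temperature below absolute zero", class = "ejectkin_invalid_argument")
  }
  stopifnot(
    translocation_duration_s > 0, irf_tau_s > 0, sampling_dt_s > 0,
    ls_relax_tau_s > 0, activation_energy >= 0, noise_sd_ucal_s >= 0,
    jitter_max_s >= 0, length(pulse_shape) == 2, all(pulse_shape > 0),
    ls_condensate_weight >= 0, ls_condensate_weight <= 1
  )
  arrhenius_prefactor <- arrhenius_prefactor %||%
    default_prefactor(activation_energy)
  t_star <- tstar_for_mg(mg_mM, tstar_map)
  if (is.null(phi_fast)) {
    if (mode == "table") {
      row <- condition_defaults() %>%
        filter(.data$temperature_C == !!temperature_C, .data$mg_mM == !!mg_mM)
      if (nrow(row) == 1) {
        phi_fast <- row$phi_fast
        slow_mean_delay_s <- slow_mean_delay_s %||% row$slow_mean_delay_s
      } else {
        # condition absent from the calibration table: fluid above T*,
        # mostly solid below
        phi_fast <- if (temperature_C > t_star) 0.99 else 0.12
      }
    } else {
      phi_fast <- if (temperature_C > t_star) 1 else 0
    }
  }
  if (phi_fast < 0 || phi_fast > 1) {
    abort("phi_fast must be in [0, 1]", class = "ejectkin_invalid_argument")
  }
  if (is.null(slow_mean_delay_s)) {
    slow_mean_delay_s <- 1 / arrhenius_rate(
      temperature_C, arrhenius_prefactor, activation_energy
    )
  }
  structure(
    list(
      n_virions = as.integer(n_virions), temperature_C = temperature_C,
      mg_mM = mg_mM, mode = mode, phi_fast = phi_fast,
      slow_mean_delay_s = slow_mean_delay_s,
      arrhenius_prefactor = arrhenius_prefactor,
      activation_energy = activation_energy,
      translocation_duration_s = translocation_duration_s,
      pulse_shape = pulse_shape, jitter_max_s = jitter_max_s,
      dH_per_virion_J = dH_per_virion_J, irf_tau_s = irf_tau_s,
      sampling_dt_s = sampling_dt_s, noise_sd_ucal_s = noise_sd_ucal_s,
      t_max_s = t_max_s, t_pre_s = t_pre_s,
      ls_relax_tau_s = ls_relax_tau_s,
      ls_condensate_weight = ls_condensate_weight,
      ls_noise_sd = ls_noise_sd, titrant_uL = titrant_uL,
      titer_pfu_per_mL = titer_pfu_per_mL,
      n_titrated = titer_pfu_per_mL * titrant_uL * 1e-3,
      tstar_map = tstar_map, seed = as.integer(seed)
    ),
    class = "simulation_config"
  )
}

#' Simulate per-virion ejection event times
#'
#' Each virion is assigned the fluid-like state with probability `phi_fast`.
#' Fluid-state virions start ejecting after a small uniform jitter on
#' `[0, jitter_max_s]` (synchronized events); solid-state virions start
#' after an exponentially distributed delay (memoryless stochastic
#' initiation, rate `k(T)` in arrhenius mode or `1/slow_mean_delay_s` in
#' table mode). Every virion then translocates its genome over
#' `translocation_duration_s`.
#'
#' @param config A [simulation_config()].
#' @return A tibble of class `ejection_events` with columns `virion`,
#'   `state` (`"fluid"`/`"solid"`), `start_s`, `duration_s`; the config is
#'   attached as attribute `"config"`.
#' @export
simulate_ejection_times <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_virions
  if (n == 0) {
    ev <- tibble(
      virion = integer(), state = character(),
      start_s = numeric(), duration_s = numeric()
    )
  } else {
    fluid <- runif(n) < config$phi_fast
    start <- numeric(n)
    start[fluid] <- runif(sum(fluid), 0, config$jitter_max_s)
    start[!fluid] <- rexp(sum(!fluid), rate = 1 / config$slow_mean_delay_s)
    ev <- tibble(
      virion = seq_len(n),
      state = ifelse(fluid, "fluid", "solid"),
      start_s = start,
      duration_s = config$translocation_duration_s
    )
  }
  attr(ev, "config") <- config
  class(ev) <- c("ejection_events", class(ev))
  ev
}

events_config <- function(events) {
  cfg <- attr(events, "config")
  if (is.null(cfg)) abort("events carry no simulation config")
  cfg
}

# Fraction of each virion's genome still ordered inside the capsid at time t:
# 1 before initiation, 1 - (ejected fraction) during translocation, 0 after.
# The ejected fraction follows the cumulative Beta speed profile.
filled_fraction_at <- function(events, t, pulse_shape, duration) {
  if (nrow(events) == 0) {
    return(rep(0, length(t)))
  }
  vapply(t, function(ti) {
    x <- (ti - events$start_s) / duration
    mean(1 - pbeta(x, pulse_shape[1], pulse_shape[2]))
  }, numeric(1))
}

#' Render ejection events into an ITC differential-power trace
#'
#' Each virion contributes a unimodal asymmetric heat pulse of area
#' `dH_per_virion_J` over its translocation window (Beta-profile
#' rise-then-fall release rate: translocation speeds up as intracapsid
#' friction falls, then slows as the driving pressure drops). The population
#' sum is convolved with a normalized exponential instrument response of
#' time constant `irf_tau_s` and Gaussian noise is added. The per-bin heat
#' is computed from exact increments of the cumulative pulse profile, so the
#' noise-free trace integral equals `n_virions x dH_per_virion_J` (the
#' normalized convolution preserves area).
#'
#' @param events An `ejection_events` tibble.
#' @param noise Logical; set `FALSE` for a noise-free trace.
#' @param t_max_s Optional fixed trace end, s (default: adaptive, past the
#'   last event plus several IRF time constants).
#' @return A `dp_trace` with run metadata (temperature, Mg, titrant volume,
#'   derived titer, seed).
#' @export
synthesize_dp_trace <- function(events, noise = TRUE, t_max_s = NULL) {
  cfg <- events_config(events)
  dt <- cfg$sampling_dt_s
  t_end <- t_max_s %||% cfg$t_max_s %||%
    (ceiling(max(c(events$start_s, 0)) + cfg$translocation_duration_s +
      10 * cfg$irf_tau_s + 20))
  edges <- seq(-cfg$t_pre_s, t_end, by = dt)
  mids <- head(edges, -1) + dt / 2
  heat <- numeric(length(mids)) # ucal per bin
  if (nrow(events) > 0) {
    # each simulated event stands for n_titrated / n_virions real virions
    weight <- cfg$n_titrated / cfg$n_virions
    dH_ucal <- cfg$dH_per_virion_J * weight * UCAL_PER_J
    a <- cfg$pulse_shape[1]
    b <- cfg$pulse_shape[2]
    dur <- cfg$translocation_duration_s
    for (i in seq_len(nrow(events))) {
      s <- events$start_s[i]
      i0 <- max(1L, findInterval(s, edges))
      i1 <- min(length(mids), findInterval(s + dur, edges) + 1L)
      if (i1 < i0) next
      idx <- i0:i1
      cdf <- pbeta((edges[c(idx, i1 + 1L)] - s) / dur, a, b)
      heat[idx] <- heat[idx] + dH_ucal * diff(cdf)
    }
  }
  power <- heat / dt
  # causal exponential IRF, normalized in discrete form so area is conserved
  kern <- exp(-(0:ceiling(10 * cfg$irf_tau_s / dt)) * dt / cfg$irf_tau_s)
  kern <- kern / sum(kern)
  if (length(kern) > 1) {
    conv <- stats::convolve(power, rev(kern), type = "open")
    power <- conv[seq_along(power)]
  }
  if (noise && cfg$noise_sd_ucal_s > 0) {
    set.seed(cfg$seed + 104729L) # decoupled from the event stream
    power <- power + rnorm(length(power), 0, cfg$noise_sd_ucal_s)
  }
  dp_trace(mids, power, metadata = list(
    temperature_C = cfg$temperature_C, mg_mM = cfg$mg_mM,
    titrant_uL = cfg$titrant_uL,
    titer_pfu_per_mL = cfg$titer_pfu_per_mL,
    injection_time_s = 0, seed = cfg$seed,
    dH_per_virion_J = cfg$dH_per_virion_J,
    noise_sd_ucal_s = if (noise) cfg$noise_sd_ucal_s else 0,
    background_subtracted = TRUE
  ))
}

#' Render ejection events into a light-scattering intensity trace
#'
#' The LS intensity is the filled-capsid fraction plus `w` times the
#' fraction of ejected-but-unrelaxed DNA condensates: a capsid contributes 1
#' until its translocation completes, after which its condensate contributes
#' `w * exp(-(t - t_complete) / ls_relax_tau_s)`. For `w <= 1` the
#' noise-free trace is monotone non-increasing. This condensate relaxation
#' term is the bias that makes LS overestimate the total ejection time.
#'
#' @param events An `ejection_events` tibble.
#' @param w Condensate weight in `[0,1]`; default from the config.
#' @param sampling_dt_s LS sampling interval, s.
#' @param t_max_s Optional fixed trace end, s.
#' @param noise Logical; add Gaussian noise of config sigma.
#' @return A tibble of class `ls_trace` with columns `time_s`, `intensity`.
#' @export
synthesize_ls_trace <- function(events, w = NULL, sampling_dt_s = 1,
                                t_max_s = NULL, noise = TRUE) {
  cfg <- events_config(events)
  w <- w %||% cfg$ls_condensate_weight
  t_end <- t_max_s %||%
    (ceiling(max(c(events$start_s, 0)) + cfg$translocation_duration_s +
      5 * cfg$ls_relax_tau_s))
  tt <- seq(0, t_end, by = sampling_dt_s)
  n <- max(nrow(events), 1L)
  done <- sort(events$start_s + events$duration_s)
  tau <- cfg$ls_relax_tau_s
  # filled count and condensate sum via the sorted completion times:
  # sum_i exp(-(t - done_i)/tau) over done_i <= t = exp(-t/tau) cumsum(exp(done_i/tau))
  idx <- findInterval(tt, done)
  filled <- length(done) - idx
  if (w > 0 && length(done) > 0 && max(done) / tau < 500) {
    cs <- c(0, cumsum(exp(done / tau)))
    relax <- w * exp(-tt / tau) * cs[idx + 1]
  } else if (w > 0 && length(done) > 0) {
    relax <- vapply(tt, function(ti) {
      el <- ti - done[done <= ti]
      w * sum(exp(-el / tau))
    }, numeric(1))
  } else {
    relax <- 0
  }
  intensity <- (filled + relax) / n
  if (noise && cfg$ls_noise_sd > 0) {
    set.seed(cfg$seed + 224737L)
    intensity <- intensity + rnorm(length(intensity), 0, cfg$ls_noise_sd)
  }
  out <- tibble(time_s = tt, intensity = intensity)
  attr(out, "metadata") <- list(
    temperature_C = cfg$temperature_C, mg_mM = cfg$mg_mM,
    ls_relax_tau_s = cfg$ls_relax_tau_s, condensate_weight = w,
    n_virions = cfg$n_virions, n_titrated = cfg$n_titrated, seed = cfg$seed
  )
  class(out) <- c("ls_trace", class(out))
  out
}

#' Default SAXS rendering parameters
#'
#' @param q_min,q_max,dq q-grid, 1/Angstrom.
#' @param peak_center_invA DNA diffraction peak center `q0`; fixed in time
#'   (short-range interaxial DNA spacing does not change while the capsid
#'   drains on this timescale).
#' @param peak_sigma_invA Gaussian peak width.
#' @param peak_area_max Peak area at full capsid occupancy, intensity x
#'   1/Angstrom.
#' @param frame_interval_s Time between frames, s (instrumentally 2-10 s).
#' @param t_max_s Last frame time, s.
#' @param noise_sd Additive intensity noise per q-point.
#' @param bg_coefs Mixing coefficients of the component backgrounds
#'   (TM buffer, 1% oPOE, LamB).
#' @param local_slope,local_intercept Linear local background under the
#'   peak window.
#' @return A list of class `saxs_config`.
#' @export
saxs_config <- function(q_min = 0.10, q_max = 0.40, dq = 0.002,
                        peak_center_invA = 0.25, peak_sigma_invA = 0.015,
                        peak_area_max = 5, frame_interval_s = 5,
                        t_max_s = 400, noise_sd = 0,
                        bg_coefs = c(buffer = 1, opoe = 0.8, lamb = 0.5),
                        local_slope = -0.4, local_intercept = 0.3) {
  if (frame_interval_s <= 0) {
    abort("frame interval must be positive", class = "ejectkin_invalid_argument")
  }
  stopifnot(q_min < 0.15, q_max > 0.35, dq > 0)
  structure(as.list(environment()), class = "saxs_config")
}

saxs_component_profiles <- function(q) {
  # smooth featureless scatterers on the DNA-peak flanks
  tibble(
    q_invA = q,
    buffer = 2.0 * exp(-3.0 * q) + 0.20,
    opoe = 1.2 * exp(-((q - 0.05) / 0.12)^2) + 0.10,
    lamb = 0.9 / (1 + (q / 0.08)^2) + 0.05
  )
}

#' Render ejection events into a time-resolved SAXS frame series
#'
#' Each frame is a Gaussian DNA diffraction peak centered at `q0` whose area
#' is proportional to the ordered intracapsid DNA remaining at frame time
#' (the filled-capsid count), plus a linear local background and a fixed
#' linear combination of component backgrounds (TM buffer, oPOE detergent,
#' LamB receptor) with known coefficients, plus optional noise.
#'
#' @param events An `ejection_events` tibble.
#' @param cfg A [saxs_config()].
#' @return A tibble of class `saxs_series` with columns `time_s`, `q_invA`,
#'   `intensity`; attributes `"backgrounds"` (component profiles on the
#'   q-grid), `"truth"` (per-frame filled fraction and true peak area) and
#'   `"saxs_config"`.
#' @export
synthesize_saxs_series <- function(events, cfg = saxs_config()) {
  stopifnot(inherits(cfg, "saxs_config"))
  sim <- events_config(events)
  q <- seq(cfg$q_min, cfg$q_max, by = cfg$dq)
  comps <- saxs_component_profiles(q)
  bg_fixed <- cfg$bg_coefs["buffer"] * comps$buffer +
    cfg$bg_coefs["opoe"] * comps$opoe +
    cfg$bg_coefs["lamb"] * comps$lamb
  times <- seq(0, cfg$t_max_s, by = cfg$frame_interval_s)
  filled <- filled_fraction_at(
    events, times, sim$pulse_shape, sim$translocation_duration_s
  )
  peak_shape <- dnorm(q, cfg$peak_center_invA, cfg$peak_sigma_invA)
  local_bg <- cfg$local_intercept + cfg$local_slope * q
  if (cfg$noise_sd > 0) set.seed(sim$seed + 350377L)
  frames <- purrr::map2(times, filled, function(ti, fi) {
    intens <- fi * cfg$peak_area_max * peak_shape + local_bg + bg_fixed
    if (cfg$noise_sd > 0) intens <- intens + rnorm(length(q), 0, cfg$noise_sd)
    tibble(time_s = ti, q_invA = q, intensity = intens)
  })
  out <- bind_rows(frames)
  attr(out, "backgrounds") <- comps
  attr(out, "truth") <- tibble(
    time_s = times, filled_fraction = filled,
    peak_area = filled * cfg$peak_area_max
  )
  attr(out, "saxs_config") <- cfg
  attr(out, "metadata") <- list(
    temperature_C = sim$temperature_C, mg_mM = sim$mg_mM, seed = sim$seed
  )
  class(out) <- c("saxs_series", class(out))
  out
}

#' Write / read a SAXS frame series as per-frame text files
#'
#' Frames are written as two-column whitespace-separated text
#' (`q_invA intensity`) named `frame_<time>.dat`; component backgrounds as
#' `background_<name>.dat` in the same format.
#'
#' @param series A `saxs_series`.
#' @param dir Output directory (created if needed).
#' @return `dir` invisibly (write); a `saxs_series` without truth
#'   attributes (read).
#' @export
write_saxs_frames <- function(series, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ti in unique(series$time_s)) {
    fr <- series[series$time_s == ti, c("q_invA", "intensity")]
    write.table(fr, file.path(dir, sprintf("frame_%g.dat", ti)),
      row.names = FALSE, col.names = FALSE
    )
  }
  comps <- attr(series, "backgrounds")
  if (!is.null(comps)) {
    for (nm in setdiff(names(comps), "q_invA")) {
      write.table(comps[, c("q_invA", nm)],
        file.path(dir, sprintf("background_%s.dat", nm)),
        row.names = FALSE, col.names = FALSE
      )
    }
  }
  invisible(dir)
}

#' @rdname write_saxs_frames
#' @export
read_saxs_frames <- function(dir) {
  files <- list.files(dir, pattern = "^frame_.*\\.dat$", full.names = TRUE)
  times <- as.numeric(sub("^frame_(.*)\\.dat$", "\\1", basename(files)))
  ord <- order(times)
  out <- bind_rows(purrr::map2(files[ord], times[ord], function(f, ti) {
    df <- read.table(f, col.names = c("q_invA", "intensity"))
    tibble(time_s = ti, q_invA = df$q_invA, intensity = df$intensity)
  }))
  bg_files <- list.files(dir, pattern = "^background_.*\\.dat$", full.names = TRUE)
  if (length(bg_files)) {
    comps <- NULL
    for (f in bg_files) {
      nm <- sub("^background_(.*)\\.dat$", "\\1", basename(f))
      df <- read.table(f, col.names = c("q_invA", nm))
      comps <- if (is.null(comps)) as_tibble(df) else dplyr::left_join(comps, df, by = "q_invA")
    }
    attr(out, "backgrounds") <- comps
  }
  class(out) <- c("saxs_series", class(out))
  out
}

#' Generate a synthetic ejection-enthalpy-versus-temperature series
#'
#' Piecewise-linear `dH_ej(T)` with opposite-sign slopes meeting at the
#' transition temperature `T*` for the given Mg concentration (from the
#' transition map), with optional Gaussian noise. The slope inversion is the
#' calorimetric signature of the intracapsid solid-to-fluid DNA transition.
#'
#' @param temperatures_C Measurement temperatures, degrees C (increasing).
#' @param mg_mM MgCl2 concentration, mM.
#' @param noise_sd Gaussian noise sigma on `dH_ej`, J (0 = noise-free).
#' @param dH_at_tstar_J Enthalpy per virion at the breakpoint, J.
#' @param slope_below_J_per_C,slope_above_J_per_C Segment slopes (specific
#'   heat proxies), J/virion/degree C; must have opposite signs.
#' @param tstar_map Transition map as [default_tstar_map()].
#' @param seed RNG seed used when `noise_sd > 0`.
#' @return A tibble of class `enthalpy_series` with columns
#'   `temperature_C`, `dH_ej_J`, `se_J`; attributes `mg_mM`,
#'   `t_star_true_C` and `few_points_warning` (fewer than 3 temperatures on
#'   either side of `T*`).
#' @export
synthesize_enthalpy_series <- function(temperatures_C, mg_mM = 10,
                                       noise_sd = 0,
                                       dH_at_tstar_J = 1.6e-15,
                                       slope_below_J_per_C = 4e-17,
                                       slope_above_J_per_C = -6e-17,
                                       tstar_map = default_tstar_map(),
                                       seed = 1L) {
  stopifnot(all(diff(temperatures_C) > 0))
  if (sign(slope_below_J_per_C) == sign(slope_above_J_per_C)) {
    warn("segment slopes share a sign: no inversion will be present")
  }
  t_star <- tstar_for_mg(mg_mM, tstar_map)
  dH <- ifelse(
    temperatures_C <= t_star,
    dH_at_tstar_J + slope_below_J_per_C * (temperatures_C - t_star),
    dH_at_tstar_J + slope_above_J_per_C * (temperatures_C - t_star)
  )
  if (noise_sd > 0) {
    set.seed(seed)
    dH <- dH + rnorm(length(dH), 0, noise_sd)
  }
  few <- sum(temperatures_C < t_star) < 3 || sum(temperatures_C > t_star) < 3
  if (few) warn("fewer than 3 temperatures on one side of T*")
  out <- tibble(
    temperature_C = temperatures_C,
    dH_ej_J = dH,
    se_J = rep(noise_sd, length(dH))
  )
  attr(out, "mg_mM") <- mg_mM
  attr(out, "t_star_true_C") <- t_star
  attr(out, "few_points_warning") <- few
  class(out) <- c("enthalpy_series", class(out))
  out
}
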
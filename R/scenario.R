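#' Paper-defaults scenario landmarks
#'
#' The headline quantities the default synthetic scenario is calibrated to
#' reproduce, with the tolerance used in the report's pass/fail column.
#'
#' @return A tibble: `metric`, `target`, `tolerance`, `tolerance_kind`.
#' @export
scenario_landmarks <- function() {
  tibble::tribble(
    ~metric, ~target, ~tolerance, ~tolerance_kind,
    "median_fast_s_common", 10, 0.2, "relative",
    "median_slow_s_22C_10mM", 30, 0.2, "relative",
    "median_slow_s_32C_10mM", 45, 0.2, "relative",
    "median_slow_s_37C_20mM", 55, 0.2, "relative",
    "equilibration_fast_s", 20, 0.2, "relative",
    "equilibration_slow_s_22C", 250, 0.2, "relative",
    "fraction_fast_pct_5mM_37C", 100, 5, "absolute",
    "fraction_fast_pct_20mM_37C", 10, 5, "absolute",
    "t_star_C_10mM", 33, 1, "absolute",
    "t_star_C_20mM", 37, 1, "absolute",
    "Ea_J_saxs", 1.2e-19, 0.25, "relative"
  )
}

itc_scenario_conditions <- function() {
  condition_defaults()[, c("temperature_C", "mg_mM")]
}

#' Run one ITC condition of the default scenario
#'
#' Simulates events, renders the DP trace, deconvolves it and derives the
#' population metrics.
#'
#' @param temperature_C,mg_mM Condition.
#' @param n_virions Simulated virions.
#' @param seed RNG seed.
#' @param mode EMG model selection mode (see [fit_dp_curve()]).
#' @return A one-row tibble of condition, fit mode and population metrics,
#'   with the `dp_fit` attached as attribute `"fit"`.
#' @export
run_itc_condition <- function(temperature_C, mg_mM, n_virions = 100000,
                              seed = 1L, mode = "auto") {
  cfg <- simulation_config(
    n_virions = n_virions, temperature_C = temperature_C, mg_mM = mg_mM,
    seed = seed
  )
  events <- simulate_ejection_times(cfg)
  trace <- synthesize_dp_trace(events)
  fit <- fit_dp_curve(trace, mode = mode)
  metrics <- population_metrics(fit)
  out <- bind_cols(
    tibble(
      temperature_C = temperature_C, mg_mM = mg_mM,
      mode = fit$mode, phi_fast_true = cfg$phi_fast
    ),
    metrics
  )
  attr(out, "fit") <- fit
  out
}

#' Run the SAXS Arrhenius arm of the default scenario
#'
#' Simulates solid-population (desynchronized) peak-area decays at the
#' given temperatures in Arrhenius mode, reduces each frame series to peak
#' areas, extracts the slow-regime rate constants (`t > t_split`) and fits
#' the Arrhenius law.
#'
#' @param temperatures_C Temperatures of the rate series.
#' @param n_virions Virions per temperature.
#' @param seed RNG seed.
#' @param activation_energy,arrhenius_prefactor Ground-truth Arrhenius
#'   parameters of the simulation (defaults: the package defaults).
#' @param t_split_s Fast/slow regime split, s.
#' @param phi_fast Fluid (synchronized) share; 0 isolates the
#'   desynchronized population whose rates carry the activation energy.
#' @param noise_sd Per-point SAXS intensity noise.
#' @return A list: `arrhenius` (an `arrhenius_fit`), `rates` (per
#'   temperature), `truth` (generator parameters).
#' @export
run_saxs_scenario <- function(temperatures_C = c(25, 30, 37),
                              n_virions = 5000, seed = 1L,
                              activation_energy = 1.2e-19,
                              arrhenius_prefactor = NULL,
                              t_split_s = 20, noise_sd = 0.005,
                              phi_fast = 0) {
  rates <- purrr::imap_dfr(temperatures_C, function(temp, i) {
    cfg <- simulation_config(
      n_virions = n_virions, temperature_C = temp, mode = "arrhenius",
      phi_fast = phi_fast, activation_energy = activation_energy,
      arrhenius_prefactor = arrhenius_prefactor,
      seed = seed + 1000L * i
    )
    events <- simulate_ejection_times(cfg)
    k_true <- 1 / cfg$slow_mean_delay_s
    # follow the decay over a few characteristic times
    t_max <- min(max(120, ceiling(4 / k_true)), 900)
    series <- synthesize_saxs_series(
      events,
      saxs_config(t_max_s = t_max, noise_sd = noise_sd)
    )
    areas <- peak_area_series(series)
    bind_cols(
      ejection_rates(areas, t_split_s = t_split_s)[, c(
        "k_fast", "k_slow", "r2_fast", "r2_slow"
      )],
      tibble(temperature_C = temp, k_true = k_true)
    )
  })
  arr <- arrhenius_fit(
    tibble(temperature_C = rates$temperature_C, k = rates$k_slow)
  )
  list(
    arrhenius = arr,
    rates = rates,
    truth = list(
      activation_energy = activation_energy,
      arrhenius_prefactor = arrhenius_prefactor %||%
        default_prefactor(activation_energy)
    )
  )
}

#' Run the transition-temperature arm of the default scenario
#'
#' Generates a noise-free enthalpy series per Mg concentration on a 2
#' degree grid around the condition's transition temperature and fits the
#' two-segment breakpoint.
#'
#' @param mg_mM Concentrations to scan.
#' @param grid_from_C Lower edge of the temperature grid (default 22,
#'   lowered when `T*` sits close to it).
#' @return A tibble from [tstar_vs_mg()] plus the true `T*` per entry.
#' @export
run_transition_scenario <- function(mg_mM = c(5, 10, 20, 50),
                                    grid_from_C = 22) {
  series_list <- purrr::map(mg_mM, function(mg) {
    t_star <- tstar_for_mg(mg)
    lo <- min(grid_from_C, t_star - 7)
    temps <- seq(lo, t_star + 9, by = 2)
    synthesize_enthalpy_series(temps, mg_mM = mg, noise_sd = 0)
  })
  map <- tstar_vs_mg(series_list)
  map$t_star_true_C <- tstar_for_mg(map$mg_mM)
  map
}

#' Run the light-scattering comparison arm of the default scenario
#'
#' Simulates the 22 C / 10 mM condition, renders matched DP and LS traces,
#' normalizes and differentiates the LS decay and scales it into heat-flow
#' units for overlay.
#'
#' @param n_virions,seed As elsewhere.
#' @return A list: `overlay` (tibble `time_s`, `power_ucal_s` from LS),
#'   `dp_equilibration_s`, `ls_rate`, `dp_trace`.
#' @export
run_ls_scenario <- function(n_virions = 100000, seed = 1L) {
  cfg <- simulation_config(
    n_virions = n_virions, temperature_C = 22, mg_mM = 10, seed = seed
  )
  events <- simulate_ejection_times(cfg)
  dp <- synthesize_dp_trace(events)
  ls <- synthesize_ls_trace(events, noise = FALSE)
  norm <- normalize_intensity(ls)
  deriv <- differentiate_decay(norm)
  overlay <- scale_to_itc(deriv, cfg$n_titrated, cfg$dH_per_virion_J)
  list(
    overlay = overlay,
    dp_equilibration_s = as.numeric(detect_equilibration(dp)),
    ls_rate = attr(norm, "fit")$rate,
    dp_trace = dp
  )
}

check_landmark <- function(value, target, tolerance, kind) {
  if (!is.finite(value)) {
    return(FALSE)
  }
  if (kind == "relative") {
    abs(value - target) <= tolerance * abs(target)
  } else {
    abs(value - target) <= tolerance
  }
}

#' Run the full reproduce-defaults scenario
#'
#' Simulates every default ITC condition, the transition-temperature scan,
#' the SAXS Arrhenius arm and the LS comparison, and assembles a structured
#' report comparing the recovered metrics to the generator ground truth and
#' to the scenario landmarks. With `out_dir` set, traces (CSV), per-stage
#' tables (CSV) and the report (JSON) are written; runs with the same seed
#' produce byte-identical reports.
#'
#' @param seed Integer seed driving every stage.
#' @param n_virions Virions per simulated condition.
#' @param out_dir Optional output directory.
#' @return A list of class `scenario_report`: `itc_metrics`, `tstar_map`,
#'   `saxs`, `ls`, `landmarks` (with `value` and `pass` columns), `seed`.
#' @export
run_scenario <- function(seed = 1L, n_virions = 100000, out_dir = NULL) {
  conds <- itc_scenario_conditions()
  itc <- purrr::imap(
    purrr::transpose(as.list(conds)),
    function(cond, i) {
      run_itc_condition(
        cond$temperature_C, cond$mg_mM,
        n_virions = n_virions, seed = seed + 100L * i
      )
    }
  )
  itc_metrics <- bind_rows(itc)
  tstar_map <- run_transition_scenario()
  saxs <- run_saxs_scenario(seed = seed, n_virions = n_virions)
  ls <- run_ls_scenario(n_virions = n_virions, seed = seed)

  pick <- function(temp, mg, col) {
    row <- itc_metrics$temperature_C == temp & itc_metrics$mg_mM == mg
    if (!any(row)) {
      return(NA_real_)
    }
    itc_metrics[[col]][row][1]
  }
  fast_meds <- itc_metrics$median_fast_s[itc_metrics$mg_mM == 10]
  lm_tbl <- scenario_landmarks()
  values <- c(
    median_fast_s_common = mean(fast_meds),
    median_slow_s_22C_10mM = pick(22, 10, "median_slow_s"),
    median_slow_s_32C_10mM = pick(32, 10, "median_slow_s"),
    median_slow_s_37C_20mM = pick(37, 20, "median_slow_s"),
    equilibration_fast_s = mean(c(
      pick(22, 10, "equilibration_fast_s"), pick(32, 10, "equilibration_fast_s")
    )),
    equilibration_slow_s_22C = pick(22, 10, "equilibration_slow_s"),
    fraction_fast_pct_5mM_37C = 100 * pick(37, 5, "fraction_fast"),
    fraction_fast_pct_20mM_37C = 100 * pick(37, 20, "fraction_fast"),
    t_star_C_10mM = tstar_map$t_star_C[tstar_map$mg_mM == 10],
    t_star_C_20mM = tstar_map$t_star_C[tstar_map$mg_mM == 20],
    Ea_J_saxs = saxs$arrhenius$Ea_J
  )
  lm_tbl$value <- unname(values[lm_tbl$metric])
  lm_tbl$pass <- purrr::pmap_lgl(
    lm_tbl[, c("value", "target", "tolerance", "tolerance_kind")],
    function(value, target, tolerance, tolerance_kind) {
      check_landmark(value, target, tolerance, tolerance_kind)
    }
  )
  report <- structure(
    list(
      itc_metrics = itc_metrics,
      tstar_map = tstar_map,
      saxs_rates = saxs$rates,
      arrhenius = glance(saxs$arrhenius),
      ls = tibble(
        ls_rate_per_s = ls$ls_rate,
        dp_equilibration_s = ls$dp_equilibration_s
      ),
      landmarks = lm_tbl,
      seed = seed,
      n_virions = n_virions,
      units = list(
        median_s = "s", equilibration_s = "s", fraction_fast = "unitless",
        t_star_C = "degC", Ea_J = "J/virion", k = "1/s"
      )
    ),
    class = "scenario_report"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(itc_metrics[, !vapply(itc_metrics, is.list, logical(1))],
      file.path(out_dir, "itc_metrics.csv"),
      row.names = FALSE
    )
    write.csv(tstar_map, file.path(out_dir, "tstar_map.csv"), row.names = FALSE)
    write.csv(saxs$rates, file.path(out_dir, "saxs_rates.csv"), row.names = FALSE)
    write.csv(lm_tbl, file.path(out_dir, "landmarks.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(
        seed = seed, n_virions = n_virions,
        landmarks = lm_tbl, tstar_map = tstar_map,
        arrhenius = glance(saxs$arrhenius),
        itc_metrics = itc_metrics
      ),
      file.path(out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  report
}

#' @export
print.scenario_report <- function(x, ...) {
  cat(sprintf(
    "<scenario_report> seed %d, %d virions/condition\n", x$seed, x$n_virions
  ))
  print(x$landmarks[, c("metric", "target", "value", "pass")])
  invisible(x)
}
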
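test_that("event simulation honours population structure and degenerate limits", {
  empty <- simulate_ejection_times(simulation_config(n_virions = 0, seed = 1))
  expect_equal(nrow(empty), 0)

  all_fast <- simulate_ejection_times(simulation_config(
    n_virions = 50, phi_fast = 1, jitter_max_s = 0, seed = 1
  ))
  expect_true(all(all_fast$start_s == 0))
  expect_true(all(all_fast$state == "fluid"))

  expect_error(
    simulation_config(n_virions = -1),
    class = "ejectkin_invalid_argument"
  )
  expect_error(
    simulation_config(temperature_C = -300),
    class = "ejectkin_invalid_argument"
  )
})

test_that("solid-state delays follow the exponential law with the configured mean", {
  D <- 80
  cfg <- simulation_config(
    n_virions = 1e5, phi_fast = 0, slow_mean_delay_s = D, seed = 3
  )
  ev <- simulate_ejection_times(cfg)
  # sample mean within 3 standard errors of the analytic exponential mean
  se <- D / sqrt(nrow(ev))
  expect_lt(abs(mean(ev$start_s) - D), 3 * se)
  # empirical survival matches exp(-t/D): KS distance below 0.02
  ks <- suppressWarnings(stats::ks.test(ev$start_s, "pexp", rate = 1 / D))
  expect_lt(unname(ks$statistic), 0.02)
})

test_that("Arrhenius mode rates increase strictly with temperature", {
  k <- arrhenius_rate(c(10, 20, 30, 40), 4.6e10, 1.2e-19)
  expect_true(all(diff(k) > 0))
  cfg_cold <- simulation_config(temperature_C = 20, mode = "arrhenius", seed = 1)
  cfg_warm <- simulation_config(temperature_C = 35, mode = "arrhenius", seed = 1)
  expect_gt(cfg_cold$slow_mean_delay_s, cfg_warm$slow_mean_delay_s)
})

test_that("identical config and seed give bit-identical events and traces", {
  cfg <- simulation_config(n_virions = 2000, temperature_C = 22, seed = 11)
  e1 <- simulate_ejection_times(cfg)
  e2 <- simulate_ejection_times(cfg)
  expect_identical(serialize(e1, NULL), serialize(e2, NULL))
  t1 <- synthesize_dp_trace(e1)
  t2 <- synthesize_dp_trace(e2)
  expect_identical(serialize(t1, NULL), serialize(t2, NULL))
})

test_that("the noise-free DP trace conserves the released heat", {
  # one titrated virion: trace integral equals dH_per_virion to 0.1%
  cfg1 <- simulation_config(
    n_virions = 1, phi_fast = 1, titrant_uL = 2.69,
    titer_pfu_per_mL = 1 / 2.69e-3, seed = 4
  )
  tr1 <- synthesize_dp_trace(simulate_ejection_times(cfg1), noise = FALSE)
  area1 <- sum(diff(tr1$time_s) * (head(tr1$power_ucal_s, -1) + tail(tr1$power_ucal_s, -1)) / 2)
  expect_equal(area1 / (1e6 / 4.184), cfg1$dH_per_virion_J, tolerance = 1e-3)

  # full default 22 C condition: integral equals titrated count x dH
  cfg <- simulation_config(n_virions = 5000, temperature_C = 22, mg_mM = 10, seed = 4)
  tr <- synthesize_dp_trace(simulate_ejection_times(cfg), noise = FALSE)
  area <- sum(diff(tr$time_s) * (head(tr$power_ucal_s, -1) + tail(tr$power_ucal_s, -1)) / 2)
  expect_equal(
    area / (1e6 / 4.184),
    cfg$n_titrated * cfg$dH_per_virion_J,
    tolerance = 1e-3
  )
})

test_that("a vanishing instrument response leaves the pulse sum unchanged", {
  cfg <- simulation_config(
    n_virions = 200, phi_fast = 1, sampling_dt_s = 0.25,
    irf_tau_s = 0.25 / 100, seed = 6
  )
  ev <- simulate_ejection_times(cfg)
  tr <- synthesize_dp_trace(ev, noise = FALSE)
  # oracle: direct per-virion accumulation of exact pulse increments
  edges <- c(tr$time_s - 0.125, tail(tr$time_s, 1) + 0.125)
  expected <- numeric(nrow(tr))
  dH_ucal <- cfg$dH_per_virion_J * (cfg$n_titrated / cfg$n_virions) * (1e6 / 4.184)
  for (s in ev$start_s) {
    cdf <- pbeta((edges - s) / cfg$translocation_duration_s, 8, 4)
    expected <- expected + dH_ucal * diff(cdf) / 0.25
  }
  rms_rel <- sqrt(mean((tr$power_ucal_s - expected)^2)) / max(expected)
  expect_lt(rms_rel, 0.01)
})

test_that("default conditions reproduce the single- vs two-peak phenomenology", {
  # above the transition temperature: one exothermic peak (unimodal fit)
  warm <- run_itc_condition(37, 10, seed = 1)
  expect_equal(warm$mode, "unimodal")
  # below it: the DP curve splits into two resolvable modes
  cold <- run_itc_condition(22, 10, seed = 1)
  expect_equal(cold$mode, "bimodal")
  expect_lt(cold$median_fast_s, cold$median_slow_s)
})

test_that("LS trace counts filled capsids exactly when condensates are off", {
  cfg <- simulation_config(n_virions = 500, temperature_C = 22, seed = 7)
  ev <- simulate_ejection_times(cfg)
  ls <- synthesize_ls_trace(ev, w = 0, noise = FALSE)
  done <- ev$start_s + ev$duration_s
  expected <- vapply(ls$time_s, function(ti) sum(done > ti) / 500, numeric(1))
  expect_equal(ls$intensity, expected, tolerance = 1e-12)
  # monotone non-increasing for w <= 1
  ls_w <- synthesize_ls_trace(ev, w = 0.7, noise = FALSE)
  expect_true(all(diff(ls_w$intensity) <= 1e-12))
})

test_that("a non-ejecting population gives a flat LS trace", {
  cfg <- simulation_config(
    n_virions = 300, phi_fast = 0, slow_mean_delay_s = 1e9, seed = 8
  )
  ls <- synthesize_ls_trace(simulate_ejection_times(cfg),
    t_max_s = 500, noise = FALSE
  )
  expect_true(all(ls$intensity == 1))
})

test_that("SAXS frames carry the configured peak, backgrounds and timestamps", {
  scfg <- saxs_config(frame_interval_s = 5, t_max_s = 60)
  # delayed population: every capsid still filled at t = 0
  cfg <- simulation_config(
    n_virions = 100, phi_fast = 0, slow_mean_delay_s = 1e6, seed = 9
  )
  ev <- simulate_ejection_times(cfg)
  ser <- synthesize_saxs_series(ev, scfg)
  expect_equal(unique(ser$time_s), seq(0, 60, by = 5))

  comps <- attr(ser, "backgrounds")
  f0 <- ser[ser$time_s == 0, ]
  bg_fixed <- comps$buffer * 1 + comps$opoe * 0.8 + comps$lamb * 0.5
  local_bg <- 0.3 - 0.4 * f0$q_invA
  residual <- f0$intensity - bg_fixed - local_bg
  # quadrature of the residual Gaussian equals the configured maximum area
  area <- sum(diff(f0$q_invA) * (head(residual, -1) + tail(residual, -1)) / 2)
  expect_equal(area, scfg$peak_area_max, tolerance = 1e-3)

  # fully ejected: pure background remains
  ev2 <- ev
  ev2$start_s <- rep(0, nrow(ev2))
  attr(ev2, "config") <- attr(ev, "config")
  ser2 <- synthesize_saxs_series(ev2, scfg)
  f_late <- ser2[ser2$time_s == 60, ]
  expect_equal(
    f_late$intensity, bg_fixed + 0.3 - 0.4 * f_late$q_invA,
    tolerance = 1e-12
  )
  expect_error(saxs_config(frame_interval_s = 0), class = "ejectkin_invalid_argument")
})

test_that("the synthetic enthalpy series is an exact two-segment construction", {
  temps <- seq(23, 43, by = 2)
  ser <- synthesize_enthalpy_series(temps, mg_mM = 10, noise_sd = 0)
  t_star <- attr(ser, "t_star_true_C")
  expect_equal(t_star, 33)
  below <- ser$temperature_C <= t_star
  d_below <- diff(ser$dH_ej_J[below]) / diff(ser$temperature_C[below])
  d_above <- diff(ser$dH_ej_J[!below]) / diff(ser$temperature_C[!below])
  expect_true(all(abs(d_below - d_below[1]) < 1e-25))
  expect_true(all(abs(d_above - d_above[1]) < 1e-25))
  expect_true(sign(d_below[1]) != sign(d_above[1]))

  expect_warning(
    synthesize_enthalpy_series(c(31, 33, 35, 37, 39), mg_mM = 10),
    "fewer than 3"
  )
  # 50 mM shares the saturated 20 mM breakpoint
  expect_equal(
    attr(synthesize_enthalpy_series(seq(26, 46, 2), mg_mM = 50), "t_star_true_C"),
    attr(synthesize_enthalpy_series(seq(26, 46, 2), mg_mM = 20), "t_star_true_C")
  )
})
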
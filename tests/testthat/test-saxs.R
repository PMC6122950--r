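test_that("background decomposition recovers constructed mixtures exactly", {
  q <- seq(0.10, 0.40, 0.002)
  comps <- ejectkin:::saxs_component_profiles(q)
  truth <- c(buffer = 1.3, opoe = 0.4, lamb = 0.9)
  frame <- tibble::tibble(
    q_invA = q,
    intensity = truth["buffer"] * comps$buffer +
      truth["opoe"] * comps$opoe + truth["lamb"] * comps$lamb
  )
  bg <- construct_background(frame, comps)
  expect_equal(unname(bg$coefficients), unname(truth), tolerance = 1e-8)
  expect_lt(abs(bg$fit_region_residual_mean), 1e-10)

  zero <- tibble::tibble(q_invA = q, intensity = rep(0, length(q)))
  bg0 <- construct_background(zero, comps)
  expect_true(all(bg0$coefficients == 0))
})

test_that("the Gaussian-plus-line peak fit recovers known areas", {
  q <- seq(0.10, 0.40, 0.002)
  true_area <- 0.8
  amp <- true_area / (0.015 * sqrt(2 * pi))
  frame <- tibble::tibble(
    q_invA = q,
    intensity = amp * exp(-(q - 0.25)^2 / (2 * 0.015^2)) + 0.2 - 0.3 * q
  )
  fit <- fit_dna_peak(frame)
  expect_false(fit$peak_absent)
  expect_equal(fit$area, true_area, tolerance = 0.01)
  expect_equal(fit$center_invA, 0.25, tolerance = 1e-3)

  # pure line: peak flagged absent, zero area
  line_only <- tibble::tibble(q_invA = q, intensity = 0.2 - 0.3 * q)
  fit0 <- fit_dna_peak(line_only)
  expect_true(fit0$peak_absent)
  expect_equal(fit0$area, 0)
})

test_that("fitted peak area is linear in the filled-capsid count", {
  scfg <- saxs_config(frame_interval_s = 50, t_max_s = 50, noise_sd = 0.002)
  base <- simulation_config(
    n_virions = 100, phi_fast = 0, slow_mean_delay_s = 1e6, seed = 12
  )
  ev <- simulate_ejection_times(base)
  ser <- synthesize_saxs_series(ev, scfg)
  areas <- peak_area_series(ser)

  half_cfg <- saxs_config(
    frame_interval_s = 50, t_max_s = 50,
    peak_area_max = scfg$peak_area_max / 2, noise_sd = 0.002
  )
  ser_half <- synthesize_saxs_series(ev, half_cfg)
  areas_half <- peak_area_series(ser_half)
  expect_equal(areas_half$area[1] / areas$area[1], 0.5, tolerance = 0.01)
})

test_that("log-linear rate extraction is exact on exponential decays", {
  tt <- seq(0, 200, 5)
  k <- 0.015
  exact <- tibble::tibble(time_s = tt, area = 3 * exp(-k * tt), peak_absent = FALSE)
  r <- ejection_rates(exact)
  expect_equal(r$k_fast, k, tolerance = 1e-10)
  expect_equal(r$k_slow, k, tolerance = 1e-10)

  const <- tibble::tibble(time_s = tt, area = rep(2, length(tt)), peak_absent = FALSE)
  r0 <- ejection_rates(const)
  expect_equal(r0$k_fast, 0, tolerance = 1e-12)
  expect_equal(r0$k_slow, 0, tolerance = 1e-12)

  sparse <- tibble::tibble(time_s = c(1, 5), area = c(1, 0.9), peak_absent = FALSE)
  expect_true(is.na(ejection_rates(sparse)$k_fast))
})

test_that("the Arrhenius fit inverts exactly constructed rate laws", {
  A <- 5e9
  Ea <- 9e-20
  temps <- c(20, 28, 36)
  k <- arrhenius_rate(temps, A, Ea)
  fit <- arrhenius_fit(tibble::tibble(temperature_C = temps, k = k))
  expect_equal(fit$Ea_J, Ea, tolerance = 1e-10)
  expect_equal(exp(fit$ln_prefactor), A, tolerance = 1e-6)

  flat <- arrhenius_fit(tibble::tibble(temperature_C = temps, k = rep(0.02, 3)))
  expect_equal(flat$Ea_J, 0, tolerance = 1e-25)

  expect_warning(
    arrhenius_fit(tibble::tibble(temperature_C = temps, k = c(0.01, -1, 0.02))),
    "excluded"
  )
})

test_that("an activation energy of 1.2e-19 J is about 29 kT at 25 C", {
  expect_equal(ea_in_kt(1.2e-19, 25), 29, tolerance = 0.02)
})

test_that("the slow-regime decay is log-linear and the fast regime nearly athermal", {
  sax <- run_saxs_scenario(n_virions = 3000, seed = 2, noise_sd = 0.003)
  expect_true(all(sax$rates$r2_slow > 0.95))
  # with coexisting populations the first 20 s are dominated by
  # synchronized (translocation-limited) ejections, whose rate shows
  # essentially no temperature dependence
  mixed <- run_saxs_scenario(
    n_virions = 3000, seed = 2, noise_sd = 0.003, phi_fast = 0.5
  )
  fast_fit <- arrhenius_fit(
    tibble::tibble(temperature_C = mixed$rates$temperature_C, k = mixed$rates$k_fast)
  )
  expect_lt(abs(fast_fit$Ea_J), 0.2 * sax$arrhenius$Ea_J)
})

test_that("activation-energy recovery is accurate across stochastic replicates", {
  errs <- vapply(1:10, function(i) {
    sax <- run_saxs_scenario(n_virions = 1500, seed = 100 + i, noise_sd = 0.003)
    abs(sax$arrhenius$Ea_J - 1.2e-19) / 1.2e-19
  }, numeric(1))
  expect_lt(median(errs), 0.15)
})

test_that("SAXS frames round-trip through per-frame text files", {
  cfg <- simulation_config(n_virions = 50, phi_fast = 1, seed = 13)
  ser <- synthesize_saxs_series(
    simulate_ejection_times(cfg),
    saxs_config(frame_interval_s = 10, t_max_s = 30)
  )
  dir <- tempfile()
  write_saxs_frames(ser, dir)
  back <- read_saxs_frames(dir)
  expect_equal(unique(back$time_s), unique(ser$time_s))
  expect_equal(back$intensity, ser$intensity, tolerance = 1e-6)
  expect_equal(
    attr(back, "backgrounds")$buffer,
    attr(ser, "backgrounds")$buffer,
    tolerance = 1e-6
  )
  unlink(dir, recursive = TRUE)
})
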
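make_trace <- function(tt, pw, temp = 25, ...) {
  dp_trace(tt, pw, metadata = c(list(temperature_C = temp), list(...)))
}

test_that("background subtraction is the stated control algebra", {
  tt <- seq(-20, 100, 0.5)
  signal <- ifelse(tt >= 0 & tt < 20, 0.05, 0)
  c1 <- 0.01 * exp(-pmax(tt, 0) / 5) * (tt >= 0)
  c2 <- 0.02 * exp(-pmax(tt, 0) / 3) * (tt >= 0)
  c3 <- 0.005 * exp(-pmax(tt, 0) / 4) * (tt >= 0)
  sample <- make_trace(tt, signal + c1 + c2 - c3)
  out <- subtract_backgrounds(
    sample,
    make_trace(tt, c1), make_trace(tt, c2), make_trace(tt, c3)
  )
  expect_equal(out$power_ucal_s, signal, tolerance = 1e-12)

  # identically-zero controls leave the sample untouched
  zero <- make_trace(tt, rep(0, length(tt)))
  out0 <- subtract_backgrounds(sample, zero, zero, zero)
  expect_equal(out0$power_ucal_s, sample$power_ucal_s)

  # control transients confined to t < 10 s leave later samples unchanged
  early <- make_trace(tt, ifelse(tt >= 0 & tt < 10, 0.03, 0))
  out_e <- subtract_backgrounds(sample, early, zero, zero)
  late <- tt >= 10
  expect_equal(out_e$power_ucal_s[late], sample$power_ucal_s[late])

  expect_error(
    subtract_backgrounds(sample, make_trace(tt, c1, temp = 30), zero, zero),
    class = "ejectkin_condition_mismatch"
  )
})

test_that("enthalpy integration converts a rectangular pulse exactly", {
  tt <- seq(-20, 40, 0.5)
  pw <- ifelse(tt >= 0 & tt < 10, 1, 0) # 1 ucal/s for 10 s
  tr <- dp_trace(tt, pw, metadata = list(
    titrant_uL = 2.69, titer_pfu_per_mL = 1e10 / 2.69e-3,
    temperature_C = 25, mg_mM = 10
  ))
  res <- integrate_ejection_enthalpy(tr)
  expect_equal(res$total_heat_J, 10 * 4.184e-6, tolerance = 1e-12)
  expect_equal(res$n_virions, 1e10)
  expect_equal(res$dH_ej_J, 4.184e-15, tolerance = 1e-12)

  # the titration example: 2.69 uL at 1e12 pfu/mL titrates 2.69e9 virions
  tr2 <- dp_trace(tt, pw, metadata = list(
    titrant_uL = 2.69, titer_pfu_per_mL = 1e12
  ))
  expect_equal(integrate_ejection_enthalpy(tr2)$n_virions, 2.69e9)

  no_meta <- dp_trace(tt, pw)
  expect_error(integrate_ejection_enthalpy(no_meta), class = "ejectkin_unit_error")
})

test_that("integration recovers the generator's per-virion enthalpy", {
  cfg <- simulation_config(n_virions = 5000, temperature_C = 22, seed = 2)
  tr <- synthesize_dp_trace(simulate_ejection_times(cfg), noise = FALSE)
  res <- integrate_ejection_enthalpy(tr)
  expect_equal(res$dH_ej_J, cfg$dH_per_virion_J, tolerance = 5e-3)
})

test_that("subtraction and integration commute (linearity)", {
  tt <- seq(-20, 60, 0.5)
  meta <- list(titrant_uL = 1, titer_pfu_per_mL = 1e12, temperature_C = 25)
  a <- dp_trace(tt, dnorm(tt, 20, 5), metadata = meta)
  b <- dp_trace(tt, 0.3 * dnorm(tt, 15, 4), metadata = meta)
  zero <- dp_trace(tt, rep(0, length(tt)), metadata = meta)
  diff_trace <- subtract_backgrounds(a, b, zero, zero)
  expect_equal(
    integrate_ejection_enthalpy(diff_trace)$total_heat_J,
    integrate_ejection_enthalpy(a)$total_heat_J -
      integrate_ejection_enthalpy(b)$total_heat_J,
    tolerance = 1e-12
  )
})

test_that("equilibration detection matches the analytic threshold crossing", {
  tt <- seq(-20, 300, 0.25)
  tau <- 12
  A <- 0.05
  pw <- ifelse(tt >= 0, A * exp(-tt / tau), 0)
  tr <- dp_trace(tt, pw)
  sigma <- 1e-3
  t_eq <- detect_equilibration(tr, noise_k = 2, hold_window = 10, sigma = sigma)
  t_cross <- tau * log(A / (2 * sigma)) # analytic 2-sigma crossing
  expect_lt(abs(as.numeric(t_eq) - t_cross), 10)
  expect_false(attr(t_eq, "censored"))

  # never returns to baseline: censored at end of trace
  flat_high <- dp_trace(tt, ifelse(tt >= 0, A, 0))
  t_c <- detect_equilibration(flat_high, sigma = sigma)
  expect_true(attr(t_c, "censored"))
  expect_equal(as.numeric(t_c), max(tt))
})

test_that("equilibration time does not decrease with the hold window", {
  cfg <- simulation_config(n_virions = 5000, temperature_C = 22, seed = 5)
  tr <- synthesize_dp_trace(simulate_ejection_times(cfg))
  times <- vapply(
    c(5, 10, 20),
    function(h) as.numeric(detect_equilibration(tr, hold_window = h)),
    numeric(1)
  )
  expect_true(all(diff(times) >= 0))
})

test_that("DP traces survive a CSV round trip at full precision", {
  cfg <- simulation_config(n_virions = 300, temperature_C = 22, seed = 10)
  tr <- synthesize_dp_trace(simulate_ejection_times(cfg))
  path <- tempfile(fileext = ".csv")
  write_dp_trace(tr, path)
  back <- read_dp_trace(path)
  expect_equal(back$time_s, tr$time_s, tolerance = 1e-12)
  expect_equal(back$power_ucal_s, tr$power_ucal_s, tolerance = 1e-12)
  expect_equal(
    trace_metadata(back)$temperature_C,
    trace_metadata(tr)$temperature_C
  )
  unlink(c(path, paste0(path, ".meta")))
})
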
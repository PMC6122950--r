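# shared fixtures, built in code

# a trace that is exactly a sum of EMG components on a regular grid, with a
# pre-injection baseline window so noise/baseline estimation has samples
emg_trace <- function(comps, t_max = 300, dt = 0.25, noise_sd = 0,
                      seed = 1, metadata = list()) {
  tt <- seq(-30, t_max, by = dt)
  pw <- numeric(length(tt))
  for (i in seq_len(nrow(comps))) {
    pw <- pw + emg_value(tt, comps$a[i], comps$b[i], comps$c[i], comps$d[i])
  }
  if (noise_sd > 0) {
    set.seed(seed)
    pw <- pw + rnorm(length(tt), 0, noise_sd)
  }
  dp_trace(tt, pw, metadata = metadata)
}

# two cleanly separated populations (fast translocation-limited, slow
# delay-dominated); medians ~19 s and ~52 s
bimodal_components <- function() {
  tibble::tibble(
    a = c(2, 3),
    b = c(3, 25),
    c = c(2, 4),
    d = c(15, 40)
  )
}

# memoised default-scenario ITC fits shared by the acceptance blocks
acceptance_itc <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      conds <- list(
        c(22, 10), c(32, 10), c(37, 10), c(42, 10), c(37, 5), c(37, 20)
      )
      cache <<- dplyr::bind_rows(lapply(conds, function(cn) {
        run_itc_condition(cn[1], cn[2], seed = 1L)
      }))
    }
    cache
  }
})

pick_metric <- function(df, temp, mg, col) {
  df[[col]][df$temperature_C == temp & df$mg_mM == mg][1]
}
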
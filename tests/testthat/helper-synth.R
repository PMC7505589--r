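# Shared fixtures, generated once per test file.

# default-condition gas simulation (5 min keeps module tests quick)
cached_gas_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- sim_gas_exchange(coupling_spec(seed = 42), duration_s = 300)
    }
    cache
  }
})

# noiseless simulation: every stochastic amplitude off, no delay
noiseless_gas_sim <- function(duration_s = 120, seed = 1,
                              gas_line_delay_s = 0, modulator_amp = 0) {
  sim_gas_exchange(
    coupling_spec(seed = seed, modulator_amp = modulator_amp,
                  gas_line_delay_s = gas_line_delay_s),
    duration_s = duration_s,
    vent_sd = 0, breath_noise_sd = 0, trace_noise_sd = 0
  )
}

# square-wave gas trace: instantaneous plateaus, for closed-form checks
square_gas_trace <- function(n_breaths = 10, period_s = 5, dt = 0.05,
                             po2_hi = 150, po2_lo = 110,
                             pco2_hi = 42, pco2_lo = 2,
                             insp_frac = 0.4) {
  time <- seq(0, n_breaths * period_s - dt, by = dt)
  phase <- (time %% period_s) / period_s
  insp <- phase < insp_frac
  tibble::tibble(
    time = time,
    po2 = ifelse(insp, po2_hi, po2_lo),
    pco2 = ifelse(insp, pco2_lo, pco2_hi)
  )
}

unit_modulator <- function(duration_s = 600, freq = 0.01, dt = 0.05) {
  t <- seq(0, duration_s, by = dt)
  tibble::tibble(time = t, value = sin(2 * pi * freq * t))
}

band_mean <- function(profile, col, lo = 0.008, hi = 0.03) {
  inband <- profile$freq_hz >= lo & profile$freq_hz <= hi
  mean(profile[[col]][inband])
}
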
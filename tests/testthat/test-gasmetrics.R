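test_that("gas-line delay is recovered by cross-correlation", {
  sim <- sim_gas_exchange(coupling_spec(seed = 1, gas_line_delay_s = 3),
                          duration_s = 300, trace_noise_sd = 0)
  g <- correct_gas_delay(sim$gas, sim$resp)
  expect_equal(attr(g, "lag_s"), 3, tolerance = 0.051)  # one 20 Hz sample

  noisy <- sim_gas_exchange(coupling_spec(seed = 1, gas_line_delay_s = 3),
                            duration_s = 300)
  gn <- correct_gas_delay(noisy$gas, noisy$resp)
  expect_lt(abs(attr(gn, "lag_s") - 3), 0.16)

  zero <- sim_gas_exchange(coupling_spec(seed = 2, gas_line_delay_s = 0),
                           duration_s = 300, trace_noise_sd = 0)
  g0 <- correct_gas_delay(zero$gas, zero$resp)
  expect_equal(attr(g0, "lag_s"), 0)
})

test_that("delay correction is idempotent", {
  sim <- sim_gas_exchange(coupling_spec(seed = 3, gas_line_delay_s = 4),
                          duration_s = 300, trace_noise_sd = 0)
  g1 <- correct_gas_delay(sim$gas, sim$resp)
  g2 <- correct_gas_delay(g1, sim$resp)
  expect_lte(abs(attr(g2, "lag_s")), 0.051)
})

test_that("an unusable respiration reference falls back to zero lag", {
  sim <- noiseless_gas_sim(duration_s = 100)
  flat <- sim$resp
  flat$displacement <- 0
  expect_warning(g <- correct_gas_delay(sim$gas, flat), "zero lag")
  expect_equal(attr(g, "lag_s"), 0)
})

test_that("breath phases land on the generator's end points", {
  sim <- noiseless_gas_sim(duration_s = 60)
  ph <- detect_breath_phases(sim$gas)
  expect_true(nrow(ph) %in% c(11, 12))
  truth <- sim$truth[seq_len(nrow(ph)), ]
  expect_lt(max(abs(ph$t_end_exp - truth$t_end_exp)), 0.051)
  expect_lt(max(abs(ph$t_end_insp - truth$t_end_insp)), 0.051)
})

test_that("constant traces yield no breaths, with a diagnostic", {
  gas <- tibble::tibble(time = seq(0, 60, 0.05), po2 = 120, pco2 = 30)
  expect_warning(ph <- detect_breath_phases(gas), "no breaths")
  expect_equal(nrow(ph), 0)
})

test_that("a short spurious spike does not change the breath count", {
  sim <- noiseless_gas_sim(duration_s = 120)
  n_clean <- nrow(detect_breath_phases(sim$gas))
  spiked <- sim$gas
  i <- which(spiked$time >= 32.2 & spiked$time < 32.7)  # mid-plateau spike
  spiked$pco2[i] <- spiked$pco2[i] + 15
  expect_equal(nrow(detect_breath_phases(spiked)), n_clean)
})

test_that("square-wave breaths give the closed-form metrics", {
  gas <- square_gas_trace()
  ph <- detect_breath_phases(gas)
  bt <- compute_rge_metrics(gas, ph)
  expect_true(all(abs(bt$d_po2 - 40) < 1e-9))
  expect_true(all(abs(bt$d_pco2 - 40) < 1e-9))
  expect_true(all(abs(bt$ber - 1) < 1e-9))
})

test_that("noiseless pipeline reproduces the generator ground truth", {
  sim <- noiseless_gas_sim(duration_s = 120, seed = 6)
  ph <- detect_breath_phases(sim$gas)
  bt <- compute_rge_metrics(sim$gas, ph)
  truth <- sim$truth[seq_len(nrow(bt)), ]
  expect_lt(max(abs(bt$d_pco2 - truth$d_pco2)), 0.1)
  expect_lt(max(abs(bt$d_po2 - truth$d_po2)), 0.1)
  expect_lt(max(abs(bt$pet_co2 - truth$pet_co2)), 0.1)
  expect_lt(max(abs(bt$t_end_exp - truth$t_end_exp)), 0.051)
})

test_that("bER times the CO2 excursion is exactly the O2 excursion", {
  sim <- cached_gas_sim()
  g <- correct_gas_delay(sim$gas, sim$resp)
  bt <- compute_rge_metrics(g, detect_breath_phases(g))
  expect_equal(bt$ber * bt$d_pco2, bt$d_po2, tolerance = 1e-12)
})

test_that("time-mean bER matches the ratio of mean excursions", {
  sim <- cached_gas_sim()
  g <- correct_gas_delay(sim$gas, sim$resp)
  bt <- compute_rge_metrics(g, detect_breath_phases(g))
  ok <- bt$valid
  expect_equal(mean(bt$ber[ok]),
               mean(bt$d_po2[ok]) / mean(bt$d_pco2[ok]),
               tolerance = 0.05)
})

test_that("records dominated by sub-floor CO2 excursions are rejected", {
  gas <- square_gas_trace(pco2_hi = 2.5, pco2_lo = 2)
  ph <- detect_breath_phases(gas, min_period_s = 1.5)
  if (nrow(ph) >= 2) {
    expect_error(compute_rge_metrics(gas, ph), "unusable")
  } else {
    succeed()  # sub-floor plateaus may not even parse as breaths
  }
})

test_that("RVT has the closed form 2A/T on a sinusoidal bellow", {
  tt <- seq(0, 60, by = 0.05)
  resp <- tibble::tibble(time = tt,
                         displacement = 2 * sin(2 * pi * tt / 5))
  rv <- compute_rvt(resp)
  expect_gt(nrow(rv), 8)
  expect_equal(rv$rvt, rep(2 * 2 / 5, nrow(rv)), tolerance = 0.01)
})

test_that("RVT tracks the ventilation envelope of generated data", {
  sim <- sim_gas_exchange(coupling_spec(seed = 11), duration_s = 600,
                          vent_sd = 0.15, trace_noise_sd = 0)
  rv <- compute_rvt(sim$resp)
  truth_at <- approx(sim$truth$t_end_insp, sim$truth$rvt,
                     xout = rv$time, rule = 2)$y
  expect_gt(cor(rv$rvt, truth_at), 0.95)
})

test_that("a flat bellow yields a diagnostic and no RVT", {
  resp <- tibble::tibble(time = seq(0, 60, 0.05), displacement = 1)
  expect_warning(rv <- compute_rvt(resp), "no RVT")
  expect_equal(nrow(rv), 0)
})

test_that("per-breath series interpolate linearly onto the uniform grid", {
  tab <- tibble::tibble(t_end_exp = c(0, 10), value = c(1, 2))
  u <- breath_series_to_uniform(tab, "value", dt_s = 5)
  expect_equal(u$value, c(1, 1.5, 2))

  const <- tibble::tibble(t_end_exp = seq(0, 50, 5), value = 3)
  expect_true(all(breath_series_to_uniform(const, "value")$value == 3))

  expect_error(breath_series_to_uniform(const, "nope"), "unknown field")
  expect_error(breath_series_to_uniform(const[1, ], "value"),
               "at least 2")
})

test_that("modulated bER series keeps its spectral peak after resampling", {
  sim <- sim_gas_exchange(coupling_spec(seed = 8), duration_s = 600,
                          vent_sd = 0, breath_noise_sd = 0,
                          trace_noise_sd = 0)
  u <- breath_series_to_uniform(sim$truth, "ber", dt_s = 1)
  sp <- stats::spec.pgram(stats::ts(u$value, deltat = 1), plot = FALSE,
                          detrend = TRUE, taper = 0)
  expect_equal(sp$freq[which.max(sp$spec)], 0.01, tolerance = 0.003)
})
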
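# minimal hand-built coherence result for enumeration checks
toy_result <- function(coherence, phase, sig, periods, coi, dt = 1) {
  n <- ncol(coherence)
  structure(
    list(
      time = (seq_len(n) - 1) * dt,
      scales = periods / (4 * pi / (6 + sqrt(2 + 36))),
      periods = periods,
      freq_hz = 1 / periods,
      coherence = coherence,
      phase = phase,
      coi = coi,
      sig_mask = sig,
      sig_threshold = rep(0.5, length(periods)),
      n_surrogates = 100L,
      dt = dt,
      dj = 1 / 12,
      series = list(x = rnorm(n), y = rnorm(n))
    ),
    class = "coherence_result"
  )
}

test_that("the Morlet transform localizes a sinusoid at its Fourier period", {
  t <- 0:599
  for (f in c(0.02, 0.05)) {
    cw <- morlet_cwt(sin(2 * pi * f * t), dt_s = 1)
    pow <- rowMeans(Mod(cw$wave)^2)
    expect_equal(cw$periods[which.max(pow)], 1 / f, tolerance = 0.06)
  }
})

test_that("the transform is linear and vanishes on the zero series", {
  t <- 0:199
  x <- sin(2 * pi * 0.05 * t) + 0.5 * cos(2 * pi * 0.02 * t)
  z <- morlet_cwt(rep(0, 200), dt_s = 1)
  expect_true(all(Mod(z$wave) == 0))
  a <- morlet_cwt(x, dt_s = 1)
  b <- morlet_cwt(3 * x, dt_s = 1)
  expect_equal(b$wave, 3 * a$wave, tolerance = 1e-10)
})

test_that("coherence of a series with itself is one, at zero phase", {
  set.seed(5)
  x <- sin(2 * pi * 0.01 * (0:599)) + 0.3 * rnorm(600)
  res <- wavelet_coherence(x, x, dt_s = 1)
  incoi <- outer(res$periods, res$coi, `<=`)
  expect_gte(min(res$coherence[incoi]), 0.99)
  expect_lte(max(abs(res$phase[incoi])), 0.01)
})

test_that("a quarter-period lag shows as a phase of pi/2, x leading", {
  t <- 0:599
  f <- 0.02
  x <- sin(2 * pi * f * t)
  y <- sin(2 * pi * f * (t - 1 / (4 * f)))
  res <- wavelet_coherence(x, y, dt_s = 1)
  j <- which.min(abs(res$periods - 1 / f))
  ph <- res$phase[j, res$periods[j] <= res$coi]
  expect_lt(max(abs(ph - pi / 2)), 0.15)
})

test_that("coherence is invariant to affine maps of either input", {
  set.seed(8)
  x <- as.numeric(arima.sim(list(ar = 0.5), 300))
  y <- as.numeric(arima.sim(list(ar = 0.5), 300))
  a <- wavelet_coherence(x, y, dt_s = 1)
  b <- wavelet_coherence(3 * x + 7, -2 * y + 1, dt_s = 1)
  expect_lt(max(abs(a$coherence - b$coherence)), 1e-6)
})

test_that("independent red noise shows low typical coherence", {
  set.seed(9)
  meds <- replicate(4, {
    x <- as.numeric(arima.sim(list(ar = 0.6), 500))
    y <- as.numeric(arima.sim(list(ar = 0.6), 500))
    r <- wavelet_coherence(x, y, dt_s = 1)
    incoi <- outer(r$periods, r$coi, `<=`)
    median(r$coherence[incoi])
  })
  expect_lt(median(meds), 0.5)
})

test_that("the cone of influence follows the e-folding closed form", {
  n <- 201
  dt <- 2
  coi <- cone_of_influence(n, dt)
  ff <- 4 * pi / (6 + sqrt(38))
  mid <- (n - 1) / 2 * dt
  expect_equal(coi[101], ff / sqrt(2) * mid, tolerance = 1e-9)
  expect_equal(coi, rev(coi))
  expect_lt(coi[1], 1e-6)
  expect_error(cone_of_influence(1, 1), ">= 2")
})

test_that("red-noise surrogate thresholds are reproducible and sane", {
  set.seed(10)
  x <- sin(2 * pi * 0.02 * (0:399)) + 0.5 * as.numeric(arima.sim(list(ar = 0.4), 400))
  res <- wavelet_coherence(x, x, dt_s = 1)
  a <- rednoise_significance(res, n_surrogates = 100, seed = 3)
  b <- rednoise_significance(res, n_surrogates = 100, seed = 3)
  expect_identical(a$sig_mask, b$sig_mask)
  incoi <- outer(a$periods, a$coi, `<=`)
  has_cells <- rowSums(incoi) > 0
  expect_true(all(a$sig_threshold[has_cells] > 0 &
                    a$sig_threshold[has_cells] <= 1))
  # identical series: everything inside the cone is significant
  expect_gt(mean(a$sig_mask[incoi]), 0.99)
  expect_error(rednoise_significance(res, n_surrogates = 50), "at least 100")
})

test_that("TAC reproduces the hand-enumerated toy example", {
  coh <- matrix(0, 1, 10)
  coh[1, 1:4] <- 0.8
  sig <- matrix(FALSE, 1, 10)
  sig[1, 1:4] <- TRUE
  phase <- matrix(0, 1, 10)
  res <- toy_result(coh, phase, sig, periods = 4, coi = rep(10, 10))
  tac <- time_averaged_coherence(res)
  expect_equal(tac$tac_inphase, 0.32)
  expect_equal(tac$tac_antiphase, 0)
  expect_equal(tac$tac_total, 0.32)

  # no significant cells
  res0 <- toy_result(coh, phase, matrix(FALSE, 1, 10),
                     periods = 4, coi = rep(10, 10))
  expect_equal(time_averaged_coherence(res0)$tac_total, 0)

  # saturated upper bound
  res1 <- toy_result(matrix(1, 1, 10), phase, matrix(TRUE, 1, 10),
                     periods = 4, coi = rep(10, 10))
  expect_equal(time_averaged_coherence(res1)$tac_inphase, 1)

  # boundary phase (cos = 0) counts as anti-phase
  resb <- toy_result(coh, matrix(pi / 2, 1, 10), sig,
                     periods = 4, coi = rep(10, 10))
  tacb <- time_averaged_coherence(resb)
  expect_equal(tacb$tac_inphase, 0)
  expect_equal(tacb$tac_antiphase, 0.32)

  # magnitude summand uses the root of each cell's squared coherence
  tacm <- time_averaged_coherence(res, summand = "magnitude")
  expect_equal(tacm$tac_inphase, 4 * sqrt(0.8) / 10)

  # scale fully outside the cone is flagged and zero
  resz <- toy_result(coh, phase, sig, periods = 4, coi = rep(1, 10))
  tacz <- time_averaged_coherence(resz)
  expect_true(tacz$outside_coi)
  expect_equal(tacz$tac_total, 0)
})

test_that("quadrant TAC components sum exactly to the total", {
  set.seed(11)
  x <- as.numeric(arima.sim(list(ar = 0.5), 300))
  y <- 0.6 * x + as.numeric(arima.sim(list(ar = 0.5), 300))
  res <- rednoise_significance(wavelet_coherence(x, y, dt_s = 1),
                               n_surrogates = 100, seed = 4)
  tac <- time_averaged_coherence(res)
  expect_identical(tac$tac_inphase + tac$tac_antiphase, tac$tac_total)
  expect_true(all(tac$tac_total >= 0 & tac$tac_total <= 1))
})

test_that("group TAC averaging has the closed-form mean and SEM", {
  p1 <- tibble::tibble(freq_hz = c(0.01, 0.02), period_s = c(100, 50),
                       tac_inphase = c(0.2, 0.4),
                       tac_antiphase = c(0, 0.1))
  p1$tac_total <- p1$tac_inphase + p1$tac_antiphase
  p2 <- p1
  p2$tac_inphase <- c(0.4, 0.2)
  p2$tac_total <- p2$tac_inphase + p2$tac_antiphase
  g <- group_mean_tac(list(p1, p2))
  expect_equal(g$mean_inphase, c(0.3, 0.3))
  expect_equal(g$sem_inphase, c(0.1, 0.1))
  g_swapped <- group_mean_tac(list(p2, p1))
  expect_equal(g$mean_inphase, g_swapped$mean_inphase)
  ident <- group_mean_tac(list(p1, p1))
  expect_equal(ident$mean_inphase, p1$tac_inphase)
  expect_equal(ident$sem_inphase, c(0, 0))
  expect_error(group_mean_tac(list(p1)), "at least 2")
})

test_that("in-phase coupling at 0.01 Hz concentrates TAC in the slow band", {
  set.seed(12)
  t <- 0:599
  m <- sin(2 * pi * 0.01 * t)
  x <- m + 0.4 * as.numeric(arima.sim(list(ar = 0.7), 600))
  y <- m + 0.4 * as.numeric(arima.sim(list(ar = 0.7), 600))
  res <- rednoise_significance(wavelet_coherence(x, y, dt_s = 1),
                               n_surrogates = 100, seed = 5)
  tac <- time_averaged_coherence(res)
  inband_in <- band_mean(tac, "tac_inphase")
  inband_anti <- band_mean(tac, "tac_antiphase")
  outband <- tac$freq_hz > 0.03 & !tac$outside_coi
  expect_gt(inband_in, 2 * max(inband_anti, 0.01))
  expect_gt(inband_in, mean(tac$tac_inphase[outband]))
})
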
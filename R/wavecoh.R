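#' @name wavecoh
#' @title Morlet wavelet transform coherence
#' @description
#' Time-frequency coherence between two uniformly sampled series, following
#' the standard continuous-wavelet formulation: Morlet mother wavelet with
#' centre frequency `omega0 = 6`, dyadic scales `s_j = s0 * 2^(j*dj)` with
#' `s0 = 2*dt` and `dj = 1/12`, Fourier period `s * 4*pi / (omega0 +
#' sqrt(2 + omega0^2))`, FFT convolution with zero padding, coherence from
#' scale-normalized smoothed spectra (Gaussian in time, boxcar across
#' scales), a cone of influence from the wavelet e-folding time, and
#' pointwise 95% significance against AR(1) red-noise surrogates estimated
#' by Monte Carlo.
NULL

OMEGA0 <- 6
FOURIER_FACTOR <- 4 * pi / (OMEGA0 + sqrt(2 + OMEGA0^2))

# Shared scale/frequency grid for a record of n samples at spacing dt.
cwt_grid <- function(n, dt, dj = 1 / 12, s0 = 2 * dt, max_period = NULL) {
  if (is.null(max_period)) max_period <- n * dt / 2
  j_max <- floor(log2(max_period / (FOURIER_FACTOR * s0)) / dj)
  scales <- s0 * 2^(dj * 0:max(j_max, 0))
  npad <- 2^ceiling(log2(n))
  k <- 0:(npad - 1)
  omega <- 2 * pi * ifelse(k <= npad / 2, k, k - npad) / (npad * dt)
  list(n = n, dt = dt, dj = dj, scales = scales,
       periods = scales * FOURIER_FACTOR, npad = npad, omega = omega)
}

#' Continuous Morlet wavelet transform
#'
#' @param x Numeric series on a uniform grid (length >= 32); the mean is
#'   removed before transforming.
#' @param dt_s Sampling interval (s).
#' @param dj Scale resolution in octaves (default 1/12, i.e. 12 sub-octaves
#'   per octave).
#' @param s0 Smallest scale (default `2 * dt_s`).
#' @param max_period Largest Fourier period analysed (default half the
#'   record length).
#'
#' @return List with the complex `wave` matrix (scales x time), `scales`,
#'   `periods` (s) and the grid parameters.
#' @export
morlet_cwt <- function(x, dt_s, dj = 1 / 12, s0 = 2 * dt_s,
                       max_period = NULL) {
  n <- length(x)
  if (n < 32) abort("series must have at least 32 samples")
  grid <- cwt_grid(n, dt_s, dj, s0, max_period)
  wave <- cwt_core(x, grid)
  list(wave = wave, scales = grid$scales, periods = grid$periods,
       dt = dt_s, dj = dj, n = n)
}

cwt_core <- function(x, grid) {
  n <- grid$n
  xf <- fft(c(x - mean(x), rep(0, grid$npad - n)))
  pos <- grid$omega > 0
  # one column per scale: xf * psi_hat(s*omega), then inverse FFT
  mats <- vapply(grid$scales, function(s) {
    psi <- sqrt(2 * pi * s / grid$dt) * pi^(-1 / 4) *
      exp(-((s * grid$omega - OMEGA0)^2) / 2) * pos
    xf * psi
  }, complex(grid$npad))
  w <- stats::mvfft(mats, inverse = TRUE) / grid$npad
  t(w[seq_len(n), , drop = FALSE])
}

# Smoothing operator of the coherence estimator: Gaussian in time with
# standard deviation scale/sqrt(2), then a boxcar across scales spanning the
# 0.6-octave decorrelation length of the Morlet wavelet.
smooth_field <- function(field, grid) {
  j_n <- nrow(field)
  n <- grid$n
  npad <- grid$npad
  padded <- rbind(t(field), matrix(0, npad - n, j_n))
  f <- stats::mvfft(padded)
  sig <- grid$scales / sqrt(2)
  damp <- exp(-0.5 * outer(grid$omega^2, sig^2))
  sm <- Re(stats::mvfft(f * damp, inverse = TRUE)) / npad
  out <- t(sm[seq_len(n), , drop = FALSE])
  # boxcar over scales
  h <- max(0L, floor(0.6 / grid$dj / 2))
  if (h == 0 || j_n == 1) return(out)
  cs <- apply(rbind(0, out), 2, cumsum)
  lo <- pmax(seq_len(j_n) - h, 1L)
  hi <- pmin(seq_len(j_n) + h, j_n)
  (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) / (hi - lo + 1)
}

wtc_maps <- function(x, y, grid) {
  wx <- cwt_core(x, grid)
  wy <- cwt_core(y, grid)
  inv_s <- 1 / grid$scales
  sx <- smooth_field(sweep(Mod(wx)^2, 1, inv_s, "*"), grid)
  sy <- smooth_field(sweep(Mod(wy)^2, 1, inv_s, "*"), grid)
  cross <- sweep(wx * Conj(wy), 1, inv_s, "*")
  sxy_re <- smooth_field(Re(cross), grid)
  sxy_im <- smooth_field(Im(cross), grid)
  coh <- (sxy_re^2 + sxy_im^2) / pmax(sx * sy, .Machine$double.eps)
  list(coherence = pmin(pmax(coh, 0), 1), phase = atan2(sxy_im, sxy_re))
}

#' Cone of influence
#'
#' Per time point, the largest Fourier period not contaminated by edge
#' effects: the wavelet e-folding time is `sqrt(2) * scale`, so at distance
#' `d` from the nearer record edge only scales up to `d / sqrt(2)` — periods
#' up to `fourier_factor * d / sqrt(2)` — are trusted.
#'
#' @param n Number of samples (>= 2).
#' @param dt_s Sampling interval (s).
#' @return Numeric vector of length `n`: the COI period (s) per time point.
#' @export
cone_of_influence <- function(n, dt_s) {
  if (n < 2) abort("n must be >= 2")
  d <- pmin(seq_len(n) - 1, n - seq_len(n)) * dt_s
  FOURIER_FACTOR / sqrt(2) * pmax(d, 1e-8)
}

#' Squared wavelet coherence between two series
#'
#' Computes the localized squared coherence
#' `R^2 = |S(s^-1 Wxy)|^2 / (S(s^-1 |Wx|^2) S(s^-1 |Wy|^2))`
#' and the cross-spectrum phase on the shared dyadic scale grid, where `S`
#' is the time/scale smoothing operator. Both inputs are linearly detrended
#' and standardized first, so the result is invariant to affine maps of
#' either series. Positive phase means `x` leads `y`.
#'
#' @param x,y Numeric vectors or (time, value) tibbles on the same uniform
#'   grid.
#' @param dt_s Sampling interval (s); taken from the time column when tibbles
#'   are given.
#' @param dj Scale resolution (default 1/12).
#' @param max_period Largest analysed Fourier period (default half the
#'   record).
#'
#' @return An object of class `coherence_result`: list with `time`,
#'   `scales`, `periods`, `freq_hz`, `coherence` and `phase` matrices
#'   (scales x time), `coi`, and empty significance fields to be filled by
#'   [rednoise_significance()].
#' @export
wavelet_coherence <- function(x, y, dt_s = NULL, dj = 1 / 12,
                              max_period = NULL) {
  if (is.data.frame(x)) {
    dt_s <- dt_s %||% assert_uniform_time(x$time, "x")
    time <- x$time
    x <- x$value
  } else {
    if (is.null(dt_s)) abort("dt_s is required for bare numeric input")
    time <- (seq_along(x) - 1) * dt_s
  }
  if (is.data.frame(y)) y <- y$value
  if (length(x) != length(y)) abort("x and y must have equal length")
  n <- length(x)
  if (n < 32) abort("series must have at least 32 samples")
  xs <- as.numeric(scale(linear_detrend(x)))
  ys <- as.numeric(scale(linear_detrend(y)))
  grid <- cwt_grid(n, dt_s, dj, max_period = max_period)
  maps <- wtc_maps(xs, ys, grid)
  structure(
    list(
      time = time,
      scales = grid$scales,
      periods = grid$periods,
      freq_hz = 1 / grid$periods,
      coherence = maps$coherence,
      phase = maps$phase,
      coi = cone_of_influence(n, dt_s),
      sig_mask = NULL,
      sig_threshold = NULL,
      n_surrogates = 0L,
      dt = dt_s,
      dj = dj,
      series = list(x = xs, y = ys)
    ),
    class = "coherence_result"
  )
}

#' @export
print.coherence_result <- function(x, ...) {
  cat("<coherence_result> ", length(x$time), " time points x ",
      length(x$scales), " scales (periods ",
      signif(min(x$periods), 3), "-", signif(max(x$periods), 3), " s)\n",
      sep = "")
  if (!is.null(x$sig_mask)) {
    cat("  red-noise significance: ", x$n_surrogates,
        " surrogates, ", round(100 * mean(x$sig_mask), 1),
        "% of cells above the 95% level\n", sep = "")
  }
  invisible(x)
}

#' Red-noise Monte Carlo significance for wavelet coherence
#'
#' Fits AR(1) coefficients to both input series by lag-1 autocorrelation,
#' generates `n_surrogates` independent AR(1) ("red noise") pairs of
#' matching length, and computes their wavelet coherence on the same scale
#' grid. The per-scale 95th percentile of the surrogate coherence, pooled
#' over the in-COI cells of all surrogates, is the significance threshold;
#' observed cells above it are flagged significant.
#'
#' @param result A [wavelet_coherence()] result.
#' @param n_surrogates Number of surrogate pairs (>= 100; default 300).
#' @param alpha Significance level (default 0.05 -> 95th percentile).
#' @param seed Integer seed for the surrogate stream (mandatory for
#'   reproducibility).
#'
#' @return The `coherence_result` with `sig_mask`, `sig_threshold`,
#'   `n_surrogates` and the fitted `ar1` coefficients filled in.
#' @export
rednoise_significance <- function(result, n_surrogates = 300, alpha = 0.05,
                                  seed = 1L) {
  stopifnot(inherits(result, "coherence_result"))
  if (n_surrogates < 100) abort("n_surrogates must be at least 100")
  ax <- ar1_fit(result$series$x)
  ay <- ar1_fit(result$series$y)
  if (abs(ax) >= 1 || abs(ay) >= 1) {
    abort("fitted AR(1) coefficient is non-stationary")
  }
  n <- length(result$time)
  grid <- cwt_grid(n, result$dt, result$dj,
                   max_period = max(result$periods))
  incoi <- outer(result$periods, result$coi, `<=`)
  j_n <- length(result$periods)
  pooled <- vector("list", j_n)
  for (j in seq_len(j_n)) pooled[[j]] <- vector("list", n_surrogates)
  withr::with_seed(substream_seed(seed, "surrogate"), {
    for (s in seq_len(n_surrogates)) {
      xs <- ar1_noise(n, ax)
      ys <- ar1_noise(n, ay)
      coh <- wtc_maps(as.numeric(scale(xs)), as.numeric(scale(ys)),
                      grid)$coherence
      for (j in seq_len(j_n)) pooled[[j]][[s]] <- coh[j, incoi[j, ]]
    }
  })
  threshold <- vapply(pooled, function(v) {
    v <- unlist(v)
    if (length(v) == 0) Inf else quantile(v, 1 - alpha, names = FALSE)
  }, numeric(1))
  result$sig_threshold <- threshold
  result$sig_mask <- sweep(result$coherence, 1, threshold, `>`)
  result$n_surrogates <- as.integer(n_surrogates)
  result$ar1 <- c(x = ax, y = ay)
  result
}

#' Quadrant-resolved time-averaged coherence (TAC)
#'
#' For each scale, the total squared coherence over cells that lie outside
#' the cone of influence and exceed the 95% red-noise level, normalized by
#' the maximum possible coherence outside the cone at that scale (the count
#' of in-COI cells, since coherence is bounded by 1). The total is split by
#' cross-spectrum phase-lag quadrant: `tac_inphase` collects cells with
#' phase in 0 +/- pi/2 (positive correlation), `tac_antiphase` cells with
#' phase in pi +/- pi/2 (negative correlation); boundary cells with
#' `cos(phase) == 0` count as anti-phase. The two quadrant profiles sum to
#' `tac_total` exactly.
#'
#' @param result A [rednoise_significance()]-annotated `coherence_result`.
#' @param summand Whether each significant cell contributes its squared
#'   coherence (`"squared"`, the quantity that is plotted and thresholded;
#'   default) or its magnitude (`"magnitude"`, the square root).
#'
#' @return A tibble of class `tac_profile`: `freq_hz`, `period_s`,
#'   `tac_inphase`, `tac_antiphase`, `tac_total`, `n_incoi`, and
#'   `outside_coi` flagging scales with no in-COI cells (TAC reported as 0).
#' @export
time_averaged_coherence <- function(result,
                                    summand = c("squared", "magnitude")) {
  stopifnot(inherits(result, "coherence_result"))
  summand <- match.arg(summand)
  if (is.null(result$sig_mask)) {
    abort("run rednoise_significance() before time_averaged_coherence()")
  }
  coh <- if (summand == "squared") result$coherence else sqrt(result$coherence)
  incoi <- outer(result$periods, result$coi, `<=`)
  denom <- rowSums(incoi)
  use <- incoi & result$sig_mask
  # boundary cells (cos(phase) numerically zero, e.g. phase exactly pi/2)
  # are assigned to the anti-phase quadrant
  is_in <- cos(result$phase) > 1e-9
  inph <- rowSums(coh * (use & is_in))
  anti <- rowSums(coh * (use & !is_in))
  safe <- pmax(denom, 1)
  out <- tibble(
    freq_hz = 1 / result$periods,
    period_s = result$periods,
    tac_inphase = ifelse(denom > 0, inph / safe, 0),
    tac_antiphase = ifelse(denom > 0, anti / safe, 0),
    n_incoi = as.integer(denom),
    outside_coi = denom == 0
  )
  out$tac_total <- out$tac_inphase + out$tac_antiphase
  class(out) <- c("tac_profile", class(out))
  out
}

#' Group mean and SEM of TAC profiles
#'
#' Averages per-subject TAC profiles scale by scale. Profiles on different
#' scale grids are first interpolated (linearly in log period) onto the
#' grid of the first profile.
#'
#' @param profiles List of [time_averaged_coherence()] tibbles (>= 2).
#'
#' @return Tibble `freq_hz`, `period_s`, and per quadrant the group `mean_*`
#'   and `sem_*`, plus `n` subjects.
#' @export
group_mean_tac <- function(profiles) {
  if (length(profiles) < 2) abort("need at least 2 profiles")
  ref <- profiles[[1]]
  aligned <- purrr::map(profiles, function(p) {
    if (nrow(p) == nrow(ref) &&
        max(abs(log(p$period_s) - log(ref$period_s))) < 1e-9) {
      return(p[, c("tac_inphase", "tac_antiphase", "tac_total")])
    }
    tibble(
      tac_inphase = approx(log(p$period_s), p$tac_inphase,
                           xout = log(ref$period_s), rule = 2)$y,
      tac_antiphase = approx(log(p$period_s), p$tac_antiphase,
                             xout = log(ref$period_s), rule = 2)$y,
      tac_total = approx(log(p$period_s), p$tac_total,
                         xout = log(ref$period_s), rule = 2)$y
    )
  })
  n <- length(aligned)
  stat <- function(field, f) {
    m <- vapply(aligned, function(a) a[[field]], numeric(nrow(ref)))
    apply(m, 1, f)
  }
  sem <- function(v) sd(v) / sqrt(length(v))
  tibble(
    freq_hz = ref$freq_hz,
    period_s = ref$period_s,
    mean_inphase = stat("tac_inphase", mean),
    sem_inphase = stat("tac_inphase", sem),
    mean_antiphase = stat("tac_antiphase", mean),
    sem_antiphase = stat("tac_antiphase", sem),
    mean_total = stat("tac_total", mean),
    sem_total = stat("tac_total", sem),
    n = n
  )
}
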
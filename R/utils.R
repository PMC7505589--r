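#' @importFrom rlang .data abort warn inform `%||%`
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   bind_rows left_join n
#' @importFrom purrr map map_dbl map2 imap
#' @importFrom stats approx fft sd cor var quantile rnorm runif qnorm pt
#'   t.test cor.test p.adjust lm coef residuals median IQR pnorm
NULL

# Derive a reproducible substream seed from a master seed and a stream label.
# Kept below 2^31 so it is always a valid R integer.
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  offsets <- c(
    gas = 101L, resp = 211L, cbfv = 307L, bold = 401L, paradigm = 503L,
    surrogate = 601L, cluster = 701L, subject = 809L, noise = 907L
  )
  off <- offsets[[stream]]
  as.integer((as.numeric(seed) * 7919 + off) %% 2147483647)
}

# Stationary AR(1) ("red") noise with unit marginal variance, scaled by sd.
ar1_noise <- function(n, phi, sd = 1) {
  stopifnot(abs(phi) < 1)
  if (n == 0) return(numeric(0))
  innov_sd <- sqrt(1 - phi^2)
  x <- numeric(n)
  x[1] <- rnorm(1)
  if (n > 1) {
    e <- rnorm(n - 1, sd = innov_sd)
    for (i in 2:n) x[i] <- phi * x[i - 1] + e[i - 1]
  }
  x * sd
}

# Lag-1 autocorrelation, the AR(1) coefficient estimate used for red-noise
# surrogates.
ar1_fit <- function(x) {
  x <- x - mean(x)
  n <- length(x)
  sum(x[-1] * x[-n]) / sum(x^2)
}

assert_uniform_time <- function(time, what = "series") {
  if (length(time) < 2) abort(paste0(what, " needs at least 2 samples"))
  dt <- diff(time)
  if (any(dt <= 0)) abort(paste0(what, " time grid must be strictly increasing"))
  if (diff(range(dt)) > 1e-6 * mean(dt)) {
    abort(paste0(what, " must be uniformly sampled"))
  }
  invisible(mean(dt))
}

# Two-column uniform trace constructor/validator used across modules.
new_trace <- function(time, value, value_name = "value") {
  assert_uniform_time(time, "trace")
  out <- tibble(time = as.numeric(time))
  out[[value_name]] <- as.numeric(value)
  out
}

trace_dt <- function(trace) assert_uniform_time(trace$time, "trace")

cap_r <- function(r, eps = 1e-12) pmax(pmin(r, 1 - eps), -(1 - eps))

fisher_z <- function(r) atanh(cap_r(r))

linear_detrend <- function(x) {
  t <- seq_along(x)
  residuals(lm(x ~ t))
}

# Local maxima at least min_dist samples apart whose topographic prominence
# reaches min_prom. The prominence of a candidate is its height above the
# higher of the two saddle minima separating it from the nearest higher
# candidate (or record edge) on each side — so noise wiggles riding on a
# plateau are rejected while the plateau's own summit is kept.
find_prominent_peaks <- function(x, min_dist = 1L, min_prom = 0) {
  x <- as.numeric(x)
  # zero = "+" so flat-topped peaks (e.g. after median filtering) count
  pk <- pracma::findpeaks(x, zero = "+",
                          minpeakdistance = max(1L, as.integer(min_dist)))
  if (is.null(pk) || nrow(pk) == 0) return(integer(0))
  pos <- sort(pk[, 2])
  h <- x[pos]
  k <- length(pos)
  prom <- vapply(seq_len(k), function(i) {
    higher_l <- which(h[seq_len(i - 1)] > h[i])
    from <- if (length(higher_l)) pos[max(higher_l)] else 1L
    left_min <- min(x[from:pos[i]])
    higher_r <- which(h[seq(i + 1, length.out = k - i)] > h[i]) + i
    to <- if (length(higher_r)) pos[min(higher_r)] else length(x)
    right_min <- min(x[pos[i]:to])
    h[i] - max(left_min, right_min)
  }, numeric(1))
  pos[prom >= min_prom]
}

# Zero-phase Butterworth low-pass with odd-reflection padding at both ends
# (signal::filtfilt zero-pads, which leaves large edge transients for
# signals with nonzero boundary values).
butter_lowpass_zerophase <- function(x, fc_hz, fs_hz, order = 4) {
  n <- length(x)
  bf <- signal::butter(order, fc_hz / (fs_hz / 2), type = "low")
  p <- min(n - 1, ceiling(6 * fs_hz / fc_hz))
  head_pad <- 2 * x[1] - x[seq(p + 1, 2)]
  tail_pad <- 2 * x[n] - x[seq(n - 1, n - p)]
  y <- as.numeric(signal::filtfilt(bf, c(head_pad, x, tail_pad)))
  y[(p + 1):(p + n)]
}

# Gaussian-smoothed impulse train marking event samples; used to
# cross-correlate timing landmarks without waveform-shape bias.
event_train <- function(n, events, sigma = 2L) {
  tr <- numeric(n)
  tr[events] <- 1
  r <- 3L * sigma
  k <- exp(-0.5 * ((-r:r) / sigma)^2)
  out <- stats::filter(c(numeric(r), tr, numeric(r)), k, sides = 2)
  as.numeric(out)[(r + 1):(r + n)]
}
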
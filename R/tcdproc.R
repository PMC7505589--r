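#' Remove artifactual spikes from a velocity envelope
#'
#' Running-median filter (default window 5 samples) applied to the Doppler
#' velocity envelope; single-sample probe artifacts are removed while the
#' pulsatile waveform is preserved.
#'
#' @param trace Tibble (`time`, `velocity`) on a uniform grid.
#' @param window Odd window length >= 3.
#' @return Filtered trace tibble of the same length.
#' @export
despike_velocity <- function(trace, window = 5) {
  trace_dt(trace)
  if (window < 3 || window %% 2 == 0) {
    abort("window must be an odd integer >= 3")
  }
  trace$velocity <- as.numeric(
    stats::runmed(trace$velocity, k = window, endrule = "keep")
  )
  trace
}

#' Detect cardiac beats on a velocity envelope
#'
#' Locates systolic peaks (prominent local maxima at least `min_ibi_s`
#' apart) and the end-diastolic trough preceding each peak. Beats are
#' delimited trough to trough. Beats overlapping user-declared artifact
#' spans are excluded (persistent-artifact segments are flagged manually in
#' practice).
#'
#' @param trace Tibble (`time`, `velocity`), ideally despiked first.
#' @param min_ibi_s Minimal inter-beat interval in seconds, within
#'   `[0.3, 2]` (default 0.4).
#' @param exclude Optional tibble (`start`, `end`) of artifact spans
#'   (seconds); beats overlapping any span are dropped.
#'
#' @return Tibble with one row per beat: `onset` (trough time), `end` (next
#'   trough), `peak_time`. Aborts when fewer than 10 beats are found in a
#'   record of a minute or more.
#' @export
detect_beats <- function(trace, min_ibi_s = 0.4, exclude = NULL) {
  if (min_ibi_s < 0.3 || min_ibi_s > 2) {
    abort("min_ibi_s must be within [0.3, 2] seconds")
  }
  dt <- trace_dt(trace)
  v <- trace$velocity
  span <- diff(range(trace$time))
  prom <- 0.5 * IQR(v)
  peaks <- find_prominent_peaks(v, floor(min_ibi_s / dt), prom)
  if (length(peaks) < 2) {
    if (span >= 60) abort("fewer than 10 beats detected in a >= 60 s trace")
    return(tibble(onset = numeric(0), end = numeric(0),
                  peak_time = numeric(0)))
  }
  # end-diastolic trough preceding each peak
  troughs <- vapply(seq_along(peaks), function(i) {
    from <- if (i == 1) 1L else peaks[i - 1]
    seg <- from:peaks[i]
    seg[which.min(v[seg])]
  }, integer(1))
  n_beats <- length(peaks) - 1
  beats <- tibble(
    onset = trace$time[troughs[seq_len(n_beats)]],
    end = trace$time[troughs[seq_len(n_beats) + 1]],
    peak_time = trace$time[peaks[seq_len(n_beats)]]
  )
  if (!is.null(exclude) && nrow(exclude) > 0) {
    bad <- purrr::map_lgl(seq_len(nrow(beats)), function(i) {
      any(beats$onset[i] < exclude$end & beats$end[i] > exclude$start)
    })
    beats <- beats[!bad, ]
  }
  if (span >= 60 && nrow(beats) < 10) {
    abort("fewer than 10 beats detected in a >= 60 s trace")
  }
  beats
}

#' Beat-integrated mean velocity and percent-change series
#'
#' The mean velocity of each cardiac cycle is the trapezoidal integral of
#' the envelope over the beat divided by the beat duration. The baseline is
#' the mean of the beat means whose onsets fall in the opening
#' `baseline_s` seconds, and `delta_cbfv` is the percent change of each beat
#' mean relative to that baseline — the normalization that removes
#' insonation-angle and absolute-velocity differences between subjects.
#'
#' @param trace Tibble (`time`, `velocity`).
#' @param beats Beat tibble from [detect_beats()].
#' @param baseline_s Length of the opening baseline window (default 30 s).
#'
#' @return Beat-series tibble: `beat_onset`, `beat_mean_velocity`,
#'   `delta_cbfv` (percent), with the baseline in attribute `baseline`.
#' @export
beat_mean_delta_cbfv <- function(trace, beats, baseline_s = 30) {
  if (nrow(beats) == 0) abort("no beats supplied")
  if (max(trace$time) < baseline_s) {
    abort("trace must span at least the baseline window plus one beat")
  }
  means <- purrr::map_dbl(seq_len(nrow(beats)), function(i) {
    idx <- which(trace$time >= beats$onset[i] & trace$time <= beats$end[i])
    pracma::trapz(trace$time[idx], trace$velocity[idx]) /
      (trace$time[idx[length(idx)]] - trace$time[idx[1]])
  })
  in_base <- beats$onset < baseline_s
  if (!any(in_base)) abort("no beats inside the baseline window")
  baseline <- mean(means[in_base])
  if (baseline == 0) abort("zero baseline velocity")
  out <- tibble(
    beat_onset = beats$onset,
    beat_mean_velocity = means,
    delta_cbfv = 100 * (means - baseline) / baseline
  )
  attr(out, "baseline") <- baseline
  out
}

#' Zero-phase low-pass filter
#'
#' 4th-order Butterworth applied forward and backward (`signal::filtfilt`),
#' so the passband has unit DC gain and zero phase shift. The default
#' 0.03 Hz cutoff isolates the slow band in which gas-exchange metrics and
#' cerebral hemodynamics share power.
#'
#' @param series Uniform tibble (`time`, `value`).
#' @param fc_hz Cutoff frequency (Hz), below Nyquist.
#' @param order Filter order (default 4).
#' @return Filtered series tibble.
#' @export
lowpass_cutoff <- function(series, fc_hz = 0.03, order = 4) {
  dt <- assert_uniform_time(series$time, "series")
  fs <- 1 / dt
  if (fc_hz >= fs / 2) abort("cutoff must be below the Nyquist frequency")
  tau <- 1 / (2 * pi * fc_hz)
  if (diff(range(series$time)) < 6 * tau) {
    abort("series shorter than 6 filter time constants")
  }
  series$value <- butter_lowpass_zerophase(series$value, fc_hz, fs, order)
  series
}
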
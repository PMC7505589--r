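#' Correct the technical gas-sampling-line delay
#'
#' Gas analyzers see each breath only after the sample has travelled down the
#' nasal sampling line, so the PO2/PCO2 traces lag the respiration reference.
#' The lag is estimated by cross-correlating an expiration signal derived
#' from the respiration trace (negative bellow deflection) with the PCO2
#' upslope, and the gas trace is advanced by that lag.
#'
#' Because both signals are nearly periodic at the breath rate, the
#' cross-correlation has near-equal peaks at the true delay plus whole breath
#' periods; the smallest local maximum within 90% of the global peak is taken
#' as the technical delay.
#'
#' @param gas Tibble with columns `time`, `po2`, `pco2` on a uniform grid.
#' @param resp Tibble with columns `time`, `displacement` (positive during
#'   inspiration) on the same grid.
#' @param max_lag_s Largest delay searched (default 15 s).
#'
#' @return The delay-corrected gas tibble, with the applied lag (seconds)
#'   in attribute `lag_s`.
#' @export
correct_gas_delay <- function(gas, resp, max_lag_s = 15) {
  dt <- trace_dt(gas)
  if (max_lag_s <= 0) abort("max_lag_s must be positive")
  n <- nrow(gas)
  common <- min(n, nrow(resp))
  disp <- resp$displacement[seq_len(common)]
  pco2 <- gas$pco2[seq_len(common)]
  # timing landmarks: expiration onset (negative-going bellow zero-crossing)
  # matches the capnogram minimum at end inspiration, whatever the plateau
  # time constant, so the cross-correlation of their smoothed event trains
  # peaks at the technical delay without waveform bias.
  exp_onset <- which(disp[-1] <= 0 & disp[-common] > 0) + 1L
  co2_min <- find_prominent_peaks(-pco2, floor(1.5 / dt), 0.25 * IQR(pco2))
  if (length(exp_onset) < 3 || length(co2_min) < 3) {
    warn("no usable respiration reference; applying zero lag")
    attr(gas, "lag_s") <- 0
    return(gas)
  }
  exhale <- event_train(common, exp_onset)
  upslope <- event_train(common, co2_min)
  max_lag <- min(floor(max_lag_s / dt), common - 10)
  lags <- 0:max_lag
  cc <- vapply(lags, function(l) {
    cor(exhale[seq_len(common - l)], upslope[seq_len(common - l) + l])
  }, numeric(1))
  if (max(cc, na.rm = TRUE) < 0.2) {
    warn("peak cross-correlation below 0.2; applying zero lag")
    attr(gas, "lag_s") <- 0
    return(gas)
  }
  is_peak <- vapply(seq_along(cc), function(i) {
    left <- if (i > 1) cc[i - 1] else -Inf
    right <- if (i < length(cc)) cc[i + 1] else -Inf
    cc[i] >= left && cc[i] >= right
  }, logical(1))
  cand <- which(is_peak & cc >= 0.9 * max(cc, na.rm = TRUE))
  lag_samples <- lags[cand[1]]
  corrected <- gas
  if (lag_samples > 0) {
    keep <- seq_len(n - lag_samples)
    corrected$po2 <- c(gas$po2[keep + lag_samples],
                       rep(gas$po2[n], lag_samples))
    corrected$pco2 <- c(gas$pco2[keep + lag_samples],
                        rep(gas$pco2[n], lag_samples))
  }
  attr(corrected, "lag_s") <- lag_samples * dt
  corrected
}

#' Detect breath phases on the capnogram
#'
#' End expiration is the local maximum of PCO2 at the end of each expiratory
#' plateau; end inspiration is the local minimum of PCO2 immediately
#' preceding it. Detection is anchored on PCO2 because the capnogram plateau
#' is the sharper landmark; the oxigram is read at the same time stamps so
#' that the PO2 and PCO2 excursions refer to the same breath. A prominence
#' filter (25% of the trace inter-quartile range) rejects sub-breath wiggles.
#'
#' @param gas Gas trace tibble (`time`, `po2`, `pco2`).
#' @param min_period_s,max_period_s Plausible breath-period bounds (defaults
#'   1.5 and 15 s); successive end-expirations must be separated by a lag in
#'   this range.
#'
#' @return Tibble with one row per breath: `t_end_insp`, `t_end_exp`. Empty
#'   (with a warning) when no breaths are detectable.
#' @export
detect_breath_phases <- function(gas, min_period_s = 1.5, max_period_s = 15) {
  stopifnot(min_period_s > 0, min_period_s < max_period_s)
  dt <- trace_dt(gas)
  x <- gas$pco2
  empty <- tibble(t_end_insp = numeric(0), t_end_exp = numeric(0))
  prom <- 0.25 * IQR(x)
  if (prom <= 0) {
    warn("capnogram has no breath-scale structure; no breaths detected")
    return(empty)
  }
  peak_pos <- find_prominent_peaks(x, floor(min_period_s / dt), prom)
  if (length(peak_pos) < 2) {
    warn("fewer than two expiratory peaks found; no breaths detected")
    return(empty)
  }
  # enforce inter-peak period bounds
  keep <- c(TRUE, diff(peak_pos) * dt >= min_period_s &
              diff(peak_pos) * dt <= max_period_s)
  peak_pos <- peak_pos[keep]
  if (length(peak_pos) < 2) {
    warn("no breaths with plausible period; no breaths detected")
    return(empty)
  }
  prev <- c(1L, peak_pos[-length(peak_pos)])
  t_end_insp <- vapply(seq_along(peak_pos), function(i) {
    seg <- prev[i]:peak_pos[i]
    gas$time[seg[which.min(x[seg])]]
  }, numeric(1))
  tibble(t_end_insp = t_end_insp, t_end_exp = gas$time[peak_pos])
}

#' Per-breath respiratory gas-exchange metrics
#'
#' Reads the gas traces at the detected phase times and computes, for each
#' breath, the end-tidal pressures, the within-breath excursions, and the
#' breath-by-breath O2-CO2 exchange ratio:
#' `pet_co2 = PCO2(t_end_exp)`, `pet_o2 = PO2(t_end_exp)`,
#' `d_pco2 = PCO2(t_end_exp) - PCO2(t_end_insp)` (expired minus inspired),
#' `d_po2 = PO2(t_end_insp) - PO2(t_end_exp)` (inspired minus expired) and
#' `ber = d_po2 / d_pco2`. The inspired values are read at end inspiration on
#' the delay-corrected trace rather than assumed ambient. Breaths whose CO2
#' excursion falls below `d_pco2_floor` are flagged invalid (they would blow
#' up the ratio); if more than half the breaths are invalid the trace is
#' considered unusable.
#'
#' @param gas Delay-corrected gas trace tibble.
#' @param phases Breath-phase tibble from [detect_breath_phases()].
#' @param d_pco2_floor Minimal valid CO2 excursion (mmHg, default 1).
#'
#' @return A breath table tibble: `t_end_insp`, `t_end_exp`, `pet_o2`,
#'   `pet_co2`, `d_po2`, `d_pco2`, `ber`, `valid`.
#' @export
compute_rge_metrics <- function(gas, phases, d_pco2_floor = 1) {
  if (nrow(phases) == 0) abort("phases is empty")
  po2_at <- function(t) approx(gas$time, gas$po2, xout = t, rule = 2)$y
  pco2_at <- function(t) approx(gas$time, gas$pco2, xout = t, rule = 2)$y
  out <- tibble(
    t_end_insp = phases$t_end_insp,
    t_end_exp = phases$t_end_exp,
    pet_o2 = po2_at(phases$t_end_exp),
    pet_co2 = pco2_at(phases$t_end_exp),
    d_po2 = po2_at(phases$t_end_insp) - po2_at(phases$t_end_exp),
    d_pco2 = pco2_at(phases$t_end_exp) - pco2_at(phases$t_end_insp)
  )
  out$ber <- out$d_po2 / out$d_pco2
  out$valid <- out$d_pco2 > d_pco2_floor
  if (mean(out$valid) < 0.5) {
    abort("more than half the breaths have a sub-floor CO2 excursion; trace unusable")
  }
  out
}

#' Respiration volume per unit time (RVT)
#'
#' For each respiratory cycle, RVT is the bellow excursion (inspiratory peak
#' minus the following expiratory trough) divided by the peak-to-peak
#' respiratory period. It indexes breath-to-breath changes in ventilation
#' depth and rate and is the standard respiratory-variation regressor for
#' fMRI.
#'
#' @param resp Respiration tibble (`time`, `displacement`).
#' @param min_period_s Minimal plausible breath period for peak detection.
#'
#' @return Tibble `time` (inspiratory peak time), `rvt`. Empty with a warning
#'   when fewer than 3 peaks are found.
#' @export
compute_rvt <- function(resp, min_period_s = 1.5) {
  dt <- trace_dt(resp)
  x <- resp$displacement
  empty <- tibble(time = numeric(0), rvt = numeric(0))
  if (IQR(x) <= 0) {
    warn("respiration trace has no breath-scale structure; no RVT computed")
    return(empty)
  }
  peak_pos <- find_prominent_peaks(x, floor(min_period_s / dt), 0.25 * IQR(x))
  if (length(peak_pos) < 3) {
    warn("fewer than 3 inspiratory peaks; no RVT computed")
    return(empty)
  }
  peak_val <- x[peak_pos]
  n_cyc <- length(peak_pos) - 1
  rvt <- vapply(seq_len(n_cyc), function(i) {
    seg <- peak_pos[i]:peak_pos[i + 1]
    trough <- min(x[seg])
    period <- (peak_pos[i + 1] - peak_pos[i]) * dt
    (peak_val[i] - trough) / period
  }, numeric(1))
  tibble(time = resp$time[peak_pos[seq_len(n_cyc)]], rvt = rvt)
}

#' Resample a per-breath series onto a uniform grid
#'
#' Breath-resolved metrics live on the irregular grid of end-expiration
#' times; coherence and correlation analyses need a common uniform grid.
#' Values are linearly interpolated, anchored at end expiration (the moment
#' the end-tidal values are defined), and clipped to the first/last valid
#' breath (no extrapolation).
#'
#' @param table Breath table from [compute_rge_metrics()] (invalid breaths
#'   are dropped), or any tibble with a time column and the named field.
#' @param field Column to interpolate (e.g. `"ber"`, `"d_po2"`).
#' @param dt_s Output sampling interval (default 1 s).
#' @param time_col Column holding the anchor times (default `"t_end_exp"`).
#'
#' @return Tibble (`time`, `value`) on a uniform grid.
#' @export
breath_series_to_uniform <- function(table, field, dt_s = 1,
                                     time_col = "t_end_exp") {
  if (!field %in% names(table)) {
    abort(paste0("unknown field '", field, "'"))
  }
  if (dt_s <= 0) abort("dt_s must be positive")
  if ("valid" %in% names(table)) table <- table[table$valid, ]
  if (nrow(table) < 2) abort("need at least 2 valid breaths")
  t0 <- table[[time_col]]
  grid <- seq(ceiling(min(t0) / dt_s) * dt_s, max(t0), by = dt_s)
  tibble(
    time = grid,
    value = approx(t0, table[[field]], xout = grid, rule = 1)$y
  )
}
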
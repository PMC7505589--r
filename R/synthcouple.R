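#' Specification of the synthetic brain-body coupling model
#'
#' Collects the free parameters of the synthetic-data generators in one
#' validated object. The generators emulate a resting record in which a shared
#' low-frequency oscillation (period 0.5-2 min) modulates the per-breath gas
#' excursions and, through a hemodynamic coupling coefficient, the cerebral
#' signals (Doppler velocity, BOLD). A common ventilation factor makes the
#' PO2 and PCO2 excursions interdependent without being redundant, and AR(1)
#' "red" noise matches the null model of the coherence significance test.
#'
#' @param modulator_freq_hz Frequency of the shared low-frequency oscillation
#'   (Hz). Default 0.01 Hz, the centre of the 0.008-0.03 Hz band of interest.
#' @param modulator_amp Amplitude of the per-breath PO2-excursion modulation
#'   (mmHg).
#' @param amp_ratio_po2_pco2 Ratio of the PO2 to the PCO2 modulation
#'   amplitude; 2 reproduces oscillation amplitudes of the within-breath PO2
#'   excursion up to double those of PCO2.
#' @param coupling_beta Fractional hemodynamic response per unit of the
#'   (unit-amplitude) modulator; 0.05 gives ~5% velocity swings.
#' @param coupling_lag_s Lag of the hemodynamic response behind the modulator
#'   (seconds).
#' @param ar1_coef AR(1) coefficient of the additive noise processes
#'   (|ar1_coef| < 1).
#' @param noise_sd Noise standard deviation, in the units of the signal it is
#'   added to (cm/s for velocity cycle means, percent signal for BOLD).
#' @param gas_line_delay_s Technical gas-sampling-line delay injected into the
#'   generated gas traces (seconds); the ground-truth tables are unshifted.
#' @param seed Integer master seed; all generator substreams derive from it,
#'   and an identical spec yields bit-identical output.
#'
#' @return A list of class `coupling_spec`.
#' @export
coupling_spec <- function(modulator_freq_hz = 0.01,
                          modulator_amp = 5,
                          amp_ratio_po2_pco2 = 2,
                          coupling_beta = 0.05,
                          coupling_lag_s = 0,
                          ar1_coef = 0.8,
                          noise_sd = 0.5,
                          gas_line_delay_s = 3,
                          seed = 1L) {
  if (modulator_freq_hz <= 0) abort("modulator_freq_hz must be positive")
  if (amp_ratio_po2_pco2 <= 0) abort("amp_ratio_po2_pco2 must be positive")
  if (abs(ar1_coef) >= 1) abort("|ar1_coef| must be < 1")
  if (noise_sd < 0 || modulator_amp < 0) abort("amplitudes must be non-negative")
  structure(
    list(
      modulator_freq_hz = modulator_freq_hz,
      modulator_amp = modulator_amp,
      amp_ratio_po2_pco2 = amp_ratio_po2_pco2,
      coupling_beta = coupling_beta,
      coupling_lag_s = coupling_lag_s,
      ar1_coef = ar1_coef,
      noise_sd = noise_sd,
      gas_line_delay_s = gas_line_delay_s,
      seed = as.integer(seed)
    ),
    class = "coupling_spec"
  )
}

#' Simulate breath-by-breath respiratory gas traces with known ground truth
#'
#' Generates uniformly sampled PO2/PCO2 traces (mmHg), a respiration bellow
#' trace, the latent modulator, and the ground-truth per-breath table. Within
#' each breath the capnogram rises exponentially to its expiratory plateau and
#' falls towards the inspired level during inspiration; the oxigram mirrors
#' it. The per-breath expiratory plateaus are modulated so that the
#' ground-truth PO2 and PCO2 excursions oscillate in phase at
#' `modulator_freq_hz` with amplitude ratio `amp_ratio_po2_pco2`, which makes
#' the end-tidal PO2 anti-phase with the end-tidal PCO2. A shared
#' breath-to-breath ventilation factor (AR(1) across breaths) scales both
#' excursions and the bellow amplitude, so PO2 and PCO2 excursions are
#' correlated beyond the deterministic modulation. The gas traces (only) are
#' then delayed by `spec$gas_line_delay_s`, emulating the sampling line.
#'
#' @param spec A [coupling_spec()].
#' @param duration_s Record length in seconds (default 600, a 10-minute run).
#'   Must cover at least 10 breaths.
#' @param breath_period_s Respiratory cycle length (default 5 s, within the
#'   typical 4-6 s resting range).
#' @param sample_rate_hz Gas/bellow sampling rate; must be at least
#'   10/`breath_period_s`.
#' @param base_d_po2,base_d_pco2 Baseline within-breath excursions (mmHg).
#' @param inspired_po2,inspired_pco2 Inspired partial pressures (mmHg).
#' @param insp_frac Fraction of the cycle spent in inspiration.
#' @param tau_s Time constant of the exponential approach to each plateau.
#' @param vent_sd Relative SD of the common ventilation factor.
#' @param vent_ar1 AR(1) coefficient of the ventilation factor across breaths.
#' @param breath_noise_sd Per-gas independent breath-to-breath noise (mmHg).
#' @param trace_noise_sd Additive AR(1) measurement noise on the sampled gas
#'   traces (mmHg).
#' @param co2_mod_gain Multiplier on the PCO2 modulation amplitude; the
#'   multi-subject imaging simulation draws it per subject to emulate
#'   inter-individual variability of the CO2-hemodynamics coupling.
#' @param resp_amp Bellow excursion amplitude (arbitrary units).
#'
#' @return A list with elements `gas` (tibble time/po2/pco2), `resp` (tibble
#'   time/displacement), `modulator` (tibble time/value, unit amplitude),
#'   `drive` (tibble time/value: the deterministic bER component
#'   attributable to the modulator, i.e. the hemodynamic drive), `truth`
#'   (ground-truth breath table: t_end_insp, t_end_exp, pet_o2, pet_co2,
#'   d_po2, d_pco2, ber, rvt) and `params`.
#' @export
sim_gas_exchange <- function(spec,
                             duration_s = 600,
                             breath_period_s = 5,
                             sample_rate_hz = 20,
                             base_d_po2 = 44.3,
                             base_d_pco2 = 39.4,
                             inspired_po2 = 150,
                             inspired_pco2 = 0,
                             insp_frac = 0.4,
                             tau_s = 0.4,
                             vent_sd = 0.04,
                             vent_ar1 = 0.8,
                             breath_noise_sd = 0.4,
                             trace_noise_sd = 0.2,
                             co2_mod_gain = 1,
                             resp_amp = 1) {
  stopifnot(inherits(spec, "coupling_spec"))
  if (breath_period_s <= 0) abort("breath_period_s must be positive")
  if (duration_s < 10 * breath_period_s) {
    abort("duration_s must cover at least 10 breaths")
  }
  if (sample_rate_hz < 10 / breath_period_s) {
    abort("sample_rate_hz must be at least 10 samples per breath")
  }

  dt <- 1 / sample_rate_hz
  n <- floor(duration_s * sample_rate_hz)
  time <- (seq_len(n) - 1) * dt
  tt <- breath_period_s
  n_breaths <- floor(duration_s / tt)
  a <- insp_frac

  withr::with_seed(substream_seed(spec$seed, "gas"), {
    vent <- ar1_noise(n_breaths, vent_ar1, vent_sd)
    e_o2 <- rnorm(n_breaths, sd = breath_noise_sd)
    e_co2 <- rnorm(n_breaths, sd = breath_noise_sd)
    noise_po2 <- ar1_noise(n, spec$ar1_coef, trace_noise_sd)
    noise_pco2 <- ar1_noise(n, spec$ar1_coef, trace_noise_sd)
  })

  k <- seq_len(n_breaths)
  t_start <- (k - 1) * tt
  t_end_insp <- t_start + a * tt
  t_end_exp <- t_start + tt
  m_k <- sin(2 * pi * spec$modulator_freq_hz * t_end_exp)

  d_po2_k <- base_d_po2 * (1 + vent) + spec$modulator_amp * m_k + e_o2
  d_pco2_k <- base_d_pco2 * (1 + vent) +
    (spec$modulator_amp / spec$amp_ratio_po2_pco2) * co2_mod_gain * m_k + e_co2
  pet_co2_k <- inspired_pco2 + d_pco2_k
  pet_o2_k <- inspired_po2 - d_po2_k

  # Piecewise-exponential plateaus; values tracked analytically at segment
  # boundaries so the ground truth matches the continuous waveform.
  pco2 <- numeric(n)
  po2 <- numeric(n)
  v_co2 <- pet_co2_k[1]   # value entering the first breath
  v_o2 <- pet_o2_k[1]
  gt_insp_co2 <- numeric(n_breaths)
  gt_insp_o2 <- numeric(n_breaths)
  gt_exp_co2 <- numeric(n_breaths)
  gt_exp_o2 <- numeric(n_breaths)
  for (b in k) {
    idx <- which(time >= t_start[b] & time < t_end_exp[b])
    tb <- time[idx] - t_start[b]
    in_insp <- tb < a * tt
    # inspiration: decay towards inspired values
    pco2_insp <- inspired_pco2 + (v_co2 - inspired_pco2) * exp(-tb / tau_s)
    po2_insp <- inspired_po2 + (v_o2 - inspired_po2) * exp(-tb / tau_s)
    v1_co2 <- inspired_pco2 + (v_co2 - inspired_pco2) * exp(-a * tt / tau_s)
    v1_o2 <- inspired_po2 + (v_o2 - inspired_po2) * exp(-a * tt / tau_s)
    # expiration: approach the modulated plateau
    te <- tb - a * tt
    pco2_exp <- pet_co2_k[b] + (v1_co2 - pet_co2_k[b]) * exp(-te / tau_s)
    po2_exp <- pet_o2_k[b] + (v1_o2 - pet_o2_k[b]) * exp(-te / tau_s)
    pco2[idx] <- ifelse(in_insp, pco2_insp, pco2_exp)
    po2[idx] <- ifelse(in_insp, po2_insp, po2_exp)
    gt_insp_co2[b] <- v1_co2
    gt_insp_o2[b] <- v1_o2
    v_co2 <- pet_co2_k[b] + (v1_co2 - pet_co2_k[b]) * exp(-(1 - a) * tt / tau_s)
    v_o2 <- pet_o2_k[b] + (v1_o2 - pet_o2_k[b]) * exp(-(1 - a) * tt / tau_s)
    gt_exp_co2[b] <- v_co2
    gt_exp_o2[b] <- v_o2
  }
  pco2 <- pco2 + noise_pco2
  po2 <- pmax(po2 + noise_po2, 0)

  # Bellow: positive deflection during inspiration, negative in expiration,
  # amplitude tied to the ventilation factor.
  amp_k <- resp_amp * (1 + vent)
  phase <- (time %% tt) / tt
  b_idx <- pmin(floor(time / tt) + 1, n_breaths)
  disp <- ifelse(
    phase < a,
    sin(pi * phase / a),
    -sin(pi * (phase - a) / (1 - a))
  ) * amp_k[b_idx]

  # Technical gas-line delay: the observed gas value at t is the true value
  # at t - delay. Respiration is unaffected.
  shift <- round(spec$gas_line_delay_s * sample_rate_hz)
  delay_fun <- function(x) {
    if (shift == 0) return(x)
    c(rep(x[1], shift), x[seq_len(n - shift)])
  }

  truth <- tibble(
    breath = k,
    t_end_insp = t_end_insp,
    t_end_exp = t_end_exp,
    pet_o2 = gt_exp_o2,
    pet_co2 = gt_exp_co2,
    d_po2 = gt_insp_o2 - gt_exp_o2,
    d_pco2 = gt_exp_co2 - gt_insp_co2,
    rvt = 2 * amp_k / tt
  )
  truth$ber <- truth$d_po2 / truth$d_pco2

  # deterministic bER component attributable to the shared modulator: the
  # hemodynamic drive, free of ventilation and breath-to-breath noise
  m_t <- sin(2 * pi * spec$modulator_freq_hz * time)
  ber_det <- (base_d_po2 + spec$modulator_amp * m_t) /
    (base_d_pco2 + (spec$modulator_amp / spec$amp_ratio_po2_pco2) *
       co2_mod_gain * m_t)

  list(
    gas = tibble(time = time, po2 = delay_fun(po2), pco2 = delay_fun(pco2)),
    resp = tibble(time = time, displacement = disp),
    modulator = tibble(
      time = time,
      value = m_t
    ),
    drive = tibble(time = time, value = ber_det),
    truth = truth,
    params = list(
      spec = spec, duration_s = duration_s, breath_period_s = breath_period_s,
      sample_rate_hz = sample_rate_hz, insp_frac = insp_frac, tau_s = tau_s
    )
  )
}

#' Simulate a pulsatile transcranial Doppler velocity envelope
#'
#' Builds a velocity trace whose per-cardiac-cycle mean follows
#' `baseline * (1 + coupling_beta * modulator(t - coupling_lag_s))` plus AR(1)
#' beat-level noise, with a systolic-peak/diastolic-trough pulse shape riding
#' on each cycle. The pulse shape is zero-meaned within each beat so the
#' cycle mean equals the prescribed value.
#'
#' @param spec A [coupling_spec()].
#' @param modulator Tibble (time, value) of the latent modulator in units for
#'   which `coupling_beta` is the fractional response per unit.
#' @param duration_s Record length (s).
#' @param sample_rate_hz Envelope sampling rate (default 100 Hz).
#' @param heart_rate_hz Either a scalar heart rate or a tibble (time, rate)
#'   for a time-varying rate (step changes supported). Must stay >= 0.8 Hz.
#' @param baseline_velocity Baseline cycle-mean velocity (cm/s).
#' @param pulse_amp Amplitude of the pulsatile component (cm/s).
#'
#' @return A list with `trace` (tibble time/velocity) and `truth` (tibble
#'   beat_onset/cycle_mean), the ground-truth per-cycle means.
#' @export
sim_cbfv <- function(spec,
                     modulator,
                     duration_s = 600,
                     sample_rate_hz = 100,
                     heart_rate_hz = 1.1,
                     baseline_velocity = 60,
                     pulse_amp = 25) {
  stopifnot(inherits(spec, "coupling_spec"))
  rate_fun <- if (is.data.frame(heart_rate_hz)) {
    stats::approxfun(heart_rate_hz$time, heart_rate_hz$rate,
                     method = "constant", rule = 2)
  } else {
    function(t) rep(heart_rate_hz, length(t))
  }
  if (any(rate_fun(seq(0, duration_s, length.out = 50)) < 0.8)) {
    abort("heart rate must stay >= 0.8 Hz")
  }
  mod_fun <- stats::approxfun(modulator$time, modulator$value, rule = 2)

  onsets <- 0
  while (TRUE) {
    nxt <- onsets[length(onsets)] + 1 / rate_fun(onsets[length(onsets)])
    if (nxt >= duration_s) break
    onsets <- c(onsets, nxt)
  }
  n_beats <- length(onsets)
  ends <- c(onsets[-1], duration_s)

  withr::with_seed(substream_seed(spec$seed, "cbfv"), {
    beat_noise <- ar1_noise(n_beats, spec$ar1_coef, spec$noise_sd)
  })
  cycle_mean <- baseline_velocity *
    (1 + spec$coupling_beta * mod_fun(onsets - spec$coupling_lag_s)) +
    beat_noise

  dt <- 1 / sample_rate_hz
  n <- floor(duration_s * sample_rate_hz)
  time <- (seq_len(n) - 1) * dt
  beat_of <- findInterval(time, onsets)
  phase <- (time - onsets[beat_of]) / (ends[beat_of] - onsets[beat_of])
  shape <- exp(-((phase - 0.25) / 0.12)^2)
  shape_mean <- tapply(shape, beat_of, mean)[beat_of]
  velocity <- cycle_mean[beat_of] + pulse_amp * (shape - as.numeric(shape_mean))

  list(
    trace = tibble(time = time, velocity = velocity),
    truth = tibble(beat_onset = onsets, cycle_mean = cycle_mean)
  )
}

#' In-memory 4D percent-BOLD volume
#'
#' Light container for a 4D array of percent BOLD signal change with its
#' repetition time, in-brain mask and voxel dimensions.
#'
#' @param data 4D numeric array (x, y, z, t).
#' @param tr_s Repetition time (s).
#' @param mask 3D logical array; defaults to all-in.
#' @param voxel_dims_mm Length-3 voxel dimensions in mm.
#' @return An object of class `volume_series`.
#' @export
volume_series <- function(data, tr_s, mask = NULL,
                          voxel_dims_mm = c(3.4, 3.4, 6)) {
  stopifnot(length(dim(data)) == 4, tr_s > 0)
  if (is.null(mask)) mask <- array(TRUE, dim(data)[1:3])
  stopifnot(identical(dim(mask), dim(data)[1:3]))
  structure(
    list(data = data, tr_s = tr_s, mask = mask,
         voxel_dims_mm = voxel_dims_mm),
    class = "volume_series"
  )
}

#' Integer parcellation volume
#'
#' @param labels 3D integer array of region labels (0 = outside).
#' @param region_names Optional character vector of region names.
#' @return An object of class `parcellation` with a `regions` lookup tibble.
#' @export
parcellation <- function(labels, region_names = NULL) {
  ids <- sort(unique(as.integer(labels[labels > 0])))
  if (is.null(region_names)) region_names <- paste0("region_", ids)
  structure(
    list(
      labels = labels,
      regions = tibble(
        region = ids,
        name = region_names[seq_along(ids)],
        n_voxels = as.integer(table(factor(labels[labels > 0], levels = ids)))
      )
    ),
    class = "parcellation"
  )
}

#' Simulate a 4D percent-BOLD volume coupled to a regressor
#'
#' Each voxel's time series is `beta[region] * regressor(t - lag)` plus a
#' voxel-specific linear drift and AR(1) noise. The parcellation partitions
#' the grid into contiguous slabs so clusters of truly coupled voxels are
#' spatially compact.
#'
#' @param spec A [coupling_spec()]; `ar1_coef` and `noise_sd` set the voxel
#'   noise, `coupling_lag_s` the regressor lag.
#' @param regressor Tibble (time, value).
#' @param grid_shape Integer length-3 grid (default 16^3).
#' @param n_regions Number of parcels (>= 2).
#' @param region_beta_map Named numeric vector: true percent-BOLD change per
#'   unit regressor for every region label.
#' @param tr_s Repetition time (default 1.45 s).
#' @param drift_sd SD of the per-voxel linear drift slope (percent per
#'   second).
#' @param voxel_dims_mm Voxel dimensions (mm).
#'
#' @return List with `vol` ([volume_series()]), `parc` ([parcellation()]) and
#'   `truth` (tibble region/beta).
#' @export
sim_bold_volume <- function(spec,
                            regressor,
                            grid_shape = c(16, 16, 16),
                            n_regions = 8,
                            region_beta_map,
                            tr_s = 1.45,
                            drift_sd = 0.002,
                            voxel_dims_mm = c(3.4, 3.4, 6)) {
  stopifnot(inherits(spec, "coupling_spec"), n_regions >= 2, tr_s > 0)
  n_t <- floor(max(regressor$time) / tr_s)
  if (n_t < 30) abort("regressor must cover at least 30 frames")
  frame_times <- (seq_len(n_t) - 0.5) * tr_s
  reg <- approx(regressor$time, regressor$value,
                xout = frame_times - spec$coupling_lag_s, rule = 2)$y

  n_vox <- prod(grid_shape)
  labels_vec <- as.integer(cut(seq_len(n_vox), breaks = n_regions,
                               labels = FALSE))
  labels <- array(labels_vec, grid_shape)
  ids <- seq_len(n_regions)
  if (!all(as.character(ids) %in% names(region_beta_map))) {
    abort("region_beta_map must name every region label")
  }
  beta_vox <- as.numeric(region_beta_map[as.character(labels_vec)])

  withr::with_seed(substream_seed(spec$seed, "bold"), {
    drift_slope <- rnorm(n_vox, sd = drift_sd)
    if (spec$noise_sd > 0) {
      noise <- matrix(0, n_vox, n_t)
      noise[, 1] <- rnorm(n_vox)
      innov_sd <- sqrt(1 - spec$ar1_coef^2)
      if (n_t > 1) {
        for (j in 2:n_t) {
          noise[, j] <- spec$ar1_coef * noise[, j - 1] +
            rnorm(n_vox, sd = innov_sd)
        }
      }
      noise <- noise * spec$noise_sd
    } else {
      noise <- matrix(0, n_vox, n_t)
    }
  })

  tc <- frame_times - mean(frame_times)
  y <- outer(beta_vox, reg) + outer(drift_slope, tc) + noise
  vol <- volume_series(array(y, c(grid_shape, n_t)), tr_s,
                       voxel_dims_mm = voxel_dims_mm)
  list(
    vol = vol,
    parc = parcellation(labels),
    truth = tibble(region = ids,
                   beta = as.numeric(region_beta_map[as.character(ids)]))
  )
}

#' Simulate the exogenous CO2 block paradigm
#'
#' Six 30-second mild hypercapnic epochs (three at +4 mmHg and three at
#' +8 mmHg above the resting end-tidal CO2, in randomized order) separated by
#' normocapnic gaps of 60-90 s, fitted into a run of at most 10 minutes. The
#' returned end-tidal CO2 target series has both the commanded step schedule
#' (`target`) and a first-order exponential approach to each step
#' (`approach`), emulating the finite response of the gas delivery circuit.
#'
#' @param seed Integer seed for the epoch order and gap lengths.
#' @param baseline_petco2 Resting end-tidal CO2 (mmHg), in (25, 50).
#' @param dt_s Sampling interval of the target series (s).
#' @param tau_s Time constant of the exponential approach (s).
#'
#' @return List with `paradigm` (tibble onset_s/duration_s/
#'   petco2_offset_mmHg), `target` (tibble time/target/approach) and
#'   `baseline_petco2`.
#' @export
sim_co2_paradigm <- function(seed = 1L,
                             baseline_petco2 = 40,
                             dt_s = 1,
                             tau_s = 8) {
  if (baseline_petco2 <= 25 || baseline_petco2 >= 50) {
    abort("baseline_petco2 must be in (25, 50) mmHg")
  }
  withr::with_seed(substream_seed(seed, "paradigm"), {
    offsets <- sample(c(4, 4, 4, 8, 8, 8))
    gaps <- runif(6, 60, 90)
  })
  # 6 x 30 s hypercapnia + trailing 30 s normocapnia within a 10-minute run
  gap_budget <- 600 - 6 * 30 - 30
  if (sum(gaps) > gap_budget) {
    # shrink gaps proportionally toward the 60 s floor to fit 10 minutes
    excess <- sum(gaps) - gap_budget
    slack <- gaps - 60
    gaps <- gaps - slack * (excess / sum(slack))
  }
  onsets <- cumsum(gaps) + c(0, cumsum(rep(30, 5)))
  paradigm <- tibble(
    onset_s = onsets,
    duration_s = 30,
    petco2_offset_mmHg = offsets
  )
  total <- onsets[6] + 30 + 30  # trailing half-minute of normocapnia
  time <- seq(0, total, by = dt_s)
  target <- rep(baseline_petco2, length(time))
  for (i in seq_len(6)) {
    on <- time >= onsets[i] & time < onsets[i] + 30
    target[on] <- baseline_petco2 + offsets[i]
  }
  # first-order approach to the commanded step
  approach <- numeric(length(time))
  approach[1] <- target[1]
  alpha <- 1 - exp(-dt_s / tau_s)
  for (i in seq_along(time)[-1]) {
    approach[i] <- approach[i - 1] + alpha * (target[i] - approach[i - 1])
  }
  list(
    paradigm = paradigm,
    target = tibble(time = time, target = target, approach = approach),
    baseline_petco2 = baseline_petco2
  )
}
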
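---
title: "Breath-by-breath gas exchange and cerebral hemodynamics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Breath-by-breath gas exchange and cerebral hemodynamics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(bercouple)
```

## The scientific problem

Resting cerebral hemodynamics fluctuate slowly — with periods of half a
minute to two minutes (0.008–0.03 Hz) — and those fluctuations carry the
functional-connectivity structure of networks such as the default mode
network (DMN). One physiological candidate for their origin is respiratory
gas exchange. `bercouple` implements an analysis of that hypothesis built
around the breath-by-breath O2–CO2 exchange ratio

\[ \mathrm{bER} = \frac{\Delta P_{O_2}}{\Delta P_{CO_2}}, \qquad
\Delta P_{O_2} = P_{O_2}^{\text{insp}} - P_{O_2}^{\text{exp}}, \quad
\Delta P_{CO_2} = P_{CO_2}^{\text{exp}} - P_{CO_2}^{\text{insp}}, \]

with the inspired and expired values read at end inspiration and end
expiration of each breath. bER is a ratio, so ventilatory-volume
fluctuations that scale both excursions cancel; its time average over
minutes is the reciprocal of the classical steady-state respiratory
exchange ratio. The package quantifies how bER, the individual excursions,
the end-tidal pressures and respiration volume per time (RVT) couple to two
hemodynamic read-outs: beat-resolved transcranial Doppler velocity
(percent change, ΔCBFv) and percent BOLD signal change (ΔBOLD).

Because no raw recordings are publicly deposited for this kind of study,
the package ships a synthetic-data module that generates physiological and
imaging records with the statistical structure the analysis assumes, with
full ground truth. Every downstream stage is tested against that ground
truth, and the headline qualitative findings are reproduced on synthetic
study-sized data.

## The synthetic coupling model

`coupling_spec()` collects the generator's free parameters. The model is:

* a **shared low-frequency modulator** \(M(t)=\sin(2\pi f_m t)\) with
  \(f_m = 0.01\) Hz by default, the centre of the band of interest;
* **per-breath gas excursions**
  \(\Delta P_{O_2,k} = \bar\Delta_{O_2}(1 + v_k) + A\,M(t_k) + e_{O_2,k}\) and
  \(\Delta P_{CO_2,k} = \bar\Delta_{CO_2}(1 + v_k) + (A/\rho)\,g\,M(t_k) + e_{CO_2,k}\),
  where \(v_k\) is a common ventilation factor (AR(1) across breaths,
  relative SD 0.04), \(A = 5\) mmHg the modulation amplitude,
  \(\rho = 2\) the PO2:PCO2 amplitude ratio (PO2 excursions can swing with
  double the amplitude of PCO2), \(g\) a CO2-coupling gain (1 by default),
  and \(e\) independent breath noise (0.4 mmHg). Baselines default to
  44.3 / 39.4 mmHg so the mean bER is ≈ 1.1, matching a typical resting
  subject;
* a **within-breath waveform**: the capnogram approaches its expiratory
  plateau and its near-zero inspired level exponentially (time constant
  0.4 s); the oxigram mirrors it. End-tidal PO2 is therefore anti-phase
  with end-tidal PCO2 while the excursions are in phase;
* a **technical gas-line delay** (3 s by default) applied to the gas
  traces only — the ground-truth table stays unshifted;
* **hemodynamics**: the per-cardiac-cycle mean Doppler velocity and the
  BOLD signal of coupled regions follow the modulator with coupling
  coefficient `coupling_beta` and lag `coupling_lag_s`, plus AR(1) noise —
  the same "red noise" family the coherence significance test assumes;
* the **CO2 challenge**: six 30-s mild-hypercapnic epochs, three at
  +4 mmHg and three at +8 mmHg in randomized order, separated by
  normocapnic gaps drawn uniformly from 60–90 s. A 10-minute run cannot
  always hold six maximal gaps, so when the draw overshoots, gaps are
  shrunk proportionally toward their 60-s floor. The returned end-tidal
  target carries both the commanded steps and a first-order approach
  (τ = 8 s) emulating the gas-delivery circuit.

Two generator choices deserve explanation. First, the ventilation factor's
relative SD (0.04) was fixed from a variance budget: it is large enough to
make the two excursions interdependent without being redundant, yet small
enough that more than 80% of the ground-truth ΔPO2 variance stays inside
0.008–0.03 Hz, as the band-limited oscillations in real records do. The
breath noise (0.4 mmHg) is kept small because the ratio bER amplifies
relative noise; much larger values would invert the observed ordering in
which bER couples at least as strongly as ΔPO2. Second, for multi-subject
imaging simulations the CO2 gain \(g\) is drawn per subject from
N(0, 0.5): across individuals the coupling of ΔPCO2 to the hemodynamic
drive is inconsistent, which is the regime reported for spontaneous
breathing and the reason the group ΔPCO2 map is statistically empty while
the within-subject ΔPO2–ΔPCO2 correlation (through \(v_k\)) stays
positive.

What the generator deliberately does **not** emulate: lung mechanics and
V/Q heterogeneity, the Haldane effect, real capnogram artifacts
(cardiogenic oscillations, sensor drift), vasomotion unrelated to gas
exchange, head motion, and scanner noise structure. Passing tests on these
data therefore demonstrate the correctness and calibration of the
*analysis*, not the physiological truth of the coupling model itself.

## Breath parsing and gas metrics

Breath phases are anchored on the capnogram: end expiration is the local
maximum of PCO2 terminating the expiratory plateau, end inspiration the
local minimum immediately preceding it. The oxigram is read at the same
time stamps so both excursions refer to the same breath. Candidate peaks
must be separated by a plausible breath period (1.5–15 s) and exceed a
topographic-prominence threshold of 25% of the trace inter-quartile range,
which rejects noise wiggles riding on a plateau while keeping the
plateau's own summit.

The technical delay is estimated by cross-correlation, but of *timing
landmarks* rather than raw waveforms: the negative-going zero crossing of
the bellow (expiration onset) against the capnogram minimum (end
inspiration). Both landmarks sit exactly at the inspiration-to-expiration
switch regardless of the plateau time constant, so the estimate is
unbiased; correlating the waveforms themselves is biased by the
exponential plateau shape. Both landmark trains are nearly periodic at the
breath rate, so the cross-correlation has aliases one breath period apart;
the implementation takes the smallest local maximum within 90% of the
global peak — the technical delay is the minimal consistent lag. If the
peak correlation stays below 0.2 the respiration reference is unusable and
a zero lag is applied with a warning.

Breaths whose CO2 excursion falls below 1 mmHg are flagged invalid
(division safety for the ratio); a record where more than half the breaths
fail this floor is rejected as unusable. Per-breath series are timestamped
at end expiration — the moment the end-tidal values are defined — and
resampled to a uniform grid (1 s default) by linear interpolation with no
extrapolation, the simplest scheme consistent with band-limited series
sampled a few times per cycle.

RVT follows the standard definition: bellow peak-to-trough excursion
divided by the peak-to-peak respiratory period, one value per cycle.

## Doppler processing

The velocity envelope is despiked with a running median (window 5),
systolic peaks are detected with the same prominence machinery
(minimum inter-beat interval 0.4 s), and each beat is delimited
end-diastolic trough to trough. Beat mean velocity is the trapezoidal
integral over the beat divided by its duration; ΔCBFv is the percent
change relative to the mean of the beat means in the opening 30 s. Percent
change removes insonation-angle and absolute-velocity differences between
subjects. Artifact spans are declared explicitly (an exclusion table)
rather than auto-detected, mirroring the manual practice of reviewing
beats on a GUI.

The optional low-pass for the slow band is a 4th-order Butterworth at
0.03 Hz applied forward–backward, so the passband is untouched in phase.
The implementation pads by odd reflection before filtering because a
zero-padded forward–backward pass leaves large edge transients on signals
with nonzero boundary values.

## Wavelet coherence and the quadrant-resolved TAC

The time-frequency coupling statistic is squared wavelet transform
coherence with a Morlet mother (ω₀ = 6), dyadic scales with 12 sub-octaves
per octave from s₀ = 2Δt up to half the record length, and smoothing by a
Gaussian in time (SD scale/√2) followed by a 0.6-octave boxcar across
scales. These are the defaults of the standard cross-wavelet toolbox in
this literature. Both series
are linearly detrended and standardized first, making the estimate
invariant to affine maps of either input. Positive phase means the first
series leads. The cone of influence follows the Morlet e-folding time
√2·s: at distance d from the record edge, periods above
(Fourier factor)·d/√2 are untrusted.

Significance is assessed against red noise: AR(1) coefficients are fitted
to both series by lag-1 autocorrelation, surrogate AR(1) pairs are
generated (300 by default; 100 in the reduced test configuration), and
the per-scale 95th percentile of surrogate coherence — pooled over in-COI
cells of all surrogates — is the threshold. Pooling per scale rather than
per cell trades spatial adaptivity for a far less noisy threshold, which
is also the cited toolbox's behaviour.

The **time-averaged coherence** (TAC) at each scale is the sum of squared
coherence over cells that are simultaneously inside the cone and above
the 95% threshold, normalized by the maximum possible coherence outside
the cone at that scale — interpreted as the count of in-COI cells, since
squared coherence is bounded by one. (An alternative reading of the
normalizer, per-cell maxima under significance, is equally consistent with
the verbal definition; the count interpretation is used.) The summand is the
squared coherence, matching the quantity that is plotted and thresholded;
it, too, could be read as the magnitude — the choice is exposed as the
`summand` option of `time_averaged_coherence()`. TAC is split by cross-spectrum
phase-lag quadrant: cells with phase within ±π/2 of zero count as
in-phase (positive correlation), the rest as anti-phase; a cell whose
phase is numerically exactly ±π/2 goes to anti-phase, a deterministic
tie-break of measure zero. The two quadrant profiles sum exactly to the
total by construction. Group profiles are averaged scale-wise with the
standard error of the mean; profiles on different grids are aligned by
linear interpolation in log period.

## BOLD mapping

Voxelwise association maps regress each in-mask voxel's percent-BOLD
series on `[intercept, linear drift, regressor]` by ordinary least
squares; β is the percent BOLD change per unit regressor. Regressors are
aligned to frame mid-times by linear interpolation, with no respiratory
response function: the point of the analysis is comparing metrics against
each other, and convolving all of them with the same kernel would not
change their ranking. The voxel p-value is two-sided and assumes white
residuals; with temporally correlated noise it is anti-conservative, as in
the analysis the package models, so group inference rests on the
across-subject tests rather than single-subject maps.

Cluster-extent correction is Monte Carlo: smooth Gaussian null fields at a
user-stated smoothness (the effective smoothness of real data is
unknowable without the data, so it is a required parameter), standardized
in-mask, thresholded two-sided at the voxel p (0.005), and the largest
6-connected (face-adjacent) cluster recorded per iteration; the reported
threshold is the smallest extent whose null exceedance frequency is at
most α = 0.05. Regional statistics average β over each parcel and report
the percentage of parcel voxels surviving cluster correction. Group
inference is a per-region one-sample t-test with Benjamini–Hochberg FDR
across regions (the generic FDR reference is pinned to BH).

Seed connectivity detrends and low-passes (0.03 Hz) every voxel series,
averages the filtered series over the seed parcel, correlates it with
every voxel, and maps Fisher z (`atanh` with |r| capped at 1 − 1e-12);
regional means feed the same group test. CVR under the CO2 challenge is
the voxelwise regression of ΔBOLD on the end-tidal CO2 series, in percent
per mmHg.

## Pipelines and reproducibility

`run_tcd_pipeline()` and `run_mri_pipeline()` orchestrate the two session
types from a validated config (`tcd_config()`/`mri_config()`, loadable
from YAML/JSON; unknown keys are rejected). Every stochastic component
derives its stream from the single config seed, so a rerun from the
serialized config reproduces all outputs bit-identically. Stage failures
are recorded by name in the report while earlier results are retained.
There is no shell entry point: the package's users drive these functions
from R, and the config files play the role a command line would.

## Problem sizes and numerical choices

The default study conditions are 10-minute records, 5-s breaths sampled at
20 Hz, 100 Hz Doppler sampling at 1.1 Hz heart rate, TR 1.45 s, 13 TCD and
20 MRI subjects. The test suite and the acceptance script run the same
code at reduced sizes chosen to keep a full run comfortable on one CPU:
5–10 simulated subjects per arm, 16³ grids with 8 parcels, 100 red-noise
surrogates, 200 cluster-simulation iterations, and 10–20 realizations for
null-calibration estimates. These sizes are stated here as the package's
own scaled-down analysis design; all tolerances in the tests come from
closed forms, hand enumeration, or the generator's ground truth.

Degenerate inputs are handled explicitly: constant traces yield empty
detections with diagnostics, a flat respiration reference falls back to
zero delay with a warning, zero-variance series are rejected by the
correlation routines, zero-variance paired differences are flagged
degenerate rather than tested, empty parcels are flagged and excluded
from group tests, and fitted AR(1) coefficients at or beyond unit modulus
abort the surrogate test.

## Known limitations

* The coherence significance test inherits the AR(1) null; oscillatory
  non-AR(1) noise would inflate apparent significance for both the real
  method and this implementation.
* Pearson p-values on serially correlated series are nominal by design
  (matching the modelled analysis); `correlate_series(adjust_ess = TRUE)`
  reports an effective-sample-size-adjusted p for users who want it.
* The synthetic parcellation is a slab partition, not an anatomical
  atlas; regional statistics are exercised, anatomy is not.
* Single-subject BOLD maps use nominal OLS inference; only group-level
  conclusions are calibrated.
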
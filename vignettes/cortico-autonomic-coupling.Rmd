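---
title: "Cortico-autonomic coupling, fluctuation periods and ERP extraction: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cortico-autonomic coupling, fluctuation periods and ERP extraction: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vigicouple)
```

`vigicouple` analyses the co-regulation of cortical arousal and
autonomic activity during the wake-sleep transition. Its inputs are
per-subject 1-Hz series: an ordinal EEG-vigilance stage score V
(7 = active wakefulness down to 1 = sleep onset, assigned externally by
an EEG staging algorithm), heart rate in bpm (or raw R-R intervals), and
skin conductance level in µS, each with an artifact mask; optionally a
stream of auditory oddball ERP epochs. This vignette documents the
models, the tunable parameters and their defaults, the numerical
choices, and what the synthetic test bed does and does not establish.

## Preprocessing

Artifacts marked in the EEG are propagated into the autonomic channels
(`propagate_artifacts()`), because a second that cannot be staged cannot
contribute to coupling either. Heart rate is derived from R-R intervals
as 60000 / mean(R-R in ms) over three consecutive artifact-free 1-s
segments (`hr_from_rr()`). Whether those three-segment windows were
meant to be disjoint or sliding is ambiguous; the default is a sliding
window centred on the current second, which preserves the 1-s output
resolution every downstream stage expects, and the disjoint variant is
available behind `window = "disjoint"`. SCL is the per-second mean of
its 100-Hz samples (`scl_per_segment()`).

Masked seconds are replaced by the subject's mean of the unmasked
seconds (`fill_missing()`), including for V, where the imputed value is
deliberately left continuous (non-integer): the downstream
cross-correlation is numeric and rounding would only inject
quantisation noise. `zscore()` standardises with the population (1/N)
standard deviation so that the biased cross-correlation estimator below
gives exactly r = 1 for a series against itself.

## Coupling: lagged cross-correlation

`cross_correlate()` computes r(k) = (1/N) Σₜ x(t)·y(t+k) for
k = −100…+100 s. Conventions, all of which matter for
reproducibility:

- **Biased (1/N) estimator, no tapering.** Keeps |r| ≤ 1 and matches
  the default of the common analysis routines for this statistic. The
  unbiased variant would inflate the extreme lags.
- **Lag sign.** Positive lag means the autonomic series lags the
  cortical one; the convention is stated in the output headers because
  published analyses rarely state theirs.
- **Peak rule.** The selected coefficient is the *signed* r at the lag
  of maximal |r|, not the maximal signed r. Published per-subject
  coefficient ranges extend below zero, which is essentially impossible
  under a signed-max rule; the signed-max alternative is available via
  `mode = "signed"`.
- **Tie-break.** If several lags tie on |r|, the smallest |lag| wins,
  then the negative lag. This is deterministic and biases toward "no
  measurable delay", the conservative choice given that the delay
  threshold below separates groups.
- The FFT evaluation (zero-padded, hence linear not circular) is
  checked in the test suite against a direct lag-by-lag summation at
  1e-10.

`extract_coupling()` then forms C_max = (|C_VHR| + |C_VSCL|)/2 and
T_max = (|delay_VHR| + |delay_VSCL|)/2 and assigns Group I (T_max ≥ 1 s)
or Group II (T_max < 1 s); the threshold is inclusive at exactly 1 s.

## Fluctuation periods

The period estimator characterises how slowly a signal's arousal
fluctuations unfold at a chosen time scale n_f:

1. Convolve with a normalised tent kernel of width n_f
   (`tent_kernel()`): weights w_k = 1 − |k − c|/(c + 1) with
   c = (n − 1)/2, unit sum, endpoint weights positive. The length is
   forced odd so the filter is zero-phase — peak times, and hence
   periods and downstream latency comparisons, are never shifted by
   filtering. Boundaries are handled by reflecting the signal about its
   end samples, which preserves constants exactly and avoids edge
   attenuation that would fabricate boundary extrema.
2. Detect alternating local maxima and minima (`find_cycles()`).
   Plateaus collapse to their centre sample; when two maxima occur
   without an intervening minimum the lower one is dropped
   (symmetrically for minima).
3. Score each interior maximum with the cycle amplitude
   ((max − prev min) + (max − next min))/2 (`cycle_amplitudes()`);
   boundary maxima without both flanking minima carry no cycle.
4. Retain cycles whose amplitude exceeds the median amplitude and
   report the median time between consecutive *retained* maxima
   (`fluctuation_period()`). The threshold suppresses spurious
   low-amplitude ripples. Two deliberate choices here:
   - *Tie handling.* The comparison uses a relative tolerance of 1e-9:
     amplitudes equal to the median (up to floating-point rounding) are
     retained. For a pure sinusoid every cycle amplitude ties the
     median; a strictly-greater rule would then retain a
     rounding-determined random half of the maxima and report a
     multiple of the true period. With the tolerance, the estimator
     recovers noiseless sinusoid periods to within the sampling
     resolution across the whole admissible width range (verified for
     P = 20…600 s in the tests).
   - *Periods between retained maxima.* Measuring between retained
     (rather than all) maxima reflects that the retained maxima are the
     fluctuation events of interest; the all-maxima variant is
     available via `period_between = "all"`. A consequence worth
     knowing: when cycle amplitudes hover near the median without slow
     structure, retention can skip alternate cycles and lengthen the
     estimate. In signals whose fluctuation amplitude waxes and wanes
     slowly — which is what real vigilance series and the synthetic
     generator produce — retained cycles cluster into consecutive runs
     and the estimate tracks the true period.
5. Estimates longer than 300 s are flagged invalid rather than deleted
   (`valid = FALSE`): such values typically reflect the wake-up
   interventions (subjects woken after 300 s of sleep onset) rather
   than spontaneous dynamics. Exclusion happens at cohort level, where
   `scan_filter_widths()` drops flagged subjects from each width's
   correlation with C_max and reports how many were dropped.

The analysis widths used by the per-subject pipeline default to
n_f = 170 s for V and 90 s for HR — the widths at which the
period-vs-C_max correlations are strongest — and the scan grid defaults
to 10…200 s in steps of 10 s (the scan range is prescribed; the step is
a package choice). A smoothing property used as a sanity check — wider
filters should not increase the number of detected maxima — holds
strictly for clean oscillations; on noisy signals the alternation
repair can occasionally shift a single extremum pair across a width
step, so the test suite asserts the robust form (no increases beyond
one count, strong overall decrease).

SCL periods are computed but excluded from the C_max scan by default:
the electrodermal response is so inert that its period estimates are a
multiple of the HR-derived ones and carry no additional information at
these widths.

## ERP extraction

Epochs span −100…+799 ms around stimulus onset at 1 kHz (900 samples).
Selection (`select_epochs()`) drops standards that immediately follow a
deviant (their response is contaminated by deviance processing),
rejects epochs exceeding ±100 µV on the analysed channel (the channel
scope of the rejection rule is not fixed by convention; applying it per
analysed channel is the package's choice), and optionally restricts to
a vigilance stage — stage score 6 (relaxed wakefulness, A1) for the
arousal-controlled analysis, it being the most frequently occupied
stage. Averaging (`baseline_and_average()`) subtracts each epoch's
100-ms pre-stimulus mean and requires at least 50 epochs.

`detect_peaks()` takes N1 as the most negative local extremum in its
search window and P2 as the most positive in its own; amplitudes are
window means over peak ±10 ms (N1) and ±20 ms (P2), truncated (not
shifted) at epoch boundaries, and latencies are the peak times. The
default windows — N1 70–140 ms, P2 140–260 ms — bracket the latencies
typical of ignored-oddball N1 (~90 ms) and P2 (~185–215 ms) and are
configurable, since published windows are usually derived from visual
inspection of grand averages and not printed. If a window contains no
interior local extremum the more extreme endpoint is used and a
fallback flag is set rather than failing.

No filtering happens in this module: bandpass filtering belongs to raw
EEG preprocessing, which is outside the package's scope (synthetic
epochs are generated band-limited by construction).

## Statistics

All tests are two-tailed at α = 0.05 and return a tidy one-row tibble.
Welch's t and Cohen's d accept either raw vectors or printed group
summaries (means, SDs, group sizes) — the summary path is what lets the
package re-derive published group tables, and the tests verify the raw
and summary paths agree to 1e-12. Conventions fixed by recomputation
against the published tables shipped in `inst/extdata/`:

- Cohen's d uses the pooled-SD convention (reproduces the printed
  d = 0.101 for the Fz standard-P2 latency row exactly).
- The 2×2 chi-square applies no continuity correction (reproduces the
  printed gender p = 0.267).
- Group comparisons compute both Student and Welch t and select Welch
  when a two-group Levene check (t-test on absolute deviations from
  the group means) rejects homogeneity at α = 0.05 — inferred from the
  published tables mixing integer with fractional degrees of freedom.
  Both results are always reported (`compare_groups()`).
- Correlation selection in the cohort pipeline is gated by
  Shapiro-Wilk at α = 0.05 on each variable (Spearman when either
  deviates from normality); the gating test itself is a package choice
  since none is named in the conventions this mirrors.
- Spearman's p uses the t approximation on midranks, adequate for the
  n ≈ 39 regime this package targets.

A few rows of the shipped ERP summary table are internally
inconsistent — their printed t or d cannot be reproduced from their own
printed means and SDs, with a pattern suggesting transposed rows in the
source — and are flagged (`t_consistent`, `d_consistent` columns) and
excluded from the recomputation checks.

## The synthetic generator

`synth_params()` defines the study conditions the test bed emulates:
2-h (7200 s) recordings; a latent arousal process
A(t) = envelope(t)·sin(2πt/190) + OU(t) + drift(t) in the infra-slow
~0.005 Hz range. Its components, with defaults and why:

| Parameter | Default | Meaning |
|---|---|---|
| `v_period_s` | 190 s | dominant arousal fluctuation period (~0.005 Hz) |
| `amp_mod_depth`, `amp_mod_period_s` | 0.5, 1600 s | slow waxing/waning of fluctuation bouts; also what keeps amplitude-thresholded retention coherent |
| `noise_sd_v`, `ou_tau_s` | 0.4, 5 s | Ornstein-Uhlenbeck stage flicker |
| `drift_per_hr` | −2/h | session-long wakefulness decline; brings subjects to sleep onset |
| `sleep_onset_after_s` | 90 s | sustained drowsiness (stage ≤ 2) before sleep consolidates |
| `wakeup_after_s` | 300 s | experimenter wakes the subject after 300 s at sleep onset; the latent level resets to its upper quartile and the event is counted |
| `wake_recovery_tau_s` | 300 s | relaxation of the wake-up reset |
| `delay_hr_s`, `delay_scl_s` | 8 s | planted cortico-autonomic delays |
| `coupling_gain_hr`, `noise_sd_hr` | 1.2 bpm, 3 bpm | sized so per-subject C_VHR lands near published per-subject ranges (~0.4) |
| `rsa_amplitude_bpm`, `resp_freq_hz` | 2 bpm, 0.25 Hz | respiratory sinus arrhythmia |
| `hr_fluct_period_s`, `hr_fluct_amp_bpm` | 100 s, 1.5 bpm | intrinsic vasomotor-band HR fluctuation, which is what HR-derived periods at n_f = 90 s should read |
| `scl_time_constant_s` | 50 s | inert first-order electrodermal response |
| `noise_sd_scl`, `scl_fluct_tau_s` | 0.7 µS, 200 s | slow spontaneous electrodermal fluctuation (smooth, uncorrelated with V) |
| `artifact_fraction` | 0.05 | shared random artifact mask |

Vigilance is the latent process quantised by equally spaced thresholds
over its realised range (no stage-occupancy distribution being
available to calibrate anything finer). The wake-up intervention resets
the *latent* level, not the stage, so V, HR and SCL all react
coherently at their respective delays. Sleep-onset consolidation (the
latent locking into the sleep band after sustained drowsiness, until
woken or until a sustained arousal surge) is the one nonlinearity added
beyond the stated components: without it a fluctuating latent process
essentially never stays at the sleep-onset stage for 300 consecutive
seconds, and no subject would ever be woken. With zero noise, drift and
envelope depth the machinery never engages and the latent process is an
exact sinusoid, which the tests assert.

With default parameters a subject lands near: C_VHR ≈ 0.43,
C_VSCL ≈ 0.47, V-period at n_f = 170 ≈ 192 s, HR-period at
n_f = 90 ≈ 110 s, stage-switch rate ≈ 6%, 0–1 falling-asleep events.
Cohort-level heterogeneity (delay distributions, per-subject arousal
periods, gain links) is injected per run via `generate_cohort(vary =)`.

Two signal properties of the realistic default condition are worth
stating because they are *features of the signals*, not estimator
errors, and they shape what the recovery tests can claim:

- the session-long drift is shared (at a lag) by all channels and
  flattens the cross-correlation peak toward lag 0;
- the 50 s SCL time constant shifts the SCL correlation peak by tens
  of seconds on a narrowband drive.

The parameter-recovery condition (`recovery_params()`) therefore pins
the ground truth down: strong gains, low noise, no drift, and a
0.5 s SCL time constant, under which planted delays of 0–40 s are
recovered exactly and delay-group assignment is error-free. The
planted-effect power bed (`simulate_planted_p2_cohort()`) shortens the
recording to 600 s (arousal period 150 s) and uses 150 stimuli per
subject at 2 µV epoch noise so that a 100-repetition power run of the
full chain — signals → estimated groups → measured P2 → Levene-gated
group test — stays affordable; at a planted standardised difference of
1.2 the chain detects the effect in ≈95% of repetitions.

The ERP generator (`erp_synth_params()`) plants Gaussian N1 (negative,
default −5 µV at 100 ms) and P2 (positive, 6 µV at 200 ms) components,
scaled by a per-stage modulation map (default: attenuation to 0.5
toward sleep onset), in an 80/20 oddball stream with ISIs uniform on
900–1400 ms.

### What the synthetic tests do not show

The generator produces no raw EEG, no realistic ECG morphology, no
pink-noise background, and its stage-transition statistics are only
coarsely calibrated (equally spaced quantisation thresholds, one
drift/OU family). Passing parameter-recovery tests therefore
demonstrates the correctness of the estimators under known ground
truth — not that any real cohort's numbers are recoverable, and
cohort-level published values (e.g. mean coupling coefficients) are
expressly not reproduction targets, since the underlying recordings are
not available.

## Numerical and degenerate-input conventions

- Constant series cannot be z-scored or correlated (error); fully
  masked series cannot be imputed (error), but a fully masked SCL
  channel degrades the subject to HR-only coupling with SCL fields NA.
- Fewer than two retained cycles raises a typed `vigicouple_no_cycles`
  condition, which cohort scans convert to exclusion.
- Fewer than 50 epochs raises `vigicouple_invalid_average` carrying the
  count; the condition-level table reports such cells as invalid rows
  instead of failing the subject.
- Physiological R-R bounds (200–3000 ms) flag rather than delete.
- All randomness flows through one seeded generator per subject;
  cohort seeds derive per-subject seeds, so every result in the test
  suite and acceptance script is a deterministic function of one
  integer.

## Problem sizes

The test suite and acceptance script run at the sizes the analyses are
defined at where that is cheap (7200-s series for cross-correlation
oracles, delay recovery and period grids; 10⁴ simulations for type-I
calibration) and at reduced but fully representative sizes where a full
study would add nothing but time (600-s recordings and 150-stimulus
streams in the 100-repetition planted-effect power run; 39-subject
synthetic cohorts in the acceptance script).
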
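---
title: "Methods: dyadic neural and autonomic synchrony analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dyadic neural and autonomic synchrony analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadsync)
```

## The analysis model

`dyadsync` analyzes dual-participant recordings of a structured
collaborative task: a 120-s resting baseline (BL) followed by three roughly
60-s phases — Initiation (IP), Negotiation Core (NCP) and Resolution (RP)
— annotated as half-open `[start_s, end_s)` intervals. Three signal
modalities are handled per member: 15-channel 10/20-montage EEG, skin
conductance (40 Hz) and blood-volume pulse from photoplethysmography
(100 Hz).

The core quantity is an amplitude-based synchrony index: the Euclidean
distance (EuDist) between the two members' feature vectors,
`EuDist = sqrt(sum((x1 - x2)^2))`, with lower values read as stronger
inter-member alignment. It deliberately measures *comodulation of spectral
amplitude*, not phase locking: two members whose band power rises and falls
together score as aligned even if their oscillations are not phase-coupled.
All features entering the index are baseline-normalized,
`(task - baseline) / baseline`, so that synchrony reflects task-induced
modulation rather than trait-level amplitude differences between
individuals.

Assumptions worth stating explicitly:

* EEG signals are approximately stationary within a phase, so a 2-s-epoch
  averaged periodogram is a sensible phase summary.
* Baseline power is strictly positive in every band and electrode (a
  non-positive baseline is treated as a degenerate recording and is an
  error, not silently patched).
* The dyad, not the participant, is the unit of analysis for inference:
  repeated-measures ANOVAs use dyads as subjects (13 dyads give
  denominator df 24 for three-level within factors).

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| epoch length | 2 | s | fixes the 0.5 Hz spectral resolution at any sampling rate |
| band edges | delta 0.5–3.5, theta 4–7.5, alpha 8–12.5, beta 13–30, gamma 30.5–50 | Hz | standard clinical bands, disjoint at 0.5 Hz resolution |
| artifact threshold | ±100 | µV | deterministic stand-in for visual artifact inspection |
| flat-line threshold | 0.1 | µV peak-to-peak | rejects disconnected channels |
| SCR moving-average window | 4 | s | separates phasic responses (1–5 s time scale) from tonic drift |
| SCR minimum amplitude | 0.01 | µS | conventional detection floor |
| beat refractory period | 0.3 | s | upper bound 200 bpm; suppresses dicrotic-notch double counting |
| HRV metric | RMSSD | ms | the standard ultra-short-term, vagally weighted index; defensible on ~60-s phases where frequency-domain indices are not (SDNN available) |
| power-analysis ρ | 0.5 | – | the conventional assumed correlation among repeated measures when none is reported |

ROI aggregation uses frontal (Fp1, Fp2, F3, F4), temporo-central (T7, T8,
C3, C4) and parieto-occipital (P3, P4, O1, O2) groups with left/right
splits. The midline electrodes Fz, Cz, Pz are recorded and preprocessed but
belong to no ROI, so they enter no synchrony cell — they appear in no ROI
definition, and inventing a fourth "midline ROI" would change the ANOVA
design.

## The synthetic dyad generator

Because raw recordings of this kind are rarely shareable, every stage is
validated against a generator with known ground truth
(`sim_config()`, `simulate_dyad()`, `simulate_cohort()`).

**EEG.** Each channel is a sum over bands of band-limited Gaussian
oscillators (2 Hz bandwidth around a per-band center frequency) on a pink
(1/f) background. Inter-member coupling is *shared-source amplitude
mixing*: `coupling * shared + (1 - coupling) * private`, where the shared
stream is common to the dyad. This matches what the EuDist index measures —
an amplitude-based index warrants an amplitude-based ground truth — and
deliberately does not model phase locking. Oscillators are
variance-normalized per session with sinusoid-equivalent scaling (a band of
amplitude A contributes power A²/2 at coupling 0 or 1), which pins
session-level power and makes the spectral recovery tests sharp; power over
sub-windows (epochs, phases) still fluctuates naturally. Default band
amplitudes (delta 8, theta 5, alpha 10, beta 3, gamma 1.5 µV on 2 µV pink
noise) follow the usual posterior-dominant resting spectrum.

**Cardiac.** Inter-beat intervals are a Gaussian AR(1) stream (lag-1
coefficient 0.4) whose innovation variance is set so the *expected sample
RMSSD* equals the target; a raised-cosine pulse is rendered per beat at the
cumulative beat times. HRV similarity is imposed at the phase level: for a
target divergence δ the two members' task-phase RMSSD targets are split
symmetrically, `rmssd · (1 ± δ/2)` about a common baseline, so the expected
distance between their baseline-normalized HRV values is δ. Beat-to-beat
coupling is not modeled — the analysis consumes one scalar per phase per
member, so a scalar-level ground truth is the right resolution.

**Electrodermal.** A tonic level with linear drift and slow smoothed noise,
plus phasic responses (0.75 s rise, 3 s decay) at Poisson times with
log-normal amplitudes.

**Cohort structure.** A 13-dyad cohort carries two latent phase-wise
HRV-synchrony clusters on the standardized feature scale: a low-divergence
majority (n = 10; IP −0.440, NCP −0.380, RP −0.301) and a high-divergence
minority (n = 3; IP 1.468, NCP 1.268, RP 1.002), feature sd 0.3. The
latent features map affinely to raw divergence targets
(`0.5 + 0.15 · z`, floored at 0.05), which keeps all targets positive
while preserving the cluster geometry exactly under the per-column
z-scoring that precedes clustering. Reward-responsiveness scores are drawn
per cluster (item-mean scale 1–4: 3.5 vs 2.9, sd 0.25, higher in the
low-divergence cluster); the remaining questionnaire scales are
structureless by construction. Baseline autonomic statistics are not part
of the cohort's latent structure; baselines simply reuse the task-level
generator defaults.

**What a green test does and does not establish.** Recovery tests certify
that the pipeline inverts its own generator: band power within stated
tolerances, RMSSD within 20 % through the full waveform path, cluster
labels exactly on well-separated cohorts, ANOVA rejection at the nominal
rate under the null. They do not certify behavior on real data with
eye-blink and EMG artifacts, nonstationary alpha, respiration-modulated
HRV, movement-contaminated electrodermal traces or unequal phase durations
— none of which the generator emulates.

## Numerical choices

**Filter realization.** The 0.01–50 Hz band-pass plus 50 Hz notch is
applied in the frequency domain with a magnitude response equal to a
4th-order Butterworth band-pass times a second-order notch. No
signal-processing package is part of the dependency stack, and a
frequency-domain filter is exactly zero-phase by construction (a forward–
backward IIR implementation only approximates this). The trade-off is
mild circular-boundary leakage at the recording edges, negligible for
multi-minute recordings against 2-s epochs.

**PSD convention.** Per-epoch Hamming-windowed periodograms averaged over
retained epochs, window-power normalization `2|X_k|² / (N Σw²)`: the bin
*sum* of a unit sinusoid is 0.5 and, by Parseval, total summed PSD equals
time-domain variance. Band power is the sum of bins whose center lies in
`[lo, hi]` inclusive; at 0.5 Hz resolution the printed band edges make the
five bands disjoint. Epochs are non-overlapping and epochs straddling a
phase boundary are dropped rather than truncated, so every periodogram has
identical length and leakage structure.

**Summation dimension of the EEG index.** The per-cell distance runs over
the electrodes of the (ROI × hemisphere) cell — 2 for lateralized cells, 4
for whole-ROI cells — because the ANOVA design needs exactly one scalar
per lateralization × ROI × phase cell. An epoch-wise mode
(`synchrony_mode = "epoch"`: the vector of 2-s-epoch ROI-mean powers, over
epochs retained for both members) is provided for sensitivity analyses.
Both lateralized and whole-ROI cells are always emitted, since it is not
decidable from the index definition alone which aggregation a given
workflow intends.

**Sphericity handling.** Mauchly's test is computed per within effect with
two or more numerator df; the Greenhouse–Geisser-corrected p is *always*
reported alongside the uncorrected one, and the conventional `p_reported`
switches to the corrected value when Mauchly rejects at .05. Partial η² is
`SS_effect / (SS_effect + SS_error)`. The decomposition is computed via
orthonormal contrast projections, which reproduces classical
repeated-measures sums of squares exactly (cross-checked against
`stats::aov` in the test suite) while exposing each effect's contrast
covariance for ε and Mauchly.

**Power analysis.** The within-effect noncentral-F convention:
`λ = f²·N·m·ε/(1−ρ)`, `df₁ = (m−1)ε`, `df₂ = (N−k)(m−1)ε`, searched upward
in multiples of k. With f = 0.38, α = 0.05, target 0.95, k = m = 2,
ρ = 0.5, ε = 1 the minimum is N = 26.

**Standardization before clustering.** Columns are z-scored with the
sample-variance divisor n − 1, which fixes the total sum of squares of an
n × p input at (n − 1)·p — 36.00 for 13 dyads × 3 phases. This identity is
what makes the reported σ²W/σ²B/σ²T decomposition interpretable as shares
of a known total.

**Gap-statistic selection rule.** References are drawn uniformly in the
principal-component-aligned bounding box. The chosen k defaults to
Tibshirani's published selection rule (smallest k with
`gap(k) ≥ gap(k+1) − se(k+1)`), not the curve's global maximum: at n = 13
the global maximum is unstable, because once a 2–3-point cluster is split
the observed `log(W)` keeps shrinking faster than the uniform reference
does, and the global argmax drifts to k = 5–6 on a majority of seeds
(verified against `cluster::clusGap`, whose curve matches this
implementation exactly). Only the SE-based rule reproduces the two-cluster
solution the workflow is designed around; `rule = "global-max"` remains
available.

**Bootstrap stability.** Cluster-wise Jaccard stability: each original
cluster is matched to the best-overlapping cluster of a re-clustered
bootstrap resample, with overlap computed on the original row indices
present in the resample; the index averages over clusters and resamples.
Degenerate resamples (fewer distinct points than k) fall back to
distinct-row labels rather than failing, which matters at n = 13.

**Ward dialect.** `ward.D2` — the minimum-variance update applied to
untransformed Euclidean distances — is the convention meant when "Ward's
method with Euclidean distance" is specified. The hierarchical stage is
reported descriptively (a 3-cluster reading by default); the final
solution is the Hartigan–Wong k-means partition, and both labelings are
returned without adjudication.

**Autonomic baseline normalization** mirrors the EEG formula as the
default; it is a choice, not a given, and `normalize_features()` exposes
the zero-baseline policy (`"error"` for strict use, `"na"` in the cohort
pipeline so a single SCR-free baseline window degrades one cell rather
than aborting the run; dropped cells are logged by warning and excluded
from the affected ANOVA with complete-case dyad filtering).

**Determinism.** All randomness flows from one master seed through named
substreams (per dyad, member, signal and analysis stage), so identical
configurations reproduce bit-identical cohorts and results; the pipeline
manifest records row counts and order-independent numeric checksums
(values rounded to 10 significant digits) per stage.

## Known limitations

* EuDist is a similarity-of-modulation index; it cannot detect
  phase-locked coupling, time-lagged synchrony or directionality.
* The artifact rule is amplitude-based; it will not catch low-amplitude
  ocular or muscular contamination that visual inspection (or ICA) would.
* At 13 dyads, cluster-membership inference is exploratory by nature;
  the validation indices quantify, but cannot repair, small-n instability
  (the gap-rule analysis above is a case in point).
* Session I/O is delimited text only; binary acquisition formats are
  expected to be converted upstream.
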
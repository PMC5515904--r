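---
title: "Scoring and electrophysiology of interoceptive vs. exteroceptive attention"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and electrophysiology of interoceptive vs. exteroceptive attention}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(interopipe)
```

## What this package models

`interopipe` implements an analysis pipeline for heartbeat-detection (HBD)
experiments in which participants tap a keyboard along with either an
external beat (exteroception) or their own heartbeats, before and after a
feedback block (basal and post-feedback interoception). Four analysis
strands are covered:

1. **Behaviour** — an accuracy index on a 0–1 scale per condition, compared
   with a within-subject one-way ANOVA and Tukey HSD post hoc tests.
2. **Heartbeat-evoked potentials (HEP)** — scalp EEG time-locked to the
   ECG R wave, cleaned of the cardiac-field artifact (CFA), averaged over
   frontal ROIs, and compared point-wise between conditions with
   Monte-Carlo permutation tests and a five-consecutive-sample run filter.
3. **Connectivity** — weighted symbolic mutual information (wSMI) between a
   right-frontal seed and the rest of the scalp on current-source-density
   (CSD) transformed data, contrasted between conditions and profiled as a
   function of inter-electrode distance.
4. **Intracranial recordings** — depth-contact time-frequency charts
   (windowed Fourier transform, baseline z-scored per frequency) contrasted
   between conditions in a low (1–35 Hz) and a broadband (35–110 Hz) range.

Because no public dataset accompanies this paradigm, the package ships a
first-class synthetic generator that emulates the recording structure with
known ground truth, so every estimator can be tested for recovery.

## The synthetic generator and what it does (not) emulate

`sim_config()` collects all generator parameters. Defaults encode the
experiment's recording regime: 128 scalp channels and a lead-II ECG at
1024 Hz, 2-minute blocks, mean heart rate 70 bpm with 30 ms Gaussian R-R
jitter (a 300 ms refractory floor keeps R-R intervals physiological).

* **ECG** (`gen_ecg`): each beat is a biphasic QRS-like template (Q dip,
  800 µV R peak of 7 ms width, S undershoot) on 20 µV white noise. This is
  deliberately *not* a physiological ECG model: it provides a sharp,
  detectable R wave with exact ground-truth peak times for testing the
  detector, nothing more.
* **Scalp EEG** (`gen_scalp`): per channel, 1/f background noise (default
  SD 10 µV) plus a posterior 10 Hz alpha rhythm (4 µV); a dipolar CFA
  (derivative-of-Gaussian time course within ±100 ms of R,
  anterior-negative/posterior-positive topography, 15 µV peak); a frontal
  negative evoked component over the ground-truth window (default 250–400
  ms post R) whose amplitude depends on condition (defaults −0.8 µV
  exteroception, −3 µV for both interoceptive conditions — the
  interoceptive-minus-exteroceptive difference of ≈2 µV is in the range
  reported for heartbeat-evoked effects); and band-limited 10–20 Hz
  coupling sources shared with a lag by condition-specific channel pairs.
  The injected envelope is a cosine-tapered (Tukey) window, flat over its
  central 70%, so the declared ground-truth window genuinely contains
  effect everywhere — with a fully tapered bump the window edges would
  carry no signal and no estimator could be expected to recover them.
* **Coupling structure** (`default_coupling`): for basal interoception,
  five short-range pairs (2–7 cm) inside/around the right-frontal seed
  region; for post-feedback interoception, five long-range fronto-posterior
  pairs (12–17 cm). Lags are 8 and 20 ms. One constraint worth knowing:
  wSMI zeroes out sign-opposed symbol pairs, so a lag near half a period of
  the 10–20 Hz source (25–50 ms) lands the pair in the suppressed
  anti-phase regime. Lags must stay well below a quarter period; both
  defaults do.
* **Taps** (`gen_taps`): each beat elicits a tap with probability
  1 − miss, jittered by a per-condition Gaussian SD; extra taps arrive as a
  Poisson process. The per-condition defaults (jitter 100/220/180 ms, miss
  0.05/0.25/0.15) were calibrated once so the accuracy index lands near the
  reference condition means (0.73 / 0.47 / 0.58).
* **iEEG** (`gen_ieeg`): four contacts named for the regions of interest
  (posterior insula, amygdala, somatosensory cortex, inferior frontal
  gyrus), each 1/f noise whose 35–110 Hz component is amplified (gain 2)
  after each R peak during basal interoception and whose 1–35 Hz component
  is amplified during exteroception, inside configurable post-R windows.
* **Behavioural cohorts** (`gen_cohort`): subject accuracy triplets drawn
  from a trivariate normal with the reference means (0.73, 0.47, 0.58) and
  SDs (0.20, 0.15, 0.19) and a common pairwise correlation. The default
  correlation is solved from the reference ANOVA error mean square:
  E[MS~error~] = mean(σ²)(1 − ρ) = 0.025 gives ρ ≈ 0.239. Draws are *not*
  truncated to [0, 1]: the generator prioritises fidelity to the summary
  statistics over range constraints (truncation would bias both means and
  the error term).

What the generator does **not** emulate: volume conduction through a
realistic head model (topographies are simple radial weightings),
heart-rate variability beyond Gaussian R-R jitter, eye or muscle artifacts,
electrode impedance drift, and non-stationarities across a session. Tests
passing on this synthetic world show the estimators are *correct*; they do
not show the pipeline is robust to every pathology of real recordings.

The exteroceptive condition's two sub-blocks (constant 60 bpm vs. variable
beat) are modelled as a single condition: the reference analysis pools
them, and the generator's beat process is configurable if the distinction
matters.

## The accuracy index

The task description in the literature states only that the score lives on a 0–1 scale with
higher values indicating better performance; the exact formula is in
supplementary material not reproduced with the text. `accuracy_index()`
therefore implements a matching-based definition chosen to satisfy every
stated property, **flagged here prominently as this package's own
definition**:

* taps are greedily matched to targets (nearest first), each used at most
  once, within half the local inter-target interval;
* a matched pair scores 1 − |Δt| / (half local inter-target interval);
* the index is the summed pair score divided by max(n~targets~, n~taps~),
  so both missed beats and spurious extra taps reduce the score.

The index is 1 exactly under perfect synchrony, 0 with no taps, invariant
to time shifts and time reversal, and monotonically non-increasing in tap
jitter. Scores are comparable within this package; absolute values need not
match other implementations of the task.

## Behavioural statistics

`rm_anova()` is the classical within-subject one-way ANOVA (subject and
condition effects, subject × condition interaction as error), fitted via
`stats::aov()` with uncorrected degrees of freedom — matching the reference
df of (2, 94) for 48 complete subjects. No sphericity correction is
applied. Subjects with incomplete data are dropped listwise with a logged
count (the reference df imply 2 of 50 enrolled participants were excluded;
the exclusion rule is not stated, so listwise completeness is used).
`tukey_hsd()` uses the studentized range with the ANOVA's error mean square
and denominator df.

One calibration fact worth recording: with ρ solved from MS~error~ = 0.025,
the mean F over many simulated cohorts reproduces the reference F ≈ 32, but
the *sampling spread* of the post-feedback vs basal contrast is large —
SD(mean difference) ≈ 0.031 against a true difference of 0.11 — so the
p < 0.01 bound for that contrast holds in only about two-thirds of
simulated cohorts, not in 90 % of them. This is a property of the summary
statistics themselves, not of the implementation; the acceptance script
reports the honestly computed 90th-percentile p-value.

## Scalp preprocessing choices

* **Filtering** is zero-phase in the frequency domain (FFT gain curves
  with raised-cosine transition bands). The 0.5 Hz high-pass edge at
  256 Hz would need an FIR kernel several seconds long, whose edge
  transients distort the 2-minute blocks; the frequency-domain filter has
  exactly unit pass-band gain and no phase distortion. Transition widths
  default to 25% of the edge frequency.
* **Resampling** from 1024 to 256 Hz is an anti-alias low-pass followed by
  integer decimation. Non-integer ratios are rejected rather than
  approximated.
* **Referencing**: mastoids when present; the synthetic layout has none, so
  the documented fallback is the common average (logged).
* **R-peak detection** is a local-extremum finder with a robust (MAD-based)
  magnitude threshold, a 300 ms refractory rule keeping the larger peak,
  and polarity auto-detection.
* **CFA removal**: the deterministic default is template regression — the
  R-locked median template within ±100 ms of R, least-squares scaled per
  channel, subtracted at every beat. It attenuates the R-locked artifact
  by ≳80% while leaving the 200–500 ms window untouched by construction.
  An ICA path (`ica-auto`) scores components by R-locked amplitude ratio
  and anterior–posterior topography contrast (thresholds 3 and 0.5 by
  default) and removes those exceeding both; it falls back to template
  regression if the decomposition fails. The ICA is a compact symmetric
  fixed-point implementation (tanh contrast) with deterministic
  initialisation, so results are reproducible.
* **Epoching** uses nearest-sample rounding of the −200/+500 ms edges
  (180 samples at 256 Hz, −199.2 to 500 ms) and rejects epochs containing
  any sample beyond ±300 µV. The ±300 µV bound is reused from the artifact
  context as an automatic proxy for visual epoch rejection.

## Point-wise permutation statistics

`pointwise_perm_test()` compares paired per-subject waveforms with a paired
t statistic at each time point inside 100–500 ms. The Monte-Carlo null
resamples subjects with replacement and randomly sign-flips each resampled
within-subject difference (5000 draws by default); p-values use the
add-one estimator. Runs of significant points shorter than 5 samples are
discarded (`run_filter()`). The sign-flip-plus-resampling null was checked
by simulation to be calibrated (rejection rate 0.047–0.05 at nominal 0.05,
n = 12). No multiplicity correction beyond the run filter is applied — by
design, mirroring the reference procedure.

A caution that the intracranial analysis makes concrete: the run filter
only protects against significant stretches *shorter* than the signal's
correlation length. For band-power series from 97%-overlapping windows the
correlation length is ≈31 points, so null excursions that cross the
point-wise threshold typically survive the 5-point filter; family-wise
error control should not be expected from it there.

## wSMI

Signals are CSD-transformed (each channel minus the mean of its 4 nearest
neighbours — the neighbour count is a free choice; 4 gives a compact
Laplacian-like sharpening), then symbolized: the rank pattern of k = 3
samples τ apart, ties broken by temporal order. τ = 16 ms rounds to 4
samples at 256 Hz (15.625 ms — a documented deviation of 2.3%), tuning the
patterns to roughly 10–20 Hz structure. `wsmi_pair()` is the plug-in
mutual information over the 6 × 6 joint symbol distribution with binary
weights zeroing identical pairs (common source) and sign-opposed pairs
(dipole), normalised by ln 6 (natural log; the choice of base cancels in
the normalisation). The finite-sample plug-in estimate can dip marginally
below zero for independent streams; values are clamped to zero by default
(`clamp = FALSE` recovers the raw estimate, used by the oracle-equivalence
tests).

wSMI is computed on continuous (non-epoched) blocks per condition: the
connectivity question concerns sustained information sharing, and epoching
would discard the long-range temporal structure the symbol statistics
estimate. Seed maps pair every seed electrode (labels 62–69 and 73–77,
right-frontal) with every non-seed electrode (13 × 115 = 1495 pairs).
Condition contrasts are per-pair paired t-tests masked at 0.05 and 0.01;
the distance profile bins pairs at 1 cm, averages per subject and
condition, and tests each bin with a sign-flip permutation test at
p < 0.001. With sign-flip nulls the smallest achievable two-tailed p is
2^(1−n), so a p < 0.001 criterion needs at least 12 paired subjects — the
test fixtures use exactly 12.

## Intracranial pipeline

Channel QC runs on the raw signal with two automatic criteria (an
automatic proxy for the visual screening used on real data): amplitude —
any sample beyond 5× the channel's robust peak amplitude (99.9th
percentile of |x|); gradient — any sample-to-sample step beyond 5× the
robust peak of the centred gradient. The conventional amplitude scales
(mean absolute value, SD) place a 5× threshold *inside* the natural range
of the maximum of a multi-minute recording (the expected maximum of ~10⁵
near-Gaussian samples is ≈4.5–5.5 SD), so they reject clean channels;
against the robust peak scale a clean channel scores ≈1.4–1.7 while a
gross artifact spike scores >5, and the conventional multiplier separates
them cleanly. Both alternative scales remain available by argument. A
sustained drift of the same magnitude as the signal will *not* be caught
by these criteria — they target transient artifacts.

Survivors are band-passed 1–200 Hz with notches at 50/100/150 Hz (±1 Hz
stop bands) and common-average referenced. Epochs are cut at −350 to
650 ms around R: the chart covers −200 to 500 ms, and every 250 ms
analysis window whose centre lies in that range must fit inside the epoch
— with unpadded −200..500 ms epochs no window centre could fall inside the
−200..−50 ms baseline at all, so the segmentation pads by half a window
plus margin. `tf_chart()` computes Hann-windowed Fourier power (250 ms
window, 8 ms hop — 97% overlap) on a 4–108 Hz grid in 4 Hz steps (the
resolution implied by the window length), averages over epochs, and
z-scores each frequency row by the mean and SD of the baseline columns
(−200 to −50 ms); the baseline statistics are exact by construction
(mean 0, SD 1 to numerical precision). The normalisation window is the
baseline only; the −200..500 ms span is the chart extent, not the
normalisation window.

Band contrasts average per-epoch z-power over 1–35 Hz or 35–110 Hz and
compare conditions with an epoch-level label-permutation test from 100 ms
onwards, followed by the 5-point run filter. Epoch-level (not
subject-level) inference is the appropriate unit for single-patient
intracranial recordings.

## Problem sizes used by the tests

The test suite regenerates everything from code. Fixture sizes are the
package's choices balancing statistical resolution against runtime: ERP
recovery uses 10 subjects × 2 conditions of 2-minute blocks generated at
512 Hz (the analysis itself runs at 256 Hz after resampling); the wSMI
cohort uses 12 subjects × 2 conditions of 2-minute blocks generated
directly at 256 Hz; the iEEG fixture uses one simulated patient with
90-second blocks at 512 Hz; permutation-test calibrations use 200 null
replications at 250 draws each. The acceptance script simulates 500 + 200
behavioural cohorts of 48 subjects each.

## Known limitations

* The accuracy index is this package's definition of an under-specified
  literature score; cross-implementation comparability is not guaranteed.
* The QC criteria are automatic proxies for procedures that were partly
  visual; their thresholds are defensible defaults, not fitted constants.
* The synthetic world is Gaussian and stationary; pass/fail on it bounds
  implementation correctness, not field robustness.
* EDF/BDF containers are not read or written; recordings travel as
  documented plain-text TSV matrices (`read_recording`/`write_recording`),
  and a standard electrode-position file can be substituted for the
  synthetic layout via `read_layout()`.
* `wsmi_pair()` supports k = 3 only; larger pattern lengths would need
  both a larger alphabet and longer records for stable plug-in estimates.
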
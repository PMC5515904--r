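# interopipe

Analysis pipeline for **heartbeat-detection (HBD) experiments** that
contrast attention to internal bodily signals (interoception) with
attention to external stimuli (exteroception). Participants tap along with
an external beat, then with their own heartbeats before and after a
feedback block, while scalp EEG + ECG (and, in a second study arm,
intracranial depth electrodes) are recorded. The package is aimed at
cognitive-neuroscience groups who want a tested, reproducible
implementation of the four analysis strands this paradigm uses — plus a
ground-truth synthetic generator, because no public dataset accompanies
the paradigm.

## What it computes

**Behaviour.** A tap-to-beat accuracy index on a 0–1 scale (greedy
nearest-neighbour matching within half the local inter-beat interval; a
matched pair scores 1 − |Δt|/(half interval), normalised by
max(n<sub>beats</sub>, n<sub>taps</sub>)). Conditions are compared with a
within-subject one-way ANOVA, F = MS<sub>condition</sub>/MS<sub>error</sub>
with df (k−1, (k−1)(n−1)) and no sphericity correction, followed by Tukey
HSD on the studentized range q = |m<sub>i</sub> − m<sub>j</sub>| /
√(MS<sub>error</sub>/n).

**Heartbeat-evoked potentials (HEP).** Scalp EEG referenced, resampled to
256 Hz, band-passed 0.5–30 Hz; R peaks detected on the ECG; the
cardiac-field artifact removed (R-locked template regression, or ICA with
automatic component scoring); epochs of −200..500 ms around R with ±300 µV
rejection; frontal ROI averages compared point-wise between conditions
from 100–500 ms with a Monte-Carlo permutation test (sign-flip +
subject-resampling null, 5000 draws) and a five-consecutive-sample run
filter.

**Connectivity (wSMI).** Current-source-density transform (each channel
minus its 4 nearest neighbours), ordinal-pattern symbolization (k = 3
samples, τ = 16 ms → 10–20 Hz), and weighted symbolic mutual information

> wSMI(X,Y) = (1/ln 6) Σ w(s<sub>x</sub>,s<sub>y</sub>)
> p(s<sub>x</sub>,s<sub>y</sub>) ln[ p(s<sub>x</sub>,s<sub>y</sub>) /
> (p(s<sub>x</sub>)p(s<sub>y</sub>)) ]

with w = 0 for identical and sign-opposed symbol pairs (suppressing
common-source and dipole artifacts). Seed-to-scalp maps from a
right-frontal seed (electrodes 62–69, 73–77), paired t contrasts at
p < 0.05/0.01, and wSMI as a function of Euclidean inter-electrode
distance with per-bin sign-flip permutation tests at p < 0.001.

**Intracranial time-frequency.** Channel QC (amplitude and gradient
criteria), 1–200 Hz band-pass with 50/100/150 Hz notches, common-average
reference, R-locked epochs, windowed-Fourier power (250 ms Hann window,
8 ms hop = 97% overlap), z-scored per frequency against the −200..−50 ms
baseline, and epoch-level permutation contrasts of 1–35 Hz vs broadband
35–110 Hz power between conditions.

## Worked example

```r
library(interopipe)

# 1. simulate one subject's basal-interoception block
cfg    <- sim_config(seed = 1, duration = 120)   # 128 ch @ 1024 Hz, 2 min
ecg    <- gen_ecg(cfg)                           # ECG + ground-truth R peaks
layout <- make_layout(cfg$n_channels)
raw    <- gen_scalp(cfg, ecg$r, "basal", layout)
taps   <- gen_taps(ecg$r, cfg, "basal")

# 2. behavioural score for this block
accuracy_index(ecg$r, taps)
#> [1] 0.4403922

# 3. ERP pipeline: preprocess, detect R, remove cardiac artifact, epoch
rec   <- preprocess_scalp(raw, reference = "average")
r_det <- detect_r_peaks(ecg$recording)
rec   <- remove_cfa(rec, r_det)
ep    <- epoch_recording(rec, r_det, condition = "basal", subject = "s01")
ep
#> <epoch_set> 139 epochs (0 rejected), 128 channels, 180 samples @ 256 Hz, -199..500 ms

# 4. cohort statistics from the calibrated behavioural generator
fit <- rm_anova(gen_cohort(48, seed = 1))
fit
#> Repeated-measures ANOVA: F(2, 94) = 29.21, p = 1.36e-10 (MS_error = 0.01881, n = 48)
tukey_hsd(fit)
#>                                            a             b       diff         q            p
#> exteroception vs basal         exteroception         basal  0.2139122 10.806400 5.373475e-10
#> exteroception vs post-feedback exteroception post-feedback  0.1032290  5.214915 1.094841e-03
#> basal vs post-feedback                 basal post-feedback -0.1106832  5.591484 4.344809e-04
```

Reading the output: the simulated subject scores 0.44 on the 0–1 accuracy
scale for basal interoception (the generator is calibrated so condition
means land near 0.73 / 0.47 / 0.58); the epoching yields 139 clean
R-locked epochs of 180 samples; the 48-subject cohort reproduces the
expected behavioural pattern — exteroception beats both interoceptive
conditions, and post-feedback interoception beats basal interoception.

The full chain (`wsmi_seed_map`, `wsmi_distance_profile`, `tf_chart`,
`band_contrast`, `pointwise_perm_test`) is demonstrated in the vignette
(`vignettes/interoception-pipeline.Rmd`), which also documents every
modelling decision and default.

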
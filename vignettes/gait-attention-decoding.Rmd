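---
title: "Decoding gait attention from EEG band power: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding gait attention from EEG band power: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

During treadmill walking, the attention a person devotes to gait varies with
what else they are doing. In a dual-task paradigm, four one-minute tasks are
interleaved within each run: normal walking (standard attention to gait),
mental arithmetic and watching a soundless video (both drawing attention away
from gait), and stepping on irregularly placed marks (forcing high attention
to gait). `gaitatt` implements a complete, tested pipeline for asking whether
scalp EEG recorded during such sessions carries decodable information about
which attentional task is being performed — and for validating any claimed
decoding accuracy against finite-sample chance levels.

A session is 8 runs of the four tasks (order fixed A, B, C, D) with 1-minute
breaks between runs: 32 minutes of useful task data at 1200 Hz on a
32-electrode fronto-central-to-parieto-occipital 10/10 montage.

## Pipeline

1. **Filtering** — band-pass 0.5–100 Hz plus a 50 Hz notch, both zero phase.
2. **Bad channels** — amplitude-based detection (more than 5 % of samples
   outside ±50 µV) and reconstruction by the pointwise mean of the channel's
   montage neighbors.
3. **Standardization** — each sample is divided by the cross-channel mean of
   the 32 per-channel *MV thresholds* (mean of per-second signal maxima,
   epoch width L = 1200 samples), making sessions comparable across users
   without destroying between-channel power differences.
4. **Features** — breaks removed, tasks cut into 1 s epochs with 0.5 s
   overlap (120 epochs per 60 s task, 3840 per session, 960 per task), a
   Burg maximum-entropy AR(16) spectrum per epoch and channel at 1–100 Hz,
   and band powers summed over δ(1–4), θ(4–8), α(8–12), β(12–30),
   γ_low(30–50) and γ_high(50–90) Hz.
5. **Band selection** — pairwise Bhattacharyya distances between the four
   task classes per band; a band is "highly separable" on a pair when
   Bdist ≥ 3.5.
6. **Classification** — five classifiers (RBF-SVM with C = 512 and kernel
   width 0.002, Gaussian naive Bayes, LDA, KNN with k = 30, decision tree)
   under run-wise 8-fold cross-validation (each run is one fold).
7. **Validation** — the adjusted-Wald chance interval
   p̃ ± z₁₋α/₂·√(p̃(1−p̃)/(n+4)) with p̃ = (n·X̄+2)/(n+4), plus two-sided
   Wilcoxon rank-sum tests with Bonferroni correction for comparisons
   against chance and between classifiers, bands, and subject groups.

## The synthetic world

No recordings are distributed with the source study, so every stage is
exercised on synthetic sessions whose statistical structure matches what the
analysis assumes. `sim_config()` states that world explicitly:

* **Cortical background** (12 µV RMS): spatially correlated Gaussian noise,
  correlation decaying with electrode distance (a stand-in for volume
  conduction — this is what makes neighbor-mean reconstruction meaningful).
  Temporally it is a discretized Ornstein–Uhlenbeck process with a 1 Hz
  knee: power flat below 1 Hz and falling as 1/f² above, i.e. amplitude
  ∝ 1/f. An AR(1) recursion generates this in O(n), which matters at
  2.8 million samples per session.
* **Line interference**: a 5 µV 50 Hz sinusoid on all channels.
* **Gait-locked motion artifact** (8 µV at the fundamental): harmonics 1–6
  of the 0.8 Hz stride rate (a plausible cadence at 2 km/h), amplitude
  ∝ 1/k, strongest frontally — placing artifact energy squarely in δ/θ.
* **Blinks**: Poisson events (15/min), 0.25 s raised-cosine bumps of 30 µV
  at the most frontal site, decaying toward the vertex.
* **Motor α**: a 10 Hz rhythm over the C row whose left/right envelopes
  alternate in antiphase at the stride rate.
* **Class signal**: band-limited Gaussian processes in 30–50 and 50–90 Hz
  (3 µV RMS at gain 1) on ten occipito-parietal electrodes, with a
  per-task *multiplicative power gain*. Defaults order the γ gains
  B, C > A > D — the distractor tasks push visual/occipital γ up, the
  high-gait-attention task pulls it down. A multiplicative gain (rather
  than an additive amplitude offset) makes Bhattacharyya separability scale
  smoothly with the configured effect size.

Amplitudes were fixed once from the ±50 µV "typical EEG" envelope: total
background-plus-rhythm variance keeps ≥99 % of clean samples inside ±50 µV,
which is also what the bad-channel detector assumes. `corrupt_channels()`
injects persistent out-of-range signals to exercise detection and
reconstruction.

What the generator does **not** model: biophysical source geometry, true
artifact waveforms (EMG spectra, electrode pops), non-stationarity within a
task, or inter-subject variability. A green test on this world establishes
that the *pipeline* recovers structure it is pointed at — not that real
walking EEG contains that structure.

## Numerical and design choices

* **Filters.** The filters are implemented as zero-phase frequency-domain
  multiplications with raised-cosine transition bands placed just inside the
  pass band (0.5→1.0 Hz and 95→100 Hz for the band-pass; a ±1 Hz stop band
  with 1 Hz ramps for the notch). With no IIR design library available this
  is both exact in phase and numerically robust; a 4th-order Butterworth
  band-pass at fs = 1200 Hz with a 0.5 Hz edge is ill-conditioned in
  transfer-function form. The band-pass and notch gains compose
  multiplicatively, so the pipeline applies them in a single pass.
* **MV threshold.** The signed maximum is used (an absolute-value variant is
  exposed); epochs are non-overlapping from sample 0 with the trailing
  remainder dropped. The threshold is a session constant. Division is by the
  cross-channel *mean* threshold, so a common gain cancels exactly while
  per-channel power ratios survive.
* **Epoch counts.** 60 s / 0.5 s = 120 epochs per task per run implies one
  more epoch than complete 1 s windows fit; the last epoch of each segment
  is right-padded by reflection about the segment boundary. This reproduces
  the 3840/960 counts exactly and never mixes two tasks in one epoch
  (task division happens before epoching).
* **Burg order 16.** Standard for 1 s EEG epochs; resolves the α peak
  without spurious γ lines. The spectrum is evaluated as
  E_p/|A(e^{-i2πf/fs})|² at integer frequencies 1–100 Hz. Band edges are
  half-open [low, high): a shared edge belongs to the upper band. On
  standardized (dimensionless) signals the resulting band powers are O(1–50),
  the scale at which the stated SVM hyperparameters (C = 512, width 0.002)
  operate sensibly — no further feature scaling is applied.
* **Bhattacharyya distance.** The multivariate Gaussian form
  D = ⅛·Δμᵀ Σ̄⁻¹ Δμ + ½·ln(det Σ̄ / √(det Σ₁ det Σ₂)), Σ̄ = (Σ₁+Σ₂)/2,
  with covariances shrunk toward their diagonal (λ = 0.1) because 32-dim
  covariances from a few hundred epochs can be ill-conditioned. Shrinkage
  leaves the 1-D closed forms and the zero distance of identical samples
  untouched. λ and a diagonal-only option are exposed. With small epoch
  counts the estimator is biased upward (≈ d²/n effects); tables from short
  synthetic sessions should be read relatively, not against the 3.5 cutoff.
* **Classifiers.** Implemented from first principles where no library is
  available: one-vs-one RBF C-SVC trained by SMO with maximal-violating-pair
  selection; Euclidean KNN with distance ties broken by training index and
  vote ties by the smallest class label; a Gini CART with unlimited depth
  and deterministic tie-breaks; Gaussian naive Bayes. LDA delegates to
  MASS. "y = 0.002" from the source work is read as the RBF kernel width.
  Everything is deterministic given the features, so cross-validated rates
  are exactly reproducible.
* **Chance levels.** `chance_range(n, ...)` takes the *actual* number of
  test epochs per fold (480 for a full session under run-wise folds). The
  source work states n = 960 per fold, which is inconsistent with
  3840/8 = 480; evaluating the interval formula literally at n = 960 gives
  22.37–27.84 %, not the 23.9–26.3 % printed there. Both n values remain
  available; the formula is implemented exactly as written.
* **Bonferroni families.** 10 pairs for five-classifier tables, 5 for
  per-classifier band/group contrasts; family size is an explicit argument
  since the source states the correction but not the family.
* **Chance vectors.** Comparisons against chance draw a matched-length
  uniform sample from the chance interval under a fixed, logged seed.

## Scaled-down acceptance suites

The property suites (γ-band recovery across 20 seeds, classifier calibration
on 50 null seeds) keep the full 8-run A,B,C,D layout and the 1200 Hz rate
but shorten tasks to 4–6 s so the whole suite fits a test-time budget;
chance intervals always use the fold sizes those sessions actually produce.
One full-size default session backs the structural-count criteria
(3840/960/32-min/24/32). For the qualitative separability-table criterion,
task A is given a broadband power offset (its distinct walking-focus state)
and B and C get *similar but not identical* γ gains — exactly equal
parameters would make the cross-band ranking of the BC column a coin flip.
In bands carrying no systematic effect, the ordering among the non-A pairs
is sampling noise, so "BC weakest" is asserted per band only within the two
γ bands and as a column average elsewhere.

## Known limitations

* The EDF importer handles continuous 16-bit EDF only (no EDF+ annotations);
  imported recordings carry no task segments unless supplied separately.
* Re-referencing (e.g. REST) is out of scope; data are modeled as recorded
  against the mono-auricular reference.
* The Bhattacharyya 3.5 cutoff is calibrated to pooled multi-subject epoch
  counts; on short synthetic sessions the small-sample bias dominates.
* No combined γ_low+γ_high feature set and no hyperparameter search — both
  are outside the reproduced analysis.
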
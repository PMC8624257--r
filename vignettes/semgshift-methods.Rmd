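---
title: "Electrode-shift-aware sEMG posture recognition: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Electrode-shift-aware sEMG posture recognition: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Armband surface-EMG (sEMG) sensors place a ring of eight equally spaced
electrodes around the forearm. They make myoelectric hand-posture
recognition practical for non-expert users — no electrode has to sit on a
named muscle belly — but every time the band is taken off and put back on,
the ring lands at a slightly different angle. This *electrode shift*
changes which portion of the underlying muscle activity each channel
sees, and a classifier trained on one wearing session degrades on the
next. `semgshift` provides a tested pipeline for studying that problem:
how many differently-shifted training sessions a classifier needs, which
time-domain features survive the shift, how threshold-based features
should be calibrated, and how the choice of posture vocabulary affects
accuracy.

Because raw multi-session armband recordings of this kind are not
publicly deposited, the package ships a parametric generator that
emulates the statistical structure the analysis depends on, and the whole
analysis runs end-to-end on synthetic data (or on user-supplied
recordings read with `read_emg_dataset()`).

## Signal model of the generator

Each trial is a static posture held for `trial_duration` seconds
(default 5 s) at 20% of maximum voluntary contraction (MVC), sampled at
500 Hz on 8 channels. Channel `c` is zero-mean Gaussian noise whose
spectral support is confined to the physiological 15–250 Hz band
(implemented by FFT-domain masking of white noise, then exact RMS
calibration) and whose RMS is

    rms_c = rest_rms * (1 + (g - 1) * a_c) * gain_c

* `rest_rms` — resting-channel RMS, default 3.3 mV;
* `a_c` — the posture's relative activation at the channel's (shifted)
  angular position, from a fixed catalog of 12 archetype profiles;
* `g` — the envelope gain at full activation; calibrated so that 20% MVC
  maps to `g = 5` (a fully activated channel at 5 × resting RMS),
  linearly in `mvc_fraction`. The study design fixes the contraction
  level, so `g` is a single frozen scale, not a per-trial variable;
* `gain_c` — per-channel log-normal gain jitter
  (`gain_jitter_sd = 0.015`), modelling electrode-skin impedance changes
  between sessions. The value is kept small enough that resting-channel
  RMS stays within 10% of 3.3 mV under any shift, which the study design
  treats as a fixed property of the resting signal.

No motor-unit-level structure is simulated. All 21 features under study
are time-domain functionals of the envelope and band, so
amplitude-modulated band-limited noise reproduces exactly the structure
they can see. Two consequences are worth keeping in mind when
interpreting results:

* the *spectral shape* of every channel is identical across postures, so
  autoregressive (AR) and cepstral (CC) features carry almost no posture
  information here — they sit near chance, which mirrors (more starkly)
  their observed weakness on short 500 Hz windows;
* there is no force variation, fatigue, or crosstalk drift; passing
  property tests on this generator demonstrates pipeline correctness and
  qualitative orderings, not real-data accuracy levels.

### Electrode shift

The armband is a circle, so a don/doff placement error is modelled as a
fractional circular rotation of the activation profile: session rotation
`~ Normal(0, shift_sd)` channels (default 0.5; one channel = 45°),
applied by circular linear interpolation of the 8-point profile, plus
the per-channel gain jitter. Rotation by 8 channels is exactly identity.
The magnitude of real-world shift is not known quantitatively;
`shift_sd` is therefore an explicit free parameter of the study
conditions, exposed in `synth_config()`.

### Posture archetypes and groups

The 12-posture catalog (`default_archetype_catalog()`) freezes one
8-channel activation profile per posture. Profiles are hand-crafted so
that postures sharing function and musculature are highly correlated
(palmar/tip/lateral pinch pairwise r ≥ 0.9; cylindrical/spherical grasp
r ≈ 0.99; scissor-sign/thumb-up r ≈ 0.99) while functionally distinct
postures correlate weakly or negatively (spread vs cylindrical grasp
r ≈ −0.66); rest is near-silent (activations ≤ 0.01). These
correlations are what make the posture-group comparisons meaningful:
`posture_groups()` defines G1 (6 core postures), G2–G5 (G1 plus one
posture each: finger pointing, tip pinch, spherical grasp,
scissor-sign), G6 (an alternative 7-posture set) and G7 (all 12).

## The analysis pipeline

1. **Filtering** — `bandpass_filter()`: zero-phase (forward–backward)
   Butterworth band-pass, design order 4. The literature's 15–250 Hz
   band has its upper edge exactly at Nyquist for a 500 Hz sensor, which
   is invalid for IIR design, so the default upper edge is 249 Hz.
   Odd-symmetric reflection padding (300 samples) suppresses the
   `filtfilt` edge transient (> 60 dB DC rejection). Zero-phase
   filtering doubles the effective order; offline analysis makes the
   phase-free trade worth it.
2. **Windowing** — `segment_windows()`: 250 ms windows shifted by 10 ms
   (closed–open sample intervals, 0-based starts, never spanning trial
   boundaries). A 5-s trial yields 476 windows of 125 samples.
3. **Features** — `extract_features()`: the 21 time-domain extractors
   plus the Hudgins (MAV, WL, ZC, SSC) and Du (IEMG, VAR, WL, ZC, SSC,
   WAMP) combinations, one value (or AR/CC coefficient vector) per
   channel per window.
4. **Correlation statistics** — `inter_session_pcc()`,
   `inter_feature_pcc()`, banded by `relationship_band()`.
5. **Classification** — `train_mlp()` /
   `session_protocol_evaluate()` / `kfold_cv()`.
6. **Experiments** — `run_threshold_sweep()`, `run_order_sweep()`,
   `run_session_sweep()`, `run_group_comparison()`,
   `compare_accuracy_distributions()`.

## Feature conventions

The formulas follow the conventional printed time-domain definitions
exactly, including their idiosyncrasies: VAR and SSI are *uncentered*
second moments (VAR divides by N−1); AAC sums N−1 absolute differences
but divides by N; MAV2's trailing taper `4(i−N)/N` is signed; TM3 and
TM5 take the absolute value of the signed moment; MAV1/MAV2 boundary
samples at exactly 0.25N/0.75N take weight 1. Two repairs are applied
where the printed indicator forms cannot work as written:

* **ZC** requires a genuine sign change (`x_i * x_{i+1} < 0`) together
  with the amplitude condition `|x_i − x_{i+1}| ≥ threshold`;
  thresholding the (negative) product itself could never fire.
* **MYOP** applies its indicator to `|x_i|`; on a zero-mean signal the
  one-sided form would count only positive excursions.
* **SSC** is kept exactly as printed — the indicator is applied to the
  *product* `(x_i − x_{i−1})(x_i − x_{i+1})`, whose units are mV². Its
  "unreachable threshold" is therefore the square of the amplitude
  features' one.

**MAVSLP** is computed across consecutive *analysis windows* of a trial
(the sliding-window pipeline makes adjacent windows the natural
sequence); the first window of each trial has no predecessor and is
dropped. On stationary trials MAVSLP is pure noise — by design it is the
package's canonical shift-*unstable* feature.

**Thresholds.** ZC, WAMP, MYOP and SSC take their threshold from the
`threshold_grid()` rule: threshold = R × RMS of the resting signal.
With the design values (3.3 mV rest, R = 0–10 by 0.5) the grid spans
0–33 mV in 21 steps of 1.65 mV. Outside sweeps the defaults are
R = 4.0, 3.0, 2.0, 4.0 for ZC, WAMP, MYOP, SSC — the best-performing
values of the threshold optimization (13.2, 9.9, 6.6, 13.2 mV at a
3.3 mV rest). The resting RMS is measured per subject from that
subject's rest trials by default (`per_subject = TRUE`), which matches
how a deployed system would calibrate; a pooled mode is available.

**AR/CC.** AR coefficients use the autocorrelation (Yule–Walker /
Levinson–Durbin) method via `stats::ar.yw`, without mean removal, in the
generative sign convention `x_i = Σ a_l x_{i−l} + w_i`; the method is
deterministic and fast, which matters at 10⁵ windows. The cepstral
recursion is `c_1 = −a_1`,
`c_p = −a_p − Σ_{l<p} (1 − l/p) a_l c_{p−l}` — the cepstrum of the
all-pole model `1/(1 + Σ a_l z^{−l})`, cross-checked in the tests
against a numeric FFT cepstrum. (A commonly printed variant puts `a_p`
inside the sum; that form is dimensionally inconsistent with the
recursion's own base case and is treated as a typographical slip.)
Default order is 2, the best-performing order; orders 1–10 are swept by
`run_order_sweep()`.

## Correlation statistics

Nothing in the standard description pins down *which* vectors the
inter-session correlation compares, so the package defines the session
signature explicitly: for each subject and session, the mean feature
value per (posture × channel-dimension), flattened to one vector.
`inter_session_pcc()` correlates every unordered pair of a subject's
sessions (45 pairs for 10 sessions), averages over pairs within subject,
then over subjects; the per-pair table is retained for audit. A
zero-variance signature (e.g. WAMP at threshold 0, where every window
saturates at N−1) has no measurable linear association and is assigned
r = 0 rather than NA so sweep curves stay defined.

`inter_feature_pcc()` standardizes each feature per channel (channel
gains must not dominate), pools all (window, channel) observations, and
correlates feature pairs; AR/CC contribute their first coefficient.
Tables are aligned on the intersection of window provenance, which
accommodates MAVSLP's missing first windows.

Bands follow the printed boundaries (weak 0 < r ≤ 0.3, moderate
0.3 < r ≤ 0.7, strong 0.7 < r ≤ 1). Negative r is banded weak with an
explicit flag, since the banding is defined on positive association
only.

## Classifier and evaluation protocols

The classifier is a single-hidden-layer perceptron: 8 × dims inputs, 17
hidden nodes, one softmax output per posture, trained by quasi-Newton
backpropagation (`nnet`), with per-column standardization fitted on
training data only. The hidden activation, stopping rule and learning
rate of the original design are unspecified; the package uses `nnet`'s
logistic hidden units and weight decay (default 1e-3, `maxit = 150`) as
the regularizer — the canonical R implementation of exactly this
architecture — with seeded, restartable, fully deterministic fits.
Models are subject-specific throughout; no cross-subject normalization
is attempted.

Two evaluation protocols are deliberately separated:

* `session_protocol_evaluate()` — the headline protocol. Train on `k`
  of a subject's sessions, test on the remaining sessions. Only this
  protocol can expose electrode-shift generalization, because train and
  test sessions carry different shifts. Repeats draw distinct
  k-subsets; when the requested repeats cover the whole subset space the
  evaluation becomes exhaustive (e.g. leave-one-session-out at k = 9).
* `kfold_cv()` — stratified 10-fold cross-validation within a pooled
  window set; an auxiliary check that cannot see shift, retained
  because mixed-session k-fold is what much of the literature reports.

Accuracies are reported in percent as mean (SD) over subjects × repeats,
always traceable to the per-run table and the aggregate confusion matrix
(rows = true, columns = predicted; row sums equal per-posture test
window counts).

`compare_accuracy_distributions()` applies the Kruskal–Wallis H test
with Dunn-type pairwise z comparisons (tie-corrected, Holm-adjusted,
α = 0.05). Dunn's test is written in-package; no installed package
provides it.

## Desk-scale experiment sizes

The experiment drivers default to sizes that complete in minutes on one
CPU while preserving every qualitative property under study:

* classifier sweeps use a 100 ms window shift (window length unchanged
  at 250 ms): overlapping 10 ms windows multiply the row count tenfold
  with nearly duplicate rows and change none of the tested orderings;
* the shift-vs-training study uses 3 subjects × 10 sessions × 5
  generator seeds, with MAV evaluated at k = 1, 4, 9 (exhaustive
  leave-one-out at k = 9);
* the threshold sweep uses 2 subjects × 3 seeds over the full 21-point
  grid; the group comparison 3 subjects × 5 seeds at k = 4.

Full-scale emulation (10 subjects, 10 ms shift, k = 1…9) is a matter of
changing the arguments.

## Numerical choices and degenerate inputs

* LOG clamps `|x|` at a configurable epsilon (1e-12) before the
  logarithm; exact zeros otherwise produce −Inf.
* All-zero (or constant) windows yield zero AR coefficients with a
  warning rather than a singular solve.
* Ties in the softmax argmax resolve to the first level,
  deterministically.
* Trials shorter than one window yield an empty window sequence with a
  warning; single-window trials produce empty MAVSLP output likewise.
* Band edges at or above Nyquist are rejected with an explicit message
  rather than silently clamped.

## Known limitations

* The generator's posture information lives entirely in the amplitude
  pattern across channels; spectral features (AR/CC) are uninformative
  here by construction, so their absolute accuracies are not comparable
  to real-data values — only their qualitative position (below the
  amplitude features) is meaningful.
* Shift is purely rotational plus gain jitter; real shift also tilts
  electrodes and changes the conduction volume nonlinearly.
* Accuracy levels on synthetic data depend on the frozen archetype
  correlations; orderings between groups and features are the stable
  outputs, absolute percentages are not.
* Static postures only; onset/offset transients and dynamic gestures
  are out of scope.
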
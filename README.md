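# semgshift

Electrode-shift-robust feature selection and hand-posture classification
for armband surface EMG (sEMG).

## The problem

Ring-shaped 8-channel sEMG armbands make myoelectric posture recognition
practical outside the lab, but every don/doff lands the electrode ring at
a slightly different angle. This *electrode shift* changes the signal
pattern each channel sees and silently degrades a classifier trained in a
previous wearing session. Three design questions follow, and this package
provides a tested, fully synthetic-data-driven pipeline for all three:

1. **How many differently-shifted training sessions are enough?**
   Train on `k` sessions, test on held-out sessions
   (`session_protocol_evaluate()`), sweep `k`.
2. **Which features survive the shift?** The inter-session Pearson
   correlation (PCC) of a feature's posture-by-channel signature predicts
   its classification accuracy under shift; features with r > 0.7
   ("strong") classify well, features with r < 0.3 ("weak") do not
   (`inter_session_pcc()`, `inter_feature_pcc()`, `relationship_band()`).
3. **Which posture vocabulary?** Adding a posture that shares function
   and musculature with an existing one (tip pinch next to palmar/lateral
   pinch) costs far more accuracy than adding a distinct one
   (`run_group_comparison()` over the groups G1–G7 of 12 postures).

The core machinery is:

* a parametric generator of multi-subject, multi-session 8-channel
  armband recordings (500 Hz, 5-s trials at 20% MVC, resting RMS
  3.3 mV), with electrode shift modelled as circular rotation of the
  posture's activation profile around the ring, `~N(0, shift_sd)`
  channels per session, plus per-channel gain jitter;
* the 21 classic time-domain features (IEMG, MAV, MAV1, MAV2, SSI, VAR,
  TM3–TM5, RMS, LOG, WL, AAC, DASDV, MAVSLP, ZC, WAMP, MYOP, SSC, AR,
  CC) plus the Hudgins and Du combinations, on 250 ms windows;
* the R-factor threshold rule for the threshold-based counts:

  `threshold = R × RMS(sEMG at rest)`, with R swept 0.0–10.0 in steps
  of 0.5 — at a 3.3 mV resting RMS a 0–33 mV grid in 1.65 mV steps
  (`threshold_grid()`, `run_threshold_sweep()`);
* a small MLP (8 × dims inputs, 17 hidden nodes, softmax outputs, one
  model per subject) with a sessions-of-training protocol and stratified
  k-fold CV, plus Kruskal–Wallis/Dunn comparison of accuracy
  distributions.

See `vignettes/semgshift-methods.Rmd` for the signal model, feature
conventions, and every numerical choice.

## Worked example

```r
library(semgshift)

# 2 subjects x 10 wearing sessions of the 6-posture core group,
# 0.5 channels of don/doff rotation between sessions
cfg <- synth_config(n_subjects = 2, n_sessions = 10, shift_sd = 0.5,
                    master_seed = 42)
ds  <- preprocess_dataset(generate_dataset(cfg, postures = "G1"))

measure_rest_rms(ds, by_subject = FALSE)
#> [1] 3.36

range(threshold_grid(3.36, 0, 10, 0.5)$thresholds)
#> [1]  0.0000 33.6162

mav <- extract_features(ds, "MAV",    shift_ms = 100, filter = FALSE)
slp <- extract_features(ds, "MAVSLP", shift_ms = 100, filter = FALSE)
c(MAV = inter_session_pcc(mav)$mean_r, MAVSLP = inter_session_pcc(slp)$mean_r)
#>    MAV MAVSLP
#>  0.861 -0.005

for (k in c(1, 4)) {
  ev <- session_protocol_evaluate(mav, k, n_repeats = 3, seed = 1)
  cat(sprintf("MAV, k = %d: %.1f (%.1f) %%\n", k, ev$mean_accuracy, ev$sd_accuracy))
}
#> MAV, k = 1: 69.5 (18.4) %
#> MAV, k = 4: 90.6 (3.4) %

ev <- session_protocol_evaluate(slp, 4, n_repeats = 3, seed = 1)
cat(sprintf("MAVSLP, k = 4: %.1f (%.1f) %%\n", ev$mean_accuracy, ev$sd_accuracy))
#> MAVSLP, k = 4: 48.1 (2.3) %
```

Reading: the resting RMS measured from the rest trials calibrates the
threshold grid; MAV's session signatures correlate strongly across
shifted sessions (r = 0.86, "strong") while the MAV-slope's do not
(r ≈ 0, "weak"); training on four shifted sessions instead of one lifts
MAV accuracy from ~70% to ~91%, and the shift-unstable MAVSLP stays far
below MAV at the same k.

A thin CLI wraps the common steps:

```sh
inst/exec/semgshift simulate --out data/ --seed 1 --group G1
inst/exec/semgshift extract  --in data/ --feature MAV --out mav.csv
inst/exec/semgshift pcc      --in data/ --features MAV,RMS,MAVSLP --out pcc.csv
```

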
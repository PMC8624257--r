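# Synthetic armband sEMG generator.

test_that("archetype catalog has 12 postures with valid profiles", {
  cat <- default_archetype_catalog()
  expect_length(cat, 12L)
  expect_setequal(names(cat), posture_ids())
  for (a in cat) {
    expect_s3_class(a, "posture_archetype")
    expect_length(a$activation_profile, 8L)
    expect_true(all(a$activation_profile >= 0))
    if (a$posture_id == "rest")
      expect_true(all(a$activation_profile <= 0.05))
    else
      expect_equal(max(a$activation_profile), 1)
  }
})

test_that("same-function postures correlate strongly, distinct ones weakly", {
  prof <- sapply(default_archetype_catalog(), `[[`, "activation_profile")
  r <- cor(prof)
  pinch <- c("palmar_pinch", "tip_pinch", "lateral_pinch")
  expect_true(all(r[pinch, pinch][lower.tri(r[pinch, pinch])] >= 0.8))
  expect_gte(r["cylindrical_grasp", "spherical_grasp"], 0.8)
  expect_gte(r["scissor_sign", "thumb_up"], 0.8)
  expect_lte(r["spread", "cylindrical_grasp"], 0.4)
  active <- setdiff(posture_ids(), "rest")
  expect_true(all(r["rest", active] <= 0.4))
})

test_that("posture groups match the catalog layout", {
  g <- posture_groups()
  expect_equal(unname(lengths(g)), c(6L, 7L, 7L, 7L, 7L, 7L, 12L))
  expect_setequal(g$G1, c("rest", "cylindrical_grasp", "palmar_pinch",
                          "thumb_up", "lateral_pinch", "spread"))
  expect_setequal(setdiff(g$G2, g$G1), "finger_pointing")
  expect_setequal(setdiff(g$G3, g$G1), "tip_pinch")
  expect_setequal(g$G7, posture_ids())
  expect_error(group_postures("karate_chop"), "unknown posture")
})

test_that("trial synthesis is deterministic and circular in rotation", {
  cfg <- synth_config(master_seed = 1)
  arch <- default_archetype_catalog()$cylindrical_grasp
  s0 <- shift_model(0, 0, 1)
  r1 <- synthesize_trial(arch, s0, cfg, seed = 11)
  r2 <- synthesize_trial(arch, s0, cfg, seed = 11)
  expect_identical(r1$signal, r2$signal)
  r8 <- synthesize_trial(arch, shift_model(8.0, 0, 1), cfg, seed = 11)
  expect_identical(r1$signal, r8$signal)
  r3 <- synthesize_trial(arch, s0, cfg, seed = 12)
  expect_false(identical(r1$signal, r3$signal))
})

test_that("rest trials sit within 10% of the 3.3 mV resting RMS", {
  cfg <- synth_config(master_seed = 2)
  arch <- default_archetype_catalog()$rest
  set.seed(202)
  for (sseed in 1:3) {
    sh <- shift_model(runif(1, 0, 8), cfg$gain_jitter_sd, session_seed = sseed)
    rec <- synthesize_trial(arch, sh, cfg, seed = sseed)
    rms <- sqrt(rowMeans(rec$signal^2))
    expect_true(all(abs(rms - 3.3) / 3.3 < 0.10))
  }
})

test_that("generated signal power is confined to the 15-250 Hz band", {
  cfg <- synth_config(master_seed = 3)
  arch <- default_archetype_catalog()$spread
  rec <- synthesize_trial(arch, shift_model(0.3, 0.05, 5), cfg, seed = 9)
  for (ch in c(1, 5)) {
    x <- rec$signal[ch, ]
    sp <- stats::spec.pgram(x, spans = c(11, 11), plot = FALSE)
    freq_hz <- sp$freq * cfg$sampling_rate
    in_band <- freq_hz >= 15 & freq_hz <= 250
    expect_gt(sum(sp$spec[in_band]) / sum(sp$spec), 0.95)
  }
})

test_that("every active archetype drives at least one channel above rest", {
  cfg <- synth_config(master_seed = 4)
  s0 <- shift_model(0, 0, 1)
  for (a in default_archetype_catalog()) {
    if (a$posture_id == "rest") next
    rec <- synthesize_trial(a, s0, cfg, seed = 21)
    expect_gt(max(sqrt(rowMeans(rec$signal^2))), cfg$rest_rms)
  }
})

test_that("dataset generation is reproducible with full manifests", {
  cfg <- synth_config(n_subjects = 2, n_sessions = 3, trial_duration = 1,
                      master_seed = 77)
  d1 <- generate_dataset(cfg, postures = "G1")
  d2 <- generate_dataset(cfg, postures = "G1")
  expect_identical(d1, d2)
  expect_equal(nrow(d1$manifest), 2 * 3 * 6)
  expect_named(d1$manifest, c("subject_id", "session_id", "posture_id",
                              "trial_order", "seed", "rotation_offset"))
  per_session <- table(d1$manifest$subject_id, d1$manifest$session_id)
  expect_true(all(per_session == 6))
  expect_error(generate_dataset(cfg, postures = c("rest", "nope")),
               "unknown posture")
})

test_that("zero shift pins every session to the reference rotation", {
  cfg <- synth_config(n_subjects = 2, n_sessions = 1, trial_duration = 1,
                      shift_sd = 0, master_seed = 5)
  ds <- generate_dataset(cfg, postures = c("rest", "spread"))
  expect_true(all(ds$manifest$rotation_offset == 0))
})

test_that("electrode shift degrades inter-session MAV correlation", {
  r_at <- function(shift_sd, seed) {
    cfg <- synth_config(n_subjects = 1, n_sessions = 4, trial_duration = 2,
                        shift_sd = shift_sd,
                        gain_jitter_sd = if (shift_sd == 0) 0 else 0.05,
                        master_seed = seed)
    ds <- generate_dataset(cfg, postures = c("rest", "cylindrical_grasp",
                                             "spread"))
    fm <- extract_features(ds, "MAV", shift_ms = 100)
    inter_session_pcc(fm)$mean_r
  }
  r0 <- vapply(1:5, function(s) r_at(0, 400 + s), numeric(1))
  r1 <- vapply(1:5, function(s) r_at(1.0, 400 + s), numeric(1))
  expect_gt(mean(r0), mean(r1))
  expect_true(all(r0 > 0.95))
})

test_that("rest RMS measurement requires rest trials", {
  cfg <- synth_config(n_subjects = 1, n_sessions = 2, trial_duration = 1,
                      master_seed = 6)
  ds <- generate_dataset(cfg, postures = c("spread", "thumb_up"))
  expect_error(measure_rest_rms(ds), "no rest trials")
  ds2 <- generate_dataset(cfg, postures = c("rest", "spread"))
  rr <- measure_rest_rms(ds2, by_subject = FALSE)
  expect_lt(abs(rr - 3.3) / 3.3, 0.1)
})
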
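# Experiment drivers and nonparametric comparisons.

test_that("rank comparison: null, separated and transformed conditions", {
  same <- list(a = 1:10, b = 1:10, c = 1:10)
  r0 <- compare_accuracy_distributions(same)
  expect_gt(r0$p_value, 0.9)
  expect_false(any(r0$pairwise$significant))

  apart <- list(lo = 1:10, hi = 101:110)
  r1 <- compare_accuracy_distributions(apart)
  expect_lt(r1$p_value, 0.05)
  expect_true(all(r1$pairwise$significant))

  r2 <- compare_accuracy_distributions(lapply(apart, exp))
  expect_equal(r1$statistic, r2$statistic)

  expect_warning(compare_accuracy_distributions(list(a = rep(1, 5),
                                                     b = rep(1, 5))),
                 "identical")
  expect_error(compare_accuracy_distributions(list(a = 1:2, b = 1:5)),
               "at least 3")
})

test_that("session sweep produces the feature-by-k accuracy/PCC layout", {
  ds <- tiny_dataset(c("rest", "cylindrical_grasp"), n_sessions = 3,
                     seed = 71)
  before <- serialize(ds, NULL)
  feats <- feature_names(include_combos = TRUE)
  rep <- run_session_sweep(ds, features = feats, k_values = c(1, 2),
                           group = c("rest", "cylindrical_grasp"),
                           seed = 1, shift_ms = 50, maxit = 60)
  expect_identical(serialize(ds, NULL), before)  # inputs never mutated
  expect_equal(nrow(rep$table), length(feats) * 2)
  expect_equal(nrow(rep$pcc), 23L)
  expect_setequal(rep$pcc$feature, feats)
  expect_true(all(rep$table$mean_accuracy >= 0 &
                  rep$table$mean_accuracy <= 100))
  # every cell traceable to seeded runs
  expect_true(all(paste(rep$table$feature, rep$table$k) %in%
                  paste(rep$runs$feature, rep$runs$k)))
  expect_equal(rep$config$seed, 1)
})

test_that("order sweep enumerates the requested orders", {
  ds <- tiny_dataset(c("rest", "cylindrical_grasp"), n_sessions = 2,
                     seed = 72)
  rep <- run_order_sweep(ds, "AR", orders = 1:10, k = 1, seed = 2,
                         group = c("rest", "cylindrical_grasp"),
                         shift_ms = 100, maxit = 50)
  expect_equal(rep$table$order, 1:10)
  expect_true(all(is.finite(rep$table$mean_accuracy)))
})

test_that("AR and CC carry the same information; amplitude beats both", {
  diffs <- numeric(5)
  ar_acc <- mav_acc <- numeric(5)
  for (s in 1:5) {
    ds <- preprocess_dataset(
      tiny_dataset(c("rest", "cylindrical_grasp", "spread"),
                   n_sessions = 3, seed = 80 + s))
    far <- extract_features(ds, "AR", order = 2, shift_ms = 100,
                            filter = FALSE)
    fcc <- extract_features(ds, "CC", order = 2, shift_ms = 100,
                            filter = FALSE)
    fmv <- extract_features(ds, "MAV", shift_ms = 100, filter = FALSE)
    a <- session_protocol_evaluate(far, 1, n_repeats = 2, seed = s)
    c <- session_protocol_evaluate(fcc, 1, n_repeats = 2, seed = s)
    m <- session_protocol_evaluate(fmv, 1, n_repeats = 2, seed = s)
    diffs[s] <- a$mean_accuracy - c$mean_accuracy
    ar_acc[s] <- a$mean_accuracy
    mav_acc[s] <- m$mean_accuracy
  }
  # cepstrum is an invertible transform of the AR coefficients
  expect_lt(abs(mean(diffs)), 2)
  # 125-sample windows starve the AR fit; amplitude features dominate
  expect_gt(mean(mav_acc), mean(ar_acc))
})

test_that("threshold sweep needs rest trials and spans the grid", {
  ds_no_rest <- tiny_dataset(c("spread", "thumb_up"), n_sessions = 2,
                             seed = 73)
  expect_error(run_threshold_sweep(ds_no_rest, "WAMP", k = 1),
               "no rest trials")

  run <- threshold_sweep_run()
  expect_equal(nrow(run$avg), 21L)
  # grid built from the measured resting RMS of ~3.3 mV spans ~0-33 mV
  expect_lt(abs(max(run$avg$mean_threshold_mV) - 33) / 33, 0.05)
  expect_equal(min(run$avg$mean_threshold_mV), 0)
})

test_that("group comparison reports one confusion per group at its size", {
  run <- group_comparison_run()
  expect_equal(vapply(run$confusions, nrow, integer(1)),
               c(G1 = 6L, G2 = 7L, G3 = 7L, G7 = 12L))
  for (cm in run$confusions) expect_true(all(rowSums(cm) > 0))
})

test_that("the G3 confusion concentrates on the pinch triplet", {
  cm <- group_comparison_run()$confusions$G3
  off <- cm
  diag(off) <- 0
  worst <- which(off == max(off), arr.ind = TRUE)[1, ]
  pinch <- c("palmar_pinch", "tip_pinch", "lateral_pinch")
  expect_true(rownames(cm)[worst["row"]] %in% pinch)
  expect_true(colnames(cm)[worst["col"]] %in% pinch)
})
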
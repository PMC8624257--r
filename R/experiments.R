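# Experiment drivers: threshold sweep, AR/CC order sweep, training-session
# sweep with inter-session PCC, posture-group comparison, and the
# nonparametric comparison of accuracy distributions.
#
# Desk-scale defaults: classifier sweeps use a 100 ms window shift (window
# 250 ms unchanged) so a 5-s trial contributes 48 windows instead of 476
# heavily overlapping ones; see the methods vignette.

experiment_report <- function(kind, table, runs, extra = list(), config) {
  structure(c(list(kind = kind, table = table, runs = runs,
                   config = config), extra),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("<experiment_report:%s>\n", x$kind))
  print(x$table, digits = 4)
  invisible(x)
}

prepare_group <- function(dataset, group) {
  ds <- subset_dataset(dataset, postures = group_postures(group))
  if (!isTRUE(ds$filtered)) ds <- preprocess_dataset(ds)
  ds
}

#' Threshold sweep for a threshold-based feature
#'
#' Builds the R-factor threshold grid from the dataset's measured resting
#' RMS (per subject by default), then reports classification accuracy
#' under the sessions-of-training protocol and the inter-session PCC at
#' every grid threshold.
#'
#' @param dataset an `emg_dataset` containing rest trials.
#' @param feature one of ZC, WAMP, MYOP, SSC.
#' @param R_grid unitless factor grid (default 0 to 10 by 0.5).
#' @param group posture group label or posture ids.
#' @param k training sessions per evaluation.
#' @param seed master seed.
#' @param per_subject measure resting RMS (and hence thresholds) per
#'   subject rather than pooled.
#' @param shift_ms,n_hidden,maxit,decay pipeline and classifier settings.
#' @return an `experiment_report` whose `table` has one row per grid
#'   point: `R`, `mean_threshold_mV`, `mean_accuracy`, `sd_accuracy`,
#'   `mean_pcc`.
#' @export
run_threshold_sweep <- function(dataset, feature = "WAMP",
                                R_grid = seq(0, 10, by = 0.5),
                                group = "G1", k = 4, seed = 1L,
                                per_subject = TRUE, shift_ms = 100,
                                n_hidden = 17, maxit = 150, decay = 1e-3) {
  feature <- match.arg(feature, .THRESHOLD_FEATURES)
  rr <- measure_rest_rms(dataset, by_subject = per_subject)
  ds <- prepare_group(dataset, group)
  subjects <- sort(unique(ds$manifest$subject_id))
  rows <- list()
  runs <- list()
  for (gi in seq_along(R_grid)) {
    R <- R_grid[gi]
    fm <- do.call(rbind, lapply(subjects, function(s) {
      rs <- if (per_subject) rr[[as.character(s)]] else rr
      extract_features(subset_dataset(ds, subjects = s), feature,
                       threshold = R * rs, shift_ms = shift_ms,
                       filter = FALSE)
    }))
    fm <- structure(fm, feature = feature,
                    value_cols = sprintf("ch%d_%s", 1:8, feature),
                    window_ms = 250, shift_ms = shift_ms,
                    class = c("emg_features", "data.frame"))
    ev <- session_protocol_evaluate(fm, k, seed = derive_seed(seed, gi),
                                    n_hidden = n_hidden, maxit = maxit,
                                    decay = decay)
    pcc <- inter_session_pcc(fm)
    rows[[gi]] <- data.frame(
      R = R, mean_threshold_mV = R * mean(unlist(rr)),
      mean_accuracy = ev$mean_accuracy, sd_accuracy = ev$sd_accuracy,
      mean_pcc = pcc$mean_r)
    runs[[gi]] <- cbind(R = R, ev$runs)
  }
  experiment_report(
    "threshold_sweep", do.call(rbind, rows), do.call(rbind, runs),
    extra = list(rest_rms = rr, feature = feature, k = k),
    config = list(group = group, k = k, seed = seed, shift_ms = shift_ms,
                  per_subject = per_subject))
}

#' AR/CC model-order sweep
#'
#' Classification accuracy per model order, with a rank-based comparison
#' of the per-run accuracy distributions across orders.
#'
#' @param dataset an `emg_dataset`.
#' @param feature `"AR"` or `"CC"`.
#' @param orders model orders to sweep (default 1 to 10).
#' @inheritParams run_threshold_sweep
#' @return an `experiment_report` with one table row per order and a
#'   `comparison` element from [compare_accuracy_distributions()].
#' @export
run_order_sweep <- function(dataset, feature = "AR", orders = 1:10,
                            group = "G1", k = 4, seed = 1L,
                            shift_ms = 100, n_hidden = 17, maxit = 150,
                            decay = 1e-3) {
  feature <- match.arg(feature, .ORDER_FEATURES)
  ds <- prepare_group(dataset, group)
  rows <- list()
  runs <- list()
  for (oi in seq_along(orders)) {
    fm <- extract_features(ds, feature, order = orders[oi],
                           shift_ms = shift_ms, filter = FALSE)
    ev <- session_protocol_evaluate(fm, k, seed = derive_seed(seed, oi),
                                    n_hidden = n_hidden, maxit = maxit,
                                    decay = decay)
    rows[[oi]] <- data.frame(order = orders[oi],
                             mean_accuracy = ev$mean_accuracy,
                             sd_accuracy = ev$sd_accuracy)
    runs[[oi]] <- cbind(order = orders[oi], ev$runs)
  }
  runs <- do.call(rbind, runs)
  cmp <- if (length(orders) >= 2L && nrow(runs) >= 2 * length(orders))
    tryCatch(compare_accuracy_distributions(
      split(runs$accuracy, runs$order)), error = function(e) NULL)
  experiment_report("order_sweep", do.call(rbind, rows), runs,
                    extra = list(feature = feature, comparison = cmp),
                    config = list(group = group, k = k, seed = seed,
                                  shift_ms = shift_ms))
}

#' Training-session sweep across features
#'
#' The headline experiment: per feature, mean (SD) classification accuracy
#' at each number of training sessions `k`, plus one inter-session PCC
#' column — the layout used to read off which features are shift-robust.
#'
#' @param dataset an `emg_dataset`.
#' @param features feature names (optionally including `"HUDGINS"`,
#'   `"DU"`); default all 21 + 2.
#' @param k_values numbers of training sessions to evaluate.
#' @inheritParams run_threshold_sweep
#' @param order AR/CC order used for those features.
#' @return an `experiment_report`; `table` has one row per
#'   (feature, k) with accuracy mean/SD, `pcc` one row per feature.
#' @export
run_session_sweep <- function(dataset, features = feature_names(TRUE),
                              k_values = 1:9, group = "G1", seed = 1L,
                              order = 2L, shift_ms = 100, n_hidden = 17,
                              maxit = 150, decay = 1e-3) {
  ds <- prepare_group(dataset, group)
  rows <- list()
  pccs <- list()
  runs <- list()
  for (fi in seq_along(features)) {
    f <- features[fi]
    fm <- extract_features(ds, f, order = order, shift_ms = shift_ms,
                           filter = FALSE)
    pccs[[fi]] <- data.frame(feature = f,
                             mean_r = inter_session_pcc(fm)$mean_r)
    for (k in k_values) {
      ev <- session_protocol_evaluate(fm, k,
                                      seed = derive_seed(seed, fi, k),
                                      n_hidden = n_hidden, maxit = maxit,
                                      decay = decay)
      rows[[length(rows) + 1L]] <- data.frame(
        feature = f, k = k, mean_accuracy = ev$mean_accuracy,
        sd_accuracy = ev$sd_accuracy)
      runs[[length(runs) + 1L]] <- cbind(feature = f, ev$runs)
    }
  }
  experiment_report(
    "session_sweep", do.call(rbind, rows), do.call(rbind, runs),
    extra = list(pcc = do.call(rbind, pccs)),
    config = list(group = group, k_values = k_values, seed = seed,
                  order = order, shift_ms = shift_ms))
}

#' Posture-group comparison
#'
#' Accuracy and confusion matrix per posture group at a fixed feature and
#' number of training sessions.
#'
#' @param dataset an `emg_dataset` containing all postures of the
#'   requested groups.
#' @param feature feature name.
#' @param groups group labels (default G1..G7).
#' @inheritParams run_threshold_sweep
#' @return an `experiment_report`; `table` has one row per group,
#'   `confusions` is a named list of group confusion matrices.
#' @export
run_group_comparison <- function(dataset, feature = "MAV",
                                 groups = paste0("G", 1:7), k = 4,
                                 seed = 1L, shift_ms = 100, n_hidden = 17,
                                 maxit = 150, decay = 1e-3) {
  if (!isTRUE(dataset$filtered)) dataset <- preprocess_dataset(dataset)
  rows <- list()
  runs <- list()
  cms <- list()
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    ds <- subset_dataset(dataset, postures = group_postures(g))
    fm <- extract_features(ds, feature, shift_ms = shift_ms,
                           filter = FALSE)
    ev <- session_protocol_evaluate(fm, k, seed = derive_seed(seed, gi),
                                    n_hidden = n_hidden, maxit = maxit,
                                    decay = decay)
    rows[[gi]] <- data.frame(group = g,
                             n_postures = length(group_postures(g)),
                             mean_accuracy = ev$mean_accuracy,
                             sd_accuracy = ev$sd_accuracy)
    runs[[gi]] <- cbind(group = g, ev$runs)
    cms[[g]] <- ev$confusion
  }
  experiment_report(
    "group_comparison", do.call(rbind, rows), do.call(rbind, runs),
    extra = list(confusions = cms, feature = feature),
    config = list(groups = groups, k = k, seed = seed,
                  shift_ms = shift_ms))
}

#' Nonparametric comparison of accuracy distributions
#'
#' Kruskal-Wallis omnibus test across conditions followed by Dunn-type
#' pairwise rank comparisons (normal approximation with tie correction)
#' under Holm multiplicity control, at significance level
#' `alpha` (default 0.05).
#'
#' @param samples_by_condition named list (or data.frame with columns
#'   `condition`, `value`) of at least 2 conditions with at least 3
#'   samples each.
#' @param alpha significance level for flagging pairs.
#' @return list with `statistic` (Kruskal-Wallis H), `p_value`,
#'   `pairwise` (data.frame: conditions, z, p, Holm-adjusted p,
#'   `significant`), and `alpha`.
#' @export
compare_accuracy_distributions <- function(samples_by_condition,
                                           alpha = 0.05) {
  if (is.data.frame(samples_by_condition))
    samples_by_condition <- split(samples_by_condition$value,
                                  samples_by_condition$condition)
  stopifnot(length(samples_by_condition) >= 2L)
  if (any(vapply(samples_by_condition, length, integer(1)) < 3L))
    stopf("every condition needs at least 3 samples")
  values <- unlist(samples_by_condition, use.names = FALSE)
  cond <- factor(rep(names(samples_by_condition),
                     vapply(samples_by_condition, length, integer(1))),
                 levels = names(samples_by_condition))
  if (sd(values) == 0)
    warnf("all samples identical across conditions; rank test is degenerate")
  kw <- suppressWarnings(kruskal.test(values, cond))
  ranks <- rank(values)
  n <- length(values)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  sigma2 <- n * (n + 1) / 12 - tie_term
  mean_rank <- tapply(ranks, cond, mean)
  n_i <- tapply(ranks, cond, length)
  pairs <- combn(levels(cond), 2)
  z <- p <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    se <- sqrt(sigma2 * (1 / n_i[[a]] + 1 / n_i[[b]]))
    z[j] <- if (se == 0) 0 else (mean_rank[[a]] - mean_rank[[b]]) / se
    p[j] <- 2 * pnorm(-abs(z[j]))
  }
  p_adj <- p.adjust(p, method = "holm")
  list(statistic = unname(kw$statistic), p_value = kw$p.value,
       pairwise = data.frame(condition_a = pairs[1, ],
                             condition_b = pairs[2, ], z = z, p = p,
                             p_adj = p_adj,
                             significant = p_adj < alpha),
       alpha = alpha, method = "Kruskal-Wallis + Dunn (Holm)")
}
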
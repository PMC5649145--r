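test_that("stratified shuffle splits preserve class proportions and partition indices", {
  labels <- rep(c("aMCI", "CN"), c(42, 115))
  splits <- shuffle_split(labels, n_splits = 10, test_fraction = 0.1, seed = 3)
  expect_length(splits, 10L)
  for (sp in splits) {
    expect_identical(sort(c(sp$train, sp$test)), seq_along(labels))
    expect_length(intersect(sp$train, sp$test), 0L)
    # stratified rounding oracle: round(4.2) = 4 aMCI, round(11.5) = 12 CN
    expect_identical(length(sp$test), 16L)
    expect_identical(sum(labels[sp$test] == "aMCI"), 4L)
    expect_identical(sum(labels[sp$test] == "CN"), 12L)
  }
  # shuffle property: different iterations differ, reruns are identical
  expect_false(identical(splits[[1]]$test, splits[[2]]$test))
  splits2 <- shuffle_split(labels, n_splits = 10, test_fraction = 0.1, seed = 3)
  expect_identical(splits, splits2)
  expect_error(shuffle_split(c("a", "b", "b"), n_splits = 2), "at least 2")
})

test_that("confusion metrics match hand arithmetic and the AUC is rank-based", {
  m <- compute_metrics(
    truth = rep(c("pos", "neg"), c(4, 6)),
    predicted = c("pos", "pos", "pos", "neg", "neg", "neg", "neg", "neg", "pos", "pos"),
    scores = c(0.9, 0.8, 0.7, 0.3, 0.2, 0.1, 0.15, 0.05, 0.6, 0.55),
    positive = "pos"
  )
  expect_equal(m$sensitivity, 0.75)
  expect_equal(m$specificity, 4 / 6, tolerance = 1e-12)
  expect_equal(m$accuracy, 0.7)
  expect_identical(c(m$tp, m$fn, m$tn, m$fp), c(3L, 1L, 4L, 2L))

  # limit cases
  perfect <- compute_metrics(rep(c("pos", "neg"), each = 3),
                             rep(c("pos", "neg"), each = 3),
                             c(0.9, 0.8, 0.7, 0.3, 0.2, 0.1), "pos")
  expect_equal(perfect$auc, 1)
  ties <- compute_metrics(rep(c("pos", "neg"), each = 3),
                          rep("neg", 6), rep(0.5, 6), "pos")
  expect_equal(ties$auc, 0.5)

  # independent oracle: pROC on random scores
  set.seed(10)
  truth <- sample(c("pos", "neg"), 40, replace = TRUE)
  scores <- rnorm(40)
  ours <- compute_metrics(truth, rep("neg", 40), scores, "pos")$auc
  ref <- as.numeric(pROC::auc(pROC::roc(response = factor(truth, c("neg", "pos")),
                                        predictor = scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref)

  # single-class fold: undefined metrics reported as missing
  one <- compute_metrics(rep("neg", 5), rep("neg", 5), rnorm(5), "pos")
  expect_true(is.na(one$sensitivity) && is.na(one$auc))
  expect_false(is.na(one$specificity))
})

small_cfg <- function(task = "aMCI_vs_CN", feature_set = "baseline",
                      cv_iterations = 2, seed = 1) {
  experiment_config(
    task = task, feature_set = feature_set, cv_iterations = cv_iterations,
    selection = selection_config(n_subsamples = 10, filter_keep = 30,
                                 wrapper_keep = 10, nf_grid = c(5, 4),
                                 nf_repeats = 2, rfe_step = 0.5, seed = 1),
    seed = seed
  )
}

test_that("run_fold never reads test labels and keeps selections within the cap", {
  fx <- make_fixture("separable")
  d <- fx$baseline[as.character(fx$baseline$diagnosis) %in% c("aMCI", "CN"), ]
  idx <- seq_len(nrow(d))
  set.seed(2)
  test_idx <- c(sample(which(d$diagnosis == "aMCI"), 3),
                sample(which(d$diagnosis == "CN"), 4))
  train <- d[setdiff(idx, test_idx), ]
  test <- d[test_idx, ]
  cfg <- small_cfg()
  f1 <- run_fold(train, test, cfg)
  expect_length(f1$selections, 3L)
  for (sel in f1$selections) expect_lte(length(sel$optimal_features), 10L)

  # leakage check: permuting test labels changes nothing, byte for byte
  test_perm <- test
  test_perm$diagnosis <- rev(test_perm$diagnosis)
  f2 <- run_fold(train, test_perm, cfg)
  expect_identical(f1$selections, f2$selections)
  expect_identical(f1$predictions, f2$predictions)
  expect_identical(f1$scaler, f2$scaler)
})

test_that("a 1-iteration, 1-resample experiment reduces to a single fold", {
  fx <- make_fixture("separable")
  cfg <- small_cfg(cv_iterations = 1, seed = 5)
  cfg$n_resamples <- 1L
  ex <- run_experiment(fx$baseline, config = cfg)
  expect_identical(nrow(ex$metrics), 1L)
  # aggregated frequencies are a single subsampling tally
  expect_identical(sum(ex$frequencies$frequency), 10L * 10L)
  expect_true(all(ex$frequencies$frequency <= 10L))
})

test_that("the full pipeline is deterministic under one master seed", {
  fx <- make_fixture("separable")
  cfg <- small_cfg(seed = 11)
  e1 <- run_experiment(fx$baseline, config = cfg)
  e2 <- run_experiment(fx$baseline, config = cfg)
  expect_identical(e1$metrics, e2$metrics)
  expect_identical(e1$frequencies, e2$frequencies)
  expect_identical(e1$top_features, e2$top_features)
  e3 <- run_experiment(fx$baseline, config = small_cfg(seed = 12))
  expect_false(identical(e1$frequencies, e3$frequencies))

  # results do not depend on the calling session's RNG configuration
  old_kind <- RNGkind()
  RNGkind("L'Ecuyer-CMRG")
  e4 <- run_experiment(fx$baseline, config = small_cfg(seed = 11))
  do.call(RNGkind, as.list(old_kind))
  expect_identical(e1$metrics, e4$metrics)
  expect_identical(e1$frequencies, e4$frequencies)
})

test_that("experiment bookkeeping: caps, wave-2 and longitudinal feature sets, tidiers", {
  fx <- make_fixture("separable")
  cfg <- small_cfg(task = "naMCI_vs_aMCI", feature_set = "longitudinal", seed = 21)
  ex <- run_experiment(fx$baseline, fx$wave2, config = cfg)
  cap <- cfg$n_resamples * cfg$selection$n_subsamples * cfg$cv_iterations
  expect_identical(ex$max_frequency, as.integer(cap))
  expect_true(all(ex$frequencies$frequency <= cap))
  expect_identical(nrow(ex$frequencies), 300L)  # 2 x 150 longitudinal features
  expect_true(all(c("accuracy", "sensitivity", "specificity", "auc") %in%
                    names(ex$metrics)))
  expect_true(all(ex$summary >= 0 & ex$summary <= 1, na.rm = TRUE))

  td <- tidy(ex)
  expect_identical(nrow(td), 2L)
  gl <- glance(ex)
  expect_identical(gl$task, "naMCI_vs_aMCI")
  expect_identical(gl$n_iterations, 2L)
  expect_s3_class(autoplot(ex), "ggplot")
  expect_s3_class(plot_selection_frequencies(ex), "ggplot")
  expect_identical(nrow(ex$top_features), 10L)
  expect_true(all(ex$top_features$p_value >= 0 & ex$top_features$p_value <= 1))

  # wave-2 feature set requires the wave-2 table
  expect_error(run_experiment(fx$baseline, config = small_cfg(feature_set = "wave2")))
})

test_that("null data yields fold accuracy near the majority-class rate", {
  fx <- make_fixture("null")
  cfg <- small_cfg(task = "aMCI_vs_CN", cv_iterations = 3, seed = 31)
  ex <- run_experiment(fx$baseline, config = cfg)
  # 40 CN / 25 aMCI: majority rate ~0.615; test folds of 6 (2 aMCI / 4 CN).
  # permutation/null oracle: accuracy within binomial noise of the rate
  maj <- 4 / 6
  se <- sqrt(maj * (1 - maj) / 6) / sqrt(3)
  expect_lt(abs(mean(ex$metrics$accuracy) - maj), 4 * se)
})

test_that("compare_runs performs a Welch test across per-iteration accuracies", {
  fx <- make_fixture("null")
  e1 <- run_experiment(fx$baseline, config = small_cfg(cv_iterations = 4, seed = 41))
  e2 <- run_experiment(fx$baseline, config = small_cfg(cv_iterations = 4, seed = 42))
  cmp <- compare_runs(e1, e2)
  ref <- t.test(e1$metrics$accuracy, e2$metrics$accuracy)
  expect_equal(cmp$p_value, ref$p.value)
  expect_equal(cmp$mean1, mean(e1$metrics$accuracy))

  # degenerate comparisons (e.g. two perfect runs) are handled gracefully
  e_const <- e1
  e_const$metrics$accuracy <- rep(1, 4)
  expect_equal(compare_runs(e_const, e_const)$p_value, 1)
})
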
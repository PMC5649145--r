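# Monte Carlo cross-validated evaluation: 10 stratified shuffle-splits at a
# 9:1 train-test ratio; per fold the training set is min-max scaled,
# rebalanced 3 times, stability selection and a voting model are run per
# resample, and the test set is predicted by 3-model majority vote.  The test
# set is never resampled and never touches selection.

task_levels <- function() c("aMCI_vs_CN", "naMCI_vs_CN", "naMCI_vs_aMCI")

task_classes <- function(task) {
  parts <- strsplit(task, "_vs_", fixed = TRUE)[[1]]
  # positive class = the clinically affected / minority class (first token)
  list(positive = parts[1], negative = parts[2])
}

#' Experiment configuration
#'
#' Bundles every pipeline constant: 10 cross-validation iterations at a 9:1
#' train-test ratio, 3 resampled training sets per fold, the stability
#' selection constants (100 subsamples, filter 100, wrapper 20, Nf in
#' {10, 9, 8} validated 5 times), voting weights 1:4:1, and the 2/3
#' oversampling ratio.
#'
#' @param task One of `"aMCI_vs_CN"`, `"naMCI_vs_CN"`, `"naMCI_vs_aMCI"`;
#'   the first-named (affected, minority) class is the positive class for
#'   sensitivity/recall/AUC.
#' @param feature_set `"baseline"`, `"wave2"`, or `"longitudinal"` (means and
#'   changes of the two timepoints).
#' @param cv_iterations Monte Carlo CV iterations (default 10).
#' @param test_fraction Held-out fraction per iteration (default 0.1).
#' @param n_resamples Rebalanced training sets per fold (default 3; must be
#'   odd so the binary majority vote cannot tie).
#' @param selection A [selection_config()].
#' @param weights Voting weights `(svm, lr, rf)`, default `c(1, 4, 1)`.
#' @param undersample_target Passed to [rebalance()].
#' @param seed Master seed; child seeds are spawned per fold, and per
#'   resample within folds, so fold membership does not depend on
#'   `n_resamples`.
#' @return A list of class `mci_experiment_config`.
#' @export
experiment_config <- function(task = "aMCI_vs_CN",
                              feature_set = c("baseline", "wave2", "longitudinal"),
                              cv_iterations = 10, test_fraction = 0.1,
                              n_resamples = 3,
                              selection = selection_config(),
                              weights = c(svm = 1, lr = 4, rf = 1),
                              undersample_target = "balanced",
                              seed = 1L) {
  task <- match.arg(task, task_levels())
  feature_set <- match.arg(feature_set)
  if (test_fraction <= 0 || test_fraction >= 1) abort("test_fraction must be in (0,1)")
  if (cv_iterations < 1) abort("cv_iterations must be >= 1")
  if (n_resamples %% 2 == 0) abort("n_resamples must be odd (untied majority vote)")
  structure(list(
    task = task, feature_set = feature_set,
    cv_iterations = as.integer(cv_iterations), test_fraction = test_fraction,
    n_resamples = as.integer(n_resamples), selection = selection,
    weights = weights, undersample_target = undersample_target,
    seed = as.integer(seed)
  ), class = "mci_experiment_config")
}

#' Stratified shuffle-split (Monte Carlo) cross-validation folds
#'
#' Generates `n_splits` independent random train/test partitions preserving
#' per-class proportions: each class contributes `round(test_fraction * n_c)`
#' test samples (at least 1).  Unlike k-fold CV, splits are drawn
#' independently, so test sets of different iterations may overlap.
#'
#' @param labels Class labels (each class needs at least 2 samples and a
#'   nonzero test allocation below its size).
#' @param n_splits Number of splits (default 10).
#' @param test_fraction Test fraction (default 0.1).
#' @param seed Integer seed.
#' @return A list of `n_splits` lists with integer elements `train`, `test`
#'   (disjoint; union = all indices).
#' @export
shuffle_split <- function(labels, n_splits = 10, test_fraction = 0.1, seed = 1L) {
  y <- as_stable_factor(labels)
  tab <- table(y)
  if (any(tab < 2)) abort("each class needs at least 2 samples")
  n_test <- setNames(pmax(1L, as.integer(round(test_fraction * tab))), names(tab))
  if (any(n_test >= tab)) {
    abort("a class is too small to leave training samples under stratification")
  }
  seeds <- spawn_seeds(seed, n_splits)
  lapply(seq_len(n_splits), function(i) {
    with_seed(seeds[i], {
      test <- integer(0)
      for (lev in levels(y)) {
        idx <- which(y == lev)
        test <- c(test, sample(idx, n_test[[lev]]))
      }
      test <- sort(test)
      list(train = setdiff(seq_along(y), test), test = test)
    })
  })
}

#' Run one cross-validation fold
#'
#' Fits the full training pipeline on `train` and predicts `test`: a 0-1
#' scaler is fitted on the training set; the training set is rebalanced
#' `n_resamples` times with distinct seeds; per resample, stability selection
#' is run on the rebalanced set and a voting model is fitted on its optimal
#' features; the test set is predicted by majority vote of the models.  The
#' test set is never resampled, never scaled by its own statistics, and its
#' labels are never read here — only the caller compares predictions to
#' truth.
#'
#' @param train,test Data frames with a `diagnosis` column holding exactly
#'   the task's two classes, plus numeric feature columns.
#' @param config An [experiment_config()]; `config$seed` is used as the
#'   fold-level seed.
#' @return A list with `predictions` (tibble from [majority_predict()]),
#'   `selections` (list of `n_resamples` [choose_optimal_set()] results),
#'   `models`, `scaler`, and `positive`.
#' @export
run_fold <- function(train, test, config = experiment_config()) {
  cls <- task_classes(config$task)
  feats <- setdiff(names(train), c(meta_columns(), "provenance"))
  x_train <- as_feature_matrix(train[feats])
  y_train <- as_binary_factor(train$diagnosis, positive = cls$positive)

  scaler <- fit_scaler(x_train)
  xs_train <- apply_scaler(scaler, x_train)

  n_r <- config$n_resamples
  seeds <- matrix(spawn_seeds(config$seed, 3L * n_r), nrow = 3)
  scaled_df <- dplyr::bind_cols(tibble(diagnosis = y_train), as_tibble(xs_train))

  models <- vector("list", n_r)
  selections <- vector("list", n_r)
  for (r in seq_len(n_r)) {
    reb <- rebalance(scaled_df, label_col = "diagnosis", seed = seeds[1, r],
                     undersample_target = config$undersample_target)
    xr <- as_feature_matrix(reb[setdiff(names(reb), c("diagnosis", "provenance"))])
    yr <- reb$diagnosis
    sel_cfg <- config$selection
    sel_cfg$seed <- seeds[2, r]
    freq <- run_subsampling(xr, yr, sel_cfg)
    sel <- choose_optimal_set(xr, yr, freq, sel_cfg, positive = cls$positive)
    selections[[r]] <- sel
    models[[r]] <- fit_voting(xr, yr, features = sel$optimal_features,
                              weights = config$weights, positive = cls$positive,
                              seed = seeds[3, r])
  }

  x_test <- as_feature_matrix(test[intersect(feats, names(test))])
  xs_test <- apply_scaler(scaler, x_test)
  preds <- if (n_r == 3) {
    majority_predict(models, xs_test)
  } else if (n_r == 1) {
    # single-resample smoke path: the "majority" of one model is that model
    pp <- predict_proba(models[[1]], xs_test)
    tibble(.pred_class = pp$.pred_class, .pred_prob = pp[[cls$positive]])
  } else {
    pps <- lapply(models, predict_proba, x = xs_test)
    pos_votes <- Reduce(`+`, lapply(pps, function(p) as.integer(p$.pred_class == cls$positive)))
    tibble(
      .pred_class = factor(ifelse(pos_votes > n_r / 2, cls$positive, cls$negative),
                           levels = c(cls$negative, cls$positive)),
      .pred_prob = Reduce(`+`, lapply(pps, `[[`, cls$positive)) / n_r
    )
  }

  list(predictions = preds, selections = selections, models = models,
       scaler = scaler, positive = cls$positive)
}

#' Classification metrics from predictions and scores
#'
#' Computes accuracy `(Tp+Tn)/n`, sensitivity `Tp/(Tp+Fn)` (recall of the
#' positive class), specificity `Tn/(Tn+Fp)`, and the rank-based AUC: the
#' probability that a random positive's score exceeds a random negative's,
#' with ties counted 1/2 (Mann-Whitney form).  If the test fold contains a
#' single class, the undefined metrics are reported as `NA` and excluded
#' from downstream averages.
#'
#' @param truth True labels.
#' @param predicted Predicted labels.
#' @param scores Numeric positive-class scores (for AUC).
#' @param positive Positive class label.
#' @return A one-row tibble: accuracy, sensitivity, specificity, auc, tp,
#'   fn, tn, fp.
#' @export
#' @examples
#' compute_metrics(truth = c("a","a","a","a","b","b","b","b","b","b"),
#'                 predicted = c("a","a","a","b","b","b","b","b","b","a"),
#'                 scores = c(.9,.8,.7,.4,.3,.2,.1,.15,.25,.6), positive = "a")
compute_metrics <- function(truth, predicted, scores, positive) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  pos <- truth == positive
  tp <- sum(pos & predicted == positive)
  fn <- sum(pos & predicted != positive)
  tn <- sum(!pos & predicted != positive)
  fp <- sum(!pos & predicted == positive)
  n_pos <- sum(pos); n_neg <- sum(!pos)
  auc <- if (n_pos == 0 || n_neg == 0) NA_real_ else {
    r <- rank(scores)
    (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  }
  tibble(
    accuracy = (tp + tn) / length(truth),
    sensitivity = if (n_pos == 0) NA_real_ else tp / (tp + fn),
    specificity = if (n_neg == 0) NA_real_ else tn / (tn + fp),
    auc = auc,
    tp = tp, fn = fn, tn = tn, fp = fp
  )
}

#' Run a full Monte Carlo cross-validated experiment
#'
#' Subsets the cohort to the task's two diagnostic groups, builds the chosen
#' feature set (baseline, wave-2, or longitudinal means + changes), and runs
#' [run_fold()] on each of the [shuffle_split()] folds.  Metrics are averaged
#' over folds (over defined folds only, for metrics undefined in single-class
#' test folds); per-feature selection frequencies are summed over the
#' `n_resamples x cv_iterations` selection runs, giving a maximum possible
#' aggregated frequency of `n_resamples * n_subsamples * cv_iterations`
#' (3 x 100 x 10 = 3,000 at the defaults).  The top-10 features by aggregated
#' frequency are reported with two-sided Welch t-test p-values computed on
#' the full two-group sample.
#'
#' @param baseline Baseline feature table.
#' @param wave2 Wave-2 feature table (required unless
#'   `feature_set = "baseline"`).
#' @param config An [experiment_config()].
#' @return An object of class `mci_experiment`: list with `metrics`
#'   (per-iteration tibble), `summary` (one-row means), `frequencies`
#'   (aggregated per-feature tibble), `top_features` (feature, frequency, p),
#'   `max_frequency`, `task`, `feature_set`, `positive`, `config`.
#' @export
run_experiment <- function(baseline, wave2 = NULL, config = experiment_config()) {
  assert_feature_table(baseline)
  data <- switch(config$feature_set,
    baseline = baseline,
    wave2 = { assert_feature_table(wave2); wave2 },
    longitudinal = build_longitudinal(baseline, wave2)
  )
  cls <- task_classes(config$task)
  data <- data[as.character(data$diagnosis) %in% c(cls$positive, cls$negative), ]
  data$diagnosis <- factor(as.character(data$diagnosis),
                           levels = c(cls$negative, cls$positive))

  seeds <- spawn_seeds(config$seed, config$cv_iterations + 1L)
  splits <- shuffle_split(data$diagnosis, n_splits = config$cv_iterations,
                          test_fraction = config$test_fraction,
                          seed = seeds[config$cv_iterations + 1L])

  feats <- feature_names(data)
  agg_freq <- setNames(numeric(length(feats)), feats)
  metrics <- vector("list", config$cv_iterations)
  for (i in seq_len(config$cv_iterations)) {
    fold_cfg <- config
    fold_cfg$seed <- seeds[i]
    fold <- run_fold(data[splits[[i]]$train, ], data[splits[[i]]$test, ], fold_cfg)
    truth <- data$diagnosis[splits[[i]]$test]
    m <- compute_metrics(truth, fold$predictions$.pred_class,
                         fold$predictions$.pred_prob, cls$positive)
    metrics[[i]] <- dplyr::mutate(m, iteration = i, .before = 1)
    for (sel in fold$selections) {
      agg_freq[sel$frequencies$feature] <-
        agg_freq[sel$frequencies$feature] + sel$frequencies$frequency
    }
  }
  metrics <- dplyr::bind_rows(metrics)
  freq_tbl <- tibble(feature = names(agg_freq), frequency = as.integer(agg_freq)) %>%
    dplyr::arrange(dplyr::desc(.data$frequency))

  top <- freq_tbl[seq_len(min(10, nrow(freq_tbl))), ]
  tt <- ttest_selected(feature_values(data), data$diagnosis, top$feature)
  top_features <- dplyr::left_join(top, tt[c("feature", "p_value")], by = "feature")

  out <- list(
    metrics = metrics,
    summary = dplyr::summarise(metrics, dplyr::across(
      c("accuracy", "sensitivity", "specificity", "auc"),
      ~ mean(.x, na.rm = TRUE)
    )),
    frequencies = freq_tbl,
    top_features = top_features,
    max_frequency = config$n_resamples * config$selection$n_subsamples *
      config$cv_iterations,
    task = config$task, feature_set = config$feature_set,
    positive = cls$positive, config = config
  )
  class(out) <- "mci_experiment"
  out
}

#' @export
print.mci_experiment <- function(x, ...) {
  cat(sprintf("MCI subtype classification: %s (%s features)\n", x$task, x$feature_set))
  cat(sprintf("Mean over %d CV iterations:\n", nrow(x$metrics)))
  print(x$summary)
  cat(sprintf("Top features (max possible frequency %d):\n", x$max_frequency))
  print(x$top_features)
  invisible(x)
}

#' Compare two experiment runs
#'
#' Two-sided Welch t-test across the per-iteration accuracies of two
#' experiment configurations (e.g., baseline vs longitudinal features), the
#' conventional significance check between cross-validated methods.
#'
#' @param exp1,exp2 [run_experiment()] results.
#' @param metric Metric column to compare (default `"accuracy"`).
#' @return A one-row tibble: mean of each run, t statistic, p-value.
#' @export
compare_runs <- function(exp1, exp2, metric = "accuracy") {
  a <- exp1$metrics[[metric]]; b <- exp2$metrics[[metric]]
  if (stats::sd(c(a, b)) == 0) {
    # both runs constant and equal: no evidence of a difference
    stat <- 0; p <- 1
  } else if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    # constant but different: degenerate separation
    stat <- Inf; p <- 0
  } else {
    tt <- t.test(a, b, alternative = "two.sided", var.equal = FALSE)
    stat <- unname(tt$statistic); p <- tt$p.value
  }
  tibble(
    metric = metric,
    mean1 = mean(a, na.rm = TRUE), mean2 = mean(b, na.rm = TRUE),
    statistic = stat, p_value = p
  )
}
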
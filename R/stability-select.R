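# Stability feature selection: 100 stratified random half-splits; on one half
# an ANOVA-F filter keeps the top 100 features, on the other half SVM-RFE
# reduces those to 20; per-feature selection frequencies over the subsamples
# rank the features, and the final top-Nf set (Nf in {10, 9, 8}) is chosen by
# recall-validated classification on the training data.

#' Selection configuration
#'
#' @param n_subsamples Number of random half-split subsampling iterations
#'   (default 100).
#' @param filter_keep Features kept by the ANOVA-F filter (default 100).
#' @param wrapper_keep Features retained by RFE per iteration (default 20).
#' @param nf_grid Candidate final set sizes, validated by recall (default
#'   `c(10, 9, 8)`; the final set never exceeds 10 features).
#' @param nf_repeats Random 50/50 validation splits per Nf (default 5).
#' @param rfe_step Features eliminated per RFE round: an integer (default 1,
#'   one feature per refit) or a fraction in (0,1) of the current feature
#'   count, for large runs.
#' @param svm_cost Cost parameter of the internal SVMs (library default 1).
#' @param seed Integer seed.
#' @return A list of class `mci_selection_config`.
#' @export
selection_config <- function(n_subsamples = 100, filter_keep = 100,
                             wrapper_keep = 20, nf_grid = c(10, 9, 8),
                             nf_repeats = 5, rfe_step = 1, svm_cost = 1,
                             seed = 1L) {
  if (wrapper_keep > filter_keep) abort("wrapper_keep must be <= filter_keep")
  if (max(nf_grid) > wrapper_keep) abort("max(nf_grid) must be <= wrapper_keep")
  if (rfe_step <= 0) abort("rfe_step must be positive")
  structure(list(
    n_subsamples = as.integer(n_subsamples), filter_keep = as.integer(filter_keep),
    wrapper_keep = as.integer(wrapper_keep), nf_grid = as.integer(nf_grid),
    nf_repeats = as.integer(nf_repeats), rfe_step = rfe_step,
    svm_cost = svm_cost, seed = as.integer(seed)
  ), class = "mci_selection_config")
}

#' Rank features by two-group ANOVA F
#'
#' One-way, two-group ANOVA F per feature:
#' `F = (SS_between / 1) / (SS_within / (n - 2))`, equal to the square of the
#' pooled-variance t statistic.  Features constant across all samples (zero
#' between-group sum of squares) receive `F = 0`; features constant within
#' groups but differing between them receive `F = Inf` and rank first.
#'
#' @param x Matrix or data frame of features (columns).
#' @param y Binary class labels (each class with at least 2 samples).
#' @return A tibble with columns `feature`, `f_stat`, `rank` (1 = largest F),
#'   ordered by descending F.
#' @export
#' @examples
#' anova_f_rank(data.frame(f = c(0, 0, 1, 2, 2, 3)),
#'              rep(c("a", "b"), each = 3))  # F = 18
anova_f_rank <- function(x, y) {
  x <- as_feature_matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  y <- as_binary_factor(y)
  n1 <- sum(y == levels(y)[1]); n2 <- sum(y == levels(y)[2])
  if (min(n1, n2) < 2) abort("each class needs at least 2 samples")
  x1 <- x[y == levels(y)[1], , drop = FALSE]
  x2 <- x[y == levels(y)[2], , drop = FALSE]
  m1 <- colMeans(x1); m2 <- colMeans(x2)
  g <- (n1 * m1 + n2 * m2) / (n1 + n2)
  ssb <- n1 * (m1 - g)^2 + n2 * (m2 - g)^2
  ssw <- colSums(sweep(x1, 2, m1)^2) + colSums(sweep(x2, 2, m2)^2)
  f <- ifelse(ssb == 0, 0, (ssb / 1) / (ssw / (n1 + n2 - 2)))
  tibble(feature = colnames(x), f_stat = unname(f)) %>%
    dplyr::arrange(dplyr::desc(.data$f_stat)) %>%
    dplyr::mutate(rank = dplyr::row_number())
}

fit_linear_svm <- function(x, y, cost) {
  e1071::svm(x, y, kernel = "linear", cost = cost, scale = FALSE)
}

svm_weights <- function(fit) {
  drop(t(fit$coefs) %*% fit$SV)
}

#' Recursive feature elimination with a linear SVM
#'
#' Iteratively fits a linear maximum-margin classifier and removes the
#' feature(s) with the smallest squared weight until `keep` features remain.
#' The internal estimator is linear because elimination needs per-feature
#' weights; inputs are assumed to be on comparable scales (the pipeline
#' min-max scales first).
#'
#' @inheritParams anova_f_rank
#' @param keep Number of features to retain (`<=` candidate count).
#' @param step Elimination step per round: integer count or fraction of the
#'   current feature count (default 1).
#' @param cost SVM cost parameter.
#' @return Character vector of retained feature names, in input column order.
#' @export
rfe_reduce <- function(x, y, keep, step = 1, cost = 1) {
  x <- as_feature_matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  y <- as_binary_factor(y)
  if (keep > ncol(x)) abort("keep exceeds the number of candidate features")
  current <- colnames(x)
  while (length(current) > keep) {
    fit <- fit_linear_svm(x[, current, drop = FALSE], y, cost)
    w2 <- svm_weights(fit)^2
    n_rm <- if (step >= 1) as.integer(step) else max(1L, floor(step * length(current)))
    n_rm <- min(n_rm, length(current) - keep)
    drop_idx <- order(w2)[seq_len(n_rm)]
    current <- current[-drop_idx]
  }
  colnames(x)[colnames(x) %in% current]
}

# Stratified split of indices into two halves (floor(n_c/2) per class in A).
stratified_halves <- function(y) {
  a <- integer(0)
  for (lev in levels(y)) {
    idx <- sample(which(y == lev))
    a <- c(a, idx[seq_len(floor(length(idx) / 2))])
  }
  list(a = sort(a), b = setdiff(seq_along(y), a))
}

#' Selection frequencies over random half-split subsamples
#'
#' Runs `n_subsamples` iterations of: stratified random half-split into
#' subsets A and B; ANOVA-F filter on A keeping the top `filter_keep`
#' features; RFE on B restricted to those candidates, retaining
#' `wrapper_keep`; tally the retained features.  Per-feature tallies lie in
#' `[0, n_subsamples]` and sum to `n_subsamples * wrapper_keep` (2,000 at the
#' defaults) when the feature count is at least `wrapper_keep`.
#'
#' @inheritParams anova_f_rank
#' @param config A [selection_config()].
#' @return A tibble of class `mci_frequency` with columns `feature` and
#'   `frequency`, in input column order; attributes `n_subsamples` and
#'   `wrapper_keep` record the tally maxima.
#' @export
run_subsampling <- function(x, y, config = selection_config()) {
  x <- as_feature_matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  y <- as_binary_factor(y)
  if (min(table(y)) < 4) {
    abort("each class needs at least 4 samples to stratify half-splits")
  }
  p <- ncol(x)
  tally <- setNames(integer(p), colnames(x))
  seeds <- spawn_seeds(config$seed, config$n_subsamples)
  for (i in seq_len(config$n_subsamples)) {
    with_seed(seeds[i], {
      halves <- stratified_halves(y)
      fr <- anova_f_rank(x[halves$a, , drop = FALSE], y[halves$a])
      cand <- fr$feature[seq_len(min(config$filter_keep, p))]
      kept <- rfe_reduce(x[halves$b, cand, drop = FALSE], y[halves$b],
                         keep = min(config$wrapper_keep, length(cand)),
                         step = config$rfe_step, cost = config$svm_cost)
      tally[kept] <- tally[kept] + 1L
    })
  }
  out <- tibble(feature = names(tally), frequency = unname(tally))
  attr(out, "n_subsamples") <- config$n_subsamples
  attr(out, "wrapper_keep") <- config$wrapper_keep
  class(out) <- c("mci_frequency", class(out))
  out
}

#' Choose the optimal feature set by recall-validated frequency thresholds
#'
#' For each candidate size Nf in `nf_grid`, repeats `nf_repeats` times: split
#' the training data into stratified 50/50 halves, train an RBF-kernel SVM on
#' the top-Nf features by selection frequency, and compute the recall
#' `Tp / (Tp + Fn)` of the positive class on the held-out half.  The Nf with
#' the highest mean recall wins (ties go to the smaller Nf, for parsimony);
#' frequency ties among features are broken by the larger full-training ANOVA
#' F.  Recall is used because it is robust to the class imbalance of the
#' cohort; the positive class is the clinically affected (minority) one.
#'
#' @inheritParams run_subsampling
#' @param frequency_table Output of [run_subsampling()].
#' @param positive Positive class label for recall (default: the minority
#'   class of `y`).
#' @return An object of class `mci_selection`: list with `chosen_nf`,
#'   `optimal_features` (descending frequency order), `frequencies`,
#'   `recalls` (per Nf and repeat), `recall_summary`, `p_values` (Welch t
#'   per optimal feature via [ttest_selected()]), and `positive`.
#' @export
choose_optimal_set <- function(x, y, frequency_table,
                               config = selection_config(), positive = NULL) {
  x <- as_feature_matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  if (nrow(frequency_table) == 0) abort("empty frequency table")
  if (is.null(positive)) {
    tab <- table(y)
    positive <- names(tab)[which.min(tab)]
  }
  y <- as_binary_factor(y, positive = positive)

  f_full <- anova_f_rank(x, y)
  ord <- frequency_table %>%
    dplyr::left_join(f_full[c("feature", "f_stat")], by = "feature") %>%
    dplyr::arrange(dplyr::desc(.data$frequency), dplyr::desc(.data$f_stat))

  seeds <- spawn_seeds(config$seed + 1L, length(config$nf_grid) * config$nf_repeats)
  recalls <- tidyr::expand_grid(nf = config$nf_grid, rep = seq_len(config$nf_repeats))
  recalls$recall <- purrr::map2_dbl(recalls$nf, seq_len(nrow(recalls)), function(nf, k) {
    feats <- ord$feature[seq_len(min(nf, nrow(ord)))]
    with_seed(seeds[k], {
      halves <- stratified_halves(y)
      fit <- e1071::svm(x[halves$a, feats, drop = FALSE], y[halves$a],
                        kernel = "radial", cost = config$svm_cost, scale = FALSE)
      pred <- predict(fit, x[halves$b, feats, drop = FALSE])
      truth <- y[halves$b]
      tp <- sum(pred == positive & truth == positive)
      fn <- sum(pred != positive & truth == positive)
      if (tp + fn == 0) NA_real_ else tp / (tp + fn)
    })
  })
  summary <- recalls %>%
    dplyr::group_by(.data$nf) %>%
    dplyr::summarise(mean_recall = mean(.data$recall, na.rm = TRUE), .groups = "drop")
  best <- max(summary$mean_recall)
  chosen_nf <- min(summary$nf[summary$mean_recall >= best - 1e-12])
  optimal <- ord$feature[seq_len(min(chosen_nf, nrow(ord)))]

  out <- list(
    chosen_nf = as.integer(chosen_nf),
    optimal_features = optimal,
    frequencies = frequency_table,
    recalls = recalls,
    recall_summary = summary,
    p_values = ttest_selected(x, y, optimal),
    positive = positive
  )
  class(out) <- "mci_selection"
  out
}

#' @export
print.mci_selection <- function(x, ...) {
  cat("Stability selection: Nf =", x$chosen_nf,
      "(positive class:", paste0(x$positive, ")\n"))
  print(tidy(x))
  invisible(x)
}

#' Welch t-tests for selected features
#'
#' Two-sided Welch (unequal-variance) t-test of the two class means, per
#' selected feature.  Features with zero variance in both groups have an
#' undefined t statistic; they are reported with `p = 1` (equal means) or
#' `p = 0` (unequal means) and flagged `degenerate`.
#'
#' @inheritParams anova_f_rank
#' @param features Character vector of feature names to test.
#' @return A tibble with columns `feature`, `statistic`, `p_value`,
#'   `degenerate`.
#' @export
ttest_selected <- function(x, y, features) {
  x <- as_feature_matrix(x)
  y <- as_binary_factor(y)
  if (min(table(y)) < 2) abort("each class needs at least 2 samples")
  purrr::map_dfr(features, function(f) {
    v1 <- x[y == levels(y)[1], f]
    v2 <- x[y == levels(y)[2], f]
    if (stats::sd(v1) == 0 && stats::sd(v2) == 0) {
      equal <- isTRUE(all.equal(mean(v1), mean(v2)))
      tibble(feature = f, statistic = if (equal) 0 else Inf,
             p_value = if (equal) 1 else 0, degenerate = TRUE)
    } else {
      tt <- t.test(v1, v2, alternative = "two.sided", var.equal = FALSE)
      tibble(feature = f, statistic = unname(tt$statistic),
             p_value = tt$p.value, degenerate = FALSE)
    }
  })
}
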
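test_that("two-group ANOVA F matches hand computation and aov()", {
  # hand oracle: groups [0,0,1] vs [2,2,3]: SSB = 6, SSW = 4/3, F = 18
  fr <- anova_f_rank(data.frame(f = c(0, 0, 1, 2, 2, 3)), rep(c("a", "b"), each = 3))
  expect_equal(fr$f_stat, 18)

  # zero between-group sum of squares gives F = 0 even with unequal spreads
  fr0 <- anova_f_rank(data.frame(f = c(-1, 0, 1, -5, 0, 5)), rep(c("a", "b"), each = 3))
  expect_equal(fr0$f_stat, 0)

  # independent oracle: stats::aov on random data, plus F == pooled-t^2
  set.seed(21)
  x <- matrix(rnorm(40 * 6), 40, 6, dimnames = list(NULL, paste0("f", 1:6)))
  y <- rep(c("a", "b"), each = 20)
  fr2 <- anova_f_rank(x, y)
  for (j in 1:6) {
    f_aov <- summary(stats::aov(x[, j] ~ factor(y)))[[1]]$`F value`[1]
    expect_equal(fr2$f_stat[fr2$feature == paste0("f", j)], f_aov)
    t_pooled <- t.test(x[y == "a", j], x[y == "b", j], var.equal = TRUE)$statistic
    expect_equal(fr2$f_stat[fr2$feature == paste0("f", j)], unname(t_pooled)^2)
  }
  expect_error(anova_f_rank(x[c(1, 21:40), ], y[c(1, 21:40)]), "at least 2")
})

test_that("RFE retains the separating feature and respects keep/step contracts", {
  d <- two_class_data(n_per_class = 10, p = 5, seed = 1)
  expect_setequal(rfe_reduce(d$x, d$y, keep = 5), colnames(d$x))
  expect_error(rfe_reduce(d$x, d$y, keep = 6), "exceeds")
  expect_length(rfe_reduce(d$x, d$y, keep = 2, step = 1), 2L)

  # planted-feature oracle: one perfectly separating feature among noise
  hits <- 0
  for (s in 1:20) {
    dd <- two_class_data(n_per_class = 30, p = 3, d = 4, n_informative = 1, seed = s)
    kept <- rfe_reduce(dd$x, dd$y, keep = 1)
    hits <- hits + (kept == "f1")
  }
  expect_gte(hits, 19)
})

test_that("subsampling tallies conserve mass and respect per-feature bounds", {
  d <- two_class_data(n_per_class = 20, p = 30, d = 1.5, n_informative = 2, seed = 2)
  cfg <- selection_config(n_subsamples = 25, filter_keep = 25, wrapper_keep = 10,
                          nf_grid = c(5, 4), nf_repeats = 3, seed = 9)
  fr <- run_subsampling(d$x, d$y, cfg)
  expect_identical(sum(fr$frequency), 25L * 10L)
  expect_true(all(fr$frequency >= 0 & fr$frequency <= 25))
  # determinism
  expect_identical(run_subsampling(d$x, d$y, cfg)$frequency, fr$frequency)

  # dataset of exactly wrapper_keep features: every feature tallied every time
  d20 <- two_class_data(n_per_class = 10, p = 10, seed = 3)
  cfg20 <- selection_config(n_subsamples = 15, filter_keep = 10, wrapper_keep = 10,
                            nf_grid = c(5), seed = 1)
  fr20 <- run_subsampling(d20$x, d20$y, cfg20)
  expect_true(all(fr20$frequency == 15L))

  expect_error(run_subsampling(d20$x[c(1:3, 11:20), ], d20$y[c(1:3, 11:20)], cfg20),
               "at least 4")
})

test_that("planted separable features are recovered with high tallies across seeds", {
  fx <- make_fixture("separable")
  sl <- scale_slice(task_slice(fx$baseline, c("aMCI", "CN")))
  x <- as.matrix(sl[setdiff(names(sl), "diagnosis")])
  planted <- unique(fx$truth$feature_name)
  good <- 0
  for (s in 1:10) {
    cfg <- selection_config(rfe_step = 0.5, seed = s)
    fr <- run_subsampling(x, sl$diagnosis, cfg)
    good <- good + all(fr$frequency[match(planted, fr$feature)] >= 80)
  }
  expect_gte(good, 9)
})

test_that("the optimal set obeys the Nf grid, tie-breaks, and the 10-feature cap", {
  # naMCI vs aMCI is the widest contrast of the fixture (|d| = 5 per planted
  # feature), so recall saturates at 1 for every Nf and exercises the
  # parsimony tie-break (smaller Nf wins)
  fx <- make_fixture("separable")
  sl <- scale_slice(task_slice(fx$baseline, c("naMCI", "aMCI")))
  x <- as.matrix(sl[setdiff(names(sl), "diagnosis")])
  cfg <- selection_config(rfe_step = 0.5, seed = 4)
  fr <- run_subsampling(x, sl$diagnosis, cfg)
  sel <- choose_optimal_set(x, sl$diagnosis, fr, cfg, positive = "naMCI")
  expect_true(sel$chosen_nf %in% cfg$nf_grid)
  expect_length(sel$optimal_features, sel$chosen_nf)
  expect_lte(length(sel$optimal_features), 10L)
  expect_identical(max(sel$recall_summary$mean_recall), 1)
  expect_identical(sel$chosen_nf, min(cfg$nf_grid))
  # the planted features head the optimal set
  expect_true(all(unique(fx$truth$feature_name) %in% sel$optimal_features))

  # all-noise data still returns a valid Nf of the requested size
  d <- two_class_data(n_per_class = 12, p = 15, seed = 5)
  cfgn <- selection_config(n_subsamples = 10, filter_keep = 15, wrapper_keep = 8,
                           nf_grid = c(5, 4, 3), nf_repeats = 3, seed = 5)
  frn <- run_subsampling(d$x, d$y, cfgn)
  seln <- choose_optimal_set(d$x, d$y, frn, cfgn)
  expect_true(seln$chosen_nf %in% c(5L, 4L, 3L))
  expect_length(seln$optimal_features, seln$chosen_nf)
  expect_error(choose_optimal_set(d$x, d$y, frn[0, ], cfgn), "empty")
})

test_that("frequency ties are broken by the larger full-training ANOVA F", {
  set.seed(6)
  x <- matrix(rnorm(40 * 4), 40, 4, dimnames = list(NULL, paste0("f", 1:4)))
  x[21:40, 2] <- x[21:40, 2] + 3  # f2 has by far the largest F
  y <- rep(c("a", "b"), each = 20)
  freq <- tibble::tibble(feature = paste0("f", 1:4), frequency = c(5L, 5L, 5L, 5L))
  cfg <- selection_config(n_subsamples = 5, filter_keep = 4, wrapper_keep = 4,
                          nf_grid = c(1), nf_repeats = 2, seed = 3)
  sel <- choose_optimal_set(x, y, freq, cfg, positive = "b")
  expect_identical(sel$optimal_features[1], "f2")
})

test_that("Welch t-tests match stats::t.test and handle degenerate features", {
  tt <- ttest_selected(data.frame(f = c(1, 2, 3, 1, 2, 3)),
                       rep(c("a", "b"), each = 3), "f")
  expect_equal(tt$statistic, 0)
  expect_equal(tt$p_value, 1)

  # power oracle: planted d = 2.5 at n = 15/15 is essentially always significant
  d <- two_class_data(n_per_class = 15, p = 3, d = 2.5, n_informative = 1, seed = 8)
  tt2 <- ttest_selected(d$x, d$y, c("f1", "f2"))
  expect_lt(tt2$p_value[1], 0.01)
  ref <- t.test(d$x[d$y == "neg", 1], d$x[d$y == "pos", 1], var.equal = FALSE)
  expect_equal(tt2$p_value[1], ref$p.value)

  # affine rescaling leaves p unchanged
  xr <- d$x; xr[, 1] <- 1000 * xr[, 1] + 5
  expect_equal(ttest_selected(xr, d$y, "f1")$p_value, tt2$p_value[1])

  # zero variance in both groups
  xz <- matrix(c(rep(1, 6)), 6, 1, dimnames = list(NULL, "z"))
  tz <- ttest_selected(xz, rep(c("a", "b"), each = 3), "z")
  expect_true(tz$degenerate)
  expect_equal(tz$p_value, 1)
})
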
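# Weighted soft-voting ensemble: RBF SVM (with Platt-style probability
# calibration), L2-regularized logistic regression, and random forest,
# combined at weights 1:4:1; three such models fitted on independently
# resampled training sets are combined by majority vote.

#' Min-max (0-1) feature scaling
#'
#' `fit_scaler()` learns per-feature training minima and ranges;
#' `apply_scaler()` maps values through `(x - min) / (max - min)`.  Training
#' columns land exactly in `[0, 1]`; test values use the TRAINING min/max and
#' may fall outside `[0, 1]` (they are not clipped).  Constant training
#' columns map to 0.
#'
#' @param x Matrix or data frame of feature values.
#' @return `fit_scaler()`: an object of class `mci_scaler`; `apply_scaler()`:
#'   a numeric matrix of scaled values.
#' @export
#' @examples
#' sc <- fit_scaler(data.frame(f = c(2, 4, 6)))
#' apply_scaler(sc, data.frame(f = c(2, 4, 6, 8)))  # 0, 0.5, 1, 1.5
fit_scaler <- function(x) {
  x <- as_feature_matrix(x)
  mins <- apply(x, 2, min)
  ranges <- apply(x, 2, max) - mins
  structure(list(
    min = mins,
    inv_range = ifelse(ranges > 0, 1 / ranges, 0),
    features = colnames(x)
  ), class = "mci_scaler")
}

#' @param scaler A fitted `mci_scaler`.
#' @rdname fit_scaler
#' @export
apply_scaler <- function(scaler, x) {
  stopifnot(inherits(scaler, "mci_scaler"))
  x <- as_feature_matrix(x)
  if (!is.null(scaler$features)) {
    miss <- setdiff(scaler$features, colnames(x))
    if (length(miss) > 0) abort(paste0("missing feature(s): ", paste(miss, collapse = ", ")))
    x <- x[, scaler$features, drop = FALSE]
  }
  sweep(sweep(x, 2, scaler$min), 2, scaler$inv_range, `*`)
}

# Platt-style sigmoid calibration of SVM decision values on the training data
# (deterministic, unlike libsvm's internal cross-validated estimate).
platt_calibrate <- function(dv, y01) {
  df <- data.frame(y = y01, dv = dv)
  suppressWarnings(glm(y ~ dv, data = df, family = binomial()))
}

svm_decision_values <- function(fit, x) {
  p <- predict(fit, x, decision.values = TRUE)
  drop(attr(p, "decision.values"))
}

# L2-regularized (ridge) logistic regression at cost C = 1, the conventional
# library default for this estimator; an unpenalized fit diverges under the
# complete separation that rebalanced, feature-selected training sets often
# exhibit, producing degenerate 0/1 probabilities.  glmnet's lambda maps to
# cost C as lambda = 1 / (C * n).  Inputs are already 0-1 scaled, so no
# internal standardization.
fit_lr <- function(xs, y01, cost = 1) {
  x2 <- if (ncol(xs) == 1) cbind(xs, `.aux` = 0) else xs
  fit <- glmnet::glmnet(x2, y01, family = "binomial", alpha = 0,
                        lambda = 1 / (cost * nrow(x2)), standardize = FALSE)
  list(fit = fit, lambda = 1 / (cost * nrow(x2)), single = ncol(xs) == 1)
}

predict_lr <- function(lr, xs) {
  x2 <- if (lr$single) cbind(xs, `.aux` = 0) else xs
  drop(predict(lr$fit, newx = x2, s = lr$lambda, type = "response"))
}

#' Fit a weighted soft-voting classifier
#'
#' Fits three component classifiers on identical (scaled) training data — an
#' RBF-kernel SVM whose decision values are mapped to probabilities by
#' Platt-style sigmoid calibration, a logistic regression, and a random
#' forest — and stores the voting weights (default 1:4:1, chosen for
#' sensitivity under class imbalance).  All components use library-default
#' hyperparameters.
#'
#' @param x Matrix or data frame of training features (already 0-1 scaled, or
#'   raw with `scaler` supplied).
#' @param y Binary class labels (at least 2 samples per class).
#' @param features Feature subset to train on (default: all columns).
#' @param weights Named or positional numeric weights `(svm, lr, rf)`;
#'   non-negative, not all zero.
#' @param positive Positive class label (default: second factor level).
#' @param scaler Optional [fit_scaler()] object applied to `x` here and to
#'   new data at prediction time.
#' @param seed Integer seed (random forest growth is randomized).
#' @return An object of class `mci_voting`.
#' @export
fit_voting <- function(x, y, features = NULL, weights = c(svm = 1, lr = 4, rf = 1),
                       positive = NULL, scaler = NULL, seed = 1L) {
  if (length(weights) != 3 || any(weights < 0) || sum(weights) == 0) {
    abort("weights must be 3 non-negative numbers, not all zero")
  }
  y <- as_binary_factor(y, positive = positive)
  if (min(table(y)) < 1 || nlevels(droplevels(y)) < 2) {
    abort("training data must contain both classes")
  }
  x <- as_feature_matrix(x)
  if (!is.null(scaler)) x <- apply_scaler(scaler, x)
  if (is.null(features)) features <- colnames(x)
  xs <- x[, features, drop = FALSE]
  positive <- levels(y)[2]
  y01 <- as.integer(y == positive)

  model <- with_seed(seed, {
    svm_fit <- e1071::svm(xs, y, kernel = "radial", cost = 1, scale = FALSE)
    dv <- svm_decision_values(svm_fit, xs)
    calib <- platt_calibrate(dv, y01)
    lr_fit <- fit_lr(xs, y01)
    rf_fit <- randomForest::randomForest(xs, y)
    list(svm = svm_fit, calib = calib, lr = lr_fit, rf = rf_fit)
  })

  structure(list(
    components = model,
    weights = setNames(as.numeric(weights), c("svm", "lr", "rf")),
    features = features,
    classes = levels(y),
    positive = positive,
    scaler = scaler,
    seed = as.integer(seed)
  ), class = "mci_voting")
}

component_probs <- function(model, xs) {
  dv <- svm_decision_values(model$components$svm, xs)
  p_svm <- unname(predict(model$components$calib, newdata = data.frame(dv = dv),
                          type = "response"))
  p_lr <- unname(predict_lr(model$components$lr, xs))
  p_rf <- unname(predict(model$components$rf, xs, type = "prob")[, model$positive])
  cbind(svm = p_svm, lr = p_lr, rf = p_rf)
}

#' Soft-voting class probabilities
#'
#' Collects the positive-class probability from each component, multiplies by
#' the component weights and averages: `p = sum(w_c * p_c) / sum(w_c)`.  The
#' predicted label is the class with the highest averaged probability.
#' Probabilities are invariant to uniform rescaling of the weight vector.
#'
#' @param model A fitted [fit_voting()] model.
#' @param x New data containing the model's feature columns (raw if the model
#'   stores a scaler, otherwise already scaled).
#' @return A tibble with one probability column per class (summing to 1 per
#'   row) and a `.pred_class` factor column.
#' @export
predict_proba <- function(model, x) {
  stopifnot(inherits(model, "mci_voting"))
  x <- as_feature_matrix(x)
  if (!is.null(model$scaler)) x <- apply_scaler(model$scaler, x)
  xs <- x[, model$features, drop = FALSE]
  probs <- component_probs(model, xs)
  w <- model$weights
  p_pos <- drop(probs %*% w) / sum(w)
  negative <- setdiff(model$classes, model$positive)
  out <- tibble(!!negative := 1 - p_pos, !!model$positive := p_pos)
  out$.pred_class <- factor(ifelse(p_pos > 0.5, model$positive, negative),
                            levels = model$classes)
  out
}

#' Majority vote over a triplet of voting models
#'
#' The training set is resampled three times and one voting model is fitted
#' per resample; an odd count guarantees an untied binary majority vote.  The
#' final label is the mode of the three models' labels; the reported score is
#' the unweighted mean of the three models' combined positive-class
#' probabilities (used as the ROC ranking score for AUC).  Each model
#' projects the input onto its own selected feature subset.
#'
#' @param triplet A list of exactly 3 fitted [fit_voting()] models sharing
#'   the same classes.
#' @param x New data containing all models' feature columns.
#' @return A tibble with `.pred_class` (majority label) and `.pred_prob`
#'   (mean positive-class probability).
#' @export
majority_predict <- function(triplet, x) {
  if (length(triplet) != 3) abort("majority voting requires exactly 3 models")
  preds <- purrr::map(triplet, predict_proba, x = x)
  positive <- triplet[[1]]$positive
  classes <- triplet[[1]]$classes
  votes <- sapply(preds, function(p) p$.pred_class == positive)
  if (is.null(dim(votes))) votes <- matrix(votes, nrow = 1)
  n_pos <- rowSums(votes)
  pm <- sapply(preds, function(p) p[[positive]])
  if (is.null(dim(pm))) pm <- matrix(pm, nrow = 1)
  p_pos <- rowMeans(pm)
  tibble(
    .pred_class = factor(ifelse(n_pos >= 2, positive, setdiff(classes, positive)),
                         levels = classes),
    .pred_prob = p_pos
  )
}
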
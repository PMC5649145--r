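# Shared test helpers.  Fixtures are generated in code; nothing is read from
# disk.

# Binary-task slice of a fixture table: diagnosis + feature columns only.
task_slice <- function(table, classes) {
  d <- table[as.character(table$diagnosis) %in% classes, ]
  tibble::as_tibble(d[c("diagnosis", feature_names(table))])
}

# Min-max scale the feature columns of a task slice (diagnosis + features),
# as the pipeline does before resampling/selection.
scale_slice <- function(slice) {
  x <- as.matrix(slice[setdiff(names(slice), "diagnosis")])
  xs <- apply_scaler(fit_scaler(x), x)
  dplyr::bind_cols(
    tibble::tibble(diagnosis = droplevels(factor(slice$diagnosis))),
    tibble::as_tibble(xs)
  )
}

# Independent oracle for the oversampling size recursion:
# Ns -> Ns + max(1, floor(Ns/3)) until Ns >= target; returns the visited sizes.
size_path_oracle <- function(n0, target) {
  path <- as.integer(n0)
  while (path[length(path)] < target) {
    ns <- path[length(path)]
    path <- c(path, ns + max(1L, ns %/% 3L))
  }
  path
}

# A tiny two-class gaussian matrix with an optional planted mean shift on the
# first `n_informative` columns.
two_class_data <- function(n_per_class = 20, p = 10, d = 0, n_informative = 1,
                           seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(2 * n_per_class * p), 2 * n_per_class, p,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  y <- rep(c("neg", "pos"), each = n_per_class)
  if (d != 0 && n_informative > 0) {
    x[y == "pos", seq_len(n_informative)] <-
      x[y == "pos", seq_len(n_informative)] + d
  }
  list(x = x, y = y)
}
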
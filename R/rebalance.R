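# Hybrid class rebalancing: iterated k-means centroid oversampling of the
# minority class and k-medoids (PAM) undersampling of the majority class.
# Distances are Euclidean; callers are expected to pass values on comparable
# scales (the pipeline min-max scales to 0-1 before resampling).

# k-means++ seeding: first center uniform, then points with prob proportional
# to squared distance from the nearest chosen center.
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1)
  if (k > 1) {
    d2 <- rowSums((x - matrix(x[centers[1], ], n, ncol(x), byrow = TRUE))^2)
    for (i in 2:k) {
      if (all(d2 == 0)) {
        # fewer distinct points than centers; fall back to distinct rows
        remaining <- setdiff(which(!duplicated(x)), centers[seq_len(i - 1)])
        centers[i] <- if (length(remaining) > 0) remaining[1] else centers[1]
      } else {
        centers[i] <- sample.int(n, 1, prob = d2)
      }
      di <- rowSums((x - matrix(x[centers[i], ], n, ncol(x), byrow = TRUE))^2)
      d2 <- pmin(d2, di)
    }
  }
  x[centers, , drop = FALSE]
}

cluster_centroids <- function(x, k, iter_max = 300) {
  distinct <- unique(x)
  if (nrow(distinct) <= k) {
    # degenerate geometry: recycle the distinct rows so exactly k centroids
    # are emitted and the size recursion is unchanged
    return(distinct[rep_len(seq_len(nrow(distinct)), k), , drop = FALSE])
  }
  init <- kmeanspp_init(x, k)
  fit <- tryCatch(
    kmeans(x, centers = init, iter.max = iter_max),
    error = function(e) kmeans(x, centers = init, iter.max = iter_max,
                               algorithm = "Lloyd")
  )
  centers <- fit$centers
  bad <- !stats::complete.cases(centers)
  if (any(bad)) centers[bad, ] <- init[bad, ]
  centers
}

#' Oversample a minority class by iterated k-means centroids
#'
#' Repeatedly clusters the current minority set of size `Ns` into
#' `k = max(1, floor(Ns/3))` clusters and appends the `k` cluster centroids as
#' synthetic minority samples; the centroids and the original samples together
#' form the next iteration's input.  Iteration stops at the first state whose
#' size reaches `target` (overshoot is kept, not trimmed).  All original rows
#' are retained.
#'
#' @param minority Matrix or data frame of minority-class samples (at least 2
#'   rows).
#' @param target Desired minimum size (at least the current size; a smaller
#'   target is a warning and a no-op).
#' @param seed Integer seed (k-means++ seeding is randomized).
#' @return A tibble with a `provenance` column (`"original"` or `"centroid"`)
#'   followed by the feature columns.
#' @export
#' @examples
#' x <- matrix(rnorm(24), 12, 2, dimnames = list(NULL, c("a", "b")))
#' nrow(kmeans_oversample(x, target = 16))  # 12 -> 12 + floor(12/3) = 16
kmeans_oversample <- function(minority, target, seed = 1L) {
  x <- as_feature_matrix(minority)
  if (nrow(x) < 2) abort("cannot cluster a minority class with fewer than 2 rows")
  if (target < nrow(x)) {
    warn("target below current size; returning input unchanged")
    target <- nrow(x)
  }
  prov <- rep("original", nrow(x))
  with_seed(seed, {
    while (nrow(x) < target) {
      k <- max(1L, floor(nrow(x) / 3))
      cent <- cluster_centroids(x, k)
      x <- rbind(x, cent)
      prov <- c(prov, rep("centroid", k))
    }
  })
  out <- dplyr::bind_cols(tibble(provenance = prov), as_tibble(x))
  out
}

#' Undersample a majority class by k-medoids
#'
#' Runs PAM (partitioning around medoids) with `k = target` clusters and keeps
#' the `k` medoids.  Medoids are actual data points, so every retained row is
#' an exact row of the input — no synthetic majority samples are created.
#'
#' @param majority Matrix or data frame of majority-class samples.
#' @param target Number of rows to keep, in `[1, nrow(majority)]`.
#' @param seed Unused (PAM's BUILD + SWAP phases are deterministic); kept for
#'   API symmetry with [kmeans_oversample()].
#' @return A tibble of `target` rows, each an exact input row.
#' @export
kmedoids_undersample <- function(majority, target, seed = 1L) {
  x <- as_feature_matrix(majority)
  if (target < 1 || target > nrow(x)) {
    abort(sprintf("target must be in [1, %d]", nrow(x)))
  }
  if (target == nrow(x)) return(as_tibble(x))
  fit <- cluster::pam(x, k = target, keep.diss = FALSE, keep.data = FALSE)
  as_tibble(x[fit$id.med, , drop = FALSE])
}

#' Rebalance a binary training set
#'
#' The minority class is oversampled by [kmeans_oversample()] until its size
#' reaches at least 2/3 of the original majority size `M` (target
#' `ceiling(2M/3)`; the `floor(Ns/3)`-centroid recursion may overshoot, and
#' the overshoot is kept).  The majority class is then undersampled by
#' [kmedoids_undersample()].  The undersampling target is controlled by
#' `undersample_target`:
#' \describe{
#'   \item{`"balanced"` (default)}{down to the final oversampled minority size,
#'     giving a balanced training set;}
#'   \item{`"ratio_3_2"`}{down to `ceiling(1.5 x minority)` (capped at `M`),
#'     a 3:2 majority:minority ratio;}
#'   \item{`"none"`}{no undersampling.}
#' }
#'
#' @param data Data frame whose label column holds exactly two classes, with
#'   all other columns numeric features (values are used as given; scale
#'   before calling if features have incommensurate units).
#' @param label_col Name of the label column (default `"diagnosis"`).
#' @param seed Integer seed.
#' @param undersample_target See above.
#' @return A tibble of class `mci_rebalanced` with the label column, a
#'   `provenance` column (`"original"` / `"centroid"`), and the features.
#'   Attribute `sizes` records the original and final class sizes.
#' @export
#' @examples
#' fx <- make_fixture("imbalanced")
#' d <- dplyr::filter(fx$baseline, diagnosis %in% c("naMCI", "CN"))
#' d <- droplevels(d[, c("diagnosis", feature_names(fx$baseline)[1:5])])
#' reb <- rebalance(d)
#' attr(reb, "sizes")
rebalance <- function(data, label_col = "diagnosis", seed = 1L,
                      undersample_target = c("balanced", "ratio_3_2", "none")) {
  undersample_target <- match.arg(undersample_target)
  if (!label_col %in% names(data)) abort(paste0("no column '", label_col, "'"))
  y <- as_stable_factor(data[[label_col]])
  if (nlevels(y) != 2) {
    abort(paste0("rebalance needs a binary-labeled training set, got ",
                 nlevels(y), " class(es)"))
  }
  drop_cols <- c(label_col, intersect("provenance", names(data)))
  x <- as_feature_matrix(data[setdiff(names(data), drop_cols)])
  sizes <- table(y)
  min_lab <- names(sizes)[which.min(sizes)]
  maj_lab <- names(sizes)[which.max(sizes)]
  m_min <- as.integer(sizes[min_lab]); m_maj <- as.integer(sizes[maj_lab])
  if (m_min < 2) abort("minority class needs at least 2 samples")

  seeds <- spawn_seeds(seed, 2)
  threshold <- ceiling(2 / 3 * m_maj)
  minority <- kmeans_oversample(x[y == min_lab, , drop = FALSE],
                                target = max(threshold, m_min), seed = seeds[1])
  n_min_final <- nrow(minority)

  maj_target <- switch(undersample_target,
    balanced = min(n_min_final, m_maj),
    ratio_3_2 = min(ceiling(1.5 * n_min_final), m_maj),
    none = m_maj
  )
  majority <- kmedoids_undersample(x[y == maj_lab, , drop = FALSE],
                                   target = maj_target, seed = seeds[2])

  out <- dplyr::bind_rows(
    dplyr::bind_cols(tibble(!!label_col := min_lab), minority),
    dplyr::bind_cols(tibble(!!label_col := maj_lab, provenance = "original"), majority)
  )
  out[[label_col]] <- factor(out[[label_col]], levels = levels(y))
  attr(out, "sizes") <- c(
    minority_original = m_min, majority_original = m_maj,
    minority_final = n_min_final, majority_final = nrow(majority)
  )
  class(out) <- c("mci_rebalanced", class(out))
  out
}
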
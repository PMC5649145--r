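# Synthetic two-timepoint, three-group cohorts with planted group effects.
#
# Latent model per subject i, feature j (standardized scale):
#   baseline  z1_ij = delta_{g(i),j} + sd_noise * u1_ij
#   wave-2    z2_ij = delta_{g(i),j} + slope_{g(i),j} + sd_noise * u2_ij
# with u2 = rho * u1 + sqrt(1 - rho^2) * u' (within-subject correlation rho),
# and u carrying an optional within-family equicorrelation block.  Observed
# values are an affine family transform mu_f + sigma_f * z, giving realistic
# mixed units (mm, mm^3) so that 0-1 min-max scaling downstream is non-trivial.

family_scales <- function() {
  tibble(
    family = c("sulcal", "thickness", "gm_volume", "subcortical", "wmh"),
    mu = c(2.2, 2.5, 11000, 4200, 1500),
    sigma = c(0.45, 0.16, 1400, 520, 600)
  )
}

# Split n_features across the five families proportionally to the reference
# 12/68/68/14/16 layout (largest-remainder apportionment; exact at 178).
family_split <- function(n_features) {
  ref <- feature_families()
  quota <- n_features * ref$expected_count / sum(ref$expected_count)
  base <- floor(quota)
  rem <- n_features - sum(base)
  if (rem > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  setNames(as.integer(base), ref$family)
}

#' Default planted group effects
#'
#' A realistic default effect pattern for the cohort generator: amnestic MCI
#' (aMCI) shows moderate atrophy (negative shifts) concentrated on
#' medial-temporal-like subcortical volumes and a few temporal/frontal
#' thickness features, with continuing decline over the 2-year follow-up;
#' non-amnestic MCI (naMCI) shows smaller shifts scattered across all feature
#' families; cognitively normal subjects carry no effect.
#'
#' @param n_features Total feature count the effects index into.
#' @param d_amci,d_namci Cross-sectional mean shifts in within-group SD units
#'   (Cohen's d; negative = atrophy).
#' @param slope_amci,slope_namci Additional change at wave-2, in SD units per
#'   2 years.
#' @return A tibble with columns `feature` (index), `group`, `d`, `slope_d`.
#' @export
default_planted_effects <- function(n_features = 178, d_amci = -0.8, d_namci = -0.5,
                                    slope_amci = -0.4, slope_namci = -0.3) {
  counts <- family_split(n_features)
  start <- cumsum(c(1, counts[-length(counts)]))
  names(start) <- names(counts)
  take <- function(fam, k) start[[fam]] + seq_len(min(k, counts[[fam]])) - 1
  amci <- c(take("subcortical", 4), take("thickness", 4))
  namci <- unlist(lapply(names(counts), function(f) {
    idx <- take(f, 2)
    idx + counts[[f]] - length(idx)  # last features of each family: disjoint from aMCI's
  }))
  dplyr::bind_rows(
    tibble(feature = as.integer(amci), group = "aMCI", d = d_amci, slope_d = slope_amci),
    tibble(feature = as.integer(namci), group = "naMCI", d = d_namci, slope_d = slope_namci)
  )
}

#' Simulation configuration for synthetic cohorts
#'
#' Defaults follow the study conditions: wave-2 group sizes 115 CN / 42 aMCI /
#' 27 naMCI, 178 features in the five-family layout, within-subject
#' test-retest correlation 0.8 between timepoints, and a within-family
#' equicorrelation of 0.3 standing in for the (unknown) anatomical covariance
#' of real morphometrics.
#'
#' @param n_cn,n_amci,n_namci Group sizes (each at least 2).
#' @param n_features Total feature count (split across families as in
#'   [feature_families()]).
#' @param planted Data frame of planted effects with columns `feature`
#'   (index), `group` (`"aMCI"`, `"naMCI"` or `"CN"`), `d` (cross-sectional
#'   shift, Cohen's d units) and `slope_d` (additional wave-2 shift, SD units
#'   per 2 years); `NULL` for a null cohort.  Defaults to
#'   [default_planted_effects()].
#' @param within_subject_corr Correlation of a subject's latent noise between
#'   the two timepoints; in `[0, 1)`.
#' @param within_family_corr Equicorrelation of features within a family.
#' @param noise_sd Latent noise SD (1 by convention, so `d` is scale-free).
#' @param seed Integer seed; identical configs generate bit-identical cohorts.
#' @return A list of class `mci_sim_config`.
#' @export
simulation_config <- function(n_cn = 115, n_amci = 42, n_namci = 27,
                              n_features = 178,
                              planted = default_planted_effects(n_features),
                              within_subject_corr = 0.8,
                              within_family_corr = 0.3,
                              noise_sd = 1, seed = 1L) {
  if (any(c(n_cn, n_amci, n_namci) < 2)) abort("each group needs at least 2 subjects")
  if (abs(within_subject_corr) >= 1) abort("|within_subject_corr| must be < 1")
  if (within_family_corr < 0 || within_family_corr >= 1) {
    abort("within_family_corr must be in [0, 1)")
  }
  if (!is.null(planted)) {
    planted <- as_tibble(planted)
    need <- c("feature", "group", "d", "slope_d")
    miss <- setdiff(need, names(planted))
    if (length(miss) > 0) abort(paste0("planted is missing column(s): ", paste(miss, collapse = ", ")))
    if (any(planted$feature < 1 | planted$feature > n_features)) {
      abort("planted feature index out of range")
    }
    if (anyDuplicated(planted[c("feature", "group")])) {
      abort("planted indices must be unique per (feature, group)")
    }
    bad <- setdiff(unique(planted$group), diagnosis_levels())
    if (length(bad) > 0) abort(paste0("unknown planted group(s): ", paste(bad, collapse = ", ")))
  }
  structure(list(
    n_cn = as.integer(n_cn), n_amci = as.integer(n_amci), n_namci = as.integer(n_namci),
    n_features = as.integer(n_features), planted = planted,
    within_subject_corr = within_subject_corr,
    within_family_corr = within_family_corr,
    noise_sd = noise_sd, seed = as.integer(seed)
  ), class = "mci_sim_config")
}

# One draw of the family-correlated latent noise matrix (n x p, unit variance).
draw_latent <- function(n, fam, r) {
  p <- length(fam)
  e <- matrix(rnorm(n * p), n, p)
  if (r > 0) {
    for (f in unique(fam)) {
      cols <- which(fam == f)
      g <- rnorm(n)
      e[, cols] <- sqrt(r) * g + sqrt(1 - r) * e[, cols]
    }
  }
  e
}

#' Generate a synthetic two-timepoint cohort
#'
#' Draws baseline and wave-2 feature tables under the latent model described
#' in [simulation_config()], with the configured group effects planted on the
#' standardized scale and mapped through per-family affine transforms to
#' realistic units.
#'
#' @param config A [simulation_config()].
#' @return A list with elements `baseline` and `wave2` (feature tables that
#'   pass [validate_schema()] when `n_features` matches the standard layout)
#'   and `truth` (tibble of planted effects with feature names).
#' @export
#' @examples
#' cohort <- generate_cohort(simulation_config(n_cn = 10, n_amci = 5, n_namci = 5,
#'                                             n_features = 20, planted = NULL))
#' dim(cohort$baseline)
generate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "mci_sim_config"))
  counts <- family_split(config$n_features)
  fam <- rep(names(counts), counts)
  within_fam_idx <- unlist(lapply(counts, seq_len))
  fname <- paste0(fam, "__f", sprintf("%02d", within_fam_idx))
  sc <- family_scales()
  mu <- sc$mu[match(fam, sc$family)]
  sigma <- sc$sigma[match(fam, sc$family)]

  groups <- rep(c("CN", "aMCI", "naMCI"), c(config$n_cn, config$n_amci, config$n_namci))
  n <- length(groups)
  ids <- sprintf("S%04d", seq_len(n))

  delta <- matrix(0, n, config$n_features)
  slope <- matrix(0, n, config$n_features)
  if (!is.null(config$planted)) {
    for (k in seq_len(nrow(config$planted))) {
      rows <- groups == config$planted$group[k]
      j <- config$planted$feature[k]
      delta[rows, j] <- delta[rows, j] + config$planted$d[k]
      slope[rows, j] <- slope[rows, j] + config$planted$slope_d[k]
    }
  }

  rho <- config$within_subject_corr
  out <- with_seed(config$seed, {
    u1 <- draw_latent(n, fam, config$within_family_corr)
    uf <- draw_latent(n, fam, config$within_family_corr)
    u2 <- rho * u1 + sqrt(1 - rho^2) * uf
    z1 <- delta + config$noise_sd * u1
    z2 <- delta + slope + config$noise_sd * u2
    x1 <- sweep(sweep(z1, 2, sigma, `*`), 2, mu, `+`)
    x2 <- sweep(sweep(z2, 2, sigma, `*`), 2, mu, `+`)
    colnames(x1) <- colnames(x2) <- fname
    list(x1 = x1, x2 = x2)
  })

  truth <- if (is.null(config$planted)) {
    tibble(feature = integer(), feature_name = character(),
           group = character(), d = double(), slope_d = double())
  } else {
    dplyr::mutate(config$planted, feature_name = fname[.data$feature],
                  .after = "feature")
  }

  list(
    baseline = feature_table(out$x1, ids, groups, "baseline"),
    wave2 = feature_table(out$x2, ids, groups, "wave2"),
    truth = truth
  )
}

#' Bundled deterministic fixtures
#'
#' Small known-truth cohorts used throughout the test suite:
#' \describe{
#'   \item{`"separable"`}{90 subjects (40 CN / 30 aMCI / 20 naMCI), 150
#'     features, 5 planted features (indices 1-5) at |d| = 2.5 with opposite
#'     signs for aMCI (-2.5) and naMCI (+2.5), so every pairwise group
#'     contrast is strongly separated on the same 5 features.}
#'   \item{`"null"`}{80 subjects (40 / 25 / 15), 60 features, no planted
#'     effects.}
#'   \item{`"imbalanced"`}{The study's wave-2 class sizes (115 CN / 42 aMCI /
#'     27 naMCI; minority:majority 27:115), 60 features, no planted effects.}
#' }
#' Each fixture uses a fixed internal seed and is bit-reproducible.
#'
#' @param name One of `"separable"`, `"null"`, `"imbalanced"`.
#' @return As [generate_cohort()]: list of `baseline`, `wave2`, `truth`.
#' @export
#' @examples
#' fx <- make_fixture("null")
#' nrow(fx$baseline)
make_fixture <- function(name) {
  cfg <- switch(name,
    separable = simulation_config(
      n_cn = 40, n_amci = 30, n_namci = 20, n_features = 150,
      planted = dplyr::bind_rows(
        tibble(feature = 1:5, group = "aMCI", d = -2.5, slope_d = 0),
        tibble(feature = 1:5, group = "naMCI", d = 2.5, slope_d = 0)
      ),
      seed = 4242L
    ),
    null = simulation_config(
      n_cn = 40, n_amci = 25, n_namci = 15, n_features = 60,
      planted = NULL, seed = 77L
    ),
    imbalanced = simulation_config(
      n_cn = 115, n_amci = 42, n_namci = 27, n_features = 60,
      planted = NULL, seed = 99L
    ),
    abort(paste0("unknown fixture name: '", name,
                 "' (known: separable, null, imbalanced)"))
  )
  generate_cohort(cfg)
}
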
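# Internal helpers: seeding, RNG hygiene, matrix extraction.

# Evaluate `code` under `seed`, restoring the caller's RNG state afterwards.
# The generator kind is pinned so results do not depend on the calling
# session's RNGkind() (set.seed() alone would inherit it).
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  suppressWarnings(set.seed(seed, kind = "Mersenne-Twister",
                            normal.kind = "Inversion", sample.kind = "Rejection"))
  force(code)
}

# Derive `n` independent child seeds from a master seed.  Children are drawn
# from the seeded stream so that seeds for unit i do not depend on how many
# units follow it.
spawn_seeds <- function(seed, n) {
  with_seed(seed, sample.int(2147483646L, n))
}

# Coerce a features-only data frame / matrix to a double matrix.
as_feature_matrix <- function(x) {
  if (is.matrix(x)) {
    storage.mode(x) <- "double"
    return(x)
  }
  if (is.data.frame(x)) {
    bad <- names(x)[!vapply(x, is.numeric, logical(1))]
    if (length(bad) > 0) {
      abort(paste0("non-numeric feature column(s): ", paste(bad, collapse = ", ")))
    }
    return(as.matrix(x))
  }
  abort("expected a matrix or data frame of feature values")
}

# Factor preserving the caller's level order; bare character/other input gets
# locale-independent (radix/byte) level ordering so that results never depend
# on the session's LC_COLLATE.
as_stable_factor <- function(y) {
  if (is.factor(y)) return(droplevels(y))
  factor(as.character(y),
         levels = sort(unique(as.character(y)), method = "radix"))
}

# Two-level factor with `positive` as the second level.
as_binary_factor <- function(y, positive = NULL) {
  y <- as_stable_factor(y)
  lev <- levels(y)
  if (length(lev) != 2) {
    abort(paste0("expected exactly 2 classes, got ", length(lev), ": ",
                 paste(lev, collapse = ", ")))
  }
  if (!is.null(positive)) {
    if (!positive %in% lev) abort(paste0("positive class '", positive, "' not present"))
    y <- factor(y, levels = c(setdiff(lev, positive), positive))
  }
  y
}
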
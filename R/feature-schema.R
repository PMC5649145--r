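#' Morphometric feature families
#'
#' The cross-sectional feature layout groups the 178 MRI-derived measurements
#' into five families: 12 sulcal measures (sulcal widths and the global sulcal
#' index, per hemisphere), 68 regional cortical thickness measures, 68 regional
#' cortical gray-matter volumes, 14 subcortical volumes, and 16 regional
#' white-matter-hyperintensity (WMH) volumes.
#'
#' @return A tibble with columns `family` and `expected_count`; the counts sum
#'   to 178.
#' @export
#' @examples
#' feature_families()
feature_families <- function() {
  tibble(
    family = c("sulcal", "thickness", "gm_volume", "subcortical", "wmh"),
    expected_count = c(12L, 68L, 68L, 14L, 16L)
  )
}

#' Admissible diagnosis labels
#'
#' @return Character vector `c("CN", "aMCI", "naMCI")`: cognitively normal,
#'   amnestic MCI, non-amnestic MCI.
#' @export
diagnosis_levels <- function() c("CN", "aMCI", "naMCI")

#' Admissible timepoint tags
#' @return Character vector `c("baseline", "wave2", "longitudinal")`.
#' @export
timepoint_levels <- function() c("baseline", "wave2", "longitudinal")

meta_columns <- function() c("subject_id", "diagnosis", "timepoint")

#' Construct a feature table
#'
#' A feature table is a tibble with three metadata columns — `subject_id`,
#' `diagnosis` (one of [diagnosis_levels()]) and `timepoint` (one of
#' [timepoint_levels()]) — followed by one numeric column per morphometric
#' feature.  Feature names are family-prefixed, e.g. `thickness__f01`, so that
#' the layout can be validated from column names alone.
#'
#' @param values Numeric matrix or data frame, subjects in rows, features in
#'   columns (column names required).
#' @param subject_id Character vector of unique subject identifiers.
#' @param diagnosis Per-subject diagnosis label.
#' @param timepoint Single timepoint tag for the whole table.
#' @return A tibble of class `mci_feature_table`.
#' @export
feature_table <- function(values, subject_id, diagnosis, timepoint) {
  values <- as_feature_matrix(values)
  if (is.null(colnames(values))) abort("feature columns must be named")
  if (anyDuplicated(colnames(values))) abort("duplicate feature names")
  if (anyDuplicated(subject_id)) abort("duplicate subject_ids")
  if (nrow(values) != length(subject_id) || length(subject_id) != length(diagnosis)) {
    abort("values, subject_id and diagnosis dimensions do not match")
  }
  diagnosis <- as.character(diagnosis)
  bad <- setdiff(unique(diagnosis), diagnosis_levels())
  if (length(bad) > 0) {
    abort(paste0("unknown diagnosis label(s): ", paste(bad, collapse = ", ")))
  }
  if (length(timepoint) != 1 || !timepoint %in% timepoint_levels()) {
    abort(paste0("timepoint must be one of: ", paste(timepoint_levels(), collapse = ", ")))
  }
  out <- dplyr::bind_cols(
    tibble(
      subject_id = as.character(subject_id),
      diagnosis = factor(diagnosis, levels = diagnosis_levels()),
      timepoint = timepoint
    ),
    as_tibble(values)
  )
  class(out) <- c("mci_feature_table", class(out))
  out
}

#' Feature column names of a feature table
#' @param table A feature table (see [feature_table()]).
#' @return Character vector of feature names (metadata columns excluded).
#' @export
feature_names <- function(table) setdiff(names(table), meta_columns())

#' Extract the subjects-by-features value matrix
#' @inheritParams feature_names
#' @return Numeric matrix with subject ids as row names.
#' @export
feature_values <- function(table) {
  m <- as_feature_matrix(table[feature_names(table)])
  rownames(m) <- table$subject_id
  m
}

assert_feature_table <- function(table) {
  if (!is.data.frame(table)) abort("expected a feature table (data frame)")
  miss <- setdiff(meta_columns(), names(table))
  if (length(miss) > 0) {
    abort(paste0("missing required column(s): ", paste(miss, collapse = ", ")))
  }
  if (nrow(table) == 0 || length(feature_names(table)) == 0) {
    abort("empty feature table: no subjects or no feature columns")
  }
  invisible(table)
}

feature_family_of <- function(feature_names) {
  has_prefix <- grepl("__", feature_names, fixed = TRUE)
  if (any(!has_prefix)) {
    abort(paste0(
      "feature name(s) without a family prefix ('<family>__<name>'): ",
      paste(feature_names[!has_prefix], collapse = ", ")
    ))
  }
  sub("__.*$", "", feature_names)
}

#' Validate the cross-sectional feature layout
#'
#' Checks that each feature family holds exactly its expected number of
#' columns (12 sulcal, 68 thickness, 68 gray-matter volume, 14 subcortical,
#' 16 WMH at the defaults, 178 in total).  Validation is a pure function of
#' the column names: values are never inspected.
#'
#' @inheritParams feature_names
#' @param families Expected layout, as returned by [feature_families()].
#' @return An object of class `mci_schema_report`: a list with elements `ok`
#'   (logical), `total` (observed feature count), `expected_total`, and
#'   `counts` (a tibble with per-family `expected`, `observed` and `ok`).
#' @export
#' @examples
#' cohort <- generate_cohort(simulation_config(n_cn = 4, n_amci = 3, n_namci = 3,
#'                                             n_features = 178, planted = NULL))
#' validate_schema(cohort$baseline)
validate_schema <- function(table, families = feature_families()) {
  assert_feature_table(table)
  fam <- feature_family_of(feature_names(table))
  observed <- table(factor(fam, levels = union(families$family, unique(fam))))
  counts <- tibble(family = names(observed), observed = as.integer(observed)) %>%
    dplyr::left_join(families, by = "family") %>%
    dplyr::mutate(
      expected = ifelse(is.na(.data$expected_count), 0L, .data$expected_count),
      ok = .data$observed == .data$expected
    ) %>%
    dplyr::select("family", "expected", "observed", "ok")
  # families expected but absent entirely
  absent <- setdiff(families$family, counts$family)
  if (length(absent) > 0) {
    counts <- dplyr::bind_rows(counts, tibble(
      family = absent,
      expected = families$expected_count[match(absent, families$family)],
      observed = 0L, ok = FALSE
    ))
  }
  counts <- counts[match(union(families$family, counts$family), counts$family), ]
  out <- list(
    ok = all(counts$ok),
    total = length(feature_names(table)),
    expected_total = sum(families$expected_count),
    counts = counts
  )
  class(out) <- "mci_schema_report"
  out
}

#' @export
print.mci_schema_report <- function(x, ...) {
  cat("Feature schema:", if (x$ok) "OK" else "INVALID",
      sprintf("(%d features, expected %d)\n", x$total, x$expected_total))
  print(x$counts)
  invisible(x)
}

#' Build the longitudinal feature set from two timepoints
#'
#' For every feature `f` measured at baseline and at the 2-year follow-up
#' (wave-2), the longitudinal set contains `mean_f = (baseline + wave2) / 2`
#' and `change_f = wave2 - baseline`, doubling the feature count (178 becomes
#' 356 at the standard layout).  With `change = wave2 - baseline`, atrophy
#' appears as negative thickness/volume change.  Labels are taken from wave-2,
#' the diagnostic ground truth of the study design.
#'
#' @param baseline,wave2 Feature tables sharing the same subjects and features.
#' @return A feature table with `timepoint = "longitudinal"` and twice the
#'   input feature count.
#' @export
#' @examples
#' fx <- make_fixture("separable")
#' long <- build_longitudinal(fx$baseline, fx$wave2)
#' ncol(long) - 3L  # 2 x 150
build_longitudinal <- function(baseline, wave2) {
  assert_feature_table(baseline)
  assert_feature_table(wave2)
  fb <- feature_names(baseline); fw <- feature_names(wave2)
  if (!setequal(fb, fw)) {
    d <- c(setdiff(fb, fw), setdiff(fw, fb))
    abort(paste0("feature mismatch between timepoints: ", paste(d, collapse = ", ")))
  }
  if (!setequal(baseline$subject_id, wave2$subject_id)) {
    d <- c(setdiff(baseline$subject_id, wave2$subject_id),
           setdiff(wave2$subject_id, baseline$subject_id))
    abort(paste0("subject mismatch between timepoints: ", paste(d, collapse = ", ")))
  }
  wave2 <- wave2[match(baseline$subject_id, wave2$subject_id), ]
  xb <- feature_values(baseline)
  xw <- feature_values(wave2)[, colnames(xb), drop = FALSE]
  means <- (xb + xw) / 2
  changes <- xw - xb
  colnames(means) <- paste0("mean_", colnames(xb))
  colnames(changes) <- paste0("change_", colnames(xb))
  feature_table(
    cbind(means, changes),
    subject_id = baseline$subject_id,
    diagnosis = as.character(wave2$diagnosis),
    timepoint = "longitudinal"
  )
}

#' Read and write feature-table CSV files
#'
#' The CSV dialect is UTF-8, comma-separated, with a header row
#' `subject_id, diagnosis, timepoint, <feature columns...>`.  Missing values
#' are not permitted: subjects with failed-QC scans are excluded upstream
#' rather than imputed.  The round trip `write_feature_csv()` then
#' [read_feature_csv()] is lossless.
#'
#' @param path Path to a CSV file.
#' @return For `read_feature_csv()`, a feature table; `write_feature_csv()`
#'   returns its input invisibly.
#' @export
read_feature_csv <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  miss <- setdiff(meta_columns(), names(raw))
  if (length(miss) > 0) {
    abort(paste0("missing required column(s): ", paste(miss, collapse = ", ")))
  }
  feats <- setdiff(names(raw), meta_columns())
  vals <- matrix(NA_real_, nrow(raw), length(feats), dimnames = list(NULL, feats))
  for (f in feats) {
    cell <- raw[[f]]
    parsed <- suppressWarnings(as.numeric(cell))
    bad <- which(is.na(parsed))
    if (length(bad) > 0) {
      abort(sprintf(
        "non-numeric or blank feature cell at row %d, column '%s' (value: '%s')",
        bad[1], f, ifelse(is.na(cell[bad[1]]), "", cell[bad[1]])
      ))
    }
    vals[, f] <- parsed
  }
  tp <- unique(raw$timepoint)
  if (length(tp) != 1) abort("timepoint column must hold a single value")
  feature_table(vals, raw$subject_id, raw$diagnosis, tp)
}

#' @param table A feature table to write.
#' @rdname read_feature_csv
#' @export
write_feature_csv <- function(table, path) {
  assert_feature_table(table)
  out <- as_tibble(table)
  out$diagnosis <- as.character(out$diagnosis)
  readr::write_csv(out, path, progress = FALSE)
  invisible(table)
}
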
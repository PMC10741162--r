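#' Construct a feature table
#'
#' The central container of the package: an LC-MS feature intensity matrix
#' (features in rows, injections in columns) together with feature metadata
#' (m/z, retention time, ionization mode) and sample metadata (injection
#' order, QC/study kind, pig, wound type, treatment, biopsy day).
#'
#' @param intensities Numeric matrix, features x injections. Missing
#'   measurements are `NA`; all non-missing values must be >= 0.
#' @param features `data.frame` with columns `feature_id`, `mz`, `rt`,
#'   `mode`; one row per matrix row. `mz` must lie in the instrument scan
#'   range (50-1000 Da) and `rt` within the 10-minute gradient.
#' @param samples `data.frame` with columns `sample_id`, `injection_order`,
#'   `kind` (`"QC"` or `"study"`), and for study samples `pig_id`,
#'   `wound_type` (`"DPT"`/`"FT"`), `treatment` and `day`; one row per
#'   matrix column. QC samples must have the design columns `NA`.
#'
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(intensities, features, samples) {
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  rownames(features) <- NULL
  rownames(samples) <- NULL
  obj <- structure(
    list(intensities = intensities, features = features, samples = samples),
    class = "feature_table"
  )
  validate_feature_table(obj)
  dimnames(obj$intensities) <- list(features$feature_id, samples$sample_id)
  obj
}

MZ_RANGE <- c(50, 1000)
RT_RANGE <- c(0, 10)
DAY_LEVELS <- c(7L, 14L, 21L, 28L, 60L)
TREATMENT_LEVELS <- c("AFSG", "FBD", "CS", "STSG_sandwich")

validate_feature_table <- function(x) {
  stopifnot(is.matrix(x$intensities))
  f <- x$features
  s <- x$samples
  need_f <- c("feature_id", "mz", "rt", "mode")
  if (!all(need_f %in% names(f))) {
    stop("feature metadata must have columns: ", paste(need_f, collapse = ", "))
  }
  need_s <- c("sample_id", "injection_order", "kind")
  if (!all(need_s %in% names(s))) {
    stop("sample metadata must have columns: ", paste(need_s, collapse = ", "))
  }
  if (nrow(x$intensities) != nrow(f)) {
    stop("intensity row count (", nrow(x$intensities),
         ") != number of feature records (", nrow(f), ")")
  }
  if (ncol(x$intensities) != nrow(s)) {
    stop("intensity column count (", ncol(x$intensities),
         ") != number of sample records (", nrow(s), ")")
  }
  if (anyDuplicated(f$feature_id)) {
    stop("duplicate feature IDs: ",
         paste(unique(f$feature_id[duplicated(f$feature_id)]), collapse = ", "))
  }
  if (anyDuplicated(s$sample_id)) {
    stop("duplicate sample IDs: ",
         paste(unique(s$sample_id[duplicated(s$sample_id)]), collapse = ", "))
  }
  if (anyDuplicated(s$injection_order)) {
    stop("duplicate injection orders: ",
         paste(unique(s$injection_order[duplicated(s$injection_order)]),
               collapse = ", "))
  }
  if (any(s$injection_order < 1 | s$injection_order != round(s$injection_order))) {
    stop("injection orders must be unique positive integers")
  }
  bad_mz <- which(f$mz < MZ_RANGE[1] | f$mz > MZ_RANGE[2])
  if (length(bad_mz)) {
    stop("m/z outside scan range [50, 1000] for feature(s): ",
         paste(f$feature_id[bad_mz], collapse = ", "))
  }
  bad_rt <- which(f$rt < RT_RANGE[1] | f$rt > RT_RANGE[2])
  if (length(bad_rt)) {
    stop("retention time outside gradient [0, 10] min for feature(s): ",
         paste(f$feature_id[bad_rt], collapse = ", "))
  }
  if (!all(f$mode %in% c("pos", "neg"))) {
    stop("ionization mode must be 'pos' or 'neg'")
  }
  if (!all(s$kind %in% c("QC", "study"))) {
    stop("sample kind must be 'QC' or 'study'")
  }
  is_qc <- s$kind == "QC"
  design_cols <- intersect(c("pig_id", "wound_type", "treatment", "day"), names(s))
  for (col in design_cols) {
    if (any(!is.na(s[[col]][is_qc]))) {
      stop("QC samples must not carry design metadata (column '", col, "')")
    }
    if (any(is.na(s[[col]][!is_qc]))) {
      stop("study samples must have non-missing '", col, "'")
    }
  }
  if ("wound_type" %in% names(s) &&
      !all(s$wound_type[!is_qc] %in% c("DPT", "FT"))) {
    stop("wound_type must be 'DPT' or 'FT'")
  }
  if ("treatment" %in% names(s) &&
      !all(s$treatment[!is_qc] %in% TREATMENT_LEVELS)) {
    stop("treatment must be one of: ", paste(TREATMENT_LEVELS, collapse = ", "))
  }
  if ("day" %in% names(s) && !all(s$day[!is_qc] %in% DAY_LEVELS)) {
    stop("day must be one of: ", paste(DAY_LEVELS, collapse = ", "))
  }
  if (any(x$intensities < 0, na.rm = TRUE)) {
    stop("intensities must be nonnegative (or missing)")
  }
  invisible(x)
}

#' @export
print.feature_table <- function(x, ...) {
  n_qc <- sum(x$samples$kind == "QC")
  cat("feature_table: ", nrow(x$intensities), " features x ",
      ncol(x$intensities), " injections (", n_qc, " QC, ",
      ncol(x$intensities) - n_qc, " study)\n", sep = "")
  cat("  modes: ", paste(sprintf("%s=%d", names(table(x$features$mode)),
                                 table(x$features$mode)), collapse = ", "),
      "\n", sep = "")
  miss <- mean(is.na(x$intensities))
  cat(sprintf("  missing: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$intensities)

#' Subset a feature table
#'
#' @param x A `feature_table`.
#' @param i Feature index (integer, logical, or feature IDs).
#' @param j Sample index (integer, logical, or sample IDs).
#' @param ... Unused.
#' @return A `feature_table` restricted to the selected rows/columns.
#' @export
`[.feature_table` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$intensities))
  if (missing(j)) j <- seq_len(ncol(x$intensities))
  if (is.character(i)) i <- match(i, x$features$feature_id)
  if (is.character(j)) j <- match(j, x$samples$sample_id)
  feature_table(x$intensities[i, j, drop = FALSE],
                x$features[i, , drop = FALSE],
                x$samples[j, , drop = FALSE])
}

#' Study-sample selector
#'
#' Logical index over the columns of a feature table, optionally restricted
#' to one wound type, treatment arm, or biopsy day.
#'
#' @param x A `feature_table`.
#' @param wound_type,treatment,day Optional restrictions.
#' @return Logical vector over samples (QC columns are always `FALSE`).
#' @export
study_samples <- function(x, wound_type = NULL, treatment = NULL, day = NULL) {
  s <- x$samples
  keep <- s$kind == "study"
  if (!is.null(wound_type)) keep <- keep & !is.na(s$wound_type) & s$wound_type == wound_type
  if (!is.null(treatment)) keep <- keep & !is.na(s$treatment) & s$treatment == treatment
  if (!is.null(day)) keep <- keep & !is.na(s$day) & s$day == day
  keep
}
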
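#' Per-feature QC statistics
#'
#' For each feature, the fraction of pooled-QC injections in which it was
#' detected and the relative standard deviation (sample sd / mean x 100)
#' of its non-missing QC intensities. RSD is `NA` when fewer than two QC
#' values are available.
#'
#' @param x A [feature_table()] containing at least one QC sample.
#' @return data.frame with columns `feature_id`, `qc_presence`, `qc_rsd`.
#' @export
qc_stats <- function(x) {
  qc_idx <- x$samples$kind == "QC"
  if (!any(qc_idx)) stop("no QC samples in table; QC statistics undefined")
  qc <- x$intensities[, qc_idx, drop = FALSE]
  presence <- rowMeans(!is.na(qc))
  rsd <- apply(qc, 1, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2) return(NA_real_)
    100 * stats::sd(v) / mean(v)
  })
  data.frame(feature_id = x$features$feature_id,
             qc_presence = presence, qc_rsd = as.numeric(rsd),
             stringsAsFactors = FALSE)
}

#' QC presence filter
#'
#' Removes features detected in fewer than `min_fraction` of the QC
#' injections. A feature present in exactly the threshold fraction is
#' retained.
#'
#' @param x A [feature_table()].
#' @param min_fraction Minimum QC detection fraction (default 0.80).
#' @return Filtered `feature_table` (feature order preserved).
#' @export
qc_presence_filter <- function(x, min_fraction = 0.80) {
  stats <- qc_stats(x)
  keep <- stats$qc_presence >= min_fraction
  x[which(keep), ]
}

#' QC RSD filter
#'
#' Removes features whose QC relative standard deviation exceeds
#' `max_rsd_pct` (default 25%): only features measured precisely across the
#' pooled-QC injections are kept. A feature at exactly the threshold is
#' retained. The direction is configurable for auditing the opposite
#' convention.
#'
#' @param x A [feature_table()]; every feature must have >= 2 QC values
#'   (apply [qc_presence_filter()] first).
#' @param max_rsd_pct RSD threshold in percent.
#' @param direction `"remove_above"` (default, keep precise features) or
#'   `"remove_below"`.
#' @return Filtered `feature_table`.
#' @export
qc_rsd_filter <- function(x, max_rsd_pct = 25,
                          direction = c("remove_above", "remove_below")) {
  direction <- match.arg(direction)
  stats <- qc_stats(x)
  if (anyNA(stats$qc_rsd)) {
    stop("feature(s) with < 2 QC values reached the RSD filter: ",
         paste(stats$feature_id[is.na(stats$qc_rsd)], collapse = ", "),
         " (apply the presence filter first)")
  }
  keep <- if (direction == "remove_above") {
    stats$qc_rsd <= max_rsd_pct
  } else {
    stats$qc_rsd >= max_rsd_pct
  }
  x[which(keep), ]
}

#' QC-anchored LOESS drift correction
#'
#' Per feature, fits a locally weighted regression (degree 1, tricube
#' weights) of QC intensity on injection order, evaluates the fitted drift
#' trend at every injection, and rescales each measurement by
#' `reference / fitted`, where the reference is the median of the fitted
#' values at the QC positions. When fewer than `min_loess_qc` QC values are
#' available for a feature the fit falls back to an ordinary least-squares
#' line. Features whose fitted trend is nonpositive anywhere are dropped
#' with a warning.
#'
#' @param x A QC-filtered [feature_table()] with >= 4 QC samples.
#' @param span LOESS span (default 0.75).
#' @param min_loess_qc Minimum QC count for a LOESS fit (default 7);
#'   below this an OLS line is used.
#' @return Corrected `feature_table` with an attribute `n_dropped` giving
#'   the number of features removed for nonpositive fitted trends.
#' @export
loess_drift_correct <- function(x, span = 0.75, min_loess_qc = 7) {
  qc_idx <- which(x$samples$kind == "QC")
  if (length(qc_idx) < 4) {
    stop("LOESS drift correction needs >= 4 QC samples, found ",
         length(qc_idx))
  }
  ord <- x$samples$injection_order
  qc_ord <- ord[qc_idx]
  nf <- nrow(x$intensities)
  corrected <- x$intensities
  bad <- logical(nf)
  for (i in seq_len(nf)) {
    qv <- x$intensities[i, qc_idx]
    ok <- !is.na(qv)
    xs <- qc_ord[ok]
    ys <- qv[ok]
    if (length(ys) < 2) { bad[i] <- TRUE; next }
    fitted_all <- if (length(ys) >= min_loess_qc) {
      fit <- stats::loess(ys ~ xs, span = span, degree = 1,
                          family = "gaussian",
                          control = stats::loess.control(surface = "direct"))
      as.numeric(stats::predict(fit, newdata = data.frame(xs = ord)))
    } else {
      fit <- stats::lm(ys ~ xs)
      as.numeric(stats::predict(fit, newdata = data.frame(xs = ord)))
    }
    if (any(!is.finite(fitted_all)) || any(fitted_all <= 0)) {
      bad[i] <- TRUE
      next
    }
    reference <- stats::median(fitted_all[match(qc_ord, ord)])
    corrected[i, ] <- x$intensities[i, ] * reference / fitted_all
  }
  if (any(bad)) {
    warning(sum(bad), " feature(s) dropped: nonpositive or undefined ",
            "fitted QC trend")
  }
  out <- feature_table(corrected[!bad, , drop = FALSE],
                       x$features[!bad, , drop = FALSE], x$samples)
  attr(out, "n_dropped") <- sum(bad)
  out
}
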
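#' Per-feature two-way ANOVA scan (time x treatment)
#'
#' For every feature, fits a fixed-effects two-way ANOVA of log2 intensity
#' on biopsy day and treatment (with interaction) over the study samples of
#' one wound type, using Type-II sums of squares so that mild unbalance
#' from missing measurements does not contaminate the main effects. Rows
#' with missing intensity are dropped per feature; features with fewer than
#' 3 residual degrees of freedom receive missing p-values and are excluded
#' from multiplicity correction.
#'
#' @param x A normalized [feature_table()].
#' @param wound_type `"DPT"` or `"FT"`.
#' @return data.frame with columns `feature_id`, `p_time`, `p_treatment`,
#'   `p_interaction`, `q_time`, `q_treatment`.
#' @export
two_way_anova_scan <- function(x, wound_type) {
  keep <- study_samples(x, wound_type = wound_type)
  if (!any(keep)) stop("no study samples of wound type ", wound_type)
  s <- x$samples[keep, , drop = FALSE]
  day <- factor(s$day)
  treatment <- factor(s$treatment)
  if (nlevels(day) < 2) stop("factor 'time' has a single level")
  if (nlevels(treatment) < 2) stop("factor 'treatment' has a single level")
  y_all <- log2(x$intensities[, keep, drop = FALSE])

  nf <- nrow(y_all)
  p_time <- p_treat <- p_int <- rep(NA_real_, nf)
  for (i in seq_len(nf)) {
    res <- anova_type2(y_all[i, ], day, treatment)
    if (!is.null(res)) {
      p_time[i] <- res["time"]
      p_treat[i] <- res["treatment"]
      p_int[i] <- res["interaction"]
    }
  }
  data.frame(feature_id = x$features$feature_id,
             p_time = p_time, p_treatment = p_treat, p_interaction = p_int,
             q_time = bh_adjust(p_time), q_treatment = bh_adjust(p_treat),
             stringsAsFactors = FALSE)
}

# Type-II two-way ANOVA via nested least-squares fits:
#   SS(A|B) = RSS(B) - RSS(A+B); SS(AB) = RSS(A+B) - RSS(A*B).
# Returns named p-value vector, or NULL when the fit is degenerate.
anova_type2 <- function(y, a, b) {
  ok <- !is.na(y)
  y <- y[ok]; a <- droplevels(a[ok]); b <- droplevels(b[ok])
  if (length(y) < 4 || nlevels(a) < 2 || nlevels(b) < 2) return(NULL)
  rss <- function(form) {
    f <- stats::lm.fit(stats::model.matrix(form), y)
    c(sum(f$residuals^2), length(y) - f$rank)
  }
  fa <- rss(~a); fb <- rss(~b); fab <- rss(~a + b); ffull <- rss(~a * b)
  df_res <- ffull[2]
  if (df_res < 3) return(NULL)
  mse <- ffull[1] / df_res
  ss <- c(time = fb[1] - fab[1], treatment = fa[1] - fab[1],
          interaction = fab[1] - ffull[1])
  df <- c(time = fb[2] - fab[2], treatment = fa[2] - fab[2],
          interaction = fab[2] - ffull[2])
  p <- rep(NA_real_, 3)
  names(p) <- names(ss)
  for (k in seq_along(ss)) {
    if (df[k] < 1) next
    if (mse == 0) {
      # saturated cells: zero residual variance; an effect either exists
      # exactly (p -> 0) or not at all (F = 0 -> p = 1)
      p[k] <- if (ss[k] <= 1e-12) 1 else 0
    } else {
      fstat <- (ss[k] / df[k]) / mse
      p[k] <- stats::pf(fstat, df[k], df_res, lower.tail = FALSE)
    }
  }
  p
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment with monotonicity
#' enforcement. Missing entries are passed through as missing and do not
#' count toward the family size.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NA allowed).
#' @return Vector of q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' Per-day treatment t-test and fold change
#'
#' Two-sided pooled-variance (Student's) t-test on log2 intensities between
#' two treatment arms at one biopsy day within one wound type. The fold
#' change is the ratio of arithmetic group means on the linear (normalized,
#' unlogged) scale, group A over group B. Bonferroni correction uses the
#' number of features actually tested for this contrast as the family size.
#'
#' @param x A normalized [feature_table()].
#' @param wound_type `"DPT"` or `"FT"`.
#' @param day Biopsy day.
#' @param group_a,group_b Treatment labels (A is the numerator of the fold
#'   change; conventionally the AFSG arm).
#' @return data.frame with columns `feature_id`, `p_raw`, `p_bonf`, `fc`.
#' @export
day_ttest <- function(x, wound_type, day, group_a = "AFSG", group_b = "FBD") {
  ia <- study_samples(x, wound_type = wound_type, treatment = group_a, day = day)
  ib <- study_samples(x, wound_type = wound_type, treatment = group_b, day = day)
  if (!any(ia) || !any(ib)) {
    stop("no samples for contrast ", group_a, " vs ", group_b,
         " at day ", day, " (", wound_type, ")")
  }
  nf <- nrow(x$intensities)
  p_raw <- fc <- rep(NA_real_, nf)
  for (i in seq_len(nf)) {
    va <- x$intensities[i, ia]; va <- va[!is.na(va)]
    vb <- x$intensities[i, ib]; vb <- vb[!is.na(vb)]
    if (length(va) < 2 || length(vb) < 2) next
    la <- log2(va); lb <- log2(vb)
    pooled_ss <- sum((la - mean(la))^2) + sum((lb - mean(lb))^2)
    if (pooled_ss == 0) {
      p_raw[i] <- if (isTRUE(all.equal(mean(la), mean(lb)))) 1 else 0
    } else {
      p_raw[i] <- stats::t.test(la, lb, var.equal = TRUE)$p.value
    }
    fc[i] <- mean(va) / mean(vb)
  }
  m <- sum(!is.na(p_raw))
  data.frame(feature_id = x$features$feature_id,
             p_raw = p_raw, p_bonf = pmin(1, p_raw * m), fc = fc,
             stringsAsFactors = FALSE)
}

#' Volcano responder classification
#'
#' A feature responds to treatment when its Bonferroni-adjusted t-test
#' p-value falls below `p_thresh` and its fold change exceeds `fc_thresh`
#' in either direction (`fc > fc_thresh` or `fc < 1/fc_thresh`).
#'
#' @param tt Output of [day_ttest()].
#' @param p_thresh Bonferroni-adjusted p threshold (default 0.1).
#' @param fc_thresh Absolute fold-change threshold (default 1.5).
#' @return data.frame of responders: `feature_id`, `p_bonf`, `fc`,
#'   `direction` (`"up_in_A"` / `"up_in_B"`).
#' @export
volcano_classify <- function(tt, p_thresh = 0.1, fc_thresh = 1.5) {
  hit <- !is.na(tt$p_bonf) & !is.na(tt$fc) & tt$p_bonf < p_thresh &
    (tt$fc > fc_thresh | tt$fc < 1 / fc_thresh)
  out <- tt[hit, c("feature_id", "p_bonf", "fc"), drop = FALSE]
  out$direction <- ifelse(out$fc > 1, "up_in_A", "up_in_B")
  rownames(out) <- NULL
  out
}

#' Select features of interest from an ANOVA scan
#'
#' Features significantly associated with time: BH q-value below
#' `q_thresh` and raw p-value below `p_thresh` for the time main effect.
#'
#' @param scan Output of [two_way_anova_scan()].
#' @param q_thresh BH threshold (default 0.05).
#' @param p_thresh Raw-p threshold (default 0.05).
#' @return Character vector of feature IDs.
#' @export
features_of_interest <- function(scan, q_thresh = 0.05, p_thresh = 0.05) {
  sel <- !is.na(scan$q_time) & scan$q_time < q_thresh &
    !is.na(scan$p_time) & scan$p_time < p_thresh
  scan$feature_id[sel]
}
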
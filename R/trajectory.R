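#' Z-score features across study samples
#'
#' Per feature, standardizes log2 intensity over the non-missing study
#' samples of one wound type using the population (divisor n) standard
#' deviation. Constant rows map to all-zero; missing entries stay missing.
#'
#' @param x A normalized [feature_table()], typically restricted to the
#'   features of interest.
#' @param wound_type `"DPT"` or `"FT"`.
#' @return Numeric matrix (feature x study sample) of z-scores, with the
#'   corresponding sample metadata as attribute `"samples"`.
#' @export
zscore_features <- function(x, wound_type) {
  keep <- study_samples(x, wound_type = wound_type)
  if (!any(keep)) stop("no study samples of wound type ", wound_type)
  y <- log2(x$intensities[, keep, drop = FALSE])
  z <- t(apply(y, 1, function(v) {
    ok <- !is.na(v)
    if (sum(ok) < 2) {
      stop("feature with fewer than 2 non-missing values cannot be z-scored")
    }
    mu <- mean(v[ok])
    sd_pop <- sqrt(mean((v[ok] - mu)^2))
    if (sd_pop == 0) {
      v[ok] <- 0
    } else {
      v[ok] <- (v[ok] - mu) / sd_pop
    }
    v
  }))
  rownames(z) <- x$features$feature_id
  attr(z, "samples") <- x$samples[keep, , drop = FALSE]
  z
}

#' Mean z-score profile per biopsy day
#'
#' @param z Z-score matrix from [zscore_features()].
#' @param samples Sample metadata aligned with the columns of `z`
#'   (defaults to the `"samples"` attribute of `z`).
#' @return Matrix (feature x day), day columns in ascending day order.
#' @export
day_profile <- function(z, samples = attr(z, "samples")) {
  if (is.null(samples)) stop("sample metadata required")
  days <- sort(unique(samples$day))
  prof <- vapply(days, function(d) {
    cols <- which(samples$day == d)
    if (!length(cols)) stop("day ", d, " has zero samples")
    rowMeans(z[, cols, drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(z)))
  prof <- matrix(prof, nrow = nrow(z),
                 dimnames = list(rownames(z), paste0("day", days)))
  attr(prof, "days") <- days
  prof
}

# Cosine distance (1 - cosine similarity) with missing z filled as 0 and
# zero vectors at distance 1 to everything (logged via warning upstream).
cosine_distance <- function(z) {
  z[is.na(z)] <- 0
  nrm <- sqrt(rowSums(z^2))
  zero <- nrm == 0
  nrm[zero] <- 1
  u <- z / nrm
  d <- 1 - u %*% t(u)
  if (any(zero)) {
    d[zero, ] <- 1
    d[, zero] <- 1
    diag(d) <- 0
    warning(sum(zero), " zero z-vector(s): cosine undefined, distance set to 1")
  }
  d[d < 0] <- 0
  stats::as.dist(d)
}

#' Agglomerative clustering of feature trajectories
#'
#' Complete-linkage hierarchical clustering on pairwise cosine distance of
#' feature z-vectors, cut to exactly `k` clusters. Missing z entries are
#' imputed as 0 (the z-scale mean) for the distance computation only.
#'
#' @param z Z-score matrix (feature x sample).
#' @param k Number of clusters (>= 2).
#' @return Integer cluster labels (1..k), named by feature.
#' @export
cluster_features <- function(z, k) {
  if (k < 2) stop("k must be >= 2")
  if (nrow(z) < k) stop("need at least k features")
  hc <- stats::hclust(cosine_distance(z), method = "complete")
  stats::cutree(hc, k = k)
}

# internal: silhouette / Calinski-Harabasz / Davies-Bouldin for one partition
partition_metrics <- function(z, labels, d_cos) {
  z[is.na(z)] <- 0
  k <- length(unique(labels))
  n <- nrow(z)
  sil <- if (k >= 2 && k <= n - 1) {
    mean(cluster::silhouette(labels, d_cos)[, "sil_width"])
  } else NA_real_
  mu <- colMeans(z)
  sizes <- as.vector(table(labels))
  cent <- rowsum(z, labels) / sizes
  between <- sum(sizes * rowSums(sweep(cent, 2, mu)^2))
  within <- sum((z - cent[labels, , drop = FALSE])^2)
  ch <- if (within == 0) Inf else (between / (k - 1)) / (within / (n - k))
  scatter <- vapply(seq_len(k), function(i) {
    pts <- z[labels == i, , drop = FALSE]
    mean(sqrt(rowSums(sweep(pts, 2, cent[i, ])^2)))
  }, numeric(1))
  cd <- as.matrix(stats::dist(cent))
  db <- mean(vapply(seq_len(k), function(i) {
    r <- (scatter[i] + scatter[-i]) / cd[i, -i]
    max(r[is.finite(r)], 0)
  }, numeric(1)))
  c(silhouette = sil, calinski_harabasz = ch, davies_bouldin = db)
}

#' Consensus selection of the cluster count
#'
#' Clusters the z-matrix at every candidate `k`, scores each partition with
#' the silhouette coefficient (on cosine distance), the Calinski-Harabasz
#' index and the Davies-Bouldin index (both on the z-vectors in Euclidean
#' geometry), ranks the candidates per metric (silhouette and CH: higher is
#' better; DB: lower is better) and picks the `k` with the smallest mean
#' rank, breaking ties toward the smaller `k`.
#'
#' @param z Z-score matrix.
#' @param k_range Candidate cluster counts (default 2..10).
#' @return List with `k` (chosen count), `metric_table` (data.frame of the
#'   three metrics plus mean rank per candidate), and `labels` (cluster
#'   labels at the chosen `k`).
#' @export
select_k_consensus <- function(z, k_range = 2:10) {
  if (nrow(z) < 4) stop("need at least 4 features for consensus selection")
  k_range <- k_range[k_range >= 2 & k_range <= nrow(z) - 1]
  if (!length(k_range)) stop("empty candidate k range")
  d_cos <- cosine_distance(z)
  hc <- stats::hclust(d_cos, method = "complete")
  metrics <- t(vapply(k_range, function(k) {
    partition_metrics(z, stats::cutree(hc, k = k), d_cos)
  }, numeric(3)))
  tab <- consensus_rank(data.frame(k = k_range, metrics))
  best <- tab$k[which.min(tab$mean_rank)]
  list(k = best, metric_table = tab,
       labels = stats::cutree(hc, k = best))
}

# rank-mean consensus over the three metrics; smallest mean rank wins,
# ties resolved toward smaller k by which.min on the ascending k order
consensus_rank <- function(tab) {
  tab$mean_rank <- (rank(-tab$silhouette, ties.method = "average") +
                    rank(-tab$calinski_harabasz, ties.method = "average") +
                    rank(tab$davies_bouldin, ties.method = "average")) / 3
  tab
}

#' Classify a centroid trajectory as U, D, or P
#'
#' U (upregulated monotone saturating): every day-to-day step is at least
#' `-tol` and the profile rises overall. D (downregulated monotone
#' saturating): every step is at most `+tol` and the profile falls overall.
#' Everything else is P (peaking): the peak day is the argmax; pure
#' valley-shaped centroids also map to P with the peak at the largest
#' absolute deviation.
#'
#' @param centroid Z-profile over days (length >= 3).
#' @param tol Monotonicity tolerance in z-units (default 0.2).
#' @return List with `letter` (`"U"`, `"D"` or `"P"`) and for P the
#'   `peak_day_index`.
#' @export
classify_pattern <- function(centroid, tol = 0.2) {
  if (length(centroid) < 3) stop("centroid must cover at least 3 days")
  steps <- diff(centroid)
  rise <- centroid[length(centroid)] - centroid[1]
  if (all(steps >= -tol) && rise > 0) {
    return(list(letter = "U", peak_day_index = NA_integer_))
  }
  if (all(steps <= tol) && rise < 0) {
    return(list(letter = "D", peak_day_index = NA_integer_))
  }
  pk <- which.max(centroid)
  if (pk == 1L || pk == length(centroid)) {
    # valley-shaped: peak taken at the largest absolute deviation
    pk <- which.max(abs(centroid))
  }
  list(letter = "P", peak_day_index = as.integer(pk))
}

#' Assign timing numerals to lettered clusters
#'
#' Within the U and D letters, numerals order the clusters by the first day
#' at which the centroid crosses zero (upward for U, downward for D);
#' earlier crossing gets the smaller numeral. Within P, the numeral encodes
#' the day-7 centroid value: above `+tau` is 1, within `±tau` is 2, below
#' `-tau` is 3. Numerals within a letter are then made consecutive starting
#' at 1 (preserving order); more than three clusters sharing a letter
#' continue 4, 5, ... with a warning.
#'
#' @param centroids Matrix (cluster x day) of mean z-profiles.
#' @param letters Character vector of letters from [classify_pattern()].
#' @param tau Day-7 threshold for P numbering (default 0.3).
#' @return Character vector of pattern labels (e.g. `"U1"`, `"P3"`).
#' @export
assign_timing_labels <- function(centroids, letters, tau = 0.3) {
  centroids <- as.matrix(centroids)
  n <- nrow(centroids)
  stopifnot(length(letters) == n)
  labels <- character(n)
  for (lt in unique(letters)) {
    idx <- which(letters == lt)
    key <- vapply(idx, function(i) {
      cen <- centroids[i, ]
      if (lt == "U") {
        cross <- which(cen >= 0)[1]
        if (is.na(cross)) cross <- length(cen) + 1
        cross
      } else if (lt == "D") {
        cross <- which(cen <= 0)[1]
        if (is.na(cross)) cross <- length(cen) + 1
        cross
      } else {
        if (cen[1] > tau) 1 else if (cen[1] >= -tau) 2 else 3
      }
    }, numeric(1))
    ord <- idx[order(key, idx)]
    numerals <- seq_along(ord)
    if (length(ord) > 3) {
      warning("more than 3 clusters share letter '", lt,
              "'; numerals continue past 3")
    }
    labels[ord] <- paste0(lt, numerals)
  }
  labels
}

#' Full trajectory analysis of the features of interest
#'
#' Z-scores the selected features, picks the cluster count by three-metric
#' consensus, computes per-day cluster centroids, and labels each cluster
#' with its U/D/P letter and timing numeral.
#'
#' @param x A normalized [feature_table()].
#' @param feature_ids Features of interest (from [features_of_interest()]).
#' @param wound_type `"DPT"` or `"FT"`.
#' @param k_range Candidate cluster counts.
#' @param tol,tau Pattern-rule thresholds (see [classify_pattern()] and
#'   [assign_timing_labels()]).
#' @return A `trajectory_result`: list with `feature_ids`, `labels`
#'   (cluster index per feature), `k`, `metric_table`, `centroids`
#'   (cluster x day), `pattern_labels` (per cluster), `pattern_by_feature`,
#'   and `days`.
#' @export
trajectory_analysis <- function(x, feature_ids, wound_type,
                                k_range = 2:10, tol = 0.2, tau = 0.3) {
  sub <- x[feature_ids, ]
  z <- zscore_features(sub, wound_type)
  sel <- select_k_consensus(z, k_range)
  prof <- day_profile(z)
  k <- sel$k
  centroids <- rowsum(prof, sel$labels) / as.vector(table(sel$labels))
  letters <- vapply(seq_len(k), function(i) {
    classify_pattern(centroids[i, ], tol = tol)$letter
  }, character(1))
  pattern <- assign_timing_labels(centroids, letters, tau = tau)
  structure(list(feature_ids = rownames(z), labels = sel$labels, k = k,
                 metric_table = sel$metric_table, centroids = centroids,
                 pattern_labels = pattern,
                 pattern_by_feature = pattern[sel$labels],
                 days = attr(prof, "days"), wound_type = wound_type),
            class = "trajectory_result")
}

#' @export
print.trajectory_result <- function(x, ...) {
  cat("trajectory_result (", x$wound_type, "): ", length(x$feature_ids),
      " features in k = ", x$k, " clusters\n", sep = "")
  tab <- table(factor(x$pattern_by_feature, levels = x$pattern_labels))
  for (p in names(tab)) {
    cat(sprintf("  %-3s %4d features\n", p, tab[[p]]))
  }
  invisible(x)
}

#' Plot trajectory cluster centroids
#'
#' One line per cluster centroid over the biopsy days, labeled with the
#' U/D/P pattern label (the style of the per-cluster trajectory panels).
#'
#' @param x A `trajectory_result`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.trajectory_result <- function(x, ...) {
  graphics::matplot(x$days, t(x$centroids), type = "b", pch = 16, lty = 1,
                    xlab = "day of healing", ylab = "mean z-score", ...)
  graphics::legend("topright", legend = x$pattern_labels,
                   col = seq_len(x$k), lty = 1, pch = 16, cex = 0.8)
  invisible(x)
}
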
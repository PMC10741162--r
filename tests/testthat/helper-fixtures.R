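# In-code fixtures shared across the suite.

# Hand-built tiny table: 3 features, 2 QC + 2 study samples.
tiny_table <- function() {
  intens <- matrix(c(100, 110, 105, 98,
                     200, NA, 210, 190,
                     50, 55, 52, 51),
                   nrow = 3, byrow = TRUE)
  features <- data.frame(
    feature_id = c("F1", "F2", "F3"),
    mz = c(157.0367, 175.1193, 300.5),
    rt = c(3.4, 5.0, 6.1),
    mode = c("neg", "pos", "pos"),
    stringsAsFactors = FALSE)
  samples <- data.frame(
    sample_id = c("QC1", "S1", "QC2", "S2"),
    injection_order = c(1L, 2L, 3L, 4L),
    kind = c("QC", "study", "QC", "study"),
    pig_id = c(NA, "pig01", NA, "pig01"),
    wound_type = c(NA, "DPT", NA, "DPT"),
    treatment = c(NA, "AFSG", NA, "FBD"),
    day = c(NA, 7L, NA, 7L),
    stringsAsFactors = FALSE)
  feature_table(intens, features, samples)
}

# QC-anchored table with arbitrary QC intensity vectors per feature and a
# configurable study column, for exercising the filters and LOESS stage.
qc_table <- function(qc_values, study_values = NULL,
                     qc_orders = NULL, study_orders = NULL) {
  qc_values <- as.matrix(qc_values)   # feature x QC
  nf <- nrow(qc_values)
  nqc <- ncol(qc_values)
  if (is.null(study_values)) study_values <- matrix(100, nf, 1)
  study_values <- as.matrix(study_values)
  ns <- ncol(study_values)
  if (is.null(qc_orders)) qc_orders <- seq_len(nqc)
  if (is.null(study_orders)) study_orders <- nqc + seq_len(ns)
  intens <- cbind(qc_values, study_values)
  features <- data.frame(
    feature_id = sprintf("F%d", seq_len(nf)),
    mz = seq(100, 200, length.out = nf), rt = rep(5, nf),
    mode = rep("pos", nf), stringsAsFactors = FALSE)
  samples <- data.frame(
    sample_id = c(sprintf("QC%d", seq_len(nqc)), sprintf("S%d", seq_len(ns))),
    injection_order = c(qc_orders, study_orders),
    kind = c(rep("QC", nqc), rep("study", ns)),
    pig_id = c(rep(NA, nqc), rep("pig01", ns)),
    wound_type = c(rep(NA, nqc), rep("DPT", ns)),
    treatment = c(rep(NA, nqc), rep("AFSG", ns)),
    day = c(rep(NA, nqc), rep(7L, ns)),
    stringsAsFactors = FALSE)
  feature_table(intens, features, samples)
}

# Balanced two-factor single-feature table for the ANOVA worked examples:
# one intensity per (day, treatment, replicate), already on a known scale.
anova_toy_table <- function(values, days, treatments) {
  n <- length(values)
  features <- data.frame(feature_id = "F1", mz = 150, rt = 5, mode = "pos",
                         stringsAsFactors = FALSE)
  samples <- data.frame(
    sample_id = sprintf("S%d", seq_len(n)),
    injection_order = seq_len(n), kind = "study",
    pig_id = "pig01", wound_type = "DPT",
    treatment = treatments, day = days, stringsAsFactors = FALSE)
  feature_table(matrix(2^values, nrow = 1), features, samples)
}

# Independent brute-force betweenness: enumerate all shortest paths.
brute_betweenness <- function(nodes, edges) {
  n <- length(nodes)
  adj <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  if (nrow(edges)) {
    for (r in seq_len(nrow(edges))) {
      adj[edges[r, 1], edges[r, 2]] <- TRUE
      adj[edges[r, 2], edges[r, 1]] <- TRUE
    }
  }
  # all shortest paths between s,t by BFS path enumeration
  paths_between <- function(s, t) {
    best <- Inf; found <- list()
    queue <- list(s)
    while (length(queue)) {
      path <- queue[[1]]; queue <- queue[-1]
      last <- path[length(path)]
      if (length(path) - 1 > best) next
      if (last == t) {
        if (length(path) - 1 < best) { best <- length(path) - 1; found <- list() }
        if (length(path) - 1 == best) found[[length(found) + 1]] <- path
        next
      }
      for (nb in nodes[adj[last, ]]) {
        if (!nb %in% path) queue[[length(queue) + 1]] <- c(path, nb)
      }
    }
    found
  }
  bet <- stats::setNames(rep(0, n), nodes)
  if (n >= 3) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        ps <- paths_between(nodes[i], nodes[j])
        if (!length(ps)) next
        for (p in ps) {
          inner <- p[-c(1, length(p))]
          for (v in inner) bet[v] <- bet[v] + 1 / length(ps)
        }
      }
    }
    bet <- bet / ((n - 1) * (n - 2) / 2)
    if (max(bet) > 0) bet <- bet / max(bet)
  }
  bet
}

# Exhaustive hypergeometric upper tail: enumerate all C(N, n) draws.
brute_hypergeom <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  in_pathway <- seq_len(K)
  mean(apply(draws, 2, function(d) sum(d %in% in_pathway) >= k))
}

# Classical cell-mean sums-of-squares oracle for BALANCED two-way layouts
# (where Type II equals the textbook decomposition), computed from explicit
# group means rather than regression fits.
oracle_anova_balanced <- function(y, a, b) {
  a <- factor(a); b <- factor(b)
  grand <- mean(y)
  na <- tapply(y, a, length); nb <- tapply(y, b, length)
  ma <- tapply(y, a, mean); mb <- tapply(y, b, mean)
  cell_mean <- tapply(y, list(a, b), mean)
  cell_n <- table(a, b)
  ss_a <- sum(na * (ma - grand)^2)
  ss_b <- sum(nb * (mb - grand)^2)
  ss_cells <- sum(cell_n * (cell_mean - grand)^2)
  ss_ab <- ss_cells - ss_a - ss_b
  ss_res <- sum((y - cell_mean[cbind(a, b)])^2)
  df_a <- nlevels(a) - 1; df_b <- nlevels(b) - 1
  df_ab <- df_a * df_b
  df_res <- length(y) - nlevels(a) * nlevels(b)
  mse <- ss_res / df_res
  list(ss_time = ss_a, ss_treat = ss_b, ss_int = ss_ab, ss_res = ss_res,
       p_time = stats::pf((ss_a / df_a) / mse, df_a, df_res, lower.tail = FALSE),
       p_treat = stats::pf((ss_b / df_b) / mse, df_b, df_res, lower.tail = FALSE),
       p_int = stats::pf((ss_ab / df_ab) / mse, df_ab, df_res,
                         lower.tail = FALSE))
}

# Adjusted Rand index between two labelings (direct pair-counting formula).
ari_index <- function(a, b) {
  tab <- table(a, b)
  sum_ij <- sum(choose(tab, 2))
  sum_i <- sum(choose(rowSums(tab), 2))
  sum_j <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  expected <- sum_i * sum_j / n2
  (sum_ij - expected) / ((sum_i + sum_j) / 2 - expected)
}
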
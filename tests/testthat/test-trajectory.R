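make_study_table <- function(log2_rows, wound_type = "DPT",
                             days = rep(c(7L, 14L, 21L, 28L, 60L), each = 2)) {
  nf <- nrow(log2_rows); ns <- ncol(log2_rows)
  stopifnot(length(days) == ns)
  features <- data.frame(feature_id = sprintf("F%02d", seq_len(nf)),
                         mz = seq(100, 900, length.out = nf), rt = 5,
                         mode = "pos")
  samples <- data.frame(
    sample_id = sprintf("S%d", seq_len(ns)), injection_order = seq_len(ns),
    kind = "study", pig_id = "pig01", wound_type = wound_type,
    treatment = "AFSG", day = days)
  feature_table(2^log2_rows, features, samples)
}

test_that("z-scoring standardizes with the population sd", {
  tab <- make_study_table(rbind(c(10, 20, 30, 20, 20),
                                c(5, 5, 5, 5, 5)),
                          days = c(7L, 14L, 21L, 28L, 60L))
  z <- zscore_features(tab, "DPT")
  expect_equal(unname(z[1, ]),
               c(-1.5811, 0, 1.5811, 0, 0), tolerance = 1e-4)
  expect_equal(unname(z[2, ]), rep(0, 5))
  # every non-constant row has mean 0 and population sd 1
  expect_equal(mean(z[1, ]), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(z[1, ]^2)), 1, tolerance = 1e-12)
  # missing entries stay missing
  tab2 <- make_study_table(rbind(c(10, 20, 30, NA, 20)),
                           days = c(7L, 14L, 21L, 28L, 60L))
  z2 <- zscore_features(tab2, "DPT")
  expect_true(is.na(z2[1, 4]))
  # too few values is an error
  tab3 <- make_study_table(rbind(c(10, NA, NA, NA, NA)),
                           days = c(7L, 14L, 21L, 28L, 60L))
  expect_error(zscore_features(tab3, "DPT"), "fewer than 2")
})

test_that("day profiles average z per day in ascending day order", {
  tab <- make_study_table(rbind(rep(3, 10), 1:10))
  z <- zscore_features(tab, "DPT")
  prof <- day_profile(z)
  expect_equal(unname(prof[1, ]), rep(0, 5))       # constant row -> zeros
  # one sample per day: profile equals the z values
  tab1 <- make_study_table(rbind(c(1, 4, 2, 8, 5)),
                           days = c(7L, 14L, 21L, 28L, 60L))
  z1 <- zscore_features(tab1, "DPT")
  expect_equal(unname(day_profile(z1)[1, ]), unname(z1[1, ]))
  # linearity: profile of a mean equals mean of profiles
  expect_equal(colMeans(prof), day_profile(rbind(colMeans(z)),
                                           attr(z, "samples"))[1, ])
})

test_that("cosine clustering separates antipodal groups and is scale invariant", {
  base <- c(1, 1, 1, 1, 1)
  z <- unname(rbind(base, base * 2, -base, -base * 3))
  lab <- cluster_features(z, 2)
  expect_equal(lab[1], lab[2])
  expect_equal(lab[3], lab[4])
  expect_false(lab[1] == lab[3])
  # scaling a row by c > 0 never changes its assignment
  z2 <- z; z2[1, ] <- z2[1, ] * 17
  expect_equal(cluster_features(z2, 2), lab)
  # identical vectors land together at distance zero
  z3 <- rbind(c(1, 2, 3), c(1, 2, 3), c(-3, 1, 0))
  expect_equal(cluster_features(z3, 2)[1], cluster_features(z3, 2)[2])
})

test_that("consensus rank rule picks the smallest mean rank", {
  # unanimous winner
  tab <- woundmetab:::consensus_rank(data.frame(
    k = c(2, 3, 4),
    silhouette = c(0.70, 0.55, 0.30),
    calinski_harabasz = c(150, 120, 90),
    davies_bouldin = c(0.40, 0.70, 1.10)))
  expect_equal(tab$k[which.min(tab$mean_rank)], 2)
  # split vote: k=3 wins on mean rank (1.67 vs 1.33)
  tab2 <- woundmetab:::consensus_rank(data.frame(
    k = c(2, 3),
    silhouette = c(0.80, 0.60),
    calinski_harabasz = c(100, 140),
    davies_bouldin = c(0.90, 0.50)))
  expect_equal(round(tab2$mean_rank, 2), c(1.67, 1.33))
  expect_equal(tab2$k[which.min(tab2$mean_rank)], 3)
})

test_that("consensus selection recovers three planted archetypes", {
  hits <- vapply(1:10, function(s) {
    cfg <- sim_config(n_features = 90, frac_time_responsive = 1,
                      trajectory_mix = c(U1 = 1/3, D1 = 1/3, P2 = 1/3),
                      frac_day7_treatment_responsive = 0,
                      effect_size_log2 = 1.5, noise_cv = 0.1,
                      drift_amplitude = 0, missing_rate = 0, seed = s)
    gen <- simulate_study(cfg)
    z <- zscore_features(gen$table, "DPT")
    sel <- select_k_consensus(z, 2:8)
    sel$k == 3
  }, logical(1))
  expect_gte(sum(hits), 9)
})

test_that("pattern classification follows the U/D/P rules", {
  expect_equal(classify_pattern(c(-1.5, -0.5, 0.5, 1.0, 1.2))$letter, "U")
  expect_equal(classify_pattern(c(1.2, 0.4, -0.3, -0.6, -0.7))$letter, "D")
  pk <- classify_pattern(c(-0.5, 1.5, 0.3, -0.6, -0.7))
  expect_equal(pk$letter, "P")
  expect_equal(pk$peak_day_index, 2L)
  # valley-shaped maps to P at the largest absolute deviation
  valley <- classify_pattern(c(1.0, -0.2, -1.6, -0.1, 1.0))
  expect_equal(valley$letter, "P")
  expect_equal(valley$peak_day_index, 3L)
  expect_error(classify_pattern(c(1, 2)), "3 days")
})

test_that("all eight noiseless archetypes classify to their own letter", {
  for (lab in c("U1", "U2", "D1", "D2", "D3", "P1", "P2", "P3")) {
    z <- trajectory_archetype(lab)
    expect_equal(classify_pattern(z)$letter, substr(lab, 1, 1), info = lab)
  }
})

test_that("timing numerals order U/D by zero-crossing and P by day-7 value", {
  # U crossing at day 21 vs day 28 -> U1, U2
  cen <- rbind(c(-1.0, -0.5, 0.2, 0.8, 1.0),
               c(-1.2, -0.8, -0.3, 0.4, 1.1))
  expect_equal(assign_timing_labels(cen, c("U", "U")), c("U1", "U2"))
  expect_equal(assign_timing_labels(cen[2:1, ], c("U", "U")), c("U2", "U1"))
  # P by day-7 value above / near / below
  cenp <- rbind(c(0.8, 1.2, 0.1, -0.9, -1.1),
                c(0.0, 1.3, 0.4, -0.8, -1.0),
                c(-0.9, 0.5, 1.2, 0.1, -0.8))
  expect_equal(assign_timing_labels(cenp, c("P", "P", "P")),
               c("P1", "P2", "P3"))
  # single D cluster is D1
  expect_equal(assign_timing_labels(rbind(c(1, 0.5, -0.2, -0.8, -1)), "D"),
               "D1")
  # more than three sharing a letter continues with a warning
  cen4 <- rbind(c(-1.5, 0, 0.5, 0.8, 1), c(-1.2, -0.5, 0.3, 0.8, 1),
                c(-1.1, -0.8, -0.2, 0.7, 1), c(-1, -0.9, -0.4, 0.1, 1))
  expect_warning(labs <- assign_timing_labels(cen4, rep("U", 4)),
                 "more than 3")
  expect_equal(labs, c("U1", "U2", "U3", "U4"))
})

test_that("cluster assignments are invariant under feature reordering", {
  skip_if_not_installed("mclust")
  cfg <- sim_config(n_features = 60, frac_time_responsive = 1,
                    trajectory_mix = c(U1 = 0.25, D1 = 0.25, P1 = 0.25,
                                       P3 = 0.25),
                    frac_day7_treatment_responsive = 0,
                    effect_size_log2 = 1.5, noise_cv = 0.1,
                    drift_amplitude = 0, missing_rate = 0, seed = 4)
  z <- zscore_features(simulate_study(cfg)$table, "DPT")
  lab1 <- cluster_features(z, 4)
  perm <- sample(nrow(z))
  lab2 <- cluster_features(z[perm, ], 4)
  expect_equal(mclust::adjustedRandIndex(lab1[perm], lab2), 1)
})

test_that("trajectory_analysis assembles a coherent result object", {
  cfg <- sim_config(n_features = 80, frac_time_responsive = 1,
                    trajectory_mix = c(U1 = 0.34, D1 = 0.33, P2 = 0.33),
                    frac_day7_treatment_responsive = 0,
                    effect_size_log2 = 1.5, noise_cv = 0.1,
                    drift_amplitude = 0, missing_rate = 0, seed = 8)
  gen <- simulate_study(cfg)
  res <- trajectory_analysis(gen$table, gen$truth$feature_id, "DPT", 2:8)
  expect_s3_class(res, "trajectory_result")
  expect_equal(res$k, 3)
  expect_length(res$pattern_labels, res$k)
  expect_equal(ncol(res$centroids), 5)
  expect_equal(length(res$pattern_by_feature), length(res$feature_ids))
  # letters recovered match the planted archetypes
  expect_setequal(substr(res$pattern_labels, 1, 1), c("U", "D", "P"))
})
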
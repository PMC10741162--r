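test_that("two-way ANOVA reproduces the hand-computed balanced toy", {
  # cells (log2 scale): T1A=[1,2] T1B=[1,2] T2A=[3,4] T2B=[3,4]
  # SS_time = 8, SS_treat = 0, SS_int = 0, SS_res = 2 on 4 df -> F_time 16
  tab <- anova_toy_table(values = c(1, 2, 1, 2, 3, 4, 3, 4),
                         days = rep(c(7L, 7L, 7L, 7L, 14L, 14L, 14L, 14L),
                                    times = 1)[c(1, 2, 3, 4, 5, 6, 7, 8)],
                         treatments = c("AFSG", "AFSG", "FBD", "FBD",
                                        "AFSG", "AFSG", "FBD", "FBD"))
  scan <- two_way_anova_scan(tab, "DPT")
  expect_equal(scan$p_time, pf(16, 1, 4, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_equal(pf(16, 1, 4, lower.tail = FALSE), 0.01613, tolerance = 1e-3)
  # zero between-group variance for treatment and interaction -> F = 0, p = 1
  expect_equal(scan$p_treatment, 1)
  expect_equal(scan$p_interaction, 1)
})

test_that("ANOVA p-values are invariant under sample permutation", {
  cfg <- sim_config(n_features = 15, seed = 3, missing_rate = 0.05)
  tab <- simulate_study(cfg)$table
  scan1 <- two_way_anova_scan(tab, "FT")
  perm <- sample(ncol(tab$intensities))
  tab_p <- tab[, perm]
  scan2 <- two_way_anova_scan(tab_p, "FT")
  expect_equal(scan2$p_time, scan1$p_time, tolerance = 1e-9)
  expect_equal(scan2$p_treatment, scan1$p_treatment, tolerance = 1e-9)
})

test_that("a single-level factor is reported by name", {
  tab <- anova_toy_table(values = 1:4, days = c(7L, 7L, 14L, 14L),
                         treatments = rep("AFSG", 4))
  expect_error(two_way_anova_scan(tab, "DPT"), "treatment.*single level")
})

test_that("ANOVA agrees with the explicit cell-mean oracle on balanced designs", {
  set.seed(99)
  for (rep in 1:10) {
    n_per_cell <- sample(2:3, 1)
    days <- rep(rep(c(7L, 14L, 21L), each = n_per_cell), times = 2)
    treats <- rep(c("AFSG", "FBD"), each = 3 * n_per_cell)
    y <- rnorm(length(days), mean = 10, sd = 1)
    tab <- anova_toy_table(values = y, days = days, treatments = treats)
    scan <- two_way_anova_scan(tab, "DPT")
    oracle <- oracle_anova_balanced(y, days, treats)
    expect_equal(scan$p_time, oracle$p_time, tolerance = 1e-10)
    expect_equal(scan$p_treatment, oracle$p_treat, tolerance = 1e-10)
    expect_equal(scan$p_interaction, oracle$p_int, tolerance = 1e-10)
  }
})

test_that("BH adjustment follows the step-up formula", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04, 0.05)),
               c(0.04, 0.04, 0.05, 0.05))
  expect_equal(bh_adjust(0.5), 0.5)
  expect_equal(bh_adjust(rep(0.2, 6)), rep(0.2, 6))
  # NA passthrough, family size excludes missing entries
  q <- bh_adjust(c(0.01, NA, 0.02))
  expect_true(is.na(q[2]))
  expect_equal(q[c(1, 3)], c(0.02, 0.02))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # idempotence and monotonicity
  p <- c(0.001, 0.02, 0.3, 0.7, 0.04, 0.0005)
  q1 <- bh_adjust(p)
  expect_equal(bh_adjust(q1) >= q1, rep(TRUE, 6))
  expect_true(all(diff(q1[order(p)]) >= -1e-12))
  expect_true(all(q1 >= p))
})

test_that("day t-test produces pooled-t p-values and linear-scale fold changes", {
  mk <- function(log2_a, log2_b) {
    n <- length(log2_a) + length(log2_b)
    features <- data.frame(feature_id = "F1", mz = 150, rt = 5, mode = "pos")
    samples <- data.frame(
      sample_id = sprintf("S%d", 1:n), injection_order = 1:n, kind = "study",
      pig_id = "pig01", wound_type = "DPT",
      treatment = rep(c("AFSG", "FBD"), c(length(log2_a), length(log2_b))),
      day = 7L)
    feature_table(matrix(2^c(log2_a, log2_b), 1), features, samples)
  }
  # identical groups: t = 0, p = 1, fc = 1
  tt <- day_ttest(mk(c(4, 4, 4), c(4, 4, 4)), "DPT", 7)
  expect_equal(tt$p_raw, 1)
  expect_equal(tt$fc, 1)
  # linear means 300 vs 100 -> fc = 3
  tt2 <- day_ttest(mk(log2(c(280, 300, 320)), log2(c(90, 100, 110))), "DPT", 7)
  expect_equal(tt2$fc, 3.0, tolerance = 1e-12)
  # pooled-variance Student's t matches the base implementation
  a <- c(1.2, 1.9, 2.4, 1.7); b <- c(3.0, 2.8, 3.5, 3.1)
  tt3 <- day_ttest(mk(a, b), "DPT", 7)
  expect_equal(tt3$p_raw, t.test(a, b, var.equal = TRUE)$p.value,
               tolerance = 1e-12)
})

test_that("Bonferroni uses the tested-feature family size", {
  set.seed(1)
  nf <- 100
  intens <- matrix(2^rnorm(nf * 8, 10), nf, 8)
  features <- data.frame(feature_id = sprintf("F%03d", 1:nf),
                         mz = seq(100, 900, length.out = nf), rt = 5,
                         mode = "pos")
  samples <- data.frame(
    sample_id = sprintf("S%d", 1:8), injection_order = 1:8, kind = "study",
    pig_id = "pig01", wound_type = "DPT",
    treatment = rep(c("AFSG", "FBD"), each = 4), day = 7L)
  tab <- feature_table(intens, features, samples)
  tt <- day_ttest(tab, "DPT", 7)
  expect_equal(tt$p_bonf, pmin(1, tt$p_raw * 100))
})

test_that("volcano classification applies both thresholds and direction", {
  tt <- data.frame(feature_id = c("A", "B", "C", "D"),
                   p_raw = c(0.001, 0.001, 0.002, 0.5),
                   p_bonf = c(0.05, 0.001, 0.09, 1),
                   fc = c(2.0, 1.4, 0.5, 3.0))
  out <- volcano_classify(tt, p_thresh = 0.1, fc_thresh = 1.5)
  expect_setequal(out$feature_id, c("A", "C"))
  expect_equal(out$direction[out$feature_id == "A"], "up_in_A")
  expect_equal(out$direction[out$feature_id == "C"], "up_in_B")
})

test_that("features of interest require both the BH and raw-p criteria", {
  scan <- data.frame(feature_id = c("A", "B", "C"),
                     p_time = c(0.001, 0.2, 0.04),
                     q_time = c(0.01, 0.25, 0.06))
  expect_equal(features_of_interest(scan), "A")
})
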
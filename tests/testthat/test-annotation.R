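# frozen expected masses computed by direct arithmetic from the atomic
# monoisotopic masses (C 12, H 1.00782503, N 14.00307401, O 15.99491462,
# S 31.97207117) and the proton mass 1.00727646
ALLANTOIN_M <- 4 * 12 + 6 * 1.00782503 + 4 * 14.00307401 + 3 * 15.99491462
ARGININE_M <- 6 * 12 + 14 * 1.00782503 + 4 * 14.00307401 + 2 * 15.99491462
HYPOTAURINE_M <- 2 * 12 + 7 * 1.00782503 + 14.00307401 + 2 * 15.99491462 +
  31.97207117

test_that("monoisotopic masses sum the atomic masses of the formula", {
  expect_equal(monoisotopic_mass("H2O"),
               2 * 1.00782503 + 15.99491462, tolerance = 1e-9)
  expect_equal(monoisotopic_mass("H2O"), 18.010565, tolerance = 1e-6)
  expect_equal(monoisotopic_mass("C4H6N4O3"), ALLANTOIN_M, tolerance = 1e-9)
  expect_equal(monoisotopic_mass("C4H6N4O3"), 158.043990, tolerance = 1e-6)
  expect_equal(monoisotopic_mass(parse_formula("C6H14N4O2")), ARGININE_M,
               tolerance = 1e-9)
  expect_error(monoisotopic_mass(integer(0)), "empty formula")
  expect_error(monoisotopic_mass(c(C = 2, Xx = 1)), "unsupported element")
})

test_that("adduct m/z arithmetic uses the proton mass", {
  # allantoin [M-H]- reproduces the printed negative-mode value at 4 dp
  expect_equal(round(adduct_mz(ALLANTOIN_M, "[M-H]-"), 4), 157.0367)
  expect_equal(adduct_mz(ARGININE_M, "[M+H]+"), 175.118952, tolerance = 1e-6)
  # protonated and deprotonated ions of the same M differ by 2 protons
  expect_equal(adduct_mz(100, "[M+H]+") - adduct_mz(100, "[M-H]-"),
               2 * 1.00727646, tolerance = 1e-12)
  expect_equal(adduct_mz(200, "[M+H-H2O]+"),
               200 + 1.00727646 - (2 * 1.00782503 + 15.99491462),
               tolerance = 1e-8)
  expect_error(adduct_mz(-5, "[M+H]+"), "positive")
  expect_error(adduct_mz(100, "[M+NH4]+"), "unknown adduct")
})

test_that("level-3 matching applies the ppm rule with polarity filtering", {
  db <- list(
    list(name = "Arginine", formula = parse_formula("C6H14N4O2"),
         kegg_id = "C00062", fragments = NULL, rt = NA, standard = FALSE),
    list(name = "Hypotaurine", formula = parse_formula("C2H7NO2S"),
         kegg_id = "C00519", fragments = NULL, rt = NA, standard = FALSE))
  features <- data.frame(
    feature_id = c("Fa", "Fb", "Fc"),
    mz = c(175.1193, 108.0121, 175.1500),
    rt = 5, mode = c("pos", "neg", "pos"))
  hits <- match_features_level3(features, db, tol_ppm = 10)
  ha <- hits[hits$feature_id == "Fa", ]
  expect_equal(ha$compound, "Arginine")
  expect_equal(ha$adduct, "[M+H]+")
  expect_equal(ha$ppm_error, 2.0, tolerance = 0.05)
  expect_equal(ha$level, 3L)
  hb <- hits[hits$feature_id == "Fb", ]
  expect_equal(hb$compound, "Hypotaurine")
  expect_equal(hb$adduct, "[M-H]-")
  expect_equal(hb$ppm_error, 3.45, tolerance = 0.05)
  # 175.15 is ~177 ppm away from arginine [M+H]+ -> no hit
  expect_equal(nrow(hits[hits$feature_id == "Fc", ]), 0)
  # a negative-mode feature never matches a positive adduct
  expect_false(any(hits$adduct[hits$feature_id == "Fb"] %in%
                   c("[M+H]+", "[M+Na]+", "[M+H-H2O]+")))
})

test_that("printed table m/z values are annotated with the printed compound", {
  db <- read_compound_db(system.file("extdata", "compounds.tsv",
                                     package = "woundmetab"))
  printed <- data.frame(
    feature_id = c("allantoin", "arginine", "hypotaurine", "citrulline",
                   "histidine", "serine", "hydroxyproline", "glutamate"),
    compound = c("Allantoin", "Arginine", "Hypotaurine", "Citrulline",
                 "Histidine", "Serine", "Hydroxyproline", "Glutamate"),
    mz = c(157.0367, 175.1193, 108.0121, 174.08813,
           156.07728, 104.03505, 130.05016, 148.06088),
    mode = c("neg", "pos", "neg", "neg", "pos", "neg", "neg", "pos"),
    stringsAsFactors = FALSE)
  printed$rt <- 5
  hits <- match_features_level3(printed, db, tol_ppm = 10)
  for (i in seq_len(nrow(printed))) {
    found <- hits$compound[hits$feature_id == printed$feature_id[i]]
    expect_true(printed$compound[i] %in% found,
                info = printed$compound[i])
  }
})

test_that("ppm error is near-symmetric in observed vs theoretical", {
  theo <- 175.118952
  obs <- 175.1193
  ppm1 <- abs(obs - theo) / theo * 1e6
  ppm2 <- abs(theo - obs) / obs * 1e6
  expect_equal(ppm1, ppm2, tolerance = 1e-3)
})

test_that("fragment evidence upgrades levels 2 and 1 under the shared-mass rule", {
  db <- list(
    list(name = "Arginine", formula = parse_formula("C6H14N4O2"),
         kegg_id = "C00062",
         fragments = c(60.0556, 70.0651, 116.0706, 130.0975, 158.0924, 175.119),
         rt = 5.0, standard = TRUE))
  features <- data.frame(feature_id = "Fa", mz = 175.1193, rt = 5.05,
                         mode = "pos")
  hits <- match_features_level3(features, db, 10)

  # 5 of 6 experimental fragments within 0.01 Da -> level 2 (no RT info)
  sp5 <- list(Fa = c(60.056, 70.065, 116.071, 130.097, 158.093, 999.9))
  up <- msms_upgrade(hits, sp5, db, features = NULL)
  expect_equal(up$level, 2L)
  expect_equal(up$n_shared_fragments, 5L)

  # only 4 shared -> stays level 3
  sp4 <- list(Fa = c(60.056, 70.065, 116.071, 130.097))
  expect_equal(msms_upgrade(hits, sp4, db)$level, 3L)

  # 5 shared + authentic standard + RT within 0.2 min -> level 1
  up1 <- msms_upgrade(hits, sp5, db, features = features)
  expect_equal(up1$level, 1L)

  # RT off by more than the tolerance stays level 2
  far <- transform(features, rt = 6.0)
  expect_equal(msms_upgrade(hits, sp5, db, features = far)$level, 2L)
})

test_that("greedy fragment matching is one-to-one", {
  # two experimental peaks near one DB fragment: only one may match
  n <- woundmetab:::count_shared_fragments(c(100.000, 100.005), c(100.002),
                                           tol_da = 0.01)
  expect_equal(n, 1L)
  # closest-first: the 0.002 pair wins, leaving the other experimental
  # peak to a second reference within tolerance
  n2 <- woundmetab:::count_shared_fragments(c(100.000, 100.005),
                                            c(100.002, 100.014), 0.01)
  expect_equal(n2, 2L)
  expect_equal(woundmetab:::count_shared_fragments(numeric(0), c(1), 0.01), 0L)
})
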
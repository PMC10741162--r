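# Monoisotopic atomic masses (IUPAC/CODATA), Daltons.
MONOISOTOPIC_MASS <- c(
  C = 12.000000,
  H = 1.00782503,
  N = 14.00307401,
  O = 15.99491462,
  S = 31.97207117,
  P = 30.97376163,
  Na = 22.98976928,
  K = 38.96370649,
  Cl = 34.96885268
)

PROTON_MASS <- 1.00727646  # H atom minus electron

# adduct label -> (mass shift, polarity)
ADDUCT_TABLE <- list(
  "[M+H]+" = list(shift = PROTON_MASS, mode = "pos"),
  "[M+Na]+" = list(shift = 22.98922070, mode = "pos"),
  "[M+H-H2O]+" = list(shift = -17.00328879, mode = "pos"),
  "[M-H]-" = list(shift = -PROTON_MASS, mode = "neg"),
  "[M+Cl]-" = list(shift = 34.96940126, mode = "neg")
)

#' Monoisotopic mass of a molecular formula
#'
#' Sum of element count times monoisotopic atomic mass over the supported
#' element set (C, H, N, O, P, S, Na, K, Cl).
#'
#' @param formula Element count map (named integer vector from
#'   [parse_formula()]) or a formula string.
#' @return Neutral monoisotopic mass in Daltons.
#' @export
monoisotopic_mass <- function(formula) {
  if (is.character(formula)) formula <- parse_formula(formula)
  if (!length(formula)) stop("empty formula")
  unknown <- setdiff(names(formula), names(MONOISOTOPIC_MASS))
  if (length(unknown)) {
    stop("unsupported element(s): ", paste(unknown, collapse = ", "))
  }
  if (any(formula <= 0)) stop("element counts must be positive")
  sum(formula * MONOISOTOPIC_MASS[names(formula)])
}

#' Theoretical adduct m/z
#'
#' Ion m/z for one of the five supported adduct species, using the proton
#' mass (not the H-atom mass) for protonation/deprotonation so that the
#' electron is accounted for.
#'
#' @param neutral_mass Neutral monoisotopic mass (> 0), Daltons.
#' @param adduct One of `"[M+H]+"`, `"[M+Na]+"`, `"[M+H-H2O]+"`,
#'   `"[M-H]-"`, `"[M+Cl]-"`.
#' @return Theoretical m/z in Daltons.
#' @export
adduct_mz <- function(neutral_mass, adduct) {
  if (neutral_mass <= 0) stop("neutral mass must be positive")
  entry <- ADDUCT_TABLE[[adduct]]
  if (is.null(entry)) stop("unknown adduct label: '", adduct, "'")
  neutral_mass + entry$shift
}

#' Accurate-mass (level 3) feature annotation
#'
#' For every feature, tests each compound in the database against every
#' polarity-compatible adduct; matches with mass error at or below
#' `tol_ppm` parts per million become level-3 annotation hits. Hits are
#' sorted by ascending ppm error (ties alphabetically by compound name).
#'
#' @param features data.frame of feature metadata (`feature_id`, `mz`,
#'   `mode`), e.g. the `features` slot of a [feature_table()].
#' @param db Compound database from [read_compound_db()].
#' @param tol_ppm Mass tolerance in ppm (default 10).
#' @return data.frame of hits: `feature_id`, `compound`, `kegg_id`,
#'   `adduct`, `theoretical_mz`, `ppm_error`, `level`,
#'   `n_shared_fragments` (NA until MS/MS evidence is added).
#' @export
match_features_level3 <- function(features, db, tol_ppm = 10) {
  if (!length(db)) stop("compound database is empty")
  neutral <- vapply(db, function(r) monoisotopic_mass(r$formula), numeric(1))
  names_db <- vapply(db, `[[`, character(1), "name")
  kegg_db <- vapply(db, function(r) {
    if (is.null(r$kegg_id) || is.na(r$kegg_id)) NA_character_ else r$kegg_id
  }, character(1))
  hits <- list()
  for (i in seq_len(nrow(features))) {
    fmode <- features$mode[i]
    fmz <- features$mz[i]
    for (ad in names(ADDUCT_TABLE)) {
      if (ADDUCT_TABLE[[ad]]$mode != fmode) next
      theo <- neutral + ADDUCT_TABLE[[ad]]$shift
      ppm <- abs(fmz - theo) / theo * 1e6
      sel <- which(ppm <= tol_ppm)
      if (length(sel)) {
        hits[[length(hits) + 1L]] <- data.frame(
          feature_id = features$feature_id[i],
          compound = names_db[sel], kegg_id = kegg_db[sel], adduct = ad,
          theoretical_mz = theo[sel], ppm_error = ppm[sel], level = 3L,
          n_shared_fragments = NA_integer_, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(feature_id = character(0), compound = character(0),
                      kegg_id = character(0), adduct = character(0),
                      theoretical_mz = numeric(0), ppm_error = numeric(0),
                      level = integer(0), n_shared_fragments = integer(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  out <- out[order(out$feature_id, out$ppm_error, out$compound), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# greedy one-to-one fragment matching, closest pairs first
count_shared_fragments <- function(experimental, reference, tol_da) {
  if (!length(experimental) || !length(reference)) return(0L)
  pairs <- expand.grid(e = seq_along(experimental), r = seq_along(reference))
  pairs$d <- abs(experimental[pairs$e] - reference[pairs$r])
  pairs <- pairs[pairs$d <= tol_da, , drop = FALSE]
  pairs <- pairs[order(pairs$d), , drop = FALSE]
  used_e <- used_r <- integer(0)
  n <- 0L
  for (row in seq_len(nrow(pairs))) {
    e <- pairs$e[row]; r <- pairs$r[row]
    if (e %in% used_e || r %in% used_r) next
    used_e <- c(used_e, e); used_r <- c(used_r, r)
    n <- n + 1L
  }
  n
}

#' Upgrade annotation confidence with MS/MS fragment evidence
#'
#' A level-3 hit is upgraded to level 2 when at least `min_shared`
#' experimental fragment masses match database fragment masses within
#' `frag_tol_da` (greedy one-to-one matching, closest pairs first), and to
#' level 1 when, additionally, the database record is an
#' authentic-standard entry whose retention time lies within `rt_tol_min`
#' of the feature.
#'
#' @param hits Level-3 hits from [match_features_level3()].
#' @param spectra Feature-to-fragment map from [read_spectra()].
#' @param db Compound database from [read_compound_db()].
#' @param features Optional feature metadata (`feature_id`, `rt`) for the
#'   level-1 retention check.
#' @param frag_tol_da Fragment mass tolerance, Daltons (default 0.01).
#' @param min_shared Minimum shared fragments (default 5).
#' @param rt_tol_min Retention-time tolerance for level 1, minutes
#'   (default 0.2).
#' @return `hits` with `level` and `n_shared_fragments` updated.
#' @export
msms_upgrade <- function(hits, spectra, db, features = NULL,
                         frag_tol_da = 0.01, min_shared = 5,
                         rt_tol_min = 0.2) {
  if (!nrow(hits)) return(hits)
  db_by_name <- stats::setNames(db, vapply(db, `[[`, character(1), "name"))
  for (i in seq_len(nrow(hits))) {
    fid <- hits$feature_id[i]
    exp_frag <- spectra[[fid]]
    rec <- db_by_name[[hits$compound[i]]]
    if (is.null(exp_frag) || is.null(rec) || is.null(rec$fragments)) next
    n_shared <- count_shared_fragments(exp_frag, rec$fragments, frag_tol_da)
    hits$n_shared_fragments[i] <- n_shared
    if (n_shared >= min_shared) {
      hits$level[i] <- 2L
      if (isTRUE(rec$standard) && !is.na(rec$rt) && !is.null(features)) {
        frt <- features$rt[match(fid, features$feature_id)]
        if (!is.na(frt) && abs(frt - rec$rt) <= rt_tol_min) {
          hits$level[i] <- 1L
        }
      }
    }
  }
  hits
}
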
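#' Simulation configuration for a synthetic burn-wound metabolomics study
#'
#' Parameterizes a synthetic untargeted LC-MS study that mirrors the porcine
#' burn wound design: six pigs, four deep partial-thickness (DPT) wounds per
#' pig (two AFSG-, two FBD-treated), six full-thickness (FT) wounds per pig
#' (two AFSG, two cadaver skin, two split-thickness-graft "sandwich"),
#' biopsies on days 7/14/21/28/60, and a pooled QC injected every seventh
#' position of the run.
#'
#' @param n_pigs Number of animals.
#' @param dpt_wounds_per_pig,ft_wounds_per_pig Wounds per pig by depth.
#' @param days Biopsy days.
#' @param n_features Number of m/z features to simulate.
#' @param frac_time_responsive Fraction of features with a planted temporal
#'   trajectory.
#' @param trajectory_mix Named weights over the eight trajectory archetypes
#'   `U1,U2,D1,D2,D3,P1,P2,P3`; must sum to 1.
#' @param frac_day7_treatment_responsive Fraction of features with an
#'   AFSG-vs-comparator effect confined to day 7.
#' @param effect_size_log2 Amplitude (log2 units) of planted trajectory and
#'   treatment effects.
#' @param drift_amplitude Fractional intensity change across the full
#'   injection sequence (0.4 means the last injection reads 40% high).
#' @param noise_cv Coefficient of variation of the multiplicative
#'   log-normal measurement noise.
#' @param qc_every QC injection period: every `qc_every`-th injection
#'   position is a pooled QC.
#' @param missing_rate Probability that any one measurement is missing.
#' @param frac_pos Fraction of features acquired in positive ionization
#'   mode (the remainder are negative mode).
#' @param seed Integer seed; the generated study is a pure function of the
#'   configuration including the seed.
#'
#' @return A `sim_config` object (validated list).
#' @export
sim_config <- function(n_pigs = 6,
                       dpt_wounds_per_pig = 4,
                       ft_wounds_per_pig = 6,
                       days = c(7L, 14L, 21L, 28L, 60L),
                       n_features = 1367,
                       frac_time_responsive = 0.25,
                       trajectory_mix = c(U1 = 0.05, U2 = 0.05, D1 = 0.10,
                                          D2 = 0.05, D3 = 0.05, P1 = 0.20,
                                          P2 = 0.35, P3 = 0.15),
                       frac_day7_treatment_responsive = 0.2,
                       effect_size_log2 = 1,
                       drift_amplitude = 0.2,
                       noise_cv = 0.15,
                       qc_every = 7,
                       missing_rate = 0.02,
                       frac_pos = 0.74,
                       seed = 1L) {
  cfg <- list(n_pigs = as.integer(n_pigs),
              dpt_wounds_per_pig = as.integer(dpt_wounds_per_pig),
              ft_wounds_per_pig = as.integer(ft_wounds_per_pig),
              days = sort(as.integer(days)),
              n_features = as.integer(n_features),
              frac_time_responsive = frac_time_responsive,
              trajectory_mix = trajectory_mix,
              frac_day7_treatment_responsive = frac_day7_treatment_responsive,
              effect_size_log2 = effect_size_log2,
              drift_amplitude = drift_amplitude,
              noise_cv = noise_cv,
              qc_every = as.integer(qc_every),
              missing_rate = missing_rate,
              frac_pos = frac_pos,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  fracs <- c(frac_time_responsive = cfg$frac_time_responsive,
             frac_day7_treatment_responsive = cfg$frac_day7_treatment_responsive,
             missing_rate = cfg$missing_rate, frac_pos = cfg$frac_pos)
  bad <- names(fracs)[fracs < 0 | fracs > 1]
  if (length(bad)) stop("fraction(s) outside [0,1]: ", paste(bad, collapse = ", "))
  if (abs(sum(cfg$trajectory_mix) - 1) > 1e-8) {
    stop("trajectory_mix must sum to 1")
  }
  if (!all(names(cfg$trajectory_mix) %in% ARCHETYPE_LABELS)) {
    stop("trajectory_mix names must be among: ",
         paste(ARCHETYPE_LABELS, collapse = ", "))
  }
  if (cfg$qc_every < 2) stop("qc_every must be >= 2")
  if (cfg$n_features < 1) stop("n_features must be >= 1")
  if (!length(cfg$days)) stop("day list must be nonempty")
  if (cfg$effect_size_log2 < 0) stop("effect_size_log2 must be >= 0")
  if (cfg$drift_amplitude < 0) stop("drift_amplitude must be >= 0")
  if (cfg$noise_cv < 0) stop("noise_cv must be >= 0")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config: ", x$n_pigs, " pigs, ",
      x$dpt_wounds_per_pig, " DPT + ", x$ft_wounds_per_pig,
      " FT wounds/pig, days ", paste(x$days, collapse = "/"), "\n",
      "  ", x$n_features, " features; ",
      round(100 * x$frac_time_responsive), "% time-responsive; ",
      "effect ", x$effect_size_log2, " log2; drift ",
      x$drift_amplitude, "; noise CV ", x$noise_cv,
      "; QC every ", x$qc_every, "; seed ", x$seed, "\n", sep = "")
  invisible(x)
}

ARCHETYPE_LABELS <- c("U1", "U2", "D1", "D2", "D3", "P1", "P2", "P3")

# Raw archetype shapes on a 5-point normalized time grid. U = monotone
# rising saturating, D = monotone falling saturating, P = interior peak;
# numerals order the transition/peak from early (1) to late (3).
ARCHETYPE_RAW <- list(
  U1 = c(-1.6, 0.2, 0.9, 1.0, 1.0),
  U2 = c(-1.0, -0.9, -0.5, 0.5, 1.2),
  D1 = c(1.6, -0.4, -0.8, -1.0, -1.1),
  D2 = c(1.3, 0.6, -0.3, -0.9, -1.1),
  D3 = c(1.0, 0.9, 0.6, 0.4, -1.5),
  P1 = c(0.9, 1.3, -0.2, -1.0, -1.0),
  P2 = c(0.0, 0.6, 1.4, -0.6, -1.4),
  P3 = c(-1.2, -0.4, 0.6, 1.4, -0.4)
)

#' Trajectory archetype template
#'
#' Deterministic z-score profile over the biopsy-day grid for one of the
#' eight trajectory archetypes: monotone increasing saturating (`U1`,`U2`),
#' monotone decreasing saturating (`D1`-`D3`), and interior-peak (`P1`-`P3`)
#' shapes, with the numeral moving the transition/peak from early to late.
#' Templates are centered (mean 0) and scaled (population sd 1) over the
#' day grid.
#'
#' @param label One of `U1,U2,D1,D2,D3,P1,P2,P3`.
#' @param days Day grid (default the study's 7/14/21/28/60).
#' @return Numeric z-profile, one value per day.
#' @export
trajectory_archetype <- function(label, days = c(7, 14, 21, 28, 60)) {
  if (!label %in% ARCHETYPE_LABELS) {
    stop("unknown trajectory archetype label: '", label, "'")
  }
  days <- sort(days)
  n <- length(days)
  if (n < 2) stop("day grid must have at least 2 days")
  raw <- ARCHETYPE_RAW[[label]]
  # interpolate on the rank scale so unevenly spaced day grids keep shape
  u <- (seq_len(n) - 1) / (n - 1)
  y <- stats::approx(seq(0, 1, length.out = length(raw)), raw, xout = u)$y
  (y - mean(y)) / sqrt(mean((y - mean(y))^2))
}

#' Injection-order drift factor
#'
#' Smooth monotone multiplicative run-order drift: factor 1 at the first
#' injection, `1 + amplitude` at the last.
#'
#' @param injection_order Injection position(s), >= 1.
#' @param n_injections Total number of injections in the run.
#' @param amplitude Fractional intensity change across the full run.
#' @return Multiplicative drift factor(s).
#' @export
drift_factor <- function(injection_order, n_injections, amplitude) {
  if (any(injection_order < 1)) stop("injection_order must be >= 1")
  if (n_injections < 2) return(rep(1, length(injection_order)))
  1 + amplitude * (injection_order - 1) / (n_injections - 1)
}

# Injection layout: QCs sit exactly at positions == 0 (mod qc_every);
# study samples fill the remaining positions in randomized order.
injection_layout <- function(n_study, qc_every) {
  total <- n_study
  repeat {
    n_qc <- total %/% qc_every
    if (total - n_qc == n_study) break
    total <- total + 1L
  }
  qc_pos <- seq_len(total)[seq_len(total) %% qc_every == 0]
  list(total = total, qc_pos = qc_pos,
       study_pos = setdiff(seq_len(total), qc_pos))
}

build_design <- function(cfg) {
  rows <- list()
  dpt_treat <- rep(c("AFSG", "FBD"), length.out = cfg$dpt_wounds_per_pig)
  ft_treat <- rep(c("AFSG", "CS", "STSG_sandwich"),
                  length.out = cfg$ft_wounds_per_pig)
  for (p in seq_len(cfg$n_pigs)) {
    pig <- sprintf("pig%02d", p)
    for (w in seq_len(cfg$dpt_wounds_per_pig)) {
      for (d in cfg$days) {
        rows[[length(rows) + 1L]] <- data.frame(
          pig_id = pig, wound_type = "DPT",
          wound_id = sprintf("%s_DPT%d", pig, w),
          treatment = dpt_treat[w], day = d, stringsAsFactors = FALSE)
      }
    }
    for (w in seq_len(cfg$ft_wounds_per_pig)) {
      for (d in cfg$days) {
        rows[[length(rows) + 1L]] <- data.frame(
          pig_id = pig, wound_type = "FT",
          wound_id = sprintf("%s_FT%d", pig, w),
          treatment = ft_treat[w], day = d, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Generate a synthetic study
#'
#' Simulates a complete feature table for the burn-wound design together
#' with the ground truth needed to evaluate every downstream stage. The
#' intensity model per feature is
#' `baseline * 2^(trajectory effect) * 2^(day-7 treatment effect)
#'  * drift(injection order) * lognormal noise`,
#' with the trajectory effect shared across wound types, the treatment
#' effect confined to day-7 AFSG-treated wounds, and drift shared across
#' features up to a per-feature sensitivity jitter (+/-20%). Pooled-QC
#' injections carry baseline, drift and noise only. Missing cells are
#' dropped completely at random at `missing_rate`.
#'
#' @param cfg A [sim_config()].
#' @return A list with elements `table` (a [feature_table()]) and `truth`
#'   (a data.frame with per-feature `responsive`, `trajectory`,
#'   `treatment_responsive`, `true_fc_day7`).
#' @export
simulate_study <- function(cfg = sim_config()) {
  validate_sim_config(cfg)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(cfg$seed)

  design <- build_design(cfg)
  n_study <- nrow(design)
  lay <- injection_layout(n_study, cfg$qc_every)
  # randomized acquisition order for study samples
  design <- design[sample.int(n_study), , drop = FALSE]
  design$injection_order <- lay$study_pos
  design$sample_id <- sprintf("S%03d", design$injection_order)
  qc <- data.frame(sample_id = sprintf("QC%03d", lay$qc_pos),
                   injection_order = lay$qc_pos, kind = "QC",
                   pig_id = NA_character_, wound_type = NA_character_,
                   treatment = NA_character_, day = NA_integer_,
                   stringsAsFactors = FALSE)
  study <- data.frame(sample_id = design$sample_id,
                      injection_order = design$injection_order,
                      kind = "study", pig_id = design$pig_id,
                      wound_type = design$wound_type,
                      treatment = design$treatment, day = design$day,
                      stringsAsFactors = FALSE)
  samples <- rbind(study, qc)
  samples <- samples[order(samples$injection_order), , drop = FALSE]

  nf <- cfg$n_features
  feature_id <- sprintf("F%04d", seq_len(nf))
  mode <- ifelse(stats::runif(nf) < cfg$frac_pos, "pos", "neg")
  mz <- stats::runif(nf, 50, 1000)
  rt <- stats::runif(nf, 0.5, 9.5)
  features <- data.frame(feature_id = feature_id, mz = mz, rt = rt,
                         mode = mode, stringsAsFactors = FALSE)

  responsive <- stats::runif(nf) < cfg$frac_time_responsive
  trajectory <- rep(NA_character_, nf)
  n_resp <- sum(responsive)
  if (n_resp > 0 && cfg$effect_size_log2 > 0) {
    trajectory[responsive] <- sample(names(cfg$trajectory_mix), n_resp,
                                     replace = TRUE,
                                     prob = cfg$trajectory_mix)
  } else {
    responsive[] <- FALSE
  }
  trt_resp <- stats::runif(nf) < cfg$frac_day7_treatment_responsive
  # AFSG effect sign: mostly up in AFSG-treated wounds at day 7
  trt_sign <- ifelse(stats::runif(nf) < 0.8, 1, -1)
  true_fc <- ifelse(trt_resp, 2^(trt_sign * cfg$effect_size_log2), 1)

  baseline <- 2^stats::runif(nf, 12, 20)
  drift_sens <- stats::runif(nf, 0.8, 1.2)

  archetypes <- lapply(ARCHETYPE_LABELS, trajectory_archetype, days = cfg$days)
  names(archetypes) <- ARCHETYPE_LABELS

  ns <- nrow(samples)
  is_qc <- samples$kind == "QC"
  day_idx <- match(samples$day, cfg$days)
  afsg_day7 <- !is_qc & samples$treatment == "AFSG" &
    samples$day == cfg$days[1]
  afsg_day7[is.na(afsg_day7)] <- FALSE

  sdlog <- sqrt(log(1 + cfg$noise_cv^2))
  base_drift <- drift_factor(samples$injection_order, lay$total,
                             cfg$drift_amplitude)

  intens <- matrix(NA_real_, nf, ns)
  for (i in seq_len(nf)) {
    log2_effect <- numeric(ns)
    if (responsive[i]) {
      prof <- archetypes[[trajectory[i]]]
      log2_effect[!is_qc] <- cfg$effect_size_log2 * prof[day_idx[!is_qc]]
    }
    if (trt_resp[i]) {
      log2_effect[afsg_day7] <- log2_effect[afsg_day7] +
        trt_sign[i] * cfg$effect_size_log2
    }
    drift_i <- 1 + drift_sens[i] * (base_drift - 1)
    noise <- if (cfg$noise_cv > 0) {
      exp(stats::rnorm(ns, -sdlog^2 / 2, sdlog))
    } else rep(1, ns)
    intens[i, ] <- baseline[i] * 2^log2_effect * drift_i * noise
  }
  if (cfg$missing_rate > 0) {
    intens[stats::runif(length(intens)) < cfg$missing_rate] <- NA_real_
  }

  truth <- data.frame(feature_id = feature_id, responsive = responsive,
                      trajectory = trajectory,
                      treatment_responsive = trt_resp,
                      true_fc_day7 = true_fc, stringsAsFactors = FALSE)
  list(table = feature_table(intens, features, samples), truth = truth)
}
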
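#' Pipeline run configuration
#'
#' Collects every threshold used by the stage functions plus the seed and
#' the wound types to analyze. Input paths may be omitted, in which case
#' the run starts from a simulated study and the bundled compound and
#' pathway fixtures.
#'
#' @param feature_table,sample_sidecar Paths to an existing feature table
#'   and its sample sidecar, or `NULL` to simulate.
#' @param compound_db Path to a compound database TSV (default: bundled).
#' @param pathway_file Path to a pathway edge-list TSV (default: bundled).
#' @param spectra Optional MGF path for MS/MS upgrading.
#' @param sim A [sim_config()] used when no feature table is given.
#' @param wound_types Wound types to analyze.
#' @param qc_presence,qc_rsd,loess_span QC filter / normalization settings.
#' @param anova_q,anova_p Feature-of-interest selection thresholds.
#' @param volcano_p,volcano_fc Day-7 volcano thresholds.
#' @param k_range Candidate trajectory cluster counts.
#' @param ppm Annotation mass tolerance (ppm).
#' @param min_shared_fragments Fragments required for a level-2 upgrade.
#' @param seed Integer seed for the simulated study.
#' @return A validated `run_config` object.
#' @export
run_config <- function(feature_table = NULL, sample_sidecar = NULL,
                       compound_db = system.file("extdata", "compounds.tsv",
                                                 package = "woundmetab"),
                       pathway_file = system.file("extdata",
                                                  "pathways_synthetic.tsv",
                                                  package = "woundmetab"),
                       spectra = NULL,
                       sim = sim_config(),
                       wound_types = c("DPT", "FT"),
                       qc_presence = 0.80, qc_rsd = 25, loess_span = 0.75,
                       anova_q = 0.05, anova_p = 0.05,
                       volcano_p = 0.1, volcano_fc = 1.5,
                       k_range = 2:10, ppm = 10,
                       min_shared_fragments = 5, seed = 1L) {
  cfg <- list(feature_table = feature_table, sample_sidecar = sample_sidecar,
              compound_db = compound_db, pathway_file = pathway_file,
              spectra = spectra, sim = sim, wound_types = wound_types,
              qc_presence = qc_presence, qc_rsd = qc_rsd,
              loess_span = loess_span, anova_q = anova_q, anova_p = anova_p,
              volcano_p = volcano_p, volcano_fc = volcano_fc,
              k_range = k_range, ppm = ppm,
              min_shared_fragments = min_shared_fragments,
              seed = as.integer(seed))
  class(cfg) <- "run_config"
  validate_run_config(cfg)
  cfg
}

validate_run_config <- function(cfg) {
  in_range <- function(v, lo, hi) is.numeric(v) && length(v) == 1 &&
    !is.na(v) && v >= lo && v <= hi
  if (!in_range(cfg$qc_presence, 0, 1)) stop("qc_presence must be in [0, 1]")
  if (!in_range(cfg$qc_rsd, 0, Inf)) stop("qc_rsd must be >= 0")
  if (!in_range(cfg$loess_span, 0.1, 1)) stop("loess_span must be in [0.1, 1]")
  if (!in_range(cfg$anova_q, 0, 1)) stop("anova_q must be in [0, 1]")
  if (!in_range(cfg$anova_p, 0, 1)) stop("anova_p must be in [0, 1]")
  if (!in_range(cfg$volcano_p, 0, 1)) stop("volcano_p must be in [0, 1]")
  if (!in_range(cfg$volcano_fc, 1, Inf)) stop("volcano_fc must be >= 1")
  if (!in_range(cfg$ppm, 0, Inf)) stop("ppm must be >= 0")
  if (any(cfg$k_range < 2)) stop("k_range must be >= 2")
  if (!all(cfg$wound_types %in% c("DPT", "FT"))) {
    stop("wound_types must be a subset of DPT, FT")
  }
  for (p in c("feature_table", "sample_sidecar", "compound_db",
              "pathway_file", "spectra")) {
    if (!is.null(cfg[[p]]) && nzchar(cfg[[p]]) && !file.exists(cfg[[p]])) {
      stop("config path '", p, "' does not exist: ", cfg[[p]])
    }
  }
  invisible(cfg)
}

#' Read a run configuration from a YAML file
#'
#' Scalar fields of the YAML document override the [run_config()]
#' defaults; `sim:` entries override the [sim_config()] defaults.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  doc <- yaml::read_yaml(path)
  sim_args <- doc$sim
  doc$sim <- NULL
  sim <- if (is.null(sim_args)) sim_config() else do.call(sim_config, sim_args)
  do.call(run_config, c(doc, list(sim = sim)))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
}

#' Run the full analysis pipeline
#'
#' Executes simulate/load, QC filtering, LOESS normalization, the two-way
#' ANOVA scan, day-7 volcano classification, trajectory clustering,
#' accurate-mass annotation and pathway enrichment for each requested
#' wound type, writing all stage outputs plus a JSON summary and manifest
#' into `out_dir`. Reruns with the same configuration and seed reproduce
#' all numeric outputs exactly.
#'
#' @param cfg A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results and the
#'   summary.
#' @export
run_pipeline <- function(cfg, out_dir) {
  validate_run_config(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  if (is.null(cfg$feature_table)) {
    sim <- cfg$sim
    sim$seed <- cfg$seed
    gen <- stage("simulate", simulate_study(sim))
    tab <- gen$table
    write_tsv(gen$truth, file.path(out_dir, "ground_truth.tsv"))
  } else {
    tab <- stage("load", read_feature_table(cfg$feature_table,
                                            cfg$sample_sidecar))
  }
  n0 <- nrow(tab$intensities)

  # per ionization mode: filters and LOESS are per-feature, QC-anchored
  norm_parts <- list()
  counts <- list()
  for (mode in intersect(c("pos", "neg"), unique(tab$features$mode))) {
    sub <- tab[tab$features$mode == mode, ]
    sub <- stage("qc_presence_filter",
                 qc_presence_filter(sub, cfg$qc_presence))
    n_pres <- nrow(sub$intensities)
    sub <- stage("qc_rsd_filter", qc_rsd_filter(sub, cfg$qc_rsd))
    n_rsd <- nrow(sub$intensities)
    sub <- stage("loess_normalize",
                 suppressWarnings(loess_drift_correct(sub, cfg$loess_span)))
    counts[[mode]] <- list(input = sum(tab$features$mode == mode),
                           after_presence = n_pres, after_rsd = n_rsd,
                           after_loess = nrow(sub$intensities))
    norm_parts[[mode]] <- sub
  }
  normalized <- if (length(norm_parts) == 1) norm_parts[[1]] else {
    feature_table(do.call(rbind, lapply(norm_parts, `[[`, "intensities")),
                  do.call(rbind, lapply(norm_parts, `[[`, "features")),
                  norm_parts[[1]]$samples)
  }
  write_feature_table(normalized, file.path(out_dir, "normalized.tsv"),
                      file.path(out_dir, "samples.tsv"))

  db <- stage("annotation", read_compound_db(cfg$compound_db))
  pathways <- stage("enrichment", read_pathways(cfg$pathway_file))
  spectra <- if (!is.null(cfg$spectra)) read_spectra(cfg$spectra) else list()

  per_wound <- list()
  for (wt in cfg$wound_types) {
    scan <- stage("anova_scan", two_way_anova_scan(normalized, wt))
    write_tsv(scan, file.path(out_dir, paste0("stats_", wt, ".tsv")))
    foi <- features_of_interest(scan, cfg$anova_q, cfg$anova_p)

    comparator <- if (wt == "DPT") "FBD" else "CS"
    d7 <- sort(unique(normalized$samples$day[normalized$samples$kind == "study"]))[1]
    tt <- stage("day_ttest", day_ttest(normalized, wt, d7, "AFSG", comparator))
    responders <- volcano_classify(tt, cfg$volcano_p, cfg$volcano_fc)
    write_tsv(responders, file.path(out_dir, paste0("volcano_day",
                                                    d7, "_", wt, ".tsv")))

    traj <- NULL
    if (length(foi) >= 4) {
      traj <- stage("trajectory",
                    trajectory_analysis(normalized, foi, wt, cfg$k_range))
      write_tsv(data.frame(feature_id = traj$feature_ids,
                           cluster = traj$labels,
                           pattern = traj$pattern_by_feature),
                file.path(out_dir, paste0("trajectories_", wt, ".tsv")))
      write_tsv(data.frame(pattern = traj$pattern_labels,
                           round(traj$centroids, 6)),
                file.path(out_dir, paste0("centroids_", wt, ".tsv")))
      write_tsv(traj$metric_table,
                file.path(out_dir, paste0("cluster_metrics_", wt, ".tsv")))
    }

    feat_meta <- normalized$features[normalized$features$feature_id %in% foi, ,
                                     drop = FALSE]
    ann <- stage("annotation", match_features_level3(feat_meta, db, cfg$ppm))
    if (length(spectra) && nrow(ann)) {
      ann <- msms_upgrade(ann, spectra, db, feat_meta,
                          min_shared = cfg$min_shared_fragments)
    }
    write_tsv(ann, file.path(out_dir, paste0("annotation_", wt, ".tsv")))

    enr <- NULL
    universe <- unique(ann$kegg_id[!is.na(ann$kegg_id)])
    if (length(universe)) {
      hit_ids <- unique(ann$kegg_id[!is.na(ann$kegg_id) & ann$level <= 2])
      if (!length(hit_ids)) hit_ids <- universe
      enr <- stage("enrichment", enrich(hit_ids, universe, pathways))
      write_tsv(enr, file.path(out_dir, paste0("enrichment_", wt, ".tsv")))
    }

    per_wound[[wt]] <- list(
      n_features_of_interest = length(foi),
      chosen_k = if (is.null(traj)) NA_integer_ else traj$k,
      pattern_counts = if (is.null(traj)) NULL else
        as.list(table(traj$pattern_by_feature)),
      n_day7_responders = nrow(responders),
      n_annotated = length(unique(ann$feature_id)),
      features_of_interest = foi, trajectory = traj,
      anova = scan, ttest = tt, annotation = ann, enrichment = enr)
  }

  summary <- list(
    n_features_input = n0,
    filter_counts = counts,
    n_features_normalized = nrow(normalized$intensities),
    per_wound = lapply(per_wound, function(w) {
      w[c("n_features_of_interest", "chosen_k", "pattern_counts",
          "n_day7_responders", "n_annotated")]
    })
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  cfg_for_hash <- cfg
  cfg_for_hash$sim <- unclass(cfg_for_hash$sim)
  cfg_json <- jsonlite::toJSON(unclass(cfg_for_hash), auto_unbox = TRUE,
                               digits = NA, null = "null")
  tmp <- tempfile()
  writeLines(as.character(cfg_json), tmp)
  manifest <- list(
    package = "woundmetab",
    version = as.character(utils::packageVersion("woundmetab")),
    seed = cfg$seed,
    config_hash = unname(tools::md5sum(tmp)))
  unlink(tmp)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(normalized = normalized, per_wound = per_wound,
                 summary = summary))
}
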
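#' Read a feature table from a wide TSV plus sample-metadata sidecar
#'
#' The wide TSV has one row per feature with columns `feature_id`, `mz`,
#' `rt`, `mode` followed by one intensity column per sample; empty cells are
#' missing values (never zero-filled). The sidecar TSV has one row per
#' sample with columns `sample_id`, `injection_order`, `kind`, `pig_id`,
#' `wound_type`, `treatment`, `day`.
#'
#' @param path Path to the wide intensity TSV.
#' @param samples Path to the sample-metadata sidecar TSV.
#' @param dialect Table dialect; only `"wide_tsv"` is supported.
#' @return A validated [feature_table()].
#' @export
read_feature_table <- function(path, samples, dialect = "wide_tsv") {
  dialect <- match.arg(dialect, "wide_tsv")
  if (!file.exists(path)) stop("no such file: ", path)
  if (!file.exists(samples)) stop("no such file: ", samples)
  wide <- utils::read.delim(path, check.names = FALSE, na.strings = "",
                            stringsAsFactors = FALSE)
  meta_cols <- c("feature_id", "mz", "rt", "mode")
  if (!all(meta_cols %in% names(wide)[1:4])) {
    stop("feature table must start with columns: ",
         paste(meta_cols, collapse = ", "))
  }
  smeta <- utils::read.delim(samples, na.strings = "", stringsAsFactors = FALSE)
  sample_ids <- setdiff(names(wide), meta_cols)
  missing_meta <- setdiff(sample_ids, smeta$sample_id)
  if (length(missing_meta)) {
    stop("sample(s) present in matrix but absent from sidecar: ",
         paste(missing_meta, collapse = ", "))
  }
  smeta <- smeta[match(sample_ids, smeta$sample_id), , drop = FALSE]
  intens <- as.matrix(wide[, sample_ids, drop = FALSE])
  feature_table(intens, wide[meta_cols], smeta)
}

fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else sprintf("%.15g", v)
  }, character(1))
  out
}

#' Write a feature table (wide TSV + sidecar)
#'
#' @param x A `feature_table`.
#' @param path Output path for the wide intensity TSV.
#' @param samples Output path for the sample-metadata sidecar TSV.
#' @return Invisibly, `x`.
#' @export
write_feature_table <- function(x, path, samples) {
  wide <- data.frame(
    feature_id = x$features$feature_id,
    mz = fmt_num(x$features$mz),
    rt = fmt_num(x$features$rt),
    mode = x$features$mode,
    stringsAsFactors = FALSE, check.names = FALSE
  )
  for (j in seq_len(ncol(x$intensities))) {
    wide[[x$samples$sample_id[j]]] <- fmt_num(x$intensities[, j])
  }
  utils::write.table(wide, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  s <- x$samples
  for (col in names(s)) if (is.numeric(s[[col]])) s[[col]] <- fmt_num(s[[col]])
  utils::write.table(s, samples, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(x)
}

#' Parse a molecular formula into an element count map
#'
#' Supports the elements encountered in small-molecule metabolomics
#' (C, H, N, O, P, S, Na, K, Cl). Counts default to 1 when omitted.
#'
#' @param formula Character scalar, e.g. `"C4H6N4O3"`.
#' @return Named integer vector of element counts.
#' @export
parse_formula <- function(formula) {
  if (!is.character(formula) || length(formula) != 1 || is.na(formula) ||
      !nzchar(formula)) {
    stop("formula must be a nonempty character scalar")
  }
  toks <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (!length(toks) || paste(toks, collapse = "") != formula) {
    stop("cannot parse formula: '", formula, "'")
  }
  el <- sub("[0-9]*$", "", toks)
  cnt <- sub("^[A-Za-z]+", "", toks)
  cnt <- ifelse(cnt == "", 1L, suppressWarnings(as.integer(cnt)))
  unknown <- setdiff(el, names(MONOISOTOPIC_MASS))
  if (length(unknown)) {
    stop("unknown element symbol(s) in '", formula, "': ",
         paste(unknown, collapse = ", "))
  }
  if (any(is.na(cnt)) || any(cnt <= 0)) {
    stop("invalid element count in formula: '", formula, "'")
  }
  counts <- tapply(cnt, el, sum)
  out <- as.integer(counts)
  names(out) <- names(counts)
  out
}

#' Read a compound database TSV
#'
#' Columns: `name`, `formula`, `kegg_id` (`-` or empty for none), optional
#' `fragments` (semicolon-separated fragment m/z values), optional `rt` and
#' `standard` (TRUE/FALSE flag for authentic-standard entries used by
#' level-1 annotation).
#'
#' @param path Path to the TSV file.
#' @return A list of compound records, each a list with `name`, `formula`
#'   (element count map), `kegg_id`, `fragments`, `rt`, `standard`.
#' @export
read_compound_db <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.delim(path, na.strings = "", stringsAsFactors = FALSE)
  if (!all(c("name", "formula") %in% names(tab))) {
    stop("compound DB must have columns 'name' and 'formula'")
  }
  records <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    fm <- tryCatch(parse_formula(tab$formula[i]), error = function(e) e)
    if (inherits(fm, "error")) {
      stop("compound DB line ", i + 1L, " ('", tab$name[i], "'): ",
           conditionMessage(fm))
    }
    kegg <- if ("kegg_id" %in% names(tab)) tab$kegg_id[i] else NA_character_
    if (!is.na(kegg) && (kegg == "-" || kegg == "#N/A")) kegg <- NA_character_
    frags <- NULL
    if ("fragments" %in% names(tab) && !is.na(tab$fragments[i])) {
      frags <- as.numeric(strsplit(tab$fragments[i], ";", fixed = TRUE)[[1]])
      if (any(is.na(frags)) || any(frags <= 0)) {
        stop("compound DB line ", i + 1L, ": invalid fragment m/z list")
      }
    }
    rt <- if ("rt" %in% names(tab)) suppressWarnings(as.numeric(tab$rt[i])) else NA_real_
    std <- if ("standard" %in% names(tab)) isTRUE(as.logical(tab$standard[i])) else FALSE
    records[[i]] <- list(name = tab$name[i], formula = fm, kegg_id = kegg,
                         fragments = frags, rt = rt, standard = std)
  }
  records
}

#' Write a compound database TSV
#' @param db List of compound records as returned by [read_compound_db()].
#' @param path Output path.
#' @return Invisibly, `db`.
#' @export
write_compound_db <- function(db, path) {
  fmt_formula <- function(fm) {
    ord <- intersect(c("C", "H", names(sort(fm))), names(fm))
    ord <- unique(ord)
    paste0(ord, ifelse(fm[ord] == 1, "", fm[ord]), collapse = "")
  }
  tab <- data.frame(
    name = vapply(db, `[[`, character(1), "name"),
    formula = vapply(db, function(r) fmt_formula(r$formula), character(1)),
    kegg_id = vapply(db, function(r) {
      if (is.na(r$kegg_id)) "-" else r$kegg_id
    }, character(1)),
    fragments = vapply(db, function(r) {
      if (is.null(r$fragments)) "" else paste(fmt_num(r$fragments), collapse = ";")
    }, character(1)),
    rt = vapply(db, function(r) {
      if (is.na(r$rt)) "" else fmt_num(r$rt)
    }, character(1)),
    standard = vapply(db, function(r) {
      if (isTRUE(r$standard)) "TRUE" else "FALSE"
    }, character(1)),
    stringsAsFactors = FALSE
  )
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(db)
}

#' Read pathway graphs from an edge-list TSV
#'
#' Columns: `pathway_id`, `name`, `node_a`, `node_b`. Isolated nodes are
#' listed with an empty `node_b`. Edges are undirected; self-loops are an
#' error.
#'
#' @param path Path to the TSV file.
#' @return A list of `pathway_graph` objects (fields `pathway_id`, `name`,
#'   `nodes`, `edges`; `edges` is a 2-column character matrix).
#' @export
read_pathways <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.delim(path, na.strings = "", stringsAsFactors = FALSE)
  need <- c("pathway_id", "name", "node_a", "node_b")
  if (!all(need %in% names(tab))) {
    stop("pathway file must have columns: ", paste(need, collapse = ", "))
  }
  out <- list()
  for (pid in unique(tab$pathway_id)) {
    sub <- tab[tab$pathway_id == pid, , drop = FALSE]
    has_edge <- !is.na(sub$node_b)
    if (any(is.na(sub$node_a))) stop("pathway ", pid, ": empty node_a")
    loops <- has_edge & sub$node_a == sub$node_b
    if (any(loops)) {
      stop("pathway ", pid, ": self-loop edge on node ",
           sub$node_a[which(loops)[1]])
    }
    edges <- cbind(sub$node_a[has_edge], sub$node_b[has_edge])
    nodes <- unique(c(sub$node_a, sub$node_b[has_edge]))
    out[[pid]] <- pathway_graph(pid, sub$name[1], nodes, edges)
  }
  unname(out)
}

#' Construct a pathway graph
#' @param pathway_id,name Identifiers.
#' @param nodes Character vector of compound (KEGG) IDs.
#' @param edges Two-column character matrix of undirected edges.
#' @return A `pathway_graph` object.
#' @export
pathway_graph <- function(pathway_id, name, nodes, edges = NULL) {
  if (is.null(edges) || length(edges) == 0) {
    edges <- matrix(character(0), ncol = 2)
  }
  edges <- matrix(as.character(edges), ncol = 2)
  if (any(edges[, 1] == edges[, 2])) stop("self-loop edge in pathway ", pathway_id)
  if (!all(c(edges) %in% nodes)) stop("edge endpoint not in node set")
  structure(list(pathway_id = pathway_id, name = name,
                 nodes = unique(as.character(nodes)), edges = edges),
            class = "pathway_graph")
}

#' @export
print.pathway_graph <- function(x, ...) {
  cat("pathway_graph ", x$pathway_id, " (", x$name, "): ",
      length(x$nodes), " nodes, ", nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Write pathway graphs to an edge-list TSV
#' @param pathways List of `pathway_graph` objects.
#' @param path Output path.
#' @return Invisibly, `pathways`.
#' @export
write_pathways <- function(pathways, path) {
  rows <- do.call(rbind, lapply(pathways, function(p) {
    iso <- setdiff(p$nodes, c(p$edges))
    rbind(
      if (nrow(p$edges)) data.frame(pathway_id = p$pathway_id, name = p$name,
                                    node_a = p$edges[, 1], node_b = p$edges[, 2],
                                    stringsAsFactors = FALSE),
      if (length(iso)) data.frame(pathway_id = p$pathway_id, name = p$name,
                                  node_a = iso, node_b = NA_character_,
                                  stringsAsFactors = FALSE)
    )
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(pathways)
}

#' Read MS/MS spectra from an MGF file
#'
#' Minimal Mascot Generic Format reader: each `BEGIN IONS`/`END IONS` block
#' carries a `TITLE=` line naming the feature and one `m/z intensity` peak
#' per line. Intensities are retained but downstream fragment matching uses
#' only the masses.
#'
#' @param path Path to the MGF file.
#' @return Named list mapping feature_id to a numeric vector of fragment
#'   m/z values (intensities as the `"intensity"` attribute).
#' @export
read_spectra <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- trimws(lines)
  out <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    if (!nzchar(lines[i])) { i <- i + 1L; next }
    if (lines[i] != "BEGIN IONS") {
      stop("malformed MGF: expected BEGIN IONS at line ", i)
    }
    j <- i + 1L
    title <- NULL
    mz <- numeric(0)
    inten <- numeric(0)
    ended <- FALSE
    while (j <= n) {
      ln <- lines[j]
      if (ln == "END IONS") { ended <- TRUE; break }
      if (ln == "BEGIN IONS") break
      if (grepl("^TITLE=", ln)) {
        title <- sub("^TITLE=", "", ln)
      } else if (grepl("^[A-Z]+=", ln)) {
        # other headers (PEPMASS, CHARGE, ...) ignored
      } else if (nzchar(ln)) {
        parts <- strsplit(ln, "[ \t]+")[[1]]
        v <- suppressWarnings(as.numeric(parts))
        if (is.na(v[1])) stop("malformed MGF peak line ", j, ": '", ln, "'")
        mz <- c(mz, v[1])
        inten <- c(inten, if (length(v) > 1) v[2] else NA_real_)
      }
      j <- j + 1L
    }
    if (!ended) stop("malformed MGF: block starting at line ", i,
                     " missing END IONS")
    if (is.null(title)) stop("malformed MGF: block at line ", i, " has no TITLE")
    attr(mz, "intensity") <- inten
    out[[title]] <- mz
    i <- j + 1L
  }
  out
}
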
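#' Map compound names or KEGG IDs onto a pathway dictionary
#'
#' Case-insensitive exact name matching or direct KEGG-ID matching; no
#' fuzzy matching. Inputs that match nothing are returned verbatim.
#'
#' @param names_or_ids Character vector of compound names and/or KEGG IDs.
#' @param dictionary data.frame with columns `name` and `kegg_id`.
#' @return List with `mapped` (unique KEGG IDs) and `unmapped` (inputs
#'   with no dictionary entry, verbatim).
#' @export
map_compounds <- function(names_or_ids, dictionary) {
  stopifnot(all(c("name", "kegg_id") %in% names(dictionary)))
  dict_name <- tolower(dictionary$name)
  mapped <- character(0)
  unmapped <- character(0)
  for (q in names_or_ids) {
    if (!is.na(q) && q %in% dictionary$kegg_id) {
      mapped <- c(mapped, q)
      next
    }
    hit <- which(dict_name == tolower(q))
    if (length(hit)) {
      kid <- dictionary$kegg_id[hit[1]]
      if (!is.na(kid)) {
        mapped <- c(mapped, kid)
        next
      }
    }
    unmapped <- c(unmapped, q)
  }
  list(mapped = unique(mapped), unmapped = unmapped)
}

#' Hypergeometric over-representation p-value
#'
#' Upper-tail probability `P(X >= n_overlap)` for `X` hypergeometric with
#' `n_universe` compounds of which `n_pathway` belong to the pathway and
#' `n_hits` were drawn.
#'
#' @param n_universe Background set size.
#' @param n_pathway Pathway members within the universe.
#' @param n_hits Hit compounds within the universe.
#' @param n_overlap Hits that are pathway members.
#' @return Exact tail probability.
#' @export
hypergeom_ora <- function(n_universe, n_pathway, n_hits, n_overlap) {
  if (n_overlap > min(n_pathway, n_hits) || n_pathway > n_universe ||
      n_hits > n_universe || any(c(n_universe, n_pathway, n_hits, n_overlap) < 0)) {
    stop("inconsistent hypergeometric counts")
  }
  stats::phyper(n_overlap - 1, n_pathway, n_universe - n_pathway, n_hits,
                lower.tail = FALSE)
}

#' Relative betweenness centrality of pathway compounds
#'
#' Betweenness centrality over unweighted shortest paths in the undirected
#' compound graph, pair-normalized by `(n-1)(n-2)/2` and then scaled by the
#' maximum node value so the most central compound scores 1 (graphs with
#' no intermediate nodes stay all-zero). Disconnected components are
#' handled by counting shortest paths within components only.
#'
#' @param pathway A `pathway_graph`.
#' @return Named numeric vector, centrality in `[0, 1]` per node.
#' @export
relative_betweenness <- function(pathway) {
  nodes <- pathway$nodes
  n <- length(nodes)
  out <- stats::setNames(rep(0, n), nodes)
  if (n < 3) return(out)
  g <- igraph::graph_from_data_frame(
    as.data.frame(pathway$edges, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE))
  bet <- igraph::betweenness(g, directed = FALSE, normalized = TRUE)
  if (max(bet) > 0) bet <- bet / max(bet)
  out[names(bet)] <- bet
  out
}

#' Pathway over-representation with topology impact
#'
#' For each pathway: restricts the membership to the universe, computes the
#' hypergeometric over-representation p-value of the hit compounds, and an
#' impact score defined as the sum of relative betweenness centralities of
#' the hit nodes over the sum across all pathway nodes (0 when the pathway
#' has no central nodes). Results are sorted by ascending p-value with a
#' BH-adjusted q-value across pathways.
#'
#' @param hits Character vector of hit KEGG IDs (must be within `universe`).
#' @param universe Character vector of background KEGG IDs.
#' @param pathways List of `pathway_graph` objects.
#' @return data.frame with one row per pathway: `pathway_id`, `name`,
#'   `n_universe`, `n_pathway`, `n_hits_total`, `n_overlap`, `p_value`,
#'   `q_value`, `impact`, `hit_ids`.
#' @export
enrich <- function(hits, universe, pathways) {
  universe <- unique(universe)
  hits <- unique(hits)
  if (!length(universe)) stop("empty universe")
  if (!all(hits %in% universe)) stop("hits must be a subset of the universe")
  rows <- lapply(pathways, function(p) {
    members <- intersect(p$nodes, universe)
    overlap <- intersect(members, hits)
    pval <- hypergeom_ora(length(universe), length(members), length(hits),
                          length(overlap))
    bet <- relative_betweenness(p)
    denom <- sum(bet)
    impact <- if (denom > 0) sum(bet[intersect(p$nodes, hits)]) / denom else 0
    data.frame(pathway_id = p$pathway_id, name = p$name,
               n_universe = length(universe), n_pathway = length(members),
               n_hits_total = length(hits), n_overlap = length(overlap),
               p_value = pval, impact = impact,
               hit_ids = paste(sort(overlap), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- bh_adjust(out$p_value)
  out <- out[order(out$p_value, out$pathway_id), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("pathway_id", "name", "n_universe", "n_pathway", "n_hits_total",
          "n_overlap", "p_value", "q_value", "impact", "hit_ids")]
}
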
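#' Hypergeometric over-representation of a compound set in a pathway
#'
#' With a universe of `|U|` compounds of which `K` belong to the pathway
#' and a query of `n` universe compounds with `k` pathway hits, the
#' enrichment p-value is the upper tail `P(X >= k)` of the hypergeometric
#' distribution. Query compounds outside the universe are dropped with a
#' warning.
#'
#' @param query character vector of compound ids (e.g. KEGG C-numbers).
#' @param pathway a pathway (list with `compounds`), or a character
#'   vector of compounds.
#' @param universe character vector of all background compounds.
#' @return list: `k` (hits), `K` (pathway size), `n` (mapped query size),
#'   `p`.
#' @export
ora_hypergeometric <- function(query, pathway, universe) {
  if (length(universe) == 0) abort("empty universe")
  comp <- if (is.list(pathway)) pathway$compounds else pathway
  if (!all(comp %in% universe))
    abort("pathway compounds must be a subset of the universe")
  query <- unique(query)
  unmapped <- setdiff(query, universe)
  if (length(unmapped) > 0) {
    warning(sprintf("%d query compound(s) not in universe; dropped",
                    length(unmapped)))
    query <- intersect(query, universe)
  }
  k <- length(intersect(query, comp))
  K <- length(comp)
  n <- length(query)
  p <- phyper(k - 1, K, length(universe) - K, n, lower.tail = FALSE)
  list(k = k, K = K, n = n, p = p)
}

#' Pathway impact from relative betweenness centrality
#'
#' Betweenness centrality is computed for every compound node of the
#' pathway graph (fractional credit over tied shortest paths, per
#' connected component for disconnected graphs); the impact is the summed
#' centrality of the hit compounds divided by the summed centrality of all
#' pathway compounds. Normalization constants cancel in the ratio. When
#' the denominator is zero (complete graphs, <= 2 nodes) the impact is 0.
#'
#' @param hits character vector of hit compound ids, a subset of the
#'   pathway's compounds.
#' @param pathway list with `compounds` and `edges` (2-column matrix).
#' @return impact in `[0, 1]`.
#' @export
pathway_impact <- function(hits, pathway) {
  comp <- pathway$compounds
  if (!all(hits %in% comp))
    abort("hits must be a subset of the pathway's compounds")
  if (length(comp) <= 2 || is.null(pathway$edges)) return(0)
  g <- igraph::graph_from_data_frame(
    as.data.frame(pathway$edges, stringsAsFactors = FALSE),
    directed = FALSE, vertices = data.frame(name = comp))
  bc <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  denom <- sum(bc)
  if (denom == 0) return(0)
  sum(bc[hits]) / denom
}

#' Enrich a query against a whole pathway library
#'
#' Per-pathway hypergeometric over-representation plus topology impact,
#' with BH FDR across the entire library (pathways with zero hits stay in
#' the FDR denominator), sorted by p ascending.
#'
#' @param query character vector of compound ids.
#' @param pathway_library a `pathway_library` (see
#'   [generate_pathway_library()] / [read_gmt()]).
#' @param universe background compounds; defaults to the union of all
#'   library compounds.
#' @return data.frame: `pathway_id`, `name`, `k`, `K`, `coverage`,
#'   `p_hyper`, `fdr`, `impact`.
#' @export
enrich_all <- function(query, pathway_library, universe = NULL) {
  if (length(pathway_library) == 0) abort("pathway library is empty")
  if (is.null(universe))
    universe <- sort(unique(unlist(lapply(pathway_library, `[[`,
                                          "compounds"))))
  mapped <- intersect(unique(query), universe)
  if (length(mapped) < length(unique(query)))
    warning(sprintf("%d query compound(s) not in universe; dropped",
                    length(unique(query)) - length(mapped)))
  rows <- lapply(pathway_library, function(pw) {
    o <- ora_hypergeometric(mapped, pw, universe)
    hits <- intersect(mapped, pw$compounds)
    data.frame(pathway_id = pw$pathway_id, name = pw$name, k = o$k, K = o$K,
               coverage = sprintf("%d/%d", o$k, o$K), p_hyper = o$p,
               impact = pathway_impact(hits, pw), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_fdr(out$p_hyper)
  out <- out[order(out$p_hyper), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("pathway_id", "name", "k", "K", "coverage", "p_hyper", "fdr",
          "impact")]
}
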
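#' Generate a synthetic spectral library matching a feature table
#'
#' Emulates an in-house library of characterized metabolites: a fraction
#' `config$frac_identified` of the non-contaminant features receive a
#' library entry at their exact m/z and retention time (so they match
#' within any sensible tolerance), with a KEGG-style compound id for ~70%
#' of entries and a reference MS/MS peak list for every entry. Decoy
#' entries are added at +50 ppm, beyond the 15 ppm matching window, and
#' must never be matched. Half of the identified features also receive an
#' "acquired" MS/MS spectrum (a copy of the reference within fragment
#' tolerance), exercising validation level 2; the rest stay at level 1.
#'
#' @param table an [injection_table()].
#' @param truth ground-truth data.frame from [generate_injection_table()].
#' @param config a [sim_config()] object.
#' @return a list: `library` (a `spectral_library`: `entries` data.frame
#'   with name/kegg_id/mz/rt/adduct plus a parallel `ms2` list),
#'   `feature_identity` (feature_id -> entry name for truly identified
#'   features), and `observed_ms2` (named list of acquired feature spectra,
#'   2-column matrices mz/intensity).
#' @export
generate_library <- function(table, truth, config) {
  config <- validate_sim_config(config)
  set.seed(config$seed + 2L)
  fm <- table$feature_meta
  noncontam <- fm$feature_id[!truth$is_contaminant[match(fm$feature_id,
                                                         truth$feature_id)]]
  n_id <- round(config$frac_identified * length(noncontam))
  identified <- sort(sample(noncontam, n_id))
  idx <- match(identified, fm$feature_id)

  make_ms2 <- function(precursor) {
    np <- sample(6:12, 1)
    frag_mz <- sort(round(precursor - c(0, sort(runif(np - 1, 10,
                                                      precursor - 30))), 4))
    cbind(mz = frag_mz, intensity = round(runif(np, 5, 100), 1))
  }

  entries <- data.frame(name = sprintf("MET%04d", seq_len(n_id)),
                        kegg_id = ifelse(runif(n_id) < 0.7,
                                         sprintf("C%05d", sample.int(99999, n_id)),
                                         NA_character_),
                        mz = fm$mz[idx], rt = fm$rt[idx],
                        adduct = "[M + H]", stringsAsFactors = FALSE)
  ms2 <- lapply(entries$mz, make_ms2)

  n_decoy <- max(1L, round(0.2 * n_id))
  decoy_src <- sample(nrow(fm), n_decoy)
  decoys <- data.frame(name = sprintf("DECOY%04d", seq_len(n_decoy)),
                       kegg_id = NA_character_,
                       mz = round(fm$mz[decoy_src] * (1 + 50e-6), 4),
                       rt = fm$rt[decoy_src], adduct = "[M + H]",
                       stringsAsFactors = FALSE)
  ms2 <- c(ms2, lapply(decoys$mz, make_ms2))
  entries <- rbind(entries, decoys)

  lib <- structure(list(entries = entries, ms2 = ms2),
                   class = "spectral_library")

  acq <- sample(c(TRUE, FALSE), n_id, replace = TRUE)
  observed <- setNames(ms2[seq_len(n_id)][acq], identified[acq])

  list(library = lib,
       feature_identity = data.frame(feature_id = identified,
                                     name = entries$name[seq_len(n_id)],
                                     stringsAsFactors = FALSE),
       observed_ms2 = observed)
}

#' Generate a synthetic pathway library
#'
#' Creates `n_pathways` compound sets over a universe of KEGG-style ids,
#' guaranteeing that every universe compound belongs to at least one
#' pathway (so the GMT union equals the universe) and that compounds are
#' shared across pathways. Each pathway carries a connected undirected
#' compound graph (random spanning tree plus extra edges) for
#' betweenness-based impact scoring.
#'
#' @param n_pathways number of pathways.
#' @param size_range integer range `c(min, max)` of target pathway sizes.
#' @param universe_size number of distinct compounds overall (ignored when
#'   `compounds` is given).
#' @param seed integer seed.
#' @param compounds optional character vector to use as the universe (e.g.
#'   the KEGG ids of a spectral library), instead of synthetic C-numbers.
#' @return a `pathway_library`: list of pathways, each a list with
#'   `pathway_id`, `name`, `compounds` (character) and `edges`
#'   (2-column character matrix over `compounds`).
#' @export
generate_pathway_library <- function(n_pathways, size_range, universe_size,
                                     seed = 1L, compounds = NULL) {
  universe <- if (!is.null(compounds)) sort(unique(compounds)) else
    sprintf("C%05d", seq_len(universe_size))
  universe_size <- length(universe)
  if (max(size_range) > universe_size)
    abort("size_range max (%d) exceeds universe_size (%d)",
          max(size_range), universe_size)
  if (min(size_range) < 1) abort("pathway sizes must be >= 1")
  set.seed(seed)
  # guarantee coverage: every compound seeds one pathway
  seed_assign <- sample.int(n_pathways, universe_size, replace = TRUE)
  sizes <- if (length(size_range) == 1) rep(size_range, n_pathways) else
    sample(seq(min(size_range), max(size_range)), n_pathways, replace = TRUE)
  pathways <- vector("list", n_pathways)
  for (i in seq_len(n_pathways)) {
    comp <- universe[seed_assign == i]
    if (length(comp) < sizes[i])
      comp <- union(comp, sample(setdiff(universe, comp),
                                 sizes[i] - length(comp)))
    comp <- sort(comp)
    K <- length(comp)
    edges <- NULL
    if (K >= 2) {
      to <- vapply(2:K, function(j) sample.int(j - 1L, 1L), 1L)
      edges <- cbind(comp[to], comp[2:K])
      n_extra <- max(0L, round(K / 3))
      if (K >= 3 && n_extra > 0) {
        pool <- t(combn(comp, 2))
        have <- paste(pmin(edges[, 1], edges[, 2]),
                      pmax(edges[, 1], edges[, 2]))
        pool <- pool[!paste(pmin(pool[, 1], pool[, 2]),
                            pmax(pool[, 1], pool[, 2])) %in% have, ,
                     drop = FALSE]
        if (nrow(pool) > 0)
          edges <- rbind(edges,
                         pool[sample.int(nrow(pool),
                                         min(n_extra, nrow(pool))), ,
                              drop = FALSE])
      }
    }
    pathways[[i]] <- list(pathway_id = sprintf("PW%03d", i),
                          name = sprintf("Synthetic pathway %03d", i),
                          compounds = comp, edges = edges)
  }
  structure(pathways, class = "pathway_library")
}

#' @export
print.pathway_library <- function(x, ...) {
  cat(sprintf("Pathway library: %d pathways, %d distinct compounds\n",
              length(x), length(unique(unlist(lapply(x, `[[`, "compounds"))))))
  invisible(x)
}
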
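#' Match features against a spectral library by m/z and retention time
#'
#' A feature matches a library entry when the mass error is within
#' `ppm_tol` parts per million and the retention-time error within
#' `rt_tol_s` seconds. Ties between candidate entries are broken by the
#' smallest ppm error, then the smallest RT error. Unmatched features are
#' meant to be dropped from downstream analysis (the pipeline keeps only
#' matched features).
#'
#' @param features data.frame with `feature_id`, `mz`, `rt` columns (e.g.
#'   the `feature_meta` of an [injection_table()]).
#' @param library a `spectral_library` (see [read_msp()]).
#' @param ppm_tol mass tolerance in ppm; default 15.
#' @param rt_tol_s retention-time tolerance in seconds; default 20.
#' @return data.frame, one row per feature: `feature_id`, `name`,
#'   `kegg_id`, `adduct`, `entry_index`, `ppm_error`, `rt_error`,
#'   `matched` (logical).
#' @export
match_library <- function(features, library, ppm_tol = 15, rt_tol_s = 20) {
  e <- library$entries
  if (is.null(e) || nrow(e) == 0) abort("spectral library is empty")
  out <- lapply(seq_len(nrow(features)), function(i) {
    ppm <- abs(features$mz[i] - e$mz) / e$mz * 1e6
    drt <- abs(features$rt[i] - e$rt)
    cand <- which(ppm <= ppm_tol & drt <= rt_tol_s)
    if (length(cand) == 0)
      return(data.frame(feature_id = features$feature_id[i],
                        name = NA_character_, kegg_id = NA_character_,
                        adduct = NA_character_, entry_index = NA_integer_,
                        ppm_error = NA_real_, rt_error = NA_real_,
                        matched = FALSE, stringsAsFactors = FALSE))
    best <- cand[order(ppm[cand], drt[cand])][1]
    data.frame(feature_id = features$feature_id[i], name = e$name[best],
               kegg_id = e$kegg_id[best], adduct = e$adduct[best],
               entry_index = best, ppm_error = ppm[best],
               rt_error = drt[best], matched = TRUE,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Compare an observed MS/MS spectrum with a reference spectrum
#'
#' Peaks are paired greedily by closest m/z within `frag_tol` (each peak
#' used at most once). Coverage is the number of paired peaks divided by
#' the reference peak count; the dot product is the cosine of the paired
#' intensity vectors, where unpaired peaks contribute zero to the numerator
#' but their squared intensity to the norms. A match requires
#' (coverage >= 0.5 OR shared peaks >= 5) AND dot product > 0.5.
#'
#' @param observed,reference 2-column matrices (`mz`, `intensity`).
#' @param frag_tol fragment m/z tolerance in Thomson; default 0.01.
#' @return list: `coverage`, `shared_peaks`, `dot_product`, `is_match`.
#' @export
msms_match <- function(observed, reference, frag_tol = 0.01) {
  if (is.null(observed) || nrow(observed) == 0)
    abort("observed spectrum is empty")
  if (is.null(reference) || nrow(reference) == 0)
    abort("reference spectrum is empty")
  pairs <- expand.grid(o = seq_len(nrow(observed)),
                       r = seq_len(nrow(reference)))
  pairs$d <- abs(observed[pairs$o, 1] - reference[pairs$r, 1])
  pairs <- pairs[pairs$d <= frag_tol, , drop = FALSE]
  pairs <- pairs[order(pairs$d), , drop = FALSE]
  used_o <- logical(nrow(observed)); used_r <- logical(nrow(reference))
  num <- 0; shared <- 0L
  for (k in seq_len(nrow(pairs))) {
    o <- pairs$o[k]; r <- pairs$r[k]
    if (used_o[o] || used_r[r]) next
    used_o[o] <- TRUE; used_r[r] <- TRUE
    num <- num + observed[o, 2] * reference[r, 2]
    shared <- shared + 1L
  }
  dot <- unname(num / (sqrt(sum(observed[, 2]^2)) *
                         sqrt(sum(reference[, 2]^2))))
  coverage <- shared / nrow(reference)
  list(coverage = coverage, shared_peaks = shared, dot_product = dot,
       is_match = (coverage >= 0.5 || shared >= 5) && dot > 0.5)
}

#' Assign an identification validation level
#'
#' For a library-matched feature: no acquired MS/MS gives level 1 (m/z and
#' retention time only); an acquired MS/MS that matches the reference
#' fragmentation pattern gives level 2; an acquired MS/MS that does not
#' match rejects the identity (the feature is excluded downstream).
#'
#' @param matched logical: does the feature have a library match?
#' @param msms_available logical: was an MS/MS spectrum acquired?
#' @param msms_is_match logical: did [msms_match()] declare a match
#'   (ignored when `msms_available` is FALSE)?
#' @return one of `"level1"`, `"level2"`, `"rejected"`.
#' @export
assign_validation_level <- function(matched, msms_available,
                                    msms_is_match = FALSE) {
  if (!isTRUE(matched)) abort("validation level requires a library match")
  if (!msms_available) return("level1")
  if (isTRUE(msms_is_match)) "level2" else "rejected"
}

#' Identify the features of a table and annotate them
#'
#' Convenience wrapper: matches features with [match_library()], evaluates
#' acquired MS/MS spectra with [msms_match()], assigns validation levels,
#' and returns the identification table for matched, non-rejected
#' features.
#'
#' @param table an [injection_table()].
#' @param library a `spectral_library`.
#' @param observed_ms2 named list of acquired spectra keyed by feature id.
#' @param ppm_tol,rt_tol_s,frag_tol tolerances, see [match_library()] and
#'   [msms_match()].
#' @return data.frame of identifications with `validation_level`, plus
#'   MS/MS diagnostics where available; rejected and unmatched features
#'   are absent.
#' @export
identify_features <- function(table, library, observed_ms2 = list(),
                              ppm_tol = 15, rt_tol_s = 20, frag_tol = 0.01) {
  ids <- match_library(table$feature_meta, library, ppm_tol, rt_tol_s)
  ids <- ids[ids$matched, , drop = FALSE]
  ids$msms_coverage <- NA_real_
  ids$msms_shared_peaks <- NA_integer_
  ids$msms_dot_product <- NA_real_
  ids$validation_level <- "level1"
  for (i in seq_len(nrow(ids))) {
    obs <- observed_ms2[[ids$feature_id[i]]]
    ref <- library$ms2[[ids$entry_index[i]]]
    if (is.null(obs) || is.null(ref)) next
    m <- msms_match(obs, ref, frag_tol)
    ids$msms_coverage[i] <- m$coverage
    ids$msms_shared_peaks[i] <- m$shared_peaks
    ids$msms_dot_product[i] <- m$dot_product
    ids$validation_level[i] <- assign_validation_level(TRUE, TRUE, m$is_match)
  }
  ids[ids$validation_level != "rejected", , drop = FALSE]
}
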
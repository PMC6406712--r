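#' Injection table: feature-by-injection intensities with run metadata
#'
#' The raw unit of preprocessing: an intensity matrix (features in rows,
#' injections in columns) together with the injection sequence (type,
#' order, sample, dilution volume) and per-feature m/z and retention time.
#'
#' @param intensities numeric matrix, features x injections; `NA` marks a
#'   missing (undetected) value; values must be nonnegative.
#' @param injections data.frame with columns `injection_id`, `type` (one
#'   of study/qc/blank/dilution), `injection_order` (unique, contiguous
#'   positive integers), `sample_id` (study injections only), `volume`
#'   (uL, dilution injections only).
#' @param feature_meta data.frame with `feature_id`, `mz`, `rt` (seconds);
#'   optional annotation columns are carried along.
#' @param log2 whether `intensities` are already log2-transformed.
#' @param provenance character vector of processing steps applied so far.
#' @return an object of class `injection_table`.
#' @export
injection_table <- function(intensities, injections, feature_meta,
                            log2 = FALSE, provenance = character()) {
  stopifnot(is.matrix(intensities),
            nrow(intensities) == nrow(feature_meta),
            ncol(intensities) == nrow(injections))
  types <- c("study", "qc", "blank", "dilution")
  if (!all(injections$type %in% types))
    abort("injection type must be one of %s", paste(types, collapse = ", "))
  ord <- injections$injection_order
  if (anyDuplicated(ord) || !all(sort(ord) == seq_along(ord)))
    abort("injection_order must be unique and contiguous starting at 1")
  bad <- injections$type %in% c("qc", "blank") & !is.na(injections$sample_id)
  if (any(bad)) abort("qc/blank injections must not carry a sample_id")
  if (!log2 && any(intensities < 0, na.rm = TRUE))
    abort("raw intensities must be nonnegative")
  structure(list(intensities = intensities, injections = injections,
                 feature_meta = feature_meta, log2 = log2,
                 provenance = provenance),
            class = "injection_table")
}

#' @export
print.injection_table <- function(x, ...) {
  tab <- table(x$injections$type)
  cat(sprintf("Injection table: %d features x %d injections (%s)%s\n",
              nrow(x$intensities), ncol(x$intensities),
              paste(sprintf("%d %s", tab, names(tab)), collapse = ", "),
              if (x$log2) ", log2" else ""))
  if (length(x$provenance))
    cat("  steps:", paste(x$provenance, collapse = " -> "), "\n")
  invisible(x)
}

#' @export
dim.injection_table <- function(x) dim(x$intensities)

#' Column indices of a given injection type
#' @noRd
inj_which <- function(table, type) which(table$injections$type == type)

#' Drop features from an injection table
#' @noRd
drop_features <- function(table, drop_idx, step, reason) {
  keep <- setdiff(seq_len(nrow(table$intensities)), drop_idx)
  report <- filter_report(step,
                          features_before = nrow(table$intensities),
                          features_after = length(keep),
                          samples_before = ncol(table$intensities),
                          samples_after = ncol(table$intensities),
                          removed = table$feature_meta$feature_id[drop_idx],
                          reasons = rep(reason, length(drop_idx)))
  table$intensities <- table$intensities[keep, , drop = FALSE]
  table$feature_meta <- table$feature_meta[keep, , drop = FALSE]
  table$provenance <- c(table$provenance, step)
  list(table = table, report = report)
}

#' Per-step filtering report
#'
#' @param step step name.
#' @param features_before,features_after,samples_before,samples_after counts.
#' @param removed character vector of removed ids.
#' @param reasons character vector parallel to `removed`.
#' @return an object of class `filter_report`.
#' @export
filter_report <- function(step, features_before, features_after,
                          samples_before, samples_after,
                          removed = character(), reasons = character()) {
  stopifnot(length(removed) == length(reasons))
  structure(list(step = step, features_before = features_before,
                 features_after = features_after,
                 samples_before = samples_before,
                 samples_after = samples_after,
                 removed = as.character(removed),
                 reasons = as.character(reasons)),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("[%s] features %d -> %d, injections %d -> %d (%d removed)\n",
              x$step, x$features_before, x$features_after,
              x$samples_before, x$samples_after, length(x$removed)))
  invisible(x)
}
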
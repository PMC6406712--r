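#' @noRd
raw_intensities <- function(table) {
  if (isTRUE(table$log2)) 2^table$intensities else table$intensities
}

#' Remove blank-borne contaminant features
#'
#' A feature is called a contaminant and removed when its mean intensity in
#' blank injections reaches `blank_ratio` times its mean intensity in
#' pooled-QC injections (missing values counted as zero intensity), i.e.
#' when it is present in blanks at a substantial fraction of its pooled
#' level.
#'
#' @param table an [injection_table()] containing at least one blank.
#' @param blank_ratio removal threshold on mean(blank)/mean(QC);
#'   default 0.5.
#' @return list with the filtered `table` and a [filter_report()].
#' @export
filter_blank_contaminants <- function(table, blank_ratio = 0.5) {
  blanks <- inj_which(table, "blank")
  if (length(blanks) == 0)
    abort(paste("no blank injections present; pass the table through",
                "without this step explicitly if blanks were not acquired"))
  qcs <- inj_which(table, "qc")
  if (length(qcs) == 0) abort("no qc injections present")
  raw <- raw_intensities(table)
  raw[is.na(raw)] <- 0
  blank_mean <- rowMeans(raw[, blanks, drop = FALSE])
  qc_mean <- rowMeans(raw[, qcs, drop = FALSE])
  drop <- which(blank_mean >= blank_ratio * qc_mean)
  drop_features(table, drop, "blank_filter",
                sprintf("blank/QC ratio >= %g", blank_ratio))
}

#' Keep features linear in the QC dilution series
#'
#' A feature is retained only if the absolute Pearson correlation between
#' its intensities and the injection volumes across the dilution series is
#' at least `min_abs_r`. Missing dilution values count as zero intensity
#' (absence at low volume is informative); a feature with zero variance
#' across the series cannot demonstrate linearity and is removed.
#'
#' @param table an [injection_table()] with >= 3 dilution injections at
#'   distinct volumes.
#' @param min_abs_r minimum |Pearson r|; default 0.7.
#' @return list with the filtered `table` and a [filter_report()].
#' @export
filter_dilution_series <- function(table, min_abs_r = 0.7) {
  dil <- inj_which(table, "dilution")
  vols <- table$injections$volume[dil]
  if (length(unique(vols)) < 3)
    abort("need >= 3 dilution injections with distinct volumes (got %d)",
          length(unique(vols)))
  raw <- raw_intensities(table)[, dil, drop = FALSE]
  raw[is.na(raw)] <- 0
  r <- apply(raw, 1, function(x)
    if (sd(x) == 0) NA_real_ else cor(x, vols))
  drop <- which(is.na(r) | abs(r) < min_abs_r)
  drop_features(table, drop, "dilution_filter",
                sprintf("|r| < %g vs injection volume", min_abs_r))
}

#' Log2-transform intensities
#'
#' Positive intensities become their log2; zeros and missing values stay
#' missing. Negative intensities are an input error.
#'
#' @param table an [injection_table()] with raw intensities.
#' @return the table with `log2 = TRUE`.
#' @export
log2_transform <- function(table) {
  if (isTRUE(table$log2)) abort("table is already log2-transformed")
  if (any(table$intensities < 0, na.rm = TRUE))
    abort("negative intensities cannot be log2-transformed")
  M <- table$intensities
  M[!is.na(M) & M == 0] <- NA_real_
  table$intensities <- log2(M)
  table$log2 <- TRUE
  table$provenance <- c(table$provenance, "log2")
  table
}

#' Detect and remove TIC outlier study injections
#'
#' The total ion count (TIC) of each study injection is the sum of its raw
#' (never log2) intensities. Study injections with a TIC below `min_frac`
#' of the mean study TIC are removed; QC, blank and dilution injections
#' are never removed by this rule.
#'
#' @param table an [injection_table()] with >= 2 study injections.
#' @param min_frac removal threshold as a fraction of mean TIC;
#'   default 0.6.
#' @return list with the filtered `table` and a [filter_report()].
#' @export
detect_tic_outliers <- function(table, min_frac = 0.6) {
  study <- inj_which(table, "study")
  if (length(study) < 2) abort("need >= 2 study injections")
  tic <- colSums(raw_intensities(table)[, study, drop = FALSE], na.rm = TRUE)
  out <- study[tic < min_frac * mean(tic)]
  keep <- setdiff(seq_len(ncol(table$intensities)), out)
  report <- filter_report("tic_outliers",
                          features_before = nrow(table$intensities),
                          features_after = nrow(table$intensities),
                          samples_before = ncol(table$intensities),
                          samples_after = length(keep),
                          removed = table$injections$injection_id[out],
                          reasons = rep(sprintf("TIC < %g x mean", min_frac),
                                        length(out)))
  table$intensities <- table$intensities[, keep, drop = FALSE]
  table$injections <- table$injections[keep, , drop = FALSE]
  table$injections$injection_order <- rank(table$injections$injection_order)
  table$provenance <- c(table$provenance, "tic_outliers")
  list(table = table, report = report)
}

#' Coverage filter
#'
#' Keeps a feature only if it is observed (non-missing) in at least
#' `min_coverage` of the study injections (boundary inclusive).
#'
#' @param table an [injection_table()].
#' @param min_coverage minimum fraction of study injections; default 0.75.
#' @return list with the filtered `table` and a [filter_report()].
#' @export
coverage_filter <- function(table, min_coverage = 0.75) {
  study <- inj_which(table, "study")
  cov <- rowMeans(!is.na(table$intensities[, study, drop = FALSE]))
  drop <- which(cov < min_coverage)
  drop_features(table, drop, "coverage_filter",
                sprintf("coverage < %g in study injections", min_coverage))
}

#' QC-anchored LOESS drift normalization
#'
#' For each feature, a locally weighted regression (tricube weights,
#' locally linear; `limma::loessFit`) of pooled-QC log2 intensity on
#' injection order is fitted at span `span` and evaluated at every
#' injection's order by linear interpolation between QC fits (linear
#' extrapolation beyond the QC range). The fitted drift is subtracted and
#' the feature's QC mean added back, so the QC-predicted level is flat and
#' centered. Fitting on QCs only (rather than all samples) avoids
#' absorbing genuine group differences into the drift estimate.
#'
#' @param table a log2 [injection_table()] with >= 5 QC injections.
#' @param span LOESS span as a fraction of points; default 0.3.
#' @return the normalized table.
#' @export
loess_normalize <- function(table, span = 0.3) {
  if (!isTRUE(table$log2)) abort("loess_normalize expects a log2 table")
  qcs <- inj_which(table, "qc")
  if (length(qcs) < 5)
    abort(paste("need >= 5 QC injections for LOESS normalization (got %d);",
                "consider a median-centering fallback instead"),
          length(qcs))
  ord <- table$injections$injection_order
  x_qc <- ord[qcs]
  M <- table$intensities
  for (j in seq_len(nrow(M))) {
    y <- M[j, qcs]
    ok <- !is.na(y)
    if (sum(ok) < 2) next
    fit <- limma::loessFit(y[ok], x_qc[ok], span = span)$fitted
    o <- order(x_qc[ok])
    fx <- x_qc[ok][o]; fy <- fit[o]
    pred <- approx(fx, fy, xout = ord, rule = 2)$y
    lo <- ord < fx[1]; hi <- ord > fx[length(fx)]
    if (any(lo))
      pred[lo] <- fy[1] + (fy[2] - fy[1]) / (fx[2] - fx[1]) * (ord[lo] - fx[1])
    if (any(hi)) {
      n <- length(fx)
      pred[hi] <- fy[n] + (fy[n] - fy[n - 1]) / (fx[n] - fx[n - 1]) *
        (ord[hi] - fx[n])
    }
    M[j, ] <- M[j, ] - pred + mean(y[ok])
  }
  table$intensities <- M
  table$provenance <- c(table$provenance, "loess_normalize")
  table
}

#' Per-feature QC coefficient of variation
#'
#' CV (%) of the raw-scale (inverse log2) intensities across pooled-QC
#' injections: `100 * sd / mean` of `2^log2value`. Scale-free: invariant
#' to multiplying raw intensities by a constant.
#'
#' @param table an [injection_table()] with >= 2 QC injections.
#' @return named numeric vector of CV percentages per feature.
#' @export
qc_cv <- function(table) {
  qcs <- inj_which(table, "qc")
  if (length(qcs) < 2) abort("need >= 2 QC injections")
  raw <- raw_intensities(table)[, qcs, drop = FALSE]
  apply(raw, 1, function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2) return(NA_real_)
    100 * sd(x) / mean(x)
  })
}

#' Merge technical replicates
#'
#' Groups study injections by subject, reports the minimum pairwise
#' Pearson correlation between replicate log2 profiles across subjects
#' (singleton subjects contribute no correlation), and replaces each
#' replicate group by its per-feature missing-aware mean.
#'
#' @param table a log2 [injection_table()].
#' @param replicate_map optional named list mapping sample_id to its
#'   injection ids; defaults to grouping study injections by `sample_id`.
#' @return list with the merged `table` (one study column per subject,
#'   named by sample id) and `min_replicate_correlation` (NA when no
#'   subject has >= 2 replicates).
#' @export
merge_replicates <- function(table, replicate_map = NULL) {
  if (!isTRUE(table$log2)) abort("merge_replicates expects a log2 table")
  inj <- table$injections
  study <- inj_which(table, "study")
  if (is.null(replicate_map))
    replicate_map <- split(inj$injection_id[study], inj$sample_id[study])
  min_r <- Inf
  merged_cols <- list()
  merged_meta <- list()
  for (sid in names(replicate_map)) {
    ids <- replicate_map[[sid]]
    cols <- match(ids, inj$injection_id)
    sub <- table$intensities[, cols, drop = FALSE]
    if (length(cols) > 1) {
      for (a in seq_len(ncol(sub) - 1)) for (b in (a + 1):ncol(sub)) {
        r <- suppressWarnings(cor(sub[, a], sub[, b],
                                  use = "pairwise.complete.obs"))
        if (!is.na(r)) min_r <- min(min_r, r)
      }
    }
    merged_cols[[sid]] <- rowMeans(sub, na.rm = TRUE)
    first <- inj[cols[1], , drop = FALSE]
    first$injection_id <- sid
    merged_meta[[sid]] <- first
  }
  other <- setdiff(seq_len(ncol(table$intensities)), study)
  M <- cbind(do.call(cbind, merged_cols),
             table$intensities[, other, drop = FALSE])
  M[is.nan(M)] <- NA_real_
  new_inj <- rbind(do.call(rbind, merged_meta), inj[other, , drop = FALSE])
  new_inj$injection_order <- rank(new_inj$injection_order,
                                  ties.method = "first")
  colnames(M) <- new_inj$injection_id
  table$intensities <- M
  table$injections <- new_inj
  table$provenance <- c(table$provenance, "merge_replicates")
  list(table = table,
       min_replicate_correlation = if (is.finite(min_r)) min_r else NA_real_)
}

#' Remove features correlated with the albumin ratio
#'
#' Computes the Spearman correlation between each feature and the subjects'
#' CSF/serum albumin ratio over all study samples and removes features that
#' reach a statistically significant (p < `p_threshold`) absolute
#' correlation strictly above `abs_rho_threshold` -- compounds likely to
#' originate from blood leaking through the blood-brain barrier.
#'
#' @param values log2 feature-by-sample matrix (or a `feature_matrix`).
#' @param albumin_ratios numeric vector, one value per sample column.
#' @param abs_rho_threshold remove when |rho| exceeds this; default 0.5.
#' @param p_threshold significance cut-off; default 0.05.
#' @return list with filtered `values` and a [filter_report()].
#' @export
albumin_filter <- function(values, albumin_ratios, abs_rho_threshold = 0.5,
                           p_threshold = 0.05) {
  fm <- as_feature_values(values)
  if (length(albumin_ratios) != ncol(fm))
    abort("albumin_ratios length (%d) != number of samples (%d)",
          length(albumin_ratios), ncol(fm))
  if (anyNA(albumin_ratios))
    abort("albumin ratio missing for samples: %s",
          paste(colnames(fm)[is.na(albumin_ratios)], collapse = ", "))
  res <- t(apply(fm, 1, function(x) {
    s <- spearman(x, albumin_ratios)
    c(s$rho, s$p)
  }))
  drop <- which(!is.na(res[, 1]) & res[, 2] < p_threshold &
                  abs(res[, 1]) > abs_rho_threshold)
  report <- filter_report("albumin_filter",
                          features_before = nrow(fm),
                          features_after = nrow(fm) - length(drop),
                          samples_before = ncol(fm), samples_after = ncol(fm),
                          removed = rownames(fm)[drop],
                          reasons = sprintf("|rho| = %.2f, p = %.3g vs albumin",
                                            abs(res[drop, 1]), res[drop, 2]))
  list(values = fm[setdiff(seq_len(nrow(fm)), drop), , drop = FALSE],
       report = report)
}

#' Impute missing values by the feature mean
#'
#' Each missing entry is replaced by the mean of the observed values of
#' that feature across study samples. Errors on an all-missing feature
#' (which cannot occur after [coverage_filter()]).
#'
#' @param values log2 feature-by-sample matrix.
#' @return the matrix with no missing values.
#' @export
impute_mean <- function(values) {
  fm <- as_feature_values(values)
  all_na <- rowSums(!is.na(fm)) == 0
  if (any(all_na))
    abort("features with no observed values: %s",
          paste(rownames(fm)[all_na], collapse = ", "))
  idx <- which(is.na(fm), arr.ind = TRUE)
  if (nrow(idx) > 0)
    fm[idx] <- rowMeans(fm, na.rm = TRUE)[idx[, 1]]
  fm
}

#' @noRd
as_feature_values <- function(values) {
  if (inherits(values, "injection_table")) abort(
    "pass a feature-by-sample matrix (study columns), not an injection table")
  as.matrix(values)
}
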
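#' Select altered metabolites by average VIP
#'
#' Variables whose cross-validation mean VIP is greater than or equal to
#' `threshold` (boundary inclusive) are considered altered; returned
#' sorted by mean VIP, descending.
#'
#' @param cv a `plsda_cv` object from [repeated_cv()] (or its `vip`
#'   data.frame).
#' @param threshold selection threshold; default 1.0.
#' @return the selected rows of the VIP table, sorted.
#' @export
select_altered <- function(cv, threshold = 1.0) {
  v <- if (inherits(cv, "plsda_cv")) cv$vip else cv
  sel <- v[!is.na(v$mean) & v$mean >= threshold, , drop = FALSE]
  sel[order(-sel$mean), , drop = FALSE]
}

#' Log2 fold change between two groups
#'
#' Difference of group means on already-log2 values:
#' `mean(group A) - mean(group B)`. A positive value is an average
#' increase in A relative to B.
#'
#' @param values log2 feature-by-sample matrix.
#' @param groups vector of group labels parallel to the columns.
#' @param contrast character pair `c(A, B)`.
#' @return named numeric vector of fold changes.
#' @export
log2_fc <- function(values, groups, contrast) {
  values <- as_feature_values(values)
  a <- which(groups == contrast[1]); b <- which(groups == contrast[2])
  if (length(a) == 0 || length(b) == 0)
    abort("empty group in contrast %s vs %s", contrast[1], contrast[2])
  rowMeans(values[, a, drop = FALSE], na.rm = TRUE) -
    rowMeans(values[, b, drop = FALSE], na.rm = TRUE)
}

#' Welch's two-sample t-test
#'
#' `t = (m_a - m_b) / sqrt(s_a^2/n_a + s_b^2/n_b)` with the
#' Welch-Satterthwaite degrees of freedom and a two-sided p-value from the
#' t distribution; accounts for unequal variances and sample sizes. Two
#' groups with zero variance and equal means give p = 1 by convention;
#' zero variance with different means is an error.
#'
#' @param a,b numeric vectors with >= 2 values each.
#' @return list: `t`, `df`, `p`.
#' @export
welch_t <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) abort("each group needs >= 2 values")
  va <- var(a) / length(a); vb <- var(b) / length(b)
  if (va + vb == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, df = NA_real_, p = 1))
    abort("zero variance in both groups with unequal means")
  }
  tval <- (mean(a) - mean(b)) / sqrt(va + vb)
  dfree <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = tval, df = dfree, p = 2 * pt(-abs(tval), dfree))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up procedure: for p-values sorted ascending,
#' `adj_(i) = min_{j >= i}(p_(j) * m / j)` capped at 1, mapped back to the
#' input order. Monotone (preserves the order of raw p-values) and never
#' smaller than the raw p-value.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted values in input order.
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    abort("p-values must lie in [0, 1] with no missing values")
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p)
  adj <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Canonicalize a metabolite name
#'
#' Strips adduct suffixes (`[M + H]`, `[M - H]`, with ASCII or Unicode
#' minus), footnote asterisks and markdown emphasis, collapses all
#' whitespace and case-folds, so rows reported separately per adduct
#' compare as one compound.
#'
#' @param x character vector of names.
#' @return canonical names.
#' @export
canonical_name <- function(x) {
  x <- gsub("\\*", "", x)
  x <- gsub("\\[\\s*M\\s*[+−–-]\\s*H\\s*\\]", "", x)
  x <- gsub("\\s+", "", x)
  tolower(x)
}

#' Overlap of two altered-metabolite sets
#'
#' Intersection by canonical name (see [canonical_name()]), sorted.
#'
#' @param set_a,set_b character vectors of metabolite names.
#' @return sorted character vector of common canonical names.
#' @export
overlap_altered <- function(set_a, set_b) {
  sort(intersect(unique(canonical_name(set_a)),
                 unique(canonical_name(set_b))))
}

#' Build the altered-metabolite table for a contrast
#'
#' Combines VIP selection, per-metabolite log2 fold change, Welch's
#' t-test and BH FDR (with m = the number of selected metabolites, the
#' arithmetic used for the per-contrast report tables), QC CV and
#' validation level into one table sorted by mean VIP. The change
#' direction is derived from the sign of the fold change.
#'
#' @param cv a `plsda_cv` from [repeated_cv()].
#' @param values log2 feature-by-sample matrix (rows named like the CV
#'   variables).
#' @param groups group labels parallel to the columns of `values`.
#' @param contrast character pair `c(A, B)`.
#' @param annotations optional data.frame keyed by `feature_id` with
#'   `name`, `kegg_id`, `qc_cv_percent`, `validation_level`.
#' @param vip_threshold selection threshold; default 1.0.
#' @return data.frame, one row per altered metabolite.
#' @export
altered_metabolites <- function(cv, values, groups, contrast,
                                annotations = NULL, vip_threshold = 1.0) {
  sel <- select_altered(cv, vip_threshold)
  if (nrow(sel) == 0) return(sel)
  values <- as_feature_values(values)
  keep_cols <- groups %in% contrast
  fc <- log2_fc(values[sel$variable, , drop = FALSE], groups, contrast)
  p <- vapply(sel$variable, function(f)
    welch_t(values[f, groups == contrast[1]],
            values[f, groups == contrast[2]])$p, 0)
  out <- data.frame(feature_id = sel$variable, vip_mean = sel$mean,
                    vip_lower = sel$lower, vip_upper = sel$upper,
                    log2_fc = fc, welch_p = p, fdr = bh_fdr(p),
                    direction = ifelse(fc >= 0, "up", "down"),
                    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(annotations)) {
    i <- match(out$feature_id, annotations$feature_id)
    for (col in intersect(c("name", "kegg_id", "qc_cv_percent",
                            "validation_level"), names(annotations)))
      out[[col]] <- annotations[[col]][i]
  }
  out
}
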
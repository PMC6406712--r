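#' Spearman rank correlation with p-value
#'
#' Rho is the Pearson correlation of average ranks (ties averaged) over
#' complete pairs. The two-sided p-value uses the exact null distribution
#' for n <= 9 without ties and the t-approximation
#' `t = rho * sqrt((n-2)/(1-rho^2))` otherwise. Pairs with a missing value
#' are dropped; a constant vector leaves rho undefined (`NA`).
#'
#' @param x,y numeric vectors of equal length.
#' @return list: `rho`, `p`, `n` (complete pairs used).
#' @export
spearman <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) abort("need >= 4 complete pairs (got %d)", n)
  if (sd(x) == 0 || sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n))
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  if (n <= 9 && !ties) {
    p <- suppressWarnings(cor.test(x, y, method = "spearman",
                                   exact = TRUE)$p.value)
  } else if (abs(rho) >= 1) {
    p <- 0
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tval), n - 2)
  }
  list(rho = rho, p = min(p, 1), n = n)
}

#' Associate metabolites with clinical and radiological measures
#'
#' Computes Spearman correlations between every metabolite (row of
#' `values`) and every clinical measure over MS patients only (controls
#' are excluded by default), marking cells significant at p < `alpha`
#' without multiplicity adjustment (the per-cell convention of the
#' association report).
#'
#' @param values log2 feature-by-sample matrix, columns named by sample
#'   id.
#' @param samples data.frame with `sample_id`, `group` and the measure
#'   columns.
#' @param measures measure column names; default the six radiological/
#'   clinical measures.
#' @param groups groups to include; default RRMS and SPMS.
#' @param alpha per-cell significance level; default 0.05.
#' @return an `association_matrix`: list of matrices `rho`, `p`,
#'   `significant` (metabolites x measures) and `n_samples`.
#' @export
associate_all <- function(values, samples,
                          measures = c("spinal_cord", "third_ventricle",
                                       "edss", "disease_duration",
                                       "total_t1", "total_t2"),
                          groups = c("RRMS", "SPMS"), alpha = 0.05) {
  values <- as_feature_values(values)
  meta <- samples[match(colnames(values), samples$sample_id), ]
  use <- which(meta$group %in% groups)
  rho <- p <- matrix(NA_real_, nrow(values), length(measures),
                     dimnames = list(rownames(values), measures))
  for (m in measures) {
    mv <- meta[[m]][use]
    for (j in seq_len(nrow(values))) {
      s <- spearman(values[j, use], mv)
      rho[j, m] <- s$rho; p[j, m] <- s$p
    }
  }
  structure(list(rho = rho, p = p,
                 significant = !is.na(p) & p < alpha,
                 n_samples = length(use)),
            class = "association_matrix")
}

#' @export
print.association_matrix <- function(x, ...) {
  cat(sprintf("Association matrix: %d metabolites x %d measures over %d MS samples; %d significant cells\n",
              nrow(x$rho), ncol(x$rho), x$n_samples, sum(x$significant)))
  invisible(x)
}

#' Hierarchically cluster metabolite correlation patterns
#'
#' Agglomerative clustering of the metabolite rows of an association
#' matrix using Euclidean distance between rho vectors and complete
#' linkage. Rows with undefined correlations are an error (exclude them
#' first).
#'
#' @param assoc an `association_matrix` (or a plain rho matrix).
#' @param method linkage; default `"complete"`.
#' @return list: `order` (row indices in leaf order), `labels` (row names
#'   in leaf order), `hclust` (the merge tree).
#' @export
cluster_rows <- function(assoc, method = "complete") {
  rho <- if (inherits(assoc, "association_matrix")) assoc$rho else
    as.matrix(assoc)
  if (nrow(rho) < 2) abort("need >= 2 rows to cluster")
  bad <- rownames(rho)[rowSums(is.na(rho)) > 0]
  if (length(bad) > 0)
    abort("rows with undefined correlations: %s", paste(bad, collapse = ", "))
  hc <- hclust(dist(rho, method = "euclidean"), method = method)
  list(order = hc$order, labels = rownames(rho)[hc$order], hclust = hc)
}
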
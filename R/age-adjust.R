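#' Fit per-feature linear age models on the reference groups
#'
#' Ordinary least squares of log2 level on age, fitted over the reference
#' subjects only (RRMS and controls by default). Including the progressive
#' group in the fit would risk absorbing disease-driven alterations into
#' the age trend, so it is excluded. A feature is flagged for correction
#' when the two-sided t-test on the slope gives p < `alpha`.
#'
#' @param values log2 feature-by-sample matrix (columns named by sample id).
#' @param samples data.frame with `sample_id`, `group`, `age`.
#' @param ref_groups groups used for the fit; default RRMS + control.
#' @param alpha slope significance threshold; default 0.05.
#' @return data.frame, one row per feature: `feature_id`, `intercept`,
#'   `age_slope`, `slope_p`, `corrected`, plus the reference mean age and
#'   ids as attributes `ref_mean_age`, `reference_ids`.
#' @export
fit_age_models <- function(values, samples, ref_groups = c("RRMS", "control"),
                           alpha = 0.05) {
  values <- as_feature_values(values)
  meta <- samples[match(colnames(values), samples$sample_id), ]
  ref <- which(meta$group %in% ref_groups)
  if (length(ref) < 3) abort("need >= 3 reference subjects (got %d)",
                             length(ref))
  age <- meta$age[ref]
  if (anyNA(age)) abort("reference subjects with unknown age")
  if (sd(age) == 0) abort("reference ages are constant; cannot fit age model")
  out <- data.frame(feature_id = rownames(values), intercept = NA_real_,
                    age_slope = NA_real_, slope_p = NA_real_,
                    corrected = FALSE, stringsAsFactors = FALSE)
  xc <- age - mean(age)
  sxx <- sum(xc^2)
  for (j in seq_len(nrow(values))) {
    y <- values[j, ref]
    ok <- !is.na(y)
    if (sum(ok) < 3) next
    if (all(ok)) { b <- sum(xc * y) / sxx; mx <- mean(age); s2x <- sxx }
    else {
      xo <- age[ok]; mx <- mean(xo); xoc <- xo - mx
      s2x <- sum(xoc^2); b <- sum(xoc * y[ok]) / s2x
    }
    a <- mean(y[ok]) - b * mx
    res <- y[ok] - (a + b * age[ok])
    dfree <- sum(ok) - 2
    se <- sqrt(sum(res^2) / dfree / s2x)
    tval <- if (se == 0) Inf * sign(b) else b / se
    p <- if (se == 0 && b == 0) 1 else 2 * pt(-abs(tval), dfree)
    out$intercept[j] <- a; out$age_slope[j] <- b; out$slope_p[j] <- p
    out$corrected[j] <- p < alpha
  }
  attr(out, "ref_mean_age") <- mean(age)
  attr(out, "reference_ids") <- meta$sample_id[ref]
  out
}

#' Apply age correction to all subjects
#'
#' For each feature flagged `corrected`, every subject's value is reduced
#' by `slope * (age - reference mean age)`. Centering at the reference-set
#' mean age preserves the reference-group mean of each corrected feature
#' and makes the operation idempotent with respect to refitting on the
#' reference set (the refit slope is 0 by the OLS residual property).
#'
#' @param values log2 feature-by-sample matrix.
#' @param models output of [fit_age_models()].
#' @param samples data.frame with `sample_id`, `age` covering all columns.
#' @return the corrected matrix.
#' @export
apply_age_correction <- function(values, models, samples) {
  values <- as_feature_values(values)
  if (!identical(rownames(values), models$feature_id))
    abort("models were fitted on a different feature set")
  meta <- samples[match(colnames(values), samples$sample_id), ]
  if (anyNA(meta$age))
    abort("subjects with unknown age: %s",
          paste(colnames(values)[is.na(meta$age)], collapse = ", "))
  mref <- attr(models, "ref_mean_age")
  corr <- which(models$corrected)
  if (length(corr) > 0)
    values[corr, ] <- values[corr, , drop = FALSE] -
      models$age_slope[corr] %o% (meta$age - mref)
  values
}
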
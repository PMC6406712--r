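#' Generate a synthetic injection table with ground truth
#'
#' Builds the feature-by-injection intensity matrix of a full LC-MS run:
#' study injections in randomized order (optionally with technical
#' replicates), a QC + blank pair at the start of the run and after every
#' `qc_interval` study injections, and a terminal 2-fold QC dilution
#' series. Intensities are log-normal with additive log2-scale structure:
#'
#' * a smooth injection-order drift (monotone decay plus a mild sinusoid,
#'   amplitude `drift_amplitude` log2 units; recoverable by LOESS at span
#'   0.3); the dilution series is exempt so its volume linearity is exact;
#' * SPMS group effects `group_effect_log2fc` on designated features
#'   (RRMS equals control: a true-null contrast);
#' * linear age trends on `frac_age_dependent` of the features;
#' * monotone albumin-ratio dependence on `albumin_link_frac` of the
#'   features (blood-derived compounds);
#' * progression features additionally tied to the cohort's latent
#'   progression score;
#' * blank-borne contaminants present in blanks at or above study levels
#'   and volume-independent in the dilution series;
#' * i.i.d. N(0, `noise_sd`^2) log2 noise and MCAR dropout on study
#'   injections at `missing_rate`.
#'
#' @param cohort data.frame from [generate_cohort()].
#' @param config a [sim_config()] object.
#' @return a list with `table` (an [injection_table] whose intensities are
#'   raw, i.e. not yet log2) and `truth` (per-feature flags and effect
#'   sizes: `is_contaminant`, `is_age_dependent`, `age_slope`,
#'   `albumin_linked`, `is_progression`, and `true_log2fc` with one column
#'   per contrast).
#' @export
generate_injection_table <- function(cohort, config) {
  config <- validate_sim_config(config)
  if (nrow(cohort) == 0) abort("cohort is empty")
  set.seed(config$seed + 1L)
  P <- config$n_features

  ## --- feature roles (disjoint) -------------------------------------------
  n_contam <- round(config$frac_contaminant * P)
  n_alb <- round(config$albumin_link_frac * P)
  n_age <- round(config$frac_age_dependent * P)
  n_eff <- length(config$group_effect_log2fc)
  if (n_contam + n_alb + n_age + n_eff > P)
    abort("feature roles exceed n_features (%d needed, %d available)",
          n_contam + n_alb + n_age + n_eff, P)
  roles <- sample.int(P)  # random permutation; carve out blocks
  id_contam <- sort(roles[seq_len(n_contam)])
  id_alb <- sort(roles[n_contam + seq_len(n_alb)])
  id_age <- sort(roles[n_contam + n_alb + seq_len(n_age)])
  id_eff <- sort(roles[n_contam + n_alb + n_age + seq_len(n_eff)])
  n_prog <- min(config$n_progression_features, n_eff)
  id_prog <- id_eff[seq_len(n_prog)]

  truth <- data.frame(feature_id = sprintf("F%04d", seq_len(P)),
                      is_contaminant = seq_len(P) %in% id_contam,
                      is_age_dependent = seq_len(P) %in% id_age,
                      age_slope = 0,
                      albumin_linked = seq_len(P) %in% id_alb,
                      is_progression = seq_len(P) %in% id_prog,
                      stringsAsFactors = FALSE)
  truth$age_slope[id_age] <- sample(c(-1, 1), n_age, TRUE) * runif(n_age, 0.02, 0.05)
  eff <- numeric(P); eff[id_eff] <- config$group_effect_log2fc
  truth$true_log2fc <- data.frame(SPMS_RRMS = eff, SPMS_control = eff,
                                  RRMS_control = 0)

  feature_meta <- data.frame(feature_id = truth$feature_id,
                             mz = round(runif(P, 100, 600), 4),
                             rt = round(runif(P, 60, 1080), 1),
                             stringsAsFactors = FALSE)

  ## --- expected per-subject log2 levels -----------------------------------
  base <- rnorm(P, 18, 2)
  alb_coef <- numeric(P)
  alb_coef[id_alb] <- sample(c(-1, 1), n_alb, TRUE) * runif(n_alb, 3, 5)
  n_sub <- nrow(cohort)
  L <- matrix(base, P, n_sub)
  L <- L + eff %o% as.numeric(cohort$group == "SPMS")
  L <- L + truth$age_slope %o% (cohort$age - mean(cohort$age))
  L <- L + alb_coef %o% (log2(cohort$albumin_ratio) - mean(log2(cohort$albumin_ratio)))
  zprog <- ifelse(is.na(cohort$progression_score), 0, cohort$progression_score)
  prog_coef <- numeric(P); prog_coef[id_prog] <- 0.6
  L <- L + prog_coef %o% zprog

  qc_level <- log2(rowMeans(2^L))          # pooled QC = raw-scale average
  blank_level <- rep(NA_real_, P)
  blank_level[id_contam] <- qc_level[id_contam] + 0.5

  ## --- injection sequence --------------------------------------------------
  study_ids <- rep(cohort$sample_id, each = config$n_replicates)
  study_ids <- study_ids[sample.int(length(study_ids))]
  seq_rows <- list(data.frame(type = "qc", sample_id = NA_character_,
                              volume = NA_real_, stringsAsFactors = FALSE),
                   data.frame(type = "blank", sample_id = NA_character_,
                              volume = NA_real_, stringsAsFactors = FALSE))
  since_qc <- 0L
  for (sid in study_ids) {
    seq_rows[[length(seq_rows) + 1L]] <-
      data.frame(type = "study", sample_id = sid, volume = NA_real_,
                 stringsAsFactors = FALSE)
    since_qc <- since_qc + 1L
    if (since_qc == config$qc_interval) {
      seq_rows[[length(seq_rows) + 1L]] <-
        data.frame(type = "qc", sample_id = NA_character_, volume = NA_real_,
                   stringsAsFactors = FALSE)
      seq_rows[[length(seq_rows) + 1L]] <-
        data.frame(type = "blank", sample_id = NA_character_, volume = NA_real_,
                   stringsAsFactors = FALSE)
      since_qc <- 0L
    }
  }
  for (v in config$dilution_volumes)
    seq_rows[[length(seq_rows) + 1L]] <-
      data.frame(type = "dilution", sample_id = NA_character_, volume = v,
                 stringsAsFactors = FALSE)
  injections <- do.call(rbind, seq_rows)
  O <- nrow(injections)
  injections$injection_order <- seq_len(O)
  injections$injection_id <- sprintf("I%04d", seq_len(O))
  injections <- injections[, c("injection_id", "type", "injection_order",
                               "sample_id", "volume")]

  ## --- intensities ---------------------------------------------------------
  u <- (injections$injection_order - 1) / max(1, O - 1)
  drift <- -config$drift_amplitude * u +
    0.1 * config$drift_amplitude * sin(2 * pi * u)
  drift[injections$type == "dilution"] <- 0

  M <- matrix(NA_real_, P, O,
              dimnames = list(truth$feature_id, injections$injection_id))
  sub_idx <- match(injections$sample_id, cohort$sample_id)
  for (k in seq_len(O)) {
    lev <- switch(injections$type[k],
                  study = L[, sub_idx[k]],
                  qc = qc_level,
                  blank = blank_level,
                  dilution = {
                    d <- qc_level + log2(injections$volume[k] / 10)
                    d[id_contam] <- qc_level[id_contam]  # volume-independent
                    d
                  })
    lev <- lev + drift[k]
    if (config$noise_sd > 0)
      lev <- lev + rnorm(P, 0, config$noise_sd)
    M[, k] <- 2^lev
  }
  if (config$missing_rate > 0) {
    study_cols <- which(injections$type == "study")
    drop <- matrix(runif(P * length(study_cols)) < config$missing_rate,
                   P, length(study_cols))
    M[, study_cols][drop] <- NA_real_
  }

  table <- injection_table(M, injections, feature_meta)
  list(table = table, truth = truth)
}
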
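#' Simulation configuration for a synthetic CSF metabolomics study
#'
#' Builds the configuration object consumed by [generate_cohort()],
#' [generate_injection_table()] and [generate_library()]. The defaults
#' reproduce the design of the motivating study: 10 controls, 30
#' relapsing-remitting MS (RRMS) and 16 secondary-progressive MS (SPMS)
#' subjects with group ages 39 (SD 13.1), 39 (SD 10.6) and 58 (SD 9.3)
#' years, a pooled-QC plus blank injection pair every 8th study sample, and
#' a 2-fold dilution series from 0.5 to 32 uL.
#'
#' Group effects are applied to the SPMS group only, so the RRMS-vs-control
#' contrast is a true null, mirroring the study design the generator
#' emulates. By default a quarter of the features carry effects with
#' |log2 FC| evenly spaced over 0.1--1.2 and alternating sign.
#'
#' @param n_per_group named integer vector `c(control=, RRMS=, SPMS=)`.
#' @param age_params list of `c(mean, sd)` ages in years per group, same
#'   names/order as `n_per_group`. Ages are truncated at 18.
#' @param n_features number of quantified LC-MS features.
#' @param frac_identified fraction of non-contaminant features with a
#'   matching spectral-library entry.
#' @param frac_age_dependent fraction of features given a linear age trend.
#' @param frac_contaminant fraction of blank-borne contaminant features.
#' @param group_effect_log2fc numeric vector of per-feature SPMS effect
#'   sizes (log2 units); its length sets the number of affected features.
#' @param drift_amplitude injection-order intensity drift amplitude, log2
#'   units over the whole run (monotone decay plus a mild sinusoid).
#' @param qc_interval study injections between successive QC/blank pairs.
#' @param dilution_volumes strictly increasing injection volumes (uL) for
#'   the terminal QC dilution series.
#' @param noise_sd per-measurement technical noise, log2 units.
#' @param missing_rate missing-completely-at-random dropout fraction.
#' @param albumin_link_frac fraction of features tied monotonically to the
#'   subject albumin ratio (blood-derived compounds).
#' @param n_replicates technical replicate injections per study sample.
#' @param clinical_link_rho target rank correlation between progression
#'   features and the latent progression score driving EDSS/MRI measures.
#' @param n_progression_features number of effect features additionally
#'   linked to the latent progression score.
#' @param n_transitioned number of RRMS subjects flagged as having later
#'   transitioned to SPMS.
#' @param seed integer random seed; identical configs generate identical
#'   outputs byte-for-byte.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(seed = 1)
#' cohort <- generate_cohort(cfg)
#' table(cohort$group)
sim_config <- function(n_per_group = c(control = 10L, RRMS = 30L, SPMS = 16L),
                       age_params = list(control = c(39, 13.1),
                                         RRMS = c(39, 10.6),
                                         SPMS = c(58, 9.3)),
                       n_features = 150L,
                       frac_identified = 0.8,
                       frac_age_dependent = 0.15,
                       frac_contaminant = 0.1,
                       group_effect_log2fc = NULL,
                       drift_amplitude = 0.5,
                       qc_interval = 8L,
                       dilution_volumes = c(0.5, 1, 2, 4, 8, 16, 32),
                       noise_sd = 0.3,
                       missing_rate = 0.05,
                       albumin_link_frac = 0.05,
                       n_replicates = 1L,
                       clinical_link_rho = 0.7,
                       n_progression_features = 5L,
                       n_transitioned = 4L,
                       seed = 1L) {
  if (is.null(group_effect_log2fc)) {
    n_eff <- max(1L, round(0.25 * n_features))
    mag <- seq(0.1, 1.2, length.out = n_eff)
    group_effect_log2fc <- mag * rep_len(c(1, -1), n_eff)
  }
  cfg <- list(n_per_group = n_per_group, age_params = age_params,
              n_features = as.integer(n_features),
              frac_identified = frac_identified,
              frac_age_dependent = frac_age_dependent,
              frac_contaminant = frac_contaminant,
              group_effect_log2fc = group_effect_log2fc,
              drift_amplitude = drift_amplitude,
              qc_interval = as.integer(qc_interval),
              dilution_volumes = dilution_volumes,
              noise_sd = noise_sd, missing_rate = missing_rate,
              albumin_link_frac = albumin_link_frac,
              n_replicates = as.integer(n_replicates),
              clinical_link_rho = clinical_link_rho,
              n_progression_features = as.integer(n_progression_features),
              n_transitioned = as.integer(n_transitioned),
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

#' @noRd
validate_sim_config <- function(cfg) {
  groups <- c("control", "RRMS", "SPMS")
  if (!all(groups %in% names(cfg$n_per_group)))
    abort("'n_per_group' must be named with %s", paste(groups, collapse = ", "))
  if (any(cfg$n_per_group < 1))
    abort("'n_per_group' entries must all be >= 1")
  if (!all(groups %in% names(cfg$age_params)) ||
      !all(vapply(cfg$age_params, length, 0L) == 2L))
    abort("'age_params' must hold c(mean, sd) for each of %s",
          paste(groups, collapse = ", "))
  if (cfg$n_features < 1) abort("'n_features' must be >= 1")
  for (f in c("frac_identified", "frac_age_dependent", "frac_contaminant",
              "missing_rate", "albumin_link_frac"))
    check_frac(cfg[[f]], f)
  check_frac(abs(cfg$clinical_link_rho), "clinical_link_rho")
  if (!is.numeric(cfg$group_effect_log2fc))
    abort("'group_effect_log2fc' must be numeric")
  if (cfg$drift_amplitude < 0) abort("'drift_amplitude' must be >= 0")
  if (cfg$qc_interval < 1) abort("'qc_interval' must be >= 1")
  if (length(cfg$dilution_volumes) > 1 &&
      any(diff(cfg$dilution_volumes) <= 0))
    abort("'dilution_volumes' must be strictly increasing")
  if (any(cfg$dilution_volumes <= 0)) abort("'dilution_volumes' must be > 0")
  if (cfg$noise_sd < 0) abort("'noise_sd' must be >= 0")
  if (cfg$n_replicates < 1) abort("'n_replicates' must be >= 1")
  if (cfg$n_progression_features < 0)
    abort("'n_progression_features' must be >= 0")
  if (cfg$n_transitioned < 0) abort("'n_transitioned' must be >= 0")
  if (length(cfg$seed) != 1L || is.na(cfg$seed))
    abort("'seed' must be a single integer")
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic study configuration\n")
  cat(sprintf("  cohort: %s\n",
              paste(sprintf("%d %s", x$n_per_group, names(x$n_per_group)),
                    collapse = ", ")))
  cat(sprintf("  features: %d (%.0f%% identified, %.0f%% contaminant, %d with group effect)\n",
              x$n_features, 100 * x$frac_identified,
              100 * x$frac_contaminant, length(x$group_effect_log2fc)))
  cat(sprintf("  QC/blank every %d injections; dilution %s uL; drift %.2g log2; noise SD %.2g; seed %d\n",
              x$qc_interval,
              paste(range(x$dilution_volumes), collapse = "-"),
              x$drift_amplitude, x$noise_sd, x$seed))
  invisible(x)
}
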
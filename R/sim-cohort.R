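#' Generate a synthetic study cohort
#'
#' Draws per-subject demographics and clinical/radiological measures with
#' the structure of a two-phenotype MS study plus controls: ages from
#' per-group normal distributions truncated at 18 years, EDSS on the 0--10
#' half-point scale with SPMS medians above RRMS, disease duration in
#' months (log-normal, SPMS > RRMS), MRI measures, a CSF/serum albumin
#' ratio, and a `transitioned` flag on a subset of RRMS subjects.
#'
#' Within each MS group, EDSS, disease duration and the MRI measures are
#' rank-linked (Gaussian copula, target correlation
#' `config$clinical_link_rho`) to a latent progression score stored in the
#' `progression_score` column; the injection-table generator ties the
#' designated progression features to the same score, so association
#' analyses have recoverable signal. The column is synthetic scaffolding,
#' not a clinical measurement.
#'
#' @param config a [sim_config()] object.
#' @return a `data.frame` with one row per subject: `sample_id`, `group`
#'   (factor control/RRMS/SPMS), `age`, `sex`, `on_treatment`, `edss`,
#'   `disease_duration` (months), `albumin_ratio`, `third_ventricle`,
#'   `spinal_cord`, `total_t1`, `total_t2`, `transitioned`,
#'   `progression_score`.
#' @export
generate_cohort <- function(config) {
  config <- validate_sim_config(config)
  set.seed(config$seed)
  groups <- c("control", "RRMS", "SPMS")
  n <- config$n_per_group[groups]
  grp <- factor(rep(groups, n), levels = groups)
  ntot <- sum(n)

  age <- numeric(ntot)
  for (g in groups) {
    idx <- which(grp == g)
    p <- config$age_params[[g]]
    a <- rnorm(length(idx), p[1], p[2])
    while (any(a < 18)) a[a < 18] <- rnorm(sum(a < 18), p[1], p[2])
    age[idx] <- round(a, 1)
  }

  sex <- factor(ifelse(runif(ntot) < 0.65, "F", "M"), levels = c("F", "M"))
  on_treatment <- grp == "RRMS" & runif(ntot) < 0.5
  on_treatment[grp == "SPMS"] <- runif(sum(grp == "SPMS")) < 0.1

  # latent progression score driving clinical severity (MS subjects only)
  z <- rnorm(ntot)
  z[grp == "control"] <- NA_real_

  half_step <- function(x, lo, hi) pmin(pmax(round(x * 2) / 2, lo), hi)
  edss <- rep(NA_real_, ntot)
  dur <- rep(NA_real_, ntot)
  tv <- numeric(ntot); sc <- numeric(ntot)
  t1 <- integer(ntot); t2 <- integer(ntot)

  rho <- config$clinical_link_rho
  link <- function(base, target, decreasing = FALSE) {
    # reorder marginal draws so their ranks follow the blended target
    o <- order(target, decreasing = decreasing)
    out <- base
    out[o] <- sort(base)
    out
  }
  blend <- function(zz) rho * zz + sqrt(max(0, 1 - rho^2)) * rnorm(length(zz))

  for (g in c("RRMS", "SPMS")) {
    idx <- which(grp == g)
    zz <- z[idx]
    if (g == "RRMS") {
      edss_base <- half_step(rnorm(length(idx), 2.5, 1.6), 0, 7.5)
      dur_base <- round(rlnorm(length(idx), log(92), 0.9), 1)
    } else {
      edss_base <- half_step(rnorm(length(idx), 5.5, 1.1), 3, 7.5)
      dur_base <- round(rlnorm(length(idx), log(283), 0.45), 1)
    }
    edss[idx] <- link(edss_base, blend(zz))
    dur[idx] <- link(dur_base, blend(zz))
    tv[idx] <- link(round(rnorm(length(idx), if (g == "SPMS") 7 else 5, 1.5), 2),
                    blend(zz))
    sc[idx] <- link(round(rnorm(length(idx), if (g == "SPMS") 74 else 80, 6), 2),
                    blend(zz), decreasing = TRUE)
    t1[idx] <- link(rbinom(length(idx), 40, if (g == "SPMS") 0.25 else 0.15),
                    blend(zz))
    t2[idx] <- link(rbinom(length(idx), 60, if (g == "SPMS") 0.35 else 0.25),
                    blend(zz))
  }
  ctrl <- which(grp == "control")
  tv[ctrl] <- round(rnorm(length(ctrl), 4.5, 1.2), 2)
  sc[ctrl] <- round(rnorm(length(ctrl), 82, 5), 2)
  t1[ctrl] <- 0L; t2[ctrl] <- 0L

  albumin <- round(rlnorm(ntot, log(6), 0.25), 3)

  transitioned <- rep(FALSE, ntot)
  rr <- which(grp == "RRMS")
  k <- min(config$n_transitioned, length(rr))
  if (k > 0) transitioned[sample(rr, k)] <- TRUE

  data.frame(sample_id = sprintf("S%03d", seq_len(ntot)),
             group = grp, age = age, sex = sex,
             on_treatment = on_treatment, edss = edss,
             disease_duration = dur, albumin_ratio = albumin,
             third_ventricle = tv, spinal_cord = sc,
             total_t1 = t1, total_t2 = t2,
             transitioned = transitioned, progression_score = z,
             stringsAsFactors = FALSE)
}
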
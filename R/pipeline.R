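#' Pipeline configuration
#'
#' Collects every tunable threshold of the pipeline with its default:
#' blank ratio 0.5, dilution |r| 0.7, TIC fraction 0.6, coverage 0.75,
#' 15 ppm / 20 s library tolerances, LOESS span 0.3, albumin |rho| 0.5 at
#' p < 0.05, age alpha 0.05, 5-fold x 10-repeat cross-validation, VIP
#' threshold 1.0, 100 permutations, alpha 0.05. Unknown keys are rejected.
#'
#' @param ... overrides for any of the defaults, plus optionally `sim`
#'   (a [sim_config()] for synthetic runs), `seed`, `contrasts` (character
#'   vector "A:B"; the first-named group is coded positive).
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(blank_ratio = 0.5, dilution_min_r = 0.7,
                   tic_min_frac = 0.6, coverage = 0.75, ppm = 15,
                   rt_s = 20, frag_tol = 0.01, span = 0.3,
                   albumin_rho = 0.5, albumin_p = 0.05, age_alpha = 0.05,
                   k = 5, repeats = 10, vip_threshold = 1.0, n_perm = 100,
                   alpha = 0.05, seed = 1L,
                   contrasts = c("SPMS:RRMS", "SPMS:control",
                                 "RRMS:control"),
                   sim = NULL, n_pathways = 10,
                   pathway_size_range = c(5, 15))
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0)
    abort("unknown config keys: %s", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, overrides)
  for (f in c("coverage", "albumin_p", "age_alpha", "alpha"))
    check_frac(cfg[[f]], f)
  if (cfg$blank_ratio < 0 || cfg$dilution_min_r < 0 || cfg$dilution_min_r > 1)
    abort("blank_ratio must be >= 0 and dilution_min_r in [0, 1]")
  if (cfg$tic_min_frac < 0 || cfg$tic_min_frac > 1)
    abort("tic_min_frac must be in [0, 1]")
  if (cfg$ppm <= 0 || cfg$rt_s < 0 || cfg$span <= 0)
    abort("ppm and span must be > 0, rt_s >= 0")
  if (cfg$k < 2 || cfg$repeats < 1) abort("k >= 2 and repeats >= 1 required")
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from file
#'
#' JSON is the canonical on-disk format; YAML is accepted when the yaml
#' package is installed.
#'
#' @param path path to a .json or .yaml/.yml file.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  lst <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      abort("YAML config requires the 'yaml' package; use JSON instead")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(lst$sim)) {
    sim <- lst$sim
    # JSON loses vector names; restore the structured fields
    if (!is.null(sim$n_per_group))
      sim$n_per_group <- setNames(unlist(sim$n_per_group),
                                  c("control", "RRMS", "SPMS"))
    if (!is.null(sim$age_params) && is.null(names(sim$age_params)))
      names(sim$age_params) <- c("control", "RRMS", "SPMS")
    lst$sim <- do.call(sim_config, sim)
  }
  do.call(pipeline_config, lst)
}

#' Run the full pipeline on a synthetic or supplied study
#'
#' Executes the stages in order: simulate (or ingest), blank filter,
#' dilution filter, log2, TIC outliers, coverage, library identification,
#' LOESS normalization, QC CV, replicate merge, albumin filter,
#' imputation, age adjustment, then per-contrast PLS-DA with repeated
#' cross-validation, permutation tests, altered-metabolite tables,
#' pathway enrichment, and association analysis over the union of altered
#' metabolites. A contrast whose full-data model has Q2 < 0 is flagged
#' non-predictive and excluded from the downstream tables. For contrasts
#' involving RRMS, transitioned RRMS subjects are held out of training and
#' projected into the model space afterwards.
#'
#' @param config a [pipeline_config()]; `config$sim` must hold a
#'   [sim_config()] unless `study` is supplied.
#' @param study optional pre-generated study (the `"study"` attribute of
#'   [write_study()]); overrides `config$sim`.
#' @param outdir optional output directory; when given, all result tables
#'   and a manifest are written there.
#' @return a list with the cleaned matrix, annotations, filter reports,
#'   per-contrast results, associations and the manifest.
#' @export
run_all <- function(config = pipeline_config(), study = NULL,
                    outdir = NULL) {
  stage <- "setup"
  reports <- list()
  note <- function(r) reports[[length(reports) + 1L]] <<- r
  tryCatch({
    stage <- "simulate"
    if (is.null(study)) {
      if (is.null(config$sim)) abort("no input study and no sim config")
      cohort <- generate_cohort(config$sim)
      gen <- generate_injection_table(cohort, config$sim)
      libgen <- generate_library(gen$table, gen$truth, config$sim)
      kegg <- libgen$library$entries$kegg_id
      kegg <- kegg[!is.na(kegg)]
      pw <- generate_pathway_library(config$n_pathways,
                                     config$pathway_size_range,
                                     seed = config$sim$seed + 3L,
                                     compounds = kegg)
      study <- list(cohort = cohort, table = gen$table, truth = gen$truth,
                    library = libgen$library,
                    observed_ms2 = libgen$observed_ms2,
                    pathway_library = pw)
    }
    table <- study$table
    cohort <- study$cohort

    stage <- "blank_filter"
    st <- filter_blank_contaminants(table, config$blank_ratio)
    table <- st$table; note(st$report)
    stage <- "dilution_filter"
    st <- filter_dilution_series(table, config$dilution_min_r)
    table <- st$table; note(st$report)
    stage <- "log2"
    table <- log2_transform(table)
    stage <- "tic_outliers"
    st <- detect_tic_outliers(table, config$tic_min_frac)
    table <- st$table; note(st$report)
    stage <- "coverage_filter"
    st <- coverage_filter(table, config$coverage)
    table <- st$table; note(st$report)

    stage <- "identification"
    if (is.null(study$library)) abort("no spectral library supplied")
    ids <- identify_features(table, study$library,
                             study$observed_ms2 %||% list(),
                             config$ppm, config$rt_s, config$frag_tol)
    keep <- match(ids$feature_id, table$feature_meta$feature_id)
    st <- drop_features(table,
                        setdiff(seq_len(nrow(table$intensities)), keep),
                        "identification", "no library match")
    table <- st$table; note(st$report)

    stage <- "loess_normalize"
    table <- loess_normalize(table, config$span)
    stage <- "qc_cv"
    cvs <- qc_cv(table)
    stage <- "merge_replicates"
    mr <- merge_replicates(table)
    table <- mr$table

    stage <- "albumin_filter"
    study_cols <- inj_which(table, "study")
    values <- table$intensities[, study_cols, drop = FALSE]
    alb <- cohort$albumin_ratio[match(colnames(values), cohort$sample_id)]
    af <- albumin_filter(values, alb, config$albumin_rho, config$albumin_p)
    values <- af$values; note(af$report)
    stage <- "impute"
    values <- impute_mean(values)
    stage <- "age_adjust"
    models <- fit_age_models(values, cohort, alpha = config$age_alpha)
    values <- apply_age_correction(values, models, cohort)

    annotations <- data.frame(feature_id = ids$feature_id,
                              name = ids$name, kegg_id = ids$kegg_id,
                              validation_level = ids$validation_level,
                              qc_cv_percent = cvs[ids$feature_id],
                              stringsAsFactors = FALSE)
    annotations <- annotations[annotations$feature_id %in% rownames(values), ]

    stage <- "discriminate"
    groups <- as.character(cohort$group[match(colnames(values),
                                              cohort$sample_id)])
    contrasts <- list()
    for (ct in config$contrasts) {
      ab <- strsplit(ct, ":", fixed = TRUE)[[1]]
      in_ct <- groups %in% ab
      sid <- colnames(values)[in_ct]
      hold <- cohort$sample_id[cohort$transitioned &
                                 cohort$sample_id %in% sid]
      train_ids <- setdiff(sid, hold)
      Xt <- t(values[, train_ids, drop = FALSE])
      yt <- factor(groups[match(train_ids, colnames(values))],
                   levels = c(ab[2], ab[1]))
      fit <- fit_plsda(Xt, yt, cv_seed = config$seed)
      res <- list(contrast = ct, r2y = fit$r2y, q2 = fit$q2,
                  n_components = fit$n_components,
                  predictive = fit$q2 >= 0)
      if (res$predictive) {
        pt <- permutation_test(Xt, yt, fit$n_components,
                               n_perm = config$n_perm, seed = config$seed)
        res$r2_perm_p <- pt$r2_perm_p; res$q2_perm_p <- pt$q2_perm_p
        cv <- repeated_cv(Xt, yt, k = config$k, repeats = config$repeats,
                          seed = config$seed,
                          n_components = fit$n_components)
        res$cv <- cv
        res$altered <- altered_metabolites(cv, values, groups, ab,
                                           annotations,
                                           config$vip_threshold)
        if (!is.null(study$pathway_library) && nrow(res$altered) > 0) {
          q <- res$altered$kegg_id
          res$enrichment <- suppressWarnings(
            enrich_all(q[!is.na(q)], study$pathway_library))
        }
        if (length(hold) > 0) {
          pr <- project(fit, t(values[, hold, drop = FALSE]))
          res$projected <- data.frame(sample_id = hold,
                                      y_score = pr$y_score,
                                      class = pr$class,
                                      stringsAsFactors = FALSE)
        }
      }
      contrasts[[ct]] <- res
    }

    stage <- "associate"
    altered_union <- unique(unlist(lapply(contrasts, function(r)
      if (!is.null(r$altered)) r$altered$feature_id)))
    assoc <- clust <- NULL
    if (length(altered_union) >= 2) {
      assoc <- associate_all(values[altered_union, , drop = FALSE], cohort,
                             alpha = config$alpha)
      ok <- rowSums(is.na(assoc$rho)) == 0
      if (sum(ok) >= 2)
        clust <- cluster_rows(assoc$rho[ok, , drop = FALSE])
    }

    stage <- "manifest"
    manifest <- list(
      package_version = as.character(utils::packageVersion("csfmet")),
      r_version = R.version.string, seed = config$seed,
      config_hash = config_hash(config),
      stages = lapply(reports, unclass),
      n_samples = ncol(values), n_metabolites = nrow(values),
      contrasts = lapply(contrasts, function(r)
        r[intersect(names(r), c("contrast", "r2y", "q2", "n_components",
                                "predictive", "r2_perm_p", "q2_perm_p"))]))

    result <- list(values = values, annotations = annotations,
                   qc_cv = cvs, age_models = models,
                   min_replicate_correlation = mr$min_replicate_correlation,
                   reports = reports, contrasts = contrasts,
                   associations = assoc, clustering = clust,
                   manifest = manifest, cohort = cohort)
    if (!is.null(outdir)) write_results(result, outdir, config)
    result
  }, error = function(e) {
    abort("pipeline halted at stage '%s': %s", stage, conditionMessage(e))
  })
}

#' @noRd
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  cfg <- unclass(config)
  if (!is.null(cfg$sim)) cfg$sim <- unclass(cfg$sim)
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                              null = "null", force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

#' @noRd
write_results <- function(result, outdir, config) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write.csv(data.frame(feature_id = rownames(result$values),
                       result$values, check.names = FALSE),
            file.path(outdir, "cleaned_matrix.csv"), row.names = FALSE)
  write.csv(result$annotations, file.path(outdir, "identifications.csv"),
            row.names = FALSE)
  write.csv(data.frame(feature_id = names(result$qc_cv),
                       cv_percent = result$qc_cv),
            file.path(outdir, "qc_cv.csv"), row.names = FALSE)
  write.csv(result$age_models, file.path(outdir, "age_models.csv"),
            row.names = FALSE)
  jsonlite::write_json(lapply(result$reports, unclass),
                       file.path(outdir, "filter_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  for (ct in names(result$contrasts)) {
    r <- result$contrasts[[ct]]
    tag <- gsub(":", "_vs_", ct)
    if (!is.null(r$cv)) {
      write.csv(r$cv$vip, file.path(outdir, sprintf("cv_summary_%s.csv", tag)),
                row.names = FALSE)
      write.csv(r$cv$roc, file.path(outdir, sprintf("roc_curve_%s.csv", tag)),
                row.names = FALSE)
    }
    if (!is.null(r$altered))
      write.csv(r$altered,
                file.path(outdir, sprintf("altered_metabolites_%s.csv", tag)),
                row.names = FALSE)
    if (!is.null(r$enrichment))
      write.csv(r$enrichment,
                file.path(outdir, sprintf("enrichment_%s.csv", tag)),
                row.names = FALSE)
  }
  if (!is.null(result$associations)) {
    a <- result$associations
    long <- expand.grid(metabolite = rownames(a$rho),
                        measure = colnames(a$rho), stringsAsFactors = FALSE)
    long$rho <- a$rho[cbind(long$metabolite, long$measure)]
    long$p <- a$p[cbind(long$metabolite, long$measure)]
    long$significant <- a$significant[cbind(long$metabolite, long$measure)]
    write.csv(long, file.path(outdir, "associations.csv"), row.names = FALSE)
  }
  jsonlite::write_json(result$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(outdir)
}

#' Demographic comparison table
#'
#' Per-group summaries and SPMS-vs-RRMS post hoc tests for age, EDSS and
#' disease duration: Shapiro-Wilk normality at 0.05 routes each variable
#' to Welch's t-test (normal; summarized mean (SD)) or the Mann-Whitney
#' test (non-normal; summarized median (range)); sex uses a chi-squared
#' test across all groups.
#'
#' @param samples cohort data.frame (see [generate_cohort()]).
#' @return data.frame: variable, one summary column per group, `test`,
#'   `p`.
#' @export
demographics_report <- function(samples) {
  grps <- levels(droplevels(factor(samples$group)))
  if (length(grps) < 2) abort("need >= 2 groups")
  vars <- intersect(c("age", "edss", "disease_duration"), names(samples))
  rows <- list()
  for (v in vars) {
    x_r <- samples[[v]][samples$group == "RRMS"]
    x_s <- samples[[v]][samples$group == "SPMS"]
    x_r <- x_r[!is.na(x_r)]; x_s <- x_s[!is.na(x_s)]
    normal <- length(unique(x_r)) > 2 && length(unique(x_s)) > 2 &&
      shapiro.test(x_r)$p.value >= 0.05 && shapiro.test(x_s)$p.value >= 0.05
    p <- if (length(x_r) < 2 || length(x_s) < 2) NA_real_
    else if (normal) welch_t(x_s, x_r)$p
    else suppressWarnings(wilcox.test(x_s, x_r)$p.value)
    summ <- vapply(grps, function(g) {
      x <- samples[[v]][samples$group == g]
      x <- x[!is.na(x)]
      if (length(x) == 0) return("n/a")
      if (normal) sprintf("%.1f (%.1f)", mean(x), sd(x))
      else sprintf("%.1f (%.1f-%.1f)", median(x), min(x), max(x))
    }, "")
    rows[[v]] <- c(variable = v, summ,
                   test = if (normal) "welch" else "mann-whitney",
                   p = format(p, digits = 3))
  }
  if ("sex" %in% names(samples)) {
    tab <- table(samples$group, samples$sex)
    p <- suppressWarnings(chisq.test(tab)$p.value)
    summ <- vapply(grps, function(g)
      paste(table(samples$sex[samples$group == g]), collapse = "/"), "")
    rows$sex <- c(variable = "sex (F/M)", summ, test = "chi-squared",
                  p = format(p, digits = 3))
  }
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
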
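test_that("generate_cohort reproduces the study design and is deterministic", {
  cfg <- sim_config(seed = 1)
  cohort <- generate_cohort(cfg)
  expect_equal(nrow(cohort), 56)
  expect_equal(sum(cohort$group == "SPMS"), 16)
  expect_equal(sum(cohort$group == "RRMS"), 30)
  expect_true(all(cohort$age >= 18))
  expect_true(all(is.na(cohort$edss[cohort$group == "control"])))
  expect_true(all(cohort$edss >= 0 & cohort$edss <= 10, na.rm = TRUE))
  expect_true(all(cohort$edss %% 0.5 == 0, na.rm = TRUE))
  expect_true(median(cohort$edss[cohort$group == "SPMS"]) >
                median(cohort$edss[cohort$group == "RRMS"]))
  expect_true(median(cohort$disease_duration[cohort$group == "SPMS"]) >
                median(cohort$disease_duration[cohort$group == "RRMS"]))
  expect_true(all(cohort$group[cohort$transitioned] == "RRMS"))

  tiny <- generate_cohort(sim_config(n_per_group = c(control = 1, RRMS = 1,
                                                     SPMS = 1)))
  expect_equal(nrow(tiny), 3)
  expect_equal(sort(as.character(tiny$group)), c("RRMS", "SPMS", "control"))

  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
})

test_that("invalid configs are rejected with the offending field named", {
  expect_error(sim_config(frac_contaminant = 1.5), "frac_contaminant")
  expect_error(sim_config(dilution_volumes = c(2, 1)), "dilution_volumes")
  expect_error(sim_config(n_per_group = c(control = 0, RRMS = 1, SPMS = 1)),
               "n_per_group")
  expect_error(sim_config(noise_sd = -1), "noise_sd")
})

test_that("noise-free, drift-free tables have identical QC injections", {
  cfg <- small_cfg(noise_sd = 0, drift_amplitude = 0, missing_rate = 0)
  gen <- generate_injection_table(generate_cohort(cfg), cfg)
  qc <- gen$table$intensities[, gen$table$injections$type == "qc"]
  expect_true(all(abs(qc - qc[, 1]) < 1e-9))
})

test_that("contaminant flags match the matrix' own blank/study structure", {
  cfg <- sim_config(n_per_group = c(control = 4, RRMS = 6, SPMS = 5),
                    n_features = 100, frac_contaminant = 0.1,
                    noise_sd = 0, missing_rate = 0, seed = 7)
  gen <- generate_injection_table(generate_cohort(cfg), cfg)
  M <- gen$table$intensities
  M[is.na(M)] <- 0
  blank_mean <- rowMeans(M[, gen$table$injections$type == "blank"])
  study_mean <- rowMeans(M[, gen$table$injections$type == "study"])
  flagged <- which(blank_mean >= study_mean)
  expect_equal(length(flagged), sum(gen$truth$is_contaminant))
  expect_setequal(gen$truth$feature_id[flagged],
                  gen$truth$feature_id[gen$truth$is_contaminant])
})

test_that("dilution intensities are linear in volume for clean features", {
  cfg <- small_cfg(noise_sd = 0, missing_rate = 0)
  gen <- generate_injection_table(generate_cohort(cfg), cfg)
  dil <- gen$table$injections$type == "dilution"
  vols <- gen$table$injections$volume[dil]
  clean <- which(!gen$truth$is_contaminant)
  r <- apply(gen$table$intensities[clean, dil], 1, function(x) cor(x, vols))
  expect_true(all(r >= 0.99))
})

test_that("the generator is deterministic and fast", {
  cfg <- sim_config(seed = 42)
  elapsed <- system.time({
    g1 <- generate_injection_table(generate_cohort(cfg), cfg)
  })["elapsed"]
  g2 <- generate_injection_table(generate_cohort(cfg), cfg)
  expect_identical(g1, g2)
  expect_lt(elapsed, 10)
})

test_that("library generation covers identified features and round-trips MSP", {
  cfg <- small_cfg(frac_identified = 1.0, noise_sd = 0, missing_rate = 0)
  gen <- generate_injection_table(generate_cohort(cfg), cfg)
  lg <- generate_library(gen$table, gen$truth, cfg)
  noncontam <- gen$truth$feature_id[!gen$truth$is_contaminant]
  expect_setequal(lg$feature_identity$feature_id, noncontam)

  ids <- match_library(gen$table$feature_meta, lg$library)
  matched_names <- ids$name[ids$matched]
  expect_false(any(grepl("^DECOY", matched_names)))

  f1 <- tempfile(); f2 <- tempfile()
  write_msp(lg$library, f1)
  write_msp(generate_library(gen$table, gen$truth, cfg)$library, f2)
  expect_identical(readLines(f1), readLines(f2))
  back <- read_msp(f1)
  expect_equal(back$entries$name, lg$library$entries$name)
  expect_equal(back$entries$mz, lg$library$entries$mz, tolerance = 1e-8)
  expect_equal(length(back$ms2), length(lg$library$ms2))
})

test_that("pathway libraries cover the universe and are deterministic", {
  pw <- generate_pathway_library(10, c(5, 15), 80, seed = 3)
  expect_equal(length(unique(unlist(lapply(pw, `[[`, "compounds")))), 80)
  for (p in pw) {
    g <- igraph::graph_from_data_frame(as.data.frame(p$edges),
                                       directed = FALSE,
                                       vertices = p$compounds)
    expect_true(igraph::is_connected(g))
    expect_true(all(as.vector(p$edges) %in% p$compounds))
  }
  f1 <- tempfile(); f2 <- tempfile()
  write_gmt(pw, f1)
  write_gmt(generate_pathway_library(10, c(5, 15), 80, seed = 3), f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_error(generate_pathway_library(3, c(5, 100), 80), "exceeds")
})

test_that("default filters recover ground-truth flags across seeds", {
  tp_b <- fp_b <- fn_b <- tn_b <- 0
  tp_a <- fp_a <- fn_a <- tn_a <- 0
  for (seed in 1:20) {
    cfg <- small_cfg(seed = seed, noise_sd = 0.05, missing_rate = 0)
    gen <- generate_injection_table(generate_cohort(cfg), cfg)
    truth <- gen$truth

    st <- filter_blank_contaminants(gen$table)
    called <- truth$feature_id %in% st$report$removed
    tp_b <- tp_b + sum(called & truth$is_contaminant)
    fp_b <- fp_b + sum(called & !truth$is_contaminant)
    fn_b <- fn_b + sum(!called & truth$is_contaminant)
    tn_b <- tn_b + sum(!called & !truth$is_contaminant)

    tb <- log2_transform(st$table)
    study <- tb$injections$type == "study"
    vals <- tb$intensities[, study]
    colnames(vals) <- tb$injections$sample_id[study]
    cohort <- generate_cohort(cfg)
    alb <- cohort$albumin_ratio[match(colnames(vals), cohort$sample_id)]
    af <- albumin_filter(vals, alb)
    sub_truth <- truth[match(rownames(vals), truth$feature_id), ]
    called_a <- sub_truth$feature_id %in% af$report$removed
    tp_a <- tp_a + sum(called_a & sub_truth$albumin_linked)
    fp_a <- fp_a + sum(called_a & !sub_truth$albumin_linked)
    fn_a <- fn_a + sum(!called_a & sub_truth$albumin_linked)
    tn_a <- tn_a + sum(!called_a & !sub_truth$albumin_linked)
  }
  expect_gte(tp_b / (tp_b + fn_b), 0.9)
  expect_gte(tn_b / (tn_b + fp_b), 0.9)
  expect_gte(tp_a / (tp_a + fn_a), 0.9)
  expect_gte(tn_a / (tn_a + fp_a), 0.9)
})
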
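make_lib <- function(mz, rt, names = sprintf("E%02d", seq_along(mz)),
                     ms2 = vector("list", length(mz))) {
  structure(list(entries = data.frame(name = names,
                                      kegg_id = rep(NA_character_,
                                                    length(mz)),
                                      mz = mz, rt = rt,
                                      adduct = rep("[M + H]", length(mz)),
                                      stringsAsFactors = FALSE),
                 ms2 = ms2), class = "spectral_library")
}

test_that("m/z + RT matching honors tolerances and tie-breaking", {
  feats <- data.frame(feature_id = "F1", mz = 180.0634, rt = 300)

  exact <- match_library(feats, make_lib(180.0634, 300))
  expect_true(exact$matched)
  expect_equal(exact$ppm_error, 0)
  expect_equal(exact$rt_error, 0)

  off16 <- match_library(feats, make_lib(180.0634 * (1 + 16e-6), 300))
  expect_false(off16$matched)
  off14 <- match_library(feats, make_lib(180.0634 * (1 + 14e-6), 300))
  expect_true(off14$matched)
  rt_out <- match_library(feats, make_lib(180.0634, 321))
  expect_false(rt_out$matched)

  # +5 ppm beats -10 ppm when both are within tolerance
  two <- make_lib(c(180.0634 * (1 + 5e-6), 180.0634 * (1 - 10e-6)),
                  c(300, 300), names = c("plus5", "minus10"))
  expect_equal(match_library(feats, two)$name, "plus5")

  expect_error(match_library(feats, make_lib(numeric(0), numeric(0))),
               "empty")
})

test_that("widening the ppm tolerance never shrinks the matched set", {
  set.seed(11)
  feats <- data.frame(feature_id = sprintf("F%02d", 1:40),
                      mz = runif(40, 100, 600), rt = runif(40, 60, 900))
  lib <- make_lib(feats$mz * (1 + rnorm(40, 0, 10e-6)),
                  feats$rt + rnorm(40, 0, 10))
  prev <- 0
  for (tol in c(2, 5, 10, 15, 25, 50)) {
    n <- sum(match_library(feats, lib, ppm_tol = tol)$matched)
    expect_gte(n, prev)
    prev <- n
  }
})

test_that("MS/MS comparison computes coverage, shared peaks and cosine", {
  ref <- cbind(mz = c(50, 60, 70, 80), intensity = c(10, 20, 30, 40))
  ident <- msms_match(ref, ref)
  expect_equal(ident$coverage, 1)
  expect_equal(ident$dot_product, 1)
  expect_true(ident$is_match)

  disjoint <- cbind(mz = c(150, 160, 170, 180), intensity = c(1, 1, 1, 1))
  none <- msms_match(disjoint, ref)
  expect_equal(none$shared_peaks, 0)
  expect_equal(none$dot_product, 0)
  expect_false(none$is_match)

  # 8-peak reference; observed shares 5 proportionally, adds 3 extras
  ref8 <- cbind(mz = seq(100, 170, by = 10), intensity = c(5, 10, 15, 20, 25,
                                                           30, 35, 40))
  obs <- rbind(cbind(mz = seq(100, 140, by = 10),
                     intensity = 2 * c(5, 10, 15, 20, 25)),
               cbind(mz = c(300, 310, 320), intensity = c(7, 8, 9)))
  m <- msms_match(obs, ref8)
  expect_equal(m$shared_peaks, 5)
  num <- sum((2 * c(5, 10, 15, 20, 25)) * c(5, 10, 15, 20, 25))
  dot_hand <- num / (sqrt(sum(obs[, 2]^2)) * sqrt(sum(ref8[, 2]^2)))
  expect_equal(m$dot_product, dot_hand, tolerance = 1e-12)
  expect_true(m$is_match)  # shared >= 5 and dot > 0.5

  expect_error(msms_match(ref[0, , drop = FALSE], ref), "empty")
})

test_that("validation levels follow the MS/MS availability rules", {
  expect_equal(assign_validation_level(TRUE, FALSE), "level1")
  expect_equal(assign_validation_level(TRUE, TRUE, TRUE), "level2")
  expect_equal(assign_validation_level(TRUE, TRUE, FALSE), "rejected")
  expect_error(assign_validation_level(FALSE, TRUE), "library match")
})

test_that("on synthetic data the matched fraction equals frac_identified", {
  for (f in c(0.5, 1.0)) {
    cfg <- small_cfg(frac_identified = f, noise_sd = 0, missing_rate = 0)
    gen <- generate_injection_table(generate_cohort(cfg), cfg)
    lg <- generate_library(gen$table, gen$truth, cfg)
    ids <- identify_features(gen$table, lg$library, lg$observed_ms2)
    noncontam <- gen$truth$feature_id[!gen$truth$is_contaminant]
    expect_equal(sum(ids$feature_id %in% noncontam) / length(noncontam),
                 round(f * length(noncontam)) / length(noncontam))
    expect_false(any(grepl("^DECOY", ids$name)))
    # acquired MS/MS spectra are copies of the reference: level 2
    expect_setequal(ids$feature_id[ids$validation_level == "level2"],
                    intersect(names(lg$observed_ms2), ids$feature_id))
  }
})
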
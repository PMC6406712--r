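two_class_data <- function(n1 = 10, n2 = 10, p = 5, delta = 2, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n1 * p), n1), matrix(rnorm(n2 * p) + delta, n2))
  colnames(X) <- sprintf("v%02d", seq_len(p))
  list(X = X, y = factor(rep(c("A", "B"), c(n1, n2))))
}

test_that("fitting basics: separation, degenerate input, guard rails", {
  # a single binary variable identical to the class indicator: R2Y = 1
  Xb <- matrix(rep(c(0, 1), each = 8), ncol = 1,
               dimnames = list(NULL, "v1"))
  yb <- factor(rep(c("A", "B"), each = 8))
  mb <- fit_plsda(Xb, yb, n_components = 1, compute_q2 = FALSE)
  expect_equal(mb$n_components, 1)
  expect_equal(mb$r2y, 1, tolerance = 1e-10)

  # X built to carry (almost) no class information
  set.seed(2)
  X <- matrix(rnorm(20 * 5), 20)
  y <- factor(rep(c("A", "B"), each = 10))
  yc <- ifelse(y == "B", 1, -1)
  X <- apply(X, 2, function(col) residuals(lm(col ~ yc)) + 0.01 * rnorm(20))
  colnames(X) <- sprintf("v%d", 1:5)
  m0 <- fit_plsda(X, y, n_components = 1)
  expect_lt(m0$r2y, 0.2)
  expect_lt(m0$q2, 0)
  d <- two_class_data(p = 1, delta = 6)

  expect_error(fit_plsda(d$X[1:10, , drop = FALSE], d$y[1:10]), "2 classes")
  expect_warning(fit_plsda(cbind(d$X, const = 1), d$y, n_components = 1,
                           compute_q2 = FALSE), "zero-variance")
  expect_warning(fit_plsda(d$X, d$y, n_components = 50, compute_q2 = FALSE),
                 "truncated")
})

test_that("NIPALS algebraic identities hold", {
  d <- two_class_data(p = 5, seed = 3)
  m <- fit_plsda(d$X, d$y, n_components = 2, compute_q2 = FALSE)
  G <- crossprod(m$T)
  expect_lt(abs(G[1, 2]), 1e-8 * sqrt(G[1, 1] * G[2, 2]))
  expect_equal(colSums(m$W^2), c(1, 1), tolerance = 1e-10,
               ignore_attr = TRUE)
  Xs <- scale(d$X, m$x_means, m$x_sds)
  expect_equal(unname(m$T), unname(Xs %*% m$R), tolerance = 1e-10)
  # full-rank fit reconstructs the scaled matrix exactly
  mf <- fit_plsda(d$X, d$y, n_components = 5, compute_q2 = FALSE)
  expect_equal(unname(mf$T %*% t(mf$P)), unname(Xs), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("VIP satisfies its normalization and closed forms", {
  d1 <- two_class_data(p = 1, delta = 3, seed = 4)
  expect_equal(unname(vip(fit_plsda(d1$X, d1$y, 1, compute_q2 = FALSE))), 1,
               tolerance = 1e-12)

  for (seed in 1:5) {
    d <- two_class_data(p = 7, seed = seed)
    m <- fit_plsda(d$X, d$y, n_components = 3, compute_q2 = FALSE)
    expect_equal(mean(vip(m)^2), 1, tolerance = 1e-10)
  }

  # A = 1: VIP_j = sqrt(p) |w_1j| with w_1 the normalized X'y direction
  d <- two_class_data(p = 4, n1 = 5, n2 = 5, seed = 6)
  m1 <- fit_plsda(d$X, d$y, n_components = 1, compute_q2 = FALSE)
  Xs <- scale(d$X, m1$x_means, m1$x_sds)
  yc <- ifelse(d$y == "B", 1, -1); yc <- yc - mean(yc)
  w_direct <- crossprod(Xs, yc); w_direct <- w_direct / sqrt(sum(w_direct^2))
  expect_equal(unname(vip(m1)), as.numeric(sqrt(4) * abs(w_direct)),
               tolerance = 1e-10)
})

test_that("Q2 rewards signal and punishes noise", {
  set.seed(7)
  y <- factor(rep(c("A", "B"), each = 10))
  yc <- ifelse(y == "B", 1, -1)
  X <- cbind(yc, yc)
  colnames(X) <- sprintf("v%d", 1:2)
  expect_gt(q2(X, y, 1, seed = 1), 0.9)
  expect_lte(q2(X, y, 1, seed = 1), fit_plsda(X, y, 1, compute_q2 = FALSE)$r2y)

  q2_null <- vapply(1:50, function(s) {
    set.seed(100 + s)
    q2(matrix(rnorm(20 * 10), 20), sample(y), 1, seed = s)
  }, 0)
  expect_lte(median(q2_null), 0)
})

test_that("permutation test formula and null behavior", {
  d <- two_class_data(delta = 4, seed = 8)
  pt <- permutation_test(d$X, d$y, 1, n_perm = 19, seed = 1)
  expect_equal(pt$q2_perm_p, 1 / 20)
  expect_equal(pt$r2_perm_p, 1 / 20)
  expect_error(permutation_test(d$X, d$y, 1, n_perm = 0), "n_perm")

  over05 <- vapply(1:30, function(s) {
    set.seed(200 + s)
    X <- matrix(rnorm(16 * 6), 16)
    y <- factor(rep(c("A", "B"), each = 8))
    permutation_test(X, y, 1, n_perm = 49, seed = s)$q2_perm_p > 0.05
  }, TRUE)
  expect_gte(mean(over05), 0.8)
})

test_that("repeated CV counts folds, is reproducible, and nails easy data", {
  d <- two_class_data(n1 = 23, n2 = 23, p = 3, delta = 6, seed = 9)
  cv <- repeated_cv(d$X, d$y, k = 5, repeats = 10, seed = 1,
                    n_components = 1)
  expect_equal(cv$n_models, 50)
  # balanced folds; every sample held out exactly once per repeat
  expect_true(all(apply(cv$fold_assignments, 2, function(f)
    all(table(f) %in% 8:10) && length(f) == 46)))
  expect_equal(cv$auroc_mean, 1)
  expect_identical(repeated_cv(d$X, d$y, k = 5, repeats = 10, seed = 1,
                               n_components = 1)$vip, cv$vip)

  # stratification: 7 + 7 samples in 7 folds -> one of each class per fold
  d14 <- two_class_data(n1 = 7, n2 = 7, p = 3, seed = 10)
  cv14 <- repeated_cv(d14$X, d14$y, k = 7, repeats = 1, seed = 1,
                      n_components = 1)
  folds <- cv14$fold_assignments[, 1]
  expect_true(all(table(folds, d14$y) == 1))

  expect_error(repeated_cv(d14$X, d14$y, k = 9), "smaller k")
})

test_that("single informative variable gives VIP 1 with zero-width CI", {
  set.seed(11)
  X <- matrix(c(rnorm(8, 0), rnorm(8, 5)), ncol = 1,
              dimnames = list(NULL, "v1"))
  y <- factor(rep(c("A", "B"), each = 8))
  cv <- repeated_cv(X, y, k = 4, repeats = 3, seed = 1, n_components = 1)
  expect_equal(cv$vip$mean, 1, tolerance = 1e-12)
  expect_equal(cv$vip$upper - cv$vip$lower, 0, tolerance = 1e-12)
})

test_that("projection is consistent with training and centering", {
  d <- two_class_data(seed = 12)
  m <- fit_plsda(d$X, d$y, n_components = 2, compute_q2 = FALSE)
  pr <- project(m, d$X)
  expect_equal(unname(pr$scores), unname(m$T), tolerance = 1e-8)
  mean_row <- matrix(m$x_means, 1, dimnames = list(NULL, m$variables))
  expect_equal(max(abs(project(m, mean_row)$scores)), 0, tolerance = 1e-10)
  expect_error(project(m, d$X[, 1:3]), "missing model variables")

  # samples drawn from the positive class's distribution project positive
  set.seed(13)
  new_b <- matrix(rnorm(50 * 5) + 2, 50,
                  dimnames = list(NULL, colnames(d$X)))
  frac <- mean(project(m, new_b)$y_score > m$threshold)
  expect_gt(frac, 0.5)
})

test_that("auroc equals the Mann-Whitney construction", {
  expect_equal(auroc(c(1, 2, 3, 4), factor(c("a", "a", "b", "b"))), 1)
  expect_equal(auroc(c(4, 3, 2, 1), factor(c("a", "a", "b", "b"))), 0)
  expect_equal(auroc(rep(1, 6), factor(rep(c("a", "b"), 3))), 0.5)
  expect_equal(auroc(c(1, 2, 3, 4), factor(c("a", "b", "a", "b"))), 0.75)
  expect_error(auroc(1:3, factor(c("a", "a", "a"))), "both classes")
})
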
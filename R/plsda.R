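#' Two-class PLS-DA via NIPALS
#'
#' Fits a partial least squares discriminant model for a single binary
#' response. Predictors are autoscaled (zero mean, unit variance;
#' zero-variance variables are dropped with a warning) and the class
#' labels coded -1/+1 (first factor level negative, second positive) and
#' centered. Components are extracted by the iterative NIPALS algorithm,
#' which for a single response reduces to: `w_a = X_a'y_a` normalized,
#' `t_a = X_a w_a`, `p_a = X_a't_a / t_a't_a`, `c_a = y_a't_a / t_a't_a`,
#' followed by deflation of `X_a` and `y_a`.
#'
#' When `n_components` is `NULL` the component count is chosen
#' automatically: components are added while the inner cross-validated
#' Q2 improves by at least 0.01 (minimum 1, maximum `max_components`).
#'
#' @param X numeric n-by-p matrix.
#' @param y two-level factor (or coercible), length n.
#' @param n_components number of latent components, or `NULL` for
#'   automatic selection.
#' @param max_components cap for automatic selection; default 10.
#' @param inner_folds folds of the inner Q2 cross-validation; default 7.
#' @param cv_seed seed for the inner fold draw; default 1.
#' @param compute_q2 whether to attach the inner-CV Q2 to the model.
#' @return an object of class `plsda`: weights `W` (p-by-A, unit columns),
#'   loadings `P`, y-loadings `c`, scores `T` (mutually orthogonal
#'   columns), scaling parameters, `r2y`, `q2`, the class coding and the
#'   prediction threshold (midpoint of class-mean fitted scores).
#' @export
fit_plsda <- function(X, y, n_components = NULL, max_components = 10,
                      inner_folds = 7, cv_seed = 1, compute_q2 = TRUE) {
  X <- as.matrix(X)
  y <- droplevels(as.factor(y))
  if (nlevels(y) != 2)
    abort("y must have exactly 2 classes (got %d)", nlevels(y))
  if (any(table(y) < 2)) abort("each class needs >= 2 samples")
  if (nrow(X) != length(y)) abort("nrow(X) != length(y)")

  sds <- apply(X, 2, sd)
  keep <- sds > 0
  if (!all(keep)) {
    warning(sprintf("dropping %d zero-variance variable(s)", sum(!keep)))
    X <- X[, keep, drop = FALSE]
    sds <- sds[keep]
  }
  if (ncol(X) < 1) abort("no variables with nonzero variance")
  mns <- colMeans(X)
  Xs <- scale(X, center = mns, scale = sds)

  ycode <- ifelse(y == levels(y)[2], 1, -1)
  y_mean <- mean(ycode)
  yc <- ycode - y_mean

  max_rank <- min(nrow(X) - 1L, ncol(X))
  if (is.null(n_components)) {
    A <- 1L
    q2_prev <- q2(X, y, 1L, n_inner_folds = inner_folds, seed = cv_seed)
    while (A < min(max_components, max_rank)) {
      q2_next <- q2(X, y, A + 1L, n_inner_folds = inner_folds,
                    seed = cv_seed)
      if (!is.finite(q2_next) || q2_next - q2_prev < 0.01) break
      A <- A + 1L; q2_prev <- q2_next
    }
  } else {
    A <- as.integer(n_components)
    if (A > max_rank) {
      warning(sprintf("n_components truncated from %d to rank %d", A,
                      max_rank))
      A <- max_rank
    }
  }

  core <- nipals_pls1(Xs, yc, A)
  A <- ncol(core$W)
  fitted <- core$T %*% core$c
  r2y <- 1 - sum((yc - fitted)^2) / sum(yc^2)

  m <- structure(list(n_components = A, W = core$W, P = core$P, c = core$c,
                      T = core$T, x_means = mns, x_sds = sds,
                      y_mean = y_mean,
                      class_coding = setNames(c(-1, 1), levels(y)),
                      variables = colnames(X) %||% as.character(seq_len(ncol(X))),
                      r2y = r2y, q2 = NA_real_, r2_perm_p = NA_real_,
                      q2_perm_p = NA_real_),
                 class = "plsda")
  # projection matrix R = W (P'W)^-1 so that T = Xs R
  m$R <- core$W %*% solve(crossprod(core$P, core$W))
  yhat <- as.numeric(fitted) + y_mean
  m$threshold <- mean(c(mean(yhat[ycode == 1]), mean(yhat[ycode == -1])))
  if (compute_q2)
    m$q2 <- q2(X, y, A, n_inner_folds = inner_folds, seed = cv_seed)
  m
}

#' @noRd
nipals_pls1 <- function(Xs, yc, A) {
  p <- ncol(Xs)
  W <- matrix(0, p, 0); P <- matrix(0, p, 0)
  Tm <- matrix(0, nrow(Xs), 0); cvec <- numeric(0)
  Xa <- Xs; ya <- yc
  for (a in seq_len(A)) {
    w <- crossprod(Xa, ya)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    t_a <- Xa %*% w
    tt <- sum(t_a^2)
    if (tt < 1e-12) break
    p_a <- crossprod(Xa, t_a) / tt
    c_a <- sum(ya * t_a) / tt
    Xa <- Xa - t_a %*% t(p_a)
    ya <- ya - t_a * c_a
    W <- cbind(W, w); P <- cbind(P, p_a)
    Tm <- cbind(Tm, t_a); cvec <- c(cvec, c_a)
  }
  if (ncol(W) == 0) abort("no PLS component could be extracted")
  list(W = W, P = P, T = Tm, c = cvec)
}

#' @export
print.plsda <- function(x, ...) {
  cat(sprintf("PLS-DA model: %d component(s), %d variables (%s vs %s)\n",
              x$n_components, length(x$variables),
              names(x$class_coding)[2], names(x$class_coding)[1]))
  cat(sprintf("  R2Y = %.3f, Q2 = %.3f\n", x$r2y, x$q2))
  invisible(x)
}

#' Variable Importance in the Projection
#'
#' `VIP_j = sqrt(p * sum_a(SSY_a w_aj^2) / sum_a(SSY_a))` with unit-norm
#' weight vectors and `SSY_a = c_a^2 t_a't_a`, the y-variance explained by
#' component a. The squared VIPs average to exactly 1 over variables.
#'
#' @param model a fitted [fit_plsda()] model.
#' @return named numeric vector of VIP scores.
#' @export
vip <- function(model) {
  ssy <- model$c^2 * colSums(model$T^2)
  p <- nrow(model$W)
  v <- sqrt(p * as.numeric(model$W^2 %*% ssy) / sum(ssy))
  setNames(v, model$variables)
}

#' Cross-validated Q2
#'
#' `Q2 = 1 - PRESS/TSS` over stratified inner folds: per fold the model is
#' refit on the training part (with training-fold scaling and y
#' centering), held-out centered class codes are predicted, and squared
#' prediction errors accumulated. Negative Q2 means the model predicts
#' worse than the class mean -- no predictivity.
#'
#' @param X,y as in [fit_plsda()].
#' @param n_components number of components.
#' @param n_inner_folds number of folds; default 7.
#' @param seed seed for the fold draw.
#' @return the Q2 value.
#' @export
q2 <- function(X, y, n_components, n_inner_folds = 7, seed = 1) {
  X <- as.matrix(X)
  y <- droplevels(as.factor(y))
  if (nrow(X) < n_inner_folds) abort("n (%d) < n_inner_folds (%d)",
                                     nrow(X), n_inner_folds)
  folds <- stratified_folds(y, n_inner_folds, seed)
  ycode <- ifelse(y == levels(y)[2], 1, -1)
  press <- 0; tss <- 0
  for (f in seq_len(n_inner_folds)) {
    test <- which(folds == f)
    if (length(test) == 0) next
    train <- setdiff(seq_along(y), test)
    if (length(unique(ycode[train])) < 2) next
    sds <- apply(X[train, , drop = FALSE], 2, sd)
    keep <- sds > 0
    mns <- colMeans(X[train, keep, drop = FALSE])
    Xs <- scale(X[train, keep, drop = FALSE], mns, sds[keep])
    ym <- mean(ycode[train])
    yc <- ycode[train] - ym
    A <- min(n_components, length(train) - 1L, sum(keep))
    core <- nipals_pls1(Xs, yc, A)
    R <- core$W %*% solve(crossprod(core$P, core$W))
    Xt <- scale(X[test, keep, drop = FALSE], mns, sds[keep])
    pred <- (Xt %*% R) %*% core$c
    ytc <- ycode[test] - ym
    press <- press + sum((ytc - pred)^2)
    tss <- tss + sum(ytc^2)
  }
  1 - press / tss
}

#' @noRd
stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  folds <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    folds[idx] <- rep_len(sample.int(k), length(idx))
  }
  folds
}

#' Permutation test for PLS-DA quality metrics
#'
#' Permutes the class labels `n_perm` times, refits, and reports
#' `p = (1 + #{permuted metric >= observed}) / (n_perm + 1)` for both R2Y
#' and Q2.
#'
#' @param X,y as in [fit_plsda()].
#' @param n_components component count (fixed across permutations).
#' @param n_perm number of permutations; default 100.
#' @param seed seed.
#' @param n_inner_folds folds for the Q2 computations.
#' @return list: `r2_perm_p`, `q2_perm_p`, plus the observed and permuted
#'   metric values.
#' @export
permutation_test <- function(X, y, n_components = 1, n_perm = 100, seed = 1,
                             n_inner_folds = 7) {
  if (n_perm < 1) abort("n_perm must be >= 1")
  y <- droplevels(as.factor(y))
  obs_fit <- fit_plsda(X, y, n_components, compute_q2 = FALSE)
  obs_r2 <- obs_fit$r2y
  obs_q2 <- q2(X, y, n_components, n_inner_folds, seed = seed)
  set.seed(seed)
  perm_r2 <- numeric(n_perm); perm_q2 <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    yp <- sample(y)
    perm_r2[i] <- fit_plsda(X, yp, n_components, compute_q2 = FALSE)$r2y
    perm_q2[i] <- q2(X, yp, n_components, n_inner_folds, seed = seed + i)
  }
  list(r2_perm_p = (1 + sum(perm_r2 >= obs_r2)) / (n_perm + 1),
       q2_perm_p = (1 + sum(perm_q2 >= obs_q2)) / (n_perm + 1),
       r2y = obs_r2, q2 = obs_q2, perm_r2 = perm_r2, perm_q2 = perm_q2)
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney U statistic divided by `n1 * n2`, with
#' ties counted one half. Higher scores are expected for the positive
#' class (second factor level).
#'
#' @param scores numeric prediction scores.
#' @param labels two-level factor (or coercible).
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2) abort("auroc needs both classes present")
  pos <- labels == levels(labels)[2]
  n1 <- sum(pos); n0 <- sum(!pos)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @noRd
roc_sens_at <- function(scores, labels, fpr_grid) {
  labels <- droplevels(as.factor(labels))
  pos <- labels == levels(labels)[2]
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- c(0, vapply(thr, function(t) mean(scores[pos] >= t), 0), 1)
  fpr <- c(0, vapply(thr, function(t) mean(scores[!pos] >= t), 0), 1)
  # step ROC: sensitivity achievable at false-positive rate <= grid value
  vapply(fpr_grid, function(g) max(tpr[fpr <= g]), 0)
}

#' Repeated stratified cross-validation of a PLS-DA contrast
#'
#' Runs `repeats` independent stratified `k`-fold partitions (seeded).
#' Each fold-model is fitted on the remaining folds with a fixed component
#' count (chosen once on the full data when `n_components` is `NULL`),
#' VIP scores are computed on the fold-model, held-out samples are
#' predicted, and a fold AUROC recorded. Aggregates per-variable VIP mean
#' with a normal-approximation 95% CI over all `k * repeats` fold-models,
#' AUROC mean and SD, and a vertically averaged ROC curve (mean
#' sensitivity with SEM on a fixed 101-point 1-specificity grid).
#'
#' @param X,y as in [fit_plsda()].
#' @param k folds per repeat; default 5.
#' @param repeats number of repeats; default 10.
#' @param seed seed; repeat r uses `seed + r` for its fold draw.
#' @param n_components fixed component count, or `NULL` to auto-select
#'   once on the full data.
#' @return an object of class `plsda_cv`: `vip` data.frame (variable,
#'   mean, lower, upper), `auroc_mean`, `auroc_sd`, `roc` data.frame
#'   (fpr, sens_mean, sens_sem), `n_models`, `fold_assignments`,
#'   `n_components`.
#' @export
repeated_cv <- function(X, y, k = 5, repeats = 10, seed = 1,
                        n_components = NULL) {
  X <- as.matrix(X)
  y <- droplevels(as.factor(y))
  if (any(table(y) < k))
    abort("smallest class (%d) has fewer members than k = %d; use smaller k",
          min(table(y)), k)
  if (is.null(n_components))
    n_components <- fit_plsda(X, y, NULL, compute_q2 = FALSE,
                              cv_seed = seed)$n_components
  vars <- colnames(X) %||% as.character(seq_len(ncol(X)))
  colnames(X) <- vars
  fpr_grid <- seq(0, 1, by = 0.01)
  vips <- matrix(NA_real_, 0, length(vars), dimnames = list(NULL, vars))
  aurocs <- numeric(0)
  sens <- matrix(NA_real_, 0, length(fpr_grid))
  assignments <- matrix(NA_integer_, length(y), repeats)
  for (r in seq_len(repeats)) {
    folds <- stratified_folds(y, k, seed + r)
    assignments[, r] <- folds
    for (f in seq_len(k)) {
      test <- which(folds == f)
      train <- setdiff(seq_along(y), test)
      m <- fit_plsda(X[train, , drop = FALSE], y[train], n_components,
                     compute_q2 = FALSE)
      v <- vip(m)
      row <- setNames(rep(NA_real_, length(vars)), vars)
      row[names(v)] <- v
      vips <- rbind(vips, row)
      pr <- project(m, X[test, , drop = FALSE])
      if (length(unique(y[test])) == 2) {
        aurocs <- c(aurocs, auroc(pr$y_score, y[test]))
        sens <- rbind(sens, roc_sens_at(pr$y_score, y[test], fpr_grid))
      }
    }
  }
  n_models <- nrow(vips)
  vip_mean <- colMeans(vips, na.rm = TRUE)
  vip_sd <- apply(vips, 2, sd, na.rm = TRUE)
  half <- 1.96 * vip_sd / sqrt(n_models)
  structure(list(vip = data.frame(variable = vars, mean = vip_mean,
                                  lower = vip_mean - half,
                                  upper = vip_mean + half,
                                  row.names = NULL,
                                  stringsAsFactors = FALSE),
                 auroc_mean = mean(aurocs), auroc_sd = sd(aurocs),
                 roc = data.frame(fpr = fpr_grid,
                                  sens_mean = colMeans(sens),
                                  sens_sem = apply(sens, 2, sd) /
                                    sqrt(nrow(sens))),
                 n_models = n_models, fold_assignments = assignments,
                 n_components = n_components,
                 classes = levels(y)),
            class = "plsda_cv")
}

#' @export
print.plsda_cv <- function(x, ...) {
  cat(sprintf("PLS-DA repeated CV (%s vs %s): %d fold-models, A = %d\n",
              x$classes[2], x$classes[1], x$n_models, x$n_components))
  cat(sprintf("  AUROC %.3f (SD %.3f); %d variables with mean VIP >= 1\n",
              x$auroc_mean, x$auroc_sd, sum(x$vip$mean >= 1)))
  invisible(x)
}

#' Project new samples into a fitted PLS-DA model space
#'
#' Applies the training scaling, computes scores
#' `T_new = X_scaled W (P'W)^-1` and the predicted class score; never
#' refits. Projecting a training sample reproduces its stored score row.
#'
#' @param model a fitted [fit_plsda()] model.
#' @param X_new matrix with (at least) the model's variables as columns.
#' @return list: `scores` (n-by-A), `y_score` (predicted class score on
#'   the -1/+1 scale), `class` (predicted labels by the model threshold).
#' @export
project <- function(model, X_new) {
  X_new <- as.matrix(X_new)
  if (is.null(colnames(X_new)) && ncol(X_new) == length(model$variables))
    colnames(X_new) <- model$variables
  missing <- setdiff(model$variables, colnames(X_new))
  if (length(missing) > 0)
    abort("X_new is missing model variables: %s",
          paste(missing, collapse = ", "))
  Xs <- scale(X_new[, model$variables, drop = FALSE],
              center = model$x_means, scale = model$x_sds)
  scores <- Xs %*% model$R
  y_score <- as.numeric(scores %*% model$c) + model$y_mean
  cls <- names(model$class_coding)[ifelse(y_score >= model$threshold, 2, 1)]
  list(scores = scores, y_score = y_score, class = cls)
}
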
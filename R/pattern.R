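# Bootstrapped pattern derivation --------------------------------------------
#
# Two-stage derivation of the disease-related pattern from variability
# loadings.  Stage 1 (feature selection): bootstrap-resampled lasso
# (L1-penalised logistic regression, one-standard-error lambda rule) counts
# how often each component is selected; the component set is cut at the
# inflection point of the descending frequency histogram, found with
# discrete finite differences.  Stage 2 (pattern construction): bootstrapped
# unpenalised logistic regression on the selected loadings; per-iteration
# coefficients linearly combine the group maps into a pattern image, whose
# bootstrap mean is the derived pattern; voxels whose 99% bootstrap CI
# straddles zero are masked as non-informative; subject scores are the mean
# linear combination of loadings, scaled by the absolute coefficient sum.

# descending-profile finite differences: forward difference at the first
# point, centred at midpoints, backward at the last
finite_diff <- function(x) {
  n <- length(x)
  if (n < 2) return(numeric(n))
  d <- numeric(n)
  d[1] <- x[2] - x[1]
  if (n > 2) d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / 2
  d[n] <- x[n] - x[n - 1]
  d
}

binary_labels <- function(labels, positive) {
  u <- unique(labels)
  if (length(u) < 2) stop_invalid("both classes must be present")
  if (length(u) > 2) stop_invalid("labels must be binary")
  as.integer(labels == positive)
}

#' L1-penalised logistic regression with the one-standard-error rule
#'
#' Fits the lasso path over a geometric lambda grid (100 points from the
#' smallest lambda that nulls all coefficients, down by 10^4), estimates
#' per-lambda cross-validated binomial deviance with stratified folds, and
#' chooses the largest lambda whose deviance is within one standard error
#' of the minimum.  Predictors are standardised inside the fit and
#' coefficients are reported on the original scale.
#'
#' @param loadings numeric matrix, subjects x components.
#' @param labels group labels (two classes).
#' @param n_folds cross-validation folds (>= 2, <= smaller class size).
#' @param seed integer seed for fold assignment.
#' @param positive label treated as the positive class.
#' @param fold_groups optional identity vector (one entry per row): rows
#'   sharing an identity (bootstrap duplicates of the same subject) are
#'   kept in the same fold, so cross-validation never tests on a copy of a
#'   training row.
#' @return object of class `lasso_fit`: `lambda_grid`, `cv_deviance`
#'   (data frame lambda/mean/se), `chosen_lambda`, `nonzero_set`,
#'   `coefficients`.
#' @export
lasso_one_se <- function(loadings, labels, n_folds = 10L, seed = 1L,
                         positive = "patient", fold_groups = NULL) {
  x <- as.matrix(loadings)
  if (!all(is.finite(x))) stop_data("non-finite predictor values")
  y <- binary_labels(labels, positive)
  n_min <- min(table(y))
  if (n_folds < 2 || n_folds > n_min)
    stop_invalid("n_folds must be in [2, smaller class size]")

  col_sd <- apply(x, 2, sd)
  if (all(col_sd == 0))                        # no signal at all: intercept-only
    return(structure(list(lambda_grid = numeric(0),
                          cv_deviance = data.frame(lambda = numeric(0),
                                                   mean = numeric(0),
                                                   se = numeric(0)),
                          chosen_lambda = NA_real_,
                          nonzero_set = integer(0),
                          coefficients = rep(0, ncol(x))),
                     class = "lasso_fit"))

  # lambda grid from the null-model gradient on standardised predictors
  xs <- scale(x[, col_sd > 0, drop = FALSE])
  lmax <- max(abs(crossprod(xs, y - mean(y)))) / length(y)
  grid <- exp(seq(log(lmax), log(lmax / 1e4), length.out = 100L))

  set.seed(child_seed(seed, 4L))
  foldid <- integer(length(y))
  if (is.null(fold_groups)) {
    for (g in unique(y)) {                     # stratified fold assignment
      w <- sample(which(y == g))
      foldid[w] <- rep_len(seq_len(n_folds), length(w))
    }
  } else {
    # assign unique identities to folds (stratified by class), then expand,
    # so duplicated rows never straddle the train/test split
    for (g in unique(y)) {
      ids <- sample(unique(fold_groups[y == g]))
      fid <- rep_len(seq_len(n_folds), length(ids))
      for (k in seq_along(ids))
        foldid[fold_groups == ids[k]] <- fid[k]
    }
  }

  dev_fold <- matrix(NA_real_, n_folds, length(grid))
  for (f in seq_len(n_folds)) {
    tr <- foldid != f
    if (all(tr) || length(unique(y[tr])) < 2) next
    # tiny-lambda non-convergence on separable resamples is benign: the
    # one-SE rule only ever picks large lambdas
    fit <- suppressWarnings(
      glmnet::glmnet(x[tr, , drop = FALSE], y[tr], family = "binomial",
                     lambda = grid, standardize = TRUE))
    p <- predict(fit, x[!tr, , drop = FALSE], s = grid, type = "response")
    p <- pmin(pmax(p, 1e-10), 1 - 1e-10)
    yt <- y[!tr]
    dev_fold[f, ] <- colMeans(-2 * (yt * log(p) + (1 - yt) * log(1 - p)))
  }
  used <- rowSums(is.na(dev_fold)) < ncol(dev_fold)
  cvm <- colMeans(dev_fold[used, , drop = FALSE])
  cvse <- apply(dev_fold[used, , drop = FALSE], 2, sd) / sqrt(sum(used))
  i_min <- which.min(cvm)
  ok <- cvm <= cvm[i_min] + cvse[i_min]
  chosen <- max(grid[ok])                      # grid is descending: largest ok

  full <- suppressWarnings(
    glmnet::glmnet(x, y, family = "binomial", lambda = grid,
                   standardize = TRUE))
  beta <- as.numeric(predict(full, s = chosen, type = "coefficients",
                             exact = FALSE))[-1]
  structure(list(lambda_grid = grid,
                 cv_deviance = data.frame(lambda = grid, mean = cvm, se = cvse),
                 chosen_lambda = chosen,
                 nonzero_set = which(beta != 0),
                 coefficients = beta),
            class = "lasso_fit")
}

#' Bootstrap selection frequencies of components under the lasso
#'
#' Per iteration: resample subjects with replacement (stratified by group,
#' preserving group sizes), run [lasso_one_se()] on the resample, and count
#' each component that survives with a nonzero coefficient.  Returns the
#' frequency histogram with its descending order and discrete first/second
#' derivative sequences.
#'
#' @param loadings numeric matrix, subjects x components.
#' @param labels group labels.
#' @param n_boot bootstrap iterations.
#' @param n_folds cross-validation folds per iteration.
#' @param seed integer seed; iteration b uses distinct child seeds.
#' @param positive positive-class label.
#' @param cv_scope "subject" keeps bootstrap duplicates of a subject inside
#'   one cross-validation fold (honest CV); "row" treats resampled rows as
#'   independent (the behaviour of off-the-shelf CV on a resampled matrix).
#' @return object of class `selection_profile`: `frequency`, `sorted_order`,
#'   `d1`, `d2`, `selected` (filled by [select_by_inflection()]), `n_boot`,
#'   `seed`.
#' @export
bootstrap_lasso_frequencies <- function(loadings, labels, n_boot = 5000L,
                                        n_folds = 10L, seed = 1L,
                                        positive = "patient",
                                        cv_scope = c("subject", "row")) {
  cv_scope <- match.arg(cv_scope)
  x <- as.matrix(loadings)
  if (n_boot < 1) stop_invalid("n_boot must be >= 1")
  freq <- integer(ncol(x))
  budget <- 10L * n_boot
  b <- 0L; draws <- 0L
  while (b < n_boot) {
    draws <- draws + 1L
    if (draws > budget) stop_data("bootstrap retry budget exhausted")
    set.seed(child_seed(seed, 5L, draws))
    idx <- stratified_resample(labels)
    fit <- tryCatch(
      lasso_one_se(x[idx, , drop = FALSE], labels[idx], n_folds,
                   seed = child_seed(seed, 6L, draws), positive = positive,
                   fold_groups = if (cv_scope == "subject") idx else NULL),
      error = function(e) NULL)
    if (is.null(fit)) next
    b <- b + 1L
    freq[fit$nonzero_set] <- freq[fit$nonzero_set] + 1L
  }
  ord <- order(-freq, seq_along(freq))
  d1 <- finite_diff(freq[ord])
  structure(list(frequency = freq, sorted_order = ord,
                 d1 = d1, d2 = finite_diff(d1), selected = NULL,
                 n_boot = as.integer(n_boot), seed = as.integer(seed)),
            class = "selection_profile")
}

#' Cut the selection-frequency histogram at its inflection point
#'
#' Frequencies are sorted descending; the discrete first derivative is
#' computed with a forward difference at the first point, centred
#' differences at midpoints, and a backward difference at the last point.
#' The selected set is the prefix of the sorted order ending at the
#' minimum of the first derivative (the steepest drop).  The second
#' derivative (same scheme applied to the first) is reported for
#' diagnostics.
#'
#' @param profile a `selection_profile`.
#' @return integer vector of selected component ids (original column
#'   indices).
#' @export
select_by_inflection <- function(profile) {
  stopifnot(inherits(profile, "selection_profile"))
  f <- profile$frequency[profile$sorted_order]
  if (length(f) < 3) stop_invalid("need at least 3 components")
  d1 <- finite_diff(f)
  if (diff(range(d1)) == 0)
    stop_data("no inflection: selection frequencies fall linearly")
  cut <- which.min(d1)
  profile$sorted_order[seq_len(cut)]
}

# ridge-stabilised logistic regression by IRLS; lambda penalises the
# standardised slopes only.  Returns slopes on the original scale.
ridge_logistic <- function(x, y, lambda = 1e-6, max_iter = 100L, tol = 1e-8) {
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[scl == 0] <- 1
  xs <- cbind(1, sweep(sweep(x, 2, ctr), 2, scl, "/"))
  k <- ncol(xs)
  pen <- diag(c(0, rep(lambda, k - 1L)), k)
  beta <- numeric(k)
  for (it in seq_len(max_iter)) {
    eta <- drop(xs %*% beta)
    p <- 1 / (1 + exp(-eta))
    w <- pmax(p * (1 - p), 1e-10)
    z <- eta + (y - p) / w
    xtw <- t(xs * w)
    new_beta <- tryCatch(solve(xtw %*% xs + pen, xtw %*% z),
                         error = function(e) NULL)
    if (is.null(new_beta) || !all(is.finite(new_beta))) return(NULL)
    done <- max(abs(new_beta - beta)) < tol
    beta <- drop(new_beta)
    if (done) break
  }
  beta[-1] / scl
}

#' Bootstrapped logistic-regression pattern, CI mask, and subject scores
#'
#' Per iteration: stratified resample of subjects; unpenalised (tiny-ridge
#' stabilised) logistic regression of group on the selected loadings; the
#' coefficients linearly combine the selected group maps into a spatial map
#' and linearly combine every subject's loadings into a score.  The pattern
#' image is the mean map across iterations; voxels whose bootstrap
#' `1 - alpha` confidence interval straddles zero are flagged
#' non-informative; the final subject scores are the mean per-iteration
#' scores scaled by the absolute sum of the mean coefficients.
#'
#' @param loadings_selected numeric matrix, subjects x selected components.
#' @param labels group labels.
#' @param group_maps_selected matrix, selected components x voxels
#'   (z units).
#' @param n_boot bootstrap iterations.
#' @param seed integer seed.
#' @param alpha CI tail probability (two-sided total), default 0.01.
#' @param positive positive-class label.
#' @return object of class `pattern_model`: `coefficient_draws`,
#'   `mean_coefficients`, `pattern_map`, `ci_low`, `ci_high`, `stable_mask`,
#'   `subject_scores`, `oob_scores` (out-of-bag diagnostic scores, averaged
#'   only over iterations whose resample excluded the subject),
#'   `iteration_scores`, `n_boot`, `seed`, `alpha`.
#' @export
bootstrap_pattern <- function(loadings_selected, labels, group_maps_selected,
                              n_boot = 5000L, seed = 1L, alpha = 0.01,
                              positive = "patient") {
  x <- as.matrix(loadings_selected)
  maps <- as.matrix(group_maps_selected)
  if (ncol(x) < 1) stop_invalid("zero selected components")
  if (ncol(x) != nrow(maps))
    stop_invalid("loadings columns must match the selected group maps")
  y <- binary_labels(labels, positive)
  if (n_boot < 1) stop_invalid("n_boot must be >= 1")

  draws <- matrix(NA_real_, n_boot, ncol(x))
  inbag <- matrix(FALSE, n_boot, nrow(x))
  budget <- 10L * n_boot
  b <- 0L; tries <- 0L; n_failed <- 0L
  while (b < n_boot) {
    tries <- tries + 1L
    if (tries > budget)
      stop_data("logistic fits kept failing beyond the retry budget (",
                n_failed, " failures)")
    set.seed(child_seed(seed, 7L, tries))
    idx <- stratified_resample(labels)
    coefs <- ridge_logistic(x[idx, , drop = FALSE], y[idx])
    if (is.null(coefs)) { n_failed <- n_failed + 1L; next }
    b <- b + 1L
    draws[b, ] <- coefs
    inbag[b, unique(idx)] <- TRUE
  }

  map_iter <- draws %*% maps                       # n_boot x voxels
  iteration_scores <- draws %*% t(x)               # n_boot x subjects
  mean_coefficients <- colMeans(draws)
  ci <- ci_mask(map_iter, alpha)
  scale_factor <- sum(abs(mean_coefficients))
  subject_scores <- colMeans(iteration_scores) / scale_factor
  names(subject_scores) <- rownames(x)
  # out-of-bag diagnostic scores: averaged only over iterations whose
  # resample excluded the subject, so they carry no in-sample optimism
  oob <- iteration_scores
  oob[inbag] <- NA_real_
  oob_scores <- colMeans(oob, na.rm = TRUE) / scale_factor
  names(oob_scores) <- rownames(x)

  structure(list(coefficient_draws = draws,
                 mean_coefficients = mean_coefficients,
                 pattern_map = colMeans(map_iter),
                 ci_low = ci$low, ci_high = ci$high,
                 stable_mask = ci$retained,
                 subject_scores = subject_scores,
                 oob_scores = oob_scores,
                 iteration_scores = iteration_scores,
                 n_failed = n_failed, n_boot = as.integer(n_boot),
                 seed = as.integer(seed), alpha = alpha),
            class = "pattern_model")
}

#' Percentile confidence-interval mask over bootstrap draws
#'
#' Bounds are the `alpha/2` and `1 - alpha/2` percentiles per voxel; a
#' voxel is retained (informative) only when both bounds are strictly on
#' the same side of zero.
#'
#' @param draws numeric matrix, draws x voxels (a vector is treated as one
#'   voxel).
#' @param alpha total tail probability in (0, 0.5); requires at least
#'   `1/alpha` draws.
#' @return list with `low`, `high`, `retained` (logical per voxel).
#' @export
ci_mask <- function(draws, alpha = 0.01) {
  if (alpha <= 0 || alpha >= 0.5) stop_invalid("alpha must be in (0, 0.5)")
  if (is.vector(draws)) draws <- matrix(draws, ncol = 1L)
  if (nrow(draws) < 1 / alpha)
    stop_invalid("need at least 1/alpha draws per voxel")
  q <- apply(draws, 2, quantile, probs = c(alpha / 2, 1 - alpha / 2),
             names = FALSE)
  low <- q[1, ]; high <- q[2, ]
  list(low = low, high = high,
       retained = (low > 0 & high > 0) | (low < 0 & high < 0))
}
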
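# Bootstrapped lasso selection, inflection cut, and pattern construction.

make_labels <- function(n_pat = 20, n_ctl = 20)
  c(rep("patient", n_pat), rep("control", n_ctl))

test_that("lasso keeps an informative predictor and drops pure noise", {
  labels <- make_labels(20, 20)
  y <- as.integer(labels == "patient")
  hits <- vapply(1:100, function(r) {
    set.seed(r)
    x <- cbind(y + rnorm(40, 0, 0.05), matrix(rnorm(40 * 9), 40, 9))
    fit <- lasso_one_se(x, labels, n_folds = 10, seed = r)
    1L %in% fit$nonzero_set
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("constant predictors give an intercept-only fit", {
  labels <- make_labels(6, 6)
  x <- matrix(5, 12, 4)
  fit <- lasso_one_se(x, labels, n_folds = 3, seed = 1)
  expect_identical(fit$nonzero_set, integer(0))
  expect_true(all(fit$coefficients == 0))
})

test_that("the one-SE choice matches an exhaustive scan of the stored path", {
  set.seed(91)
  labels <- make_labels(15, 15)
  y <- as.integer(labels == "patient")
  x <- cbind(y + rnorm(30, 0, 0.8), matrix(rnorm(30 * 5), 30, 5))
  fit <- lasso_one_se(x, labels, n_folds = 5, seed = 9)
  cv <- fit$cv_deviance
  i_min <- which.min(cv$mean)
  admissible <- cv$lambda[cv$mean <= cv$mean[i_min] + cv$se[i_min]]
  expect_identical(fit$chosen_lambda, max(admissible))
  expect_true(fit$chosen_lambda %in% fit$lambda_grid)
  expect_lte(cv$mean[cv$lambda == fit$chosen_lambda],
             min(cv$mean) + cv$se[i_min])
})

test_that("lasso preconditions are enforced", {
  x <- matrix(rnorm(20), 10, 2)
  expect_error(lasso_one_se(x, rep("patient", 10), 2, 1), "both classes")
  expect_error(lasso_one_se(x, make_labels(5, 5), n_folds = 6, 1), "n_folds")
  xb <- x; xb[1] <- Inf
  expect_error(lasso_one_se(xb, make_labels(5, 5), 2, 1), "finite")
})

test_that("selection is scale-equivariant in the loadings", {
  set.seed(92)
  labels <- make_labels(15, 15)
  y <- as.integer(labels == "patient")
  x <- cbind(y * 2 + rnorm(30, 0, 0.5), matrix(rnorm(30 * 4), 30, 4))
  a <- lasso_one_se(x, labels, n_folds = 5, seed = 4)
  b <- lasso_one_se(x * 1000, labels, n_folds = 5, seed = 4)
  expect_identical(a$nonzero_set, b$nonzero_set)
})

test_that("a single bootstrap iteration yields a 0/1 indicator", {
  set.seed(93)
  labels <- make_labels(10, 10)
  y <- as.integer(labels == "patient")
  x <- cbind(y + rnorm(20, 0, 0.3), matrix(rnorm(20 * 3), 20, 3))
  prof <- bootstrap_lasso_frequencies(x, labels, n_boot = 1, n_folds = 5,
                                      seed = 2)
  expect_true(all(prof$frequency %in% c(0L, 1L)))
  set.seed(icapattern:::child_seed(2L, 5L, 1L))
  idx <- icapattern:::stratified_resample(labels)
  fit <- lasso_one_se(x[idx, ], labels[idx], 5,
                      seed = icapattern:::child_seed(2L, 6L, 1L),
                      fold_groups = idx)
  expect_identical(which(prof$frequency == 1L), fit$nonzero_set)
})

test_that("under permuted labels planted components lose their advantage", {
  src <- small_sources()
  dec <- decomposition_from_sources(src)
  sim <- small_cohort(seed = 55, n_pat = 8, n_ctl = 8, affected = 1:2,
                      effect_size = 1.5, sources = src)
  sub <- back_reconstruct(dec, sim$cohort)
  ld <- compute_loadings(sub, dec)
  labs <- cohort_labels(sim$cohort)
  true_prof <- bootstrap_lasso_frequencies(ld$values, labs, n_boot = 50,
                                           n_folds = 5, seed = 4500)
  true_planted <- mean(true_prof$frequency[1:2])
  perm_planted <- vapply(1:20, function(r) {
    set.seed(3000 + r)
    perm <- sample(labs)
    prof <- bootstrap_lasso_frequencies(ld$values, perm, n_boot = 50,
                                        n_folds = 5, seed = 4000 + r)
    mean(prof$frequency[1:2])
  }, numeric(1))
  # with the real labels the planted pair saturates; permutation collapses
  # its selection frequency in every replicate
  expect_gte(true_planted, 45)
  expect_true(all(perm_planted < 0.6 * true_planted))
})

test_that("inflection cut reproduces the hand-computed finite differences", {
  prof1 <- structure(list(
    frequency = c(4980, 4876, 4510, 1230, 1150, 1100, 1050),
    sorted_order = 1:7, n_boot = 5000L, seed = 0L,
    d1 = NULL, d2 = NULL, selected = NULL), class = "selection_profile")
  d1 <- icapattern:::finite_diff(prof1$frequency)
  expect_identical(d1, c(-104, -235, -1823, -1680, -65, -50, -50))
  expect_identical(select_by_inflection(prof1), 1:3)

  prof2 <- structure(list(
    frequency = c(4900, 100, 90), sorted_order = 1:3, n_boot = 5000L,
    seed = 0L, d1 = NULL, d2 = NULL, selected = NULL),
    class = "selection_profile")
  expect_identical(icapattern:::finite_diff(prof2$frequency),
                   c(-4800, -2405, -10))
  expect_identical(select_by_inflection(prof2), 1L)

  # the sorted order, not the raw column order, defines the prefix
  prof3 <- prof1
  prof3$frequency <- prof1$frequency[c(4, 1, 5, 2, 6, 3, 7)]
  prof3$sorted_order <- order(-prof3$frequency)
  expect_setequal(select_by_inflection(prof3), c(2L, 4L, 6L))
})

test_that("degenerate frequency profiles raise selection errors", {
  linear <- structure(list(frequency = c(500, 400, 300, 200, 100),
                           sorted_order = 1:5, n_boot = 500L, seed = 0L,
                           d1 = NULL, d2 = NULL, selected = NULL),
                      class = "selection_profile")
  expect_error(select_by_inflection(linear), "no inflection")
  tiny <- linear; tiny$frequency <- c(5, 3); tiny$sorted_order <- 1:2
  expect_error(select_by_inflection(tiny), "at least 3")
})

test_that("bootstrap pattern trace replays from the seed exactly", {
  set.seed(94)
  labels <- make_labels(8, 8)
  y <- as.integer(labels == "patient")
  x <- cbind(y * 2 + rnorm(16, 0, 0.8), rnorm(16), rnorm(16))
  maps <- matrix(rnorm(3 * 30), 3, 30)
  pm <- bootstrap_pattern(x, labels, maps, n_boot = 15, seed = 6,
                          alpha = 0.2)
  # straight-line reimplementation of the documented loop
  draws <- matrix(NA_real_, 15, 3)
  b <- 0L; tries <- 0L
  while (b < 15) {
    tries <- tries + 1L
    set.seed(icapattern:::child_seed(6L, 7L, tries))
    idx <- icapattern:::stratified_resample(labels)
    coefs <- icapattern:::ridge_logistic(x[idx, ], y[idx])
    if (is.null(coefs)) next
    b <- b + 1L
    draws[b, ] <- coefs
  }
  expect_identical(pm$coefficient_draws, draws)
  expect_equal(pm$pattern_map, colMeans(draws %*% maps), tolerance = 1e-10)
  expect_equal(unname(pm$subject_scores),
               colMeans(draws %*% t(x)) / sum(abs(colMeans(draws))),
               tolerance = 1e-10)
})

test_that("subject scores rescale to the mean iteration scores exactly", {
  set.seed(95)
  labels <- make_labels(9, 9)
  y <- as.integer(labels == "patient")
  x <- cbind(y + rnorm(18, 0, 0.5), rnorm(18))
  maps <- matrix(rnorm(2 * 25), 2, 25)
  pm <- bootstrap_pattern(x, labels, maps, n_boot = 120, seed = 3,
                          alpha = 0.02)
  expect_equal(unname(pm$subject_scores),
               colMeans(pm$iteration_scores) /
                 sum(abs(pm$mean_coefficients)), tolerance = 1e-12)
})

test_that("an uninformative constant component contributes nothing", {
  # its coefficient is exactly zero in every draw, so the scores reduce to
  # the informative component's loadings (after the documented rescaling)
  set.seed(96)
  labels <- make_labels(10, 10)
  y <- as.integer(labels == "patient")
  x <- cbind(y * 3 + rnorm(20, 0, 0.4), rep(5, 20))
  maps <- matrix(rnorm(2 * 25), 2, 25)
  pm <- bootstrap_pattern(x, labels, maps, n_boot = 60, seed = 8,
                          alpha = 0.05)
  expect_true(all(pm$coefficient_draws[, 2] == 0))
  expect_equal(unname(pm$subject_scores), unname(x[, 1]), tolerance = 1e-10)
  expect_equal(pm$pattern_map, mean(pm$coefficient_draws[, 1]) * maps[1, ],
               tolerance = 1e-10)
})

test_that("component order does not affect the pattern or the scores", {
  set.seed(97)
  labels <- make_labels(9, 9)
  y <- as.integer(labels == "patient")
  x <- cbind(y + rnorm(18, 0, 0.5), y + rnorm(18, 0, 0.7), rnorm(18))
  maps <- matrix(rnorm(3 * 20), 3, 20)
  a <- bootstrap_pattern(x, labels, maps, n_boot = 40, seed = 5, alpha = 0.1)
  perm <- c(3, 1, 2)
  b <- bootstrap_pattern(x[, perm], labels, maps[perm, ], n_boot = 40,
                         seed = 5, alpha = 0.1)
  expect_equal(a$pattern_map, b$pattern_map, tolerance = 1e-10)
  expect_equal(a$subject_scores, b$subject_scores, tolerance = 1e-10)
})

test_that("pattern preconditions are enforced", {
  labels <- make_labels(5, 5)
  x <- matrix(rnorm(10 * 2), 10, 2)
  maps <- matrix(rnorm(3 * 10), 3, 10)
  expect_error(bootstrap_pattern(x, labels, maps, 10, 1), "match")
  expect_error(bootstrap_pattern(x[, 0], labels, maps[0, ], 10, 1), "zero")
  expect_error(bootstrap_pattern(x, rep("patient", 10), maps[1:2, ], 10, 1),
               "both classes")
})

test_that("CI mask follows the percentile rule and its Gaussian oracle", {
  expect_error(ci_mask(matrix(rnorm(300), 100, 3), alpha = 0.6), "alpha")
  expect_error(ci_mask(matrix(rnorm(50), 50, 1), alpha = 0.01), "draws")

  all_pos <- matrix(abs(rnorm(200)) + 0.1, 200, 1)
  expect_true(ci_mask(all_pos, 0.01)$retained)
  sym <- matrix(c(rnorm(100), -rnorm(100)), 200, 1)
  expect_false(ci_mask(sym, 0.01)$retained[1])

  set.seed(98)
  sigma <- 2
  shifted <- matrix(rnorm(5000, 3 * sigma, sigma), 5000, 1)
  near_null <- matrix(rnorm(5000, 0.1 * sigma, sigma), 5000, 1)
  cm <- ci_mask(cbind(shifted, near_null), 0.01)
  # 0.5th percentile of N(3s, s^2) ~ 3s - 2.58s > 0 -> retained;
  # of N(0.1s, s^2) ~ 0.1s - 2.58s < 0 -> masked
  expect_true(cm$retained[1])
  expect_false(cm$retained[2])
  expect_equal(cm$low[1], sigma * (3 - 2.576), tolerance = 0.15)
})
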
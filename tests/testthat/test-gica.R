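# Group ICA: MDL order, Infomax/ICASSO recovery, back-reconstruction, SBM.

test_that("MDL recovers the true order for strong sources in weak noise", {
  src <- small_sources(k = 5, seed = 9)
  sim <- generate_cohort(src, 4, 4, affected = 1, effect_size = 0,
                         t_points = 60, noise_sd = 0.05, seed = 21)
  expect_identical(estimate_order(sim$cohort, smoothness_correction = 1), 5L)
})

test_that("estimated order is non-increasing in the smoothness correction", {
  src <- small_sources(k = 5, seed = 9)
  sim <- generate_cohort(src, 4, 4, affected = 1, effect_size = 0,
                         t_points = 60, noise_sd = 0.3, seed = 22)
  orders <- vapply(c(1, 5, 25, 125),
                   function(s) estimate_order(sim$cohort, s), integer(1))
  expect_true(all(diff(orders) <= 0))
})

test_that("degenerate inputs raise estimation errors", {
  sim <- small_cohort()
  zero <- sim$cohort
  for (i in seq_along(zero$subjects)) zero$subjects[[i]]$series[] <- 0
  expect_error(estimate_order(zero), "degenerate")
})

test_that("single noiseless source is recovered exactly at order 1", {
  src <- small_sources(k = 2, seed = 3)
  one <- src
  one$sources <- src$sources[1, , drop = FALSE]
  sim <- generate_cohort(one, 2, 2, affected = integer(0), effect_size = 0,
                         t_points = 20, noise_sd = 0, seed = 5)
  dec <- fit_group_ica(sim$cohort, order = 1, n_runs = 1, seed = 2)
  r <- cor(dec$group_maps[1, ], one$sources[1, ])
  expect_gte(abs(r), 1 - 1e-6)
})

test_that("group maps follow the z-scoring and sign conventions", {
  sim <- small_cohort(seed = 13)
  dec <- fit_group_ica(sim$cohort, order = 4, n_runs = 3, seed = 6)
  for (j in seq_len(dec$order)) {
    m <- dec$group_maps[j, ]
    expect_equal(mean(m), 0, tolerance = 1e-10)
    expect_equal(sd(m), 1, tolerance = 1e-10)
    # positive side at least as heavy as negative side
    expect_gte(sum(m[m > 0]) + 1e-8, abs(sum(m[m < 0])))
    # heavier tail is positive (operative flip rule)
    expect_gte(mean(m^3), 0)
  }
  expect_true(all(dec$stability_index >= 0 & dec$stability_index <= 1))
})

test_that("stability is high on structured data and lower on pure noise", {
  sim <- small_cohort(seed = 17, noise_sd = 0.2)
  dec <- fit_group_ica(sim$cohort, order = 4, n_runs = 6, seed = 6)
  expect_true(all(dec$stability_index >= 0.8))
  noise_stab <- vapply(1:5, function(r) {
    nz <- sim$cohort
    set.seed(900 + r)
    for (i in seq_along(nz$subjects))
      nz$subjects[[i]]$series[] <- rnorm(length(nz$subjects[[i]]$series))
    mean(fit_group_ica(nz, order = 4, n_runs = 6,
                       seed = 600 + r)$stability_index)
  }, numeric(1))
  expect_true(all(noise_stab < mean(dec$stability_index)))
})

test_that("centrotype selection matches brute-force maximisation", {
  # small instances: enumerate every member's within-cluster similarity sum
  set.seed(44)
  for (rep in 1:5) {
    maps <- matrix(rnorm(15 * 40), 15, 40)
    sim <- abs(cor(t(maps)))
    cl <- cutree(hclust(as.dist(1 - sim), method = "average"), k = 5)
    for (c in unique(cl)) {
      members <- which(cl == c)
      sums <- vapply(members, function(m)
        sum(sim[m, setdiff(members, m)]), numeric(1))
      best <- members[which.max(sums + sim[cbind(members, members)] - 1)]
      # package rule: rowSums(within) - 1
      within <- sim[members, members, drop = FALSE]
      pick <- members[which.max(rowSums(within) - 1)]
      expect_identical(pick, best)
    }
  }
})

test_that("back-reconstruction is symmetric, consistent and deviation-sensitive", {
  src <- small_sources()
  sim <- small_cohort(seed = 23, noise_sd = 0.3, affected = 1,
                      effect_size = 1.5, sources = src)
  dec <- fit_group_ica(sim$cohort, order = 4, n_runs = 3, seed = 8)
  sub <- back_reconstruct(dec, sim$cohort)

  # identical subjects yield identical maps
  clone <- sim$cohort
  for (i in seq_along(clone$subjects))
    clone$subjects[[i]]$series <- sim$cohort$subjects[[1]]$series
  sub_clone <- back_reconstruct(dec, clone)
  for (i in 2:length(clone$subjects))
    expect_lt(max(abs(sub_clone$subjects[[i]]$maps -
                        sub_clone$subjects[[1]]$maps)), 1e-6)

  # mean subject map tracks the group map per component
  mean_maps <- Reduce(`+`, lapply(sub$subjects, `[[`, "maps")) /
    length(sub$subjects)
  for (j in seq_len(dec$order))
    expect_gte(cor(mean_maps[j, ], dec$group_maps[j, ]), 0.95)

  # subjects with a planted deviation sit farther from the group map
  ld <- compute_loadings(sub, dec)
  labs <- cohort_labels(sim$cohort)
  cc <- abs(cor(t(dec$group_maps), t(src$sources)))
  j_aff <- which.max(cc[, 1])
  col <- match(j_aff, ld$component_ids)
  expect_gt(max(ld$values[labs == "patient", col]),
            max(ld$values[labs == "control", col]))

  # mask mismatch is rejected
  other <- sim$cohort
  other$mask_idx <- other$mask_idx[-1]
  expect_error(back_reconstruct(dec, other), "mask")
})

test_that("relabelling subjects permutes the reconstruction identically", {
  sim <- small_cohort(seed = 29)
  dec <- fit_group_ica(sim$cohort, order = 4, n_runs = 2, seed = 8)
  perm <- c(3, 1, 2, 4, 5, 7, 6, 8, 10, 9)
  permuted <- sim$cohort
  permuted$subjects <- sim$cohort$subjects[perm]
  a <- back_reconstruct(dec, sim$cohort)
  b <- back_reconstruct(dec, permuted)
  for (i in seq_along(perm))
    expect_identical(b$subjects[[i]]$maps, a$subjects[[perm[i]]]$maps)
})

test_that("component labels gate downstream loadings", {
  sim <- small_cohort(seed = 37)
  dec <- fit_group_ica(sim$cohort, order = 4, n_runs = 2, seed = 8)
  sub <- back_reconstruct(dec, sim$cohort)

  expect_error(apply_component_labels(dec, NULL), "empty")
  expect_error(apply_component_labels(
    dec, data.frame(component = 1:3, label = "neural")), "cover all")
  expect_error(apply_component_labels(
    dec, data.frame(component = c(1:4, 9), label = "neural")), "unknown")

  all_neural <- apply_component_labels(
    dec, data.frame(component = 1:4, label = "neural"))
  expect_identical(ncol(compute_loadings(sub, all_neural)$values), 4L)

  mixed <- apply_component_labels(
    dec, data.frame(component = paste0("IC", 1:4),
                    label = c("neural", "artefact", "neural", "artefact")))
  ld <- compute_loadings(sub, mixed)
  expect_identical(ncol(ld$values), 2L)
  expect_identical(ld$component_ids, c(1L, 3L))
})

test_that("a 34-component labelling with 11 artefacts retains 23 columns", {
  # label ingestion contract at the published scale: 23 neural + 11 artefact
  n_sub <- 6; order <- 34; v <- 50
  maps <- lapply(seq_len(n_sub), function(i) {
    set.seed(500 + i); matrix(rnorm(order * v), order, v)
  })
  dec <- as_group_decomp(matrix(rnorm(order * v), order, v))
  labels <- data.frame(component = 1:34,
                       label = c(rep("neural", 23), rep("artefact", 11)))
  dec <- apply_component_labels(dec, labels)
  ld <- compute_loadings(as_subject_decomp(maps), dec)
  expect_identical(ncol(ld$values), 23L)
})

test_that("source-based morphometry recovers a planted atrophy component", {
  src <- small_sources(seed = 51)
  base <- src$sources[1, ] + 1
  atrophy <- src$sources[3, ]
  labs <- c(rep("patient", 8), rep("control", 8))
  gm <- generate_gm_maps(base, atrophy, labs, effect_size = 1.5, seed = 61,
                         noise_sd = 0)
  expect_error(fit_sbm(gm$maps, order = 16, n_runs = 1, seed = 1), "order")

  dec <- fit_sbm(gm$maps, order = 1, n_runs = 3, seed = 71)
  expect_identical(dim(dec$mixing), c(16L, 1L))
  expect_gte(abs(cor(dec$sources[1, ], atrophy)), 0.95)
  expect_gte(abs(cor(dec$mixing[, 1], gm$a)), 0.95)

  # with noise and several extracted sources the atrophy source is still
  # matched and its mixing column tracks the planted loadings
  gm2 <- generate_gm_maps(base, atrophy, labs, effect_size = 1.5, seed = 62,
                          noise_sd = 0.05)
  dec2 <- fit_sbm(gm2$maps, order = 3, n_runs = 5, seed = 72)
  expect_identical(dim(dec2$mixing), c(16L, 3L))
  j <- which.max(abs(cor(t(dec2$sources), atrophy)))
  expect_gte(abs(cor(dec2$mixing[, j], gm2$a)), 0.9)
})
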
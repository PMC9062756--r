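# Group spatial ICA ----------------------------------------------------------
#
# Temporal-concatenation group ICA in the GIFT tradition: two-stage PCA
# reduction, repeated Infomax runs aggregated by ICASSO-style clustering
# (centrotype per cluster), MDL model-order estimation, dual-regression
# back-reconstruction of subject maps, and the same ICA core applied to
# stacked grey-matter maps (source-based morphometry).

# ---- MDL order estimation ---------------------------------------------------

#' Estimate the number of components by minimum description length
#'
#' Computes the eigenvalue spectrum of the voxel covariance of the
#' concatenated (time x voxel) data and minimises the Wax-Kailath MDL
#' criterion.  Spatially smoothed data violate the i.i.d.-sample assumption;
#' the effective sample size is therefore divided by `smoothness_correction`
#' (1 = no correction).
#'
#' @param cohort a `cohort` object.
#' @param smoothness_correction scalar >= 1 dividing the effective number of
#'   samples.
#' @param max_order largest order considered (defaults to the spectrum size
#'   minus one).
#' @return integer order in [2, min(total timepoints, voxels) - 1].
#' @export
estimate_order <- function(cohort, smoothness_correction = 1,
                           max_order = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  if (smoothness_correction < 1)
    stop_invalid("smoothness_correction must be >= 1")
  x <- concat_series(cohort)
  if (all(abs(x) < .Machine$double.eps))
    stop_data("degenerate (zero-variance) data: order cannot be estimated")
  tt <- nrow(x); v <- ncol(x)
  # nonzero spectrum of the voxel covariance, via the smaller Gram matrix
  p <- min(tt, v)
  g <- if (tt <= v) tcrossprod(x) / tt else crossprod(x) / tt
  ev <- eigen(g, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev[seq_len(p)], .Machine$double.eps)
  n_eff <- tt / smoothness_correction
  kmax <- p - 1L
  if (!is.null(max_order)) kmax <- min(kmax, max_order)
  mdl <- vapply(seq_len(kmax), function(k) {
    tail_ev <- ev[(k + 1):p]
    m <- p - k
    loglik <- n_eff * m * (log(mean(tail_ev)) - mean(log(tail_ev)))
    loglik + 0.5 * k * (2 * p - k) * log(n_eff)
  }, numeric(1))
  ord <- which.min(mdl)
  as.integer(min(max(ord, 2L), p - 1L))
}

concat_series <- function(cohort) {
  do.call(rbind, lapply(cohort$subjects, function(s)
    sweep(s$series, 2, colMeans(s$series))))
}

# ---- Infomax ICA core -------------------------------------------------------

# Natural-gradient Infomax with the logistic nonlinearity on pre-whitened
# data x (k x n samples).  Learning rate anneals on oscillation; restarts
# with a halved rate if the update diverges.
infomax <- function(x, max_iter = 500L, tol = 1e-7, lr = 0.05) {
  k <- nrow(x); n <- ncol(x)
  w0 <- qr.Q(qr(matrix(rnorm(k * k), k)))
  for (attempt in 1:8) {
    w <- w0
    rate <- lr
    prev_delta <- NULL
    ok <- TRUE
    for (it in seq_len(max_iter)) {
      u <- w %*% x
      y <- 1 / (1 + exp(-u))
      grad <- diag(k) + ((1 - 2 * y) %*% t(u)) / n
      delta <- grad %*% w
      if (!all(is.finite(delta))) { ok <- FALSE; break }
      w <- w + rate * delta
      gnorm <- sqrt(sum(grad^2) / k)
      if (gnorm < tol) break
      if (!is.null(prev_delta) && sum(delta * prev_delta) < 0)
        rate <- rate * 0.9
      prev_delta <- delta
    }
    if (ok && all(is.finite(w))) return(w)
    lr <- lr / 2
  }
  stop_data("Infomax failed to converge after retries")
}

# skewness-positive sign convention: the heavier tail of each map is made
# positive, so component "activations" carry positive z-scores
flip_signs <- function(maps) {
  sk <- apply(maps, 1, function(m) mean((m - mean(m))^3))
  ifelse(sk < 0, -1, 1)
}

# ---- ICASSO-style stability aggregation ------------------------------------

# Runs Infomax n_runs times with distinct child seeds on whitened data
# (k x voxels), pools all runs' maps, clusters them on 1 - |spatial r|
# (average linkage, k clusters) and keeps each cluster's centrotype: the
# member with maximal summed similarity to its cluster.  The stability
# index is mean within-cluster minus mean between-cluster similarity.
run_icasso <- function(white, order, n_runs, seed) {
  all_maps <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    set.seed(child_seed(seed, 3L, r))
    w <- infomax(white)
    all_maps[[r]] <- w %*% white
  }
  pooled <- do.call(rbind, all_maps)
  if (nrow(pooled) == 1L)
    return(list(maps = pooled, stability = 1))
  sim <- abs(cor(t(pooled)))
  cl <- cutree(hclust(as.dist(1 - sim), method = "average"), k = order)
  pick <- integer(order)
  stability <- numeric(order)
  for (c in seq_len(order)) {
    members <- which(cl == c)
    within <- sim[members, members, drop = FALSE]
    sums <- rowSums(within) - 1          # exclude self-similarity
    pick[c] <- members[which.max(sums)]
    n_m <- length(members)
    w_mean <- if (n_m > 1) sum(within[upper.tri(within)]) /
      (n_m * (n_m - 1) / 2) else 1
    between <- sim[members, -members, drop = FALSE]
    b_mean <- if (length(between)) mean(between) else 0
    stability[c] <- min(1, max(0, w_mean - b_mean))
  }
  maps <- pooled[pick, , drop = FALSE]
  list(maps = maps, stability = stability)
}

# ---- Group decomposition ----------------------------------------------------

#' Fit a group spatial ICA by temporal concatenation
#'
#' Per-subject temporal PCA (to `ceiling(1.5 * order)` dimensions), group
#' PCA of the concatenated reduced data to `order`, whitening, `n_runs`
#' Infomax runs aggregated by ICASSO-style clustering with centrotype
#' selection.  Group maps are z-scored over in-mask voxels and sign-flipped
#' so the heavier amplitude tail is positive; group time courses are the
#' least-squares projection of the concatenated data onto the maps.
#'
#' @param cohort a `cohort` object.
#' @param order number of components.
#' @param n_runs Infomax repetitions for the stability analysis.
#' @param seed integer seed; run r uses a distinct child seed.
#' @return object of class `group_decomp` with `order`, `group_maps`
#'   (order x voxels, z units), `group_timecourses` (total timepoints x
#'   order), `stability_index`, `component_labels`, `reduction`, and the
#'   cohort's mask geometry.
#' @export
fit_group_ica <- function(cohort, order, n_runs = 20L, seed = 1L) {
  stopifnot(inherits(cohort, "cohort"))
  t_i <- nrow(cohort$subjects[[1]]$series)
  v <- ncol(cohort$subjects[[1]]$series)
  n_sub <- length(cohort$subjects)
  if (order < 1) stop_invalid("order must be positive")
  l_sub <- min(max(order, ceiling(1.5 * order)), t_i, v)
  if (order > min(n_sub * l_sub, v))
    stop_invalid("order exceeds the rank of the reduced data")

  # stage 1: per-subject temporal PCA to l_sub rows
  reduced <- lapply(cohort$subjects, function(s) {
    y <- sweep(s$series, 2, colMeans(s$series))
    e <- eigen(tcrossprod(y), symmetric = TRUE)
    t(e$vectors[, seq_len(l_sub), drop = FALSE]) %*% y
  })
  xg <- do.call(rbind, reduced)

  # stage 2: group PCA + whitening (voxels as samples)
  g <- tcrossprod(xg) / v
  e <- eigen(g, symmetric = TRUE)
  if (e$values[order] <= 1e-12 * e$values[1])
    stop_invalid("order exceeds the effective rank of the data")
  dewhite <- e$vectors[, seq_len(order), drop = FALSE] %*%
    diag(sqrt(e$values[seq_len(order)]), order)
  white <- diag(1 / sqrt(e$values[seq_len(order)]), order) %*%
    t(e$vectors[, seq_len(order), drop = FALSE]) %*% xg

  ic <- run_icasso(white, order, n_runs, seed)
  maps <- t(apply(ic$maps, 1, zscore))
  signs <- flip_signs(maps)
  maps <- maps * signs

  # group time courses by projection of the concatenated centred data
  xall <- concat_series(cohort)
  tc <- xall %*% t(maps) %*% solve(tcrossprod(maps))

  structure(list(order = as.integer(order), group_maps = maps,
                 group_timecourses = tc, stability_index = ic$stability,
                 component_labels = rep("neural", order),
                 reduction = list(subject_dims = l_sub,
                                  group_eigenvalues = e$values[seq_len(order)],
                                  dewhitening = dewhite,
                                  back_reconstruction = "dual_regression"),
                 mask = cohort$mask, mask_idx = cohort$mask_idx,
                 grid_dims = cohort$grid_dims, n_runs = as.integer(n_runs),
                 seed = as.integer(seed)),
            class = "group_decomp")
}

#' Back-reconstruct subject-specific component maps and time courses
#'
#' Dual (spatial-temporal) regression: each subject's centred series is
#' regressed on the group maps to obtain subject time courses, then the
#' series is regressed on those time courses to obtain subject spatial
#' maps, which are z-scored per component.  Voxel values express how
#' strongly each voxel's signal (anti-)correlates with the component time
#' course.
#'
#' @param decomp a `group_decomp`.
#' @param cohort the cohort to reconstruct (must share the mask geometry).
#' @return object of class `subject_decomp`: per subject a list with
#'   `maps` (order x voxels, z units) and `timecourses` (T x order).
#' @export
back_reconstruct <- function(decomp, cohort) {
  stopifnot(inherits(decomp, "group_decomp"), inherits(cohort, "cohort"))
  if (!identical(decomp$mask_idx, cohort$mask_idx))
    stop_invalid("cohort mask does not match the decomposition mask")
  s <- decomp$group_maps
  proj <- t(s) %*% solve(tcrossprod(s))
  subjects <- lapply(cohort$subjects, function(sub) {
    y <- sweep(sub$series, 2, colMeans(sub$series))
    tc <- y %*% proj
    m <- solve(crossprod(tc), crossprod(tc, y))
    list(id = sub$id, maps = t(apply(m, 1, zscore)), timecourses = tc)
  })
  structure(list(subjects = subjects, order = decomp$order,
                 subject_ids = vapply(subjects, `[[`, "", "id")),
            class = "subject_decomp")
}

#' Attach neural/artefact labels to a group decomposition
#'
#' Downstream stages (variability loadings, pattern derivation) use only
#' components labelled `neural`.
#'
#' @param decomp a `group_decomp`.
#' @param labels data frame with columns `component` (integer index or
#'   "IC<k>" string) and `label` ("neural" or "artefact"), covering every
#'   component.
#' @return the decomposition with `component_labels` set.
#' @export
apply_component_labels <- function(decomp, labels) {
  stopifnot(inherits(decomp, "group_decomp"))
  if (is.null(labels) || nrow(labels) == 0)
    stop_invalid("empty component label table")
  comp <- labels$component
  if (is.character(comp)) comp <- as.integer(sub("^IC", "", comp))
  if (any(is.na(comp)) || any(comp < 1) || any(comp > decomp$order))
    stop_invalid("unknown component id in label table")
  if (!all(seq_len(decomp$order) %in% comp))
    stop_invalid("label table must cover all components")
  if (!all(labels$label %in% c("neural", "artefact")))
    stop_invalid("labels must be 'neural' or 'artefact'")
  decomp$component_labels[comp] <- labels$label
  decomp
}

#' Build a reference group decomposition from known spatial maps
#'
#' Wraps a set of spatial maps (e.g. published group components, or the
#' generator's planted sources) as a `group_decomp`, z-scored and
#' sign-flipped to the package conventions, so subjects can be
#' back-reconstructed and scored against a reference decomposition without
#' re-estimating the ICA.
#'
#' @param sources a `source_set`, or a components x voxels matrix plus
#'   `mask`/`mask_idx`/`grid_dims` attributes taken from `geometry`.
#' @param geometry optional list with `mask`, `mask_idx`, `grid_dims`
#'   (required when `sources` is a bare matrix).
#' @return a `group_decomp` with unit stability and all-neural labels.
#' @export
decomposition_from_sources <- function(sources, geometry = NULL) {
  if (inherits(sources, "source_set")) {
    maps <- sources$sources
    geometry <- sources[c("mask", "mask_idx", "grid_dims")]
  } else {
    maps <- as.matrix(sources)
    if (is.null(geometry))
      stop_invalid("geometry required for a bare source matrix")
  }
  maps <- t(apply(maps, 1, zscore))
  maps <- maps * flip_signs(maps)
  structure(list(order = nrow(maps), group_maps = maps,
                 group_timecourses = NULL,
                 stability_index = rep(1, nrow(maps)),
                 component_labels = rep("neural", nrow(maps)),
                 reduction = list(back_reconstruction = "dual_regression",
                                  source = "reference"),
                 mask = geometry$mask, mask_idx = geometry$mask_idx,
                 grid_dims = geometry$grid_dims,
                 n_runs = 0L, seed = NA_integer_),
            class = "group_decomp")
}

# ---- Source-based morphometry ----------------------------------------------

#' Source-based morphometry: ICA on stacked grey-matter maps
#'
#' The subjects x voxels matrix is column-centred, reduced to `order`
#' principal components, whitened, and decomposed with the same Infomax +
#' ICASSO core as the group fMRI path.  The mixing matrix A[i, j] gives
#' subject i's loading on grey-matter source j.
#'
#' @param gm_maps numeric matrix, subjects x voxels (e.g. from
#'   [generate_gm_maps()]).
#' @param order number of sources (< number of subjects).
#' @param n_runs Infomax repetitions.
#' @param seed integer seed.
#' @return object of class `gm_decomp` with `order`, `sources`
#'   (order x voxels, z units), `mixing` (subjects x order), `stability_index`.
#' @export
fit_sbm <- function(gm_maps, order, n_runs = 20L, seed = 1L) {
  x <- as.matrix(gm_maps)
  n <- nrow(x)
  if (order >= n) stop_invalid("order must be smaller than the subject count")
  if (order < 1) stop_invalid("order must be positive")
  xc <- sweep(x, 2, colMeans(x))
  v <- ncol(xc)
  g <- tcrossprod(xc) / v
  e <- eigen(g, symmetric = TRUE)
  if (e$values[order] <= 1e-12 * max(e$values[1], .Machine$double.eps))
    stop_invalid("order exceeds the effective rank of the grey-matter data")
  white <- diag(1 / sqrt(e$values[seq_len(order)]), order) %*%
    t(e$vectors[, seq_len(order), drop = FALSE]) %*% xc
  ic <- run_icasso(white, order, n_runs, seed)
  sources <- t(apply(ic$maps, 1, zscore))
  sources <- sources * flip_signs(sources)
  mixing <- xc %*% t(sources) %*% solve(tcrossprod(sources))
  structure(list(order = as.integer(order), sources = sources,
                 mixing = mixing, stability_index = ic$stability,
                 seed = as.integer(seed)),
            class = "gm_decomp")
}
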
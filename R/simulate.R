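# Synthetic cohort generator -------------------------------------------------
#
# Produces multi-subject 4D image series with the statistical structure the
# pattern-derivation pipeline assumes: smooth group sources, subject series
# mixing those sources through smooth time courses, and, for patients, a
# spatial perturbation of a subset of "affected" sources whose magnitude
# grows with a per-subject severity.  Every draw is governed by a documented
# child-seed scheme so cohorts are bit-reproducible and extensible.

#' Generate smooth spatial sources on a masked 3D grid
#'
#' Sources are Gaussian blobs (random centres inside the mask, width set by
#' a full-width-at-half-maximum in voxels).  Candidate blobs are rejected
#' until all pairwise spatial correlations satisfy |r| < 0.4, so the sources
#' are spatially distinct by construction.  The mask is the `mask_fraction`
#' of voxels closest (in normalised ellipsoidal radius) to the grid centre.
#'
#' @param k number of sources (>= 2).
#' @param grid_dims integer vector of length 3, voxels per axis.
#' @param mask_fraction proportion of the grid covered by the brain mask.
#' @param smoothness_fwhm blob width, full width at half maximum, in voxels.
#' @param seed integer seed; identical seeds give bit-identical output.
#' @param n_blobs blobs per source.
#' @return An object of class `source_set`: list with `grid_dims`, `mask`
#'   (logical 3D array), `mask_idx` (ascending linear voxel indices, fastest
#'   axis first), `sources` (k x in-mask-voxels matrix), `smoothness_fwhm`,
#'   `seed`.
#' @export
generate_sources <- function(k, grid_dims, mask_fraction = 0.6,
                             smoothness_fwhm = 3, seed = 1L, n_blobs = 2L) {
  if (length(grid_dims) != 3L || any(grid_dims < 1))
    stop_invalid("grid_dims must be 3 positive integers")
  if (prod(grid_dims) < 500)
    stop_invalid("grid volume must be at least 500 voxels")
  if (k < 2) stop_invalid("k must be >= 2")

  # mask: the mask_fraction voxels with smallest normalised radius
  cx <- (grid_dims + 1) / 2
  gx <- expand.grid(x = seq_len(grid_dims[1]), y = seq_len(grid_dims[2]),
                    z = seq_len(grid_dims[3]))
  r2 <- ((gx$x - cx[1]) / grid_dims[1])^2 + ((gx$y - cx[2]) / grid_dims[2])^2 +
    ((gx$z - cx[3]) / grid_dims[3])^2
  n_in <- max(1L, floor(mask_fraction * prod(grid_dims)))
  mask <- array(FALSE, grid_dims)
  mask[order(r2)[seq_len(n_in)]] <- TRUE
  mask_idx <- which(mask)            # ascending linear index, fastest axis first
  if (k > length(mask_idx)) stop_invalid("k exceeds the in-mask voxel count")

  sigma <- smoothness_fwhm / (2 * sqrt(2 * log(2)))
  coords <- gx[mask_idx, , drop = FALSE]

  set.seed(child_seed(seed, 0L))
  sources <- matrix(0, k, length(mask_idx))
  for (j in seq_len(k)) {
    for (try in seq_len(300L)) {
      m <- numeric(length(mask_idx))
      for (b in seq_len(n_blobs)) {
        ctr <- coords[sample.int(nrow(coords), 1L), ]
        d2 <- (coords$x - ctr$x)^2 + (coords$y - ctr$y)^2 + (coords$z - ctr$z)^2
        m <- m + exp(-d2 / (2 * sigma^2))
      }
      ok <- j == 1L ||
        all(abs(cor(m, t(sources[seq_len(j - 1L), , drop = FALSE]))) < 0.4)
      if (ok) { sources[j, ] <- m; break }
      if (try == 300L)
        stop_data("could not place source ", j,
                  " with pairwise |r| < 0.4; enlarge the grid or lower k")
    }
  }
  structure(list(grid_dims = as.integer(grid_dims), mask = mask,
                 mask_idx = mask_idx, sources = sources,
                 smoothness_fwhm = smoothness_fwhm, seed = as.integer(seed)),
            class = "source_set")
}

# deviation template for one source: partial replacement by a copy shifted
# `shift` voxels along `axis` (periodic at the grid edge).  The difference
# is orthogonalised against the span of all sources so the planted
# deviation stays specific to its component and does not leak into the
# others through back-reconstruction, and is rescaled to the norm of the
# source so deviation weights are comparable across components.
shifted_deviation <- function(sources_set, j, shift = 2L, axis = 1L) {
  dims <- sources_set$grid_dims
  full <- array(0, dims)
  full[sources_set$mask_idx] <- sources_set$sources[j, ]
  ix <- ((seq_len(dims[axis]) - 1L - shift) %% dims[axis]) + 1L
  sh <- switch(axis, full[ix, , ], full[, ix, ], full[, , ix])
  d <- sh[sources_set$mask_idx] - sources_set$sources[j, ]
  s <- t(sources_set$sources)
  d <- d - s %*% solve(crossprod(s), crossprod(s, d))
  drop(d) * sqrt(sum(sources_set$sources[j, ]^2) / sum(d^2))
}

#' Generate a synthetic cohort with planted disease structure
#'
#' Each subject's 4D series mixes subject-specific spatial maps through
#' temporally smoothed random time courses, plus i.i.d. Gaussian noise.
#' Patients' maps on the `affected` components are partially replaced by a
#' spatially shifted copy of the source, with replacement weight
#' proportional to `severity * effect_size`, so the squared-Euclidean
#' spatial deviation grows monotonically with severity.  Controls have
#' severity 0 and unperturbed maps.  The clinical severity score is
#' `10 * severity` plus unit Gaussian noise (floored at 0), resembling an
#' ataxia rating scale; two severity-linked neurocognitive columns and an
#' external pattern-score stand-in are included.
#'
#' @param sources a `source_set` from [generate_sources()].
#' @param n_patients,n_controls group sizes (each >= 2).
#' @param affected indices of sources perturbed in patients.
#' @param effect_size nonnegative scalar scaling the perturbation weight.
#' @param t_points timepoints per subject (>= 3 x number of sources).
#' @param noise_sd additive Gaussian noise SD on the series.
#' @param seed master seed; subject i uses child seed stream i.
#' @param tr_seconds repetition time recorded in the cohort.
#' @param ma_window moving-average window (timepoints) smoothing the
#'   time courses.
#' @param deviation_scale weight per unit `severity * effect_size`
#'   (capped at 0.95).
#' @param shift_voxels shift of the perturbing copy, in voxels.
#' @return list with `cohort`, `clinical`, `ground_truth`.
#' @export
generate_cohort <- function(sources, n_patients, n_controls, affected,
                            effect_size, t_points, noise_sd, seed = 1L,
                            tr_seconds = 2.45, ma_window = 5L,
                            deviation_scale = 0.5, shift_voxels = 2L,
                            affected_multipliers = NULL, weight_cap = 1.2) {
  stopifnot(inherits(sources, "source_set"))
  k <- nrow(sources$sources)
  if (n_patients < 2 || n_controls < 2)
    stop_invalid("each group needs at least 2 subjects")
  if (length(affected) > 0 && (any(affected < 1) || any(affected > k)))
    stop_invalid("affected indices outside 1..k")
  if (length(affected) == 0 && effect_size > 0)
    stop_invalid("affected set empty while effect_size > 0")
  if (effect_size < 0) stop_invalid("effect_size must be >= 0")
  if (t_points < 3 * k) stop_invalid("t_points must be >= 3 x number of sources")

  v <- length(sources$mask_idx)
  n <- n_patients + n_controls
  ids <- sprintf("sub-%02d", seq_len(n))
  groups <- c(rep("patient", n_patients), rep("control", n_controls))

  # graded per-component effect multipliers (strongest to mildest), so the
  # affected components span a range of effect sizes as diseases do
  if (is.null(affected_multipliers))
    affected_multipliers <- if (length(affected) > 1)
      seq(1.1, 0.9, length.out = length(affected)) else
        rep(1, length(affected))
  if (length(affected_multipliers) != length(affected))
    stop_invalid("affected_multipliers must match the affected set")

  subjects <- vector("list", n)
  severity <- numeric(n)
  weights <- matrix(0, n, length(affected))
  clin <- vector("list", n)
  dev_dirs <- matrix(list(), n, length(affected))
  for (i in seq_len(n)) {
    set.seed(child_seed(seed, 1L, i))
    # disease expression is drawn independently per affected network
    # (multi-system disorders hit different networks to different degrees);
    # the subject's severity is the aggregate of the per-network severities,
    # the way a clinical sum score aggregates multiple systems
    n_aff <- max(1L, length(affected))
    sev_comp <- if (groups[i] == "patient") runif(n_aff, 0.5, 2.0) else
      numeric(n_aff)
    sev <- mean(sev_comp)
    severity[i] <- sev
    w <- pmin(weight_cap, deviation_scale * effect_size *
                affected_multipliers * sev_comp[seq_along(affected)])
    weights[i, ] <- w
    maps <- sources$sources
    if (sev > 0 && length(affected)) {
      # each patient deviates along an idiosyncratic spatial direction
      # (random shift axis and sign), as spatial reorganisation differs
      # between individuals; a shared template would instead be absorbed
      # into the group decomposition as a coherent variance direction
      for (a in seq_along(affected)) {
        axis <- sample(1:2, 1L)
        sgn <- sample(c(-1L, 1L), 1L)
        d <- shifted_deviation(sources, affected[a], sgn * shift_voxels, axis)
        dev_dirs[[i, a]] <- d
        maps[affected[a], ] <- maps[affected[a], ] + w[a] * d
      }
    }
    tc <- ma_smooth(matrix(rnorm(t_points * k), t_points, k), ma_window)
    tc <- sweep(tc, 2, apply(tc, 2, sd), "/")
    series <- tc %*% maps
    if (noise_sd > 0)
      series <- series + matrix(rnorm(t_points * v, 0, noise_sd), t_points, v)
    subjects[[i]] <- list(id = ids[i], group = groups[i], series = series)
    clin[[i]] <- data.frame(
      subject_id = ids[i], group = groups[i],
      severity_score = max(0, 10 * sev + rnorm(1)),
      sdmt = 55 - 9 * sev + rnorm(1, 0, 4),
      fluency = 32 - 6 * sev + rnorm(1, 0, 5),
      external_pattern_score = sev + rnorm(1, 0, 0.25),
      stringsAsFactors = FALSE)
  }

  cohort <- structure(list(subjects = subjects, mask = sources$mask,
                           mask_idx = sources$mask_idx,
                           grid_dims = sources$grid_dims,
                           tr_seconds = tr_seconds),
                      class = "cohort")
  clinical <- do.call(rbind, clin)
  ground_truth <- structure(list(
    affected_components = as.integer(affected), severity = severity,
    deviation_weights = weights, deviation_maps = dev_dirs,
    sources = sources, noise_sd = noise_sd, effect_size = effect_size,
    seed = as.integer(seed), groups = groups, subject_ids = ids),
    class = "ground_truth")
  list(cohort = cohort, clinical = clinical, ground_truth = ground_truth)
}

#' True spatial-deviation norms implied by the ground truth
#'
#' Returns the subjects x components matrix of planted L2 deviation norms
#' `w_i * ||deviation_j||` (zero off the affected set); the oracle against
#' which recovered variability loadings are compared.
#'
#' @param ground_truth a `ground_truth` object.
#' @return numeric matrix, subjects x components.
#' @export
deviation_norms <- function(ground_truth) {
  gt <- ground_truth
  k <- nrow(gt$sources$sources)
  out <- matrix(0, length(gt$severity), k)
  if (length(gt$affected_components))
    for (a in seq_along(gt$affected_components)) {
      j <- gt$affected_components[a]
      # deviation templates are rescaled to the source norm, so the norm of
      # subject i's planted deviation is w[i, a] * ||source_j||
      out[, j] <- gt$deviation_weights[, a] *
        sqrt(sum(gt$sources$sources[j, ]^2))
    }
  dimnames(out) <- list(gt$subject_ids, paste0("IC", seq_len(k)))
  out
}

#' Generate per-subject grey-matter maps with a planted atrophy component
#'
#' Subject map = base - a_i * atrophy + noise, where the loading a_i is
#' Gaussian around `a_mean` with SD `a_sd`, shifted upward by
#' `effect_size * a_sd` for patients.  The planted loadings are returned so
#' source-based-morphometry recovery can be tested.
#'
#' @param base,atrophy_component numeric vectors over the same voxel set
#'   (or 3D arrays of identical dimensions).
#' @param cohort_labels character vector of "patient"/"control".
#' @param effect_size group shift of the atrophy loading, in units of `a_sd`.
#' @param seed master seed (subject i uses child stream 2, index i).
#' @param noise_sd voxel noise SD.
#' @param a_mean,a_sd loading distribution parameters.
#' @return list with `maps` (subjects x voxels), `a` (planted loadings),
#'   `labels`.
#' @export
generate_gm_maps <- function(base, atrophy_component, cohort_labels,
                             effect_size, seed = 1L, noise_sd = 0.05,
                             a_mean = 1, a_sd = 0.3) {
  if (is.array(base) || is.array(atrophy_component)) {
    if (!identical(dim(base), dim(atrophy_component)))
      stop_invalid("base and atrophy maps are on different grids")
    base <- as.numeric(base); atrophy_component <- as.numeric(atrophy_component)
  }
  if (length(base) != length(atrophy_component))
    stop_invalid("base and atrophy maps are on different grids")
  n <- length(cohort_labels)
  v <- length(base)
  maps <- matrix(0, n, v)
  a <- numeric(n)
  for (i in seq_len(n)) {
    set.seed(child_seed(seed, 2L, i))
    a[i] <- a_mean + effect_size * a_sd * (cohort_labels[i] == "patient") +
      rnorm(1, 0, a_sd)
    maps[i, ] <- base - a[i] * atrophy_component
    if (noise_sd > 0) maps[i, ] <- maps[i, ] + rnorm(v, 0, noise_sd)
  }
  list(maps = maps, a = a, labels = cohort_labels)
}
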
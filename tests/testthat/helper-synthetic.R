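# Shared fixtures, built in code at test time.

# a small source set on a grid just above the 500-voxel floor
small_sources <- function(k = 4, seed = 101) {
  generate_sources(k, c(12, 12, 6), mask_fraction = 0.6,
                   smoothness_fwhm = 2.5, seed = seed)
}

# a small cohort with planted structure; fast enough for per-test use
small_cohort <- function(seed = 202, n_pat = 5, n_ctl = 5, affected = 1:2,
                         effect_size = 1.5, t_points = 40, noise_sd = 0.5,
                         sources = small_sources(), ...) {
  generate_cohort(sources, n_pat, n_ctl, affected = affected,
                  effect_size = effect_size, t_points = t_points,
                  noise_sd = noise_sd, seed = seed, ...)
}

cohort_labels <- function(cohort) {
  vapply(cohort$subjects, `[[`, "", "group")
}

# wrap an arbitrary maps matrix as a subject decomposition (for oracles)
as_subject_decomp <- function(maps_list, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("sub-%02d", seq_along(maps_list))
  structure(list(
    subjects = Map(function(m, id) list(id = id, maps = m,
                                        timecourses = NULL),
                   maps_list, ids),
    order = nrow(maps_list[[1]]), subject_ids = ids),
    class = "subject_decomp")
}

# wrap a maps matrix as a group decomposition without z-scoring (so exact
# closed-form loading values can be asserted)
as_group_decomp <- function(maps, labels = rep("neural", nrow(maps))) {
  structure(list(order = nrow(maps), group_maps = maps,
                 group_timecourses = NULL,
                 stability_index = rep(1, nrow(maps)),
                 component_labels = labels,
                 reduction = list(), mask = NULL, mask_idx = NULL,
                 grid_dims = NULL, n_runs = 0L, seed = NA_integer_),
            class = "group_decomp")
}
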
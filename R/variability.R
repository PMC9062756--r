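# Spatial-variability loadings ------------------------------------------------

#' Compute the subjects x components spatial-variability loading matrix
#'
#' For every subject i and retained (neural) component j,
#' `C[i, j] = sum over in-mask voxels of (subject z-map - group z-map)^2`:
#' the squared Euclidean (L2) distance between the subject's z-scored
#' spatial map and the group map.  Larger values mean the subject's
#' component is more spatially deviant from the group average.  Components
#' labelled artefact in the decomposition are excluded.
#'
#' @param subject_decomp a `subject_decomp` from [back_reconstruct()].
#' @param group_decomp the matching `group_decomp`.
#' @return object of class `variability_loadings`: list with `values`
#'   (subjects x retained components), `subject_ids`, `component_ids`.
#' @export
compute_loadings <- function(subject_decomp, group_decomp) {
  stopifnot(inherits(subject_decomp, "subject_decomp"),
            inherits(group_decomp, "group_decomp"))
  if (subject_decomp$order != group_decomp$order)
    stop_invalid("subject and group decompositions have different orders")
  keep <- which(group_decomp$component_labels == "neural")
  g <- group_decomp$group_maps
  raw <- vapply(subject_decomp$subjects, function(s) {
    if (!identical(dim(s$maps), dim(g)))
      stop_invalid("subject map shape does not match the group maps")
    if (!all(is.finite(s$maps)))
      stop_data("non-finite values in subject maps")
    rowSums((s$maps - g)^2)[keep]
  }, numeric(length(keep)))
  vals <- if (length(keep) == 1L) matrix(raw, ncol = 1L) else t(raw)
  dimnames(vals) <- list(subject_decomp$subject_ids, paste0("IC", keep))
  structure(list(values = vals, subject_ids = subject_decomp$subject_ids,
                 component_ids = keep),
            class = "variability_loadings")
}

#' L2 distance between two spatial maps (oracle-friendly direct form)
#'
#' @param a,b numeric vectors over the same voxel set.
#' @return sum((a - b)^2).
#' @export
l2_distance <- function(a, b) {
  if (length(a) != length(b)) stop_invalid("maps differ in length")
  if (!all(is.finite(a)) || !all(is.finite(b)))
    stop_data("non-finite map values")
  sum((a - b)^2)
}
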
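# File I/O and pipeline driver ------------------------------------------------
#
# NIfTI-1 round-tripping of cohorts and voxelwise outputs, TSV tables, JSON
# manifests, YAML configuration with strict key checking, and the
# end-to-end driver: GICA -> labels -> variability loadings -> bootstrap
# feature selection -> bootstrap pattern -> clinical statistics.  Every
# stochastic stage draws its seed from the master seed, so a config fully
# determines all numeric outputs.

embed_mask <- function(values, mask_idx, grid_dims) {
  a <- array(0, grid_dims)
  a[mask_idx] <- values
  a
}

#' Write a synthetic cohort to disk
#'
#' One 4D NIfTI per subject (`<id>_bold.nii`), the mask (`mask.nii`), the
#' clinical table (`clinical.tsv`) and the ground truth as a JSON sidecar.
#'
#' @param sim list from [generate_cohort()] (`cohort`, `clinical`,
#'   `ground_truth`).
#' @param dir output directory (created if missing).
#' @param voxel_size edge length stored in the NIfTI header, in mm.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir, voxel_size = 3.5) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- sim$cohort
  dims <- cohort$grid_dims
  for (s in cohort$subjects) {
    arr <- array(0, c(dims, nrow(s$series)))
    for (t in seq_len(nrow(s$series)))
      arr[, , , t] <- embed_mask(s$series[t, ], cohort$mask_idx, dims)
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- c(rep(voxel_size, 3), cohort$tr_seconds)
    RNifti::writeNifti(img, file.path(dir, paste0(s$id, "_bold.nii")))
  }
  mask_img <- RNifti::asNifti(array(as.integer(cohort$mask), dims))
  RNifti::pixdim(mask_img) <- rep(voxel_size, 3)
  RNifti::writeNifti(mask_img, file.path(dir, "mask.nii"))
  write.table(sim$clinical, file.path(dir, "clinical.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  gt <- sim$ground_truth
  jsonlite::write_json(
    list(affected_components = gt$affected_components,
         severity = gt$severity, deviation_weights = gt$deviation_weights,
         deviation_norms = deviation_norms(gt),
         noise_sd = gt$noise_sd, effect_size = gt$effect_size,
         seed = gt$seed, groups = gt$groups, subject_ids = gt$subject_ids),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load a cohort of 4D NIfTI series
#'
#' Reads every `*_bold.nii[.gz]` in `directory` (subjects ordered
#' lexicographically by filename), applies the mask, and drops the first
#' `drop_volumes` volumes of each run for signal equilibrium.  Group labels
#' are merged from `clinical` when given.
#'
#' @param directory directory containing at least 4 subject series.
#' @param mask_path path to the binary mask NIfTI.
#' @param drop_volumes leading volumes discarded per run (default 3).
#' @param clinical optional clinical data frame with `subject_id`, `group`.
#' @param tr_seconds repetition time recorded on the cohort.
#' @return a `cohort` object.
#' @export
load_cohort <- function(directory, mask_path, drop_volumes = 3L,
                        clinical = NULL, tr_seconds = 2.45) {
  files <- sort(list.files(directory, pattern = "_bold\\.nii(\\.gz)?$",
                           full.names = TRUE))
  if (length(files) < 4)
    stop_data("need at least 4 subject series in ", directory)
  mask_img <- tryCatch(RNifti::readNifti(mask_path),
                       error = function(e) stop_data("unreadable mask: ",
                                                     mask_path))
  mask <- array(as.logical(mask_img != 0), dim(mask_img))
  dims <- dim(mask)
  mask_idx <- which(mask)
  subjects <- lapply(files, function(f) {
    img <- tryCatch(RNifti::readNifti(f),
                    error = function(e) stop_data("unreadable file: ", f))
    d <- dim(img)
    if (length(d) != 4 || !identical(d[1:3], dims))
      stop_data("grid mismatch between ", f, " and the mask")
    if (d[4] <= drop_volumes)
      stop_data("too few volumes after dropping ", drop_volumes, " in ", f)
    keep_t <- (drop_volumes + 1L):d[4]
    flat <- matrix(img, prod(dims), d[4])
    id <- sub("_bold\\.nii(\\.gz)?$", "", basename(f))
    list(id = id, group = NA_character_,
         series = t(flat[mask_idx, keep_t, drop = FALSE]))
  })
  if (!is.null(clinical)) {
    m <- match(vapply(subjects, `[[`, "", "id"), clinical$subject_id)
    if (any(is.na(m)))
      stop_data("clinical table does not cover every subject")
    for (i in seq_along(subjects)) subjects[[i]]$group <- clinical$group[m[i]]
  }
  structure(list(subjects = subjects, mask = mask, mask_idx = mask_idx,
                 grid_dims = dims, tr_seconds = tr_seconds),
            class = "cohort")
}

write_map_nifti <- function(values, mask_idx, grid_dims, path) {
  if (is.matrix(values)) {
    arr <- array(0, c(grid_dims, nrow(values)))
    for (j in seq_len(nrow(values)))
      arr[, , , j] <- embed_mask(values[j, ], mask_idx, grid_dims)
  } else {
    arr <- embed_mask(values, mask_idx, grid_dims)
  }
  RNifti::writeNifti(RNifti::asNifti(arr), path)
  path
}

pipeline_defaults <- function() {
  list(cohort_dir = NULL, mask = NULL, clinical = NULL, labels = NULL,
       out_dir = NULL, order = "AUTO", n_runs = 20L, n_boot_select = 5000L,
       n_boot_pattern = 5000L, folds = 10L, alpha_ci = 0.01,
       fdr_method = "BH", seed = 1L, drop_volumes = 3L,
       smoothness_correction = 1, positive = "patient")
}

#' Validate and complete a pipeline configuration
#'
#' Unknown keys are errors (a silently ignored typo in `n_boot_select`
#' would invalidate a run); missing keys take documented defaults.
#'
#' @param config named list, or path to a YAML file.
#' @return completed configuration list.
#' @export
pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop_invalid("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  for (key in c("cohort_dir", "mask", "clinical", "out_dir"))
    if (is.null(cfg[[key]])) stop_invalid("config key '", key, "' is required")
  for (key in c("n_runs", "n_boot_select", "n_boot_pattern", "folds")) {
    if (!is.numeric(cfg[[key]]) || cfg[[key]] < 1)
      stop_invalid("config key '", key, "' must be a positive count")
    cfg[[key]] <- as.integer(cfg[[key]])
  }
  for (key in c("seed", "drop_volumes"))
    cfg[[key]] <- as.integer(cfg[[key]])
  if (cfg$alpha_ci <= 0 || cfg$alpha_ci >= 0.5)
    stop_invalid("alpha_ci must be in (0, 0.5)")
  if (!identical(cfg$order, "AUTO") &&
      (!is.numeric(cfg$order) || cfg$order < 2))
    stop_invalid("order must be 'AUTO' or an integer >= 2")
  cfg
}

#' Run the full pattern-derivation pipeline
#'
#' Executes, in order: cohort loading, (optional) MDL order estimation,
#' group ICA, component labelling, back-reconstruction, variability
#' loadings, bootstrapped lasso feature selection with inflection-point
#' cut, bootstrapped logistic-regression pattern, and clinical association
#' statistics.  All artifacts are written under `out_dir` together with a
#' JSON manifest of every parameter, derived seed and result summary;
#' re-running the same config reproduces all numeric outputs bit-identically.
#'
#' @param config named list or YAML path accepted by [pipeline_config()].
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  cfg <- pipeline_config(config)
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  marker <- file.path(out, "INCOMPLETE")
  file.create(marker)
  log_line <- function(...) message("[icapattern] ", ...)

  stage <- "load"
  res <- tryCatch({
    clinical <- read.table(cfg$clinical, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
    cohort <- load_cohort(cfg$cohort_dir, cfg$mask,
                          drop_volumes = cfg$drop_volumes,
                          clinical = clinical)
    labels_vec <- vapply(cohort$subjects, `[[`, "", "group")
    log_line("loaded ", length(cohort$subjects), " subjects, T=",
             nrow(cohort$subjects[[1]]$series), ", ",
             length(cohort$mask_idx), " in-mask voxels")

    stage <- "order"
    order <- if (identical(cfg$order, "AUTO"))
      estimate_order(cohort, cfg$smoothness_correction) else
        as.integer(cfg$order)
    log_line("model order: ", order)

    stage <- "gica"
    decomp <- fit_group_ica(cohort, order, n_runs = cfg$n_runs,
                            seed = child_seed(cfg$seed, 10L))
    if (!is.null(cfg$labels)) {
      lab <- read.table(cfg$labels, sep = "\t", header = TRUE,
                        stringsAsFactors = FALSE)
      decomp <- apply_component_labels(decomp, lab)
    }

    stage <- "back_reconstruction"
    subj <- back_reconstruct(decomp, cohort)

    stage <- "loadings"
    loadings <- compute_loadings(subj, decomp)

    stage <- "selection"
    profile <- bootstrap_lasso_frequencies(
      loadings$values, labels_vec, n_boot = cfg$n_boot_select,
      n_folds = cfg$folds, seed = child_seed(cfg$seed, 11L),
      positive = cfg$positive)
    sel_cols <- select_by_inflection(profile)
    sel_ids <- loadings$component_ids[sel_cols]
    log_line("selected components: ", paste0("IC", sel_ids, collapse = ", "))

    stage <- "pattern"
    pattern <- bootstrap_pattern(
      loadings$values[, sel_cols, drop = FALSE], labels_vec,
      decomp$group_maps[sel_ids, , drop = FALSE],
      n_boot = cfg$n_boot_pattern, seed = child_seed(cfg$seed, 12L),
      alpha = cfg$alpha_ci, positive = cfg$positive)

    stage <- "stats"
    scores_df <- data.frame(subject_id = loadings$subject_ids,
                            group = labels_vec,
                            pattern_score = unname(pattern$subject_scores),
                            oob_score = unname(pattern$oob_scores),
                            stringsAsFactors = FALSE)
    merged <- merge(scores_df, clinical, by = c("subject_id", "group"),
                    sort = TRUE)
    clin_vars <- setdiff(names(clinical),
                         c("subject_id", "group", "severity_score"))
    clin_vars <- clin_vars[vapply(merged[clin_vars], is.numeric, TRUE)]
    assoc <- association_table(merged, "pattern_score",
                               c("severity_score", clin_vars),
                               gate_alpha = 0.05, fdr_method = cfg$fdr_method)
    grp <- group_compare(merged$pattern_score, merged$group,
                         varname = "pattern_score")

    stage <- "write"
    write_map_nifti(decomp$group_maps, cohort$mask_idx, cohort$grid_dims,
                    file.path(out, "group_maps.nii"))
    write_map_nifti(pattern$pattern_map, cohort$mask_idx, cohort$grid_dims,
                    file.path(out, "pattern.nii"))
    write_map_nifti(as.numeric(pattern$stable_mask), cohort$mask_idx,
                    cohort$grid_dims, file.path(out, "pattern_stable_mask.nii"))
    write_map_nifti(rbind(pattern$ci_low, pattern$ci_high), cohort$mask_idx,
                    cohort$grid_dims, file.path(out, "pattern_ci.nii"))
    lt <- data.frame(subject_id = loadings$subject_ids, loadings$values,
                     check.names = FALSE)
    write.table(lt, file.path(out, "loadings.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(scores_df, file.path(out, "scores.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(data.frame(component = paste0("IC", loadings$component_ids),
                           frequency = profile$frequency),
                file.path(out, "selection_frequencies.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(rbind(assoc[, c("x", "y", "method", "estimate", "p_value",
                                "q_value", "n")]),
                file.path(out, "stats.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(data.frame(component = paste0("IC", seq_len(decomp$order)),
                           stability = decomp$stability_index,
                           label = decomp$component_labels),
                file.path(out, "stability.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)

    manifest <- list(
      package = "icapattern",
      config = cfg[order(names(cfg))],
      input_md5 = as.list(tools::md5sum(c(cfg$clinical, cfg$mask))),
      n_subjects = length(cohort$subjects),
      order = order,
      stability_index = decomp$stability_index,
      selected_components = paste0("IC", sel_ids),
      mean_coefficients = pattern$mean_coefficients,
      n_failed_logistic_fits = pattern$n_failed,
      group_test = list(test = grp$test, p_value = grp$p_value),
      artifacts = c("group_maps.nii", "pattern.nii",
                    "pattern_stable_mask.nii", "pattern_ci.nii",
                    "loadings.tsv", "scores.tsv",
                    "selection_frequencies.tsv", "stats.tsv",
                    "stability.tsv"))
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    manifest
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  file.remove(marker)
  invisible(res)
}

#' Read a pipeline manifest, refusing incomplete runs
#'
#' @param out_dir a pipeline output directory.
#' @param allow_incomplete read even when the run never finished.
#' @return the manifest list.
#' @export
read_manifest <- function(out_dir, allow_incomplete = FALSE) {
  if (!allow_incomplete && file.exists(file.path(out_dir, "INCOMPLETE")))
    stop_data("run in ", out_dir, " is marked incomplete")
  jsonlite::read_json(file.path(out_dir, "manifest.json"),
                      simplifyVector = TRUE)
}
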
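#' Run configuration
#'
#' A single JSON-serializable document holding every knob of an end-to-end
#' run. Unknown keys are rejected so silent typos cannot change a run.
#'
#' @param ... named fields among: `inputs` (character vector of 4D volume
#'   paths), `mask` (mask path), `out_dir`, `transform` (name), `param`,
#'   `k`, `k_min`, `k_max`, `k_step`, `ratio_exploration`, `seed`,
#'   `kmeans_restarts`, `eig_tol`, `repair_contiguity` (logical),
#'   `folds`, `c_reg`, `alpha`, `filter_scope`.
#' @return An object of class `run_config`.
#' @export
run_config <- function(...) {
  fields <- list(...)
  allowed <- c("inputs", "mask", "out_dir", "transform", "param", "k",
               "k_min", "k_max", "k_step", "ratio_exploration", "seed",
               "kmeans_restarts", "eig_tol", "repair_contiguity", "folds",
               "c_reg", "alpha", "filter_scope")
  unknown <- setdiff(names(fields), allowed)
  if (length(unknown) > 0)
    stop("unknown run_config key(s): ", paste(unknown, collapse = ", "))
  defaults <- list(transform = "origin", param = NULL, k = 10L,
                   k_min = 10L, k_max = 200L, k_step = 5L,
                   ratio_exploration = 0.7, seed = 1L, kmeans_restarts = 10L,
                   eig_tol = 1e-8, repair_contiguity = FALSE, folds = 5L,
                   c_reg = 1, alpha = 0.05, filter_scope = "within_fold")
  cfg <- utils::modifyList(defaults, fields)
  if (is.null(cfg$seed)) stop("run_config requires an explicit seed")
  structure(cfg, class = "run_config")
}

#' Read / write a run configuration as JSON
#' @param path JSON file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  do.call(run_config, jsonlite::read_json(path, simplifyVector = TRUE))
}

#' @rdname read_run_config
#' @param cfg a [run_config()].
#' @export
write_run_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Write a run manifest
#'
#' Records what a run produced and from what: parameters, seeds, package
#' version, input paths, output artifacts and completion status, so every
#' artifact on disk is traceable.
#'
#' @param out_dir run output directory.
#' @param command subcommand name.
#' @param params named list of parameters (seed included).
#' @param artifacts character vector of files written.
#' @param complete logical completion flag.
#' @return manifest path, invisibly.
#' @export
write_manifest <- function(out_dir, command, params, artifacts,
                           complete = TRUE) {
  manifest <- list(command = command, params = params,
                   artifacts = as.character(artifacts),
                   package_version = as.character(utils::packageVersion("specparc")),
                   r_version = R.version.string,
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   complete = complete)
  path <- file.path(out_dir, paste0(command, "_manifest.json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' End-to-end group parcellation run
#'
#' Orchestrates the full pipeline on in-memory volumes: per-subject
#' similarity construction (spatial constraint + transform), the two-level
#' ensemble at K, optional contiguity repair, and validation-set
#' reproducibility metrics.
#'
#' @param volumes list of 4D arrays (or [read_volume_nifti()] results).
#' @param mask a [voxel_mask()].
#' @param K number of clusters.
#' @param transform a [transform_spec()].
#' @param seed RNG seed.
#' @param split optional [split_cohort()] result over `seq_along(volumes)`;
#'   when given, the group partition is built on the exploration subjects
#'   and reproducibility is evaluated on the validation subjects.
#' @param repair apply [contiguity_repair()] to the group partition.
#' @return list with `group`, `subjects`, `consensus`, `reproducibility`
#'   (NULL without a split), `graph`.
#' @export
run_group_pipeline <- function(volumes, mask, K,
                               transform = transform_spec("origin"),
                               seed = 1, split = NULL, repair = FALSE) {
  graph <- build_neighbor_graph(mask)
  sims <- lapply(volumes, build_similarity, mask = mask, spec = transform,
                 graph = graph)
  expl <- if (is.null(split)) seq_along(sims) else split$exploration_ids
  res <- group_partition(sims[expl], K, seed = seed)
  if (repair)
    res$group <- contiguity_repair(res$group, graph, mode = "repair")$partition
  repro <- NULL
  if (!is.null(split) && length(split$validation_ids) > 0) {
    cfg <- spectral_config(K, seed = seed)
    val_parts <- lapply(sims[split$validation_ids], spectral_partition, cfg = cfg)
    repro <- reproducibility(res$group, val_parts)
  }
  c(res, list(reproducibility = repro, graph = graph))
}
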
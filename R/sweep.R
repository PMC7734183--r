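# Multi-scale driver: run the full pipeline (grid -> layers -> multiplex ->
# features -> filter -> cross-validation -> assessment) at each patch volume
# and tabulate performance against scale.

#' Pipeline configuration
#'
#' Gathers every tunable of the pipeline in one place, with the method's
#' standard defaults: patch volumes 1000..8000 in steps of 1000, correlation
#' threshold 0.3, minimum brain fraction 0.9 (at most 10% non-brain voxels
#' per patch), feature-correlation filter 0.95, 1000 rounds of 80/20
#' stratified cross-validation with 500-tree forests and third-quartile
#' importance selection, and the proportion-test assessment at alpha 0.05
#' with null selection rate 0.25 and 10% minimum region overlap.
#'
#' @param scales Integer vector of patch volumes V to sweep.
#' @param threshold Correlation threshold for network links.
#' @param brain_fraction_min Minimum patch brain fraction.
#' @param corr_filter Feature-correlation filter threshold.
#' @param rounds,train_fraction,n_trees,importance_quantile Passed to
#'   [cv_config()].
#' @param alpha,p0,region_min_fraction Assessment parameters.
#' @param seed Master seed for the whole sweep.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(scales = seq(1000, 8000, by = 1000),
                            threshold = 0.3, brain_fraction_min = 0.9,
                            corr_filter = 0.95, rounds = 1000,
                            train_fraction = 0.8, n_trees = 500,
                            importance_quantile = 0.75, alpha = 0.05,
                            p0 = 0.25, region_min_fraction = 0.10, seed = 1) {
  stopifnot(all(scales >= 1), threshold >= 0, threshold <= 1,
            brain_fraction_min > 0, brain_fraction_min <= 1,
            corr_filter > 0, corr_filter <= 1)
  structure(list(scales = as.integer(scales), threshold = threshold,
                 brain_fraction_min = brain_fraction_min,
                 corr_filter = corr_filter,
                 cv = cv_config(rounds = rounds,
                                train_fraction = train_fraction,
                                n_trees = n_trees,
                                importance_quantile = importance_quantile,
                                seed = seed),
                 alpha = alpha, p0 = p0,
                 region_min_fraction = region_min_fraction,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Unknown fields are rejected with a message naming the field.
#'
#' @param path YAML or JSON file whose keys are [pipeline_config()]
#'   arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    stop("unknown configuration field: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  do.call(pipeline_config, vals)
}

#' Run the full pipeline at one scale
#'
#' @param cohort A `brain_cohort` or `syn_cohort`.
#' @param V Patch volume in voxels.
#' @param config A `pipeline_config`.
#' @return List with the `grid`, `multiplex`, filtered `features`, `cv`
#'   (`cv_result`), and `assessment`; or `NULL` (with a warning) when the
#'   scale does not fit the volume or leaves fewer than 2 valid nodes.
#' @param label_volume Optional `label_volume` for region naming.
#' @export
run_scale <- function(cohort, V, config, label_volume = NULL) {
  if (inherits(cohort, "syn_cohort")) cohort <- as_brain_cohort(cohort)
  stopifnot(inherits(cohort, "brain_cohort"))
  shape <- choose_patch_shape(V)
  vol_shape <- dim(cohort$volumes[[1]])
  if (any(c(shape$dx, shape$dy, shape$dz) > vol_shape) ||
      vol_shape[1] < 2 * shape$dx) {
    warning("scale V=", V, " does not fit the volume; skipped", call. = FALSE)
    return(NULL)
  }
  grid <- tryCatch(
    apply_mask(build_grid(vol_shape, shape), cohort$mask,
               min_fraction = config$brain_fraction_min),
    error = function(e) NULL)
  if (is.null(grid) || grid$n_nodes < 2) {
    warning("scale V=", V, " yields fewer than 2 valid nodes; skipped",
            call. = FALSE)
    return(NULL)
  }
  layers <- purrr::map2(cohort$volumes, names(cohort$volumes),
                        function(v, id) build_layer(v, grid,
                                                    threshold = config$threshold,
                                                    subject_id = id))
  multiplex <- assemble_multiplex(unname(layers))
  features <- filter_features(build_feature_matrix(multiplex),
                              corr_threshold = config$corr_filter)
  cv <- run_cv(features, cohort$labels$group, config$cv)
  assessment <- assess_features(cv, grid, alpha = config$alpha, p0 = config$p0,
                                label_volume = label_volume,
                                features = features)
  list(V = V, grid = grid, multiplex = multiplex, features = features,
       cv = cv, assessment = assessment)
}

#' Sweep the pipeline across patch scales
#'
#' Runs [run_scale()] for every configured V and gathers a cross-scale
#' summary of classification performance (the scale sweep answers which
#' spatial scales carry the discriminative alterations).
#'
#' @param cohort A `brain_cohort` or `syn_cohort`.
#' @param config A [pipeline_config()].
#' @param label_volume Optional `label_volume`.
#' @return An object of class `scale_sweep`: `per_scale` (named list of
#'   [run_scale()] results, skipped scales omitted) and `summary` (tibble
#'   with one row per completed scale: V, n_nodes, n_features, metric means
#'   and SDs, Wilson bounds, number of significant features).
#' @export
run_scale_sweep <- function(cohort, config = pipeline_config(),
                            label_volume = NULL) {
  per_scale <- list()
  for (V in config$scales) {
    res <- run_scale(cohort, V, config, label_volume)
    if (!is.null(res)) per_scale[[as.character(V)]] <- res
  }
  summary <- purrr::map_dfr(per_scale, function(res) {
    sm <- res$cv$summary
    g <- function(m, col) sm[[col]][sm$metric == m]
    tibble::tibble(
      V = res$V, n_nodes = res$grid$n_nodes,
      n_features = ncol(res$features) - 1L,
      accuracy = g("accuracy", "mean"), accuracy_sd = g("accuracy", "sd"),
      specificity = g("specificity", "mean"),
      specificity_sd = g("specificity", "sd"),
      sensitivity = g("sensitivity", "mean"),
      sensitivity_sd = g("sensitivity", "sd"),
      auc = g("auc", "mean"), auc_sd = g("auc", "sd"),
      wilson_lo = res$cv$wilson["lo"], wilson_hi = res$cv$wilson["hi"],
      n_significant = sum(res$assessment$features$significant))
  })
  structure(list(per_scale = per_scale, summary = summary, config = config),
            class = "scale_sweep")
}

#' @export
print.scale_sweep <- function(x, ...) {
  cat("<scale_sweep> ", nrow(x$summary), " scale(s)\n", sep = "")
  print(x$summary[c("V", "n_nodes", "accuracy", "accuracy_sd", "auc",
                    "auc_sd", "n_significant")])
  invisible(x)
}
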
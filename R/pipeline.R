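# Orchestration of the nine-step analysis: sample selection, multiple
# imputation, three-way ANOVA, preprocessing, complexity selection, Tucker3
# fitting with Joint Orthomax, generalized Procrustes pooling, fit
# accounting, and interpretation. Every intermediate is persisted as CSV
# plus a JSON manifest, so a run is reproducible from its config alone.

#' Configuration for a full pipeline run
#'
#' @param input a [three_way_data()], or a path to a long-format CSV.
#' @param external optional person x variable table (or CSV path) of
#'   baseline external variables.
#' @param output_dir directory for run artifacts (created if needed);
#'   `NULL` to keep everything in memory only.
#' @param min_timepoints,timepoint_rule sample selection (see
#'   [select_sample()]).
#' @param m,ridge,imputation_seed multiple imputation settings (see
#'   [em_bootstrap_impute()]).
#' @param ranks fixed rank triple, or `"auto"` to select via
#'   [scree_grid()] + [select_complexity()].
#' @param max_ranks grid bound used when `ranks = "auto"`.
#' @param rotation `"standard"` for the default [rotation_weights()] preset
#'   (person-mode weight 0), `"none"` to skip rotation, or a
#'   `rotation_weights` object.
#' @param stability_splits,stability_threshold split-half repetitions and
#'   the congruence floor used in complexity selection.
#' @param alpha,correlation_method external-correlation settings (see
#'   [external_correlations()]).
#' @param symptom_salience,time_salience,correlation_salience thresholds for
#'   flagging salient entries in the rendered tables.
#' @param seed master seed; stage seeds are derived deterministically.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(input, external = NULL, output_dir = NULL,
                            min_timepoints = 5L, timepoint_rule = 0.5,
                            m = 20L, ridge = 0.005, imputation_seed = NULL,
                            ranks = "auto", max_ranks = c(4L, 3L, 3L),
                            rotation = "standard",
                            stability_splits = 10L,
                            stability_threshold = 0.85,
                            alpha = 0.05, correlation_method = "auto",
                            symptom_salience = 0.20, time_salience = 0.30,
                            correlation_salience = c(0.30, 0.40),
                            seed = 1L) {
  if (!identical(ranks, "auto")) ranks <- as.integer(ranks)
  m <- as.integer(m)
  min_timepoints <- as.integer(min_timepoints)
  stability_splits <- as.integer(stability_splits)
  max_ranks <- as.integer(max_ranks)
  structure(as.list(environment()), class = "pipeline_config")
}

derive_seed <- function(seed, offset) (seed * 7919L + offset * 104729L) %% 2147483629L

#' Run the full pipeline
#'
#' Executes selection, imputation, ANOVA, preprocessing, complexity
#' selection, per-imputation Tucker3 fits with Joint Orthomax, generalized
#' Procrustes pooling, fit accounting, split-half stability and (when an
#' external table is supplied) external correlations. Artifacts are written
#' under `config$output_dir` when set.
#'
#' @param config a [pipeline_config()].
#' @return a `pipeline_run` list with all stage outputs: `selection`,
#'   `imputations`, `anova`, `preprocessing` (per-imputation states),
#'   `scree`, `ranks`, `models`, `pooled`, `fit_accounts`, `fit_summary`,
#'   `stability`, `correlations`, `trajectories`, `core_ev`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  dataset <- if (inherits(config$input, "three_way_data")) config$input
             else read_long_table(config$input)
  external <- config$external
  if (is.character(external))
    external <- utils::read.csv(external, row.names = 1)

  # (1) sample selection
  sel <- select_sample(dataset, config$min_timepoints, config$timepoint_rule)
  dataset <- sel$dataset
  if (!is.null(external) && nrow(external) != dim(dataset)[1]) {
    keep <- rownames(external) %in% dataset$person_ids
    if (sum(keep) == dim(dataset)[1]) external <- external[dataset$person_ids, , drop = FALSE]
    else stop("external table does not align with the selected persons")
  }

  # (2) multiple imputation
  imp_seed <- if (is.null(config$imputation_seed))
    derive_seed(config$seed, 1L) else config$imputation_seed
  imps <- em_bootstrap_impute(dataset,
                              covariates = if (is.null(external)) NULL
                                           else as.matrix(external),
                              m = config$m, ridge = config$ridge,
                              seed = imp_seed)

  # (3) three-way ANOVA on each completed raw-scale cube
  anova_pooled <- pool_anova(lapply(imps$completed, three_way_anova))

  # (4) preprocessing, independently per imputed cube
  pre <- lapply(imps$completed, function(x) preprocess_cube(x$values))
  pre_data <- lapply(pre, `[[`, "data")
  states <- lapply(pre, `[[`, "state")

  # (5) complexity selection
  scree <- NULL
  if (identical(config$ranks, "auto")) {
    scree <- scree_grid(lapply(imps$completed, `[[`, "values"),
                        config$max_ranks)
    selection <- select_complexity(scree,
                                   stability_threshold = config$stability_threshold)
    ranks <- selection$ranks
  } else {
    ranks <- check_ranks(config$ranks, dim(dataset))
    selection <- NULL
  }

  # (6) Tucker3 fit + Joint Orthomax per imputation
  weights <- rotation_config_weights(config$rotation, dim(dataset), ranks)
  models <- lapply(pre_data, function(x) {
    fit <- tucker3_als(x, ranks)
    if (!is.null(weights)) joint_orthomax(fit, weights) else fit
  })

  # (7) generalized Procrustes pooling
  pooled <- if (length(models) >= 2L) generalized_procrustes(models)
            else NULL
  pooled_model <- if (is.null(pooled)) models[[1]] else pooled$mean_model

  # (8) fit accounting: pooled model evaluated in each imputed dataset
  fit_accounts <- lapply(seq_along(imps$completed), function(i)
    total_fit_with_trend(pooled_model, states[[i]], imps$completed[[i]]$values))
  het <- vapply(fit_accounts, `[[`, 0, "heterogeneity_fit_pct")
  tot <- vapply(fit_accounts, `[[`, 0, "total_fit_pct")
  fit_summary <- data.frame(
    quantity = c("heterogeneity_fit_pct", "total_fit_pct"),
    mean = c(mean(het), mean(tot)),
    sd = c(if (length(het) > 1) stats::sd(het) else 0,
           if (length(tot) > 1) stats::sd(tot) else 0))

  # split-half stability of the chosen complexity (first imputed dataset)
  stability <- split_half_stability(imps$completed[[1]]$values, ranks,
                                    n_splits = config$stability_splits,
                                    weights = weights,
                                    seed = derive_seed(config$seed, 2L))

  # (9) interpretation
  d <- dim(dataset)
  core_ev <- core_explained_variance(if (is.null(pooled)) pooled_model else pooled,
                                     ss_preprocessed = prod(d))
  trajectories <- component_trajectories(pooled_model, states[[1]],
                                         time_labels = dataset$time_labels)
  correlations <- NULL
  if (!is.null(external)) {
    score_sets <- if (is.null(pooled)) list(models[[1]]$A)
                  else lapply(pooled$rotated, `[[`, "A")
    correlations <- external_correlations(score_sets, external,
                                          method = config$correlation_method,
                                          alpha = config$alpha)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("threemode")),
    seed = config$seed, imputation_seed = imp_seed,
    m = imps$m, ridge = imps$ridge, ranks = unname(ranks),
    dims = dim(dataset),
    n_before = sel$report$n_before, n_after = sel$report$n_after,
    em_iterations = imps$em_iterations_used,
    runtime_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  run <- structure(list(
    config = config, selection = sel$report, dataset = dataset,
    imputations = imps, anova = anova_pooled, preprocessing = states,
    scree = scree, complexity = selection, ranks = ranks, models = models,
    pooled = pooled, pooled_model = pooled_model,
    fit_accounts = fit_accounts, fit_summary = fit_summary,
    stability = stability, correlations = correlations,
    trajectories = trajectories, core_ev = core_ev, manifest = manifest),
    class = "pipeline_run")

  if (!is.null(config$output_dir)) persist_run(run, config$output_dir)
  run
}

#' @noRd
rotation_config_weights <- function(rotation, dims, ranks) {
  if (inherits(rotation, "rotation_weights")) return(rotation)
  if (identical(rotation, "none")) return(NULL)
  if (identical(rotation, "standard")) return(rotation_weights(dims, ranks))
  stop("rotation must be 'standard', 'none' or a rotation_weights object")
}

#' @noRd
persist_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, name) utils::write.csv(x, file.path(dir, name), row.names = FALSE)
  w(data.frame(person_id = names(run$selection$per_person_observed_timepoints),
               observed_timepoints = run$selection$per_person_observed_timepoints),
    "selection_report.csv")
  w(as.data.frame(run$anova), "anova_table.csv")
  if (!is.null(run$scree))
    w(run$scree$entries[, c("P", "Q", "R", "S", "mean_fit", "sd_fit", "hull")],
      "scree_table.csv")
  st <- run$preprocessing[[1]]
  utils::write.csv(st$trend, file.path(dir, "trend.csv"))
  w(data.frame(item = seq_along(st$scales), scale = st$scales), "scales.csv")
  m <- run$pooled_model
  utils::write.csv(m$A, file.path(dir, "person_components.csv"))
  utils::write.csv(m$B, file.path(dir, "symptom_components.csv"))
  utils::write.csv(m$C, file.path(dir, "time_components.csv"))
  utils::write.csv(unfold(m$G, 1L), file.path(dir, "core_mode1.csv"))
  w(run$fit_summary, "fit_summary.csv")
  w(run$core_ev, "core_explained_variance.csv")
  w(run$stability$per_split_congruence, "stability_report.csv")
  w(run$trajectories$curves, "trajectories.csv")
  if (!is.null(run$correlations))
    w(as.data.frame(run$correlations), "correlation_table.csv")
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("three-mode PCA pipeline run\n")
  print(x$selection)
  cat(sprintf("  m = %d imputations; ranks (%s)\n", x$imputations$m,
              paste(x$ranks, collapse = ",")))
  cat(sprintf("  heterogeneity fit %.1f%%, total fit (with trend) %.1f%%\n",
              x$fit_summary$mean[1], x$fit_summary$mean[2]))
  cat(sprintf("  split-half min congruence %.3f\n",
              x$stability$min_congruence))
  invisible(x)
}

#' Render publication-style tables from a pipeline run
#'
#' Pure function of a completed run: re-rendering yields identical tables.
#' Salience flags use the thresholds from the run's config.
#'
#' @param run a `pipeline_run`.
#' @return list of data frames: `anova` (effect, SS, sd, pct, sd),
#'   `symptom_components` (sorted by leading component, salience-flagged),
#'   `time_components`, `core` (core elements with %EV), `correlations`
#'   (flagged; `NULL` without external data).
#' @export
render_tables <- function(run) {
  stopifnot(inherits(run, "pipeline_run"))
  cfg <- run$config
  m <- run$pooled_model
  esd <- if (!is.null(run$pooled)) run$pooled$element_sd else NULL

  symptom <- data.frame(item = run$dataset$item_labels, m$B,
                        check.names = FALSE)
  names(symptom)[-1] <- paste0("component", seq_len(ncol(m$B)))
  if (!is.null(esd))
    symptom[paste0("sd", seq_len(ncol(m$B)))] <- esd$B
  lead <- apply(abs(m$B), 1L, which.max)
  symptom$leading <- lead
  symptom$salient <- abs(m$B[cbind(seq_len(nrow(m$B)), lead)]) >= cfg$symptom_salience
  ord <- order(lead, -abs(m$B[cbind(seq_len(nrow(m$B)), lead)]))
  symptom <- symptom[ord, ]

  timec <- data.frame(time = run$dataset$time_labels, m$C, check.names = FALSE)
  names(timec)[-1] <- paste0("component", seq_len(ncol(m$C)))
  if (!is.null(esd)) timec[paste0("sd", seq_len(ncol(m$C)))] <- esd$C
  timec$salient <- apply(abs(m$C) >= cfg$time_salience, 1L, any)

  core <- run$core_ev

  correlations <- NULL
  if (!is.null(run$correlations)) {
    correlations <- as.data.frame(run$correlations)
    correlations$salient <- abs(correlations$r) >= cfg$correlation_salience[1]
    correlations$strong <- abs(correlations$r) >= cfg$correlation_salience[2]
  }

  list(anova = as.data.frame(run$anova),
       symptom_components = symptom,
       time_components = timec,
       core = core,
       correlations = correlations)
}
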
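# End-to-end orchestration: configuration, staged execution, report bundle
# with a content-hash manifest.  The numbered scripts under analysis/ are
# thin drivers over this and the module functions.

#' Build a pipeline configuration
#'
#' @param scenario Name of a built-in scenario (see [builtin_scenarios()]);
#'   ignored when `input` is given.
#' @param input Optional CSV of observation records to analyze instead of
#'   synthetic data.
#' @param adjustment_set Covariates for the adjusted estimators.
#' @param methods Estimators to run.
#' @param outcome_engine,propensity_engine `"logistic"` or `"superlearner"`.
#' @param tree_controls List: max_depth, min_leaf, complexity.
#' @param sensitivity Re-run estimates with process-of-care indicators.
#' @param with_missingness Impose and then complete-case-filter MAR outcome
#'   missingness on synthetic data.
#' @param n_patients_per_clinic Synthetic cohort size per clinic.
#' @param boot Bootstrap replicates for g-computation CIs.
#' @param seed Master seed.
#' @param out_dir Output directory for the report bundle.
#' @return Validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(scenario = "original-like", input = NULL,
                            adjustment_set = default_adjustment_set(),
                            methods = c("unadjusted", "gcomp", "tmle"),
                            outcome_engine = "logistic",
                            propensity_engine = "logistic",
                            tree_controls = list(max_depth = 5,
                                                 min_leaf = 20,
                                                 complexity = 0.01),
                            sensitivity = FALSE,
                            with_missingness = TRUE,
                            n_patients_per_clinic = 500,
                            boot = 200, seed = 1, out_dir = "results") {
  if (is.null(input) &&
      !scenario %in% names(builtin_scenarios())) {
    stop("unknown scenario: ", scenario, call. = FALSE)
  }
  if (!is.null(input) && !file.exists(input)) {
    stop("input file not found: ", input, call. = FALSE)
  }
  structure(list(scenario = scenario, input = input,
                 adjustment_set = adjustment_set, methods = methods,
                 outcome_engine = outcome_engine,
                 propensity_engine = propensity_engine,
                 tree_controls = tree_controls, sensitivity = sensitivity,
                 with_missingness = with_missingness,
                 n_patients_per_clinic = n_patients_per_clinic,
                 boot = boot, seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path Config file; keys as in [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  vals <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(pipeline_config, vals)
}

write_stage_csv <- function(x, out_dir, name, manifest) {
  path <- file.path(out_dir, name)
  utils::write.csv(x, path, row.names = FALSE)
  manifest[[name]] <- unname(tools::md5sum(path))
  manifest
}

#' Run the full analysis pipeline
#'
#' Stages: data acquisition (synthetic scenario or CSV) -> missingness and
#' complete-case analysis set -> descriptive cross-tabs -> clinic-stratified
#' and pooled estimates -> blip estimation and subgroup tree ->
#' control-clinic impact prediction -> PCA and propensity diagnostics ->
#' optional sensitivity analysis.  Every artifact is a CSV/text/JSON file in
#' `out_dir`; a manifest lists each file with its MD5 hash, and the
#' effective configuration is serialized alongside.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the main in-memory results and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (config$sensitivity && is.null(config$input)) {
    # synthetic data always carry the indicators; a CSV might not
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  log <- function(...) message("[pipeline] ", sprintf(...))

  # --- data ---------------------------------------------------------------
  if (is.null(config$input)) {
    cfg <- builtin_scenarios(
      n_patients_per_clinic = config$n_patients_per_clinic,
      seed = config$seed)[[config$scenario]]
    study <- generate_study(cfg)
    records <- study$records
    if (config$with_missingness) records <- impose_missingness(records, cfg)
    log("generated scenario '%s': %d records", config$scenario,
        nrow(records))
  } else {
    records <- load_observations(config$input)
    study <- NULL
    log("loaded %d records from %s", nrow(records), config$input)
  }
  if (config$sensitivity &&
      !all(process_indicator_columns() %in% names(records))) {
    stop("sensitivity analysis requested but process indicators absent",
         call. = FALSE)
  }

  analysis <- build_analysis_set(records, config$adjustment_set)
  log("analysis set: %d rows (dropped: %s)", nrow(analysis),
      paste(names(attr(analysis, "drop_log")), attr(analysis, "drop_log"),
            sep = "=", collapse = ", "))
  manifest <- write_stage_csv(analysis, config$out_dir, "analysis_set.csv",
                              manifest)

  # --- descriptives -------------------------------------------------------
  ct <- do.call(rbind, lapply(
    c("previous_control", "n_complications", "risk_factors", "sex"),
    function(cv) cbind(covariate = cv, crosstab_outcome(records, cv))))
  manifest <- write_stage_csv(ct, config$out_dir, "crosstabs.csv", manifest)

  # --- estimates ----------------------------------------------------------
  estimates <- estimate_by_clinic_and_pooled(
    analysis, methods = config$methods,
    adjustment_set = config$adjustment_set, boot = config$boot,
    outcome_engine = config$outcome_engine,
    propensity_engine = config$propensity_engine, seed = config$seed)
  manifest <- write_stage_csv(estimates, config$out_dir, "estimates.csv",
                              manifest)
  log("estimates: %d rows", nrow(estimates))

  # --- heterogeneity ------------------------------------------------------
  treated <- analysis[analysis$exposed %in% c(0, 1) &
                        (if ("diabetimss_clinic" %in% names(analysis))
                          analysis$diabetimss_clinic else TRUE), ,
                      drop = FALSE]
  blips <- estimate_blips(treated, config$adjustment_set,
                          engine = config$outcome_engine,
                          seed = config$seed)
  tree <- fit_blip_tree(blips,
                        max_depth = config$tree_controls$max_depth,
                        min_leaf = config$tree_controls$min_leaf,
                        complexity = config$tree_controls$complexity)
  export_blip_tree_text(tree, file.path(config$out_dir, "blip_tree.txt"))
  manifest[["blip_tree.txt"]] <-
    unname(tools::md5sum(file.path(config$out_dir, "blip_tree.txt")))
  export_blip_tree_json(tree, file.path(config$out_dir, "blip_tree.json"))
  manifest[["blip_tree.json"]] <-
    unname(tools::md5sum(file.path(config$out_dir, "blip_tree.json")))
  log("blip tree: %d leaves", nrow(tree$leaves))

  control_rows <- if ("diabetimss_clinic" %in% names(records)) {
    ok <- stats::complete.cases(records[config$adjustment_set])
    records[!records$diabetimss_clinic & ok, , drop = FALSE]
  } else records[0, , drop = FALSE]
  impact <- predict_control_clinic_impact(tree, control_rows)
  manifest <- write_stage_csv(impact$by_clinic, config$out_dir,
                              "control_clinic_impact.csv", manifest)

  # --- diagnostics --------------------------------------------------------
  pca_cov <- setdiff(config$adjustment_set, character())
  pca <- pca_covariates(analysis, pca_cov, grouping = "clinic")
  manifest <- write_stage_csv(pca_group_centroids(pca), config$out_dir,
                              "pca_clinic_centroids.csv", manifest)
  ok <- stats::complete.cases(records[config$adjustment_set])
  pca_miss <- pca_covariates(records[ok, , drop = FALSE], pca_cov,
                             grouping = "outcome-missingness")
  manifest <- write_stage_csv(pca_group_centroids(pca_miss), config$out_dir,
                              "pca_missingness_centroids.csv", manifest)

  sens <- NULL
  prop_report <- NULL
  if (config$sensitivity) {
    pooled <- pooled_treated_data(treated, config$adjustment_set)
    g_base <- fit_propensity(pooled$data, pooled$adjustment_set,
                             engine = config$propensity_engine,
                             seed = config$seed)
    g_ext <- fit_propensity(pooled$data,
                            c(pooled$adjustment_set,
                              process_indicator_columns()),
                            engine = config$propensity_engine,
                            seed = config$seed)
    prop_report <- propensity_distribution_report(g_base, g_ext)
    manifest <- write_stage_csv(
      data.frame(set = c("base", "extended"),
                 frac_near_zero = c(prop_report$base$frac_near_zero,
                                    prop_report$extended$frac_near_zero),
                 frac_near_one = c(prop_report$base$frac_near_one,
                                   prop_report$extended$frac_near_one)),
      config$out_dir, "propensity_summary.csv", manifest)
    sens <- sensitivity_with_process_indicators(
      analysis, config$adjustment_set, methods = config$methods,
      boot = 0, outcome_engine = config$outcome_engine,
      propensity_engine = config$propensity_engine, seed = config$seed)
    manifest <- write_stage_csv(sens$deltas, config$out_dir,
                                "sensitivity_deltas.csv", manifest)
  }

  # --- manifest + config --------------------------------------------------
  cfg_path <- file.path(config$out_dir, "pipeline_config.json")
  jsonlite::write_json(unclass(config), cfg_path, auto_unbox = TRUE,
                       null = "null", digits = NA)
  manifest[["pipeline_config.json"]] <- unname(tools::md5sum(cfg_path))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  log("wrote %d artifacts to %s", length(manifest), config$out_dir)

  invisible(list(records = records, analysis = analysis,
                 estimates = estimates, tree = tree, impact = impact,
                 pca = pca, sensitivity = sens,
                 propensity_report = prop_report, manifest = manifest,
                 study = study))
}
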
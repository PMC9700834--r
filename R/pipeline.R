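#' Default pipeline configuration
#'
#' @param out_dir Output directory.
#' @param seed Master seed propagated to every stochastic stage.
#' @param simulate List of [sim_params()] overrides, or `NULL` to read real
#'   inputs from `records_csv` / `counts_csv` + `geojson`.
#' @param records_csv,counts_csv,geojson Input files for a non-synthetic run.
#' @param id_prop GeoJSON property holding the zone id.
#' @param per_period_quartiles Compute quartile covariates within each period.
#' @param per_period_standardization Standardize expected counts per period.
#' @param sampler List of [sampler_config()] overrides.
#' @param model List of [car_model_spec()] prior/flag overrides.
#' @return A `pipeline_config` list, writable as YAML.
#' @export
pipeline_config <- function(out_dir = "stcarmap_run", seed = 1,
                            simulate = list(), records_csv = NULL,
                            counts_csv = NULL, geojson = NULL,
                            id_prop = "zone_id",
                            per_period_quartiles = TRUE,
                            per_period_standardization = FALSE,
                            sampler = list(), model = list()) {
  structure(list(out_dir = out_dir, seed = seed, simulate = simulate,
                 records_csv = records_csv, counts_csv = counts_csv,
                 geojson = geojson, id_prop = id_prop,
                 per_period_quartiles = per_period_quartiles,
                 per_period_standardization = per_period_standardization,
                 sampler = sampler, model = model),
            class = "pipeline_config")
}

#' Run the full disease-mapping pipeline
#'
#' Stages, in order: simulate (or load) inputs, build the queen adjacency,
#' tabulate counts and quartile covariates, compute expected counts and crude
#' RRs, fit the CAR model by MCMC, write convergence diagnostics and DIC, and
#' export the smoothed risk surface (CSV and GeoJSON). Every stage's artifact
#' lands in `config$out_dir` and is listed, with an MD5 content hash, in
#' `manifest.json`; re-running with an identical config reproduces identical
#' files.
#'
#' @param config A `pipeline_config`, or the path to a YAML file holding one.
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- do.call(pipeline_config, yaml::read_yaml(config))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  step <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  synthetic <- is.null(config$records_csv) && is.null(config$counts_csv)
  if (synthetic && is.null(config$simulate)) {
    stop("pipeline config is missing its inputs: provide 'records_csv' or ",
         "'counts_csv' (or a 'simulate' block)")
  }
  if (synthetic) {
    sim <- step("simulate", {
      sp <- do.call(sim_params, utils::modifyList(list(seed = config$seed),
                                                  config$simulate))
      simulate_dataset(sp)
    })
    zones <- sim$zones
    records <- sim$records
    utils::write.csv(records, file.path(config$out_dir, "records.csv"), row.names = FALSE)
    write_geojson(zones, file.path(config$out_dir, "zones.geojson"))
    jsonlite::write_json(sim$truth[c("alpha", "beta1", "beta", "sigma_u",
                                     "sigma_v", "base_rate", "seed")],
                         file.path(config$out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  } else {
    if (is.null(config$geojson)) stop("pipeline needs 'geojson' when reading real inputs")
    zones <- step("read_geometry", read_geojson(config$geojson, config$id_prop))
    records <- if (!is.null(config$records_csv)) {
      step("read_records", utils::read.csv(config$records_csv, stringsAsFactors = FALSE))
    } else NULL
  }

  A <- step("adjacency", queen_adjacency(zones))
  write_adjacency(A, file.path(config$out_dir, "adjacency"))

  if (!is.null(records)) {
    periods <- sort(unique(records$survey_year))
    C <- step("tabulate", tabulate_counts(records, A$zone_ids, periods))
    X <- step("covariates",
              quartile_covariates(records, A$zone_ids, periods,
                                  per_period = config$per_period_quartiles))
  } else if (!is.null(config$counts_csv)) {
    df <- utils::read.csv(config$counts_csv, stringsAsFactors = FALSE)
    C <- step("counts", count_table(df, zone_ids = A$zone_ids))
    X <- NULL
  } else {
    stop("pipeline has neither records nor counts input")
  }
  if (synthetic) X <- sim$covariates  # quartiles from the true zone proportions
  utils::write.csv(as.data.frame(C), file.path(config$out_dir, "counts.csv"),
                   row.names = FALSE)
  if (!is.null(X)) {
    utils::write.csv(as.data.frame(X), file.path(config$out_dir, "covariates.csv"),
                     row.names = FALSE)
  }

  E <- step("expected", expected_counts(C, per_period = config$per_period_standardization))
  exp_df <- as.data.frame(C)
  exp_df$E <- as.vector(E$E)
  exp_df$crude_rr <- as.vector(crude_rr(C, E))
  utils::write.csv(exp_df, file.path(config$out_dir, "expected.csv"), row.names = FALSE)

  spec <- step("model_spec", do.call(car_model_spec, utils::modifyList(
    list(adjacency = A, n_periods = length(C$periods),
         include_covariates = !is.null(X)),
    config$model)))
  cfg <- do.call(sampler_config, utils::modifyList(list(seed = config$seed),
                                                   config$sampler))
  samples <- step("fit", run_mcmc(spec, C, E, X, cfg))
  write_samples(samples, file.path(config$out_dir, "samples"))

  diag_rep <- step("diagnose", diagnostics_report(samples))
  model_dic <- dic(samples, C)
  od <- overdispersion_check(C)
  jsonlite::write_json(list(dic = model_dic, overdispersion = od),
                       file.path(config$out_dir, "diagnostics.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(diag_rep, file.path(config$out_dir, "convergence.csv"),
                   row.names = FALSE)

  surface <- step("surfaces", risk_surface(samples, C))
  utils::write.csv(surface, file.path(config$out_dir, "risk_surface.csv"),
                   row.names = FALSE)
  export_surface_geojson(surface, zones,
                         file.path(config$out_dir, "risk_surface.geojson"))
  fx <- fixed_effect_table(samples)
  utils::write.csv(fx, file.path(config$out_dir, "fixed_effects.csv"),
                   row.names = FALSE)

  files <- list.files(config$out_dir, recursive = TRUE, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  manifest <- list(
    seed = config$seed,
    synthetic = synthetic,
    files = lapply(stats::setNames(files, sub(paste0("^", config$out_dir, "/?"), "", files)),
                   function(f) unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(adjacency = A, counts = C, covariates = X, expected = E,
                 samples = samples, diagnostics = diag_rep, dic = model_dic,
                 surface = surface, fixed_effects = fx, manifest = manifest))
}
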
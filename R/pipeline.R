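#' Assemble an end-to-end run configuration
#'
#' Scale presets resolve to concrete model counts, sampling densities and
#' training lengths: `"ci"` is a smoke-test scale (a handful of models,
#' a few hundred points), `"desk"` is the scaled-down study configuration
#' (50 models per variant at roughly 2,000 query points each), and
#' `"full_scale"` mirrors the full design (500 models, about 5e4-point
#' model clouds and 2.6e5-point query clouds) and is intended for long
#' offline runs only.
#'
#' @param preset `"ci"`, `"desk"` or `"full_scale"`.
#' @param seed master run seed; all stage seeds derive from it.
#' @param out_dir output directory (NULL = nothing written).
#' @param ... named overrides of any resolved field.
#' @return a `run_config` list.
#' @export
run_config <- function(preset = c("ci", "desk", "full_scale"),
                       seed = 1, out_dir = NULL, ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
    ci = list(n_type1 = 2, n_type2 = 6,
              surface_density = 0.015, interior_density = 0.008,
              split_ratio = 0.75,
              max_epochs = 12, patience = 6,
              query_batch = NULL, model_cap = 150),
    desk = list(n_type1 = 10, n_type2 = 40,
                surface_density = 0.08, interior_density = 0.13,
                split_ratio = 0.9,
                max_epochs = 170, patience = 25,
                query_batch = 384, model_cap = 192),
    full_scale = list(n_type1 = 100, n_type2 = 400,
                           surface_density = 7.4, interior_density = 18,
                           split_ratio = 0.9,
                           max_epochs = 300, patience = 25,
                           query_batch = 4096, model_cap = 2048)
  )
  cfg <- utils::modifyList(
    c(base, list(preset = preset, seed = seed, out_dir = out_dir,
                 noise_fraction = 0.02, sac_side = 1,
                 ranges = default_param_ranges(),
                 inlet_mass_flow = 0.004375,
                 stent_K_mm2 = 0.001489, stent_C_per_m = 7665,
                 stent_thickness_um = 150)),
    list(...))
  structure(cfg, class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Top-level keys `preset`, `seed`, `out_dir` plus any [run_config()]
#' override (nested keys `stent.K_mm2`, `stent.C_per_m`,
#' `stent.thickness_um`, `flow.inlet_mass_flow_kg_s`, `flow.noise_fraction`
#' and `geometry.*` are mapped onto the flat fields).
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  flat <- y[setdiff(names(y), c("stent", "flow", "geometry", "preset", "seed",
                                "out_dir"))]
  if (!is.null(y$stent)) {
    if (!is.null(y$stent$K_mm2)) flat$stent_K_mm2 <- y$stent$K_mm2
    if (!is.null(y$stent$C_per_m)) flat$stent_C_per_m <- y$stent$C_per_m
    if (!is.null(y$stent$thickness_um)) flat$stent_thickness_um <- y$stent$thickness_um
  }
  if (!is.null(y$flow)) {
    if (!is.null(y$flow$inlet_mass_flow_kg_s)) flat$inlet_mass_flow <- y$flow$inlet_mass_flow_kg_s
    if (!is.null(y$flow$noise_fraction)) flat$noise_fraction <- y$flow$noise_fraction
  }
  if (!is.null(y$geometry)) {
    if (!is.null(y$geometry$surface_density)) flat$surface_density <- y$geometry$surface_density
    if (!is.null(y$geometry$interior_density)) flat$interior_density <- y$geometry$interior_density
    if (!is.null(y$geometry$sac_side)) flat$sac_side <- y$geometry$sac_side
    if (!is.null(y$geometry$ranges)) flat$ranges <- lapply(y$geometry$ranges, unlist)
  }
  do.call(run_config, c(list(preset = y$preset %||% "ci",
                             seed = y$seed %||% 1,
                             out_dir = y$out_dir), flat))
}

variant_names <- function() {
  c("preop_velocity", "preop_pressure", "postop_velocity", "postop_pressure")
}

#' Run the full pipeline
#'
#' Generate -> simulate -> extract -> split -> train -> evaluate for all
#' four data-set variants, writing reports, checkpoints and a manifest
#' (with every derived seed, parameter draw and output checksum) into
#' `config$out_dir` when set.
#'
#' @param config a [run_config()].
#' @param verbose print per-stage progress and timing.
#' @return list with `reports` (four `error_report`s), `models` (four
#'   `trained_model`s), `datasets` (train/test split per variant) and
#'   `manifest`.
#' @export
run_pipeline <- function(config = run_config(), verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  t_all <- proc.time()[3]
  timings <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[3]
    out <- tryCatch(force(expr), error = function(e)
      stop("pipeline stage [", name, "] failed: ", conditionMessage(e),
           call. = FALSE))
    timings[[name]] <<- round(proc.time()[3] - t0, 2)
    if (verbose) message(sprintf("[%s] %.1fs", name, timings[[name]]))
    out
  }
  bc <- boundary_conditions(inlet_mass_flow = config$inlet_mass_flow)
  layer <- porous_layer(thickness = config$stent_thickness_um * 1e-6,
                        K = config$stent_K_mm2 * 1e-6,
                        C = config$stent_C_per_m)
  datasets <- stage("generate+simulate+extract", build_datasets(
    config$n_type1, config$n_type2, config$seed,
    surface_density = config$surface_density,
    interior_density = config$interior_density,
    noise_fraction = config$noise_fraction,
    bc = bc, layer = layer, sac_side = config$sac_side))
  split_seed <- derive_seed(config$seed, "split")
  splits <- stage("split", lapply(datasets, split_dataset,
                                  ratio = config$split_ratio,
                                  seed = split_seed))
  models <- list()
  reports <- list()
  for (v in variant_names()) {
    out_dim <- if (grepl("velocity", v)) 3L else 1L
    # pressure fields converge much faster than velocity; post-operative
    # networks are warm-started from the pre-operative ones of the same
    # quantity (the fields differ only through the stent attenuation)
    ep <- config$max_epochs
    if (out_dim == 1L) ep <- max(10L, round(ep * 0.45))
    warm <- NULL
    if (grepl("^postop", v)) {
      ep <- max(10L, round(ep * 0.55))
      warm <- models[[sub("postop", "preop", v)]]$net
    }
    ncfg <- network_config(output_dim = out_dim,
                           max_epochs = ep,
                           patience = config$patience,
                           query_batch = config$query_batch,
                           model_cap = config$model_cap)
    models[[v]] <- stage(paste0("train/", v),
                         train_network(splits[[v]]$train, ncfg,
                                       seed = derive_seed(config$seed,
                                                          paste0("train/", v)),
                                       init = warm))
    reports[[v]] <- stage(paste0("evaluate/", v),
                          evaluate_network(models[[v]], splits[[v]]$test))
  }
  manifest <- list(
    preset = config$preset, seed = config$seed,
    variants = variant_names(),
    n_models = config$n_type1 + config$n_type2,
    split = list(ratio = config$split_ratio, seed = split_seed,
                 n_train = length(splits[[1]]$train$pairs),
                 n_test = length(splits[[1]]$test$pairs)),
    params = lapply(datasets[[1]]$pairs, function(p) unclass(p$params)),
    stage_seconds = timings,
    total_seconds = round(proc.time()[3] - t_all, 2)
  )
  out <- list(reports = reports, models = models, datasets = splits,
              manifest = manifest, config = config)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- character(0)
    for (v in variant_names()) {
      rf <- file.path(config$out_dir, paste0("report_", v, ".json"))
      write_error_report(reports[[v]], rf)
      cf <- file.path(config$out_dir, paste0("model_", v, ".rds"))
      save_model(models[[v]], cf)
      files <- c(files, rf, cf)
    }
    manifest$checksums <- as.list(tools::md5sum(files))
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    out$manifest <- manifest
  }
  out
}
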
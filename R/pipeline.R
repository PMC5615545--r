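# End-to-end pipeline: simulate/ingest -> preprocess -> covariates ->
# variogram -> interpolate (13 surfaces per variable) -> validate -> map.
# Every stage reads its inputs from and writes its outputs to `out_dir`,
# which makes the pipeline resumable stage by stage.

PIPELINE_STAGES <- c("acquire", "preprocess", "covariates", "variogram",
                     "interpolate", "validate")

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg[order(names(cfg))], auto_unbox = TRUE,
                              digits = 12), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full mapping pipeline
#'
#' Executes the stages in order, writing all artefacts into `out_dir`:
#' transect CSV + scene GeoJSON (+ truth rasters when simulating), clean
#' points, covariate table, variogram fits (CSV + PNG), one ESRI ASCII
#' surface per method and variable, the cross-validation report (CSV), and a
#' JSON run manifest carrying the seed and the config hash.  Deterministic
#' stages are byte-identical across reruns with the same config and seed.
#'
#' @param config an `mk_config` (from [read_run_config()]) or a plain list
#'   accepted by the same schema.
#' @param out_dir output directory (created if needed).
#' @param stages subset of stages to run (default: all, in order).
#' @param quiet suppress stage messages.
#' @return (invisibly) the manifest list.
#' @export
run_pipeline <- function(config, out_dir, stages = PIPELINE_STAGES,
                         quiet = FALSE) {
  cfg <- if (inherits(config, "mk_config")) config else validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  hash <- config_hash(unclass(cfg))
  say <- function(...) if (!quiet) message("[", format(Sys.time(), "%H:%M:%S"),
                                           "] ", ...)
  t0 <- Sys.time()
  ran <- character(0)
  for (stage in PIPELINE_STAGES) {
    if (!stage %in% stages) next
    say("stage: ", stage)
    handler <- switch(stage,
      acquire = stage_acquire, preprocess = stage_preprocess,
      covariates = stage_covariates, variogram = stage_variogram,
      interpolate = stage_interpolate, validate = stage_validate)
    tryCatch(handler(cfg, out_dir),
             error = function(e) mk_stop("pipeline stage '", stage,
                                         "' failed: ", conditionMessage(e),
                                         " (partial outputs kept in ",
                                         out_dir, ")"))
    ran <- c(ran, stage)
  }
  manifest <- list(
    package = "microkrige",
    version = as.character(packageVersion("microkrige")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = cfg$seed, config_hash = hash, config = unclass(cfg),
    stages_run = ran,
    surfaces = list.files(out_dir, pattern = "^surface_.*\\.asc$"),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              digits = 12),
             file.path(out_dir, "manifest.json"))
  invisible(manifest)
}

stage_acquire <- function(cfg, out_dir) {
  if (isTRUE(cfg$simulate)) {
    sc <- synth_scenario(seed = cfg$seed, layout = cfg$layout)
    write_transect_csv(sc$records, file.path(out_dir, "transect.csv"))
    write_scene_geojson(sc$scene, file.path(out_dir, "scene.geojson"))
    tr <- sc$truth
    write_surface(list(grid = tr$grid, values = tr$pm25),
                  file.path(out_dir, "truth_pm25.asc"))
    write_surface(list(grid = tr$grid, values = tr$pm10),
                  file.path(out_dir, "truth_pm10.asc"))
    meta <- list(true_variogram = unclass(tr$true_variogram),
                 hotspots = tr$hotspots, mean_level = tr$mean_level,
                 covariate_betas = as.list(tr$covariate_betas),
                 pm10_ratio = tr$pm10_ratio, seed = cfg$seed)
    writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, pretty = TRUE,
                                digits = 12, null = "null"),
               file.path(out_dir, "truth_meta.json"))
  } else {
    file.copy(cfg$transect_csv, file.path(out_dir, "transect.csv"),
              overwrite = TRUE)
    file.copy(cfg$scene_geojson, file.path(out_dir, "scene.geojson"),
              overwrite = TRUE)
  }
  invisible(NULL)
}

stage_preprocess <- function(cfg, out_dir) {
  rec <- read_transect_csv(file.path(out_dir, "transect.csv"))
  if (cfg$thin > 1L) rec <- rec[seq(1, nrow(rec), by = cfg$thin), ]
  clean <- preprocess_transect(rec, merge_radius = cfg$merge_radius)
  write_clean_csv(clean, file.path(out_dir, "clean.csv"))
  invisible(NULL)
}

stage_covariates <- function(cfg, out_dir) {
  scene <- read_scene_geojson(file.path(out_dir, "scene.geojson"))
  clean <- read_clean_csv(file.path(out_dir, "clean.csv"))
  cv <- extract_covariates(scene, clean)
  data.table::fwrite(cbind(clean[, c("x", "y")], cv),
                     file.path(out_dir, "covariates.csv"))
  invisible(NULL)
}

stage_variogram <- function(cfg, out_dir) {
  clean <- read_clean_csv(file.path(out_dir, "clean.csv"))
  coords <- as.matrix(clean[, c("x", "y")])
  rows <- list()
  for (v in cfg$variables) {
    emp <- empirical_semivariogram(coords, clean[[v]])
    sel <- select_model(emp)
    m <- sel$model
    rows[[v]] <- data.frame(variable = v, kind = m$kind, nugget = m$nugget,
                            psill = m$psill, range = m$range,
                            shape = m$shape, major_range = major_range(m))
    png(file.path(out_dir, paste0("variogram_", v, ".png")), 640, 480)
    plot(emp$lag, emp$gamma, pch = 16, xlab = "lag (m)",
         ylab = expression(gamma(d)), main = paste("semivariogram,", v))
    dd <- seq(0, max(emp$lag), length.out = 200)
    lines(dd, model_gamma(m, dd), col = "red3", lwd = 2)
    dev.off()
    data.table::fwrite(cbind(emp, variable = v),
                       file.path(out_dir, paste0("empvario_", v, ".csv")),
                       append = FALSE)
  }
  data.table::fwrite(do.call(rbind, rows),
                     file.path(out_dir, "variogram_fits.csv"))
  invisible(NULL)
}

pipeline_inputs <- function(cfg, out_dir) {
  scene <- read_scene_geojson(file.path(out_dir, "scene.geojson"))
  clean <- read_clean_csv(file.path(out_dir, "clean.csv"))
  covp <- file.path(out_dir, "covariates.csv")
  covariates <- if (file.exists(covp))
    as.data.frame(data.table::fread(covp))[, c("svf50", "fai50", "rda50")]
  else extract_covariates(scene, clean)
  list(scene = scene, clean = clean, covariates = covariates)
}

stage_interpolate <- function(cfg, out_dir) {
  inp <- pipeline_inputs(cfg, out_dir)
  grid <- mk_grid_for_extent(inp$scene$extent, cfg$grid_cell)
  kernel <- kernel_spec("exponential", cfg$bandwidth)
  configs <- all_method_configs(kernel = kernel,
                                variogram_kind = cfg$variogram_kind)
  configs <- configs[cfg$methods]
  coords <- as.matrix(inp$clean[, c("x", "y")])
  for (v in cfg$variables) {
    emp <- empirical_semivariogram(coords, inp$clean[[v]])
    vg <- fit_variogram(emp, cfg$variogram_kind)
    for (cf in configs) {
      sf <- run_method(cf, inp$clean, inp$scene, grid, variable = v,
                       covariates = inp$covariates, variogram = vg)
      write_surface(sf, file.path(out_dir,
                                  sprintf("surface_%s_%s.asc", v, cf$name)))
    }
  }
  invisible(NULL)
}

stage_validate <- function(cfg, out_dir) {
  inp <- pipeline_inputs(cfg, out_dir)
  kernel <- kernel_spec("exponential", cfg$bandwidth)
  configs <- all_method_configs(kernel = kernel,
                                variogram_kind = cfg$variogram_kind)
  configs <- configs[cfg$methods]
  rep <- compare_methods(inp$clean, inp$scene, configs,
                         variables = cfg$variables, k = cfg$k,
                         seed = cfg$seed, kib_res = cfg$kib_res)
  data.table::fwrite(rep$full, file.path(out_dir, "cvreport.csv"))
  data.table::fwrite(rep$by_algorithm,
                     file.path(out_dir, "cvreport_by_algorithm.csv"))
  data.table::fwrite(rep$by_covariate,
                     file.path(out_dir, "cvreport_by_covariate.csv"))
  txt <- utils::capture.output(print(rep))
  writeLines(txt, file.path(out_dir, "cvreport.txt"))
  invisible(NULL)
}
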
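#' Configuration for a synthetic enhancement experiment
#'
#' Collects every knob of the simulate - train - enhance - reconstruct -
#' evaluate pipeline with the synthetic benchmark's defaults. A YAML file
#' with the same field names can be loaded with [read_run_config()].
#'
#' @param name experiment label.
#' @param size phantom edge in voxels.
#' @param n_spheres particle count.
#' @param d_min,d_max particle diameter range in voxels.
#' @param n_angles equispaced projection angles over `[0, 180]`.
#' @param noise_levels noise fractions to simulate.
#' @param train_angles projection angles (degrees) whose low/high-dose pairs
#'   train the network; must be on the angle grid.
#' @param epochs,batch_size,lr,patch_edge,train_stride network training
#'   hyperparameters.
#' @param infer_stride patch stride at inference (default `patch_edge / 2`).
#' @param val_frac held-out patch fraction.
#' @param filter reconstruction filter.
#' @param data_range intensity range for the quality metrics.
#' @param n_bins histogram bins for mode counting.
#' @param seed master seed; phantom, noise, initialisation and shuffling use
#'   derived independent streams.
#' @param out_dir output directory, or `NULL` to keep everything in memory.
#' @export
run_config <- function(name = "synthetic", size = 128, n_spheres = 16,
                       d_min = 4, d_max = 20, n_angles = 181,
                       noise_levels = 0.1, train_angles = c(0, 45),
                       epochs = 40, batch_size = 32, lr = 1e-3,
                       patch_edge = 64, train_stride = 16,
                       infer_stride = NULL, val_frac = 0.1,
                       filter = "parzen", data_range = 1, n_bins = 256,
                       seed = 1, out_dir = NULL) {
  cfg <- as.list(environment())
  cfg$infer_stride <- infer_stride %||% (patch_edge / 2)
  structure(cfg, class = "run_config")
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the [run_config()] arguments.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  do.call(run_config, vals)
}

#' Run the full synthetic enhancement experiment
#'
#' Executes, for each configured noise level: phantom generation and forward
#' projection (shared), noise injection, training on the configured angle
#' pairs, enhancement of the full stack, reconstruction of the clean, noisy
#' and enhanced stacks, and quality evaluation (slice-wise PSNR/SSIM against
#' the clean reconstruction plus histogram mode counts). With `out_dir` set,
#' stacks and volumes are written as float32 TIFF, reports as JSON, and a
#' manifest records the effective configuration, derived seeds and package
#' version so the run can be reproduced.
#'
#' @param config a [run_config()] (or a YAML path).
#' @param write_outputs write stacks/volumes/reports to `config$out_dir`.
#' @param verbose print stage progress.
#' @return a `tomo_experiment`: `summary` tibble (one row per noise level),
#'   per-level details (`reports`, `histograms`, `models`), the clean
#'   reconstruction, and the manifest.
#' @export
run_pipeline <- function(config = run_config(), write_outputs = !is.null(config$out_dir),
                         verbose = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (verbose) message("[", config$name, "] ", ...)
  angles <- seq(0, 180, length.out = config$n_angles)
  if (!all(config$train_angles %in% round(angles, 9))) {
    miss <- setdiff(config$train_angles, round(angles, 9))
    stop("training angles not on the angle grid: ",
         paste(miss, collapse = ", "))
  }
  say("generating phantom ", config$size, "^3")
  phantom <- generate_phantom(config$size, config$n_spheres, config$d_min,
                              config$d_max, seed = seed_for(config$seed, 1))
  say("projecting ", config$n_angles, " angles")
  p_o <- forward_project(phantom, angles)
  say("reconstructing clean volume")
  r_o <- reconstruct(p_o, config$filter)
  hist_o <- histogram_modes(r_o, config$n_bins)
  results <- list()
  for (lev in config$noise_levels) {
    key <- paste0("noise_", lev * 100)
    say("noise level ", lev * 100, "%")
    p_n <- add_noise(p_o, lev, seed = seed_for(config$seed, 2))
    model <- build_network(network_spec(config$patch_edge),
                           seed = seed_for(config$seed, 3))
    pairs <- training_pairs(p_n, p_o, config$train_angles)
    say("training (", config$epochs, " epochs)")
    model <- train_cnn(model, pairs, epochs = config$epochs,
                       batch_size = config$batch_size, lr = config$lr,
                       patch_stride = config$train_stride,
                       val_frac = config$val_frac,
                       seed = seed_for(config$seed, 4), verbose = verbose)
    say("enhancing ", length(angles), " projections")
    p_e <- enhance(model, p_n, patch_stride = config$infer_stride)
    r_n <- reconstruct(p_n, config$filter)
    r_e <- reconstruct(p_e, config$filter)
    results[[key]] <- list(
      level = lev,
      report_noisy = volume_report(r_n, r_o, config$data_range),
      report_enhanced = volume_report(r_e, r_o, config$data_range),
      hist_noisy = histogram_modes(r_n, config$n_bins),
      hist_enhanced = histogram_modes(r_e, config$n_bins),
      model = model,
      stacks = list(noisy = p_n, enhanced = p_e),
      volumes = list(noisy = r_n, enhanced = r_e))
  }
  summary <- dplyr::bind_rows(lapply(results, function(r) {
    tibble::tibble(
      noise_level = r$level,
      psnr_noisy = r$report_noisy$psnr_mean,
      psnr_enhanced = r$report_enhanced$psnr_mean,
      ssim_noisy = r$report_noisy$ssim_mean,
      ssim_enhanced = r$report_enhanced$ssim_mean,
      modes_noisy = r$hist_noisy$n_modes,
      modes_enhanced = r$hist_enhanced$n_modes,
      final_val_mse = r$model$log$val_mse[nrow(r$model$log)])
  }))
  manifest <- list(
    config = unclass(config),
    seeds = list(master = config$seed,
                 phantom = seed_for(config$seed, 1),
                 noise = seed_for(config$seed, 2),
                 init = seed_for(config$seed, 3),
                 train = seed_for(config$seed, 4)),
    package_version = as.character(utils::packageVersion("tomodenoise")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC"))
  exp <- structure(list(config = config, summary = summary,
                        results = results, clean_volume = r_o,
                        clean_projections = p_o, hist_clean = hist_o,
                        manifest = manifest),
                   class = "tomo_experiment")
  if (write_outputs) write_experiment(exp, config$out_dir, verbose = verbose)
  exp
}

write_experiment <- function(exp, out_dir, verbose = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  put_stack <- function(ps, name) {
    f <- file.path(out_dir, paste0(name, ".tif"))
    write_stack(ps, f)
    files[[name]] <<- f
  }
  put_vol <- function(vol, name) {
    f <- file.path(out_dir, paste0(name, ".tif"))
    write_float_tiff(vol$voxels, f)
    files[[name]] <<- f
  }
  put_stack(exp$clean_projections, "projections_clean")
  put_vol(exp$clean_volume, "volume_clean")
  for (key in names(exp$results)) {
    r <- exp$results[[key]]
    put_stack(r$stacks$noisy, paste0("projections_", key))
    put_stack(r$stacks$enhanced, paste0("projections_enhanced_", key))
    put_vol(r$volumes$noisy, paste0("volume_", key))
    put_vol(r$volumes$enhanced, paste0("volume_enhanced_", key))
    jsonlite::write_json(
      list(noisy = glance(r$report_noisy), enhanced = glance(r$report_enhanced)),
      file.path(out_dir, paste0("report_", key, ".json")),
      dataframe = "rows", auto_unbox = TRUE, digits = NA)
    utils::write.csv(r$model$log,
                     file.path(out_dir, paste0("training_log_", key, ".csv")),
                     row.names = FALSE)
  }
  manifest <- exp$manifest
  manifest$files <- as.list(files)
  manifest$summary <- exp$summary
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, dataframe = "rows", digits = NA,
                       null = "null", pretty = TRUE)
  if (verbose) message("outputs written to ", out_dir)
  invisible(out_dir)
}

#' @export
print.tomo_experiment <- function(x, ...) {
  cat("<tomo_experiment> '", x$config$name, "': ", x$config$size, "^3, ",
      x$config$n_angles, " angles\n", sep = "")
  print(x$summary)
  invisible(x)
}
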
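#' Pipeline configuration
#'
#' Describes a full run: input (a TIFF path with calibration, or a simulator
#' preset), optional registration, the filter branches to analyze, STICS
#' parameters, and the output directory. Exactly one of `input` /
#' `sim_preset` must be set.
#'
#' @param input Path to a single-channel multi-page TIFF, or `NULL`.
#' @param sim_preset A [default_sim_config()] preset name, or `NULL`.
#' @param pixel_size,frame_interval Calibration for TIFF input (ignored for
#'   simulations; the sidecar is used when present).
#' @param register Run [register_series()] before filtering. Off by default:
#'   registration cancels whole-frame translation and must only be used to
#'   remove stage/cell drift in real recordings, never on rigidly drifting
#'   simulations whose flow is the signal.
#' @param branches Character vector of filter branches among `"original"`,
#'   `"gaussian"`, `"heterogeneity"`.
#' @param gaussian_sigma Sigma (px) of the Gaussian branch.
#' @param hm_kernel_diameter Disk diameter (px) of the heterogeneity branch.
#' @param stics A [stics_params()].
#' @param out_dir Output directory (created if missing).
#' @param seed Seed recorded in the manifest and used for simulation presets.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input = NULL, sim_preset = NULL,
                            pixel_size = NULL, frame_interval = NULL,
                            register = FALSE,
                            branches = c("original", "gaussian",
                                         "heterogeneity"),
                            gaussian_sigma = 7, hm_kernel_diameter = 16,
                            stics = stics_params(), out_dir = "sticsflow_out",
                            seed = 1L) {
  if (is.null(input) == is.null(sim_preset))
    stop("exactly one of 'input' and 'sim_preset' must be given")
  branches <- match.arg(branches, c("original", "gaussian", "heterogeneity"),
                        several.ok = TRUE)
  structure(list(input = input, sim_preset = sim_preset,
                 pixel_size = pixel_size, frame_interval = frame_interval,
                 register = isTRUE(register), branches = branches,
                 gaussian_sigma = gaussian_sigma,
                 hm_kernel_diameter = hm_kernel_diameter,
                 stics = stics, out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from a flat-key YAML file
#'
#' Recognized keys mirror the arguments of [pipeline_config()] and
#' [stics_params()] (`roi_size`, `roi_shift`, `toi_size`, `toi_shift`,
#' `max_lag`, `r2_threshold`, ...).
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sp_names <- intersect(names(y), names(formals(stics_params)))
  sp <- do.call(stics_params, y[sp_names])
  pc_names <- intersect(names(y), setdiff(names(formals(pipeline_config)),
                                          "stics"))
  do.call(pipeline_config, c(y[pc_names], list(stics = sp)))
}

#' Run the full filtering + STICS pipeline
#'
#' Simulates or reads the input series, optionally registers it, then for
#' every requested filter branch applies the filter, runs [stics_analyze()],
#' and writes the filtered TIFF, the vector CSV and a per-TOI summary CSV.
#' A `manifest.json` capturing every parameter and the package version is
#' written last, so the run can be reproduced from the manifest alone.
#'
#' @param config A [pipeline_config()] or the path to a YAML file for
#'   [read_pipeline_config()].
#' @return The output directory, invisibly. Artifacts per branch `<b>`:
#'   `<b>.tif` (+ `.json` sidecar), `vectors_<b>.csv`, `summary_<b>.csv`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(config$sim_preset)) {
    sim <- simulate_series(default_sim_config(config$sim_preset,
                                              seed = config$seed))
    series <- sim$series
    jsonlite::write_json(sim$truth$displacement_um,
                         file.path(config$out_dir, "ground_truth.json"),
                         digits = NA)
  } else {
    series <- read_tiff_series(config$input, config$pixel_size,
                               config$frame_interval)
  }
  if (config$register) series <- register_series(series)$series
  for (b in config$branches) {
    filtered <- apply_filter(series, b,
                             gaussian_sigma = config$gaussian_sigma,
                             hm_kernel_diameter = config$hm_kernel_diameter)
    write_tiff_series(filtered, file.path(config$out_dir, paste0(b, ".tif")))
    res <- stics_analyze(filtered, config$stics)
    vecs <- bind_fields(res)
    utils::write.csv(vecs,
                     file.path(config$out_dir, paste0("vectors_", b, ".csv")),
                     row.names = FALSE)
    summaries <- do.call(rbind, lapply(unclass(res), summarize_field))
    summaries <- cbind(toi_index = seq_len(nrow(summaries)), summaries)
    utils::write.csv(summaries,
                     file.path(config$out_dir, paste0("summary_", b, ".csv")),
                     row.names = FALSE)
  }
  manifest <- unclass(config)
  manifest$stics <- unclass(manifest$stics)
  manifest$package_version <-
    as.character(utils::packageVersion("sticsflow"))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(config$out_dir)
}
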
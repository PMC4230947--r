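#' Write a phantom specification to JSON or YAML
#'
#' @param spec a [phantom_spec()].
#' @param path output path; a .yaml/.yml suffix selects YAML (requires the
#'   yaml package), anything else JSON.
#' @return the path, invisibly.
#' @export
write_phantom_spec <- function(spec, path) {
  x <- unclass(spec)
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required for YAML output")
    writeLines(yaml::as.yaml(x), path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a phantom specification written by [write_phantom_spec()]
#' @param path .json or .yaml path.
#' @return a validated `phantom_spec`.
#' @export
read_phantom_spec <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required for YAML input")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  tp <- lapply(x$tissue_params, function(cl)
    list(mean = as.numeric(cl$mean),
         between_sd = as.numeric(cl$between_sd),
         within_sd = as.numeric(cl$within_sd)))
  phantom_spec(grid_shape = x$grid_shape, voxel_size = x$voxel_size,
               tissue_params = tp,
               lesion_model = x$lesion_model,
               diffuse_delta = as.numeric(x$diffuse_delta),
               gm_delta = as.numeric(x$gm_delta),
               atrophy_factor = x$atrophy_factor,
               noise_sigma = x$noise_sigma,
               misalignment = x$misalignment,
               edss_model = x$edss_model,
               age_model = x$age_model,
               clip_floor = x$clip_floor,
               seed = x$seed)
}

#' Serialize a run configuration to JSON
#' @param config a [run_config()].
#' @param path output .json path.
#' @return the path, invisibly.
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  x$spec <- unclass(x$spec)
  x$protocol <- unclass(x$protocol)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a run configuration written by [write_run_config()]
#' @param path .json path.
#' @return a `run_config` equal to the one written.
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec_file <- tempfile(fileext = ".json")
  on.exit(unlink(spec_file))
  jsonlite::write_json(x$spec, spec_file, auto_unbox = TRUE, digits = NA)
  spec <- read_phantom_spec(spec_file)
  run_config(spec = spec,
             n_ref = x$n_ref, n_pat = x$n_pat, seed = x$seed,
             protocol = acq_protocol(x$protocol$saturation_delays,
                                     x$protocol$echo_times,
                                     x$protocol$repetition_time,
                                     x$protocol$gain),
             fwhm = x$fwhm, target_res = x$target_res,
             t_threshold = x$t_threshold,
             bins_wholebrain = x$bins_wholebrain, bins_roi = x$bins_roi,
             threshold_frac = x$threshold_frac,
             erosion_levels = x$erosion_levels,
             n_perm = x$n_perm, stages = x$stages,
             outdir = if (is.null(x$outdir) || length(x$outdir) == 0) NULL
             else x$outdir)
}
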
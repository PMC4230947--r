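#' Write a signal stack as 4-D NIfTI plus a JSON sidecar
#'
#' The (delay, echo) grid is flattened into the 4th dimension in
#' delay-fastest order; the sidecar records the saturation delays, echo
#' times, repetition time and gain needed to reconstruct the protocol.
#'
#' @param stack a `signal_stack`.
#' @param path output NIfTI path (.nii or .nii.gz); the sidecar is written
#'   next to it with extension .json.
#' @return the NIfTI path, invisibly.
#' @export
write_signal_stack <- function(stack, path) {
  d <- dim(stack$data)
  vol4 <- aperm(stack$data, c(3, 4, 5, 1, 2))
  dim(vol4) <- c(d[3:5], d[1] * d[2])
  im <- geometry_to_nifti(vol4, stack$geometry)
  RNifti::writeNifti(im, path, datatype = "float")
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(list(
    saturation_delays = stack$protocol$saturation_delays,
    echo_times = stack$protocol$echo_times,
    repetition_time = stack$protocol$repetition_time,
    gain = stack$protocol$gain,
    layout = "delay_fastest"), side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a signal stack written by [write_signal_stack()]
#' @param path the NIfTI path (sidecar expected alongside).
#' @return a `signal_stack`.
#' @export
read_signal_stack <- function(path) {
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  if (!file.exists(side)) stop("missing protocol sidecar: ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  pr <- acq_protocol(meta$saturation_delays, meta$echo_times,
                     meta$repetition_time, meta$gain)
  v <- read_volume(path)
  im <- RNifti::readNifti(path)
  d4 <- dim(im)
  nd <- length(pr$saturation_delays); ne <- length(pr$echo_times)
  if (d4[4] != nd * ne)
    stop("volume count does not match the protocol grid")
  arr <- array(as.numeric(im), c(d4[1:3], nd, ne))
  arr <- aperm(arr, c(4, 5, 1, 2, 3))
  geom <- nifti_to_geometry(im)
  structure(list(data = arr, protocol = pr, geometry = geom),
            class = "signal_stack")
}

#' Serialize an affine transform to JSON
#'
#' Writes the 12 parameters and the composed 4x4 matrix; coordinates are
#' world-space mm (RAS), and the matrix is the pull-back mapping used by
#' [apply_and_regrid()].
#'
#' @param t an `affine_transform`.
#' @param path output .json path.
#' @return the path, invisibly.
#' @export
write_transform <- function(t, path) {
  jsonlite::write_json(list(
    convention = "world_mm_RAS_pullback",
    translation = t$translation, rotation = t$rotation,
    scale = t$scale, shear = t$shear,
    matrix = t$matrix), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an affine transform written by [write_transform()]
#' @param path the .json path.
#' @return an `affine_transform`.
#' @export
read_transform <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- affine_transform(j$translation, j$rotation, j$scale, j$shear)
  # the stored matrix is authoritative (guards against convention drift)
  out$matrix <- matrix(unlist(j$matrix), 4, 4)
  out
}

#' Plot a statistic overlay on a synthetic contrast background
#'
#' Renders one axial slice of a background image (typically a synthetic
#' T2-weighted image for visual guidance) with the thresholded statistic
#' overlaid in colour.
#'
#' @param map a `stat_map`.
#' @param background 3-D array on the same grid.
#' @param slice z index (default: middle slice).
#' @param t_min display threshold (default 2).
#' @return a ggplot object.
#' @export
plot_stat_overlay <- function(map, background, slice = NULL, t_min = 2) {
  sh <- map$geometry$shape
  stopifnot(identical(dim(background), sh))
  if (is.null(slice)) slice <- ceiling(sh[3] / 2)
  bg <- background[, , slice]
  tv <- map$stat[, , slice]
  keep <- threshold_map(map, t_min)[, , slice]
  df <- expand.grid(x = seq_len(sh[1]), y = seq_len(sh[2]))
  df$bg <- as.vector(bg)
  df$t <- ifelse(as.vector(keep), as.vector(tv), NA)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(alpha = .data$bg), fill = "grey10") +
    ggplot2::scale_alpha(range = c(1, 0), guide = "none") +
    ggplot2::geom_raster(data = df[!is.na(df$t), ],
                         ggplot2::aes(fill = .data$t)) +
    ggplot2::scale_fill_viridis_c(option = "inferno", name = "T") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = map$contrast, x = NULL, y = NULL) +
    ggplot2::theme_void()
}
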
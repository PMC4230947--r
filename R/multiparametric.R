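#' @title Multi-parametric 2-D difference histograms
#' @name multiparametric
#' @description The signature multi-parametric representation: voxel counts
#'   over a 2-D grid in a parameter-pair space ((R1,R2), (R1,PD) or
#'   (R2,PD)), pooled over the subjects of a group, and signed differences
#'   between two groups (positive = reference excess, negative = patient
#'   excess). Whole-brain histograms default to 200 bins over the standard
#'   display windows (R1 0-3 1/s, R2 0-15 1/s, PD 50-100 %); ROI histograms
#'   default to 50 bins over pooled 1st-99th percentile ranges.
NULL

#' Default display ranges per parameter
#' @param param "R1", "R2" or "PD".
#' @return numeric length-2 range.
#' @export
default_param_range <- function(param) {
  switch(param,
         R1 = c(0, 3),
         R2 = c(0, 15),
         PD = c(50, 100),
         stop("unknown parameter ", param))
}

#' Pooled 2-D histogram of a parameter pair over a group
#'
#' Bins the (pair\[1\], pair\[2\]) values of every in-mask voxel of every
#' subject onto a `bins` x `bins` grid. Voxels outside the ranges are
#' dropped.
#'
#' @param maps_list list of `parameter_maps` (one group), common grid.
#' @param pair character length-2, e.g. `c("R1", "R2")`.
#' @param bins number of bins per axis (>= 2).
#' @param ranges list with elements `x` and `y` (length-2 numeric); default
#'   the standard display windows.
#' @param inclusion_mask optional logical array further restricting voxels.
#' @return list: `counts` (bins x bins matrix, x = rows), `x_edges`,
#'   `y_edges`, `n_included` (voxel-subject pairs binned), `n_subjects`.
#' @export
build_histogram <- function(maps_list, pair = c("R1", "R2"), bins = 200L,
                            ranges = list(x = default_param_range(pair[1]),
                                          y = default_param_range(pair[2])),
                            inclusion_mask = NULL) {
  stopifnot(bins >= 2, length(maps_list) >= 1, length(pair) == 2)
  g0 <- maps_list[[1]]$geometry
  counts <- matrix(0, bins, bins)
  wx <- (ranges$x[2] - ranges$x[1]) / bins
  wy <- (ranges$y[2] - ranges$y[1]) / bins
  n_inc <- 0
  for (m in maps_list) {
    if (!geom_equal(m$geometry, g0)) stop("subjects on mismatched grids")
    keep <- as.vector(m$mask)
    if (!is.null(inclusion_mask)) keep <- keep & as.vector(inclusion_mask)
    xv <- as.vector(m[[pair[1]]])[keep]
    yv <- as.vector(m[[pair[2]]])[keep]
    ix <- floor((xv - ranges$x[1]) / wx) + 1
    iy <- floor((yv - ranges$y[1]) / wy) + 1
    ok <- ix >= 1 & ix <= bins & iy >= 1 & iy <= bins
    if (!any(ok)) next
    tab <- tabulate((ix[ok] - 1) * bins + iy[ok], nbins = bins * bins)
    counts <- counts + matrix(tab, bins, bins, byrow = TRUE)
    n_inc <- n_inc + sum(ok)
  }
  list(counts = counts,
       x_edges = seq(ranges$x[1], ranges$x[2], length.out = bins + 1),
       y_edges = seq(ranges$y[1], ranges$y[2], length.out = bins + 1),
       n_included = n_inc, n_subjects = length(maps_list))
}

#' Signed difference histogram between two groups
#'
#' Per-group 2-D histograms are divided by their subject counts (so unequal
#' cohorts remain comparable) and subtracted: positive entries mean more
#' voxels per subject in group A (the reference group by convention, shown
#' blue), negative entries more in group B (patients, red). Inclusion
#' follows the study rule: only voxels whose group-A mean PD exceeds
#' `threshold_frac` of its maximum enter the histograms.
#'
#' @param maps_a,maps_b lists of `parameter_maps` for the two groups, on a
#'   common grid.
#' @param pair parameter pair, e.g. `c("R1","R2")`.
#' @param bins bins per axis (200 whole-brain, 50 for ROI use).
#' @param ranges list(x=, y=) or NULL for defaults.
#' @param threshold_frac inclusion threshold as a fraction of the maximum
#'   reference mean-PD intensity (default 0.10); set to 0 to disable.
#' @param inclusion_mask optional explicit mask overriding the threshold
#'   rule (e.g. an eroded ROI).
#' @return Object of class `diff_histogram`: `signed` matrix, bin edges,
#'   per-group counts and subject numbers, the inclusion threshold used.
#' @export
difference_histogram <- function(maps_a, maps_b, pair = c("R1", "R2"),
                                 bins = 200L, ranges = NULL,
                                 threshold_frac = 0.10,
                                 inclusion_mask = NULL) {
  g0 <- maps_a[[1]]$geometry
  for (m in c(maps_a, maps_b))
    if (!geom_equal(m$geometry, g0)) stop("groups on mismatched grids")
  if (is.null(inclusion_mask)) {
    if (threshold_frac > 0) {
      mean_pd <- Reduce(`+`, lapply(maps_a, function(m) m$PD)) /
        length(maps_a)
      inclusion_mask <- mean_pd > threshold_frac * max(mean_pd)
    } else {
      inclusion_mask <- array(TRUE, g0$shape)
    }
  }
  if (is.null(ranges))
    ranges <- list(x = default_param_range(pair[1]),
                   y = default_param_range(pair[2]))
  ha <- build_histogram(maps_a, pair, bins, ranges, inclusion_mask)
  hb <- build_histogram(maps_b, pair, bins, ranges, inclusion_mask)
  structure(list(signed = ha$counts / ha$n_subjects -
                   hb$counts / hb$n_subjects,
                 x_edges = ha$x_edges, y_edges = ha$y_edges, pair = pair,
                 counts_a = ha$counts, counts_b = hb$counts,
                 n_subjects_a = ha$n_subjects, n_subjects_b = hb$n_subjects,
                 n_included_a = ha$n_included, n_included_b = hb$n_included,
                 threshold_frac = threshold_frac),
            class = "diff_histogram")
}

#' @export
print.diff_histogram <- function(x, ...) {
  cat(sprintf(paste0("diff_histogram %s-%s, %d bins: %d vs %d voxels ",
                     "(A vs B), net signed mass %.2f / subject\n"),
              x$pair[1], x$pair[2], nrow(x$signed),
              x$n_included_a, x$n_included_b, sum(x$signed)))
  invisible(x)
}

#' ROI mean markers in a parameter-pair space
#'
#' Computes, per ROI, the pooled-voxel group means of the two parameters
#' (the positions drawn as square/circle markers on difference histograms)
#' and the arrow from the reference mean to the patient mean. Means should
#' normally be computed on eroded ROIs; pass masks from [erode_roi()].
#'
#' @param maps_a,maps_b reference and patient map lists, common grid.
#' @param roi_masks named list of logical arrays.
#' @param pair parameter pair.
#' @return data.frame: roi, a_x, a_y, b_x, b_y, dx, dy (arrow components,
#'   b minus a). Empty ROIs are skipped with a warning.
#' @export
roi_markers <- function(maps_a, maps_b, roi_masks, pair = c("R1", "R2")) {
  pooled_mean <- function(maps_list, roi, param) {
    v <- unlist(lapply(maps_list,
                       function(m) as.vector(m[[param]])[as.vector(roi) &
                                                           as.vector(m$mask)]))
    mean(v)
  }
  rows <- list()
  for (nm in names(roi_masks)) {
    roi <- roi_masks[[nm]]
    if (!any(roi)) {
      warning("ROI ", nm, " is empty; skipped")
      next
    }
    ax <- pooled_mean(maps_a, roi, pair[1])
    ay <- pooled_mean(maps_a, roi, pair[2])
    bx <- pooled_mean(maps_b, roi, pair[1])
    by <- pooled_mean(maps_b, roi, pair[2])
    rows[[nm]] <- data.frame(roi = nm, a_x = ax, a_y = ay,
                             b_x = bx, b_y = by,
                             dx = bx - ax, dy = by - ay)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Plot a signed difference histogram
#'
#' Renders the signed matrix with a diverging palette (blue = reference
#' excess, red = patient excess) and symmetric colour limits; optional ROI
#' markers with reference-to-patient arrows.
#'
#' @param dh a [difference_histogram()] result.
#' @param markers optional [roi_markers()] data.frame.
#' @return a ggplot object.
#' @export
plot_diff_histogram <- function(dh, markers = NULL) {
  xc <- (dh$x_edges[-1] + dh$x_edges[-length(dh$x_edges)]) / 2
  yc <- (dh$y_edges[-1] + dh$y_edges[-length(dh$y_edges)]) / 2
  df <- expand.grid(x = xc, y = yc)
  df$value <- as.vector(dh$signed)       # signed is x-by-y, column-major
  lim <- max(abs(df$value), 1e-12)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                        fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "white",
                                  high = "#2166ac",
                                  limits = c(-lim, lim),
                                  name = "voxels/subject\n(ref - patient)") +
    ggplot2::labs(x = dh$pair[1], y = dh$pair[2]) +
    ggplot2::theme_minimal()
  if (!is.null(markers) && nrow(markers) > 0) {
    p <- p +
      ggplot2::geom_segment(data = markers,
                            ggplot2::aes(x = .data$a_x, y = .data$a_y,
                                         xend = .data$b_x, yend = .data$b_y),
                            inherit.aes = FALSE,
                            arrow = ggplot2::arrow(length =
                                                     ggplot2::unit(2, "mm"))) +
      ggplot2::geom_point(data = markers,
                          ggplot2::aes(x = .data$a_x, y = .data$a_y),
                          inherit.aes = FALSE, shape = 15) +
      ggplot2::geom_point(data = markers,
                          ggplot2::aes(x = .data$b_x, y = .data$b_y),
                          inherit.aes = FALSE, shape = 16)
  }
  p
}
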
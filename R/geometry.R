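#' Voxel grid geometry
#'
#' Describes a regular 3-D voxel grid: its shape (voxels per axis), voxel
#' size in mm, and the position of the first voxel centre in world (RAS, mm)
#' coordinates. World coordinates of voxel (i, j, k) (0-based) are
#' `origin + voxdim * (i, j, k)`. By default the grid is centred on the
#' world origin so that rotations in world space pivot about the volume
#' centre.
#'
#' @param shape integer length-3, voxels per axis.
#' @param voxdim numeric length-3, voxel size in mm (default 2 mm isotropic).
#' @param origin world coordinates (mm) of the centre of voxel (0,0,0).
#' @return An object of class `qmri_geometry`.
#' @export
qmri_geometry <- function(shape, voxdim = c(2, 2, 2),
                          origin = -(shape - 1) * voxdim / 2) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L),
            length(voxdim) == 3L, all(voxdim > 0),
            length(origin) == 3L)
  structure(list(shape = shape, voxdim = as.numeric(voxdim),
                 origin = as.numeric(origin)),
            class = "qmri_geometry")
}

#' @export
print.qmri_geometry <- function(x, ...) {
  cat(sprintf("qmri_geometry: %d x %d x %d voxels, %g x %g x %g mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$voxdim[1], x$voxdim[2], x$voxdim[3]))
  invisible(x)
}

#' @export
format.qmri_geometry <- function(x, ...) {
  sprintf("[%s] @ [%s] mm", paste(x$shape, collapse = "x"),
          paste(x$voxdim, collapse = "x"))
}

geom_equal <- function(a, b, tol = 1e-6) {
  identical(a$shape, b$shape) &&
    all(abs(a$voxdim - b$voxdim) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

#' Voxel-to-world affine matrix (4x4) for a geometry
#' @param geom a `qmri_geometry`.
#' @return 4x4 matrix mapping 0-based voxel indices to world mm.
#' @export
geometry_affine <- function(geom) {
  m <- diag(4)
  m[1:3, 1:3] <- diag(geom$voxdim, 3, 3)
  m[1:3, 4] <- geom$origin
  m
}

# World coordinates (V x 3) of all voxel centres, in array (column-major) order
grid_world_coords <- function(geom) {
  sh <- geom$shape
  i <- rep.int(seq_len(sh[1]) - 1L, sh[2] * sh[3])
  j <- rep.int(rep(seq_len(sh[2]) - 1L, each = sh[1]), sh[3])
  k <- rep(seq_len(sh[3]) - 1L, each = sh[1] * sh[2])
  cbind(geom$origin[1] + geom$voxdim[1] * i,
        geom$origin[2] + geom$voxdim[2] * j,
        geom$origin[3] + geom$voxdim[3] * k)
}

#' Trilinear interpolation of a 3-D array at world coordinates
#'
#' Samples `arr` (laid out on `geom`) at arbitrary world-space points.
#' Points outside the grid return `fill`.
#'
#' @param arr 3-D numeric array.
#' @param geom the `qmri_geometry` of `arr`.
#' @param coords V x 3 matrix of world coordinates (mm).
#' @param fill value for out-of-grid points (default 0).
#' @return numeric vector of length V.
#' @export
interp_trilinear <- function(arr, geom, coords, fill = 0) {
  sh <- geom$shape
  cx <- (coords[, 1] - geom$origin[1]) / geom$voxdim[1]
  cy <- (coords[, 2] - geom$origin[2]) / geom$voxdim[2]
  cz <- (coords[, 3] - geom$origin[3]) / geom$voxdim[3]
  ok <- cx >= 0 & cx <= sh[1] - 1L & cy >= 0 & cy <= sh[2] - 1L &
    cz >= 0 & cz <= sh[3] - 1L
  ok[is.na(ok)] <- FALSE
  out <- rep(fill, length(cx))
  if (!any(ok)) return(out)
  cx <- cx[ok]; cy <- cy[ok]; cz <- cz[ok]
  x0 <- pmin(floor(cx), sh[1] - 2L); y0 <- pmin(floor(cy), sh[2] - 2L)
  z0 <- pmin(floor(cz), sh[3] - 2L)
  x0 <- pmax(x0, 0); y0 <- pmax(y0, 0); z0 <- pmax(z0, 0)
  fx <- cx - x0; fy <- cy - y0; fz <- cz - z0
  # 1-based linear index of the (x0,y0,z0) corner
  n1 <- sh[1]; n12 <- sh[1] * sh[2]
  idx <- x0 + y0 * n1 + z0 * n12 + 1
  v000 <- arr[idx];            v100 <- arr[idx + 1]
  v010 <- arr[idx + n1];       v110 <- arr[idx + n1 + 1]
  v001 <- arr[idx + n12];      v101 <- arr[idx + n12 + 1]
  v011 <- arr[idx + n1 + n12]; v111 <- arr[idx + n1 + n12 + 1]
  c00 <- v000 * (1 - fx) + v100 * fx
  c10 <- v010 * (1 - fx) + v110 * fx
  c01 <- v001 * (1 - fx) + v101 * fx
  c11 <- v011 * (1 - fx) + v111 * fx
  c0 <- c00 * (1 - fy) + c10 * fy
  c1 <- c01 * (1 - fy) + c11 * fy
  out[ok] <- c0 * (1 - fz) + c1 * fz
  out
}

# Nearest-neighbour sampling (for masks)
interp_nearest <- function(arr, geom, coords, fill = 0) {
  sh <- geom$shape
  i <- round((coords[, 1] - geom$origin[1]) / geom$voxdim[1])
  j <- round((coords[, 2] - geom$origin[2]) / geom$voxdim[2])
  k <- round((coords[, 3] - geom$origin[3]) / geom$voxdim[3])
  ok <- i >= 0 & i <= sh[1] - 1L & j >= 0 & j <= sh[2] - 1L &
    k >= 0 & k <= sh[3] - 1L
  ok[is.na(ok)] <- FALSE
  out <- rep(fill, length(i))
  idx <- i[ok] + j[ok] * sh[1] + k[ok] * sh[1] * sh[2] + 1
  out[ok] <- arr[idx]
  out
}

#' Bundle R1/R2/PD volumes sharing one geometry
#'
#' The canonical container for a subject's quantitative maps: longitudinal
#' relaxation rate R1 (1/s), transversal relaxation rate R2 (1/s) and proton
#' density PD (% of pure water at 37 C), all on a common voxel grid, plus an
#' optional brain mask.
#'
#' @param R1,R2,PD 3-D arrays of identical shape.
#' @param geometry a `qmri_geometry`.
#' @param mask optional logical 3-D array (same shape).
#' @return Object of class `parameter_maps`.
#' @export
parameter_maps <- function(R1, R2, PD, geometry, mask = NULL) {
  stopifnot(identical(dim(R1), dim(R2)), identical(dim(R1), dim(PD)),
            identical(as.integer(dim(R1)), geometry$shape))
  if (is.null(mask)) mask <- array(TRUE, dim = dim(R1))
  stopifnot(identical(dim(mask), dim(R1)))
  structure(list(R1 = R1, R2 = R2, PD = PD,
                 geometry = geometry, mask = mask),
            class = "parameter_maps")
}

#' @export
print.parameter_maps <- function(x, ...) {
  cat("parameter_maps", format(x$geometry), "\n")
  cat(sprintf("  R1 [%g, %g] s^-1; R2 [%g, %g] s^-1; PD [%g, %g] %%\n",
              min(x$R1), max(x$R1), min(x$R2), max(x$R2),
              min(x$PD), max(x$PD)))
  invisible(x)
}

# Largest 6-connected component of a logical 3-D array, via iterative
# minimum-label propagation (vectorised; converges in O(diameter) sweeps).
largest_component <- function(mask) {
  sh <- dim(mask)
  lab <- array(0, sh)
  lab[mask] <- seq_len(sum(mask))
  shift_min <- function(l) {
    m <- l
    n <- l
    # +/- x
    n[] <- Inf; n[-sh[1], , ] <- l[-1, , ]; m <- pmin(m, n, na.rm = FALSE)
    n[] <- Inf; n[-1, , ] <- l[-sh[1], , ]; m <- pmin(m, n)
    n[] <- Inf; n[, -sh[2], ] <- l[, -1, ]; m <- pmin(m, n)
    n[] <- Inf; n[, -1, ] <- l[, -sh[2], ]; m <- pmin(m, n)
    n[] <- Inf; n[, , -sh[3]] <- l[, , -1]; m <- pmin(m, n)
    n[] <- Inf; n[, , -1] <- l[, , -sh[3]]; m <- pmin(m, n)
    m
  }
  l <- array(Inf, sh)
  l[mask] <- lab[mask]
  repeat {
    l2 <- shift_min(l)
    l2[!mask] <- Inf
    if (all(l2[mask] == l[mask])) break
    l <- l2
  }
  if (!any(mask)) return(mask)
  labs <- l[mask]
  big <- as.numeric(names(which.max(table(labs))))
  out <- array(FALSE, sh)
  out[mask] <- labs == big
  out
}
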
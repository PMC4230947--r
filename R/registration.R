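#' 12-parameter affine transform
#'
#' Builds a world-to-world affine from translation (mm), rotation (degrees,
#' about the world origin, applied as Rz Ry Rx), anisotropic scale and shear
#' (xy, xz, yz). The composed 4x4 matrix maps homogeneous world coordinates
#' of the *target* space into the *source* space (the pull-back convention
#' used by [apply_and_regrid()]).
#'
#' @param translation,rotation,scale,shear numeric length-3 each.
#' @return Object of class `affine_transform` with fields `translation`,
#'   `rotation`, `scale`, `shear` and the composed `matrix`.
#' @export
affine_transform <- function(translation = c(0, 0, 0),
                             rotation = c(0, 0, 0),
                             scale = c(1, 1, 1),
                             shear = c(0, 0, 0)) {
  stopifnot(length(translation) == 3, length(rotation) == 3,
            length(scale) == 3, length(shear) == 3, all(scale != 0))
  r <- rotation * pi / 180
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  Sh <- rbind(c(1, shear[1], shear[2]), c(0, 1, shear[3]), c(0, 0, 1))
  A <- Rz %*% Ry %*% Rx %*% Sh %*% diag(scale, 3, 3)
  m <- diag(4)
  m[1:3, 1:3] <- A
  m[1:3, 4] <- translation
  structure(list(translation = translation, rotation = rotation,
                 scale = scale, shear = shear, matrix = m),
            class = "affine_transform")
}

#' @export
print.affine_transform <- function(x, ...) {
  cat("affine_transform\n")
  cat("  translation (mm): ", paste(signif(x$translation, 4), collapse = ", "), "\n")
  cat("  rotation (deg):   ", paste(signif(x$rotation, 4), collapse = ", "), "\n")
  cat("  scale:            ", paste(signif(x$scale, 4), collapse = ", "), "\n")
  cat("  shear:            ", paste(signif(x$shear, 4), collapse = ", "), "\n")
  invisible(x)
}

params_to_transform <- function(p) {
  affine_transform(translation = p[1:3], rotation = p[4:6],
                   scale = p[7:9], shear = p[10:12])
}

#' Invert an affine transform
#' @param t an `affine_transform`.
#' @return an `affine_transform` whose matrix is the inverse (the parameter
#'   decomposition is left at neutral values; only the matrix is meaningful).
#' @export
invert_transform <- function(t) {
  out <- affine_transform()
  out$matrix <- solve(t$matrix)
  out$decomposed <- FALSE
  out
}

transform_points <- function(m, coords) {
  # coords V x 3; m 4x4
  sweep(coords %*% t(m[1:3, 1:3]), 2, m[1:3, 4], "+")
}

#' Gaussian smoothing of a 3-D volume
#'
#' Separable discrete Gaussian convolution with the kernel standard
#' deviation set per axis to `fwhm / (2 sqrt(2 log 2))` mm, converted to
#' voxels by the voxel size. Boundaries are renormalised (kernel mass
#' outside the grid is redistributed), so a constant image is exactly
#' unchanged. `fwhm = 0` returns the input.
#'
#' @param arr 3-D numeric array.
#' @param fwhm full width at half maximum of the kernel, mm.
#' @param voxdim voxel size, mm (length 3 or scalar).
#' @return smoothed array of the same shape.
#' @export
smooth_gaussian <- function(arr, fwhm, voxdim = c(2, 2, 2)) {
  stopifnot(fwhm >= 0)
  if (fwhm == 0) return(arr)
  if (length(voxdim) == 1) voxdim <- rep(voxdim, 3)
  sigma_mm <- fwhm / (2 * sqrt(2 * log(2)))
  out <- arr
  ones <- array(1, dim(arr))
  for (ax in 1:3) {
    sig <- sigma_mm / voxdim[ax]
    rad <- max(1L, ceiling(4 * sig))
    k <- stats::dnorm(seq(-rad, rad), sd = sig)
    k <- k / sum(k)
    out <- conv_axis(out, k, ax)
    ones <- conv_axis(ones, k, ax)
  }
  out / ones
}

# Convolve along one axis with kernel k (odd length), zero padding.
conv_axis <- function(arr, k, axis) {
  sh <- dim(arr)
  rad <- (length(k) - 1L) / 2L
  out <- array(0, sh)
  n <- sh[axis]
  for (o in seq_along(k)) {
    off <- o - rad - 1L           # offset in [-rad, rad]
    w <- k[o]
    src_lo <- max(1L, 1L - off); src_hi <- min(n, n - off)
    if (src_lo > src_hi) next
    dst <- src_lo:src_hi
    src <- dst + off
    if (axis == 1L) out[dst, , ] <- out[dst, , ] + w * arr[src, , ]
    else if (axis == 2L) out[, dst, ] <- out[, dst, ] + w * arr[, src, ]
    else out[, , dst] <- out[, , dst] + w * arr[, , src]
  }
  out
}

# Block-mean downsampling by a power-of-two factor per axis (pyramid).
downsample_mean <- function(arr, geom, factor = 2L) {
  stopifnot(factor >= 1L, bitwAnd(factor, factor - 1L) == 0L)
  g <- geom
  while (factor > 1L) {
    sh <- dim(arr)
    ns <- pmax(1L, sh %/% 2L)
    i1 <- seq(1L, 2L * ns[1], by = 2L); i2 <- i1 + 1L
    j1 <- seq(1L, 2L * ns[2], by = 2L); j2 <- j1 + 1L
    k1 <- seq(1L, 2L * ns[3], by = 2L); k2 <- k1 + 1L
    arr <- (arr[i1, j1, k1] + arr[i2, j1, k1] + arr[i1, j2, k1] +
            arr[i1, j1, k2] + arr[i2, j2, k1] + arr[i2, j1, k2] +
            arr[i1, j2, k2] + arr[i2, j2, k2]) / 8
    dim(arr) <- ns
    g <- qmri_geometry(ns, g$voxdim * 2, origin = g$origin + g$voxdim / 2)
    factor <- factor %/% 2L
  }
  list(arr = arr, geom = g)
}

#' Estimate a 12-parameter affine registration
#'
#' Finds the affine that resamples `source` onto the grid of `template` with
#' minimum mean squared intensity difference, by multi-resolution
#' quasi-Newton optimisation over translation, rotation, scale and shear.
#' Both images should already be smoothed (see [smooth_gaussian()]); the
#' returned transform is the pull-back mapping for [apply_and_regrid()]
#' (template-world to source-world).
#'
#' @param source 3-D array (the subject's synthetic contrast image).
#' @param source_geom,template_geom geometries of the two images.
#' @param template 3-D array (the target).
#' @param levels integer downsampling factors, coarse to fine.
#' @param stride voxel subsampling stride of the cost at the finest level.
#' @param maxit optim iteration cap per level.
#' @param reg_lambda weight of the quadratic zoom/shear regulariser,
#'   relative to the initial cost at each level (0 disables it).
#' @return `affine_transform` with extra fields `cost_trace` (per-level
#'   initial/final cost) and `converged`.
#' @export
estimate_affine <- function(source, source_geom, template, template_geom,
                            levels = c(4L, 2L, 1L), stride = 3L,
                            maxit = c(80L, 50L, 15L), reg_lambda = 0.02) {
  stopifnot(length(levels) == length(maxit))
  p <- c(0, 0, 0, 0, 0, 0, 1, 1, 1, 0, 0, 0)
  parscale <- c(rep(1, 3), rep(0.5, 3), rep(0.01, 3), rep(0.01, 3))
  trace <- data.frame(level = integer(), cost_init = numeric(),
                      cost_final = numeric(), convergence = integer())
  converged <- TRUE
  for (li in seq_along(levels)) {
    f <- as.integer(levels[li])
    if (f > 1L) {
      ds <- downsample_mean(template, template_geom, f)
      tmpl <- ds$arr; tg <- ds$geom
      dss <- downsample_mean(source, source_geom, f)
      src <- dss$arr; sg <- dss$geom
      st <- 1L
    } else {
      tmpl <- template; tg <- template_geom
      src <- source; sg <- source_geom
      st <- as.integer(stride)
    }
    coords <- grid_world_coords(tg)
    vals <- as.vector(tmpl)
    # informative voxels: the imaged object plus a sparse background
    # lattice (keeps the field-of-view constraint without paying for
    # empty space)
    keep <- which(vals > 0.02 * max(vals))
    lattice <- seq(1L, length(vals), by = 8L)
    keep <- sort(unique(c(keep, lattice)))
    if (st > 1L) keep <- keep[seq(1L, length(keep), by = st)]
    coords <- coords[keep, , drop = FALSE]
    vals <- vals[keep]
    fill <- stats::median(src[c(1, length(src))])  # background level
    raw_cost <- function(pp) {
      m <- params_to_transform(pp)$matrix
      s <- interp_trilinear(src, sg, transform_points(m, coords), fill = fill)
      mean((s - vals)^2)
    }
    raw0 <- raw_cost(p)
    # mild zoom/shear regularization: breaks the rotation-shear ridge of
    # near-ellipsoidal images without noticeably biasing the fit
    cost <- function(pp) {
      if (any(pp[7:9] <= 0.05)) return(raw0 * 1e6)
      raw_cost(pp) + reg_lambda * raw0 *
        (100 * sum(pp[10:12]^2) + 100 * sum(log(pp[7:9])^2))
    }
    c0 <- cost(p)
    if (li == 1L) {
      # rigid (translation + rotation) first at the coarsest level
      rigid_cost <- function(pr6) cost(c(pr6, p[7:12]))
      opt6 <- stats::optim(p[1:6], rigid_cost, method = "BFGS",
                           control = list(maxit = maxit[li],
                                          parscale = parscale[1:6],
                                          reltol = 1e-10))
      if (opt6$value <= c0) p[1:6] <- opt6$par
    }
    opt <- stats::optim(p, cost, method = "BFGS",
                        control = list(maxit = maxit[li],
                                       parscale = parscale,
                                       reltol = 1e-10))
    if (opt$value <= cost(p)) p <- opt$par else converged <- FALSE
    trace <- rbind(trace, data.frame(level = f, cost_init = c0,
                                     cost_final = min(opt$value, c0),
                                     convergence = opt$convergence))
  }
  out <- params_to_transform(p)
  out$cost_trace <- trace
  out$converged <- converged
  out
}

#' Resample parameter maps through an affine onto a target grid
#'
#' Applies the pull-back transform `t` (target-world to source-world) and
#' re-grids `maps` onto `target_geom` (default 2 mm isotropic grids are the
#' common-analysis convention). Parameter volumes are interpolated
#' trilinearly; the brain mask is resampled nearest-neighbour so it stays
#' crisp.
#'
#' @param maps a `parameter_maps` object.
#' @param t an `affine_transform` (or a bare 4x4 matrix).
#' @param target_geom a `qmri_geometry` for the output grid.
#' @return `parameter_maps` on the target grid.
#' @export
apply_and_regrid <- function(maps, t, target_geom) {
  m <- if (inherits(t, "affine_transform")) t$matrix else t
  stopifnot(is.matrix(m), all(dim(m) == c(4, 4)))
  coords <- transform_points(m, grid_world_coords(target_geom))
  sh <- target_geom$shape
  sample3 <- function(a) array(interp_trilinear(a, maps$geometry, coords), sh)
  msk <- array(interp_nearest(maps$mask + 0, maps$geometry, coords), sh) > 0.5
  # detect transforms that push the object out of the field of view
  src_obj <- sum(maps$mask)
  if (src_obj > 0 && sum(msk) < 0.05 * src_obj)
    stop("transform maps the brain outside the target field of view")
  parameter_maps(sample3(maps$R1), sample3(maps$R2), sample3(maps$PD),
                 target_geom, mask = msk)
}

#' Dice overlap of two binary masks
#' @param a,b logical arrays of equal shape.
#' @return Dice coefficient in [0, 1].
#' @export
dice_overlap <- function(a, b) {
  2 * sum(a & b) / (sum(a) + sum(b))
}
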
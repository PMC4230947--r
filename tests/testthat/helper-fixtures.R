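# Shared fixtures. Everything is generated in code; heavyweight objects are
# memoised so several test files can reuse them within one run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# Small phantom: 4 mm voxels keep the anatomy but shrink the grid ~8x.
tiny_spec <- function(..., grid_shape = c(34, 36, 28), voxel_size = 4) {
  phantom_spec(grid_shape = grid_shape, voxel_size = voxel_size, ...)
}

tiny_template <- function() memo("tiny_template", build_template(tiny_spec()))

# A noise-free spec: no texture, no between-subject spread, no lesions.
exact_spec <- function(...) {
  tp <- phantom_spec()$tissue_params
  for (cl in names(tp)) {
    tp[[cl]]$between_sd <- c(0, 0, 0)
    tp[[cl]]$within_sd <- c(0, 0, 0)
  }
  phantom_spec(grid_shape = c(34, 36, 28), voxel_size = 4,
               tissue_params = tp,
               lesion_model = list(count_lambda = 0,
                                   radius_range = c(2.5, 5),
                                   periventricular_prob = 0.8,
                                   severity = 0.5),
               noise_sigma = 0, ...)
}

# Arbitrary in-range parameter maps on a small grid, for fit round-trips.
random_maps <- function(shape = c(10, 8, 6), seed = 99, voxdim = c(2, 2, 2)) {
  set.seed(seed)
  nv <- prod(shape)
  g <- qmri_geometry(shape, voxdim)
  parameter_maps(array(runif(nv, 0.2, 2.5), shape),
                 array(runif(nv, 1, 14), shape),
                 array(runif(nv, 40, 100), shape), g)
}

# Single-voxel "maps" holding one scalar per subject, for GLM oracles.
scalar_maps <- function(values) {
  g <- qmri_geometry(c(1, 1, 1))
  lapply(values, function(v)
    parameter_maps(array(v, c(1, 1, 1)), array(v, c(1, 1, 1)),
                   array(v, c(1, 1, 1)), g))
}

# Maps with given constant values inside/outside a region.
block_maps <- function(shape, region, r1, r2, pd, base = c(0.8, 8, 80)) {
  g <- qmri_geometry(shape)
  a1 <- array(base[1], shape); a2 <- array(base[2], shape)
  a3 <- array(base[3], shape)
  a1[region] <- r1; a2[region] <- r2; a3[region] <- pd
  parameter_maps(a1, a2, a3, g)
}

# The default full-size cohort pipeline, run once and shared by the
# acceptance checks (criterion-level assertions all read from it).
default_pipeline_report <- function() memo("default_report", {
  suppressWarnings(run_pipeline(run_config(seed = 1L), verbose = FALSE))
})

# Brute-force 2-D histogram oracle (independent of build_histogram).
brute_hist2d <- function(x, y, bins, xr, yr) {
  counts <- matrix(0, bins, bins)
  wx <- (xr[2] - xr[1]) / bins
  wy <- (yr[2] - yr[1]) / bins
  for (i in seq_along(x)) {
    ix <- floor((x[i] - xr[1]) / wx) + 1
    iy <- floor((y[i] - yr[1]) / wy) + 1
    if (ix >= 1 && ix <= bins && iy >= 1 && iy <= bins)
      counts[ix, iy] <- counts[ix, iy] + 1
  }
  counts
}

# Brute-force distance-from-surface oracle: nearest background voxel centre.
brute_distance <- function(mask, voxdim) {
  sh <- dim(mask)
  out <- array(0, sh)
  bg <- which(!mask, arr.ind = TRUE)
  fg <- which(mask, arr.ind = TRUE)
  for (r in seq_len(nrow(fg))) {
    d2 <- (voxdim[1] * (bg[, 1] - fg[r, 1]))^2 +
      (voxdim[2] * (bg[, 2] - fg[r, 2]))^2 +
      (voxdim[3] * (bg[, 3] - fg[r, 3]))^2
    out[fg[r, 1], fg[r, 2], fg[r, 3]] <- sqrt(min(d2))
  }
  out
}
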
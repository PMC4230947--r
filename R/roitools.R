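#' @title ROI erosion and mixed-model summaries
#' @name roitools
#' @description Atlas-style region-of-interest handling on the common 2 mm
#'   grid: exact Euclidean distance-from-surface maps, erosion in
#'   millimetre steps (the partial-volume reduction procedure), per-ROI
#'   parameter summaries across erosion levels, and the mixed linear model
#'   group comparison with subjects as random samples.
NULL

# Exact 1-D squared distance transform (lower envelope of parabolas),
# Felzenszwalb & Huttenlocher. f: costs (Inf allowed), spacing: mm.
dt1d <- function(f, spacing) {
  n <- length(f)
  d <- rep(Inf, n)
  v <- integer(n); z <- numeric(n + 1)
  k <- 0L
  x <- (seq_len(n) - 1) * spacing
  for (q in seq_len(n)) {
    if (!is.finite(f[q])) next
    if (k == 0L) {
      k <- 1L; v[1] <- q; z[1] <- -Inf; z[2] <- Inf
      next
    }
    repeat {
      p <- v[k]
      s <- ((f[q] + x[q]^2) - (f[p] + x[p]^2)) / (2 * x[q] - 2 * x[p])
      if (s <= z[k]) {
        k <- k - 1L
        if (k == 0L) { k <- 1L; v[1] <- q; z[1] <- -Inf; z[2] <- Inf; break }
      } else {
        k <- k + 1L; v[k] <- q; z[k] <- s; z[k + 1] <- Inf
        break
      }
    }
  }
  if (k == 0L) return(d)
  j <- 1L
  for (q in seq_len(n)) {
    while (z[j + 1] < x[q]) j <- j + 1L
    p <- v[j]
    d[q] <- (x[q] - x[p])^2 + f[p]
  }
  d
}

#' Euclidean distance from the ROI surface
#'
#' For every in-mask voxel, the exact Euclidean distance (mm, respecting
#' anisotropic voxel sizes) to the nearest out-of-mask voxel centre,
#' computed with the separable exact squared distance transform. Out-of-mask
#' voxels get 0. On the default 2 mm grid a surface voxel (one with a
#' face-adjacent background neighbour) has distance 2 mm.
#'
#' @param mask logical 3-D array with at least one `TRUE` voxel.
#' @param voxdim voxel size in mm (length 3 or scalar).
#' @return numeric array of distances (mm).
#' @export
distance_from_surface <- function(mask, voxdim = c(2, 2, 2)) {
  if (!any(mask)) stop("empty mask")
  if (length(voxdim) == 1) voxdim <- rep(voxdim, 3)
  sh <- dim(mask)
  f <- array(ifelse(mask, Inf, 0), sh)
  # pass along each axis in turn
  for (ax in 1:3) {
    sp <- voxdim[ax]
    f <- apply_lines(f, ax, function(line) dt1d(line, sp))
  }
  sqrt(f)
}

# Apply fun to every 1-D line of arr along axis `ax`.
apply_lines <- function(arr, ax, fun) {
  sh <- dim(arr)
  perm <- switch(ax, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  a <- aperm(arr, perm)
  m <- matrix(a, nrow = sh[ax])
  m <- vapply(seq_len(ncol(m)), function(j) fun(m[, j]),
              numeric(sh[ax]))
  a <- array(m, dim(a))
  aperm(a, order(perm))
}

#' Erode an ROI mask by a millimetre level
#'
#' Retains voxels whose [distance_from_surface()] strictly exceeds `level`
#' mm; level 0 returns the input unchanged. On the 2 mm grid each 2 mm step
#' strips the one-voxel surface shell. Eroded masks are nested across
#' levels. An empty result is allowed.
#'
#' @param mask logical 3-D array.
#' @param level erosion level in mm (typically 0, 2, 4, 6, 8).
#' @param voxdim voxel size, mm.
#' @return logical array.
#' @export
erode_roi <- function(mask, level, voxdim = c(2, 2, 2)) {
  stopifnot(level >= 0)
  if (level == 0) return(mask)
  mask & distance_from_surface(mask, voxdim) > level
}

#' Per-ROI parameter summaries across erosion levels
#'
#' For each ROI, group and erosion level: the number of retained voxels and
#' the pooled-voxel mean and SD of each parameter across the group's
#' subjects. Also returns per-distance-band means (2 mm bands of
#' distance-from-surface) for trajectory plots of the partial-volume
#' purification effect.
#'
#' @param maps_list named list of `parameter_maps`, common grid.
#' @param groups character vector, one group label per subject.
#' @param roi_masks named list of logical arrays.
#' @param levels erosion levels in mm (default 0, 2, 4, 6, 8).
#' @param params parameters to summarise.
#' @return list: `summary` (data.frame roi, group, level_mm, n_voxels,
#'   param, mean, sd) and `bands` (data.frame roi, group, band_mm, n_voxels,
#'   param, mean). Levels at which an ROI erodes away are skipped with a
#'   warning.
#' @export
roi_summary <- function(maps_list, groups, roi_masks,
                        levels = c(0, 2, 4, 6, 8),
                        params = c("R1", "R2", "PD")) {
  stopifnot(length(groups) == length(maps_list))
  g0 <- maps_list[[1]]$geometry
  out <- list(); bands <- list()
  for (nm in names(roi_masks)) {
    roi <- roi_masks[[nm]]
    dmap <- distance_from_surface(roi, g0$voxdim)
    for (lv in levels) {
      keep <- as.vector(roi & dmap > lv) | (lv == 0 & as.vector(roi))
      if (!any(keep)) {
        warning(sprintf("ROI %s empty at erosion level %g mm; skipped",
                        nm, lv))
        next
      }
      for (grp in unique(groups)) {
        idx <- which(groups == grp)
        for (pp in params) {
          v <- unlist(lapply(maps_list[idx],
                             function(m) as.vector(m[[pp]])[keep]))
          out[[length(out) + 1]] <- data.frame(
            roi = nm, group = grp, level_mm = lv, n_voxels = sum(keep),
            param = pp, mean = mean(v), sd = stats::sd(v))
        }
      }
    }
    # 2 mm distance bands (within the full ROI)
    band <- 2 * floor(pmax(as.vector(dmap)[as.vector(roi)] - 1e-9, 0) / 2)
    for (grp in unique(groups)) {
      idx <- which(groups == grp)
      for (pp in params) {
        v <- rowMeans(matrix(unlist(lapply(
          maps_list[idx],
          function(m) as.vector(m[[pp]])[as.vector(roi)])),
          nrow = sum(roi)))
        agg <- tapply(v, band, mean)
        cnt <- tapply(v, band, length)
        bands[[length(bands) + 1]] <- data.frame(
          roi = nm, group = grp, band_mm = as.numeric(names(agg)),
          n_voxels = as.integer(cnt), param = pp, mean = as.numeric(agg))
      }
    }
  }
  list(summary = do.call(rbind, out), bands = do.call(rbind, bands))
}

#' Mixed linear model group comparison within an ROI
#'
#' Fits `y_sv = b0 + b1 * group + subject + noise` with a random intercept
#' per subject over all (subject, voxel) observations inside the ROI, and
#' returns the group fixed effect (patient minus reference) and its p
#' value. In the balanced case (every subject contributes the same voxel
#' count, the norm on a common grid) the REML solution has a closed form:
#' the fixed effect and its standard error equal those of the two-sample
#' analysis of subject means, with df = n_subjects - 2. Unbalanced data are
#' fitted by iterative REML (lme4). A fit with zero between-subject
#' variance is flagged (`singular = TRUE`); the subject-means inference
#' remains exact either way.
#'
#' @param maps_list list of `parameter_maps`, common grid.
#' @param groups character vector ("reference"/"patient") per subject.
#' @param roi logical array.
#' @param param which parameter to test.
#' @param method "closed_form" (balanced only), "reml" (lme4), or "auto".
#' @return list: `estimate` (patient - reference), `se`, `df`, `t`, `p`,
#'   `method`, `singular`, `n_subjects`, `n_voxels`.
#' @export
mixed_model_group_test <- function(maps_list, groups, roi, param = "R1",
                                   method = c("auto", "closed_form",
                                              "reml")) {
  method <- match.arg(method)
  stopifnot(length(groups) == length(maps_list),
            all(groups %in% c("reference", "patient")))
  counts <- table(factor(groups, levels = c("reference", "patient")))
  if (min(counts) < 2) stop("need >= 2 subjects per group")
  if (!any(roi)) stop("empty ROI")
  keep <- as.vector(roi)
  vals <- lapply(maps_list, function(m) as.vector(m[[param]])[keep])
  nvox <- lengths(vals)
  balanced <- length(unique(nvox)) == 1
  if (method == "auto") method <- if (balanced) "closed_form" else "reml"

  n_s <- length(vals)
  if (method == "closed_form") {
    if (!balanced) stop("closed form requires balanced voxel counts")
    m_s <- vapply(vals, mean, numeric(1))
    g <- as.numeric(groups == "patient")
    n1 <- sum(g == 1); n0 <- sum(g == 0)
    est <- mean(m_s[g == 1]) - mean(m_s[g == 0])
    s2 <- (sum((m_s[g == 1] - mean(m_s[g == 1]))^2) +
             sum((m_s[g == 0] - mean(m_s[g == 0]))^2)) / (n_s - 2)
    se <- sqrt(s2 * (1 / n1 + 1 / n0))
    tval <- est / se
    df <- n_s - 2
    p <- 2 * stats::pt(-abs(tval), df)
    # between-subject variance component (can hit the zero boundary)
    within <- mean(vapply(vals, stats::var, numeric(1)))
    sig_b2 <- s2 - within / nvox[1]
    return(list(estimate = est, se = se, df = df, t = tval, p = p,
                method = "closed_form", singular = sig_b2 <= 0,
                n_subjects = n_s, n_voxels = nvox[1]))
  }
  dat <- data.frame(
    y = unlist(vals),
    subject = factor(rep(seq_len(n_s), nvox)),
    group = factor(rep(groups, nvox), levels = c("reference", "patient")))
  fit <- lmerTest::lmer(y ~ group + (1 | subject), data = dat, REML = TRUE)
  singular <- lme4::isSingular(fit)
  co <- stats::coef(summary(fit))["grouppatient", ]
  if (singular) {
    # zero between-subject variance: fall back to subject-means t test
    m_s <- vapply(vals, mean, numeric(1))
    tt <- stats::t.test(m_s[groups == "patient"], m_s[groups == "reference"],
                        var.equal = TRUE)
    return(list(estimate = unname(tt$estimate[1] - tt$estimate[2]),
                se = tt$stderr, df = unname(tt$parameter),
                t = unname(tt$statistic), p = tt$p.value,
                method = "subject_means_fallback", singular = TRUE,
                n_subjects = n_s, n_voxels = sum(nvox)))
  }
  list(estimate = unname(co["Estimate"]), se = unname(co["Std. Error"]),
       df = unname(co["df"]), t = unname(co["t value"]),
       p = unname(co["Pr(>|t|)"]), method = "reml", singular = FALSE,
       n_subjects = n_s, n_voxels = sum(nvox))
}
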
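#' @title Voxel-wise group statistics on normalized cohorts
#' @name voxelstats
#' @description Voxel-wise general-linear-model inference over cohorts of
#'   spatially normalized parameter maps: two-sample group contrasts
#'   controlling for age, disability (EDSS) slope maps with age as a
#'   nuisance variable, simple T thresholding, and permutation-based
#'   family-wise-error-corrected small-volume inference.
NULL

# Stack one parameter across subjects: V x n matrix plus the intersection
# analysis mask.
cohort_param_matrix <- function(maps_list, param) {
  stopifnot(length(maps_list) >= 1)
  g0 <- maps_list[[1]]$geometry
  for (m in maps_list)
    if (!geom_equal(m$geometry, g0))
      stop("all subjects must share one grid; run the normalization stage first")
  Y <- vapply(maps_list, function(m) as.vector(m[[param]]),
              numeric(prod(g0$shape)))
  mask <- Reduce(`&`, lapply(maps_list, function(m) as.vector(m$mask)))
  list(Y = Y, mask = mask, geometry = g0)
}

# Vectorised least squares of Y (V x n) on design X (n x p); returns the
# t statistic for contrast column `col` and the coefficient itself.
glm_tmap <- function(Y, X, col) {
  n <- nrow(X); p <- ncol(X)
  XtXi <- tryCatch(solve(crossprod(X)), error = function(e) {
    qrX <- qr(X)
    bad <- colnames(X)[-seq_len(qrX$rank)]
    stop("rank-deficient design; collinear columns: ",
         paste(if (length(bad)) bad else "(unnamed)", collapse = ", "))
  })
  H <- X %*% XtXi                       # n x p
  B <- Y %*% H                          # V x p coefficients
  R <- Y - B %*% t(X)
  df <- n - p
  sigma2 <- rowSums(R^2) / df
  se <- sqrt(sigma2 * XtXi[col, col])
  t <- B[, col] / se
  t[se == 0] <- 0
  list(beta = B[, col], t = t, df = df)
}

new_stat_map <- function(stat, kind, df, contrast, mask, geometry,
                         tstat = NULL, threshold = NA_real_) {
  structure(list(stat = stat, tstat = tstat, kind = kind, df = df,
                 contrast = contrast, mask = mask, geometry = geometry,
                 threshold = threshold),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  v <- x$stat[x$mask]
  cat(sprintf("stat_map (%s, df=%d): %s; range [%.3g, %.3g] over %d voxels\n",
              x$kind, x$df, x$contrast, min(v), max(v), sum(x$mask)))
  invisible(x)
}

#' Voxel-wise two-sample group contrast controlling for age
#'
#' Fits `y = b0 + b1 * group + b2 * age` per voxel by least squares and
#' returns the T statistic for the group term with `df = n - 3`. The group
#' regressor codes reference = 1, patient = 0, so positive T means
#' reference > patient. Age is mean-centred (stabilises the intercept; the
#' T statistic is unchanged).
#'
#' @param maps_list named list of `parameter_maps` on a common grid.
#' @param design data.frame with one row per subject: columns `id`, `group`
#'   ("reference"/"patient"), `age`. Order must match `maps_list`.
#' @param param which map to analyse: "R1", "R2" or "PD".
#' @return A `stat_map` (kind "t").
#' @export
glm_group_contrast <- function(maps_list, design, param = "R1") {
  stopifnot(length(maps_list) == nrow(design),
            all(design$group %in% c("reference", "patient")))
  if (min(table(design$group)) < 2)
    stop("need at least 2 subjects per group")
  cm <- cohort_param_matrix(maps_list, param)
  X <- cbind(intercept = 1,
             group = as.numeric(design$group == "reference"),
             age = design$age - mean(design$age))
  fit <- glm_tmap(cm$Y, X, col = 2L)
  sh <- cm$geometry$shape
  tarr <- array(fit$t, sh); tarr[!cm$mask] <- 0
  new_stat_map(tarr, "t", fit$df,
               sprintf("%s: reference > patient (age-adjusted)", param),
               array(cm$mask, sh), cm$geometry)
}

#' Voxel-wise EDSS slope map with age as nuisance
#'
#' For the patient group only, fits `y = b0 + b1 * EDSS + b2 * age` per
#' voxel and returns the EDSS slope `b1` (units per EDSS point: 1/s for
#' R1/R2, % for PD) together with its T statistic (df = n - 3).
#'
#' @param maps_list list of patient `parameter_maps` on a common grid.
#' @param design data.frame with columns `id`, `edss`, `age` (one row per
#'   subject, same order).
#' @param param which map to analyse.
#' @return A `stat_map` (kind "slope") whose `stat` is the slope and
#'   `tstat` its T map.
#' @export
edss_slope_map <- function(maps_list, design, param = "R1") {
  stopifnot(length(maps_list) == nrow(design))
  if (any(is.na(design$edss)))
    stop("every included subject must have an EDSS score")
  if (stats::var(design$edss) == 0)
    stop("EDSS is constant across subjects; the slope is not identifiable")
  cm <- cohort_param_matrix(maps_list, param)
  X <- cbind(intercept = 1, edss = design$edss,
             age = design$age - mean(design$age))
  fit <- glm_tmap(cm$Y, X, col = 2L)
  sh <- cm$geometry$shape
  sarr <- array(fit$beta, sh); sarr[!cm$mask] <- 0
  tarr <- array(fit$t, sh); tarr[!cm$mask] <- 0
  new_stat_map(sarr, "slope", fit$df,
               sprintf("%s ~ EDSS (age-adjusted)", param),
               array(cm$mask, sh), cm$geometry, tstat = tarr)
}

#' Threshold a T map into a binary overlay
#'
#' Retains voxels with T strictly greater than `t_min` (one-sided, the
#' display convention for difference overlays) or `|T| > t_min`
#' (two-sided).
#'
#' @param map a `stat_map` with T statistics.
#' @param t_min threshold (default 2).
#' @param sided "one" or "two".
#' @return logical array (the overlay).
#' @export
threshold_map <- function(map, t_min = 2, sided = c("one", "two")) {
  sided <- match.arg(sided)
  tval <- if (map$kind == "t") map$stat else map$tstat
  if (is.null(tval)) stop("map carries no T statistics")
  ov <- if (sided == "one") tval > t_min else abs(tval) > t_min
  ov & map$mask
}

# all n-choose-k index subsets (exhaustive permutation support)
all_group_assignments <- function(n, k) {
  utils::combn(n, k, simplify = FALSE)
}

#' Permutation max-T small-volume FWE-corrected ROI inference
#'
#' For each region of interest, computes the observed maximum T of the
#' group contrast ([glm_group_contrast()]) and its family-wise-error
#' corrected p value from the permutation distribution of the max T under
#' relabelling of the group assignments (age travels with its subject, so
#' the nuisance structure is preserved). If the number of distinct
#' assignments does not exceed `n_perm`, the enumeration is exhaustive.
#' A Bonferroni factor equal to the number of ROIs is applied on top of the
#' within-ROI max-T correction.
#'
#' @param maps_list list of `parameter_maps` (all subjects, common grid).
#' @param design data.frame with `id`, `group`, `age`.
#' @param roi_set named list of logical arrays on the common grid.
#' @param param which map to analyse.
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed for the permutation draw.
#' @param alternative "greater" tests reference > patient (e.g. R1, R2
#'   lower in patients); "less" tests patient > reference (e.g. PD higher
#'   in patients); "two.sided" uses |T|.
#' @return data.frame: roi, n_voxels, max_t, p_fwe (max-T corrected),
#'   p_fwe_bonf (additionally Bonferroni-corrected across ROIs), n_perm,
#'   exhaustive, seed.
#' @export
permutation_fwe_svc <- function(maps_list, design, roi_set, param = "R1",
                                n_perm = 500L, seed = 1L,
                                alternative = c("greater", "less",
                                                "two.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(n_perm >= 100)
  cm <- cohort_param_matrix(maps_list, param)
  sh <- cm$geometry$shape
  roi_idx <- lapply(roi_set, function(m) {
    stopifnot(identical(dim(m), sh))
    which(as.vector(m) & cm$mask)
  })
  vox <- sort(unique(unlist(roi_idx)))
  if (!length(vox)) stop("no ROI voxels inside the analysis mask")
  roi_local <- lapply(roi_idx, function(ix) match(ix, vox))
  Y <- cm$Y[vox, , drop = FALSE]
  n <- nrow(design)
  ref <- design$group == "reference"
  k <- sum(ref)
  age_c <- design$age - mean(design$age)

  score <- function(tv) switch(alternative, greater = tv, less = -tv,
                               two.sided = abs(tv))
  # fast T map via RSS = y'y - b'X'Xb (design changes per permutation,
  # Y and rowSums(Y^2) are fixed)
  Ysq <- rowSums(Y^2)
  df <- n - 3L
  tmap_for <- function(ref_idx) {
    g <- as.numeric(seq_len(n) %in% ref_idx)
    X <- cbind(1, g, age_c)
    XtX <- crossprod(X)
    XtXi <- solve(XtX)
    B <- Y %*% (X %*% XtXi)
    quad <- rowSums((B %*% XtX) * B)
    sigma2 <- pmax(Ysq - quad, 0) / df
    se <- sqrt(sigma2 * XtXi[2, 2])
    tv <- B[, 2] / se
    tv[se == 0] <- 0
    score(tv)
  }
  obs <- tmap_for(which(ref))
  obs_max <- vapply(roi_local, function(ix) max(obs[ix]), numeric(1))

  n_total <- choose(n, k)
  exhaustive <- is.finite(n_total) && n_total <= n_perm
  set.seed(as.integer(seed) %% .Machine$integer.max)
  assigns <- if (exhaustive) {
    all_group_assignments(n, k)
  } else {
    c(list(which(ref)),
      replicate(n_perm - 1L, sample.int(n, k), simplify = FALSE))
  }
  nP <- length(assigns)
  perm_max <- matrix(0, nP, length(roi_local))
  for (p_i in seq_len(nP)) {
    tv <- tmap_for(assigns[[p_i]])
    perm_max[p_i, ] <- vapply(roi_local, function(ix) max(tv[ix]),
                              numeric(1))
  }
  p_fwe <- vapply(seq_along(roi_local), function(r)
    mean(perm_max[, r] >= obs_max[r] - 1e-12), numeric(1))
  data.frame(roi = names(roi_set),
             n_voxels = lengths(roi_local),
             max_t = obs_max,
             p_fwe = p_fwe,
             p_fwe_bonf = pmin(1, p_fwe * length(roi_local)),
             n_perm = nP,
             exhaustive = exhaustive,
             seed = as.integer(seed),
             row.names = NULL)
}

#' Regression of disability slopes on group-difference T values
#'
#' Ordinary least squares of the EDSS slope-map values on the group T-map
#' values across all in-mask voxels (significant or not), quantifying how
#' much of the group-difference pattern is mirrored by the
#' disability-correlation pattern.
#'
#' @param t_map a `stat_map` from [glm_group_contrast()].
#' @param slope_map a `stat_map` from [edss_slope_map()].
#' @param mask optional logical array restricting the voxels (defaults to
#'   the intersection of the two map masks).
#' @return list: `slope`, `intercept`, `r_squared`, `n_voxels`.
#' @export
map_regression <- function(t_map, slope_map, mask = NULL) {
  stopifnot(geom_equal(t_map$geometry, slope_map$geometry))
  if (is.null(mask)) mask <- t_map$mask & slope_map$mask
  if (!any(mask)) stop("empty mask")
  x <- t_map$stat[mask]
  y <- slope_map$stat[mask]
  fit <- stats::lm.fit(cbind(1, x), y)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  list(slope = unname(fit$coefficients[2]),
       intercept = unname(fit$coefficients[1]),
       r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
       n_voxels = sum(mask))
}
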
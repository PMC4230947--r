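#' Digital brain phantom specification
#'
#' Collects every parameter of the synthetic cohort generator: grid, tissue
#' parameter distributions, lesion model, diffuse normal-appearing white
#' matter (NAWM) shifts for the patient group, ventricular atrophy,
#' acquisition noise and per-subject misalignment.
#'
#' Tissue means are quantitative-MRI literature values for white matter
#' (WM), cortical grey matter (GM) and cerebrospinal fluid (CSF):
#' WM (1.20 s^-1, 11.1 s^-1, 74 %), GM (1.02, 10.0, 75), and pure-CSF-like
#' values (0.25, 1.5, 100). The default diffuse patient shift in NAWM is
#' (-0.13 s^-1, -0.9 s^-1, +3 %), i.e. lower R1 and R2 and higher PD.
#' `within_sd` is per-voxel texture; `between_sd` is the subject-to-subject
#' spread of class means.
#'
#' @param grid_shape voxels per axis (default 64 x 64 x 48).
#' @param voxel_size mm, isotropic scalar or length 3 (default 2 mm).
#' @param tissue_params named list (WM, GM, CSF), each a list with `mean`,
#'   `between_sd`, `within_sd`, numeric length-3 vectors in (R1, R2, PD)
#'   order.
#' @param lesion_model list: `count_lambda` (Poisson mean per patient),
#'   `radius_range` mm, `periventricular_prob`, `severity` in \[0,1\]
#'   (interpolation towards CSF values inside lesions).
#' @param diffuse_delta length-3 additive NAWM shift for patients
#'   (dR1, dR2, dPD).
#' @param gm_delta length-3 additive grey-matter shift for patients,
#'   emulating the diffuse cortical/deep-GM involvement seen alongside the
#'   white-matter change.
#' @param atrophy_factor ventricular volume multiplier for patients (>= 1).
#' @param noise_sigma acquisition noise SD as a fraction of the maximum
#'   noiseless signal (used by the signal simulator).
#' @param misalignment list: `max_translation` mm, `max_rotation` deg,
#'   `max_scale` (fractional), for per-subject affine jitter.
#' @param edss_model list: `mean`, `sd`, `range`, and `reference` (the EDSS
#'   value at which frontal-WM diffuse change equals `diffuse_delta`; the
#'   frontal shift scales linearly as EDSS / reference).
#' @param age_model list: `mean`, `sd`, `range` (years) and
#'   `match_tolerance` (max per-pair group age jitter, years).
#' @param clip_floor lower clip for sampled R1/R2 (s^-1).
#' @param seed default integer seed used when none is passed explicitly.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64, 64, 48),
                         voxel_size = 2,
                         tissue_params = list(
                           WM  = list(mean = c(1.20, 11.1, 74),
                                      between_sd = c(0.08, 0.5, 2.0),
                                      within_sd = c(0.15, 1.2, 5)),
                           GM  = list(mean = c(1.02, 10.0, 75),
                                      between_sd = c(0.08, 0.5, 2.0),
                                      within_sd = c(0.20, 1.5, 7)),
                           CSF = list(mean = c(0.25, 1.5, 100),
                                      between_sd = c(0.03, 0.2, 1.0),
                                      within_sd = c(0.15, 1.0, 4))),
                         lesion_model = list(count_lambda = 6,
                                             radius_range = c(2.5, 5),
                                             periventricular_prob = 0.8,
                                             severity = 0.5),
                         diffuse_delta = c(-0.13, -0.9, 3),
                         gm_delta = c(-0.10, -0.9, 2),
                         atrophy_factor = 2.5,
                         noise_sigma = 0.02,
                         misalignment = list(max_translation = 4,
                                             max_rotation = 3,
                                             max_scale = 0.02),
                         edss_model = list(mean = 3.7, sd = 1.8,
                                           range = c(1, 8.5),
                                           reference = 3.7),
                         age_model = list(mean = 47.7, sd = 11.9,
                                          range = c(20, 75),
                                          match_tolerance = 2),
                         clip_floor = 0.01,
                         seed = 1L) {
  if (length(voxel_size) == 1) voxel_size <- rep(voxel_size, 3)
  spec <- structure(list(grid_shape = as.integer(grid_shape),
                         voxel_size = voxel_size,
                         tissue_params = tissue_params,
                         lesion_model = lesion_model,
                         diffuse_delta = diffuse_delta,
                         gm_delta = gm_delta,
                         atrophy_factor = atrophy_factor,
                         noise_sigma = noise_sigma,
                         misalignment = misalignment,
                         edss_model = edss_model,
                         age_model = age_model,
                         clip_floor = clip_floor,
                         seed = as.integer(seed)),
                    class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  for (cls in c("WM", "GM", "CSF")) {
    tp <- spec$tissue_params[[cls]]
    if (is.null(tp)) stop("tissue_params must define ", cls)
    if (any(tp$between_sd < 0) || any(tp$within_sd < 0))
      stop("all SDs must be >= 0")
    if (tp$mean[3] <= 0 || tp$mean[3] > 110)
      stop("PD means must lie in (0, 110]")
    if (tp$mean[1] <= 0 || tp$mean[2] <= 0)
      stop("R1 and R2 means must be > 0")
  }
  if (spec$atrophy_factor < 1) stop("atrophy_factor must be >= 1")
  if (any(spec$lesion_model$radius_range <= 0))
    stop("lesion radii must be > 0")
  if (any(spec$grid_shape < 16))
    stop("grid_shape must be at least 16 voxels per axis")
  invisible(spec)
}

# Ellipsoid "radial coordinate": rho = 1 on the surface, < 1 inside.
ellipsoid_rho <- function(coords, centre, semi) {
  sqrt(((coords[, 1] - centre[1]) / semi[1])^2 +
       ((coords[, 2] - centre[2]) / semi[2])^2 +
       ((coords[, 3] - centre[3]) / semi[3])^2)
}

# |gradient| of rho, for converting a voxel extent into rho units.
ellipsoid_rho_grad <- function(coords, centre, semi, rho) {
  g <- sqrt(((coords[, 1] - centre[1]) / semi[1]^2)^2 +
            ((coords[, 2] - centre[2]) / semi[2]^2)^2 +
            ((coords[, 3] - centre[3]) / semi[3]^2)^2)
  g / pmax(rho, 1e-9)
}

# Soft in/out fraction from a rho field: linear ramp of one voxel width
# across the rho = s iso-surface (approximate partial volume).
rho_fraction <- function(rho, grad, s, voxel_mm) {
  w <- pmax(voxel_mm * grad, 1e-9)
  pmin(1, pmax(0, (s - rho) / w + 0.5))
}

# Anatomy constants (world mm, volume centred at the origin):
# brain/ICV ellipsoids, two lateral ventricles, deep GM nuclei.
phantom_anatomy <- function(spec) {
  list(icv_semi   = c(48, 59, 42),
       brain_semi = c(46, 57, 40),
       cortex_depth = 8,                 # cortical band thickness, mm
       vent_centres = list(c(-10, 6, 2), c(10, 6, 2)),
       vent_semi  = c(5, 16, 7),
       deep_centres = list(c(-16, -14, 0), c(16, -14, 0)),
       deep_semi  = c(7, 9, 7),
       cc_box = list(x = c(-12, 12), y = c(-8, 20), z = c(10, 18)),
       periventricular_mm = 6,
       frontal_y = 12)
}

#' Build the ground-truth template of the digital brain phantom
#'
#' Constructs per-voxel tissue fractions (WM, GM, CSF, background) for a
#' simplified brain: an intracranial ellipsoid with a subarachnoid CSF rim,
#' a cortical GM band, deep GM nuclei, two lateral ventricles and WM filling
#' the remainder. Partial volume at structure interfaces comes from 2x
#' supersampling (ventricles use an analytic ramp so their size can be
#' re-scaled per subject). Also returns named ROI masks (ventricles,
#' periventricular WM, corpus-callosum-like slab, deep GM nucleus, cortical
#' band, whole WM, frontal WM) and the ventricular radial field used for
#' atrophy re-scaling.
#'
#' @param spec a [phantom_spec()].
#' @param atrophy_factor ventricular volume multiplier for the template's
#'   own ventricles (defaults to `spec$atrophy_factor`; [generate_cohort()]
#'   builds its shared template at 1, the reference anatomy, and dilates
#'   per patient instead).
#' @return Object of class `phantom_template`: `fractions` (4-D array,
#'   classes WM/GM/CSF/BG), `rois` (list of logical arrays), `vent_rho`,
#'   `vent_grad` (3-D arrays), `geometry`.
#' @export
build_template <- function(spec = phantom_spec(),
                           atrophy_factor = spec$atrophy_factor) {
  validate_phantom_spec(spec)
  an <- phantom_anatomy(spec)
  geom <- qmri_geometry(spec$grid_shape, spec$voxel_size)
  sh <- geom$shape
  # margin check: ICV plus 2 voxels of background must fit
  fov_half <- (sh - 1) * geom$voxdim / 2
  if (any(an$icv_semi + 2 * geom$voxdim > fov_half + geom$voxdim / 2))
    stop("grid too small to contain the phantom anatomy with a background margin")

  # --- hard labels on a 2x supersampled grid (ventricles excluded here)
  ss <- qmri_geometry(sh * 2L, geom$voxdim / 2,
                      origin = geom$origin - geom$voxdim / 4)
  co <- grid_world_coords(ss)
  rho_icv <- ellipsoid_rho(co, c(0, 0, 0), an$icv_semi)
  rho_brain <- ellipsoid_rho(co, c(0, 0, 0), an$brain_semi)
  rho_cortex_in <- ellipsoid_rho(co, c(0, 0, 0), an$brain_semi - an$cortex_depth)
  lab <- integer(nrow(co))                 # 0 bg, 1 WM, 2 GM, 3 CSF
  lab[rho_icv <= 1] <- 3L                  # CSF rim (brain carved out next)
  lab[rho_brain <= 1] <- 2L                # cortical band ...
  lab[rho_cortex_in <= 1] <- 1L            # ... interior is WM
  for (dc in an$deep_centres)
    lab[lab == 1L & ellipsoid_rho(co, dc, an$deep_semi) <= 1] <- 2L
  ssh <- ss$shape
  frac <- vapply(1:3, function(cl) {
    a <- array(as.numeric(lab == cl), ssh)
    downsample_mean(a, ss, 2L)$arr
  }, array(0, sh))                         # sh x 3 classes (WM, GM, CSF)
  dim(frac) <- c(sh, 3)

  # --- ventricles: analytic rho field on the analysis grid
  co1 <- grid_world_coords(geom)
  rho_v <- rep(Inf, nrow(co1)); grad_v <- rep(1, nrow(co1))
  for (vc in an$vent_centres) {
    r <- ellipsoid_rho(co1, vc, an$vent_semi)
    g <- ellipsoid_rho_grad(co1, vc, an$vent_semi, r)
    upd <- r < rho_v
    rho_v[upd] <- r[upd]; grad_v[upd] <- g[upd]
  }
  vent_rho <- array(rho_v, sh); vent_grad <- array(grad_v, sh)
  stopifnot(atrophy_factor >= 1)
  s_vent <- atrophy_factor^(1 / 3)
  vf <- array(rho_fraction(rho_v, grad_v, s_vent, mean(geom$voxdim)), sh)

  fractions <- array(0, c(sh, 4))
  rem <- 1 - vf
  for (cl in 1:3) fractions[, , , cl] <- frac[, , , cl] * rem
  fractions[, , , 3] <- fractions[, , , 3] + vf       # ventricular CSF
  fractions[, , , 4] <- pmax(0, 1 - fractions[, , , 1] -
                               fractions[, , , 2] - fractions[, , , 3])

  # --- ROI masks on the analysis grid
  wm_mask <- array(fractions[, , , 1] >= 0.5, sh)
  gm_mask <- array(fractions[, , , 2] >= 0.5, sh)
  vent_mask <- vf >= 0.5
  dist_to_vent <- distance_from_surface(!vent_mask, geom$voxdim)
  perivent <- wm_mask & dist_to_vent > 0 &
    dist_to_vent <= an$periventricular_mm
  cc <- array(co1[, 1] >= an$cc_box$x[1] & co1[, 1] <= an$cc_box$x[2] &
              co1[, 2] >= an$cc_box$y[1] & co1[, 2] <= an$cc_box$y[2] &
              co1[, 3] >= an$cc_box$z[1] & co1[, 3] <= an$cc_box$z[2], sh) &
    wm_mask
  deep <- array(FALSE, sh)
  for (dc in an$deep_centres)
    deep <- deep | array(ellipsoid_rho(co1, dc, an$deep_semi) <= 0.9, sh)
  deep <- deep & gm_mask
  frontal <- wm_mask & array(co1[, 2] > an$frontal_y, sh)
  rois <- list(ventricles = vent_mask,
               periventricular_wm = perivent,
               corpus_callosum = cc,
               deep_gm = deep,
               cortical_gm = gm_mask & !deep,
               white_matter = wm_mask,
               frontal_wm = frontal)
  structure(list(fractions = fractions, rois = rois,
                 vent_rho = vent_rho, vent_grad = vent_grad,
                 vent_scale = s_vent, geometry = geom, spec = spec),
            class = "phantom_template")
}

#' @export
print.phantom_template <- function(x, ...) {
  cat("phantom_template", format(x$geometry), "\n")
  cat("  ROIs:", paste(names(x$rois), collapse = ", "), "\n")
  invisible(x)
}

# Per-subject tissue fractions: re-scale ventricles by the atrophy factor
# (volume multiplier) and renormalise the displaced tissue.
subject_fractions <- function(template, atrophy_factor) {
  sh <- template$geometry$shape
  s <- atrophy_factor^(1 / 3)
  vf <- rho_fraction(as.vector(template$vent_rho),
                     as.vector(template$vent_grad), s,
                     mean(template$geometry$voxdim))
  base <- template$fractions
  base_vf <- rho_fraction(as.vector(template$vent_rho),
                          as.vector(template$vent_grad),
                          template$vent_scale,
                          mean(template$geometry$voxdim))
  out <- array(0, dim(base))
  rem_old <- pmax(1e-12, 1 - base_vf)
  rem_new <- 1 - vf
  for (cl in 1:4) {
    b <- as.vector(base[, , , cl])
    if (cl == 3) b <- b - base_vf          # non-ventricular CSF
    b <- pmax(0, b)
    out[, , , cl] <- array(b / rem_old * rem_new, sh)
  }
  out[, , , 3] <- out[, , , 3] + array(vf, sh)
  list(fractions = out, vent_mask = array(vf, sh) >= 0.5)
}

#' Sample one subject's parameter maps from the phantom
#'
#' Draws per-class subject means from the between-subject Gaussians, adds
#' per-voxel Gaussian texture, and mixes classes by the ground-truth
#' fractions. Patients additionally receive the diffuse NAWM shift (scaled
#' by EDSS / reference EDSS inside frontal-labelled WM), spherical focal
#' lesions whose parameters are interpolated towards CSF values, and
#' atrophy-dilated ventricles. Sampled R1/R2 are clipped at
#' `spec$clip_floor` and PD to \[0, 110\]; the clipping rate is returned.
#'
#' @param template a [build_template()] result.
#' @param record one-row data.frame with columns `id`, `group`
#'   ("reference"/"patient"), `age`, `edss` (NA allowed for references).
#' @param spec the [phantom_spec()].
#' @param seed integer seed for this subject.
#' @return A `parameter_maps` object with attributes `ground_truth` (list:
#'   `fractions`, `vent_mask`, `lesion_mask`, `clip_rate`).
#' @export
sample_subject_maps <- function(template, record, spec = template$spec,
                                seed = spec$seed) {
  stopifnot(record$group %in% c("reference", "patient"))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  geom <- template$geometry
  sh <- geom$shape
  nv <- prod(sh)
  is_pat <- record$group == "patient"
  sf <- subject_fractions(template,
                          if (is_pat) spec$atrophy_factor else 1)
  fr <- sf$fractions

  classes <- c("WM", "GM", "CSF")
  # per-subject class means (between-subject variation)
  submeans <- lapply(classes, function(cl) {
    tp <- spec$tissue_params[[cl]]
    tp$mean + stats::rnorm(3) * tp$between_sd
  })
  names(submeans) <- classes

  # per-voxel class value fields: subject mean + texture (+ NAWM shift)
  vals <- list()
  for (p in 1:3) {
    acc <- numeric(nv)
    for (ci in seq_along(classes)) {
      cl <- classes[ci]
      field <- rep(submeans[[cl]][p], nv)
      if (cl == "WM" && is_pat) {
        delta <- spec$diffuse_delta[p]
        scalef <- rep(1, nv)
        if (!is.na(record$edss) && spec$edss_model$reference > 0)
          scalef[as.vector(template$rois$frontal_wm)] <-
            record$edss / spec$edss_model$reference
        field <- field + delta * scalef
      }
      if (cl == "GM" && is_pat)
        field <- field + spec$gm_delta[p]
      acc <- acc + as.vector(fr[, , , ci]) * field
    }
    vals[[p]] <- acc
  }

  # voxel texture: fraction-weighted class SDs (independent across params)
  for (p in 1:3) {
    sdmix <- numeric(nv)
    for (ci in seq_along(classes)) {
      tp <- spec$tissue_params[[classes[ci]]]
      sdmix <- sdmix + as.vector(fr[, , , ci]) * tp$within_sd[p]
    }
    vals[[p]] <- vals[[p]] + stats::rnorm(nv) * sdmix
  }

  # focal lesions (patients): spheres, parameters pulled towards CSF
  lesion_mask <- array(FALSE, sh)
  if (is_pat && spec$lesion_model$count_lambda > 0) {
    nles <- stats::rpois(1, spec$lesion_model$count_lambda)
    if (nles > 0) {
      co <- grid_world_coords(geom)
      peri_idx <- which(as.vector(template$rois$periventricular_wm))
      wm_idx <- which(as.vector(template$rois$white_matter))
      sev <- spec$lesion_model$severity
      csfm <- submeans$CSF
      for (l in seq_len(nles)) {
        pool <- if (stats::runif(1) < spec$lesion_model$periventricular_prob &&
                    length(peri_idx) > 0) peri_idx else wm_idx
        ctr <- co[pool[sample.int(length(pool), 1)], ]
        rad <- stats::runif(1, spec$lesion_model$radius_range[1],
                            spec$lesion_model$radius_range[2])
        d2 <- (co[, 1] - ctr[1])^2 + (co[, 2] - ctr[2])^2 +
          (co[, 3] - ctr[3])^2
        inles <- d2 <= rad^2
        lesion_mask[inles] <- TRUE
        for (p in 1:3)
          vals[[p]][inles] <- (1 - sev) * vals[[p]][inles] + sev * csfm[p]
      }
    }
  }

  # physical clipping
  nclip <- sum(vals[[1]] < spec$clip_floor & as.vector(fr[, , , 4]) < 0.5) +
    sum(vals[[2]] < spec$clip_floor & as.vector(fr[, , , 4]) < 0.5) +
    sum((vals[[3]] < 0 | vals[[3]] > 110) & as.vector(fr[, , , 4]) < 0.5)
  vals[[1]] <- pmax(vals[[1]], spec$clip_floor)
  vals[[2]] <- pmax(vals[[2]], spec$clip_floor)
  vals[[3]] <- pmin(pmax(vals[[3]], 0), 110)

  # background: zero signal
  bg <- as.vector(fr[, , , 4]) >= 0.999
  vals[[1]][bg] <- spec$clip_floor; vals[[2]][bg] <- spec$clip_floor
  vals[[3]][bg] <- 0

  maps <- parameter_maps(array(vals[[1]], sh), array(vals[[2]], sh),
                         array(vals[[3]], sh), geom,
                         mask = array(!bg, sh))
  attr(maps, "ground_truth") <- list(
    fractions = fr, vent_mask = sf$vent_mask, lesion_mask = lesion_mask,
    clip_rate = nclip / (3 * sum(!bg)), class_means = submeans)
  maps
}

#' Generate a synthetic two-group cohort
#'
#' Builds the template once, samples subject records (age-matched groups;
#' EDSS for patients on the 0.5-step scale) and per-subject parameter maps,
#' and applies a random small affine misalignment to each subject to create
#' "native-space" maps for the registration stage. All randomness flows
#' from `seed`.
#'
#' @param spec a [phantom_spec()].
#' @param n_ref,n_pat group sizes (each >= 1 allowed to be 0 for the other).
#' @param seed integer master seed.
#' @param misalign logical; apply per-subject affine jitter (default TRUE).
#' @return Object of class `phantom_cohort`: `subjects` (data.frame id,
#'   group, age, edss, msss), `maps` (list of native `parameter_maps`),
#'   `template_maps` (pre-jitter maps), `true_transforms` (list of
#'   `affine_transform`), `ground_truth` (per subject), `template`, `spec`.
#' @export
generate_cohort <- function(spec = phantom_spec(), n_ref = 19, n_pat = 19,
                            seed = spec$seed, misalign = TRUE) {
  stopifnot(n_ref >= 0, n_pat >= 0, n_ref + n_pat >= 1)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  template <- build_template(spec, atrophy_factor = 1)
  am <- spec$age_model
  n <- n_ref + n_pat
  base_age <- pmin(pmax(stats::rnorm(max(n_ref, n_pat), am$mean, am$sd),
                        am$range[1]), am$range[2])
  age_ref <- base_age[seq_len(n_ref)] +
    stats::runif(n_ref, -am$match_tolerance, am$match_tolerance)
  age_pat <- base_age[seq_len(n_pat)]
  em <- spec$edss_model
  edss <- pmin(pmax(round(stats::rnorm(n_pat, em$mean, em$sd) * 2) / 2,
                    em$range[1]), em$range[2])
  msss <- if (n_pat > 0)
    pmin(pmax(edss + stats::rnorm(n_pat, 0.5, 0.8), 0.5), 9.6)
  else numeric(0)
  subjects <- data.frame(
    id = c(sprintf("ref%02d", seq_len(n_ref)),
           sprintf("pat%02d", seq_len(n_pat))),
    group = c(rep("reference", n_ref), rep("patient", n_pat)),
    age = c(age_ref, age_pat),
    edss = c(rep(NA_real_, n_ref), edss),
    msss = c(rep(NA_real_, n_ref), msss),
    stringsAsFactors = FALSE)

  subj_seeds <- sample.int(2^30, n)
  mis <- spec$misalignment
  jitters <- lapply(seq_len(n), function(i) {
    if (!misalign) return(affine_transform())
    affine_transform(
      translation = stats::runif(3, -mis$max_translation, mis$max_translation),
      rotation = stats::runif(3, -mis$max_rotation, mis$max_rotation),
      scale = 1 + stats::runif(3, -mis$max_scale, mis$max_scale))
  })

  template_maps <- vector("list", n)
  native_maps <- vector("list", n)
  gts <- vector("list", n)
  for (i in seq_len(n)) {
    m <- sample_subject_maps(template, subjects[i, ], spec, subj_seeds[i])
    gts[[i]] <- attr(m, "ground_truth")
    template_maps[[i]] <- m
    native_maps[[i]] <- if (misalign)
      apply_and_regrid(m, invert_transform(jitters[[i]]), m$geometry)
    else m
  }
  names(template_maps) <- names(native_maps) <- names(gts) <- subjects$id
  structure(list(subjects = subjects, maps = native_maps,
                 template_maps = template_maps,
                 true_transforms = stats::setNames(jitters, subjects$id),
                 ground_truth = gts, template = template, spec = spec,
                 seed = as.integer(seed)),
            class = "phantom_cohort")
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat(sprintf("phantom_cohort: %d reference + %d patient subjects, %s\n",
              sum(x$subjects$group == "reference"),
              sum(x$subjects$group == "patient"),
              format(x$template$geometry)))
  invisible(x)
}
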
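#' Pipeline run configuration
#'
#' Collects every stage parameter of the end-to-end analysis. Numeric
#' defaults are the study-protocol values: the 4 x 5 timing grid with TR
#' 2950 ms, 8 mm smoothing before affine normalization, a 2 mm isotropic
#' target grid, display threshold T = 2, 200 whole-brain / 50 ROI histogram
#' bins, a 10 % signal inclusion threshold and 2 mm erosion steps.
#'
#' @param spec a [phantom_spec()] describing the simulated cohort.
#' @param n_ref,n_pat group sizes (default 19 + 19).
#' @param seed master seed; all stage seeds derive from it.
#' @param protocol an [acq_protocol()].
#' @param fwhm smoothing kernel FWHM (mm) for the registration sources.
#' @param target_res normalized grid resolution (mm, isotropic).
#' @param t_threshold display threshold for T overlays.
#' @param bins_wholebrain,bins_roi histogram bins.
#' @param threshold_frac histogram inclusion threshold (fraction of max).
#' @param erosion_levels ROI erosion levels, mm.
#' @param n_perm permutations for the FWE small-volume correction.
#' @param stages stages to run, in dependency order; any of "simulate",
#'   "fit", "segment", "normalize", "stats", "hist", "roi".
#' @param outdir optional output directory for [write_outputs()].
#' @return list of class `run_config`.
#' @export
run_config <- function(spec = phantom_spec(),
                       n_ref = 19, n_pat = 19,
                       seed = 1L,
                       protocol = acq_protocol(),
                       fwhm = 8,
                       target_res = 2,
                       t_threshold = 2,
                       bins_wholebrain = 200L,
                       bins_roi = 50L,
                       threshold_frac = 0.10,
                       erosion_levels = c(0, 2, 4, 6, 8),
                       n_perm = 500L,
                       stages = c("simulate", "fit", "segment", "normalize",
                                  "stats", "hist", "roi"),
                       outdir = NULL) {
  structure(list(spec = spec, n_ref = n_ref, n_pat = n_pat,
                 seed = as.integer(seed), protocol = protocol, fwhm = fwhm,
                 target_res = target_res, t_threshold = t_threshold,
                 bins_wholebrain = as.integer(bins_wholebrain),
                 bins_roi = as.integer(bins_roi),
                 threshold_frac = threshold_frac,
                 erosion_levels = erosion_levels,
                 n_perm = as.integer(n_perm),
                 stages = stages, outdir = outdir),
            class = "run_config")
}

# Noiseless template-space reference maps: class means mixed by the
# template fractions (the registration target).
template_reference_maps <- function(template, spec = template$spec) {
  fr <- template$fractions
  sh <- template$geometry$shape
  mk <- function(p) {
    acc <- array(0, sh)
    for (ci in seq_along(c("WM", "GM", "CSF"))) {
      cl <- c("WM", "GM", "CSF")[ci]
      acc <- acc + fr[, , , ci] * spec$tissue_params[[cl]]$mean[p]
    }
    acc
  }
  bg <- fr[, , , 4] >= 0.999
  r1 <- mk(1); r2 <- mk(2); pd <- mk(3)
  r1[bg] <- spec$clip_floor; r2[bg] <- spec$clip_floor; pd[bg] <- 0
  parameter_maps(r1, r2, pd, template$geometry, mask = !bg)
}

#' Run the voxel-based qMRI analysis pipeline
#'
#' Executes the requested stages in order: simulate (phantom cohort with
#' misalignment), fit (signal simulation at the protocol's timing grid and
#' per-voxel R1/R2/PD estimation), segment (partial-volume tissue
#' classification and volumetry), normalize (smoothed synthetic-T2
#' affine registration to the template and re-gridding), stats (voxel-wise
#' group T maps, EDSS slope maps and their map-on-map regression), hist
#' (whole-brain and ROI signed difference histograms), roi (erosion
#' summaries, mixed-model group tests and permutation FWE small-volume
#' correction). Later stages error if their inputs were not produced.
#'
#' @param config a [run_config()].
#' @param verbose print stage progress.
#' @return A `pipeline_report` list; see the individual stage functions for
#'   the component formats. Includes a `qc` list (fit fallback counts,
#'   clipping rates, registration Dice, seeds).
#' @export
run_pipeline <- function(config = run_config(), verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  st <- config$stages
  need <- function(dep, what, stage) {
    if (is.null(what))
      stop(sprintf("stage '%s' needs outputs of stage '%s'; run it first",
                   stage, dep))
    what
  }
  rep_ <- list(config = config)
  cohort <- NULL; fitted <- NULL; segs <- NULL; normalized <- NULL

  if ("simulate" %in% st) {
    say("simulate: %d + %d subjects on %s grid", config$n_ref, config$n_pat,
        paste(config$spec$grid_shape, collapse = "x"))
    cohort <- generate_cohort(config$spec, config$n_ref, config$n_pat,
                              seed = config$seed)
    rep_$cohort <- cohort
  }

  if ("fit" %in% st) {
    cohort <- need("simulate", cohort, "fit")
    say("fit: %d subjects x %d images", nrow(cohort$subjects),
        length(config$protocol$saturation_delays) *
          length(config$protocol$echo_times))
    set.seed(config$seed + 1L)
    stack_seeds <- sample.int(2^30, nrow(cohort$subjects))
    fitted <- list(); fit_qc <- list()
    for (i in seq_len(nrow(cohort$subjects))) {
      id <- cohort$subjects$id[i]
      stack <- simulate_signal_stack(cohort$maps[[id]], config$protocol,
                                     noise_sigma = config$spec$noise_sigma,
                                     seed = stack_seeds[i])
      # pure-CSF reference for the PD % calibration: the subject's own
      # ventricle mask carried into native space and eroded by one shell,
      # so partial-volume voxels do not deflate the reference
      vent_native <- native_mask(cohort, id, "vent")
      csf_ref <- erode_roi(vent_native, 2,
                           cohort$maps[[id]]$geometry$voxdim)
      if (!any(csf_ref)) csf_ref <- vent_native
      f <- fit_parameter_maps(stack, csf_mask = csf_ref)
      fitted[[id]] <- f
      fit_qc[[id]] <- attr(f, "qc")
    }
    rep_$fitted <- fitted
    rep_$fit_qc <- fit_qc
  }

  if ("segment" %in% st) {
    fitted <- need("fit", fitted, "segment")
    say("segment: %d subjects", length(fitted))
    segs <- list(); volrows <- list()
    for (id in names(fitted)) {
      seg <- classify_tissue(fitted[[id]])
      vr <- compute_volumes(seg, native_mask(cohort, id, "vent"))
      segs[[id]] <- seg
      volrows[[id]] <- data.frame(
        id = id,
        group = cohort$subjects$group[cohort$subjects$id == id],
        icv_ml = vr$intracranial_volume, brain_ml = vr$brain_volume,
        ventricles_ml = vr$ventricular_volume,
        bpf_pct = vr$brain_parenchymal_fraction,
        vf_pct = vr$ventricular_fraction)
    }
    rep_$segmentations <- segs
    rep_$volumes <- do.call(rbind, c(volrows, list(make.row.names = FALSE)))
  }

  if ("normalize" %in% st) {
    fitted <- need("fit", fitted, "normalize")
    say("normalize: affine registration to template (fwhm %g mm)",
        config$fwhm)
    template <- cohort$template
    tg <- template$geometry
    target <- qmri_geometry(tg$shape, rep(config$target_res, 3))
    ref_maps <- template_reference_maps(template)
    # mean-normalise the contrast images: the squared-difference cost is
    # not invariant to the per-subject PD calibration scale
    norm_img <- function(img) img / mean(img[img > 0.05 * max(img)])
    tmpl_img <- norm_img(smooth_gaussian(synthesize_contrast_image(ref_maps),
                                         config$fwhm, tg$voxdim))
    normalized <- list(); dice <- numeric(0); transforms <- list()
    for (id in names(fitted)) {
      src_img <- norm_img(
        smooth_gaussian(synthesize_contrast_image(fitted[[id]]),
                        config$fwhm, fitted[[id]]$geometry$voxdim))
      tr <- estimate_affine(src_img, fitted[[id]]$geometry, tmpl_img, tg)
      normalized[[id]] <- apply_and_regrid(fitted[[id]], tr, target)
      transforms[[id]] <- tr
      vn <- native_mask(cohort, id, "vent")
      vw <- array(interp_nearest(vn + 0, tg,
                                 transform_points(tr$matrix,
                                                  grid_world_coords(target))),
                  target$shape) > 0.5
      dice[id] <- dice_overlap(vw, resample_mask(template$rois$ventricles,
                                                 tg, target))
    }
    rep_$normalized <- normalized
    rep_$transforms <- transforms
    rep_$registration_dice <- dice
  }

  if ("stats" %in% st) {
    normalized <- need("normalize", normalized, "stats")
    say("stats: voxel-wise GLM over %d subjects", length(normalized))
    subj <- cohort$subjects
    pat <- subj$group == "patient"
    rep_$stat_maps <- list(); rep_$overlays <- list()
    rep_$map_regression <- list()
    for (p in c("R1", "R2", "PD")) {
      tm <- glm_group_contrast(normalized, subj, p)
      rep_$stat_maps[[paste0("t_", p)]] <- tm
      rep_$overlays[[paste0("t_", p)]] <-
        threshold_map(tm, config$t_threshold)
      if (sum(pat) >= 3 && !all(is.na(subj$edss[pat]))) {
        sm <- edss_slope_map(normalized[subj$id[pat]], subj[pat, ], p)
        rep_$stat_maps[[paste0("slope_", p)]] <- sm
        rep_$map_regression[[p]] <- map_regression(tm, sm)
      }
    }
  }

  if ("hist" %in% st) {
    normalized <- need("normalize", normalized, "hist")
    say("hist: difference histograms (%d / %d bins)",
        config$bins_wholebrain, config$bins_roi)
    subj <- cohort$subjects
    ref_m <- normalized[subj$id[subj$group == "reference"]]
    pat_m <- normalized[subj$id[subj$group == "patient"]]
    rep_$histograms <- list()
    for (pr in list(c("R1", "R2"), c("R1", "PD"), c("R2", "PD"))) {
      nm <- tolower(paste0(pr[1], pr[2]))
      rep_$histograms[[nm]] <- difference_histogram(
        ref_m, pat_m, pr, bins = config$bins_wholebrain,
        threshold_frac = config$threshold_frac)
    }
    # ROI-level histogram (2 mm eroded whole-WM ROI, data-driven ranges)
    tgt_geom <- normalized[[1]]$geometry
    wm <- resample_mask(cohort$template$rois$white_matter,
                        cohort$template$geometry, tgt_geom)
    wm2 <- erode_roi(wm, 2, tgt_geom$voxdim)
    pool <- function(param) unlist(lapply(normalized, function(m)
      as.vector(m[[param]])[as.vector(wm2)]))
    rng <- list(x = stats::quantile(pool("R1"), c(0.01, 0.99), names = FALSE),
                y = stats::quantile(pool("R2"), c(0.01, 0.99), names = FALSE))
    rep_$histograms$roi_wm_r1r2 <- difference_histogram(
      ref_m, pat_m, c("R1", "R2"), bins = config$bins_roi, ranges = rng,
      inclusion_mask = wm2)
    rep_$roi_markers <- roi_markers(
      ref_m, pat_m,
      lapply(resampled_rois(cohort, tgt_geom),
             erode_roi, level = 2, voxdim = tgt_geom$voxdim),
      c("R1", "R2"))
  }

  if ("roi" %in% st) {
    normalized <- need("normalize", normalized, "roi")
    say("roi: erosion summaries, mixed models, permutation FWE (n=%d)",
        config$n_perm)
    subj <- cohort$subjects
    tgt_geom <- normalized[[1]]$geometry
    rois <- resampled_rois(cohort, tgt_geom)
    rep_$roi_summary <- roi_summary(normalized, subj$group, rois,
                                    levels = config$erosion_levels)
    mm <- list()
    for (nm in names(rois)) for (p in c("R1", "R2", "PD")) {
      r <- mixed_model_group_test(normalized, subj$group, rois[[nm]], p)
      mm[[paste(nm, p)]] <- data.frame(roi = nm, param = p,
                                       estimate = r$estimate, se = r$se,
                                       t = r$t, p_value = r$p,
                                       method = r$method,
                                       singular = r$singular)
    }
    rep_$mixed_models <- do.call(rbind, c(mm, list(make.row.names = FALSE)))
    wm_family <- rois[intersect(c("white_matter", "frontal_wm",
                                  "periventricular_wm", "corpus_callosum"),
                                names(rois))]
    svc <- list()
    for (p in c("R1", "R2", "PD")) {
      res <- permutation_fwe_svc(normalized, subj, wm_family, p,
                                 n_perm = config$n_perm,
                                 seed = config$seed + 7L,
                                 alternative = if (p == "PD") "less"
                                 else "greater")
      res$param <- p
      svc[[p]] <- res
    }
    rep_$svc <- do.call(rbind, c(svc, list(make.row.names = FALSE)))
  }

  rep_$qc <- list(
    seed = config$seed,
    fit_fallbacks = if (!is.null(rep_$fit_qc))
      sum(vapply(rep_$fit_qc, function(q) q$n_fallback, numeric(1))) else NA,
    clip_rate = if (!is.null(cohort))
      mean(vapply(cohort$ground_truth, function(g) g$clip_rate, numeric(1)))
    else NA,
    # patients' atrophy-dilated ventricles cannot overlap the reference
    # template fully under any affine, so the registration QC averages the
    # reference subjects only
    registration_dice = if (!is.null(rep_$registration_dice))
      unname(mean(rep_$registration_dice[
        cohort$subjects$group == "reference"])) else NA)
  class(rep_) <- "pipeline_report"
  if (!is.null(config$outdir)) write_outputs(rep_, config$outdir)
  rep_
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline_report; stages:", paste(x$config$stages, collapse = ", "),
      "\n")
  if (!is.na(x$qc$registration_dice))
    cat(sprintf("  mean registration Dice: %.3f\n", x$qc$registration_dice))
  if (!is.null(x$volumes)) {
    agg <- stats::aggregate(cbind(bpf_pct, vf_pct) ~ group, x$volumes, mean)
    print(agg)
  }
  invisible(x)
}

# The subject's ground-truth ventricle (or lesion) mask carried into its
# native (misaligned) space.
native_mask <- function(cohort, id, which = c("vent", "lesion")) {
  which <- match.arg(which)
  gt <- cohort$ground_truth[[id]]
  m <- if (which == "vent") gt$vent_mask else gt$lesion_mask
  jit <- cohort$true_transforms[[id]]
  geom <- cohort$template$geometry
  co <- transform_points(solve(jit$matrix), grid_world_coords(geom))
  array(interp_nearest(m + 0, geom, co), geom$shape) > 0.5
}

# Template ROI masks resampled (nearest neighbour) onto the analysis grid.
resampled_rois <- function(cohort, target_geom) {
  tg <- cohort$template$geometry
  lapply(cohort$template$rois, resample_mask, src_geom = tg,
         target_geom = target_geom)
}

resample_mask <- function(mask, src_geom, target_geom) {
  if (geom_equal(src_geom, target_geom)) return(mask)
  co <- grid_world_coords(target_geom)
  array(interp_nearest(mask + 0, src_geom, co), target_geom$shape) > 0.5
}
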
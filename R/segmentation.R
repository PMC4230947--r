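#' Tissue class ranges in (R1, R2, PD) space
#'
#' Each tissue class is characterised by a central point in parameter space
#' and an acceptance radius per parameter. A voxel lying inside exactly one
#' class's acceptance box is assigned to that class outright; intermediate
#' voxels are treated as partial-volume mixtures (see [classify_tissue()]).
#' Default centres are cropped-ROI (least partial-volume-contaminated)
#' literature values for WM, cortical GM and ventricular CSF.
#'
#' @param classes named list; each element a list with `center` and `radius`
#'   (numeric length-3, (R1 1/s, R2 1/s, PD %) order).
#' @return Object of class `tissue_class_ranges`.
#' @export
tissue_class_ranges <- function(classes = list(
  WM  = list(center = c(1.35, 11.7, 71), radius = c(0.25, 2.0, 6.0)),
  GM  = list(center = c(1.01, 10.0, 77), radius = c(0.10, 0.7, 2.5)),
  CSF = list(center = c(0.29, 3.4, 96),  radius = c(0.30, 2.5, 8.0)))) {
  stopifnot(length(classes) >= 2)
  ctrs <- t(vapply(classes, function(x) x$center, numeric(3)))
  if (anyDuplicated(ctrs)) stop("class centers must be pairwise distinct")
  for (cl in classes) {
    stopifnot(length(cl$center) == 3, length(cl$radius) == 3)
    if (any(cl$radius <= 0)) stop("acceptance radii must be > 0")
  }
  # a class is unreachable if its centre lies inside another class's box
  nm <- names(classes)
  for (i in seq_along(classes)) for (j in seq_along(classes)) {
    if (i == j) next
    if (all(abs(classes[[i]]$center - classes[[j]]$center) <=
            classes[[j]]$radius))
      stop(sprintf("class %s is unreachable: its center lies inside the %s box",
                   nm[i], nm[j]))
  }
  structure(list(classes = classes), class = "tissue_class_ranges")
}

#' Partial-volume tissue classification from parameter maps
#'
#' Voxels inside exactly one class's acceptance box get fraction 1 for that
#' class. All other non-background voxels are mixed between their two
#' nearest classes, with weights proportional to the inverse of the
#' normalised distance `d_c = sqrt(sum(((x - center_c) / radius_c)^2))`
#' (a Mahalanobis-style distance with per-parameter scales set to the
#' acceptance radii). Voxels whose nearest-class distance exceeds
#' `outlier_dist` are non-brain.
#'
#' @param maps a `parameter_maps` object.
#' @param ranges a [tissue_class_ranges()].
#' @param outlier_dist normalised-distance cut-off for non-brain
#'   (default 6; background voxels sit at distance > 10 from every class,
#'   noisy tissue voxels rarely beyond 5).
#' @return Object of class `segmentation_result`: `fractions` (4-D array,
#'   one volume per class plus `nonbrain`, summing to 1 per voxel),
#'   `class_names`, `geometry`.
#' @export
classify_tissue <- function(maps, ranges = tissue_class_ranges(),
                            outlier_dist = 6) {
  cls <- ranges$classes
  k <- length(cls)
  sh <- maps$geometry$shape
  nv <- prod(sh)
  x <- cbind(as.vector(maps$R1), as.vector(maps$R2), as.vector(maps$PD))
  D <- matrix(0, nv, k)
  inbox <- matrix(FALSE, nv, k)
  for (c_i in seq_len(k)) {
    ctr <- cls[[c_i]]$center; rad <- cls[[c_i]]$radius
    z1 <- (x[, 1] - ctr[1]) / rad[1]
    z2 <- (x[, 2] - ctr[2]) / rad[2]
    z3 <- (x[, 3] - ctr[3]) / rad[3]
    D[, c_i] <- sqrt(z1^2 + z2^2 + z3^2)
    inbox[, c_i] <- abs(z1) <= 1 & abs(z2) <= 1 & abs(z3) <= 1
  }
  nbox <- rowSums(inbox)
  frac <- matrix(0, nv, k + 1)

  # unique box membership -> pure tissue
  pure <- which(nbox == 1)
  if (length(pure)) {
    wcl <- max.col(inbox[pure, , drop = FALSE], ties.method = "first")
    frac[cbind(pure, wcl)] <- 1
  }
  # order classes by distance once (k is small)
  ord1 <- max.col(-D, ties.method = "first")
  Dmin <- D[cbind(seq_len(nv), ord1)]
  D2 <- D; D2[cbind(seq_len(nv), ord1)] <- Inf
  ord2 <- max.col(-D2, ties.method = "first")
  Dsec <- D2[cbind(seq_len(nv), ord2)]

  rest <- which(nbox != 1)
  if (length(rest)) {
    far <- rest[Dmin[rest] > outlier_dist]
    mix <- setdiff(rest, far)
    frac[far, k + 1] <- 1
    if (length(mix)) {
      d1 <- pmax(Dmin[mix], 1e-12); d2 <- pmax(Dsec[mix], 1e-12)
      w1 <- 1 / d1; w2 <- 1 / d2
      frac[cbind(mix, ord1[mix])] <- w1 / (w1 + w2)
      frac[cbind(mix, ord2[mix])] <- frac[cbind(mix, ord2[mix])] +
        w2 / (w1 + w2)
    }
  }
  fractions <- array(frac, c(sh, k + 1))
  structure(list(fractions = fractions,
                 class_names = c(names(cls), "nonbrain"),
                 geometry = maps$geometry),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat("segmentation_result", format(x$geometry), "\n")
  vols <- apply(x$fractions, 4, sum) * prod(x$geometry$voxdim) / 1000
  cat("  ", paste(sprintf("%s %.1f mL", x$class_names, vols),
                  collapse = "; "), "\n")
  invisible(x)
}

seg_class <- function(seg, name) {
  i <- match(name, seg$class_names)
  if (is.na(i)) stop("no class named ", name)
  seg$fractions[, , , i]
}

#' Brain volume measures from a segmentation
#'
#' Brain volume is the summed WM + GM fraction inside the largest
#' 6-connected component of brain-dominant voxels; intracranial volume (ICV)
#' additionally includes CSF; ventricular volume is the CSF fraction summed
#' inside the supplied ventricle mask. Brain parenchymal fraction
#' BPF = 100 * brain / ICV and ventricular fraction VF = 100 * ventricles /
#' ICV.
#'
#' @param seg a [classify_tissue()] result.
#' @param ventricle_mask logical array on the same grid (e.g. phantom ground
#'   truth, or a manually drawn mask on real data).
#' @return Object of class `volume_report`: `intracranial_volume`,
#'   `brain_volume`, `ventricular_volume` (mL), `brain_parenchymal_fraction`
#'   and `ventricular_fraction` (%).
#' @export
compute_volumes <- function(seg, ventricle_mask) {
  stopifnot(identical(dim(ventricle_mask), seg$geometry$shape))
  vv <- prod(seg$geometry$voxdim) / 1000   # mL per voxel
  wm <- seg_class(seg, if ("WM" %in% seg$class_names) "WM" else
    seg$class_names[1])
  gm <- seg_class(seg, if ("GM" %in% seg$class_names) "GM" else
    seg$class_names[2])
  csf <- seg_class(seg, if ("CSF" %in% seg$class_names) "CSF" else
    seg$class_names[3])
  parenchyma <- wm + gm
  if (sum(parenchyma) == 0) {
    warning("empty segmentation; returning zero volumes")
    return(structure(list(intracranial_volume = 0, brain_volume = 0,
                          ventricular_volume = 0,
                          brain_parenchymal_fraction = NA_real_,
                          ventricular_fraction = NA_real_),
                     class = "volume_report"))
  }
  brain_cc <- largest_component(parenchyma >= 0.5)
  icv_cc <- largest_component((parenchyma + csf) >= 0.5)
  brain_vol <- sum(parenchyma[brain_cc]) * vv
  icv_vol <- sum((parenchyma + csf)[icv_cc]) * vv
  vent_vol <- sum(csf[ventricle_mask]) * vv
  structure(list(intracranial_volume = icv_vol,
                 brain_volume = brain_vol,
                 ventricular_volume = vent_vol,
                 brain_parenchymal_fraction = 100 * brain_vol / icv_vol,
                 ventricular_fraction = 100 * vent_vol / icv_vol),
            class = "volume_report")
}

#' @export
print.volume_report <- function(x, ...) {
  cat(sprintf(paste0("volume_report: ICV %.1f mL, brain %.1f mL, ",
                     "ventricles %.1f mL, BPF %.1f%%, VF %.2f%%\n"),
              x$intracranial_volume, x$brain_volume, x$ventricular_volume,
              x$brain_parenchymal_fraction, x$ventricular_fraction))
  invisible(x)
}
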
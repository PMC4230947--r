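#' @title Cohort I/O
#' @name cohort_io
#' @description Reading and writing cohorts as NIfTI volumes plus a TSV
#'   subject table. Each subject contributes `<id>_R1.nii.gz`,
#'   `<id>_R2.nii.gz`, `<id>_PD.nii.gz` (32-bit float) and optionally
#'   `<id>_mask.nii.gz`; the table `subjects.tsv` has columns id, group,
#'   age, edss, msss.
NULL

geometry_to_nifti <- function(arr, geom) {
  im <- RNifti::asNifti(arr)
  # set pixdim first: RNifti derives the stored quaternion scale from it
  nd <- length(dim(arr))
  RNifti::pixdim(im) <- c(geom$voxdim, rep(1, nd - 3))[seq_len(nd)]
  aff <- geometry_affine(geom)
  im <- RNifti::`sform<-`(im, structure(aff, code = 2L))
  im <- RNifti::`qform<-`(im, structure(aff, code = 2L))
  im
}

nifti_to_geometry <- function(im) {
  d <- dim(im)
  aff <- RNifti::xform(im)
  voxdim <- sqrt(colSums(aff[1:3, 1:3]^2))
  qmri_geometry(d[1:3], voxdim, origin = aff[1:3, 4])
}

#' Write a 3-D volume as NIfTI with the grid's affine
#' @param arr 3-D array (numeric or logical).
#' @param geom a `qmri_geometry`.
#' @param path output path (.nii or .nii.gz).
#' @return the path, invisibly.
#' @export
write_volume <- function(arr, geom, path) {
  im <- geometry_to_nifti(arr + 0, geom)
  RNifti::writeNifti(im, path, datatype = "float")
  invisible(path)
}

#' Read a 3-D NIfTI volume
#' @param path file path.
#' @return list: `arr` (3-D array), `geom` (`qmri_geometry`).
#' @export
read_volume <- function(path) {
  im <- RNifti::readNifti(path)
  list(arr = array(as.numeric(im), dim(im)[1:3]),
       geom = nifti_to_geometry(im))
}

#' Write a cohort to a directory
#'
#' Writes per-subject parameter volumes (32-bit NIfTI), the brain masks and
#' the subject table `subjects.tsv`.
#'
#' @param maps_list named list of `parameter_maps` (names = subject ids).
#' @param subjects data.frame with columns id, group, age, edss, msss.
#' @param dir output directory (created if needed).
#' @return character vector of written paths, invisibly.
#' @export
write_cohort <- function(maps_list, subjects, dir) {
  stopifnot(identical(names(maps_list), subjects$id))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (id in subjects$id) {
    m <- maps_list[[id]]
    for (p in c("R1", "R2", "PD")) {
      f <- file.path(dir, sprintf("%s_%s.nii.gz", id, p))
      write_volume(m[[p]], m$geometry, f)
      paths <- c(paths, f)
    }
    f <- file.path(dir, sprintf("%s_mask.nii.gz", id))
    write_volume(m$mask, m$geometry, f)
    paths <- c(paths, f)
  }
  tsv <- file.path(dir, "subjects.tsv")
  utils::write.table(subjects, tsv, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(c(paths, tsv))
}

#' Read a cohort directory
#'
#' Loads `subjects.tsv` and the per-subject R1/R2/PD (and mask) volumes,
#' checking the schema and that all volumes share one geometry.
#'
#' @param dir directory written by [write_cohort()] (or arranged likewise).
#' @return list: `subjects` (data.frame), `maps` (named list of
#'   `parameter_maps`).
#' @export
read_cohort <- function(dir) {
  tsv <- file.path(dir, "subjects.tsv")
  if (!file.exists(tsv)) stop("missing subjects.tsv in ", dir)
  subjects <- utils::read.table(tsv, sep = "\t", header = TRUE,
                                stringsAsFactors = FALSE)
  required <- c("id", "group", "age")
  missing_cols <- setdiff(required, names(subjects))
  if (length(missing_cols))
    stop("subject table schema error; missing columns: ",
         paste(missing_cols, collapse = ", "))
  if (!"edss" %in% names(subjects)) subjects$edss <- NA_real_
  if (!"msss" %in% names(subjects)) subjects$msss <- NA_real_
  maps <- list()
  g0 <- NULL
  for (id in subjects$id) {
    vols <- list()
    for (p in c("R1", "R2", "PD")) {
      f <- file.path(dir, sprintf("%s_%s.nii.gz", id, p))
      if (!file.exists(f)) stop("missing volume: ", f)
      v <- read_volume(f)
      if (is.null(g0)) g0 <- v$geom
      if (!geom_equal(v$geom, g0, tol = 1e-4))
        stop("geometry mismatch in ", f)
      vols[[p]] <- v$arr
    }
    fm <- file.path(dir, sprintf("%s_mask.nii.gz", id))
    msk <- if (file.exists(fm)) read_volume(fm)$arr > 0.5 else NULL
    maps[[id]] <- parameter_maps(vols$R1, vols$R2, vols$PD, g0, mask = msk)
  }
  list(subjects = subjects, maps = maps)
}

#' Write pipeline artifacts to a directory
#'
#' Serialises the run report's tables as TSV, scalar summaries and
#' transforms as JSON, stat maps and overlays as NIfTI, and difference
#' histograms as TSV matrices with their bin edges.
#'
#' @param report a [run_pipeline()] result.
#' @param dir output directory.
#' @return character vector of written paths, invisibly.
#' @export
write_outputs <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  put <- function(p) { paths <<- c(paths, p); p }
  wtsv <- function(df, name) {
    f <- put(file.path(dir, name))
    utils::write.table(df, f, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  if (!is.null(report$volumes)) wtsv(report$volumes, "volumes.tsv")
  if (!is.null(report$roi_summary)) {
    wtsv(report$roi_summary$summary, "roi_summary.tsv")
    wtsv(report$roi_summary$bands, "roi_bands.tsv")
  }
  if (!is.null(report$svc)) wtsv(report$svc, "roi_fwe.tsv")
  if (!is.null(report$mixed_models)) wtsv(report$mixed_models,
                                          "roi_mixed_model.tsv")
  if (!is.null(report$stat_maps)) {
    for (nm in names(report$stat_maps)) {
      sm <- report$stat_maps[[nm]]
      put(write_volume(sm$stat, sm$geometry,
                       file.path(dir, sprintf("stat_%s.nii.gz", nm))))
      side <- put(file.path(dir, sprintf("stat_%s.json", nm)))
      jsonlite::write_json(list(kind = sm$kind, df = sm$df,
                                contrast = sm$contrast,
                                threshold = sm$threshold),
                           side, auto_unbox = TRUE, digits = NA)
    }
  }
  if (!is.null(report$transforms)) {
    tdir <- file.path(dir, "transforms")
    dir.create(tdir, showWarnings = FALSE)
    for (id in names(report$transforms))
      put(write_transform(report$transforms[[id]],
                          file.path(tdir, paste0(id, ".json"))))
  }
  if (!is.null(report$histograms)) {
    for (nm in names(report$histograms)) {
      dh <- report$histograms[[nm]]
      f <- put(file.path(dir, sprintf("hist_%s.tsv", nm)))
      utils::write.table(dh$signed, f, sep = "\t", row.names = FALSE,
                         col.names = FALSE)
      ed <- data.frame(axis = c(rep("x", length(dh$x_edges)),
                                rep("y", length(dh$y_edges))),
                       edge = c(dh$x_edges, dh$y_edges))
      wtsv(ed, sprintf("hist_%s_edges.tsv", nm))
    }
  }
  if (!is.null(report$qc)) {
    f <- put(file.path(dir, "qc.json"))
    jsonlite::write_json(report$qc, f, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(paths)
}
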
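test_that("distance transform matches the exhaustive oracle", {
  set.seed(51)
  # random small masks, isotropic and anisotropic spacings
  for (voxdim in list(c(2, 2, 2), c(1, 2, 3))) {
    m <- array(runif(7^3) > 0.4, c(7, 7, 7))
    m[1, 1, 1] <- FALSE                       # keep background non-empty
    d <- distance_from_surface(m, voxdim)
    expect_equal(d, brute_distance(m, voxdim), tolerance = 1e-9)
  }
  expect_error(distance_from_surface(array(FALSE, c(3, 3, 3))), "empty")
})

test_that("single-voxel ROI: distance equals voxel size, 2 mm erosion empties", {
  m <- array(FALSE, c(5, 5, 5)); m[3, 3, 3] <- TRUE
  d <- distance_from_surface(m, c(2, 2, 2))
  expect_lte(max(d), 2)
  expect_equal(d[3, 3, 3], 2)
  expect_false(any(erode_roi(m, 2, c(2, 2, 2))))
  expect_identical(erode_roi(m, 0), m)
})

test_that("a digitised 10 mm ball has max depth within one voxel of 10 mm", {
  sh <- c(15, 15, 15)
  g <- qmri_geometry(sh)
  co <- qmrivox:::grid_world_coords(g)
  ball <- array(sqrt(rowSums(co^2)) <= 10, sh)
  d <- distance_from_surface(ball, g$voxdim)
  expect_lte(abs(max(d) - 10), 2)
})

test_that("erosion equals the strict distance rule and nests", {
  set.seed(52)
  m <- array(runif(9^3) > 0.3, c(9, 9, 9))
  m[9, 9, 9] <- FALSE
  d_oracle <- brute_distance(m, c(2, 2, 2))
  for (lv in c(2, 4, 6)) {
    e <- erode_roi(m, lv, c(2, 2, 2))
    expect_identical(e, m & d_oracle > lv)
  }
  e2 <- erode_roi(m, 2, c(2, 2, 2))
  e22 <- erode_roi(e2, 2, c(2, 2, 2))
  expect_true(all(!e22 | e2))                   # nested
  e4 <- erode_roi(m, 4, c(2, 2, 2))
  expect_true(all(!e4 | e2))                    # level 4 inside level 2
})

test_that("roi_summary: uniform ROI constant across levels; bands emitted", {
  sh <- c(12, 12, 10)
  roi <- array(FALSE, sh); roi[3:10, 3:10, 3:8] <- TRUE
  maps <- list(block_maps(sh, roi, 1.3, 11, 72),
               block_maps(sh, roi, 1.3, 11, 72))
  rs <- roi_summary(maps, c("reference", "reference"), list(box = roi),
                    levels = c(0, 2, 4))
  s <- subset(rs$summary, param == "R1")
  expect_equal(unique(s$mean), 1.3)
  expect_true(all(diff(s$n_voxels) < 0))        # shrinking with erosion
  expect_true(all(c("roi", "group", "band_mm", "param", "mean")
                  %in% names(rs$bands)))
  # a level that erodes the ROI away is skipped with a warning
  tiny <- array(FALSE, sh); tiny[6, 6, 5] <- TRUE
  expect_warning(roi_summary(maps, c("reference", "reference"),
                             list(dot = tiny), levels = c(0, 2)),
                 "empty")
})

test_that("erosion purifies partial-volume ROIs in the phantom", {
  tmpl <- tiny_template()
  maps <- list(qmrivox:::template_reference_maps(tmpl))
  rs <- roi_summary(maps, "reference",
                    list(ventricles = tmpl$rois$ventricles,
                         corpus_callosum = tmpl$rois$corpus_callosum),
                    levels = c(0, 4))
  vpd <- subset(rs$summary, roi == "ventricles" & param == "PD")$mean
  expect_gt(vpd[2], vpd[1])       # towards pure CSF (higher PD)
  vr1 <- subset(rs$summary, roi == "ventricles" & param == "R1")$mean
  expect_lt(vr1[2], vr1[1])       # and lower R1
  cpd <- subset(rs$summary, roi == "corpus_callosum" & param == "PD")$mean
  expect_lt(cpd[2], cpd[1])       # WM slab sheds its CSF rim (lower PD)
})

test_that("balanced mixed model equals the closed form and lme4 REML", {
  set.seed(53)
  sh <- c(6, 6, 4)
  g <- qmri_geometry(sh)
  roi <- array(TRUE, sh)
  groups <- rep(c("reference", "patient"), each = 5)
  maps <- lapply(seq_along(groups), function(i) {
    mu <- 1.2 - 0.1 * (groups[i] == "patient") + rnorm(1, 0, 0.07)
    v <- array(rnorm(prod(sh), mu, 0.2), sh)
    parameter_maps(v, v, v, g)
  })
  cf <- mixed_model_group_test(maps, groups, roi, "R1",
                               method = "closed_form")
  re <- mixed_model_group_test(maps, groups, roi, "R1", method = "reml")
  expect_equal(cf$estimate, re$estimate, tolerance = 1e-6)
  expect_equal(cf$se, re$se, tolerance = 1e-6)
  expect_equal(cf$p, re$p, tolerance = 1e-6)

  # subject-means oracle
  m_s <- vapply(maps, function(m) mean(m$R1[roi]), numeric(1))
  tt <- t.test(m_s[groups == "patient"], m_s[groups == "reference"],
               var.equal = TRUE)
  expect_equal(cf$estimate, unname(tt$estimate[1] - tt$estimate[2]),
               tolerance = 1e-12)
  expect_equal(cf$p, tt$p.value, tolerance = 1e-12)
})

test_that("mixed model null case and input validation", {
  set.seed(54)
  sh <- c(4, 4, 4)
  g <- qmri_geometry(sh)
  roi <- array(TRUE, sh)
  groups <- rep(c("reference", "patient"), each = 4)
  ps <- vapply(1:20, function(r) {
    maps <- lapply(seq_along(groups), function(i) {
      v <- array(rnorm(prod(sh), 1.2 + rnorm(1, 0, 0.05), 0.1), sh)
      parameter_maps(v, v, v, g)
    })
    mixed_model_group_test(maps, groups, roi, "R1")$p
  }, numeric(1))
  expect_gt(median(ps), 0.1)              # roughly uniform under the null
  expect_error(mixed_model_group_test(list(), character(0), roi), "subjects")
  m1 <- block_maps(sh, roi, 1, 10, 70)
  expect_error(mixed_model_group_test(list(m1, m1, m1, m1),
                                      c("reference", "reference",
                                        "patient", "patient"),
                                      array(FALSE, sh)), "empty ROI")
})

test_that("erosion walks ROI means towards the deepest-band values", {
  # for a partial-volume-contaminated ROI, the most-eroded mean should sit
  # closer (in standardized (R1, R2) space) to the deep-band mean than the
  # un-eroded mean does
  tmpl <- tiny_template()
  maps <- list(qmrivox:::template_reference_maps(tmpl))
  rs <- roi_summary(maps, "reference",
                    list(wm = tmpl$rois$white_matter),
                    levels = c(0, 4, 8), params = c("R1", "R2"))
  s <- rs$summary
  b <- rs$bands
  deepest <- max(b$band_mm)
  deep <- c(b$mean[b$band_mm == deepest & b$param == "R1"],
            b$mean[b$band_mm == deepest & b$param == "R2"])
  at_level <- function(lv) c(s$mean[s$level_mm == lv & s$param == "R1"],
                             s$mean[s$level_mm == lv & s$param == "R2"])
  sdv <- c(s$sd[s$level_mm == 0 & s$param == "R1"],
           s$sd[s$level_mm == 0 & s$param == "R2"])
  dist_to_deep <- function(m) sqrt(sum(((m - deep) / sdv)^2))
  lmax <- max(s$level_mm)
  expect_lt(dist_to_deep(at_level(lmax)), dist_to_deep(at_level(0)))
})
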
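test_that("pure-class, midpoint and background voxels classify correctly", {
  rng <- tissue_class_ranges()
  wm_c <- rng$classes$WM$center
  csf_c <- rng$classes$CSF$center
  mid <- (wm_c + csf_c) / 2
  sh <- c(4, 1, 1)
  g <- qmri_geometry(sh)
  vals <- rbind(c(1.20, 11.1, 74),    # WM tissue point
                mid,                  # WM/CSF interface
                c(1.01, 10.0, 77),    # GM centre
                c(0.01, 0.01, 0))     # background
  maps <- parameter_maps(array(vals[, 1], sh), array(vals[, 2], sh),
                         array(vals[, 3], sh), g)
  seg <- classify_tissue(maps, rng)
  fr <- matrix(seg$fractions, 4, 4)
  colnames(fr) <- seg$class_names
  expect_equal(unname(fr[1, "WM"]), 1)
  expect_gt(fr[2, "WM"], 0); expect_lt(fr[2, "WM"], 1)
  expect_gt(fr[2, "CSF"], 0); expect_lt(fr[2, "CSF"], 1)
  expect_equal(unname(fr[3, "GM"]), 1)
  expect_equal(unname(fr[4, "nonbrain"]), 1)
  expect_equal(unname(rowSums(fr)), rep(1, 4), tolerance = 1e-12)
})

test_that("fraction partition holds for arbitrary maps", {
  maps <- random_maps(seed = 12)
  seg <- classify_tissue(maps)
  sums <- apply(seg$fractions, 1:3, sum)
  expect_equal(range(sums), c(1, 1), tolerance = 1e-12)
  expect_true(all(seg$fractions >= 0))
})

test_that("unreachable class definitions are rejected", {
  expect_error(tissue_class_ranges(list(
    A = list(center = c(1, 10, 70), radius = c(1, 5, 20)),
    B = list(center = c(1.2, 11, 75), radius = c(0.1, 0.5, 2)))),
    "unreachable")
  expect_error(tissue_class_ranges(list(
    A = list(center = c(1, 10, 70), radius = c(0, 1, 1)),
    B = list(center = c(2, 12, 80), radius = c(0.1, 0.5, 2)))),
    "radii")
})

test_that("volume arithmetic: CSF sphere, BPF identity, empty input", {
  sh <- c(20, 20, 20)
  g <- qmri_geometry(sh)          # 2 mm isotropic
  fr <- array(0, c(sh, 4))
  fr[, , , 4] <- 1
  # a 5^3 WM block (brain) and a separate N-voxel pure-CSF "ventricle"
  fr[3:7, 3:7, 3:7, 1] <- 1; fr[3:7, 3:7, 3:7, 4] <- 0
  vent <- array(FALSE, sh); vent[10:12, 10:12, 10:12] <- TRUE   # N = 27
  fr[, , , 3][vent] <- 1; fr[, , , 4][vent] <- 0
  seg <- structure(list(fractions = fr,
                        class_names = c("WM", "GM", "CSF", "nonbrain"),
                        geometry = g), class = "segmentation_result")
  vr <- compute_volumes(seg, vent)
  expect_equal(vr$ventricular_volume, 27 * 0.008)
  expect_equal(vr$brain_volume, 125 * 0.008)
  expect_equal(vr$brain_parenchymal_fraction,
               100 * vr$brain_volume / vr$intracranial_volume)
  expect_equal(vr$ventricular_fraction,
               100 * vr$ventricular_volume / vr$intracranial_volume)

  fr0 <- array(0, c(4, 1, 1, 4)); fr0[, , , 4] <- 1
  empty <- structure(list(fractions = fr0,
                          class_names = c("WM", "GM", "CSF", "nonbrain"),
                          geometry = qmri_geometry(c(4, 1, 1))),
                     class = "segmentation_result")
  expect_warning(vr0 <- compute_volumes(empty, array(FALSE, c(4, 1, 1))),
                 "empty")
  expect_equal(vr0$brain_volume, 0)
})

test_that("ground-truth fractions reproduce ground-truth BPF within 1 point", {
  tmpl <- tiny_template()
  spec <- tiny_spec()
  m <- sample_subject_maps(tmpl,
                           data.frame(id = "p", group = "patient", age = 50,
                                      edss = 4), spec, seed = 21)
  gt <- attr(m, "ground_truth")
  fr <- gt$fractions[, , , c(1, 2, 3, 4)]
  seg <- structure(list(fractions = fr,
                        class_names = c("WM", "GM", "CSF", "nonbrain"),
                        geometry = tmpl$geometry),
                   class = "segmentation_result")
  vr <- compute_volumes(seg, gt$vent_mask)
  direct_bpf <- 100 * sum(fr[, , , 1] + fr[, , , 2]) /
    sum(fr[, , , 1] + fr[, , , 2] + fr[, , , 3])
  expect_lt(abs(vr$brain_parenchymal_fraction - direct_bpf), 1)
})

test_that("volumes are stable under grid refinement (< 2 %)", {
  vol_at <- function(vox, shape) {
    spec <- phantom_spec(grid_shape = shape, voxel_size = vox)
    tmpl <- build_template(spec, atrophy_factor = 1)
    fr <- tmpl$fractions
    seg <- structure(list(fractions = fr,
                          class_names = c("WM", "GM", "CSF", "nonbrain"),
                          geometry = tmpl$geometry),
                     class = "segmentation_result")
    compute_volumes(seg, tmpl$rois$ventricles)
  }
  v4 <- vol_at(4, c(34, 36, 28))
  v2 <- vol_at(2, c(64, 64, 48))
  expect_lt(abs(v4$intracranial_volume - v2$intracranial_volume) /
              v2$intracranial_volume, 0.02)
  expect_lt(abs(v4$brain_volume - v2$brain_volume) / v2$brain_volume, 0.02)
})

test_that("atrophy raises measured ventricular fraction and lowers BPF", {
  out <- lapply(c(1, 1.6, 2.5), function(f) {
    spec <- tiny_spec(atrophy_factor = f,
                      lesion_model = list(count_lambda = 0,
                                          radius_range = c(2.5, 5),
                                          periventricular_prob = 0.8,
                                          severity = 0.5))
    tmpl <- build_template(spec, atrophy_factor = 1)
    m <- sample_subject_maps(tmpl,
                             data.frame(id = "p", group = "patient",
                                        age = 50, edss = 4), spec, seed = 9)
    gt <- attr(m, "ground_truth")
    compute_volumes(classify_tissue(m), gt$vent_mask)
  })
  vf <- vapply(out, function(v) v$ventricular_fraction, numeric(1))
  bpf <- vapply(out, function(v) v$brain_parenchymal_fraction, numeric(1))
  expect_true(all(diff(vf) > 0))
  expect_true(all(diff(bpf) < 0))
})
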
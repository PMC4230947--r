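test_that("template fractions are a proper partition and ROIs lie in-brain", {
  tmpl <- tiny_template()
  fr <- tmpl$fractions
  sums <- fr[, , , 1] + fr[, , , 2] + fr[, , , 3] + fr[, , , 4]
  expect_equal(range(sums), c(1, 1), tolerance = 1e-12)
  expect_true(all(fr >= 0 & fr <= 1))
  inbrain <- fr[, , , 4] < 0.5
  for (nm in names(tmpl$rois))
    expect_true(all(inbrain[tmpl$rois[[nm]]]), label = nm)
  # at least one simply-connected ventricle region
  vent_cc <- qmrivox:::largest_component(tmpl$rois$ventricles)
  expect_gt(sum(vent_cc), 0)
  expect_gt(sum(tmpl$rois$periventricular_wm), 0)
})

test_that("template is deterministic and rejects tiny grids", {
  s <- tiny_spec()
  a <- build_template(s)
  b <- build_template(s)
  expect_identical(a$fractions, b$fractions)
  expect_identical(a$rois, b$rois)
  expect_error(phantom_spec(grid_shape = c(8, 8, 8)), "at least 16")
  expect_error(build_template(tiny_spec(voxel_size = 2)), "too small")
})

test_that("ventricle mask grows strictly with the atrophy factor", {
  n1 <- sum(build_template(tiny_spec(atrophy_factor = 1))$rois$ventricles)
  n2 <- sum(build_template(tiny_spec(atrophy_factor = 2))$rois$ventricles)
  expect_gt(n2, n1)
})

test_that("spec invariants are enforced", {
  expect_error(tiny_spec(atrophy_factor = 0.5), "atrophy_factor")
  tp <- phantom_spec()$tissue_params
  tp$WM$within_sd <- c(-1, 0, 0)
  expect_error(tiny_spec(tissue_params = tp), "SDs")
  tp <- phantom_spec()$tissue_params
  tp$GM$mean <- c(1, 10, 150)
  expect_error(tiny_spec(tissue_params = tp), "PD")
  lm0 <- phantom_spec()$lesion_model
  lm0$radius_range <- c(0, 3)
  expect_error(tiny_spec(lesion_model = lm0), "radii")
})

test_that("noise-free subjects hit the configured tissue values exactly", {
  spec <- exact_spec()
  tmpl <- build_template(spec, atrophy_factor = 1)
  pure_wm <- tmpl$fractions[, , , 1] == 1
  expect_gt(sum(pure_wm), 100)

  ref <- sample_subject_maps(
    tmpl, data.frame(id = "r", group = "reference", age = 50, edss = NA),
    spec, seed = 1)
  expect_equal(unique(ref$R1[pure_wm]), 1.20, tolerance = 1e-12)
  expect_equal(unique(ref$R2[pure_wm]), 11.1, tolerance = 1e-12)
  expect_equal(unique(ref$PD[pure_wm]), 74, tolerance = 1e-12)

  # patient NAWM carries the diffuse shift; at the reference EDSS the
  # frontal scaling is exactly 1, so all pure WM sits at the shifted values
  pat <- sample_subject_maps(
    tmpl, data.frame(id = "p", group = "patient", age = 50, edss = 3.7),
    spec, seed = 2)
  gt <- attr(pat, "ground_truth")
  # pure WM in the *subject's* anatomy (dilated ventricles shrink it)
  nawm <- (gt$fractions[, , , 1] == 1) & !gt$lesion_mask
  expect_equal(unique(round(pat$R1[nawm], 10)), 1.07)
  expect_equal(unique(round(pat$R2[nawm], 10)), 10.2)
  expect_equal(unique(round(pat$PD[nawm], 10)), 77)
})

test_that("subject sampling is seed-deterministic", {
  tmpl <- tiny_template()
  rec <- data.frame(id = "x", group = "patient", age = 40, edss = 5)
  a <- sample_subject_maps(tmpl, rec, tiny_spec(), seed = 7)
  b <- sample_subject_maps(tmpl, rec, tiny_spec(), seed = 7)
  expect_identical(a$R1, b$R1)
  expect_identical(attr(a, "ground_truth")$lesion_mask,
                   attr(b, "ground_truth")$lesion_mask)
  c_ <- sample_subject_maps(tmpl, rec, tiny_spec(), seed = 8)
  expect_false(identical(a$R1, c_$R1))
})

test_that("cohort structure, EDSS coverage and age matching", {
  spec <- tiny_spec()
  co <- generate_cohort(spec, n_ref = 5, n_pat = 5, seed = 3,
                        misalign = FALSE)
  expect_equal(nrow(co$subjects), 10)
  expect_equal(sum(!is.na(co$subjects$edss)), 5)
  expect_true(all(co$subjects$edss[co$subjects$group == "patient"] >= 1))
  expect_true(all(co$subjects$edss[co$subjects$group == "patient"] <= 8.5))
  agg <- tapply(co$subjects$age, co$subjects$group, mean)
  expect_lte(abs(diff(agg)), 2.6)
  expect_true(all(co$subjects$age > 0))

  solo <- generate_cohort(spec, n_ref = 1, n_pat = 0, seed = 4,
                          misalign = FALSE)
  expect_equal(nrow(solo$subjects), 1)
  expect_true(all(is.na(solo$subjects$edss)))

  # ground truth emitted per subject for downstream oracles
  gt <- co$ground_truth[[1]]
  expect_true(all(c("fractions", "vent_mask", "lesion_mask", "clip_rate")
                  %in% names(gt)))
  expect_length(co$true_transforms, 10)
})

test_that("all cohort randomness flows from the single seed", {
  spec <- tiny_spec()
  a <- generate_cohort(spec, 2, 2, seed = 11)
  b <- generate_cohort(spec, 2, 2, seed = 11)
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$maps[[3]]$R1, b$maps[[3]]$R1)
  expect_identical(a$true_transforms, b$true_transforms)
})

test_that("empirical WM group means converge to configured means (LLN)", {
  # coarse 6 mm grid keeps 200 subjects per group cheap
  spec <- phantom_spec(grid_shape = c(20, 24, 18), voxel_size = 6)
  tmpl <- build_template(spec, atrophy_factor = 1)
  pure_wm <- tmpl$fractions[, , , 1] == 1
  n <- 200
  wm_mean <- function(group, edss, seed_off) {
    vapply(seq_len(n), function(i) {
      m <- sample_subject_maps(
        tmpl, data.frame(id = "s", group = group, age = 50,
                         edss = edss), spec, seed = i + seed_off)
      gt <- attr(m, "ground_truth")
      keep <- pure_wm & !gt$lesion_mask
      c(mean(m$R1[keep]), mean(m$R2[keep]), mean(m$PD[keep]))
    }, numeric(3))
  }
  ref <- wm_mean("reference", NA, 0)
  pat <- wm_mean("patient", 3.7, 10000)
  tp <- spec$tissue_params$WM
  for (p in 1:3) {
    se <- tp$between_sd[p] / sqrt(n)
    expect_lt(abs(mean(ref[p, ]) - tp$mean[p]), 3 * se + 1e-9)
    expect_lt(abs(mean(pat[p, ]) -
                    (tp$mean[p] + spec$diffuse_delta[p])),
              3 * se + 0.05 * abs(spec$diffuse_delta[p]))
  }
  # the sign pattern of the patient-minus-reference WM difference
  d <- rowMeans(pat) - rowMeans(ref)
  expect_lt(d[1], 0); expect_lt(d[2], 0); expect_gt(d[3], 0)
})
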
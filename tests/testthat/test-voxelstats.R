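test_that("identical groups give T = 0 everywhere", {
  vals <- c(1.1, 0.9, 1.3, 1.1, 0.9, 1.3)
  maps <- scalar_maps(vals)
  design <- data.frame(id = letters[1:6],
                       group = rep(c("reference", "patient"), each = 3),
                       age = rep(c(40, 50, 60), 2))
  sm <- glm_group_contrast(maps, design, "R1")
  expect_equal(unname(sm$stat[1, 1, 1]), 0)
  expect_equal(sm$df, 3)
})

test_that("group T matches the explicit normal-equations oracle", {
  y <- c(1.30, 1.15, 1.25, 1.02, 0.95, 1.10)
  age <- c(38, 55, 47, 41, 60, 50)
  design <- data.frame(id = letters[1:6],
                       group = rep(c("reference", "patient"), each = 3),
                       age = age)
  sm <- glm_group_contrast(scalar_maps(y), design, "R1")
  # independent oracle: solve the normal equations by hand
  X <- cbind(1, c(1, 1, 1, 0, 0, 0), age - mean(age))
  XtXi <- solve(t(X) %*% X)
  beta <- XtXi %*% t(X) %*% y
  res <- y - X %*% beta
  s2 <- sum(res^2) / (6 - 3)
  t_or <- beta[2] / sqrt(s2 * XtXi[2, 2])
  expect_equal(unname(sm$stat[1, 1, 1]), unname(t_or), tolerance = 1e-10)
  # positive T means reference > patient
  expect_gt(sm$stat[1, 1, 1], 0)
})

test_that("rank-deficient designs are rejected with the offending columns", {
  design <- data.frame(id = letters[1:6],
                       group = rep(c("reference", "patient"), each = 3),
                       age = rep(c(1, 0), each = 3))  # age == group coding
  expect_error(glm_group_contrast(scalar_maps(rnorm(6)), design, "R1"),
               "collinear")
})

test_that("EDSS slope equals the closed-form partial-regression oracle", {
  y <- c(1.2, 1.0, 0.9, 1.1, 0.8)
  edss <- c(1, 3, 5, 2, 6.5)
  age <- c(40, 52, 47, 61, 45)
  design <- data.frame(id = letters[1:5], edss = edss, age = age)
  sm <- edss_slope_map(scalar_maps(y), design, "R1")
  # oracle via lm(), an independent fitting route
  fit <- lm(y ~ edss + I(age - mean(age)))
  expect_equal(unname(sm$stat[1, 1, 1]), unname(coef(fit)["edss"]),
               tolerance = 1e-10)
  expect_equal(unname(sm$tstat[1, 1, 1]),
               unname(summary(fit)$coefficients["edss", "t value"]),
               tolerance = 1e-8)
  expect_error(edss_slope_map(scalar_maps(y),
                              transform(design, edss = 3), "R1"),
               "constant")
  expect_error(edss_slope_map(scalar_maps(y),
                              transform(design, edss = NA), "R1"),
               "EDSS")
})

test_that("slope maps are centred at zero when EDSS carries no signal", {
  set.seed(40)
  n <- 40
  sh <- c(12, 10, 8)
  g <- qmri_geometry(sh)
  maps <- lapply(seq_len(n), function(i) {
    v <- array(rnorm(prod(sh), 1.2, 0.1), sh)
    parameter_maps(v, v, v, g)
  })
  design <- data.frame(id = as.character(seq_len(n)),
                       edss = sample(seq(1, 8.5, by = 0.5), n, TRUE),
                       age = runif(n, 30, 65))
  sm <- edss_slope_map(maps, design, "R1")
  expect_lt(abs(mean(sm$stat)), 0.005)
})

test_that("thresholding is strict and respects sidedness", {
  g <- qmri_geometry(c(3, 1, 1))
  sm <- qmrivox:::new_stat_map(array(c(1.9, 2.0, 2.1), c(3, 1, 1)), "t", 10,
                               "toy", array(TRUE, c(3, 1, 1)), g)
  ov <- threshold_map(sm, 2)
  expect_equal(as.vector(ov), c(FALSE, FALSE, TRUE))
  expect_false(any(threshold_map(sm, Inf)))
  expect_equal(as.vector(threshold_map(sm, 0)), rep(TRUE, 3))
  sm$stat[1, 1, 1] <- -2.5
  expect_equal(as.vector(threshold_map(sm, 2, sided = "two")),
               c(TRUE, FALSE, TRUE))
})

test_that("4+4 permutation inference is exhaustive and matches enumeration", {
  set.seed(17)
  n <- 8
  sh <- c(2, 2, 2)
  g <- qmri_geometry(sh)
  maps <- lapply(seq_len(n), function(i) {
    v <- array(rnorm(prod(sh), 1 + 0.3 * (i <= 4), 0.2), sh)
    parameter_maps(v, v, v, g)
  })
  design <- data.frame(id = as.character(1:8),
                       group = rep(c("reference", "patient"), each = 4),
                       age = c(40, 45, 50, 55, 41, 46, 51, 56))
  roi <- array(TRUE, sh)
  res <- permutation_fwe_svc(maps, design, list(all = roi), "R1",
                             n_perm = 100, seed = 5)
  expect_true(res$exhaustive)
  expect_equal(res$n_perm, choose(8, 4))

  # independent enumeration oracle via lm() per assignment
  Y <- vapply(maps, function(m) as.vector(m$R1), numeric(8))
  maxt_for <- function(ref_idx) {
    gvec <- as.numeric(seq_len(n) %in% ref_idx)
    max(apply(Y, 1, function(yv) {
      summary(lm(yv ~ gvec + design$age))$coefficients["gvec", "t value"]
    }))
  }
  obs <- maxt_for(1:4)
  perms <- combn(8, 4, simplify = FALSE)
  p_or <- mean(vapply(perms, maxt_for, numeric(1)) >= obs - 1e-12)
  expect_equal(res$p_fwe, p_or, tolerance = 1e-12)
  expect_equal(res$p_fwe_bonf, min(1, p_or * 1))
})

test_that("null permutation p-values are calibrated (median near 0.5)", {
  set.seed(23)
  n <- 10
  sh <- c(3, 3, 2)
  g <- qmri_geometry(sh)
  design <- data.frame(id = as.character(1:n),
                       group = rep(c("reference", "patient"), each = 5),
                       age = runif(n, 35, 65))
  roi <- array(TRUE, sh)
  ps <- vapply(1:40, function(r) {
    maps <- lapply(seq_len(n), function(i) {
      v <- array(rnorm(prod(sh)), sh)
      parameter_maps(v, v, v, g)
    })
    permutation_fwe_svc(maps, design, list(all = roi), "R1",
                        n_perm = 120, seed = r)$p_fwe
  }, numeric(1))
  expect_gt(median(ps), 0.25)
  expect_lt(median(ps), 0.75)
})

test_that("null T maps match the t-distribution tail (type-I calibration)", {
  set.seed(77)
  n <- 12
  sh <- c(25, 20, 20)               # 10^4 voxels
  g <- qmri_geometry(sh)
  maps <- lapply(seq_len(n), function(i) {
    v <- array(rnorm(prod(sh)), sh)
    parameter_maps(v, v, v, g)
  })
  design <- data.frame(id = as.character(1:n),
                       group = rep(c("reference", "patient"), each = 6),
                       age = runif(n, 30, 70))
  sm <- glm_group_contrast(maps, design, "R1")
  frac <- mean(sm$stat > 2)
  expected <- pt(2, df = n - 3, lower.tail = FALSE)
  se <- sqrt(expected * (1 - expected) / prod(sh))
  expect_lt(abs(frac - expected), 4 * se)
})

test_that("map regression recovers exact and null relations", {
  sh <- c(20, 20, 25)               # 10^4 voxels
  g <- qmri_geometry(sh)
  set.seed(9)
  tv <- array(rnorm(prod(sh)), sh)
  msk <- array(TRUE, sh)
  t_map <- qmrivox:::new_stat_map(tv, "t", 10, "toy", msk, g)
  s_exact <- qmrivox:::new_stat_map(0.5 * tv, "slope", 10, "toy", msk, g)
  mr <- map_regression(t_map, s_exact)
  expect_equal(mr$slope, 0.5, tolerance = 1e-12)
  expect_equal(mr$r_squared, 1, tolerance = 1e-12)

  s_null <- qmrivox:::new_stat_map(array(rnorm(prod(sh)), sh), "slope", 10,
                                   "toy", msk, g)
  expect_lt(map_regression(t_map, s_null)$r_squared, 0.01)
  empty <- array(FALSE, sh)
  expect_error(map_regression(t_map, s_null, empty), "empty")
})

test_that("permutation p-values are invariant to id relabeling and rescaling", {
  set.seed(29)
  n <- 8
  sh <- c(3, 3, 2)
  g <- qmri_geometry(sh)
  maps <- lapply(seq_len(n), function(i) {
    v <- array(rnorm(prod(sh), 1 + 0.2 * (i <= 4), 0.15), sh)
    parameter_maps(v, v, v, g)
  })
  design <- data.frame(id = letters[1:n],
                       group = rep(c("reference", "patient"), each = 4),
                       age = runif(n, 35, 65))
  roi <- list(all = array(TRUE, sh))
  base <- permutation_fwe_svc(maps, design, roi, "R1", n_perm = 100,
                              seed = 3)
  # relabel subject ids (order and data unchanged)
  design2 <- design; design2$id <- LETTERS[1:n]
  rel <- permutation_fwe_svc(maps, design2, roi, "R1", n_perm = 100,
                             seed = 3)
  expect_equal(rel$p_fwe, base$p_fwe)
  # map-wide affine rescaling of intensities
  maps3 <- lapply(maps, function(m) {
    m$R1 <- 5.5 * m$R1 + 2; m
  })
  sc <- permutation_fwe_svc(maps3, design, roi, "R1", n_perm = 100,
                            seed = 3)
  expect_equal(sc$p_fwe, base$p_fwe)
  expect_equal(sc$max_t, base$max_t, tolerance = 1e-9)
})
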
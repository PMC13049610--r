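test_that("spherical Hertz closed form evaluates correctly", {
  expect_identical(hertz_force_sphere(0, 1000, 5.4e-6), 0)
  # E = 1 kPa, nu = 0.5, R = 5.4 um, delta = 1 um
  F_expected <- (4 / 3) * (1000 / (1 - 0.25)) * sqrt(5.4e-6) * (1e-6)^1.5
  expect_equal(hertz_force_sphere(1e-6, 1000, 5.4e-6, 0.5), F_expected)
  expect_equal(F_expected, 4.131e-9, tolerance = 1e-3)
  # power-law scaling F(2 delta) = 2^(3/2) F(delta)
  d <- c(1e-7, 5e-7, 2e-6)
  expect_equal(hertz_force_sphere(2 * d, 777, 5.4e-6, 0.3),
               2^1.5 * hertz_force_sphere(d, 777, 5.4e-6, 0.3))
  expect_error(hertz_force_sphere(-1e-9, 1000, 5.4e-6), "delta")
  expect_error(hertz_force_sphere(1e-9, -5, 5.4e-6), "modulus")
})

test_that("exact Sneddon sphere agrees with Hertz at shallow depth", {
  R <- 5.4e-6
  d <- c(1e-8, 1e-7, 6e-7)
  fh <- hertz_force_sphere(d, 3000, R, 0.5)
  fs <- sneddon_force_sphere(d, 3000, R, 0.5)
  expect_true(all(abs(fs - fh) / fh < 0.05))
  # the two converge as delta / R -> 0
  expect_lt(abs(fs[1] - fh[1]) / fh[1], abs(fs[3] - fh[3]) / fh[3])
})

test_that("noiseless round trips are exact for both instrument presets", {
  for (preset in c("colloidal", "nanoindenter")) {
    inst <- inst_noiseless(preset)
    off <- mean(inst$offset_range)
    for (E_kPa in c(0.5, 1, 3, 8, 10, 30)) {
      cv <- generate_force_curve(E_kPa * 1000, inst, contact_offset = off)
      fit <- hertz_fit(cv, inst)
      expect_true(fit$valid)
      expect_lt(abs(fit$E - E_kPa * 1000) / (E_kPa * 1000), 1e-6)
    }
  }
})

test_that("Poisson ratio enters only through 1/(1 - nu^2)", {
  inst <- inst_noiseless("colloidal")
  cv <- generate_force_curve(5000, inst, contact_offset = 1e-6)
  fit05 <- hertz_fit(cv, inst)
  fit045 <- hertz_fit(cv, instrument_preset(
    "colloidal", noise_sd = 0, baseline_slope_sd = 0, nu = 0.45))
  expect_equal(fit045$E / fit05$E,
               (1 - 0.45^2) / (1 - 0.5^2), tolerance = 1e-9)
})

test_that("fitted E is linear in the force scale and monotone in force", {
  # rigid cantilever so indentation is independent of the force channel
  inst <- inst_noiseless("colloidal", k = 1e6)
  cv <- generate_force_curve(3000, inst, contact_offset = 1e-6)
  for (c_scale in c(0.5, 2, 3.7)) {
    cv2 <- cv
    cv2$f <- cv$f * c_scale
    cv2$d <- cv$d * c_scale
    fit2 <- hertz_fit(cv2, inst)
    expect_equal(fit2$E, hertz_fit(cv, inst)$E * c_scale,
                 tolerance = 1e-6)
  }
  # monotonicity under the default compliant cantilever
  instd <- instrument_preset("colloidal")
  cvd <- generate_force_curve(3000, instd, contact_offset = 1e-6,
                              seed = 21)
  up <- cvd
  up$f <- cvd$f * 1.1
  up$d <- cvd$d * 1.1
  expect_gt(hertz_fit(up, instd)$E, hertz_fit(cvd, instd)$E)
})

test_that("default-noise fits are accurate and unbiased", {
  sim <- sim_default_noise_fits()
  E_hat <- vapply(sim$fits, function(f) f$E, numeric(1))
  rel <- (E_hat - sim$E_true) / sim$E_true
  expect_lt(median(abs(rel)), 0.02)
  # no systematic sign bias at alpha = 0.01
  bt <- stats::binom.test(sum(rel > 0), length(rel))
  expect_gt(bt$p.value, 0.01)
})

test_that("fitting uses the extend segment only", {
  inst <- instrument_preset("colloidal")
  cv_clean <- generate_force_curve(4000, inst, contact_offset = 1e-6,
                                   seed = 31, adhesion_force = 0)
  set.seed(31)
  cv_adh <- generate_force_curve(4000, inst, contact_offset = 1e-6,
                                 seed = 31, adhesion_force = 5e-9)
  expect_equal(hertz_fit(cv_adh, inst)$E, hertz_fit(cv_clean, inst)$E)
})

test_that("batch fitting isolates failures and is order invariant", {
  inst <- inst_noiseless("colloidal", grid_n = 4)
  set.seed(12)
  curves <- list()
  n <- inst$grid_n
  for (j in seq_len(n)) for (i in seq_len(n)) {
    cv <- generate_force_curve(3000 * i, inst, contact_offset = 1e-6)
    cv$pixel <- c(i, j)
    curves[[length(curves) + 1L]] <- cv
  }
  batch <- batch_fit(curves, inst)
  expect_identical(attr(batch, "summary")$n_valid, 16L)
  # poison one pixel with pure noise: that pixel fails, others unaffected
  z <- seq(0, 6e-6, by = 5e-9)
  set.seed(4)
  bad <- force_curve(z, force = rnorm(length(z), 0, 5e-11))
  bad$pixel <- c(2L, 2L)
  curves2 <- curves
  curves2[[which(vapply(curves, function(cv)
    identical(cv$pixel, c(2L, 2L)), logical(1)))]] <- bad
  b2 <- batch_fit(curves2, inst)
  df2 <- as.data.frame(b2)
  expect_identical(sum(!df2$valid), 1L)
  expect_false(df2$valid[df2$pixel_row == 2 & df2$pixel_col == 2])
  # order invariance
  set.seed(99)
  perm <- sample(length(curves))
  d1 <- as.data.frame(batch_fit(curves, inst))
  d3 <- as.data.frame(batch_fit(curves[perm], inst))
  o1 <- order(d1$pixel_row, d1$pixel_col)
  o3 <- order(d3$pixel_row, d3$pixel_col)
  expect_equal(d1[o1, ], d3[o3, ], ignore_attr = TRUE)
  expect_error(batch_fit(list(), inst), "at least one")
})
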
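test_that("zero-variance preset yields exactly constant fields", {
  preset <- tissue_preset(NULL, mean_kPa = 3.0, sd_kPa = 0, pixel_cv = 0)
  inst <- instrument_preset("colloidal", grid_n = 8)
  secs <- sample_stiffness_field(preset, inst, n_sections = 1,
                                 n_fields = 2, seed = 123)
  for (f in secs[[1]]$fields)
    expect_true(all(f == 3000))
})

test_that("generators are bit-identical under a fixed seed", {
  preset <- tissue_preset("cortical")
  inst <- instrument_preset("colloidal", grid_n = 4)
  s1 <- sample_stiffness_field(preset, inst, 3, seed = 7)
  s2 <- sample_stiffness_field(preset, inst, 3, seed = 7)
  expect_identical(s1, s2)
  d1 <- generate_map_dataset(preset, inst, n_maps = 2, seed = 7)
  d2 <- generate_map_dataset(preset, inst, n_maps = 2, seed = 7)
  expect_identical(d1, d2)
  p1 <- generate_section_phantom(seed = 7)
  p2 <- generate_section_phantom(seed = 7)
  expect_identical(p1, p2)
  c1 <- generate_cell_table(cell_preset("yap_fibrin_dmso"), 100, seed = 7)
  expect_identical(c1, generate_cell_table(cell_preset("yap_fibrin_dmso"),
                                           100, seed = 7))
})

test_that("section scales are moment-matched to the preset", {
  # Monte-Carlo check of the log-normal moment matching
  scales <- draw_section_scales("cortical", 1e4, seed = 1)
  se_mean <- 2.9 / sqrt(1e4)
  expect_lt(abs(mean(scales) - 8.1), 3 * se_mean)
  se_sd <- 2.9 / sqrt(2 * (1e4 - 1))   # normal-theory SE of the SD
  expect_lt(abs(sd(scales) - 2.9), 5 * se_sd)
  # smaller draw per the generator contract
  s200 <- draw_section_scales("cortical", 200, seed = 1)
  expect_lt(abs(mean(s200) - 8.1), 3 * 2.9 / sqrt(200))
})

test_that("noiseless curves are physical and correctly constructed", {
  inst <- inst_noiseless()
  cv <- generate_force_curve(8100, inst, contact_offset = 1e-6)
  ext <- cv$segment == "extend"
  post <- ext & cv$z > 1e-6
  expect_true(all(diff(cv$f[post]) >= 0))      # monotone in contact
  expect_true(all(abs(cv$f[ext & cv$z <= 1e-6]) < 1e-20))
  expect_true(max(cv$f) >= inst$setpoint)      # truncated at setpoint
  # contact_offset = 0: first strictly positive force within one z-step
  cv0 <- generate_force_curve(8100, inst, contact_offset = 0)
  first_pos <- which(cv0$f[cv0$segment == "extend"] > 0)[1]
  expect_lte(cv0$z[first_pos], inst$z_step)
  # deflection channel is F / k
  expect_equal(cv$d, cv$f / inst$k)
})

test_that("force noise magnitude is calibrated", {
  inst <- instrument_preset("colloidal")
  cv <- generate_force_curve(30000, inst, contact_offset = 3e-6,
                             seed = 77, baseline_slope = 0,
                             retract = FALSE)
  pre <- cv$z < 2.9e-6   # >= 500 pre-contact samples
  expect_gte(sum(pre), 500)
  expect_lt(abs(sd(cv$f[pre]) - 5e-11) / 5e-11, 0.10)
})

test_that("pathologically soft samples raise the setpoint error", {
  inst <- instrument_preset("colloidal")
  expect_error(generate_force_curve(1, inst, contact_offset = 1e-6),
               "setpoint unreachable")
  expect_error(generate_force_curve(-5, inst), "positive")
  expect_error(generate_force_curve(3000, inst, contact_offset = 7e-6),
               "within the z ramp")
})

test_that("map datasets have the expected shape", {
  preset <- tissue_preset(NULL, mean_kPa = 5, sd_kPa = 0, pixel_cv = 0)
  inst <- inst_noiseless("colloidal", grid_n = 16)
  ds <- generate_map_dataset(preset, inst, n_maps = 3, seed = 2)
  expect_identical(sum(lengths(ds$curves)), 768L)
  expect_length(ds$fields, 3L)
  pix <- ds$curves[[1]][[17]]$pixel
  expect_identical(pix, c(1L, 2L))
})

test_that("section phantoms honour geometry and Poisson densities", {
  ph <- generate_section_phantom(seed = 42)
  expect_setequal(unique(as.vector(ph$labels)),
                  c("myocardium", "DAPI_plus", "DAPI_minus",
                    "DAPI_plus_plus"))
  # fibrin band is the requested rectangle
  mor <- fibrin_morphometry(ph$labels == "DAPI_minus",
                            pixel_um = ph$pixel_um)
  expect_equal(mor$length_um, ph$band$length_um)
  expect_equal(mor$width_um, ph$band$width_um)
  # empirical densities within 3 Poisson SE of the request
  for (lab in c("DAPI_plus_plus", "DAPI_plus", "DAPI_minus")) {
    dens_req <- switch(lab, DAPI_plus_plus = ph$densities[["center"]],
                       DAPI_plus = ph$densities[["border"]],
                       DAPI_minus = ph$densities[["fibrin"]])
    area <- sum(ph$labels == lab) * ph$pixel_um^2
    n_obs <- sum(ph$nuclei$region == lab)
    expect_lt(abs(n_obs - dens_req * area), 3 * sqrt(dens_req * area) + 1)
  }
  # nuclei density ordering holds by construction
  dens_of <- vapply(c("DAPI_plus_plus", "DAPI_plus", "DAPI_minus"),
                    function(lab) {
                      sum(ph$nuclei$region == lab) /
                        (sum(ph$labels == lab) * ph$pixel_um^2)
                    }, numeric(1))
  expect_gt(dens_of[["DAPI_plus_plus"]], dens_of[["DAPI_plus"]])
  expect_gt(dens_of[["DAPI_plus"]], dens_of[["DAPI_minus"]])
})

test_that("phantom edge cases behave", {
  # zero density in the fibrin band leaves it empty
  ph0 <- generate_section_phantom(
    densities = c(center = 0.008, border = 0.003, fibrin = 0,
                  myocardium = 0.006), seed = 3)
  expect_identical(sum(ph0$nuclei$region == "DAPI_minus"), 0L)
  expect_error(generate_section_phantom(band_width_um = 500),
               "overlapping region geometry")
  expect_error(generate_section_phantom(band_width_um = -1), "> 0")
  expect_error(generate_section_phantom(
    densities = c(center = 0.001, border = 0.003, fibrin = 0.0005,
                  myocardium = 0.006)), "center >= border")
})

test_that("cell tables are Bernoulli with the preset probability", {
  p0 <- cell_preset(NULL, p_positive = 0)
  expect_identical(sum(generate_cell_table(p0, 500, seed = 1)$positive),
                   0L)
  p1 <- cell_preset(NULL, p_positive = 1)
  expect_identical(sum(generate_cell_table(p1, 500, seed = 1)$positive),
                   500L)
  py <- cell_preset("yap_fibrin_dmso")
  tab <- generate_cell_table(py, 1e5, seed = 8)
  se <- sqrt(0.345 * 0.655 / 1e5)
  expect_lt(abs(mean(tab$positive) - 0.345), 3 * se)
  expect_error(generate_cell_table(py, 0), "n_cells")
})
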
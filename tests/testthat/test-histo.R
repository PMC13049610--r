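test_that("nuclei density counts centres in half-open windows", {
  nuc <- data.frame(x_um = seq(5, 95, by = 10), y_um = rep(5, 10))
  win <- data.frame(x0 = 0, y0 = 0, x1 = 10, y1 = 10)
  res <- nuclei_density(nuc, win)
  expect_equal(res$density_per_um2, 0.01)
  expect_equal(nuclei_density(nuc, data.frame(x0 = 0, y0 = 50, x1 = 100,
                                              y1 = 100))$density_per_um2,
               0)
  # boundary convention: left-closed, right-open
  b <- data.frame(x_um = c(0, 10), y_um = c(0, 0))
  expect_equal(nuclei_density(b, win)$count, 1)
  expect_error(nuclei_density(nuc, data.frame(x0 = 0, y0 = 0, x1 = 0,
                                              y1 = 10)), "degenerate")
})

test_that("densities are translation invariant and Poisson-consistent", {
  ph <- generate_section_phantom(seed = 10)
  win <- data.frame(x0 = c(100, 300), y0 = c(20, 60),
                    x1 = c(150, 350), y1 = c(70, 110))
  d1 <- nuclei_density(ph$nuclei, win)
  shift <- ph$nuclei
  shift$x_um <- shift$x_um + 13.7
  shift$y_um <- shift$y_um - 4.2
  win2 <- win
  win2$x0 <- win$x0 + 13.7; win2$x1 <- win$x1 + 13.7
  win2$y0 <- win$y0 - 4.2; win2$y1 <- win$y1 - 4.2
  expect_equal(nuclei_density(shift, win2)$count, d1$count)
  # homogeneous Poisson field: mean window density within 3 SE
  set.seed(20)
  lam <- 0.005
  n <- rpois(1, lam * 1000 * 1000)
  nuc <- data.frame(x_um = runif(n, 0, 1000), y_um = runif(n, 0, 1000))
  wins <- expand.grid(ix = 0:9, iy = 0:4)
  wins <- data.frame(x0 = wins$ix * 50, y0 = wins$iy * 50,
                     x1 = wins$ix * 50 + 50, y1 = wins$iy * 50 + 50)
  dens <- nuclei_density(nuc, wins)$density_per_um2
  se <- sqrt(lam / (2500 * nrow(wins)))
  expect_lt(abs(mean(dens) - lam), 3 * se)
})

test_that("region classification is correct, ordered and monotone", {
  expect_identical(classify_regions(c(0.0002, 0.003, 0.01),
                                    t_low = 0.001, t_high = 0.006),
                   c("DAPI_minus", "DAPI_plus", "DAPI_plus_plus"))
  expect_true(all(classify_regions(rep(0.0005, 10), 0.001, 0.006) ==
                    "DAPI_minus"))
  expect_error(classify_regions(0.1, t_low = 0.5, t_high = 0.2),
               "t_low < t_high")
  # monotone: raising t_low never turns DAPI- into a denser class
  set.seed(2)
  dens <- runif(200, 0, 0.01)
  lab1 <- classify_regions(dens, 0.001, 0.006)
  lab2 <- classify_regions(dens, 0.002, 0.006)
  expect_true(all(lab2[lab1 == "DAPI_minus"] == "DAPI_minus"))
})

test_that("phantom classification agrees with ground truth away from
           boundaries", {
  ph <- generate_section_phantom(seed = 99)
  dm <- density_map(ph$nuclei, ph$extent_um)
  lab <- classify_regions(dm$density)
  # expected class per window from the density regime of the true label at
  # the window centre; windows overlapping a region boundary are excluded
  expected <- matrix(NA_character_, nrow(lab), ncol(lab))
  pure <- matrix(FALSE, nrow(lab), ncol(lab))
  half <- dm$window_um / 2
  for (i in seq_len(nrow(lab))) for (j in seq_len(ncol(lab))) {
    ys <- dm$y[i] + c(-half + 0.1, half - 0.1)
    xs <- dm$x[j] + c(-half + 0.1, half - 0.1)
    rows <- pmin(pmax(ceiling(ys / ph$pixel_um), 1), nrow(ph$labels))
    cols <- pmin(pmax(ceiling(xs / ph$pixel_um), 1), ncol(ph$labels))
    corner_labs <- unique(as.vector(ph$labels[rows, cols]))
    pure[i, j] <- length(corner_labs) == 1L
    truth <- ph$labels[rows[1], cols[1]]
    expected[i, j] <- switch(truth,
                             DAPI_plus_plus = "DAPI_plus_plus",
                             DAPI_minus = "DAPI_minus",
                             "DAPI_plus")   # border and myocardium
  }
  agree <- mean(lab[pure] == expected[pure])
  expect_gte(agree, 0.95)
})

test_that("fibrin morphometry measures rectangles at any orientation", {
  # axis-aligned 100 x 10 um rectangle at 1 um pixels
  mask <- matrix(FALSE, 60, 140)
  mask[21:30, 21:120] <- TRUE
  mor <- fibrin_morphometry(mask, pixel_um = 1)
  expect_equal(mor$length_um, 100)
  expect_equal(mor$width_um, 10)
  expect_length(mor$transect_widths_um, 3L)
  expect_lte(mor$width_um, mor$length_um)
  # width x length approximates the area within 5%
  expect_lt(abs(mor$width_um * mor$length_um - sum(mask)) / sum(mask),
            0.05)
  # same rectangle rotated 30 degrees: same result within a pixel
  th <- 30 * pi / 180
  rot <- matrix(FALSE, 140, 140)
  ctr <- 70
  for (i in seq_len(140)) for (j in seq_len(140)) {
    u <- (j - ctr) * cos(th) + (i - ctr) * sin(th)
    v <- -(j - ctr) * sin(th) + (i - ctr) * cos(th)
    rot[i, j] <- abs(u) <= 50 & abs(v) <= 5
  }
  mr <- fibrin_morphometry(rot, pixel_um = 1)
  expect_lt(abs(mr$length_um - 100), 1.5)
  expect_lt(abs(mr$width_um - 10), 1.5)
  # degenerate single-pixel mask
  one <- matrix(FALSE, 5, 5)
  one[3, 3] <- TRUE
  m1 <- fibrin_morphometry(one, pixel_um = 2)
  expect_equal(m1$length_um, 2)
  expect_equal(m1$width_um, 2)
  expect_error(fibrin_morphometry(matrix(FALSE, 5, 5)), "empty mask")
  split_mask <- matrix(FALSE, 5, 5)
  split_mask[1, 1] <- TRUE
  split_mask[5, 5] <- TRUE
  expect_error(fibrin_morphometry(split_mask), "connected")
})

test_that("area fractions behave like set measures", {
  roi <- matrix(c(TRUE, TRUE, TRUE, TRUE), 2, 2)
  expect_equal(area_fraction(roi, roi), 100)
  expect_equal(area_fraction(!roi, roi), 0)
  half <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  expect_equal(area_fraction(half, roi), 50)
  expect_error(area_fraction(roi, !roi), "empty region")
})

test_that("positive fractions per group recover preset probabilities", {
  tab <- data.frame(region = rep(c("a", "b"), c(100, 50)),
                    positive = c(rep(c(TRUE, FALSE), c(34, 66)),
                                 rep(FALSE, 50)))
  pf <- positive_fraction(tab)
  expect_equal(pf$percent_positive[pf$region == "a"], 34)
  expect_equal(pf$percent_positive[pf$region == "b"], 0)
  big <- generate_cell_table(cell_preset("yap_periphery_dmso"), 1e5,
                             seed = 6)
  pf2 <- positive_fraction(big)
  se <- 100 * sqrt(0.228 * 0.772 / 1e5)
  expect_lt(abs(pf2$percent_positive - 22.8), 3 * se)
  expect_error(positive_fraction(tab[0, ]), "empty")
})

test_that("masks round-trip through CSV", {
  ph <- generate_section_phantom(seed = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_mask(ph$labels == "DAPI_minus", path)
  back <- read_mask(path)
  expect_equal(unname(back == 1), unname(ph$labels == "DAPI_minus"))
})
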
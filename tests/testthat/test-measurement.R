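test_that("segmentation finds exactly the rendered particles", {
  masks <- segment_particles(img3$image, co_default)
  expect_length(masks, 3)
  # masks are disjoint
  expect_true(max(Reduce(`+`, lapply(masks, `+`, 0))) <= 1)
})

test_that("blank images yield an empty particle list with a warning", {
  blank <- matrix(0.02, 80, 80)
  expect_warning(masks <- segment_particles(blank, co_default), "no particles")
  expect_length(masks, 0)
})

test_that("particles straddling the border are excluded when flagged", {
  tm <- make_thickness_map(coccolith_spec(2.5), co_default)
  ri <- render_image(list(tm), cal_default, co_default, noise_sd = 0)
  img <- ri$image
  # crop so the particle touches the left edge
  cropped <- img[, 40:ncol(img)]
  expect_warning(masks <- segment_particles(cropped, co_default),
                 "no particles")
  expect_length(masks, 0)
  masks2 <- segment_particles(
    cropped, co_default, segmentation_params(exclude_border = FALSE))
  expect_length(masks2, 1)
})

test_that("a uniform-thickness disk measures to its analytic geometry", {
  # hand-built disk, bypassing the coccolith profile: diameter 2 um,
  # uniform thickness 0.1 um
  px <- co_default$pixel_size
  n <- 151
  ctr <- (n + 1) / 2
  xs <- (seq_len(n) - ctr) * px
  d2 <- outer(xs^2, xs^2, `+`)
  map <- matrix(0, n, n)
  map[d2 <= 1^2] <- 0.1
  tm <- structure(list(map = map, pixel_size = px,
                       spec = coccolith_spec(2), truth = NULL),
                  class = "thickness_map")
  grey <- matrix(retardation_to_grey(
    cal_default, thickness_to_retardation(as.vector(map), co_default)), n, n)
  mask <- map > 0
  m <- measure_particle(mask, grey, cal_default, co_default)
  expect_lt(abs(m$length_um - 2.0), 2 * px)
  expect_lt(abs(m$width_um - 2.0), 2 * px)
  expect_equal(m$mean_thickness_um, 0.1, tolerance = 1e-6)
  # integration identity holds exactly
  expect_equal(m$mass_pg, co_default$density * m$area_um2 *
                 m$mean_thickness_um)
  # uniform thickness distribution has zero skewness
  expect_equal(m$skewness, 0)
  # Feret diameter of a disk is the diameter
  m2 <- measure_particle(mask, grey, cal_default, co_default, feret = TRUE)
  expect_lt(abs(m2$feret_um - 2.0), 2 * px)
})

test_that("skewness follows the Fisher-Pearson moment definition", {
  # brute-force moments: {1,1,1,5} -> m2 = 3, m3 = 6, g1 = 6/3^1.5
  expect_equal(moment_skewness(c(1, 1, 1, 5)), 6 / 3^1.5, tolerance = 1e-12)
  expect_equal(moment_skewness(c(1, 1, 2, 2)), 0)
  x <- rexp(200)
  # invariant under positive affine transformation
  expect_equal(moment_skewness(2.5 * x + 7), moment_skewness(x))
  # sign flips under mirroring
  expect_equal(moment_skewness(-x), -moment_skewness(x))
})

test_that("tiny masks and out-of-range greys are rejected", {
  mask <- matrix(FALSE, 10, 10); mask[5, 5:6] <- TRUE
  img <- matrix(0.1, 10, 10)
  expect_error(measure_particle(mask, img, cal_default, co_default),
               "4 pixels")
  mask[6, 5:6] <- TRUE; mask[7, 5] <- TRUE
  img[5, 5] <- 0.999
  expect_error(measure_particle(mask, img, cal_default, co_default),
               "first-order")
})

test_that("zero-noise measurement recovers ground truth within tolerance", {
  meas <- measure_sample(list(img3), cal_default, co_default,
                         strain = "T", salinity = 34)
  df <- meas$measurements
  expect_equal(nrow(df), 3)
  idx <- match_particles(df, img3$truth)
  expect_false(anyNA(idx))
  tr <- img3$truth[idx, ]
  expect_true(all(abs(df$length_um - tr$length_um) <
                    2 * co_default$pixel_size))
  expect_true(all(abs(df$mass_pg / tr$mass_pg - 1) < 0.02))
  expect_true(all(abs(df$mean_thickness_um / tr$mean_thickness_um - 1)
                  < 0.02))
  # identity m = d * area * T-bar holds exactly for every particle
  expect_equal(df$mass_pg,
               co_default$density * df$area_um2 * df$mean_thickness_um)
})

test_that("measuring the same images twice gives identical tables", {
  m1 <- measure_sample(list(img3), cal_default, co_default)
  m2 <- measure_sample(list(img3), cal_default, co_default)
  expect_identical(m1$measurements, m2$measurements)
})

test_that("a blank image yields an empty sample with a warning", {
  blank <- matrix(0.02, 60, 60)
  expect_warning(tb <- measure_sample(list(blank), cal_default, co_default),
                 "no particles")
  expect_equal(nrow(tb$measurements), 0)
})

test_that("uncertainty propagation is quadrature at 95% confidence", {
  meas <- data.frame(length_um = 2.7, mean_thickness_um = 0.07,
                     mass_pg = 0.8, n_pixels = 10000)
  zero <- uncertainty_budget(grey_noise_sd = 0, cal_rel = 0, light_rel = 0,
                             resolution_rel = 0, pixel_rel = 0, edge_px = 0)
  expect_equal(unname(propagate_uncertainty(meas, zero, co_default)),
               c(0, 0, 0))
  # two equal independent relative components combine as a*sqrt(2)
  two <- uncertainty_budget(grey_noise_sd = 0, cal_rel = 0.03,
                            light_rel = 0.03, resolution_rel = 0,
                            pixel_rel = 0, edge_px = 0)
  u <- propagate_uncertainty(meas, two, co_default)
  expect_equal(u[["u_mass"]] / meas$mass_pg, 1.96 * 0.03 * sqrt(2),
               tolerance = 1e-10)
  expect_error(uncertainty_budget(cal_rel = -0.1), ">= 0")
})

test_that("default budget lands in the stated uncertainty bands", {
  meas <- data.frame(length_um = 2.7, mean_thickness_um = 0.07,
                     mass_pg = 0.8, n_pixels = 12000)
  u <- propagate_uncertainty(meas, uncertainty_budget(), co_default,
                             cal = cal_default)
  expect_lt(abs(u[["u_length"]] - 0.2), 0.05)
  expect_lt(abs(u[["u_thickness"]] - 0.007), 0.002)
  rel <- u[["u_mass"]] / meas$mass_pg
  expect_gte(rel, 0.13); expect_lte(rel, 0.20)
  # G. oceanica-scale particle: absolute mass uncertainty near 0.9 pg
  big <- data.frame(length_um = 4.7, mean_thickness_um = 0.15,
                    mass_pg = 6.1, n_pixels = 45000)
  ub <- propagate_uncertainty(big, uncertainty_budget(), co_default,
                              cal = cal_default)
  expect_lt(abs(ub[["u_mass"]] - 0.9), 0.25)
})
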
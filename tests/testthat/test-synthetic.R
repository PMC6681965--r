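test_that("rasterized coccoliths have the requested extent and exact mass identity", {
  spec <- coccolith_spec(3.0, aspect_ratio = 1.25, orientation = 0)
  tm <- make_thickness_map(spec, co_default)
  # support extent along the major axis within one pixel of the length
  cols_on <- range(which(colSums(tm$map > 0) > 0))
  extent <- (cols_on[2] - cols_on[1] + 1) * co_default$pixel_size
  expect_lt(abs(extent - 3.0), co_default$pixel_size)
  # mass equals the direct summation oracle
  expect_equal(tm$truth$mass_pg,
               2.71 * 3e-4 * sum(tm$map))
  # central area carries no calcite
  ctr <- dim(tm$map) %/% 2
  expect_equal(tm$map[ctr[1], ctr[2]], 0)
})

test_that("degenerate geometries are flagged", {
  expect_warning(
    tm <- make_thickness_map(coccolith_spec(2.5, thickness_peak = 0),
                             co_default),
    "zero mass")
  expect_true(tm$truth$empty)
  expect_equal(tm$truth$mass_pg, 0)
  expect_error(make_thickness_map(coccolith_spec(0.02), co_default),
               "unresolvable")
  expect_error(coccolith_spec(-1), "length")
  expect_error(coccolith_spec(2, aspect_ratio = 0.8), "aspect_ratio")
  expect_error(coccolith_spec(2, central_fraction = 1), "central_fraction")
})

test_that("mass shrinks monotonically as the central opening grows", {
  masses <- vapply(c(0.2, 0.5, 0.8, 0.95), function(fc) {
    make_thickness_map(coccolith_spec(2.8, central_fraction = fc),
                       co_default)$truth$mass_pg
  }, numeric(1))
  expect_true(all(diff(masses) < 0))
})

test_that("isometric coupling without residual gives perfectly correlated thickness", {
  pop <- population_spec(n = 50, coupling = "isometric", coupling_c = 0.026,
                         sd_thickness = 0)
  s <- sample_population(pop, 34, seed = 3)
  expect_equal(cor(s$truth$length_um, s$truth$mean_thickness_um), 1)
})

test_that("decoupled thickness is uncorrelated with length", {
  pop <- population_spec(n = 1000, coupling = "decoupled",
                         thickness_mean = 0.07, sd_thickness = 0.006)
  s <- sample_population(pop, 34, seed = 4)
  expect_lt(abs(cor(s$truth$length_um, s$truth$mean_thickness_um)), 0.08)
})

test_that("sampled lengths follow the salinity-shifted truncated normal", {
  pop <- population_spec(n = 1000, mean_length = 2.7, sd_length = 0.3,
                         beta_salinity = 0.05, ref_salinity = 34)
  s <- sample_population(pop, 34, seed = 5)
  expect_lt(abs(mean(s$truth$length_um) - 2.7), 3 * 0.3 / sqrt(1000))
  s44 <- sample_population(pop, 44, seed = 6)
  expect_lt(abs(mean(s44$truth$length_um) - 3.2), 3 * 0.3 / sqrt(1000))
})

test_that("ground-truth k_s is constant across lengths under isometric scaling", {
  # fixed shape parameters, thickness proportional to length: the regime
  # where the cubic mass model is exact up to discretization
  ks <- vapply(c(2.2, 2.7, 3.2, 4.2, 5.0), function(L) {
    make_thickness_map(
      coccolith_spec(L, thickness_peak = 0.12 * L / 2.7), co_default
    )$truth$ks
  }, numeric(1))
  expect_lt((max(ks) - min(ks)) / mean(ks), 0.03)
})

test_that("decoupled populations have mass growing as length squared", {
  pop <- population_spec(n = 400, coupling = "decoupled", sd_length = 0.5,
                         thickness_mean = 0.07, sd_thickness = 0,
                         aspect_sd = 0)
  s <- sample_population(pop, 34, seed = 8)
  fit <- linear_regression(log(s$truth$length_um), log(s$truth$mass_pg))
  expect_equal(fit$slope, 2, tolerance = 1e-6)
})

test_that("study simulation is reproducible and bookkeeps the full design", {
  design <- default_study_design()
  expect_length(design, 24)
  st1 <- simulate_study(design, seed = 21, mode = "table")
  st2 <- simulate_study(design, seed = 21, mode = "table")
  expect_identical(study_tables(st1), study_tables(st2))
  all_rows <- do.call(rbind, lapply(study_tables(st1),
                                    `[[`, "measurements"))
  expect_equal(nrow(all_rows), 720)
  expect_equal(length(unique(paste(all_rows$strain, all_rows$salinity))), 24)
  # distinct seeds give distinct draws
  st3 <- simulate_study(design, seed = 22, mode = "table")
  expect_false(identical(study_tables(st1), study_tables(st3)))
})

test_that("duplicate design cells are rejected", {
  pop <- population_spec()
  design <- list(list(strain = "A", salinity = 34, pop = pop),
                 list(strain = "A", salinity = 34, pop = pop))
  expect_error(simulate_study(design), "duplicate")
})

test_that("an empty map list renders to uniform background plus noise", {
  ri <- render_image(list(), cal_default, co_default, noise_sd = 0)
  expect_true(all(ri$image == quantize_grey_for_test(cal_default$offset)))
  set.seed(1)
  ri2 <- render_image(list(), cal_default, co_default, noise_sd = 5e-4)
  expect_lt(abs(mean(ri2$image) - cal_default$offset), 1e-4)
  expect_lt(abs(sd(ri2$image) - 5e-4), 1e-4)
})

test_that("reference-film patches render at the calibration reference greys", {
  tm <- make_thickness_map(coccolith_spec(2.5), co_default)
  set.seed(2)
  ri <- render_image(list(tm), cal_default, co_default, noise_sd = 2e-4,
                     ref_patches = TRUE, patch_px = 16L)
  expected <- retardation_to_grey(cal_default, c(31, 129))
  p1 <- mean(ri$image[5:20, 5:20])
  p2 <- mean(ri$image[5:20, 29:44])
  tol <- 3 * 2e-4 / 16 + 1 / 65535
  expect_lt(abs(p1 - expected[1]), tol)
  expect_lt(abs(p2 - expected[2]), tol)
})

test_that("analytic ground truth agrees with the rasterized ground truth", {
  pop <- population_spec(n = 6, coupling = "isometric", sd_thickness = 0)
  s <- sample_population(pop, 34, seed = 13)
  for (i in seq_along(s$specs)) {
    tm <- make_thickness_map(s$specs[[i]], co_default)
    expect_equal(tm$truth$mass_pg, s$truth$mass_pg[i], tolerance = 0.02)
    expect_equal(tm$truth$mean_thickness_um, s$truth$mean_thickness_um[i],
                 tolerance = 0.02)
    expect_equal(tm$truth$skewness, s$truth$skewness[i], tolerance = 0.05)
  }
})
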
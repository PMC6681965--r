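#' Measurement uncertainty budget
#'
#' First-order (GUM-style) uncertainty components of the imaging method. The
#' relative components are standard (1-sigma) relative uncertainties; they
#' are combined in quadrature and scaled by 1.96 so stated uncertainties are
#' at 95% confidence. Defaults reflect the method's known error sources:
#' calibration-curve fit, illumination variation, calibration-curve
#' resolution, pixel-size (stage micrometer) calibration, edge localization
#' of the segmentation, and camera grey noise.
#'
#' @param grey_noise_sd Camera grey noise sd (normalized grey units).
#' @param cal_rel Relative sd of the grey-to-retardation calibration.
#' @param light_rel Relative sd from illumination variation (mass only).
#' @param resolution_rel Relative sd from calibration-curve resolution
#'   (mass only).
#' @param pixel_rel Relative sd of the pixel-size calibration.
#' @param edge_px Edge localization sd per boundary, in pixels.
#' @return Named list of budget components.
#' @export
uncertainty_budget <- function(grey_noise_sd = 2e-4, cal_rel = 0.05,
                               light_rel = 0.04, resolution_rel = 0.03,
                               pixel_rel = 0.01, edge_px = 4) {
  b <- list(grey_noise_sd = grey_noise_sd, cal_rel = cal_rel,
            light_rel = light_rel, resolution_rel = resolution_rel,
            pixel_rel = pixel_rel, edge_px = edge_px)
  if (any(unlist(b) < 0)) stop("budget components must be >= 0")
  b
}

# per-pixel thickness sd induced by grey noise, from the local slope of the
# inverse calibration at the particle's mean signal grey
thickness_noise_per_px <- function(mean_thickness, cal, constants,
                                   grey_noise_sd) {
  if (grey_noise_sd == 0 || is.null(cal)) return(0)
  g <- retardation_to_grey(cal, thickness_to_retardation(mean_thickness,
                                                         constants))
  dg <- max(grey_noise_sd, 1e-6)
  g1 <- min(g + dg, cal$gain)
  g0 <- max(g - dg, cal$offset)
  t1 <- retardation_to_thickness(grey_to_retardation(cal, g1, quiet = TRUE),
                                 constants)
  t0 <- retardation_to_thickness(grey_to_retardation(cal, g0, quiet = TRUE),
                                 constants)
  abs(t1 - t0) / (g1 - g0) * grey_noise_sd
}

#' Propagate measurement uncertainties for one particle
#'
#' Combines the budget components in quadrature and scales by 1.96 to report
#' standard uncertainties at 95% confidence:
#' * length: pixel-size calibration plus edge localization at both
#'   boundaries;
#' * mean thickness: calibration-curve uncertainty plus grey noise averaged
#'   over the particle's pixels;
#' * mass: calibration, illumination, curve-resolution, pixel-area (twice
#'   the linear pixel-size component) and the averaged grey-noise term.
#'
#' @param measurement One-row data frame with `length_um`,
#'   `mean_thickness_um`, `mass_pg` and `n_pixels`.
#' @param budget See [uncertainty_budget()].
#' @param constants An `optical_constants` object.
#' @param cal Optional `retardation_calibration` used to evaluate the local
#'   slope of the inverse calibration for the grey-noise term.
#' @return Named numeric vector `c(u_length, u_thickness, u_mass)` (um, um,
#'   pg) at 95% confidence.
#' @export
propagate_uncertainty <- function(measurement, budget = uncertainty_budget(),
                                  constants = optical_constants(),
                                  cal = NULL) {
  stopifnot(is.data.frame(measurement), nrow(measurement) == 1L)
  if (is.na(measurement$length_um) || measurement$n_pixels < 1)
    stop("empty measurement")
  l <- measurement$length_um
  tbar <- measurement$mean_thickness_um
  m <- measurement$mass_pg
  N <- measurement$n_pixels
  px <- constants$pixel_size

  sd_t_px <- thickness_noise_per_px(tbar, cal, constants,
                                    budget$grey_noise_sd)
  sd_l <- sqrt(2 * (budget$edge_px * px)^2 + (budget$pixel_rel * l)^2)
  sd_T <- sqrt((budget$cal_rel * tbar)^2 + sd_t_px^2 / N)
  rel_noise <- if (tbar > 0) sd_t_px / (tbar * sqrt(N)) else 0
  rel_m <- sqrt(budget$cal_rel^2 + budget$light_rel^2 +
                  budget$resolution_rel^2 + (2 * budget$pixel_rel)^2 +
                  rel_noise^2)
  c(u_length = 1.96 * sd_l, u_thickness = 1.96 * sd_T,
    u_mass = 1.96 * rel_m * m)
}

# ImageJ-style equal-area moment ellipse: axis ratio from the second-moment
# eigenvalues, axes rescaled so the ellipse area equals the mask area
moment_ellipse <- function(mask_idx, nrow_img, pixel_size) {
  rows <- ((mask_idx - 1) %% nrow_img) + 1
  cols <- ((mask_idx - 1) %/% nrow_img) + 1
  x <- cols * pixel_size
  y <- rows * pixel_size
  n <- length(x)
  cx <- mean(x); cy <- mean(y)
  # + pixel_size^2/12: second moment of the square pixel footprint
  sxx <- mean((x - cx)^2) + pixel_size^2 / 12
  syy <- mean((y - cy)^2) + pixel_size^2 / 12
  sxy <- mean((x - cx) * (y - cy))
  tr <- sxx + syy
  det <- sxx * syy - sxy^2
  disc <- sqrt(max(tr^2 / 4 - det, 0))
  l1 <- tr / 2 + disc
  l2 <- max(tr / 2 - disc, .Machine$double.eps)
  ratio <- sqrt(l1 / l2)
  area <- n * pixel_size^2
  b <- sqrt(area / (pi * ratio))
  a <- ratio * b
  list(major = 2 * a, minor = 2 * b, aspect = ratio, cx = cx, cy = cy)
}

# maximum Feret diameter from the convex hull of the mask pixels
feret_diameter <- function(mask_idx, nrow_img, pixel_size) {
  rows <- ((mask_idx - 1) %% nrow_img) + 1
  cols <- ((mask_idx - 1) %/% nrow_img) + 1
  pts <- cbind(cols, rows)
  h <- grDevices::chull(pts)
  hp <- pts[h, , drop = FALSE]
  d <- 0
  for (i in seq_len(nrow(hp))) {
    di <- sqrt((hp[, 1] - hp[i, 1])^2 + (hp[, 2] - hp[i, 2])^2)
    d <- max(d, max(di))
  }
  (d + 1) * pixel_size # +1 px: pixel extent beyond centre-to-centre distance
}

#' Measure one segmented coccolith
#'
#' Converts the particle's grey values to calcite thickness through the
#' calibration, then reports moment-ellipse length and width (ImageJ
#' convention: equal second moments and equal area), area, mean thickness,
#' mass (`density * pixel_area * sum(thickness)` -- so the identity
#' `mass = density * area * mean_thickness` holds exactly), Fisher-Pearson
#' skewness of the within-mask thickness values, and propagated 95%
#' uncertainties.
#'
#' @param mask Logical matrix (particle mask, holes filled).
#' @param image Numeric grey matrix in `[0, 1]`.
#' @param cal A `retardation_calibration`.
#' @param constants An `optical_constants` object.
#' @param budget See [uncertainty_budget()]; its `grey_noise_sd` should match
#'   the imaging conditions.
#' @param feret Also report the maximum Feret diameter.
#' @param skewness_on `"thickness"` (default) or `"grey"`: compute the shape
#'   descriptor on calibrated thickness values or on raw grey values (they
#'   differ under the nonlinear calibration).
#' @return One-row data frame: `length_um`, `width_um`, `aspect_ratio`,
#'   `area_um2`, `mean_thickness_um`, `mass_pg`, `skewness`, `ks`,
#'   `n_pixels`, `n_clamped`, `cx_um`, `cy_um`, `u_length`, `u_thickness`,
#'   `u_mass` (and `feret_um` if requested).
#' @export
measure_particle <- function(mask, image, cal, constants,
                             budget = uncertainty_budget(), feret = FALSE,
                             skewness_on = c("thickness", "grey")) {
  skewness_on <- match.arg(skewness_on)
  stopifnot(is.matrix(mask), all(dim(mask) == dim(image)),
            inherits(cal, "retardation_calibration"),
            inherits(constants, "optical_constants"))
  idx <- which(mask)
  if (length(idx) < 4L) stop("mask smaller than 4 pixels")
  greys <- image[idx]
  ret <- grey_to_retardation(cal, greys, quiet = TRUE)
  thick <- retardation_to_thickness(as.numeric(ret), constants)

  ell <- moment_ellipse(idx, nrow(image), constants$pixel_size)
  n_px <- length(idx)
  area <- n_px * constants$pixel_area
  mass <- constants$density * constants$pixel_area * sum(thick)
  tbar <- mean(thick)
  out <- data.frame(
    length_um = ell$major, width_um = ell$minor, aspect_ratio = ell$aspect,
    area_um2 = area, mean_thickness_um = tbar, mass_pg = mass,
    skewness = if (skewness_on == "thickness") moment_skewness(thick)
               else moment_skewness(greys),
    ks = if (mass > 0) ks_from_mass_length(mass, ell$major,
                                           constants$density) else 0,
    n_pixels = n_px, n_clamped = attr(ret, "n_clamped"),
    cx_um = ell$cx, cy_um = ell$cy
  )
  if (feret)
    out$feret_um <- feret_diameter(idx, nrow(image), constants$pixel_size)
  u <- propagate_uncertainty(out, budget, constants, cal)
  out$u_length <- u[["u_length"]]
  out$u_thickness <- u[["u_thickness"]]
  out$u_mass <- u[["u_mass"]]
  out
}

#' Measure all coccoliths of one sample
#'
#' Segments and measures every image of a sample, concatenating the particle
#' measurements in deterministic order (by image, then centroid).
#'
#' @param images List of grey matrices or `rendered_image` objects.
#' @param cal A `retardation_calibration`.
#' @param constants An `optical_constants` object.
#' @param params Segmentation parameters, see [segmentation_params()].
#' @param strain,salinity,species Sample labels.
#' @param budget Uncertainty budget.
#' @param feret Also report Feret diameters.
#' @return A `sample_table`; its measurements carry `image` and
#'   `coccolith_id` columns in addition to the [measure_particle()] schema.
#' @export
measure_sample <- function(images, cal, constants,
                           params = segmentation_params(),
                           strain = "sample", salinity = NA_real_,
                           species = NA_character_,
                           budget = uncertainty_budget(), feret = FALSE) {
  if (length(images) < 1L) stop("at least one image is required")
  rows <- list()
  for (j in seq_along(images)) {
    img <- images[[j]]
    if (inherits(img, "rendered_image")) img <- img$image
    masks <- withCallingHandlers(
      segment_particles(img, constants, params),
      warning = function(w) invokeRestart("muffleWarning")
    )
    for (msk in masks) {
      pm <- tryCatch(
        measure_particle(msk, img, cal, constants, budget, feret = feret),
        error = function(e)
          stop(sprintf("image %d: %s", j, conditionMessage(e)))
      )
      pm$image <- j
      rows[[length(rows) + 1L]] <- pm
    }
  }
  if (length(rows) == 0L) {
    warning(sprintf("sample %s: no particles found in %d image(s)",
                    strain, length(images)))
    meas <- data.frame()
    return(suppressWarnings(sample_table(strain, salinity, meas,
                                         species = species)))
  } else {
    meas <- do.call(rbind, rows)
    meas$coccolith_id <- seq_len(nrow(meas))
    meas <- cbind(data.frame(strain = strain, salinity = salinity,
                             species = species), meas)
  }
  sample_table(strain, salinity, meas, species = species)
}

#' Match measured particles to ground-truth particles by centroid
#'
#' @param measured Data frame with `cx_um`, `cy_um` (e.g. from
#'   [measure_sample()], one image).
#' @param truth Ground-truth data frame with `cx_um`, `cy_um`.
#' @param max_dist_um Maximum centroid distance for a match.
#' @return Integer vector: for each measured row, the matching truth row
#'   index (NA when unmatched).
#' @export
match_particles <- function(measured, truth, max_dist_um = 1) {
  vapply(seq_len(nrow(measured)), function(i) {
    d <- sqrt((truth$cx_um - measured$cx_um[i])^2 +
                (truth$cy_um - measured$cy_um[i])^2)
    j <- which.min(d)
    if (d[j] <= max_dist_um) j else NA_integer_
  }, integer(1))
}
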
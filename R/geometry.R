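#' Specification of one model coccolith
#'
#' A simple placolith model: two concentric ellipses (outer shield and inner
#' central-area opening) with a smooth radial thickness profile across the
#' shield. The profile rises from a finite rim value to a peak mid-shield and
#' falls to zero at the central-area edge, giving the sharp outer boundary
#' seen in polarised-light micrographs of isolated coccoliths. The exact
#' profile form is a modelling choice; only integrated quantities (area, mean
#' thickness, mass, thickness-distribution skewness) are treated as
#' meaningful.
#'
#' @param length Outer major-axis length L in micrometres (> 0).
#' @param aspect_ratio Major/minor axis ratio (>= 1).
#' @param central_fraction Relative size of the central-area opening: the
#'   inner ellipse's axes as a fraction of the outer ones (in `[0, 1)`).
#' @param thickness_peak Peak shield thickness in micrometres (>= 0).
#' @param rim_floor Thickness at the outer rim as a fraction of the peak
#'   (in `[0, 1]`); a positive floor gives a crisp rim edge.
#' @param position Centre position `c(x, y)` in micrometres (used when a
#'   coccolith is placed on an image canvas).
#' @param orientation Major-axis orientation in radians.
#' @return An object of class `coccolith_spec`.
#' @export
coccolith_spec <- function(length, aspect_ratio = 1.25,
                           central_fraction = 0.45, thickness_peak = 0.12,
                           rim_floor = 0.35, position = c(0, 0),
                           orientation = 0) {
  stopifnot(is.numeric(length), is.numeric(aspect_ratio),
            is.numeric(central_fraction), is.numeric(thickness_peak))
  if (length <= 0) stop("coccolith `length` must be > 0")
  if (aspect_ratio < 1) stop("`aspect_ratio` must be >= 1")
  if (central_fraction < 0 || central_fraction >= 1)
    stop("`central_fraction` must be in [0, 1)")
  if (thickness_peak < 0) stop("`thickness_peak` must be >= 0")
  if (rim_floor < 0 || rim_floor > 1) stop("`rim_floor` must be in [0, 1]")
  structure(
    list(length = length, aspect_ratio = aspect_ratio,
         central_fraction = central_fraction,
         thickness_peak = thickness_peak, rim_floor = rim_floor,
         position = position, orientation = orientation),
    class = "coccolith_spec"
  )
}

# Radial thickness profile on the normalized elliptical radius rho:
# zero inside the central area (rho < fc) and outside the shield (rho > 1);
# across the shield a raised half-sine from rim_floor at the rim to 1 at
# mid-shield, scaled by the peak thickness.
shield_profile <- function(rho, central_fraction, rim_floor) {
  out <- numeric(length(rho))
  on_shield <- rho >= central_fraction & rho <= 1
  # v runs 0 (central-area edge) .. 1 (outer rim): a half-sine peaking
  # mid-shield plus a linear ramp so the outer rim keeps a finite thickness
  # step (sharp edge), while the central-area edge tapers to zero
  v <- (rho[on_shield] - central_fraction) / (1 - central_fraction)
  out[on_shield] <- (1 - rim_floor) * sin(pi * v) + rim_floor * v
  out
}

# Moments of the thickness distribution over the full outer-ellipse support
# (central-area zeros included), with rho distributed as 2*rho on [0, 1].
# Used for analytic ground truth in table mode.
profile_moments <- function(central_fraction, rim_floor, peak = 1) {
  f <- function(rho) shield_profile(rho, central_fraction, rim_floor) * peak
  mom <- function(k) {
    stats::integrate(function(r) f(r)^k * 2 * r, lower = 0, upper = 1,
                     subdivisions = 400L, rel.tol = 1e-9)$value
  }
  m1 <- mom(1); m2 <- mom(2); m3 <- mom(3)
  mu2 <- m2 - m1^2
  mu3 <- m3 - 3 * m1 * m2 + 2 * m1^3
  list(mean = m1, skewness = mu3 / mu2^1.5)
}

# Scale factor converting a target mean thickness (over the outer-ellipse
# support) to the peak thickness parameter of the profile.
mean_profile_factor <- function(central_fraction, rim_floor) {
  profile_moments(central_fraction, rim_floor)$mean
}

#' Fisher-Pearson moment skewness
#'
#' The biased moment form `g1 = m3 / m2^(3/2)` used by common image-analysis
#' software; the adjusted (sample-size corrected) form is available via
#' `adjusted = TRUE`.
#'
#' @param x Numeric vector.
#' @param adjusted Apply the `sqrt(n(n-1))/(n-2)` correction.
#' @return Skewness (dimensionless).
#' @export
moment_skewness <- function(x, adjusted = FALSE) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3L) return(NA_real_)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  if (m2 <= 0) return(0)
  g1 <- m3 / m2^1.5
  if (adjusted) g1 <- g1 * sqrt(n * (n - 1)) / (n - 2)
  g1
}

#' Rasterize a model coccolith into a thickness map with ground truth
#'
#' Renders the coccolith's calcite thickness field onto a pixel grid at the
#' calibrated pixel size, together with the exact ground truth implied by the
#' rasterization: mass satisfies `mass = density * pixel_area * sum(map)`
#' identically.
#'
#' @param spec A `coccolith_spec`.
#' @param constants An `optical_constants` object (sets the pixel size).
#' @param margin_px Background margin around the coccolith, in pixels.
#' @return An object of class `thickness_map`: list with `map` (numeric
#'   matrix, um), `pixel_size` (um), `spec`, and `truth`, a one-row data
#'   frame with columns `length_um`, `width_um`, `aspect_ratio`,
#'   `area_um2`, `mean_thickness_um`, `mass_pg`, `skewness`, `ks`, and
#'   `empty` (flag for zero-mass particles).
#' @export
make_thickness_map <- function(spec, constants, margin_px = 4L) {
  stopifnot(inherits(spec, "coccolith_spec"),
            inherits(constants, "optical_constants"))
  px <- constants$pixel_size
  if (spec$length < 3 * px)
    stop(sprintf("coccolith length %.3g um spans < 3 pixels: unresolvable",
                 spec$length))
  a <- spec$length / 2
  b <- spec$length / (2 * spec$aspect_ratio)
  # bounding half-extents of the rotated ellipse
  co <- cos(spec$orientation); si <- sin(spec$orientation)
  hx <- sqrt((a * co)^2 + (b * si)^2)
  hy <- sqrt((a * si)^2 + (b * co)^2)
  nx <- 2L * (as.integer(ceiling(hx / px)) + margin_px)
  ny <- 2L * (as.integer(ceiling(hy / px)) + margin_px)
  # pixel-centre coordinates relative to the ellipse centre
  xs <- (seq_len(nx) - (nx + 1) / 2) * px
  ys <- (seq_len(ny) - (ny + 1) / 2) * px
  X <- matrix(xs, ny, nx, byrow = TRUE)
  Y <- matrix(ys, ny, nx)
  xr <- X * co + Y * si
  yr <- -X * si + Y * co
  rho <- sqrt((xr / a)^2 + (yr / b)^2)
  map <- spec$thickness_peak *
    matrix(shield_profile(as.vector(rho), spec$central_fraction,
                          spec$rim_floor), ny, nx)
  support <- rho <= 1
  n_support <- sum(support)
  tvals <- map[support]
  mass <- constants$density * constants$pixel_area * sum(map)
  mean_t <- if (n_support > 0) sum(map) / n_support else 0
  truth <- data.frame(
    length_um = spec$length,
    width_um = spec$length / spec$aspect_ratio,
    aspect_ratio = spec$aspect_ratio,
    area_um2 = n_support * constants$pixel_area,
    mean_thickness_um = mean_t,
    mass_pg = mass,
    skewness = moment_skewness(tvals),
    ks = ks_from_mass_length(mass, spec$length, constants$density),
    empty = mass <= 0
  )
  if (truth$empty)
    warning("coccolith has zero mass (thickness_peak = 0 or fully open)")
  structure(list(map = map, pixel_size = px, spec = spec, truth = truth),
            class = "thickness_map")
}
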
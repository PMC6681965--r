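#' Optical constants for calcite birefringence imaging
#'
#' Bundles the physical constants that convert optical retardation into
#' calcite thickness and per-pixel mass: the effective birefringence of
#' calcite under the imaging geometry, the density of calcite, and the
#' calibrated area of one image pixel.
#'
#' @param delta_n Effective birefringence (dimensionless). Default 0.172,
#'   the maximum birefringence of calcite; the effective value depends on
#'   crystallographic orientation and is configurable.
#' @param density Calcite density in pg per cubic micrometre. Default 2.71.
#' @param pixel_area Calibrated pixel area in square micrometres.
#'   Default 0.0003.
#' @return An object of class `optical_constants`: a list with elements
#'   `delta_n`, `density`, `pixel_area` and the derived `pixel_size`
#'   (micrometres, the side of one square pixel).
#' @export
optical_constants <- function(delta_n = 0.172, density = 2.71,
                              pixel_area = 3e-4) {
  stopifnot(is.numeric(delta_n), length(delta_n) == 1L,
            is.numeric(density), length(density) == 1L,
            is.numeric(pixel_area), length(pixel_area) == 1L)
  if (delta_n <= 0) stop("effective birefringence `delta_n` must be > 0")
  if (density <= 0) stop("calcite `density` must be > 0")
  if (pixel_area <= 0) stop("`pixel_area` must be > 0")
  structure(
    list(delta_n = delta_n, density = density, pixel_area = pixel_area,
         pixel_size = sqrt(pixel_area)),
    class = "optical_constants"
  )
}

#' Fit a grey-value / retardation calibration curve
#'
#' Fits the monotone map between image grey value and optical retardation
#' from reference measurements (e.g. polymer retardation films at 31 nm and
#' 129 nm imaged alongside the samples). Two model kinds are supported:
#'
#' * `"sin2"` (default): the single-wavelength crossed-circular-polarizer
#'   intensity law `grey = offset + amp * sin^2(pi * G / lambda)`, restricted
#'   to the first interference order (`G <= lambda / 2`) so the curve is
#'   strictly increasing and invertible.
#' * `"piecewise"`: monotone linear interpolation through the reference
#'   points, with the first segment extrapolated to zero retardation to
#'   define the dark offset.
#'
#' @param references A two-column matrix or data frame: retardation (nm) and
#'   grey value (normalized, typically in `[0, 1]`). At least two rows with
#'   distinct retardations, all within the first-order range.
#' @param model `"sin2"` or `"piecewise"`.
#' @param lambda Effective wavelength in nm (default 550).
#' @param tol Tolerance for reproducing the reference grey values
#'   (same units as grey).
#' @return An object of class `retardation_calibration` with elements
#'   `model`, `lambda`, `offset` (dark-offset grey), `amp`, `gain` (grey at
#'   the top of the working range), `working_range` (nm), `references`, `tol`.
#' @export
fit_retardation_curve <- function(references, model = c("sin2", "piecewise"),
                                  lambda = 550, tol = 0.02) {
  model <- match.arg(model)
  refs <- as.data.frame(references)
  if (ncol(refs) < 2L) stop("`references` needs retardation and grey columns")
  names(refs)[1:2] <- c("retardation", "grey")
  refs <- refs[order(refs$retardation), 1:2]
  if (nrow(refs) < 2L)
    stop("at least 2 reference points are required to fit a calibration")
  if (anyDuplicated(refs$retardation))
    stop("reference retardations must be distinct")
  if (any(refs$retardation < 0) || any(refs$retardation > lambda / 2))
    stop("reference retardations must lie in the first-order range [0, lambda/2]")
  if (any(diff(refs$grey) <= 0))
    stop("reference grey values must be strictly increasing with retardation")

  if (model == "sin2") {
    s <- sin(pi * refs$retardation / lambda)^2
    fit <- stats::lm.fit(cbind(1, s), refs$grey)
    offset <- unname(fit$coefficients[1])
    amp <- unname(fit$coefficients[2])
    if (!is.finite(amp) || amp <= 0)
      stop("degenerate references: fitted curve is not increasing")
    gain <- offset + amp
    working_range <- c(0, lambda / 2)
    pred <- offset + amp * s
  } else {
    # anchor the dark offset by extrapolating the first segment to 0 nm
    slope1 <- (refs$grey[2] - refs$grey[1]) /
      (refs$retardation[2] - refs$retardation[1])
    offset <- refs$grey[1] - slope1 * refs$retardation[1]
    amp <- NA_real_
    gain <- refs$grey[nrow(refs)]
    working_range <- c(0, max(refs$retardation))
    pred <- refs$grey
  }
  resid <- abs(pred - refs$grey)
  if (any(resid > tol))
    stop(sprintf(
      "fitted calibration misses a reference grey by %.4g (> tol %.4g)",
      max(resid), tol))
  structure(
    list(model = model, lambda = lambda, offset = offset, amp = amp,
         gain = gain, working_range = working_range,
         references = refs, tol = tol),
    class = "retardation_calibration"
  )
}

#' @export
print.retardation_calibration <- function(x, ...) {
  cat(sprintf(
    "Retardation calibration (%s): offset %.4g, gain %.4g, range [%g, %g] nm\n",
    x$model, x$offset, x$gain, x$working_range[1], x$working_range[2]))
  invisible(x)
}

#' Forward model: retardation to image grey value
#'
#' @param cal A `retardation_calibration`.
#' @param retardation Retardation in nm; must lie within the calibration's
#'   working range.
#' @return Grey values on the calibration's grey scale.
#' @export
retardation_to_grey <- function(cal, retardation) {
  stopifnot(inherits(cal, "retardation_calibration"))
  if (any(!is.finite(retardation)))
    stop("non-finite retardation")
  if (any(retardation < 0))
    stop("retardation must be non-negative")
  if (any(retardation > cal$working_range[2] + 1e-9))
    stop("retardation above the first-order working range")
  if (cal$model == "sin2") {
    cal$offset + cal$amp * sin(pi * retardation / cal$lambda)^2
  } else {
    r <- cal$references
    stats::approx(c(0, r$retardation), c(cal$offset, r$grey),
                  xout = retardation, rule = 2)$y
  }
}

#' Inverse model: image grey value to retardation
#'
#' Grey values below the dark offset (background noise) are clamped to zero
#' retardation; the number of clamped values is attached as attribute
#' `n_clamped` and reported with a message unless `quiet = TRUE`. Grey values
#' above the gain level are outside the invertible first-order regime and
#' raise an error.
#'
#' @param cal A `retardation_calibration`.
#' @param grey Grey values on the calibration's grey scale.
#' @param quiet Suppress the clamp message.
#' @return Retardation in nm, with attribute `n_clamped`.
#' @export
grey_to_retardation <- function(cal, grey, quiet = FALSE) {
  stopifnot(inherits(cal, "retardation_calibration"))
  if (any(!is.finite(grey))) stop("non-finite grey value")
  if (any(grey > cal$gain + 1e-9))
    stop("grey value above gain level: out of the first-order regime")
  below <- grey < cal$offset
  g <- pmax(grey, cal$offset)
  if (cal$model == "sin2") {
    frac <- pmin(pmax((g - cal$offset) / cal$amp, 0), 1)
    out <- (cal$lambda / pi) * asin(sqrt(frac))
  } else {
    r <- cal$references
    out <- stats::approx(c(cal$offset, r$grey), c(0, r$retardation),
                         xout = g, rule = 2)$y
  }
  n_clamped <- sum(below)
  if (n_clamped > 0L && !quiet)
    message(sprintf("%d grey value(s) below dark offset clamped to 0 nm",
                    n_clamped))
  attr(out, "n_clamped") <- n_clamped
  out
}

#' Convert optical retardation to calcite thickness
#'
#' Applies the standard retardation law `thickness = G / delta_n`, with the
#' nm-to-um unit change folded in.
#'
#' @param retardation Retardation in nm (non-negative).
#' @param constants An `optical_constants` object.
#' @return Thickness in micrometres.
#' @export
retardation_to_thickness <- function(retardation, constants) {
  stopifnot(inherits(constants, "optical_constants"))
  if (any(retardation < 0)) stop("retardation must be non-negative")
  retardation / (1000 * constants$delta_n)
}

#' Convert calcite thickness to optical retardation
#'
#' @param thickness Thickness in micrometres (non-negative).
#' @param constants An `optical_constants` object.
#' @return Retardation in nm.
#' @export
thickness_to_retardation <- function(thickness, constants) {
  stopifnot(inherits(constants, "optical_constants"))
  if (any(thickness < 0)) stop("thickness must be non-negative")
  thickness * 1000 * constants$delta_n
}

#' Calcite mass of one pixel
#'
#' @param thickness Calcite thickness in micrometres (non-negative).
#' @param constants An `optical_constants` object.
#' @return Mass in pg: `thickness * pixel_area * density`.
#' @export
pixel_mass <- function(thickness, constants) {
  stopifnot(inherits(constants, "optical_constants"))
  if (any(thickness < 0)) stop("thickness must be non-negative")
  thickness * constants$pixel_area * constants$density
}

#' Total calcite mass of a thickness map
#'
#' The conservation identity used throughout the package:
#' `mass = density * pixel_area * sum(thickness)`.
#'
#' @param map A numeric matrix of per-pixel thickness (um) or a
#'   `thickness_map` object.
#' @param constants An `optical_constants` object.
#' @return Total mass in pg.
#' @export
map_mass <- function(map, constants) {
  if (inherits(map, "thickness_map")) map <- map$map
  stopifnot(inherits(constants, "optical_constants"))
  constants$density * constants$pixel_area * sum(map)
}

#' Write a calibration to / read it from JSON
#'
#' @param cal A `retardation_calibration`.
#' @param path File path.
#' @return `read_calibration_json` returns the calibration object;
#'   `write_calibration_json` returns `path` invisibly.
#' @export
write_calibration_json <- function(cal, path) {
  stopifnot(inherits(cal, "retardation_calibration"))
  jsonlite::write_json(unclass(cal), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration_json
#' @export
read_calibration_json <- function(path) {
  if (!file.exists(path)) stop("calibration file not found: ", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$references <- as.data.frame(x$references)
  structure(x, class = "retardation_calibration")
}
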
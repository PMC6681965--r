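#' A default forward-model calibration
#'
#' A convenience calibration of the single-wavelength interference model,
#' anchored the way the real microscope is calibrated: by fitting the curve
#' through the grey values of two reference retardation films (31 nm and
#' 129 nm). The generating dark offset and gain are recovered exactly
#' because the fit inverts the same two-parameter model.
#'
#' @param offset Dark-offset grey level (normalized grey, default 0.02).
#' @param gain Grey level at the top of the first-order range (default 0.98).
#' @param lambda Effective wavelength in nm (default 550).
#' @return A `retardation_calibration`.
#' @export
default_calibration <- function(offset = 0.02, gain = 0.98, lambda = 550) {
  amp <- gain - offset
  refs <- data.frame(
    retardation = c(31, 129),
    grey = offset + amp * sin(pi * c(31, 129) / lambda)^2
  )
  fit_retardation_curve(refs, model = "sin2", lambda = lambda)
}

# quantize continuous normalized grey to an integer bit depth, back to [0,1]
quantize_grey <- function(grey, bit_depth) {
  levels <- 2^bit_depth - 1
  pmin(pmax(round(grey * levels) / levels, 0), 1)
}

#' Render coccolith thickness maps into a grey-scale micrograph
#'
#' The forward imaging model: per-pixel grey is the calibrated interference
#' grey of the pixel's retardation (`thickness * delta_n * 1000` nm) plus
#' Gaussian camera noise, quantized to the requested bit depth. Particles are
#' laid out on a non-overlapping grid with their background margins;
#' optionally two reference-film patches (31 nm and 129 nm) are rendered in
#' the top-left corner, mirroring the calibration films imaged alongside real
#' samples.
#'
#' @param maps List of `thickness_map` objects (may be empty).
#' @param cal A `retardation_calibration`.
#' @param constants An `optical_constants` object.
#' @param noise_sd Gaussian grey noise standard deviation (normalized grey
#'   units; default 2e-4, about 13 counts at 16 bit).
#' @param bit_depth 8 or 16 (default 16).
#' @param quantize Quantize grey values to `bit_depth` (default TRUE);
#'   disable to keep the continuous synthesis values.
#' @param canvas_px Optional `c(rows, cols)` canvas size; default sized to
#'   the grid layout.
#' @param ref_patches Render the two reference-film patches.
#' @param patch_px Side of each reference patch in pixels.
#' @return An object of class `rendered_image`: list with `image` (matrix in
#'   `[0, 1]`), `truth` (ground-truth rows with centroid columns `cx_um`,
#'   `cy_um`; x along image columns, y along rows), `noise_sd`, `bit_depth`,
#'   and `ref_patch_greys` (when rendered).
#' @export
render_image <- function(maps, cal, constants, noise_sd = 2e-4,
                         bit_depth = 16L, quantize = TRUE, canvas_px = NULL,
                         ref_patches = FALSE, patch_px = 16L,
                         border_px = 16L) {
  stopifnot(inherits(cal, "retardation_calibration"),
            inherits(constants, "optical_constants"))
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  px <- constants$pixel_size
  n <- length(maps)
  pad <- if (ref_patches) 2L * patch_px + 8L else 0L

  if (n == 0L) {
    dims <- if (is.null(canvas_px)) c(128L, 128L) else as.integer(canvas_px)
    thick <- matrix(0, dims[1], dims[2])
    truth <- NULL
  } else {
    ncol_g <- ceiling(sqrt(n))
    nrow_g <- ceiling(n / ncol_g)
    heights <- vapply(maps, function(m) nrow(m$map), integer(1))
    widths <- vapply(maps, function(m) ncol(m$map), integer(1))
    tile_h <- max(heights); tile_w <- max(widths)
    dims <- c(nrow_g * tile_h + pad + 2L * border_px,
              ncol_g * tile_w + 2L * border_px)
    if (!is.null(canvas_px)) {
      if (any(as.integer(canvas_px) < dims))
        stop("`canvas_px` too small for the particle layout")
      dims <- as.integer(canvas_px)
    }
    thick <- matrix(0, dims[1], dims[2])
    truth <- vector("list", n)
    for (i in seq_len(n)) {
      gi <- (i - 1) %/% ncol_g
      gj <- (i - 1) %% ncol_g
      r0 <- border_px + pad + gi * tile_h + (tile_h - heights[i]) %/% 2
      c0 <- border_px + gj * tile_w + (tile_w - widths[i]) %/% 2
      rows <- (r0 + 1):(r0 + heights[i])
      cols <- (c0 + 1):(c0 + widths[i])
      patch <- thick[rows, cols]
      if (any(patch > 0 & maps[[i]]$map > 0))
        stop("particle placement overlap detected")
      thick[rows, cols] <- patch + maps[[i]]$map
      ti <- maps[[i]]$truth
      ti$cx_um <- (c0 + widths[i] / 2) * px
      ti$cy_um <- (r0 + heights[i] / 2) * px
      truth[[i]] <- ti
    }
    truth <- do.call(rbind, truth)
  }

  ret <- thickness_to_retardation(thick, constants)
  if (any(ret > cal$working_range[2]))
    stop("thickness out of the calibration working range")
  grey <- matrix(retardation_to_grey(cal, as.vector(ret)),
                 nrow(thick), ncol(thick))

  ref_patch_greys <- NULL
  if (ref_patches) {
    ref_ret <- c(31, 129)
    ref_patch_greys <- retardation_to_grey(cal, ref_ret)
    for (k in 1:2) {
      rows <- 5:(4 + patch_px)
      cols <- (5 + (k - 1) * (patch_px + 8)):(4 + (k - 1) * (patch_px + 8) + patch_px)
      grey[rows, cols] <- ref_patch_greys[k]
    }
  }

  if (noise_sd > 0)
    grey <- grey + matrix(stats::rnorm(length(grey), 0, noise_sd),
                          nrow(grey), ncol(grey))
  if (quantize) grey <- quantize_grey(grey, bit_depth)

  structure(
    list(image = grey, truth = truth, noise_sd = noise_sd,
         bit_depth = as.integer(bit_depth),
         ref_patch_greys = ref_patch_greys),
    class = "rendered_image"
  )
}

#' Write / read a grey-scale image as TIFF
#'
#' @param image A `rendered_image` or a numeric matrix in `[0, 1]`.
#' @param path File path.
#' @param bit_depth Bits per sample (8 or 16).
#' @return `write_image_tiff` returns `path` invisibly; `read_image_tiff`
#'   returns a numeric matrix in `[0, 1]`.
#' @export
write_image_tiff <- function(image, path, bit_depth = 16L) {
  if (inherits(image, "rendered_image")) {
    bit_depth <- image$bit_depth
    image <- image$image
  }
  tiff::writeTIFF(image, path, bits.per.sample = as.integer(bit_depth))
  invisible(path)
}

#' @rdname write_image_tiff
#' @export
read_image_tiff <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img
}
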
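#' Sample table: labeled coccolith measurements for one culture
#'
#' @param strain Strain label.
#' @param salinity Salinity of the culture.
#' @param measurements Data frame of per-coccolith measurements (schema of
#'   [measure_sample()] / the simulator's table mode).
#' @param species Optional species label.
#' @return An object of class `sample_table`.
#' @export
sample_table <- function(strain, salinity, measurements, species = NA_character_) {
  stopifnot(is.data.frame(measurements))
  if (nrow(measurements) < 1L)
    warning(sprintf("sample %s at salinity %s is empty", strain, salinity))
  structure(
    list(strain = strain, salinity = salinity, species = species,
         measurements = measurements),
    class = "sample_table"
  )
}

#' @export
print.sample_table <- function(x, ...) {
  cat(sprintf("Sample %s (salinity %s): %d coccoliths\n",
              x$strain, x$salinity, nrow(x$measurements)))
  invisible(x)
}

#' Build a factorial study design
#'
#' @param pops Named list of `population_spec` objects, one per strain.
#' @param salinities Numeric vector of salinity levels (default 25, 34, 44,
#'   the study's levels).
#' @param species Optional named character vector of species labels keyed by
#'   strain.
#' @return A list of design cells, each `list(strain, species, salinity, pop)`.
#' @export
study_design <- function(pops, salinities = c(25, 34, 44), species = NULL) {
  stopifnot(is.list(pops), !is.null(names(pops)))
  cells <- list()
  for (st in names(pops)) {
    for (sal in salinities) {
      cells[[length(cells) + 1L]] <- list(
        strain = st,
        species = if (!is.null(species) && st %in% names(species))
          unname(species[st]) else NA_character_,
        salinity = sal,
        pop = pops[[st]]
      )
    }
  }
  cells
}

# derive a per-observation sd from a printed t-based 95% CI half-width
sd_from_ci <- function(ci, n) ci * sqrt(n) / stats::qt(0.975, n - 1)

#' The study's default design, parameterized from the published summaries
#'
#' Builds an 8-strain x 3-salinity design (seven *E. huxleyi* strains plus
#' one *G. oceanica* strain, n = 30 coccoliths per sample) whose population
#' parameters are taken from the published per-sample means: mean length at
#' 34 salinity, the per-strain length-vs-salinity slope from the 25-to-44
#' contrast, and spreads back-computed from the printed 95% confidence
#' intervals. *E. huxleyi* strains use decoupled thickness (the study's
#' finding); the *G. oceanica* strain uses isometric coupling.
#'
#' @return A design list as from [study_design()].
#' @export
default_study_design <- function() {
  t3 <- published_summary()
  cells <- list()
  for (st in unique(t3$strain)) {
    rows <- t3[t3$strain == st, ]
    rows <- rows[order(rows$salinity), ]
    n <- rows$n[1]
    mu34 <- rows$length_mean[rows$salinity == 34]
    beta <- (rows$length_mean[rows$salinity == 44] -
               rows$length_mean[rows$salinity == 25]) / (44 - 25)
    sdl <- mean(sd_from_ci(rows$length_ci, n))
    sdt <- mean(sd_from_ci(rows$thickness_ci, n))
    species <- rows$species[1]
    if (species == "G. oceanica") {
      pop <- population_spec(
        n = n, mean_length = mu34, sd_length = sdl, beta_salinity = beta,
        coupling = "isometric",
        coupling_c = mean(rows$thickness_mean / rows$length_mean),
        sd_thickness = sdt, aspect_mean = 1.2
      )
    } else {
      pop <- population_spec(
        n = n, mean_length = mu34, sd_length = sdl, beta_salinity = beta,
        coupling = "decoupled", thickness_mean = mean(rows$thickness_mean),
        sd_thickness = sdt
      )
    }
    for (sal in rows$salinity) {
      cells[[length(cells) + 1L]] <- list(strain = st, species = species,
                                          salinity = sal, pop = pop)
    }
  }
  cells
}

#' Default table-mode measurement noise
#'
#' Standard deviations of the independent Gaussian measurement noise added to
#' ground truth in table mode, set to half the stated 95%-level measurement
#' uncertainties of the imaging method (length 0.1 um, thickness 0.0035 um,
#' mass 8% relative).
#'
#' @return Named list of noise parameters.
#' @export
table_noise_defaults <- function() {
  list(length_sd = 0.1, thickness_sd = 0.0035, mass_rel_sd = 0.08,
       skewness_sd = 0.05, aspect_sd = 0.02, area_rel_sd = 0.02)
}

#' Simulate a multi-strain, multi-salinity coccolith study
#'
#' Generates one sample per design cell. In `"table"` mode the imaging step
#' is bypassed: per-coccolith ground truth is computed analytically and
#' measurement noise with the method's stated uncertainties is added
#' directly, which is fast and is what the statistical layer is tested on.
#' In `"image"` mode every coccolith is rasterized and rendered into
#' grey-scale micrographs for the full inverse pipeline.
#'
#' @param design A design list (see [study_design()],
#'   [default_study_design()]).
#' @param seed Master seed; all randomness derives from it.
#' @param mode `"table"` or `"image"`.
#' @param constants An `optical_constants` object.
#' @param cal A `retardation_calibration` (image mode).
#' @param noise Table-mode noise parameters, see [table_noise_defaults()].
#' @param image_noise_sd Grey noise sd for image mode.
#' @param n_per_image Coccoliths per rendered image (image mode).
#' @param bit_depth Image quantization depth (image mode).
#' @return An object of class `coccolith_study`: list with `mode`, `seed`,
#'   `samples` (per cell: `strain`, `species`, `salinity`, `truth` data
#'   frame, and `measured` (`sample_table`, table mode) or `images` (list of
#'   `rendered_image`, image mode)), and `manifest`.
#' @export
simulate_study <- function(design, seed = 1L,
                           mode = c("table", "image"),
                           constants = optical_constants(),
                           cal = default_calibration(),
                           noise = table_noise_defaults(),
                           image_noise_sd = 2e-4, n_per_image = 6L,
                           bit_depth = 16L) {
  mode <- match.arg(mode)
  if (length(design) < 1L) stop("design must contain at least one cell")
  keys <- vapply(design, function(cl) paste(cl$strain, cl$salinity, sep = "@"),
                 character(1))
  if (anyDuplicated(keys))
    stop("duplicate (strain, salinity) cells in design: ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "))
  set.seed(seed)
  cell_seeds <- sample.int(2147483646L, length(design))

  samples <- vector("list", length(design))
  for (k in seq_along(design)) {
    cl <- design[[k]]
    sp <- sample_population(cl$pop, cl$salinity, seed = cell_seeds[k],
                            constants = constants)
    if (mode == "table") {
      tr <- sp$truth
      n <- nrow(tr)
      len <- tr$length_um + stats::rnorm(n, 0, noise$length_sd)
      thick <- pmax(tr$mean_thickness_um +
                      stats::rnorm(n, 0, noise$thickness_sd), 1e-5)
      mass <- pmax(tr$mass_pg * (1 + stats::rnorm(n, 0, noise$mass_rel_sd)),
                   1e-6)
      aspect <- pmax(tr$aspect_ratio + stats::rnorm(n, 0, noise$aspect_sd), 1)
      meas <- data.frame(
        strain = cl$strain, salinity = cl$salinity,
        species = if (is.null(cl$species)) NA_character_ else cl$species,
        coccolith_id = tr$coccolith_id,
        length_um = len, width_um = len / aspect, aspect_ratio = aspect,
        mean_thickness_um = thick, mass_pg = mass,
        skewness = tr$skewness + stats::rnorm(n, 0, noise$skewness_sd),
        area_um2 = tr$area_um2 * (1 + stats::rnorm(n, 0, noise$area_rel_sd)),
        ks = NA_real_,
        u_length = 1.96 * noise$length_sd,
        u_thickness = 1.96 * noise$thickness_sd,
        u_mass = 1.96 * noise$mass_rel_sd * mass
      )
      meas$ks <- ks_from_mass_length(meas$mass_pg, meas$length_um,
                                     constants$density)
      samples[[k]] <- list(
        strain = cl$strain, species = cl$species, salinity = cl$salinity,
        truth = tr,
        measured = sample_table(cl$strain, cl$salinity, meas,
                                species = cl$species)
      )
    } else {
      maps <- lapply(sp$specs, make_thickness_map, constants = constants)
      groups <- split(seq_along(maps),
                      ceiling(seq_along(maps) / n_per_image))
      images <- lapply(groups, function(ix)
        render_image(maps[ix], cal, constants, noise_sd = image_noise_sd,
                     bit_depth = bit_depth))
      truth <- do.call(rbind, lapply(seq_along(images), function(j) {
        ti <- images[[j]]$truth
        ti$image <- j
        ti
      }))
      truth$coccolith_id <- seq_len(nrow(truth))
      samples[[k]] <- list(
        strain = cl$strain, species = cl$species, salinity = cl$salinity,
        truth = truth, images = images
      )
    }
  }
  manifest <- list(
    seed = seed, mode = mode, n_cells = length(design),
    cells = data.frame(
      strain = vapply(design, `[[`, character(1), "strain"),
      salinity = vapply(design, function(cl) as.numeric(cl$salinity),
                        numeric(1)),
      n = vapply(design, function(cl) cl$pop$n, integer(1)),
      seed = cell_seeds
    ),
    constants = unclass(constants),
    noise = if (mode == "table") noise else list(grey_sd = image_noise_sd)
  )
  structure(list(mode = mode, seed = seed, samples = samples,
                 manifest = manifest),
            class = "coccolith_study")
}

#' Extract the sample tables of a simulated table-mode study
#'
#' @param study A `coccolith_study` in table mode.
#' @return List of `sample_table` objects.
#' @export
study_tables <- function(study) {
  stopifnot(inherits(study, "coccolith_study"))
  if (study$mode != "table")
    stop("study was not simulated in table mode")
  lapply(study$samples, `[[`, "measured")
}
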
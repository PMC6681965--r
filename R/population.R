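#' Specification of a coccolith population
#'
#' Describes the distribution from which one culture sample of coccoliths is
#' drawn: a truncated-normal length distribution whose mean shifts linearly
#' with salinity, and a length-thickness coupling in one of three modes,
#' encoding the competing hypotheses about coccolith growth:
#'
#' * `"isometric"`: mean thickness proportional to length,
#'   `T = c * L + eps` — the assumption behind the k_s mass model.
#' * `"allometric"`: power-law coupling `T = c * L^b + eps`.
#' * `"decoupled"`: thickness independent of length,
#'   `T ~ Normal(T0, sd_thickness)` — the pattern found for *E. huxleyi*.
#'
#' Thickness here means the mean calcite thickness over the coccolith's
#' outer-ellipse support, the quantity the imaging method reports.
#'
#' @param n Coccoliths per sample (default 30, the study's sample size).
#' @param mean_length Mean length (um) at the reference salinity.
#' @param sd_length Length standard deviation (um).
#' @param beta_salinity Length shift per salinity unit (um).
#' @param ref_salinity Salinity at which `mean_length` applies (default 34).
#' @param coupling `"isometric"`, `"allometric"` or `"decoupled"`.
#' @param coupling_c Coupling coefficient `c` (isometric/allometric). For
#'   isometric coupling `c = T/L`; e.g. 0.026 gives a 0.07 um thick coccolith
#'   at 2.7 um length.
#' @param coupling_b Allometric exponent `b` (default 1).
#' @param thickness_mean Mean thickness `T0` (um) for decoupled mode.
#' @param sd_thickness Residual thickness standard deviation (um).
#' @param aspect_mean,aspect_sd Aspect-ratio distribution (truncated >= 1).
#' @param central_fraction_mean,central_fraction_sd Central-area fraction
#'   distribution (truncated to `[0, 0.9]`).
#' @param rim_floor Rim thickness floor passed to [coccolith_spec()].
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(n = 30L, mean_length = 2.7, sd_length = 0.3,
                            beta_salinity = 0, ref_salinity = 34,
                            coupling = c("isometric", "allometric",
                                         "decoupled"),
                            coupling_c = 0.026, coupling_b = 1,
                            thickness_mean = 0.07, sd_thickness = 0.006,
                            aspect_mean = 1.25, aspect_sd = 0.05,
                            central_fraction_mean = 0.45,
                            central_fraction_sd = 0.03,
                            rim_floor = 0.35) {
  coupling <- match.arg(coupling)
  if (!is.numeric(n) || n < 1) stop("`n` must be >= 1")
  if (mean_length <= 0) stop("`mean_length` must be > 0")
  if (sd_length < 0 || sd_thickness < 0)
    stop("standard deviations must be >= 0")
  structure(
    list(n = as.integer(n), mean_length = mean_length, sd_length = sd_length,
         beta_salinity = beta_salinity, ref_salinity = ref_salinity,
         coupling = coupling, coupling_c = coupling_c,
         coupling_b = coupling_b, thickness_mean = thickness_mean,
         sd_thickness = sd_thickness, aspect_mean = aspect_mean,
         aspect_sd = aspect_sd,
         central_fraction_mean = central_fraction_mean,
         central_fraction_sd = central_fraction_sd, rim_floor = rim_floor),
    class = "population_spec"
  )
}

# truncated-normal draw by rejection (bounds far from the mean in practice)
rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(rep(pmin(pmax(mean, lower), upper), n))
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    draw <- stats::rnorm(length(need), mean, sd)
    ok <- draw >= lower & draw <= upper
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

#' Draw one sample of coccoliths from a population
#'
#' Draws `pop$n` coccolith specifications at the given salinity and computes
#' their analytic ground truth (exact for the continuous geometry; the
#' rasterized ground truth from [make_thickness_map()] converges to it as the
#' pixel size shrinks).
#'
#' @param pop A `population_spec`.
#' @param salinity Salinity of the culture.
#' @param seed Optional integer seed for reproducibility.
#' @param constants An `optical_constants` object (for density, used in the
#'   ground-truth mass and k_s).
#' @return A list with `specs` (list of `coccolith_spec`) and `truth`
#'   (data frame with columns `coccolith_id`, `length_um`, `width_um`,
#'   `aspect_ratio`, `area_um2`, `mean_thickness_um`, `mass_pg`, `skewness`,
#'   `ks`).
#' @export
sample_population <- function(pop, salinity, seed = NULL,
                              constants = optical_constants()) {
  stopifnot(inherits(pop, "population_spec"))
  if (!is.null(seed)) set.seed(seed)
  n <- pop$n
  mu <- pop$mean_length + pop$beta_salinity * (salinity - pop$ref_salinity)
  if (mu <= 0) stop("salinity-shifted mean length is non-positive")
  len <- rtrunc_norm(n, mu, pop$sd_length, lower = .Machine$double.eps)
  tbar <- switch(pop$coupling,
    isometric  = pop$coupling_c * len,
    allometric = pop$coupling_c * len^pop$coupling_b,
    decoupled  = rep(pop$thickness_mean, n)
  )
  if (pop$sd_thickness > 0 || pop$coupling == "decoupled")
    tbar <- tbar + stats::rnorm(n, 0, pop$sd_thickness)
  tbar <- pmax(tbar, 1e-4)
  ar <- rtrunc_norm(n, pop$aspect_mean, pop$aspect_sd, lower = 1)
  fc <- rtrunc_norm(n, pop$central_fraction_mean, pop$central_fraction_sd,
                    lower = 0, upper = 0.9)
  specs <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    pm <- profile_moments(fc[i], pop$rim_floor)
    peak <- tbar[i] / pm$mean
    specs[[i]] <- coccolith_spec(
      length = len[i], aspect_ratio = ar[i], central_fraction = fc[i],
      thickness_peak = peak, rim_floor = pop$rim_floor,
      orientation = stats::runif(1, 0, pi)
    )
    area <- pi * (len[i] / 2) * (len[i] / (2 * ar[i]))
    mass <- constants$density * area * tbar[i]
    truth[[i]] <- data.frame(
      coccolith_id = i, length_um = len[i], width_um = len[i] / ar[i],
      aspect_ratio = ar[i], area_um2 = area, mean_thickness_um = tbar[i],
      mass_pg = mass, skewness = pm$skewness,
      ks = ks_from_mass_length(mass, len[i], constants$density)
    )
  }
  list(specs = specs, truth = do.call(rbind, truth))
}
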
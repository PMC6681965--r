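#' Published per-sample summary statistics
#'
#' The printed per-culture summary of the salinity study (eight strains at
#' 25, 34 and 44 salinity, n = 30 coccoliths per sample): mean and 95%
#' confidence interval of coccolith length, mean thickness, mass, skewness of
#' the thickness distribution, and estimated k_s. Shipped as a plain-text
#' fixture; used to parameterize the default synthetic study design and to
#' audit the k_s model arithmetic against the published values.
#'
#' @return Data frame with columns `strain`, `species`, `salinity`, `n`, and
#'   `<metric>_mean` / `<metric>_ci` for length (um), thickness (um), mass
#'   (pg), skewness and k_s.
#' @export
published_summary <- function() {
  path <- system.file("extdata", "published_summary.csv", package = "coccomorph",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Published growth rates and end-of-experiment cell densities
#'
#' @return Data frame with columns `strain`, `species`, `salinity`,
#'   `growth_rate_per_day`, `end_density_cells_per_ml`.
#' @export
published_growth_rates <- function() {
  path <- system.file("extdata", "published_growth.csv", package = "coccomorph",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
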
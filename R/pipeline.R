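#' Summarize one sample the way the published per-culture table does
#'
#' Per metric (length, mean thickness, mass, skewness, k_s): the sample mean
#' and the t-based 95% confidence half-width of the mean. Values are kept at
#' full precision; [round_summary()] applies the published printing
#' precision.
#'
#' @param table A `sample_table` with at least one measurement row.
#' @param conf Confidence level (default 0.95).
#' @return One-row data frame: `strain`, `salinity`, `n`, then
#'   `<metric>_mean` and `<metric>_ci` for `length`, `thickness`, `mass`,
#'   `skewness`, `ks`. With n = 1 the CIs are `NA` (with a warning).
#' @export
summarize_sample <- function(table, conf = 0.95) {
  stopifnot(inherits(table, "sample_table"))
  df <- table$measurements
  if (nrow(df) < 1L) stop("empty sample table")
  n <- nrow(df)
  if (n < 2L) warning("n < 2: confidence intervals not computable")
  cols <- c(length = "length_um", thickness = "mean_thickness_um",
            mass = "mass_pg", skewness = "skewness", ks = "ks")
  out <- data.frame(strain = table$strain, salinity = table$salinity, n = n)
  tq <- if (n >= 2L) stats::qt(1 - (1 - conf) / 2, n - 1) else NA_real_
  for (i in seq_along(cols)) {
    v <- df[[cols[i]]]
    out[[paste0(names(cols)[i], "_mean")]] <- mean(v)
    out[[paste0(names(cols)[i], "_ci")]] <-
      if (n >= 2L) tq * stats::sd(v) / sqrt(n) else NA_real_
  }
  out
}

#' Round a summary table to the published printing precision
#'
#' @param summary Data frame from [summarize_sample()] (possibly several rows
#'   bound together).
#' @param digits Named precision map (decimal places).
#' @return The rounded data frame.
#' @export
round_summary <- function(summary,
                          digits = c(length = 1, thickness = 3, mass = 1,
                                     skewness = 3, ks = 3)) {
  for (metric in names(digits)) {
    for (suffix in c("_mean", "_ci")) {
      col <- paste0(metric, suffix)
      if (col %in% names(summary))
        summary[[col]] <- round(summary[[col]], digits[[metric]])
    }
  }
  summary
}

#' Write sample tables to a per-particle CSV / read them back
#'
#' The CSV schema is shared with the simulator's table mode: one row per
#' coccolith with `strain` and `salinity` labels. `read_measurement_csv`
#' accepts a column map for externally produced files whose headers differ.
#'
#' @param tables List of `sample_table` objects.
#' @param path CSV path.
#' @param column_map Named character vector mapping canonical names
#'   (`strain`, `salinity`, `length_um`, `mean_thickness_um`, `mass_pg`, and
#'   optionally others) to the file's headers. `NULL` assumes canonical
#'   headers.
#' @param sep Field separator of the file (`","`, `";"` or `"\t"`).
#' @return `write_measurement_csv` returns `path` invisibly;
#'   `read_measurement_csv` returns a list of `sample_table` objects grouped
#'   by (strain, salinity).
#' @export
write_measurement_csv <- function(tables, path) {
  df <- do.call(rbind, lapply(tables, `[[`, "measurements"))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_measurement_csv
#' @export
read_measurement_csv <- function(path, column_map = NULL, sep = ",") {
  if (!file.exists(path)) stop("measurement file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("strain", "salinity", "length_um", "mean_thickness_um",
                "mass_pg")
  if (!is.null(column_map)) {
    missing_cols <- setdiff(unname(column_map), names(df))
    if (length(missing_cols))
      stop("mapped column(s) not in file: ",
           paste(missing_cols, collapse = ", "),
           "; available headers: ", paste(names(df), collapse = ", "))
    for (canonical in names(column_map))
      names(df)[names(df) == column_map[[canonical]]] <- canonical
  }
  missing_req <- setdiff(required, names(df))
  if (length(missing_req))
    stop("missing required column(s): ",
         paste(missing_req, collapse = ", "),
         "; available headers: ", paste(names(df), collapse = ", "))
  numeric_cols <- setdiff(required, c("strain", "salinity"))
  for (col in numeric_cols) {
    if (!is.numeric(df[[col]])) {
      parsed <- suppressWarnings(as.numeric(df[[col]]))
      bad <- is.na(parsed) & !is.na(df[[col]])
      if (any(bad))
        message(sprintf("dropped %d row(s) with unparseable `%s`",
                        sum(bad), col))
      df[[col]] <- parsed
      df <- df[!bad, , drop = FALSE]
    }
  }
  key <- interaction(df$strain, df$salinity, drop = TRUE)
  groups <- split(df, key)
  message(sprintf("read %d rows in %d samples", nrow(df), length(groups)))
  unname(lapply(groups, function(g) {
    sample_table(g$strain[1], g$salinity[1], g,
                 species = if ("species" %in% names(g)) g$species[1]
                           else NA_character_)
  }))
}

#' Run the full simulate-measure-model-analyze pipeline
#'
#' Orchestrates one reproducible run: simulate the study (table or image
#' mode), measure (image mode), write the per-particle table, the
#' per-culture summary, the k_s audit and the statistical report, plus a
#' JSON manifest recording the configuration, seeds and output hashes.
#' Identical config and seed give byte-identical CSV outputs.
#'
#' @param config A named list (or path to a YAML file) with optional
#'   entries: `mode` (`"table"` or `"image"`), `design` (a design list; the
#'   default is [default_study_design()]), `calibration` (path to a
#'   calibration JSON), `constants` (list for [optical_constants()]),
#'   `reference_ks` (named by species or single value), `alpha`,
#'   `uncertainties` (for [analyze_study()]), `n_per_image`, `image_noise_sd`.
#' @param out_dir Output directory (created).
#' @param seed Master seed.
#' @return The run manifest (class `run_manifest`), invisibly.
#' @export
run_study_pipeline <- function(config = list(), out_dir, seed = 1L) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  mode <- config$mode %||% "table"
  design <- config$design %||% default_study_design()
  constants <- if (!is.null(config$constants))
    do.call(optical_constants, config$constants) else optical_constants()
  cal <- if (!is.null(config$calibration)) {
    if (!file.exists(config$calibration))
      stop("calibration file not found: ", config$calibration)
    read_calibration_json(config$calibration)
  } else default_calibration()
  reference_ks <- config$reference_ks %||%
    c("E. huxleyi" = 0.02, "G. oceanica" = 0.05)
  alpha <- config$alpha %||% 0.05

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  warnings_log <- character(0)

  study <- simulate_study(design, seed = seed, mode = mode,
                          constants = constants, cal = cal,
                          n_per_image = config$n_per_image %||% 6L,
                          image_noise_sd = config$image_noise_sd %||% 2e-4)
  tables <- if (mode == "table") {
    study_tables(study)
  } else {
    lapply(study$samples, function(sm)
      measure_sample(sm$images, cal, constants, strain = sm$strain,
                     salinity = sm$salinity, species = sm$species))
  }

  particle_csv <- file.path(out_dir, "particles.csv")
  write_measurement_csv(tables, particle_csv)

  summary_df <- do.call(rbind, lapply(tables, summarize_sample))
  summary_csv <- file.path(out_dir, "sample_summary.csv")
  utils::write.csv(round_summary(summary_df), summary_csv, row.names = FALSE)

  audit <- ks_audit(tables, reference_ks = reference_ks,
                    density = constants$density)
  audit_csv <- file.path(out_dir, "ks_audit.csv")
  utils::write.csv(audit, audit_csv, row.names = FALSE)

  report <- withCallingHandlers(
    analyze_study(tables, alpha = alpha,
                  uncertainties = config$uncertainties %||%
                    list(length = 0.2, thickness = 0.007, mass_rel = 0.15)),
    warning = function(w) {
      warnings_log <<- c(warnings_log, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  stats_csv <- file.path(out_dir, "stat_report_anova.csv")
  utils::write.csv(report$anova, stats_csv, row.names = FALSE)
  tukey_csv <- file.path(out_dir, "stat_report_tukey.csv")
  utils::write.csv(report$tukey %||% data.frame(), tukey_csv,
                   row.names = FALSE)
  reg_csv <- file.path(out_dir, "stat_report_regressions.csv")
  utils::write.csv(report$regressions %||% data.frame(), reg_csv,
                   row.names = FALSE)

  files <- c(particle_csv, summary_csv, audit_csv, stats_csv, tukey_csv,
             reg_csv)
  manifest <- list(
    package_version = as.character(utils::packageVersion("coccomorph")),
    seed = seed, mode = mode, timestamp = format(Sys.time(), tz = "UTC"),
    config = config[setdiff(names(config), "design")],
    study_manifest = study$manifest,
    outputs = data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files))),
    warnings = warnings_log
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  structure(manifest, class = "run_manifest")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
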
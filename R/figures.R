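#' Standard figures for a completed study run
#'
#' Produces the study's figure analogs from sample tables and their analysis:
#' per-strain salinity-trend panels (mean with 95% CI for length, thickness
#' and mass), length-versus-mass and length-versus-thickness scatter panels
#' with per-sample regression lines and significance stars, and the
#' measured-versus-model mass comparison that visualizes the k_s model bias.
#'
#' @param tables List of `sample_table` objects.
#' @param report A `stat_report` from [analyze_study()] (for the
#'   significance stars); `NULL` recomputes regressions silently.
#' @param audit A k_s audit data frame from [ks_audit()] for the
#'   model-vs-measured panel; `NULL` skips that figure.
#' @param dir Output directory for PNG files.
#' @return Character vector of the files written, invisibly.
#' @export
report_figures <- function(tables, report = NULL, audit = NULL, dir = ".") {
  if (length(tables) < 1L) stop("no outputs to plot")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)

  summary_df <- do.call(rbind, lapply(tables, summarize_sample))
  long <- do.call(rbind, lapply(
    c("length", "thickness", "mass"),
    function(m) data.frame(
      strain = summary_df$strain, salinity = summary_df$salinity,
      metric = m, mean = summary_df[[paste0(m, "_mean")]],
      ci = summary_df[[paste0(m, "_ci")]])))
  p_trend <- ggplot2::ggplot(long, ggplot2::aes(x = salinity, y = mean)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = mean - ci, ymax = mean + ci),
                           width = 1) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linetype = "dashed", linewidth = 0.4) +
    ggplot2::facet_grid(metric ~ strain, scales = "free_y") +
    ggplot2::labs(x = "Salinity", y = "Mean (95% CI)") +
    ggplot2::theme_bw(base_size = 9)
  f <- file.path(dir, "salinity_trends.png")
  ggplot2::ggsave(f, p_trend, width = 11, height = 6, dpi = 150)
  written <- c(written, f)

  particles <- do.call(rbind, lapply(tables, `[[`, "measurements"))
  for (resp in c("mass_pg", "mean_thickness_um")) {
    stars <- NULL
    if (!is.null(report) && !is.null(report$regressions)) {
      rname <- if (resp == "mass_pg") "mass" else "thickness"
      rr <- report$regressions[report$regressions$response == rname, ]
      rr$stars <- ifelse(rr$p < 0.01, "**", ifelse(rr$p < 0.05, "*", ""))
      stars <- rr[rr$stars != "", ]
    }
    p_sc <- ggplot2::ggplot(
      particles,
      ggplot2::aes(x = length_um, y = .data[[resp]],
                   colour = factor(salinity))) +
      ggplot2::geom_point(size = 0.6, alpha = 0.7) +
      ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                           linewidth = 0.5) +
      ggplot2::facet_wrap(~strain, scales = "free") +
      ggplot2::labs(x = "Coccolith length (um)",
                    y = if (resp == "mass_pg") "Mass (pg)"
                        else "Mean thickness (um)",
                    colour = "Salinity") +
      ggplot2::theme_bw(base_size = 9)
    if (!is.null(stars) && nrow(stars) > 0) {
      pos <- stats::aggregate(particles[[resp]],
                              list(strain = particles$strain), max)
      names(pos)[2] <- "y"
      stars <- merge(stars, pos, by = "strain")
      xpos <- stats::aggregate(particles$length_um,
                               list(strain = particles$strain), min)
      names(xpos)[2] <- "x"
      stars <- merge(stars, xpos, by = "strain")
      p_sc <- p_sc + ggplot2::geom_text(
        data = stars, ggplot2::aes(x = x, y = y, label = stars),
        inherit.aes = FALSE, size = 3)
    }
    f <- file.path(dir, paste0("length_vs_",
                               if (resp == "mass_pg") "mass"
                               else "thickness", ".png"))
    ggplot2::ggsave(f, p_sc, width = 9, height = 6, dpi = 150)
    written <- c(written, f)
  }

  if (!is.null(audit)) {
    p_bias <- ggplot2::ggplot(audit, ggplot2::aes(x = salinity)) +
      ggplot2::geom_point(ggplot2::aes(y = mass_measured_pg,
                                       shape = "measured")) +
      ggplot2::geom_point(ggplot2::aes(y = mass_model_pg,
                                       shape = "k_s model"),
                          colour = "red") +
      ggplot2::facet_wrap(~strain, scales = "free_y") +
      ggplot2::labs(x = "Salinity", y = "Mean coccolith mass (pg)",
                    shape = NULL) +
      ggplot2::theme_bw(base_size = 9)
    f <- file.path(dir, "mass_model_vs_measured.png")
    ggplot2::ggsave(f, p_bias, width = 9, height = 6, dpi = 150)
    written <- c(written, f)
  }
  invisible(written)
}
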
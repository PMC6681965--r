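#' Full statistical analysis of a multi-salinity coccolith study
#'
#' Reproduces the study's statistical layer on a set of labeled sample
#' tables. Per strain and metric (length, mean thickness, mass): one-way
#' ANOVA across salinity levels, followed by Tukey HSD when significant,
#' with each pairwise difference additionally flagged as resolved when it is
#' at least twice the measurement's stated 95%-level uncertainty. Per sample:
#' ordinary least-squares regressions of thickness, mass, skewness and
#' aspect ratio on length, each passed through the global assumption
#' validation with the log-transform policy.
#'
#' @param tables List of `sample_table` objects (>= 2 salinity levels per
#'   strain; strains with fewer are skipped with a warning).
#' @param uncertainties Named list of stated 95%-level measurement
#'   uncertainties used by the resolvability rule: `length` (um),
#'   `thickness` (um) and `mass_rel` (relative, applied to the strain's
#'   grand mean mass). When the tables carry `u_length` / `u_thickness` /
#'   `u_mass` columns, their means are used instead.
#' @param alpha Significance level.
#' @return An object of class `stat_report`: list with `anova` (per strain x
#'   metric), `tukey` (per pair, with `significant` and `resolved` flags),
#'   `regressions` (per sample x response), `skipped` (strain labels).
#' @export
analyze_study <- function(tables,
                          uncertainties = list(length = 0.2,
                                               thickness = 0.007,
                                               mass_rel = 0.15),
                          alpha = 0.05) {
  stopifnot(length(tables) >= 1L,
            all(vapply(tables, inherits, logical(1), "sample_table")))
  strains <- unique(vapply(tables, `[[`, character(1), "strain"))
  metrics <- c(length = "length_um", thickness = "mean_thickness_um",
               mass = "mass_pg")
  anova_rows <- list(); tukey_rows <- list(); skipped <- character(0)

  for (st in strains) {
    tabs <- Filter(function(tb) tb$strain == st, tables)
    sals <- vapply(tabs, function(tb) as.numeric(tb$salinity), numeric(1))
    ord <- order(sals)
    tabs <- tabs[ord]; sals <- sals[ord]
    if (length(unique(sals)) < 2L) {
      warning(sprintf("strain %s has < 2 salinity levels: skipped", st))
      skipped <- c(skipped, st)
      next
    }
    for (mi in seq_along(metrics)) {
      mname <- names(metrics)[mi]; mcol <- metrics[mi]
      groups <- lapply(tabs, function(tb) tb$measurements[[mcol]])
      names(groups) <- as.character(sals)
      an <- one_way_anova(groups)
      anova_rows[[length(anova_rows) + 1L]] <- data.frame(
        strain = st, metric = mname,
        ss_between = an$ss_between, df_between = an$df_between,
        ms_between = an$ms_between, ss_within = an$ss_within,
        df_within = an$df_within, ms_within = an$ms_within,
        f = an$f, p = an$p, significant = an$p < alpha
      )
      if (an$p < alpha) {
        tk <- tukey_hsd(groups, alpha = alpha)
        u <- metric_uncertainty(mname, tabs, uncertainties)
        for (r in seq_len(nrow(tk))) {
          tukey_rows[[length(tukey_rows) + 1L]] <- data.frame(
            strain = st, metric = mname, pair = tk$pair[r],
            diff = tk$diff[r], lwr = tk$lwr[r], upr = tk$upr[r],
            p_adj = tk$p_adj[r], significant = tk$p_adj[r] < alpha,
            uncertainty = u,
            resolved = tk$p_adj[r] < alpha &&
              resolvable_difference(tk$diff[r], u)
          )
        }
      }
    }
  }

  reg_rows <- list()
  responses <- c(thickness = "mean_thickness_um", mass = "mass_pg",
                 skewness = "skewness", aspect_ratio = "aspect_ratio")
  for (tb in tables) {
    df <- tb$measurements
    if (nrow(df) < 8L) next
    for (ri in seq_along(responses)) {
      rname <- names(responses)[ri]; rcol <- responses[ri]
      if (!rcol %in% names(df)) next
      reg <- linear_regression(df$length_um, df[[rcol]])
      rep_ <- suppressWarnings(validate_assumptions(reg, alpha = alpha))
      final <- if (rep_$decision == "log-transform") rep_$transformed else reg
      reg_rows[[length(reg_rows) + 1L]] <- data.frame(
        strain = tb$strain, salinity = tb$salinity, response = rname,
        n = reg$n, transform = final$transform, slope = final$slope,
        intercept = final$intercept, r2 = final$r2, p = final$p_slope,
        significant = final$p_slope < alpha,
        assumption_global_p = rep_$global_p, decision = rep_$decision,
        n_influential = length(rep_$influential)
      )
    }
  }

  structure(
    list(anova = do.call(rbind, anova_rows),
         tukey = if (length(tukey_rows)) do.call(rbind, tukey_rows) else NULL,
         regressions = if (length(reg_rows)) do.call(rbind, reg_rows)
                       else NULL,
         skipped = skipped, alpha = alpha),
    class = "stat_report"
  )
}

# stated 95%-level uncertainty for one metric, preferring the tables' own
# propagated columns
metric_uncertainty <- function(metric, tabs, uncertainties) {
  ucol <- c(length = "u_length", thickness = "u_thickness",
            mass = "u_mass")[metric]
  vals <- unlist(lapply(tabs, function(tb) tb$measurements[[ucol]]))
  if (!is.null(vals) && length(vals) && all(is.finite(vals)))
    return(mean(vals))
  if (metric == "mass") {
    mm <- mean(unlist(lapply(tabs,
                             function(tb) tb$measurements$mass_pg)))
    return(uncertainties$mass_rel * mm)
  }
  uncertainties[[metric]]
}

#' @export
print.stat_report <- function(x, ...) {
  cat(sprintf(
    "Study statistics: %d ANOVA rows, %d Tukey pairs, %d regressions\n",
    NROW(x$anova), NROW(x$tukey), NROW(x$regressions)))
  invisible(x)
}
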
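#!/usr/bin/env Rscript

# Stage 4: the statistical layer on the simulated study from stage 1.
# Per strain: one-way ANOVA of length, thickness and mass across salinity,
# Tukey HSD pairs with the twice-the-uncertainty resolvability flag.
# Per sample: OLS regressions of thickness/mass/skewness/aspect ratio on
# length with global assumption validation and the log-transform policy.
# Writes results/stats/*.csv and prints the headline pattern.

suppressMessages(library(coccomorph))

particles <- "results/study/particles.csv"
if (!file.exists(particles))
  stop("run analysis/01_simulate_study.R first")
tables <- suppressMessages(read_measurement_csv(particles))
report <- suppressWarnings(analyze_study(tables))

dir.create("results/stats", recursive = TRUE, showWarnings = FALSE)
write.csv(report$anova, "results/stats/anova.csv", row.names = FALSE)
if (!is.null(report$tukey))
  write.csv(report$tukey, "results/stats/tukey.csv", row.names = FALSE)
write.csv(report$regressions, "results/stats/regressions.csv",
          row.names = FALSE)

an <- report$anova
eh <- an[an$strain != "RCC 1223", ]
cat(sprintf("E. huxleyi strains with significant length effect: %d of %d\n",
            sum(eh$significant[eh$metric == "length"]),
            sum(eh$metric == "length")))
cat(sprintf("E. huxleyi strains with significant thickness effect: %d of %d\n",
            sum(eh$significant[eh$metric == "thickness"]),
            sum(eh$metric == "thickness")))
go <- an[an$strain == "RCC 1223", ]
cat(sprintf("G. oceanica: length %s, thickness %s\n",
            ifelse(go$significant[go$metric == "length"], "significant",
                   "n.s."),
            ifelse(go$significant[go$metric == "thickness"], "significant",
                   "n.s.")))
regs <- report$regressions
lt <- regs[regs$response == "thickness", ]
cat(sprintf("Samples with significant length-thickness slope: %d of %d\n",
            sum(lt$significant), nrow(lt)))
lm_ <- regs[regs$response == "mass", ]
cat(sprintf("Samples with significant length-mass slope: %d of %d (r2 %.2f-%.2f)\n",
            sum(lm_$significant), nrow(lm_), min(lm_$r2), max(lm_$r2)))
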
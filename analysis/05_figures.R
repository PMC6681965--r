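#!/usr/bin/env Rscript

# Stage 5: figures. Salinity-trend panels per strain, length-vs-mass and
# length-vs-thickness scatter panels with regression lines and significance
# stars, and the measured-vs-model mass comparison that shows the k_s bias.
# Writes PNGs under results/figures/.

suppressMessages(library(coccomorph))

particles <- "results/study/particles.csv"
if (!file.exists(particles))
  stop("run analysis/01_simulate_study.R first")
tables <- suppressMessages(read_measurement_csv(particles))
report <- suppressWarnings(analyze_study(tables))
audit <- ks_audit(tables, reference_ks = c("E. huxleyi" = 0.02,
                                           "G. oceanica" = 0.05))

files <- suppressMessages(
  report_figures(tables, report, audit, dir = "results/figures"))
cat("Wrote figures:\n")
cat(paste(" -", files, collapse = "\n"), "\n")
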
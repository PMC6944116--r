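#!/usr/bin/env Rscript

# Stage 3 — high-content screen scoring.
#
# Summarizes the stage-1 per-cell table into per-well phenotypes
# (DNA-content cell-cycle fractions, mean RPA foci), computes focus
# fold changes with Tukey HSD adjusted p values against the
# non-targeting control, scores each perturbation on the five siRNA
# phenotype axes, and assigns two-cell-line confidence tiers. Writes the
# per-well table, the volcano-style focus table, and the score table.

suppressPackageStartupMessages(library(uvg2pipe))

data_dir <- "results/data"
out <- "results/screen"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cells <- read.delim(file.path(data_dir, "screen_cells.tsv"))
cat("Loaded", nrow(cells), "cells from", length(unique(cells$well)), "wells\n")

ws <- summarize_wells(cells)
write.table(ws, file.path(out, "well_summaries.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

ft <- do.call(rbind, lapply(split(ws, list(ws$line, ws$timepoint)),
                            function(df) {
  r <- foci_stats(df)
  r$line <- df$line[1]; r$timepoint <- df$timepoint[1]
  r
}))
rownames(ft) <- NULL
write.table(ft, file.path(out, "foci_volcano.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

scores <- score_sirna(ws, ft)
write.table(scores, file.path(out, "sirna_scores.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("\nPer-gene totals and tiers (tier rule: total >=",
    default_screen_rubric()$sirna_high_total, "in both lines = high):\n")
print(scores[, c("gene", "line", "viability", "entry24", "exit40",
                 "foci_up", "foci_down", "total", "tier")],
      row.names = FALSE)

sig <- ft[!is.na(ft$p_adj) & ft$p_adj < 0.05 & ft$timepoint != "noUV", ]
cat("\nSignificant focus changes vs control (adjusted p < 0.05):\n")
if (nrow(sig)) {
  print(sig[order(sig$p_adj), ], row.names = FALSE)
} else cat("  none\n")
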
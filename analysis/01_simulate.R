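#!/usr/bin/env Rscript

# Stage 1 — generate the synthetic study inputs.
#
# Writes, under results/data/:
#   * matched microarray + RNA-seq polysome-profiling matrices with sample
#     metadata and the per-gene planted truth table;
#   * the per-cell high-content screen table (siRNA mode);
#   * the cohort expression + UV-signature mutation-load tables.
# All three generators are pure functions of their seed, so this stage is
# bit-reproducible.

suppressPackageStartupMessages(library(uvg2pipe))

seed <- 1
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cat("Simulating polysome-profiling experiment (seed", seed, ")...\n")
psim <- gen_polysome(polysome_sim_spec(seed = seed))
write_expression(psim$microarray, file.path(out, "microarray.tsv"),
                 file.path(out, "microarray_meta.tsv"))
write_expression(psim$rnaseq, file.path(out, "rnaseq.tsv"),
                 file.path(out, "rnaseq_meta.tsv"))
write.table(psim$truth, file.path(out, "polysome_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("  ", nrow(psim$truth), "genes;",
    sum(psim$truth$class != "null"), "carry planted effects\n")

cat("Simulating high-content siRNA screen...\n")
arch <- list(
  HIT = screen_archetype(viability = 0.4, d4n_24 = -0.25, d4n_40 = 0.3,
                         foci_24 = 3, foci_40 = 3),
  ONE = screen_archetype(viability = 0.4, d4n_24 = -0.25, d4n_40 = 0.3,
                         foci_24 = 3, foci_40 = 3, lines = "lineA"),
  NUL = screen_archetype()
)
cells <- gen_screen(screen_sim_spec(archetypes = arch, seed = seed))
write.table(cells, file.path(out, "screen_cells.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("  ", nrow(cells), "cells across", length(unique(cells$well)), "wells\n")

cat("Simulating melanoma-like cohort...\n")
co <- gen_cohort(cohort_sim_spec(seed = seed))
expr_df <- data.frame(sample_id = rownames(co$expr), co$expr,
                      check.names = FALSE)
write.table(expr_df, file.path(out, "cohort_expression.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(co$loads, file.path(out, "cohort_loads.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(co$truth, file.path(out, "cohort_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("  ", nrow(co$expr), "samples x", ncol(co$expr), "pathway genes;",
    sum(co$loads$usm_per_mb == 0), "zero-load baseline samples\n")
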
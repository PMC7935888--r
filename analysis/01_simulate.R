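#!/usr/bin/env Rscript
# Stage 1 — synthetic study generation.
# Plants a detoxification-gene expression time course (3-hourly, 3 cycles)
# with the observed day/night/arrhythmic proportions, promoters with
# class-dependent E-box densities, and behavioral series (LD feeding and
# defecation, DD locomotion and feeding). All later stages read only the
# files written here.

suppressMessages(library(circadetox))

seed <- 1L
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

sim <- simulate_expression(300, seq(0, 69, by = 3),
                           acrophase_grid = 3,
                           seed = stage_seed(seed, "expression"))
write_expression_tsv(sim$matrix, file.path(out, "expression.tsv"))
write.table(sim$truth, file.path(out, "truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("expression: %d genes x %d timepoints; planted classes: %s\n",
            nrow(sim$matrix), ncol(sim$matrix),
            paste(names(table(sim$truth$class)), table(sim$truth$class),
                  sep = "=", collapse = " ")))

psim <- simulate_promoters(sim$truth, seed = stage_seed(seed, "promoters"))
write_promoter_files(psim, file.path(out, "genome.fa"),
                     file.path(out, "genes.gff3"))
write.table(psim$truth_ebox, file.path(out, "truth_ebox.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(psim$planted, file.path(out, "planted_ebox.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("promoters: %d contigs, %d planted E-boxes (background masked)\n",
            length(psim$genome), nrow(psim$planted)))

bseed <- stage_seed(seed, "behavior")
series <- list(
  feeding_ld = simulate_behavior(3, "LD", 18, n_groups = 9, noise_sd = 1,
                                 seed = bseed),
  defecation_ld = simulate_behavior(3, "LD", 9, n_groups = 9, noise_sd = 1,
                                    seed = bseed + 1L),
  locomotion_dd = simulate_behavior(3, "DD", 18, period_hours = 25,
                                    n_groups = 9, noise_sd = 1,
                                    seed = bseed + 2L),
  feeding_dd = simulate_behavior(3, "DD", 18, period_hours = 23,
                                 n_groups = 9, noise_sd = 1, seed = bseed + 3L))
for (nm in names(series)) {
  write.table(series[[nm]], file.path(out, paste0(nm, ".tsv")), sep = "\t",
              quote = FALSE, row.names = FALSE)
}
cat("behavior: LD feeding (acrophase ZT18), LD defecation (ZT9),",
    "DD locomotion (tau 25 h), DD feeding (tau 23 h)\n")
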
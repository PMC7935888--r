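#!/usr/bin/env Rscript
# Stage 4 — peak bins and day/night/arrhythmic classes.
# Peak bin = 3 h bin of the cycle-averaged maximum; DAY = rhythmic with
# acrophase in ZT[0,12), NIGHT = rhythmic in ZT[12,24), else ARRHYTHMIC.

suppressMessages(library(circadetox))

expr <- read_expression_tsv("results/data/expression.tsv")
calls <- read.delim("results/rhythm_calls.tsv")

bins <- vapply(seq_len(nrow(expr$matrix)), function(g) {
  b <- assign_peak_bin(expr$matrix[g, ], expr$timepoints)
  if (b$constant) NA_character_ else b$peak_bin
}, character(1))

labels <- classify_phase(calls, photoperiod = c(0, 12), peak_bins = bins)
write.table(labels, "results/labels.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

dist <- phase_distribution(labels)
jsonlite::write_json(dist, "results/distribution.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE)

cat("class fractions:\n")
print(round(dist$class_fractions, 3))
cat("peak-bin distribution of rhythmic genes:\n")
print(round(dist$bin_fractions, 3))
cat(sprintf("daytime-peaking share: %.1f%% of all genes\n",
            100 * dist$class_fractions[["DAY"]]))
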
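#!/usr/bin/env Rscript
# Stage 2: screen differential expression for the five contrasts the memory
# definition needs (each stress/recovery state versus the untreated control
# R0, and the later states versus the first stress S1), with the exact
# conditional count test, BH correction within contrast and the
# |log2FC| > 1 & FDR < 0.05 screen.

suppressMessages(library(memoryseq))
expr <- read_expression("results/data/expression.tsv")
samples <- read_sample_sheet("results/data/samples.tsv")
dir.create("results/de", showWarnings = FALSE, recursive = TRUE)

contrasts <- list(c("S1", "R0"), c("R3", "R0"), c("S4", "R0"),
                  c("R3", "S1"), c("S4", "S1"))
for (ct in contrasts) {
  de <- run_de(expr$counts, samples, ct)
  nm <- paste0(ct[1], "_vs_", ct[2])
  write_tsv(de, file.path("results/de", paste0("de_", nm, ".tsv")))
  message(sprintf("%s: %d up, %d down of %d genes", nm,
                  sum(de$status == "up"), sum(de$status == "down"), nrow(de)))
}
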
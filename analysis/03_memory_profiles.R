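#!/usr/bin/env Rscript
# Stage 3: assign every gene its nearest unit-change trajectory profile
# (centred correlation on the log-ratio-transformed per-condition mean FPKM),
# flag memory genes (stress-responsive and different from S1 at R3 or S4)
# and classify the five memory categories. Ends by scoring calls against the
# planted truth.

suppressMessages(library(memoryseq))
expr <- read_expression("results/data/expression.tsv")
samples <- read_sample_sheet("results/data/samples.tsv")
truth <- read.delim("results/data/expression_truth.tsv")
contrasts <- c("S1_vs_R0", "R3_vs_R0", "S4_vs_R0", "R3_vs_S1", "S4_vs_S1")
de <- lapply(contrasts, function(nm) {
  read.delim(file.path("results/de", paste0("de_", nm, ".tsv")))
})
names(de) <- contrasts
dir.create("results/profiles", showWarnings = FALSE, recursive = TRUE)

catalog <- enumerate_profiles(4)
write_tsv(as.data.frame(unclass(catalog)), "results/profiles/profile_catalog.tsv")
message(nrow(catalog), " candidate trajectory profiles enumerated")

fpkm <- compute_fpkm(expr$counts, expr$gene_info$length,
                     effective_library_sizes(expr$counts))
calls <- classify_memory(fpkm, samples, de, catalog = catalog)
write_tsv(calls, "results/profiles/memory_calls.tsv")

message(sum(calls$is_memory), " memory genes called; by category:")
print(table(calls$category[calls$is_memory]))

ev <- evaluate_memory_calls(calls, truth)
message(sprintf(
  "recovery vs planted truth: memory sensitivity %.3f, shape accuracy %.3f, category accuracy %.3f",
  ev$memory_sensitivity, ev$shape_accuracy, ev$category_accuracy))
write_tsv(data.frame(metric = names(ev), value = unlist(ev)),
          "results/profiles/recovery.tsv")
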
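#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study data with planted ground truth.
#
# Emulates the sequencing design of a repeated drought/re-watering
# experiment: expression counts for conditions R0, S1, R3, S4 with three
# replicates and planted unit-change trajectory shapes, plus a two-condition
# whole-genome bisulfite methylome with planted DMRs, plus gene models placed
# so that planted DMRs fall in gene bodies or promoters.

suppressMessages(library(memoryseq))
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)

message("simulating expression (2000 genes, 4 conditions x 3 replicates)")
expr <- simulate_expression(sim_config(n_genes = 2000, seed = seed))
write_expression(expr, "results/data/expression.tsv")
write_tsv(expr$samples, "results/data/samples.tsv")
write_tsv(expr$truth, "results/data/expression_truth.tsv")

message("simulating methylome (1 Mb, planted DMRs at delta 0.3, depth 30)")
meth <- simulate_methylome(meth_sim_config(n_dmrs = 40, seed = seed + 1))
write_cytosine_report(meth$cytosines_a, "results/data/cytosines_A.tsv")
write_cytosine_report(meth$cytosines_b, "results/data/cytosines_B.tsv")
write_tsv(meth$truth, "results/data/methylome_truth.tsv")

# gene models: each planted DMR gets a host gene (alternately overlapping the
# gene body or sitting in the 2 kb promoter), borrowed from the simulated
# memory-gene pool so expression is available for linkage; plus background
# genes elsewhere
set.seed(seed + 2)
mem_ids <- expr$truth$gene_id[expr$truth$is_memory]
tr <- meth$truth
host <- sample(mem_ids, nrow(tr))
strand <- rep(c("+", "-"), length.out = nrow(tr))
in_body <- rep(c(TRUE, FALSE), length.out = nrow(tr))
gstart <- ifelse(in_body, tr$start - 300,
                 ifelse(strand == "+", tr$end + 500, tr$start - 2000))
gend <- ifelse(in_body, tr$end + 300,
               ifelse(strand == "+", tr$end + 2000, tr$start - 500))
models <- data.frame(chrom = tr$chrom, start = pmax(gstart, 0), end = gend,
                     gene_id = host, strand = strand,
                     planted_dmr_id = tr$dmr_id)
bg <- data.frame(chrom = "chr1",
                 start = sort(sample.int(9e5, 60)) + 5e4, end = NA,
                 gene_id = sample(setdiff(expr$truth$gene_id, host), 60),
                 strand = sample(c("+", "-"), 60, replace = TRUE),
                 planted_dmr_id = NA)
bg$end <- bg$start + 2000
models <- rbind(models, bg)
write_tsv(models, "results/data/gene_models.tsv")
write_bed6(models, "results/data/gene_models.bed")

message("done: ", nrow(expr$counts), " genes (",
        sum(expr$truth$is_memory), " planted memory), ",
        nrow(meth$truth), " planted DMRs, ", nrow(models), " gene models")
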
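#!/usr/bin/env Rscript
# Stage 5: link methylation to memory-gene expression. Called DMRs are
# associated with gene models (gene body or strand-aware 2 kb promoter);
# per-sample methylation levels for the planted DMR-gene couplings are then
# correlated with FPKM across the 12 samples and thresholded at the
# permissive published +/-0.04 cuts. Memory genes are finally tested for
# term enrichment with an upper-tail hypergeometric test.

suppressMessages(library(memoryseq))
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1
expr <- read_expression("results/data/expression.tsv")
models <- read.delim("results/data/gene_models.tsv")
dmrs <- read.delim("results/dmr/dmrs.tsv")
calls <- read.delim("results/profiles/memory_calls.tsv")
dir.create("results/linkage", showWarnings = FALSE, recursive = TRUE)

pairs <- associate_dmr_gene(dmrs, models, promoter_bp = 2000)
message(nrow(pairs), " DMR-gene pairs; by zone:")
print(table(pairs$zone))
write_tsv(pairs, "results/linkage/association.tsv")

# per-sample methylation for the planted couplings (gene hosts of planted
# DMRs), coupled to expression with moderate noise
fpkm <- compute_fpkm(expr$counts, expr$gene_info$length,
                     effective_library_sizes(expr$counts))
rownames(fpkm) <- expr$gene_info$gene_id
hosts <- models[!is.na(models$planted_dmr_id), ]
coupled <- simulate_linkage(fpkm[hosts$gene_id, ], gene_ids = hosts$gene_id,
                            dmr_ids = hosts$planted_dmr_id,
                            link_sign = 1, noise_sd = 0.05, seed = seed + 3)
linkage <- score_linkage(coupled$pairs, coupled$meth_levels, fpkm)
write_tsv(linkage, "results/linkage/linkage.tsv")
message(sprintf("linkage at r > 0.04 / r < -0.04: %d of %d coupled pairs linked, %d with the planted sign",
                sum(linkage$linked), nrow(linkage),
                sum(linkage$link_sign == linkage$true_sign)))

# term enrichment of the called memory genes (synthetic annotation: ten
# random terms plus one concentrated in memory genes)
set.seed(seed + 4)
universe <- calls$gene_id
memory_genes <- calls$gene_id[calls$is_memory]
ann <- do.call(rbind, lapply(1:10, function(i) {
  data.frame(gene_id = sample(universe, 100), term = sprintf("TERM:%04d", i))
}))
ann <- rbind(ann, data.frame(
  gene_id = c(sample(memory_genes, 40), sample(universe, 10)),
  term = "TERM:MEMORY"))
enr <- hypergeometric_enrichment(memory_genes, ann, universe)
write_tsv(enr, "results/linkage/enrichment.tsv")
message("top enriched terms:")
print(head(enr, 3))
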
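#' Default pipeline configuration
#'
#' All stage parameters in one list; defaults equal the study's printed
#' values (DE: |log2FC| > 1 and FDR < 0.05; profiles: 4 conditions, unit
#' change; DMR: 200 bp windows at 50 bp steps, Fisher p <= 0.05 and BH
#' q <= 0.05; linkage: Pearson r > 0.04 or < -0.04; promoter 2000 bp).
#'
#' @param ... Overrides of the default entries.
#' @return Named list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    conditions = c("R0", "S1", "R3", "S4"),
    fc_threshold = 1,
    fdr_threshold = 0.05,
    memory_rule = "any",
    max_unit_change = 1,
    window = 200,
    step = 50,
    p_cut = 0.05,
    q_cut = 0.05,
    min_coverage = 5,
    pos_thr = 0.04,
    neg_thr = -0.04,
    promoter_bp = 2000,
    seed = 1,
    simulate = TRUE,
    sim = list(),        # overrides for sim_config()
    meth_sim = list(),   # overrides for meth_sim_config()
    n_linked_pairs = 20,
    link_noise_sd = 0.05
  )
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; entries override [pipeline_config()] defaults.
#' @return Config list.
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the yaml package is required to read YAML configs")
  }
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the full drought-memory pipeline
#'
#' Stages in order: simulate (expression + methylome + coupled linkage data) ->
#' differential expression (five contrasts) -> profile/memory classification ->
#' DMR calling per context -> DMR-gene linkage -> term enrichment of memory
#' genes. Every stage writes a self-describing TSV under `outdir`, and a
#' machine-readable `summary.json` reports counts per stage. Reruns with the
#' same config and seed are identical.
#'
#' @param config List from [pipeline_config()].
#' @param outdir Output directory (created if missing).
#' @param annotation Optional `gene_id`/`term` annotation data frame for the
#'   enrichment stage; when `NULL` under `simulate`, a synthetic annotation
#'   with a planted memory-enriched term is generated.
#' @return Invisibly, a list with every stage's in-memory result and the
#'   summary.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = tempfile("memrun"),
                         annotation = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!isTRUE(config$simulate)) {
    stop("file-based inputs are run through the stage functions directly; ",
         "run_pipeline() currently drives the simulated end-to-end analysis")
  }
  msg <- function(...) message("[memoryseq] ", ...)

  msg("stage simulate")
  scfg <- do.call(sim_config, c(list(seed = config$seed), config$sim))
  expr <- simulate_expression(scfg)
  mcfg <- do.call(meth_sim_config, c(list(seed = config$seed + 1), config$meth_sim))
  meth <- simulate_methylome(mcfg)
  write_expression(expr, file.path(outdir, "expression.tsv"))
  write_tsv(expr$samples, file.path(outdir, "samples.tsv"))
  write_tsv(expr$truth, file.path(outdir, "expression_truth.tsv"))
  write_cytosine_report(meth$cytosines_a, file.path(outdir, "cytosines_A.tsv"))
  write_cytosine_report(meth$cytosines_b, file.path(outdir, "cytosines_B.tsv"))
  write_tsv(meth$truth, file.path(outdir, "methylome_truth.tsv"))

  msg("stage de")
  conds <- config$conditions
  contrasts <- list(c(conds[2], conds[1]), c(conds[3], conds[1]),
                    c(conds[4], conds[1]), c(conds[3], conds[2]),
                    c(conds[4], conds[2]))
  de <- lapply(contrasts, function(ct) {
    run_de(expr$counts, expr$samples, ct,
           fc_threshold = config$fc_threshold,
           fdr_threshold = config$fdr_threshold)
  })
  names(de) <- vapply(contrasts, function(ct) paste0(ct[1], "_vs_", ct[2]), "")
  for (nm in names(de)) write_tsv(de[[nm]], file.path(outdir, paste0("de_", nm, ".tsv")))

  msg("stage profiles")
  fpkm <- compute_fpkm(expr$counts, expr$gene_info$length,
                       effective_library_sizes(expr$counts))
  catalog <- enumerate_profiles(length(conds), config$max_unit_change)
  calls <- classify_memory(fpkm, expr$samples, de,
                           conditions = conds, rule = config$memory_rule,
                           catalog = catalog)
  write_tsv(as.data.frame(unclass(catalog)), file.path(outdir, "profile_catalog.tsv"))
  write_tsv(calls, file.path(outdir, "memory_calls.tsv"))

  msg("stage dmr")
  windows <- make_windows(mcfg$genome_length, config$window, config$step)
  binned <- make_windows(mcfg$genome_length, max(config$step %/% 2, 1),
                         max(config$step %/% 2, 1))
  dmr_by_ctx <- lapply(c("CG", "CHG", "CHH"), function(ctx) {
    pooled <- pool_windows(meth$cytosines_a, meth$cytosines_b, windows, ctx)
    bins <- pool_windows(meth$cytosines_a, meth$cytosines_b, binned, ctx)
    call_dmrs(pooled, config$p_cut, config$q_cut, config$min_coverage,
              bins = bins)
  })
  names(dmr_by_ctx) <- c("CG", "CHG", "CHH")
  dmrs <- do.call(rbind, lapply(dmr_by_ctx, `[[`, "dmrs"))
  rownames(dmrs) <- NULL
  if (nrow(dmrs)) dmrs$dmr_id <- sprintf("called_dmr_%04d", seq_len(nrow(dmrs)))
  write_tsv(dmrs, file.path(outdir, "dmrs.tsv"))
  if (nrow(dmrs)) write_bed6(dmrs, file.path(outdir, "dmrs.bed"))

  msg("stage link")
  memory_genes <- calls$gene_id[calls$is_memory]
  n_pairs <- min(config$n_linked_pairs, length(memory_genes), nrow(meth$truth))
  linkage <- NULL
  if (n_pairs > 0) {
    set.seed(config$seed + 2)
    link_genes <- sample(memory_genes, n_pairs)
    coupled <- simulate_linkage(fpkm[link_genes, , drop = FALSE],
                                dmr_ids = meth$truth$dmr_id[seq_len(n_pairs)],
                                noise_sd = config$link_noise_sd,
                                seed = config$seed + 3)
    linkage <- score_linkage(coupled$pairs, coupled$meth_levels, fpkm,
                             config$pos_thr, config$neg_thr)
    write_tsv(linkage, file.path(outdir, "linkage.tsv"))
  }

  msg("stage enrich")
  universe <- calls$gene_id
  if (is.null(annotation)) {
    set.seed(config$seed + 4)
    annotation <- synthetic_annotation(universe, memory_genes)
  }
  enrichment <- hypergeometric_enrichment(memory_genes, annotation, universe)
  write_tsv(enrichment, file.path(outdir, "enrichment.tsv"))

  summary <- list(
    seed = config$seed,
    n_genes = nrow(expr$counts),
    n_samples = ncol(expr$counts),
    deg_per_contrast = lapply(de, function(d) sum(d$status != "unchanged")),
    n_memory = sum(calls$is_memory),
    memory_by_category = as.list(table(calls$category[calls$is_memory])),
    dmrs_per_context = lapply(dmr_by_ctx, function(x) nrow(x$dmrs)),
    n_linked = if (is.null(linkage)) 0 else sum(linkage$linked),
    n_enriched_terms = sum(enrichment$q_value < 0.05)
  )
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(expr = expr, meth = meth, de = de, calls = calls,
                 dmrs = dmrs, linkage = linkage, enrichment = enrichment,
                 summary = summary, outdir = outdir))
}

# Toy annotation map: random terms over the universe plus one term
# concentrated in memory genes so the enrichment stage has signal.
synthetic_annotation <- function(universe, memory_genes, n_terms = 10) {
  base <- do.call(rbind, lapply(seq_len(n_terms), function(i) {
    data.frame(gene_id = sample(universe, max(5, length(universe) %/% 20)),
               term = sprintf("TERM:%04d", i))
  }))
  planted <- data.frame(
    gene_id = unique(c(sample(memory_genes, min(length(memory_genes), 40)),
                       sample(universe, 10))),
    term = "TERM:MEMORY"
  )
  rbind(base, planted)
}
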
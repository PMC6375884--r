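#' Associate DMRs with genes
#'
#' Pairs a DMR with a gene when the DMR overlaps the gene body, the
#' strand-aware promoter window (`promoter_bp` upstream of the transcription
#' start) or, when `downstream_bp > 0`, the downstream window. When a DMR
#' overlaps several zones of one gene, body takes precedence over promoter
#' over downstream. DMRs on chromosomes absent from the gene models are
#' skipped with a warning.
#'
#' @param dmrs Data frame with `chrom`, `start`, `end` (0-based half-open)
#'   and optionally `dmr_id`.
#' @param gene_models Data frame with `chrom`, `start`, `end` (0-based
#'   half-open), `gene_id`, `strand` (`"+"`/`"-"`).
#' @param promoter_bp Promoter window size upstream of the TSS (default 2000).
#' @param downstream_bp Downstream window size (default 0, disabled).
#' @return Data frame of candidate pairs: `dmr_id`, `gene_id`, `zone`.
#' @export
associate_dmr_gene <- function(dmrs, gene_models, promoter_bp = 2000,
                               downstream_bp = 0) {
  if (is.null(dmrs$dmr_id)) dmrs$dmr_id <- sprintf("dmr_%03d", seq_len(nrow(dmrs)))
  empty <- data.frame(dmr_id = character(0), gene_id = character(0),
                      zone = character(0))
  if (nrow(dmrs) == 0 || nrow(gene_models) == 0) return(empty)
  known <- dmrs$chrom %in% gene_models$chrom
  if (any(!known)) {
    warning("skipping ", sum(!known), " DMR(s) on chromosome(s) absent from gene models")
    dmrs <- dmrs[known, , drop = FALSE]
    if (nrow(dmrs) == 0) return(empty)
  }
  gr_dmr <- GenomicRanges::GRanges(dmrs$chrom,
                                   IRanges::IRanges(dmrs$start + 1, dmrs$end))
  zones <- list()
  plus <- gene_models$strand != "-"
  body <- GenomicRanges::GRanges(gene_models$chrom,
                                 IRanges::IRanges(gene_models$start + 1,
                                                  gene_models$end))
  prom_start <- ifelse(plus, gene_models$start - promoter_bp, gene_models$end)
  prom_end <- ifelse(plus, gene_models$start, gene_models$end + promoter_bp)
  prom <- GenomicRanges::GRanges(gene_models$chrom,
                                 IRanges::IRanges(pmax(prom_start + 1, 1), prom_end))
  zones <- list(body = body, promoter = prom)
  if (downstream_bp > 0) {
    dn_start <- ifelse(plus, gene_models$end, gene_models$start - downstream_bp)
    dn_end <- ifelse(plus, gene_models$end + downstream_bp, gene_models$start)
    zones$downstream <- GenomicRanges::GRanges(
      gene_models$chrom, IRanges::IRanges(pmax(dn_start + 1, 1), dn_end))
  }
  found <- lapply(names(zones), function(zn) {
    hits <- GenomicRanges::findOverlaps(gr_dmr, zones[[zn]])
    data.frame(
      dmr_id = dmrs$dmr_id[S4Vectors::queryHits(hits)],
      gene_id = gene_models$gene_id[S4Vectors::subjectHits(hits)],
      zone = zn
    )
  })
  pairs <- do.call(rbind, found)
  if (nrow(pairs) == 0) return(empty)
  # zone precedence: body > promoter > downstream for a given pair
  pairs$zone <- factor(pairs$zone, levels = c("body", "promoter", "downstream"))
  pairs <- pairs[order(pairs$dmr_id, pairs$gene_id, pairs$zone), , drop = FALSE]
  pairs <- pairs[!duplicated(pairs[, c("dmr_id", "gene_id")]), , drop = FALSE]
  pairs$zone <- as.character(pairs$zone)
  rownames(pairs) <- NULL
  pairs
}

#' Correlate methylation with expression across samples
#'
#' Pearson correlation between a DMR's per-sample methylation level and a
#' gene's per-sample expression. A pair is linked when `r > pos_thr` or
#' `r < neg_thr` (the study's printed thresholds are +0.04 / -0.04; a
#' conventional screen would use +/-0.4). Constant vectors have undefined
#' correlation and are unlinked.
#'
#' @param meth_levels Numeric vector (one DMR) or pairs x samples matrix.
#' @param expression Numeric vector (one gene) or pairs x samples matrix,
#'   rows aligned with `meth_levels`.
#' @param pos_thr,neg_thr Link thresholds (defaults +0.04 / -0.04).
#' @return Data frame with `r`, `linked`, `link_sign` (0 when unlinked).
#' @export
correlate_linkage <- function(meth_levels, expression,
                              pos_thr = 0.04, neg_thr = -0.04) {
  if (is.null(dim(meth_levels))) meth_levels <- matrix(meth_levels, nrow = 1)
  if (is.null(dim(expression))) expression <- matrix(expression, nrow = 1)
  stopifnot(dim(meth_levels) == dim(expression))
  if (ncol(meth_levels) < 3) stop("at least 3 paired samples are required")
  if (any(!is.finite(meth_levels)) || any(!is.finite(expression))) {
    stop("non-finite values in input")
  }
  r <- vapply(seq_len(nrow(meth_levels)), function(i) {
    m <- meth_levels[i, ]; e <- expression[i, ]
    if (sd(m) == 0 || sd(e) == 0) return(NA_real_)
    cor(m, e)
  }, numeric(1))
  linked <- !is.na(r) & (r > pos_thr | r < neg_thr)
  data.frame(r = r, linked = linked,
             link_sign = ifelse(linked, sign(r), 0))
}

#' Score DMR-gene linkage for candidate pairs
#'
#' Looks up per-sample methylation levels and expression for each candidate
#' pair and applies [correlate_linkage()]. Each pair is scored independently.
#'
#' @param pairs Data frame with `dmr_id`, `gene_id` (e.g. from
#'   [associate_dmr_gene()]).
#' @param meth_levels DMRs x samples matrix, rownames = DMR ids.
#' @param expression Genes x samples matrix, rownames = gene ids, same sample
#'   order as `meth_levels`.
#' @param pos_thr,neg_thr Link thresholds.
#' @return `pairs` with `r`, `linked`, `link_sign` columns appended.
#' @export
score_linkage <- function(pairs, meth_levels, expression,
                          pos_thr = 0.04, neg_thr = -0.04) {
  stopifnot(all(pairs$dmr_id %in% rownames(meth_levels)),
            all(pairs$gene_id %in% rownames(expression)))
  m <- meth_levels[pairs$dmr_id, , drop = FALSE]
  e <- expression[pairs$gene_id, , drop = FALSE]
  cbind(pairs, correlate_linkage(m, e, pos_thr, neg_thr))
}

#' Hypergeometric term enrichment
#'
#' Upper-tail hypergeometric test per term: the probability of observing at
#' least the seen number of term-annotated genes in the set, given the term's
#' prevalence in the universe. Benjamini-Hochberg correction across terms.
#'
#' @param gene_set Character vector of genes of interest (subset of
#'   `universe`).
#' @param annotation Data frame with columns `gene_id`, `term`.
#' @param universe Character vector of all genes considered.
#' @return Data frame per term: `term`, `k` (set genes with term), `n` (set
#'   size), `K` (universe genes with term), `N` (universe size), `p_value`,
#'   `q_value`, ordered by p.
#' @export
hypergeometric_enrichment <- function(gene_set, annotation, universe) {
  if (length(universe) == 0) stop("empty universe")
  if (!all(gene_set %in% universe)) stop("gene_set must be a subset of universe")
  annotation <- annotation[annotation$gene_id %in% universe, , drop = FALSE]
  gene_set <- unique(gene_set)
  N <- length(unique(universe))
  n <- length(gene_set)
  terms <- unique(annotation$term)
  res <- lapply(terms, function(tm) {
    genes_with <- unique(annotation$gene_id[annotation$term == tm])
    K <- length(genes_with)
    k <- sum(gene_set %in% genes_with)
    # P(X >= k), X ~ Hypergeometric(N, K, n)
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, k = k, n = n, K = K, N = N, p_value = p)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    return(data.frame(term = character(0), k = integer(0), n = integer(0),
                      K = integer(0), N = integer(0), p_value = numeric(0),
                      q_value = numeric(0)))
  }
  out$q_value <- benjamini_hochberg(out$p_value)
  out[order(out$p_value), , drop = FALSE]
}
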
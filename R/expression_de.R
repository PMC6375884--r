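#' FPKM normalisation
#'
#' Fragments per kilobase of transcript per million mapped fragments:
#' `fpkm = count / (length/1e3) / (library_size/1e6)`.
#'
#' @param counts Genes x samples matrix of non-negative counts.
#' @param gene_lengths Gene lengths in bp, one per row of `counts`.
#' @param library_sizes Per-sample library sizes; default column sums.
#' @return Matrix of FPKM values, same shape as `counts`.
#' @export
compute_fpkm <- function(counts, gene_lengths, library_sizes = colSums(counts)) {
  counts <- as.matrix(counts)
  if (length(gene_lengths) != nrow(counts)) stop("one length per gene required")
  if (any(gene_lengths <= 0) || any(is.na(gene_lengths))) {
    stop("gene lengths must be positive")
  }
  if (any(library_sizes <= 0)) stop("library sizes must be positive")
  sweep(counts / (gene_lengths / 1e3), 2, library_sizes / 1e6, "/")
}

#' Median-ratio library size factors
#'
#' DESeq-style size factors: per-sample median of count ratios to the row-wise
#' geometric mean, over genes expressed in every sample. Falls back to
#' column-sum scaling when fewer than 10 genes are everywhere-positive.
#'
#' @param counts Genes x samples count matrix.
#' @return Numeric vector of size factors, geometric mean 1.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  pos <- rowSums(counts > 0) == ncol(counts)
  if (sum(pos) < 10) {
    sf <- colSums(counts)
    sf <- sf / exp(mean(log(sf)))
    return(sf)
  }
  lg <- log(counts[pos, , drop = FALSE])
  geo <- rowMeans(lg)
  sf <- apply(exp(lg - geo), 2, median)
  sf / exp(mean(log(sf)))
}

#' Composition-robust effective library sizes
#'
#' Median-ratio size factors scaled to the geometric-mean raw library size.
#' Column sums are distorted when a large share of counts shifts between
#' conditions (composition bias); these effective sizes are the conventional
#' replacement for FPKM and fold-change normalisation.
#'
#' @param counts Genes x samples count matrix.
#' @return Numeric vector of effective library sizes.
#' @export
effective_library_sizes <- function(counts) {
  size_factors(counts) * exp(mean(log(colSums(as.matrix(counts)))))
}

#' Exact conditional count test for one gene
#'
#' Tests for a difference in abundance between two groups of count samples.
#' Replicates are pooled within each group after library-size scaling;
#' conditioning on the pooled total, the two-sided p-value sums the
#' probabilities of all splits at most as likely as the observed one
#' (minimum-likelihood rejection region):
#'
#' * `dispersion = 0`: the split is Binomial(total, 1/2) under the null
#'   (equal effective library sizes), and the tail is summed exactly.
#' * `dispersion > 0`: each group total is negative binomial with variance
#'   `mu + dispersion * mu^2` at the replicate level, so a pooled group of
#'   `n` replicates is NB with dispersion `dispersion / n`; the split
#'   probabilities are products of the two NB masses, renormalised over all
#'   splits of the total.
#'
#' The log2 fold change is computed on normalised per-replicate means with a
#' pseudocount. Swapping the groups negates the fold change and leaves p
#' unchanged. A gene with zero counts in both groups is untestable:
#' p = 1, log2FC = 0.
#'
#' @param counts_a,counts_b Integer count vectors over replicates (group A is
#'   the numerator of the fold change).
#' @param dispersion NB dispersion alpha >= 0 (variance `mu + alpha mu^2`).
#' @param size_factors_a,size_factors_b Library size factors per replicate;
#'   default 1 (equal libraries).
#' @param pseudocount Added to normalised means for the fold change.
#' @return List with `p_value`, `log2fc`, `testable`.
#' @export
exact_count_test <- function(counts_a, counts_b, dispersion = 0,
                             size_factors_a = rep(1, length(counts_a)),
                             size_factors_b = rep(1, length(counts_b)),
                             pseudocount = 1) {
  if (dispersion < 0) stop("dispersion must be >= 0")
  norm_a <- counts_a / size_factors_a
  norm_b <- counts_b / size_factors_b
  mean_a <- mean(norm_a)
  mean_b <- mean(norm_b)
  log2fc <- log2((mean_a + pseudocount) / (mean_b + pseudocount))
  ya <- round(sum(norm_a))
  yb <- round(sum(norm_b))
  if (ya + yb == 0) {
    return(list(p_value = 1, log2fc = 0, testable = FALSE))
  }
  p <- exact_split_pvalue(ya, yb, length(counts_a), length(counts_b), dispersion)
  list(p_value = p, log2fc = log2fc, testable = TRUE)
}

# Two-sided minimum-likelihood p for an observed split (ya, yb) of the pooled
# total between groups of na and nb replicates with common per-replicate mean.
exact_split_pvalue <- function(ya, yb, na, nb, dispersion) {
  total <- ya + yb
  k <- 0:total
  if (dispersion == 0) {
    # conditional on the total, the group-A count is Binomial(total, na/(na+nb))
    pr <- dbinom(k, total, na / (na + nb))
    obs <- pr[ya + 1]
  } else {
    mu <- total / (na + nb)           # per-replicate mean under the null
    pa <- dnbinom(k, size = na / dispersion, mu = na * mu)
    pb <- dnbinom(total - k, size = nb / dispersion, mu = nb * mu)
    pr <- pa * pb
    pr <- pr / sum(pr)
    obs <- pr[ya + 1]
  }
  min(1, sum(pr[pr <= obs * (1 + 1e-7)]))
}

#' Moment estimate of the common NB dispersion
#'
#' Method-of-moments across genes: per gene and group, `alpha_g =
#' (s^2 - mu) / mu^2` on size-factor-normalised counts (the excess of the
#' variance over the Poisson expectation, relative to the squared mean). The
#' common estimate is the across-gene mean of the per-gene values — the
#' per-gene moment is unbiased but extremely noisy at few replicates, so
#' averaging, not a robust location, recovers the common alpha. Genes with
#' mean below `min_mean` are excluded (the moment ratio is unstable there);
#' negative net estimates clip to 0 (Poisson).
#'
#' @param counts Genes x samples count matrix.
#' @param groups Factor/vector of group labels per sample.
#' @param sf Size factors per sample; default [size_factors()].
#' @param min_mean Minimum normalised gene mean for inclusion (default 5).
#' @return Single dispersion estimate >= 0.
#' @export
estimate_dispersion <- function(counts, groups, sf = size_factors(counts),
                                min_mean = 5) {
  norm <- sweep(as.matrix(counts), 2, sf, "/")
  ests <- unlist(lapply(unique(groups), function(g) {
    x <- norm[, groups == g, drop = FALSE]
    if (ncol(x) < 2) return(numeric(0))
    mu <- rowMeans(x)
    v <- apply(x, 1, var)
    a <- (v - mu) / mu^2
    a[is.finite(a) & mu >= min_mean]
  }))
  if (length(ests) == 0) return(0)
  max(0, mean(ests))
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up q-values: `q_i = min_{j >= rank(i)} p_(j) * n / j`, clipped at 1.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`, no NAs.
#' @return q-values in the input order.
#' @export
benjamini_hochberg <- function(p_values) {
  if (any(is.na(p_values))) stop("NA p-values are not allowed")
  if (any(p_values < 0 | p_values > 1)) stop("p-values must lie in [0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Screen differential-expression status
#'
#' Applies the fold-change and FDR cuts: up when `log2FC > fc_threshold` and
#' `q < fdr_threshold`, down when `log2FC < -fc_threshold` and
#' `q < fdr_threshold`, otherwise unchanged.
#'
#' @param log2fc,q Numeric vectors per gene.
#' @param fc_threshold log2 fold-change cut (default 1).
#' @param fdr_threshold FDR cut (default 0.05).
#' @return Character vector in `{"up", "down", "unchanged"}`.
#' @export
screen_deg <- function(log2fc, q, fc_threshold = 1, fdr_threshold = 0.05) {
  status <- rep("unchanged", length(log2fc))
  status[log2fc > fc_threshold & q < fdr_threshold] <- "up"
  status[log2fc < -fc_threshold & q < fdr_threshold] <- "down"
  status
}

#' Differential expression for one contrast
#'
#' Runs the exact conditional count test gene-wise for `contrast[1]` versus
#' `contrast[2]`, applies BH correction within the contrast and the DEG
#' screen.
#'
#' @param counts Genes x samples count matrix (rownames = gene ids).
#' @param samples Sample sheet data frame (`sample`, `condition`).
#' @param contrast Length-2 character vector, numerator condition first
#'   (e.g. `c("S1", "R0")`).
#' @param dispersion NB dispersion; `NULL` (default) estimates it by the
#'   method of moments across all genes and both groups.
#' @param fc_threshold,fdr_threshold Screen cuts (defaults 1 and 0.05).
#' @param pseudocount Fold-change pseudocount.
#' @return Data frame: `gene_id`, `contrast`, `log2fc`, `p_value`, `q_value`,
#'   `status`, `testable`.
#' @export
run_de <- function(counts, samples, contrast, dispersion = NULL,
                   fc_threshold = 1, fdr_threshold = 0.05, pseudocount = 1) {
  counts <- as.matrix(counts)
  stopifnot(length(contrast) == 2, ncol(counts) == nrow(samples))
  idx_a <- which(samples$condition == contrast[1])
  idx_b <- which(samples$condition == contrast[2])
  if (!length(idx_a) || !length(idx_b)) {
    stop("contrast condition missing from sample sheet")
  }
  sf <- size_factors(counts)
  if (is.null(dispersion)) {
    sub <- counts[, c(idx_a, idx_b), drop = FALSE]
    grp <- rep(contrast, c(length(idx_a), length(idx_b)))
    dispersion <- estimate_dispersion(sub, grp, sf[c(idx_a, idx_b)])
  }
  res <- lapply(seq_len(nrow(counts)), function(i) {
    exact_count_test(counts[i, idx_a], counts[i, idx_b], dispersion,
                     sf[idx_a], sf[idx_b], pseudocount)
  })
  p <- vapply(res, `[[`, numeric(1), "p_value")
  lfc <- vapply(res, `[[`, numeric(1), "log2fc")
  testable <- vapply(res, `[[`, logical(1), "testable")
  q <- benjamini_hochberg(p)
  data.frame(
    gene_id = if (is.null(rownames(counts))) seq_len(nrow(counts)) else rownames(counts),
    contrast = paste0(contrast[1], "_vs_", contrast[2]),
    log2fc = lfc,
    p_value = p,
    q_value = q,
    status = screen_deg(lfc, q, fc_threshold, fdr_threshold),
    testable = testable
  )
}
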
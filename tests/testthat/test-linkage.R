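test_that("DMR-gene association respects zones and strand-aware promoters", {
  genes <- data.frame(
    chrom = c("chr1", "chr1"), start = c(10000, 30000), end = c(12000, 33000),
    gene_id = c("gplus", "gminus"), strand = c("+", "-")
  )
  dmrs <- data.frame(
    chrom = "chr1",
    start = c(10500, 9999, 33000, 31000, 50000, 8000 - 2001),
    end   = c(10700, 10000, 33500, 31500, 50200, 7999),
    dmr_id = paste0("d", 1:6)
  )
  pairs <- associate_dmr_gene(dmrs, genes, promoter_bp = 2000)
  get <- function(id) pairs[pairs$dmr_id == id, ]
  expect_equal(get("d1")$zone, "body")               # fully inside gene
  expect_equal(get("d1")$gene_id, "gplus")
  expect_equal(get("d2")$zone, "promoter")           # 1 bp upstream of + TSS
  expect_equal(get("d3")$zone, "promoter")           # upstream of - strand TSS
  expect_equal(get("d4")$zone, "body")               # inside minus-strand gene
  expect_equal(nrow(get("d5")), 0)                   # 17 kb away: no pair
  expect_equal(nrow(get("d6")), 0)                   # beyond the 2 kb window
  # unknown chromosome is skipped with a warning
  expect_warning(
    p2 <- associate_dmr_gene(data.frame(chrom = "chrX", start = 1, end = 100),
                             genes),
    "absent")
  expect_equal(nrow(p2), 0)
})

test_that("linkage correlation applies the +/-0.04 thresholds", {
  level <- c(0.2, 0.4, 0.6, 0.8, 0.3, 0.5, 0.7, 0.1, 0.9, 0.45, 0.55, 0.35)
  out <- correlate_linkage(level, 2 * level + 1)
  expect_equal(out$r, 1)
  expect_true(out$linked)
  expect_equal(out$link_sign, 1)
  out_neg <- correlate_linkage(level, -level)
  expect_equal(out_neg$r, -1)
  expect_equal(out_neg$link_sign, -1)
  # constant methylation: undefined correlation, unlinked
  out_const <- correlate_linkage(rep(0.5, 12), level)
  expect_true(is.na(out_const$r))
  expect_false(out_const$linked)
  # sub-threshold correlation is unlinked
  set.seed(41)
  weak <- correlate_linkage(level, rnorm(12), pos_thr = 0.999, neg_thr = -0.999)
  expect_false(weak$linked)
  expect_error(correlate_linkage(1:2, 1:2))
  # invariance under positive affine transforms; sign flip under negation
  set.seed(42)
  for (i in 1:10) {
    m <- runif(8); e <- rnorm(8)
    r0 <- correlate_linkage(m, e)$r
    expect_equal(correlate_linkage(m * 2 + 0.1, e * 5 + 3)$r, r0)
    expect_equal(correlate_linkage(m, -e)$r, -r0)
  }
})

test_that("score_linkage joins pairs to their sample vectors", {
  ml <- matrix(c(0.1, 0.5, 0.9, 0.9, 0.5, 0.1), 2, 3, byrow = TRUE,
               dimnames = list(c("d1", "d2"), NULL))
  ex <- matrix(c(1, 5, 9, 1, 5, 9), 2, 3, byrow = TRUE,
               dimnames = list(c("g1", "g2"), NULL))
  pairs <- data.frame(dmr_id = c("d1", "d2"), gene_id = c("g1", "g2"))
  out <- score_linkage(pairs, ml, ex)
  expect_equal(out$r, c(1, -1))
  expect_true(all(out$linked))
})

test_that("hypergeometric enrichment matches direct computation", {
  universe <- paste0("g", 1:20)
  ann <- data.frame(gene_id = paste0("g", 1:5), term = "T1")
  res <- hypergeometric_enrichment(paste0("g", 1:5), ann, universe)
  expect_equal(res$p_value, 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(res$k, 5)
  # no overlap: upper-tail p is 1
  res0 <- hypergeometric_enrichment(paste0("g", 6:10), ann, universe)
  expect_equal(res0$p_value, 1)
  # term annotating the whole universe: p = 1
  ann_all <- data.frame(gene_id = universe, term = "ALL")
  expect_equal(hypergeometric_enrichment(paste0("g", 1:4), ann_all,
                                         universe)$p_value, 1)
  expect_error(hypergeometric_enrichment("zz", ann, universe), "subset")
  expect_error(hypergeometric_enrichment("g1", ann, character(0)))
})

test_that("enrichment p equals brute-force enumeration for small universes", {
  # oracle: sum over all draws of size n of the indicator k' >= k, by
  # explicit binomial coefficients
  brute <- function(k, K, n, N) {
    sum(vapply(k:min(n, K), function(kk) {
      choose(K, kk) * choose(N - K, n - kk)
    }, numeric(1))) / choose(N, n)
  }
  set.seed(23)
  for (i in 1:20) {
    N <- sample(8:25, 1)
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    universe <- paste0("g", 1:N)
    ann <- data.frame(gene_id = universe[1:K], term = "T")
    gene_set <- sample(universe, n)
    k <- sum(gene_set %in% universe[1:K])
    res <- hypergeometric_enrichment(gene_set, ann, universe)
    expect_equal(res$p_value, brute(k, K, n, N), tolerance = 1e-10)
  }
})
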
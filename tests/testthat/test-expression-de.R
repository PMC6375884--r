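test_that("FPKM normalisation follows the definition", {
  counts <- matrix(c(0, 10, 100), ncol = 1)
  fp <- compute_fpkm(counts, gene_lengths = c(500, 1000, 2000),
                     library_sizes = 1e6)
  expect_equal(fp[1, 1], 0)
  expect_equal(fp[2, 1], 10)   # 10 / (1000/1e3) / (1e6/1e6)
  expect_equal(fp[3, 1], 50)
  # doubling every count doubles the library, FPKM unchanged
  c2 <- matrix(rpois(40, 50), 10, 4)
  f1 <- compute_fpkm(c2, rep(1000, 10))
  f2 <- compute_fpkm(2 * c2, rep(1000, 10))
  expect_equal(f1, f2)
  expect_error(compute_fpkm(c2, rep(-1, 10)))
  expect_error(compute_fpkm(c2, rep(1000, 10), library_sizes = rep(0, 4)))
})

test_that("exact count test: null identity, symmetry, untestable genes", {
  null <- exact_count_test(c(10, 10), c(10, 10), 0)
  expect_equal(null$p_value, 1)
  expect_equal(null$log2fc, 0)
  set.seed(4)
  for (i in 1:25) {
    a <- rpois(3, 80); b <- rpois(3, 120)
    disp <- sample(c(0, 0.05, 0.2), 1)
    r1 <- exact_count_test(a, b, disp)
    r2 <- exact_count_test(b, a, disp)
    expect_equal(r1$p_value, r2$p_value)
    expect_equal(r1$log2fc, -r2$log2fc)
  }
  zero <- exact_count_test(c(0, 0, 0), c(0, 0, 0), 0.1)
  expect_false(zero$testable)
  expect_equal(zero$p_value, 1)
  expect_equal(zero$log2fc, 0)
})

test_that("dispersion-0 exact test equals the brute-force binomial tail", {
  # oracle: direct summation over all outcomes of Binomial(n, 1/2)
  binom_oracle <- function(ya, yb) {
    n <- ya + yb
    pr <- choose(n, 0:n) / 2^n
    sum(pr[pr <= pr[ya + 1] * (1 + 1e-7)])
  }
  expect_equal(exact_count_test(15, 5, 0)$p_value, binom_oracle(15, 5))
  set.seed(9)
  for (i in 1:50) {
    ya <- rpois(1, 40); yb <- rpois(1, 60)
    expect_equal(exact_count_test(ya, yb, 0)$p_value, binom_oracle(ya, yb))
  }
})

test_that("NB exact test matches edgeR's small-p exact test", {
  skip_if_not_installed("edgeR")
  set.seed(2)
  disp <- 0.1
  y1 <- matrix(rnbinom(60, size = 1 / disp, mu = 100), 20, 3)
  y2 <- matrix(rnbinom(60, size = 1 / disp, mu = 150), 20, 3)
  p_ref <- edgeR::exactTestBySmallP(y1, y2, dispersion = disp)
  p_ours <- vapply(seq_len(20), function(i) {
    exact_count_test(y1[i, ], y2[i, ], disp)$p_value
  }, numeric(1))
  expect_equal(p_ours, as.numeric(p_ref), tolerance = 1e-12)
})

test_that("fold-change screen applies the |log2FC| > 1 and FDR < 0.05 cuts", {
  # an NCED3-like jump from FPKM 9.0 to 100.4 clears the fold-change cut
  lfc <- log2(100.4 / 9.0)
  expect_gt(abs(lfc), 1)
  expect_equal(lfc, 3.48, tolerance = 0.01)
  expect_equal(screen_deg(c(0.99, 3.0, -2.0), c(0.001, 0.20, 0.01)),
               c("unchanged", "unchanged", "down"))
  expect_equal(screen_deg(2, 0.04, fc_threshold = 2.5), "unchanged")
})

test_that("Benjamini-Hochberg equals the brute-force step-up procedure", {
  # oracle: literal step-up definition
  bh_oracle <- function(p) {
    n <- length(p)
    o <- order(p)
    q_sorted <- rev(cummin(rev(p[o] * n / seq_len(n))))
    pmin(1, q_sorted)[order(o)]
  }
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(benjamini_hochberg(rep(1, 5)), rep(1, 5))
  expect_equal(benjamini_hochberg(0.37), 0.37)
  set.seed(13)
  for (i in 1:50) {
    p <- runif(sample(5:200, 1))
    q <- benjamini_hochberg(p)
    expect_equal(q, bh_oracle(p))
    expect_true(all(q >= p))                      # q >= p elementwise
    expect_true(all(diff(q[order(p)]) >= -1e-15)) # order-preserving
  }
  expect_error(benjamini_hochberg(c(0.1, NA)))
  expect_error(benjamini_hochberg(c(0.1, 1.2)))
})

test_that("run_de screens planted changes and keeps nulls quiet", {
  cfg <- sim_config(n_genes = 600, seed = 31,
                    profile_mixture = c(flat = 0.5, "25" = 0.25, "0" = 0.25))
  e <- simulate_expression(cfg)
  de <- run_de(e$counts, e$samples, c("S4", "R0"))
  up_true <- !is.na(e$truth$shape_id) & e$truth$shape_id == 25
  dn_true <- !is.na(e$truth$shape_id) & e$truth$shape_id == 0
  flat <- is.na(e$truth$shape_id)
  expect_gt(mean(de$status[up_true] == "up"), 0.9)
  expect_gt(mean(de$status[dn_true] == "down"), 0.9)
  expect_lt(mean(de$status[flat] != "unchanged"), 0.02)
  expect_true(all(de$q_value >= de$p_value))
})
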
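# small fabricated pooled-window tables used by the calling tests
fake_pooled <- function(starts, meth_a, unmeth_a, meth_b, unmeth_b,
                        window = 200, context = "CG") {
  cov_a <- meth_a + unmeth_a; cov_b <- meth_b + unmeth_b
  data.frame(
    chrom = "chr1", start = starts, end = starts + window, context = context,
    meth_a = meth_a, unmeth_a = unmeth_a, meth_b = meth_b, unmeth_b = unmeth_b,
    level_a = ifelse(cov_a > 0, meth_a / cov_a, NA),
    level_b = ifelse(cov_b > 0, meth_b / cov_b, NA),
    covered = cov_a > 0 & cov_b > 0
  )
}

test_that("sliding windows tile the chromosome with truncated tails", {
  w <- make_windows(200, 200, 50)
  expect_equal(w$start, c(0, 50, 100, 150))
  expect_equal(w$end, c(200, 200, 200, 200))
  w2 <- make_windows(50, 200, 50)
  expect_equal(nrow(w2), 1)
  expect_equal(c(w2$start, w2$end), c(0, 50))
  # every interior position is covered by window/step windows
  w3 <- make_windows(10000, 200, 50)
  pos <- 300:9700
  hits <- vapply(pos, function(p) sum(w3$start < p & w3$end >= p), numeric(1))
  expect_true(all(hits == 4))
  expect_error(make_windows(1000, 0, 50))
  expect_error(make_windows(1000, 50, 200))
})

test_that("window pooling sums matching-context cytosines on both strands", {
  cyt <- function(pos, meth, unmeth, ctx, strand = "+") {
    data.frame(chrom = "chr1", pos = pos, strand = strand,
               meth = meth, unmeth = unmeth, context = ctx)
  }
  a <- rbind(cyt(10, 3, 1, "CG"), cyt(20, 2, 4, "CG", "-"),
             cyt(30, 7, 7, "CHH"))
  b <- rbind(cyt(10, 5, 5, "CG"), cyt(20, 5, 5, "CG", "-"),
             cyt(30, 1, 13, "CHH"))
  win <- data.frame(start = 0, end = 50)
  p_cg <- pool_windows(a, b, win, "CG")
  expect_equal(c(p_cg$meth_a, p_cg$unmeth_a), c(5, 5))  # 3+2, 1+4
  expect_equal(c(p_cg$meth_b, p_cg$unmeth_b), c(10, 10))
  expect_true(p_cg$covered)
  # empty window is uncovered
  p_far <- pool_windows(a, b, data.frame(start = 1000, end = 1200), "CG")
  expect_false(p_far$covered)
  # boundary convention: 1-based position p belongs to [start, end) iff
  # start < p <= end
  edge <- pool_windows(cyt(50, 1, 0, "CG"), cyt(50, 1, 0, "CG"),
                       data.frame(start = c(0, 50), end = c(50, 100)), "CG")
  expect_equal(edge$meth_a, c(1, 0))
})

test_that("two-sided Fisher p matches enumeration and fisher.test", {
  expect_equal(window_fisher(10, 0, 0, 10), 2 / choose(20, 10),
               tolerance = 1e-12)
  expect_equal(window_fisher(5, 5, 5, 5), 1)
  # transposing conditions leaves p unchanged; zero margins are untestable
  expect_equal(window_fisher(3, 9, 7, 2), window_fisher(7, 2, 3, 9))
  expect_equal(window_fisher(0, 0, 5, 5), 1)
  set.seed(17)
  for (i in 1:50) {
    t <- rpois(4, 8)
    expect_equal(window_fisher(t[1], t[2], t[3], t[4]),
                 fisher.test(matrix(t, 2, byrow = TRUE))$p.value,
                 tolerance = 1e-9)
  }
  expect_error(window_fisher(-1, 2, 3, 4))
})

test_that("DMR calling merges overlapping significant windows", {
  # three strong hyper windows [0,200), [50,250), [100,300) over a null rest
  starts <- seq(0, 5000, 50)
  n <- length(starts)
  ma <- rep(50, n); ua <- rep(50, n); mb <- rep(50, n); ub <- rep(50, n)
  hot <- starts %in% c(0, 50, 100)
  mb[hot] <- 95; ub[hot] <- 5
  res <- call_dmrs(fake_pooled(starts, ma, ua, mb, ub))
  expect_equal(nrow(res$dmrs), 1)
  expect_equal(c(res$dmrs$start, res$dmrs$end), c(0, 300))
  expect_equal(res$dmrs$direction, "hyper")
  expect_equal(res$dmrs$n_windows, 3L)
  # merging is order-independent
  perm <- sample(n)
  res2 <- call_dmrs(fake_pooled(starts[perm], ma[perm], ua[perm],
                                mb[perm], ub[perm]))
  expect_equal(res2$dmrs$start, res$dmrs$start)
  expect_equal(res2$dmrs$end, res$dmrs$end)
  # no significant windows -> no DMRs
  res3 <- call_dmrs(fake_pooled(starts, ma, ua, ma, ua))
  expect_equal(nrow(res3$dmrs), 0)
  # an isolated significant window is not a region
  mb2 <- rep(50, n); ub2 <- rep(50, n)
  mb2[10] <- 95; ub2[10] <- 5
  res4 <- call_dmrs(fake_pooled(starts, ma, ua, mb2, ub2))
  expect_equal(nrow(res4$dmrs), 0)
  # per-context processing is enforced
  two_ctx <- fake_pooled(starts, ma, ua, mb, ub)
  two_ctx$context[1] <- "CHH"
  expect_error(call_dmrs(two_ctx), "single context")
})

test_that("low-coverage windows are excluded before testing", {
  pooled <- fake_pooled(c(0, 50), c(1, 40), c(1, 40), c(2, 80), c(0, 10))
  res <- call_dmrs(pooled, min_coverage = 5)
  expect_equal(nrow(res$windows), 1)
  expect_equal(res$windows$start, 50)
})

test_that("planted DMRs are recovered with refined boundaries", {
  cfg <- meth_sim_config(genome_length = 3e5,
                         n_cytosines_per_context = c(CG = 25500, CHG = 18000, CHH = 75000),
                         depth_mean = 30, n_dmrs = 8, dmr_delta = 0.5,
                         dmr_width = 200, seed = 19)
  m <- simulate_methylome(cfg)
  w <- make_windows(3e5)
  bw <- make_windows(3e5, 25, 25)
  called <- NULL
  for (ctx in unique(m$truth$context)) {
    pooled <- pool_windows(m$cytosines_a, m$cytosines_b, w, ctx)
    bins <- pool_windows(m$cytosines_a, m$cytosines_b, bw, ctx)
    res <- call_dmrs(pooled, bins = bins)
    expect_true(all(res$dmrs$min_q <= 0.05))
    called <- rbind(called, res$dmrs)
  }
  ev <- evaluate_dmr_calls(called, m$truth, tol = 50)
  expect_gte(ev$sensitivity, 0.85)
  expect_gte(ev$precision, 0.85)
})
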
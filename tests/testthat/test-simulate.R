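test_that("expression simulation is deterministic and validates its config", {
  cfg <- sim_config(n_genes = 120, seed = 77)
  e1 <- simulate_expression(cfg)
  e2 <- simulate_expression(cfg)
  expect_identical(e1, e2)
  expect_identical(dim(e1$counts), c(120L, 12L))
  expect_error(sim_config(profile_mixture = c(flat = 0.7, "25" = 0.2)),
               "sum to 1")
  expect_error(sim_config(profile_mixture = c(flat = 0.5, "99" = 0.5)),
               "unknown")
  expect_error(sim_config(baseline_mean = -5))
  expect_error(sim_config(nb_dispersion = -0.1))
})

test_that("null effect size gives equal condition means at the baseline", {
  cfg <- sim_config(n_genes = 3000, effect_size = 0, baseline_mean = 100,
                    nb_dispersion = 0, seed = 5)
  e <- simulate_expression(cfg)
  cm <- condition_means(e$counts, e$samples, c("R0", "S1", "R3", "S4"))
  grand <- colMeans(cm)
  se <- sqrt(100 / (3000 * 3))  # Poisson, 9000 draws per condition
  expect_true(all(abs(grand - 100) < 3 * se))
})

test_that("planted shapes set condition means to baseline * 2^(effect*value)", {
  # one shape with values (0, 1, 0, 0): S1 mean 400, others 100
  cfg <- sim_config(n_genes = 10000, profile_mixture = c("18" = 1),
                    effect_size = 2, baseline_mean = 100,
                    nb_dispersion = 0.05, seed = 12)
  e <- simulate_expression(cfg)
  cm <- condition_means(e$counts, e$samples, c("R0", "S1", "R3", "S4"))
  n <- 10000 * 3
  se_100 <- sqrt((100 + 0.05 * 100^2) / n)
  se_400 <- sqrt((400 + 0.05 * 400^2) / n)
  mm <- colMeans(cm)
  expect_lt(abs(mm["R0"] - 100), 3 * se_100)
  expect_lt(abs(mm["S1"] - 400), 3 * se_400)
  expect_lt(abs(mm["R3"] - 100), 3 * se_100)
  expect_lt(abs(mm["S4"] - 100), 3 * se_100)
})

test_that("dosage-class genes are flat at the first stress by construction", {
  cfg <- sim_config(n_genes = 400, seed = 8)
  e <- simulate_expression(cfg)
  dosage <- e$truth$category == "dosage"
  expect_true(any(dosage))
  expect_true(all(e$truth$v2[dosage] == 0))  # same mean at R0 and S1
  # and memory truth implies responsiveness plus a later difference
  mem <- e$truth$is_memory
  later <- e$truth$v3 != e$truth$v2 | e$truth$v4 != e$truth$v2
  resp <- e$truth$v2 != 0 | e$truth$v3 != 0 | e$truth$v4 != 0
  expect_equal(mem, resp & later)
})

test_that("methylome simulation plants disjoint context-specific DMRs", {
  cfg <- meth_sim_config(genome_length = 2e5,
                         n_cytosines_per_context = c(CG = 17000, CHG = 12000, CHH = 50000),
                         n_dmrs = 10, seed = 21)
  m1 <- simulate_methylome(cfg)
  m2 <- simulate_methylome(cfg)
  expect_identical(m1, m2)
  tr <- m1$truth[order(m1$truth$start), ]
  expect_true(all(tr$start[-1] >= tr$end[-nrow(tr)]))  # disjoint
  expect_true(all(m1$cytosines_a$context %in% c("CG", "CHG", "CHH")))
  expect_identical(m1$cytosines_a$pos, m1$cytosines_b$pos)
  expect_error(meth_sim_config(dmr_width = 2e6))
  expect_error(meth_sim_config(baseline_level = c(CG = 0.9, CHG = 0.9, CHH = 0.9),
                               dmr_delta = 0.3))
})

test_that("null methylome (delta 0) leaves both conditions identical in law", {
  cfg <- meth_sim_config(genome_length = 1e5,
                         n_cytosines_per_context = c(CG = 8500, CHG = 6000, CHH = 25000),
                         n_dmrs = 5, dmr_delta = 0, seed = 33)
  m <- simulate_methylome(cfg)
  for (ctx in c("CG", "CHG", "CHH")) {
    a <- m$cytosines_a[m$cytosines_a$context == ctx, ]
    b <- m$cytosines_b[m$cytosines_b$context == ctx, ]
    la <- sum(a$meth) / sum(a$meth + a$unmeth)
    lb <- sum(b$meth) / sum(b$meth + b$unmeth)
    n <- sum(a$meth + a$unmeth)
    expect_lt(abs(la - lb), 4 * sqrt(2 * la * (1 - la) / n))
  }
})

test_that("zero depth yields uncovered windows downstream", {
  cfg <- meth_sim_config(genome_length = 1e4,
                         n_cytosines_per_context = c(CG = 850, CHG = 600, CHH = 2500),
                         depth_mean = 0, n_dmrs = 0, seed = 2)
  m <- simulate_methylome(cfg)
  expect_true(all(m$cytosines_a$meth + m$cytosines_a$unmeth == 0))
  pooled <- pool_windows(m$cytosines_a, m$cytosines_b, make_windows(1e4), "CG")
  expect_false(any(pooled$covered))
  res <- call_dmrs(pooled)
  expect_equal(nrow(res$windows), 0)
  expect_equal(nrow(res$dmrs), 0)
})

test_that("a planted hyper-DMR shifts the pooled window level by delta", {
  cfg <- meth_sim_config(genome_length = 1e5,
                         n_cytosines_per_context = c(CG = 8500, CHG = 6000, CHH = 25000),
                         depth_mean = 30, n_dmrs = 3, dmr_delta = 0.5,
                         baseline_level = c(CG = 0.3, CHG = 0.2, CHH = 0.05),
                         dmr_width = 200, seed = 14)
  m <- simulate_methylome(cfg)
  tr <- m$truth[1, ]
  win <- data.frame(start = tr$start, end = tr$end)
  pooled <- pool_windows(m$cytosines_a, m$cytosines_b, win, tr$context)
  n <- with(pooled, min(meth_a + unmeth_a, meth_b + unmeth_b))
  diff <- pooled$level_b - pooled$level_a
  expect_lt(abs(diff - 0.5), 4 * sqrt(2 * 0.5 * 0.5 / n))
})

test_that("linkage coupling produces exact correlations without noise", {
  expr <- matrix(2^seq(0, 5.5, 0.5), nrow = 1)  # 12 samples
  li_pos <- simulate_linkage(expr, gene_ids = "g1", dmr_ids = "d1",
                             link_sign = 1, noise_sd = 0, seed = 3)
  r_pos <- correlate_linkage(li_pos$meth_levels[1, ], log2(expr[1, ] + 1))
  expect_equal(r_pos$r, 1)
  expect_true(r_pos$linked)
  li_neg <- simulate_linkage(expr, gene_ids = "g1", dmr_ids = "d1",
                             link_sign = -1, noise_sd = 0, seed = 3)
  r_neg <- correlate_linkage(li_neg$meth_levels[1, ], log2(expr[1, ] + 1))
  expect_equal(r_neg$r, -1)
  expect_true(r_neg$linked)
  expect_true(all(li_pos$meth_levels >= 0 & li_pos$meth_levels <= 1))
})

test_that("noisy linkage correlations centre near the coupling strength", {
  set.seed(6)
  expr <- matrix(2^rnorm(12, 5, 1.5), nrow = 1)
  rs <- vapply(1:200, function(i) {
    li <- simulate_linkage(expr, gene_ids = "g", dmr_ids = "d",
                           link_sign = 1, noise_sd = 0.05, seed = i)
    correlate_linkage(li$meth_levels[1, ], log2(expr[1, ] + 1))$r
  }, numeric(1))
  expect_gt(mean(rs), 0.8)   # strong positive coupling at this noise level
  expect_lt(sd(rs), 0.2)
})
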
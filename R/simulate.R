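#' Expression simulation configuration
#'
#' Defines a 4-condition x 3-replicate (by default) negative-binomial count
#' experiment whose per-gene mean trajectories follow planted unit-change
#' profile shapes. `profile_mixture` maps shape labels (`"flat"` or a profile
#' id from the catalog for `length(conditions)` conditions) to the fraction of
#' genes drawn with that shape; fractions must sum to 1.
#'
#' @param n_genes Number of genes.
#' @param conditions Ordered condition labels (default R0, S1, R3, S4).
#' @param n_replicates Replicates per condition (default 3).
#' @param profile_mixture Named numeric vector of shape fractions. Default:
#'   60% flat, the rest spread evenly over all 26 non-flat profiles.
#' @param effect_size log2-units of expression change per unit profile step
#'   (default 2, i.e. 4-fold per step).
#' @param baseline_mean Mean count of an unchanged gene (default 100).
#' @param nb_dispersion NB dispersion alpha, variance `mu + alpha mu^2`;
#'   0 degenerates to Poisson (default 0.05).
#' @param seed Integer seed; all randomness flows from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 2000,
                       conditions = c("R0", "S1", "R3", "S4"),
                       n_replicates = 3,
                       profile_mixture = NULL,
                       effect_size = 2,
                       baseline_mean = 100,
                       nb_dispersion = 0.05,
                       seed = 1) {
  if (n_genes < 1 || n_replicates < 1) stop("n_genes and n_replicates must be positive")
  if (baseline_mean <= 0) stop("baseline_mean must be positive")
  if (nb_dispersion < 0) stop("nb_dispersion must be >= 0")
  if (effect_size < 0) stop("effect_size must be >= 0")
  catalog <- enumerate_profiles(length(conditions))
  if (is.null(profile_mixture)) {
    ids <- as.character(catalog$profile_id)
    profile_mixture <- c(flat = 0.6, stats::setNames(rep(0.4 / length(ids), length(ids)), ids))
  }
  if (abs(sum(profile_mixture) - 1) > 1e-9) stop("profile_mixture must sum to 1")
  bad <- setdiff(names(profile_mixture), c("flat", as.character(catalog$profile_id)))
  if (length(bad)) stop("unknown shape id(s) in profile_mixture: ", paste(bad, collapse = ", "))
  structure(list(
    n_genes = as.integer(n_genes), conditions = conditions,
    n_replicates = as.integer(n_replicates), profile_mixture = profile_mixture,
    effect_size = effect_size, baseline_mean = baseline_mean,
    nb_dispersion = nb_dispersion, seed = as.integer(seed),
    catalog = catalog
  ), class = "sim_config")
}

# NB draw with variance mu + alpha mu^2; alpha = 0 is Poisson.
rnb <- function(n, mu, alpha) {
  if (alpha == 0) rpois(n, mu) else rnbinom(n, size = 1 / alpha, mu = mu)
}

#' Simulate a planted-trajectory expression experiment
#'
#' Draws per-gene shapes from the configured mixture, sets condition means to
#' `baseline_mean * 2^(effect_size * value)` along each shape's cumulative
#' values, and samples replicate counts from the negative binomial. Gene
#' lengths are log-uniform on 500-5000 bp so FPKM normalisation is
#' exercised. Deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return List with `counts` (genes x samples integer matrix), `gene_info`
#'   (`gene_id`, `length`), `samples` (`sample`, `condition`, `replicate`) and
#'   `truth` (`gene_id`, `shape_id` (`NA` for flat), per-condition shape
#'   values `v1..vT`, `is_memory`, `category` implied by the planted shape).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  nc <- length(config$conditions)
  nrep <- config$n_replicates
  shapes <- sample(names(config$profile_mixture), config$n_genes,
                   replace = TRUE, prob = config$profile_mixture)
  vals <- matrix(0, config$n_genes, nc)
  planted <- shapes != "flat"
  if (any(planted)) {
    pv <- profile_values(config$catalog)
    idx <- match(as.integer(shapes[planted]),  config$catalog$profile_id)
    vals[planted, ] <- pv[idx, , drop = FALSE]
  }
  mu <- config$baseline_mean * 2^(config$effect_size * vals)
  counts <- matrix(0L, config$n_genes, nc * nrep)
  for (ci in seq_len(nc)) {
    for (ri in seq_len(nrep)) {
      counts[, (ci - 1) * nrep + ri] <-
        rnb(config$n_genes, mu[, ci], config$nb_dispersion)
    }
  }
  gene_id <- sprintf("gene_%05d", seq_len(config$n_genes))
  rownames(counts) <- gene_id
  samples <- data.frame(
    sample = paste0(rep(config$conditions, each = nrep), "_rep", rep(seq_len(nrep), nc)),
    condition = rep(config$conditions, each = nrep),
    replicate = rep(seq_len(nrep), nc)
  )
  colnames(counts) <- samples$sample
  lengths <- round(exp(runif(config$n_genes, log(500), log(5000))))
  truth <- data.frame(
    gene_id = gene_id,
    shape_id = ifelse(planted, suppressWarnings(as.integer(shapes)), NA_integer_)
  )
  colnames(vals) <- paste0("v", seq_len(nc))
  truth <- cbind(truth, vals)
  truth$is_memory <- true_memory_from_values(vals)
  truth$category <- true_category_from_shape(truth$shape_id, truth$is_memory, config$catalog)
  list(
    counts = counts,
    gene_info = data.frame(gene_id = gene_id, length = lengths),
    samples = samples,
    truth = truth
  )
}

# Memory status implied by a planted shape over (R0, S1, R3, S4) values:
# responsive (some condition differs from R0) and S4 or R3 differs from S1.
true_memory_from_values <- function(vals) {
  if (ncol(vals) != 4) return(rep(NA, nrow(vals)))
  responsive <- vals[, 2] != 0 | vals[, 3] != 0 | vals[, 4] != 0
  later <- vals[, 3] != vals[, 2] | vals[, 4] != vals[, 2]
  responsive & later
}

true_category_from_shape <- function(shape_id, is_memory, catalog) {
  cats <- profile_categories(catalog, scheme = "paper")
  out <- rep("non-memory", length(shape_id))
  mem <- !is.na(is_memory) & is_memory
  key <- as.character(shape_id[mem])
  out[mem] <- ifelse(key %in% names(cats), cats[key], "other-memory")
  out
}

#' Methylome simulation configuration
#'
#' Two-condition per-cytosine bisulfite count experiment on one chromosome
#' with planted differentially methylated windows. Context baselines default
#' to rice-like levels (CG 0.50, CHG 0.25, CHH 0.05).
#'
#' @param genome_length Chromosome length in bp (default 1e6).
#' @param n_cytosines_per_context Named vector of cytosine counts per context.
#' @param depth_mean Mean sequencing depth per cytosine (Poisson; default 30).
#' @param baseline_level Named methylation fractions per context.
#' @param n_dmrs Number of planted DMRs (default 40).
#' @param dmr_delta Methylation-fraction shift inside a planted DMR
#'   (default 0.3).
#' @param dmr_direction `"hyper"` (condition B gains methylation) or
#'   `"hypo"`.
#' @param dmr_width Planted DMR width in bp (default 200).
#' @param dmr_contexts Contexts eligible for planted DMRs; defaults to those
#'   whose shifted level stays in `[0, 1]`.
#' @param seed Integer seed.
#' @return A `meth_sim_config` list.
#' @export
meth_sim_config <- function(genome_length = 1e6,
                            n_cytosines_per_context = c(CG = 85000, CHG = 60000, CHH = 250000),
                            depth_mean = 30,
                            baseline_level = c(CG = 0.50, CHG = 0.25, CHH = 0.05),
                            n_dmrs = 40,
                            dmr_delta = 0.3,
                            dmr_direction = "hyper",
                            dmr_width = 200,
                            dmr_contexts = NULL,
                            seed = 1) {
  ctx <- c("CG", "CHG", "CHH")
  stopifnot(all(ctx %in% names(n_cytosines_per_context)),
            all(ctx %in% names(baseline_level)))
  if (depth_mean < 0) stop("depth_mean must be >= 0")
  if (dmr_width > genome_length) stop("dmr_width exceeds genome_length")
  if (dmr_delta < 0 || dmr_delta > 1) stop("dmr_delta must lie in [0, 1]")
  shift <- if (dmr_direction == "hyper") dmr_delta else -dmr_delta
  valid_ctx <- ctx[baseline_level[ctx] + shift >= 0 & baseline_level[ctx] + shift <= 1]
  if (is.null(dmr_contexts)) dmr_contexts <- valid_ctx
  if (n_dmrs > 0 && length(dmr_contexts) == 0) {
    stop("no context admits the requested methylation shift")
  }
  if (!all(dmr_contexts %in% valid_ctx)) {
    stop("shifted methylation level outside [0, 1] for context(s): ",
         paste(setdiff(dmr_contexts, valid_ctx), collapse = ", "))
  }
  structure(list(
    genome_length = genome_length,
    n_cytosines_per_context = n_cytosines_per_context,
    depth_mean = depth_mean, baseline_level = baseline_level,
    n_dmrs = as.integer(n_dmrs), dmr_delta = dmr_delta,
    dmr_direction = dmr_direction, dmr_width = dmr_width,
    dmr_contexts = dmr_contexts, seed = as.integer(seed)
  ), class = "meth_sim_config")
}

#' Simulate a two-condition methylome with planted DMRs
#'
#' Places cytosines uniformly at random per context (strands alternating),
#' draws per-cytosine depth Poisson(`depth_mean`) and methylated counts
#' Binomial(depth, level). Inside a planted DMR, the condition-B level of the
#' DMR's context is shifted by `dmr_delta` in the configured direction.
#' Planted DMR intervals are disjoint and separated by at least one window
#' width. Deterministic given `config$seed`.
#'
#' @param config A [meth_sim_config()].
#' @return List with `cytosines_a`, `cytosines_b` (cytosine report data
#'   frames: `chrom`, `pos` 1-based, `strand`, `meth`, `unmeth`, `context`)
#'   and `truth` (`dmr_id`, `chrom`, `start`, `end` 0-based half-open,
#'   `context`, `direction`, `delta`).
#' @export
simulate_methylome <- function(config) {
  stopifnot(inherits(config, "meth_sim_config"))
  set.seed(config$seed)
  L <- config$genome_length
  ctxs <- rep(names(config$n_cytosines_per_context), config$n_cytosines_per_context)
  pos <- sample.int(L, length(ctxs), replace = FALSE)
  o <- order(pos)
  pos <- pos[o]
  ctx <- ctxs[o]
  strand <- rep(c("+", "-"), length.out = length(pos))
  # disjoint planted DMRs on a spaced grid so merged calls cannot bridge them
  truth <- plant_dmr_intervals(config)
  level_a <- unname(config$baseline_level[ctx])
  level_b <- level_a
  shift <- if (config$dmr_direction == "hyper") config$dmr_delta else -config$dmr_delta
  if (nrow(truth) > 0) {
    for (i in seq_len(nrow(truth))) {
      inside <- pos > truth$start[i] & pos <= truth$end[i] & ctx == truth$context[i]
      level_b[inside] <- level_a[inside] + shift
    }
  }
  depth_a <- rpois(length(pos), config$depth_mean)
  depth_b <- rpois(length(pos), config$depth_mean)
  meth_a <- rbinom(length(pos), depth_a, level_a)
  meth_b <- rbinom(length(pos), depth_b, level_b)
  mk <- function(depth, meth) data.frame(
    chrom = "chr1", pos = pos, strand = strand,
    meth = meth, unmeth = depth - meth, context = ctx
  )
  list(cytosines_a = mk(depth_a, meth_a), cytosines_b = mk(depth_b, meth_b),
       truth = truth)
}

plant_dmr_intervals <- function(config) {
  if (config$n_dmrs == 0) {
    return(data.frame(dmr_id = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      context = character(0), direction = character(0),
                      delta = numeric(0)))
  }
  w <- config$dmr_width
  gap <- 3 * w  # spacing so window-level calls of adjacent DMRs never merge
  slots <- floor((config$genome_length - w) / (w + gap))
  if (slots < config$n_dmrs) stop("genome too short for the requested DMRs")
  chosen <- sort(sample.int(slots, config$n_dmrs))
  starts <- (chosen - 1) * (w + gap) + sample.int(gap, config$n_dmrs, replace = TRUE)
  data.frame(
    dmr_id = sprintf("dmr_%03d", seq_len(config$n_dmrs)),
    chrom = "chr1", start = starts, end = starts + w,
    context = sample(config$dmr_contexts, config$n_dmrs, replace = TRUE),
    direction = config$dmr_direction,
    delta = config$dmr_delta
  )
}

#' Couple methylation levels to expression across samples
#'
#' Builds the coupled per-sample dataset used by the linkage stage: for each
#' planted DMR-gene pair, the per-sample window methylation level is an affine
#' function of the standardised per-sample log2 expression (slope sign
#' `link_sign`) plus Gaussian noise, clamped into `[0, 1]` with enough
#' headroom that noise-free levels are never clipped.
#'
#' @param expression Genes x samples abundance matrix (counts or FPKM) for
#'   the genes to couple.
#' @param gene_ids Gene ids, default rownames of `expression`.
#' @param dmr_ids DMR ids to pair with the genes (recycled/truncated to the
#'   number of genes).
#' @param link_sign +1 or -1 coupling sign (default +1).
#' @param noise_sd Gaussian noise on the methylation level (default 0.05).
#' @param base_level Centre methylation level (default 0.5).
#' @param amplitude Maximum level excursion from the centre (default 0.4).
#' @param seed Integer seed.
#' @return List with `meth_levels` (pairs x samples matrix), `pairs`
#'   (`dmr_id`, `gene_id`, `true_sign`) and the input `expression` echoed.
#' @export
simulate_linkage <- function(expression, gene_ids = rownames(expression),
                             dmr_ids = sprintf("dmr_%03d", seq_len(nrow(expression))),
                             link_sign = 1, noise_sd = 0.05,
                             base_level = 0.5, amplitude = 0.4, seed = 1) {
  stopifnot(link_sign %in% c(-1, 1))
  if (is.null(dim(expression))) expression <- matrix(expression, nrow = 1)
  n <- nrow(expression)
  dmr_ids <- rep_len(dmr_ids, n)
  set.seed(seed)
  z <- t(apply(log2(expression + 1), 1, function(x) {
    s <- sd(x)
    if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }))
  zmax <- apply(abs(z), 1, max)
  slope <- ifelse(zmax > 0, amplitude / zmax, 0) * link_sign
  levels <- base_level + z * slope
  levels <- levels + matrix(rnorm(length(levels), 0, noise_sd), n)
  levels <- pmin(pmax(levels, 0), 1)
  dimnames(levels) <- list(dmr_ids, colnames(expression))
  list(
    meth_levels = levels,
    pairs = data.frame(dmr_id = dmr_ids, gene_id = gene_ids,
                       true_sign = link_sign),
    expression = expression
  )
}
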
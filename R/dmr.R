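#' Sliding windows along a chromosome
#'
#' Generates the window grid `[k*step, k*step + window)` (0-based half-open)
#' for all starts below `chrom_length`; the final windows are truncated at the
#' chromosome end.
#'
#' @param chrom_length Chromosome length in bp.
#' @param window Window width in bp (default 200).
#' @param step Slide interval in bp (default 50); `step <= window`.
#' @return Data frame with columns `start`, `end` (0-based half-open).
#' @export
make_windows <- function(chrom_length, window = 200, step = 50) {
  if (window < 1 || step < 1) stop("window and step must be positive")
  if (step > window) stop("step must not exceed window")
  if (chrom_length < 1) stop("chrom_length must be positive")
  starts <- seq(0, chrom_length - 1, by = step)
  data.frame(start = starts, end = pmin(starts + window, chrom_length))
}

#' Pool cytosine counts into windows for two conditions
#'
#' For each window and context, sums methylated and unmethylated counts of
#' cytosines whose 1-based position falls inside the 0-based half-open window
#' (`start < pos <= end`), pooling both strands. Windows with no covered
#' cytosine in either condition are flagged `covered = FALSE`.
#'
#' @param cytosines_a,cytosines_b Cytosine report data frames for the two
#'   conditions: columns `chrom`, `pos` (1-based), `strand`, `meth`, `unmeth`,
#'   `context`. Both conditions must report the same positions (the usual
#'   cytosine-report convention); only counts differ.
#' @param windows Data frame from [make_windows()].
#' @param context One of `"CG"`, `"CHG"`, `"CHH"`.
#' @param chrom Chromosome to process; default the first in `cytosines_a`.
#' @return Data frame, one row per window: `chrom`, `start`, `end`, `context`,
#'   `meth_a`, `unmeth_a`, `meth_b`, `unmeth_b`, `level_a`, `level_b`,
#'   `covered`.
#' @export
pool_windows <- function(cytosines_a, cytosines_b, windows, context,
                         chrom = cytosines_a$chrom[1]) {
  sel_a <- cytosines_a$context == context & cytosines_a$chrom == chrom
  sel_b <- cytosines_b$context == context & cytosines_b$chrom == chrom
  ca <- cytosines_a[sel_a, , drop = FALSE]
  cb <- cytosines_b[sel_b, , drop = FALSE]
  n <- nrow(windows)
  sum_in <- function(pos, counts, starts, ends) {
    # windows overlap, so each cytosine contributes to window/step windows;
    # accumulate per window via cumulative sums over sorted positions
    o <- order(pos)
    pos <- pos[o]; counts <- counts[o]
    cs <- c(0, cumsum(counts))
    lo <- findInterval(starts, pos)       # pos <= start  -> excluded
    hi <- findInterval(ends, pos)         # pos <= end    -> included
    cs[hi + 1] - cs[lo + 1]
  }
  meth_a <- sum_in(ca$pos, ca$meth, windows$start, windows$end)
  unmeth_a <- sum_in(ca$pos, ca$unmeth, windows$start, windows$end)
  meth_b <- sum_in(cb$pos, cb$meth, windows$start, windows$end)
  unmeth_b <- sum_in(cb$pos, cb$unmeth, windows$start, windows$end)
  cov_a <- meth_a + unmeth_a
  cov_b <- meth_b + unmeth_b
  data.frame(
    chrom = rep(chrom, n),
    start = windows$start, end = windows$end, context = rep(context, n),
    meth_a = meth_a, unmeth_a = unmeth_a,
    meth_b = meth_b, unmeth_b = unmeth_b,
    level_a = ifelse(cov_a > 0, meth_a / cov_a, NA_real_),
    level_b = ifelse(cov_b > 0, meth_b / cov_b, NA_real_),
    covered = cov_a > 0 & cov_b > 0
  )
}

#' Two-sided Fisher exact p-values for 2x2 count tables
#'
#' For each table `[[a, b], [c, d]]` (rows = conditions, columns =
#' methylated/unmethylated), conditions on all margins and sums the
#' hypergeometric probabilities of every table at most as likely as the
#' observed one (the standard two-sided Fisher convention). Vectorised over
#' tables. A table with a zero row or column margin is untestable and gets
#' p = 1.
#'
#' @param a,b,c,d Non-negative integer vectors: `a` methylated and `b`
#'   unmethylated in condition A, `c` and `d` likewise in condition B.
#' @return Numeric vector of two-sided p-values.
#' @export
window_fisher <- function(a, b, c, d) {
  n <- length(a)
  stopifnot(length(b) == n, length(c) == n, length(d) == n)
  if (any(c(a, b, c, d) < 0)) stop("counts must be non-negative")
  p <- rep(1, n)
  m1 <- a + b      # condition-A margin
  k1 <- a + c      # methylated margin
  tot <- a + b + c + d
  testable <- m1 > 0 & (c + d) > 0 & k1 > 0 & (b + d) > 0
  for (i in which(testable)) {
    kk <- max(0, k1[i] - (tot[i] - m1[i])):min(k1[i], m1[i])
    pr <- dhyper(kk, m1[i], tot[i] - m1[i], k1[i])
    obs <- pr[match(a[i], kk)]
    p[i] <- min(1, sum(pr[pr <= obs * (1 + 1e-7)]))
  }
  p
}

#' Test windows and call differentially methylated regions
#'
#' Filters windows to those with at least `min_coverage` reads in each
#' condition, computes the two-sided Fisher p per window, applies
#' Benjamini-Hochberg correction within the context, keeps windows with
#' `p <= p_cut` and `q <= q_cut`, and (optionally) merges overlapping or
#' bookended significant windows of the same direction into DMRs. Direction
#' is the sign of `level_b - level_a` (`hyper` when condition B is more
#' methylated).
#'
#' Region extraction works in two stages, because a single 200 bp window is a
#' noisy unit: overlapping windows smear evidence up to `window - step` beyond
#' a true region's edges, and a region whose every individual window is
#' marginal can still be decisively non-null when its full extent is pooled.
#' Candidate regions are therefore the merged runs of raw-significant windows
#' (at least `min_windows` of them, same direction); each candidate is then
#' re-tested by Fisher's exact test on the counts pooled over its whole
#' extent, with BH correction across candidates, and must reach
#' `q <= q_cut`. When `bins` is supplied (the same pooling at step-width
#' resolution, i.e. `pool_windows()` on `make_windows(len, step, step)`),
#' each surviving region is boundary-refined by a two-segment binomial
#' changepoint fit and must show a refined methylation-level difference of at
#' least `min_diff`.
#'
#' @param pooled Data frame from [pool_windows()] (a single context).
#' @param p_cut,q_cut Significance cuts (defaults 0.05 each).
#' @param min_coverage Minimum reads per condition per window (default 5).
#' @param merge Merge windows into DMRs (default `TRUE`; `FALSE` keeps
#'   FDR-significant windows as single-window DMRs).
#' @param min_windows Minimum raw-significant windows supporting a candidate
#'   region (default 2; an isolated significant window is not a region).
#' @param bins Optional fine-resolution tiling pooling (width dividing
#'   `step`, e.g. `pool_windows()` on `make_windows(len, 25, 25)`) used for
#'   exact region counts and boundary refinement; without it no refinement is
#'   done and regions keep their merged window extent.
#' @param min_diff Minimum absolute refined methylation-level difference for
#'   a reported DMR (default 0.2; applied when `bins` is available).
#' @return List with `windows` (the tested windows with `p_value`, `q_value`,
#'   `significant`, `direction`) and `dmrs` (data frame: `chrom`, `start`,
#'   `end`, `context`, `direction`, `n_windows`, `min_q` (region BH q),
#'   `mean_level_diff`).
#' @export
call_dmrs <- function(pooled, p_cut = 0.05, q_cut = 0.05, min_coverage = 5,
                      merge = TRUE, min_windows = 2, bins = NULL,
                      min_diff = 0.2) {
  if (length(unique(pooled$context)) > 1) {
    stop("call_dmrs() expects a single context; BH is applied per context")
  }
  ok <- pooled$covered &
    (pooled$meth_a + pooled$unmeth_a) >= min_coverage &
    (pooled$meth_b + pooled$unmeth_b) >= min_coverage
  tested <- pooled[ok, , drop = FALSE]
  tested$p_value <- window_fisher(tested$meth_a, tested$unmeth_a,
                                  tested$meth_b, tested$unmeth_b)
  tested$q_value <- benjamini_hochberg(tested$p_value)
  diff <- tested$level_b - tested$level_a
  tested$direction <- ifelse(diff >= 0, "hyper", "hypo")
  tested$significant <- tested$p_value <= p_cut & tested$q_value <= q_cut &
    diff != 0
  raw_sig <- tested$p_value <= p_cut & diff != 0
  if (!merge) {
    keep <- tested[tested$significant, , drop = FALSE]
    dmrs <- merge_significant_windows(keep, merge = FALSE)
    return(list(windows = tested, dmrs = dmrs))
  }
  cand <- merge_significant_windows(tested[raw_sig, , drop = FALSE])
  cand <- cand[cand$n_windows >= min_windows, , drop = FALSE]
  rownames(cand) <- NULL
  if (nrow(cand) == 0) return(list(windows = tested, dmrs = cand))
  # a region must contain at least one FDR-significant seed window; raw-
  # significant neighbours only extend it
  dmrs <- cand[cand$min_q <= q_cut, , drop = FALSE]
  rownames(dmrs) <- NULL
  if (!is.null(bins) && nrow(dmrs) > 0) {
    dmrs <- refine_dmr_boundaries(dmrs, bins)
    rc <- region_counts(dmrs, bins)
    dmrs$mean_level_diff <- rc$meth_b / (rc$meth_b + rc$unmeth_b) -
      rc$meth_a / (rc$meth_a + rc$unmeth_a)
    dmrs <- dmrs[!is.na(dmrs$mean_level_diff) &
                   abs(dmrs$mean_level_diff) >= min_diff, , drop = FALSE]
    rownames(dmrs) <- NULL
  }
  dmrs <- dmrs[, c("chrom", "start", "end", "context", "direction",
                   "n_windows", "min_q", "mean_level_diff")]
  list(windows = tested, dmrs = dmrs)
}

# Pool bin counts over each region's extent (bins must tile at step width).
region_counts <- function(regions, bins) {
  out <- data.frame(meth_a = numeric(nrow(regions)), unmeth_a = 0,
                    meth_b = 0, unmeth_b = 0)
  for (i in seq_len(nrow(regions))) {
    sel <- bins$chrom == regions$chrom[i] &
      bins$start >= regions$start[i] & bins$end <= regions$end[i]
    out$meth_a[i] <- sum(bins$meth_a[sel])
    out$unmeth_a[i] <- sum(bins$unmeth_a[sel])
    out$meth_b[i] <- sum(bins$meth_b[sel])
    out$unmeth_b[i] <- sum(bins$unmeth_b[sel])
  }
  out
}

# Refine each DMR's extent by a two-segment binomial changepoint fit at
# step-bin resolution. The merged extent plus a margin of (window-ish) flank
# bins is segmented into inside [L, R) / outside; for every candidate pair of
# bin edges the binomial log-likelihood with segment-wise MLE methylation
# levels (per condition) is computed from pooled bin counts, and the
# maximising (L, R) becomes the DMR extent. Window unions overstate a
# region's extent by up to window - step per side; the likelihood fit
# localises the level change at bin resolution instead.
refine_dmr_boundaries <- function(dmrs, bins, margin_bins = 6) {
  bw <- median(bins$end - bins$start)
  for (i in seq_len(nrow(dmrs))) {
    sel <- which(bins$chrom == dmrs$chrom[i] &
                   bins$start >= dmrs$start[i] - margin_bins * bw &
                   bins$end <= dmrs$end[i] + margin_bins * bw)
    # bins are assumed to tile; require at least the original extent
    if (length(sel) < 2) next
    b <- bins[sel, , drop = FALSE]
    b <- b[order(b$start), , drop = FALSE]
    run <- changepoint_extent(b)
    if (is.null(run)) next
    dmrs$start[i] <- b$start[run[1]]
    dmrs$end[i] <- b$end[run[2]]
  }
  dmrs
}

# Best (first_bin, last_bin) under a two-segment binomial model applied to
# both conditions: inside and outside segments each get their own MLE level
# per condition; returns NULL when no interior segmentation beats the
# single-segment fit.
changepoint_extent <- function(b) {
  n <- nrow(b)
  cma <- c(0, cumsum(b$meth_a)); cua <- c(0, cumsum(b$unmeth_a))
  cmb <- c(0, cumsum(b$meth_b)); cub <- c(0, cumsum(b$unmeth_b))
  seg_ll <- function(m, u) {
    t <- m + u
    ifelse(t == 0, 0,
           ifelse(m == 0, 0, m * log(m / t)) + ifelse(u == 0, 0, u * log(u / t)))
  }
  tot_ll <- function(lo, hi) {  # bins lo..hi inclusive, 1-based
    ma_in <- cma[hi + 1] - cma[lo]; ua_in <- cua[hi + 1] - cua[lo]
    mb_in <- cmb[hi + 1] - cmb[lo]; ub_in <- cub[hi + 1] - cub[lo]
    ma_out <- cma[n + 1] - ma_in; ua_out <- cua[n + 1] - ua_in
    mb_out <- cmb[n + 1] - mb_in; ub_out <- cub[n + 1] - ub_in
    seg_ll(ma_in, ua_in) + seg_ll(mb_in, ub_in) +
      seg_ll(ma_out, ua_out) + seg_ll(mb_out, ub_out)
  }
  base <- seg_ll(cma[n + 1], cua[n + 1]) + seg_ll(cmb[n + 1], cub[n + 1])
  best <- base; best_run <- NULL
  for (lo in 1:n) {
    for (hi in lo:n) {
      ll <- tot_ll(lo, hi)
      if (ll > best + 1e-9) { best <- ll; best_run <- c(lo, hi) }
    }
  }
  best_run
}

# Merge overlapping/bookended windows of the same chrom, context and
# direction into candidate regions. With merge = FALSE each window becomes
# its own single-window region.
merge_significant_windows <- function(sig, merge = TRUE) {
  empty <- data.frame(
    chrom = character(0), start = numeric(0), end = numeric(0),
    context = character(0), direction = character(0),
    n_windows = integer(0), min_p = numeric(0), min_q = numeric(0),
    mean_level_diff = numeric(0)
  )
  if (nrow(sig) == 0) return(empty)
  if (!merge) {
    out <- data.frame(
      chrom = sig$chrom, start = sig$start, end = sig$end,
      context = sig$context, direction = sig$direction,
      n_windows = 1L, min_p = sig$p_value, min_q = sig$q_value,
      mean_level_diff = sig$level_b - sig$level_a
    )
    rownames(out) <- NULL
    return(out)
  }
  out <- lapply(split(sig, list(sig$chrom, sig$direction), drop = TRUE),
    function(g) {
      ir <- IRanges::IRanges(start = g$start + 1, end = g$end)  # to 1-based closed
      red <- IRanges::reduce(ir, min.gapwidth = 1)
      hits <- IRanges::findOverlaps(ir, red)
      grp <- S4Vectors::subjectHits(hits)
      data.frame(
        chrom = g$chrom[1],
        start = IRanges::start(red) - 1,
        end = IRanges::end(red),
        context = g$context[1],
        direction = g$direction[1],
        n_windows = as.integer(tabulate(grp, nbins = length(red))),
        min_p = vapply(seq_along(red), function(j) {
          min(g$p_value[grp == j])
        }, numeric(1)),
        min_q = vapply(seq_along(red), function(j) {
          min(g$q_value[grp == j])
        }, numeric(1)),
        mean_level_diff = vapply(seq_along(red), function(j) {
          mean((g$level_b - g$level_a)[grp == j])
        }, numeric(1))
      )
    })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$chrom, res$start), , drop = FALSE]
}
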
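#' Enumerate unit-change trajectory profiles
#'
#' Builds the catalog of discretised expression trajectories over `n_conditions`
#' ordered conditions: every vector of per-transition steps in
#' `{-max_unit_change, ..., +max_unit_change}` except the flat (all-zero)
#' vector. For four conditions and unit changes this yields the 26 candidate
#' profiles used to cluster drought-memory trajectories.
#'
#' Profiles are numbered canonically: lexicographic rank of the step vector
#' (with -1 < 0 < +1), the flat vector's slot removed and higher ranks shifted
#' down by one. Under this numbering, for four conditions, profile 0 is
#' monotone down (steps -1,-1,-1) and profile 25 monotone up (+1,+1,+1).
#'
#' @param n_conditions Number of ordered conditions (time points), >= 2.
#' @param max_unit_change Maximum absolute per-transition step (default 1).
#' @return An object of class `profile_catalog`: a data frame with one row per
#'   profile and columns `profile_id`, `step1..step{T-1}`, `v1..vT` (cumulative
#'   values, `v1` always 0). The step and value matrices are also attached as
#'   attributes `steps` and `values`.
#' @examples
#' cat4 <- enumerate_profiles(4)
#' nrow(cat4)  # 26
#' @export
enumerate_profiles <- function(n_conditions, max_unit_change = 1) {
  if (!is.numeric(n_conditions) || length(n_conditions) != 1 ||
      n_conditions < 2 || n_conditions != round(n_conditions)) {
    stop("`n_conditions` must be a single integer >= 2")
  }
  if (max_unit_change < 1 || max_unit_change != round(max_unit_change)) {
    stop("`max_unit_change` must be a positive integer")
  }
  n_steps <- n_conditions - 1
  levels <- seq(-max_unit_change, max_unit_change)
  # expand.grid varies the first factor fastest; feed reversed factor list and
  # flip columns back so rows come out in lexicographic order, leftmost step
  # most significant
  g <- expand.grid(rev(rep(list(levels), n_steps)), KEEP.OUT.ATTRS = FALSE)
  steps <- as.matrix(g[, rev(seq_len(ncol(g))), drop = FALSE])
  dimnames(steps) <- NULL
  flat <- rowSums(steps != 0) == 0
  steps <- steps[!flat, , drop = FALSE]
  values <- cbind(0, t(apply(steps, 1, cumsum)))
  if (n_steps == 1) values <- cbind(0, steps)  # apply() drops dims for 1 step
  ids <- seq_len(nrow(steps)) - 1L
  out <- data.frame(profile_id = ids)
  colnames(steps) <- paste0("step", seq_len(n_steps))
  colnames(values) <- paste0("v", seq_len(n_conditions))
  out <- cbind(out, steps, values)
  attr(out, "steps") <- unname(steps)
  attr(out, "values") <- unname(values)
  attr(out, "n_conditions") <- n_conditions
  attr(out, "max_unit_change") <- max_unit_change
  class(out) <- c("profile_catalog", "data.frame")
  out
}

#' Profile catalog value matrix
#'
#' @param catalog A `profile_catalog` from [enumerate_profiles()].
#' @return Numeric matrix, profiles x conditions, of cumulative profile values.
#' @export
profile_values <- function(catalog) {
  v <- attr(catalog, "values")
  if (is.null(v)) stop("not a profile catalog")
  v
}

#' Log-ratio transform of a trajectory
#'
#' Expresses a non-negative abundance trajectory relative to its first
#' condition: `v[t] = log2((x[t] + pc) / (x[1] + pc))`, so the first entry is
#' always 0. This is the standard transform applied before matching a gene's
#' per-condition means against candidate profiles.
#'
#' @param trajectory Numeric vector (or matrix, genes x conditions) of
#'   non-negative abundances.
#' @param pseudocount Added to every value before taking ratios (default 1).
#' @return Transformed vector (or matrix) of the same shape; first entry
#'   (column) exactly 0.
#' @export
log_ratio_transform <- function(trajectory, pseudocount = 1) {
  if (any(trajectory < 0, na.rm = TRUE)) stop("abundances must be non-negative")
  if (is.matrix(trajectory)) {
    v <- log2((trajectory + pseudocount) / (trajectory[, 1] + pseudocount))
    v[, 1] <- 0
  } else {
    v <- log2((trajectory + pseudocount) / (trajectory[1] + pseudocount))
    v[1] <- 0
  }
  v
}

#' Assign trajectories to their best-matching profile
#'
#' Matches each transformed trajectory against every profile in the catalog by
#' centred Pearson correlation and returns the profile with the maximum
#' correlation. Ties break toward the lower profile id. Trajectories with zero
#' variance (constant, e.g. all-zero after transform) are unassignable and get
#' `NA` ids rather than an error.
#'
#' @param transformed Numeric vector of length T, or a genes x T matrix, of
#'   log-ratio-transformed trajectories.
#' @param catalog A `profile_catalog` whose profiles have length T.
#' @return Data frame with columns `profile_id` (integer, `NA` if
#'   unassignable) and `correlation` (the maximising correlation, `NA` if
#'   unassignable). One row per input trajectory.
#' @export
assign_profile <- function(transformed, catalog) {
  vals <- profile_values(catalog)
  if (!is.matrix(transformed)) transformed <- matrix(transformed, nrow = 1)
  if (ncol(transformed) != ncol(vals)) {
    stop("trajectory length does not match profile length")
  }
  ok <- apply(transformed, 1, sd) > 0
  n <- nrow(transformed)
  best_id <- rep(NA_integer_, n)
  best_cor <- rep(NA_real_, n)
  if (any(ok)) {
    cc <- suppressWarnings(cor(t(transformed[ok, , drop = FALSE]), t(vals)))
    # ties broken toward the lower profile id: max.col over negated tolerance
    pick <- apply(cc, 1, function(r) {
      m <- max(r)
      which(r >= m - 1e-12)[1]
    })
    best_id[ok] <- catalog$profile_id[pick]
    best_cor[ok] <- cc[cbind(seq_len(sum(ok)), pick)]
  }
  data.frame(profile_id = best_id, correlation = best_cor)
}

#' Per-condition mean trajectories from an expression table
#'
#' Averages replicate columns within each condition (the clustering works on
#' one value per condition per gene).
#'
#' @param abundance Genes x samples numeric matrix (typically FPKM).
#' @param samples Sample sheet data frame with columns `sample`, `condition`;
#'   `condition` order follows `conditions`.
#' @param conditions Ordered condition labels; default the order of first
#'   appearance in `samples$condition`.
#' @return Genes x conditions matrix of means.
#' @export
condition_means <- function(abundance, samples,
                            conditions = unique(samples$condition)) {
  stopifnot(ncol(abundance) == nrow(samples))
  out <- sapply(conditions, function(cond) {
    idx <- which(samples$condition == cond)
    if (length(idx) == 0) stop("condition absent from sample sheet: ", cond)
    rowMeans(abundance[, idx, drop = FALSE])
  })
  if (!is.matrix(out)) out <- matrix(out, nrow = 1, dimnames = list(NULL, conditions))
  out
}
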
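#' Evaluate DMR calls against planted truth
#'
#' A planted DMR counts as recovered when a called DMR of the same context
#' overlaps it with both boundaries within `tol` bp. A called DMR is a true
#' positive when it matches some planted DMR under the same rule.
#'
#' @param called Data frame of called DMRs (`chrom`, `start`, `end`,
#'   `context`).
#' @param truth Data frame of planted DMRs (`chrom`, `start`, `end`,
#'   `context`).
#' @param tol Boundary tolerance in bp (default 50, one window step).
#' @return List with `sensitivity`, `precision`, `n_called`, `n_truth`.
#' @export
evaluate_dmr_calls <- function(called, truth, tol = 50) {
  match_one <- function(s, e, ch, ctx, against) {
    any(against$chrom == ch & against$context == ctx &
          abs(against$start - s) <= tol & abs(against$end - e) <= tol)
  }
  recovered <- vapply(seq_len(nrow(truth)), function(i) {
    match_one(truth$start[i], truth$end[i], truth$chrom[i], truth$context[i], called)
  }, logical(1))
  true_pos <- vapply(seq_len(nrow(called)), function(i) {
    match_one(called$start[i], called$end[i], called$chrom[i], called$context[i], truth)
  }, logical(1))
  list(
    sensitivity = if (nrow(truth)) mean(recovered) else NA_real_,
    precision = if (nrow(called)) mean(true_pos) else NA_real_,
    n_called = nrow(called), n_truth = nrow(truth)
  )
}

#' Evaluate memory calls against planted truth
#'
#' @param calls Data frame from [categorize_memory()] / [classify_memory()].
#' @param truth Truth table from [simulate_expression()].
#' @return List with `memory_sensitivity` (planted memory genes flagged),
#'   `shape_accuracy` (planted non-flat genes assigned their true profile),
#'   `category_accuracy` (planted memory genes given their true category).
#' @export
evaluate_memory_calls <- function(calls, truth) {
  stopifnot(identical(as.character(calls$gene_id), as.character(truth$gene_id)))
  mem <- truth$is_memory
  planted <- !is.na(truth$shape_id)
  list(
    memory_sensitivity = mean(calls$is_memory[mem]),
    shape_accuracy = mean(!is.na(calls$profile_id[planted]) &
                            calls$profile_id[planted] == truth$shape_id[planted]),
    category_accuracy = mean(calls$category[mem] == truth$category[mem])
  )
}
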
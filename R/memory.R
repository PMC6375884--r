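#' Memory-profile preset
#'
#' The curated list of 16 trajectory profiles (out of the 26 four-condition
#' unit-change profiles, canonical numbering) treated as memory patterns in
#' the source study's clustering. The list is partly curated rather than
#' derivable from a single shape predicate, so it is shipped as an explicit
#' preset.
#'
#' @return Integer vector of 16 profile ids.
#' @export
memory_profile_preset <- function() {
  c(0L, 1L, 3L, 4L, 7L, 9L, 10L, 12L, 13L, 15L, 16L, 18L, 21L, 22L, 24L, 25L)
}

#' Map profiles to memory categories
#'
#' Two schemes are available. `"paper"` (default) uses the published explicit
#' id lists under the canonical four-condition numbering: stable = {21, 24},
#' accumulated = {22}, lineage = {25}, initial = {7, 18},
#' dosage = {9, 10, 12, 13, 15, 16}; any other profile maps to
#' `"other-memory"`. `"shape"` derives categories from sign-symmetric
#' predicates on the step vector and works for any four-condition catalog:
#' dosage (no change at the first stress, `v2 == 0`), initial (respond once
#' then return to baseline and hold), lineage (strictly monotone), stable
#' (respond then hold the final level, no reversals), accumulated (respond,
#' plateau, respond again in the same direction).
#'
#' @param catalog A four-condition `profile_catalog`.
#' @param scheme `"paper"` or `"shape"`.
#' @return Character vector of categories, one per catalog profile, named by
#'   profile id.
#' @export
profile_categories <- function(catalog = enumerate_profiles(4),
                               scheme = c("paper", "shape")) {
  scheme <- match.arg(scheme)
  if (attr(catalog, "n_conditions") != 4 || attr(catalog, "max_unit_change") != 1) {
    stop("category schemes are defined for the 4-condition unit-change catalog")
  }
  ids <- catalog$profile_id
  cat_out <- rep("other-memory", length(ids))
  if (scheme == "paper") {
    lists <- list(
      stable      = c(21L, 24L),
      accumulated = 22L,
      lineage     = 25L,
      initial     = c(7L, 18L),
      dosage      = c(9L, 10L, 12L, 13L, 15L, 16L)
    )
    for (nm in names(lists)) cat_out[ids %in% lists[[nm]]] <- nm
  } else {
    s <- attr(catalog, "steps")
    v <- attr(catalog, "values")
    for (i in seq_along(ids)) {
      si <- s[i, ]; vi <- v[i, ]
      no_reversal <- !(any(si > 0) && any(si < 0))
      cat_out[i] <-
        if (vi[2] == 0) "dosage"
        else if (vi[3] == 0 && vi[4] == 0) "initial"
        else if (all(si == si[1]) && si[1] != 0) "lineage"
        else if (no_reversal && si[3] == 0) "stable"
        else if (no_reversal && si[1] != 0 && any(si == 0) && si[3] != 0) "accumulated"
        else "other-memory"
    }
  }
  names(cat_out) <- ids
  cat_out
}

#' Flag memory genes from differential-expression results
#'
#' A gene is a memory gene when it is responsive to the stress (differentially
#' expressed versus the untreated control R0 in at least one of S1, R3, S4)
#' and its level in a later stress (S4) or re-watering (R3) differs
#' significantly from its level in the first stress (S1). `rule = "any"`
#' requires one of the two later-versus-S1 contrasts to be significant;
#' `rule = "all"` requires both.
#'
#' @param de_results Named list of DE result data frames (as returned by
#'   [run_de()]), indexed by contrast name. Required names:
#'   `"S4_vs_S1"`, `"R3_vs_S1"`, `"S1_vs_R0"`, `"R3_vs_R0"`, `"S4_vs_R0"`.
#'   Each must have columns `gene_id` and `status`.
#' @param rule `"any"` (default) or `"all"`.
#' @return Data frame with columns `gene_id`, `is_memory`, `responsive`,
#'   `sig_R3_vs_S1`, `sig_S4_vs_S1`.
#' @export
flag_memory <- function(de_results, rule = c("any", "all")) {
  rule <- match.arg(rule)
  need <- c("S4_vs_S1", "R3_vs_S1", "S1_vs_R0", "R3_vs_R0", "S4_vs_R0")
  missing_c <- setdiff(need, names(de_results))
  if (length(missing_c)) {
    stop("missing DE contrast(s): ", paste(missing_c, collapse = ", "))
  }
  genes <- de_results[[need[1]]]$gene_id
  sig <- function(contrast) {
    d <- de_results[[contrast]]
    stopifnot(identical(d$gene_id, genes))
    d$status != "unchanged"
  }
  responsive <- sig("S1_vs_R0") | sig("R3_vs_R0") | sig("S4_vs_R0")
  a <- sig("R3_vs_S1"); b <- sig("S4_vs_S1")
  later <- if (rule == "any") a | b else a & b
  data.frame(
    gene_id = genes,
    is_memory = responsive & later,
    responsive = responsive,
    sig_R3_vs_S1 = a,
    sig_S4_vs_S1 = b
  )
}

#' Categorise memory genes
#'
#' Combines a profile assignment with memory flags: non-memory genes get
#' `"non-memory"`; memory genes get the category of their assigned profile
#' (see [profile_categories()]); memory genes without an assignable profile
#' get `"other-memory"`.
#'
#' @param assignment Data frame from [assign_profile()] (plus a `gene_id`
#'   column, or in the row order of `memory_flags`).
#' @param memory_flags Data frame from [flag_memory()].
#' @param categories Named category vector from [profile_categories()].
#' @return Data frame with columns `gene_id`, `profile_id`, `correlation`,
#'   `is_memory`, `category`.
#' @export
categorize_memory <- function(assignment, memory_flags,
                              categories = profile_categories()) {
  stopifnot(nrow(assignment) == nrow(memory_flags))
  cat_of <- function(pid, mem) {
    if (!mem) return("non-memory")
    if (is.na(pid)) return("other-memory")
    key <- as.character(pid)
    if (!key %in% names(categories)) return("other-memory")
    categories[[key]]
  }
  category <- mapply(cat_of, assignment$profile_id, memory_flags$is_memory)
  data.frame(
    gene_id = memory_flags$gene_id,
    profile_id = assignment$profile_id,
    correlation = assignment$correlation,
    is_memory = memory_flags$is_memory,
    category = unname(category)
  )
}

#' Profile and classify memory genes end to end
#'
#' Convenience wrapper: per-condition mean FPKM, log-ratio transform, nearest
#' profile assignment, memory flagging from DE results and categorisation.
#'
#' @param fpkm Genes x samples FPKM matrix.
#' @param samples Sample sheet (`sample`, `condition`, `replicate`).
#' @param de_results Named list of DE results (see [flag_memory()]).
#' @param gene_ids Gene identifiers, default rownames of `fpkm`.
#' @param conditions Ordered condition labels (default R0, S1, R3, S4).
#' @param rule Memory rule, `"any"` or `"all"`.
#' @param pseudocount Pseudocount for the log-ratio transform.
#' @param catalog Profile catalog; default the 26-profile four-condition one.
#' @param categories Category map; default the published lists.
#' @return The [categorize_memory()] data frame.
#' @export
classify_memory <- function(fpkm, samples, de_results,
                            gene_ids = rownames(fpkm),
                            conditions = c("R0", "S1", "R3", "S4"),
                            rule = "any", pseudocount = 1,
                            catalog = enumerate_profiles(length(conditions)),
                            categories = profile_categories(catalog)) {
  means <- condition_means(fpkm, samples, conditions)
  transformed <- log_ratio_transform(means, pseudocount)
  assignment <- assign_profile(transformed, catalog)
  flags <- flag_memory(de_results, rule = rule)
  stopifnot(identical(as.character(flags$gene_id), as.character(gene_ids)))
  categorize_memory(assignment, flags, categories)
}
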
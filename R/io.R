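#' Read an expression table
#'
#' Tab-separated file with columns `gene_id`, `length`, then one column per
#' sample.
#'
#' @param path File path.
#' @return List with `counts` (matrix), `gene_info` (`gene_id`, `length`).
#' @export
read_expression <- function(path) {
  d <- read.delim(path, check.names = FALSE)
  if (!all(c("gene_id", "length") %in% colnames(d))) {
    stop("expression table needs gene_id and length columns")
  }
  counts <- as.matrix(d[, setdiff(colnames(d), c("gene_id", "length")), drop = FALSE])
  rownames(counts) <- d$gene_id
  list(counts = counts, gene_info = d[, c("gene_id", "length")])
}

#' Write an expression table
#' @param expr List with `counts` and `gene_info` (as from
#'   [simulate_expression()]).
#' @param path Output path.
#' @export
write_expression <- function(expr, path) {
  out <- cbind(expr$gene_info[, c("gene_id", "length")], as.data.frame(expr$counts))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a sample sheet (`sample`, `condition`, `replicate`)
#' @param path File path.
#' @return Data frame.
#' @export
read_sample_sheet <- function(path) {
  d <- read.delim(path)
  if (!all(c("sample", "condition") %in% colnames(d))) {
    stop("sample sheet needs sample and condition columns")
  }
  d
}

#' Read a cytosine report
#'
#' Tab-separated dialect of the per-cytosine bisulfite report: columns
#' `chrom`, `pos` (1-based), `strand`, `meth`, `unmeth`, `context`.
#'
#' @param path File path.
#' @return Data frame with those columns.
#' @export
read_cytosine_report <- function(path) {
  d <- read.delim(path)
  need <- c("chrom", "pos", "strand", "meth", "unmeth", "context")
  if (!all(need %in% colnames(d))) {
    stop("cytosine report needs columns: ", paste(need, collapse = ", "))
  }
  if (any(d$meth < 0 | d$unmeth < 0)) stop("negative counts in cytosine report")
  if (!all(d$context %in% c("CG", "CHG", "CHH"))) {
    stop("context must be CG, CHG or CHH")
  }
  d
}

#' Write a cytosine report
#' @param cytosines Data frame (`chrom`, `pos`, `strand`, `meth`, `unmeth`,
#'   `context`).
#' @param path Output path.
#' @export
write_cytosine_report <- function(cytosines, path) {
  write.table(cytosines, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read gene models from BED6
#'
#' @param path BED6 file (chrom, start, end, name, score, strand; 0-based
#'   half-open).
#' @return Data frame with `chrom`, `start`, `end`, `gene_id`, `strand`.
#' @export
read_gene_models_bed <- function(path) {
  d <- read.delim(path, header = FALSE)
  if (ncol(d) < 6) stop("BED6 requires 6 columns")
  data.frame(chrom = d[[1]], start = d[[2]], end = d[[3]],
             gene_id = d[[4]], strand = d[[6]])
}

#' Write gene models / DMRs as BED6
#'
#' @param x Data frame with `chrom`, `start`, `end` plus a name column
#'   (`gene_id` or `dmr_id`), optional `score` and `strand`.
#' @param path Output path.
#' @export
write_bed6 <- function(x, path) {
  name <- if (!is.null(x$gene_id)) x$gene_id else
    if (!is.null(x$dmr_id)) x$dmr_id else seq_len(nrow(x))
  score <- if (!is.null(x$score)) x$score else 0
  strand <- if (!is.null(x$strand)) x$strand else "."
  out <- data.frame(x$chrom, x$start, x$end, name, score, strand)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
}

#' Write a generic result table as TSV
#' @param x Data frame.
#' @param path Output path.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
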
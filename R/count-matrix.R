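#' Gene-by-sample count matrix with group labels
#'
#' A light container for RNA-seq read counts: a `d x n` matrix of
#' non-negative integers (rows = genes, columns = samples) together with one
#' group label per sample (e.g. `"infected"` / `"control"`).
#'
#' @param counts Numeric matrix of non-negative, integer-valued counts with
#'   unique rownames (gene ids) and unique colnames (sample ids).
#' @param groups Character or factor of length `ncol(counts)`: the condition
#'   (or replicate-id) label per sample.
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   (numeric matrix) and `groups` (named factor).
#' @examples
#' m <- matrix(rpois(12, 10), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' count_matrix(m, c("A", "A", "B", "B"))
#' @export
count_matrix <- function(counts, groups) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stopf("count matrix needs gene ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(counts)))
    stopf("duplicated gene id: '%s'", rownames(counts)[duplicated(rownames(counts))][1L])
  if (anyDuplicated(colnames(counts)))
    stopf("duplicated sample id: '%s'", colnames(counts)[duplicated(colnames(counts))][1L])
  if (!is.numeric(counts) || any(!is.finite(counts)))
    stopf("counts must be finite numbers")
  if (any(counts < 0))
    stopf("counts must be non-negative")
  if (any(counts != round(counts)))
    stopf("counts must be integer-valued")
  if (length(groups) != ncol(counts))
    stopf("'groups' must have one label per sample (%d needed, %d given)",
          ncol(counts), length(groups))
  groups <- as.factor(groups)
  names(groups) <- colnames(counts)
  structure(list(counts = counts, groups = groups), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples\n", nrow(x$counts), ncol(x$counts)))
  cat("  groups:", paste(sprintf("%s=%d", levels(x$groups), table(x$groups)),
                         collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' @export
as.matrix.count_matrix <- function(x, ...) x$counts

# Accept either a count_matrix or a bare matrix (groups optional downstream).
as_counts <- function(x) {
  if (inherits(x, "count_matrix")) x$counts else as.matrix(x)
}

#' Read / write a count matrix as TSV
#'
#' The matrix file is tab-separated with gene ids in the first column and
#' sample ids in the header; group labels live in a sidecar two-column TSV
#' (`sample_id`, `group`). The pair round-trips losslessly.
#'
#' @param path Path to the counts TSV.
#' @param groups_path Path to the sample/group sidecar TSV.
#' @return `read_counts_tsv()` returns a [count_matrix()];
#'   `write_counts_tsv()` returns `path` invisibly.
#' @export
read_counts_tsv <- function(path, groups_path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character")
  if (ncol(tab) < 2L) stopf("'%s': expected gene id column plus sample columns", path)
  gene_ids <- tab[[1L]]
  sample_ids <- colnames(tab)[-1L]
  if (anyDuplicated(sample_ids))
    stopf("'%s': duplicated sample id in header: '%s'", path,
          sample_ids[duplicated(sample_ids)][1L])
  if (anyDuplicated(gene_ids))
    stopf("'%s': duplicated gene id: '%s'", path, gene_ids[duplicated(gene_ids)][1L])
  vals <- suppressWarnings(vapply(tab[-1L], as.numeric, numeric(nrow(tab))))
  vals <- matrix(vals, nrow = nrow(tab),
                 dimnames = list(gene_ids, sample_ids))
  bad <- which(is.na(vals) | vals != round(vals), arr.ind = TRUE)
  if (nrow(bad))
    stopf("'%s': non-integer count at gene '%s', sample '%s'", path,
          gene_ids[bad[1L, 1L]], sample_ids[bad[1L, 2L]])
  gr <- utils::read.delim(groups_path, header = TRUE, sep = "\t",
                          colClasses = "character")
  if (!all(c("sample_id", "group") %in% colnames(gr)))
    stopf("'%s': expected columns 'sample_id' and 'group'", groups_path)
  missing <- setdiff(sample_ids, gr$sample_id)
  if (length(missing))
    stopf("'%s': no group label for sample '%s'", groups_path, missing[1L])
  groups <- gr$group[match(sample_ids, gr$sample_id)]
  count_matrix(vals, groups)
}

#' @rdname read_counts_tsv
#' @param x A [count_matrix()].
#' @export
write_counts_tsv <- function(x, path, groups_path) {
  x <- count_matrix(as_counts(x), if (inherits(x, "count_matrix")) x$groups
                    else rep("all", ncol(as_counts(x))))   # re-validate
  tab <- data.frame(gene_id = rownames(x$counts), x$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  gr <- data.frame(sample_id = colnames(x$counts), group = as.character(x$groups))
  utils::write.table(gr, groups_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
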
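#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated fields `set_id`,
#' `description`, then one or more member gene ids. Member ids are
#' whitespace-trimmed and case-preserved.
#'
#' @param path Path to a GMT file.
#' @return An object of class `gene_sets`: list with `sets` (named list of
#'   character vectors) and `descriptions` (named character).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- vector("list", length(lines))
  ids <- character(length(lines))
  desc <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stopf("GMT '%s' line %d: expected at least 3 tab-separated fields, got %d",
            path, i, length(f))
    members <- trimws(f[-(1:2)])
    members <- members[nzchar(members)]
    if (!length(members))
      stopf("GMT '%s' line %d: set '%s' has no members", path, i, f[1L])
    ids[i] <- trimws(f[1L])
    desc[i] <- f[2L]
    sets[[i]] <- members
  }
  if (anyDuplicated(ids))
    stopf("GMT '%s': duplicated set id '%s'", path, ids[duplicated(ids)][1L])
  names(sets) <- ids
  names(desc) <- ids
  structure(list(sets = sets, descriptions = desc), class = "gene_sets")
}

#' @export
print.gene_sets <- function(x, ...) {
  sizes <- lengths(x$sets)
  cat(sprintf("gene_sets: %d sets, member counts %d-%d (median %g)\n",
              length(x$sets), min(sizes), max(sizes), stats::median(sizes)))
  invisible(x)
}

#' @export
length.gene_sets <- function(x) length(x$sets)

#' Hypergeometric over-representation analysis
#'
#' One-sided over-representation test (upper-tail hypergeometric, the
#' one-tailed Fisher test) of a selected gene list against each set of a
#' collection. Set members are intersected with the universe before testing;
#' sets with no member left in the universe are reported untested (`NA` p).
#' P values are BH-adjusted across the tested sets.
#'
#' @param selected Character vector of selected gene ids; must be a subset of
#'   `universe`.
#' @param universe Character vector of all testable gene ids (typically the
#'   genes with a computable p in the DE step).
#' @param collection A [read_gmt()] collection, or a named list of character
#'   vectors.
#' @param alpha Significance level for the `enriched` flag (default 0.05).
#' @return A data frame of class `ora_result` with one row per set:
#'   `set_id`, `description`, `overlap`, `set_size`, `p`, `padj`, `enriched`.
#' @export
fisher_ora <- function(selected, universe, collection, alpha = 0.05) {
  universe <- unique(universe)
  if (!length(universe)) stopf("the gene universe is empty")
  selected <- unique(selected)
  extra <- setdiff(selected, universe)
  if (length(extra))
    stopf("selected gene '%s' is not in the universe", extra[1L])
  sets <- if (inherits(collection, "gene_sets")) collection$sets else collection
  desc <- if (inherits(collection, "gene_sets")) collection$descriptions
          else setNames(rep("", length(sets)), names(sets))
  U <- length(universe)
  nsel <- length(selected)
  res <- data.frame(set_id = names(sets),
                    description = unname(desc[names(sets)]),
                    overlap = NA_integer_, set_size = NA_integer_,
                    p = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(sets)) {
    members <- intersect(sets[[i]], universe)
    s <- length(members)
    res$set_size[i] <- s
    if (s == 0L) next
    ov <- length(intersect(members, selected))
    res$overlap[i] <- ov
    # P(X >= ov), X ~ Hypergeom(white = s, black = U - s, drawn = nsel)
    res$p[i] <- stats::phyper(ov - 1L, s, U - s, nsel, lower.tail = FALSE)
  }
  res$padj <- adjust_bh(res$p)
  res$enriched <- !is.na(res$padj) & res$padj < alpha
  class(res) <- c("ora_result", "data.frame")
  res
}

#' @rdname fisher_ora
#' @param res An `ora_result`.
#' @param path Output TSV path.
#' @export
write_ora_tsv <- function(res, path) {
  utils::write.table(as.data.frame(res), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
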
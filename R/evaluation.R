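#' Collect per-gene result vectors from several analyses
#'
#' Builds the gene-by-analysis value matrix that the similarity analyses work
#' on: one column per labeled differential-expression result, holding either
#' the raw p values or the absolute log2 fold changes, aligned on the shared
#' gene index.
#'
#' @param results Named list of `nb_de` results (see [nb_wald()]); all must
#'   cover the same genes.
#' @param metric `"pvalue"` or `"abs_log2fc"`.
#' @return Numeric matrix, genes in rows, analysis labels in columns; `NA`
#'   where a gene had no computable test.
#' @export
de_catalog <- function(results, metric = c("pvalue", "abs_log2fc")) {
  metric <- match.arg(metric)
  stopifnot(is.list(results), length(results) >= 1L)
  if (is.null(names(results)) || anyDuplicated(names(results)))
    stopf("'results' must have unique names")
  genes <- results[[1L]]$gene_id
  cols <- lapply(names(results), function(lab) {
    r <- results[[lab]]
    if (!identical(sort(r$gene_id), sort(genes)))
      stopf("result '%s' covers a different gene index", lab)
    v <- if (metric == "pvalue") r$pvalue else abs(r$log2FoldChange)
    v[is.na(r$pvalue)] <- NA_real_          # sentinel: untestable gene
    v[match(genes, r$gene_id)]
  })
  out <- do.call(cbind, cols)
  dimnames(out) <- list(genes, names(results))
  out
}

#' Spearman-correlation distance between result lists
#'
#' Distance `1 - rho` between each pair of per-gene value vectors, with
#' `rho` Spearman's rank correlation (average ranks at ties). Genes with a
#' missing value in any vector are dropped listwise, so all pairwise
#' correlations use one common gene index.
#'
#' @param catalog Numeric matrix as from [de_catalog()] (genes x labels), or
#'   a named list of equally indexed numeric vectors.
#' @return Symmetric distance matrix with zero diagonal; entries in `[0, 2]`.
#' @export
spearman_distance <- function(catalog) {
  if (is.list(catalog) && !is.data.frame(catalog))
    catalog <- do.call(cbind, catalog)
  catalog <- as.matrix(catalog)
  if (ncol(catalog) < 2L) stopf("need at least 2 labeled result vectors")
  complete <- stats::complete.cases(catalog)
  if (sum(complete) < 3L)
    stopf("fewer than 3 genes with complete values across all results")
  rho <- stats::cor(catalog[complete, , drop = FALSE], method = "spearman")
  d <- 1 - rho
  d[abs(d) < 1e-15] <- 0
  diag(d) <- 0
  d
}

#' Ward cluster tree from a distance matrix
#'
#' Agglomerative hierarchical clustering of result lists under the Ward
#' criterion, by default the `ward.D2` convention (squared-distance update),
#' with `ward.D` available for comparison.
#'
#' @param d Symmetric distance matrix with zero diagonal (e.g. from
#'   [spearman_distance()]).
#' @param variant `"ward.D2"` (default) or `"ward.D"`.
#' @return An [stats::hclust] tree; convert with [tree_newick()] for export.
#' @export
ward_tree <- function(d, variant = c("ward.D2", "ward.D")) {
  variant <- match.arg(variant)
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8))
    stopf("distance matrix must be symmetric")
  if (any(abs(diag(d)) > 1e-12))
    stopf("distance matrix must have a zero diagonal")
  stats::hclust(stats::as.dist(d), method = variant)
}

#' Serialize a cluster tree as Newick
#'
#' @param tree An [stats::hclust] tree (e.g. from [ward_tree()]).
#' @param path Optional file; when given the string is also written there.
#' @return The Newick string, invisibly when written to file.
#' @export
tree_newick <- function(tree, path = NULL) {
  phy <- ape::as.phylo(tree)
  s <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(s, path)
    return(invisible(s))
  }
  s
}

#' Asymmetric overlap matrix of selected-gene sets
#'
#' For each ordered pair of labeled selections the percentage of the
#' reference (row) set that is re-detected in the comparison (column) set:
#' `100 * |A intersect B| / |A|`. The matrix is intentionally not symmetric;
#' the diagonal is 100 for non-empty sets. Empty reference sets give 0 and
#' are flagged in the `"empty_reference"` attribute.
#'
#' @param selections Named list (>= 2 entries) of character vectors of gene
#'   (or gene-set) ids.
#' @return A square percentage matrix of class `overlap_matrix`.
#' @examples
#' overlap_matrix(list(A = c("g1", "g2", "g3"), B = c("g2", "g3")))
#' @export
overlap_matrix <- function(selections) {
  stopifnot(is.list(selections))
  if (length(selections) < 2L) stopf("need at least 2 labeled selections")
  if (is.null(names(selections)) || anyDuplicated(names(selections)))
    stopf("'selections' must have unique names")
  labs <- names(selections)
  k <- length(labs)
  p <- matrix(0, k, k, dimnames = list(labs, labs))
  for (a in seq_len(k)) {
    A <- unique(selections[[a]])
    for (b in seq_len(k)) {
      B <- unique(selections[[b]])
      p[a, b] <- if (length(A)) 100 * length(intersect(A, B)) / length(A) else 0
    }
  }
  empty <- labs[lengths(lapply(selections, unique)) == 0L]
  structure(p, empty_reference = empty, class = c("overlap_matrix", "matrix"))
}

#' @export
print.overlap_matrix <- function(x, ...) {
  cat("overlap of selections, % of row set found in column set:\n")
  print(round(unclass(x)))
  if (length(attr(x, "empty_reference")))
    cat("empty reference set(s):",
        paste(attr(x, "empty_reference"), collapse = ", "), "\n")
  invisible(x)
}

#' Write a numeric matrix as TSV
#'
#' Helper for exporting distance and overlap matrices; values are rounded to
#' `digits` decimals, labels go in the first column.
#'
#' @param m Matrix with dimnames.
#' @param path Output path.
#' @param digits Decimal places kept in the file (default 1, matching
#'   percent reporting; use more for distances).
#' @export
write_matrix_tsv <- function(m, path, digits = 1) {
  m <- round(as.matrix(unclass(m)), digits)
  tab <- data.frame(label = rownames(m), m, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Compare dispersion distributions across data sets
#'
#' Estimates the gene-wise NB dispersion distribution of each data set and
#' measures how far each artificial distribution is from a designated
#' reference ("truth") distribution with the two-sample Kolmogorov-Smirnov
#' statistic.
#'
#' In `"biological"` mode each element of `datasets` is a [count_matrix()]
#' with condition labels and dispersions are estimated under the condition
#' design. In `"technical"` mode each element is a pooled matrix whose
#' `groups` factor identifies the biological sample each column replicates
#' (so the dispersions reflect variance between technical replicates).
#'
#' @param datasets Named list of [count_matrix()] objects.
#' @param mode `"biological"` or `"technical"`.
#' @param reference Label of the truth data set (default: first).
#' @return List of class `dispersion_comparison` with `dispersions` (named
#'   list of per-gene vectors), `ks` (named KS distance of every non-reference
#'   data set to the reference), `mode` and `reference`.
#' @export
dispersion_comparison <- function(datasets, mode = c("biological", "technical"),
                                  reference = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.list(datasets), length(datasets) >= 1L)
  if (is.null(names(datasets)) || anyDuplicated(names(datasets)))
    stopf("'datasets' must have unique names")
  if (is.null(reference)) reference <- names(datasets)[1L]
  if (!reference %in% names(datasets))
    stopf("reference '%s' is not among the data sets", reference)
  disp <- lapply(datasets, function(x) estimate_dispersions(x, x$groups))
  ref <- disp[[reference]]
  ks <- vapply(setdiff(names(datasets), reference), function(lab) {
    ks_distance(disp[[lab]], ref)
  }, numeric(1L))
  structure(list(dispersions = disp, ks = ks, mode = mode,
                 reference = reference),
            class = "dispersion_comparison")
}

# Two-sample Kolmogorov-Smirnov distance sup|F_a - F_b| on finite values.
ks_distance <- function(a, b) {
  a <- a[is.finite(a)]
  b <- b[is.finite(b)]
  if (!length(a) || !length(b)) return(NA_real_)
  grid <- sort(unique(c(a, b)))
  max(abs(stats::ecdf(a)(grid) - stats::ecdf(b)(grid)))
}

#' @export
print.dispersion_comparison <- function(x, ...) {
  cat(sprintf("dispersion comparison (%s mode), reference = %s\n",
              x$mode, x$reference))
  meds <- vapply(x$dispersions, function(v) stats::median(v, na.rm = TRUE),
                 numeric(1L))
  print(round(meds, 4))
  if (length(x$ks)) {
    cat("KS distance to reference:\n")
    print(round(x$ks, 4))
  }
  invisible(x)
}

#' Selection-frequency stability report
#'
#' Cross-tabulates the reference gene selection against how many of the `B`
#' artificial replicate runs re-selected each gene, and pairs each selected
#' gene's reference raw p value with its selection frequency (the basis of a
#' p-value-vs-frequency scatter).
#'
#' @param reference_selected Character vector: genes selected in the
#'   reference analysis.
#' @param replicate_selections List of `B` character vectors: genes selected
#'   in each artificial replicate.
#' @param universe Character vector of all genes under consideration; every
#'   selection must be a subset of it.
#' @param reference_pvalues Optional named numeric vector of reference raw p
#'   values (names = gene ids) for the scatter pairing.
#' @return An object of class `stability_report`: list with `frequency`
#'   (named 0..B counts per gene), `crosstab` (2 x (B+1) table, rows
#'   reference FALSE/TRUE, columns 0..B), `genes` (per-gene data frame) and
#'   `B`.
#' @export
stability_report <- function(reference_selected, replicate_selections,
                             universe, reference_pvalues = NULL) {
  universe <- unique(universe)
  check_sub <- function(s, what) {
    extra <- setdiff(s, universe)
    if (length(extra))
      stopf("%s contains gene '%s' outside the universe", what, extra[1L])
  }
  check_sub(reference_selected, "the reference selection")
  B <- length(replicate_selections)
  freq <- setNames(integer(length(universe)), universe)
  for (i in seq_len(B)) {
    check_sub(replicate_selections[[i]], sprintf("replicate selection %d", i))
    hit <- universe %in% replicate_selections[[i]]
    freq[hit] <- freq[hit] + 1L
  }
  in_ref <- universe %in% reference_selected
  crosstab <- table(
    reference = factor(in_ref, levels = c(FALSE, TRUE)),
    runs = factor(freq, levels = 0:B))
  genes <- data.frame(gene_id = universe, in_reference = in_ref,
                      n_selected = as.integer(freq),
                      stringsAsFactors = FALSE)
  if (!is.null(reference_pvalues))
    genes$ref_pvalue <- unname(reference_pvalues[universe])
  structure(list(frequency = freq, crosstab = unclass(crosstab),
                 genes = genes, B = B),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("selection stability over B = %d artificial replicates\n", x$B))
  cat("reference selection (rows) vs number of runs re-selecting (columns):\n")
  print(x$crosstab)
  ref_n <- sum(x$genes$in_reference)
  if (ref_n && x$B > 0L) {
    always <- sum(x$genes$in_reference & x$genes$n_selected == x$B)
    cat(sprintf("%d of %d reference genes re-selected in all %d runs\n",
                always, ref_n, x$B))
  }
  invisible(x)
}

#' @rdname stability_report
#' @param x A `stability_report`.
#' @param path Output TSV path for the cross-tabulation.
#' @export
write_stability_tsv <- function(x, path) {
  tab <- data.frame(reference = rownames(x$crosstab), x$crosstab,
                    check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
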
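#' Median-of-ratios size factors
#'
#' Per-sample normalization constants for sequencing depth: for each sample,
#' the median over genes (restricted to genes with a positive geometric mean
#' across samples) of the ratio count / geometric-mean. If no gene is
#' positive in all samples the estimator falls back to total-count scaling
#' (normalized to geometric mean 1) with a warning.
#'
#' @param x A [count_matrix()] or bare numeric count matrix.
#' @return Numeric vector of `n` positive size factors, named by sample.
#' @examples
#' m <- matrix(c(10, 20, 30, 20, 40, 60), 3, 2,
#'             dimnames = list(paste0("g", 1:3), c("a", "b")))
#' size_factors(m)   # 1/sqrt(2), sqrt(2)
#' @export
size_factors <- function(x) {
  counts <- as_counts(x)
  logg <- rowMeans(log(counts))
  use <- is.finite(logg)
  if (!any(use)) {
    warning("no gene with positive counts in all samples; falling back to total-count scaling",
            call. = FALSE)
    tot <- colSums(counts)
    if (any(tot <= 0)) stopf("sample with zero total count; cannot normalize")
    return(tot / exp(mean(log(tot))))
  }
  sf <- apply(counts[use, , drop = FALSE], 2L,
              function(cnt) stats::median(exp(log(cnt) - logg[use])))
  if (any(!is.finite(sf) | sf <= 0))
    stopf("non-positive size factor; too many zero counts")
  sf
}

# Normalize a design argument: NULL -> condition groups of x.
design_factor <- function(x, design) {
  f <- if (is.null(design)) {
    if (!inherits(x, "count_matrix")) stopf("a design factor is required for bare matrices")
    x$groups
  } else as.factor(design)
  if (length(f) != ncol(as_counts(x)))
    stopf("design has %d labels but the matrix has %d samples",
          length(f), ncol(as_counts(x)))
  f <- droplevels(f)
  if (nlevels(f) < 2L) stopf("design needs at least 2 levels")
  f
}

#' Gene-wise negative-binomial dispersion estimates
#'
#' Method-of-moments estimate of the NB dispersion `alpha` in
#' `Var = mu + alpha * mu^2`, computed on size-factor-normalized counts with
#' the design-level means removed. With within-level residual variance `s2`
#' (pooled over levels, `df = n - L`) the estimator is
#' `alpha = (s2 - mbar) / m2bar`, where `mbar` and `m2bar` are the
#' df-weighted means of the level means and squared level means, truncated at
#' 0. Setting the design to the condition factor yields "biological"
#' dispersion; setting it to a replicate-id factor (technical replicates of
#' the same samples pooled in one matrix) yields "technical" dispersion.
#'
#' @param x A [count_matrix()] (or bare matrix, then `design` is required).
#' @param design Factor with one level per design cell; default: the
#'   condition groups of `x`. Every level needs at least one sample and the
#'   total sample count must exceed the number of levels.
#' @return Numeric vector of length `d` aligned to the gene ids:
#'   non-negative dispersions, `NA` for genes with zero counts in all
#'   samples.
#' @export
estimate_dispersions <- function(x, design = NULL) {
  counts <- as_counts(x)
  f <- design_factor(x, design)
  n <- ncol(counts)
  L <- nlevels(f)
  if (n < L + 1L)
    stopf("not enough degrees of freedom: %d samples for %d design levels", n, L)
  sf <- size_factors(counts)
  y <- sweep(counts, 2L, sf, "/")
  df <- n - L
  ss <- 0
  mbar <- 0
  m2bar <- 0
  for (lev in levels(f)) {
    cols <- which(f == lev)
    nl <- length(cols)
    ml <- rowMeans(y[, cols, drop = FALSE])
    if (nl > 1L)
      ss <- ss + rowSums((y[, cols, drop = FALSE] - ml)^2)
    w <- max(nl - 1L, 0L)
    mbar <- mbar + w * ml
    m2bar <- m2bar + w * ml^2
  }
  s2 <- ss / df
  mbar <- mbar / df
  m2bar <- m2bar / df
  alpha <- ifelse(m2bar > 0, pmax(0, (s2 - mbar) / m2bar), 0)
  alpha[rowSums(counts) == 0] <- NA_real_
  names(alpha) <- rownames(counts)
  alpha
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment: `padj_(i) = min_{j >= i} p_(j) * m / j`, capped at
#' 1, with `m` the number of computable (non-`NA`) p values. `NA` entries
#' (genes without a computable test) stay `NA` and do not count toward `m`.
#'
#' @param pvalues Numeric vector in `[0, 1]`, `NA` allowed.
#' @return Adjusted p values, same length and order.
#' @export
adjust_bh <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1))
    stopf("p values must lie in [0, 1]")
  out <- pvalues
  out[ok] <- stats::p.adjust(pvalues[ok], method = "BH")
  out
}

#' Negative-binomial Wald test for differential expression
#'
#' A self-contained two-group differential-expression analysis with the same
#' pipeline shape as the standard NB workflow: median-of-ratios size factors,
#' gene-wise dispersion, a Wald test on the log2 fold change, and
#' Benjamini-Hochberg adjustment. It is deliberately plain: no dispersion
#' trend or LFC shrinkage, no independent filtering, no outlier refitting.
#'
#' Per gene, `log2fc = log2(m2 / m1)` from the normalized level means
#' (second condition level vs first); when either level mean is zero a 0.5
#' pseudocount is added to both, so zeros stay finite while fold changes of
#' positive genes remain exactly invariant to depth rescaling. The standard
#' error comes from the NB variance at the
#' fitted means, `Var(y_i) = mu/s_i + alpha * mu^2` on the normalized scale,
#' and the two-sided p value from the normal reference. The gene-wise
#' moment dispersion estimate is variance-stabilized by a mild shrink toward
#' the pooled mean-dispersion trend before it enters the standard error (see
#' the methods vignette); pass `moderate = FALSE` for the raw plug-in.
#' Genes with zero counts in every sample get `NA` p values and are excluded
#' from the BH family.
#'
#' @param x A [count_matrix()].
#' @param design Two-level condition factor; default: the groups of `x`.
#' @param dispersions Optional externally supplied gene-wise dispersions
#'   (aligned to the gene ids); default: [estimate_dispersions()].
#' @param moderate Shrink gene-wise dispersions toward the mean-dispersion
#'   trend for the Wald standard error (default `TRUE`).
#' @return An object of classes `nb_de` and `data.frame` with columns
#'   `gene_id`, `baseMean`, `log2FoldChange`, `dispersion`, `stat`, `pvalue`,
#'   `padj`, plus attributes `levels` (reference, comparison) and
#'   `size_factors`.
#' @export
nb_wald <- function(x, design = NULL, dispersions = NULL, moderate = TRUE) {
  counts <- as_counts(x)
  f <- design_factor(x, design)
  if (nlevels(f) != 2L)
    stopf("the condition design must have exactly 2 levels, got %d", nlevels(f))
  sf <- size_factors(counts)
  y <- sweep(counts, 2L, sf, "/")
  lev <- levels(f)
  i1 <- which(f == lev[1L]); i2 <- which(f == lev[2L])
  n1 <- length(i1); n2 <- length(i2)
  if (n1 == 0L || n2 == 0L) stopf("each condition level needs at least one sample")
  m1 <- rowMeans(y[, i1, drop = FALSE])
  m2 <- rowMeans(y[, i2, drop = FALSE])
  base_mean <- rowMeans(y)
  if (is.null(dispersions)) dispersions <- estimate_dispersions(x, f)
  alpha <- dispersions
  alpha[is.na(alpha)] <- 0
  alpha_se <- if (moderate) moderate_dispersions(alpha, base_mean, df = n1 + n2 - 2L)
              else alpha
  # pseudocount 0.5 on both level means, applied only where a mean is zero:
  # keeps zeros finite without breaking exact scale invariance elsewhere
  at_zero <- m1 == 0 | m2 == 0
  m1p <- m1 + 0.5 * at_zero
  m2p <- m2 + 0.5 * at_zero
  lfc <- log2(m2p / m1p)
  # Var of a normalized level mean, evaluated at the regularized fitted mean
  # mu + 0.5 (guards the relative variance at very low counts):
  #   (1/n_l^2) * sum_i (mu / s_i + alpha * mu^2)
  v1 <- ((m1 + 0.5) * sum(1 / sf[i1]) + alpha_se * (m1 + 0.5)^2 * n1) / n1^2
  v2 <- ((m2 + 0.5) * sum(1 / sf[i2]) + alpha_se * (m2 + 0.5)^2 * n2) / n2^2
  se <- sqrt(v1 / (m1 + 0.5)^2 + v2 / (m2 + 0.5)^2) / log(2)
  stat <- ifelse(se > 0, lfc / se, 0)
  p <- 2 * stats::pnorm(-abs(stat))
  zero <- rowSums(counts) == 0
  p[zero] <- NA_real_
  stat[zero] <- NA_real_
  res <- data.frame(gene_id = rownames(counts), baseMean = base_mean,
                    log2FoldChange = lfc, dispersion = dispersions,
                    stat = stat, pvalue = p, padj = adjust_bh(p),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(res, "levels") <- lev
  attr(res, "size_factors") <- sf
  class(res) <- c("nb_de", "data.frame")
  res
}

# Shrink gene-wise moment dispersions toward a smooth mean-dispersion trend
# alpha_tr(mu) = a1/mu + a0 (the usual parametric trend), with weight
# df / (df + prior_df). Few-sample moment estimates are extremely noisy and
# frequently truncate at zero; plugging them straight into the Wald SE makes
# the normal reference anti-conservative. Borrowing strength across the
# thousands of genes restores calibration while leaving genuinely
# high-dispersion genes shrunk only mildly.
moderate_dispersions <- function(alpha, base_mean, df, prior_df = 20) {
  use <- is.finite(alpha) & base_mean > 0
  trend <- rep(mean(alpha[use]), length(alpha))
  if (sum(use) >= 10L) {
    fit <- try(stats::lm(alpha[use] ~ I(1 / base_mean[use])), silent = TRUE)
    if (!inherits(fit, "try-error")) {
      cf <- stats::coef(fit)
      tr <- pmax(cf[1L] + cf[2L] / pmax(base_mean, 1e-8), 0)
      if (all(is.finite(tr))) trend <- tr
    }
  }
  w <- df / (df + prior_df)
  pmax(w * alpha + (1 - w) * trend, 0)
}

#' @export
print.nb_de <- function(x, ...) {
  lev <- attr(x, "levels")
  cat(sprintf("NB Wald differential expression: %s vs %s, %d genes (%d testable)\n",
              lev[2L], lev[1L], nrow(x), sum(!is.na(x$pvalue))))
  print.data.frame(utils::head(as.data.frame(x), 6L), digits = 4)
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

#' @export
summary.nb_de <- function(object, alpha = 0.05, lfc_threshold = 2, ...) {
  sel <- select_genes(object, alpha, lfc_threshold)
  cat(sprintf("%d genes; %d testable; %d with padj < %s; %d selected (padj < %s & |log2FC| > %s)\n",
              nrow(object), sum(!is.na(object$pvalue)),
              as.integer(sum(object$padj < alpha, na.rm = TRUE)),
              format(alpha), length(sel), format(alpha),
              format(lfc_threshold)))
  invisible(sel)
}

#' Select differentially expressed genes
#'
#' Applies the standard double threshold: FDR-adjusted p value below `alpha`
#' and absolute log2 fold change above `lfc_threshold`. Genes without a
#' computable adjusted p value are never selected.
#'
#' @param res An `nb_de` result (or any data frame with `gene_id`, `padj`,
#'   `log2FoldChange`).
#' @param alpha Adjusted-p threshold (default 0.05).
#' @param lfc_threshold Absolute log2-fold-change threshold (default 2).
#' @return Character vector of selected gene ids.
#' @export
select_genes <- function(res, alpha = 0.05, lfc_threshold = 2) {
  keep <- !is.na(res$padj) & res$padj < alpha &
    abs(res$log2FoldChange) > lfc_threshold
  res$gene_id[keep]
}

#' Read a precomputed differential-expression table
#'
#' External-backend hook: accepts a TSV with the standard column names
#' (`gene_id`, `baseMean`, `log2FoldChange`, `dispersion`, `pvalue`, `padj`),
#' e.g. exported from another NB engine, and returns it as an `nb_de` object
#' so the evaluation layer can consume it unchanged.
#'
#' @param path Path to the TSV.
#' @return An `nb_de` data frame.
#' @export
read_de_tsv <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("gene_id", "baseMean", "log2FoldChange", "pvalue", "padj")
  missing <- setdiff(need, colnames(tab))
  if (length(missing))
    stopf("'%s': missing column '%s'", path, missing[1L])
  if (is.null(tab$dispersion)) tab$dispersion <- NA_real_
  class(tab) <- c("nb_de", "data.frame")
  tab
}

#' @rdname read_de_tsv
#' @param res An `nb_de` result.
#' @export
write_de_tsv <- function(res, path) {
  utils::write.table(as.data.frame(res), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
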
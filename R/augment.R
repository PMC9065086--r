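#' Bootstrap columns of the expression matrix (CB approach)
#'
#' Generates a new realization of the whole experiment by drawing `n` columns
#' with replacement from the `n` columns of the count matrix; no new
#' expression values are created, only a new arrangement of existing samples.
#' For a 10-column matrix a valid draw is, e.g., columns
#' `{8, 3, 4, 6, 3, 4, 1, 1, 8, 9}`.
#'
#' With `stratify = TRUE` (default) columns are resampled within their
#' condition group, so every artificial experiment keeps the original number
#' of samples per condition and stays analysable for differential expression.
#' `stratify = FALSE` draws from all columns regardless of label.
#'
#' @param x A [count_matrix()] with at least two samples.
#' @param stratify Resample within condition groups (see Details).
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @return A [count_matrix()] with the same genes and the same number of
#'   samples; each column is byte-identical to some input column, its group
#'   label is the source column's label, and sample ids carry a `.b<j>` draw
#'   suffix to stay unique.
#' @export
column_bootstrap <- function(x, stratify = TRUE, seed = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  n <- ncol(x$counts)
  if (n < 2L) stopf("column bootstrap needs at least 2 samples")
  draw <- with_seed(seed, {
    if (stratify) {
      idx <- integer(n)
      for (lev in levels(x$groups)) {
        pos <- which(x$groups == lev)
        if (length(pos) == 1L) {
          warning(sprintf("group '%s' has a single sample; copied unchanged", lev),
                  call. = FALSE)
          idx[pos] <- pos
        } else {
          idx[pos] <- sample(pos, length(pos), replace = TRUE)
        }
      }
      idx
    } else {
      sample.int(n, n, replace = TRUE)
    }
  })
  out <- x$counts[, draw, drop = FALSE]
  colnames(out) <- paste0(colnames(x$counts)[draw], ".b", seq_len(n))
  count_matrix(out, as.character(x$groups)[draw])
}

#' Mix observations of the expression matrix (MO approach)
#'
#' Generates artificial samples as weighted means of existing columns:
#' `x_new = sum_i w_i x_i` with non-negative weights summing to 1. Mixed
#' values are rounded to the nearest integer (round half to even) so that the
#' result remains a valid count matrix. `n_out` new samples (default: `n`)
#' are bound together as a new experiment.
#'
#' By default each output sample mixes only columns of one condition group
#' and inherits that group's label (mixing across conditions would average
#' away the treatment effect); `within_group = FALSE` mixes over all columns.
#' When `weights` is not given, fresh weights are drawn per output sample
#' from a symmetric Dirichlet with concentration `dirichlet_alpha`.
#'
#' @param x A [count_matrix()] with at least two samples.
#' @param weights Optional fixed weight vector (length = mixing-pool size,
#'   non-negative, summing to 1 within `1e-9`); used for every output sample.
#' @param dirichlet_alpha Concentration of the symmetric Dirichlet used when
#'   `weights` is `NULL`.
#' @param within_group Restrict each mixture to columns sharing a group label.
#' @param n_out Number of artificial samples to generate (default `n`).
#' @param seed Integer seed.
#' @return A [count_matrix()] of `d` genes by `n_out` mixed samples.
#' @export
mix_observations <- function(x, weights = NULL, dirichlet_alpha = 1,
                             within_group = TRUE, n_out = NULL, seed = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  n <- ncol(x$counts)
  if (n < 2L) stopf("mixing needs at least 2 samples")
  if (is.null(n_out)) n_out <- n
  if (!is.null(weights)) {
    if (any(weights < 0)) stopf("weights must be non-negative")
    if (abs(sum(weights) - 1) > 1e-9)
      stopf("weights must sum to 1 (got %.12f)", sum(weights))
  }
  # group label of each output sample: the original layout, recycled if needed
  out_groups <- as.character(x$groups)[rep_len(seq_len(n), n_out)]
  pools <- if (within_group) {
    lapply(out_groups, function(g) which(x$groups == g))
  } else {
    rep(list(seq_len(n)), n_out)
  }
  out <- with_seed(seed, {
    cols <- lapply(seq_len(n_out), function(j) {
      pool <- pools[[j]]
      w <- if (!is.null(weights)) {
        if (length(weights) != length(pool))
          stopf("weights have length %d but the mixing pool has %d columns",
                length(weights), length(pool))
        weights
      } else {
        rdirichlet1(length(pool), dirichlet_alpha)
      }
      round(as.vector(x$counts[, pool, drop = FALSE] %*% w))
    })
    do.call(cbind, cols)
  })
  dimnames(out) <- list(rownames(x$counts), paste0("mix", seq_len(n_out)))
  count_matrix(out, out_groups)
}
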
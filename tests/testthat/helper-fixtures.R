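# Fixture builders and independent brute-force oracles used across tests.
# Oracles are deliberately naive re-derivations of the definitions, kept
# separate from the package implementations they check.

# Write a FASTQ file with n random reads, by hand (independent of write_fastq).
make_fastq <- function(n, path = tempfile(fileext = ".fastq"),
                       read_len = 20, seed = 1) {
  set.seed(seed)
  lines <- character(0)
  if (n > 0) {
    seqs <- vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T"), read_len, TRUE), collapse = ""), "")
    quals <- vapply(seq_len(n), function(i)
      paste(sample(strsplit(rawToChar(as.raw(33:73)), "")[[1]], read_len, TRUE),
            collapse = ""), "")
    lines <- as.vector(rbind(paste0("@read", seq_len(n), " extra", seq_len(n)),
                             seqs, "+", quals))
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  writeLines(lines, con)
  close(con)
  path
}

# Small random count_matrix with two groups.
make_cm <- function(d = 10, n = 6, seed = 1, groups = NULL, mu = 50) {
  set.seed(seed)
  m <- matrix(rpois(d * n, mu), d, n,
              dimnames = list(paste0("g", seq_len(d)), paste0("s", seq_len(n))))
  if (is.null(groups)) groups <- rep(c("A", "B"), c(ceiling(n / 2), floor(n / 2)))
  count_matrix(m, groups)
}

# Brute-force BH step-up: padj_(i) = min_{j >= i} p_(j) * m / j, capped at 1.
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(ps[i:m] * m / (i:m))
  }
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Exhaustive hypergeometric upper tail P(X >= x) by direct summation.
hyper_tail_brute <- function(x, s, U, nsel) {
  ks <- x:min(s, nsel)
  ks <- ks[ks >= max(0, nsel - (U - s))]
  if (!length(ks)) return(0)
  sum(choose(s, ks) * choose(U - s, nsel - ks)) / choose(U, nsel)
}

# Spearman distance from first principles: 1 - Pearson on average ranks.
spearman_dist_brute <- function(a, b) {
  ra <- rank(a); rb <- rank(b)
  1 - sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
}

# Median-of-ratios size factors by literal definition, with loops.
sf_brute <- function(m) {
  d <- nrow(m); n <- ncol(m)
  geo <- numeric(d)
  for (g in seq_len(d)) geo[g] <- prod(m[g, ])^(1 / n)
  keep <- geo > 0
  out <- numeric(n)
  for (j in seq_len(n)) out[j] <- median(m[keep, j] / geo[keep])
  out
}

# Strip the duplicate-disambiguation suffix from a bootstrapped read id.
strip_bs <- function(ids) sub("/bs[0-9]+", "", ids)
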
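# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG state without disturbing the caller's
# stream. `seed = NULL` means: use (and advance) the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer", call. = FALSE)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1L)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a base seed; kept below 2^31 - 1 so it is always a
# valid R integer seed.
derive_seed <- function(seed, ...) {
  offsets <- c(...)
  as.integer((as.double(seed) * 1000003 + sum(offsets * 7919)) %% 2147483629)
}

# One draw from Dirichlet(alpha * 1_n).
rdirichlet1 <- function(n, alpha) {
  g <- stats::rgamma(n, shape = alpha)
  if (sum(g) <= 0) {                      # guard against underflow at tiny alpha
    g <- rep(0, n)
    g[sample.int(n, 1L)] <- 1
    return(g)
  }
  g / sum(g)
}

# Connection for a plain or gzip-compressed text file, chosen by extension.
text_connection <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
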
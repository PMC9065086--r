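#' Synthetic benchmark of the three replicate-generation strategies
#'
#' Runs one seeded end-to-end experiment mirroring the study layout: a
#' two-condition experiment with two true technical replicates R1/R2 is
#' simulated; `B` artificial replicates are generated from R1 by each
#' requested strategy (FB at the FASTQ level via the toy transcriptome and
#' exact-match quantifier; CB and MO on the count matrix); differential
#' expression is run on everything; and each strategy is scored by (a) the
#' mean Spearman correlation between its replicate p-value lists and the
#' p-value list of the held-out true replicate R2 and (b) the median KS
#' distance between its replicate biological-dispersion distributions and
#' the dispersion distribution of R2.
#'
#' @param seed Integer seed driving the whole run.
#' @param d Number of genes/transcripts (default 300; the benchmark runs the
#'   FASTQ path for every replicate, so it is kept compact).
#' @param B Artificial replicates per strategy (default 10).
#' @param pi FB read fraction (default 1).
#' @param strategies Subset of `c("FB", "CB", "MO")`.
#' @param read_length,tx_length Read and transcript lengths for the FASTQ
#'   path.
#' @param design_args Extra arguments passed to [sim_design()] (e.g.
#'   `mean_log_range`).
#' @param keep_dir Optional directory for the intermediate FASTQ files
#'   (default: a session temp dir, deleted afterwards).
#' @return A list of class `strategy_benchmark` with per-strategy elements
#'   `rho` (B Spearman correlations with R2), `mean_rho`, `ks` (B KS
#'   distances to R2's dispersion distribution), `median_ks`, plus
#'   `rho_r1_r2` (correlation between the two true replicates) and the
#'   simulated experiment's truth table.
#' @export
replicate_benchmark <- function(seed, d = 300, B = 10, pi = 1,
                                strategies = c("FB", "CB", "MO"),
                                read_length = 50, tx_length = 200,
                                design_args = list(), keep_dir = NULL) {
  strategies <- match.arg(strategies, several.ok = TRUE)
  design <- do.call(sim_design, c(list(d = d, seed = derive_seed(seed, 1)),
                                  design_args))
  sim <- simulate_counts(design)
  work <- keep_dir %||% file.path(tempdir(), sprintf("bench_%d", seed))
  dir.create(work, recursive = TRUE, showWarnings = FALSE)
  if (is.null(keep_dir)) on.exit(unlink(work, recursive = TRUE), add = TRUE)

  de_r1 <- nb_wald(sim$R1)
  de_r2 <- nb_wald(sim$R2)
  disp_r2 <- estimate_dispersions(sim$R2)

  rho_with <- function(de_b) {
    cat_ <- de_catalog(list(b = de_b, R2 = de_r2), "pvalue")
    ok <- stats::complete.cases(cat_)
    stats::cor(cat_[ok, 1L], cat_[ok, 2L], method = "spearman")
  }

  fb_matrices <- NULL
  if ("FB" %in% strategies) {
    tx <- build_toy_transcriptome(d, tx_length, seed = derive_seed(seed, 2),
                                  path = file.path(work, "transcriptome.fasta"))
    seqs <- attr(tx, "sequences")
    names(seqs) <- rownames(sim$R1$counts)     # transcript per gene
    samples <- colnames(sim$R1$counts)
    r1_fastq <- vapply(seq_along(samples), function(i) {
      p <- file.path(work, sprintf("R1_%s.fastq", samples[i]))
      simulate_fastq(seqs, sim$R1$counts[, i], p, read_length = read_length,
                     error_rate = 0, seed = derive_seed(seed, 3, i),
                     sample_id = samples[i])
      p
    }, "")
    fb_matrices <- lapply(seq_len(B), function(b) {
      cols <- lapply(seq_along(samples), function(i) {
        out <- file.path(work, sprintf("FB%d_%s.fastq", b, samples[i]))
        bootstrap_fastq(r1_fastq[i], out, pi = pi,
                        seed = derive_seed(seed, 4, b * 100 + i))
        cnt <- quantify_exact(out, seqs)$counts
        unlink(out)
        cnt
      })
      m <- do.call(cbind, cols)
      colnames(m) <- paste0(samples, ".fb", b)
      count_matrix(m, as.character(sim$R1$groups))
    })
  }

  gen <- function(strategy, b) {
    switch(strategy,
           FB = fb_matrices[[b]],
           CB = column_bootstrap(sim$R1, stratify = TRUE,
                                 seed = derive_seed(seed, 5, b)),
           MO = mix_observations(sim$R1, within_group = TRUE,
                                 seed = derive_seed(seed, 6, b)))
  }

  out <- list()
  for (st in strategies) {
    rho <- numeric(B)
    ks <- numeric(B)
    for (b in seq_len(B)) {
      mat <- gen(st, b)
      de_b <- nb_wald(mat)
      rho[b] <- rho_with(de_b)
      ks[b] <- ks_distance(estimate_dispersions(mat), disp_r2)
    }
    out[[st]] <- list(rho = rho, mean_rho = mean(rho), ks = ks,
                      median_ks = stats::median(ks))
  }
  out$rho_r1_r2 <- rho_with(de_r1)
  out$truth <- sim$truth
  out$seed <- seed
  class(out) <- "strategy_benchmark"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.strategy_benchmark <- function(x, ...) {
  cat(sprintf("strategy benchmark, seed %d (rho(R1, R2) = %.3f):\n",
              x$seed, x$rho_r1_r2))
  for (st in intersect(c("FB", "CB", "MO"), names(x)))
    cat(sprintf("  %s: mean rho with held-out replicate = %.3f, median dispersion KS = %.3f\n",
                st, x[[st]]$mean_rho, x[[st]]$median_ks))
  invisible(x)
}
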
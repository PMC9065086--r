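#' Design of a synthetic two-condition experiment with technical replicates
#'
#' Collects the parameters of the synthetic benchmark: two experimental
#' groups (default 5 infected vs 4 control samples), a fraction of truly
#' differentially expressed genes, negative-binomial biological variability,
#' and paired technical replicates drawn from a shared latent sample.
#'
#' @param d Number of genes.
#' @param n_per_group Samples per group, `c(n_infected, n_control)`; both at
#'   least 2.
#' @param de_fraction Fraction of genes that are truly DE (at least one gene
#'   when positive).
#' @param log2fc_magnitude Absolute log2 fold change of DE genes (sign drawn
#'   at random per gene).
#' @param mean_log_range Range `(lo, hi)` of baseline log-means; gene means
#'   are `exp(Uniform(lo, hi))`.
#' @param dispersion_alpha NB dispersion of the biological variability
#'   (`Var = mu + alpha mu^2`).
#' @param technical_model `"poisson_resample"` (two independent Poisson draws
#'   from one latent sample mean) or `"multinomial_thin"` (binomial split of
#'   one latent deep count).
#' @param seed Integer seed.
#' @return A list of class `sim_design`.
#' @export
sim_design <- function(d = 2000, n_per_group = c(5, 4), de_fraction = 0.1,
                       log2fc_magnitude = 3, mean_log_range = log(c(5, 500)),
                       dispersion_alpha = 0.1,
                       technical_model = c("poisson_resample", "multinomial_thin"),
                       seed = 1) {
  technical_model <- match.arg(technical_model)
  stopifnot(length(n_per_group) == 2L)
  if (any(n_per_group < 2L)) stopf("each group needs at least 2 samples")
  if (de_fraction < 0 || de_fraction > 1) stopf("'de_fraction' must be in [0, 1]")
  if (de_fraction > 0 && de_fraction * d < 1)
    stopf("'de_fraction' too small: no DE gene at d = %d", d)
  if (log2fc_magnitude <= 0) stopf("'log2fc_magnitude' must be positive")
  if (dispersion_alpha < 0) stopf("'dispersion_alpha' must be non-negative")
  structure(list(d = d, n_per_group = n_per_group, de_fraction = de_fraction,
                 log2fc_magnitude = log2fc_magnitude,
                 mean_log_range = mean_log_range,
                 dispersion_alpha = dispersion_alpha,
                 technical_model = technical_model, seed = as.integer(seed)),
            class = "sim_design")
}

#' Simulate paired technical replicates of a two-condition experiment
#'
#' For every biological sample a latent expected expression is drawn per gene
#' (gamma-distributed around the group mean so that counts are marginally
#' negative-binomial with the requested dispersion; DE genes have their
#' infected-group mean shifted by `+/- log2fc_magnitude`). The two technical
#' replicates R1 and R2 are then two conditionally independent sequencing
#' draws from the SAME latent sample, which guarantees that technical pairs
#' correlate more strongly than biologically independent samples.
#'
#' @param design A [sim_design()].
#' @return A list of class `sim_experiment` with elements `R1`, `R2` (two
#'   [count_matrix()] objects over the same samples) and `truth` (data frame
#'   `gene_id`, `is_de`, `true_log2fc`).
#' @export
simulate_counts <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  with_seed(design$seed, {
    d <- design$d
    n1 <- design$n_per_group[1L]; n2 <- design$n_per_group[2L]
    n <- n1 + n2
    gene_ids <- sprintf("g%04d", seq_len(d))
    mu0 <- exp(stats::runif(d, design$mean_log_range[1L], design$mean_log_range[2L]))
    n_de <- round(design$de_fraction * d)
    is_de <- rep(FALSE, d)
    true_lfc <- rep(0, d)
    if (n_de > 0L) {
      de_idx <- sample.int(d, n_de)
      is_de[de_idx] <- TRUE
      true_lfc[de_idx] <- sample(c(-1, 1), n_de, replace = TRUE) *
        design$log2fc_magnitude
    }
    mu_ctl <- mu0
    mu_inf <- mu0 * 2^true_lfc
    mu_by_sample <- cbind(matrix(mu_inf, d, n1), matrix(mu_ctl, d, n2))
    a <- design$dispersion_alpha
    lambda <- if (a > 0) {
      matrix(stats::rgamma(d * n, shape = 1 / a, scale = a * mu_by_sample), d, n)
    } else mu_by_sample
    if (design$technical_model == "poisson_resample") {
      r1 <- matrix(stats::rpois(d * n, lambda), d, n)
      r2 <- matrix(stats::rpois(d * n, lambda), d, n)
    } else {
      deep <- matrix(stats::rpois(d * n, 2 * lambda), d, n)
      r1 <- matrix(stats::rbinom(d * n, deep, 0.5), d, n)
      r2 <- deep - r1
    }
    sample_ids <- sprintf("s%d", seq_len(n))
    groups <- c(rep("infected", n1), rep("control", n2))
    groups <- factor(groups, levels = c("control", "infected"))
    dimnames(r1) <- dimnames(r2) <- list(gene_ids, sample_ids)
    structure(list(
      R1 = count_matrix(r1, groups),
      R2 = count_matrix(r2, groups),
      truth = data.frame(gene_id = gene_ids, is_de = is_de,
                         true_log2fc = true_lfc, stringsAsFactors = FALSE)),
      class = "sim_experiment")
  })
}

#' @export
print.sim_experiment <- function(x, ...) {
  cat(sprintf("sim_experiment: %d genes, %d samples x 2 technical replicates, %d DE genes\n",
              nrow(x$R1$counts), ncol(x$R1$counts), sum(x$truth$is_de)))
  invisible(x)
}

#' Build a toy transcriptome
#'
#' Writes `n_transcripts` random, pairwise distinct nucleotide sequences of
#' equal length as a FASTA file with ids `tx1, tx2, ...`. Intended as a
#' miniature reference so the read simulator and the exact-match quantifier
#' can exercise the FASTQ workflow without a genome.
#'
#' @param n_transcripts Number of transcripts (>= 1).
#' @param tx_length Sequence length in bases; must be at least twice the
#'   read length used downstream.
#' @param seed Integer seed; same seed, same FASTA.
#' @param path Output FASTA path.
#' @return `path`, invisibly; the sequences are attached as the `sequences`
#'   attribute (named character vector).
#' @export
build_toy_transcriptome <- function(n_transcripts, tx_length = 300, seed = 1,
                                    path = tempfile(fileext = ".fasta")) {
  stopifnot(n_transcripts >= 1L, tx_length >= 20L)
  seqs <- with_seed(seed, {
    out <- character(n_transcripts)
    for (i in seq_len(n_transcripts)) {
      repeat {
        s <- paste(sample(c("A", "C", "G", "T"), tx_length, replace = TRUE),
                   collapse = "")
        if (!s %in% out[seq_len(i - 1L)]) break
      }
      out[i] <- s
    }
    out
  })
  names(seqs) <- paste0("tx", seq_len(n_transcripts))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  out <- invisible(path)
  attr(out, "sequences") <- seqs
  invisible(out)
}

# Read a transcriptome given as FASTA path or named character vector.
load_transcriptome <- function(transcriptome) {
  if (is.character(transcriptome) && length(transcriptome) == 1L &&
      file.exists(transcriptome)) {
    ss <- Biostrings::readDNAStringSet(transcriptome)
    seqs <- as.character(ss)
    names(seqs) <- sub("\\s.*$", "", names(ss))
    return(seqs)
  }
  if (is.character(transcriptome) && !is.null(names(transcriptome)))
    return(transcriptome)
  stopf("'transcriptome' must be a FASTA path or a named character vector")
}

#' Simulate sequencing reads from a toy transcriptome
#'
#' Emits, for each transcript, exactly `counts[transcript]` reads of length
#' `read_length` starting at uniformly random positions, optionally with
#' per-base substitution errors. Read ids encode only the sample and a
#' serial number (never the source transcript), and qualities are constant
#' high (`I`, Phred 40).
#'
#' @param transcriptome FASTA path or named character vector of transcript
#'   sequences.
#' @param counts Named non-negative integer vector: reads per transcript.
#'   Names must be transcript ids.
#' @param path Output FASTQ path.
#' @param read_length Read length; at most the shortest transcript length.
#' @param error_rate Per-base substitution probability, in `[0, 0.2]`.
#' @param seed Integer seed; same seed, byte-identical FASTQ.
#' @param sample_id Prefix used in read ids.
#' @return `path`, invisibly.
#' @export
simulate_fastq <- function(transcriptome, counts, path,
                           read_length = 50, error_rate = 0, seed = 1,
                           sample_id = "S1") {
  seqs <- load_transcriptome(transcriptome)
  if (error_rate < 0 || error_rate > 0.2)
    stopf("'error_rate' must be in [0, 0.2]")
  unknown <- setdiff(names(counts), names(seqs))
  if (length(unknown))
    stopf("counts reference unknown transcript '%s'", unknown[1L])
  if (read_length > min(nchar(seqs)))
    stopf("read_length %d exceeds the shortest transcript (%d)",
          read_length, min(nchar(seqs)))
  counts <- counts[counts > 0]
  reads <- with_seed(seed, {
    per_tx <- lapply(names(counts), function(tx) {
      nreads <- counts[[tx]]
      L <- nchar(seqs[[tx]])
      starts <- sample.int(L - read_length + 1L, nreads, replace = TRUE)
      substring(seqs[[tx]], starts, starts + read_length - 1L)
    })
    out <- unlist(per_tx, use.names = FALSE)
    if (error_rate > 0 && length(out)) {
      bases <- c("A", "C", "G", "T")
      chars <- strsplit(out, "", fixed = TRUE)
      chars <- lapply(chars, function(cc) {
        hit <- which(stats::runif(length(cc)) < error_rate)
        if (length(hit))
          cc[hit] <- vapply(cc[hit],
                            function(b) sample(setdiff(bases, b), 1L), "")
        cc
      })
      out <- vapply(chars, paste, "", collapse = "")
    }
    out
  })
  if (is.null(reads)) reads <- character(0)
  rec <- data.frame(
    read_id = sprintf("%s_%06d", sample_id, seq_along(reads)),
    sequence = reads,
    quality = strrep("I", read_length),
    stringsAsFactors = FALSE)
  write_fastq(rec, path)
  invisible(path)
}

#' Quantify reads by exact substring match
#'
#' A miniature quantifier for toy transcriptomes: each read is assigned to
#' the transcript that contains it as an exact forward-strand substring.
#' Reads matching several transcripts are counted as ambiguous, reads
#' matching none as unassigned; both are excluded from the counts, and
#' `assigned + ambiguous + unassigned` always equals the number of reads.
#'
#' @param fastq Path to a FASTQ file.
#' @param transcriptome FASTA path or named character vector.
#' @return List of class `quantification`: `counts` (named vector over all
#'   transcripts), `ambiguous`, `unassigned`, `total`.
#' @export
quantify_exact <- function(fastq, transcriptome) {
  seqs <- load_transcriptome(transcriptome)
  reads <- read_fastq(fastq)
  counts <- setNames(integer(length(seqs)), names(seqs))
  if (!nrow(reads))
    return(structure(list(counts = counts, ambiguous = 0L, unassigned = 0L,
                          total = 0L), class = "quantification"))
  mult <- table(reads$sequence)
  uniq <- names(mult)
  nhits <- integer(length(uniq))
  which_tx <- integer(length(uniq))
  widths <- nchar(uniq)
  if (length(unique(widths)) == 1L) {
    # constant-width reads: hash every window of that width in the
    # transcriptome once, then assign reads by exact lookup
    w <- widths[1L]
    wins <- lapply(seq_along(seqs), function(i) {
      L <- nchar(seqs[[i]])
      if (L < w) return(character(0))
      unique(substring(seqs[[i]], 1:(L - w + 1L), w:L))
    })
    win_seq <- unlist(wins)
    win_tx <- rep.int(seq_along(seqs), lengths(wins))
    ambiguous_win <- unique(win_seq[duplicated(win_seq)])  # window in >1 transcript
    first <- !duplicated(win_seq)
    tab_seq <- win_seq[first]
    tab_tx <- win_tx[first]
    tab_tx[tab_seq %in% ambiguous_win] <- 0L
    hit <- match(uniq, tab_seq)
    found <- !is.na(hit)
    nhits[found] <- ifelse(tab_tx[hit[found]] == 0L, 2L, 1L)
    which_tx[found] <- tab_tx[hit[found]]
  } else {
    for (i in seq_along(uniq)) {
      hit <- which(vapply(seqs, function(s) grepl(uniq[i], s, fixed = TRUE),
                          logical(1L)))
      nhits[i] <- length(hit)
      if (length(hit) == 1L) which_tx[i] <- hit
    }
  }
  mult <- as.integer(mult)
  one <- nhits == 1L
  if (any(one)) {
    agg <- tapply(mult[one], which_tx[one], sum)
    counts[as.integer(names(agg))] <- as.integer(agg)
  }
  structure(list(counts = counts,
                 ambiguous = sum(mult[nhits > 1L]),
                 unassigned = sum(mult[nhits == 0L]),
                 total = sum(mult)),
            class = "quantification")
}

#' @export
print.quantification <- function(x, ...) {
  cat(sprintf("quantification: %d reads; %d assigned, %d ambiguous, %d unassigned\n",
              x$total, sum(x$counts), x$ambiguous, x$unassigned))
  invisible(x)
}
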
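test_that("simulation design validates its parameters", {
  expect_s3_class(sim_design(), "sim_design")
  expect_error(sim_design(n_per_group = c(1, 4)), "at least 2")
  expect_error(sim_design(de_fraction = 2), "de_fraction")
  expect_error(sim_design(d = 5, de_fraction = 0.01), "no DE gene")
  expect_error(sim_design(log2fc_magnitude = 0), "positive")
})

test_that("null simulations carry no systematic fold change", {
  # no DE genes: per-seed median |log2fc| over well-expressed genes sits at
  # the pure-noise level. With alpha = 0.1 and 5+4 samples the theoretical
  # median of the estimate is 0.674 * sqrt(alpha * (1/5 + 1/4)) / ln(2),
  # about 0.21, far below the |log2fc| = 3 of true effects.
  meds <- vapply(1:20, function(s) {
    sim <- simulate_counts(sim_design(d = 300, de_fraction = 0, seed = s))
    r <- nb_wald(sim$R1)
    median(abs(r$log2FoldChange[r$baseMean >= 50]))
  }, numeric(1))
  expect_lte(median(meds), 0.25)
  expect_gte(median(meds), 0.1)
})

test_that("technical pairs correlate more strongly than independent samples", {
  for (s in 1:20) {
    sim <- simulate_counts(sim_design(d = 400, seed = s))
    l1 <- log1p(sim$R1$counts); l2 <- log1p(sim$R2$counts)
    within <- mean(vapply(1:9, function(i)
      cor(l1[, i], l2[, i], method = "spearman"), numeric(1)))
    between <- mean(vapply(1:8, function(i)
      cor(l1[, i], l1[, i + 1], method = "spearman"), numeric(1)))
    expect_gt(within, between)
  }
})

test_that("counts concentrate at the design mean in the Poisson limit", {
  # alpha = 0: counts are Poisson(mu); the mean over many draws approaches mu
  mu <- 40
  draws <- vapply(1:200, function(s) {
    sim <- simulate_counts(sim_design(d = 1, n_per_group = c(2, 2),
                                      de_fraction = 0, dispersion_alpha = 0,
                                      mean_log_range = log(c(mu, mu)), seed = s))
    mean(sim$R1$counts)
  }, numeric(1))
  se <- sqrt(mu / (4 * 200))
  expect_lt(abs(mean(draws) - mu), 4 * se)
})

test_that("the multinomial thinning technical model also pairs replicates", {
  sim <- simulate_counts(sim_design(d = 300, seed = 3,
                                    technical_model = "multinomial_thin"))
  l1 <- log1p(sim$R1$counts); l2 <- log1p(sim$R2$counts)
  within <- mean(vapply(1:9, function(i)
    cor(l1[, i], l2[, i], method = "spearman"), numeric(1)))
  between <- mean(vapply(1:8, function(i)
    cor(l1[, i], l1[, i + 1], method = "spearman"), numeric(1)))
  expect_gt(within, between)
})

test_that("toy transcriptomes are deterministic and pairwise distinct", {
  p1 <- tempfile(fileext = ".fasta")
  p2 <- tempfile(fileext = ".fasta")
  t1 <- build_toy_transcriptome(5, 300, seed = 9, path = p1)
  build_toy_transcriptome(5, 300, seed = 9, path = p2)
  expect_identical(readLines(p1), readLines(p2))
  seqs <- attr(t1, "sequences")
  expect_length(seqs, 5L)
  expect_true(all(nchar(seqs) == 300))
  expect_equal(anyDuplicated(seqs), 0L)

  td <- attr(build_toy_transcriptome(2, 50, seed = 1), "sequences")
  expect_gt(sum(strsplit(td[1], "")[[1]] != strsplit(td[2], "")[[1]]), 0)
})

test_that("simulated reads are exact substrings with honest ids", {
  tx <- build_toy_transcriptome(3, 120, seed = 5)
  seqs <- attr(tx, "sequences")
  fq <- tempfile(fileext = ".fastq")
  simulate_fastq(seqs, c(tx1 = 3, tx2 = 0, tx3 = 2), fq, read_length = 40,
                 seed = 6, sample_id = "S9")
  rec <- read_fastq(fq)
  expect_equal(nrow(rec), 5L)
  expect_true(all(grepl("^S9_", rec$read_id)))
  expect_false(any(grepl("tx", rec$read_id)))    # ids never leak the source
  expect_true(all(vapply(rec$sequence, function(r)
    any(vapply(seqs, function(s) grepl(r, s, fixed = TRUE), logical(1))),
    logical(1))))

  # determinism and error handling
  fq2 <- tempfile(fileext = ".fastq")
  simulate_fastq(seqs, c(tx1 = 3, tx2 = 0, tx3 = 2), fq2, read_length = 40,
                 seed = 6, sample_id = "S9")
  expect_identical(readLines(fq), readLines(fq2))
  expect_error(simulate_fastq(seqs, c(bad = 1), tempfile()), "unknown transcript")
  expect_error(simulate_fastq(seqs, c(tx1 = 1), tempfile(), error_rate = 0.5),
               "error_rate")
  expect_error(simulate_fastq(seqs, c(tx1 = 1), tempfile(), read_length = 500),
               "shortest transcript")
})

test_that("exact quantification inverts error-free simulation", {
  tx <- build_toy_transcriptome(8, 150, seed = 31)
  seqs <- attr(tx, "sequences")
  for (s in 1:5) {
    set.seed(1000 + s)
    counts <- setNames(rpois(8, 20), names(seqs))
    fq <- tempfile(fileext = ".fastq")
    simulate_fastq(seqs, counts, fq, read_length = 50, seed = s)
    q <- quantify_exact(fq, seqs)
    expect_equal(q$counts, counts)
    expect_equal(q$ambiguous, 0L)
    expect_equal(q$unassigned, 0L)
  }

  # empty FASTQ -> all-zero counts
  q0 <- quantify_exact(make_fastq(0), seqs)
  expect_true(all(q0$counts == 0))

  # conservation with an alien read
  fq <- tempfile(fileext = ".fastq")
  simulate_fastq(seqs, setNames(c(4, rep(0, 7)), names(seqs)), fq,
                 read_length = 50, seed = 2)
  rec <- read_fastq(fq)
  rec <- rbind(rec, data.frame(read_id = "alien", sequence = strrep("A", 50),
                               quality = strrep("I", 50)))
  write_fastq(rec, fq)
  q <- quantify_exact(fq, seqs)
  expect_equal(q$unassigned, 1L)
  expect_equal(sum(q$counts) + q$ambiguous + q$unassigned, 5L)
})

test_that("reads matching several transcripts are counted as ambiguous", {
  seqs <- c(tx1 = paste0(strrep("A", 10), "CGCGTTAACC", strrep("G", 10)),
            tx2 = paste0(strrep("T", 10), "CGCGTTAACC", strrep("C", 10)))
  fq <- tempfile(fileext = ".fastq")
  write_fastq(data.frame(read_id = "r1", sequence = "CGCGTTAACC",
                         quality = strrep("I", 10)), fq)
  q <- quantify_exact(fq, seqs)
  expect_equal(q$ambiguous, 1L)
  expect_true(all(q$counts == 0))
})
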
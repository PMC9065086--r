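test_that("size factors implement median-of-ratios", {
  m <- matrix(c(10, 20, 30, 20, 40, 60), 3, 2,
              dimnames = list(paste0("g", 1:3), c("a", "b")))
  expect_equal(unname(size_factors(m)), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-4)

  # identical columns -> all factors 1
  m2 <- matrix(rep(c(3, 8, 1), 3), 3, 3,
               dimnames = list(paste0("g", 1:3), paste0("s", 1:3)))
  expect_equal(unname(size_factors(m2)), rep(1, 3))

  # doubling one column doubles that factor relative to every other sample
  # (median-of-ratios factors are defined only up to a common rescale: the
  # geometric-mean reference itself moves when a column is scaled)
  x <- make_cm(20, 4, seed = 2)$counts
  sf <- size_factors(x)
  x2 <- x; x2[, 3] <- x2[, 3] * 2
  sf2 <- size_factors(x2)
  expect_equal(unname(sf2[3] / sf2[-3]), 2 * unname(sf[3] / sf[-3]),
               tolerance = 1e-12)
  expect_equal(unname(sf2[-3] / sf[-3]), rep(2^(-1 / 4), 3), tolerance = 1e-12)

  # fallback when no gene is positive everywhere
  z <- matrix(c(0, 5, 7, 0), 2, 2, dimnames = list(c("g1", "g2"), c("a", "b")))
  expect_warning(sfz <- size_factors(z), "total-count")
  expect_equal(unname(sfz), c(5, 7) / exp(mean(log(c(5, 7)))))
})

test_that("size factors agree with an independent NB workflow implementation", {
  requireNamespace("DESeq2", quietly = TRUE)
  x <- make_cm(200, 7, seed = 13, mu = 80)$counts
  expect_equal(unname(size_factors(x)),
               unname(DESeq2::estimateSizeFactorsForMatrix(x)),
               tolerance = 1e-6)
})

test_that("dispersion estimation concentrates at the truth", {
  n <- 20
  groups <- rep(c("A", "B"), each = n / 2)

  # Poisson counts: alpha ~ 0
  set.seed(101)
  mp <- matrix(rpois(500 * n, 100), 500, n,
               dimnames = list(paste0("g", 1:500), paste0("s", 1:n)))
  ap <- estimate_dispersions(count_matrix(mp, groups))
  expect_lte(median(ap, na.rm = TRUE), 0.05)

  # NB alpha = 0.2: median estimate lands in [0.1, 0.3]
  set.seed(102)
  mn <- matrix(rnbinom(500 * n, mu = 100, size = 1 / 0.2), 500, n,
               dimnames = list(paste0("g", 1:500), paste0("s", 1:n)))
  an <- estimate_dispersions(count_matrix(mn, groups))
  expect_gte(median(an, na.rm = TRUE), 0.1)
  expect_lte(median(an, na.rm = TRUE), 0.3)

  # a gene with identical counts everywhere has zero dispersion,
  # an all-zero gene is flagged NA
  mc <- rbind(g1 = rep(7, 6), g2 = rep(0, 6), g3 = rpois(6, 20))
  colnames(mc) <- paste0("s", 1:6)
  ac <- estimate_dispersions(count_matrix(mc, rep(c("A", "B"), 3)))
  expect_equal(unname(ac["g1"]), 0)
  expect_true(is.na(ac["g2"]))

  # degrees-of-freedom guard
  x2 <- make_cm(5, 2, seed = 1, groups = c("A", "B"))
  expect_error(estimate_dispersions(x2), "degrees of freedom")
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(adjust_bh(0.03), 0.03)
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(adjust_bh(c(0.5, 1.2)), "\\[0, 1\\]")

  # NA entries are excluded from the family and preserved in place
  p <- c(0.01, NA, 0.04)
  out <- adjust_bh(p)
  expect_true(is.na(out[2]))
  expect_equal(out[c(1, 3)], bh_brute(p[c(1, 3)]))

  set.seed(33)
  for (i in 1:200) {
    p <- runif(sample(1:30, 1))
    out <- adjust_bh(p)
    expect_equal(out, bh_brute(p), tolerance = 1e-12)
    expect_true(all(out >= p))
    expect_true(all(diff(out[order(p)]) >= -1e-12))
  }
})

test_that("NB Wald test behaves correctly on degenerate and transformed input", {
  # identical count vectors in both groups: no effect
  m <- cbind(matrix(rep(c(10, 40, 90), 3), 3, 3),
             matrix(rep(c(10, 40, 90), 3), 3, 3))
  dimnames(m) <- list(paste0("g", 1:3), paste0("s", 1:6))
  x <- count_matrix(m, rep(c("A", "B"), each = 3))
  r <- nb_wald(x)
  expect_equal(r$log2FoldChange, rep(0, 3))
  expect_equal(r$pvalue, rep(1, 3))

  # swapping condition labels negates log2fc and keeps p values
  x1 <- make_cm(50, 9, seed = 21, groups = c(rep("A", 5), rep("B", 4)), mu = 120)
  ra <- nb_wald(x1)
  x2 <- count_matrix(x1$counts,
                     factor(as.character(x1$groups), levels = c("B", "A")))
  rb <- nb_wald(x2)
  expect_equal(rb$log2FoldChange, -ra$log2FoldChange, tolerance = 1e-12)
  expect_equal(rb$pvalue, ra$pvalue, tolerance = 1e-12)

  # scaling one sample's counts is absorbed by the size factors
  for (cc in c(2, 10)) {
    xs <- x1$counts; xs[, 2] <- xs[, 2] * cc
    rs <- nb_wald(count_matrix(xs, x1$groups))
    expect_equal(rs$log2FoldChange, ra$log2FoldChange, tolerance = 1e-6)
  }

  # all-zero genes get NA p and are excluded from the BH family
  mz <- rbind(x1$counts[1:20, ], gz = 0)
  rz <- nb_wald(count_matrix(mz, x1$groups))
  expect_true(is.na(rz$pvalue[21]))
  expect_true(is.na(rz$padj[21]))
  expect_equal(rz$padj[1:20],
               bh_brute(rz$pvalue[1:20]),
               tolerance = 1e-12)

  expect_error(nb_wald(make_cm(5, 6, seed = 1, groups = rep(c("A", "B", "C"), 2))),
               "exactly 2 levels")
})

test_that("gene selection applies the double threshold", {
  res <- data.frame(gene_id = c("up", "weak", "flat", "na"),
                    log2FoldChange = c(2.5, 1.9, 0.1, 5),
                    padj = c(0.01, 0.01, 0.9, NA))
  expect_equal(select_genes(res), "up")
  expect_equal(select_genes(res, alpha = 0.05, lfc_threshold = 1.5),
               c("up", "weak"))
  expect_equal(select_genes(res[0, ]), character(0))
})

test_that("DE tables round-trip through TSV for the external backend hook", {
  x <- make_cm(30, 6, seed = 41, mu = 100)
  r <- nb_wald(x)
  p <- tempfile(fileext = ".tsv")
  write_de_tsv(r, p)
  r2 <- read_de_tsv(p)
  expect_equal(r2$gene_id, r$gene_id)
  expect_equal(r2$pvalue, r$pvalue, tolerance = 1e-6)
  expect_equal(select_genes(r2), select_genes(r))
  expect_error(read_de_tsv(make_fastq(1)), "missing column")
})
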
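test_that("Spearman distance matches hand-computed rank correlations", {
  a <- c(1, 2, 3, 4, 5)
  d <- spearman_distance(cbind(a = a, b = a, c = rev(a), d = c(1, 3, 2, 4, 5)))
  expect_equal(unname(d["a", "b"]), 0)
  expect_equal(unname(d["a", "c"]), 2)
  expect_equal(unname(d["a", "d"]), 0.1, tolerance = 1e-12)
  expect_true(isSymmetric(unname(d)))
  expect_equal(unname(diag(d)), rep(0, 4))

  # invariance under strictly monotone transforms
  set.seed(7)
  x <- runif(40); y <- rnorm(40)
  d0 <- spearman_distance(cbind(x = x, y = y))["x", "y"]
  d1 <- spearman_distance(cbind(x = exp(3 * x), y = y))["x", "y"]
  d2 <- spearman_distance(cbind(x = x, y = rank(y)^3))["x", "y"]
  expect_equal(d1, d0, tolerance = 1e-12)
  expect_equal(d2, d0, tolerance = 1e-12)

  # listwise deletion of genes with missing values
  xm <- c(x[1:38], NA, x[40])
  dn <- spearman_distance(cbind(x = xm, y = y))["x", "y"]
  expect_equal(unname(dn),
               spearman_dist_brute(xm[-39], y[-39]), tolerance = 1e-12)

  expect_error(spearman_distance(cbind(a = c(1, NA, 3), b = c(NA, 2, 3))),
               "fewer than 3")
})

test_that("Ward trees merge the closest pair first and export Newick", {
  d <- matrix(c(0, 0, 1, 0, 0, 1, 1, 1, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- ward_tree(d)
  expect_equal(sort(abs(tr$merge[1, ])), c(1, 2))   # a and b merge first
  expect_equal(tr$height[1], 0)
  expect_true(all(diff(tr$height) >= 0))

  # n = 2 base case
  d2 <- matrix(c(0, 0.4, 0.4, 0), 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  t2 <- ward_tree(d2)
  expect_equal(length(t2$height), 1L)

  # two well-separated pairs give topology ((a,b),(c,d))
  d4 <- matrix(10, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  d4["a", "b"] <- d4["b", "a"] <- 0.1
  d4["c", "d"] <- d4["d", "c"] <- 0.2
  diag(d4) <- 0
  t4 <- ward_tree(d4)
  nwk <- tree_newick(t4)
  expect_match(nwk, "\\(a:[0-9.e-]+,b:[0-9.e-]+\\)|\\(b:[0-9.e-]+,a:[0-9.e-]+\\)")
  expect_match(nwk, "\\(c:[0-9.e-]+,d:[0-9.e-]+\\)|\\(d:[0-9.e-]+,c:[0-9.e-]+\\)")

  # ward.D and ward.D2 are both available and deterministic
  expect_identical(ward_tree(d4, "ward.D")$merge, t4$merge)

  dns <- d4; dns["a", "b"] <- 5
  expect_error(ward_tree(dns), "symmetric")
})

test_that("overlap matrices are asymmetric percentages with a 100 diagonal", {
  # the worked example: |A| = 595, |B| = 565, |A n B| = 447
  A <- paste0("g", 1:595)
  B <- paste0("g", c(1:447, 1000:1117))
  ov <- overlap_matrix(list(R1 = A, R2 = B))
  expect_equal(round(unname(ov["R1", "R2"])), 75)
  expect_equal(round(unname(ov["R2", "R1"])), 79)
  expect_equal(unname(diag(ov)), c(100, 100))

  ov2 <- overlap_matrix(list(A = c("g1", "g2", "g3"), B = c("g2", "g3")))
  expect_equal(unname(ov2["A", "B"]), 100 * 2 / 3, tolerance = 1e-12)
  expect_equal(unname(ov2["B", "A"]), 100)

  ove <- overlap_matrix(list(A = character(0), B = "g1"))
  expect_equal(unname(ove["A", "B"]), 0)
  expect_equal(attr(ove, "empty_reference"), "A")

  expect_error(overlap_matrix(list(A = "g1")), "at least 2")
})

test_that("stability reports cross-tabulate selection frequencies", {
  # hand-enumerated example: reference {g1,g2}, replicates {g1} and {g1,g3}
  uni <- c("g1", "g2", "g3", "g4")
  st <- stability_report(c("g1", "g2"), list("g1", c("g1", "g3")), uni,
                         reference_pvalues = setNames(c(0.001, 0.01, 0.2, 0.9), uni))
  expect_equal(unname(st$frequency), c(2L, 0L, 1L, 0L))
  expect_equal(unname(st$crosstab["TRUE", ]), c(1, 0, 1))   # g2 at 0, g1 at 2
  expect_equal(unname(st$crosstab["FALSE", ]), c(1, 1, 0))  # g4 at 0, g3 at 1
  expect_equal(sum(st$crosstab), length(uni))
  expect_equal(unname(rowSums(st$crosstab)), c(2, 2))
  expect_equal(st$genes$ref_pvalue[st$genes$gene_id == "g2"], 0.01)

  # perfect stability concentrates the TRUE row at column B
  stp <- stability_report(c("g1", "g2"), rep(list(c("g1", "g2")), 10), uni)
  expect_equal(unname(stp$crosstab["TRUE", "10"]), 2)
  expect_equal(unname(stp$crosstab["FALSE", "0"]), 2)

  # B = 0 degenerates to a single column
  st0 <- stability_report("g1", list(), uni)
  expect_equal(ncol(st0$crosstab), 1L)

  expect_error(stability_report("zz", list("g1"), uni), "outside the universe")
  expect_error(stability_report("g1", list("zz"), uni), "outside the universe")
})

test_that("dispersion comparisons recover identity and zero technical variance", {
  x <- make_cm(40, 9, seed = 61, groups = c(rep("A", 5), rep("B", 4)), mu = 90)
  dc <- dispersion_comparison(list(truth = x, same = x), mode = "biological",
                              reference = "truth")
  expect_equal(dc$dispersions$same, dc$dispersions$truth)
  expect_equal(unname(dc$ks["same"]), 0)

  # exact technical copies: replicate-design dispersions are all zero
  m <- make_cm(30, 4, seed = 62, mu = 70)$counts
  pooled <- cbind(m, m)
  colnames(pooled) <- paste0(rep(colnames(m), 2), c(rep(".r1", 4), rep(".r2", 4)))
  xp <- count_matrix(pooled, rep(colnames(m), 2))
  dt <- dispersion_comparison(list(pool = xp), mode = "technical")
  expect_true(all(dt$dispersions$pool == 0, na.rm = TRUE))

  expect_error(dispersion_comparison(list(a = x), reference = "zz"),
               "not among")
})

test_that("de_catalog aligns result vectors on the shared gene index", {
  x <- make_cm(25, 9, seed = 71, groups = c(rep("A", 5), rep("B", 4)), mu = 60)
  r1 <- nb_wald(x)
  r2 <- nb_wald(column_bootstrap(x, seed = 5))
  cat_ <- de_catalog(list(one = r1, two = r2), "pvalue")
  expect_equal(dim(cat_), c(25L, 2L))
  expect_equal(cat_[, "one"], setNames(r1$pvalue, r1$gene_id))
  catf <- de_catalog(list(one = r1), "abs_log2fc")
  expect_equal(unname(catf[, 1]), abs(r1$log2FoldChange))
  expect_error(de_catalog(list(r1, r2)), "unique names")
})
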
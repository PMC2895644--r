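test_that("expression matrix counts exonic reads, excluding junction reads", {
  annot <- toy_annotation()
  reads <- list(
    s1 = make_reads("chr1", c(1100, 1200, 3100, 20100), sample_id = "s1"),
    s2 = make_reads("chr1", c(1150, 50000), sample_id = "s2"))
  # junction read in an exon must not be counted in the matrix
  jr <- make_reads("chr1", 1300, sample_id = "s1", is_junction = TRUE)
  reads$s1 <- c(reads$s1, jr)
  em <- build_expression_matrix(reads, annot, detected_in_min = 1)
  expect_equal(em$counts["g1", "s1"], 3L)   # junction read excluded
  expect_equal(em$counts["g1", "s2"], 1L)
  expect_equal(em$counts["g2", "s1"], 1L)
  # rate = count / exonic length (g1: 500 + 600 nt)
  expect_equal(em$rates["g1", "s1"], 3 / 1100)
  # detection threshold: g2 seen in one sample only
  em2 <- build_expression_matrix(reads, annot, detected_in_min = 2)
  expect_false("g2" %in% rownames(em2$counts))
  expect_true("g1" %in% rownames(em2$counts))
})

test_that("a read spanning two exons of one gene counts once", {
  annot <- toy_annotation()
  # exon1 ends 1500, exon2 starts 3001; a (hypothetical) long feature read
  r <- gr("chr1", 1490, 3010)
  r$sample_id <- "s1"; r$n_locations <- 1L; r$is_junction <- FALSE
  em <- build_expression_matrix(list(s1 = r), annot, detected_in_min = 1)
  expect_equal(em$counts["g1", "s1"], 1L)
})

test_that("quantile normalization makes sorted columns identical", {
  m <- cbind(a = c(1, 2), b = c(3, 4))
  qn <- quantile_normalize(m)
  expect_equal(sort(qn[, 1]), c(2, 3))
  expect_equal(sort(qn[, 2]), c(2, 3))
  # identical columns are a fixed point
  m2 <- cbind(a = c(5, 1, 3), b = c(5, 1, 3))
  expect_equal(quantile_normalize(m2), m2, ignore_attr = TRUE)
  # property: identical sorted content on tie-free random matrices
  set.seed(31)
  for (i in 1:10) {
    mm <- matrix(rnorm(40), 10, 4)
    qq <- quantile_normalize(mm)
    sorted <- apply(qq, 2, sort)
    expect_true(all(abs(sorted - sorted[, 1]) < 1e-12))
  }
})

test_that("distances: 3-4-5 example, symmetry, zero diagonal", {
  m <- cbind(s1 = c(0, 3), s2 = c(0, 4), s3 = c(4, 0))
  d_man <- expression_distance(m, "manhattan")
  d_euc <- expression_distance(m, "euclidean")
  expect_equal(d_man["s1", "s2"], 1)
  expect_equal(d_man["s2", "s3"], 8)
  expect_equal(d_euc["s2", "s3"], sqrt(32))
  two <- cbind(a = c(0, 0, 3), b = c(0, 4, 0))  # rows differ by (0,4,-3)
  expect_equal(expression_distance(two, "manhattan")["a", "b"], 7)
  expect_equal(expression_distance(two, "euclidean")["a", "b"], 5)
  expect_true(isSymmetric(d_euc))
  expect_equal(unname(diag(d_euc)), rep(0, 3))
})

test_that("identical samples are at distance zero under all measures", {
  m <- cbind(a = c(1, 5, 2, 8), b = c(1, 5, 2, 8), c = c(2, 6, 3, 9))
  expect_equal(expression_distance(m, "euclidean")["a", "b"], 0)
  expect_equal(expression_distance(m, "manhattan")["a", "b"], 0)
  expect_equal(expression_distance(m, "one_minus_rho")["a", "b"], 0)
})

test_that("1 - rho is invariant to monotone transforms of one column", {
  set.seed(17)
  m <- cbind(a = rnorm(50), b = rnorm(50), c = rnorm(50))
  d1 <- expression_distance(m, "one_minus_rho")
  m2 <- m; m2[, "b"] <- exp(2 * m2[, "b"]) + 5  # strictly monotone
  d2 <- expression_distance(m2, "one_minus_rho")
  expect_equal(d1, d2, tolerance = 1e-12)
  mc <- m; mc[, 1] <- 1
  expect_error(expression_distance(mc, "one_minus_rho"),
               "constant column")
})

test_that("Z-transform standardises rows and drops constant ones", {
  m <- cbind(a = c(1, 10, 7), b = c(3, 10, 8), c = c(5, 10, 12))
  expect_message(d <- expression_distance(m, "euclidean", z_transform = TRUE),
                 "constant row")
  # after dropping row 2 and standardising, distances depend only on shape
  zm <- t(scale(t(m[c(1, 3), ])))
  expect_equal(unname(d), unname(as.matrix(dist(t(zm)))))
})

test_that("UPGMA reproduces the hand-worked 3-taxon agglomeration", {
  d <- matrix(c(0, 2, 8,
                2, 0, 8,
                8, 8, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tree <- upgma_tree(d)
  # topology ((A,B),C); cophenetic distances reproduce the input
  cd <- ape::cophenetic.phylo(tree)
  expect_equal(cd["A", "B"], 2)
  expect_equal(cd["A", "C"], 8)
  expect_equal(cd["B", "C"], 8)
  # ultrametric heights 1 and 4
  bt <- sort(unname(ape::branching.times(tree)))
  expect_equal(bt, c(1, 4))
})

test_that("UPGMA trees are ultrametric on random distance matrices", {
  set.seed(23)
  for (i in 1:20) {
    n <- sample(4:7, 1)
    x <- matrix(rnorm(n * 10), 10, n,
                dimnames = list(NULL, paste0("t", 1:n)))
    d <- as.matrix(dist(t(x)))
    cd <- ape::cophenetic.phylo(upgma_tree(d))
    for (a in 1:(n - 2)) for (b in (a + 1):(n - 1)) for (cc in (b + 1):n) {
      trio <- sort(c(cd[a, b], cd[a, cc], cd[b, cc]), decreasing = TRUE)
      expect_equal(trio[1], trio[2], tolerance = 1e-9)
    }
  }
})

test_that("tie in minimal distance merges deterministically", {
  d <- matrix(c(0, 1, 5, 5,
                1, 0, 5, 5,
                5, 5, 0, 1,
                5, 5, 1, 0), 4, 4,
              dimnames = list(c("d", "c", "b", "a"), c("d", "c", "b", "a")))
  t1 <- upgma_tree(d)
  t2 <- upgma_tree(d[c(3, 4, 1, 2), c(3, 4, 1, 2)])  # same matrix, reordered
  expect_equal(sort(htrtools:::.clades(t1)), sort(htrtools:::.clades(t2)))
})

test_that("bootstrap support finds the planted replicate pair", {
  set.seed(41)
  base <- matrix(rlnorm(200 * 4, 0, 1), 200, 4,
                 dimnames = list(NULL, c("H1", "H2", "C", "M")))
  sig <- rlnorm(200, 0, 1)
  m <- base * 0.05 + cbind(sig, sig, sig * rlnorm(200, 0, 0.5),
                           sig * rlnorm(200, 0, 0.8))
  res <- upgma_bootstrap(m, measure = "euclidean", z_transform = TRUE,
                         B = 100, seed = 2)
  expect_true("H1,H2" %in% names(res$support))
  expect_gte(res$support[["H1,H2"]], 0.99)
  expect_true(ape::is.ultrametric(res$tree, tol = 1e-8))
})

test_that("BH adjustment matches the step-up closed form", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_adjust(0.2), 0.2)
  set.seed(3)
  p <- runif(50)
  q <- bh_adjust(p)
  expect_true(all(q >= p))
  expect_true(all(q <= 1))
  # order preservation: sorting p sorts q the same way
  expect_equal(q[order(p)], sort(q))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})
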
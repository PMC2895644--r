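bg <- gr("chr1", 1, 100000)

test_that("matched random regions conserve the length multiset exactly", {
  template <- gr("chr1", c(100, 5000, 9000, 20000, 60000),
                 c(399, 5799, 9099, 21999, 60099))
  out <- matched_random_regions(template, bg, seed = 4)
  expect_length(out, 5)
  expect_equal(sort(width(out)), sort(width(template)))
  # mutually non-overlapping
  expect_equal(length(GenomicRanges::reduce(out, min.gapwidth = 0L)), 5)
  # seed-reproducible
  out2 <- matched_random_regions(template, bg, seed = 4)
  expect_identical(start(out), start(out2))
})

test_that("a region as large as the background is placed identically", {
  bg1 <- gr("chr1", 1001, 2000)
  out <- matched_random_regions(gr("chr1", 1, 1000), bg1, seed = 1)
  expect_equal(start(out), 1001)
  expect_equal(end(out), 2000)
})

test_that("placements avoid the exclusion set and impossible lengths error", {
  excl <- gr("chr1", 1, 90000)
  out <- matched_random_regions(gr("chr1", 1, 500), bg, exclusion = excl,
                                seed = 2)
  expect_false(IRanges::overlapsAny(out, excl))
  expect_error(
    matched_random_regions(gr("chr1", 1, 20000), bg, exclusion = excl),
    "exceeds every background piece")
})

test_that("placement starts are uniform over the background", {
  set.seed(8)
  flat <- htrtools:::.flatten_space(gr("chr1", 1, 10000))
  starts <- vapply(1:5000, function(i)
    htrtools:::.place_lengths(flat, 100)$start, numeric(1))
  # start positions lie in 1..9901; chi-square over 10 bins
  bins <- cut(starts, breaks = seq(0, 9910, length.out = 11))
  expect_gt(chisq.test(table(bins))$p.value, 0.01)
})

test_that("overlap permutation test flags enrichment and saturates to p = 1", {
  set.seed(5)
  query <- gr("chr1", seq(1000, 96000, by = 2000), seq(1300, 96300, by = 2000))
  # features covering 60% of the query directly
  feats <- query[1:29]
  res <- overlap_permutation_test(query, feats, bg, B = 200, seed = 6)
  expect_s3_class(res, "PermutationResult")
  expect_equal(res$observed, 29)
  expect_lte(res$empirical_p, 0.01)
  expect_gte(res$empirical_p, 1 / 201)

  # saturation: features tile the whole background
  sat <- overlap_permutation_test(query, bg, bg, B = 50, seed = 6)
  expect_equal(sat$observed, length(query))
  expect_true(all(sat$null_values == length(query)))
  expect_equal(sat$empirical_p, 1)

  # empty features: observed 0, p = 1 under direction greater
  none <- overlap_permutation_test(query, GRanges(), bg, B = 50, seed = 6)
  expect_equal(none$observed, 0)
  expect_equal(none$empirical_p, 1)
})

test_that("feature extension widens features before testing", {
  query <- gr("chr1", 50000, 50100)
  feats <- gr("chr1", 50600, 50620)  # 500 nt away
  res0 <- overlap_permutation_test(query, feats, bg, B = 20, seed = 1)
  expect_equal(res0$observed, 0)
  res1 <- overlap_permutation_test(query, feats, bg, B = 20, seed = 1,
                                   extend = 1000)
  expect_equal(res1$observed, 1)
})

test_that("EST connections need distinct blocks of one EST on both members", {
  ig <- gr("chr1", c(30000, 32000), c(30500, 32500))
  ig$cluster <- c(1L, 1L)
  annot <- toy_annotation()
  est_two_block <- methods::as(list(
    e1 = gr("chr1", c(30100, 32100), c(30200, 32200))), "GRangesList")
  res <- connection_permutation_test("ightr_ightr", ig, annot,
                                     est_two_block, bg, B = 30, seed = 2)
  expect_equal(res$observed, 1)
  # a single-block EST overlapping both members is not a connection
  est_one_block <- methods::as(list(
    e1 = gr("chr1", 30100, 32200)), "GRangesList")
  res1 <- connection_permutation_test("ightr_ightr", ig, annot,
                                      est_one_block, bg, B = 30, seed = 2)
  expect_equal(res1$observed, 0)
  # a single-block EST overlapping only one member: no connection
  est_single <- methods::as(list(e1 = gr("chr1", 30100, 30200)),
                            "GRangesList")
  res2 <- connection_permutation_test("ightr_ightr", ig, annot, est_single,
                                      bg, B = 30, seed = 2)
  expect_equal(res2$observed, 0)
})

test_that("gene-3' connections link terminal exons to downstream igHTR", {
  annot <- toy_annotation()
  # igHTR 5 kb downstream of g1 (+ strand; terminal exon [3001,3600])
  ig <- gr("chr1", 8600, 9000)
  cl <- cluster_and_assign_genes(ig, annot)
  est <- methods::as(list(
    bridge = gr("chr1", c(3400, 8700), c(3600, 8800))), "GRangesList")
  res <- connection_permutation_test("gene3_ightr", cl$ightrs, annot, est,
                                     bg, B = 30, seed = 3)
  expect_equal(res$observed, 1)
})

test_that("conservation resampling: constant track gives zero-width CIs", {
  sc <- gr("chr1", 1, 100000); sc$score <- 0.5
  tr <- conservation_track(sc, c(chr1 = 100000L))
  res <- conservation_resampled_ci(
    list(ightr = gr("chr1", 1000, 1999),
         exon = gr("chr1", 5000, 9999),
         intergenic = gr("chr1", 20000, 59999)),
    tr, n_resamples = 50, seed = 1)
  expect_equal(res$mean_score, rep(0.5, 3))
  expect_equal(res$ci_low[-1], rep(0.5, 2))
  expect_equal(res$ci_high[-1], rep(0.5, 2))
  expect_false(res$resampled[1])  # focal class is not resampled
})

test_that("conservation resampling flags classes smaller than the focal set", {
  sc <- gr("chr1", 1, 10000); sc$score <- 0.3
  tr <- conservation_track(sc, c(chr1 = 10000L))
  expect_warning(
    res <- conservation_resampled_ci(
      list(focal = gr("chr1", 1, 5000), tiny = gr("chr1", 6001, 6100)),
      tr, n_resamples = 20, seed = 1),
    "with replacement")
  expect_true(res$with_replacement[2])
})

test_that("hypergeometric enrichment matches the closed form", {
  background <- sprintf("g%02d", 1:20)
  categories <- list(hit = background[1:5], other = background[6:15])
  fg <- background[1:5]
  res <- enrichment_test(fg, background, categories, B = 200, seed = 2)
  # all 5 draws in a 5-gene category out of 20: p = 1/C(20,5)
  expect_equal(res$table$raw_p[res$table$category == "hit"],
               1 / choose(20, 5), tolerance = 1e-12)
  expect_lte(res$global_p, 0.05)
  # foreground = background makes every raw p 1
  res_all <- enrichment_test(background, background, categories, B = 20,
                             seed = 2)
  expect_equal(res_all$table$raw_p, rep(1, 2))
})

test_that("hypergeometric tail equals direct enumeration", {
  # population 12, category 4, draws 5: P(X >= k) by enumerating dhyper
  for (k in 0:4) {
    enum <- sum(dhyper(k:4, 4, 8, 5))
    expect_equal(phyper(k - 1, 4, 8, 5, lower.tail = FALSE), enum,
                 tolerance = 1e-12)
  }
  # and the same through enrichment_test's reported raw p
  background <- sprintf("g%02d", 1:12)
  categories <- list(cat = background[1:4])
  fg <- background[c(1, 2, 5, 6, 7)]  # k = 2
  res <- enrichment_test(fg, background, categories, B = 10, seed = 1)
  expect_equal(res$table$raw_p, sum(dhyper(2:4, 4, 8, 5)), tolerance = 1e-12)
})

test_that("categories disjoint from the background are skipped with warning", {
  background <- c("a", "b", "c", "d")
  expect_warning(
    res <- enrichment_test(c("a", "b"), background,
                           list(good = c("a", "c"), alien = c("x", "y")),
                           B = 10, seed = 1),
    "skipped")
  expect_equal(res$table$category, "good")
})

test_that("binomial excess test is the exact upper tail", {
  expect_equal(binomial_excess_test(0, 10, 0.3), 1)
  expect_equal(binomial_excess_test(10, 10, 0.5), 2^-10, tolerance = 1e-12)
  # direct pmf summation oracle
  enum <- sum(dbinom(7:10, 10, 0.3))
  expect_equal(binomial_excess_test(7, 10, 0.3), enum, tolerance = 1e-12)
  expect_error(binomial_excess_test(3, 10, 0), "strictly")
  expect_error(binomial_excess_test(3, 10, 1), "strictly")
})

test_that("empirical p-values use the add-one rule and are never zero", {
  r <- htrtools:::.permutation_result(100, rep(0, 99), "greater")
  expect_equal(r$empirical_p, 1 / 100)
  r2 <- htrtools:::.permutation_result(0, rep(100, 99), "greater")
  expect_equal(r2$empirical_p, 1)
})
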
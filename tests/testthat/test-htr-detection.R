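annot <- toy_annotation()

test_that("abutting reads chain into one region spanning first to last", {
  # 10 abutting 36-nt reads starting every 36 nt
  reads <- make_reads("chr1", 30001 + 36 * (0:9))
  h <- call_htr(reads, htr_params())
  expect_length(h, 1)
  expect_equal(width(h), 360)
  expect_equal(h$read_count, 10L)
  expect_equal(start(h), 30001)
})

test_that("minhits filters chains below the threshold", {
  reads <- make_reads("chr1", 30001 + 36 * (0:8))  # 9 reads
  expect_length(call_htr(reads, htr_params(minhits = 10)), 0)
  expect_length(call_htr(reads, htr_params(minhits = 9)), 1)
  expect_length(call_htr(GRanges(), htr_params()), 0)
})

test_that("maxspacing boundary: gap of exactly 150 chains, 151 breaks", {
  c1 <- 30001 + 36 * (0:9)                 # chain ends at 30360
  gap150 <- make_reads("chr1", c(c1, 30361 + 150 + 36 * (0:9)))
  h150 <- call_htr(gap150, htr_params())
  expect_length(h150, 1)
  expect_equal(h150$read_count, 20L)
  gap151 <- make_reads("chr1", c(c1, 30361 + 151 + 36 * (0:9)))
  h151 <- call_htr(gap151, htr_params())
  expect_length(h151, 2)
  expect_equal(h151$read_count, c(10L, 10L))
})

test_that("caller matches the brute-force chain oracle on random instances", {
  set.seed(101)
  for (i in 1:60) {
    n <- sample(5:100, 1)
    reads <- make_reads("chr1", sort(sample.int(10000, n, replace = TRUE)))
    params <- htr_params(maxspacing = sample(c(0, 50, 150, 300), 1),
                         minhits = sample(c(1, 3, 10), 1))
    got <- call_htr(reads, params)
    want <- oracle_htr(reads, params$maxspacing, params$minhits)
    expect_equal(length(got), nrow(want))
    expect_equal(start(got), want$start)
    expect_equal(end(got), want$end)
    expect_equal(got$read_count, want$count)
  }
})

test_that("HTR calls are invariant to read input order", {
  set.seed(11)
  reads <- make_reads("chr1", sample.int(20000, 300, replace = TRUE))
  h1 <- call_htr(reads, htr_params(50, 5))
  h2 <- call_htr(reads[sample(300)], htr_params(50, 5))
  expect_equal(as.data.frame(h1), as.data.frame(h2))
})

test_that("chain count is monotone in maxspacing; HTR count in minhits", {
  set.seed(12)
  reads <- make_reads("chr1", sample.int(30000, 400, replace = TRUE))
  # more spacing only merges chains (count non-increasing at minhits = 1);
  # at higher minhits merges may push chains over the threshold, so the
  # guarantee is on chains, not filtered HTRs
  n_by_spacing <- vapply(c(0, 25, 50, 100, 200, 400), function(ms)
    length(call_htr(reads, htr_params(ms, 1))), numeric(1))
  expect_true(all(diff(n_by_spacing) <= 0))
  n_by_minhits <- vapply(c(1, 2, 5, 10, 20), function(mh)
    length(call_htr(reads, htr_params(100, mh))), numeric(1))
  expect_true(all(diff(n_by_minhits) <= 0))
})

test_that("start-to-start spacing mode measures between read starts", {
  reads <- make_reads("chr1", c(1000, 1140, 1290))  # start gaps 140, 150
  expect_length(call_htr(reads, htr_params(150, 3, "start_to_start")), 1)
  reads2 <- make_reads("chr1", c(1000, 1151))       # start gap 151
  expect_length(call_htr(reads2, htr_params(150, 2, "start_to_start")), 0)
  # same reads chain under end-to-start (gap = 1151-1035-1 = 115)
  expect_length(call_htr(reads2, htr_params(150, 2)), 1)
})

test_that("igHTR must lie wholly intergenic with no transcript overlap", {
  h <- c(gr("chr1", 50000, 50500),   # clean intergenic
         gr("chr1", 3590, 4100),     # 11 nt inside gene g1 span
         gr("chr1", 60400, 60900),   # overlaps ncRNA (transcript exclusion)
         gr("chr1", 40100, 40300))   # inside an intergenic repeat
  h$read_count <- rep(12L, 4)
  out <- classify_ightr(h, annot)
  expect_equal(out$is_ightr, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(out$category[2], "exon")  # span touches gene: hierarchy label
  expect_equal(out$category[4], "intergenic_repeat")
})

test_that("cross-sample unification takes 5'-most/3'-most boundaries", {
  a <- gr("chr1", 30100, 30500); a$read_count <- 12L
  b <- gr("chr1", 30300, 30700); b$read_count <- 15L
  only_a <- gr("chr1", 45000, 45400); only_a$read_count <- 11L
  u <- unify_htr_across_samples(list(s1 = c(a, only_a), s2 = b))
  expect_length(u, 2)
  expect_equal(start(u), c(30100, 45000))
  expect_equal(end(u), c(30700, 45400))
  expect_equal(u$count_s1, c(12L, 11L))
  expect_equal(u$count_s2, c(15L, 0L))
  expect_equal(u$n_samples, c(2L, 1L))

  # abutting but non-overlapping HTRs stay separate (overlap >= 1 nt rule)
  c1 <- gr("chr1", 1000, 1999); c1$read_count <- 10L
  c2 <- gr("chr1", 2000, 2999); c2$read_count <- 10L
  u2 <- unify_htr_across_samples(list(s1 = c1, s2 = c2))
  expect_length(u2, 2)

  # counts recomputed within unified boundaries when reads are supplied
  reads2 <- list(s1 = make_reads("chr1", c(30100, 30200, 30600)),
                 s2 = make_reads("chr1", 30400))
  u3 <- unify_htr_across_samples(list(s1 = a, s2 = b), reads2)
  expect_equal(u3$count_s1, 3L)
  expect_equal(u3$count_s2, 1L)
})

test_that("clusters form within one intergenic region; genes get side calls", {
  # four igHTR share the region between g2 and the repeats; two more share
  # the region between g1 and g2 (same-region rule clusters both groups)
  ig <- c(gr("chr1", c(30000, 31000, 32000, 33000),
             c(30400, 31400, 32400, 33400)),
          gr("chr1", 8600, 9000),    # just downstream of g1 (+): 3' side
          gr("chr1", 19000, 19400))  # just upstream of g2 (-): its 3' side
  res <- cluster_and_assign_genes(ig, annot, near_gene_distance = 10000)
  expect_length(unique(res$ightrs$cluster), 2)
  expect_equal(res$ightrs$cluster[1:4], rep(res$ightrs$cluster[1], 4))
  expect_equal(res$ightrs$cluster[5], res$ightrs$cluster[6])
  expect_false(res$ightrs$cluster[1] == res$ightrs$cluster[5])
  expect_equal(sort(res$clusters$n_members), c(2L, 4L))
  expect_equal(res$ightrs$nearest_gene[5], "g1")
  expect_equal(res$ightrs$gene_side[5], "3prime")
  expect_true(res$ightrs$within_near[5])
  expect_equal(res$ightrs$gene_side[6], "3prime")  # g2 is on the minus strand
  expect_equal(res$ightrs$gene_side[1], "5prime")  # downstream of g2 (-)
})

test_that("max_cluster_gap caps cluster membership", {
  ig <- gr("chr1", c(30000, 31000, 45000), c(30400, 31400, 45400))
  res <- cluster_and_assign_genes(ig, annot, max_cluster_gap = 5000)
  expect_equal(res$ightrs$cluster, c(1, 1, NA))
})

test_that("equal-read windows hold exactly N reads and drop the remainder", {
  set.seed(3)
  reads <- list(
    human = make_reads("chr1", sort(sample.int(50000, 70)), sample_id = "h"),
    chimp = make_reads("chr1", sort(sample.int(50000, 50)), sample_id = "c"),
    macaque = make_reads("chr1", sort(sample.int(50000, 29)), sample_id = "m"))
  gw <- equal_read_windows(reads, blocks = NULL, n_per_window = 50)
  expect_length(gw, 2)  # 149 reads -> 2 windows, 49 dropped
  counts <- as.matrix(S4Vectors::mcols(gw)[, c("count_human", "count_chimp",
                                               "count_macaque")])
  expect_equal(unname(rowSums(counts)), c(50, 50))
  expect_equal(gw$total_reads, c(50L, 50L))
  # windows are disjoint in read membership (boundaries may touch since
  # they snap to member reads): consecutive windows start after one another
  expect_true(start(gw)[2] > start(gw)[1])

  expect_warning(ew <- equal_read_windows(
    list(h = make_reads("chr1", 1:10)), NULL, 50), "fewer than")
  expect_length(ew, 0)
})

test_that("windows respect alignment-block coverage restriction", {
  reads <- list(h = make_reads("chr1", seq(1000, 6000, by = 50)))
  df <- data.frame(block = c(1, 1), species = c("h", "c"), contig = "chr1",
                   start = c(999, 10999), end = c(3999, 13999))
  bs <- alignment_block_set_from_table(df, reference = "h")
  gw <- equal_read_windows(reads, bs, n_per_window = 20, reference = "h")
  # only reads in [1000, 3999] (61 reads) are eligible -> 3 windows
  expect_length(gw, 3)
  expect_true(all(end(gw) <= 3999 + 35))
})
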
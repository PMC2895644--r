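cfg <- small_config()
sim <- simulate_genome(cfg)

test_that("category tracks partition the genome exactly", {
  lens <- category_lengths(sim$annot)
  expect_equal(sum(lens), cfg$genome_length)
  # pairwise disjoint
  all_cat <- unlist(GRangesList(sim$annot$categories))
  expect_equal(sum(as.numeric(width(GenomicRanges::reduce(all_cat)))),
               sum(as.numeric(width(all_cat))))
})

test_that("simulation is deterministic under a fixed seed", {
  sim2 <- simulate_genome(small_config())
  expect_identical(as.data.frame(sim2$truth$planted_ightr),
                   as.data.frame(sim$truth$planted_ightr))
  expect_identical(category_lengths(sim2$annot), category_lengths(sim$annot))
  r1 <- simulate_reads(sim$annot, sim$truth, cfg, "s", "human")
  r2 <- simulate_reads(sim2$annot, sim2$truth, cfg, "s", "human")
  expect_identical(as.data.frame(r1), as.data.frame(r2))
})

test_that("a gene-free genome is wall-to-wall intergenic", {
  cfg0 <- simulation_config(genome_length = 5e5, mito_length = 16000,
                            n_genes = 0, n_ncrna = 0, n_rrna = 0,
                            repeat_families = NULL, n_planted_ightr = 0,
                            library_size = 1000, seed = 2)
  sim0 <- simulate_genome(cfg0)
  lens <- category_lengths(sim0$annot)
  expect_equal(unname(lens["intergenic"]), 5e5 - 16000)
  expect_equal(unname(lens["mito"]), 16000)
  expect_equal(sum(lens[c("exon", "intron", "intronic_repeat",
                          "intergenic_repeat", "ncRNA")]), 0)
})

test_that("planted igHTR lie entirely in intergenic non-repeat space", {
  pl <- sim$truth$planted_ightr
  expect_gt(length(pl), 0)
  ig <- sim$annot$categories$intergenic
  expect_true(all(countOverlaps(pl, ig, type = "within") > 0))
  expect_false(any(IRanges::overlapsAny(pl, sim$annot$transcript_exclusion)))
  expect_false(any(IRanges::overlapsAny(pl, sim$truth$repeats)))
})

test_that("exactly library_size reads are emitted", {
  r <- simulate_reads(sim$annot, sim$truth, cfg, "s1", "human")
  expect_equal(length(r), cfg$library_size)
})

test_that("rRNA reads make up the configured fraction of the library", {
  r <- simulate_reads(sim$annot, sim$truth, cfg, "s1", "human")
  frac <- mean(IRanges::overlapsAny(r, sim$annot$rrna))
  expect_equal(frac, cfg$rrna_fraction, tolerance = 0.01)
})

test_that("phi = 0 gives Poisson per-locus counts (variance ~ mean)", {
  cfgp <- small_config(seed = 9, nb_dispersion = 0)
  simp <- simulate_genome(cfgp)
  # counts of reads in each planted unit across many replicate samples
  pl <- simp$truth$planted_ightr
  counts <- sapply(1:40, function(i)
    countOverlaps(pl, simulate_reads(simp$annot, simp$truth, cfgp,
                                     paste0("rep", i), "human")))
  m <- rowMeans(counts); v <- apply(counts, 1, var)
  # index of dispersion ~ 1 for Poisson; NB with phi would give 1 + phi*m >> 1
  expect_equal(mean(v / m), 1, tolerance = 0.25)
})

test_that("planted igHTR read density is elevated over matched background", {
  r <- filter_reads(simulate_reads(sim$annot, sim$truth, cfg, "s1", "human"),
                    sim$annot)
  pl <- sim$truth$planted_ightr
  dens_pl <- sum(countOverlaps(pl, r)) / sum(width(pl))
  ig_free <- GenomicRanges::setdiff(sim$annot$categories$intergenic,
                                    pl + 500)
  dens_bg <- sum(countOverlaps(ig_free, r)) /
    sum(as.numeric(width(ig_free)))
  expect_gt(dens_pl, 100 * dens_bg)
})

test_that("category read proportions track rate x length expectations", {
  # Poisson sampling: the law-of-large-numbers claim concerns read-sampling
  # proportionality; NB expression noise (per-unit Gamma factors) adds
  # biological variation on top that no library size averages away
  cfgl <- small_config(seed = 13, library_size = 1e6, nb_dispersion = 0)
  siml <- simulate_genome(cfgl)
  r <- simulate_reads(siml$annot, siml$truth, cfgl, "s1", "human")
  f <- filter_reads(r, siml$annot)
  cs <- composition_summary(f, siml$annot, mode = "reads")
  # expectation from the generator's own locus weights (per-gene factors and
  # family multipliers included); multi-mapped reads excluded uniformly
  loci <- htrtools:::.read_loci(siml$annot, siml$truth, cfgl)
  exp_by_cat <- tapply(loci$weight, loci$src, sum)
  src_to_cat <- c(exon = "exon", intron = "intron",
                  intergenic = "intergenic", mito = "mito", ncRNA = "ncRNA",
                  planted_ightr = "intergenic")
  expected <- setNames(numeric(7), category_hierarchy())
  for (s_ in names(exp_by_cat)) {
    if (s_ == "repeat") next
    expected[src_to_cat[[s_]]] <- expected[src_to_cat[[s_]]] +
      exp_by_cat[[s_]]
  }
  # repeats split by compartment
  reps <- siml$truth$repeats
  in_gene <- IRanges::overlapsAny(reps, siml$annot$genes)
  rl <- loci[loci$src == "repeat", ]
  expected["intronic_repeat"] <- sum(rl$weight[in_gene])
  expected["intergenic_repeat"] <- sum(rl$weight[!in_gene])
  expected <- expected / sum(expected)
  got <- setNames(cs$proportion, cs$category)[names(expected)]
  expect_true(all(abs(got - expected) < 0.02))
})

test_that("EST support honours its configured fraction, including zero", {
  anc <- simulate_ancillary(sim$annot, sim$truth, cfg)
  fp <- unlist(anc$ests)
  pl <- sim$truth$planted_ightr
  sup <- IRanges::overlapsAny(pl, fp)
  expect_gte(mean(sup), cfg$est_support_fraction - 0.05)

  cfg0 <- small_config(seed = 5, est_support_fraction = 0,
                       est_bridge_fraction = 0, utr3_connect_fraction = 0,
                       n_background_ests = 0)
  anc0 <- simulate_ancillary(sim$annot, sim$truth, cfg0)
  expect_length(anc0$ests, 0)
})

test_that("conservation is ordered exon > planted igHTR > intergenic", {
  anc <- simulate_ancillary(sim$annot, sim$truth, cfg)
  tr <- anc$conservation
  m_ex <- mean(conservation_values(tr, sim$annot$categories$exon))
  m_pl <- mean(conservation_values(tr, sim$truth$planted_ightr))
  bg <- GenomicRanges::setdiff(sim$annot$categories$intergenic,
                               sim$truth$planted_ightr)
  m_bg <- mean(conservation_values(tr, bg))
  expect_gt(m_ex, m_pl)
  expect_gt(m_pl, m_bg)
})

test_that("full alignment coverage makes every interval projectable", {
  cfg1 <- small_config(seed = 5, alignment_coverage = 1)
  anc1 <- simulate_ancillary(sim$annot, sim$truth, cfg1)
  pl <- sim$truth$planted_ightr
  proj <- project_intervals(pl, anc1$blocks, "human", "chimp")
  expect_equal(length(proj), length(pl))
})
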
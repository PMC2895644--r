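# Shared fixtures: all built in code at test time.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

gr <- function(ctg, start, end, ...) {
  GenomicRanges::GRanges(ctg, IRanges::IRanges(start, end), ...)
}

# Reads GRanges with the mcols the package expects.
make_reads <- function(ctg, start, width = 36L, sample_id = "s1",
                       n_locations = 1L, is_junction = FALSE) {
  g <- gr(ctg, start, start + width - 1L)
  g$sample_id <- sample_id
  g$n_locations <- n_locations
  g$is_junction <- is_junction
  g
}

# A small hand-laid annotation on a 100-kb contig:
#   gene g1 (+): exons [1001,1500], [3001,3600]; span [1001,3600]
#   gene g2 (-): exons [20001,20800], [23001,23500]; span [20001,23500]
#   intronic repeat [2001,2300]; intergenic repeats [40001,40400], [40800,41000]
#   ncRNA [60001,60500]; rRNA [80001,82000]; chrM of 16 kb
toy_annotation <- function() {
  exons <- c(gr("chr1", c(1001, 3001), c(1500, 3600), strand = "+"),
             gr("chr1", c(20001, 23001), c(20800, 23500), strand = "-"))
  exons$gene_id <- c("g1", "g1", "g2", "g2")
  genes <- c(gr("chr1", 1001, 3600, strand = "+"),
             gr("chr1", 20001, 23500, strand = "-"))
  genes$gene_id <- c("g1", "g2")
  repeats <- gr("chr1", c(2001, 40001, 40800), c(2300, 40400, 41000))
  repeats$family <- c("AluY", "AluY", "L1M")
  repeats$mappable <- c(200L, 300L, 150L)
  ncrna <- gr("chr1", 60001, 60500)
  rrna <- gr("chr1", 80001, 82000)
  chr1 <- gr("chr1", 1, 100000)
  mito <- gr("chrM", 1, 16000)
  exon_track <- GenomicRanges::reduce(exons, ignore.strand = TRUE)
  gene_track <- GenomicRanges::reduce(genes, ignore.strand = TRUE)
  intron0 <- GenomicRanges::setdiff(gene_track, exon_track)
  rep_track <- GenomicRanges::reduce(repeats)
  categories <- list(
    exon = exon_track,
    intronic_repeat = GenomicRanges::intersect(rep_track, intron0),
    intron = GenomicRanges::setdiff(intron0, rep_track),
    intergenic_repeat = GenomicRanges::setdiff(rep_track, gene_track),
    mito = mito,
    ncRNA = ncrna,
    intergenic = GenomicRanges::setdiff(
      GenomicRanges::setdiff(GenomicRanges::setdiff(chr1, gene_track),
                             rep_track), ncrna))
  annotation_set(categories, rrna = rrna,
                 transcript_exclusion = GenomicRanges::reduce(
                   c(gene_track, ncrna)),
                 genes = genes, exons = exons,
                 contig_lengths = c(chr1 = 100000L, chrM = 16000L))
}

# Small simulation config for fast end-to-end tests; ... overrides any
# default, including the scaled-down ones set here.
small_config <- function(seed = 5, ...) {
  args <- list(
    genome_length = 2e6, mito_length = 16000, n_genes = 30,
    n_ncrna = 8, n_rrna = 2, rrna_length = 3000,
    repeat_families = transform(default_repeat_families(),
                                n_elements = c(60, 50, 40, 70, 50)),
    n_planted_ightr = 15, library_size = 3e5, n_background_ests = 15,
    seed = seed)
  args[names(list(...))] <- list(...)
  do.call(simulation_config, args)
}

# Independent brute-force HTR oracle: single-linkage connected components of
# the "gap <= maxspacing" relation over all read pairs (igraph), then the
# minhits filter; O(n^2), usable for <= a few hundred reads.
oracle_htr <- function(reads, maxspacing, minhits) {
  n <- length(reads)
  if (n == 0) return(data.frame(start = integer(), end = integer(),
                                count = integer()))
  s <- BiocGenerics::start(reads); e <- BiocGenerics::end(reads)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    gap <- max(s[j] - e[i] - 1L, s[i] - e[j] - 1L, 0L)
    adj[i, j] <- gap <= maxspacing
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  out <- do.call(rbind, lapply(unique(comp), function(k) {
    idx <- comp == k
    data.frame(start = min(s[idx]), end = max(e[idx]), count = sum(idx))
  }))
  out <- out[out$count >= minhits, , drop = FALSE]
  out[order(out$start), , drop = FALSE]
}
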
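#' Simulation configuration
#'
#' Parameters of the synthetic genome/transcriptome generator. Defaults
#' describe a 10-Mb desk-scale genome whose read composition mimics an
#' unstranded 36-nt total-RNA brain library: rRNA dominates raw reads,
#' exons dominate the remainder, intergenic background is sparse, and the
#' planted structures (igHTR clusters, an elevated young repeat family,
#' species-specific genes) carry the signals the pipeline is built to find.
#'
#' @param genome_length Total genome size in nt (main contig plus
#'   mitochondrial contig).
#' @param mito_length Mitochondrial contig length in nt.
#' @param n_genes Number of protein-coding genes.
#' @param exons_per_gene Mean exon count per gene (>= 2).
#' @param exon_meanlog,exon_sdlog Log-normal exon length parameters (nt).
#' @param intron_meanlog,intron_sdlog Log-normal intron length parameters.
#' @param n_ncrna Number of non-coding RNA loci.
#' @param ncrna_meanlog,ncrna_sdlog Log-normal ncRNA length parameters.
#' @param n_rrna,rrna_length Count and length of rRNA loci.
#' @param repeat_families Data frame with columns `name`, `class`,
#'   `n_elements`, `len_meanlog`, `len_sdlog`, `mappable_fraction`,
#'   `activity_multiplier`, `age_rank`. The default plants one young family
#'   (highest age rank) at 3x transcriptional activity.
#' @param n_planted_ightr Number of planted intergenic transcription units
#'   (each an exon-like segment; ground-truth igHTR).
#' @param ightr_exons_per_cluster Units per cluster (intron-like spacing
#'   separates them, so each unit is called as its own igHTR).
#' @param ightr_exon_meanlog,ightr_exon_sdlog Unit length distribution.
#' @param ightr_spacing_meanlog,ightr_spacing_sdlog Within-cluster spacing.
#' @param ightr_rate_multiplier Fold elevation of planted units over the
#'   intergenic background read rate. Intergenic background is kept at a
#'   realistic per-nt read density (sparse relative to the chaining gap),
#'   so highly transcribed units sit orders of magnitude above it.
#' @param ightr_buffer Feature-free margin (nt) enforced around planted
#'   clusters so ground-truth boundaries are recoverable.
#' @param utr3_cluster_fraction Fraction of clusters planted just downstream
#'   of a gene's 3' end (3'-UTR-extension-like), the rest in open intergenic
#'   space.
#' @param ightr_species_specific_fraction Fraction of planted units given
#'   species-specific elevation (fold `species_specific_fold`).
#' @param background_rates Named reads-per-nt rates for the seven categories
#'   at the nominal library size; relative values set the composition.
#' @param gene_factor_sdlog Between-gene expression spread (log-normal,
#'   mean-normalised).
#' @param species Character vector of species names; the first is the
#'   reference and is sampled twice (two replicates).
#' @param species_divergence_sdlog Per-species genome-wide expression
#'   divergence (log-normal sd of per-gene factors relative to the
#'   reference, one value per species; 0 for the reference). Increasing
#'   values with phylogenetic distance give divergence trees their
#'   expected structure: replicates pair, the closer species joins next.
#' @param species_specific_fraction Fraction of genes planted with
#'   species-specific expression.
#' @param species_specific_fold Fold change of planted species-specific loci.
#' @param nb_dispersion Common NB dispersion phi (0 = Poisson) of per-locus
#'   counts across samples.
#' @param library_size Reads emitted per sample (before rRNA exclusion).
#' @param rrna_fraction Fraction of raw reads drawn from rRNA loci.
#' @param multimap_fraction Fraction of non-rRNA reads flagged as mapping to
#'   2-100 locations.
#' @param junction_fraction Fraction of exonic reads flagged as junction
#'   reads.
#' @param read_length Read length in nt.
#' @param est_support_fraction Fraction of planted igHTR covered by an EST.
#' @param est_bridge_fraction Fraction of igHTR clusters whose consecutive
#'   units are bridged by one spliced EST.
#' @param utr3_connect_fraction Fraction of 3'-UTR-extension clusters linked
#'   to their gene's terminal exon by an EST.
#' @param n_background_ests Unrelated gene-overlapping ESTs.
#' @param alignment_coverage Fraction of the main contig covered by
#'   three-species alignment blocks.
#' @param cons_base,cons_ightr,cons_exon Conservation track levels for
#'   background, planted igHTR, and exons.
#' @param seed Integer seed; fixed seed gives byte-identical outputs.
#' @return A `SimulationConfig` (validated S3 list).
#' @export
simulation_config <- function(genome_length = 1e7,
                              mito_length = 16000,
                              n_genes = 100,
                              exons_per_gene = 6,
                              exon_meanlog = log(250), exon_sdlog = 0.5,
                              intron_meanlog = log(1500), intron_sdlog = 0.7,
                              n_ncrna = 30,
                              ncrna_meanlog = log(500), ncrna_sdlog = 0.5,
                              n_rrna = 4, rrna_length = 5000,
                              repeat_families = default_repeat_families(),
                              n_planted_ightr = 50,
                              ightr_exons_per_cluster = 3,
                              ightr_exon_meanlog = log(800),
                              ightr_exon_sdlog = 0.2,
                              ightr_spacing_meanlog = log(1500),
                              ightr_spacing_sdlog = 0.4,
                              ightr_rate_multiplier = 6000,
                              ightr_buffer = 500,
                              utr3_cluster_fraction = 0.25,
                              ightr_species_specific_fraction = 0.2,
                              background_rates = c(
                                exon = 3.0, intronic_repeat = 0.2,
                                intron = 0.15, intergenic_repeat = 0.12,
                                mito = 1.0, ncRNA = 0.8, intergenic = 2e-5),
                              gene_factor_sdlog = 0.8,
                              species = c("human", "chimp", "macaque"),
                              species_divergence_sdlog = c(0, 0.3, 0.6),
                              species_specific_fraction = 0.05,
                              species_specific_fold = 4,
                              nb_dispersion = 0.1,
                              library_size = 1500000,
                              rrna_fraction = 0.37,
                              multimap_fraction = 0.05,
                              junction_fraction = 0.02,
                              read_length = 36,
                              est_support_fraction = 0.48,
                              est_bridge_fraction = 0.25,
                              utr3_connect_fraction = 0.5,
                              n_background_ests = 40,
                              alignment_coverage = 0.9,
                              cons_base = 0.08, cons_ightr = 0.35,
                              cons_exon = 0.7,
                              seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(genome_length > mito_length, mito_length > 0,
            all(background_rates >= 0), nb_dispersion >= 0,
            library_size >= 1, rrna_fraction >= 0, rrna_fraction < 1,
            ightr_rate_multiplier > 0, read_length >= 1,
            all(CATEGORY_HIERARCHY %in% names(background_rates)))
  if (!is.null(repeat_families) && nrow(repeat_families) > 0)
    stopifnot(all(c("name", "class", "n_elements", "len_meanlog", "len_sdlog",
                    "mappable_fraction", "activity_multiplier", "age_rank")
                  %in% names(repeat_families)))
  class(cfg) <- "SimulationConfig"
  cfg
}

#' Default repeat family table
#'
#' Five families spanning an age gradient; the youngest (highest age rank)
#' is planted at 3x transcriptional activity, emulating the elevated
#' activity of evolutionarily young transposable-element families.
#' Mappable fraction falls with youth (younger elements are more similar to
#' each other, hence less uniquely mappable).
#'
#' @return Data frame of family parameters.
#' @export
default_repeat_families <- function() {
  data.frame(
    name = c("MIR", "L2", "L1M", "AluSx", "AluY"),
    class = c("SINE/MIR", "LINE/L2", "LINE/L1", "SINE/Alu", "SINE/Alu"),
    n_elements = c(350, 300, 250, 400, 300),
    len_meanlog = log(c(180, 350, 900, 300, 300)),
    len_sdlog = c(0.4, 0.5, 0.6, 0.15, 0.15),
    mappable_fraction = c(0.9, 0.85, 0.7, 0.5, 0.35),
    activity_multiplier = c(1, 1, 1, 1, 3),
    age_rank = 1:5,
    stringsAsFactors = FALSE)
}

#' Simulate an annotated genome with planted ground truth
#'
#' Lays out genes (alternating exons/introns), ncRNA, rRNA loci, repeat
#' elements (in introns and intergenic space) and planted intergenic
#' transcription-unit clusters on a main contig, plus a mitochondrial
#' contig. The seven category tracks partition the genome. Planted igHTR lie
#' entirely in intergenic non-repeat space and never overlap annotated
#' transcripts.
#'
#' @param cfg A [simulation_config()].
#' @return List with elements `annot` (an `AnnotationSet`), `truth` (a
#'   `GroundTruth` list: `planted_ightr` GRanges with `cluster`, `type`,
#'   `near_gene` mcols; `repeats` GRanges with `family`, `mappable` mcols;
#'   `elevated_families`; `gene_factors`; `species_specific` data frame;
#'   `category_fractions`), and `cfg`.
#' @export
simulate_genome <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  set.seed(cfg$seed)
  main_len <- cfg$genome_length - cfg$mito_length
  contigs <- c(chr1 = as.integer(main_len), chrM = as.integer(cfg$mito_length))

  ## --- genes: alternating exon/intron structure, non-overlapping spans
  n_exons <- pmax(2L, rpois(cfg$n_genes, cfg$exons_per_gene))
  gene_parts <- lapply(seq_len(cfg$n_genes), function(i) {
    ne <- n_exons[i]
    ex <- pmax(30L, as.integer(rlnorm(ne, cfg$exon_meanlog, cfg$exon_sdlog)))
    iv <- pmax(200L, as.integer(rlnorm(ne - 1, cfg$intron_meanlog,
                                       cfg$intron_sdlog)))
    list(exons = ex, introns = iv, span = sum(ex) + sum(iv))
  })
  spans <- vapply(gene_parts, `[[`, numeric(1), "span")
  if (sum(spans) * 1.5 > main_len)
    stop("simulation error: genome too small to place genes")
  gpos <- .place_lengths(list(ctg = "chr1", gstart = 1L, len = main_len),
                         spans)
  gene_strand <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)
  exon_list <- vector("list", cfg$n_genes)
  gene_spans <- GenomicRanges::GRanges()
  for (i in seq_len(cfg$n_genes)) {
    p <- gene_parts[[i]]
    widths <- as.integer(rbind(p$exons, c(p$introns, 0L)))
    widths <- widths[widths > 0]
    starts <- gpos$start[i] + cumsum(c(0L, head(widths, -1)))
    is_exon <- rep(c(TRUE, FALSE), length.out = length(widths))
    ex <- GenomicRanges::GRanges("chr1",
      IRanges::IRanges(starts[is_exon], width = widths[is_exon]),
      strand = gene_strand[i])
    ex$gene_id <- sprintf("gene%04d", i)
    exon_list[[i]] <- ex
  }
  if (cfg$n_genes > 0) {
    exons <- do.call(c, exon_list)
    genes <- GenomicRanges::GRanges("chr1",
      IRanges::IRanges(gpos$start, gpos$end), strand = gene_strand)
    genes$gene_id <- sprintf("gene%04d", seq_len(cfg$n_genes))
  } else {
    exons <- GenomicRanges::GRanges()
    exons$gene_id <- character(0)
    genes <- GenomicRanges::GRanges()
    genes$gene_id <- character(0)
  }

  ## --- intergenic scaffold (everything outside gene spans on chr1)
  chr1_all <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, main_len))
  intergenic0 <- GenomicRanges::setdiff(chr1_all, genes, ignore.strand = TRUE)

  ## --- ncRNA and rRNA loci in intergenic space
  nc_len <- pmax(100L, as.integer(rlnorm(cfg$n_ncrna, cfg$ncrna_meanlog,
                                         cfg$ncrna_sdlog)))
  anc <- .place_lengths(.flatten_space(intergenic0),
                        c(nc_len, rep(cfg$rrna_length, cfg$n_rrna)))
  idx_nc <- seq_len(cfg$n_ncrna)
  idx_rr <- cfg$n_ncrna + seq_len(cfg$n_rrna)
  ncrna <- GenomicRanges::GRanges(anc$ctg[idx_nc],
    IRanges::IRanges(anc$start[idx_nc], anc$end[idx_nc]))
  rrna <- GenomicRanges::GRanges(anc$ctg[idx_rr],
    IRanges::IRanges(anc$start[idx_rr], anc$end[idx_rr]))

  ## --- repeats: placed in introns and remaining intergenic space
  fam <- cfg$repeat_families
  introns_gr <- GenomicRanges::setdiff(genes, exons, ignore.strand = TRUE)
  free_intergenic <- GenomicRanges::setdiff(
    GenomicRanges::setdiff(intergenic0, ncrna, ignore.strand = TRUE),
    rrna, ignore.strand = TRUE)
  repeats <- GenomicRanges::GRanges()
  if (!is.null(fam) && nrow(fam) > 0) {
    fam_lens <- lapply(seq_len(nrow(fam)), function(f)
      pmax(50L, as.integer(rlnorm(fam$n_elements[f], fam$len_meanlog[f],
                                  fam$len_sdlog[f]))))
    all_lens <- unlist(fam_lens)
    fam_id <- rep(fam$name, lengths(fam_lens))
    # roughly half of elements in introns, half intergenic (by coin flip),
    # placed within one shared non-overlap pass per compartment
    in_intron <- rbinom(length(all_lens), 1, 0.5) == 1
    rep_list <- list()
    for (compartment in c(TRUE, FALSE)) {
      sel <- in_intron == compartment
      if (!any(sel)) next
      space <- if (compartment) introns_gr else free_intergenic
      pos <- .place_lengths(.flatten_space(space), all_lens[sel])
      g <- GenomicRanges::GRanges(pos$ctg, IRanges::IRanges(pos$start, pos$end))
      g$family <- fam_id[sel]
      rep_list[[length(rep_list) + 1]] <- g
    }
    repeats <- do.call(c, rep_list)
    repeats$mappable <- as.integer(round(
      BiocGenerics::width(repeats) *
        fam$mappable_fraction[match(repeats$family, fam$name)]))
  }

  ## --- planted igHTR clusters in intergenic non-repeat, non-transcript space
  open_space <- GenomicRanges::setdiff(free_intergenic, repeats,
                                       ignore.strand = TRUE)
  n_units <- cfg$n_planted_ightr
  planted <- GenomicRanges::GRanges()
  if (n_units > 0) {
    k <- cfg$ightr_exons_per_cluster
    n_clusters <- ceiling(n_units / k)
    sizes <- rep(k, n_clusters)
    sizes[n_clusters] <- n_units - k * (n_clusters - 1)
    unit_len <- lapply(sizes, function(s)
      pmax(150L, as.integer(rlnorm(s, cfg$ightr_exon_meanlog,
                                   cfg$ightr_exon_sdlog))))
    gaps <- lapply(sizes, function(s)
      pmax(400L, as.integer(rlnorm(max(s - 1, 0), cfg$ightr_spacing_meanlog,
                                   cfg$ightr_spacing_sdlog))))
    cl_span <- mapply(function(u, g) sum(u) + sum(g), unit_len, gaps)
    buf <- as.integer(cfg$ightr_buffer)
    n_utr3 <- round(cfg$utr3_cluster_fraction * n_clusters)
    is_utr3 <- seq_len(n_clusters) <= n_utr3
    # 3'-UTR-extension clusters anchor 1-3 kb downstream of a gene's 3' end;
    # the rest are placed uniformly in open intergenic space
    placed_start <- integer(n_clusters)
    utr3_gene <- rep(NA_integer_, n_clusters)
    occupied <- open_space
    if (n_utr3 > 0) {
      cand_genes <- sample(seq_along(genes), length(genes))
      gi <- 1
      for (ci in which(is_utr3)) {
        placed <- FALSE
        while (!placed && gi <= length(cand_genes)) {
          g <- genes[cand_genes[gi]]; gi <- gi + 1
          off <- 1000L + sample.int(2000L, 1)
          st <- if (as.character(BiocGenerics::strand(g)) == "+")
            BiocGenerics::end(g) + off else
            BiocGenerics::start(g) - off - cl_span[ci] + 1L
          if (st - buf < 1) next
          cand <- GenomicRanges::GRanges("chr1",
            IRanges::IRanges(st - buf, width = cl_span[ci] + 2L * buf))
          inside <- sum(BiocGenerics::width(GenomicRanges::intersect(
            cand, occupied, ignore.strand = TRUE))) ==
            BiocGenerics::width(cand)
          if (inside) {
            placed_start[ci] <- st
            utr3_gene[ci] <- cand_genes[gi - 1]
            occupied <- GenomicRanges::setdiff(occupied, cand,
                                               ignore.strand = TRUE)
            placed <- TRUE
          }
        }
        if (!placed) is_utr3[ci] <- FALSE  # fall back to open placement
      }
    }
    open_idx <- which(placed_start == 0)
    if (length(open_idx)) {
      pos <- .place_lengths(.flatten_space(occupied),
                            cl_span[open_idx] + 2L * buf)
      placed_start[open_idx] <- pos$start + buf
    }
    unit_rows <- lapply(seq_len(n_clusters), function(ci) {
      u <- unit_len[[ci]]; g <- gaps[[ci]]
      widths <- as.integer(rbind(u, c(g, 0L)))
      widths <- widths[widths > 0]
      starts <- placed_start[ci] + cumsum(c(0L, head(widths, -1)))
      is_unit <- rep(c(TRUE, FALSE), length.out = length(widths))
      data.frame(start = starts[is_unit], width = widths[is_unit],
                 cluster = ci,
                 type = if (is_utr3[ci]) "utr3_extension" else "standalone",
                 near_gene = if (is_utr3[ci])
                   genes$gene_id[utr3_gene[ci]] else NA_character_)
    })
    ur <- do.call(rbind, unit_rows)
    planted <- GenomicRanges::GRanges("chr1",
      IRanges::IRanges(ur$start, width = ur$width))
    planted$cluster <- ur$cluster
    planted$type <- ur$type
    planted$near_gene <- ur$near_gene
  }

  ## --- category tracks (partition of chr1 + chrM)
  mito <- GenomicRanges::GRanges("chrM", IRanges::IRanges(1, cfg$mito_length))
  exon_track <- GenomicRanges::reduce(exons, ignore.strand = TRUE)
  intron_track0 <- GenomicRanges::setdiff(genes, exon_track,
                                          ignore.strand = TRUE)
  rep_track <- GenomicRanges::reduce(repeats, ignore.strand = TRUE)
  intronic_repeat <- GenomicRanges::intersect(rep_track, intron_track0,
                                              ignore.strand = TRUE)
  intron_track <- GenomicRanges::setdiff(intron_track0, rep_track,
                                         ignore.strand = TRUE)
  intergenic_repeat <- GenomicRanges::setdiff(rep_track, genes,
                                              ignore.strand = TRUE)
  ncRNA_track <- GenomicRanges::reduce(ncrna, ignore.strand = TRUE)
  intergenic_track <- GenomicRanges::setdiff(
    GenomicRanges::setdiff(intergenic0, rep_track, ignore.strand = TRUE),
    ncRNA_track, ignore.strand = TRUE)
  categories <- list(
    exon = exon_track, intronic_repeat = intronic_repeat,
    intron = intron_track, intergenic_repeat = intergenic_repeat,
    mito = mito, ncRNA = ncRNA_track, intergenic = intergenic_track)

  transcript_exclusion <- GenomicRanges::reduce(
    c(GenomicRanges::granges(genes), ncRNA_track), ignore.strand = TRUE)

  annot <- annotation_set(categories, rrna = rrna,
                          transcript_exclusion = transcript_exclusion,
                          genes = genes, exons = exons,
                          contig_lengths = contigs)

  ## --- planted species-specific genes and graded species divergence
  gene_factors <- rlnorm(cfg$n_genes, 0, cfg$gene_factor_sdlog)
  gene_factors <- gene_factors / mean(gene_factors)
  names(gene_factors) <- genes$gene_id
  sdd <- cfg$species_divergence_sdlog
  stopifnot(length(sdd) == length(cfg$species))
  species_factors <- matrix(1, cfg$n_genes, length(cfg$species),
                            dimnames = list(genes$gene_id, cfg$species))
  for (si in seq_along(cfg$species))
    if (sdd[si] > 0 && cfg$n_genes > 0)  # mean-1 log-normal multipliers
      species_factors[, si] <- rlnorm(cfg$n_genes, -sdd[si]^2 / 2, sdd[si])
  n_ss <- round(cfg$species_specific_fraction * cfg$n_genes)
  ss <- data.frame(gene_id = character(), species = character(),
                   fold = numeric())
  if (n_ss > 0) {
    ss_genes <- sample(genes$gene_id, n_ss)
    ss <- data.frame(gene_id = ss_genes,
                     species = sample(cfg$species, n_ss, replace = TRUE),
                     fold = cfg$species_specific_fold,
                     stringsAsFactors = FALSE)
  }

  ss_ightr <- data.frame(unit = integer(), species = character(),
                         fold = numeric())
  n_ssu <- round(cfg$ightr_species_specific_fraction * length(planted))
  if (n_ssu > 0) {
    ssu <- sort(sample(seq_along(planted), n_ssu))
    ss_ightr <- data.frame(unit = ssu,
                           species = sample(cfg$species, n_ssu,
                                            replace = TRUE),
                           fold = cfg$species_specific_fold,
                           stringsAsFactors = FALSE)
  }

  lens <- category_lengths(annot)
  truth <- list(
    planted_ightr = planted,
    repeats = repeats,
    elevated_families = if (!is.null(fam) && nrow(fam))
      fam$name[fam$activity_multiplier > 1] else character(0),
    gene_factors = gene_factors,
    species_factors = species_factors,
    species_specific = ss,
    species_specific_ightr = ss_ightr,
    category_fractions = lens / sum(lens))
  class(truth) <- "GroundTruth"
  list(annot = annot, truth = truth, cfg = cfg)
}
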
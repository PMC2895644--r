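# Expression-unit table shared by all samples: one row per emitting locus,
# grouped into units (a gene's exons form one unit; every other locus is its
# own unit) so per-unit totals are exactly NB across samples while member
# loci share the unit's Gamma multiplier.
.read_loci <- function(annot, truth, cfg) {
  rate <- cfg$background_rates
  rows <- list()
  add <- function(gr, rate_nt, unit, src, gene = NA_character_) {
    if (length(gr) == 0) return()
    rows[[length(rows) + 1]] <<- data.frame(
      ctg = as.character(GenomicRanges::seqnames(gr)),
      start = BiocGenerics::start(gr), end = BiocGenerics::end(gr),
      rate_nt = rate_nt, unit = unit, src = src, gene = gene,
      stringsAsFactors = FALSE)
  }
  ## genes: exon loci, one unit per gene, per-gene expression factor
  ex <- annot$exons
  if (length(ex)) {
    gf <- truth$gene_factors[ex$gene_id]
    add(ex, rate[["exon"]] * unname(gf), paste0("g_", ex$gene_id), "exon",
        ex$gene_id)
  }
  ## repeats: element-level units with family activity multipliers; the
  ## per-element rate is scaled by its mappable fraction so that uniquely
  ## mapped reads accrue in proportion to uniquely mappable positions
  reps <- truth$repeats
  if (length(reps)) {
    fam <- cfg$repeat_families
    mult <- fam$activity_multiplier[match(reps$family, fam$name)]
    in_gene <- suppressWarnings(
      IRanges::overlapsAny(reps, annot$genes, ignore.strand = TRUE))
    base <- ifelse(in_gene, rate[["intronic_repeat"]],
                   rate[["intergenic_repeat"]])
    map_frac <- reps$mappable / BiocGenerics::width(reps)
    add(reps, base * mult * map_frac, sprintf("r_%06d", seq_along(reps)),
        "repeat")
  }
  ## plain category background (introns, intergenic, mito, ncRNA)
  for (cat_ in c("intron", "intergenic", "mito", "ncRNA")) {
    gr <- annot$categories[[cat_]]
    add(gr, rate[[cat_]], sprintf("%s_%06d", cat_, seq_along(gr)), cat_)
  }
  ## planted igHTR: extra rate on top of intergenic background
  pl <- truth$planted_ightr
  if (length(pl))
    add(pl, (cfg$ightr_rate_multiplier - 1) * rate[["intergenic"]],
        sprintf("p_%04d", seq_along(pl)), "planted_ightr")
  out <- do.call(rbind, rows)
  out$weight <- out$rate_nt * (out$end - out$start + 1)
  out
}

#' Simulate one sample's mapped reads
#'
#' Draws per-unit read counts from a negative binomial (common dispersion
#' `cfg$nb_dispersion`; Poisson when 0), with species multipliers applied to
#' planted species-specific genes, places 36-nt reads uniformly within the
#' emitting locus, emits rRNA reads at `cfg$rrna_fraction` of the library,
#' flags a configurable fraction as multi-mapping (2-100 locations) and a
#' fraction of exonic reads as junction reads, and adjusts the total to
#' exactly `cfg$library_size` reads.
#'
#' @param annot,truth Output of [simulate_genome()].
#' @param cfg The [simulation_config()].
#' @param sample_id Sample name.
#' @param species Species name (must appear in `cfg$species`).
#' @param seed Integer seed; default derives one from `cfg$seed` and
#'   `sample_id` so samples differ but runs are reproducible.
#' @return A `GRanges` of reads with mcols `sample_id`, `n_locations`,
#'   `is_junction`, `src` (emitting compartment).
#' @export
simulate_reads <- function(annot, truth, cfg, sample_id, species,
                           seed = NULL) {
  stopifnot(species %in% cfg$species)
  if (is.null(seed))
    seed <- (cfg$seed * 131L + sum(utf8ToInt(sample_id))) %% .Machine$integer.max
  set.seed(seed)
  loci <- .read_loci(annot, truth, cfg)
  ## genome-wide graded divergence: per-gene species factors shared by all
  ## samples of one species
  if (!is.null(truth$species_factors) && species %in%
        colnames(truth$species_factors)) {
    sf <- truth$species_factors[, species]
    hit <- !is.na(loci$gene)
    loci$weight[hit] <- loci$weight[hit] * sf[loci$gene[hit]]
  }
  ## species multiplier on planted species-specific genes and igHTR units
  ss <- truth$species_specific
  if (nrow(ss)) {
    hit <- !is.na(loci$gene) & loci$gene %in% ss$gene_id[ss$species == species]
    loci$weight[hit] <- loci$weight[hit] *
      ss$fold[match(loci$gene[hit], ss$gene_id)]
  }
  ssu <- truth$species_specific_ightr
  if (!is.null(ssu) && nrow(ssu)) {
    tgt <- sprintf("p_%04d", ssu$unit[ssu$species == species])
    hit <- loci$unit %in% tgt
    loci$weight[hit] <- loci$weight[hit] *
      ssu$fold[match(loci$unit[hit], sprintf("p_%04d", ssu$unit))]
  }
  ## per-unit Gamma multiplier -> unit totals are NB(mean, 1/phi)
  units <- unique(loci$unit)
  phi <- cfg$nb_dispersion
  gamma_u <- if (phi > 0)
    stats::rgamma(length(units), shape = 1 / phi, scale = phi) else
    rep(1, length(units))
  lambda <- loci$weight * gamma_u[match(loci$unit, units)]
  counts <- rpois(nrow(loci), lambda)

  L <- cfg$library_size
  n_rrna <- as.integer(round(cfg$rrna_fraction * L))
  n_rest <- L - n_rrna
  read_locus <- rep.int(seq_len(nrow(loci)), counts)
  if (length(read_locus) > n_rest) {
    read_locus <- read_locus[sort(sample.int(length(read_locus), n_rest))]
  } else if (length(read_locus) < n_rest) {
    # top-up follows the realized per-locus rates (Gamma multipliers
    # included), so the NB dispersion of unit totals is preserved
    extra <- sample.int(nrow(loci), n_rest - length(read_locus),
                        replace = TRUE, prob = lambda)
    read_locus <- c(read_locus, extra)
  }
  rlen <- cfg$read_length
  w <- loci$end[read_locus] - loci$start[read_locus] + 1L
  eff <- pmin(rlen, w)
  starts <- loci$start[read_locus] +
    as.integer(floor(runif(length(read_locus)) * (w - eff + 1L)))
  reads <- GenomicRanges::GRanges(loci$ctg[read_locus],
                                  IRanges::IRanges(starts, width = eff))
  reads$src <- loci$src[read_locus]

  ## rRNA reads, placed uniformly across rRNA loci
  if (n_rrna > 0 && length(annot$rrna)) {
    rw <- BiocGenerics::width(annot$rrna)
    li <- sample.int(length(annot$rrna), n_rrna, replace = TRUE, prob = rw)
    eff_r <- pmin(rlen, rw[li])
    st <- BiocGenerics::start(annot$rrna)[li] +
      as.integer(floor(runif(n_rrna) * (rw[li] - eff_r + 1L)))
    rr <- GenomicRanges::GRanges(
      as.character(GenomicRanges::seqnames(annot$rrna))[li],
      IRanges::IRanges(st, width = eff_r))
    rr$src <- "rrna"
    reads <- c(reads, rr)
  }
  n <- length(reads)
  reads$sample_id <- sample_id
  reads$n_locations <- 1L
  multi <- runif(n) < cfg$multimap_fraction
  reads$n_locations[multi] <- sample(2:100, sum(multi), replace = TRUE)
  reads$is_junction <- reads$src == "exon" & runif(n) < cfg$junction_fraction
  sort_intervals(reads)
}

#' Simulate ESTs, alignment blocks and a conservation track
#'
#' Builds the ancillary evidence layers: spliced ESTs covering a fraction of
#' planted igHTR (plus ESTs bridging consecutive units of a cluster, ESTs
#' linking a gene's 3'-terminal exon to its downstream planted cluster, and
#' unrelated gene ESTs); three-species colinear alignment blocks covering a
#' fraction of the main contig with per-species coordinate drift; and a
#' per-base conservation track elevated at exons > planted igHTR >
#' background.
#'
#' @param annot,truth Output of [simulate_genome()].
#' @param cfg The [simulation_config()].
#' @param seed Integer seed (default `cfg$seed + 7`).
#' @return List with `ests` (`GRangesList`), `blocks` (`AlignmentBlockSet`),
#'   `conservation` (`ConservationTrack`), and `est_truth` (data frame of
#'   which planted units got direct EST support).
#' @export
simulate_ancillary <- function(annot, truth, cfg, seed = NULL) {
  if (is.null(seed)) seed <- (cfg$seed + 7L) %% .Machine$integer.max
  set.seed(seed)
  pl <- truth$planted_ightr
  ests <- list()
  supported <- integer(0)

  ## direct support: single-block ESTs over a fraction of planted units
  if (length(pl) && cfg$est_support_fraction > 0) {
    n_sup <- round(cfg$est_support_fraction * length(pl))
    supported <- sort(sample(seq_along(pl), n_sup))
    for (i in supported) {
      g <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
        max(1, BiocGenerics::start(pl)[i] - 100L),
        BiocGenerics::end(pl)[i] + 100L))
      ests[[sprintf("est_sup_%04d", i)]] <- g
    }
  }
  ## bridges: spliced ESTs whose two blocks cover consecutive cluster units
  if (length(pl) && cfg$est_bridge_fraction > 0) {
    cl <- split(seq_along(pl), pl$cluster)
    cl <- cl[lengths(cl) >= 2]
    if (length(cl)) {
      n_br <- max(1, round(cfg$est_bridge_fraction * length(cl)))
      pick <- sample(names(cl), min(n_br, length(cl)))
      for (cn in pick) {
        i <- cl[[cn]][1]; j <- cl[[cn]][2]
        g <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
          c(BiocGenerics::start(pl)[i], BiocGenerics::start(pl)[j]),
          c(BiocGenerics::end(pl)[i], BiocGenerics::end(pl)[j])))
        ests[[paste0("est_bridge_", cn)]] <- BiocGenerics::sort(g)
      }
    }
  }
  ## gene-3' connections for 3'-UTR-extension clusters
  utr3 <- which(pl$type == "utr3_extension" & !is.na(pl$near_gene))
  if (length(utr3) && cfg$utr3_connect_fraction > 0) {
    first_units <- utr3[!duplicated(pl$cluster[utr3])]
    n_con <- round(cfg$utr3_connect_fraction * length(first_units))
    if (n_con > 0) for (i in sample(first_units, n_con)) {
      gid <- pl$near_gene[i]
      ex <- annot$exons[annot$exons$gene_id == gid]
      term <- if (as.character(BiocGenerics::strand(ex))[1] == "+")
        ex[which.max(BiocGenerics::end(ex))] else
        ex[which.min(BiocGenerics::start(ex))]
      ## the unit of this cluster nearest the gene
      cl_units <- which(pl$cluster == pl$cluster[i])
      d <- pmin(abs(BiocGenerics::start(pl)[cl_units] - BiocGenerics::end(term)),
                abs(BiocGenerics::end(pl)[cl_units] - BiocGenerics::start(term)))
      u <- cl_units[which.min(d)]
      g <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
        c(BiocGenerics::start(term), BiocGenerics::start(pl)[u]),
        c(BiocGenerics::end(term), BiocGenerics::end(pl)[u])))
      ests[[paste0("est_utr3_", pl$cluster[i])]] <- BiocGenerics::sort(g)
    }
  }
  ## background ESTs over random genes (2-3 consecutive exons)
  if (cfg$n_background_ests > 0 && length(annot$genes)) {
    gids <- sample(annot$genes$gene_id, cfg$n_background_ests, replace = TRUE)
    for (k in seq_along(gids)) {
      ex <- BiocGenerics::sort(annot$exons[annot$exons$gene_id == gids[k]])
      nb <- min(length(ex), sample(2:3, 1))
      st <- sample.int(length(ex) - nb + 1L, 1)
      ests[[sprintf("est_bg_%04d", k)]] <-
        GenomicRanges::granges(ex[st:(st + nb - 1L)])
    }
  }
  ests <- methods::as(ests, "GRangesList")

  ## --- alignment blocks with per-species drift
  main_len <- annot$contig_lengths[["chr1"]]
  cov <- cfg$alignment_coverage
  blocks <- .simulate_blocks(main_len, cov, cfg$species)

  ## --- conservation: 1-kb piecewise base with exon/igHTR elevation
  track <- .simulate_conservation(annot, truth, cfg)

  list(ests = ests, blocks = blocks, conservation = track,
       est_truth = data.frame(unit = supported))
}

.simulate_blocks <- function(main_len, coverage, species) {
  if (coverage <= 0) {
    return(alignment_block_set_from_table(
      data.frame(block = integer(), species = character(),
                 contig = character(), start = integer(), end = integer())))
  }
  pos <- 1
  starts <- integer(0); ends <- integer(0)
  while (pos < main_len) {
    len <- sample(10000:30000, 1)
    gap <- if (coverage >= 1) 0L else
      as.integer(round(len * (1 - coverage) / coverage *
                         runif(1, 0.5, 1.5)))
    end <- min(pos + len - 1L, main_len)
    starts <- c(starts, pos); ends <- c(ends, end)
    pos <- end + 1L + gap
  }
  nb <- length(starts)
  rows <- list()
  for (si in seq_along(species)) {
    drift <- if (si == 1) rep(0L, nb) else
      cumsum(sample(-200:200, nb, replace = TRUE)) + si * 10000L
    rows[[si]] <- data.frame(block = seq_len(nb), species = species[si],
                             contig = "chr1",
                             start = starts - 1L + drift,
                             end = ends + drift)
  }
  df <- do.call(rbind, rows)
  ## drift could in principle make consecutive target blocks overlap; nudge
  for (si in seq_along(species)[-1]) {
    sel <- df$species == species[si]
    d <- df[sel, ]
    for (k in seq_len(nrow(d) - 1)) {
      if (d$start[k + 1] <= d$end[k]) {
        shift <- d$end[k] - d$start[k + 1] + 1L
        d$start[(k + 1):nrow(d)] <- d$start[(k + 1):nrow(d)] + shift
        d$end[(k + 1):nrow(d)] <- d$end[(k + 1):nrow(d)] + shift
      }
    }
    df[sel, ] <- d
  }
  alignment_block_set_from_table(df, reference = species[1])
}

.simulate_conservation <- function(annot, truth, cfg) {
  jit <- function(n, mu) pmin(1, pmax(0, mu + stats::rnorm(n, 0, 0.02)))
  out <- lapply(names(annot$contig_lengths), function(ctg) {
    len <- annot$contig_lengths[[ctg]]
    ntile <- ceiling(len / 1000)
    base <- rep(jit(ntile, cfg$cons_base), each = 1000)[seq_len(len)]
    v <- S4Vectors::Rle(base)
    paint <- function(v, gr, mu) {
      g <- gr[as.character(GenomicRanges::seqnames(gr)) == ctg]
      if (length(g) == 0) return(v)
      g <- GenomicRanges::reduce(g, ignore.strand = TRUE)
      for (i in seq_along(g)) {
        s <- BiocGenerics::start(g)[i]; e <- min(BiocGenerics::end(g)[i], len)
        v[s:e] <- S4Vectors::Rle(jit(e - s + 1, mu))
      }
      v
    }
    v <- paint(v, truth$planted_ightr, cfg$cons_ightr)
    v <- paint(v, annot$categories$exon, cfg$cons_exon)
    v
  })
  names(out) <- names(annot$contig_lengths)
  class(out) <- "ConservationTrack"
  out
}
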
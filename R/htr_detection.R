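#' HTR caller parameters
#'
#' @param maxspacing Maximum allowed gap between neighbouring reads on a
#'   chain, in nt (default 150). The gap is measured end-to-start (true
#'   inter-read gap); set `spacing_mode = "start_to_start"` for the
#'   start-to-start variant.
#' @param minhits Minimum number of reads in a region (default 10).
#' @param spacing_mode `"end_to_start"` (default) or `"start_to_start"`.
#' @return An `HTRParams` list.
#' @export
htr_params <- function(maxspacing = 150L, minhits = 10L,
                       spacing_mode = c("end_to_start", "start_to_start")) {
  stopifnot(maxspacing >= 0, minhits >= 1)
  out <- list(maxspacing = as.integer(maxspacing),
              minhits = as.integer(minhits),
              spacing_mode = match.arg(spacing_mode))
  class(out) <- "HTRParams"
  out
}

#' Call highly transcribed regions (HTR)
#'
#' Chains reads along each contig, 5' to 3' on the forward strand: a chain
#' breaks when the gap to the next read exceeds `maxspacing` (a gap exactly
#' equal to `maxspacing` still chains). Chains with at least `minhits` reads
#' are emitted; region boundaries run from the 5'-most read start to the
#' 3'-most read end among member reads.
#'
#' @param reads `GRanges` of one sample's filtered, uniquely mapped reads
#'   (sorted internally if needed).
#' @param params An [htr_params()].
#' @param sample_id Sample label carried on the output (default taken from
#'   the reads' `sample_id` mcol when unique).
#' @return `GRanges` of HTRs with mcols `read_count`, `expression_level`
#'   (reads per nt), `sample_id`.
#' @export
call_htr <- function(reads, params = htr_params(), sample_id = NULL) {
  if (is.null(sample_id))
    sample_id <- if (!is.null(reads$sample_id) &&
                     length(unique(reads$sample_id)) == 1)
      unique(reads$sample_id) else NA_character_
  if (length(reads) == 0) {
    out <- GenomicRanges::GRanges()
    out$read_count <- integer(0); out$expression_level <- numeric(0)
    out$sample_id <- character(0)
    return(out)
  }
  reads <- sort_intervals(reads)
  ctg <- as.character(GenomicRanges::seqnames(reads))
  s <- BiocGenerics::start(reads); e <- BiocGenerics::end(reads)
  n <- length(reads)
  ## gap between read i and i+1; running max of ends handles contained reads
  run_end <- cummax_by(e, ctg)
  gap <- if (params$spacing_mode == "end_to_start")
    s[-1] - run_end[-n] - 1L else s[-1] - s[-n]
  new_chain <- c(TRUE, ctg[-1] != ctg[-n] | gap > params$maxspacing)
  chain <- cumsum(new_chain)
  cnt <- tabulate(chain)
  keep <- cnt >= params$minhits
  if (!any(keep)) {
    out <- GenomicRanges::GRanges()
    out$read_count <- integer(0); out$expression_level <- numeric(0)
    out$sample_id <- character(0)
    return(out)
  }
  st <- tapply(s, chain, min)[keep]
  en <- tapply(e, chain, max)[keep]
  cg <- tapply(ctg, chain, `[`, 1)[keep]
  out <- GenomicRanges::GRanges(as.character(cg),
                                IRanges::IRanges(as.integer(st),
                                                 as.integer(en)))
  out$read_count <- cnt[keep]
  out$expression_level <- out$read_count / BiocGenerics::width(out)
  out$sample_id <- sample_id
  out
}

# Running maximum within contig groups.
cummax_by <- function(x, g) stats::ave(x, g, FUN = cummax)

#' Flag intergenic HTR (igHTR)
#'
#' An HTR qualifies as igHTR when it lies entirely within intergenic space
#' (gene spans of protein-coding genes, non-coding genes and pseudogenes
#' excluded) and overlaps no annotated transcript from the exclusion track.
#' Non-igHTR keep their hierarchy category.
#'
#' @param htrs `GRanges` from [call_htr()].
#' @param annot An `AnnotationSet` (uses `transcript_exclusion`).
#' @return `htrs` with added mcols `is_ightr` (logical) and `category` (the
#'   hierarchy label of the region, by its span).
#' @export
classify_ightr <- function(htrs, annot) {
  ig_space <- annot$categories$intergenic
  if (length(htrs) == 0) {
    htrs$is_ightr <- logical(0); htrs$category <- character(0)
    return(htrs)
  }
  within_ig <- GenomicRanges::countOverlaps(htrs, ig_space, type = "within",
                                            ignore.strand = TRUE) > 0
  excl <- IRanges::overlapsAny(htrs, annot$transcript_exclusion,
                               ignore.strand = TRUE)
  htrs$is_ightr <- within_ig & !excl
  htrs$category <- assign_read_category(GenomicRanges::granges(htrs), annot)
  htrs
}

#' Unify HTR across samples
#'
#' Single-linkage merges HTRs from several samples that overlap by at least
#' one nucleotide (cross-species HTRs must be projected to the reference
#' coordinates first; see [project_intervals()]). Unified boundaries are the
#' 5'-most and 3'-most coordinates among contributing samples; per-sample
#' read counts are recomputed within the unified boundaries when read sets
#' are supplied.
#'
#' @param per_sample Named list of `GRanges` (HTR calls per sample).
#' @param reads_by_sample Optional named list of read `GRanges` used to
#'   recount within unified boundaries; otherwise member HTR counts are
#'   summed.
#' @return `GRanges` of unified HTRs with a count mcol per sample and
#'   `n_samples` (number of samples contributing an HTR).
#' @export
unify_htr_across_samples <- function(per_sample, reads_by_sample = NULL) {
  stopifnot(!is.null(names(per_sample)))
  all_htr <- do.call(c, lapply(names(per_sample), function(sn) {
    g <- GenomicRanges::granges(per_sample[[sn]])
    g$from <- sn
    g$orig_count <- per_sample[[sn]]$read_count %||% rep(NA_integer_,
                                                          length(g))
    g
  }))
  if (length(all_htr) == 0) return(GenomicRanges::GRanges())
  merged <- GenomicRanges::reduce(all_htr, min.gapwidth = 0L,
                                  ignore.strand = TRUE)
  hits <- GenomicRanges::findOverlaps(all_htr, merged, ignore.strand = TRUE)
  memb <- S4Vectors::subjectHits(hits)
  for (sn in names(per_sample)) {
    if (!is.null(reads_by_sample)) {
      cnt <- GenomicRanges::countOverlaps(merged, reads_by_sample[[sn]],
                                          ignore.strand = TRUE)
    } else {
      sel <- all_htr$from == sn
      cnt <- integer(length(merged))
      agg <- tapply(all_htr$orig_count[sel], memb[sel], sum)
      cnt[as.integer(names(agg))] <- as.integer(agg)
    }
    S4Vectors::mcols(merged)[[paste0("count_", sn)]] <- cnt
  }
  pres <- table(factor(memb[!duplicated(paste(memb, all_htr$from))],
                       levels = seq_along(merged)))
  merged$n_samples <- as.integer(pres)
  merged
}

#' Cluster igHTR and assign nearest genes
#'
#' Clusters are maximal groups of two or more igHTR sharing one intergenic
#' region (optionally capped by a maximum within-cluster spacing). Each
#' igHTR is assigned its nearest gene, the distance to it, the gene side it
#' sits on (3' or 5', by gene strand) and a within-`near_gene_distance`
#' flag.
#'
#' @param ightrs `GRanges` of igHTR.
#' @param annot An `AnnotationSet`.
#' @param near_gene_distance Proximity window in nt (default 10000).
#' @param max_cluster_gap Optional cap on the gap between cluster members
#'   (default `Inf` = same intergenic region suffices).
#' @return List with `ightrs` (input plus mcols `cluster` (NA when
#'   unclustered), `nearest_gene`, `gene_distance`, `gene_side`,
#'   `within_near`) and `clusters` (data frame `cluster`, `n_members`).
#' @export
cluster_and_assign_genes <- function(ightrs, annot,
                                     near_gene_distance = 10000L,
                                     max_cluster_gap = Inf) {
  ig_space <- intergenic_space(annot)
  n <- length(ightrs)
  region <- GenomicRanges::findOverlaps(ightrs, ig_space,
                                        ignore.strand = TRUE,
                                        select = "first")
  ord <- order(region, BiocGenerics::start(ightrs))
  cluster <- rep(NA_integer_, n)
  cid <- 0L
  i <- 1
  while (i <= length(ord)) {
    j <- i
    while (j < length(ord) && !is.na(region[ord[j + 1]]) &&
           identical(region[ord[j + 1]], region[ord[i]]) &&
           (BiocGenerics::start(ightrs)[ord[j + 1]] -
              BiocGenerics::end(ightrs)[ord[j]] - 1) <= max_cluster_gap)
      j <- j + 1
    if (j > i && !is.na(region[ord[i]])) {
      cid <- cid + 1L
      cluster[ord[i:j]] <- cid
    }
    i <- j + 1
  }
  ightrs$cluster <- cluster

  genes <- annot$genes
  if (length(genes) == 0) {
    ightrs$nearest_gene <- NA_character_
    ightrs$gene_distance <- NA_real_
    ightrs$gene_side <- NA_character_
    ightrs$within_near <- NA
  } else {
    nst <- GenomicRanges::distanceToNearest(ightrs, genes,
                                            ignore.strand = TRUE)
    gi <- rep(NA_integer_, n); dist <- rep(NA_real_, n)
    gi[S4Vectors::queryHits(nst)] <- S4Vectors::subjectHits(nst)
    dist[S4Vectors::queryHits(nst)] <- S4Vectors::mcols(nst)$distance
    ightrs$nearest_gene <- ifelse(is.na(gi), NA_character_,
                                  genes$gene_id[gi])
    ightrs$gene_distance <- dist
    gstrand <- as.character(BiocGenerics::strand(genes))[gi]
    downstream <- BiocGenerics::start(ightrs) >
      BiocGenerics::end(genes)[pmax(gi, 1L)]
    ightrs$gene_side <- ifelse(is.na(gi), NA_character_,
      ifelse((downstream & gstrand == "+") | (!downstream & gstrand == "-"),
             "3prime", "5prime"))
    ightrs$within_near <- dist <= near_gene_distance
  }
  cl_tab <- if (all(is.na(cluster)))
    data.frame(cluster = integer(), n_members = integer()) else
    setNames(as.data.frame(table(cluster), stringsAsFactors = FALSE),
             c("cluster", "n_members"))
  list(ightrs = ightrs, clusters = cl_tab)
}

#' Equal-read genomic windows over the consensus alignment
#'
#' Groups reads from all species (in reference/consensus coordinates,
#' restricted to alignment-covered regions) into consecutive runs of exactly
#' `n_per_window` reads; the trailing remainder is dropped. Window
#' boundaries snap to the first and last member read.
#'
#' @param reads_by_species Named list of `GRanges`, reads per species in
#'   consensus coordinates.
#' @param blocks An `AlignmentBlockSet`; reads outside its reference
#'   coverage are excluded (pass `NULL` to skip the restriction).
#' @param n_per_window Reads per window (default 50).
#' @param reference Reference species name for the coverage restriction.
#' @return `GRanges` of windows with per-species count mcols and
#'   `total_reads` (always exactly `n_per_window`).
#' @export
equal_read_windows <- function(reads_by_species, blocks = NULL,
                               n_per_window = 50L, reference = NULL) {
  stopifnot(!is.null(names(reads_by_species)))
  all_reads <- do.call(c, lapply(names(reads_by_species), function(sp) {
    g <- GenomicRanges::granges(reads_by_species[[sp]])
    g$species <- sp
    g
  }))
  if (!is.null(blocks)) {
    if (is.null(reference)) reference <- blocks$species[1]
    cov <- GenomicRanges::reduce(blocks$ivs[[reference]])
    all_reads <- all_reads[IRanges::overlapsAny(all_reads, cov,
                                                ignore.strand = TRUE)]
  }
  if (length(all_reads) < n_per_window) {
    warning("fewer than ", n_per_window, " reads; no windows emitted")
    out <- GenomicRanges::GRanges()
    out$total_reads <- integer(0)
    return(out)
  }
  all_reads <- sort_intervals(all_reads)
  ## windows never span contigs: group per contig, drop remainder per contig
  ctg <- as.character(GenomicRanges::seqnames(all_reads))
  out <- list()
  for (cc in unique(ctg)) {
    r <- all_reads[ctg == cc]
    nwin <- length(r) %/% n_per_window
    if (nwin == 0) next
    idx <- rep(seq_len(nwin), each = n_per_window)
    r <- r[seq_len(nwin * n_per_window)]
    st <- tapply(BiocGenerics::start(r), idx, min)
    en <- tapply(BiocGenerics::end(r), idx, max)
    g <- GenomicRanges::GRanges(cc, IRanges::IRanges(as.integer(st),
                                                     as.integer(en)))
    for (sp in names(reads_by_species))
      S4Vectors::mcols(g)[[paste0("count_", sp)]] <-
        as.integer(tapply(r$species == sp, idx, sum))
    g$total_reads <- n_per_window
    out[[cc]] <- g
  }
  if (length(out) == 0) {
    warning("no contig held ", n_per_window, " reads; no windows emitted")
    g <- GenomicRanges::GRanges(); g$total_reads <- integer(0)
    return(g)
  }
  suppressWarnings(do.call(c, unname(out)))  # per-contig seqlevels differ
}
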
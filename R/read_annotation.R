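#' Assign reads to annotation categories by the fixed hierarchy
#'
#' Each read receives the highest-precedence category (see
#' [category_hierarchy()]) whose genomic track it overlaps by at least one
#' nucleotide, strand ignored. Junction-flagged reads are assigned to exons
#' unconditionally. Reads are assumed to have passed rRNA exclusion
#' ([filter_reads()]).
#'
#' @param reads `GRanges` of reads (mcol `is_junction` honoured if present).
#' @param annot An `AnnotationSet`.
#' @return Character vector of category labels, parallel to `reads`.
#' @export
assign_read_category <- function(reads, annot) {
  ctgs <- unique(as.character(GenomicRanges::seqnames(reads)))
  known <- unique(unlist(lapply(annot$categories, function(g)
    as.character(GenomicRanges::seqnames(g)))))
  bad <- setdiff(ctgs, c(known, names(annot$contig_lengths)))
  if (length(bad))
    stop("annotation error: contig(s) absent from annotation: ",
         paste(bad, collapse = ", "))
  cat_out <- rep(NA_character_, length(reads))
  for (cat_ in CATEGORY_HIERARCHY) {
    open <- is.na(cat_out)
    if (!any(open)) break
    # disjoint seqlevels (e.g. chr1 reads vs the chrM-only mito track) mean
    # "no overlap", which is exactly the semantics wanted here
    hit <- suppressWarnings(
      IRanges::overlapsAny(reads[open], annot$categories[[cat_]],
                           ignore.strand = TRUE))
    cat_out[which(open)[hit]] <- cat_
  }
  if (!is.null(reads$is_junction))
    cat_out[reads$is_junction] <- "exon"
  cat_out
}

#' Filter reads: rRNA exclusion, uniqueness, subsampling
#'
#' Removes reads overlapping any rRNA locus (regardless of mapping
#' uniqueness), restricts to uniquely mapped reads or to reads with at most
#' `max_locations` placements, and optionally subsamples a fixed number of
#' reads without replacement for library-size equalisation across samples.
#'
#' @param reads `GRanges` with `n_locations` mcol.
#' @param annot An `AnnotationSet` (provides the rRNA track).
#' @param unique_only Keep only `n_locations == 1` reads (default TRUE).
#' @param max_locations When `unique_only = FALSE`, keep reads with at most
#'   this many placements (default 100).
#' @param subsample_n Subsample exactly this many surviving reads (default
#'   `NULL` = keep all). Sample libraries are equalised by subsampling each
#'   to the size of the smallest (1,500,000 in the original study design).
#' @param seed Seed for the subsample draw.
#' @return Filtered (and possibly subsampled) `GRanges`, sorted.
#' @export
filter_reads <- function(reads, annot, unique_only = TRUE,
                         max_locations = 100L, subsample_n = NULL,
                         seed = 1L) {
  keep <- !IRanges::overlapsAny(reads, annot$rrna, ignore.strand = TRUE)
  nl <- if (!is.null(reads$n_locations)) reads$n_locations else
    rep(1L, length(reads))
  keep <- keep & if (unique_only) nl == 1L else nl <= max_locations
  out <- reads[keep]
  if (!is.null(subsample_n)) {
    if (subsample_n > length(out))
      stop("argument error: subsample_n (", subsample_n,
           ") exceeds surviving read count (", length(out), ")")
    set.seed(seed)
    out <- out[sort(sample.int(length(out), subsample_n))]
  }
  sort_intervals(out)
}

#' Transcriptome composition summary
#'
#' Summarises per-category read proportions (mode `"reads"`: one assignment
#' per read by the hierarchy) or per-category proportions of genomic bases
#' covered by at least one read (mode `"covered_nucleotides"`: the union of
#' read footprints is computed first, then each covered base is labelled by
#' the same hierarchy). Genome per-category fractions are reported
#' alongside for comparison.
#'
#' @param reads Filtered `GRanges` of reads.
#' @param annot An `AnnotationSet`.
#' @param mode `"reads"` or `"covered_nucleotides"`.
#' @return A `CompositionSummary`: data frame with columns `category`,
#'   `count`, `proportion`, `genome_fraction`; attribute `mode`; attribute
#'   `empty` flags an empty read set (proportions `NaN`).
#' @export
composition_summary <- function(reads, annot,
                                mode = c("reads", "covered_nucleotides")) {
  mode <- match.arg(mode)
  if (mode == "reads") {
    lab <- assign_read_category(reads, annot)
    counts <- vapply(CATEGORY_HIERARCHY, function(cc) sum(lab == cc),
                     numeric(1))
  } else {
    covered <- GenomicRanges::reduce(GenomicRanges::granges(reads),
                                     ignore.strand = TRUE)
    remaining <- covered
    counts <- numeric(length(CATEGORY_HIERARCHY))
    names(counts) <- CATEGORY_HIERARCHY
    for (cat_ in CATEGORY_HIERARCHY) {
      # disjoint seqlevels (chr1-only footprints vs the chrM track) mean an
      # empty intersection, which is the semantics wanted
      hit <- suppressWarnings(
        GenomicRanges::intersect(remaining, annot$categories[[cat_]],
                                 ignore.strand = TRUE))
      counts[cat_] <- sum(as.numeric(BiocGenerics::width(hit)))
      remaining <- GenomicRanges::setdiff(remaining, hit,
                                          ignore.strand = TRUE)
    }
  }
  lens <- category_lengths(annot)
  out <- data.frame(category = CATEGORY_HIERARCHY,
                    count = as.numeric(counts),
                    proportion = counts / sum(counts),
                    genome_fraction = lens / sum(lens),
                    row.names = NULL)
  attr(out, "mode") <- mode
  attr(out, "empty") <- sum(counts) == 0
  class(out) <- c("CompositionSummary", "data.frame")
  out
}

#' Fraction of repeat-assigned reads not fully inside repeat elements
#'
#' The hierarchy assigns a read to a repeat category on a single overlapping
#' nucleotide; this reports how often that assignment is partial (the read
#' is not wholly contained in repeat space), a bound on the annotation bias
#' the precedence rule introduces.
#'
#' @param reads Filtered `GRanges`.
#' @param annot An `AnnotationSet`.
#' @return List with `fraction_partial` and `n_repeat_reads`.
#' @export
repeat_assignment_bias <- function(reads, annot) {
  lab <- assign_read_category(reads, annot)
  rep_reads <- reads[lab %in% c("intronic_repeat", "intergenic_repeat")]
  if (length(rep_reads) == 0)
    return(list(fraction_partial = NA_real_, n_repeat_reads = 0L))
  rep_space <- GenomicRanges::reduce(c(annot$categories$intronic_repeat,
                                       annot$categories$intergenic_repeat))
  ov <- GenomicRanges::countOverlaps(rep_reads, rep_space, type = "within",
                                     ignore.strand = TRUE)
  list(fraction_partial = mean(ov == 0), n_repeat_reads = length(rep_reads))
}
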
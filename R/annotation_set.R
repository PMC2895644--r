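#' Construct an AnnotationSet
#'
#' Bundles the layered annotation tracks the read-annotation hierarchy
#' consumes: one interval track per category in [category_hierarchy()], an
#' rRNA exclusion track, a transcript-exclusion track (all annotated
#' transcripts, used to disqualify igHTR), and the gene records.
#'
#' @param categories Named list of `GRanges`, one per category, in any order;
#'   all seven hierarchy categories must be present (empty `GRanges` allowed).
#' @param rrna `GRanges` of rRNA loci (reads touching these are excluded).
#' @param transcript_exclusion `GRanges` of all annotated transcripts.
#' @param genes `GRanges` of gene spans with mcols `gene_id` and strand set.
#' @param exons `GRanges` of exons with mcol `gene_id`; exons of one gene
#'   must be disjoint.
#' @param contig_lengths Named integer vector of contig lengths.
#' @return An `AnnotationSet` (S3 list).
#' @export
annotation_set <- function(categories, rrna = GenomicRanges::GRanges(),
                           transcript_exclusion = GenomicRanges::GRanges(),
                           genes = GenomicRanges::GRanges(),
                           exons = GenomicRanges::GRanges(),
                           contig_lengths = integer()) {
  missing <- setdiff(CATEGORY_HIERARCHY, names(categories))
  if (length(missing))
    stop("annotation error: missing category track(s): ",
         paste(missing, collapse = ", "))
  categories <- categories[CATEGORY_HIERARCHY]  # store in hierarchy order
  if (length(exons) && !is.null(exons$gene_id)) {
    by_gene <- split(IRanges::ranges(exons), exons$gene_id)
    disj <- vapply(by_gene, function(r)
      sum(BiocGenerics::width(IRanges::reduce(r))) == sum(BiocGenerics::width(r)),
      logical(1))
    if (!all(disj))
      stop("annotation error: overlapping exons within gene(s): ",
           paste(names(by_gene)[!disj], collapse = ", "))
  }
  out <- list(categories = categories, rrna = rrna,
              transcript_exclusion = transcript_exclusion,
              genes = genes, exons = exons,
              contig_lengths = contig_lengths)
  class(out) <- "AnnotationSet"
  out
}

#' @export
print.AnnotationSet <- function(x, ...) {
  cat("AnnotationSet:", sum(lengths(x$categories)), "category intervals,",
      length(x$genes), "genes,", length(x$rrna), "rRNA loci\n")
  lens <- category_lengths(x)
  for (cat_ in names(lens))
    cat(sprintf("  %-18s %12.0f nt\n", cat_, lens[[cat_]]))
  invisible(x)
}

#' Genomic length of each annotation category
#' @param annot An `AnnotationSet`.
#' @return Named numeric vector of total nucleotides per category.
#' @export
category_lengths <- function(annot) {
  vapply(annot$categories, function(g)
    sum(as.numeric(BiocGenerics::width(GenomicRanges::reduce(g)))),
    numeric(1))
}

#' Intergenic space of an annotation
#'
#' The complement of gene spans (plus ncRNA, mito and rRNA loci) within the
#' contigs: where igHTR may live and where matched random regions are placed.
#'
#' @param annot An `AnnotationSet`.
#' @return `GRanges` of the intergenic track (repeat space included; the
#'   `intergenic` category track itself excludes intergenic repeats).
#' @export
intergenic_space <- function(annot) {
  GenomicRanges::reduce(c(annot$categories$intergenic,
                          annot$categories$intergenic_repeat))
}
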
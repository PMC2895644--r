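#' Build a gene expression count/rate matrix
#'
#' Counts uniquely mapped exonic reads per gene and sample (junction reads
#' excluded, since exon boundaries may not match across genomes), computes
#' rates as count per nt of exonic length, and keeps genes detected (count
#' >= 1) in at least `detected_in_min` samples.
#'
#' @param reads_by_sample Named list of filtered read `GRanges`.
#' @param annot An `AnnotationSet` (uses `exons`).
#' @param detected_in_min Detection threshold across samples (default 2).
#' @return List with `counts` (genes x samples integer matrix), `rates`
#'   (counts / exonic length), `exonic_length` (named vector), and
#'   `dropped_zero_length` (gene ids excluded for zero exonic length).
#' @export
build_expression_matrix <- function(reads_by_sample, annot,
                                    detected_in_min = 2L) {
  stopifnot(!is.null(names(reads_by_sample)))
  ex <- annot$exons
  exlen <- vapply(split(BiocGenerics::width(ex), ex$gene_id), sum, numeric(1))
  zero <- names(exlen)[exlen == 0]
  gene_ids <- setdiff(names(exlen), zero)
  counts <- sapply(reads_by_sample, function(r) {
    if (!is.null(r$is_junction)) r <- r[!r$is_junction]
    hits <- GenomicRanges::findOverlaps(r, ex, ignore.strand = TRUE)
    ## a read overlapping several exons of one gene counts once for it
    gid <- ex$gene_id[S4Vectors::subjectHits(hits)]
    uq <- !duplicated(paste(S4Vectors::queryHits(hits), gid))
    tab <- table(factor(gid[uq], levels = gene_ids))
    as.integer(tab)
  })
  rownames(counts) <- gene_ids
  keep <- rowSums(counts >= 1) >= detected_in_min
  counts <- counts[keep, , drop = FALSE]
  rates <- counts / exlen[rownames(counts)]
  list(counts = counts, rates = rates, exonic_length = exlen[gene_ids],
       dropped_zero_length = zero)
}

#' Quantile normalization across samples
#'
#' Makes the value distribution of every column identical: each column's
#' sorted values are replaced by the across-column mean of sorted values;
#' ties receive the average of their would-be quantile values.
#'
#' @param mat Numeric matrix (rows = loci, columns = samples; >= 2 columns).
#' @return Normalized matrix of the same shape.
#' @export
quantile_normalize <- function(mat) {
  stopifnot(is.matrix(mat), ncol(mat) >= 2)
  limma::normalizeQuantiles(mat, ties = TRUE)
}

#' Expression divergence distance between samples
#'
#' Pairwise sample divergence under Euclidean distance, Manhattan distance,
#' or 1 - rho (Spearman correlation, average ranks for ties). Optional
#' Z-transform standardises each row (locus) to mean 0, sd 1 across samples
#' first, removing expression-level influence.
#'
#' @param mat Normalized rate matrix (loci x samples).
#' @param measure `"euclidean"`, `"manhattan"`, or `"one_minus_rho"`.
#' @param z_transform Standardise rows first (default FALSE). Constant rows
#'   (sd 0) are dropped with a message.
#' @return Symmetric sample x sample distance matrix with zero diagonal.
#' @export
expression_distance <- function(mat, measure = c("euclidean", "manhattan",
                                                 "one_minus_rho"),
                                z_transform = FALSE) {
  measure <- match.arg(measure)
  if (z_transform) {
    sds <- apply(mat, 1, sd)
    if (any(sds == 0)) {
      message(sum(sds == 0), " constant row(s) dropped before Z-transform")
      mat <- mat[sds > 0, , drop = FALSE]
      sds <- sds[sds > 0]
    }
    mat <- (mat - rowMeans(mat)) / sds
  }
  if (measure == "one_minus_rho") {
    if (any(apply(mat, 2, function(x) length(unique(x))) == 1))
      stop("correlation undefined: constant column")
    d <- 1 - cor(mat, method = "spearman")
    diag(d) <- 0
    return(d)
  }
  as.matrix(dist(t(mat), method = measure))
}

#' UPGMA tree with gene-bootstrap node support
#'
#' Average-linkage agglomeration over the sample divergence matrix yields an
#' ultrametric tree; support for each internal bipartition is the fraction
#' of `B` trees built from row (gene) resamples that contain it. Ties in the
#' minimal distance merge the lexicographically smallest pair
#' (deterministic).
#'
#' @param mat Normalized matrix (loci x samples, >= 3 samples).
#' @param measure,z_transform Passed to [expression_distance()].
#' @param B Bootstrap replicates over rows (default 1000).
#' @param seed Seed.
#' @return List with `tree` (`phylo`, ultrametric), `support` (named vector,
#'   fraction of bootstrap trees containing each internal bipartition of the
#'   main tree), and `dist` (the observed distance matrix).
#' @export
upgma_bootstrap <- function(mat, measure = "euclidean", z_transform = FALSE,
                            B = 1000L, seed = 1L) {
  stopifnot(ncol(mat) >= 3)
  d <- expression_distance(mat, measure, z_transform)
  tree <- upgma_tree(d)
  set.seed(seed)
  obs_clades <- .clades(tree)
  hits <- setNames(numeric(length(obs_clades)), obs_clades)
  for (b in seq_len(B)) {
    idx <- sample.int(nrow(mat), nrow(mat), replace = TRUE)
    db <- tryCatch(expression_distance(mat[idx, , drop = FALSE], measure,
                                       z_transform),
                   error = function(e) NULL)
    if (is.null(db)) next
    bp <- .clades(upgma_tree(db))
    hits[obs_clades %in% bp] <- hits[obs_clades %in% bp] + 1
  }
  list(tree = tree, support = hits / B, dist = d)
}

#' UPGMA agglomeration of a distance matrix
#'
#' @param d Symmetric distance matrix (or `dist`).
#' @return An ultrametric `phylo` tree (edge heights = merge height / 2).
#' @export
upgma_tree <- function(d) {
  dm <- as.matrix(d)
  ## deterministic tie-break: hclust breaks ties by order of appearance;
  ## order labels lexicographically so the smallest pair merges first
  ord <- order(rownames(dm))
  dm <- dm[ord, ord]
  hc <- hclust(stats::as.dist(dm), method = "average")
  ape::as.phylo(hc)
}

# Internal clades of a rooted tree as canonical comma-joined label strings
# (the root clade containing all tips is dropped).
.clades <- function(tree) {
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  keys <- vapply(pp, function(p) paste(sort(labs[p]), collapse = ","),
                 character(1))
  unique(keys[lengths(pp) > 1 & lengths(pp) < length(labs)])
}
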
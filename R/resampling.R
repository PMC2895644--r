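#' Length-matched random regions
#'
#' Draws the same number of regions with the exact same multiset of lengths
#' as the template, placed uniformly over positions where a region fits
#' entirely inside the background space and outside the exclusion set;
#' sampled regions are mutually non-overlapping.
#'
#' @param template `GRanges` whose lengths are matched.
#' @param background `GRanges` placement space.
#' @param exclusion Optional `GRanges` removed from the background first.
#' @param seed Optional seed (`NULL` = use the current RNG state, as the
#'   permutation tests do within their seeded loops).
#' @param max_tries Retry bound before declaring placement infeasible.
#' @return `GRanges` of placed regions, same length multiset as `template`.
#' @export
matched_random_regions <- function(template, background,
                                   exclusion = NULL, seed = NULL,
                                   max_tries = 1000L) {
  if (!is.null(seed)) set.seed(seed)
  space <- background
  if (!is.null(exclusion) && length(exclusion))
    space <- GenomicRanges::setdiff(space, exclusion, ignore.strand = TRUE)
  flat <- .flatten_space(space)
  pos <- .place_lengths(flat, BiocGenerics::width(template),
                        max_tries = max_tries)
  GenomicRanges::GRanges(pos$ctg, IRanges::IRanges(pos$start, pos$end))
}

# Shared empirical p-value convention: add-one rule, never 0.
.empirical_p <- function(observed, null_values, direction) {
  m <- if (direction == "greater") sum(null_values >= observed) else
    sum(null_values <= observed)
  (1 + m) / (1 + length(null_values))
}

.permutation_result <- function(observed, null_values, direction) {
  out <- list(observed = observed, null_values = null_values,
              empirical_p = .empirical_p(observed, null_values, direction),
              direction = direction)
  class(out) <- "PermutationResult"
  out
}

#' @export
print.PermutationResult <- function(x, ...) {
  cat(sprintf(
    "PermutationResult: observed = %g, null mean = %g (B = %d), p = %g (%s)\n",
    x$observed, mean(x$null_values), length(x$null_values), x$empirical_p,
    x$direction))
  invisible(x)
}

#' Permutation test for interval overlap
#'
#' Tests whether more query regions overlap the feature set than expected
#' for length-matched random regions drawn from the background (minus
#' exclusion). The statistic is the number of query regions overlapping at
#' least one feature by at least one nucleotide. Features may be extended
#' first (e.g. 1 kb each side for short structural-RNA predictions).
#'
#' @param query `GRanges` of regions under test (e.g. igHTR).
#' @param features `GRanges` of annotation features (e.g. EST footprints,
#'   lincRNA loci).
#' @param background,exclusion Placement space for the null (see
#'   [matched_random_regions()]).
#' @param B Number of permutations (default 1000).
#' @param extend Symmetric feature extension in nt (default 0).
#' @param seed Seed.
#' @return A `PermutationResult` (direction `"greater"`).
#' @export
overlap_permutation_test <- function(query, features, background,
                                     exclusion = NULL, B = 1000L,
                                     extend = 0L, seed = 1L) {
  set.seed(seed)
  if (extend > 0) {
    features <- GenomicRanges::resize(features,
      BiocGenerics::width(features) + 2L * extend, fix = "center")
    features <- GenomicRanges::trim(features)
  }
  idx <- .overlap_index(features)
  space <- background
  if (!is.null(exclusion) && length(exclusion))
    space <- GenomicRanges::setdiff(space, exclusion, ignore.strand = TRUE)
  flat <- .flatten_space(space)
  qdf <- data.frame(ctg = as.character(GenomicRanges::seqnames(query)),
                    start = BiocGenerics::start(query),
                    end = BiocGenerics::end(query))
  observed <- .count_overlapping(qdf, idx)
  lens <- BiocGenerics::width(query)
  null_values <- vapply(seq_len(B), function(b)
    .count_overlapping(.place_lengths(flat, lens), idx), numeric(1))
  .permutation_result(observed, null_values, "greater")
}

# Count connected pairs: a connection exists when distinct blocks of one
# EST overlap both members of a pair.
.count_connections <- function(pairs_a, pairs_b, ests) {
  if (length(ests) == 0 || length(pairs_a) == 0) return(0L)
  flat <- unlist(ests, use.names = FALSE)
  est_id <- rep(seq_along(ests), lengths(ests))
  block_id <- seq_along(flat)
  hits_a <- GenomicRanges::findOverlaps(pairs_a, flat, ignore.strand = TRUE)
  hits_b <- GenomicRanges::findOverlaps(pairs_b, flat, ignore.strand = TRUE)
  if (length(hits_a) == 0 || length(hits_b) == 0) return(0L)
  con <- logical(length(pairs_a))
  da <- data.frame(p = S4Vectors::queryHits(hits_a),
                   est = est_id[S4Vectors::subjectHits(hits_a)],
                   blk = block_id[S4Vectors::subjectHits(hits_a)])
  db <- data.frame(p = S4Vectors::queryHits(hits_b),
                   est = est_id[S4Vectors::subjectHits(hits_b)],
                   blk = block_id[S4Vectors::subjectHits(hits_b)])
  m <- merge(da, db, by = c("p", "est"))
  m <- m[m$blk.x != m$blk.y, , drop = FALSE]  # distinct blocks required
  con[unique(m$p)] <- TRUE
  sum(con)
}

#' Permutation test for EST connections
#'
#' Tests whether spliced ESTs connect more region pairs than expected by
#' chance. In mode `"ightr_ightr"` the pairs are consecutive igHTR within a
#' cluster; in mode `"gene3_ightr"` each pair is a gene's 3'-terminal exon
#' and a downstream igHTR within the proximity window. A pair is connected
#' when two distinct blocks of a single EST overlap both members. The null
#' re-places the igHTR by [matched_random_regions()] (keeping the pairing
#' structure) and recounts.
#'
#' @param pairs_mode `"ightr_ightr"` or `"gene3_ightr"`.
#' @param ightrs `GRanges` of igHTR with a `cluster` mcol (for
#'   `"ightr_ightr"`) or mcols `nearest_gene`, `gene_side`, `within_near`
#'   (for `"gene3_ightr"`; see [cluster_and_assign_genes()]).
#' @param annot An `AnnotationSet` (gene/exon records for the gene mode).
#' @param ests `GRangesList` of spliced EST block alignments.
#' @param background,exclusion Null placement space for the igHTR.
#' @param B Permutations (default 1000).
#' @param seed Seed.
#' @return A `PermutationResult`, statistic = number of connected pairs.
#' @export
connection_permutation_test <- function(pairs_mode = c("ightr_ightr",
                                                       "gene3_ightr"),
                                        ightrs, annot, ests, background,
                                        exclusion = NULL, B = 1000L,
                                        seed = 1L) {
  pairs_mode <- match.arg(pairs_mode)
  set.seed(seed)
  ## treat blockless ESTs as single-block
  ests <- methods::as(ests, "GRangesList")
  if (pairs_mode == "ightr_ightr") {
    stopifnot(!is.null(ightrs$cluster))
    keep <- !is.na(ightrs$cluster)
    ig <- ightrs[keep]
    ord <- order(ig$cluster, BiocGenerics::start(ig))
    ig <- ig[ord]
    same <- ig$cluster[-1] == ig$cluster[-length(ig)]
    ia <- which(same); ib <- which(same) + 1L
    pairs_a <- ig[ia]; pairs_b <- ig[ib]
    moving <- "both"
  } else {
    stopifnot(!is.null(ightrs$nearest_gene))
    sel <- !is.na(ightrs$gene_side) & ightrs$gene_side == "3prime" &
      !is.na(ightrs$within_near) & ightrs$within_near
    ig <- ightrs[sel]
    ex <- annot$exons
    term <- do.call(c, lapply(unique(ig$nearest_gene), function(gid) {
      e <- ex[ex$gene_id == gid]
      if (as.character(BiocGenerics::strand(e))[1] == "+")
        e[which.max(BiocGenerics::end(e))] else
        e[which.min(BiocGenerics::start(e))]
    }))
    names(term) <- unique(ig$nearest_gene)
    pairs_a <- GenomicRanges::granges(term[match(ig$nearest_gene,
                                                 names(term))])
    pairs_b <- ig
    moving <- "b"
  }
  observed <- .count_connections(pairs_a, pairs_b, ests)
  space <- background
  if (!is.null(exclusion) && length(exclusion))
    space <- GenomicRanges::setdiff(space, exclusion, ignore.strand = TRUE)
  flat <- .flatten_space(space)
  null_values <- vapply(seq_len(B), function(b) {
    if (moving == "both") {
      all_ig <- unique(c(pairs_a, pairs_b))
      pos <- .place_lengths(flat, BiocGenerics::width(all_ig))
      ra <- GenomicRanges::GRanges(pos$ctg, IRanges::IRanges(pos$start,
                                                             pos$end))
      ii <- match(paste0(BiocGenerics::start(pairs_a), "_",
                         BiocGenerics::end(pairs_a)),
                  paste0(BiocGenerics::start(all_ig), "_",
                         BiocGenerics::end(all_ig)))
      jj <- match(paste0(BiocGenerics::start(pairs_b), "_",
                         BiocGenerics::end(pairs_b)),
                  paste0(BiocGenerics::start(all_ig), "_",
                         BiocGenerics::end(all_ig)))
      .count_connections(ra[ii], ra[jj], ests)
    } else {
      pos <- .place_lengths(flat, BiocGenerics::width(pairs_b))
      rb <- GenomicRanges::GRanges(pos$ctg, IRanges::IRanges(pos$start,
                                                             pos$end))
      .count_connections(pairs_a, rb, ests)
    }
  }, numeric(1))
  .permutation_result(observed, null_values, "greater")
}

#' Conservation means with resampled confidence intervals
#'
#' Reports the mean per-base conservation of the focal class (e.g. igHTR)
#' over all its bases, and for each comparison class the mean plus a 95%
#' interval obtained by resampling the focal base count from the class's
#' bases `n_resamples` times.
#'
#' @param regions_by_class Named list of `GRanges`; the first element is the
#'   focal class whose base count sets the resample size.
#' @param track A `ConservationTrack`.
#' @param n_resamples Resampling iterations (default 1000).
#' @param seed Seed.
#' @return Data frame: `class`, `n_bases`, `mean_score`, `ci_low`,
#'   `ci_high`, `resampled`, `with_replacement`.
#' @export
conservation_resampled_ci <- function(regions_by_class, track,
                                      n_resamples = 1000L, seed = 1L) {
  stopifnot(!is.null(names(regions_by_class)))
  set.seed(seed)
  focal <- names(regions_by_class)[1]
  vals <- lapply(regions_by_class, function(gr)
    conservation_values(track, GenomicRanges::reduce(gr,
                                                     ignore.strand = TRUE)))
  n_focal <- length(vals[[focal]])
  rows <- lapply(names(vals), function(cl) {
    v <- vals[[cl]]
    if (cl == focal)
      return(data.frame(class = cl, n_bases = length(v),
                        mean_score = mean(v), ci_low = NA_real_,
                        ci_high = NA_real_, resampled = FALSE,
                        with_replacement = FALSE))
    replace <- length(v) < n_focal
    if (replace)
      warning("class ", cl, " has fewer bases than the focal class; ",
              "resampling with replacement")
    means <- vapply(seq_len(n_resamples), function(i)
      mean(v[sample.int(length(v), n_focal, replace = replace)]), numeric(1))
    q <- quantile(means, c(0.025, 0.975))
    data.frame(class = cl, n_bases = length(v), mean_score = mean(v),
               ci_low = q[[1]], ci_high = q[[2]], resampled = TRUE,
               with_replacement = replace)
  })
  do.call(rbind, rows)
}

#' Hypergeometric enrichment with a permutation global p-value
#'
#' Per-category raw p-values are hypergeometric upper tails
#' P(X >= k) for k foreground genes in the category; the global p-value is
#' the fraction of `B` random same-size foregrounds (drawn from the
#' background) whose minimum raw p is at most the observed minimum.
#'
#' @param foreground Character vector of genes, a subset of `background`.
#' @param background Character vector of all genes.
#' @param categories Named list of character vectors (gene sets).
#' @param B Permutations (default 1000).
#' @param seed Seed.
#' @return List with `table` (data frame `category`, `k`, `m`, `raw_p`) and
#'   `global_p`.
#' @export
enrichment_test <- function(foreground, background, categories, B = 1000L,
                            seed = 1L) {
  stopifnot(all(foreground %in% background))
  set.seed(seed)
  N <- length(background); n <- length(foreground)
  keep <- vapply(categories, function(g) length(intersect(g, background)) > 0,
                 logical(1))
  if (any(!keep))
    warning("categor(ies) disjoint from background skipped: ",
            paste(names(categories)[!keep], collapse = ", "))
  categories <- categories[keep]
  cat_bg <- lapply(categories, intersect, background)
  raw_p_for <- function(fg) {
    vapply(cat_bg, function(g) {
      k <- length(intersect(fg, g)); m <- length(g)
      stats::phyper(k - 1, m, N - m, n, lower.tail = FALSE)
    }, numeric(1))
  }
  raw <- raw_p_for(foreground)
  obs_min <- min(raw)
  null_min <- vapply(seq_len(B), function(b)
    min(raw_p_for(sample(background, n))), numeric(1))
  list(table = data.frame(category = names(categories),
                          k = vapply(cat_bg, function(g)
                            length(intersect(foreground, g)), numeric(1)),
                          m = lengths(cat_bg), raw_p = raw,
                          row.names = NULL),
       global_p = .empirical_p(-obs_min, -null_min, "greater"))
}

#' One-sided binomial excess test
#'
#' Exact upper-tail probability P(Binomial(n, p0) >= k): is the category
#' represented more often than its background proportion predicts?
#'
#' @param k Observed count in the category.
#' @param n Total count.
#' @param p0 Background proportion (strictly between 0 and 1).
#' @return One-sided p-value.
#' @export
binomial_excess_test <- function(k, n, p0) {
  if (p0 <= 0 || p0 >= 1) stop("argument error: p0 must lie strictly in (0,1)")
  stopifnot(k >= 0, k <= n)
  stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
}
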
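# Uniform placement of non-overlapping intervals inside an allowed space.
# Shared by the genome simulator and the matched-random-region null; kept
# numeric (no GRanges in the inner loop) because permutation calibration
# draws hundreds of thousands of placements.

# Flatten a GRanges space into per-piece numeric records.
.flatten_space <- function(space_gr) {
  space_gr <- GenomicRanges::reduce(sort_intervals(space_gr))
  list(ctg = as.character(GenomicRanges::seqnames(space_gr)),
       gstart = BiocGenerics::start(space_gr),
       len = BiocGenerics::width(space_gr))
}

# Sample starts for `lengths`, each region fully inside one piece, mutually
# non-overlapping, uniform over all feasible positions. Returns a data.frame
# (ctg, start, end) in 1-based closed genome coordinates.
.place_lengths <- function(flat, lengths, max_tries = 1000L) {
  n <- length(lengths)
  if (n == 0)
    return(data.frame(ctg = character(), start = integer(), end = integer()))
  npieces <- length(flat$len)
  avail <- outer(flat$len, lengths, function(L, l) pmax(L - l + 1, 0))
  if (any(colSums(avail) == 0))
    stop("simulation error: a region length exceeds every background piece")
  # virtual offsets with a 1-base gap between pieces so regions in different
  # pieces can never collide
  voff <- cumsum(c(0, flat$len + 1))[seq_len(npieces)]
  piece <- integer(n); vstart <- numeric(n)
  todo <- seq_len(n)
  tries <- 0L
  repeat {
    for (k in todo) {
      p <- if (npieces == 1) 1L else
        sample.int(npieces, 1L, prob = avail[, k])
      piece[k] <- p
      vstart[k] <- voff[p] + floor(runif(1) * avail[p, k])
    }
    ord <- order(vstart)
    vend <- vstart + lengths - 1
    bad <- ord[c(FALSE, vstart[ord][-1] <= vend[ord][-n])]
    if (n == 1 || length(bad) == 0) break
    todo <- unique(bad)
    tries <- tries + 1L
    if (tries > max_tries)
      stop("simulation error: infeasible non-overlapping placement")
  }
  data.frame(ctg = flat$ctg[piece],
             start = as.integer(flat$gstart[piece] + (vstart - voff[piece])),
             end = as.integer(flat$gstart[piece] + (vstart - voff[piece]) +
                              lengths - 1))
}

# Overlap predicate: does each query [qs, qe] overlap >=1 feature by >=1 nt?
# Features must be pre-sorted by start with a running maximum of ends.
.overlap_any <- function(qs, qe, f_start_sorted, f_end_cummax) {
  if (length(f_start_sorted) == 0) return(rep(FALSE, length(qs)))
  idx <- findInterval(qe, f_start_sorted)
  idx > 0 & f_end_cummax[pmax(idx, 1L)] >= qs
}

# Precompute the sorted-feature structure .overlap_any consumes, per contig.
.overlap_index <- function(gr) {
  by_ctg <- split(data.frame(s = BiocGenerics::start(gr),
                             e = BiocGenerics::end(gr)),
                  as.character(GenomicRanges::seqnames(gr)))
  lapply(by_ctg, function(d) {
    d <- d[order(d$s), , drop = FALSE]
    list(start = d$s, end_cummax = cummax(d$e))
  })
}

# Count queries (data.frame ctg/start/end) overlapping any indexed feature.
.count_overlapping <- function(q, idx) {
  if (nrow(q) == 0) return(0L)
  hit <- logical(nrow(q))
  for (ctg in unique(q$ctg)) {
    sel <- q$ctg == ctg
    if (!is.null(idx[[ctg]]))
      hit[sel] <- .overlap_any(q$start[sel], q$end[sel],
                               idx[[ctg]]$start, idx[[ctg]]$end_cummax)
  }
  sum(hit)
}
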
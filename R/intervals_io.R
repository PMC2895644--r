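#' Read genomic intervals from BED or GTF
#'
#' Imports a BED (0-based half-open on disk) or GTF (1-based inclusive) file
#' into a `GRanges`. Coordinates are converted to the 1-based closed
#' convention `GRanges` uses; BED and GTF therefore describe the same
#' nucleotides after import. Records are returned sorted by (contig, start).
#'
#' @param path Path to the file.
#' @param format Either `"BED"` or `"GTF"`.
#' @return A sorted `GRanges`. GTF feature metadata (type, gene_id when
#'   present) is kept in `mcols`.
#' @export
read_intervals <- function(path, format = c("BED", "GTF")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (format == "BED") .validate_bed_lines(path)
  gr <- tryCatch(
    rtracklayer::import(path, format = tolower(format)),
    error = function(e) stop("parse error in ", path, ": ", conditionMessage(e))
  )
  gr <- as(gr, "GRanges")
  if (any(BiocGenerics::width(gr) < 1))
    stop("validation error: interval with start >= end in ", path)
  sort_intervals(gr)
}

# Cheap structural scan so malformed BED input is reported with a line number
# (rtracklayer's own errors do not carry one).
.validate_bed_lines <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  for (i in which(keep)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3 || is.na(suppressWarnings(as.numeric(f[2]))) ||
        is.na(suppressWarnings(as.numeric(f[3]))))
      stop("parse error: malformed BED at line ", i, " of ", path)
    if (as.numeric(f[2]) >= as.numeric(f[3]))
      stop("validation error: start >= end at line ", i, " of ", path)
  }
  invisible(TRUE)
}

#' Write genomic intervals to BED
#'
#' Exports a `GRanges` as BED (3 columns, or 6 when any strand is set so the
#' strand column is preserved). `read_intervals(write_intervals(x))` returns
#' the same intervals.
#'
#' @param records A `GRanges`.
#' @param path Output path.
#' @param format Only `"BED"`.
#' @return The path, invisibly.
#' @export
write_intervals <- function(records, path, format = "BED") {
  stopifnot(identical(format, "BED"), is(records, "GRanges"))
  gr <- sort_intervals(records)
  stranded <- any(as.character(BiocGenerics::strand(gr)) != "*")
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr))
  if (stranded) {
    nm <- if (!is.null(names(gr))) names(gr) else
      if ("name" %in% names(S4Vectors::mcols(gr)))
        as.character(gr$name) else sprintf("iv%06d", seq_along(gr))
    df$name <- nm
    df$score <- 0L
    df$strand <- as.character(BiocGenerics::strand(gr))
    df$strand[df$strand == "*"] <- "."
  }
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Sort intervals by (contig, start, end)
#' @param gr A `GRanges`.
#' @return The sorted `GRanges`.
#' @export
sort_intervals <- function(gr) {
  gr[order(as.character(GenomicRanges::seqnames(gr)),
           BiocGenerics::start(gr), BiocGenerics::end(gr))]
}

#' Read a three-species alignment block file
#'
#' Parses the tab-separated block format this package uses for colinear
#' multi-species alignment blocks (a desk-scale stand-in for MAF): columns
#' `block`, `species`, `contig`, `start`, `end` with BED-style 0-based
#' half-open coordinates, one row per species per block. Blocks are gapless
#' within themselves, so all species spans of one block must have equal
#' length, and every block must list the same species set.
#'
#' @param path Path to the block file.
#' @param reference Reference species used to order blocks; defaults to the
#'   first species encountered.
#' @return An `AlignmentBlockSet`.
#' @export
read_alignment_blocks <- function(path, reference = NULL) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  df <- tryCatch(
    read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE),
    error = function(e) {
      # an empty file (header only or nothing) yields an empty set
      if (grepl("no lines available", conditionMessage(e)))
        return(data.frame(block = integer(), species = character(),
                          contig = character(), start = integer(),
                          end = integer()))
      stop("format error in ", path, ": ", conditionMessage(e))
    })
  alignment_block_set_from_table(df, reference = reference)
}

#' Build an AlignmentBlockSet from a long-format table
#'
#' @param df Data frame with columns `block`, `species`, `contig`, `start`,
#'   `end` (0-based half-open, one row per species per block).
#' @param reference Reference species name (default: first species listed).
#' @return An `AlignmentBlockSet`: a list with `species` (ordered names) and
#'   `ivs` (named list of parallel `GRanges`, one per species; element i of
#'   each is species' span of block i).
#' @export
alignment_block_set_from_table <- function(df, reference = NULL) {
  need <- c("block", "species", "contig", "start", "end")
  if (!all(need %in% names(df))) stop("format error: need columns ",
                                      paste(need, collapse = ", "))
  if (nrow(df) == 0) {
    out <- list(species = character(0), ivs = list())
    class(out) <- "AlignmentBlockSet"
    return(out)
  }
  species <- unique(df$species)
  if (is.null(reference)) reference <- species[1]
  if (!reference %in% species) stop("argument error: unknown reference species")
  per_block <- split(df, df$block)
  for (b in per_block) {
    if (!setequal(b$species, species) || nrow(b) != length(species))
      stop("format error: block ", b$block[1],
           " does not list the full species set exactly once")
    lens <- b$end - b$start
    if (length(unique(lens)) != 1)
      stop("format error: unequal block lengths in block ", b$block[1])
    if (any(lens < 1)) stop("format error: empty block ", b$block[1])
  }
  ids <- names(per_block)
  ivs <- lapply(species, function(sp) {
    rows <- do.call(rbind, lapply(per_block, function(b) b[b$species == sp, ]))
    GenomicRanges::GRanges(rows$contig,
                           IRanges::IRanges(rows$start + 1L, rows$end))
  })
  names(ivs) <- species
  ord <- order(as.character(GenomicRanges::seqnames(ivs[[reference]])),
               BiocGenerics::start(ivs[[reference]]))
  ivs <- lapply(ivs, function(g) g[ord])
  for (sp in species) {
    g <- ivs[[sp]]
    if (length(g) > 1) {
      red <- GenomicRanges::reduce(g, min.gapwidth = 0L)
      if (sum(BiocGenerics::width(red)) != sum(BiocGenerics::width(g)))
        stop("format error: overlapping blocks for species ", sp)
    }
  }
  out <- list(species = species, ivs = ivs)
  class(out) <- "AlignmentBlockSet"
  out
}

#' Write an AlignmentBlockSet to the block file format
#' @param blocks An `AlignmentBlockSet`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_alignment_blocks <- function(blocks, path) {
  stopifnot(inherits(blocks, "AlignmentBlockSet"))
  rows <- do.call(rbind, lapply(blocks$species, function(sp) {
    g <- blocks$ivs[[sp]]
    data.frame(block = seq_along(g), species = sp,
               contig = as.character(GenomicRanges::seqnames(g)),
               start = BiocGenerics::start(g) - 1L,
               end = BiocGenerics::end(g))
  }))
  if (is.null(rows))
    rows <- data.frame(block = integer(), species = character(),
                       contig = character(), start = integer(),
                       end = integer())
  rows <- rows[order(rows$block, match(rows$species, blocks$species)), ]
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Project an interval between species through alignment blocks
#'
#' Maps an interval from one species' coordinates to another using gapless
#' colinear blocks: each aligned base keeps its offset within its block. The
#' result is the span covering all aligned bases of `iv` in the target
#' species (on the target contig carrying the most aligned bases, should the
#' blocks hit several contigs). `NULL` is returned when no base of `iv` is
#' aligned. The result carries a `partial` metadata flag when some bases of
#' `iv` fall between blocks.
#'
#' @param iv A length-1 `GRanges` in `from_species` coordinates.
#' @param blocks An `AlignmentBlockSet`.
#' @param from_species,to_species Species names present in `blocks`.
#' @return A length-1 `GRanges` with a logical `partial` mcol, or `NULL`.
#' @export
project_interval <- function(iv, blocks, from_species, to_species) {
  stopifnot(inherits(blocks, "AlignmentBlockSet"), length(iv) == 1)
  if (!from_species %in% blocks$species || !to_species %in% blocks$species)
    stop("argument error: unknown species")
  src <- blocks$ivs[[from_species]]
  dst <- blocks$ivs[[to_species]]
  hits <- GenomicRanges::findOverlaps(iv, src)
  if (length(hits) == 0) return(NULL)
  j <- S4Vectors::subjectHits(hits)
  ov_start <- pmax(BiocGenerics::start(iv), BiocGenerics::start(src)[j])
  ov_end <- pmin(BiocGenerics::end(iv), BiocGenerics::end(src)[j])
  t_start <- BiocGenerics::start(dst)[j] + (ov_start - BiocGenerics::start(src)[j])
  t_end <- BiocGenerics::start(dst)[j] + (ov_end - BiocGenerics::start(src)[j])
  t_contig <- as.character(GenomicRanges::seqnames(dst))[j]
  covered <- sum(ov_end - ov_start + 1)
  if (length(unique(t_contig)) > 1) {
    per <- tapply(ov_end - ov_start + 1, t_contig, sum)
    best <- names(per)[which.max(per)]
    keep <- t_contig == best
    t_start <- t_start[keep]; t_end <- t_end[keep]; t_contig <- best
  }
  out <- GenomicRanges::GRanges(t_contig[1],
                                IRanges::IRanges(min(t_start), max(t_end)))
  out$partial <- covered < BiocGenerics::width(iv)
  out
}

#' Project many intervals between species
#'
#' Vectorised [project_interval()]: unmapped intervals are dropped and the
#' mapping back to the input recorded in the `origin` mcol.
#'
#' @inheritParams project_interval
#' @param ivs A `GRanges`.
#' @return A `GRanges` with mcols `origin` (index into `ivs`) and `partial`.
#' @export
project_intervals <- function(ivs, blocks, from_species, to_species) {
  res <- lapply(seq_along(ivs), function(i)
    project_interval(ivs[i], blocks, from_species, to_species))
  keep <- !vapply(res, is.null, logical(1))
  if (!any(keep)) {
    out <- GenomicRanges::GRanges()
    out$origin <- integer(0); out$partial <- logical(0)
    return(out)
  }
  out <- do.call(c, res[keep])
  out$origin <- which(keep)
  out
}

#' Read a per-base conservation track from bedGraph
#'
#' @param path bedGraph file with scores in \[0, 1\].
#' @param contig_lengths Named integer vector of contig lengths.
#' @return A `ConservationTrack`: a named `list` of per-contig numeric `Rle`
#'   vectors of per-base scores.
#' @export
read_conservation <- function(path, contig_lengths) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  conservation_track(gr, contig_lengths)
}

#' Build a conservation track from scored intervals
#' @param gr `GRanges` with a numeric `score` mcol in \[0, 1\].
#' @param contig_lengths Named integer vector of contig lengths.
#' @return A `ConservationTrack` (list of per-contig `Rle`).
#' @export
conservation_track <- function(gr, contig_lengths) {
  if (any(gr$score < 0 | gr$score > 1))
    stop("validation error: conservation scores must lie in [0, 1]")
  out <- lapply(names(contig_lengths), function(ctg) {
    v <- S4Vectors::Rle(0, contig_lengths[[ctg]])
    g <- gr[as.character(GenomicRanges::seqnames(gr)) == ctg]
    if (length(g))
      v[IRanges::IRanges(BiocGenerics::start(g), BiocGenerics::end(g))] <-
        S4Vectors::Rle(rep(g$score, BiocGenerics::width(g)))
    v
  })
  names(out) <- names(contig_lengths)
  class(out) <- "ConservationTrack"
  out
}

#' Per-base conservation scores under a set of intervals
#' @param track A `ConservationTrack`.
#' @param gr `GRanges` of regions.
#' @return Numeric vector of the per-base scores under `gr` (bases covered
#'   twice are counted twice; callers pass reduced regions when union
#'   semantics are wanted).
#' @export
conservation_values <- function(track, gr) {
  unlist(lapply(seq_along(gr), function(i) {
    ctg <- as.character(GenomicRanges::seqnames(gr))[i]
    if (!ctg %in% names(track)) stop("annotation error: contig ", ctg,
                                     " absent from conservation track")
    as.numeric(track[[ctg]][BiocGenerics::start(gr)[i]:BiocGenerics::end(gr)[i]])
  }), use.names = FALSE)
}

#' Read spliced EST alignments from BED12
#' @param path BED12 file; block structure describes the aligned exons.
#' @return A `GRangesList`, one element per EST, each a sorted disjoint
#'   `GRanges` of aligned blocks.
#' @export
read_ests <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  if (!"blocks" %in% names(S4Vectors::mcols(gr)))
    return(methods::as(gr, "GRangesList"))
  bl <- rtracklayer::blocks(gr)
  names(bl) <- if (!is.null(gr$name)) gr$name else sprintf("est%05d", seq_along(gr))
  bl
}

#' Write spliced EST alignments as BED12
#' @param ests A `GRangesList` of per-EST block `GRanges`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_ests <- function(ests, path) {
  lines <- vapply(seq_along(ests), function(i) {
    g <- BiocGenerics::sort(ests[[i]])
    ctg <- as.character(GenomicRanges::seqnames(g))[1]
    s <- BiocGenerics::start(g) - 1L
    e <- BiocGenerics::end(g)
    chromStart <- min(s); chromEnd <- max(e)
    paste(ctg, chromStart, chromEnd,
          if (!is.null(names(ests))) names(ests)[i] else sprintf("est%05d", i),
          0, ".", chromStart, chromEnd, "0", length(g),
          paste0(paste(e - s, collapse = ","), ","),
          paste0(paste(s - chromStart, collapse = ","), ","),
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
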
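#' Build repeat family records
#'
#' @param elements `GRanges` of repeat elements with mcols `family` and
#'   `mappable` (count of uniquely mappable positions per element,
#'   `<= width`).
#' @param family_table Optional data frame with columns `name`, `class`,
#'   `age_rank` joining family metadata.
#' @return A named list of `RepeatFamily` records (`name`, `class`,
#'   `elements` GRanges, `mappable` integer vector, `age_rank`).
#' @export
repeat_families <- function(elements, family_table = NULL) {
  stopifnot(!is.null(elements$family), !is.null(elements$mappable))
  if (any(elements$mappable > BiocGenerics::width(elements)))
    stop("validation error: mappable count exceeds element length")
  fams <- split(seq_along(elements), elements$family)
  out <- lapply(names(fams), function(fn) {
    idx <- fams[[fn]]
    rec <- list(name = fn,
                class = if (!is.null(family_table))
                  family_table$class[match(fn, family_table$name)] else NA,
                elements = elements[idx],
                mappable = elements$mappable[idx],
                age_rank = if (!is.null(family_table))
                  family_table$age_rank[match(fn, family_table$name)] else NA)
    class(rec) <- "RepeatFamily"
    rec
  })
  names(out) <- names(fams)
  out
}

#' Uniquely mappable length of a repeat family
#'
#' Sums the uniquely mappable position counts over all elements of the
#' family, or only over the expressed elements (those touched by at least
#' one assigned read).
#'
#' @param family A `RepeatFamily`.
#' @param which `"all"` or `"expressed"`.
#' @param reads `GRanges` of unique reads (required for `"expressed"`).
#' @return Mappable length in nt.
#' @export
unique_mappable_length <- function(family, which = c("all", "expressed"),
                                   reads = NULL) {
  which <- match.arg(which)
  if (length(family$elements) == 0) {
    warning("family ", family$name, " has zero elements")
    return(0)
  }
  if (which == "all") return(sum(as.numeric(family$mappable)))
  stopifnot(!is.null(reads))
  expressed <- IRanges::overlapsAny(family$elements, reads,
                                    ignore.strand = TRUE)
  sum(as.numeric(family$mappable[expressed]))
}

# Assign each read to at most one repeat family: the family of the element
# with the largest overlap, ties to the lower-coordinate element.
.read_family <- function(reads, elements) {
  hits <- GenomicRanges::findOverlaps(reads, elements, ignore.strand = TRUE)
  if (length(hits) == 0) return(rep(NA_character_, length(reads)))
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  ov <- pmin(BiocGenerics::end(reads)[q], BiocGenerics::end(elements)[s]) -
    pmax(BiocGenerics::start(reads)[q], BiocGenerics::start(elements)[s]) + 1L
  ord <- order(q, -ov, BiocGenerics::start(elements)[s])
  first <- !duplicated(q[ord])
  fam <- rep(NA_character_, length(reads))
  fam[q[ord][first]] <- elements$family[s[ord][first]]
  fam
}

#' Repeat family transcriptional activity with bootstrap CIs
#'
#' Counts uniquely mapped reads per family (a read overlapping repeat
#' elements of several families counts once, for the family with the
#' largest overlap), normalises by the family's uniquely mappable length
#' (over all elements, and over expressed elements only), and attaches
#' percentile bootstrap confidence intervals from `bootstrap_B` resamples of
#' the read set with replacement.
#'
#' @param families A list from [repeat_families()].
#' @param reads `GRanges` of filtered, uniquely mapped reads.
#' @param bootstrap_B Number of bootstrap resamples (default 1000).
#' @param seed Seed for the bootstrap.
#' @param ci_level Confidence level of the percentile interval (default
#'   0.95; simultaneous statements across several families warrant a
#'   Bonferroni-widened level).
#' @return A `FamilyActivity` data frame: `family`, `read_count`,
#'   `mappable_length_all`, `mappable_length_expressed`, `activity_all`,
#'   `activity_expressed`, `ci_low`, `ci_high` (bootstrap CI on
#'   `activity_all`), `flagged` (TRUE when mappable length is 0 with
#'   nonzero reads, activity undefined).
#' @export
family_activity <- function(families, reads, bootstrap_B = 1000L, seed = 1L,
                            ci_level = 0.95) {
  elements <- do.call(c, unname(lapply(families, function(f) f$elements)))
  fam_of_read <- .read_family(reads, elements)
  fam_names <- names(families)
  counts <- vapply(fam_names, function(fn) sum(fam_of_read == fn, na.rm = TRUE),
                   numeric(1))
  len_all <- vapply(families, unique_mappable_length, numeric(1),
                    which = "all")
  len_exp <- vapply(families, unique_mappable_length, numeric(1),
                    which = "expressed", reads = reads)
  act_all <- ifelse(len_all > 0, counts / len_all, NA_real_)
  act_exp <- ifelse(len_exp > 0, counts / len_exp, NA_real_)
  ## bootstrap over reads: resampling the read set with replacement is a
  ## multinomial redraw of per-read family labels
  set.seed(seed)
  n <- length(fam_of_read)
  ci <- matrix(NA_real_, length(fam_names), 2)
  if (n > 0 && bootstrap_B > 0) {
    lab <- factor(fam_of_read, levels = fam_names)  # NA = non-repeat read
    tab <- tabulate(lab, nbins = length(fam_names))
    p <- c(tab, n - sum(tab)) / n
    draws <- stats::rmultinom(bootstrap_B, n, p)[seq_along(fam_names), ,
                                                 drop = FALSE]
    boots <- draws / len_all
    a <- (1 - ci_level) / 2
    ci <- t(apply(boots, 1, quantile, probs = c(a, 1 - a), na.rm = TRUE))
  }
  out <- data.frame(family = fam_names, read_count = counts,
                    mappable_length_all = len_all,
                    mappable_length_expressed = len_exp,
                    activity_all = act_all, activity_expressed = act_exp,
                    ci_low = ci[, 1], ci_high = ci[, 2],
                    flagged = len_all == 0 & counts > 0,
                    row.names = NULL)
  class(out) <- c("FamilyActivity", "data.frame")
  out
}

#' Order family activities by repeat age rank
#'
#' Joins age ranks onto a [family_activity()] table and sorts by rank
#' (higher rank = evolutionarily younger family). Families without a rank
#' are flagged and moved to the end, unsorted.
#'
#' @param activities A `FamilyActivity` data frame.
#' @param families The list from [repeat_families()] (carries `age_rank`).
#' @return Data frame sorted by `age_rank` with an added `rank_missing`
#'   flag.
#' @export
age_activity_table <- function(activities, families) {
  rank <- vapply(families[activities$family], function(f)
    as.numeric(f$age_rank %||% NA), numeric(1))
  out <- activities
  out$age_rank <- rank
  out$rank_missing <- is.na(rank)
  ok <- out[!out$rank_missing, , drop = FALSE]
  ok <- ok[order(ok$age_rank), , drop = FALSE]
  rbind(ok, out[out$rank_missing, , drop = FALSE])
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a
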
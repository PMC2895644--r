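BASES <- c("A", "C", "G", "T")

#' All 64 codons
#' @return Character vector of codons in lexicographic order.
#' @export
all_codons <- function() {
  g <- expand.grid(b3 = BASES, b2 = BASES, b1 = BASES,
                   stringsAsFactors = FALSE)
  paste0(g$b1, g$b2, g$b3)
}

.revcomp <- function(s) {
  chartr("ACGTacgt-", "TGCAtgca-",
         vapply(s, function(x) paste(rev(strsplit(x, "")[[1]]),
                                     collapse = ""), character(1),
                USE.NAMES = FALSE))
}

#' CSF scan parameters
#'
#' @param window Window size in nt (default 90 = 30 codons; must be a
#'   multiple of 3).
#' @param step Slide step in nt (default 3, codon-resolved).
#' @param cutoff Classification cutoff on the max score (default 2).
#' @return A `CSFParams` list.
#' @export
csf_params <- function(window = 90L, step = 3L, cutoff = 2) {
  stopifnot(window %% 3 == 0, step >= 1, step %% 3 == 0)
  out <- list(window = as.integer(window), step = as.integer(step),
              cutoff = cutoff)
  class(out) <- "CSFParams"
  out
}

# Split an aligned sequence pair into codon-pair index columns: alignment
# columns are chunked in consecutive triples from `offset` (0, 1, 2);
# triples containing a gap or ambiguity in either sequence give NA.
.codon_pairs <- function(ref, other, offset = 0L) {
  r <- strsplit(ref, "")[[1]]; o <- strsplit(other, "")[[1]]
  stopifnot(length(r) == length(o))
  n <- length(r) - offset
  ncod <- n %/% 3
  if (ncod < 1) return(data.frame(ref = character(0), other = character(0)))
  idx <- offset + seq_len(ncod * 3)
  rm_ <- matrix(r[idx], nrow = 3); om <- matrix(o[idx], nrow = 3)
  rc <- apply(rm_, 2, paste, collapse = "")
  oc <- apply(om, 2, paste, collapse = "")
  ok <- !grepl("[^ACGT]", rc) & !grepl("[^ACGT]", oc)
  data.frame(ref = ifelse(ok, rc, NA), other = ifelse(ok, oc, NA),
             stringsAsFactors = FALSE)
}

#' Build a CSF scoring matrix from training alignments
#'
#' Counts reference/aligned codon pairs in coding (in-frame on the
#' reference) and noncoding training alignments and forms the log-odds
#' matrix `entry(c1, c2) = log2 f_cod(c1, c2) - log2 f_non(c1, c2)` with
#' Laplace smoothing: `f = (n + pseudocount) / sum(n + pseudocount)`. Codon
#' pairs containing gaps or ambiguity codes are skipped in counting.
#'
#' @param coding_alignments,noncoding_alignments Lists of alignments, each
#'   a `list(ref =, other =)` pair of equal-length gapped strings over
#'   `A,C,G,T,-`.
#' @param pseudocount Added to every pair count (default 1).
#' @return A `CSFMatrix`: list with `scores` (64 x 64, rows = reference
#'   codon), `pseudocount`, and the raw training count matrices.
#' @export
build_csf_matrix <- function(coding_alignments, noncoding_alignments,
                             pseudocount = 1) {
  if (length(coding_alignments) == 0 || length(noncoding_alignments) == 0)
    stop("empty training set")
  codons <- all_codons()
  count <- function(alns) {
    m <- matrix(0, 64, 64, dimnames = list(codons, codons))
    for (a in alns) {
      cp <- .codon_pairs(a$ref, a$other, 0L)
      cp <- cp[!is.na(cp$ref), , drop = FALSE]
      if (nrow(cp) == 0) next
      t2 <- table(factor(cp$ref, codons), factor(cp$other, codons))
      m <- m + unclass(t2)
    }
    m
  }
  n_cod <- count(coding_alignments)
  n_non <- count(noncoding_alignments)
  f_cod <- (n_cod + pseudocount) / sum(n_cod + pseudocount)
  f_non <- (n_non + pseudocount) / sum(n_non + pseudocount)
  out <- list(scores = log2(f_cod) - log2(f_non), pseudocount = pseudocount,
              n_cod = n_cod, n_non = n_non)
  class(out) <- "CSFMatrix"
  out
}

#' Maximum CSF score of a locus alignment
#'
#' Slides a `window`-nt (30-codon) window along the alignment in each of the
#' six reading frames (three codon offsets on the forward alignment and
#' three on the reverse complement of both sequences), sums the matrix
#' entries over the window's codon pairs (gapped codons contribute 0), and
#' returns the maximum over all windows and frames.
#'
#' @param ref,other Equal-length gapped aligned sequences.
#' @param matrix A `CSFMatrix`.
#' @param params A [csf_params()].
#' @return List with `max_score`, `trace` (data frame: strand, offset,
#'   window start in alignment columns, score).
#' @export
max_csf_score <- function(ref, other, matrix, params = csf_params()) {
  stopifnot(inherits(matrix, "CSFMatrix"))
  if (nchar(ref) < params$window)
    stop("locus shorter than the scan window")
  wc <- params$window %/% 3L
  stepc <- max(params$step %/% 3L, 1L)
  trace <- list()
  for (strand_ in c("+", "-")) {
    r <- if (strand_ == "+") ref else .revcomp(ref)
    o <- if (strand_ == "+") other else .revcomp(other)
    for (off in 0:2) {
      cp <- .codon_pairs(r, o, off)
      if (nrow(cp) < wc) next
      sc <- ifelse(is.na(cp$ref), 0,
                   matrix$scores[cbind(cp$ref, cp$other)])
      cum <- cumsum(c(0, sc))
      starts <- seq(1, nrow(cp) - wc + 1, by = stepc)
      wsc <- cum[starts + wc] - cum[starts]
      trace[[length(trace) + 1]] <- data.frame(
        strand = strand_, offset = off,
        col_start = off + (starts - 1) * 3 + 1, score = wsc)
    }
  }
  trace <- do.call(rbind, trace)
  if (is.null(trace) || nrow(trace) == 0)
    stop("locus shorter than the scan window in every frame")
  list(max_score = max(trace$score), trace = trace)
}

#' Classify loci as protein-coding by max CSF score
#'
#' @param scores Numeric vector of per-locus max CSF scores.
#' @param cutoff Score threshold (default 2); `score >= cutoff` is called
#'   coding.
#' @return List with `coding` (logical vector) and `fraction_coding`.
#' @export
classify_coding <- function(scores, cutoff = 2) {
  stopifnot(all(is.finite(scores)))
  flag <- scores >= cutoff
  list(coding = flag, fraction_coding = mean(flag))
}

#' Choose a CSF classification cutoff from training score distributions
#'
#' Picks the threshold maximising sensitivity + specificity (Youden) over
#' the max-CSF scores of loci of known class, breaking ties by the midpoint
#' of the optimal interval. This mirrors choosing the cutoff that
#' discriminates known coding from known non-coding regions; the cutoff is
#' then applied to loci of unknown class.
#'
#' @param scores_coding,scores_noncoding Max-CSF scores of training loci.
#' @return A scalar cutoff (classify with `score >= cutoff`).
#' @export
choose_csf_cutoff <- function(scores_coding, scores_noncoding) {
  stopifnot(length(scores_coding) > 0, length(scores_noncoding) > 0)
  all_sc <- sort(unique(c(scores_coding, scores_noncoding)))
  cand <- c(all_sc[1] - 1, (head(all_sc, -1) + tail(all_sc, -1)) / 2,
            tail(all_sc, 1) + 1)
  youden <- vapply(cand, function(ct)
    mean(scores_coding >= ct) + mean(scores_noncoding < ct), numeric(1))
  best <- which(youden == max(youden))
  cand[best[ceiling(length(best) / 2)]]
}

#' Analytic codon-pair probabilities of the built-in training processes
#'
#' Two explicit substitution processes generate synthetic training and test
#' alignments. The coding-like process preserves the codon (p = 0.55),
#' substitutes a third-position variant (p = 0.35, uniform over the three),
#' or draws a uniform random codon (p = 0.10), mimicking synonymous-biased
#' evolution. The noncoding-like process mutates each base independently
#' (stay probability 0.75, else uniform over the other three). Reference
#' codons are uniform over the 64.
#'
#' @param process `"coding"` or `"noncoding"`.
#' @return 64 x 64 matrix of joint pair probabilities (rows = reference).
#' @export
codon_pair_probs <- function(process = c("coding", "noncoding")) {
  process <- match.arg(process)
  codons <- all_codons()
  P <- matrix(0, 64, 64, dimnames = list(codons, codons))
  if (process == "coding") {
    for (c1 in codons) {
      p <- setNames(rep(0.10 / 64, 64), codons)
      p[c1] <- p[c1] + 0.55
      third <- paste0(substr(c1, 1, 2), setdiff(BASES, substr(c1, 3, 3)))
      p[third] <- p[third] + 0.35 / 3
      P[c1, ] <- p / 64
    }
  } else {
    base_p <- function(b1, b2) if (b1 == b2) 0.75 else 0.25 / 3
    for (c1 in codons) for (c2 in codons) {
      s1 <- strsplit(c1, "")[[1]]; s2 <- strsplit(c2, "")[[1]]
      P[c1, c2] <- prod(mapply(base_p, s1, s2)) / 64
    }
  }
  P
}

#' Simulate an aligned sequence pair from a training process
#'
#' Draws `n_codons` reference codons uniformly and the aligned codons from
#' the conditional distribution of [codon_pair_probs()] for the chosen
#' process. Purely synthetic stand-in for real two-species alignments;
#' gapless.
#'
#' @param n_codons Number of codons.
#' @param process `"coding"` or `"noncoding"`.
#' @return `list(ref =, other =)` alignment.
#' @export
simulate_codon_alignment <- function(n_codons,
                                     process = c("coding", "noncoding")) {
  process <- match.arg(process)
  P <- codon_pair_probs(process)
  codons <- all_codons()
  ref <- sample(codons, n_codons, replace = TRUE)
  other <- character(n_codons)
  for (c1 in unique(ref)) {
    idx <- which(ref == c1)
    other[idx] <- sample(codons, length(idx), replace = TRUE, prob = P[c1, ])
  }
  list(ref = paste(ref, collapse = ""), other = paste(other, collapse = ""))
}
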
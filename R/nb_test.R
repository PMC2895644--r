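# Conditional distribution of the split (x, s - x) given total s for two
# equal-mean, equal-library NB samples with common dispersion phi:
# a Dirichlet-multinomial with both shape parameters r = 1/phi, reducing to
# Binomial(s, 1/2) at phi = 0.
.split_logpmf <- function(s, phi) {
  x <- 0:s
  if (phi < 1e-12) return(dbinom(x, s, 0.5, log = TRUE))
  r <- 1 / phi
  (lgamma(x + r) - lgamma(r) - lfactorial(x)) +
    (lgamma(s - x + r) - lgamma(r) - lfactorial(s - x)) -
    (lgamma(s + 2 * r) - lgamma(2 * r) - lfactorial(s))
}

#' Exact NB test for a two-sample count split
#'
#' Conditions on the total s = `count_a` + `count_b` and sums the
#' probabilities of all splits as or less probable than the observed one,
#' under equal-mean negative binomials with common dispersion `phi` and
#' equal library sizes (library equalisation by subsampling is assumed
#' upstream). With `phi = 0` this is the two-sided exact Binomial(s, 1/2)
#' test. `variant = "doubling"` gives the doubled-one-tail alternative.
#'
#' @param count_a,count_b Non-negative integer counts.
#' @param phi Common dispersion (>= 0).
#' @param lib_a,lib_b Optional library sizes; must be equal when given.
#' @param variant `"small_p"` (default; sum of splits with probability <=
#'   observed) or `"doubling"` (twice the smaller tail, capped at 1).
#' @return Two-sided p-value.
#' @export
nb_exact_test <- function(count_a, count_b, phi, lib_a = NULL, lib_b = NULL,
                          variant = c("small_p", "doubling")) {
  variant <- match.arg(variant)
  stopifnot(count_a >= 0, count_b >= 0, phi >= 0)
  if (!is.null(lib_a) && !is.null(lib_b) && lib_a != lib_b)
    stop("argument error: libraries must be equalised before the exact test")
  s <- count_a + count_b
  if (s == 0) return(1)
  lp <- .split_logpmf(s, phi)
  obs <- lp[count_a + 1]
  if (variant == "small_p") {
    p <- sum(exp(lp[lp <= obs + 1e-10]))
  } else {
    pr <- exp(lp)
    p <- 2 * min(sum(pr[0:s + 1 <= count_a + 1]),
                 sum(pr[0:s + 1 >= count_a + 1]))
  }
  min(p, 1)
}

# Vectorised exact test: one pmf evaluation per unique total.
.nb_exact_pvec <- function(xa, xb, phi, variant = "small_p") {
  s <- xa + xb
  p <- rep(1, length(s))
  for (ss in unique(s[s > 0])) {
    lp <- .split_logpmf(ss, phi)
    pr <- exp(lp)
    sel <- which(s == ss)
    if (variant == "small_p") {
      ord <- order(lp)
      cum <- cumsum(pr[ord])
      ## p for observed x = total mass of splits with lp <= lp[x] (+ ties)
      rankp <- numeric(ss + 1)
      thr <- lp[ord]  # ascending
      last_tie <- findInterval(thr + 1e-10, thr)
      rankp[ord] <- cum[last_tie]
      p[sel] <- pmin(rankp[xa[sel] + 1], 1)
    } else {
      cdf <- cumsum(pr)
      surv <- rev(cumsum(rev(pr)))
      p[sel] <- pmin(2 * pmin(cdf[xa[sel] + 1], surv[xa[sel] + 1]), 1)
    }
  }
  p
}

#' Estimate the common NB dispersion from two replicate samples
#'
#' Maximises the summed conditional log-likelihood of each row's count split
#' given its row total (the two libraries must already be equalised, e.g. by
#' subsampling) over a common dispersion shared by all rows: a grid search
#' on the log scale followed by golden-section refinement.
#'
#' @param replicate_counts Two-column integer matrix (rows = loci).
#' @param phi_max Upper search bound (default 5).
#' @return Estimated dispersion phi (>= 0; 0 means no overdispersion
#'   detected).
#' @export
estimate_common_dispersion <- function(replicate_counts, phi_max = 5) {
  stopifnot(ncol(replicate_counts) == 2)
  x1 <- replicate_counts[, 1]; s <- rowSums(replicate_counts)
  keep <- s > 0
  if (!any(keep)) stop("dispersion undefined: all rows have zero counts")
  x1 <- x1[keep]; s <- s[keep]
  loglik <- function(phi) {
    if (phi < 1e-12) return(sum(dbinom(x1, s, 0.5, log = TRUE)))
    r <- 1 / phi
    sum((lgamma(x1 + r) - lgamma(r) - lfactorial(x1)) +
          (lgamma(s - x1 + r) - lgamma(r) - lfactorial(s - x1)) -
          (lgamma(s + 2 * r) - lgamma(2 * r) - lfactorial(s)))
  }
  grid <- c(0, 10^seq(-4, log10(phi_max), length.out = 30))
  ll <- vapply(grid, loglik, numeric(1))
  i <- which.max(ll)
  lo <- grid[max(i - 1, 1)]; hi <- grid[min(i + 1, length(grid))]
  if (lo == hi) return(lo)
  opt <- stats::optimize(loglik, c(lo, hi), maximum = TRUE, tol = 1e-8)
  if (loglik(0) >= opt$objective) 0 else opt$maximum
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up q-values controlling the false discovery rate; monotone, capped
#' at 1, original order preserved.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("argument error: p-values must lie in [0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' Classify species-specific expression with the two-group replication rule
#'
#' For each of the two replicate-defined sample triples (G1: replicate 1 of
#' the duplicated species plus the two others; G2: replicate 2 likewise),
#' runs the exact NB test on all three pairwise comparisons, adjusts with
#' Benjamini-Hochberg within each comparison (or pooled across the three,
#' with `bh_scope = "pooled"`), and calls a row specific to species S when
#' both comparisons involving S are significant and the out-group comparison
#' is not — in both groups.
#'
#' @param counts Integer matrix, loci x 4 samples (equalised libraries).
#' @param phi Common dispersion from [estimate_common_dispersion()].
#' @param sample_species Named character vector mapping each column of
#'   `counts` to a species; exactly one species must have two samples.
#' @param fdr_q FDR threshold (default 0.05).
#' @param bh_scope `"per_comparison"` (default) or `"pooled"`.
#' @param variant Exact-test variant, see [nb_exact_test()].
#' @return List with `call` (character vector per row: a species name or
#'   `"none"`) and `details` (per-group significance matrices).
#' @export
classify_species_specific <- function(counts, phi, sample_species,
                                      fdr_q = 0.05,
                                      bh_scope = c("per_comparison",
                                                   "pooled"),
                                      variant = "small_p") {
  bh_scope <- match.arg(bh_scope)
  stopifnot(ncol(counts) == 4, !is.null(names(sample_species)),
            all(colnames(counts) %in% names(sample_species)))
  sp <- sample_species[colnames(counts)]
  dup_species <- names(which(table(sp) == 2))
  if (length(dup_species) != 1)
    stop("argument error: exactly one species must be duplicated")
  others <- setdiff(unique(sp), dup_species)
  stopifnot(length(others) == 2)
  reps <- names(sp)[sp == dup_species]
  other_cols <- vapply(others, function(s) names(sp)[sp == s], character(1))

  group_sig <- list()
  for (g in 1:2) {
    cols <- c(reps[g], other_cols)
    spg <- c(dup_species, others)          # species of each column in cols
    pairs <- utils::combn(3, 2)
    pmat <- sapply(seq_len(ncol(pairs)), function(k) {
      i <- pairs[1, k]; j <- pairs[2, k]
      .nb_exact_pvec(counts[, cols[i]], counts[, cols[j]], phi, variant)
    })
    colnames(pmat) <- apply(pairs, 2, function(ij)
      paste(spg[ij[1]], spg[ij[2]], sep = "_vs_"))
    qmat <- if (bh_scope == "per_comparison") apply(pmat, 2, bh_adjust) else
      matrix(bh_adjust(as.vector(pmat)), ncol = ncol(pmat),
             dimnames = dimnames(pmat))
    group_sig[[g]] <- qmat < fdr_q
  }
  comp_names <- colnames(group_sig[[1]])
  all_species <- c(dup_species, others)
  call <- rep("none", nrow(counts))
  for (s_ in all_species) {
    inv <- grepl(paste0("(^|_vs_)", s_, "($|_vs_)"), comp_names)
    stopifnot(sum(inv) == 2, sum(!inv) == 1)
    ok <- Reduce(`&`, lapply(group_sig, function(sig)
      sig[, which(inv)[1]] & sig[, which(inv)[2]] & !sig[, which(!inv)]))
    call[ok & call == "none"] <- s_
  }
  list(call = call, details = group_sig)
}
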
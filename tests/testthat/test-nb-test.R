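# Independent enumeration oracle for the conditional split distribution:
# joint NB probabilities (any mean; the conditional is mean-free), normalised
# over all splits of the total, then small-p summation.
oracle_nb_exact <- function(xa, xb, phi, mu = 5) {
  s <- xa + xb
  if (s == 0) return(1)
  size <- if (phi > 0) 1 / phi else Inf
  joint <- if (is.finite(size))
    dnbinom(0:s, size = size, mu = mu) * dnbinom(s:0, size = size, mu = mu)
  else
    dpois(0:s, mu) * dpois(s:0, mu)
  pr <- joint / sum(joint)
  sum(pr[pr <= pr[xa + 1] * (1 + 1e-10)])
}

test_that("equal counts give p = 1 and zero totals give p = 1", {
  expect_equal(nb_exact_test(7, 7, 0.1), 1)
  expect_equal(nb_exact_test(0, 0, 0.1), 1)
  expect_equal(nb_exact_test(0, 0, 0), 1)
})

test_that("unequal libraries are rejected", {
  expect_error(nb_exact_test(3, 5, 0.1, lib_a = 100, lib_b = 200),
               "equalised")
})

test_that("phi = 0 reduces to the exact Binomial(s, 1/2) test", {
  set.seed(19)
  for (i in 1:100) {
    s <- sample(1:80, 1)
    xa <- sample(0:s, 1)
    got <- nb_exact_test(xa, s - xa, 0)
    pr <- dbinom(0:s, s, 0.5)
    want <- sum(pr[pr <= pr[xa + 1] * (1 + 1e-10)])
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("exact test equals the enumeration oracle, including (30, 5)", {
  expect_equal(nb_exact_test(30, 5, 0.5), oracle_nb_exact(30, 5, 0.5),
               tolerance = 1e-10)
  set.seed(29)
  for (phi in c(0, 0.1, 0.5)) for (i in 1:40) {
    s <- sample(1:120, 1)
    xa <- sample(0:s, 1)
    expect_equal(nb_exact_test(xa, s - xa, phi),
                 oracle_nb_exact(xa, s - xa, phi), tolerance = 1e-9)
  }
})

test_that("vectorised p-values match the scalar implementation", {
  set.seed(7)
  xa <- rpois(200, 20); xb <- rpois(200, 20)
  pv <- htrtools:::.nb_exact_pvec(xa, xb, 0.2)
  ps <- mapply(nb_exact_test, xa, xb, MoreArgs = list(phi = 0.2))
  expect_equal(pv, ps, tolerance = 1e-12)
  # doubling variant too
  pv2 <- htrtools:::.nb_exact_pvec(xa, xb, 0.2, variant = "doubling")
  ps2 <- mapply(nb_exact_test, xa, xb,
                MoreArgs = list(phi = 0.2, variant = "doubling"))
  expect_equal(pv2, ps2, tolerance = 1e-12)
})

test_that("common dispersion is recovered from replicate data", {
  set.seed(57)
  n <- 5000
  mu <- rlnorm(n, log(60), 0.7)
  # phi = 0.2
  counts <- cbind(rnbinom(n, mu = mu, size = 5), rnbinom(n, mu = mu, size = 5))
  phi_hat <- estimate_common_dispersion(counts)
  expect_gt(phi_hat, 0.15)
  expect_lt(phi_hat, 0.25)
  # Poisson data drives the estimate to the boundary
  counts0 <- cbind(rpois(n, mu), rpois(n, mu))
  expect_lte(estimate_common_dispersion(counts0), 0.01)
  # identical columns: no overdispersion signal at all
  x <- rpois(500, 30)
  expect_lte(estimate_common_dispersion(cbind(x, x)), 1e-6)
  expect_error(estimate_common_dispersion(matrix(0L, 10, 2)),
               "all rows have zero")
})

test_that("dispersion estimate agrees with edgeR's qCML at equal libraries", {
  set.seed(91)
  n <- 4000
  mu <- rlnorm(n, log(50), 0.6)
  counts <- cbind(rnbinom(n, mu = mu, size = 10),
                  rnbinom(n, mu = mu, size = 10))
  # equalise library sizes exactly so the conditional likelihood applies
  # without pseudocount adjustment differences
  phi_ours <- estimate_common_dispersion(counts)
  d <- edgeR::DGEList(counts = counts,
                      lib.size = rep(round(mean(colSums(counts))), 2))
  phi_edger <- edgeR::estimateCommonDisp(d)$common.dispersion
  expect_equal(phi_ours, phi_edger, tolerance = 0.02)
})

test_that("exact test p-values agree with edgeR's exactTest", {
  set.seed(93)
  n <- 300
  mu <- rlnorm(n, log(40), 0.5)
  counts <- cbind(rnbinom(n, mu = mu, size = 8),
                  rnbinom(n, mu = 4 * mu, size = 8))
  phi <- 1 / 8
  lib <- round(mean(colSums(counts)))
  d <- edgeR::DGEList(counts = counts, lib.size = c(lib, lib),
                      group = c(1, 2))
  d$common.dispersion <- phi
  p_edger <- edgeR::exactTest(d, dispersion = phi)$table$PValue
  p_ours <- htrtools:::.nb_exact_pvec(counts[, 1], counts[, 2], phi)
  expect_equal(p_ours, p_edger, tolerance = 1e-6)
})

test_that("the two-group rule never calls rows significant in one group only", {
  set.seed(77)
  n <- 800
  mu <- rlnorm(n, log(40), 0.5)
  phi <- 0.1
  draw <- function(m) rnbinom(n, mu = m, size = 1 / phi)
  # plant H1-only spikes: G1 would call them, G2 must veto
  spike <- seq_len(80)
  muH1 <- mu; muH1[spike] <- mu[spike] * 8
  counts <- cbind(H1 = draw(muH1), H2 = draw(mu), C = draw(mu), M = draw(mu))
  res <- classify_species_specific(
    counts, phi, c(H1 = "human", H2 = "human", C = "chimp", M = "macaque"))
  g1_only <- res$details[[1]] & !res$details[[2]]
  # rows flagged human-like in G1 alone never survive to a call
  hc <- which(g1_only[, grep("human_vs_chimp", colnames(g1_only))] &
                g1_only[, grep("human_vs_macaque", colnames(g1_only))])
  expect_true(all(res$call[setdiff(hc, which(res$details[[2]][, 1] &
                                               res$details[[2]][, 2]))]
                  == "none"))
  # and with a real shared human shift, calls do appear
  muH <- mu; muH[spike] <- mu[spike] * 6
  counts2 <- cbind(H1 = draw(muH), H2 = draw(muH), C = draw(mu),
                   M = draw(mu))
  res2 <- classify_species_specific(
    counts2, phi, c(H1 = "human", H2 = "human", C = "chimp", M = "macaque"))
  expect_gt(sum(res2$call[spike] == "human"), 40)
  expect_lt(mean(res2$call[-spike] != "none"), 0.02)
})

test_that("identical rows are never called species-specific", {
  counts <- matrix(25L, 50, 4,
                   dimnames = list(NULL, c("H1", "H2", "C", "M")))
  res <- classify_species_specific(
    counts, 0.1, c(H1 = "human", H2 = "human", C = "chimp", M = "macaque"))
  expect_true(all(res$call == "none"))
})

test_that("species labels permute calls symmetrically", {
  set.seed(15)
  n <- 400
  mu <- rlnorm(n, log(50), 0.4)
  phi <- 0.05
  draw <- function(m) rnbinom(n, mu = m, size = 1 / phi)
  spike <- 1:40
  muC <- mu; muC[spike] <- mu[spike] * 6
  counts <- cbind(H1 = draw(mu), H2 = draw(mu), C = draw(muC), M = draw(mu))
  sp <- c(H1 = "human", H2 = "human", C = "chimp", M = "macaque")
  res <- classify_species_specific(counts, phi, sp)
  # relabel chimp<->macaque columns and check calls swap
  sp_swapped <- c(H1 = "human", H2 = "human", C = "macaque", M = "chimp")
  res_sw <- classify_species_specific(counts, phi, sp_swapped)
  expect_equal(res_sw$call == "macaque", res$call == "chimp")
})
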
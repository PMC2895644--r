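#' Generate the full synthetic input bundle
#'
#' Simulates the genome with planted ground truth, one read sample per
#' species (two for the reference species, giving the four-sample design
#' Human1/Human2/Chimpanzee/Macaque), the ancillary evidence (ESTs,
#' three-species alignment blocks, conservation), then rRNA-excludes,
#' restricts to uniquely mapped reads and equalises library sizes by
#' subsampling every sample to the smallest surviving count.
#'
#' @param cfg A [simulation_config()].
#' @return List: `annot`, `truth`, `cfg`, `reads_raw` (named list),
#'   `reads` (filtered, equalised), `samples` (data frame sample/species),
#'   `ancillary`.
#' @export
pipeline_inputs <- function(cfg = simulation_config()) {
  sim <- simulate_genome(cfg)
  ref <- cfg$species[1]
  samples <- data.frame(
    sample = c(paste0(ref, 1), paste0(ref, 2), cfg$species[-1]),
    species = c(ref, ref, cfg$species[-1]), stringsAsFactors = FALSE)
  reads_raw <- lapply(seq_len(nrow(samples)), function(i)
    simulate_reads(sim$annot, sim$truth, cfg, samples$sample[i],
                   samples$species[i]))
  names(reads_raw) <- samples$sample
  filtered <- lapply(reads_raw, filter_reads, annot = sim$annot,
                     unique_only = TRUE)
  eq_n <- min(lengths(filtered))
  reads <- lapply(seq_along(filtered), function(i)
    filter_reads(filtered[[i]], sim$annot, unique_only = TRUE,
                 subsample_n = eq_n, seed = cfg$seed + i))
  names(reads) <- names(filtered)
  anc <- simulate_ancillary(sim$annot, sim$truth, cfg)
  list(annot = sim$annot, truth = sim$truth, cfg = cfg,
       reads_raw = reads_raw, reads = reads, samples = samples,
       ancillary = anc)
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes every stage on one seed-pinned synthetic dataset: transcriptome
#' composition, repeat-family activity, HTR/igHTR detection with
#' cross-sample unification, clustering and gene proximity, EST overlap and
#' connection permutation tests, conservation resampling, expression
#' divergence (quantile normalisation, distances, UPGMA bootstrap),
#' common-dispersion estimation and species-specific calls for genes and
#' equal-read genomic windows, the intergenic-excess binomial test, and CSF
#' coding-potential training/evaluation. All randomness derives from
#' `cfg$seed`, so two runs write byte-identical outputs.
#'
#' @param cfg A [simulation_config()].
#' @param outdir Output directory for the result tables (created if
#'   needed); `NULL` skips writing.
#' @param perm_B Permutation iterations for the overlap/connection tests.
#' @param boot_B Bootstrap iterations (repeat CIs, tree support).
#' @return Invisible list with every stage's result object.
#' @export
run_pipeline <- function(cfg = simulation_config(), outdir = NULL,
                         perm_B = 1000L, boot_B = 1000L) {
  inp <- pipeline_inputs(cfg)
  annot <- inp$annot; truth <- inp$truth
  res <- list(inputs_summary = data.frame(
    sample = inp$samples$sample, species = inp$samples$species,
    raw_reads = lengths(inp$reads_raw), equalised_reads = lengths(inp$reads)))

  ## 1. composition
  res$composition <- do.call(rbind, lapply(names(inp$reads), function(sn) {
    cs <- composition_summary(inp$reads[[sn]], annot, mode = "reads")
    cbind(sample = sn, as.data.frame(cs))
  }))
  res$repeat_bias <- repeat_assignment_bias(inp$reads[[1]], annot)

  ## 2. repeat activity (reference sample), ordered by age rank
  fams <- repeat_families(truth$repeats, cfg$repeat_families)
  act <- family_activity(fams, inp$reads[[1]], bootstrap_B = boot_B,
                         seed = cfg$seed + 101)
  res$repeat_activity <- age_activity_table(act, fams)

  ## 3. HTR calling per sample, igHTR, unification, clusters
  htr_by_sample <- lapply(names(inp$reads), function(sn)
    classify_ightr(call_htr(inp$reads[[sn]], htr_params(), sample_id = sn),
                   annot))
  names(htr_by_sample) <- names(inp$reads)
  res$htr_by_sample <- htr_by_sample
  res$unified_htr <- unify_htr_across_samples(
    lapply(htr_by_sample, GenomicRanges::granges),
    reads_by_sample = inp$reads)
  ref_ightr <- htr_by_sample[[1]][htr_by_sample[[1]]$is_ightr]
  cl <- cluster_and_assign_genes(ref_ightr, annot)
  res$ightr <- cl$ightrs
  res$clusters <- cl$clusters

  ## 4. permutation evidence: EST overlap, connections, conservation
  ig_space <- intergenic_space(annot)
  est_fp <- unlist(inp$ancillary$ests)
  if (length(ref_ightr)) {
    res$est_overlap <- overlap_permutation_test(
      GenomicRanges::granges(ref_ightr), est_fp, background = ig_space,
      exclusion = truth$repeats, B = perm_B, seed = cfg$seed + 201)
    res$est_connection <- connection_permutation_test(
      "ightr_ightr", res$ightr, annot, inp$ancillary$ests,
      background = ig_space, exclusion = truth$repeats, B = perm_B,
      seed = cfg$seed + 202)
    res$gene3_connection <- connection_permutation_test(
      "gene3_ightr", res$ightr, annot, inp$ancillary$ests,
      background = ig_space, exclusion = truth$repeats, B = perm_B,
      seed = cfg$seed + 203)
    res$conservation <- conservation_resampled_ci(
      list(ightr = GenomicRanges::granges(ref_ightr),
           exon = annot$categories$exon,
           genic = GenomicRanges::granges(annot$genes),
           intergenic = annot$categories$intergenic),
      inp$ancillary$conservation, n_resamples = boot_B,
      seed = cfg$seed + 204)
  }

  ## 5. expression divergence over genes
  em <- build_expression_matrix(inp$reads, annot, detected_in_min = 2)
  res$expression <- em
  qn <- quantile_normalize(em$rates)
  res$divergence_tree <- upgma_bootstrap(qn, measure = "euclidean",
                                         z_transform = TRUE, B = boot_B,
                                         seed = cfg$seed + 301)
  res$distances <- lapply(
    c(euclidean = "euclidean", manhattan = "manhattan",
      one_minus_rho = "one_minus_rho"),
    function(m) expression_distance(qn, m, z_transform = (m != "one_minus_rho")))

  ## 6. species-specific expression: genes
  ref <- cfg$species[1]
  sample_species <- setNames(inp$samples$species, inp$samples$sample)
  phi <- estimate_common_dispersion(
    em$counts[, inp$samples$sample[sample_species == ref], drop = FALSE])
  res$phi <- phi
  res$gene_calls <- classify_species_specific(em$counts, phi, sample_species)

  ## 7. equal-read genomic windows and their species-specific calls
  by_species <- lapply(unique(inp$samples$species), function(sp)
    do.call(c, unname(lapply(inp$reads[inp$samples$sample[
      inp$samples$species == sp]], GenomicRanges::granges))))
  names(by_species) <- unique(inp$samples$species)
  gw <- equal_read_windows(by_species, inp$ancillary$blocks,
                           n_per_window = 50L)
  res$gw <- gw
  if (length(gw)) {
    gw_counts <- sapply(inp$reads, function(r)
      GenomicRanges::countOverlaps(gw, r, ignore.strand = TRUE))
    res$gw_calls <- classify_species_specific(gw_counts, phi, sample_species)
    gw_cat <- assign_read_category(GenomicRanges::granges(gw), annot)
    ss <- res$gw_calls$call != "none"
    if (any(ss)) {
      p0 <- mean(gw_cat %in% c("intergenic", "intergenic_repeat"))
      k <- sum(gw_cat[ss] %in% c("intergenic", "intergenic_repeat"))
      res$gw_intergenic_excess <- list(
        k = k, n = sum(ss), p0 = p0,
        p = binomial_excess_test(k, sum(ss), p0))
    }
  }

  ## 8. CSF coding potential: train on one half, evaluate held out
  set.seed(cfg$seed + 401)
  train_c <- replicate(40, simulate_codon_alignment(500, "coding"),
                       simplify = FALSE)
  train_n <- replicate(40, simulate_codon_alignment(500, "noncoding"),
                       simplify = FALSE)
  csf <- build_csf_matrix(train_c, train_n)
  res$csf_matrix <- csf
  score_loci <- function(n, proc) vapply(seq_len(n), function(i) {
    a <- simulate_codon_alignment(120, proc)
    max_csf_score(a$ref, a$other, csf)$max_score
  }, numeric(1))
  # cutoff chosen on training loci, applied to held-out loci
  cutoff <- choose_csf_cutoff(score_loci(40, "coding"),
                              score_loci(40, "noncoding"))
  sc_c <- score_loci(50, "coding")
  sc_n <- score_loci(50, "noncoding")
  res$csf_eval <- list(
    cutoff = cutoff,
    sensitivity = mean(classify_coding(sc_c, cutoff)$coding),
    specificity = 1 - mean(classify_coding(sc_n, cutoff)$coding),
    scores_coding = sc_c, scores_noncoding = sc_n)

  ## ground-truth benchmarking of igHTR recovery
  res$ightr_recovery <- ightr_recovery(ref_ightr, truth)

  if (!is.null(outdir)) .write_pipeline_outputs(res, inp, outdir)
  invisible(c(res, list(inputs = inp)))
}

#' Planted igHTR recovery metrics
#'
#' @param called `GRanges` of called igHTR.
#' @param truth `GroundTruth` with `planted_ightr`.
#' @return List: `recall`, `n_planted`, `n_called`, `max_boundary_error`
#'   (per recovered unit, the unified boundary of its matching calls -- the
#'   5'-most/3'-most rule the method itself uses -- is compared with truth;
#'   the maximum absolute deviation in nt is reported), `precision`
#'   (fraction of calls overlapping a planted unit).
#' @export
ightr_recovery <- function(called, truth) {
  pl <- truth$planted_ightr
  if (length(pl) == 0)
    return(list(recall = NA_real_, n_planted = 0L,
                n_called = length(called), max_boundary_error = NA_real_,
                precision = NA_real_))
  hits <- GenomicRanges::findOverlaps(pl, called, ignore.strand = TRUE)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  recovered <- unique(q)
  berr <- NA_real_
  if (length(hits)) {
    uni_start <- tapply(BiocGenerics::start(called)[s], q, min)
    uni_end <- tapply(BiocGenerics::end(called)[s], q, max)
    ui <- as.integer(names(uni_start))
    berr <- max(abs(uni_start - BiocGenerics::start(pl)[ui]),
                abs(uni_end - BiocGenerics::end(pl)[ui]))
  }
  list(recall = length(recovered) / length(pl), n_planted = length(pl),
       n_called = length(called), max_boundary_error = berr,
       precision = if (length(called))
         mean(IRanges::overlapsAny(called, pl, ignore.strand = TRUE)) else
         NA_real_)
}

.write_pipeline_outputs <- function(res, inp, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, f) write.table(x, file.path(outdir, f), sep = "\t",
                                   quote = FALSE, row.names = FALSE)
  wt(res$inputs_summary, "samples.tsv")
  wt(res$composition, "composition.tsv")
  wt(res$repeat_activity, "repeat_activity.tsv")
  wt(as.data.frame(res$unified_htr), "unified_htr.tsv")
  wt(as.data.frame(res$ightr), "ightr.tsv")
  write_intervals(GenomicRanges::granges(res$ightr),
                  file.path(outdir, "ightr.bed"))
  if (!is.null(res$est_overlap))
    wt(data.frame(test = c("est_overlap", "est_connection",
                           "gene3_connection"),
                  observed = c(res$est_overlap$observed,
                               res$est_connection$observed,
                               res$gene3_connection$observed),
                  null_mean = c(mean(res$est_overlap$null_values),
                                mean(res$est_connection$null_values),
                                mean(res$gene3_connection$null_values)),
                  p = c(res$est_overlap$empirical_p,
                        res$est_connection$empirical_p,
                        res$gene3_connection$empirical_p)),
       "permutation_tests.tsv")
  if (!is.null(res$conservation)) wt(res$conservation, "conservation.tsv")
  ape::write.tree(res$divergence_tree$tree,
                  file.path(outdir, "divergence_upgma.nwk"))
  wt(data.frame(clade = names(res$divergence_tree$support),
                support = res$divergence_tree$support),
     "tree_support.tsv")
  wt(data.frame(gene = rownames(res$expression$counts),
                res$expression$counts, call = res$gene_calls$call),
     "gene_species_specific.tsv")
  wt(data.frame(phi = res$phi, n_ightr = sum(res$ightr$is_ightr %||% NA),
                recall = res$ightr_recovery$recall,
                csf_sensitivity = res$csf_eval$sensitivity,
                csf_specificity = res$csf_eval$specificity),
     "summary.tsv")
  if (!is.null(res$gw) && length(res$gw))
    wt(as.data.frame(res$gw), "genomic_windows.tsv")
  if (!is.null(res$gw_intergenic_excess))
    wt(as.data.frame(res$gw_intergenic_excess), "gw_intergenic_excess.tsv")
  invisible(outdir)
}
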
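#' Simulation configuration
#'
#' Parameters of the synthetic MeDIP-seq study generator. Defaults describe
#' the two-group (sedentary vs exercise-trained) design the package is built
#' around: 200 genes on a 1 Mb genome, 4 samples per group, 10% of promoters
#' carrying a planted 3-fold methylation shift, and 10,000 aligned reads per
#' sample of which 10% are uniform background.
#'
#' @param genome_length Genome size in bp (single contig); must be >= 10,000
#'   and large enough to host `n_genes` non-overlapping gene loci with their
#'   promoter windows (about 2,600 bp per gene).
#' @param n_genes Number of non-overlapping gene models to plant.
#' @param n_samples_per_group Biological replicates per condition.
#' @param island_density Planted CpG islands per 100 kb of genome.
#' @param planted_dmr_fraction Fraction of promoters given a differential
#'   methylation effect between conditions.
#' @param dmr_effect Multiplicative methylation shift of planted promoters
#'   (>= 1; hyper- and hypomethylation directions are assigned at random).
#' @param mean_depth Expected aligned reads per sample (Poisson).
#' @param background_rate Fraction of reads placed uniformly on the genome
#'   irrespective of methylation.
#' @param pyro_depth Pyrosequencing reads per CpG site.
#' @param conversion_efficiency Bisulfite conversion probability of an
#'   unmethylated cytosine, in `[0, 1]`.
#' @param seed Root RNG seed; every simulator output is a pure function of
#'   the configuration including this seed.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(genome_length = 1e6,
                       n_genes = 200,
                       n_samples_per_group = 4,
                       island_density = 10,
                       planted_dmr_fraction = 0.1,
                       dmr_effect = 3,
                       mean_depth = 10000,
                       background_rate = 0.1,
                       pyro_depth = 100,
                       conversion_efficiency = 0.99,
                       seed = 1L) {
  for (nm in c("n_genes", "n_samples_per_group", "mean_depth", "pyro_depth")) {
    if (!.is_count(get(nm))) .stopf("sim_config: '%s' must be a count >= 1", nm)
  }
  if (!is.numeric(genome_length) || length(genome_length) != 1L ||
      genome_length < 10000) {
    .stopf("sim_config: 'genome_length' must be >= 10,000 bp")
  }
  for (nm in c("planted_dmr_fraction", "background_rate",
               "conversion_efficiency")) {
    if (!.is_fraction(get(nm))) .stopf("sim_config: '%s' must lie in [0, 1]", nm)
  }
  if (!is.numeric(dmr_effect) || dmr_effect < 1) {
    .stopf("sim_config: 'dmr_effect' must be >= 1")
  }
  if (!is.numeric(island_density) || island_density < 0) {
    .stopf("sim_config: 'island_density' must be >= 0")
  }
  if (!.is_count(seed + 1)) .stopf("sim_config: 'seed' must be an integer")
  structure(list(
    genome_length = as.integer(genome_length),
    n_genes = as.integer(n_genes),
    n_samples_per_group = as.integer(n_samples_per_group),
    island_density = island_density,
    planted_dmr_fraction = planted_dmr_fraction,
    dmr_effect = dmr_effect,
    mean_depth = as.integer(mean_depth),
    background_rate = background_rate,
    pyro_depth = as.integer(pyro_depth),
    conversion_efficiency = conversion_efficiency,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Annotation configuration
#'
#' Windows and composition thresholds used to derive promoter, gene-body and
#' CpG-island annotations. Defaults: promoters span -700/+200 bp around the
#' TSS; gene bodies run from +2,000 bp downstream of the TSS to the TTS for
#' genes longer than 3,000 bp; CpG islands are >= 200 bp with GC content
#' >= 50% and CpG observed/expected ratio >= 0.6.
#'
#' @param promoter_upstream,promoter_downstream Promoter extent in bp
#'   upstream/downstream of the TSS (strand-aware).
#' @param body_offset Distance in bp from the TSS at which the gene body
#'   starts.
#' @param body_min_gene_length Genes must be strictly longer than this (bp)
#'   to receive a gene-body interval.
#' @param island_min_length Minimum CpG-island length in bp.
#' @param island_min_gc Minimum G+C fraction of an island, in `(0, 1]`.
#' @param island_min_obs_exp Minimum CpG observed/expected ratio, in `(0, 2]`.
#' @return A validated list of class `"annotation_config"`.
#' @export
annotation_config <- function(promoter_upstream = 700,
                              promoter_downstream = 200,
                              body_offset = 2000,
                              body_min_gene_length = 3000,
                              island_min_length = 200,
                              island_min_gc = 0.50,
                              island_min_obs_exp = 0.6) {
  vals <- c(promoter_upstream = promoter_upstream,
            promoter_downstream = promoter_downstream,
            body_offset = body_offset,
            body_min_gene_length = body_min_gene_length,
            island_min_length = island_min_length)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    .stopf("annotation_config: window sizes must all be positive")
  }
  if (!(island_min_gc > 0 && island_min_gc <= 1)) {
    .stopf("annotation_config: 'island_min_gc' must lie in (0, 1]")
  }
  if (!(island_min_obs_exp > 0 && island_min_obs_exp <= 2)) {
    .stopf("annotation_config: 'island_min_obs_exp' must lie in (0, 2]")
  }
  structure(list(
    promoter_upstream = as.integer(promoter_upstream),
    promoter_downstream = as.integer(promoter_downstream),
    body_offset = as.integer(body_offset),
    body_min_gene_length = as.integer(body_min_gene_length),
    island_min_length = as.integer(island_min_length),
    island_min_gc = island_min_gc,
    island_min_obs_exp = island_min_obs_exp
  ), class = "annotation_config")
}

#' Scoring configuration
#'
#' Read extension and methylation-status thresholds for regional MeDIP
#' scoring. Each uniquely aligned read is extended to `extension_length`
#' (default 250 bp) toward its 3' end; a region scores as extended reads per
#' kb, and is called unmethylated below `unmethylated_max` (9.48 reads/kb),
#' completely methylated above `methylated_min` (50.62 reads/kb), and
#' partially methylated in the closed interval between them.
#'
#' @param extension_length Extended read length in bp.
#' @param unmethylated_max Upper score bound (exclusive) of the unmethylated
#'   state, reads/kb.
#' @param methylated_min Lower score bound (exclusive) of the completely
#'   methylated state, reads/kb.
#' @param normalize `"none"` (scores are absolute reads/kb, matching the
#'   status thresholds) or `"per-million"` (counts scaled to reads per
#'   million before the per-kb division, for cross-sample comparison).
#' @return A validated list of class `"scoring_config"`.
#' @export
scoring_config <- function(extension_length = 250,
                           unmethylated_max = 9.48,
                           methylated_min = 50.62,
                           normalize = c("none", "per-million")) {
  normalize <- match.arg(normalize)
  if (!.is_pos_scalar(extension_length)) {
    .stopf("scoring_config: 'extension_length' must be positive")
  }
  if (!(.is_pos_scalar(unmethylated_max) && .is_pos_scalar(methylated_min) &&
        unmethylated_max < methylated_min)) {
    .stopf("scoring_config: need 0 < unmethylated_max < methylated_min")
  }
  structure(list(
    extension_length = as.integer(extension_length),
    unmethylated_max = unmethylated_max,
    methylated_min = methylated_min,
    normalize = normalize
  ), class = "scoring_config")
}

#' DMR-calling configuration
#'
#' Thresholds of the differential-methylation filter cascade: a promoter is
#' called differentially methylated when P < `p_threshold` and fold change
#' > `fc_threshold`; candidate reporting additionally requires the larger
#' group-mean MeDIP score to exceed `min_medip_score`.
#'
#' @param p_threshold Raw P-value cut-off (default 0.05).
#' @param fc_threshold Fold-change cut-off, strict, on the >= 1 folded ratio
#'   (default 1.5).
#' @param min_medip_score Candidate filter: larger group-mean score must
#'   exceed this many reads/kb (default 10).
#' @param test `"welch_t_log"` (Welch's t on log2(score + pseudocount)) or
#'   `"permutation"` (exact enumeration of group-label reassignments when
#'   there are at most 12,870 arrangements, Monte Carlo otherwise).
#' @param pseudocount Reads/kb added to means and scores before ratios and
#'   logs (guards division by zero).
#' @param candidate_window Half-width in bp of the TSS-centred window used
#'   for candidate reporting (distinct from the scoring promoter window).
#' @param n_perm Monte-Carlo permutation count when exact enumeration is not
#'   feasible.
#' @param adjust If `TRUE`, the pass filter uses Benjamini-Hochberg adjusted
#'   P-values instead of raw ones (raw is the default behaviour).
#' @return A validated list of class `"dmr_config"`.
#' @export
dmr_config <- function(p_threshold = 0.05,
                       fc_threshold = 1.5,
                       min_medip_score = 10,
                       test = c("welch_t_log", "permutation"),
                       pseudocount = 0.5,
                       candidate_window = 500,
                       n_perm = 10000,
                       adjust = FALSE) {
  test <- match.arg(test)
  if (!(is.numeric(p_threshold) && p_threshold > 0 && p_threshold < 1)) {
    .stopf("dmr_config: 'p_threshold' must lie in (0, 1)")
  }
  if (!(is.numeric(fc_threshold) && fc_threshold > 1)) {
    .stopf("dmr_config: 'fc_threshold' must be > 1")
  }
  if (!.is_pos_scalar(pseudocount)) {
    .stopf("dmr_config: 'pseudocount' must be > 0")
  }
  if (!is.numeric(min_medip_score) || min_medip_score < 0) {
    .stopf("dmr_config: 'min_medip_score' must be >= 0")
  }
  if (!.is_count(n_perm)) .stopf("dmr_config: 'n_perm' must be a count")
  structure(list(
    p_threshold = p_threshold,
    fc_threshold = fc_threshold,
    min_medip_score = min_medip_score,
    test = test,
    pseudocount = pseudocount,
    candidate_window = as.integer(candidate_window),
    n_perm = as.integer(n_perm),
    adjust = isTRUE(adjust)
  ), class = "dmr_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("MeDIP simulation config:\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
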
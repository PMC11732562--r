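#' Pipeline configuration
#'
#' Bundles the per-stage configurations plus enrichment, motif and pyro
#' settings into one object that fully determines a pipeline run (together
#' with nothing else: all randomness derives from `sim$seed`).
#'
#' @param sim A [sim_config()].
#' @param annotation An [annotation_config()].
#' @param scoring A [scoring_config()].
#' @param dmr A [dmr_config()].
#' @param gsea List: `n_perm`, `weight_p`, and optionally `gene_sets` (a
#'   GMT path; when `NULL`, demonstration sets are built from the
#'   simulation, including the planted gene set).
#' @param motif List: `pfm` (JASPAR PFM path or `NULL` for the built-in
#'   [nbre_like_motif()]) and `threshold` (fraction of max).
#' @param pyro List: `n_replicates` per condition and `min_efficiency` for
#'   conversion QC.
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            annotation = annotation_config(),
                            scoring = scoring_config(),
                            dmr = dmr_config(),
                            gsea = list(n_perm = 1000, weight_p = 1,
                                        gene_sets = NULL),
                            motif = list(pfm = NULL, threshold = 0.8),
                            pyro = list(n_replicates = 4,
                                        min_efficiency = 0.95)) {
  stopifnot(inherits(sim, "sim_config"), inherits(annotation, "annotation_config"),
            inherits(scoring, "scoring_config"), inherits(dmr, "dmr_config"))
  structure(list(sim = sim, annotation = annotation, scoring = scoring,
                 dmr = dmr, gsea = gsea, motif = motif, pyro = pyro),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' The YAML echo written into every output directory reproduces the run
#' exactly when read back.
#'
#' @param cfg A `"pipeline_config"`.
#' @param path YAML path.
#' @export
write_pipeline_config <- function(cfg, path) {
  plain <- lapply(cfg, function(x) if (is.list(x)) unclass(x) else x)
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  pipeline_config(
    sim = do.call(sim_config, y$sim),
    annotation = do.call(annotation_config, y$annotation),
    scoring = do.call(scoring_config, y$scoring),
    dmr = do.call(dmr_config, y$dmr),
    gsea = if (!is.null(y$gsea)) y$gsea else list(n_perm = 1000, weight_p = 1,
                                                  gene_sets = NULL),
    motif = if (!is.null(y$motif)) y$motif else list(pfm = NULL, threshold = 0.8),
    pyro = if (!is.null(y$pyro)) y$pyro else list(n_replicates = 4,
                                                  min_efficiency = 0.95))
}

#' Run the full pipeline: simulate, annotate, score, call DMRs, enrich,
#' scan motifs, pyro-validate
#'
#' Executes every stage on synthetic data with planted truth, writes all
#' stage artifacts (FASTA, BED, TSV, GMT, PFM, YAML echo, Markdown report)
#' into `out_dir`, and returns a run report. Identical configuration gives
#' byte-identical outputs.
#'
#' @param cfg A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress progress messages.
#' @return List of class `"run_report"`: per-stage record counts, the DMR
#'   cascade counts, truth-based evaluation (sensitivity, observed FDR,
#'   direction accuracy), enrichment and motif summaries, and pyro
#'   concordance.
#' @export
run_pipeline <- function(cfg = pipeline_config(), out_dir = tempfile("mediprun"),
                         quiet = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  write_pipeline_config(cfg, file.path(out_dir, "config.yaml"))

  ## stage 1: simulate ------------------------------------------------
  sim <- simulate_genome(cfg$sim, cfg$annotation)
  write_genome_fasta(sim$genome, file.path(out_dir, "genome.fa"))
  write_gene_models_bed12(sim$genes, file.path(out_dir, "genes.bed"))
  write_methylome_tsv(sim$methylome, file.path(out_dir, "methylome_truth.tsv"))
  .write_tsv(sim$truth, file.path(out_dir, "truth_table.tsv"))
  reads <- c(simulate_medip_reads(sim, "sedentary"),
             simulate_medip_reads(sim, "trained"))
  for (nm in names(reads)) {
    write_bed6(reads[[nm]], file.path(out_dir, paste0("reads_", nm, ".bed")))
  }
  groups <- stats::setNames(
    ifelse(grepl("^sed", names(reads)), "sedentary", "trained"), names(reads))
  say("simulated %d genes, %d samples, ~%d reads/sample",
      length(sim$genes), length(reads), cfg$sim$mean_depth)

  ## stage 2: annotate ------------------------------------------------
  prom <- promoter_intervals(sim$genes, cfg$annotation)
  body <- gene_body_intervals(sim$genes, cfg$annotation)
  islands <- find_cpg_islands(sim$genome, cfg$annotation)
  write_bed6(prom, file.path(out_dir, "promoters.bed"), name_col = "gene_id")
  write_bed6(body, file.path(out_dir, "gene_bodies.bed"), name_col = "gene_id")
  S4Vectors::mcols(islands)$name <- sprintf("cpg_island_%03d",
                                            seq_along(islands))
  write_bed6(islands, file.path(out_dir, "cpg_islands.bed"))
  say("annotated %d promoters, %d gene bodies, %d CpG islands",
      length(prom), length(body), length(islands))

  ## stage 3: score ---------------------------------------------------
  S4Vectors::mcols(prom)$region_id <- S4Vectors::mcols(prom)$gene_id
  scores <- score_matrix(reads, prom, cfg$scoring, groups = groups)
  write_scores_tsv(scores, file.path(out_dir, "promoter_scores.tsv"),
                   cfg$scoring)
  status_tab <- table(scores$status)

  ## stage 4: DMR cascade ---------------------------------------------
  dmrs <- call_dmrs(scores, groups, cfg$dmr, seed = cfg$sim$seed)
  candidates <- filter_candidates(dmrs, cfg$dmr)
  write_dmr_tsv(dmrs, file.path(out_dir, "dmr_all.tsv"), cfg$dmr)
  write_dmr_tsv(candidates, file.path(out_dir, "dmr_candidates.tsv"), cfg$dmr)
  eval_res <- evaluate_dmrs(dmrs, sim$truth)
  .write_tsv(data.frame(metric = c("sensitivity", "fdr", "direction_accuracy"),
                        value = c(eval_res$sensitivity, eval_res$fdr,
                                  eval_res$direction_accuracy)),
             file.path(out_dir, "dmr_evaluation.tsv"))
  say("DMR cascade: %d tested -> %d pass P&FC -> %d pass score filter",
      nrow(dmrs), sum(dmrs$passes_filters), nrow(candidates))

  ## stage 5: enrichment ----------------------------------------------
  metric <- stats::setNames(dmrs$log2fc, dmrs$gene_id)
  gene_sets <- if (!is.null(cfg$gsea$gene_sets)) {
    read_gmt(cfg$gsea$gene_sets)
  } else {
    .demo_gene_sets(sim)
  }
  write_gmt(gene_sets, file.path(out_dir, "gene_sets.gmt"))
  enr <- gsea_table(metric, gene_sets, n_perm = cfg$gsea$n_perm,
                    seed = cfg$sim$seed, weight_p = cfg$gsea$weight_p)
  .write_tsv(enr, file.path(out_dir, "enrichment.tsv"))

  ## stage 6: motif scan over candidate promoters ---------------------
  motif <- if (!is.null(cfg$motif$pfm)) read_jaspar_pfm(cfg$motif$pfm)[[1L]]
           else nbre_like_motif()
  write_jaspar_pfm(motif, file.path(out_dir, "motif.pfm"))
  scan_set <- if (nrow(candidates) > 0) candidates else utils::head(dmrs, 5L)
  hit_rows <- list()
  for (i in seq_len(nrow(scan_set))) {
    s <- scan_set$start[i] + 1L; e <- scan_set$end[i]
    seq_i <- as.character(Biostrings::subseq(sim$genome[[1L]], s, e))
    h <- scan_sequence(motif, seq_i, threshold = cfg$motif$threshold)
    if (nrow(h) > 0) {
      h$start <- h$start + s - 1L; h$end <- h$end + s - 1L
      h$gene_id <- scan_set$gene_id[i]
      hit_rows[[length(hit_rows) + 1L]] <- h
    }
  }
  hits <- if (length(hit_rows)) do.call(rbind, hit_rows) else .empty_hits()
  if (nrow(hits) > 0) {
    write_motif_hits_bed(hits[, 1:6], file.path(out_dir, "motif_hits.bed"),
                         chrom = "chrS", offset = 0L)
  } else {
    file.create(file.path(out_dir, "motif_hits.bed"))
  }

  ## stage 7: pyro validation of the top candidate --------------------
  pyro_gene <- if (nrow(candidates) > 0) candidates$gene_id[1L]
               else dmrs$gene_id[1L]
  pyro_rows <- list()
  for (cond in c("sedentary", "trained")) {
    for (r in seq_len(cfg$pyro$n_replicates)) {
      pc <- simulate_pyro_counts(sim, pyro_gene, cond, replicate = r)
      qc <- conversion_qc(pc$controls, min_efficiency = cfg$pyro$min_efficiency)
      pyro_rows[[length(pyro_rows) + 1L]] <- data.frame(
        sample = sprintf("%s_rep%d", cond, r), condition = cond,
        site = pc$sites$pos, nC = pc$sites$nC, nT = pc$sites$nT,
        conversion_ok = qc$pass, efficiency = qc$efficiency,
        true_level = pc$level)
    }
  }
  pyro_df <- do.call(rbind, pyro_rows)
  pyro_df$percent <- percent_methylation(pyro_df$nC, pyro_df$nT)
  usable <- pyro_df[pyro_df$conversion_ok, ]
  an <- two_way_anova(usable[, c("condition", "site", "percent")])
  per_site <- per_cpg_tests(usable[, c("condition", "site", "percent")])
  .write_tsv(pyro_df, file.path(out_dir, "pyro_counts.tsv"))
  .write_tsv(as.data.frame(an), file.path(out_dir, "pyro_anova.tsv"))
  .write_tsv(per_site, file.path(out_dir, "pyro_per_cpg.tsv"))
  concord <- stats::aggregate(percent ~ condition, data = usable, FUN = mean)
  truth_lev <- stats::aggregate(true_level ~ condition, data = usable,
                                FUN = mean)
  pyro_concordance <- merge(concord, truth_lev, by = "condition")
  pyro_concordance$abs_error <- abs(pyro_concordance$percent -
                                      100 * pyro_concordance$true_level)

  report <- structure(list(
    out_dir = out_dir,
    thresholds = list(extension_bp = cfg$scoring$extension_length,
                      unmethylated_max = cfg$scoring$unmethylated_max,
                      methylated_min = cfg$scoring$methylated_min,
                      p_threshold = cfg$dmr$p_threshold,
                      fc_threshold = cfg$dmr$fc_threshold,
                      min_medip_score = cfg$dmr$min_medip_score),
    counts = list(genes = length(sim$genes),
                  samples = length(reads),
                  promoters = length(prom),
                  gene_bodies = length(body),
                  cpg_islands = length(islands),
                  scored_records = nrow(scores),
                  dmr_tested = nrow(dmrs),
                  dmr_pass_p_fc = sum(dmrs$passes_filters),
                  dmr_pass_score = nrow(candidates),
                  motif_hits = nrow(hits)),
    status_distribution = as.list(status_tab),
    evaluation = eval_res,
    enrichment = enr,
    pyro = list(gene = pyro_gene, anova = an, per_site = per_site,
                concordance = pyro_concordance)),
    class = "run_report")
  .write_run_report_md(report, file.path(out_dir, "report.md"))
  say("run complete: %s", out_dir)
  report
}

# demonstration gene sets derived from the simulation: the planted DMR
# genes (a set enrichment must recover) plus seeded random sets
.demo_gene_sets <- function(sim) {
  ids <- sim$truth$gene_id
  planted <- sim$truth$gene_id[sim$truth$is_planted_dmr]
  set.seed(.derive_seed(sim$config$seed, 50000L))
  sets <- list()
  if (length(planted) >= 2L) sets$planted_dmr_genes <- planted
  for (k in 1:3) {
    sets[[sprintf("random_set_%d", k)]] <-
      sample(ids, max(5L, min(20L, length(ids) %/% 10L)))
  }
  sets
}

.write_run_report_md <- function(report, path) {
  con <- file(path, "w"); on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("# MeDIP-seq differential methylation run report\n")
  w("## Thresholds applied\n")
  for (nm in names(report$thresholds)) {
    w("- %s: %s", nm, format(report$thresholds[[nm]]))
  }
  w("\n## Stage record counts\n")
  for (nm in names(report$counts)) w("- %s: %d", nm, report$counts[[nm]])
  w("\n## Methylation status distribution (promoter x sample)\n")
  for (nm in names(report$status_distribution)) {
    w("- %s: %d", nm, report$status_distribution[[nm]])
  }
  ev <- report$evaluation
  w("\n## DMR evaluation against planted truth\n")
  w("- sensitivity: %s", format(ev$sensitivity))
  w("- observed FDR: %s", format(ev$fdr))
  w("- direction accuracy: %s", format(ev$direction_accuracy))
  w("\n## Enrichment (top sets)\n")
  en <- utils::head(report$enrichment, 5L)
  for (i in seq_len(nrow(en))) {
    w("- %s: ES=%.3f, p=%.4g", en$set[i], en$es[i], en$p_value[i])
  }
  w("\n## Pyrosequencing validation (%s)\n", report$pyro$gene)
  pc <- report$pyro$concordance
  for (i in seq_len(nrow(pc))) {
    w("- %s: mean %.1f%% vs planted %.1f%% (|error| %.2f points)",
      pc$condition[i], pc$percent[i], 100 * pc$true_level[i], pc$abs_error[i])
  }
  invisible(path)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf(
    "MeDIP pipeline run: %d promoters tested, %d pass P&FC, %d candidates; sensitivity %.2f, FDR %.2f\n",
    x$counts$dmr_tested, x$counts$dmr_pass_p_fc, x$counts$dmr_pass_score,
    x$evaluation$sensitivity, x$evaluation$fdr))
  cat(sprintf("artifacts: %s\n", x$out_dir))
  invisible(x)
}
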
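#' Folded fold change between group means
#'
#' The ratio of pseudocounted means `(mean_trained + pc) /
#' (mean_sedentary + pc)`, folded to be >= 1, with a direction recording
#' the sign: `hyper` when the trained mean is larger, `hypo` when smaller,
#' `tie` when equal. Folding lets one threshold serve both directions and
#' makes the statistic symmetric under group swap (direction flips).
#'
#' @param mean_trained,mean_sedentary Non-negative group-mean MeDIP scores
#'   (vectorised).
#' @param pseudocount Added to both means before the ratio (default 0.5
#'   reads/kb); guards division by zero.
#' @return data.frame with columns `fc` (>= 1), `log2fc` (signed,
#'   trained over sedentary) and `direction`.
#' @examples
#' fold_change(30, 15)  # fc = 30.5/15.5, hyper
#' @export
fold_change <- function(mean_trained, mean_sedentary, pseudocount = 0.5) {
  if (any(mean_trained < 0) || any(mean_sedentary < 0)) {
    .stopf("fold_change: group means must be >= 0")
  }
  if (!.is_pos_scalar(pseudocount)) .stopf("fold_change: pseudocount must be > 0")
  r <- (mean_trained + pseudocount) / (mean_sedentary + pseudocount)
  data.frame(
    fc = pmax(r, 1 / r),
    log2fc = log2(r),
    direction = ifelse(r > 1, "hyper", ifelse(r < 1, "hypo", "tie")),
    stringsAsFactors = FALSE)
}

#' Two-sided differential test on per-sample scores
#'
#' `welch_t_log` applies Welch's t-test to `log2(score + pseudocount)` and
#' needs at least two samples per group. `permutation` uses the absolute
#' difference of group means of log scores as statistic; all group-label
#' reassignments are enumerated exactly when there are at most 12,870
#' arrangements (i.e. up to a balanced 8 + 8 design), otherwise `n_perm`
#' Monte-Carlo draws with the `+1` correction are used.
#'
#' @param scores_trained,scores_sedentary Per-sample MeDIP scores.
#' @param cfg A [dmr_config()] (test choice, pseudocount, `n_perm`).
#' @param seed Seed for Monte-Carlo permutations only.
#' @return Two-sided p-value in `[0, 1]`.
#' @export
dmr_test <- function(scores_trained, scores_sedentary, cfg = dmr_config(),
                     seed = 1L) {
  a <- log2(scores_trained + cfg$pseudocount)
  b <- log2(scores_sedentary + cfg$pseudocount)
  if (cfg$test == "welch_t_log") {
    if (length(a) < 2L || length(b) < 2L) {
      .stopf(paste0("dmr_test: welch_t_log needs >= 2 samples per group ",
                    "(zero-variance / single-sample groups are degenerate); ",
                    "use test = \"permutation\""))
    }
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
    }
    return(stats::t.test(a, b)$p.value)
  }
  ## permutation on |difference of group means|
  if (length(a) < 1L || length(b) < 1L) {
    .stopf("dmr_test: permutation needs >= 1 sample per group")
  }
  pooled <- c(a, b)
  na <- length(a); n <- length(pooled)
  obs <- abs(mean(a) - mean(b))
  n_arr <- choose(n, na)
  if (n_arr <= 12870) {
    idx <- utils::combn(n, na)
    tot <- sum(pooled)
    stat <- abs(colSums(matrix(pooled[idx], nrow = na)) / na -
                  (tot - colSums(matrix(pooled[idx], nrow = na))) / (n - na))
    mean(stat >= obs - 1e-12)
  } else {
    set.seed(seed)
    stat <- replicate(cfg$n_perm, {
      p <- sample(pooled)
      abs(mean(p[seq_len(na)]) - mean(p[-seq_len(na)]))
    })
    (1 + sum(stat >= obs - 1e-12)) / (1 + cfg$n_perm)
  }
}

#' Call differentially methylated promoters
#'
#' For each promoter region in a score matrix, computes group means, folded
#' fold change, and a two-sided p-value, and flags records passing the
#' differential filter `p < p_threshold AND fc > fc_threshold` (both
#' strict, mirroring "P < 0.05 and fold change > 1.5"). Benjamini-Hochberg
#' q-values are always reported; they replace raw p in the filter only when
#' `cfg$adjust` is `TRUE`.
#'
#' @param scores A `"medip_scores"` data.frame from [score_matrix()]
#'   computed on promoter regions.
#' @param groups Named character vector mapping each sample name to
#'   `"sedentary"` or `"trained"`.
#' @param cfg A [dmr_config()].
#' @param seed Seed forwarded to Monte-Carlo permutation tests.
#' @return data.frame of class `"dmr_table"`, one row per promoter, sorted
#'   by p-value: `gene_id, chrom, start, end, strand, mean_sedentary,
#'   mean_trained, fc, log2fc, direction, p_value, q_value, passes_filters`.
#' @export
call_dmrs <- function(scores, groups, cfg = dmr_config(), seed = 1L) {
  if (is.null(groups) || is.null(names(groups))) {
    .stopf("call_dmrs: 'groups' must be a named sample -> condition vector")
  }
  smp <- unique(scores$sample)
  missing <- setdiff(smp, names(groups))
  if (length(missing) > 0L) {
    .stopf("call_dmrs: group labels missing for sample(s) %s",
           paste(sQuote(missing), collapse = ", "))
  }
  if (!all(sort(unique(groups[smp])) %in% c("sedentary", "trained")) ||
      length(unique(groups[smp])) != 2L) {
    .stopf("call_dmrs: 'groups' must cover both conditions 'sedentary' and 'trained'")
  }
  wide <- score_wide(scores)
  meta <- unique(scores[, c("region_id", "chrom", "start", "end", "strand")])
  meta <- meta[match(rownames(wide), meta$region_id), , drop = FALSE]
  cond <- groups[colnames(wide)]
  A <- wide[, cond == "trained", drop = FALSE]
  B <- wide[, cond == "sedentary", drop = FALSE]
  mean_trn <- rowMeans(A)
  mean_sed <- rowMeans(B)
  fcres <- fold_change(mean_trn, mean_sed, cfg$pseudocount)
  p <- vapply(seq_len(nrow(wide)), function(i) {
    dmr_test(A[i, ], B[i, ], cfg, seed = .derive_seed(seed, i))
  }, numeric(1))
  q <- stats::p.adjust(p, method = "BH")
  p_used <- if (cfg$adjust) q else p
  out <- data.frame(
    gene_id = meta$region_id, chrom = meta$chrom, start = meta$start,
    end = meta$end, strand = meta$strand,
    mean_sedentary = mean_sed, mean_trained = mean_trn,
    fc = fcres$fc, log2fc = fcres$log2fc, direction = fcres$direction,
    p_value = p, q_value = q,
    passes_filters = p_used < cfg$p_threshold & fcres$fc > cfg$fc_threshold,
    stringsAsFactors = FALSE)
  out <- out[order(out$p_value, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("dmr_table", "data.frame")
  out
}

#' Score filter on called DMRs
#'
#' From the promoters passing the differential filter, retains those whose
#' larger group-mean MeDIP score exceeds `min_medip_score` (default 10
#' reads/kb) — the "reliable dataset" narrowing step of the cascade.
#'
#' @param dmrs A `"dmr_table"` from [call_dmrs()].
#' @param cfg A [dmr_config()].
#' @param passing_only Apply the score rule only to records that passed the
#'   differential filter (default, reproducing the cascade); set `FALSE`
#'   to filter all records regardless.
#' @return The retained subset, same columns, still sorted by p-value.
#' @export
filter_candidates <- function(dmrs, cfg = dmr_config(), passing_only = TRUE) {
  stopifnot(inherits(dmrs, "data.frame"))
  keep <- pmax(dmrs$mean_sedentary, dmrs$mean_trained) > cfg$min_medip_score
  if (passing_only) keep <- keep & dmrs$passes_filters
  out <- dmrs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Evaluate DMR calls against planted truth
#'
#' @param dmrs A `"dmr_table"`.
#' @param truth The truth table of a `"medip_simulation"`.
#' @return List: `sensitivity` (detected planted / planted), `fdr`
#'   (false detections / detections; 0 when nothing is detected),
#'   `direction_accuracy` (fraction of detected planted DMRs whose
#'   direction matches truth), and the underlying counts.
#' @export
evaluate_dmrs <- function(dmrs, truth) {
  m <- merge(dmrs, truth, by = "gene_id")
  det <- m$passes_filters
  planted <- m$is_planted_dmr
  tp <- sum(det & planted)
  fp <- sum(det & !planted)
  dir_ok <- if (tp > 0) {
    mean(m$direction.x[det & planted] == m$direction.y[det & planted])
  } else NA_real_
  list(sensitivity = if (sum(planted) > 0) tp / sum(planted) else NA_real_,
       fdr = if (tp + fp > 0) fp / (tp + fp) else 0,
       direction_accuracy = dir_ok,
       n_planted = sum(planted), n_detected = tp + fp,
       true_positives = tp, false_positives = fp)
}
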
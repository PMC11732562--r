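#' Read gene sets from a GMT file
#'
#' @param path Path to a tab-separated GMT file (set name, description,
#'   then member gene ids).
#' @return Named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) .stopf("read_gmt: no such file: %s", path)
  fgsea::gmtPathways(path)
}

#' Write gene sets to a GMT file
#'
#' @param gene_sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of set descriptions
#'   (defaults to `"na"`).
#' @export
write_gmt <- function(gene_sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(gene_sets))
  lines <- vapply(seq_along(gene_sets), function(i) {
    paste(c(names(gene_sets)[i], descriptions[i], gene_sets[[i]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
}

#' GSEA enrichment score
#'
#' The classic weighted Kolmogorov-Smirnov-like running sum over a ranked
#' gene list: walking down the list sorted by decreasing metric, set
#' members ("hits") increment the sum by `|metric|^weight_p` normalised by
#' the total hit weight, non-members decrement by `1/(N - N_hit)`. The
#' enrichment score is the extremum of the running sum; the leading edge is
#' the set members at or before the extremum (at or after it for negative
#' scores).
#'
#' @param metric Named numeric vector: ranking metric per gene (e.g. signed
#'   log2 fold change of promoter methylation). Sorted internally in
#'   decreasing order; ties keep their input order.
#' @param gene_set Character vector of member gene ids; must intersect the
#'   ranked list.
#' @param weight_p Hit-weight exponent: 1 (default, "weighted" GSEA) or 0
#'   (unweighted, analytically tractable).
#' @return List with `es` in `[-1, 1]`, `leading_edge` (gene ids),
#'   `peak` (index of the extremum) and `running` (the running-sum vector).
#' @export
gsea_es <- function(metric, gene_set, weight_p = 1) {
  if (is.null(names(metric)) || anyDuplicated(names(metric))) {
    .stopf("gsea_es: 'metric' must be named with unique gene ids")
  }
  ord <- order(metric, decreasing = TRUE)
  metric <- metric[ord]
  hit <- names(metric) %in% gene_set
  N <- length(metric); Nh <- sum(hit)
  if (Nh == 0L) .stopf("gsea_es: gene set does not overlap the ranked list")
  w <- abs(metric)^weight_p
  wh <- sum(w[hit])
  inc <- if (wh > 0) w / wh else rep(1 / Nh, N)
  dec <- if (N > Nh) 1 / (N - Nh) else 0
  step <- ifelse(hit, inc, -dec)
  running <- cumsum(step)
  peak <- which.max(abs(running))
  es <- running[peak]
  leading <- if (es >= 0) {
    names(metric)[seq_len(peak)][hit[seq_len(peak)]]
  } else {
    names(metric)[peak:N][hit[peak:N]]
  }
  list(es = unname(es), leading_edge = leading, peak = peak,
       running = unname(running))
}

#' GSEA significance by gene-label permutation
#'
#' Builds a null distribution of enrichment scores by redrawing the gene
#' set's labels at random over the ranked list (`n_perm` times), and
#' reports `p = (1 + #{|ES_null| >= |ES|}) / (1 + n_perm)` together with a
#' normalised score `NES = ES / mean(|ES_null| of the same sign)`.
#' Sample permutation is not possible at the small group sizes this
#' pipeline targets; the gene-label null is a stated limitation.
#'
#' @inheritParams gsea_es
#' @param n_perm Number of permutations, at least 100.
#' @param seed RNG seed; results are deterministic given the seed.
#' @return List of class `"gsea_result"`: `es, nes, p_value,
#'   leading_edge, n_perm, set_size`.
#' @export
gsea_significance <- function(metric, gene_set, n_perm = 1000, seed = 1L,
                              weight_p = 1) {
  if (n_perm < 100) .stopf("gsea_significance: n_perm must be >= 100")
  obs <- gsea_es(metric, gene_set, weight_p)
  k <- sum(names(metric) %in% gene_set)
  N <- length(metric)
  set.seed(seed)
  null_es <- vapply(seq_len(n_perm), function(i) {
    gsea_es(metric, sample(names(metric), k), weight_p)$es
  }, numeric(1))
  p <- (1 + sum(abs(null_es) >= abs(obs$es))) / (1 + n_perm)
  same <- null_es[sign(null_es) == sign(obs$es)]
  nes <- if (length(same) > 0) obs$es / mean(abs(same)) else NA_real_
  structure(list(es = obs$es, nes = nes, p_value = p,
                 leading_edge = obs$leading_edge, n_perm = n_perm,
                 set_size = k),
            class = "gsea_result")
}

#' Over-representation test for an unranked selection
#'
#' Hypergeometric (one-sided) test of whether a selected gene list is
#' enriched for a gene set relative to a universe — the cut-off-based
#' alternative when no ranking metric is available.
#'
#' @param selected Character vector of selected gene ids.
#' @param universe Character vector of all testable gene ids.
#' @param gene_set Character vector of set member ids.
#' @return List: `p_value`, `overlap`, `expected`.
#' @export
ora_test <- function(selected, universe, gene_set) {
  selected <- intersect(selected, universe)
  set_u <- intersect(gene_set, universe)
  q <- length(intersect(selected, set_u))
  p <- stats::phyper(q - 1, length(set_u), length(universe) - length(set_u),
                     length(selected), lower.tail = FALSE)
  list(p_value = p, overlap = q,
       expected = length(selected) * length(set_u) / length(universe))
}

#' Enrichment of many gene sets against one ranking
#'
#' @inheritParams gsea_significance
#' @param gene_sets Named list of gene-id vectors (e.g. from [read_gmt()]).
#'   Sets that do not overlap the ranked list are skipped.
#' @return data.frame: one row per tested set with `set, size, es, nes,
#'   p_value, leading_edge` (comma-separated).
#' @export
gsea_table <- function(metric, gene_sets, n_perm = 1000, seed = 1L,
                       weight_p = 1) {
  rows <- lapply(seq_along(gene_sets), function(i) {
    gs <- gene_sets[[i]]
    if (!any(names(metric) %in% gs)) return(NULL)
    r <- gsea_significance(metric, gs, n_perm = n_perm,
                           seed = .derive_seed(seed, i), weight_p = weight_p)
    data.frame(set = names(gene_sets)[i], size = r$set_size, es = r$es,
               nes = r$nes, p_value = r$p_value,
               leading_edge = paste(r$leading_edge, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(set = character(0), size = integer(0), es = numeric(0),
                      nes = numeric(0), p_value = numeric(0),
                      leading_edge = character(0))
  }
  out[order(out$p_value), , drop = FALSE]
}
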
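#' Strand-aware promoter windows
#'
#' Derives the promoter interval of each gene as the window from
#' `promoter_upstream` bp upstream to `promoter_downstream` bp downstream of
#' the transcription start site (default -700/+200), on the gene's strand.
#' Windows running past the start of the contig are clipped at position 1
#' with a warning.
#'
#' @param genes A [GenomicRanges::GRanges] of gene models with a `gene_id`
#'   metadata column and strand `+` or `-`. The TSS is the 5' end of the
#'   range on its strand.
#' @param cfg An [annotation_config()].
#' @return A `GRanges` of promoter windows carrying `gene_id` and a
#'   `region_class = "promoter"` column, in the input gene order.
#' @seealso [gene_body_intervals()], [find_cpg_islands()]
#' @export
promoter_intervals <- function(genes, cfg = annotation_config()) {
  .check_gene_granges(genes)
  prom <- suppressWarnings(GenomicRanges::promoters(
    genes, upstream = cfg$promoter_upstream,
    downstream = cfg$promoter_downstream))
  clipped <- BiocGenerics::start(prom) < 1L
  if (any(clipped)) {
    .warnf("%d promoter window(s) clipped at the contig start", sum(clipped))
    prom <- IRanges::restrict(prom, start = 1L)
  }
  sl <- GenomeInfoDb::seqlengths(prom)
  if (!all(is.na(sl))) prom <- GenomicRanges::trim(prom)
  S4Vectors::mcols(prom)$region_class <- "promoter"
  prom
}

#' Gene-body windows
#'
#' The gene body runs from `body_offset` bp (default 2,000) downstream of
#' the TSS to the transcription termination site, and is only defined for
#' genes strictly longer than `body_min_gene_length` bp (default 3,000).
#' Shorter genes are dropped from the result.
#'
#' @inheritParams promoter_intervals
#' @return A `GRanges` of gene-body windows (`gene_id`,
#'   `region_class = "gene_body"`) for qualifying genes; genes at or below
#'   the length cut-off contribute no interval.
#' @export
gene_body_intervals <- function(genes, cfg = annotation_config()) {
  .check_gene_granges(genes)
  keep <- BiocGenerics::width(genes) > cfg$body_min_gene_length
  g <- genes[keep]
  if (length(g) == 0L) return(g)
  # trim body_offset bp off the 5' (TSS) side, strand-aware
  w <- BiocGenerics::width(g) - cfg$body_offset
  body <- GenomicRanges::resize(g, width = pmax(w, 1L), fix = "end")
  S4Vectors::mcols(body)$region_class <- "gene_body"
  body
}

.check_gene_granges <- function(genes) {
  if (!methods::is(genes, "GRanges")) .stopf("'genes' must be a GRanges")
  if (is.null(S4Vectors::mcols(genes)$gene_id)) {
    .stopf("'genes' must carry a 'gene_id' metadata column")
  }
  if (any(BiocGenerics::strand(genes) == "*")) {
    .stopf("gene models must be stranded (+ or -)")
  }
  invisible(genes)
}

#' TSS positions of gene models
#'
#' @inheritParams promoter_intervals
#' @return A `GRanges` of width-1 TSS positions, one per gene.
#' @export
gene_tss <- function(genes) {
  .check_gene_granges(genes)
  GenomicRanges::resize(genes, width = 1L, fix = "start")
}

#' G+C content of a sequence
#'
#' Fraction of G or C bases among non-N bases. `N` bases are excluded from
#' both numerator and denominator.
#'
#' @param sequence A character string, `DNAString`, or length-1
#'   `DNAStringSet` over the alphabet `{A, C, G, T, N}`.
#' @return The G+C fraction in `[0, 1]`.
#' @export
gc_content <- function(sequence) {
  x <- .seq_letters(sequence)
  if (length(x) == 0L) .stopf("gc_content: empty sequence")
  nonN <- sum(x != "N")
  if (nonN == 0L) .stopf("gc_content: all-N sequence has undefined composition")
  sum(x == "G" | x == "C") / nonN
}

#' CpG observed/expected ratio
#'
#' The Gardiner-Garden dinucleotide statistic
#' `obs/exp = (N_CpG / (N_C * N_G)) * L`, where `N_CpG` counts `CG`
#' dinucleotides, `N_C` and `N_G` count the mononucleotides and `L` is the
#' sequence length. Defined as 0 (not an error) when the sequence contains
#' no C or no G.
#'
#' @inheritParams gc_content
#' @return A non-negative ratio.
#' @export
cpg_obs_exp <- function(sequence) {
  x <- .seq_letters(sequence)
  if (length(x) < 2L) .stopf("cpg_obs_exp: sequence must have length >= 2")
  nC <- sum(x == "C")
  nG <- sum(x == "G")
  if (nC == 0L || nG == 0L) return(0)
  nCpG <- sum(x[-length(x)] == "C" & x[-1L] == "G")
  (nCpG / (nC * nG)) * length(x)
}
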
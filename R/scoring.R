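#' Extend aligned reads to a fixed length
#'
#' Each uniquely aligned read is extended to `extension_length` bp (default
#' 250) from its 5' end toward its 3' end, emulating the sequenced fragment:
#' a `+` strand read keeps its start, a `-` strand read keeps its end.
#' Extensions running past position 1 (or past the contig end when sequence
#' lengths are known) are clipped with a warning.
#'
#' @param reads A stranded [GenomicRanges::GRanges] of aligned reads.
#' @param cfg A [scoring_config()].
#' @return A `GRanges` of extended reads, same order as input.
#' @export
extend_reads <- function(reads, cfg = scoring_config()) {
  if (!methods::is(reads, "GRanges")) .stopf("'reads' must be a GRanges")
  if (any(BiocGenerics::strand(reads) == "*")) {
    .stopf("extend_reads: reads with ambiguous strand '*' cannot be extended")
  }
  ext <- suppressWarnings(
    GenomicRanges::resize(reads, width = cfg$extension_length, fix = "start"))
  clipped <- BiocGenerics::start(ext) < 1L
  sl <- GenomeInfoDb::seqlengths(ext)
  if (any(clipped)) {
    .warnf("%d extended read(s) clipped at the contig start", sum(clipped))
    ext <- suppressWarnings(IRanges::restrict(ext, start = 1L))
  }
  if (!all(is.na(sl))) ext <- suppressWarnings(GenomicRanges::trim(ext))
  ext
}

#' MeDIP score of regions
#'
#' The MeDIP score of a region is the number of extended reads overlapping
#' it (by at least 1 bp) per kb of region length. With
#' `normalize = "per-million"` the overlap count is first scaled to reads
#' per million of the library size.
#'
#' @param regions A `GRanges` of regions (positive widths).
#' @param extended_reads A `GRanges` of reads already extended with
#'   [extend_reads()].
#' @param cfg A [scoring_config()].
#' @param library_size Total aligned reads in the sample; defaults to
#'   `length(extended_reads)`. Only used for per-million normalisation.
#' @return Numeric vector of scores in reads/kb, one per region.
#' @export
medip_score <- function(regions, extended_reads, cfg = scoring_config(),
                        library_size = length(extended_reads)) {
  if (any(BiocGenerics::width(regions) <= 0L)) {
    .stopf("medip_score: regions must have positive width")
  }
  n <- GenomicRanges::countOverlaps(regions, extended_reads,
                                    minoverlap = 1L, ignore.strand = TRUE)
  n <- as.numeric(n)
  if (cfg$normalize == "per-million") {
    if (library_size <= 0) .stopf("medip_score: empty library cannot be normalised")
    n <- n * 1e6 / library_size
  }
  n / (BiocGenerics::width(regions) / 1000)
}

#' Methylation status of a MeDIP score
#'
#' Three-state call: `unmethylated` below `unmethylated_max` (default 9.48
#' reads/kb), `methylated` above `methylated_min` (default 50.62 reads/kb),
#' `partial` in the closed interval between them, so the three classes
#' partition `[0, Inf)` and both boundary values are `partial`.
#'
#' @param score Numeric vector of non-negative MeDIP scores.
#' @param cfg A [scoring_config()].
#' @return Character vector in `{unmethylated, partial, methylated}`.
#' @export
classify_status <- function(score, cfg = scoring_config()) {
  if (any(!is.finite(score)) || any(score < 0)) {
    .stopf("classify_status: scores must be finite and >= 0")
  }
  ifelse(score < cfg$unmethylated_max, "unmethylated",
         ifelse(score > cfg$methylated_min, "methylated", "partial"))
}

#' Score a set of regions across samples
#'
#' Extends every sample's reads, scores every region in every sample, and
#' assigns methylation-status calls. Output rows are sorted by region
#' coordinate then sample name, so the result is invariant to the order in
#' which samples are supplied.
#'
#' @param samples Named list of raw (unextended) read `GRanges`, one per
#'   sample.
#' @param regions A `GRanges` of regions with a `gene_id` or `region_id`
#'   metadata column (falls back to coordinates as identifiers).
#' @param cfg A [scoring_config()].
#' @param groups Optional named character vector mapping sample name to
#'   condition; when given and library depths differ between groups by more
#'   than 10% under `normalize = "none"`, a diagnostic message is emitted.
#' @return A `data.frame` of class `"medip_scores"` with columns
#'   `region_id, chrom, start, end, strand, sample, n_reads, score, status`.
#' @seealso [score_wide()] for the region-by-sample matrix form.
#' @export
score_matrix <- function(samples, regions, cfg = scoring_config(),
                         groups = NULL) {
  if (!is.list(samples) || is.null(names(samples)) ||
      any(names(samples) == "")) {
    .stopf("'samples' must be a named list of read GRanges")
  }
  region_id <- S4Vectors::mcols(regions)$region_id
  if (is.null(region_id)) region_id <- S4Vectors::mcols(regions)$gene_id
  if (is.null(region_id)) {
    region_id <- paste0(GenomeInfoDb::seqnames(regions), ":",
                        BiocGenerics::start(regions) - 1L, "-",
                        BiocGenerics::end(regions))
  }
  reg_chroms <- GenomeInfoDb::seqlevelsInUse(regions)
  for (nm in names(samples)) {
    rd <- samples[[nm]]
    bad <- setdiff(GenomeInfoDb::seqlevelsInUse(rd), reg_chroms)
    if (length(bad) > 0L) {
      .stopf("score_matrix: sample '%s' has reads on chromosome(s) %s absent from the regions",
             nm, paste(sQuote(bad), collapse = ", "))
    }
  }
  if (!is.null(groups) && cfg$normalize == "none") {
    depth <- vapply(samples, length, integer(1))
    gm <- tapply(depth, groups[names(samples)], mean)
    if (length(gm) == 2L && max(gm) > 1.1 * min(gm)) {
      message("score_matrix: group library depths differ by more than 10%; ",
              "absolute reads/kb scores conflate depth with methylation ",
              "(consider normalize = \"per-million\")")
    }
  }
  ord <- order(as.integer(GenomeInfoDb::seqnames(regions)),
               BiocGenerics::start(regions), BiocGenerics::end(regions))
  rows <- lapply(sort(names(samples)), function(nm) {
    # contig-edge clipping is routine at scale; the per-read contract (and
    # its warning) lives in extend_reads()
    ext <- withCallingHandlers(
      extend_reads(samples[[nm]], cfg),
      warning = function(w) {
        if (grepl("clipped", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
    sc <- medip_score(regions, ext, cfg, library_size = length(ext))
    data.frame(
      region_id = region_id,
      chrom = as.character(GenomeInfoDb::seqnames(regions)),
      start = BiocGenerics::start(regions) - 1L,   # BED convention, 0-based
      end = BiocGenerics::end(regions),
      strand = as.character(BiocGenerics::strand(regions)),
      sample = nm,
      n_reads = GenomicRanges::countOverlaps(regions, ext,
                                             ignore.strand = TRUE),
      score = sc,
      status = classify_status(sc, cfg),
      stringsAsFactors = FALSE
    )[ord, , drop = FALSE]
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$start, out$end, out$sample), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("medip_scores", "data.frame")
  out
}

#' Region-by-sample score matrix
#'
#' @param scores A `"medip_scores"` data.frame from [score_matrix()].
#' @return Numeric matrix, rows = regions (coordinate order), columns =
#'   samples (name order).
#' @export
score_wide <- function(scores) {
  ids <- unique(scores$region_id)
  smp <- sort(unique(scores$sample))
  m <- matrix(NA_real_, nrow = length(ids), ncol = length(smp),
              dimnames = list(ids, smp))
  m[cbind(match(scores$region_id, ids), match(scores$sample, smp))] <-
    scores$score
  m
}
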
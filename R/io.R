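# File-format glue: FASTA via Biostrings, BED via rtracklayer, tables as
# TSV with a '#'-comment config echo in the header.

#' Write a genome as 60-column wrapped FASTA
#' @param genome A `DNAStringSet`.
#' @param path Output path.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path, width = 60L)
  invisible(path)
}

#' Read a (multi-contig) FASTA genome
#' @param path FASTA path.
#' @return A `DNAStringSet`.
#' @export
read_genome_fasta <- function(path) Biostrings::readDNAStringSet(path)

#' Write intervals as BED6
#'
#' Emits chrom, 0-based half-open start/end, name, score, strand.
#'
#' @param gr A `GRanges`; the `name` column (or `name_col`) populates BED
#'   field 4, `score` (default 0) field 5.
#' @param path Output path.
#' @param name_col Metadata column to use as the BED name field.
#' @export
write_bed6 <- function(gr, path, name_col = "name") {
  mc <- S4Vectors::mcols(gr)
  nm <- if (!is.null(mc[[name_col]])) as.character(mc[[name_col]])
        else if (!is.null(mc$region_id)) as.character(mc$region_id)
        else if (!is.null(mc$gene_id)) as.character(mc$gene_id)
        else rep(".", length(gr))
  sc <- if (!is.null(mc$score)) as.numeric(mc$score) else rep(0, length(gr))
  df <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    name = nm, score = sc,
    strand = sub("\\*", ".", as.character(BiocGenerics::strand(gr))))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file into a GRanges
#' @param path BED path (3-12 columns).
#' @return A `GRanges`; BED name and score become metadata columns.
#' @export
read_bed <- function(path) rtracklayer::import(path, format = "bed")

#' Write gene models as BED12 (single-block genes)
#' @param genes Gene-model `GRanges` with `gene_id`.
#' @param path Output path.
#' @export
write_gene_models_bed12 <- function(genes, path) {
  .check_gene_granges(genes)
  df <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(genes)),
    start = BiocGenerics::start(genes) - 1L,
    end = BiocGenerics::end(genes),
    name = S4Vectors::mcols(genes)$gene_id,
    score = 0L,
    strand = as.character(BiocGenerics::strand(genes)),
    thickStart = BiocGenerics::start(genes) - 1L,
    thickEnd = BiocGenerics::end(genes),
    itemRgb = "0,0,0",
    blockCount = 1L,
    blockSizes = BiocGenerics::width(genes),
    blockStarts = 0L)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene models from BED
#' @param path BED6/BED12 path whose name field carries gene ids.
#' @return A stranded `GRanges` with `gene_id`.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  S4Vectors::mcols(gr)$gene_id <- S4Vectors::mcols(gr)$name
  gr
}

#' Write gene models as GFF3
#' @param genes Gene-model `GRanges` with `gene_id`.
#' @param path Output path.
#' @export
write_gene_models_gff3 <- function(genes, path) {
  .check_gene_granges(genes)
  g <- genes
  S4Vectors::mcols(g) <- S4Vectors::DataFrame(
    type = "gene", ID = S4Vectors::mcols(genes)$gene_id,
    Name = S4Vectors::mcols(genes)$gene_id)
  rtracklayer::export(g, path, format = "gff3")
  invisible(path)
}

# TSV with '#'-prefixed header comments echoing configuration
.write_tsv <- function(df, path, comments = character(0)) {
  con <- file(path, "w"); on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' Write a score table (long TSV plus wide matrix TSV)
#'
#' @param scores A `"medip_scores"` data.frame.
#' @param path Long-format output path; the wide matrix goes to
#'   `<path base>_wide.tsv`.
#' @param cfg The [scoring_config()] echoed in header comments.
#' @export
write_scores_tsv <- function(scores, path, cfg = scoring_config()) {
  comments <- c(sprintf("extension_length=%d", cfg$extension_length),
                sprintf("unmethylated_max=%g methylated_min=%g",
                        cfg$unmethylated_max, cfg$methylated_min),
                sprintf("normalize=%s", cfg$normalize))
  .write_tsv(as.data.frame(scores), path, comments)
  wide <- score_wide(scores)
  wpath <- paste0(sub("\\.tsv$", "", path), "_wide.tsv")
  .write_tsv(data.frame(region_id = rownames(wide), wide,
                        check.names = FALSE), wpath, comments)
  invisible(path)
}

#' Write a DMR table as TSV
#' @param dmrs A `"dmr_table"`.
#' @param path Output path.
#' @param cfg The [dmr_config()] echoed in header comments.
#' @export
write_dmr_tsv <- function(dmrs, path, cfg = dmr_config()) {
  comments <- sprintf(
    "p_threshold=%g fc_threshold=%g min_medip_score=%g test=%s pseudocount=%g",
    cfg$p_threshold, cfg$fc_threshold, cfg$min_medip_score, cfg$test,
    cfg$pseudocount)
  .write_tsv(as.data.frame(dmrs), path, comments)
}

#' Write the methylome ground truth as TSV
#' @param methylome The methylome `GRanges` of a simulation.
#' @param path Output path.
#' @export
write_methylome_tsv <- function(methylome, path) {
  df <- data.frame(
    region_id = S4Vectors::mcols(methylome)$region_id,
    region_class = S4Vectors::mcols(methylome)$region_class,
    chrom = as.character(GenomeInfoDb::seqnames(methylome)),
    start = BiocGenerics::start(methylome) - 1L,
    end = BiocGenerics::end(methylome),
    gene_id = S4Vectors::mcols(methylome)$gene_id,
    level_sedentary = S4Vectors::mcols(methylome)$level_sedentary,
    level_trained = S4Vectors::mcols(methylome)$level_trained,
    cpg_count = S4Vectors::mcols(methylome)$cpg_count)
  .write_tsv(df, path)
}

#' Write motif hits as BED6 (score = bits x 100, rounded)
#' @param hits Hit data.frame from [scan_sequence()].
#' @param path Output path.
#' @param chrom Chromosome name for the BED records.
#' @param offset 0-based offset of the scanned sequence on `chrom`.
#' @export
write_motif_hits_bed <- function(hits, path, chrom = "chrS", offset = 0L) {
  df <- data.frame(chrom = rep(chrom, nrow(hits)),
                   start = offset + hits$start - 1L,
                   end = offset + hits$end,
                   name = hits$motif_id,
                   score = round(hits$score * 100),
                   strand = hits$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
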
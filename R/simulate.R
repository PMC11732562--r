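# Synthetic MeDIP-seq study generator.
#
# The genome is laid out in equal per-gene slots so that every gene carries
# a -700/+200 promoter window that never overlaps a neighbouring locus, a
# constraint the downstream per-promoter tests rely on. Planted CpG islands
# live in the intergenic free zone of a slot.

.SLOT_MIN <- 2600L          # bp per gene: 900 promoter + >=1500 gene + margin
.READ_LEN_RANGE <- c(36L, 150L)

#' Simulate a genome, gene models and ground-truth methylome
#'
#' Generates a single-contig genome with a GC-poor background (40% GC),
#' CpG-containing promoter sequence at every TSS, and intergenic CpG-rich
#' segments that satisfy the island criteria by construction. Gene models
#' are non-overlapping and alternate strands. A per-region methylome for
#' the two conditions is drawn, with `planted_dmr_fraction` of promoters
#' given a `dmr_effect`-fold methylation shift (hyper- or hypomethylated in
#' the trained condition, at random), and recorded in a truth table.
#'
#' All output is a pure function of `config` (including its seed).
#'
#' @param config A [sim_config()].
#' @param ann_cfg An [annotation_config()]; used for the promoter windows of
#'   the methylome and to verify planted islands against the criteria.
#' @return A list of class `"medip_simulation"`:
#' \describe{
#'   \item{genome}{`DNAStringSet`, one contig `chrS`.}
#'   \item{genes}{`GRanges` gene models with `gene_id`.}
#'   \item{islands}{`GRanges` of planted island truth spans.}
#'   \item{methylome}{`GRanges` partitioned into promoter / gene_body /
#'     cpg_island / background regions with per-condition methylation
#'     levels (`level_sedentary`, `level_trained`) and `cpg_count`.}
#'   \item{truth}{data.frame: `gene_id, is_planted_dmr, direction, effect`.}
#'   \item{config}{the input configuration.}
#' }
#' @export
simulate_genome <- function(config = sim_config(),
                            ann_cfg = annotation_config()) {
  stopifnot(inherits(config, "sim_config"))
  L <- config$genome_length
  n <- config$n_genes
  slot <- L %/% n
  if (slot < .SLOT_MIN) {
    .stopf(paste0(
      "simulate_genome: genome too short to host the requested genes: ",
      "%d genes with -700/+200 promoter windows need at least %d bp ",
      "(%d bp per gene), got %d bp"),
      n, n * .SLOT_MIN, .SLOT_MIN, L)
  }
  set.seed(config$seed)

  ## --- background sequence, 40% GC
  chars <- sample(c("A", "C", "G", "T"), L, replace = TRUE,
                  prob = c(0.30, 0.20, 0.20, 0.30))

  ## --- gene layout (0-based slot-relative arithmetic, converted at the end)
  gene_len_max <- min(3900L, slot - 1100L)
  gene_len <- sample(1500:gene_len_max, n, replace = TRUE)
  strand <- rep_len(c("+", "-"), n)
  slot0 <- (seq_len(n) - 1L) * slot
  gstart0 <- ifelse(strand == "+", slot0 + 700L,
                    slot0 + slot - 700L - gene_len)
  gend0 <- gstart0 + gene_len                       # 0-based half-open
  genes <- GenomicRanges::GRanges(
    seqnames = "chrS",
    ranges = IRanges::IRanges(start = gstart0 + 1L, end = gend0),
    strand = strand,
    gene_id = sprintf("g%04d", seq_len(n)))
  GenomeInfoDb::seqlengths(genes) <- c(chrS = L)

  ## --- promoter sequence: CpG-containing but below island criteria
  prom <- promoter_intervals(genes, ann_cfg)
  for (i in seq_along(prom)) {
    s <- BiocGenerics::start(prom)[i]; e <- BiocGenerics::end(prom)[i]
    chars[s:e] <- .composition_chars(e - s + 1L, p_cg = 0.04, gc = 0.40)
  }

  ## --- planted CpG islands in intergenic free zones
  n_isl <- round(config$island_density * L / 1e5)
  if (n_isl > n) {
    .warnf("island_density requests %d islands; capped at one per gene slot (%d)",
           n_isl, n)
    n_isl <- n
  }
  isl_start <- integer(0); isl_end <- integer(0)
  if (n_isl > 0) {
    host <- sort(sample.int(n, n_isl))
    for (i in host) {
      zone0 <- if (strand[i] == "+") gend0[i] else slot0[i]
      zone1 <- if (strand[i] == "+") slot0[i] + slot else gstart0[i]
      usable <- zone1 - zone0 - 100L
      ilen <- min(sample(250:500, 1L), usable)
      room <- usable - ilen
      off <- zone0 + 50L + if (room > 0) sample.int(room, 1L) else 0L
      seq_i <- .island_chars(ilen, ann_cfg)
      chars[(off + 1L):(off + ilen)] <- seq_i
      isl_start <- c(isl_start, off); isl_end <- c(isl_end, off + ilen)
    }
  }
  islands <- GenomicRanges::GRanges(
    seqnames = if (length(isl_start)) "chrS" else character(0),
    ranges = IRanges::IRanges(start = isl_start + 1L, end = isl_end),
    seqinfo = GenomeInfoDb::Seqinfo("chrS", L))
  if (length(islands)) {
    S4Vectors::mcols(islands)$region_class <- "cpg_island"
  }

  genome <- Biostrings::DNAStringSet(
    stats::setNames(paste(chars, collapse = ""), "chrS"))

  ## --- ground-truth methylome and truth table
  truth <- .plant_truth(genes, config)
  methylome <- .build_methylome(genome, genes, islands, truth, config, ann_cfg)

  structure(list(genome = genome, genes = genes, islands = islands,
                 methylome = methylome, truth = truth, config = config),
            class = "medip_simulation")
}

# token sampler: emits CG dinucleotides at rate p_cg among single bases with
# the given GC fraction
.composition_chars <- function(len, p_cg, gc) {
  n_tok <- len + 10L
  tok <- sample(c("CG", "A", "C", "G", "T"), n_tok, replace = TRUE,
                prob = c(p_cg, (1 - p_cg) * c((1 - gc) / 2, gc / 2, gc / 2,
                                              (1 - gc) / 2)))
  out <- strsplit(paste(tok, collapse = ""), "")[[1L]]
  while (length(out) < len) {
    out <- c(out, sample(c("A", "C", "G", "T"), len - length(out),
                         replace = TRUE))
  }
  out[seq_len(len)]
}

# CpG-island composition; re-drawn until the segment satisfies the criteria
.island_chars <- function(len, ann_cfg, max_tries = 20L) {
  for (k in seq_len(max_tries)) {
    x <- .composition_chars(len, p_cg = 0.15, gc = 0.60)
    s <- paste(x, collapse = "")
    if (gc_content(s) >= ann_cfg$island_min_gc &&
        cpg_obs_exp(s) >= ann_cfg$island_min_obs_exp) {
      return(x)
    }
  }
  .stopf("failed to draw an island-qualifying segment of length %d", len)
}

.plant_truth <- function(genes, config) {
  ids <- S4Vectors::mcols(genes)$gene_id
  n_planted <- round(config$planted_dmr_fraction * length(ids))
  planted <- rep(FALSE, length(ids))
  if (n_planted > 0) planted[sample.int(length(ids), n_planted)] <- TRUE
  direction <- rep(NA_character_, length(ids))
  direction[planted] <- sample(c("hyper", "hypo"), sum(planted),
                               replace = TRUE)
  if (config$dmr_effect == 1) direction[planted] <- "none"
  data.frame(gene_id = ids, is_planted_dmr = planted,
             direction = direction,
             effect = ifelse(planted, config$dmr_effect, NA_real_),
             stringsAsFactors = FALSE)
}

.build_methylome <- function(genome, genes, islands, truth, config, ann_cfg) {
  prom <- promoter_intervals(genes, ann_cfg)
  body <- gene_body_intervals(genes, ann_cfg)
  eff <- config$dmr_effect

  regs <- list()
  ## promoters: planted effect applied multiplicatively
  base <- stats::runif(length(prom), 0.15, min(0.30, 0.95 / max(eff, 1)))
  lev_other <- stats::runif(length(prom), 0.20, 0.80)
  sed <- ifelse(truth$is_planted_dmr,
                ifelse(truth$direction == "hypo", base * eff, base),
                lev_other)
  trn <- ifelse(truth$is_planted_dmr,
                ifelse(truth$direction == "hypo", base, base * eff),
                lev_other)
  S4Vectors::mcols(prom) <- S4Vectors::DataFrame(
    region_id = truth$gene_id, region_class = "promoter",
    gene_id = truth$gene_id, level_sedentary = sed, level_trained = trn)
  regs$promoter <- prom

  if (length(body)) {
    lev <- stats::runif(length(body), 0.30, 0.90)
    gid <- S4Vectors::mcols(body)$gene_id
    S4Vectors::mcols(body) <- S4Vectors::DataFrame(
      region_id = paste0(gid, "_body"), region_class = "gene_body",
      gene_id = gid, level_sedentary = lev, level_trained = lev)
    regs$body <- body
  }
  if (length(islands)) {
    lev <- stats::runif(length(islands), 0.02, 0.20)
    S4Vectors::mcols(islands) <- S4Vectors::DataFrame(
      region_id = sprintf("isl%03d", seq_along(islands)),
      region_class = "cpg_island", gene_id = NA_character_,
      level_sedentary = lev, level_trained = lev)
    regs$island <- islands
  }
  covered <- c(GenomicRanges::granges(prom), GenomicRanges::granges(genes),
               if (length(islands)) GenomicRanges::granges(islands))
  bg <- GenomicRanges::gaps(
    GenomicRanges::reduce(covered, ignore.strand = TRUE))
  bg <- bg[BiocGenerics::strand(bg) == "*"]
  if (length(bg)) {
    lev <- stats::runif(length(bg), 0.05, 0.15)
    S4Vectors::mcols(bg) <- S4Vectors::DataFrame(
      region_id = sprintf("bg%04d", seq_along(bg)),
      region_class = "background", gene_id = NA_character_,
      level_sedentary = lev, level_trained = lev)
    regs$background <- bg
  }
  meth <- suppressWarnings(do.call(c, unname(regs)))
  seqs <- Biostrings::extractAt(genome[[1L]], GenomicRanges::ranges(meth))
  S4Vectors::mcols(meth)$cpg_count <-
    Biostrings::vcountPattern("CG", seqs)
  BiocGenerics::sort(meth, ignore.strand = TRUE)
}

#' Simulate aligned MeDIP reads for one condition
#'
#' Per sample, the total read count is Poisson with mean `mean_depth`; a
#' `background_rate` fraction is placed uniformly on the genome, and the
#' rest are placed region-wise with probability proportional to
#' (methylation level of the condition) x (CpG count of the region), i.e.
#' the methylated-CpG mass an anti-methylcytosine pull-down would capture.
#' Read lengths are uniform on 36-150 bp (the sequenced end of a sonicated
#' fragment); strands are uniform. Per-sample RNG streams are derived from
#' the root seed by fixed offsets, so adding samples never reshuffles
#' earlier ones.
#'
#' @param sim A `"medip_simulation"` from [simulate_genome()].
#' @param group `"sedentary"` or `"trained"`.
#' @param config Defaults to the simulation's own config; override to vary
#'   depth or replicate number without regenerating the genome.
#' @return Named list of read `GRanges` (one per sample, names like
#'   `sed_1`), each carrying `name` and `score = 0` metadata for BED6
#'   export, plus attributes `n_signal` / `n_background`.
#' @export
simulate_medip_reads <- function(sim, group = c("sedentary", "trained"),
                                 config = sim$config) {
  stopifnot(inherits(sim, "medip_simulation"))
  group <- match.arg(group)
  meth <- sim$methylome
  lev_col <- paste0("level_", group)
  lev <- S4Vectors::mcols(meth)[[lev_col]]
  if (is.null(lev) || anyNA(lev)) {
    .stopf("simulate_medip_reads: methylome is missing '%s' levels", lev_col)
  }
  L <- GenomeInfoDb::seqlengths(sim$genome)[["chrS"]]
  w <- lev * S4Vectors::mcols(meth)$cpg_count
  g_off <- if (group == "sedentary") 10000L else 20000L
  prefix <- if (group == "sedentary") "sed" else "trn"

  out <- list()
  for (i in seq_len(config$n_samples_per_group)) {
    set.seed(.derive_seed(config$seed, g_off + i))
    n_reads <- stats::rpois(1L, config$mean_depth)
    n_bg <- stats::rbinom(1L, n_reads, config$background_rate)
    n_sig <- n_reads - n_bg
    if (sum(w) == 0) n_sig <- 0L            # nothing methylated to capture
    starts <- integer(0)
    if (n_sig > 0) {
      ridx <- sample.int(length(meth), n_sig, replace = TRUE, prob = w)
      rs <- BiocGenerics::start(meth)[ridx]
      re <- BiocGenerics::end(meth)[ridx]
      starts <- rs + floor(stats::runif(n_sig) * (re - rs + 1L))
    }
    if (n_bg > 0) {
      starts <- c(starts, 1L + floor(stats::runif(n_bg) * L))
    }
    n_tot <- length(starts)
    lens <- sample(.READ_LEN_RANGE[1L]:.READ_LEN_RANGE[2L], n_tot,
                   replace = TRUE)
    ends <- pmin(starts + lens - 1L, L)
    gr <- GenomicRanges::GRanges(
      seqnames = if (n_tot) "chrS" else character(0),
      ranges = IRanges::IRanges(start = starts, end = ends),
      strand = sample(c("+", "-"), n_tot, replace = TRUE),
      name = if (n_tot) sprintf("%s%d_r%06d", prefix, i, seq_len(n_tot))
             else character(0),
      score = rep(0L, n_tot),
      seqinfo = GenomeInfoDb::Seqinfo("chrS", L))
    attr(gr, "n_signal") <- n_sig
    attr(gr, "n_background") <- n_bg
    out[[paste0(prefix, "_", i)]] <- gr
  }
  out
}

#' Simulate bisulfite pyrosequencing counts for a region
#'
#' For every CpG in the region, the cytosine count is
#' `Binomial(pyro_depth, level)` where `level` is the region's planted
#' methylation in the given condition; thymine counts make up the rest.
#' Non-CpG cytosines serve as internal conversion controls: their
#' unconverted counts are `Binomial(pyro_depth, 1 - conversion_efficiency)`.
#'
#' @param sim A `"medip_simulation"`.
#' @param region_id A region identifier present in the simulation methylome
#'   (e.g. a `gene_id` for its promoter).
#' @param condition `"sedentary"` or `"trained"`.
#' @param replicate Replicate number; selects an independent derived RNG
#'   stream.
#' @param config Defaults to the simulation's config.
#' @return List with `sites` (data.frame `pos, nC, nT`; `pos` is the
#'   1-based genome coordinate of the CpG cytosine), `controls` (data.frame
#'   `pos, converted, unconverted` over non-CpG cytosines), the planted
#'   `level`, `region_id` and `condition`.
#' @export
simulate_pyro_counts <- function(sim, region_id,
                                 condition = c("sedentary", "trained"),
                                 replicate = 1L, config = sim$config) {
  stopifnot(inherits(sim, "medip_simulation"))
  condition <- match.arg(condition)
  meth <- sim$methylome
  k <- match(region_id, S4Vectors::mcols(meth)$region_id)
  if (is.na(k)) .stopf("simulate_pyro_counts: unknown region '%s'", region_id)
  s <- BiocGenerics::start(meth)[k]; e <- BiocGenerics::end(meth)[k]
  seq_r <- .seq_letters(Biostrings::subseq(sim$genome[[1L]], s, e))
  isC <- seq_r == "C"
  cpg <- which(isC & c(seq_r[-1L] == "G", FALSE))
  if (length(cpg) == 0L) {
    .stopf("simulate_pyro_counts: region '%s' contains no CpG site", region_id)
  }
  ctrl <- which(isC & !(seq_len(length(seq_r)) %in% cpg))
  lev <- S4Vectors::mcols(meth)[[paste0("level_", condition)]][k]
  g_off <- if (condition == "sedentary") 30000L else 40000L
  set.seed(.derive_seed(config$seed, g_off + 101L * replicate + k))
  nC <- stats::rbinom(length(cpg), config$pyro_depth, lev)
  unconv <- stats::rbinom(length(ctrl), config$pyro_depth,
                          1 - config$conversion_efficiency)
  list(
    sites = data.frame(pos = s + cpg - 1L, nC = nC,
                       nT = config$pyro_depth - nC),
    controls = data.frame(pos = s + ctrl - 1L,
                          converted = config$pyro_depth - unconv,
                          unconverted = unconv),
    level = lev, region_id = region_id, condition = condition)
}

#' @export
print.medip_simulation <- function(x, ...) {
  cat(sprintf(
    "MeDIP simulation: %s bp genome, %d genes, %d planted islands, %d planted DMRs (%g-fold)\n",
    format(x$config$genome_length, big.mark = ","), length(x$genes),
    length(x$islands), sum(x$truth$is_planted_dmr), x$config$dmr_effect))
  invisible(x)
}
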
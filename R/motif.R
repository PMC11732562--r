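#' Read position frequency matrices in JASPAR text format
#'
#' Accepts the bracketed JASPAR layout (`A [ 4 19 0 ]` ...) as well as raw
#' 4-row count matrices, one or more motifs per file, each preceded by a
#' `>ID NAME` header. Rows are taken in A, C, G, T order.
#'
#' @param path Path to a JASPAR PFM text file.
#' @return Named list of motifs; each is a list with `id`, `name`, and
#'   `counts` (4 x width numeric matrix, rownames `A,C,G,T`).
#' @export
read_jaspar_pfm <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L) .stopf("read_jaspar_pfm: no '>' motif header found")
  out <- list()
  bounds <- c(hdr, length(lines) + 1L)
  for (h in seq_along(hdr)) {
    head_line <- sub("^>\\s*", "", lines[hdr[h]])
    parts <- strsplit(trimws(head_line), "\\s+")[[1L]]
    id <- parts[1L]
    name <- if (length(parts) > 1L) paste(parts[-1L], collapse = " ") else id
    body <- lines[(bounds[h] + 1L):(bounds[h + 1L] - 1L)]
    if (length(body) != 4L) {
      .stopf("read_jaspar_pfm: motif '%s' has %d matrix rows, expected 4 (near line %d)",
             id, length(body), hdr[h])
    }
    rows <- lapply(seq_along(body), function(i) {
      txt <- gsub("^[ACGTacgt]\\s*", "", trimws(body[i]))
      txt <- gsub("[\\[\\]]", " ", txt, perl = TRUE)
      vals <- suppressWarnings(as.numeric(strsplit(trimws(txt), "\\s+")[[1L]]))
      if (anyNA(vals)) {
        .stopf("read_jaspar_pfm: unparseable counts at line %d", hdr[h] + i)
      }
      vals
    })
    lens <- lengths(rows)
    if (length(unique(lens)) != 1L) {
      .stopf("read_jaspar_pfm: motif '%s' rows have unequal lengths (%s) at line %d",
             id, paste(lens, collapse = "/"), hdr[h] + 1L)
    }
    counts <- do.call(rbind, rows)
    rownames(counts) <- c("A", "C", "G", "T")
    if (any(colSums(counts) <= 0)) {
      .stopf("read_jaspar_pfm: motif '%s' has an all-zero column", id)
    }
    out[[id]] <- list(id = id, name = name, counts = counts)
  }
  out
}

#' Write motifs in JASPAR bracketed PFM format
#'
#' @param motifs List of motifs as returned by [read_jaspar_pfm()] (or a
#'   single such motif).
#' @param path Output path.
#' @export
write_jaspar_pfm <- function(motifs, path) {
  if (!is.null(motifs$counts)) motifs <- list(motifs)
  con <- file(path, "w"); on.exit(close(con))
  for (m in motifs) {
    writeLines(sprintf(">%s %s", m$id, m$name), con)
    for (b in c("A", "C", "G", "T")) {
      writeLines(sprintf("%s  [ %s ]", b,
                         paste(format(m$counts[b, ], trim = TRUE),
                               collapse = " ")), con)
    }
  }
}

#' Log-odds scoring matrix from counts
#'
#' `score(b, i) = log2( p(b, i) / background(b) )` where
#' `p(b, i) = (count(b, i) + pseudocount * background(b)) / column total`.
#' The pseudocount (default 0.8, distributed proportionally to the
#' background, the JASPAR/MEME convention) keeps every score finite.
#'
#' @param counts 4 x width count matrix (rows A, C, G, T).
#' @param background Nucleotide background frequencies summing to 1; must
#'   be strictly positive.
#' @param pseudocount Total pseudocount mass per column.
#' @return 4 x width log-odds matrix in bits.
#' @export
pwm_log_odds <- function(counts, background = rep(0.25, 4),
                         pseudocount = 0.8) {
  if (length(background) != 4L || any(background <= 0)) {
    .stopf("pwm_log_odds: background must be 4 strictly positive frequencies")
  }
  background <- background / sum(background)
  if (any(colSums(counts) <= 0)) {
    .stopf("pwm_log_odds: every column must have positive total count")
  }
  adj <- counts + pseudocount * background
  probs <- sweep(adj, 2, colSums(adj), "/")
  lo <- log2(probs / background)
  rownames(lo) <- c("A", "C", "G", "T")
  lo
}

#' Scan a sequence with a PWM on both strands
#'
#' Slides the log-odds matrix over the sequence and its reverse complement
#' and reports windows scoring at or above the threshold. A
#' `"fraction"`-type threshold `t` maps to `min + t * (max - min)` of the
#' achievable score range. Windows containing `N` never match.
#'
#' @param motif A motif (list with `counts` and optionally `id`) or a bare
#'   4 x width count matrix.
#' @param sequence Character string / `DNAString` to scan.
#' @param threshold Numeric threshold; interpretation set by
#'   `threshold_type`.
#' @param threshold_type `"fraction"` (default 0.8 of the min-max score
#'   range) or `"bits"` (absolute log-odds score).
#' @param background,pseudocount Passed to [pwm_log_odds()].
#' @return data.frame of hits sorted by position: `motif_id, start, end`
#'   (1-based inclusive on the forward strand), `strand, score, match`
#'   (forward-strand sequence of the window).
#' @export
scan_sequence <- function(motif, sequence, threshold = 0.8,
                          threshold_type = c("fraction", "bits"),
                          background = rep(0.25, 4), pseudocount = 0.8) {
  threshold_type <- match.arg(threshold_type)
  if (is.matrix(motif)) motif <- list(id = "motif", counts = motif)
  lo <- pwm_log_odds(motif$counts, background, pseudocount)
  W <- ncol(lo)
  seq_fwd <- .as_sequence(sequence)
  L <- nchar(seq_fwd)
  if (L < W) .stopf("scan_sequence: sequence shorter than the motif")
  smax <- sum(apply(lo, 2, max))
  smin <- sum(apply(lo, 2, min))
  thr <- if (threshold_type == "fraction") {
    smin + threshold * (smax - smin)
  } else threshold
  if (thr > smax + 1e-9) {
    .warnf("scan_sequence: threshold %.2f bits exceeds the maximum achievable score %.2f",
           thr, smax)
    return(.empty_hits())
  }

  score_strand <- function(s) {
    x <- match(strsplit(s, "")[[1L]], c("A", "C", "G", "T"))   # N -> NA
    n <- length(x) - W + 1L
    sc <- numeric(n)
    for (j in seq_len(W)) {
      col <- lo[, j][x[j:(j + n - 1L)]]
      sc <- sc + col
    }
    sc[is.na(sc)] <- -Inf
    sc
  }

  fwd <- score_strand(seq_fwd)
  rev <- score_strand(.revcomp(seq_fwd))
  hit_f <- which(fwd >= thr - 1e-9)
  hit_r <- which(rev >= thr - 1e-9)
  rows <- list()
  if (length(hit_f)) {
    rows$f <- data.frame(
      motif_id = motif$id, start = hit_f, end = hit_f + W - 1L,
      strand = "+", score = fwd[hit_f],
      match = substring(seq_fwd, hit_f, hit_f + W - 1L),
      stringsAsFactors = FALSE)
  }
  if (length(hit_r)) {
    st <- L - (hit_r + W - 1L) + 1L              # map back to forward coords
    rows$r <- data.frame(
      motif_id = motif$id, start = st, end = st + W - 1L,
      strand = "-", score = rev[hit_r],
      match = substring(seq_fwd, st, st + W - 1L),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(.empty_hits())
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.empty_hits <- function() {
  data.frame(motif_id = character(0), start = integer(0), end = integer(0),
             strand = character(0), score = numeric(0), match = character(0),
             stringsAsFactors = FALSE)
}

#' Synthetic NBRE-like motif
#'
#' An orphan-nuclear-receptor response-element-like position frequency
#' matrix (consensus `AAAGGTCA`) built in code for demonstrations and
#' tests; it is a synthetic stand-in, not a database matrix.
#'
#' @param peak Count given to the consensus base at each position (the
#'   remaining mass is split over the other three bases).
#' @return A motif list (`id`, `name`, `counts`) usable with
#'   [scan_sequence()].
#' @export
nbre_like_motif <- function(peak = 85) {
  consensus <- c("A", "A", "A", "G", "G", "T", "C", "A")
  counts <- matrix((100 - peak) / 3, nrow = 4, ncol = length(consensus),
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  for (i in seq_along(consensus)) counts[consensus[i], i] <- peak
  list(id = "SYN_NBRE", name = "synthetic NBRE-like", counts = counts)
}
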
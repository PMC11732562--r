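# Independent brute-force oracles used to cross-check the implementation.
# These are written against the definitions directly and share no search
# logic with the package code paths they verify.

# --- CpG islands: enumerate every substring of length >= min_len, test the
# three criteria, take maximal unions of qualifying substrings, and apply
# the same criteria-closure rule (a failing union is replaced by its
# longest, leftmost qualifying substring). 0-based half-open output.
oracle_islands <- function(seq_str, min_len = 200, min_gc = 0.5,
                           min_oe = 0.6) {
  x <- strsplit(toupper(seq_str), "")[[1L]]
  L <- length(x)
  if (L < min_len) {
    return(data.frame(start0 = integer(0), end0 = integer(0)))
  }
  cC <- cumsum(x == "C"); cG <- cumsum(x == "G")
  cN <- cumsum(!(x %in% c("A", "C", "G", "T")))
  cCG <- cumsum(c(x[-L] == "C" & x[-1L] == "G", FALSE))
  at <- function(v, i) ifelse(i >= 1L, v[pmax(i, 1L)], 0)
  ok_pair <- function(s, e) {       # 0-based [s, e), e vectorised
    len <- e - s
    nC <- at(cC, e) - at(cC, s); nG <- at(cG, e) - at(cG, s)
    nN <- at(cN, e) - at(cN, s)
    nCpG <- at(cCG, e - 1L) - at(cCG, s)
    rhs <- min_oe * nC * nG
    nN == 0 & (nC + nG) >= min_gc * len - 1e-9 & nC > 0 & nG > 0 &
      nCpG * len >= rhs - 1e-9 * pmax(1, rhs)
  }
  # exhaustive enumeration: for every start, test every admissible end.
  # Coverage is accumulated per start (the union of qualifying substrings
  # sharing a start is the prefix up to the largest qualifying end).
  starts <- 0:(L - min_len)
  qe_max <- rep(NA_integer_, length(starts))
  cov <- logical(L)
  for (s in starts) {
    e <- (s + min_len):L
    sel <- ok_pair(s, e)
    if (any(sel)) {
      qe_max[s + 1L] <- max(e[sel])
      cov[(s + 1L):qe_max[s + 1L]] <- TRUE
    }
  }
  if (!any(cov)) {
    return(data.frame(start0 = integer(0), end0 = integer(0)))
  }
  r <- rle(cov)
  hi <- cumsum(r$lengths); lo <- hi - r$lengths + 1L
  comp <- cbind(lo[r$values] - 1L, hi[r$values])   # 0-based [a, b)
  res_s <- integer(0); res_e <- integer(0)
  for (k in seq_len(nrow(comp))) {
    a <- comp[k, 1L]; b <- comp[k, 2L]
    if (isTRUE(ok_pair(a, b))) {
      res_s <- c(res_s, a); res_e <- c(res_e, b)
    } else {
      sidx <- which(!is.na(qe_max)) - 1L
      sidx <- sidx[sidx >= a & qe_max[sidx + 1L] <= b]
      lens <- qe_max[sidx + 1L] - sidx
      j <- which(lens == max(lens))[1L]
      res_s <- c(res_s, sidx[j]); res_e <- c(res_e, qe_max[sidx[j] + 1L])
    }
  }
  o <- order(res_s)
  data.frame(start0 = res_s[o], end0 = res_e[o])
}

# --- MeDIP score: per-read arithmetic extension and O(reads x regions)
# overlap counting, no interval-tree machinery.
oracle_scores <- function(region_df, read_df, ext = 250) {
  # region_df: start0/end0; read_df: start0/end0/strand (same chrom)
  rs <- ifelse(read_df$strand == "+", read_df$start0,
               pmax(0L, read_df$end0 - ext))
  re <- ifelse(read_df$strand == "+", read_df$start0 + ext, read_df$end0)
  sapply(seq_len(nrow(region_df)), function(i) {
    a <- region_df$start0[i]; b <- region_df$end0[i]
    n <- sum(rs < b & re > a)        # >= 1 bp overlap, half-open
    n / ((b - a) / 1000)
  })
}

# --- GSEA running sum: direct loop over the ranked list.
oracle_gsea_es <- function(metric, gene_set, weight_p = 0) {
  ord <- order(metric, decreasing = TRUE)
  nm <- names(metric)[ord]; v <- metric[ord]
  hit <- nm %in% gene_set
  Nh <- sum(hit); N <- length(v)
  wh <- sum(abs(v[hit])^weight_p)
  run <- 0; best <- 0
  for (i in seq_len(N)) {
    if (hit[i]) {
      run <- run + (if (wh > 0) abs(v[i])^weight_p / wh else 1 / Nh)
    } else {
      run <- run - 1 / (N - Nh)
    }
    if (abs(run) > abs(best)) best <- run
  }
  unname(best)
}

# --- Balanced two-way ANOVA sums of squares from cell/marginal means.
oracle_anova_ss <- function(y, a, b) {
  a <- factor(a); b <- factor(b)
  n <- length(y) / (nlevels(a) * nlevels(b))
  gm <- mean(y)
  am <- tapply(y, a, mean); bm <- tapply(y, b, mean)
  cm <- tapply(y, interaction(a, b), mean)
  ss_a <- n * nlevels(b) * sum((am - gm)^2)
  ss_b <- n * nlevels(a) * sum((bm - gm)^2)
  cell_of <- interaction(a, b)
  ss_within <- sum((y - cm[cell_of])^2)
  ss_tot <- sum((y - gm)^2)
  ss_ab <- ss_tot - ss_a - ss_b - ss_within
  c(a = ss_a, b = ss_b, ab = ss_ab, resid = ss_within, total = ss_tot)
}

# --- sequence builders used across tests -------------------------------

# homogeneous segment: m CG dinucleotides evenly dispersed in AT filler
cg_dispersed_seq <- function(len, n_cg) {
  if (n_cg == 0) return(strrep("AT", ceiling(len / 2)) |> substr(1, len))
  gap <- len / n_cg
  chars <- rep(c("A", "T"), length.out = len)
  pos <- floor((seq_len(n_cg) - 1) * gap) + 1L
  pos <- pmin(pos, len - 1L)
  for (p in pos) { chars[p] <- "C"; chars[p + 1L] <- "G" }
  paste(chars, collapse = "")
}

# GC-rich segment with a controlled number of CpG dinucleotides:
# "TCGA" units (one CpG each) evenly interleaved with CpG-free GC-rich
# "CCAGG" fillers (all junctions CpG-safe), AT padding to length.
# Deterministic layout keeps composition locally homogeneous.
gc_even_cpg_seq <- function(len, n_cpg, n_filler) {
  u <- n_cpg + n_filler
  is_cpg <- floor(seq_len(u) * n_cpg / u) > floor((seq_len(u) - 1) * n_cpg / u)
  s <- paste(ifelse(is_cpg, "TCGA", "CCAGG"), collapse = "")
  pad <- len - nchar(s)
  if (pad < 0) stop("units exceed target length")
  paste0(s, paste(rep(c("A", "T"), length.out = pad), collapse = ""))
}

random_seq <- function(len, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# small stranded GRanges helper (0-based half-open input)
gr0 <- function(chrom, start0, end0, strand = "+", ...) {
  GenomicRanges::GRanges(chrom,
                         IRanges::IRanges(start = start0 + 1L, end = end0),
                         strand = strand, ...)
}
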
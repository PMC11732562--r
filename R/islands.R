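#' Detect CpG islands in a sequence
#'
#' A CpG island is reported for every maximal run of positions covered by at
#' least one *qualifying substring*: a substring of length >=
#' `island_min_length` (default 200 bp), with G+C fraction >=
#' `island_min_gc` (default 0.50), CpG observed/expected ratio >=
#' `island_min_obs_exp` (default 0.6), and no `N` bases. Merging the union
#' of qualifying substrings can occasionally dilute a run below the
#' composition criteria; such a run is replaced by its longest qualifying
#' substring (leftmost on ties), so every reported island itself satisfies
#' all three criteria.
#'
#' The search is exhaustive over substrings (not a fixed-width window scan):
#' a prefix-sum formulation with a GC-feasibility pruning step restricts the
#' quadratic enumeration to candidate blocks, which keeps genome-scale
#' inputs tractable when islands are sparse.
#'
#' @param sequence A character string, `DNAString`, or a `DNAStringSet`
#'   (each contig scanned independently).
#' @param cfg An [annotation_config()] providing the three criteria.
#' @param seqname Contig name used when `sequence` is a bare string.
#' @return A [GenomicRanges::GRanges] of islands sorted by start, with
#'   metadata columns `gc_fraction`, `obs_exp` and
#'   `region_class = "cpg_island"`. Empty result if nothing qualifies.
#' @examples
#' find_cpg_islands(strrep("CG", 125))   # one island spanning all 250 bp
#' find_cpg_islands(strrep("AT", 500))   # empty
#' @export
find_cpg_islands <- function(sequence, cfg = annotation_config(),
                             seqname = "seq") {
  if (methods::is(sequence, "DNAStringSet")) {
    nms <- names(sequence)
    if (is.null(nms)) nms <- paste0("seq", seq_along(sequence))
    parts <- lapply(seq_along(sequence), function(i) {
      find_cpg_islands(as.character(sequence[[i]]), cfg, seqname = nms[i])
    })
    return(suppressWarnings(do.call(c, parts)))
  }
  x <- .seq_letters(sequence)
  hits <- .island_core(x, cfg$island_min_length, cfg$island_min_gc,
                       cfg$island_min_obs_exp)
  if (nrow(hits) == 0L) {
    gr <- GenomicRanges::GRanges(seqnames = character(0),
                                 ranges = IRanges::IRanges())
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      gc_fraction = numeric(0), obs_exp = numeric(0),
      region_class = character(0))
    return(gr)
  }
  gr <- GenomicRanges::GRanges(
    seqnames = seqname,
    ranges = IRanges::IRanges(start = hits$start0 + 1L, end = hits$end0))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    gc_fraction = hits$gc, obs_exp = hits$obs_exp,
    region_class = "cpg_island")
  gr
}

# Exhaustive-union island search on a character vector.
# Returns data.frame(start0, end0, gc, obs_exp) with 0-based half-open spans.
.island_core <- function(x, min_len, min_gc, min_oe) {
  L <- length(x)
  empty <- data.frame(start0 = integer(0), end0 = integer(0),
                      gc = numeric(0), obs_exp = numeric(0))
  if (L < min_len) return(empty)

  isC <- x == "C"
  isG <- x == "G"
  isN <- !(x %in% c("A", "C", "G", "T"))
  isGC <- isC | isG
  cgp <- c(isC[-L] & isG[-1L], FALSE)          # CG dinucleotide starts

  cumGC <- c(0, cumsum(isGC))
  cumC  <- c(0, cumsum(isC))
  cumG  <- c(0, cumsum(isG))
  cumN  <- c(0, cumsum(isN))
  cumP  <- c(0, cumsum(cgp))

  # predicate: does 0-based [s, e) qualify? (vectorised over e)
  qualifies <- function(s, e) {
    len <- e - s
    nn <- cumN[e + 1L] - cumN[s + 1L]
    gc <- cumGC[e + 1L] - cumGC[s + 1L]
    obs <- cumP[e] - cumP[s + 1L]
    Cc <- cumC[e + 1L] - cumC[s + 1L]
    Gg <- cumG[e + 1L] - cumG[s + 1L]
    rhs <- min_oe * Cc * Gg
    nn == 0L &
      gc >= min_gc * len - 1e-9 &
      Cc > 0L & Gg > 0L &                      # obs/exp is 0 without C and G
      obs * len >= rhs - 1e-9 * pmax(1, rhs)
  }

  # --- pruning: positions that can sit in a substring of length >= min_len
  # with GC fraction >= min_gc (necessary condition; N/obs-exp checked later)
  f <- cumGC - min_gc * (0:L)
  M <- rev(cummax(rev(f)))                     # suffix max of f
  nS <- L - min_len + 1L                       # starts 0 .. L - min_len
  g <- f[seq_len(nS)] <= M[(min_len + 1L):(L + 1L)] + 1e-9
  cumg <- c(0, cumsum(g))
  cumminf <- cummin(f)

  p <- 0:(L - 1L)
  condA <- rep(FALSE, L)
  iA <- p >= min_len - 1L
  condA[iA] <- cumminf[p[iA] + 2L - min_len] <= M[p[iA] + 2L] + 1e-9
  a <- pmax(0L, p + 2L - min_len)
  b <- pmin(p, L - min_len)
  condB <- b >= a & (cumg[pmin(b, nS - 1L) + 2L] - cumg[a + 1L]) > 0
  covered <- condA | condB

  r <- rle(covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  blocks <- cbind(starts[r$values] - 1L, ends[r$values])  # 0-based [a0, b0)
  if (nrow(blocks) == 0L) return(empty)

  out <- vector("list", nrow(blocks))
  for (bi in seq_len(nrow(blocks))) {
    a0 <- blocks[bi, 1L]; b0 <- blocks[bi, 2L]
    if (b0 - a0 < min_len) next
    ss <- a0:(b0 - min_len)
    emax <- rep(NA_integer_, length(ss))
    for (k in seq_along(ss)) {
      s <- ss[k]
      if (!g[s + 1L]) next                     # no GC-feasible end anywhere
      ee <- (s + min_len):b0
      ok <- qualifies(s, ee)
      if (any(ok)) emax[k] <- max(ee[ok])
    }
    has <- !is.na(emax)
    if (!any(has)) next
    iv_s <- ss[has]; iv_e <- emax[has]         # sorted by start
    # merge overlapping/touching [s, emax) intervals into components
    comp_s <- integer(0); comp_e <- integer(0)
    cs <- iv_s[1L]; ce <- iv_e[1L]
    for (k in seq_along(iv_s)[-1L]) {
      if (iv_s[k] <= ce) {
        ce <- max(ce, iv_e[k])
      } else {
        comp_s <- c(comp_s, cs); comp_e <- c(comp_e, ce)
        cs <- iv_s[k]; ce <- iv_e[k]
      }
    }
    comp_s <- c(comp_s, cs); comp_e <- c(comp_e, ce)
    # criteria closure: a merged component that fails the criteria is
    # replaced by its longest (leftmost) qualifying substring
    res_s <- integer(0); res_e <- integer(0)
    for (k in seq_along(comp_s)) {
      cs <- comp_s[k]; ce <- comp_e[k]
      if (isTRUE(qualifies(cs, ce))) {
        res_s <- c(res_s, cs); res_e <- c(res_e, ce)
      } else {
        inb <- iv_s >= cs & iv_e <= ce
        lens <- iv_e[inb] - iv_s[inb]
        j <- which(lens == max(lens))[1L]
        res_s <- c(res_s, iv_s[inb][j]); res_e <- c(res_e, iv_e[inb][j])
      }
    }
    out[[bi]] <- data.frame(start0 = res_s, end0 = res_e)
  }
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out) || nrow(out) == 0L) return(empty)
  out <- out[order(out$start0), , drop = FALSE]
  out$gc <- (cumGC[out$end0 + 1L] - cumGC[out$start0 + 1L]) /
    (out$end0 - out$start0)
  obs <- cumP[out$end0] - cumP[out$start0 + 1L]
  Cc <- cumC[out$end0 + 1L] - cumC[out$start0 + 1L]
  Gg <- cumG[out$end0 + 1L] - cumG[out$start0 + 1L]
  out$obs_exp <- ifelse(Cc == 0 | Gg == 0, 0,
                        obs * (out$end0 - out$start0) / (Cc * Gg))
  rownames(out) <- NULL
  out
}
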
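# internal helpers shared across modules

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
.warnf <- function(...) warning(sprintf(...), call. = FALSE)

.is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}

.is_fraction <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
}

.is_pos_scalar <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0
}

# Accept a character scalar, DNAString or length-1 DNAStringSet; return a
# single upper-case character string.
.as_sequence <- function(x) {
  if (methods::is(x, "DNAStringSet")) {
    if (length(x) != 1L) .stopf("expected a single sequence, got %d", length(x))
    x <- x[[1L]]
  }
  if (methods::is(x, "DNAString")) x <- as.character(x)
  if (!is.character(x) || length(x) != 1L) {
    .stopf("sequence must be a single character string or DNAString")
  }
  toupper(x)
}

.seq_letters <- function(x) strsplit(.as_sequence(x), "", fixed = TRUE)[[1L]]

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(.as_sequence(x))))
}

# Derived per-sample RNG seed: fixed offsets keep earlier streams stable when
# samples are added; kept below 2^31.
.derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + as.numeric(offset)) %% (.Machine$integer.max - 1)) + 1L
}

# comparison tolerance for ratio criteria evaluated in products of counts
.CRIT_EPS <- 1e-6
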
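#' @keywords internal
"_PACKAGE"

# All genomic coordinates in this package are 0-based half-open [start, end),
# the BED convention. substr()/substring() calls therefore use start+1:end.

#' Reverse complement of a DNA string
#'
#' Plain-character fast path used throughout the simulator and caller.
#'
#' @param x character vector of A/C/G/T strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  stringi::stri_reverse(chartr("ACGTacgt", "TGCAtgca", x))
}

# Complement without reversal (vector of single characters or a string)
comp_chars <- function(x) chartr("ACGT", "TGCA", x)

# Extract [start, end) 0-based half-open from a string
seq_slice <- function(s, start, end) substr(s, start + 1L, end)

#' Derive a named substream seed from a master seed
#'
#' One master seed drives the whole pipeline; each task (genome construction,
#' read simulation, fluctuation draws, bootstrap) gets an independent named
#' substream so stages can be re-run in isolation with identical results.
#'
#' @param master integer master seed.
#' @param stream substream name, e.g. "genome", "reads", "fluctuation".
#' @return an integer seed below 2^31.
#' @export
substream_seed <- function(master, stream) {
  offsets <- c(
    genome = 101L, reads = 211L, fluctuation = 307L, events = 401L,
    bootstrap = 503L, pipeline = 601L, other = 701L
  )
  off <- offsets[[match.arg(stream, names(offsets))]]
  as.integer((as.numeric(master) * 1009 + off * 9973) %% 2147483629)
}

# Random DNA of length n from the current RNG stream
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Count exact occurrences of pattern in subject (possibly overlapping start
# positions are not needed here; gregexpr finds non-overlapping matches)
count_occurrences <- function(subject, pattern) {
  if (nchar(pattern) == 0L) return(0L)
  hits <- gregexpr(pattern, subject, fixed = TRUE)[[1]]
  sum(hits > 0L)
}

# 2-bit base codes (A=0, C=1, G=2, T=3) as doubles; NA for any other byte.
# Numeric k-mer encoding avoids string-keyed environments, whose keys would
# be interned permanently in the symbol table.
dna_code <- function(s) {
  tbl <- rep(NA_real_, 127L)
  tbl[c(65L, 67L, 71L, 84L)] <- c(0, 1, 2, 3)
  tbl[utf8ToInt(s)]
}

# Value of every k-mer window (first base most significant), indexed by
# window start; windows containing non-ACGT bases are NA. Values are exact
# integers below 4^k (k <= 26 keeps them within double precision).
kmer_values <- function(code, k) {
  n <- length(code)
  if (n < k) return(numeric(0))
  y <- stats::filter(code, 4^(0:(k - 1)), method = "convolution", sides = 1)
  as.numeric(y)[seq.int(k, n)]
}

# Sorted-array multimap for exact k-mer value lookup. Queries go through
# findInterval and should be batched: findInterval validates the sortedness
# of its second argument on every call, so per-value calls would be O(n)
# each.
kmer_table <- function(vals) {
  keep <- which(!is.na(vals))
  ord <- keep[order(vals[keep])]
  list(v = vals[ord], pos = ord)
}

# Longest common prefix length of two equal-alphabet strings
common_prefix_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  av <- utf8ToInt(substr(a, 1L, n))
  bv <- utf8ToInt(substr(b, 1L, n))
  neq <- which(av != bv)
  if (length(neq) == 0L) n else neq[1L] - 1L
}

# Longest common suffix length
common_suffix_len <- function(a, b) {
  common_prefix_len(stringi::stri_reverse(a), stringi::stri_reverse(b))
}
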
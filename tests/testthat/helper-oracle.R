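# Independent brute-force oracle for hairpin enumeration: anchors every
# candidate innermost pair directly and extends outward by per-character
# complement tests. Deliberately structured differently from the package's
# seed-and-extend enumerator.

oracle_comp <- c(A = "T", C = "G", G = "C", T = "A")

oracle_hairpin_sites <- function(sequence, min_stem, max_loop = 49L,
                                 min_loop = 3L, dedup = TRUE) {
  v <- strsplit(toupper(sequence), "")[[1]]
  n <- length(v)
  rows <- list()
  for (L in seq.int(min_loop, max_loop)) {
    if (n < 2L + L) next
    for (a in seq_len(n - L - 1L)) {       # innermost arm1 base, 1-based
      b <- a + L + 1L                       # innermost arm2 base
      if (v[a] != oracle_comp[[v[b]]]) next
      # canonical innermost pair: the next inward pair must either violate
      # the loop floor or fail to be complementary
      if (L - 2L >= min_loop && v[a + 1L] == oracle_comp[[v[b - 1L]]]) next
      stem <- 1L
      while (a - stem >= 1L && b + stem <= n &&
             v[a - stem] == oracle_comp[[v[b + stem]]]) {
        stem <- stem + 1L
      }
      if (stem < min_stem) next
      rows[[length(rows) + 1L]] <- data.frame(
        arm1_start = a - stem, arm1_end = a,
        arm2_start = b - 1L, arm2_end = b + stem - 1L,
        stem_len = stem, loop_len = L,
        perfect_stem = TRUE, center = (a + b - 1L) / 2
      )
    }
  }
  if (length(rows) == 0L) {
    out <- data.frame(
      arm1_start = integer(), arm1_end = integer(), arm2_start = integer(),
      arm2_end = integer(), stem_len = integer(), loop_len = integer(),
      perfect_stem = logical(), center = numeric()
    )
    return(out)
  }
  out <- do.call(rbind, rows)
  if (dedup) out <- oracle_dedup(out)
  out <- out[order(out$center, out$arm1_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# same published rule, independent implementation: maximal stem wins among
# overlapping spans; ties to smaller loop, then leftmost center
oracle_dedup <- function(sites) {
  ranked <- sites[order(-sites$stem_len, sites$loop_len, sites$center), ,
                  drop = FALSE]
  taken <- ranked[0, , drop = FALSE]
  for (i in seq_len(nrow(ranked))) {
    r <- ranked[i, ]
    clash <- FALSE
    if (nrow(taken) > 0) {
      clash <- any(r$arm1_start < taken$arm2_end &
                     r$arm2_end > taken$arm1_start)
    }
    if (!clash) taken <- rbind(taken, r)
  }
  taken
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

sites_key <- function(df) {
  if (nrow(df) == 0) return(character(0))
  sort(sprintf("%d:%d:%d:%d", df$arm1_start, df$arm1_end, df$arm2_start,
               df$arm2_end))
}
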
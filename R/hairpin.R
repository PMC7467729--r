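# Hairpin-forming inverted repeat enumeration and junction-derived hairpin
# inference.
#
# A hairpin site is a pair of inverted complementary "arms" (the stem, length
# in bp) separated by an unpaired spacer (the loop, length in nt). Enumeration
# is restricted to perfect stems with loop sizes inside [min_loop, max_loop];
# the folding-convention floor for the loop is 3 nt.

#' Enumerate maximal perfect hairpin-forming inverted repeats
#'
#' Scans a sequence for all maximal perfect inverted repeats with
#' `stem_len >= min_stem` and `min_loop <= loop_len <= max_loop`. Maximality
#' means neither arm can be extended outward while preserving perfect
#' complementarity; the stem is extended inward as far as the loop floor
#' allows. Overlapping sites are deduplicated keeping the maximal-stem site
#' (ties: smaller loop, then leftmost center), mirroring the dominance of the
#' longest-stem site in the assay breakpoint region.
#'
#' @param sequence a single A/C/G/T string (or the region of interest).
#' @param min_stem minimum stem length in bp (>= 2).
#' @param max_loop maximum loop length in nt (default 49, i.e. loops < 50).
#' @param min_loop minimum loop length in nt (default 3).
#' @param dedup collapse overlapping sites (default TRUE).
#' @return a data.frame of class `hairpin_sites` with 0-based half-open arm
#'   intervals, `stem_len`, `loop_len`, `perfect_stem` and `center` columns,
#'   sorted by center.
#' @export
enumerate_hairpin_sites <- function(sequence, min_stem, max_loop = 49L,
                                    min_loop = 3L, dedup = TRUE) {
  stopifnot(length(sequence) == 1L, min_stem >= 2L, min_loop <= max_loop,
            min_loop >= 0L)
  sequence <- toupper(sequence)
  bad <- regexpr("[^ACGT]", sequence)
  if (bad > 0) {
    stop("non-ACGT character at position ", bad - 1L, " (0-based)")
  }
  n <- nchar(sequence)
  v <- utf8ToInt(sequence)
  cv <- utf8ToInt(comp_chars(sequence))

  # Pairs (a, b), 1-based, a < b, pair iff v[a] == cv[b]. A stem lies on a
  # constant anti-diagonal a + b = cs; walking outward from the loop keeps
  # the sum fixed. Any stem of length >= min_stem contains an exact
  # k-mer/reverse-complement-k-mer seed whose innermost instance sits at a
  # spacing of at most max_loop + k, independent of stem length; so seeds
  # are found by k-mer lookup and each is extended along its anti-diagonal
  # into the maximal run, which is then trimmed to the loop bounds.
  k <- max(2L, min(min_stem, 12L))
  if (n < 2L * min_stem + min_loop) return(empty_hairpin_sites())
  code <- dna_code(sequence)
  fwd_vals <- kmer_values(code, k)
  # reverse-complement value of the window at each start: complementing and
  # reversing a window maps its value to (4^k - 1) minus the value computed
  # with the last base most significant
  y <- stats::filter(code, 4^((k - 1):0), method = "convolution", sides = 1)
  rc_vals <- (4^k - 1) - as.numeric(y)[seq.int(k, n)]
  tab <- kmer_table(fwd_vals)
  starts <- seq_along(fwd_vals)
  # one batched sorted-array search for all positions at once
  hi_all <- findInterval(rc_vals, tab$v)
  lo_all <- findInterval(rc_vals - 0.5, tab$v) + 1L
  out <- vector("list", 64L)
  n_out <- 0L
  keys <- numeric(64L)
  for (i in starts) {
    if (is.na(rc_vals[i]) || hi_all[i] < lo_all[i]) next
    for (j in tab$pos[lo_all[i]:hi_all[i]]) {
      gap <- j - (i + k)  # spacing between seed windows
      if (gap < 0L || gap > max_loop) next
      cs <- i + j + k - 1L
      # extend the matched run outward (lo) and inward (hi) on the diagonal
      lo <- i
      while (lo > 1L && cs - lo + 1L <= n && v[lo - 1L] == cv[cs - lo + 1L]) {
        lo <- lo - 1L
      }
      hi <- i + k - 1L
      a_mid <- (cs - 1L) %/% 2L
      while (hi < a_mid && v[hi + 1L] == cv[cs - hi - 1L]) hi <- hi + 1L
      a_in <- min(hi, (cs - 1L - min_loop) %/% 2L)
      if (a_in < lo) next
      loop <- cs - 2L * a_in - 1L
      if (loop > max_loop) next
      stem <- a_in - lo + 1L
      if (stem < min_stem) next
      n_out <- n_out + 1L
      if (n_out > length(out)) {
        out <- c(out, vector("list", length(out)))
        keys <- c(keys, numeric(length(keys)))
      }
      out[[n_out]] <- c(lo - 1L, a_in, cs - a_in - 1L, cs - lo, stem, loop)
      keys[n_out] <- lo * (2 * n + 2) + cs  # run identity for deduplication
    }
  }
  if (n_out == 0L) {
    return(empty_hairpin_sites())
  }
  first <- !duplicated(keys[seq_len(n_out)])
  m <- do.call(rbind, out[seq_len(n_out)][first])
  sites <- data.frame(
    arm1_start = m[, 1], arm1_end = m[, 2],
    arm2_start = m[, 3], arm2_end = m[, 4],
    stem_len = m[, 5], loop_len = m[, 6],
    perfect_stem = TRUE,
    center = (m[, 2] + m[, 3]) / 2
  )
  if (dedup) sites <- dedup_hairpin_sites(sites)
  sites <- sites[order(sites$center, sites$arm1_start), , drop = FALSE]
  rownames(sites) <- NULL
  class(sites) <- c("hairpin_sites", "data.frame")
  sites
}

empty_hairpin_sites <- function() {
  sites <- data.frame(
    arm1_start = integer(), arm1_end = integer(),
    arm2_start = integer(), arm2_end = integer(),
    stem_len = integer(), loop_len = integer(),
    perfect_stem = logical(), center = numeric()
  )
  class(sites) <- c("hairpin_sites", "data.frame")
  sites
}

# Keep the maximal-stem site among overlapping spans; ties broken by smaller
# loop, then leftmost center. Spans are [arm1_start, arm2_end).
dedup_hairpin_sites <- function(sites) {
  ord <- order(-sites$stem_len, sites$loop_len, sites$center)
  keep <- logical(nrow(sites))
  acc_start <- integer(0)
  acc_end <- integer(0)
  for (i in ord) {
    s <- sites$arm1_start[i]
    e <- sites$arm2_end[i]
    if (!any(s < acc_end & e > acc_start)) {
      keep[i] <- TRUE
      acc_start <- c(acc_start, s)
      acc_end <- c(acc_end, e)
    }
  }
  sites[keep, , drop = FALSE]
}

#' Infer hairpin geometry from an inversion junction
#'
#' Given a reference sequence and an inversion junction whose two breakpoints
#' `pos_a < pos_b` flank the candidate hairpin, aligns the sequence running
#' left from `pos_b` against the reverse complement of the sequence running
#' right from `pos_a`. A perfect foldback junction formed at a planted site
#' with arms `[pos_a, pos_a + S)` and `[pos_b - S, pos_b)` recovers
#' `stem_len = S` and `loop_len = pos_b - pos_a - 2 S`.
#'
#' In exact mode (`allow_imperfect = FALSE`) the stem is the maximal run of
#' exactly complementary pairs walking outward from the innermost pair. In
#' imperfect mode a local alignment (match +1, mispair -1, gap -2) is used and
#' mispairs/unpaired bases are counted, mirroring stems predicted to contain
#' one or more mispairs or unpaired bases.
#'
#' @param reference a single A/C/G/T reference string.
#' @param junction numeric length-2, 0-based positions `(pos_a, pos_b)`.
#' @param allow_imperfect allow mispairs/gaps in the stem.
#' @param window how far to look on each side (bp).
#' @return a list of class `hairpin_inference` with `stem_len`, `loop_len`,
#'   `n_mispairs`, `n_unpaired` and `imperfect` fields.
#' @export
infer_hairpin_from_junction <- function(reference, junction,
                                        allow_imperfect = FALSE,
                                        window = 60L) {
  pos_a <- as.integer(junction[1])
  pos_b <- as.integer(junction[2])
  n <- nchar(reference)
  stopifnot(pos_a >= 0L, pos_b <= n, pos_a < pos_b)
  w_a <- min(window, n - pos_a, pos_b - pos_a)
  w_b <- min(window, pos_b, pos_b - pos_a)
  inner_a <- seq_slice(reference, pos_a, pos_a + w_a)   # arm1 side, 5'->3'
  inner_b <- seq_slice(reference, pos_b - w_b, pos_b)   # arm2 side

  if (!allow_imperfect) {
    # walk outward from the innermost pair: arm1 base i pairs arm2 base
    # (end - i + 1); equivalently inner_b reversed must complement inner_a
    a_chars <- utf8ToInt(inner_a)
    b_chars <- rev(utf8ToInt(comp_chars(inner_b)))
    k <- min(length(a_chars), length(b_chars), (pos_b - pos_a) %/% 2L)
    stem <- 0L
    while (stem < k && a_chars[stem + 1L] == b_chars[stem + 1L]) {
      stem <- stem + 1L
    }
    mis <- 0L
    unp <- 0L
  } else {
    # anchored alignment: stems start exactly at the breakpoints and extend
    # inward, allowing mispairs (-1) and unpaired bases (-2) against matches
    # (+1); free alignment would instead latch onto the whole
    # quasi-palindromic site
    span <- pos_b - pos_a
    x <- utf8ToInt(inner_a)                              # inward from pos_a
    y <- rev(utf8ToInt(comp_chars(inner_b)))             # inward from pos_b
    n1 <- length(x)
    n2 <- length(y)
    S <- matrix(-Inf, n1 + 1L, n2 + 1L)
    S[1, 1] <- 0
    S[seq_len(n1) + 1L, 1] <- -2 * seq_len(n1)
    S[1, seq_len(n2) + 1L] <- -2 * seq_len(n2)
    for (i in seq_len(n1)) {
      match_scores <- ifelse(x[i] == y, 1, -1)
      for (j in seq_len(n2)) {
        S[i + 1L, j + 1L] <- max(S[i, j] + match_scores[j],
                                 S[i, j + 1L] - 2, S[i + 1L, j] - 2)
      }
    }
    ok <- outer(0:n1, 0:n2, "+") <= span  # arms cannot cross the center
    best <- max(S[ok])
    if (best < 4) {
      stop("no hairpin inferable: best stem alignment scores below 4")
    }
    cand <- which(S == best & ok, arr.ind = TRUE)
    cell <- cand[order(-(cand[, 1] + cand[, 2]))[1], ]
    bi <- cell[1] - 1L
    bj <- cell[2] - 1L
    # traceback to count pairs, mispairs and unpaired bases
    mis <- 0L; unp <- 0L; paired <- 0L
    i <- bi; j <- bj
    while (i > 0L || j > 0L) {
      if (i > 0L && j > 0L &&
          S[i + 1L, j + 1L] == S[i, j] + (if (x[i] == y[j]) 1 else -1)) {
        paired <- paired + 1L
        if (x[i] != y[j]) mis <- mis + 1L
        i <- i - 1L; j <- j - 1L
      } else if (i > 0L && S[i + 1L, j + 1L] == S[i, j + 1L] - 2) {
        unp <- unp + 1L; i <- i - 1L
      } else {
        unp <- unp + 1L; j <- j - 1L
      }
    }
    res <- list(
      pos_a = pos_a, pos_b = pos_b, stem_len = as.integer(paired),
      loop_len = as.integer(span - bi - bj),
      n_mispairs = mis, n_unpaired = unp,
      imperfect = (mis + unp) > 0
    )
    class(res) <- "hairpin_inference"
    return(res)
  }

  if (stem < 4L) {
    stop("no hairpin inferable: exact stem shorter than 4 bp")
  }
  res <- list(
    pos_a = pos_a, pos_b = pos_b, stem_len = as.integer(stem),
    loop_len = as.integer(pos_b - pos_a - 2L * stem),
    n_mispairs = mis, n_unpaired = unp,
    imperfect = (mis + unp) > 0
  )
  class(res) <- "hairpin_inference"
  res
}

#' Classify a hairpin loop as short or large
#'
#' Short-loop hairpins are defined as loops shorter than 15 nt; large-loop
#' hairpins are 15 nt or more.
#'
#' @param loop_len loop length(s) in nt, >= 0.
#' @return character vector, "short" or "large".
#' @export
classify_loop <- function(loop_len) {
  if (any(loop_len < 0)) stop("loop_len must be non-negative")
  ifelse(loop_len < 15, "short", "large")
}

#' Summarize hairpin loop sizes per event or per site
#'
#' Counting per event tallies every observed rearrangement once; counting per
#' site collapses inferences sharing the same (chromosome, pos_a, pos_b) to a
#' single observation, removing hotspot-driven weighting. The median uses the
#' midpoint of the two middle order statistics for even n.
#'
#' @param inferences data.frame with columns `chrom`, `pos_a`, `pos_b`,
#'   `loop_len` (one row per observed rearrangement).
#' @param mode "per_event" or "per_site".
#' @return a list with `counts` (loop length tabulation), `median`,
#'   `n`, and `cumulative` (a data.frame of loop length vs cumulative
#'   fraction).
#' @export
loop_size_summary <- function(inferences, mode = c("per_event", "per_site")) {
  mode <- match.arg(mode)
  if (NROW(inferences) == 0L) stop("no hairpin inferences to summarize")
  df <- as.data.frame(inferences)
  if (mode == "per_site") {
    key <- paste(df$chrom, df$pos_a, df$pos_b)
    df <- df[!duplicated(key), , drop = FALSE]
  }
  loops <- sort(df$loop_len)
  tab <- table(loops)
  cum <- data.frame(
    loop_len = as.integer(names(tab)),
    count = as.integer(tab)
  )
  cum$cum_fraction <- cumsum(cum$count) / sum(cum$count)
  list(
    mode = mode,
    n = length(loops),
    counts = tab,
    median = stats::median(loops),
    cumulative = cum
  )
}

#' Rank hairpin sites by their propensity to mediate a DSB-proximal foldback
#'
#' Foldback inversions tend to use hairpins within a window (default 50 bp) of
#' the double-strand break; among those, longer stems and shorter loops are
#' favoured. Sites inside the window are ranked by (longer stem, shorter
#' loop, smaller distance to the DSB); sites beyond the window follow, ranked
#' by stem length alone (long stems can act at a distance).
#'
#' @param sites a `hairpin_sites` data.frame (centromeric side of the DSB).
#' @param dsb_pos 0-based DSB position.
#' @param window proximity window in bp (default 50).
#' @return the sites reordered, with `distance` and `within_window` columns.
#' @export
rank_hairpins_near_dsb <- function(sites, dsb_pos, window = 50L) {
  sites <- as.data.frame(sites)
  if (nrow(sites) == 0L) {
    sites$distance <- numeric(0)
    sites$within_window <- logical(0)
    return(sites)
  }
  # distance from the DSB to the nearest arm boundary
  d1 <- abs(dsb_pos - sites$arm1_start)
  d2 <- abs(dsb_pos - sites$arm2_end)
  sites$distance <- pmin(d1, d2)
  sites$within_window <- sites$distance <= window
  near <- sites[sites$within_window, , drop = FALSE]
  far <- sites[!sites$within_window, , drop = FALSE]
  near <- near[order(-near$stem_len, near$loop_len, near$distance), ,
               drop = FALSE]
  far <- far[order(-far$stem_len), , drop = FALSE]
  out <- rbind(near, far)
  rownames(out) <- NULL
  out
}
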
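# Read-depth and span-depth copy-number profiles, and binary-segmentation
# copy-number calling.
#
# Read depth at a base is the number of uniquely mapped reads covering it;
# span depth additionally counts the inter-mate gap of uniquely mapped
# concordant pairs (bases "contained in a read or spanned by a pair").

#' Compute read-depth and span-depth profiles
#'
#' Only pairs in which both reads mapped uniquely contribute. Read depth
#' counts read coverage; span depth counts whole-fragment coverage for
#' concordant pairs (opposite strands, plus-strand mate leftmost, implied
#' insert within `mean +/- 3 sd`) and read coverage for remaining uniquely
#' mapped reads.
#'
#' @param alignments alignment data.frame from [map_reads()].
#' @param genome the mapped genome (for chromosome lengths).
#' @param insert_mean,insert_sd fragment-size model used for concordance.
#' @return a named list (per chromosome) of lists with `read_depth` and
#'   `span_depth` integer vectors of chromosome length.
#' @export
compute_depths <- function(alignments, genome, insert_mean, insert_sd) {
  chroms <- if (inherits(genome, "toy_genome")) genome$chromosomes else genome
  lens <- nchar(chroms)
  a <- alignments[alignments$mapped & alignments$unique, ]
  if (nrow(a) > 0 && any(a$pos + a$read_len > lens[a$chrom])) {
    stop("alignment extends past chromosome end")
  }
  pr <- pair_table(alignments)
  conc <- pr[is_concordant(pr, insert_mean, insert_sd), , drop = FALSE]

  out <- vector("list", length(chroms))
  names(out) <- names(chroms)
  in_conc <- a$qname %in% conc$qname
  for (cn in names(chroms)) {
    L <- lens[[cn]]
    on_cn <- a$chrom == cn
    rd <- interval_depth(a$pos[on_cn], a$pos[on_cn] + a$read_len[on_cn], L)
    cc <- conc[conc$chrom1 == cn, , drop = FALSE]
    loose <- on_cn & !in_conc  # unique reads outside concordant pairs
    sp <- interval_depth(cc$frag_start, cc$frag_end, L) +
      interval_depth(a$pos[loose], a$pos[loose] + a$read_len[loose], L)
    out[[cn]] <- list(read_depth = rd, span_depth = sp)
  }
  out
}

# Concordance mask for a pair table: both ends uniquely mapped to the same
# chromosome, opposite strands, plus-strand mate leftmost, insert in
# mean +/- 3 sd.
is_concordant <- function(pr, insert_mean, insert_sd) {
  ok <- pr$both_unique &
    !is.na(pr$chrom1) & !is.na(pr$chrom2) &
    pr$chrom1 == pr$chrom2 &
    pr$strand1 != pr$strand2 &
    !is.na(pr$frag_start) & !is.na(pr$frag_end) &
    pr$frag_start < pr$frag_end
  ins <- pr$frag_end - pr$frag_start
  ok & !is.na(ins) &
    ins >= insert_mean - 3 * insert_sd & ins <= insert_mean + 3 * insert_sd
}

# Per-base coverage of 0-based half-open intervals on [0, L)
interval_depth <- function(starts, ends, L) {
  d <- integer(L + 1L)
  if (length(starts) > 0) {
    s <- pmax(0L, pmin(starts, L))
    e <- pmax(0L, pmin(ends, L))
    ds <- tabulate(s + 1L, nbins = L + 1L)
    de <- tabulate(e + 1L, nbins = L + 1L)
    d <- cumsum(ds - de)
  }
  as.integer(d[seq_len(L)])
}

# Pair mates into one row per read pair, with fragment geometry helpers
pair_table <- function(alignments) {
  a1 <- alignments[alignments$mate == 1L, ]
  a2 <- alignments[alignments$mate == 2L, ]
  a2 <- a2[match(a1$qname, a2$qname), ]
  pr <- data.frame(
    qname = a1$qname,
    chrom1 = a1$chrom, pos1 = a1$pos, strand1 = a1$strand,
    mapped1 = a1$mapped, unique1 = a1$unique, len1 = a1$read_len,
    chrom2 = a2$chrom, pos2 = a2$pos, strand2 = a2$strand,
    mapped2 = a2$mapped, unique2 = a2$unique, len2 = a2$read_len
  )
  both <- pr$mapped1 & pr$mapped2 & pr$unique1 & pr$unique2
  plus_first <- !is.na(pr$strand1) & pr$strand1 == "+"
  fs <- ifelse(plus_first, pr$pos1, pr$pos2)
  fe <- ifelse(plus_first, pr$pos2 + pr$len2, pr$pos1 + pr$len1)
  pr$frag_start <- fs
  pr$frag_end <- fe
  pr$both_unique <- both
  pr
}

#' Segment a read-depth profile into copy-number segments
#'
#' Recursive binary segmentation: at each step the split maximizing the
#' between-segment mean difference is accepted if the difference exceeds a
#' fraction of the genome-wide median depth (copy-number steps are whole
#' multiples of it; smaller fluctuations are sampling noise). Segment copy
#' number is `round(segment mean / genome median depth)`; adjacent segments
#' with equal copy number are merged.
#'
#' @param depth integer per-base read-depth vector.
#' @param genome_median genome-wide median per-copy depth.
#' @param min_segment minimum segment length (bp, default 200).
#' @param min_step minimum mean difference to accept a split, as a fraction
#'   of `genome_median`.
#' @return data.frame with `start`, `end` (0-based half-open), `mean_depth`,
#'   `copy_number`.
#' @export
segment_copy_number <- function(depth, genome_median, min_segment = 200L,
                                min_step = 0.4) {
  L <- length(depth)
  stopifnot(L >= 2L * min_segment)
  if (all(depth == 0)) {
    return(data.frame(start = 0L, end = L, mean_depth = 0, copy_number = 0L))
  }
  cs <- c(0, cumsum(as.numeric(depth)))
  thresh <- min_step * max(genome_median, 1e-9)
  bounds <- sort(unique(c(0L, L, find_splits(cs, 0L, L, min_segment, thresh))))
  segs <- data.frame(start = bounds[-length(bounds)], end = bounds[-1])
  segs$mean_depth <- (cs[segs$end + 1L] - cs[segs$start + 1L]) /
    (segs$end - segs$start)
  segs$copy_number <- as.integer(round(segs$mean_depth /
                                         max(genome_median, 1e-9)))
  # merge adjacent equal-copy segments
  keep <- c(TRUE, diff(segs$copy_number) != 0)
  grp <- cumsum(keep)
  out <- data.frame(
    start = tapply(segs$start, grp, min),
    end = tapply(segs$end, grp, max)
  )
  out$mean_depth <- (cs[out$end + 1L] - cs[out$start + 1L]) /
    (out$end - out$start)
  out$copy_number <- as.integer(round(out$mean_depth /
                                        max(genome_median, 1e-9)))
  rownames(out) <- NULL
  out
}

# Recursively find change points in [lo, hi) using cumulative sums
find_splits <- function(cs, lo, hi, min_segment, thresh) {
  n <- hi - lo
  if (n < 2L * min_segment) return(integer(0))
  t <- seq.int(lo + min_segment, hi - min_segment)
  mean_l <- (cs[t + 1L] - cs[lo + 1L]) / (t - lo)
  mean_r <- (cs[hi + 1L] - cs[t + 1L]) / (hi - t)
  dd <- abs(mean_l - mean_r)
  best <- which.max(dd)
  if (dd[best] < thresh) return(integer(0))
  sp <- t[best]
  c(find_splits(cs, lo, sp, min_segment, thresh), sp,
    find_splits(cs, sp, hi, min_segment, thresh))
}

#' Write a depth profile as bedGraph
#'
#' Runs of equal depth are collapsed; intervals are 0-based half-open.
#'
#' @param profiles output of [compute_depths()].
#' @param which `"read_depth"` or `"span_depth"`.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_bedgraph <- function(profiles, which = c("read_depth", "span_depth"),
                           path) {
  which <- match.arg(which)
  lines <- character(0)
  for (cn in names(profiles)) {
    d <- profiles[[cn]][[which]]
    r <- rle(d)
    e <- cumsum(r$lengths)
    s <- e - r$lengths
    lines <- c(lines, sprintf("%s\t%d\t%d\t%d", cn, s, e, r$values))
  }
  writeLines(lines, path)
  invisible(path)
}
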
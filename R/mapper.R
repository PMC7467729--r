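# Toy-scale read mapping by unique exact k-mer anchoring plus ungapped
# extension. Adequate for small simulated genomes; reads spanning novel
# junctions intentionally fail to map (their best placement exceeds the
# mismatch budget) and thereby become junction-sequencing reads, reproducing
# the signal structure used for junction assembly.

#' Map paired-end reads to a genome by k-mer anchoring
#'
#' Each read is anchored by exact k-mers taken at both ends and the middle of
#' the read, on both strands; candidate placements are scored by ungapped
#' mismatch count. Reads with no anchored placement within `max_mismatch`
#' are unmapped; reads whose best score is achieved at more than one locus
#' are mapped but flagged non-unique (and excluded from depth profiles).
#'
#' @param genome a `toy_genome` or named character vector of chromosomes.
#' @param reads a `read_set`.
#' @param k anchor k-mer length (default 21, must be <= read length).
#' @param max_mismatch maximum mismatches for a valid placement (default 5).
#' @return a data.frame of alignment records: `qname`, `mate`, `chrom`,
#'   `pos` (0-based), `strand`, `mapped`, `unique`, `nm`, `read_len`.
#' @export
map_reads <- function(genome, reads, k = 21L, max_mismatch = 5L) {
  chroms <- if (inherits(genome, "toy_genome")) genome$chromosomes else genome
  stopifnot(k <= min(nchar(c(reads$r1, reads$r2))))
  idx <- kmer_index(chroms, k)
  a1 <- map_read_vec(reads$r1, idx, k, max_mismatch)
  a2 <- map_read_vec(reads$r2, idx, k, max_mismatch)
  a1$qname <- reads$names
  a1$mate <- 1L
  a2$qname <- reads$names
  a2$mate <- 2L
  out <- rbind(a1, a2)
  out <- out[order(out$qname, out$mate), ]
  rownames(out) <- NULL
  out[, c("qname", "mate", "chrom", "pos", "strand", "mapped", "unique",
          "nm", "read_len")]
}

# Concatenated-genome k-mer index. Chromosomes are joined with an N spacer
# so no indexable k-mer spans a boundary that an A/C/G/T read could query;
# k-mers are encoded numerically and looked up in a sorted array.
kmer_index <- function(chroms, k) {
  spacer <- strrep("N", 32L)
  concat <- paste(chroms, collapse = spacer)
  offs <- cumsum(c(0L, utils::head(nchar(chroms) + 32L, -1L)))
  tab <- kmer_table(kmer_values(dna_code(concat), k))
  list(tab = tab, concat = concat, concat_int = utf8ToInt(concat),
       offsets = offs, names = names(chroms), lens = nchar(chroms), k = k)
}

# Translate 1-based concatenated positions to (chrom index, 0-based pos)
concat_to_chrom <- function(idx, pos1) {
  ci <- findInterval(pos1 - 1L, idx$offsets)
  list(ci = ci, pos0 = pos1 - 1L - idx$offsets[ci])
}

map_read_vec <- function(seqs, idx, k, max_mismatch) {
  n <- length(seqs)
  rl <- nchar(seqs)
  chrom <- rep(NA_character_, n)
  pos <- rep(NA_integer_, n)
  strand <- rep(NA_character_, n)
  mapped <- logical(n)
  uniq <- logical(n)
  nm <- rep(NA_integer_, n)
  rcs <- revcomp(seqs)
  cn <- nchar(idx$concat)
  concat_int <- idx$concat_int
  pw <- 4^((k - 1):0)

  # phase 1: batch all probe k-mer lookups (grouped by read length so probe
  # values come from one matrix product, and by strand), so the sorted-array
  # search runs over whole query vectors at once
  cr <- list(); cs <- list(); cp <- list()
  for (len in unique(rl)) {
    sel <- which(rl == len)
    offs <- unique(c(1L, max(1L, (len - k) %/% 2L + 1L), len - k + 1L))
    for (sidx in 1:2) {
      m <- matrix(dna_code(paste(if (sidx == 1L) seqs[sel] else rcs[sel],
                                 collapse = "")), nrow = len)
      for (o in offs) {
        vals <- colSums(m[o:(o + k - 1L), , drop = FALSE] * pw)
        hi <- findInterval(vals, idx$tab$v)
        lo <- findInterval(vals - 0.5, idx$tab$v) + 1L
        cnt <- hi - lo + 1L
        cnt[is.na(cnt) | cnt < 0L] <- 0L
        if (sum(cnt) == 0L) next
        pos_idx <- sequence(cnt) + rep(lo - 1L, cnt)
        cr[[length(cr) + 1L]] <- rep(sel, cnt)
        cs[[length(cs) + 1L]] <- rep.int(sidx, sum(cnt))
        cp[[length(cp) + 1L]] <- idx$tab$pos[pos_idx] - o + 1L
      }
    }
  }
  if (length(cr) == 0L) {
    return(data.frame(chrom = chrom, pos = pos, strand = strand,
                      mapped = mapped, unique = uniq, nm = nm,
                      read_len = rl))
  }
  cand_read <- unlist(cr, use.names = FALSE)
  cand_str <- unlist(cs, use.names = FALSE)
  cand_start <- unlist(cp, use.names = FALSE)
  ok <- cand_start >= 1L & cand_start + rl[cand_read] - 1L <= cn
  key <- (as.numeric(cand_read) * 2 + cand_str) * (cn + 2) + cand_start
  ok <- ok & !duplicated(key)
  cand_read <- cand_read[ok]
  cand_str <- cand_str[ok]
  cand_start <- cand_start[ok]

  # phase 2: score each read's candidate placements by mismatch count
  ord <- order(cand_read, cand_str, cand_start)
  cand_read <- cand_read[ord]
  cand_str <- cand_str[ord]
  cand_start <- cand_start[ord]
  bounds <- c(which(c(TRUE, diff(cand_read) > 0L)), length(cand_read) + 1L)
  for (b in seq_len(length(bounds) - 1L)) {
    span <- bounds[b]:(bounds[b + 1L] - 1L)
    i <- cand_read[span[1]]
    len <- rl[i]
    sv_f <- NULL
    sv_r <- NULL
    hit_pos <- integer(0)
    hit_str <- integer(0)
    hit_mm <- integer(0)
    for (ci in span) {
      if (cand_str[ci] == 1L) {
        if (is.null(sv_f)) sv_f <- utf8ToInt(seqs[i])
        sv <- sv_f
      } else {
        if (is.null(sv_r)) sv_r <- utf8ToInt(rcs[i])
        sv <- sv_r
      }
      p1 <- cand_start[ci]
      mm <- sum(sv != concat_int[p1:(p1 + len - 1L)])
      if (mm <= max_mismatch) {
        hit_pos <- c(hit_pos, p1)
        hit_str <- c(hit_str, cand_str[ci])
        hit_mm <- c(hit_mm, mm)
      }
    }
    if (length(hit_mm) > 0L) {
      best_nm <- min(hit_mm)
      at_best <- which(hit_mm == best_nm)
      j <- at_best[order(hit_pos[at_best], hit_str[at_best])][1]
      loc <- concat_to_chrom(idx, hit_pos[j])
      chrom[i] <- idx$names[loc$ci]
      pos[i] <- loc$pos0
      strand[i] <- c("+", "-")[hit_str[j]]
      mapped[i] <- TRUE
      uniq[i] <- length(at_best) == 1L
      nm[i] <- best_nm
    }
  }
  data.frame(chrom = chrom, pos = pos, strand = strand, mapped = mapped,
             unique = uniq, nm = nm, read_len = rl)
}

#' Write alignments in minimal SAM format
#'
#' Emits the 11 mandatory fields (1-based positions per the SAM standard)
#' plus an NM tag, with @SQ header lines.
#'
#' @param alignments alignment data.frame from [map_reads()].
#' @param reads the `read_set` that was mapped (for sequences).
#' @param genome the genome mapped against (for header lengths).
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_sam <- function(alignments, reads, genome, path) {
  chroms <- if (inherits(genome, "toy_genome")) genome$chromosomes else genome
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(chroms), nchar(chroms)))
  seq_of <- function(qname, mate) {
    j <- match(qname, reads$names)
    ifelse(mate == 1L, reads$r1[j], reads$r2[j])
  }
  a <- alignments
  sq <- seq_of(a$qname, a$mate)
  rc <- !is.na(a$strand) & a$strand == "-"
  sq[rc] <- revcomp(sq[rc])
  flag <- 1L +
    ifelse(a$mate == 1L, 64L, 128L) +
    ifelse(a$mapped, 0L, 4L) +
    ifelse(rc, 16L, 0L)
  lines <- sprintf(
    "%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*\tNM:i:%d",
    a$qname, flag,
    ifelse(a$mapped, a$chrom, "*"),
    ifelse(a$mapped, a$pos + 1L, 0L),
    ifelse(a$mapped & a$unique, 60L, ifelse(a$mapped, 0L, 0L)),
    ifelse(a$mapped, paste0(a$read_len, "M"), "*"),
    sq,
    ifelse(is.na(a$nm), 0L, a$nm)
  )
  writeLines(c(hdr, lines), path)
  invisible(path)
}
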
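# Discordant-pair clustering, junction-sequence assembly, and junction
# validation against span-depth profiles.

#' Detect clusters of junction-defining discordant read pairs
#'
#' A pair is discordant when both ends map uniquely but to different
#' chromosomes, in the same-strand orientation (inversion geometry), or with
#' an implied insert outside `mean +/- 3 sd`. Discordant pairs are clustered
#' when both anchors fall within `insert_mean` of each other; clusters below
#' `min_support` are discarded. Geometry is assigned from the orientation
#' pattern: different chromosomes = translocation, same strand = inversion,
#' inflated insert = deletion_like, otherwise insertion_like.
#'
#' @param alignments alignment data.frame from [map_reads()].
#' @param insert_mean,insert_sd fragment-size model.
#' @param min_support minimum supporting pairs per cluster (default 3).
#' @return data.frame of clusters: anchor intervals/strands for both sides
#'   (`chromA`, `startA`, `endA`, `strandA`, ...), `n_support`, `geometry`,
#'   and `qnames` (comma-separated supporting pair names).
#' @export
detect_discordant_clusters <- function(alignments, insert_mean, insert_sd,
                                       min_support = 3L) {
  pr <- pair_table(alignments)
  pr <- pr[pr$both_unique, , drop = FALSE]
  if (nrow(pr) == 0L) return(empty_clusters())
  conc <- is_concordant(pr, insert_mean, insert_sd)
  dis <- pr[!conc, , drop = FALSE]
  if (nrow(dis) == 0L) return(empty_clusters())

  # canonical orientation: anchor A = lexicographically smaller locus
  swap <- (dis$chrom2 < dis$chrom1) |
    (dis$chrom2 == dis$chrom1 & dis$pos2 < dis$pos1)
  d <- data.frame(
    qname = dis$qname,
    chromA = ifelse(swap, dis$chrom2, dis$chrom1),
    posA = ifelse(swap, dis$pos2, dis$pos1),
    strandA = ifelse(swap, dis$strand2, dis$strand1),
    lenA = ifelse(swap, dis$len2, dis$len1),
    chromB = ifelse(swap, dis$chrom1, dis$chrom2),
    posB = ifelse(swap, dis$pos1, dis$pos2),
    strandB = ifelse(swap, dis$strand1, dis$strand2),
    lenB = ifelse(swap, dis$len1, dis$len2)
  )
  d$geometry <- ifelse(
    d$chromA != d$chromB, "translocation",
    ifelse(d$strandA == d$strandB, "inversion",
           ifelse((d$strandA == "+") & (d$posB + d$lenB - d$posA) >
                    insert_mean + 3 * insert_sd,
                  "deletion_like", "insertion_like"))
  )
  # inversion clusters are strand-agnostic (++ and -- pairs describe the
  # same junction sampled from the two product strands)
  key <- paste(d$chromA, d$chromB, d$geometry)
  out <- list()
  for (kk in unique(key)) {
    dk <- d[key == kk, , drop = FALSE]
    dk <- dk[order(dk$posA, dk$posB), , drop = FALSE]
    grp <- cumsum(c(1L, as.integer(diff(dk$posA) > insert_mean)))
    for (gg in unique(grp)) {
      dg <- dk[grp == gg, , drop = FALSE]
      # secondary split on the B anchor
      dg <- dg[order(dg$posB), , drop = FALSE]
      g2 <- cumsum(c(1L, as.integer(diff(dg$posB) > insert_mean)))
      for (hh in unique(g2)) {
        dh <- dg[g2 == hh, , drop = FALSE]
        if (nrow(dh) < min_support) next
        out[[length(out) + 1L]] <- data.frame(
          chromA = dh$chromA[1],
          startA = min(dh$posA), endA = max(dh$posA + dh$lenA),
          strandA = names(sort(table(dh$strandA), decreasing = TRUE))[1],
          chromB = dh$chromB[1],
          startB = min(dh$posB), endB = max(dh$posB + dh$lenB),
          strandB = names(sort(table(dh$strandB), decreasing = TRUE))[1],
          n_support = nrow(dh),
          geometry = dh$geometry[1],
          qnames = paste(dh$qname, collapse = ",")
        )
      }
    }
  }
  if (length(out) == 0L) return(empty_clusters())
  res <- do.call(rbind, out)
  res <- res[order(res$chromA, res$startA), , drop = FALSE]
  rownames(res) <- NULL
  res
}

empty_clusters <- function() {
  data.frame(
    chromA = character(), startA = integer(), endA = integer(),
    strandA = character(), chromB = character(), startB = integer(),
    endB = integer(), strandB = character(), n_support = integer(),
    geometry = character(), qnames = character()
  )
}

#' Assemble the junction sequence for a discordant cluster
#'
#' Collects junction-sequencing reads (unmapped reads whose mates anchor
#' within `insert_mean` of either cluster anchor), assembles them by greedy
#' maximal-overlap consensus (minimum overlap 15 bp, majority base per
#' column), aligns the contig back to the reference from both sides to fix
#' base-precise breakpoints, and measures the junction microhomology on the
#' reference flanks. If no junction-crossing read is available the call is
#' returned at cluster resolution with `coarse = TRUE`.
#'
#' @param cluster one row of [detect_discordant_clusters()] output.
#' @param alignments alignment data.frame.
#' @param reads the `read_set`.
#' @param genome the reference genome mapped against.
#' @param insert_mean fragment-size mean (anchor search radius).
#' @return a one-row data.frame junction call: breakpoints (0-based),
#'   strands, `microhomology_len`, `inserted_bases`, `junction_seq`,
#'   `n_support`, `geometry`, `coarse`.
#' @export
assemble_junction <- function(cluster, alignments, reads, genome,
                              insert_mean) {
  chroms <- if (inherits(genome, "toy_genome")) genome$chromosomes else genome
  jreads <- junction_read_seqs(cluster, alignments, reads, insert_mean)
  coarse_call <- data.frame(
    chromA = cluster$chromA, breakpointA = cluster$endA,
    strandA = cluster$strandA,
    chromB = cluster$chromB, breakpointB = cluster$startB,
    strandB = cluster$strandB,
    microhomology_len = NA_integer_, inserted_bases = "",
    junction_seq = "", n_support = cluster$n_support,
    geometry = cluster$geometry, coarse = TRUE, telomere_units = 0L
  )
  if (length(jreads) == 0L) return(coarse_call)
  contig <- greedy_consensus(jreads, min_overlap = 15L)
  if (nchar(contig) < 40L) return(coarse_call)

  fix <- place_junction_contig(contig, cluster, chroms, insert_mean)
  if (is.null(fix)) return(coarse_call)
  data.frame(
    chromA = cluster$chromA, breakpointA = fix$bp_a, strandA = fix$strand_a,
    chromB = cluster$chromB, breakpointB = fix$bp_b, strandB = fix$strand_b,
    microhomology_len = fix$mh, inserted_bases = fix$inserted,
    junction_seq = fix$contig, n_support = cluster$n_support,
    geometry = cluster$geometry, coarse = FALSE, telomere_units = 0L
  )
}

# Unmapped (or badly mapped) reads whose mate anchors near either cluster
# anchor; candidates for sequencing across the junction.
junction_read_seqs <- function(cluster, alignments, reads, insert_mean) {
  pr <- pair_table(alignments)
  near <- function(chrom, pos) {
    hit_a <- !is.na(chrom) & chrom == cluster$chromA &
      pos >= cluster$startA - insert_mean & pos <= cluster$endA + insert_mean
    hit_b <- !is.na(chrom) & chrom == cluster$chromB &
      pos >= cluster$startB - insert_mean & pos <= cluster$endB + insert_mean
    hit_a | hit_b
  }
  take1 <- !pr$mapped1 & pr$mapped2 & pr$unique2 & near(pr$chrom2, pr$pos2)
  take2 <- !pr$mapped2 & pr$mapped1 & pr$unique1 & near(pr$chrom1, pr$pos1)
  i1 <- match(pr$qname[take1], reads$names)
  i2 <- match(pr$qname[take2], reads$names)
  c(reads$r1[i1], reads$r2[i2])
}

# Greedy maximal-overlap consensus assembly. Reads (either orientation) are
# merged into a growing contig whenever they share a >= min_overlap ungapped
# overlap with at most ~5% mismatches; per-column majority resolves
# disagreements. Offsets are proposed from shared 15-mers.
greedy_consensus <- function(seqs, min_overlap = 15L, max_rounds = 200L) {
  seqs <- seqs[order(-nchar(seqs), seqs)]
  contig_reads <- list(list(seq = seqs[1], offset = 0L))
  contig <- seqs[1]
  remaining <- seqs[-1]
  rounds <- 0L
  while (length(remaining) > 0L && rounds < max_rounds) {
    rounds <- rounds + 1L
    best <- NULL
    for (ri in seq_along(remaining)) {
      for (s in c(remaining[ri], revcomp(remaining[ri]))) {
        off <- propose_offsets(contig, s)
        for (o in off) {
          ov <- overlap_score(contig, s, o)
          if (is.null(ov) || ov$overlap < min_overlap) next
          # penalize mismatches heavily: at a quasi-palindromic foldback
          # junction the wrong orientation also overlaps, but only the
          # correct one is (near-)exact
          score <- ov$overlap - 20L * ov$mismatch
          if (is.null(best) || score > best$score) {
            best <- list(ri = ri, seq = s, offset = o, score = score)
          }
        }
      }
    }
    if (is.null(best)) break
    contig_reads[[length(contig_reads) + 1L]] <-
      list(seq = best$seq, offset = best$offset)
    if (best$offset < 0L) {
      shift <- -best$offset
      for (j in seq_along(contig_reads)) {
        contig_reads[[j]]$offset <- contig_reads[[j]]$offset + shift
      }
      contig_reads[[length(contig_reads)]]$offset <- 0L
    }
    contig <- consensus_from_layout(contig_reads, trim_cov = NULL)
    remaining <- remaining[-best$ri]
  }
  # final pass: trim single-coverage contig ends, which may carry read errors
  consensus_from_layout(contig_reads, trim_cov = 2L)
}

# Candidate alignment offsets of s against contig from shared 15-mers
propose_offsets <- function(contig, s, k = 15L) {
  if (nchar(s) < k || nchar(contig) < k) return(integer(0))
  starts <- seq_len(nchar(s) - k + 1L)
  kmers <- substring(s, starts, starts + k - 1L)
  offs <- integer(0)
  # probe a subset of k-mers across the read
  probe <- unique(c(1L, length(starts) %/% 2L + 1L, length(starts)))
  for (pi in probe) {
    hit <- gregexpr(kmers[pi], contig, fixed = TRUE)[[1]]
    if (hit[1] > 0) offs <- c(offs, hit - 1L - (starts[pi] - 1L))
  }
  unique(offs)
}

# Ungapped overlap of s placed at `offset` (0-based) relative to contig
overlap_score <- function(contig, s, offset) {
  cl <- nchar(contig)
  sl <- nchar(s)
  lo <- max(0L, offset)
  hi <- min(cl, offset + sl)
  if (hi - lo < 1L) return(NULL)
  cpart <- utf8ToInt(substr(contig, lo + 1L, hi))
  spart <- utf8ToInt(substr(s, lo - offset + 1L, hi - offset))
  mm <- sum(cpart != spart)
  if (mm > max(1L, ceiling(0.05 * (hi - lo)))) return(NULL)
  list(overlap = hi - lo, mismatch = mm)
}

# Majority-base consensus over a read layout (list of seq + 0-based offset).
# Columns covered by a single read are unreliable at the contig ends (one
# sequencing error propagates into the consensus), so when the contig has a
# >= 2x core it is trimmed to that core.
consensus_from_layout <- function(layout, trim_cov = 2L) {
  offs <- vapply(layout, function(x) x$offset, integer(1))
  lens <- vapply(layout, function(x) nchar(x$seq), integer(1))
  shift <- -min(offs, 0L)
  offs <- offs + shift
  total <- max(offs + lens)
  counts <- matrix(0L, nrow = 4L, ncol = total,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  for (x in seq_along(layout)) {
    v <- strsplit(layout[[x]]$seq, "")[[1]]
    cols <- offs[x] + seq_along(v)
    for (b in c("A", "C", "G", "T")) {
      sel <- cols[v == b]
      counts[b, sel] <- counts[b, sel] + 1L
    }
  }
  cons <- paste(rownames(counts)[max.col(t(counts), ties.method = "first")],
                collapse = "")
  if (!is.null(trim_cov) && length(layout) > 1L) {
    cov <- colSums(counts)
    core <- which(cov >= trim_cov)
    if (length(core) >= 40L) {
      cons <- substr(cons, core[1], core[length(core)])
    }
  }
  cons
}

# Fix base-precise breakpoints by walking the contig against the reference
# outward from each anchor. Returns NULL when neither contig orientation
# anchors on both sides.
place_junction_contig <- function(contig, cluster, chroms, insert_mean) {
  win <- function(chrom, lo, hi) {
    L <- nchar(chroms[[chrom]])
    lo <- max(0L, lo); hi <- min(L, hi)
    list(seq = seq_slice(chroms[[chrom]], lo, hi), off = lo)
  }
  wa <- win(cluster$chromA, cluster$startA - insert_mean,
            cluster$endA + 2L * insert_mean)
  wb <- win(cluster$chromB, cluster$startB - 2L * insert_mean,
            cluster$endB + 2L * insert_mean)
  for (cand in c(contig, revcomp(contig))) {
    left <- anchor_walk_left(cand, wa$seq)
    if (is.null(left)) next
    right_f <- anchor_walk_right(cand, wb$seq)
    right_r <- anchor_walk_right(cand, revcomp(wb$seq))
    use_rc <- FALSE
    right <- right_f
    if (is.null(right_f) ||
        (!is.null(right_r) && (is.null(right_f) ||
                               right_r$matched > right_f$matched))) {
      right <- right_r
      use_rc <- TRUE
    }
    if (is.null(right)) next
    bp_a <- wa$off + left$ref_end          # 0-based exclusive on ref A side
    if (!use_rc) {
      bp_b <- wb$off + right$ref_start     # 0-based start on ref B side
      strand_b <- "+"
    } else {
      # contig suffix matches revcomp(window): ref interval end maps to the
      # suffix start
      bp_b <- wb$off + (nchar(wb$seq) - right$ref_start)
      strand_b <- "-"
    }
    ov <- left$contig_end - right$contig_start + 1L
    inserted <- if (ov < 0L) {
      substr(cand, left$contig_end + 1L, right$contig_start - 1L)
    } else ""
    if (ov > 0L) {
      # both walks claim the overlap (junction microhomology, or the
      # self-complementary arms of a foldback junction); assign it to side A
      # so breakpoint B marks where side B's unshared sequence begins
      bp_b <- if (strand_b == "+") bp_b + ov else bp_b - ov
    }
    if (strand_b == "-" && !is.na(bp_b) && bp_a < bp_b && ov > 0L) {
      # the contig described the junction from the opposite strand: a
      # foldback read minus-wise places the fold at the inner arm ends
      # (arm1_end, arm2_start); re-describe it from the strand that keeps
      # the loop in reference orientation, shifting each breakpoint by the
      # arm overlap
      tmp <- bp_b + ov
      bp_b <- bp_a - ov
      bp_a <- tmp
    }
    mh <- junction_flank_mh(chroms, cluster$chromA, bp_a, "+",
                            cluster$chromB, bp_b, strand_b)
    return(list(
      bp_a = bp_a, strand_a = "+", bp_b = bp_b, strand_b = strand_b,
      mh = mh, inserted = inserted, contig = cand
    ))
  }
  NULL
}

# Walk the contig prefix along the reference window with a tolerant match
# rule; returns the 1-based contig index and 0-based window position where
# the alignment diverges.
anchor_walk_left <- function(contig, window, k = 18L) {
  if (nchar(contig) < k) return(NULL)
  wpos <- NA_integer_
  off_used <- 0L
  for (off in c(0L, 8L, 16L)) {
    if (off + k > nchar(contig)) break
    seed <- substr(contig, off + 1L, off + k)
    hit <- gregexpr(seed, window, fixed = TRUE)[[1]]
    if (hit[1] > 0) {
      wpos <- hit[1] - 1L - off  # 0-based window position of contig[1]
      off_used <- off
      break
    }
  }
  if (is.na(wpos) || wpos < 0L) return(NULL)
  cv <- utf8ToInt(contig)
  wv <- utf8ToInt(window)
  i <- min(off_used + k, length(cv))  # end of the verified seed
  while (i < length(cv) && wpos + i < length(wv)) {
    if (cv[i + 1L] == wv[wpos + i + 1L]) {
      i <- i + 1L
    } else if (tolerant_ahead(cv, wv, i + 1L, wpos + i + 1L)) {
      i <- i + 1L  # isolated consensus/sequencing error
    } else {
      break
    }
  }
  list(contig_end = i, ref_end = wpos + i, matched = i)
}

# Same, walking the contig suffix backward
anchor_walk_right <- function(contig, window, k = 18L) {
  n <- nchar(contig)
  if (n < k) return(NULL)
  wend <- NA_integer_
  off_used <- 0L
  for (off in c(0L, 8L, 16L)) {
    if (off + k > n) break
    seed <- substr(contig, n - off - k + 1L, n - off)
    hit <- gregexpr(seed, window, fixed = TRUE)[[1]]
    if (hit[1] > 0) {
      # 0-based window pos after contig[n]
      wend <- hit[length(hit)] - 1L + k + off
      off_used <- off
      break
    }
  }
  if (is.na(wend) || wend > nchar(window)) return(NULL)
  cv <- utf8ToInt(contig)
  wv <- utf8ToInt(window)
  i <- n - off_used - k + 1L  # leftmost verified contig index (1-based)
  repeat {
    ci <- i - 1L
    wi1 <- wend - (n - ci)  # 1-based window index of contig[ci]
    if (ci < 1L || wi1 < 1L) break
    if (cv[ci] == wv[wi1] || tolerant_behind(cv, wv, ci, wi1)) {
      i <- ci
    } else {
      break
    }
  }
  list(contig_start = i, ref_start = wend - (n - i) - 1L, matched = n - i + 1L)
}

# A mismatch is tolerated when at least 4 of the following 6 positions match
tolerant_ahead <- function(cv, wv, ci, wi) {
  look <- min(6L, length(cv) - ci, length(wv) - wi)
  if (look < 4L) return(FALSE)
  sum(cv[ci + seq_len(look)] == wv[wi + seq_len(look)]) >= look - 2L &&
    look >= 4L
}

tolerant_behind <- function(cv, wv, ci, wi) {
  look <- min(6L, ci - 1L, wi - 1L)
  if (look < 4L) return(FALSE)
  sum(cv[ci - seq_len(look)] == wv[wi - seq_len(look)]) >= look - 2L
}

# Microhomology on the reference flanks at a fixed junction
junction_flank_mh <- function(chroms, chromA, bp_a, strand_a,
                              chromB, bp_b, strand_b, F = 20L) {
  ga <- chroms[[chromA]]
  gb <- chroms[[chromB]]
  ctx_a <- seq_slice(ga, max(0L, bp_a - F), min(nchar(ga), bp_a + F))
  ctx_b <- if (strand_b == "+") {
    seq_slice(gb, max(0L, bp_b - F), min(nchar(gb), bp_b + F))
  } else {
    revcomp(seq_slice(gb, max(0L, bp_b - F), min(nchar(gb), bp_b + F)))
  }
  half_a <- min(F, bp_a)
  half_b <- min(F, if (strand_b == "+") bp_b else nchar(gb) - bp_b)
  measure_microhomology(
    junction = paste0(substr(ctx_a, 1L, half_a),
                      substr(ctx_b, half_b + 1L, nchar(ctx_b))),
    flank_a = ctx_a, flank_b = ctx_b,
    join_a = half_a, join_b = half_b, check_junction = FALSE
  )
}

#' Measure microhomology at a rearrangement junction
#'
#' The microhomology is the maximal run of bases immediately at the join
#' that is identical in both reference flanks: the shared suffix of the two
#' sequences entering the join plus the shared prefix of the two sequences
#' leaving it, capped at the flank length. Non-templated inserted bases are
#' reported separately by the assembler and are not part of this measure.
#'
#' @param junction the assembled sequence across the novel adjacency
#'   (>= 15 bp of flank on each side of the join).
#' @param flank_a reference context around breakpoint A, junction-oriented,
#'   with the breakpoint at offset `join_a`.
#' @param flank_b reference context around breakpoint B with the breakpoint
#'   at offset `join_b`.
#' @param join_a,join_b 0-based breakpoint offsets within the flanks
#'   (default: midpoint).
#' @param check_junction validate that the junction contains both flanks.
#' @return microhomology length in nt.
#' @export
measure_microhomology <- function(junction, flank_a, flank_b,
                                  join_a = nchar(flank_a) %/% 2L,
                                  join_b = nchar(flank_b) %/% 2L,
                                  check_junction = TRUE) {
  if (nchar(flank_a) < 15L || nchar(flank_b) < 15L) {
    stop("flanks must be at least 15 bp")
  }
  a_in <- substr(flank_a, 1L, join_a)                  # entering via A
  b_in <- substr(flank_b, 1L, join_b)                  # reference before B
  a_out <- substr(flank_a, join_a + 1L, nchar(flank_a))  # reference after A
  b_out <- substr(flank_b, join_b + 1L, nchar(flank_b))  # leaving via B
  if (check_junction && nchar(a_in) >= 15L && nchar(b_out) >= 15L) {
    core <- paste0(substring(a_in, nchar(a_in) - 14L),
                   substr(b_out, 1L, 15L))
    if (!grepl(core, junction, fixed = TRUE)) {
      stop("junction sequence does not span the adjacency described by the ",
           "flanks")
    }
  }
  h_left <- common_suffix_len(a_in, b_in)
  h_right <- common_prefix_len(a_out, b_out)
  min(h_left + h_right, nchar(flank_a), nchar(flank_b))
}

#' Detect de novo telomere-addition junctions
#'
#' Finds groups of read pairs in which one mate maps uniquely and the other
#' is unmapped and consists of tandem telomere repeat units. The breakpoint
#' is refined from unmapped mates that retain a non-telomeric flank matching
#' the reference near the anchor. A junction is reported when the longest
#' observed tandem run reaches `min_units` repeat units.
#'
#' @param alignments alignment data.frame.
#' @param reads the `read_set`.
#' @param genome the reference genome (supplies the telomere unit).
#' @param insert_mean anchor clustering radius.
#' @param min_units minimum tandem telomere units (default 12).
#' @param min_support minimum supporting pairs (default 3).
#' @return data.frame of telomere junction calls (chromB = "*telomere*").
#' @export
detect_telomere_junctions <- function(alignments, reads, genome,
                                      insert_mean, min_units = 12L,
                                      min_support = 3L) {
  unit <- genome$telomere_unit
  pr <- pair_table(alignments)
  half1 <- !pr$mapped1 & pr$mapped2 & pr$unique2
  half2 <- !pr$mapped2 & pr$mapped1 & pr$unique1
  recs <- rbind(
    data.frame(qname = pr$qname[half1], chrom = pr$chrom2[half1],
               pos = pr$pos2[half1], strand = pr$strand2[half1],
               seq = reads$r1[match(pr$qname[half1], reads$names)]),
    data.frame(qname = pr$qname[half2], chrom = pr$chrom1[half2],
               pos = pr$pos1[half2], strand = pr$strand1[half2],
               seq = reads$r2[match(pr$qname[half2], reads$names)])
  )
  if (nrow(recs) == 0L) return(empty_telomere_calls())
  runs <- pmax(telomere_run(recs$seq, unit), telomere_run(revcomp(recs$seq),
                                                          unit))
  recs <- recs[runs >= 2L, , drop = FALSE]
  runs <- runs[runs >= 2L]
  if (nrow(recs) == 0L) return(empty_telomere_calls())

  # exclude anchors inside reference telomere seeds (normal chromosome ends)
  feats <- genome$features
  tel_feats <- feats[feats$kind == "telomere_seed", ]
  near_ref_tel <- vapply(seq_len(nrow(recs)), function(i) {
    any(tel_feats$chrom == recs$chrom[i] &
          recs$pos[i] + insert_mean >= tel_feats$start &
          recs$pos[i] - insert_mean <= tel_feats$end)
  }, logical(1))
  recs <- recs[!near_ref_tel, , drop = FALSE]
  runs <- runs[!near_ref_tel]
  if (nrow(recs) == 0L) return(empty_telomere_calls())

  out <- list()
  ordix <- order(recs$chrom, recs$pos)
  recs <- recs[ordix, , drop = FALSE]
  runs <- runs[ordix]
  grp <- cumsum(c(1L, as.integer(recs$chrom[-1] != recs$chrom[-nrow(recs)] |
                                   diff(recs$pos) > insert_mean)))
  for (gg in unique(grp)) {
    sel <- grp == gg
    if (sum(sel) < min_support) next
    rg <- recs[sel, , drop = FALSE]
    max_units <- max(runs[sel])
    bp <- refine_telomere_breakpoint(rg, genome, unit, insert_mean)
    out[[length(out) + 1L]] <- data.frame(
      chromA = rg$chrom[1],
      breakpointA = if (is.na(bp$pos)) max(rg$pos) else bp$pos,
      strandA = bp$strand,
      chromB = "*telomere*", breakpointB = NA_integer_,
      strandB = "+",
      microhomology_len = 0L, inserted_bases = "",
      junction_seq = bp$seq, n_support = sum(sel),
      geometry = "telomere_addition",
      coarse = is.na(bp$pos), telomere_units = as.integer(max_units)
    )
  }
  if (length(out) == 0L) return(empty_telomere_calls())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

empty_telomere_calls <- function() {
  data.frame(
    chromA = character(), breakpointA = integer(), strandA = character(),
    chromB = character(), breakpointB = integer(), strandB = character(),
    microhomology_len = integer(), inserted_bases = character(),
    junction_seq = character(), n_support = integer(), geometry = character(),
    coarse = logical(), telomere_units = integer()
  )
}

# Longest tandem run of the telomere unit (any phase) in each sequence,
# in unit copies
telomere_run <- function(seqs, unit) {
  pat <- paste0("(", unit, ")+")
  best <- integer(length(seqs))
  for (ph in seq_len(nchar(unit))) {
    rot <- paste0(substr(unit, ph, nchar(unit)), substr(unit, 1L, ph - 1L))
    m <- regexpr(gsub(unit, rot, pat, fixed = TRUE), seqs)
    len <- ifelse(m > 0, attr(m, "match.length"), 0L)
    best <- pmax(best, len %/% nchar(unit))
  }
  best
}

# Vote on the telomere-addition breakpoint from split reads that retain a
# reference flank before the telomere run
refine_telomere_breakpoint <- function(rg, genome, unit, insert_mean) {
  chroms <- if (inherits(genome, "toy_genome")) genome$chromosomes else genome
  chrom <- rg$chrom[1]
  L <- nchar(chroms[[chrom]])
  lo <- max(0L, min(rg$pos) - 2L * insert_mean)
  hi <- min(L, max(rg$pos) + 2L * insert_mean)
  window <- seq_slice(chroms[[chrom]], lo, hi)
  votes <- integer(0)
  strands <- character(0)
  best_seq <- ""
  for (s0 in rg$seq) {
    for (ori in c("+", "-")) {
      s <- if (ori == "+") s0 else revcomp(s0)
      m <- find_telomere_suffix(s, unit)
      if (is.na(m) || m < 16L) next
      flank <- substr(s, 1L, m - 1L)
      hit <- gregexpr(flank, window, fixed = TRUE)[[1]]
      if (hit[1] > 0) {
        votes <- c(votes, lo + hit[1] - 1L + nchar(flank))
        strands <- c(strands, "+")
        if (nchar(s) > nchar(best_seq)) best_seq <- s
      } else {
        hit2 <- gregexpr(revcomp(flank), window, fixed = TRUE)[[1]]
        if (hit2[1] > 0) {
          votes <- c(votes, lo + hit2[1] - 1L)
          strands <- c(strands, "-")
          if (nchar(s) > nchar(best_seq)) best_seq <- s
        }
      }
    }
  }
  if (length(votes) == 0L) {
    return(list(pos = NA_integer_, strand = "+", seq = ""))
  }
  tab <- sort(table(votes), decreasing = TRUE)
  pos <- as.integer(names(tab)[1])
  list(pos = pos, strand = names(sort(table(strands), decreasing = TRUE))[1],
       seq = best_seq)
}

# 1-based start of a >= 2-unit telomere run extending to the read end, NA if
# none
find_telomere_suffix <- function(s, unit) {
  ul <- nchar(unit)
  n <- nchar(s)
  for (ph in seq_len(ul)) {
    rot <- paste0(substr(unit, ph, ul), substr(unit, 1L, ph - 1L))
    m <- regexpr(paste0("(", rot, ")+"), s)
    if (m > 0) {
      len <- attr(m, "match.length")
      if (m + len - 1L >= n - ul && len >= 2L * ul) return(as.integer(m))
    }
  }
  NA_integer_
}

#' Validate junction calls against support and span-depth criteria
#'
#' A call validates iff its supporting pair count reaches `min_support` and
#' also reaches `alpha` times the local span depth at each anchor (real
#' junctions are supported in proportion to local coverage; scattered
#' discordant pairs are not).
#'
#' @param calls junction call data.frame (rows from [assemble_junction()]
#'   and/or [detect_telomere_junctions()]).
#' @param depths profiles from [compute_depths()].
#' @param min_support minimum supporting pairs (default 3).
#' @param alpha span-depth fraction (default 0.2).
#' @param flank window (bp) over which local span depth is averaged.
#' @return the calls with `validated` and `fail_reason` columns.
#' @export
filter_junctions <- function(calls, depths, min_support = 3L, alpha = 0.2,
                             flank = 200L) {
  if (nrow(calls) == 0L) {
    calls$validated <- logical(0)
    calls$fail_reason <- character(0)
    return(calls)
  }
  local_span <- function(chrom, pos) {
    if (is.na(pos) || !chrom %in% names(depths)) return(0)
    sp <- depths[[chrom]]$span_depth
    lo <- max(1L, pos - flank)
    hi <- min(length(sp), pos + flank)
    mean(sp[lo:hi])
  }
  validated <- logical(nrow(calls))
  reason <- character(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    sup <- calls$n_support[i]
    if (sup < min_support) {
      reason[i] <- "support"
      next
    }
    spans <- c(local_span(calls$chromA[i], calls$breakpointA[i]),
               if (calls$chromB[i] %in% names(depths))
                 local_span(calls$chromB[i], calls$breakpointB[i]))
    if (any(sup < alpha * spans)) {
      reason[i] <- "fraction"
      next
    }
    validated[i] <- TRUE
  }
  calls$validated <- validated
  calls$fail_reason <- reason
  calls
}
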
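# Toy assay genome construction.
#
# The genome emulates the chrV L counter-selection assay: chromosome 1
# carries, from its centromere outward, an oppositely oriented homology block
# (the ura3-52 analogue), a Ty-like repeat, the breakpoint region with the
# planted hairpin-forming sites, and the telomere-proximal counter-selection
# cassette containing the URA3-like member of the inverted homology pair.
# Selection against the cassette recovers rearrangements that delete it while
# keeping the centromeric side of the chromosome.

#' Build an annotated toy assay genome
#'
#' Generates seeded random background sequence, plants telomere seeds,
#' centromeres, the counter-selection cassette, the inverted homology pair,
#' Ty-like repeat blocks and the requested hairpin sites (exact inverted
#' repeats). Background around each planted site is guarded so the planted
#' stem is maximal (no accidental outward or inward extension), and the
#' breakpoint region is rejection-sampled until it contains no unintended
#' inverted repeat with a stem at least as long as the longest planted stem.
#'
#' @param config a [sim_config()].
#' @return an object of class `toy_genome`: named chromosome strings, a
#'   feature data.frame (0-based half-open; kinds `cassette`,
#'   `homology_block`, `telomere_seed`, `centromere`, `hairpin_site`,
#'   `repeat_element`) and the config.
#' @export
build_toy_genome <- function(config) {
  validate_sim_config(config)
  set.seed(substream_seed(config$master_seed, "genome"))
  lens <- config$chromosome_lengths
  n_chr <- length(lens)
  chrom_names <- paste0("chr", seq_len(n_chr))
  tel <- strrep(config$telomere_unit, config$telomere_copies)
  tel_len <- nchar(tel)
  hl <- config$homology_len

  feats <- list()
  add_feat <- function(name, chrom, start, end, kind, pair_id = NA_character_,
                       stem_len = NA_integer_, loop_len = NA_integer_) {
    feats[[length(feats) + 1L]] <<- data.frame(
      name = name, chrom = chrom, start = as.integer(start),
      end = as.integer(end), kind = kind, pair_id = pair_id,
      stem_len = stem_len, loop_len = loop_len
    )
  }

  # fixed layout relative to chromosome 1 (centromere at low coordinates)
  cen <- c(800L, 920L)
  v_span <- c(2000L, 2000L + hl)      # ura3-52-like, revcomp of the U block
  y_span <- c(3500L, 3500L + hl)      # Ty-like repeat on the assay chromosome
  u_span <- c(config$cassette_span[1] + 500L,
              config$cassette_span[1] + 500L + hl)  # URA3-like, in cassette
  r_span <- c(6000L, 6000L + hl)      # Ty-like repeat on donor chromosome 2
  stopifnot(v_span[2] <= y_span[1], y_span[2] <= config$breakpoint_region[1],
            u_span[2] <= config$cassette_span[2])

  hp <- config$hairpin_specs
  hp_spans <- if (nrow(hp) > 0) {
    cbind(hp$pos, hp$pos + 2L * hp$stem_len + hp$loop_len)
  } else {
    matrix(integer(0), ncol = 2)
  }
  # collision check across all planted chromosome-1 intervals
  spans <- rbind(
    c(0L, tel_len), cen, v_span, y_span, config$cassette_span,
    c(lens[1] - tel_len, lens[1]), hp_spans
  )
  ord <- order(spans[, 1])
  s_ord <- spans[ord, , drop = FALSE]
  if (any(s_ord[-1, 1] < s_ord[-nrow(s_ord), 2])) {
    i <- which(s_ord[-1, 1] < s_ord[-nrow(s_ord), 2])[1]
    stop(sprintf(
      "feature collision on chromosome 1: [%d,%d) overlaps [%d,%d)",
      s_ord[i, 1], s_ord[i, 2], s_ord[i + 1, 1], s_ord[i + 1, 2]
    ))
  }

  max_stem <- if (nrow(hp) > 0) max(hp$stem_len) else 0L
  u_seq <- random_dna(hl)
  y_seq <- random_dna(hl)

  chr1 <- NULL
  for (attempt in seq_len(1000L)) {
    s <- random_dna(lens[1])
    s <- plant(s, 0L, tel)
    s <- plant(s, lens[1] - tel_len, tel)
    s <- plant(s, cen[1], random_dna(cen[2] - cen[1]))
    s <- plant(s, v_span[1], revcomp(u_seq))
    s <- plant(s, y_span[1], y_seq)
    s <- plant(s, u_span[1], u_seq)
    for (i in seq_len(nrow(hp))) {
      s <- plant_hairpin(s, hp$pos[i], hp$stem_len[i], hp$loop_len[i])
    }
    if (max_stem == 0L) { chr1 <- s; break }
    region <- seq_slice(s, config$breakpoint_region[1],
                        config$breakpoint_region[2])
    rogue <- find_long_stems(region, min_stem = max_stem, max_loop = 49L)
    if (nrow(rogue) > 0) {
      rogue$arm1_start <- rogue$arm1_start + config$breakpoint_region[1]
      rogue$arm2_end <- rogue$arm2_end + config$breakpoint_region[1]
      planted_ok <- vapply(seq_len(nrow(rogue)), function(i) {
        any(hp_spans[, 1] <= rogue$arm1_start[i] &
              hp_spans[, 2] >= rogue$arm2_end[i])
      }, logical(1))
      rogue <- rogue[!planted_ok, , drop = FALSE]
    }
    if (nrow(rogue) == 0L) { chr1 <- s; break }
  }
  if (is.null(chr1)) {
    stop("could not sample a breakpoint region free of unintended long-stem ",
         "inverted repeats after 1000 attempts; use shorter planted stems")
  }

  chroms <- character(n_chr)
  chroms[1] <- chr1
  for (ci in seq_len(n_chr)[-1]) {
    s <- random_dna(lens[ci])
    s <- plant(s, 0L, tel)
    s <- plant(s, lens[ci] - tel_len, tel)
    s <- plant(s, cen[1], random_dna(cen[2] - cen[1]))
    if (ci == 2L) s <- plant(s, r_span[1], revcomp(y_seq))
    chroms[ci] <- s
  }
  names(chroms) <- chrom_names

  for (ci in seq_len(n_chr)) {
    add_feat("tel_L", chrom_names[ci], 0L, tel_len, "telomere_seed")
    add_feat("tel_R", chrom_names[ci], lens[ci] - tel_len, lens[ci],
             "telomere_seed")
    add_feat(paste0("CEN", ci), chrom_names[ci], cen[1], cen[2], "centromere")
  }
  add_feat("ura3_52", "chr1", v_span[1], v_span[2], "homology_block",
           pair_id = "ura3")
  add_feat("ty_like_assay", "chr1", y_span[1], y_span[2], "repeat_element",
           pair_id = "ty")
  add_feat("CAN1_URA3_cassette", "chr1", config$cassette_span[1],
           config$cassette_span[2], "cassette")
  add_feat("URA3", "chr1", u_span[1], u_span[2], "homology_block",
           pair_id = "ura3")
  add_feat("ty_like_donor", "chr2", r_span[1], r_span[2], "repeat_element",
           pair_id = "ty")
  for (i in seq_len(nrow(hp))) {
    add_feat(paste0("hairpin_", i), "chr1", hp$pos[i],
             hp$pos[i] + 2L * hp$stem_len[i] + hp$loop_len[i], "hairpin_site",
             stem_len = hp$stem_len[i], loop_len = hp$loop_len[i])
  }
  features <- do.call(rbind, feats)
  features <- features[order(match(features$chrom, chrom_names),
                             features$start), ]
  rownames(features) <- NULL

  g <- list(
    chromosomes = chroms,
    features = features,
    config = config,
    telomere_unit = config$telomere_unit,
    coord = "0-based half-open"
  )
  class(g) <- "toy_genome"
  g
}

# Overwrite s[start, start+nchar(piece)) (0-based) with piece
plant <- function(s, start, piece) {
  paste0(substr(s, 1L, start), piece,
         substr(s, start + nchar(piece) + 1L, nchar(s)))
}

# Plant an exact inverted repeat arm/loop/revcomp(arm) at pos, with guards so
# the planted stem is maximal: the bases just outside the arms must not pair,
# and the outermost loop bases must not pair (otherwise the stem would extend
# inward and the planted geometry would not round-trip).
plant_hairpin <- function(s, pos, stem, loop) {
  arm <- random_dna(stem)
  lp <- random_dna(loop)
  # inward guard: first and last loop base must not be complementary
  while (substr(lp, 1L, 1L) == comp_chars(substr(lp, loop, loop))) {
    lp <- plant(lp, loop - 1L, random_dna(1L))
  }
  site <- paste0(arm, lp, revcomp(arm))
  s <- plant(s, pos, site)
  # outward guard: base before arm1 must not pair with base after arm2
  end <- pos + 2L * stem + loop
  if (pos > 0L && end < nchar(s)) {
    before <- substr(s, pos, pos)
    after <- substr(s, end + 1L, end + 1L)
    if (before == comp_chars(after)) {
      repl <- sample(setdiff(c("A", "C", "G", "T"),
                             c(before, comp_chars(after))), 1L)
      s <- plant(s, pos - 1L, repl)
    }
  }
  s
}

# Seed-and-extend detector for perfect inverted repeats with stem >= min_stem
# and loop <= max_loop. Much faster than full enumeration when min_stem is
# large; used by the background rejection-sampling guard.
find_long_stems <- function(sequence, min_stem, max_loop = 49L) {
  n <- nchar(sequence)
  k <- min(min_stem, 12L)
  if (n < 2L * min_stem + 3L) {
    return(data.frame(arm1_start = integer(), arm2_end = integer()))
  }
  v <- utf8ToInt(sequence)
  cv <- utf8ToInt(comp_chars(sequence))
  code <- dna_code(sequence)
  fwd_vals <- kmer_values(code, k)
  y <- stats::filter(code, 4^((k - 1):0), method = "convolution", sides = 1)
  rc_vals <- (4^k - 1) - as.numeric(y)[seq.int(k, n)]
  tab <- kmer_table(fwd_vals)
  hi_all <- findInterval(rc_vals, tab$v)
  lo_all <- findInterval(rc_vals - 0.5, tab$v) + 1L
  res <- list()
  max_span <- 2L * (min_stem + 2L) + max_loop + 2L * k
  for (i in seq_along(fwd_vals)) {
    if (is.na(rc_vals[i]) || hi_all[i] < lo_all[i]) next
    for (j in tab$pos[lo_all[i]:hi_all[i]]) {
      if (j <= i || j - i > max_span) next
      # seed: s[i, i+k) pairs s[j, j+k) reversed; extend on the anti-diagonal
      cs <- i + (j + k - 1L)
      lo <- i
      while (lo > 1L && cs - lo + 1L <= n && v[lo - 1L] == cv[cs - lo + 1L]) {
        lo <- lo - 1L
      }
      hi <- i + k - 1L
      while (hi < (cs - 1L) %/% 2L && v[hi + 1L] == cv[cs - hi - 1L]) {
        hi <- hi + 1L
      }
      # trim to the 3 nt loop floor
      hi <- min(hi, (cs - 1L - 3L) %/% 2L)
      stem <- hi - lo + 1L
      loop <- cs - 2L * hi - 1L
      if (stem >= min_stem && loop <= max_loop) {
        res[[length(res) + 1L]] <- c(lo - 1L, cs - lo)
      }
    }
  }
  if (length(res) == 0L) {
    return(data.frame(arm1_start = integer(), arm2_end = integer()))
  }
  m <- unique(do.call(rbind, res))
  data.frame(arm1_start = m[, 1], arm2_end = m[, 2])
}

#' Write a toy genome as FASTA plus a BED feature map
#'
#' @param genome a `toy_genome`.
#' @param fasta,bed output paths (BED optional). BED is 0-based half-open
#'   with the feature kind in the name column.
#' @return invisibly, the paths written.
#' @export
write_genome <- function(genome, fasta, bed = NULL) {
  dna <- Biostrings::DNAStringSet(genome$chromosomes)
  Biostrings::writeXStringSet(dna, fasta)
  if (!is.null(bed)) {
    f <- genome$features
    utils::write.table(
      data.frame(f$chrom, f$start, f$end, f$kind, 0L, "+", f$name),
      bed, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
    )
  }
  invisible(c(fasta = fasta, bed = bed))
}

#' Read a genome FASTA into the plain-string representation
#'
#' @param fasta path to a FASTA file.
#' @return a named character vector of chromosome sequences.
#' @export
read_genome_fasta <- function(fasta) {
  dna <- Biostrings::readDNAStringSet(fasta)
  out <- as.character(dna)
  names(out) <- sub("\\s.*$", "", names(dna))
  out
}

#' Render a position in the assay's anchor-offset convention
#'
#' Positions inside an inserted element are reported relative to the
#' centromeric coordinate of the insertion site, e.g. an insertion anchored at
#' 34339 with offset 110 renders as "chrV:34,339-110" meaning 110 bases
#' telomeric to the insertion site.
#'
#' @param chrom chromosome label.
#' @param anchor 0-based insertion anchor coordinate.
#' @param offset bases telomeric to the anchor (0 = the anchor itself).
#' @return a character label.
#' @export
format_anchor_offset <- function(chrom, anchor, offset) {
  sprintf("%s:%s-%d", chrom, format(anchor, big.mark = ","), offset)
}
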
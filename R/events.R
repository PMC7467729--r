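# GCR event application.
#
# A foldback inversion forms by 5'->3' resection from a break telomeric to a
# hairpin-forming site, intrastrand annealing of the inverted arms, flap
# processing, and extension of the 3' end of the hairpin toward the
# centromere. The extended end is then stabilized by a secondary
# rearrangement: single-strand annealing with the released cassette-containing
# fragment via the inverted homology pair (no duplication of the captured
# fragment), a non-reciprocal homology-mediated translocation that duplicates
# a donor chromosome's telomeric segment, or de novo telomere addition.
#
# With the centromere of chromosome 1 at low coordinates, a foldback at a
# site with arms [p, p+S) and [q-S, q) (q = p + 2S + loop) resolved at
# position s < p produces, left to right:
#
#   ref[0, q) + revcomp(ref[s, p)) + <secondary-dependent cap>
#
# The region [s, p) is duplicated in inverted orientation, [p, q) (the site
# itself) is retained once and spans the inversion junction, and everything
# telomeric of q -- including the counter-selected cassette -- is deleted
# unless re-captured by the secondary rearrangement.

#' Apply a hairpin-mediated foldback inversion
#'
#' @param genome a `toy_genome`.
#' @param site a hairpin site: either a row of the genome's `hairpin_site`
#'   features or a list with `start` (arm1 start), `stem_len`, `loop_len`.
#' @param resection_start 0-based break position, telomeric to the site
#'   (i.e. greater than the site end on chromosome 1).
#' @param flap_len length of the 3' flap processed before extension (nt,
#'   recorded in the truth; does not alter the product).
#' @param secondary one of `"ssa_capture"`, `"homology_translocation"`,
#'   `"telomere_addition"`, `"none"`.
#' @param dup_len extent of the inverted duplication (bp) for secondaries
#'   that do not anchor it at a homology (telomere_addition / none).
#' @return a list with `genome` (rearranged: chromosome 1 replaced by the
#'   GCR product, features remapped) and `truth` (a `gcr_event_truth`).
#' @export
apply_foldback_inversion <- function(genome, site, resection_start,
                                     flap_len = 0L,
                                     secondary = c("ssa_capture",
                                                   "homology_translocation",
                                                   "telomere_addition",
                                                   "none"),
                                     dup_len = 4000L) {
  secondary <- match.arg(secondary)
  stopifnot(inherits(genome, "toy_genome"), flap_len >= 0L)
  g1 <- genome$chromosomes[["chr1"]]
  p <- as.integer(site$start)
  stem <- as.integer(site$stem_len)
  loop <- as.integer(site$loop_len)
  q <- p + 2L * stem + loop
  b <- as.integer(resection_start)
  if (b <= q) stop("resection_start must be telomeric to the hairpin site")
  arm1 <- seq_slice(g1, p, p + stem)
  arm2 <- seq_slice(g1, q - stem, q)
  if (arm2 != revcomp(arm1)) {
    stop("site is not an exact inverted repeat; cannot form a hairpin")
  }

  feats <- genome$features
  mh_len <- 0L
  if (secondary == "ssa_capture") {
    hom <- feats[feats$kind == "homology_block" & !is.na(feats$pair_id), ]
    if (nrow(hom) < 2L) {
      stop("ssa_capture requires an inverted homology pair in the genome")
    }
    v <- hom[hom$chrom == "chr1" & hom$end <= p, ][1, ]   # centromeric member
    u <- hom[hom$chrom == "chr1" & hom$start >= q, ][1, ] # cassette member
    if (any(is.na(v$start)) || any(is.na(u$start))) {
      stop("ssa_capture requires homology members on both sides of the site")
    }
    s <- v$start
    product <- paste0(
      seq_slice(g1, 0L, q),
      revcomp(seq_slice(g1, s, p)),
      seq_slice(g1, u$end, nchar(g1))
    )
    mh_len <- v$end - v$start
    cap <- list(kind = "ssa", u = u, v = v)
  } else if (secondary == "homology_translocation") {
    reps <- feats[feats$kind == "repeat_element" & !is.na(feats$pair_id), ]
    y <- reps[reps$chrom == "chr1" & reps$end <= p, ][1, ]
    r <- reps[reps$chrom != "chr1", ][1, ]
    if (any(is.na(y$start)) || any(is.na(r$start))) {
      stop("homology_translocation requires a chr1 repeat and a donor repeat")
    }
    donor <- genome$chromosomes[[r$chrom]]
    s <- y$start
    product <- paste0(
      seq_slice(g1, 0L, q),
      revcomp(seq_slice(g1, s, p)),
      seq_slice(donor, r$end, nchar(donor))
    )
    mh_len <- y$end - y$start
    cap <- list(kind = "translocation", y = y, r = r)
  } else {
    s <- max(0L, p - as.integer(dup_len))
    tail_seq <- if (secondary == "telomere_addition") {
      strrep(genome$telomere_unit, genome$config$telomere_copies)
    } else {
      ""
    }
    product <- paste0(
      seq_slice(g1, 0L, q),
      revcomp(seq_slice(g1, s, p)),
      tail_seq
    )
    cap <- list(kind = secondary)
  }

  new_genome <- genome
  new_genome$chromosomes[["chr1"]] <- product
  new_genome$features <- remap_foldback_features(genome, q, s, p, cap)

  truth <- list(
    event_type = "foldback_inversion",
    chrom = "chr1",
    hairpin_site = list(start = p, end = q, stem_len = stem,
                        loop_len = loop),
    resection_start = b,
    flap_len = as.integer(flap_len),
    # junction joins ref (chr1, q, +) to ref (chr1, p, -)
    inversion_junction = list(pos_a = q, pos_b = p,
                              strand_a = "+", strand_b = "-"),
    dup_span = c(s, p),
    secondary_resolution = secondary,
    microhomology_len = as.integer(mh_len),
    product_id = "chr1"
  )
  class(truth) <- "gcr_event_truth"
  list(genome = new_genome, truth = truth)
}

# Map reference features onto the foldback product chromosome. Only features
# fully contained in a surviving piece are kept.
remap_foldback_features <- function(genome, q, s, p, cap) {
  f <- genome$features
  other <- f[f$chrom != "chr1", ]
  f1 <- f[f$chrom == "chr1", ]
  kept <- f1[f1$end <= q, ]                       # direct piece [0, q)
  inv <- f1[f1$start >= s & f1$end <= p, ]        # inverted piece [s, p)
  if (nrow(inv) > 0) {
    new_start <- q + (p - inv$end)
    new_end <- q + (p - inv$start)
    inv$start <- new_start
    inv$end <- new_end
    inv$name <- paste0(inv$name, "_inv")
  }
  len_left <- q + (p - s)
  tail_feats <- NULL
  if (cap$kind == "ssa") {
    src <- f1[f1$start >= cap$u$end, ]
    if (nrow(src) > 0) {
      off <- len_left - cap$u$end
      src$start <- src$start + off
      src$end <- src$end + off
      tail_feats <- src
    }
  } else if (cap$kind == "translocation") {
    fd <- f[f$chrom == cap$r$chrom & f$start >= cap$r$end, ]
    if (nrow(fd) > 0) {
      off <- len_left - cap$r$end
      fd$start <- fd$start + off
      fd$end <- fd$end + off
      fd$chrom <- "chr1"
      fd$name <- paste0(fd$name, "_captured")
      tail_feats <- fd
    }
  } else if (cap$kind == "telomere_addition") {
    tel_len <- nchar(genome$telomere_unit) * genome$config$telomere_copies
    tail_feats <- data.frame(
      name = "tel_denovo", chrom = "chr1", start = len_left,
      end = len_left + tel_len, kind = "telomere_seed",
      pair_id = NA_character_, stem_len = NA_integer_,
      loop_len = NA_integer_
    )
  }
  out <- rbind(kept, inv, tail_feats, other)
  out <- out[order(match(out$chrom, names(genome$chromosomes)), out$start), ]
  rownames(out) <- NULL
  out
}

#' Apply a non-foldback GCR
#'
#' Telomere addition truncates chromosome 1 at the breakpoint and heals the
#' end with tandem telomere repeat units; a microhomology-mediated
#' translocation joins the truncated chromosome to a donor chromosome across
#' exactly `mh_len` identical bases; an interstitial deletion removes an
#' internal segment whose join shares `mh_len` bases.
#'
#' @param genome a `toy_genome`.
#' @param kind `"telomere_addition"`, `"mh_translocation"` or
#'   `"interstitial_deletion"`.
#' @param breakpoint 0-based breakpoint on chromosome 1 (for deletions, the
#'   start of the removed segment).
#' @param mh_len microhomology length at the join (ignored for telomere
#'   addition).
#' @param donor donor chromosome name for translocations.
#' @param del_range for deletions, how far downstream to search for the
#'   matching end of the removed segment (bp).
#' @return a list with `genome` and `truth`, as for
#'   [apply_foldback_inversion()].
#' @export
apply_simple_gcr <- function(genome, kind = c("telomere_addition",
                                              "mh_translocation",
                                              "interstitial_deletion"),
                             breakpoint, mh_len = 0L, donor = "chr2",
                             del_range = c(1500L, 8000L)) {
  kind <- match.arg(kind)
  stopifnot(inherits(genome, "toy_genome"), mh_len >= 0L)
  g1 <- genome$chromosomes[["chr1"]]
  b <- as.integer(breakpoint)
  n1 <- nchar(g1)
  new_genome <- genome
  partner <- NULL

  if (kind == "telomere_addition") {
    tel <- strrep(genome$telomere_unit, genome$config$telomere_copies)
    product <- paste0(seq_slice(g1, 0L, b), tel)
    f <- genome$features
    f1 <- f[f$chrom == "chr1" & f$end <= b, ]
    tail_feat <- data.frame(
      name = "tel_denovo", chrom = "chr1", start = b, end = b + nchar(tel),
      kind = "telomere_seed", pair_id = NA_character_,
      stem_len = NA_integer_, loop_len = NA_integer_
    )
    new_genome$features <- rbind(f1, tail_feat, f[f$chrom != "chr1", ])
    mh <- 0L
  } else if (kind == "mh_translocation") {
    d <- genome$chromosomes[[donor]]
    cen_end <- max(genome$features$end[genome$features$chrom == donor &
                                         genome$features$kind == "centromere"])
    j <- find_mh_partner(g1, b, d, mh_len,
                         lo = cen_end + 500L,
                         hi = nchar(d) - 2000L)
    if (is.na(j)) {
      stop("no ", mh_len, "-base shared context constructible on donor ",
           donor)
    }
    product <- paste0(seq_slice(g1, 0L, b), seq_slice(d, j, nchar(d)))
    f <- genome$features
    f1 <- f[f$chrom == "chr1" & f$end <= b, ]
    fd <- f[f$chrom == donor & f$start >= j, ]
    if (nrow(fd) > 0) {
      off <- b - j
      fd$start <- fd$start + off
      fd$end <- fd$end + off
      fd$chrom <- "chr1"
      fd$name <- paste0(fd$name, "_captured")
    }
    new_genome$features <- rbind(f1, fd, f[f$chrom != "chr1", ])
    partner <- list(chrom = donor, pos = j)
    mh <- as.integer(mh_len)
  } else {
    e <- find_mh_partner(g1, b, g1, mh_len,
                         lo = b + del_range[1], hi = min(b + del_range[2], n1))
    if (is.na(e)) {
      stop("no ", mh_len, "-base shared context constructible for the ",
           "deletion join")
    }
    product <- paste0(seq_slice(g1, 0L, b), seq_slice(g1, e, n1))
    f <- genome$features
    f1 <- f[f$chrom == "chr1", ]
    keep_l <- f1[f1$end <= b, ]
    keep_r <- f1[f1$start >= e, ]
    if (nrow(keep_r) > 0) {
      keep_r$start <- keep_r$start - (e - b)
      keep_r$end <- keep_r$end - (e - b)
    }
    new_genome$features <- rbind(keep_l, keep_r, f[f$chrom != "chr1", ])
    partner <- list(chrom = "chr1", pos = e)
    mh <- as.integer(mh_len)
  }

  new_genome$chromosomes[["chr1"]] <- product
  rownames(new_genome$features) <- NULL
  truth <- list(
    event_type = kind,
    chrom = "chr1",
    hairpin_site = NULL,
    resection_start = b,
    breakpoint = b,
    partner = partner,
    secondary_resolution = "none",
    microhomology_len = mh,
    product_id = "chr1"
  )
  class(truth) <- "gcr_event_truth"
  list(genome = new_genome, truth = truth)
}

# Find a position j on `target` such that target[j-mh, j) equals
# source[b-mh, b) with mismatches at both boundaries (so the shared context
# is exactly mh bases). Returns NA if none exists in [lo, hi).
find_mh_partner <- function(source, b, target, mh, lo, hi) {
  lo <- max(lo, mh + 1L)
  hi <- min(hi, nchar(target) - 1L)
  if (mh == 0L) {
    # any position whose boundary bases differ from the source's
    for (j in seq.int(lo, hi)) {
      if (substr(target, j, j) != substr(source, b, b) &&
          substr(target, j + 1L, j + 1L) != substr(source, b + 1L, b + 1L)) {
        return(j)
      }
    }
    return(NA_integer_)
  }
  ctx <- seq_slice(source, b - mh, b)
  win <- seq_slice(target, lo, hi)
  hits <- gregexpr(ctx, win, fixed = TRUE)[[1]]
  if (hits[1] < 0) return(NA_integer_)
  for (h in hits) {
    j <- lo + h - 1L + mh  # 0-based join position on target
    before_ok <- j - mh == 0L ||
      substr(target, j - mh, j - mh) != substr(source, b - mh, b - mh)
    after_ok <- j >= nchar(target) ||
      substr(target, j + 1L, j + 1L) != substr(source, b + 1L, b + 1L)
    if (before_ok && after_ok) return(j)
  }
  NA_integer_
}

#' Count centromeres present in a chromosome sequence
#'
#' Uses exact occurrence counting of each annotated centromere sequence of the
#' reference genome; a valid GCR product is monocentric.
#'
#' @param genome the reference `toy_genome` (source of centromere sequences).
#' @param sequence the product chromosome sequence to scan.
#' @return integer, total centromere copies found.
#' @export
count_centromeres <- function(genome, sequence) {
  cen <- genome$features[genome$features$kind == "centromere", ]
  total <- 0L
  for (i in seq_len(nrow(cen))) {
    cs <- seq_slice(genome$chromosomes[[cen$chrom[i]]], cen$start[i],
                    cen$end[i])
    total <- total + count_occurrences(sequence, cs)
  }
  total
}
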
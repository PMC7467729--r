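# GCR classification from validated junctions, copy-number segments and the
# assay feature map.
#
# The foldback inversion signature requires all four features: (1) a deleted
# (copy 0) segment overlapping the counter-selection cassette; (2) a copy-2
# segment centromeric to the deletion; (3) a validated inversion-geometry
# junction at the telomeric edge of the duplication; and (4) an assembled
# junction sequence for that junction.

#' Classify a GCR from caller output
#'
#' @param junctions junction call data.frame (with `validated` column, from
#'   [filter_junctions()]; may include telomere-addition calls).
#' @param segments named list (per chromosome) of segment data.frames from
#'   [segment_copy_number()].
#' @param feature_map the feature data.frame of the reference `toy_genome`.
#' @param reference the reference `toy_genome` (for hairpin inference at
#'   inversion junctions).
#' @param min_segment segmentation resolution; the inversion junction must
#'   fall within this distance of the duplication's telomeric boundary.
#' @param telomere_min_units detection threshold for de novo telomere
#'   addition (tandem repeat units).
#' @param mh_max microhomology ceiling for "microhomology-mediated" calls.
#' @return a list of class `gcr_classification`: `event_type`, `evidence`,
#'   `hairpin`, `loop_class`, `primary_junction`, `n_extra_junctions`.
#' @export
classify_gcr <- function(junctions, segments, feature_map, reference = NULL,
                         min_segment = 200L, telomere_min_units = 12L,
                         mh_max = 10L) {
  jv <- junctions[junctions$validated, , drop = FALSE]
  known <- c(names(segments), "*telomere*")
  if (nrow(jv) > 0 && !all(jv$chromA %in% known & jv$chromB %in% known)) {
    bad <- setdiff(c(jv$chromA, jv$chromB), known)
    stop("junction references unknown chromosome: ",
         paste(bad, collapse = ", "))
  }
  res <- list(event_type = "none", evidence = character(0), hairpin = NULL,
              loop_class = NULL, primary_junction = NULL,
              n_extra_junctions = 0L)
  class(res) <- "gcr_classification"
  if (nrow(jv) == 0L) return(res)

  cass <- feature_map[feature_map$kind == "cassette", ][1, ]
  cen <- feature_map[feature_map$kind == "centromere" &
                       feature_map$chrom == cass$chrom, ][1, ]
  seg1 <- segments[[cass$chrom]]
  del <- seg1[seg1$copy_number == 0L &
                seg1$end > cass$start & seg1$start < cass$end, , drop = FALSE]
  evidence <- character(0)
  if (nrow(del) > 0L) evidence <- c(evidence, "cassette_deletion")

  dup <- NULL
  if (nrow(del) > 0L) {
    cand <- seg1[seg1$copy_number >= 2L & seg1$end <= del$start[1] &
                   seg1$start >= cen$end, , drop = FALSE]
    if (nrow(cand) > 0L) {
      dup <- cand[which.max(cand$end), , drop = FALSE]
      evidence <- c(evidence, "centromeric_duplication")
    }
  }

  inv_j <- NULL
  if (!is.null(dup)) {
    inv <- jv[jv$geometry == "inversion" & jv$chromA == cass$chrom, ,
              drop = FALSE]
    if (nrow(inv) > 0L) {
      # the junction joins ref (+) at the deletion's centromeric edge to
      # ref (-) at the duplication's telomeric edge; read depth ramps over a
      # read length at junction edges (crossing reads are unmapped), so the
      # called segment boundaries can sit up to a read length plus the
      # segmentation resolution away from the true junction
      edges <- c(dup$end[1], del$start[1])
      tol <- 2L * min_segment
      near <- vapply(seq_len(nrow(inv)), function(i) {
        any(abs(c(inv$breakpointA[i], inv$breakpointB[i]) -
                  rep(edges, each = 2L)) <= tol)
      }, logical(1))
      if (any(near)) {
        inv_j <- inv[which(near)[1], , drop = FALSE]
        evidence <- c(evidence, "inversion_junction")
        if (!inv_j$coarse && nzchar(inv_j$junction_seq)) {
          evidence <- c(evidence, "junction_sequence")
        }
      }
    }
  }

  n_val <- nrow(jv)
  if (length(evidence) == 4L) {
    res$event_type <- "foldback_inversion"
    res$evidence <- evidence
    res$primary_junction <- inv_j
    if (!is.null(reference)) {
      ref_seq <- reference$chromosomes[[cass$chrom]]
      jj <- sort(c(inv_j$breakpointA, inv_j$breakpointB))
      hp <- tryCatch(
        infer_hairpin_from_junction(ref_seq, jj, allow_imperfect = FALSE),
        error = function(e) tryCatch(
          infer_hairpin_from_junction(ref_seq, jj, allow_imperfect = TRUE),
          error = function(e2) NULL
        )
      )
      res$hairpin <- hp
      if (!is.null(hp)) res$loop_class <- classify_loop(hp$loop_len)
    }
    if (n_val - 1L >= 2L) {
      # still a foldback, but note the extra complexity
      res$n_extra_junctions <- n_val - 1L
    }
    return(res)
  }

  # non-foldback taxonomy
  tel <- jv[jv$geometry == "telomere_addition" &
              jv$telomere_units >= telomere_min_units, , drop = FALSE]
  trans <- jv[jv$geometry == "translocation", , drop = FALSE]
  dele <- jv[jv$geometry == "deletion_like", , drop = FALSE]
  primary <- NULL
  if (nrow(tel) > 0L) {
    res$event_type <- "telomere_addition"
    primary <- tel[1, , drop = FALSE]
    res$evidence <- c("telomere_junction",
                      sprintf("telomere_units=%d", tel$telomere_units[1]))
  } else if (nrow(trans) > 0L) {
    mh <- trans$microhomology_len[1]
    res$event_type <- "mh_translocation"
    primary <- trans[1, , drop = FALSE]
    res$evidence <- c("translocation_junction", sprintf("mh=%d", mh))
  } else if (nrow(dele) > 0L) {
    res$event_type <- "interstitial_deletion"
    primary <- dele[1, , drop = FALSE]
    res$evidence <- c("deletion_junction",
                      sprintf("mh=%d", dele$microhomology_len[1]))
  }
  res$primary_junction <- primary
  n_extra <- n_val - as.integer(!is.null(primary))
  res$n_extra_junctions <- max(0L, n_extra)
  if (is.null(primary) && n_val > 0L) {
    res$event_type <- if (n_val >= 2L) "complex" else "none"
  } else if (res$n_extra_junctions >= 2L) {
    res$event_type <- "complex"
  }
  res
}

#' Classify the resolution product of a foldback inversion
#'
#' Foldback inversions are stabilized by secondary rearrangements. Class 1
#' (single-strand annealing capture) joins the two members of the declared
#' inverted homology pair and leaves the captured cassette-side fragment at
#' copy 1. Class 2 (homology-mediated translocation) targets a repeat
#' element and duplicates the donor's telomeric segment (copy 2). Class 3
#' covers complex products with two or more secondary junctions. Remaining
#' products resolve by de novo telomere addition or by a microhomology
#' junction.
#'
#' @param classification a `gcr_classification` with
#'   `event_type == "foldback_inversion"`.
#' @param junctions validated junction calls (as passed to [classify_gcr()]).
#' @param segments per-chromosome segment list.
#' @param feature_map reference feature data.frame.
#' @param pad anchor-to-feature association radius (bp; about the insert
#'   size).
#' @param mh_max microhomology ceiling for microhomology_resolution.
#' @return a character scalar: `"class1_ssa_capture"`,
#'   `"class2_homology_translocation"`, `"class3_complex"`,
#'   `"telomere_addition_resolution"` or `"microhomology_resolution"`.
#' @export
classify_resolution <- function(classification, junctions, segments,
                                feature_map, pad = 600L, mh_max = 10L) {
  if (classification$event_type != "foldback_inversion") {
    stop("resolution classes apply only to foldback inversions")
  }
  jv <- junctions[junctions$validated, , drop = FALSE]
  pj <- classification$primary_junction
  is_primary <- jv$geometry == "inversion" &
    jv$chromA == pj$chromA &
    abs(jv$breakpointA - pj$breakpointA) <= pad
  sec <- jv[!is_primary, , drop = FALSE]
  if (nrow(sec) >= 2L) return("class3_complex")

  cass <- feature_map[feature_map$kind == "cassette", ][1, ]
  hom <- feature_map[feature_map$kind == "homology_block" &
                       !is.na(feature_map$pair_id), , drop = FALSE]
  reps <- feature_map[feature_map$kind == "repeat_element" &
                        !is.na(feature_map$pair_id), , drop = FALSE]
  touches <- function(j, feats) {
    hit_one <- function(chrom, pos) {
      !is.na(pos) & feats$chrom == chrom &
        pos >= feats$start - pad & pos <= feats$end + pad
    }
    apply_any <- function(i) {
      any(hit_one(j$chromA[i], j$breakpointA[i])) ||
        (j$chromB[i] != "*telomere*" &&
           any(hit_one(j$chromB[i], j$breakpointB[i])))
    }
    vapply(seq_len(nrow(j)), apply_any, logical(1))
  }
  touches_both_members <- function(j, feats) {
    vapply(seq_len(nrow(j)), function(i) {
      hits <- unique(c(
        which(feats$chrom == j$chromA[i] &
                j$breakpointA[i] >= feats$start - pad &
                j$breakpointA[i] <= feats$end + pad),
        if (j$chromB[i] != "*telomere*")
          which(feats$chrom == j$chromB[i] &
                  j$breakpointB[i] >= feats$start - pad &
                  j$breakpointB[i] <= feats$end + pad)
      ))
      length(hits) >= 2L || (length(hits) == 1L && {
        # one breakpoint can sit inside one member while the other lies just
        # beyond the second member on the same chromosome
        pid <- feats$pair_id[hits]
        mates <- feats[feats$pair_id == pid, ]
        all(vapply(seq_len(nrow(mates)), function(mi) {
          (j$breakpointA[i] >= mates$start[mi] - pad &
             j$breakpointA[i] <= mates$end[mi] + pad &
             j$chromA[i] == mates$chrom[mi]) ||
            (j$chromB[i] != "*telomere*" &&
               j$breakpointB[i] >= mates$start[mi] - pad &
               j$breakpointB[i] <= mates$end[mi] + pad &
               j$chromB[i] == mates$chrom[mi])
        }, logical(1)))
      })
    }, logical(1))
  }

  if (nrow(sec) == 0L) return("telomere_addition_resolution")

  tel_sec <- sec$geometry == "telomere_addition"
  if (nrow(hom) >= 2L) {
    ssa <- touches_both_members(sec, hom)
    if (any(ssa & !tel_sec)) {
      # captured cassette-side fragment must be copy 1
      u <- hom[hom$chrom == cass$chrom & hom$start >= cass$start, ][1, ]
      if (!any(is.na(u$start))) {
        seg1 <- segments[[cass$chrom]]
        captured <- seg1[seg1$start >= u$end - pad, , drop = FALSE]
        cn <- stats::weighted.mean(captured$copy_number,
                                   captured$end - captured$start)
        if (!is.nan(cn) && round(cn) <= 1) return("class1_ssa_capture")
      }
    }
  }
  if (nrow(reps) >= 1L) {
    hr <- touches(sec, reps)
    if (any(hr & !tel_sec)) {
      j <- sec[which(hr & !tel_sec)[1], , drop = FALSE]
      donor_side <- if (j$chromA != cass$chrom) {
        list(chrom = j$chromA, pos = j$breakpointA)
      } else {
        list(chrom = j$chromB, pos = j$breakpointB)
      }
      if (donor_side$chrom %in% names(segments)) {
        segd <- segments[[donor_side$chrom]]
        telomeric <- segd[segd$start >= donor_side$pos - pad, , drop = FALSE]
        cn <- stats::weighted.mean(telomeric$copy_number,
                                   telomeric$end - telomeric$start)
        if (!is.nan(cn) && round(cn) >= 2) {
          return("class2_homology_translocation")
        }
      }
    }
  }
  if (any(tel_sec)) return("telomere_addition_resolution")
  if (all(sec$microhomology_len <= mh_max, na.rm = TRUE)) {
    return("microhomology_resolution")
  }
  "class3_complex"
}

#' Tabulate a batch of GCR classifications
#'
#' Counts events by type and, within foldback inversions, by loop class and
#' resolution class, and emits the foldback-versus-other split used in
#' spectrum comparisons.
#'
#' @param classifications a list of `gcr_classification` objects; elements
#'   may carry a `resolution` attribute/field added by the pipeline.
#' @return a list with `event_counts`, `loop_class_counts`,
#'   `resolution_counts` and `foldback_vs_other`.
#' @export
spectrum_table <- function(classifications) {
  if (length(classifications) == 0L) stop("no classifications to tabulate")
  types <- vapply(classifications, function(x) x$event_type, character(1))
  loops <- unlist(lapply(classifications, function(x) {
    if (!is.null(x$loop_class)) x$loop_class else NULL
  }))
  resol <- unlist(lapply(classifications, function(x) {
    if (!is.null(x$resolution)) x$resolution else NULL
  }))
  fb <- sum(types == "foldback_inversion")
  list(
    event_counts = table(types),
    loop_class_counts = if (length(loops)) table(loops) else table(character()),
    resolution_counts = if (length(resol)) table(resol)
                        else table(character()),
    foldback_vs_other = c(foldback = fb, other = length(types) - fb)
  )
}
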
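test_that("discordant clustering finds the planted inversion junction", {
  fb <- foldback_sample()
  res <- fb$result
  tr <- fb$event$truth$inversion_junction
  inv <- res$clusters[res$clusters$geometry == "inversion", ]
  expect_gte(nrow(inv), 1L)
  # one cluster brackets the planted junction within the insert size
  near <- inv[inv$startA <= tr$pos_a & inv$endB >= tr$pos_b - 600 &
                inv$endA >= tr$pos_a - 600, ]
  expect_gte(nrow(near), 1L)
  expect_gte(max(inv$n_support), 20L)

  ctl <- control_sample()
  expect_equal(nrow(ctl$result$clusters), 0L)
})

test_that("a planted interstitial deletion yields a deletion-geometry cluster", {
  g <- ref_genome()
  ev <- apply_simple_gcr(g, "interstitial_deletion", breakpoint = 8000L,
                         mh_len = 3L)
  reads <- simulate_reads(ev$genome, seed = 77L)
  aln <- map_reads(g, reads)
  cl <- detect_discordant_clusters(aln, 600, 60)
  del <- cl[cl$geometry == "deletion_like", ]
  expect_equal(nrow(del), 1L)
  e <- ev$truth$partner$pos
  expect_true(del$startA <= 8000L && del$endB >= e)
})

test_that("assembly reaches base precision and measures planted microhomology", {
  fb <- foldback_sample()
  res <- fb$result
  tr <- fb$event$truth$inversion_junction
  inv <- res$junctions[res$junctions$geometry == "inversion" &
                         !res$junctions$coarse, ]
  expect_gte(nrow(inv), 1L)
  expect_lte(min(abs(inv$breakpointA - tr$pos_a)), 5L)
  expect_lte(min(abs(inv$breakpointB - tr$pos_b)), 5L)
  # the assembled contig spans the planted site sequence
  g <- ref_genome()
  site_seq <- substr(g$chromosomes[["chr1"]],
                     tr$pos_b + 1L, tr$pos_a)
  expect_true(any(grepl(site_seq, inv$junction_seq, fixed = TRUE) |
                    grepl(revcomp(site_seq), inv$junction_seq, fixed = TRUE)))

  tx <- apply_simple_gcr(g, "mh_translocation", breakpoint = 9000L,
                         mh_len = 5L)
  reads <- simulate_reads(tx$genome, seed = 78L)
  res2 <- call_gcr_sample(g, reads)
  j <- res2$junctions[res2$junctions$geometry == "translocation" &
                        res2$junctions$validated, ]
  expect_equal(nrow(j), 1L)
  expect_equal(j$microhomology_len, 5L)
  expect_lte(abs(j$breakpointA - 9000L), 5L)
})

test_that("consensus takes the majority base at disagreeing columns", {
  set.seed(10)
  base <- random_dna_str(120L)
  v1 <- base
  v2 <- base
  bad <- base
  substr(bad, 60L, 60L) <- if (substr(base, 60L, 60L) == "A") "C" else "A"
  contig <- foldbackr:::greedy_consensus(c(v1, bad, v2), min_overlap = 15L)
  expect_identical(contig, base)
})

test_that("microhomology measurement handles planted, absent and degenerate homology", {
  set.seed(12)
  sh <- "GATTC"
  mk <- function(mid_a, mid_b) {
    # guard bases force the shared run to exactly the planted context
    a <- paste0(random_dna_str(14L), "A", sh, "G", random_dna_str(19L))
    b <- paste0(random_dna_str(14L), "C", sh, "T", random_dna_str(19L))
    list(a = a, b = b)
  }
  fl <- mk()
  junction <- paste0(substr(fl$a, 1L, 20L), substr(fl$b, 21L, 40L))
  expect_equal(measure_microhomology(junction, fl$a, fl$b), 5L)

  none_a <- paste0(strrep("A", 20L), strrep("C", 20L))
  none_b <- paste0(strrep("G", 20L), strrep("T", 20L))
  expect_equal(
    measure_microhomology(paste0(strrep("A", 20L), strrep("T", 20L)),
                          none_a, none_b, check_junction = FALSE),
    0L
  )

  f20 <- random_dna_str(20L)
  expect_equal(
    measure_microhomology(paste0(f20, f20), f20, f20,
                          check_junction = FALSE),
    20L
  )
  expect_error(measure_microhomology("ACGTACGT", "ACGTACG", "ACGTACG"),
               "at least 15 bp")
})

test_that("telomere-addition junctions are detected with unit counts", {
  g <- ref_genome()
  ev <- apply_simple_gcr(g, "telomere_addition", breakpoint = 10200L)
  reads <- simulate_reads(ev$genome, seed = 79L)
  aln <- map_reads(g, reads)
  tel <- detect_telomere_junctions(aln, reads, g, 600L)
  expect_equal(nrow(tel), 1L)
  expect_gte(tel$telomere_units, 12L)
  expect_lte(abs(tel$breakpointA - 10200L), 5L)

  ctl <- control_sample()
  tel0 <- detect_telomere_junctions(ctl$result$alignments, ctl$reads, g, 600L)
  expect_equal(nrow(tel0), 0L)
})

test_that("validation applies both the support floor and the span fraction", {
  calls <- data.frame(
    chromA = "chrX", breakpointA = c(500L, 500L, 500L),
    strandA = "+", chromB = "chrX",
    breakpointB = c(900L, 900L, 900L), strandB = "+",
    microhomology_len = 0L, inserted_bases = "", junction_seq = "ACGT",
    n_support = c(12L, 2L, 3L), geometry = "inversion", coarse = FALSE,
    telomere_units = 0L
  )
  depths <- list(chrX = list(
    read_depth = rep(15L, 1200L),
    span_depth = rep(c(30L, 60L), c(700L, 500L))
  ))
  out <- filter_junctions(calls[1, ], depths)
  expect_true(out$validated)                       # 12 >= 3 and 12 >= 6
  out2 <- filter_junctions(calls[2, ], depths)
  expect_false(out2$validated)
  expect_equal(out2$fail_reason, "support")        # below min_support
  out3 <- filter_junctions(calls[3, ], depths)
  expect_false(out3$validated)                     # 3 < 0.2 * 60 at anchor B
  expect_equal(out3$fail_reason, "fraction")
})
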
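test_that("enumeration finds planted inverted repeats and nothing else trivially", {
  expect_equal(nrow(enumerate_hairpin_sites("AAAAAAAAAA", min_stem = 4)), 0L)

  s <- paste0("GGGCATG", "AAA", "CATGCCC")
  sites <- enumerate_hairpin_sites(s, min_stem = 4)
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$stem_len, 7L)
  expect_equal(sites$loop_len, 3L)
  expect_equal(sites$arm1_start, 0L)
  expect_equal(sites$arm2_end, 17L)

  expect_error(enumerate_hairpin_sites("ACGTNACGT", min_stem = 4),
               "non-ACGT")
})

test_that("the planted hotspot carries the strictly longest stem in the breakpoint region", {
  g <- ref_genome()
  cfg <- g$config
  region <- substr(g$chromosomes[["chr1"]], cfg$breakpoint_region[1] + 1L,
                   cfg$breakpoint_region[2])
  sites <- enumerate_hairpin_sites(region, min_stem = 4)
  sites$arm1_start <- sites$arm1_start + cfg$breakpoint_region[1]
  sites$arm2_end <- sites$arm2_end + cfg$breakpoint_region[1]
  hs <- hotspot_site()
  top <- sites[which.max(sites$stem_len), ]
  expect_equal(top$stem_len, 15L)
  expect_equal(top$arm1_start, hs$start)
  expect_equal(top$arm2_end, hs$end)
  expect_equal(sum(sites$stem_len == 15L), 1L)
  # every planted site is recovered with its exact geometry
  hp <- g$features[g$features$kind == "hairpin_site", ]
  for (i in seq_len(nrow(hp))) {
    hit <- sites[sites$arm1_start == hp$start[i], ]
    expect_equal(nrow(hit), 1L)
    expect_equal(hit$stem_len, hp$stem_len[i])
    expect_equal(hit$loop_len, hp$loop_len[i])
  }
})

test_that("enumeration agrees with the brute-force oracle on random sequences", {
  set.seed(911)
  for (rep in seq_len(120)) {
    n <- sample(20:200, 1)
    s <- random_dna_str(n)
    min_stem <- sample(4:6, 1)
    got <- enumerate_hairpin_sites(s, min_stem = min_stem)
    want <- oracle_hairpin_sites(s, min_stem = min_stem)
    expect_identical(sites_key(got), sites_key(want))
  }
})

test_that("junction-anchored inference round-trips planted geometry", {
  set.seed(5)
  arm <- "GATTACCA"
  loop <- "TTT"
  s <- paste0(random_dna_str(180), arm, loop, revcomp(arm),
              random_dna_str(180))
  p <- 180L
  q <- p + 2L * nchar(arm) + nchar(loop)
  inf <- infer_hairpin_from_junction(s, c(p, q))
  expect_equal(inf$stem_len, 8L)
  expect_equal(inf$loop_len, 3L)
  expect_equal(inf$n_mispairs, 0L)
  expect_false(inf$imperfect)

  # one substitution in an arm: imperfect mode counts it, exact mode
  # truncates the stem at the mispair
  s2 <- s
  old <- substr(s2, p + 6L, p + 6L)
  substr(s2, p + 6L, p + 6L) <- if (old == "C") "G" else "C"
  imp <- infer_hairpin_from_junction(s2, c(p, q), allow_imperfect = TRUE)
  expect_equal(imp$n_mispairs, 1L)
  expect_true(imp$imperfect)
  expect_gte(imp$stem_len, 7L)
  exact <- infer_hairpin_from_junction(s2, c(p, q), allow_imperfect = FALSE)
  expect_equal(exact$stem_len, 5L)

  expect_error(infer_hairpin_from_junction(strrep("A", 100), c(20, 80)),
               "no hairpin inferable")
})

test_that("every planted site round-trips through its truth junction", {
  g <- ref_genome()
  chr1 <- g$chromosomes[["chr1"]]
  hp <- g$features[g$features$kind == "hairpin_site", ]
  for (i in seq_len(nrow(hp))) {
    inf <- infer_hairpin_from_junction(chr1, c(hp$start[i], hp$end[i]))
    expect_equal(inf$stem_len, hp$stem_len[i])
    expect_equal(inf$loop_len, hp$loop_len[i])
    expect_false(inf$imperfect)
  }
})

test_that("loop classification respects the 15 nt boundary and is monotone", {
  expect_equal(classify_loop(3), "short")
  expect_equal(classify_loop(14), "short")
  expect_equal(classify_loop(15), "large")
  expect_equal(classify_loop(36), "large")
  expect_error(classify_loop(-1), "non-negative")
  x <- classify_loop(0:10000)
  expect_true(all(x[1:15] == "short"))
  expect_true(all(x[16:10001] == "large"))
})

test_that("loop size summaries reproduce the printed per-event distributions", {
  sae2 <- data.frame(
    chrom = "chr1",
    pos_a = seq_len(20), pos_b = seq_len(20) + 100,
    loop_len = rep(c(3, 4, 5, 8, 10), c(16, 1, 1, 1, 1))
  )
  sm <- loop_size_summary(sae2, mode = "per_event")
  expect_equal(sm$median, 3)
  expect_equal(sm$n, 20L)

  tel1 <- data.frame(
    chrom = "chr1",
    pos_a = seq_len(10), pos_b = seq_len(10) + 100,
    loop_len = rep(c(4, 10, 25, 35, 39, 44), c(1, 4, 1, 2, 1, 1))
  )
  expect_equal(loop_size_summary(tel1, mode = "per_event")$median, 17.5)

  expect_equal(loop_size_summary(
    data.frame(chrom = "c", pos_a = 1, pos_b = 2, loop_len = 5)
  )$median, 5)
  expect_error(loop_size_summary(data.frame()), "no hairpin")
})

test_that("per-site summaries never exceed per-event counts in any bin", {
  set.seed(21)
  inf <- data.frame(
    chrom = "chr1",
    pos_a = sample(1:6, 40, replace = TRUE),
    loop_len = sample(c(3, 3, 3, 4, 10, 25, 36), 40, replace = TRUE)
  )
  inf$pos_b <- inf$pos_a + 50 + inf$loop_len
  pe <- loop_size_summary(inf, mode = "per_event")
  ps <- loop_size_summary(inf, mode = "per_site")
  for (L in names(ps$counts)) {
    n_event <- if (L %in% names(pe$counts)) pe$counts[[L]] else 0L
    expect_lte(ps$counts[[L]], n_event)
  }
  expect_lte(ps$n, pe$n)
})

test_that("DSB-proximal ranking prefers near, long-stem, short-loop hairpins", {
  sites <- data.frame(
    arm1_start = c(940L, 2000L), arm1_end = c(946L, 2015L),
    arm2_start = c(949L, 2018L), arm2_end = c(955L, 2033L),
    stem_len = c(6L, 15L), loop_len = c(3L, 3L),
    perfect_stem = TRUE, center = c(947.5, 2016.5)
  )
  rk <- rank_hairpins_near_dsb(sites, dsb_pos = 950L, window = 50L)
  expect_true(rk$within_window[1])
  expect_equal(rk$stem_len[1], 6L)      # near site first, despite short stem
  expect_equal(rk$stem_len[2], 15L)     # far long-stem site heads the rest
  expect_false(rk$within_window[2])

  ties <- data.frame(
    arm1_start = c(900L, 1000L), arm1_end = c(909L, 1006L),
    arm2_start = c(912L, 1009L), arm2_end = c(921L, 1015L),
    stem_len = c(9L, 6L), loop_len = c(3L, 3L),
    perfect_stem = TRUE, center = c(910.5, 1007.5)
  )
  # both 30 bp from the DSB at 951/970: equidistant-ish, stem 9 wins
  rk2 <- rank_hairpins_near_dsb(ties, dsb_pos = 951L, window = 100L)
  expect_equal(rk2$stem_len[1], 9L)

  empty <- rank_hairpins_near_dsb(enumerate_hairpin_sites("AAAA", 4), 10L)
  expect_equal(nrow(empty), 0L)
})
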
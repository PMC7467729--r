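test_that("config invariants are enforced", {
  expect_error(sim_config(error_rate = 0.5), "error_rate")
  expect_error(sim_config(hairpin_specs = data.frame(pos = 6000L,
                                                     stem_len = 3L,
                                                     loop_len = 3L)))
  expect_error(sim_config(hairpin_specs = data.frame(pos = 6000L,
                                                     stem_len = 6L,
                                                     loop_len = 1L)))
  expect_error(sim_config(insert_mean = 50L))
  expect_silent(validate_sim_config <- sim_config())
})

test_that("the built genome satisfies its structural invariants", {
  g <- ref_genome()
  f <- g$features
  lens <- nchar(g$chromosomes)
  expect_true(all(f$start >= 0L & f$end <= lens[f$chrom] & f$start < f$end))
  for (cn in names(g$chromosomes)) {
    fc <- f[f$chrom == cn, ]
    expect_equal(sum(fc$kind == "centromere"), 1L)
    tel <- fc[fc$kind == "telomere_seed", ]
    expect_true(any(tel$start == 0L))
    expect_true(any(tel$end == lens[[cn]]))
  }
  # the inverted homology pair members carry reverse-complement content
  hom <- f[f$kind == "homology_block", ]
  expect_equal(nrow(hom), 2L)
  s1 <- substr(g$chromosomes[[hom$chrom[1]]], hom$start[1] + 1L, hom$end[1])
  s2 <- substr(g$chromosomes[[hom$chrom[2]]], hom$start[2] + 1L, hom$end[2])
  expect_equal(s2, revcomp(s1))
  # planted hairpin sites are exact inverted repeats with guarded maximality
  hp <- f[f$kind == "hairpin_site", ]
  for (i in seq_len(nrow(hp))) {
    s <- g$chromosomes[[hp$chrom[i]]]
    arm1 <- substr(s, hp$start[i] + 1L, hp$start[i] + hp$stem_len[i])
    arm2 <- substr(s, hp$end[i] - hp$stem_len[i] + 1L, hp$end[i])
    expect_equal(arm2, revcomp(arm1))
    out_l <- substr(s, hp$start[i], hp$start[i])
    out_r <- substr(s, hp$end[i] + 1L, hp$end[i] + 1L)
    expect_false(out_l == chartr("ACGT", "TGCA", out_r))
  }
})

test_that("a genome without hairpin specs plants none, and building is deterministic", {
  cfg0 <- sim_config(master_seed = 12L,
                     hairpin_specs = default_hairpin_specs()[0, ])
  g0 <- build_toy_genome(cfg0)
  expect_equal(sum(g0$features$kind == "hairpin_site"), 0L)

  cfg <- sim_config(master_seed = 12L)
  fa1 <- tempfile(fileext = ".fa")
  fa2 <- tempfile(fileext = ".fa")
  write_genome(build_toy_genome(cfg), fa1)
  write_genome(build_toy_genome(cfg), fa2)
  expect_identical(readLines(fa1), readLines(fa2))
  rt <- read_genome_fasta(fa1)
  expect_identical(unname(rt["chr1"]),
                   unname(build_toy_genome(cfg)$chromosomes[["chr1"]]))
})

test_that("overlapping planted features are rejected with a collision report", {
  bad <- sim_config(hairpin_specs = data.frame(pos = c(6000L, 6005L),
                                               stem_len = c(8L, 8L),
                                               loop_len = c(3L, 3L)))
  expect_error(build_toy_genome(bad), "collision")
})

test_that("foldback products match a hand-constructed string-surgery oracle", {
  tg <- tiny_genome()
  g <- tg$genome
  site <- g$features[g$features$kind == "hairpin_site", ]
  p <- tg$p
  q <- p + nchar(tg$site)
  chr <- g$chromosomes[["chr1"]]
  ev <- apply_foldback_inversion(g, site, resection_start = q + 200L,
                                 secondary = "telomere_addition",
                                 dup_len = 300L)
  # independent construction: keep [0, q), append the inverted copy of the
  # 300 bp centromeric of the site, then the telomere seed
  expected <- paste0(
    substr(chr, 1L, q),
    revcomp(substr(chr, p - 300L + 1L, p)),
    strrep(g$telomere_unit, g$config$telomere_copies)
  )
  expect_identical(ev$genome$chromosomes[["chr1"]], expected)
  # the junction window reads arm + loop + revcomp(arm)
  prod <- ev$genome$chromosomes[["chr1"]]
  expect_identical(substr(prod, q - nchar(tg$site) + 1L, q), tg$site)
  tr <- ev$truth
  expect_equal(tr$inversion_junction$pos_a, q)
  expect_equal(tr$inversion_junction$pos_b, p)
  expect_equal(tr$event_type, "foldback_inversion")
})

test_that("secondary resolutions control copy number of captured fragments", {
  g <- ref_genome()
  site <- hotspot_site()
  u <- g$features[g$features$name == "URA3", ]

  ssa <- apply_foldback_inversion(g, site, resection_start = site$end + 500L,
                                  secondary = "ssa_capture")
  prod <- ssa$genome$chromosomes[["chr1"]]
  captured <- substr(g$chromosomes[["chr1"]], u$end + 1L, u$end + 2000L)
  expect_equal(count_occurrences(prod, captured), 1L)
  expect_equal(count_centromeres(g, prod), 1L)

  r <- g$features[g$features$name == "ty_like_donor", ]
  tx <- apply_foldback_inversion(g, site, resection_start = site$end + 500L,
                                 secondary = "homology_translocation")
  donor_tail <- substr(g$chromosomes[["chr2"]], r$end + 1L, r$end + 2000L)
  genome_wide <- paste(unlist(tx$genome$chromosomes), collapse = "NNN")
  expect_equal(count_occurrences(genome_wide, donor_tail), 2L)
  expect_equal(count_centromeres(g, tx$genome$chromosomes[["chr1"]]), 1L)
  # donor chromosome left intact
  expect_identical(tx$genome$chromosomes[["chr2"]], g$chromosomes[["chr2"]])

  expect_error(
    apply_foldback_inversion(g, list(start = 6000L, stem_len = 6L,
                                     loop_len = 3L),
                             resection_start = 7000L,
                             secondary = "telomere_addition"),
    "not an exact inverted repeat"
  )
  tg <- tiny_genome()
  tsite <- tg$genome$features[tg$genome$features$kind == "hairpin_site", ]
  expect_error(
    apply_foldback_inversion(tg$genome, tsite,
                             resection_start = tsite$end + 100L,
                             secondary = "ssa_capture"),
    "inverted homology pair"
  )
})

test_that("simple GCR products follow their definitions", {
  g <- ref_genome()
  chr1 <- g$chromosomes[["chr1"]]

  tel <- apply_simple_gcr(g, "telomere_addition", breakpoint = 9000L)
  expect_identical(
    tel$genome$chromosomes[["chr1"]],
    paste0(substr(chr1, 1L, 9000L),
           strrep(g$telomere_unit, g$config$telomere_copies))
  )

  tx <- apply_simple_gcr(g, "mh_translocation", breakpoint = 9000L,
                         mh_len = 5L)
  j <- tx$truth$partner$pos
  expect_identical(substr(g$chromosomes[["chr2"]], j - 4L, j),
                   substr(chr1, 8996L, 9000L))
  # measured microhomology on the true junction equals the planted length
  mh <- measure_microhomology(
    junction = paste0(substr(chr1, 8981L, 9000L),
                      substr(g$chromosomes[["chr2"]], j + 1L, j + 20L)),
    flank_a = substr(chr1, 8981L, 9020L),
    flank_b = substr(g$chromosomes[["chr2"]], j - 19L, j + 20L)
  )
  expect_equal(mh, 5L)

  del <- apply_simple_gcr(g, "interstitial_deletion", breakpoint = 6000L,
                          mh_len = 4L)
  e <- del$truth$partner$pos
  expect_equal(nchar(del$genome$chromosomes[["chr1"]]),
               nchar(chr1) - (e - 6000L))
})

test_that("read simulation is deterministic, exact at zero error, and hits target depth", {
  set.seed(1)
  toy <- list(chrA = random_dna_str(10000L))
  r1 <- simulate_reads(toy, coverage = 30, read_length = 100L,
                       insert_mean = 400L, insert_sd = 40L, error_rate = 0,
                       seed = 99L)
  r2 <- simulate_reads(toy, coverage = 30, read_length = 100L,
                       insert_mean = 400L, insert_sd = 40L, error_rate = 0,
                       seed = 99L)
  expect_identical(r1$r1, r2$r1)
  expect_identical(r1$r2, r2$r2)
  f1 <- tempfile(); f2 <- tempfile()
  write_fastq(r1, f1, f2)
  g1 <- tempfile(); g2 <- tempfile()
  write_fastq(r2, g1, g2)
  expect_identical(readLines(f1), readLines(g1))
  back <- read_fastq_pairs(f1, f2)
  expect_identical(back$r1, r1$r1)

  # every error-free read is an exact substring of the source (or revcomp)
  for (i in sample(length(r1$r1), 50)) {
    expect_true(grepl(r1$r1[i], toy$chrA, fixed = TRUE))
    expect_true(grepl(revcomp(r1$r2[i]), toy$chrA, fixed = TRUE))
  }
  depth <- 2 * 100 * length(r1$r1) / 10000
  expect_lt(abs(depth - 30), 3)

  # a forced single pair reproduces reference substrings exactly
  expect_error(simulate_reads(toy, coverage = 1, read_length = 100L,
                              insert_mean = 20000L, insert_sd = 1L,
                              error_rate = 0, seed = 1L),
               "chromosome")
})

test_that("fluctuation counts follow the Luria-Delbruck law", {
  m <- log(2)
  counts <- simulate_fluctuation_experiment(m, 10000L, seed = 4L)
  expect_lt(abs(mean(counts == 0L) - 0.5), 0.02)

  p <- ld_pmf(2, 4000L)
  expect_true(all(p >= 0))
  partial <- sum(p)
  expect_lte(partial, 1 + 1e-9)
  # the missing mass matches the analytic heavy-tail estimate P(R > r) ~ m/r
  expect_lt(abs((1 - partial) - 2 / 4000), 3e-4)

  counts2 <- simulate_fluctuation_experiment(2, 1000L, seed = 5L)
  est <- estimate_rate(counts2)
  expect_lt(abs(est$m - 2) / 2, 0.1)
})
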
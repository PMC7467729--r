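test_that("k-mer mapping places unique reads, flags repeats, rejects noise", {
  set.seed(88)
  block <- random_dna_str(500L)
  # duplicated 500 bp block on one chromosome
  chr <- paste0(random_dna_str(1500L), block, random_dna_str(800L), block,
                random_dna_str(1200L))
  genome <- c(chrT = chr)

  uniq_read <- substr(chr, 101L, 200L)
  rep_read <- substr(block, 201L, 300L)       # wholly inside both copies
  noise_read <- random_dna_str(100L)
  reads <- structure(list(
    r1 = c(uniq_read, rep_read, noise_read),
    r2 = revcomp(c(substr(chr, 401L, 500L), substr(chr, 2301L, 2400L),
                   substr(chr, 3001L, 3100L))),
    names = c("u", "r", "n"),
    read_length = 100L
  ), class = "read_set")
  aln <- map_reads(genome, reads, k = 21L)
  a1 <- aln[aln$mate == 1L, ]
  u <- a1[a1$qname == "u", ]
  expect_true(u$mapped && u$unique)
  expect_equal(u$pos, 100L)
  expect_equal(u$strand, "+")
  r <- a1[a1$qname == "r", ]
  expect_true(r$mapped)
  expect_false(r$unique)
  n <- a1[a1$qname == "n", ]
  expect_false(n$mapped)

  sam <- tempfile(fileext = ".sam")
  write_sam(aln, reads, genome, sam)
  lines <- readLines(sam)
  expect_true(any(grepl("^@SQ\tSN:chrT", lines)))
  expect_equal(sum(!grepl("^@", lines)), 6L)
})

test_that("depth profiles follow their definitions for a single concordant pair", {
  genome <- c(chrD = strrep("ACGT", 200L))  # 800 bp
  aln <- data.frame(
    qname = "p1", mate = c(1L, 2L), chrom = "chrD",
    pos = c(100L, 300L), strand = c("+", "-"),
    mapped = TRUE, unique = TRUE, nm = 0L, read_len = 50L
  )
  d <- compute_depths(aln, genome, insert_mean = 250L, insert_sd = 30L)
  rd <- d$chrD$read_depth
  sp <- d$chrD$span_depth
  expect_true(all(rd[101:150] == 1L) && all(rd[301:350] == 1L))
  expect_true(all(rd[151:300] == 0L))
  expect_true(all(sp[101:350] == 1L))
  expect_true(all(sp[1:100] == 0L) && all(sp[351:800] == 0L))

  empty <- compute_depths(aln[0, ], genome, 250L, 30L)
  expect_true(all(empty$chrD$read_depth == 0L))
  expect_error(
    compute_depths(transform(aln, pos = 790L), genome, 250L, 30L),
    "past chromosome end"
  )
})

test_that("span depth dominates read depth with concordant-only unique pairs", {
  ctl <- control_sample()
  res <- ctl$result
  aln <- res$alignments
  pr <- foldbackr:::pair_table(aln)
  conc <- pr[foldbackr:::is_concordant(pr, 600, 60), ]
  keep <- aln$qname %in% conc$qname
  g <- ref_genome()
  d <- compute_depths(aln[keep, ], g, 600, 60)
  for (cn in names(d)) {
    expect_true(all(d[[cn]]$span_depth >= d[[cn]]$read_depth))
  }
  # median depth near the simulated coverage
  mid <- d$chr1$read_depth[2000:22000]
  expect_lt(abs(stats::median(mid) - 30), 3)
})

test_that("segmentation recovers planted copy-number structure", {
  set.seed(77)
  # synthetic profile: 1x / 3x / 1x steps with Poisson noise
  depth <- c(rpois(4000, 30), rpois(1500, 90), rpois(4500, 30))
  segs <- segment_copy_number(depth, genome_median = 30)
  expect_equal(segs$copy_number, c(1L, 3L, 1L))
  expect_lt(abs(segs$start[2] - 4000), 200)
  expect_lt(abs(segs$end[2] - 5500), 200)

  expect_equal(
    segment_copy_number(rep(0L, 1000L), genome_median = 30)$copy_number, 0L
  )

  flat <- segment_copy_number(rpois(5000, 30), genome_median = 30)
  expect_equal(flat$copy_number, 1L)
})

test_that("depth profiles export as run-length bedGraph", {
  profiles <- list(chrZ = list(read_depth = c(0L, 0L, 2L, 2L, 2L, 1L),
                               span_depth = c(0L, 1L, 2L, 2L, 2L, 1L)))
  f <- tempfile(fileext = ".bedGraph")
  write_bedgraph(profiles, "read_depth", f)
  expect_equal(readLines(f),
               c("chrZ\t0\t2\t0", "chrZ\t2\t5\t2", "chrZ\t5\t6\t1"))
})

test_that("inserted-element positions render in the anchor-offset convention", {
  expect_equal(format_anchor_offset("chrV", 34339, 110), "chrV:34,339-110")
})

test_that("an unrearranged control yields no validated junctions and flat copy number", {
  ctl <- control_sample()
  res <- ctl$result
  expect_equal(sum(res$junctions$validated), 0L)
  expect_equal(res$classification$event_type, "none")
  g <- ref_genome()
  tel_len <- nchar(g$telomere_unit) * g$config$telomere_copies
  for (cn in names(res$segments)) {
    segs <- res$segments[[cn]]
    one <- segs[segs$copy_number == 1L, ]
    expect_equal(nrow(one), 1L)
    # non-unit copy numbers are confined to the repetitive telomere seeds
    off <- segs[segs$copy_number != 1L, ]
    L <- nchar(g$chromosomes[[cn]])
    expect_true(all(off$start < tel_len + 400 | off$end > L - tel_len - 400))
  }
})
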
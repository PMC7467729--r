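# Shared lazily-built fixtures; expensive simulations are computed once per
# test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

ref_genome <- function() {
  fixture("ref_genome", function() build_toy_genome(sim_config(master_seed = 7L)))
}

hotspot_site <- function() {
  g <- ref_genome()
  hp <- g$features[g$features$kind == "hairpin_site", ]
  hp[which.max(hp$stem_len), ]
}

foldback_sample <- function() {
  fixture("foldback_sample", function() {
    g <- ref_genome()
    site <- hotspot_site()
    ev <- apply_foldback_inversion(g, site,
                                   resection_start = site$end + 500L,
                                   secondary = "ssa_capture")
    reads <- simulate_reads(ev$genome, seed = 42L)
    res <- call_gcr_sample(g, reads)
    list(event = ev, reads = reads, result = res)
  })
}

control_sample <- function() {
  fixture("control_sample", function() {
    g <- ref_genome()
    reads <- simulate_reads(g, seed = 555L)
    list(reads = reads, result = call_gcr_sample(g, reads))
  })
}

# minimal hand-assembled genome for base-by-base event oracles
tiny_genome <- function(seed = 31L) {
  set.seed(seed)
  unit <- "TGTGGG"
  tel <- strrep(unit, 5L)
  arm <- "GACCTA"
  loop <- "TCT"  # guarded: T != comp(T)
  site <- paste0(arm, loop, revcomp(arm))
  cen <- random_dna_str(60)
  chr <- paste0(tel, random_dna_str(70), cen, random_dna_str(500), site,
                random_dna_str(1000), tel)
  p <- nchar(tel) + 70L + 60L + 500L
  feats <- data.frame(
    name = c("tel_L", "CEN1", "hairpin_1", "tel_R"),
    chrom = "chr1",
    start = c(0L, nchar(tel) + 70L, p, nchar(chr) - nchar(tel)),
    end = c(nchar(tel), nchar(tel) + 130L, p + nchar(site), nchar(chr)),
    kind = c("telomere_seed", "centromere", "hairpin_site", "telomere_seed"),
    pair_id = NA_character_,
    stem_len = c(NA, NA, 6L, NA),
    loop_len = c(NA, NA, 3L, NA)
  )
  g <- list(
    chromosomes = c(chr1 = chr),
    features = feats,
    config = list(master_seed = seed, telomere_copies = 5L,
                  telomere_unit = unit),
    telomere_unit = unit,
    coord = "0-based half-open"
  )
  class(g) <- "toy_genome"
  list(genome = g, p = p, arm = arm, loop = loop, site = site)
}
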
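#' Simulation configuration for the toy assay genome
#'
#' Bundles everything needed to build a reproducible toy genome emulating a
#' yeast-style GCR assay: a small set of linear chromosomes, a
#' telomere-proximal counter-selection cassette on chromosome 1, an inverted
#' homology pair (a `URA3`-like block inside the cassette and an oppositely
#' oriented `ura3-52`-like block centromeric to the breakpoint region),
#' Ty/delta-like repeat blocks on chromosome 1 and a donor chromosome, and
#' planted hairpin-forming inverted repeats inside the breakpoint region.
#'
#' Chromosome 1 is oriented with its centromere at low coordinates and the
#' assayed (counter-selected) arm extending to the right telomere, so a GCR
#' keeps the left, centromere-containing side. All coordinates are 0-based
#' half-open.
#'
#' @param master_seed integer master seed; all stages derive named substreams
#'   from it.
#' @param chromosome_lengths integer vector of chromosome lengths (bp).
#'   Chromosome 1 carries the assay.
#' @param cassette_span length-2 integer, `[start, end)` of the
#'   counter-selection cassette on chromosome 1.
#' @param breakpoint_region length-2 integer, `[start, end)` of the assay
#'   breakpoint region on chromosome 1 (centromeric to the cassette).
#' @param hairpin_specs data.frame with columns `pos` (0-based position of the
#'   first arm on chromosome 1), `stem_len` (bp, >= 4) and `loop_len`
#'   (nt, >= 3). Planted sites are exact inverted repeats.
#' @param homology_len length (bp) of each member of the inverted homology
#'   pair and of the repeat blocks.
#' @param telomere_unit the tandem telomere seed repeat unit (6-mer).
#' @param telomere_copies copies of the unit seeded at each chromosome end.
#' @param read_length,insert_mean,insert_sd,coverage,error_rate paired-end
#'   read simulation parameters: read length (bp), fragment size mean/sd (bp),
#'   fold coverage and per-base substitution error probability.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(master_seed = 1L,
                       chromosome_lengths = c(24000L, 12000L, 9000L),
                       cassette_span = c(16500L, 21500L),
                       breakpoint_region = c(5000L, 16000L),
                       hairpin_specs = default_hairpin_specs(),
                       homology_len = 150L,
                       telomere_unit = "TGTGGG",
                       telomere_copies = 25L,
                       read_length = 100L,
                       insert_mean = 600L,
                       insert_sd = 60L,
                       coverage = 30,
                       error_rate = 0.002) {
  cfg <- list(
    master_seed = as.integer(master_seed),
    n_chromosomes = length(chromosome_lengths),
    chromosome_lengths = as.integer(chromosome_lengths),
    cassette_span = as.integer(cassette_span),
    breakpoint_region = as.integer(breakpoint_region),
    hairpin_specs = hairpin_specs,
    homology_len = as.integer(homology_len),
    telomere_unit = toupper(telomere_unit),
    telomere_copies = as.integer(telomere_copies),
    read_length = as.integer(read_length),
    insert_mean = as.integer(insert_mean),
    insert_sd = as.integer(insert_sd),
    coverage = coverage,
    error_rate = error_rate
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Default planted hairpin sites
#'
#' One 15 bp stem / 3 nt loop "hotspot" (the longest stem in the breakpoint
#' region) plus a handful of shorter-stem sites, mirroring the observed range
#' of 4-15 bp stems. Positions are spread across the breakpoint region.
#'
#' @return a data.frame with columns `pos`, `stem_len`, `loop_len`.
#' @export
default_hairpin_specs <- function() {
  data.frame(
    pos = c(12000L, 6500L, 8200L, 9900L, 14100L),
    stem_len = c(15L, 6L, 9L, 6L, 8L),
    loop_len = c(3L, 3L, 4L, 8L, 21L)
  )
}

validate_sim_config <- function(cfg) {
  stopifnot(
    cfg$n_chromosomes >= 1L,
    all(cfg$chromosome_lengths > 0L),
    length(cfg$cassette_span) == 2L,
    cfg$cassette_span[1] >= 0L,
    cfg$cassette_span[2] <= cfg$chromosome_lengths[1],
    cfg$cassette_span[1] < cfg$cassette_span[2],
    cfg$breakpoint_region[1] < cfg$breakpoint_region[2],
    cfg$breakpoint_region[2] <= cfg$cassette_span[1],
    cfg$read_length > 0L,
    cfg$insert_mean > cfg$read_length,
    cfg$coverage > 0,
    cfg$error_rate >= 0, cfg$error_rate < 0.1,
    nchar(cfg$telomere_unit) >= 2L
  )
  hp <- cfg$hairpin_specs
  if (nrow(hp) > 0) {
    stopifnot(
      all(hp$stem_len >= 4L),
      all(hp$loop_len >= 3L),
      all(hp$pos >= cfg$breakpoint_region[1]),
      all(hp$pos + 2L * hp$stem_len + hp$loop_len <= cfg$breakpoint_region[2])
    )
  }
  invisible(cfg)
}
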
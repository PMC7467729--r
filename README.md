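# foldbackr

Simulation and detection of hairpin-mediated foldback inversion gross
chromosomal rearrangements (GCRs), for researchers studying genome
instability with counter-selection GCR assays and whole-genome paired-end
sequencing.

## The problem

In budding-yeast GCR assays, a telomere-proximal cassette carrying two
counter-selectable markers is placed on one chromosome arm; simultaneous
selection against both markers recovers cells that lost the cassette through
a chromosomal rearrangement. In strains lacking hairpin surveillance (e.g.
Sae2/Mre11 function), most recovered GCRs are *foldback inversions*: 5'→3'
resection from a break exposes single-stranded DNA containing an inverted
repeat, the repeat folds into a hairpin (a paired *stem* of 4–15 bp separated
by an unpaired *loop*), and extension of the hairpin's 3' end copies the
centromeric region in inverted orientation. The resulting monocentric product
shows a characteristic signature in sequencing data:

1. a deletion spanning some or all of the counter-selected cassette;
2. a duplication (copy number 2) extending centromerically from the deletion;
3. discordant read pairs indicating an inversion junction at the telomeric
   edge of the duplication;
4. reads that sequence that junction, which reads `arm + loop +
   reverse-complement(arm)` of the hairpin site.

The inverted end is then stabilized by a secondary rearrangement: capture of
the released cassette-side fragment by single-strand annealing across an
inverted homology pair (the captured fragment stays at copy 1), a
homology-mediated non-reciprocal translocation into a repeat element (the
donor's telomeric segment is duplicated), de novo telomere addition, or more
complex multi-junction products.

`foldbackr` implements this entire analysis as testable components:

* **Simulation** — annotated toy assay genomes with planted hairpin sites
  (`sim_config()`, `build_toy_genome()`), GCR events with their secondary
  resolutions (`apply_foldback_inversion()`, `apply_simple_gcr()`), paired-end
  reads (`simulate_reads()`), and Luria–Delbrück fluctuation experiments
  (`simulate_fluctuation_experiment()`).
* **Hairpin analysis** — enumeration of all maximal perfect inverted repeats
  with loop bounds (`enumerate_hairpin_sites()`), junction-anchored hairpin
  inference (`infer_hairpin_from_junction()`), the short (<15 nt) / large
  loop dichotomy (`classify_loop()`), per-event and per-site loop-size
  summaries (`loop_size_summary()`), and ranking of hairpins near a
  double-strand break (`rank_hairpins_near_dsb()`).
* **Rearrangement calling** — k-mer read mapping (`map_reads()`), read-depth
  and span-depth profiles (`compute_depths()`), discordant-pair clustering
  (`detect_discordant_clusters()`), junction assembly with microhomology
  measurement (`assemble_junction()`, `measure_microhomology()`),
  telomere-addition detection (`detect_telomere_junctions()`), span-depth
  noise filtering (`filter_junctions()`), and copy-number segmentation
  (`segment_copy_number()`).
* **Classification** — the four-feature foldback signature and the GCR
  taxonomy (`classify_gcr()`), resolution classes (`classify_resolution()`),
  and spectrum tables (`spectrum_table()`).
* **Rate statistics** — Ma–Sandri–Sarkar fluctuation-rate estimation
  (`estimate_rate()`), bootstrap proportion CIs with a pseudo-count
  (`bootstrap_proportion_ci()`), error-propagated subtype rates
  (`propagate_subtype_rate()`), Fisher's exact and Mann–Whitney U tests.
* **Pipeline** — `run_end_to_end()` simulates a batch of isolates, calls and
  classifies each, and reports the spectrum, a truth-versus-called confusion
  matrix, and the foldback inversion rate `q = r·p` with propagated 95%
  bounds.

The subtype rate combines a GCR rate `r` (95% CI `r_lo..r_hi`) with a
foldback proportion `p` (95% CI `p_lo..p_hi`):

    q    = r·p
    q_lo = q − q·sqrt(((r − r_lo)/r)² + ((p − p_lo)/p)²)
    q_hi = q + q·sqrt(((r − r_hi)/r)² + ((p − p_hi)/p)²)

## Worked example

```r
library(foldbackr)

cfg <- sim_config(master_seed = 7)
genome <- build_toy_genome(cfg)
site <- subset(genome$features, kind == "hairpin_site" & stem_len == 15)
ev <- apply_foldback_inversion(genome, site,
                               resection_start = site$end + 500,
                               secondary = "ssa_capture")
reads <- simulate_reads(ev$genome, seed = 42)
res <- call_gcr_sample(genome, reads)

res$classification$event_type
#> [1] "foldback_inversion"
res$classification$resolution
#> [1] "class1_ssa_capture"
c(res$classification$hairpin$stem_len, res$classification$hairpin$loop_len)
#> [1] 15  3
subset(res$junctions, validated & !coarse & geometry == "inversion",
       c(breakpointA, breakpointB))
#>   breakpointA breakpointB
#> 2       12033       12000
res$segments$chr1$copy_number
#> [1] 0 1 2 0 1 0
```

The hotspot site planted at chr1:12,000 (15 bp stem, 3 nt loop) mediated the
inversion; the caller recovers the junction at the planted coordinates
(12,033 joins back to 12,000 on the minus strand — the 33 bp between them is
the hairpin site itself), classifies the event as a foldback inversion, and
identifies the single-strand-annealing resolution: the cassette-side fragment
was captured without duplication (its segments stay at copy 1), while the
region centromeric of the site is duplicated (copy 2) and the cassette region
deleted (copy 0). The short copy-0 segments at the ends of the copy-number
track are the repetitive telomere seeds, which do not map uniquely.

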
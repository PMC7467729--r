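---
title: "Simulating and detecting hairpin-mediated foldback inversions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and detecting hairpin-mediated foldback inversions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foldbackr)
```

## The generative model

The simulator emulates a counter-selection GCR assay on a small linear
chromosome. Chromosome 1 is oriented with its centromere at low coordinates;
moving telomere-ward it carries an oppositely oriented homology block (the
`ura3-52` analogue), a Ty-like repeat, a breakpoint region in which
hairpin-forming inverted repeats are planted, and finally the
counter-selection cassette containing the second member of the inverted
homology pair (the `URA3` analogue). A donor chromosome carries a repeat
whose content pairs with the chromosome-1 repeat, and a third chromosome is
plain background. All coordinates are 0-based half-open.

A foldback inversion is generated by the resection–hairpin–extension
mechanism: a break telomeric to a planted site releases the cassette-bearing
fragment; resection exposes the inverted repeat as single-stranded DNA; the
repeat folds into a hairpin (arms of `stem_len` bp, spacer of `loop_len`
nt); any 3' flap is trimmed; and extension copies the region centromeric of
the site in inverted orientation. With arms at `[p, p+S)` and `[q-S, q)`,
the product is

    ref[0, q) + revcomp(ref[s, p)) + <cap>

so the deletion `[q, ...)` removes the cassette, `[s, p)` is duplicated, and
the junction window reads `arm + loop + revcomp(arm)`. The cap models the
secondary rearrangement that stabilizes the product: `ssa_capture` anneals
the inverted copy to the released fragment across the homology pair (the
captured fragment is **not** duplicated — its hallmark),
`homology_translocation` copies a donor chromosome from its repeat to its
telomere (duplicating that segment, donor left intact), and
`telomere_addition` heals the end with tandem telomere units. Every product
is checked monocentric.

## What the generator does and does not emulate

Reads are FR-oriented pairs with normal fragment sizes and independent
per-base substitution errors; read names carry the true origin so every
downstream stage can be scored against truth. The defaults are the study
conditions used throughout the tests: three chromosomes of 24/12/9 kb,
100 bp reads, 600 ± 60 bp fragments, 30-fold coverage, 0.2% error. The
fragment size was chosen, together with coverage, so that a real junction is
supported by roughly `cov·(insert − 2·rl)/(2·rl) ≈ 60` discordant pairs,
comfortably above the span-depth validation threshold even at copy-2
anchors; at much smaller fragments the binomial fluctuation of the support
count would make validation of true junctions flaky, which is a property of
the filter, not of the biology. The generator does not model base qualities,
indel errors, GC bias, chimeric library artifacts, or the sequential
double-hairpin products occasionally seen in real data; passing tests
therefore demonstrate correctness of the calling logic under idealized
noise, not robustness to every artifact of real libraries.

Planted sites are exact inverted repeats with two guards: the bases just
outside the arms must not pair (the planted stem is outward-maximal) and the
outermost loop bases must not pair (the stem is inward-maximal at the
declared loop). The breakpoint region is rejection-sampled until it contains
no unintended inverted repeat with a stem at least as long as the longest
planted stem, so the planted hotspot is the region's unique longest-stem
site; the guard is restricted to the breakpoint region for speed.

## Hairpin enumeration and inference

`enumerate_hairpin_sites()` reports all maximal perfect inverted repeats
with `stem >= min_stem` and `min_loop <= loop <= max_loop` (defaults 3 and
49 nt — loops under 50, no stem mismatches). Stems live on anti-diagonals of
the pairing matrix; the implementation finds them by exact
k-mer/reverse-complement seeding (every valid stem contains a seed whose
innermost instance sits within `max_loop + k`, independent of stem length)
and extends each seed to its maximal run. Runs are trimmed to the loop floor
and deduplicated: among overlapping sites the maximal stem wins, ties going
to the smaller loop and then the leftmost center, mirroring the dominance of
the longest-stem hotspot. The test suite pins this enumerator to a
brute-force oracle that anchors every candidate innermost pair directly.

`infer_hairpin_from_junction()` reconstructs hairpin geometry from an
inversion junction `(pos_a, pos_b)`: the arms begin exactly at the
breakpoints and extend inward, so the alignment is anchored, not free — a
free local alignment would latch onto the whole quasi-palindromic site and
overstate the stem. Exact mode walks outward-in until the first mispair and
requires a stem of at least 4 bp (the shortest observed); imperfect mode
runs an anchored dynamic program (match +1, mispair −1, unpaired −2,
minimum reported score 4) and counts mispairs and unpaired bases. These
scores are a transparent stand-in for thermodynamic folding, which names no
parameters we could adopt; free-energy prediction is out of scope. The
inferred loop is the inner-end gap and may be smaller than the enumeration
floor, down to 0. Loops are classified short below 15 nt and large at or
above it; medians use the midpoint of the two central order statistics for
even n (made observable by the published per-event counts, e.g. the
sae2-deficient distribution 3×16, 4, 5, 8, 10 has median 3 while the
tel1-deficient counts give 17.5 under this convention).

## Rearrangement calling

The mapper anchors each read by exact 21-mers at both ends and the middle,
on both strands, and scores candidate placements by ungapped mismatch count
(budget 5). Reads spanning a novel junction exceed the budget and stay
unmapped, becoming junction-sequencing reads; reads placed equally well at
two loci are flagged non-unique and excluded from depth profiles. Read
depth counts uniquely mapped read coverage; span depth adds the inter-mate
gap of concordant pairs (opposite strands, plus-strand mate leftmost,
insert within mean ± 3 sd) and is the reference against which junction
support is judged: a call validates only if it has at least `min_support`
(3) pairs **and** at least `alpha` (0.2) times the local span depth at each
anchor. The two-criterion rule is a documented stand-in for the original
pipeline's unspecified statistical test and is validated against simulated
truth only.

Junction contigs are assembled from unmapped reads anchored by their mates,
by greedy maximal-overlap consensus (minimum overlap 15 bp, at most ~5%
mismatches, majority base per column). Mismatches are heavily penalized
when ranking candidate merges because at a quasi-palindromic foldback
junction the wrong orientation also overlaps — only the correct one is
near-exact. Consensus columns covered by a single read are trimmed (a read
error there would propagate into the contig). The contig is walked against
the reference outward from each cluster anchor with a tolerant match rule
(a mismatch is accepted when at least 4 of the following 6 positions
match, letting the walk cross isolated errors and the mismatched loop of a
hairpin); the region claimed by both walks — junction microhomology, or the
self-complementary arms of a foldback — is assigned to side A, and a
minus-strand description of a foldback junction is re-expressed from the
plus strand so that planted truth, inference and calls share one
convention. Microhomology is measured on the reference flanks as the
shared run immediately at the join (suffix side plus prefix side, capped at
the flank length); non-templated bases are reported separately.

Copy number is segmented by recursive binary splitting of the per-base read
depth, accepting a split when the between-segment mean difference exceeds
0.4 of the genome-median depth — copy steps are whole multiples of the
per-copy depth, so this threshold passes real steps and rejects Poisson
noise; any residual over-segmentation is healed by merging adjacent
segments with equal rounded copy number. Segment boundaries are accurate to
well under the 200 bp minimum segment length, which is also the tolerance
used when matching the inversion junction to the duplication's telomeric
edge.

Telomere additions are detected separately from half-mapped pairs whose
unmapped mate is tandem telomere repeat; the threshold of 12 units matches
the simulator's minimum planted tail, and the breakpoint is voted from
split reads retaining a reference flank.

## Classification

`classify_gcr()` requires all four signature features for a foldback call:
cassette-overlapping deletion, centromeric copy-2 segment, a validated
inversion junction at the duplication's telomeric edge, and an assembled
junction sequence. "At the edge" means within twice the 200 bp minimum
segment length of either the duplication's telomeric boundary or the
deletion's centromeric boundary — the two reference coordinates of the same
junction. The doubled tolerance reflects how the boundaries are called:
read depth ramps over a read length at junction edges because
junction-crossing reads are unmapped, so a called boundary can sit a read
length plus the segmentation resolution away from the true junction. Otherwise the junction geometry decides:
telomere junctions with ≥12 units are telomere additions,
cross-chromosome junctions are microhomology-mediated translocations,
deletion-geometry junctions are interstitial deletions, and two or more
unexplained junctions make the call complex. Resolution classes for
foldbacks: two or more secondary junctions is class 3; a secondary junction
touching both members of the inverted homology pair with the captured
fragment at copy 1 is class 1 (single-strand annealing); one touching a
repeat element with the donor's telomeric segment at copy 2 is class 2;
a telomere junction resolves by de novo telomere addition; and a remaining
junction with at most 10 nt of microhomology and no homology-feature
contact is microhomology-mediated. The 10 nt ceiling is a documented
choice — the distinction is drawn by name, not number, in the literature —
and class 1 and class 2 are mutually exclusive through the copy-number
criterion on the captured fragment.

## Rate statistics

Mutant counts per culture follow the Luria–Delbrück distribution, computed
by the standard recursion `p_0 = exp(−m)`,
`p_r = (m/r)·Σ_{i<r} p_i/(r−i+1)`. The distribution's tail is heavy
(`P(R > r) ≈ m/r`), so no finite recursion can close the mass to numerical
precision; the pmf is truncated at `r_max` (default 10,000) and
inverse-CDF draws beyond the truncation use the analytic tail
`r ≈ m/(1−u)`. For estimation, counts are winsorized at 1,000 — jackpot
cultures carry almost no additional information about `m` and would make
the recursion arbitrarily long — and `m` is fit by maximum likelihood
(Ma–Sandri–Sarkar) using derivative-free golden-section search on `log m`
over `[1e-4, 50]`. The 95% CI uses the standard log-scale approximation
`σ_ln m = 1.225·m^(−0.315)/√C`; it is validated by coverage simulation
(≥90% across m from 0.5 to 5) rather than against any external table. The
all-zero boundary returns rate 0 with the exact upper bound from
`P(all C cultures empty) = exp(−mC)`.

The bootstrap proportion CI resamples the n observed 0/1 GCR types with
replacement, B = 100,000 times, taking the empirical 0.025/0.975 quantiles;
a count of zero in either class first adds one observation of the missing
class (n grows by one — an added observation, not a reallocation), which
keeps the interval away from degenerate 0–0 or 1–1. Because a
with-replacement resample of iid 0/1 observations is exactly Binomial(n,
k/n), the implementation draws the resample successes directly from that
binomial; the tests check the quantiles against the exact binomial law
independently. Subtype rates propagate both intervals through
`q = r·p` with the relative-error quadrature given in the README; with a
degenerate proportion the formulas collapse algebraically to the rate CI,
which the tests assert exactly. Fisher's exact p-values sum hypergeometric
point probabilities with the conventional `1 + 1e-7` relative tolerance;
the Mann–Whitney U test is exact for small untied samples and uses the
tie-corrected normal approximation otherwise.

## Problem sizes and determinism

The test suite and acceptance script run everything at toy scale: 45 kb
genomes at 30× (about 7,500 read pairs per isolate), 50 simulated foldback
genomes for planted-truth recovery, 1,000 random sequences for the
enumeration oracle, 100 replicate fluctuation experiments of 50 cultures
per parameter value, and 100,000 bootstrap resamples. One master seed
drives named substreams (genome, reads, events, fluctuation, bootstrap) so
stages can be re-run independently and whole runs reproduce byte-identical
outputs, which the pipeline manifest records as file digests.

## Known limitations

The mapper is exact-k-mer anchored and ungapped, so it is blind to indels
and soft-clips; junction breakpoints inherit a small ambiguity from
junction microhomology and from chance matches at the fold (within the
±5 bp the tests allow); sequential double-hairpin events, dicentric
breakage–fusion–bridge cycles, and genome-wide scans of real genomes are
out of scope; and the fluctuation CI is an approximation whose coverage,
not whose provenance, is tested.
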
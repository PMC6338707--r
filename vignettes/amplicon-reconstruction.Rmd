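---
title: "Reconstructing circular extrachromosomal amplicons from short reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing circular extrachromosomal amplicons from short reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

A double minute is a circular arrangement of genomic segments: an
ordered list of (segment, orientation) pairs, closed into a ring, present
at some number of copies per tumor cell. In short-read data it leaves
three footprints that `circamp` combines:

* **coverage**: each constituent segment shows a log2 tumor/normal depth
  ratio of about `log2((2 + CN) / 2)`, where CN is the total number of
  amplicon copies carrying the segment (both chromosomal copies remain);
* **junction-spanning reads**: at each joint between consecutive
  segments, reads that cross the junction are soft-clipped at the
  breakpoint, read pairs that straddle it are discordant, and joints
  flanked by unalignable sequence still betray themselves by "bridging"
  mate clusters;
* **allele-frequency drift**: a heterozygous germline SNV on an
  amplified segment drifts from VAF 0.5 toward 1 (alternative allele on
  the amplified haplotype, the *upper branch*) or toward 0 (the *lower
  branch*). With copies counted relative to one set of chromosomes, an
  upper-branch SNV has expected alt:ref read counts of CN:1, so the
  median of alt/ref over upper-branch SNVs estimates CN directly.

Reconstruction proceeds by building a *boundary graph*: every amplified
segment contributes its 5' (L) and 3' (R) boundary as nodes plus one
*segment edge* joining them; every SV joins two boundaries; every pair
of reference-adjacent amplified segments is joined iR–(i+1)L by an
*adjacent edge*. A circular amplicon is a simple cycle of this
bidirected graph that alternates segment edges and junction edges —
cycles touching a segment through a single boundary are geometrically
impossible structures and are removed.

### Orientation conventions (frozen)

A junction breakend *uses* a segment's R boundary when the retained
sequence runs leftward (in reference orientation) into the junction, and
the L boundary when it runs rightward. The unordered side pair fixes the
class: {R, L} head-to-tail (→→), {R, R} head-to-head (→←), {L, L}
tail-to-tail (←→). Evidence encodes sides as follows:

* soft-clip: the clip side gives the source side (right clip at an
  alignment end = R, left clip at an alignment start = L); the strand of
  the clipped bases' unique hit gives the partner side (right clip:
  forward hit = L, reverse = R; mirrored for left clips). Breakpoints
  are the clip coordinate and the hit edge.
* discordant pairs: a read's own strand gives its side (forward = R,
  reverse = L, i.e. the read points into its junction), the mate's
  strand gives the partner side. This is the FLAG-only orientation rule.
* bridging: sides from the flank-read strands as above; orientations are
  "consistent" when the two boundaries' free mate clusters lie within
  `bridge_max_distance` on one chromosome with opposite predominant
  strands — one intervening fragment joining both boundaries. This is
  one reading of an under-specified rule and is deliberately
  conservative.

## Parameters

All tunables live in `dm_params()`:

| parameter | default | meaning |
|---|---|---|
| `boundary_flank` | 50 bp | read-collection window half-width at each boundary |
| `search_flank` | 1000 bp | flank half-width for clip realignment and mate matching |
| `discordant_min_distance` | 800 bp | minimum same-chromosome mate separation |
| `bridge_max_distance` | 10 kb | maximum distance between bridging mate clusters |
| `amplified_log2r_cutoff` | `"auto"` | explicit log2R cutoff, or mean + 2 sd |
| `adjacency_max_gap` | 10 bp | maximum reference gap for an adjacent edge |
| `min_clip_match` | 20 bp | minimum clipped-segment length realigned |
| `min_clip_identity` | 0.95 | minimum identity of a qualifying clip hit |
| `uniqueness_ratio` | 1.2 | best hit must score this multiple of the second best |
| `min_snv_depth` | 10 | minimum SNV depth entering the copy-number median |
| `vaf_low_max` / `vaf_high_min` | 0.10 / 0.90 | cross-sample VAF-shift thresholds |
| `corner_fold_min` | 5 | corner fold-enrichment for linked-read support |
| `corner_min_barcodes` | 10 | minimum shared barcodes in the expected corner |
| `bin_size` | 1 kb | barcode-matrix bin width |
| `max_cycle_segments` / `max_candidates` | 12 / 1e5 | enumeration guards |

The window defaults (50 bp, 1 kb, 800 bp, 10 kb) suit ~100 bp paired-end
reads with ~350 bp inserts; on other designs they should scale with the
insert size (e.g. doubling the flanks for long-insert libraries). The
`"auto"` cutoff formalizes "right tail of the log2R distribution" as
mean + 2 sd; in focused studies an explicit cutoff chosen from the
log2R histogram is usually preferable and is what the worked examples
use. The VAF-shift thresholds bracket the observable regime
(high-copy amplicons push VAFs within ~1/CN of 0 or 1), and the
linked-read thresholds were chosen so that pure background never
reaches them (the false-positive study in the test suite runs 20
background-only replicates).

## Local realignment of clipped bases

Clipped subsequences (≥ `min_clip_match` bases) are aligned with
Smith–Waterman local alignment (`Biostrings::pairwiseAlignment`, match
+2, mismatch −3, gap open 5, extend 2) against the ±1 kb flank of every
other boundary, both strands. A placement counts only if it reaches 95%
identity over ≥ 20 aligned bases, and only if it is *unique*: the best
boundary's score at least 1.2× any competitor's. Reads whose clips place
ambiguously (duplicated flank sequence) contribute nothing, which is the
behavior you want near segmental duplications.

## Cycle enumeration

Johnson's simple-cycle algorithm runs on the directed expansion of the
boundary graph (each edge becomes two arcs; strongly connected
components, computed with igraph, prune the search). Every cycle is
found once per direction — the two directions are the two strands of the
same circle — and parallel edges are expanded afterwards, which also
discards the degenerate walk that crosses a single edge there and back.
Deduplication keys cycles on a rotation- and reflection-invariant
canonical string. Enumeration is exponential in the number of cycles, so
`max_candidates` aborts pathological inputs with a clear error rather
than hanging. Cycles may not reuse a segment (simple-cycle semantics), so
intra-amplicon tandem duplications are out of reach by construction —
a known limitation.

## Linked-read validation

With window a on x and window b on y (both reference-forward, windows =
the two segments), molecules crossing a junction that uses a's R side
occupy the high half of x, and likewise for b; the expected corner
quadrant (four equal sub-grids) must be enriched at least
`corner_fold_min`-fold over the two *adjacent* quadrants and contain at
least `corner_min_barcodes` shared-barcode counts. The diagonally
opposite corner is excluded from the background because on a circle it
legitimately hosts the complementary junction between the same two
segments. When a window is shorter than the typical molecule, crossing
molecules blanket its whole axis; that axis is collapsed and the test
becomes a half-plane comparison along the informative axis (with both
axes short the junction is untestable and is excluded from the verdict,
like skips across segments longer than a molecule). A cycle is
*invalidated* by any unsupported junction, *validated* when every
testable junction and skip is supported, otherwise *inconclusive*.

One caveat of axis collapsing: on a two-segment circle whose short
segment forces a collapsed axis, the complementary junction's signal
lands in the background half-plane and can mask support; such cycles
tend to come out inconclusive rather than validated.

## The simulator

`amplicon_plan()` describes a study: a random reference (one synthetic
chromosome), planted segments, circular structures (ordered, oriented
segments with per-junction types), read/SNV/molecule specs and a seed.
Everything downstream is a deterministic function of the plan — fixed
seeds give byte-identical FASTA/SAM/TSV outputs.

Reads are emitted *pre-aligned*: junction-crossing reads carry the
soft-clip CIGAR, position and strand a correct aligner would produce,
pairs straddling junctions get discordant mate fields, and
bridging-type junctions insert an 80 bp random pad + 400 bp donor copy +
80 bp random pad, so their junction clips are untraceable while their
mates still cluster at the donor locus. This keeps the tests hermetic;
it also means the simulator does not model alignment artifacts
(mismapping, multi-mapping, quality-dependent errors), sequencing error
(off by default; evidence thresholds here are count-based), GC bias, or
tumor purity/subclonality. Passing tests therefore demonstrate the
*logic* of evidence collection, graph search, estimation and validation
— not robustness to real-world alignment noise.

Molecule lengths for linked reads are exponential around the plan mean,
truncated below at 1 kb and above at 2.5× the mean (high-molecular-weight
DNA has finite fragment lengths; an untruncated tail would let single
molecules blanket a whole fixture circle).

SNV allele counts are binomial: an upper-branch germline SNV on a
segment carried by CN total copies draws alt at probability CN/(CN+1)
(CN = 0 segments stay at 1/2), at Poisson depth
`snv_depth * (2 + CN) / 2`. The one residual chromosomal alternative
copy and tumor purity are deliberately ignored, exactly as in the
ratio-to-copies reading the estimator implements; both bias copy
numbers slightly and are documented rather than corrected.

### Bundled fixtures and their scale

The five named fixtures (`tiny`, `relapse_like`, `bridging`,
`invalid_cycle`, `two_timepoint`) scale a realistic study down so each
builds in seconds: segments 6–40 kb, circles 24–78 kb, diploid read
depth 8–25×, molecules 8 kb mean. The *ratios* that drive the method are
preserved — molecules shorter than most segments but much shorter than
circles, read length ≪ segment length, and per-structure SNV counts in
the hundreds (SNV tables are cheap, so their simulated depth follows a
36× diploid design even where read depth is scaled down; shared-segment
subtraction in particular needs the finer allele-count granularity that
depth buys, because it takes small differences of large estimates).
`relapse_like` plants five structures with copies 16/23/43/20/13 and
the sharing pattern that forces the fifth to be quantified by
subtraction along two independent routes; `invalid_cycle` plants decoy
junction evidence admitting a cycle that linked reads refute;
`two_timepoint` plants one conserved structure (24 → 43 copies), one
structure per time point, and four somatic SNVs shifting VAF 0.02 →
0.96.

## Numerical choices and degenerate inputs

* Segment selection is *strictly greater than* the cutoff; `"auto"` with
  zero log2R spread errors and asks for an explicit cutoff.
* VAF is undefined at zero depth (error, not NA); branch selection
  excludes VAF exactly 0.5 (counted and reported).
* The copy-number median excludes SNVs with zero reference reads
  (infinite ratio) and depth < 10; negative subtraction results clamp to
  0 with a warning.
* Coverage ratios add 0.5 to both depths before the log, so empty
  segments stay finite.
* Evidence counts deduplicate by read name, so one template contributes
  at most once per class per junction; report rows and cycle orderings
  are deterministically sorted so outputs diff cleanly across runs.
* Breakpoints are reported only when soft-clip evidence resolves them
  (majority position across supporting reads); discordant- or
  bridging-only junctions stay "unresolved" (NA).

## Problem sizes used in the checks

The test suite and the acceptance script run entirely on simulated
data: oracle-equivalence over random graphs up to 8 segments (the
brute-force enumerator is exponential beyond that), 100 random graphs
for the even-count/halving property, the five fixtures above, and
copy-number recovery at planted 5/20/50 copies with 200 SNVs at 30×.
These sizes keep a full run in minutes on one CPU while leaving every
code path exercised; they are choices of this package, and all scale up
by editing the plans.

## Known limitations

* Circular ecDNA cannot be computationally distinguished from
  homogeneously staining regions (chromosomally integrated tandem
  amplification) by these data; structure, orientation and abundance
  results are agnostic to that distinction.
* Junctions whose flanking repetitive/unknown region exceeds the insert
  size are invisible to all three short-read evidence classes; the
  linked-read matrix can still reveal them, but `circamp` consumes such
  junctions only when supplied as evidence, it does not call them
  de novo from barcodes alone.
* Segment reuse within one amplicon (tandem duplication on the circle)
  is excluded by simple-cycle semantics.
* Copy numbers ignore tumor purity and the residual chromosomal
  alternative allele; both make estimates slight underestimates of the
  per-tumor-cell truth in impure samples.
* The selection of a parsimonious structure set among many surviving
  candidates is intentionally left to the analyst; the package reports
  all valid cycles with their evidence.
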
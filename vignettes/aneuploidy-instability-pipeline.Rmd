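---
title: "Quantifying rearrangement and copy-number instability in aneuploid clonal lines"
author: "aneuscan authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying rearrangement and copy-number instability in aneuploid clonal lines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aneuscan)
```

## The question and the analysis chain

Cells carrying an extra chromosome experience replication stress, and a
central line of evidence that this stress destabilizes the genome comes from
two complementary assays: long-insert (mate-pair) sequencing that reveals
*de novo* structural rearrangements as discordant read-pair clusters, and
SNP-array profiling of clonal derivatives that reveals *de novo* copy-number
aberrations (CNAs) accumulating in aneuploid but not parental lines.
`aneuscan` implements the full computational chain behind that evidence at
desk scale:

1. **Discordant mate-pair SV calling** — flag pairs violating the expected
   insert geometry, cluster same-signature pairs across all samples,
   keep clusters private to one sample, and type the rearrangement from the
   junction orientation (head-to-tail tandem duplication, tail-to-head
   deletion, tail-to-tail/head-to-head inversion).
2. **Junction microhomology analysis** — place the breakpoint at nucleotide
   resolution from a junction-spanning (Sanger-style) read and its two
   reference flanks, and measure the microhomology that marks
   replication-mediated (template-switching) repair.
3. **Unique-CNA filtering** — across a cohort of clonal lines, remove every
   pair of same-type calls in different clones with reciprocal overlap of at
   least 60%, treating recurrence as shared background; what survives is the
   set of *de novo* CNAs.
4. **Label-permutation enrichment test** — shuffle case/control labels and
   ask how often all CNA-bearing clones end up labelled as cases, with an
   exact closed-form companion.
5. **Probe-threshold aberration calling** — the printed array rule: log2
   ratio ≥ 0.39 (gain) or ≤ −0.30 (loss) over at least five consecutive
   probes.
6. **Fragile-site annotation** — overlap CNA breakpoints (as points, not
   spans) with a catalog of fragile-site intervals.

Because the real inputs (mate-pair libraries, array intensity files) are not
reproducible at the desk, a first-class synthetic-data module generates toy
genomes, rearranged derivatives, mapped mate pairs, clonal CNA tables, probe
profiles and fragile-site catalogs **with exact ground truth**, so that every
analysis step can be validated end to end.

## Coordinate conventions

In memory everything is a 1-based, closed-interval `GRanges` — the
Bioconductor convention. On disk, BED, BEDPE and the package's CNA TSV are
0-based half-open (BED-native), converted exactly once at the I/O boundary;
the VCF writer anchors symbolic records on the base before the event (`POS`)
and its last base (`END`), per the VCF 4.2 symbolic-allele convention.

## The generative model

### Genomes and rearrangements

`makeToyGenome()` draws i.i.d. bases at a configurable GC fraction (default
0.41, human-like). `applyRearrangements()` applies non-overlapping events
mechanically — deletion removes its span, tandem duplication appends a
second copy, inversion reverse-complements in place, whole-chromosome gain
appends a named full copy (no novel junction; it is visible only to
read-depth analysis) — and returns an exact piecewise-affine
`CoordinateMap` from derived to reference coordinates.

**Engineered microhomology.** A junction with `m` bp of microhomology is one
whose two source loci share `m` identical junction-adjacent bases. The
generator edits the reference *before* rearranging, copying the `m` bases
adjacent to one junction side onto the other locus, and then forces a
single-base mismatch just beyond the shared window on each side so that the
realized microhomology equals `m` exactly — including `m = 0`, where chance
homology must be broken. This makes the planted value exact truth rather
than a target found by search, and the junction-analysis round trip
(`engineered value == detected value`) is one of the package's core property
tests.

### Mate pairs

`simulateMatePairs()` draws fragment starts uniformly over the derived
genome and lengths from Normal(3000, 300) bp (rounded, truncated at
`2 × readLen`), reads the terminal 50 bp of each fragment, and lifts both
reads through the coordinate map. Orientation is simulated in
forward/reverse (facing) convention; real SOLiD mate-pair chemistry differs,
but the analysis depends only on deviations from the expected signature, so
one convention is fixed and documented. Reads that fall *across* a junction
are dropped (with a logged count) rather than split-mapped — the signal
carrier here is the discordant pair, not the split read. The 300 bp insert
dispersion is a free parameter: the dispersion of real 3 kb libraries is not
something the package can derive, so a realistic round value was chosen
once.

### Clonal cohorts

`simulateClonalCohort()` emulates deriving clonal lines from single cells
and calling CNAs per clone. Its defaults are the study design: 24 case and
24 control clones in two sets of 12+12; every clone carries every shared
background CNV with independent Gaussian boundary jitter (SD 5 kb, rounded
to bp, truncated to keep intervals valid — the minimal jitter model, since
no empirical jitter distribution is available); 12 *de novo* CNAs sized
105 kb–5 Mb are planted over exactly 8 distinct case clones (positives split
as evenly as possible across sets, 4+4), none in controls; and exactly
`round(fragileFraction × 12)` events (default 8) get a breakpoint placed
inside a fragile-site interval while the rest avoid all sites at both
breakpoints, making the planted overlap fraction exact. De novo events never
overlap each other or a shared-CNV region, so the uniqueness filter has an
unambiguous truth. The de novo gain:loss mix defaults to 5:7, matching the
observed de novo spectrum (one chromosome gain plus four duplications versus
seven deletions).

### Probe profiles and fragile catalogs

`simulateProbeProfile()` places a probe every `spacing` bp and draws
`log2(copies/baseCopies) + Normal(0, noiseSd)`; profiles emulate
post-normalization data (array normalization is out of scope).
`makeFragileCatalog()` draws band-scale intervals (1–3 Mb by default —
fragile sites are cytoband-sized), named `FS1..FSn`, alternating
common/rare.

## Analysis parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `insertMean`, `insertSd` | 3000, 300 | bp | the 3 kb library geometry |
| `k` (discordance gate) | 3 | SDs | standard insert-size gating; the paper's own criterion is unpublished, so this is a declared stand-in |
| `maxGap` (clustering) | `insertMean + 3·insertSd` | bp | two pairs spanning one junction can differ by at most about one insert length |
| `minSupport` | 2 | pairs | one discordant pair is indistinguishable from chimera noise |
| `minRo` (uniqueness filter) | 0.6 | fraction | the printed "reciprocal overlap of at least 60%", inclusive |
| `ampThresh`, `delThresh`, `minRun` | 0.39, −0.30, 5 | log2, probes | the printed array thresholds and run rule |
| `minAnchor` (junction) | 15 | bp | unique anchoring at toy-genome scale |
| `mhThreshold` | 2 | bp | 1 bp of homology arises by chance 25% of the time |

**Breakpoint windows.** A cluster's uncertainty windows are oriented by its
signature: on a tail side (reads on `+`, junction to their right) the
breakpoint lies in `[max member end, max member end + slack]`; on a head
side in `[min member start − slack, min member start]`, with
`slack = insertMean + k·insertSd − 2·readLen`, the farthest a junction can
sit from a read end. For deletion-type (tail, head) clusters the windows are
additionally capped at the opposite side's innermost read edge. The naive
inner-interval formula (`[max left end, min right start]`) cannot contain
the truth for duplication-type junctions, whose breakpoints lie *outside*
the inner interval — hence the orientation-aware definition. Windows whose
bounds invert collapse to a 1 bp midpoint and are flagged low-confidence,
keeping downstream types total.

**Junction matching.** `locateJunction()` anchors the read prefix in the
left flank with its first `minAnchor` bases and extends maximally (`a*`),
likewise the suffix in the right flank (`b*`). When the alignments overlap,
every split in `[n − b*, a*]` is admissible and `mh = a* + b* − n`; when
they leave a gap, the gap is a non-templated insertion (`mh = 0` by
definition). A strict "prefix must be a flank suffix AND remainder a flank
prefix" rule admits *no* split whenever genuine microhomology is present
(the shared bases occur once in the read but would be demanded by both
flanks), so the overlap formulation is the correct — and standard —
reading. Matching is exact: these are Sanger-consensus reads, and error
tolerance is out of scope. The leftmost admissible split is reported as the
canonical breakpoint, matching the usual leftmost-alignment convention for
VCF `HOMLEN`/`HOMSEQ`.

**Permutation schemes.** The clones come in sets (batches derived in
parallel), and the reference procedure permutes labels per set; how the 8
positive clones split across the two sets is not recorded, so the generator
plants the even 4+4 split and the test implements both `per_set`
(independent within-set shuffles, the default) and `joint` (one shuffle
over all 48 clones) schemes, reporting each against its own closed form:

$$P = \prod_{\text{sets } s}\ \prod_{i=0}^{k_s-1} \frac{n^{case}_s - i}{n_s - i}$$

For 4+4 positives in two sets of 12+12 this gives 0.00217; for 8 positives
jointly over 24+24 it gives 0.00195 — both rounding to the reported 0.0021
at one significant figure. No multiple-testing correction is applied (a
single planned test), and the result object records scheme, seed and both
estimates. Whole-chromosome gains enter the statistic exactly like focal
CNAs, as the reference count of 12 implies.

**Manual curation** of unique CNA calls, performed on real array profiles,
is inherently irreproducible and is deliberately a no-op here.

## Numerical and degenerate-input choices

* All randomness flows from one master seed through `fanOutSeed(seed,
  label)`, so stages are reproducible independently of each other; every
  generator takes an explicit seed and is byte-deterministic.
* Thresholds are inclusive where the printed rules say "at least"
  (reciprocal overlap ≥ 0.60, log2 ≥ 0.39, ≤ −0.30, ≥ 5 probes).
* `reciprocalOverlap` returns 0 for different chromosomes or disjoint
  intervals; equals 1 iff the intervals are identical.
* An empty unique-CNA set makes the permutation statistic undefined: the
  test raises an error and the pipeline records the skip rather than
  fabricating a P value.
* Zero-length inputs (empty BED/BEDPE/CNA tables, empty call sets) round-trip
  as empty objects; the VCF writer emits a valid header-only file.
* Clustering is single-linkage within signature groups with a sliding
  window on sorted left-end starts, so it scales as the window occupancy,
  not as all pairs.

## What the simulations do and do not show

The generator reproduces the *statistical structure* the analysis relies on:
insert-size geometry and its truncation, junction orientation signatures,
engineered microhomology, clone-private versus shared CNAs with boundary
jitter, exact fragile-breakpoint fractions, and probe noise around
closed-form log ratios. It does **not** model read-level sequencing error,
SOLiD colour space, GC or mappability bias, B-allele frequencies, array
segmentation artifacts, or biased fragile-site landscapes. A green test
suite therefore demonstrates that the *procedures* are implemented
correctly and behave as designed under the stated model — not that the
pipeline would be robust to every artifact of real libraries. The real
junction sequences and per-junction microhomology lengths live in archived
accessions, not in printed text, and are not reproduced here as ground
truth.

Problem sizes used throughout the tests were chosen to keep the full
validation loop at desk scale while leaving the statistics well-powered: a
1 Mb two-chromosome genome at 20× fragment coverage for SV recovery, a
420 Mb seven-chromosome coordinate space for the cohort, 10^5–10^6
permutations, and 100 replicate probe profiles for the caller's recovery
rate.

## Design choices that were genuinely open

* **Interval container**: `GRanges` (1-based closed) internally rather than
  0-based half-open structs; the conversion lives solely in the readers and
  writers, which are all round-trip tested.
* **Cluster windows**: orientation-aware outward windows (above) instead of
  the inner-interval shorthand, so that window containment of the true
  breakpoint is a guarantee, not a coincidence of event type.
* **Uniqueness filter symmetry**: both partners of a cross-clone match are
  removed; with recurrence treated as background there is no principled
  asymmetry to exploit.
* **Inversions**: one physical inversion yields two reciprocal junction
  clusters (tail-tail and head-head); both are typed `inversion`, and a
  junction read is allowed to annotate every cluster it is compatible with.
* **BEDPE I/O** is implemented in-package (no installed package provides
  it); sample identity is encoded in the name column (`sample/pair`) so
  multi-sample files round-trip.
* **No shell subcommands**: the exported functions plus `runPipeline()` on a
  YAML-serializable config are the interface; an R analysis package is
  driven from R, and the acceptance script shows the full chain as a plain
  Rscript.

## Known limitations

* Dispersed (non-tandem) duplications are deliberately called
  `tandem_duplication` — resolving insertion location needs split reads or
  assembly, both out of scope.
* Translocation records are written as minimal `SVTYPE=BND` stubs without
  mate coordinates; no inter-chromosomal events are simulated.
* The insert-size tail beyond `k` SDs produces occasional spurious
  two-pair deletion-type clusters at 20× coverage; they are genuine
  consequences of the gating criterion and are left in (support/uniqueness
  filtering, not suppression, is the mechanism the method offers).
* `filterUniqueCnas` is quadratic in overlapping same-type call pairs —
  fine for cohort-scale tables (hundreds of calls), not engineered for
  genome-wide call sets from thousands of samples.

## A minimal run

```{r, eval = FALSE}
cfg <- defaultRunConfig(seed = 1)
report <- runPipeline(cfg)
report
```

The report lists per-stage record counts, the planted-versus-called
rearrangement table with microhomology, both permutation results, the
fragile-site summary and the probe-caller recovery — everything the
acceptance script (`scripts/acceptance.R`) recomputes from scratch.
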
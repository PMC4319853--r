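---
title: "Methods: the pomiR small RNA analysis pipeline"
author: "pomiR authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the pomiR small RNA analysis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pomiR)
```

pomiR implements the complete computational arc of a two-library plant
small RNA study — control (CK) versus treated (TR) — for a species
with a transcriptome assembly but no genome. This vignette is the
package's account of the models and procedures it implements, the
tunable parameters and their defaults, the design choices made where
the workflow is genuinely open, and what the synthetic-data tests do
and do not demonstrate.

## Read cleaning

Cleaning works on raw reads and produces a collapsed `TagLibrary`
(unique uppercase RNA tags with counts; the internal alphabet is RNA
throughout). The rules, applied in a fixed precedence so every read
receives exactly one removal reason:

1. the 3' adaptor is located by an exact match of its first 8 nt
   (`seedLen`); a read without it carries no recognizable insert
   (`no_insert`). A deterministic seed match stands in for vendor
   trimmers and makes the report exactly reproducible;
2. an empty insert is `no_insert`;
3. an insert containing an N, or with mean Phred below 20
   (`minMeanQ`, skipped for FASTA input), is `low_quality`;
4. an insert containing the first 8 nt of the 5' adaptor is
   adaptor-adaptor ligation contamination (`adaptor_5prime`);
5. an insert whose A fraction is at least 0.8 (`polyAFrac`) is a
   poly(A) artifact; the threshold separates oligo-A junk from genuine
   A-rich tags;
6. inserts shorter than 15 or longer than 30 nt (`minLen`, `maxLen`,
   inclusive bounds) are out of the small RNA range.

The poly(A) and quality thresholds are declared package defaults: the
originating workflow names these filters without quantifying them.
Removed + retained always equals the input read count, and collapsing
is invariant under read order.

## Annotation and conserved miRNAs

Tags map to the transcriptome only by **perfect match**, on either
strand (transcript orientation of a small RNA locus is not guaranteed
when the "genome" is an assembled transcriptome). ncRNA degradation
fragments are assigned by exact substring match against labelled
references, in the fixed priority rRNA > tRNA > snoRNA > snRNA; the
reference workflow states no order, so the package fixes one (rough
abundance order of degradation products) to make the annotation a
deterministic partition. The full per-tag category priority is
rRNA > tRNA > snoRNA > snRNA > known_miRNA > unannotated_mapped >
unmapped.

Conserved miRNAs use the three-step temporary-database procedure:

1. tags are aligned to the mature records of a family-labelled plant
   catalog. "Allowing two mismatches and free gaps" is implemented as
   **ungapped** alignment with at most two substitutions — the
   conservative, testable reading of an ambiguous phrase — with both
   terminal offsets within 2 nt (the tag must cover the mature
   end-to-end up to that slack);
2. per family, the highest-count aligning tag becomes the
   representative (count ties break to the lexicographically smaller
   sequence so output never depends on iteration order);
3. the library is re-aligned to the representatives with the same
   tolerance; each tag is assigned to at most one family (fewest
   mismatches, then lexicographic family name) and member counts are
   summed per family.

## The folding engine

Hairpin discovery and target-duplex energies both use an embedded
nearest-neighbor model (`src/fold_engine.cpp`), exposed through
`foldHairpin()`, `duplexEnergy()` and `foldParameters()`:

* canonical pairs AU/UA/GC/CG/GU/UG; minimum hairpin loop 3 nt;
* a 6x6 stack-energy table satisfying the strand-flip symmetry
  E(p, q) = E(flip q, flip p), with GC-rich stacks near -3.3 and
  GU-containing stacks between -0.5 and -2.1;
* logarithmic loop penalties: hairpin 5.4 + 1.0774 ln(n/3), bulge
  3.8 + 1.0774 ln n, internal 4.1 + 1.0774 ln(n/2); interior loops
  with more than 30 unpaired nt are disallowed *as part of the model*;
* multibranch loops cost 4.6 + 0.4 per branch (closing helix
  included), unpaired bases free;
* no dangles, no coaxial stacking, no pseudoknots; lonely pairs are
  allowed. These omissions keep an exhaustive enumeration oracle
  feasible: the test suite enumerates *every* secondary structure of
  short sequences, scores them by loop decomposition with the same
  parameter table, and requires the dynamic program to match exactly.

Energies are "engine units ~ kcal/mol". Absolute values are model
dependent (different folders disagree on absolute MFE), so the -18
kcal/mol precursor threshold is a configurable parameter rather than a
constant, and all designed test fixtures keep at least a 5 kcal/mol
margin so that reasonable parameter perturbations do not flip them.

Duplex hybridization energy is the duplex initiation constant (4.1)
plus stack terms over runs of consecutive paired positions; unpaired
positions break stacks. The perfect-complement energy is the same
routine with every position paired, which makes the target rule's
energy ratio exactly 1 for a perfect site by construction.

## Novel miRNA discovery

Around every transcriptome hit of an unannotated tag the pipeline
excises two asymmetric windows, [start - 150, end + 20) and
[start - 20, end + 150), clipped to the transcript. The flank of 150 nt
covers the observed plant precursor length range (roughly 67-370 nt)
whichever arm holds the mature; the window policy of the original
discovery tool is not published, so this one is explicit and
configurable. Each window is folded and evaluated:

* **arm placement**: at least 75 % of mature positions paired, all
  partners on the opposite arm of a single hairpin (nested, strictly
  monotone), the mature never spanning the terminal loop;
* **stability**: MFE at or below the threshold (default -18);
* **duplex quality**: no internal loop or bulge longer than 3 nt
  between consecutive paired positions of the mature:star duplex
  ("large" is quantified as > 3 nt, the community convention, and
  configurable);
* **processing geometry**: 2-nt 3' overhangs on both strands of the
  mature:star duplex, checked on the pair table with 1 nt of slack at
  helix termini because MFE structures are ambiguous there;
* **read support**: the mature's summed count — tags matching exactly
  over the mutual overlap with total terminal divergence (5' offset +
  3' offset + non-template tail) at most 3 nt — must exceed 5 in at
  least one library.

MFEI, (MFE / length x 100) / GC%, is computed and reported but not
used as a filter (it is descriptive in the reference workflow).
Accepted candidates on one transcript whose mature intervals lie
within 50 nt of each other are one stem-loop locus — this includes a
tag matching the star arm, which maps antisense into the same hairpin —
and the best-supported mature (then lowest MFE) represents the locus.
Ids `novel_mir_N` are assigned in transcript-then-position order, so
calls are reproducible.

## isomiRs

A tag places on a precursor when a prefix of length at least
(tag length - 3) matches it exactly; the unmatched 3' remainder (at
most 3 nt, matching the read-support tolerance) is the candidate
non-template tail. Placements overlapping the canonical mature by
fewer than 10 nt are not isomiRs of that mature. Classes follow the
most-specific-label-wins priority nontemplate > both > 5p/3p variant.
A tag placing on several precursors counts once, toward the precursor
with the fewest terminal differences (ties to the smaller precursor
id). The placement tolerance is declared here, not inferred: the
reference workflow does not define one.

## Target prediction

Duplexes are ungapped — the six rules speak of mismatches, never of
gaps — and positions are numbered 1-based from the miRNA 5' end. G:U
wobble contributes 0.5 to the two score rules but counts as *paired*
for the boolean adjacency and position rules: wobbles hybridize, so
the rules price them rather than forbidding them (a G:U at positions
10-11 therefore does not fail the no-mismatch rule). "No more than two
adjacent mismatches" is read as "no run of three or more". The energy
ratio uses the same duplex routine for numerator and denominator so
the model cancels out of the ratio. Overlapping accepted windows for
one miRNA/transcript pair are merged keeping the lowest mismatch
score, then the lowest energy. Note that when the transcriptome
contains the miRNA's own precursor, the star-arm region is itself an
accepted "target" — a real feature of transcriptome-based scans, not
an artifact.

## Differential expression

Expression is normalized to TPM = count / total clean reads x 10^6 and
compared as log2((TPM_TR + 0.01) / (TPM_CK + 0.01)); the pseudo-TPM of
0.01 keeps library-exclusive miRNAs finite and is far below any
quantifiable expression. Significance uses the exact conditional
(Audic-Claverie) test: given x in a library of N1 clean reads, the
count y in a library of N2 follows

p(y | x) = r^y (x+y)! / (x! y! (1+r)^(x+y+1)),   r = N2/N1,

evaluated in log space via log-gamma. The lower tail C(y' <= y | x) is
a finite sum; the infinite upper tail D is its complement (no
truncation bias), except when that complement falls below 1e-8, where
floating-point cancellation floors it and the tail is instead summed
directly in log space so extreme p-values keep their true magnitude.
The two-sided p doubles the smaller tail and is capped at 1 — the
standard doubling convention for a discrete test, which makes it
conservative (null rejection rates run below nominal; the calibration
test asserts <= 6 % at the 5 % level). Adjustment is Benjamini-
Hochberg (the reference workflow says "adjusted" without naming a
procedure), and calls require adjusted p < 0.01 *and*
|log2 fold-change| > 1, both strict.

The test conditions on the first library's count, so it is not exactly
exchangeable: swapping the libraries negates the fold-change and
rescales the point probability by r exactly, but the tails C and D do
not literally trade places. The confidence-interval form
[y_min, y_max] at level epsilon is exposed as a descriptive utility
(`acInterval()`) and plays no role in the significance path.

## The synthetic study design

`makeReferences()` + `simulateLibraries()` generate the conditions the
pipeline is tested under; their defaults are the package's study
design, fixed once:

* 24 host transcripts assembled from random spacers (320-480 nt) and
  planted elements; 30 novel and 12 conserved hairpins, alternating
  5p/3p arms; 8 planted perfect target sites; 8 ncRNA references; 30
  decoy transcripts that are dinucleotide-block-shuffled copies of the
  planted precursors (block permutation preserves composition while
  destroying stems);
* hairpins are built by explicit stem design — mature positions 1-19
  pair a reverse-complement star arm, 2-nt 3' overhangs on both
  strands, an 8-nt loop and 12-nt flanks drawn from the non-pairing
  {A, C} alphabet — and each is verified at construction to pass the
  discovery criteria with MFE <= -23, i.e. a 5 kcal/mol margin over
  the -18 threshold. Construction, not rejection sampling, guarantees
  the margins;
* per-miRNA counts are Poisson with means proportional to a planted
  TPM (conserved 10^2.3-10^4.3, novel 10^2.2-10^3.3 so read support
  clears the > 5 rule), treated means scaled by 2^lfc with |lfc| = 2
  planted on 3 conserved + 8 novel miRNAs. Poisson matches the exact
  test's own sampling assumption, so the calibration fixture tests the
  test under its model;
* each count is spread over an isomiR cloud (canonical 0.67, 5'
  variants 0.10, 3' variants 0.16, non-template tails 0.07 — 3'-end
  heterogeneity roughly twice the 5' rate, as observed in plant
  libraries), with templated extensions taken from the precursor;
* ncRNA degradation fragments and unannotated transcript fragments are
  drawn from a limited set of weighted processing hotspots — real
  degradation is position-biased, and bounding the unique-tag count
  keeps the full suite fast; junk (5'-adaptor contamination, poly(A),
  adaptorless, N-containing) enters at 3/3/2/1 % so the cleaner does
  real work; reads are 42 nt with the 3' adaptor appended;
* default depth is 10^5 raw reads per library — enough that every
  recovery statistic is stable while a full pipeline run takes about
  two minutes on one CPU. The same seed yields byte-identical FASTQ
  and truth manifests.

What passing these tests shows: the pipeline recovers what it is
specified to recover when reads follow its assumptions, with near-zero
false calls on shuffled decoys and random windows, and its statistics
match independent oracles. What it does not show: robustness to
sequencing error models beyond exact reads, biological overdispersion
(negative binomial counts), adapter variants, or the full sequence
diversity of a real degradome — real libraries are messier than the
generator in all these ways.

## Numerical and degenerate-input choices

* Sequence text is normalized to uppercase RNA on entry; all
  comparisons are case-insensitive at the boundary only.
* All tie-breaks (representative choice, best-hit assignment, locus
  deduplication, placement resolution) are total orders, so every
  output table is byte-identical across reruns and iteration orders.
* Empty inputs return typed empty results rather than errors; zero
  library size and negative counts are errors.
* The folding engine compares energies with a 1e-7 tolerance during
  traceback to absorb floating-point ties; test oracles compare at
  1e-8.
* Windows shorter than mature + 15 nt, and matures absent from their
  window, are rejected with named reasons rather than scored.

## Known limitations

Single library per condition (no replicate dispersion modelling — the
exact test is the appropriate tool for that design, and nothing more);
ungapped duplexes only in target prediction (bulged sites are
invisible); the embedded energy model is deliberately small, so
absolute MFE values should not be compared against other folders; no
genome-based discovery (intergenic miRNAs outside the transcriptome
cannot be found); A-to-I editing and SNP disambiguation of isomiRs are
out of scope.
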
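---
title: "Minicircle reconstruction and heteroplasmy analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minicircle reconstruction and heteroplasmy analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(minicircle)
```

This vignette documents the models, parameter choices, and numerical
conventions behind the package, in the spirit of a methods section: what
each stage computes, which knobs matter, and what the simulation-based
validation does and does not establish about real data.

## The biological setting

In lice with fragmented mitochondrial genomes, the *cox1* gene
(1,536 bp, 512 codons) can occur alone on a ~1.9-kb circular
minichromosome together with an isoleucine tRNA gene that overlaps the
gene start and a few hundred bp of noncoding sequence. The analysis
pipeline answers four questions about such a circle from Sanger-style
data: (1) is the gene on a circle, and how long is the circle;
(2) how much heteroplasmy — within-individual variation among genome
copies — do cloned amplicons reveal, and where; (3) does the noncoding
region carry inverted repeats consistent with an origin of replication;
and (4) which sequence blocks are conserved across related species.

## Circle reconstruction

An outward-facing primer pair amplifies the gene-external arc only when
the template is circular. `merge_amplicon()` therefore treats a
successful, doubly-anchored merge as the in-silico analog of circularity
evidence: the amplicon's leading bases must anchor inside the gene and
run to the gene's 3' end, and its trailing bases must match a prefix of
the gene. The reconstructed length is
`len(gene) + len(amplicon) − left_overlap − right_overlap`, and the
circle is rotated so the gene starts at position 0, which makes codon
arithmetic trivial (`codon position = pos mod 3 + 1`).

Anchors default to `min_overlap = 20` bp with zero mismatches: the
amplification primers are 21–22-bp exact subsequences of the gene, so
shorter or fuzzier anchors would only admit spurious placements. If an
anchor matches at several gene positions the merge fails with an
ambiguity error listing the candidates; a deterministic failure was
preferred over any tie-breaking heuristic because a mis-anchored circle
silently corrupts every downstream coordinate.

`length_bookkeeping()` checks the component identity
`gene + tRNA − overlap + noncoding = circle length` (e.g. 1,536 + 68 −
6 + 316 = 1,914 for the larger of the two organizations shipped as
simulator presets, and 1,536 + 65 − 3 + 307 = 1,905 for the smaller;
under the tetranucleotide-start reading the latter is equivalently
1,537 + 65 − 4 + 307).

## Coordinates and the genetic code

All coordinates are 0-based and half-open internally; GFF3 output
converts to 1-based inclusive, and features crossing the circle origin
use the standard circular-genome convention of an end coordinate beyond
the sequence length. A wrap-aware `interval` type (with `end < start`
denoting an origin-crossing span, and `end == start` the full circle)
keeps the arithmetic unambiguous.

Translation uses NCBI table 5 (invertebrate mitochondrial: ATA→M,
TGA→W, AGA/AGG→S; stops TAA/TAG). Codons containing IUPAC ambiguity
codes translate to `X`, and ambiguous bases are likewise excluded from
heteroplasmy calls and p-distances — uncertain base calls should never
create variation.

`classify_start()` distinguishes a standard ATG/ATA start (frame 0 free
of internal stops) from two atypical readings of an `ATGT...` gene: a
4-bp tetranucleotide start (the offset-1 frame is stop-free while frame
0 is not, as expected if mRNA editing removes the fourth base) and a
cysteine TGT start read from residues 2–4. The two atypical readings are
the same DNA in the same frame and differ only in interpretation, so an
ATGT classification always reports the cysteine reading as the
alternative. A standard classification additionally requires the frame-0
reading to be stop-free; the first three bases of an `ATGT` gene are
`ATG`, so the naive first-codon test alone would misclassify every
tetranucleotide start.

## Clone mapping and heteroplasmy

Clones of the same amplicon are >98% identical to their reference, so a
progressive multiple alignment adds nothing over per-clone global
alignment to the reference arc — and reference mapping is deterministic
and testable against a brute-force oracle. The aligner is an affine-gap
Gotoh dynamic program (compiled; a gap of length L costs
`gap_open + L × gap_extend`, defaults +2/−1/−4/−1) with a fixed
traceback tie order (diagonal, vertical, horizontal). Clones aligning
below 60% identity are excluded with a warning rather than silently
polluting the matrix.

The result is a reference-coordinate column matrix: one column per
reference position, holding each clone's base or a deletion gap;
insertions relative to the reference are stored as separate records
because they have no reference column. A heteroplasmic site is a column
with ≥2 distinct unambiguous bases; a column like {A×24, G×1, T×1}
counts as one site. Indel events are tallied separately from
substitution sites, mirroring how clone alignments distinguish
"differences in nucleotide composition" from insertion/deletion events.

Conventions worth making explicit:

- **Surveyed bp** is the reference length covered by *all* clones
  (leading/trailing alignment gaps are uncovered; internal gaps are
  deletions and count as covered). The rate statistic
  `sites / (clones × surveyed bp)` is only comparable across studies on
  such a common denominator.
- **Gene/tRNA overlap** sites are reported as region `overlap` and enter
  both the coding codon-position tallies and the tRNA tally, with the
  double counting flagged — published tallies do not state how overlap
  bases are attributed, so the report keeps both views.
- **Rounding** is half-up: 4 decimals for the rate, 1 decimal for
  sites/clone and error expectations. Base R's `round()` is
  round-half-even and would print 0.0016 where 0.0017 is expected.
- **Frameshifts** are flagged per clone when the net indel length inside
  the gene is not divisible by 3; the truncated-protein length is the
  codon count before the first stop in the shifted frame, evaluated over
  the covered gene sequence.
- **Replacement substitutions** are called codon-by-codon over fully
  covered, gap-free codons of non-frameshifted clones; a substitution is
  "unique" when its (position, amino acid) pair occurs in exactly one
  clone.

## Inverted repeats

`find_inverted_repeats()` runs a Smith–Waterman-style local alignment of
the sequence against its own reverse complement with einverted-style
scoring — match +3, mismatch −4, a linear penalty of 5 per gap position,
minimum reported score 15 — restricted to the triangle where the two
aligned segments (the arms) are disjoint and ordered. A perfect
palindromic arm of length a scores 3a, so the detection threshold is
exactly a ≥ 5. Circular sequences are scanned on a doubled linearization
with duplicates (arm-1 start beyond the original length) discarded.

Every cell reaching the threshold is a candidate hit; reported hits are
selected greedily by descending score (ties: ascending arm-1 start, then
ascending region span), dropping candidates whose arms overlap an
already selected hit's arms. Arm-based (rather than whole-region)
suppression lets nested, genuinely distinct repeats survive while
collapsing overlapping variants of one repeat. Since random sequence of
this length legitimately contains chance repeats above threshold,
`suppress_overlaps = FALSE` exposes the full candidate list; the
validation suite uses it to assert exact recovery of planted repeats
independently of what chance neighbors the greedy pass collapses.

Because the "region" length of an inverted repeat is reported in the
literature without a stated definition, hits carry both the arm lengths
and the total region span (arm-1 start through arm-2 end).

## Conserved blocks

Cross-species comparison aligns gene to gene with the default
parameters, and noncoding to noncoding with a gentler preset (+1/−1,
open −2, extend −1), since noncoding regions of related species may
align only weakly; the noncoding identity is reported as exploratory.
Percent identity is matched columns over all columns (gaps count as
mismatches), rounded to integer for reporting. `find_identical_blocks()`
extracts maximal runs of gap-free identical columns of at least 10 bp —
long enough to exclude most chance 6–8-mers while capturing the 10–23-bp
blocks of interest — and `universal_blocks()` marks a block universal
when every clone column inside it is uniform and equal to the reference
in both species (undetermined when the block lies outside a cloned
region).

## Clone trees

Distances are p-distances (mismatched bases over columns where both
rows carry unambiguous bases): clone divergence is far from saturation,
so a substitution model would add parameters without information, and
the natural scale is simply substitutions per site.
`neighbor_joining()` implements the Saitou–Nei agglomeration with a
deterministic tie-break (smallest index pair), clamps negative branch
lengths to zero with a warning, and returns an `ape` `phylo` with a
trifurcating root, serialized as Newick. The test suite checks exact
recovery of additive distance matrices for 4–10 leaves against the
generating trees and against `ape::nj`.

## The simulator

The simulator is the package's acceptance surface: every analysis stage
is validated against planted ground truth. `sim_config()` defaults
describe the canonical organization — 512 stop-free codons plus terminal
stop, a 68-bp tRNA overlapping the gene start by 6 bp, 316 bp of
noncoding sequence, a planted inverted repeat with 10-bp arms spanning
91 bp, and conserved motifs of 19 and 11 bp placed 19 bp after the stop
codon and 15 bp apart, mirroring reported spacings. Clones cover the
cloned arc (gene flanks totalling 591 coding bp, the noncoding region,
and the tRNA); substitutions are drawn independently per site per clone
at region-specific probabilities; noncoding positions initiate indels
(lengths uniform on 1–8 bp) at a per-bp rate; a configured number of
clones receive a 1-bp coding indel (alternating deletion/insertion).

Default rates: `p_coding = 0.0017` equals the observed per-bp-per-clone
coding heteroplasmy; `p_trna = 0.0012` reproduces the scale of the
observed tRNA tallies (2–3 sites); `p_noncoding = 0.01` and
`indel_rate = 0.004` per bp (~1.3 indel events per clone) are free
parameters chosen so that noncoding variation clearly dominates coding
variation and clone noncoding lengths vary over a 15–25-bp range, both
qualitative features of the real clone sets. No empirical noncoding
per-site rate is available to calibrate against, so these two values are
design choices, not estimates.

Identifiability choices: planted motifs and repeat arms are excluded
from mutation (otherwise "universal" ground truth would be false by
construction); the bases flanking the planted arms are set to
non-pairable values (A/A outside, C/C inside — neither self-pairs, and
A–C is not a Watson–Crick pair) so chance complementarity cannot blur
the planted arm boundaries; indels initiate only in the noncoding
interior, at least `indel_max` bp from a region boundary, because a gap
placed inside a boundary-spanning homopolymer is positionally ambiguous
and could otherwise be attributed to the wrong region; and the planted
coding indel avoids the terminal arc columns, where a cloned read cannot
distinguish an indel from a shorter insert. `generate_minicircle_pair()`
derives a second species at ~24% gene and ~45% noncoding per-site
divergence (targeting the reported ~76% gene and ~55% noncoding
cross-species identities), keeping the planted motifs and one 23-bp gene
block identical, with mismatches pinned at block flanks so planted block
coordinates are exact.

What passing on simulated data does *not* establish: the substitution
model is i.i.d. per site (no recombination between circles, no PCR
chimeras, no site-rate heterogeneity), clones differ from their
reference far less than real clones from a different individual would,
and real noncoding length variation includes structured repeats rather
than uniform random indels. The pipeline's statistics are deliberately
simple counts, so these simplifications affect realism, not the
correctness properties being tested.

## Numerical and testing notes

- Problem sizes in the test suite are chosen to keep the full run within
  a few minutes on one CPU: brute-force alignment enumeration on 8-mers,
  exhaustive bounded-gap inverted-repeat search on 60–80-mers (50
  seeds), neighbor joining on 4–10 leaves, and 20 simulated 30-clone
  experiments for rate recovery.
- The inverted-repeat oracle enumerates all disjoint ordered arm pairs
  whose alignment has at most k gap positions, escalating k from 2 to 4
  when needed: random 60–80-mers occasionally have optima with 3–4 gap
  positions, and a bounded-gap search is a strict lower bound on the
  unbounded DP, so the test asserts the bound at every step and equality
  at the final k.
- The expected number of called coding sites in a simulated experiment
  is `591 × (1 − (1 − p)^n)` — a site is called as soon as one of n
  clones mutates — which for small p is close to, but below, the linear
  approximation `591 × n × p`; the recovery test uses the exact form.
- Determinism: the generator seeds R's RNG from `seed` (and `seed + 1`,
  `seed + 2` for the clone and species-pair stages so each is
  reproducible standalone); repeated pipeline runs with equal seeds are
  byte-identical, which the suite asserts.

## Known limitations

- `merge_amplicon()` assembles exactly two junctions; multi-fragment
  assembly, quality-aware merging, and detection of a co-occurring
  full-length chromosome are out of scope.
- tRNA annotation is accepted as given (GFF3 or simulator); the package
  does not predict tRNA genes.
- Reference mapping assumes clones are minor variants of the reference
  arc; at the 60% identity floor the reference-coordinate matrix loses
  meaning, and highly diverged clones should be excluded upstream.
- The inverted-repeat scan reports sequence symmetry only; it does not
  fold hairpins or assess replication function.
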
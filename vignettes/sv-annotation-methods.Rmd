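---
title: "Annotating sequence-resolved structural variants: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating sequence-resolved structural variants: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`svkit` reconstructs the origin of a structural variant (SV) from its
resolved allele sequence. This vignette is the package's own account of the
models it implements, the thresholds it uses and why, what the synthetic
truth sets emulate, and where the methods' limits are.

## Coordinate and allele conventions

Internally every interval is 0-based, half-open; VCF's 1-based anchored
representation is converted at the I/O boundary only. SV type is derived
from allele lengths: REF longer with a 1-bp ALT is a deletion, the converse
an insertion, both alleles longer than 1 bp a complex (putatively
multi-part) record. Symbolic ALT alleles carry no sequence and are flagged
unresolvable rather than typed. Multiallelic records are split into
per-allele records at parse time and re-joined on writing.

## The retrotransposition model

A canonical target-primed reverse transcription (TPRT) insertion leaves
three signatures that the annotator detects in order:

1. **Target site duplication.** The longest exact terminal match between an
   insert end and the immediately adjacent reference flank (insert prefix
   versus downstream flank, or insert suffix versus upstream flank),
   searched up to 50 bp. Both pairings arise from equivalent left/right
   placements of the same insertion, so both are evaluated; ties resolve
   toward the longer match, then the 3′ end. The 50-bp bound and the tie
   rule are implementation choices (real TSDs are 5–30 bp) that keep the
   search deterministic.
2. **Poly(A/T) tail.** The longest window within 50 bp of an insert end
   with at least 10 bases and ≥90% of the tract base, required to start and
   end on the tract base. Purity is defined as the tract-base fraction of
   the window; the boundary-trimming requirement exists because a window
   padded with terminal non-A bases is not a meaningful tract and would
   otherwise outgrow the true tail. A 5′ poly(T) stronger than any 3′
   poly(A) indicates a minus-strand integration; the insert is
   reverse-complemented so that all downstream logic sees forward-oriented
   bodies.
3. **Transduction.** After trimming the outer tail, a second qualifying
   poly(A) splits the body; the sequence 3′ of it is the candidate
   transduced segment. The segment is traced against the genome with the
   package's seed-and-extend aligner and accepted when at least 80% of it
   aligns at a confident placement; below that the candidate is demoted to
   a solo insert. Segments shorter than the seed length are recorded as
   transductions with an unknown source.

The trimmed core is then decomposed against a consensus-element database
and (when needed) the reference genome, and the optimal chain of
non-overlapping alignments feeds the ≥75% classification rules, applied in
fixed precedence: processed pseudogene (exonic reference coverage), 5′
partnered transduction (genomic 5′ segment plus element consensus), 3′
partnered transduction, orphan transduction (non-exonic reference
coverage), solo element (single consensus family), solo-LTR/ERVK
(retroviral database; LTR alone versus LTR plus internal sequence), NUMT
(mitochondrial coverage, with the mitochondrial reference treated as
circular so origin-spanning inserts report two wrapped fragments), and
non-canonical MEI (element coverage without the canonical structure). The
precedence runs from most specific structure to least; it is a design
choice of this package — every rule an insert satisfies is also recorded so
a conflict is auditable. Canonical status requires a terminal tail plus a
TPRT-compatible element structure: colinear components with an intact 3′
end; a minus-strand 5′ component followed by plus-strand components is the
twin-priming signature and remains canonical. Non-canonical flags record 3′
truncation, missing poly(A) and internal rearrangement.

L1 subfamily diagnostics read consensus positions 5929–5931 (`ACG` pre-Ta,
`ACA` Ta) refined at 5535/5538 (`G`,`C` Ta-0; `T`,`G` Ta-1); uncovered
positions or other profiles leave the subfamily undetermined. The positions
refer to the consensus the database ships; a user-supplied consensus must
preserve that coordinate frame.

## The alignment engine

All classification alignments go through one in-package seed-and-extend
engine: exact k-mer seeds (rolling-hash index, cacheable per target via
`index_targets()`) grouped by diagonal, merged into runs, extended under an
X-drop criterion and trimmed to the maximal-scoring subsegment (+1 match,
−2 mismatch), so one spurious seed cannot drag a hit across a
non-homologous gap. Hits are gapless by construction; allele-internal
indels surface as separate chain segments, which is what the decomposition
logic expects. Placement confidence (`uniqueness`) is the score margin over
the best alternative placement covering half the same query interval — a
contract-level surrogate for an aligner-specific mapping quality, default
threshold 10. Classification passes ignore hits shorter than 25 bp; such
fragments carry no assignment signal and would otherwise let repetitive
alleles tile themselves onto unrelated targets.

Chaining solves weighted interval scheduling exactly by dynamic
programming: maximal covered query bases, then fewest hits, then highest
summed score; consecutive hits may overlap by ≤10 bp. An exhaustive
enumerator over all valid chains (`chain_best_exhaustive`) serves as the
independent optimum in the test suite.

## Tandem repeats and duplications

The tandem-array detector proposes periods from the lagged self-match
vector `seq[i] == seq[i+p]`, segments it into high-agreement blocks, trims
each block to its maximal-scoring subsegment and scores the block against a
majority-vote motif consensus; blocks whose consensus disagrees (which
happens when adjacent arrays with divisible periods fuse in the self-match
vector) are split recursively at the disagreement boundary. Motifs are
reported in lexicographically minimal rotation so rotation-equivalent
arrays compare equal. Arrays shorter than 10 bp or with fewer than two
copies are suppressed as chance repeats. The detector is implemented
in-package so the module is testable in isolation; its contract is fixed by
brute-force oracles on short strings, not by any external tool's exact
output.

VNTR alleles chain their arrays and classify simple (≥75% of the allele
under one motif) or complex (≥75% under more than one). Duplications align
the insert against ±2 kb of the breakpoint: ≥75% forward coverage is a
tandem duplication, ≥75% reverse is inverted, and ≥75% combined with both
orientations contributing is complex. When an allele qualifies as both
VNTR and duplication the callset driver lets the VNTR rules win, since an
array of two or more motif copies is the more specific description.

## Breakpoint junction mechanics

Two measurements are made per deletion/insertion:

* **Microhomology** — the maximal exact junction-spanning match (sum of
  left and right extensions), computed directly on the sequence and capped
  at 50 bp; for insertions only the first and last 50 bp of the insert are
  probed, which is why the cap exists. A character-loop reference
  implementation validates the vectorized one on 10⁴ simulated SVs.
* **Windowed homology scan** — insertions are first implanted into their
  contig so both junctions exist on one sequence; then co-directional local
  alignments are sought between window pairs around the two breakpoints:
  symmetric paddings of 50, 100, 200, 400, 1000, 2000, 5000 and 10000 bp
  (pairs that would overlap are skipped) and asymmetric SV-length windows
  shifted in sixths. A passing alignment must span both breakpoints at the
  same relative position (±5% of the alignment length, with a small
  boundary slack because mismatch trimming can start an alignment a few
  bases past a junction that falls on a mutated arm base). The longest
  passing homology across configurations is reported; scanning stops early
  once an alignment lies strictly inside its windows, since larger windows
  cannot extend it. Homologies under 16 bp are microhomology territory and
  left to the first measurement.

The reported homology length is the larger of the two measurements; both
are retained, since in the 16–49 bp range they can legitimately disagree.
Mechanism labels bin that length — blunt, 1–15 (NHEJ/alt-EJ/MMBIR), 16–49
(homology-independent), ≥50 (HDR), ≥200 (NAHR, the more specific label
inside the HDR range) — with VNTRs, tandem duplications and MEIs excluded,
because their flank homology is allele-structural rather than mechanistic.
Repeat mediation requires ≥85% of both homology arms covered by same-class
annotations and one arm spanning ≥85% of its element; SD mediation requires
an SD covering >85% of an arm across >200 bp or ≥50% of the SD.

## Transduction source atlas

Traced source alignments are padded ±10 kb and merged transitively into
source regions; each region intersects a database of full-length elements
(L1 longer than 5.9 kb, SVA longer than 1 kb; reference annotations plus
full-length non-reference insertions). With several candidates the element
nearest the centroid of the member alignments is chosen — the ambiguity
rule is this package's choice and ties are flagged. Loci with at least five
non-orphan transductions receive an exact two-tailed binomial test of the
5′ proportion against 0.5 and Benjamini–Hochberg adjustment across tested
loci; bias is called at adjusted p < 0.05 toward the majority side. The
null proportion is configurable because a family-wide background other than
0.5 is a defensible alternative; 0.5 is the default as the symmetric null.

## Graph augmentation support

Centromere-masked regions are replaced by Ns (lengths preserved) and
intersecting calls dropped — any intersection, not only full containment,
since a partially masked allele cannot be implanted faithfully. The callset
is partitioned into non-overlapping groups by first-fit over records sorted
by position; insertions occupy a 1-bp point so same-position insertions
separate. First-fit on sorted intervals is depth-optimal, so the group
count equals the maximum overlap depth — verified against a sweep-line
oracle. Each group implants right-to-left into the reference, guarded by
REF-allele checks against stale coordinates, and emits a coordinate map
under which every implanted allele re-extracts exactly. Records assembled
from one contig merge into a single spanning record by inserting the
intervening reference into both alleles. Bubbles of an augmented graph
count as novel at ≥1 kb from the nearest original bubble.

## Deletion recurrence screen

Candidate deletions are shorter than 5 kb with flanking homology between
200 and 9,000 bp, allele frequency 40–60%, phased, and passing
Hardy–Weinberg and Mendelian screens. A recurrence-indicating SNP has MAF
≥10%, lies within a 20-kb window centred on the deletion (outside the
deleted interval), and shows all four combinations of SNP allele ×
deletion state. Haplotypes cluster on SNPs in a 100-kb window with centroid
linkage on the normalized Hamming distance (the squared Euclidean distance
of binary haplotypes, which is what centroid linkage expects); because
centroid linkage can produce height inversions, flat groups are formed by
uniting all merges below the cut rather than by a monotone tree cut. The
default cut (0.2, the fraction of window SNPs differing) separates deeply
divergent backgrounds while ignoring private variation; it is configuration,
not a fitted constant. The automated verdict — `supported` when qualifying
SNPs flank the deletion on both sides *and* carriers occupy at least two
haplotype groups — is a proxy for what would otherwise be manual
inspection, and the per-cluster consensus table is emitted so a human can
audit each call.

## The synthetic study conditions

The generator (`simulate_genome`, `synthetic_consensus_db`,
`implant_truth_svs`, `simulate_recurrence_panel`) defines the conditions
under which the package verifies itself:

* Genomes are i.i.d. base sequences at 41% GC (the human average); 5 Mb for
  the MEI recovery set, 2–3 Mb elsewhere — large enough for unique
  transduction donors and well-separated implant sites at realistic scale,
  small enough to annotate in minutes.
* Consensus elements are random-sequence stand-ins at realistic lengths
  (300-bp Alu, 6-kb L1 with the diagnostic positions planted, three SVA
  components, 400-bp LTR, 2-kb ERVK internal, 3-kb circular mitochondrial
  stand-in). They are constructed without internal poly(A/T) tracts and
  with A/T-free 12-bp terminal guards, and transduction donors are sampled
  so an appended tail remains the maximal qualifying tract. These
  guards make every planted feature *maximal in its sequence context*, so
  a truth label such as "tail length 25" is a property of the constructed
  sequence itself, not of any detector.
* The MEI recovery mix implants 200 canonical elements: Alu/L1/SVA
  uniformly, TSDs 5–30 bp, tails 10–40 bp, both orientations and both TSD
  placements, 15% 5′ truncations, 15% twin-priming inversions, 15% 3′ and
  5% 5′ transductions of 50–500 bp.
* Junction constructs plant arm pairs of 100 bp–5 kb at identities
  0.85–1.0, blunt junctions and exact microhomologies of 1–45 bp, with
  matching repeat/SD tracks for the mediation rules.
* Recurrence panels draw two random ancestral haplotype cores, copy them
  with Poisson(1) private mutations per haplotype, and plant the deletion
  on one or both backgrounds at 50% frequency. Private mutations sit below
  the 10% MAF filter by construction, so single-origin panels cannot
  produce qualifying SNPs through them alone; the cluster condition
  provides a second, independent safeguard.

What passing these conditions does **not** show: performance on real
genomes with segmental duplication context, nested or degraded elements,
diverged non-consensus subfamilies, sequencing artefacts in the alleles, or
population structure in the panels. Real inputs also require real consensus
databases and annotation tracks, which are user-supplied configuration.

## Numerical choices and degenerate inputs

Alignment identity thresholds default to 0.8 (0.85-identity constructs
still pass because identity is measured on trimmed hits). Allele divergence
for duplicate marking is unit-cost edit distance normalized by the longer
allele. Empty callsets, empty masks, single-haplotype panels, constant
panels and contig-edge windows all degrade to defined results rather than
errors; REF mismatches and out-of-bounds masks are hard errors because
they indicate stale coordinates. Every stochastic routine takes an explicit
seed and routes it through one RNG scope, so equal seeds give bit-identical
outputs.

## Verification scales

The test suite and `scripts/acceptance.R` run: 200 implanted MEIs in 5 Mb
plus 10³ random 1-kb sequences; 12 subfamily rule cases; 10⁴ simulated
junctions against the microhomology reference; 42 junction constructs; 100
VNTR/duplication constructs; 10³ random chaining instances (≤12 hits)
against exhaustive search; 10³ random callsets for pseudo-haplotype depth
and round trips and 10³ for duplicate-marking/matching oracles; 200
bias-test replicates; 10³ single-origin and 10² dual-origin recurrence
panels. These sizes keep a full run within minutes on one CPU while leaving
each estimate's sampling error well below the margins being asserted.
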
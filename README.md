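# svkit

Sequence-resolved structural variant (SV) annotation and formation-mechanism
inference for long-read callsets.

Long-read sequencing resolves SV alleles to the base, which makes it possible
to read an SV's *history* out of its sequence: a mobile element insertion
(MEI) carries a poly(A) tail, a target site duplication (TSD) and a
recognizable element body; a retrotransposon transduction carries a unique
genomic segment downstream of a second poly(A); a VNTR allele is a tandem
array; an NAHR deletion is flanked by a homologous repeat pair. `svkit`
implements the annotation machinery that performs these reconstructions, for
people building or curating population-scale SV resources:

* **MEI classification** — per insert allele: TSD and poly(A/T) tail
  detection, orientation normalization, 3′/5′ transduction detection with
  source tracing, decomposition of the trimmed insert against consensus
  elements and the reference, and class assignment by ≥75% coverage rules
  with fixed precedence (processed pseudogene → 5′ partnered transduction →
  3′ partnered transduction → orphan transduction → solo Alu/L1/SVA →
  solo-LTR/ERVK → NUMT → non-canonical MEI). L1 subfamilies are read from
  diagnostic consensus positions 5929–5931 (ACG: pre-Ta; ACA: Ta) and
  5535/5538 (G,C: Ta-0; T,G: Ta-1).
* **VNTR and duplication rules** — an in-package tandem-array detector
  (k-mer autocorrelation plus consensus scoring) feeds the ≥75% simple /
  complex VNTR rules; duplications classify as tandem / inverted / complex
  from the strandedness of insert alignments within ±2 kb of the breakpoint.
* **Breakpoint junction mechanics** — exact junction microhomology (capped
  at 50 bp) plus a windowed homology scan (symmetric paddings 50 bp–10 kb
  and SV-length windows shifted in sixths; alignments must span both
  breakpoints at the same relative position). Homology length `h` is binned:
  `h = 0` blunt, `1–15` NHEJ/alt-EJ/MMBIR, `16–49` homology-independent,
  `≥50` HDR, `≥200` NAHR. Repeat mediation requires ≥85% of both homology
  arms in same-class annotations with one arm spanning ≥85% of its element;
  SD mediation requires an SD covering >85% of an arm over >200 bp or half
  the SD.
* **Transduction source atlas** — traced transductions cluster into source
  loci (±10 kb buffer, transitive merge), progenitors assign from
  full-length elements (L1 > 5.9 kb, SVA > 1 kb), and each locus with ≥5
  non-orphan transductions gets an exact two-tailed binomial 5′/3′ bias
  test with Benjamini–Hochberg correction.
* **Graph augmentation support** — centromere masking, greedy depth-optimal
  partitioning of a callset into non-overlapping groups, pseudo-haplotype
  FASTA construction with exact coordinate maps, merging of multi-record
  assemblies, and novel-bubble accounting (≥1 kb to the nearest original
  bubble).
* **Deletion recurrence screen** — shortlists deletions (<5 kb, flank
  homology 200–9,000 bp, allele frequency 40–60%, phased, passing
  Hardy–Weinberg/Mendelian screens), finds recurrence-indicating SNPs
  (MAF ≥10% within a 20-kb window showing all four SNP-allele × deletion
  combinations), clusters local haplotypes (centroid linkage, 100-kb
  window) and calls a deletion's recurrence `supported` when qualifying
  SNPs flank it on both sides and carriers occupy ≥2 haplotype groups.
* **Callset utilities** — duplicate marking (size ratio > 0.5, divergence
  ≤ 30%, breakpoint offset ≤ 500 bp, shared carriers ≥ 10%), callset
  matching (ratio ≥ 0.8, offset ≤ 50 bp, divergence ≤ 10%) and trio
  Mendelian-consistency statistics.
* **Synthetic truth sets** — a seeded generator implants every allele
  architecture above into random genomes with exact ground-truth labels, so
  every classifier is testable without external data.

## Worked example

```r
library(svkit)

genome <- simulate_genome(5e5, seed = 5)
db     <- synthetic_consensus_db(2)
fx <- implant_truth_svs(genome, list(
  list(type = "mei", family = "L1", tsd_len = 15, tail_len = 25,
       orientation = "-", tsd_end = "3p", trunc5 = 500, twin = 0,
       td_side = NA, td_len = 0),
  list(type = "mei", family = "SVA", tsd_len = 8, tail_len = 30,
       orientation = "+", tsd_end = "3p", trunc5 = 0, twin = 0,
       td_side = "3p", td_len = 250)
), seed = 7, db = db)

ann <- annotate_inserts(fx$records, fx$genome, db)
ann[, c("id", "class", "tsd_len", "tail_len", "td_side", "subfamily")]
#>      id           class tsd_len tail_len td_side subfamily
#> 1 sv001         solo_L1      15       25    <NA>      Ta-1
#> 2 sv002 partnered_td_3p       8       30      3p     SVA_E
```

The 5′-truncated, minus-strand L1 is re-oriented, its 15-bp TSD and 25-bp
tail are trimmed and measured, and the Ta-1 subfamily is read from the
diagnostic consensus positions; the SVA insert's second poly(A) exposes a
250-bp transduced segment that is traced back to its donor locus (`td_side
= "3p"`).

Junction mechanics on a repeat-pair-mediated deletion:

```r
fx2 <- implant_truth_svs(simulate_genome(1e6, seed = 5), list(
  list(type = "del_repeat_pair", arm_len = 300, arm_identity = 0.92,
       del_len = 800, track_mode = "same_class", sd = FALSE)
), seed = 3)
annotate_junctions(fx2$records, fx2$genome,
                   repeat_track = fx2$tracks$repeats)[,
  c("id", "hom_len", "microhomology", "hom_class", "mechanism",
    "mediating_repeat")]
#>      id hom_len microhomology      hom_class mechanism mediating_repeat
#> 1 sv001     300            22 homology_ge200      NAHR           AluSyn
```

The deletion's flanking 300-bp arm pair (planted at 92% identity) is
recovered at its exact length, binned as NAHR, and attributed to the
annotated repeat class.

A command-line front end over the same functions ships in
`inst/cli/svkit.R` (`annotate`, `junctions`, `dedup`, `match`, `trio-check`,
`atlas`, `build`, `recur`, `synth`, `pipeline`).

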
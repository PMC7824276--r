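---
title: "Methods: gene-order comparison and compositional bias in mitogenomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-order comparison and compositional bias in mitogenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitorder)
```

mitorder implements the comparative analyses that recur in mitogenome
surveys of invertebrates, developed with springtails (Collembola) in mind:
architecture summaries of newly assembled genomes, detection and
classification of gene-order rearrangements against the ancestral
Pancrustacea arrangement, and strand/codon-position-partitioned nucleotide
skew analysis. This vignette records the models, conventions and numerical
choices behind each stage, and what the accompanying synthetic-data
generator does and does not emulate.

## The genome model and its conventions

A mitogenome is a circular DNA molecule carrying 13 protein-coding genes
(PCGs), 22 tRNAs, 2 rRNAs and one non-coding control region (the A+T-rich
region). Annotations from public records use heterogeneous names; every
feature is mapped at the I/O boundary onto a closed vocabulary
(`gene_vocabulary()`) by a deterministic synonym table. The two leucine
and two serine tRNAs are only resolved when an anticodon or a codon-family
suffix disambiguates them — an ambiguous `tRNA-Leu` stays unmapped with a
warning rather than being guessed, because a wrong leucine assignment
would silently corrupt gene-order comparisons. Annotation curation in the
source literature is a manual step; the synonym table is the automatable
part of it, and unmappable features are kept (with a null gene key) so
they remain visible in logs.

Strand labels follow the majority-strand convention: **J** is the strand
encoding `cox1`, **N** the other. Tying J to a concrete gene rather than
to the deposited orientation makes every downstream quantity invariant to
which strand a record happens to be deposited on; a genome deposited
"flipped" yields byte-identical gene orders and skew tables (this is
tested). Coordinates are 0-based half-open internally and converted from
GenBank's 1-based inclusive intervals only at the boundary, which keeps
interval arithmetic (spacers, overlaps, origin wrapping) free of ±1 cases.

Duplicate annotations for one gene are an error by default (overridable to
keep-first with a warning), mirroring the practice of discarding truncated
duplicate genes during curation rather than merging them silently.

## Architecture summaries

Start codons are read as the first three mRNA-sense bases of each CDS.
ATA/ATG (methionine) are canonical; TTG (leucine) is the common
alternative; ATT/ATC (isoleucine) are kept as their own class rather than
pooled into "other", so either roll-up convention can be derived from the
table. Stop codons are whatever trails after removing complete codons: a
CDS length of 1 or 2 mod 3 implies a partial stop (`T`/`TA`), the
truncated terminator completed to UAA by polyadenylation — the standard
metazoan convention; the term is used without definition in much of the
literature, so the package pins it to exactly this rule.

Junction analysis sorts features by circular start position and reports
each adjacent gap as a spacer (≥ 1 bp) or overlap (≤ −1 bp), including the
pair wrapping the origin; abutting genes produce no row. A feature nested
wholly inside another is reported as an overlap of the inner length with a
warning, since no spacer interpretation exists. On a fully annotated
circle, feature lengths plus spacers minus overlaps tile the molecule
exactly — an invariant in the test suite.

Whole-molecule composition is counted on the deposited strand (surveys
report a single per-genome value, consistent with one-strand counting);
IUPAC ambiguity codes, including N, are excluded from both the counts and
the percentage denominator. Percentages are rounded to one decimal, the
precision at which they are conventionally quoted.

## Gene orders and rearrangement detection

A gene order is a circular signed sequence of (gene, strand) pairs. All
orders are held in a canonical frame: rotated so the anchor gene is first
and oriented so the anchor is on J. The anchor is `cox1` — present in
every genome of the comparative sets this package targets — with a logged
fallback to `cob`, then `rrnL`, then the alphabetically first gene. The
canonical frame makes "equality up to rotation" a plain vector comparison
and fixes the reference frame for displacement attribution.

`compare_orders()` decomposes the difference between a query and a
reference into:

* **deleted / inserted** — set differences of the gene sets (the control
  region is never reported deleted, because it is frequently
  unannotatable rather than absent);
* **inverted** — genes whose strand differs (a strand flip can never be
  part of a signed common subsequence, so these are necessarily
  displaced);
* **translocated** — genes outside a longest common subsequence (LCS) of
  the signed sequences whose strand is unchanged;
* **breakpoints** — signed adjacencies of the reference absent from the
  query (an adjacency survives as itself or as its reverse complement).

The LCS is computed by dynamic programming with an additive three-part
score compared lexicographically: (1) number of genes kept, (2) number of
PCG + rRNA genes kept, (3) a tie value of −2^−rank(gene) per kept gene,
rank being the alphabetical position. Criterion (2) encodes the
biological prior that large genes are reliably placed while tRNAs jump;
criterion (3) makes the *displaced* set the lexicographically smallest
among the optima — sums of distinct powers of two compare exactly like
sorted sets, so a sum-based (hence DP-compatible) score implements a true
set ordering. The source literature names no algorithm (its assignments
are descriptive); the heuristic is instead validated against a
brute-force minimal-removal oracle on signed circular orders of up to 8
genes, and by exact recovery of seeded random edit scripts (200 scripts of
up to 3 well-separated edits) on the full 38-element order. Both checks
run in the test suite and in `scripts/acceptance.R`; exhaustive
enumeration of *all* signed 8-orders is combinatorially out of reach, so
agreement is sampled under a fixed seed.

Displacement attribution has genuine ties: moving gene X next to gene Y's
ancestral neighbour can equally be read as moving Y. The tie-break above
resolves them deterministically, and the edit-script sampler used for the
recovery properties enforces the separation conditions (pairwise
non-adjacent edit footprints, translocation distance ≥ 2) under which no
tie arises.

### The model catalog

`load_catalog()` ships the named springtail gene-order models: the
ancestral Pancrustacea arrangement (fully specified from the literature),
derived models whose complete arrangement follows from their description
(Tetrodontophora, Sminthurinus, GO A, GO D, Trogolaphysa, Seira sp. 3)
and signature-only models whose descriptions name the moved genes but not
their destinations (Podura, GO B, GO C, Sminthurus, Allacma, Lipothrix,
Seira paraibensis, Pseudachorutes). Four encodings deserve a note, all
flagged as interpretations:

* *Tetrodontophora*: the translocated `trnS2`/`trnQ` pair is placed after
  `trnW`. Destinations are unreported; placing the pair next to `trnI`
  (`trnQ`'s ancestral neighbour) would make the moved set formally
  ambiguous ({trnS2, trnQ} vs {trnS2, trnI}), so the encoding uses a
  position where recovery is unique.
* *Sminthurinus*: "inversion between trnA and trnR" is encoded as
  inversion of the two-gene block.
* *GO A*: the five relocated tRNAs are encoded in the listed order
  between the control region and `trnI`, with the `trnF–trnE–trnS1`
  block strand-flipped.
* *Trogolaphysa*: the resulting `trnE-trnN-trnA-trnR` arrangement is
  encoded with `trnE`/`trnN` strand-flipped (the inversion reading of
  its description).
* *Pseudachorutes* is catalogued but never auto-matched: its description
  ("translocations involving protein-coding genes") is too vague for a
  deterministic signature.

`classify_order()` assigns, in order: **exact** (equal to a fully
specified model up to rotation; a missing control region never blocks
this), **compatible** (incomplete genome whose observed genes match a
model after removing its missing genes; fewest missing genes wins, ties to
the base model then catalog order), **signature** (rearrangements
relative to the base order equal a described edit signature, with
optional genes allowed as deleted or translocated — e.g. the unresolved
trnY of the Podura model), else **novel**. The `signature` level is an
extension of the classical exact/compatible/novel triage: without it,
genomes matching a described but destination-free model would be
indistinguishable from genuinely new arrangements. Missing genes are
treated as missing, not deleted, mirroring cautious "compatible"
assignments in curated tables.

## Compositional bias

Skews are AT-skew = (A − T)/(A + T) and CG-skew = (C − G)/(C + G) over a
base multiset; a zero denominator gives an undefined skew, encoded as
missing and excluded from downstream analysis, never as 0.

Coding bases are pooled per genome into eight strand-by-position classes:
J1/N1, J2/N2 (first/second codon positions), and third positions split by
synonymous-family size under the invertebrate mitochondrial code
(translation table 5) into two-fold (2J3/2N3) and four-fold (4J3/4N3)
classes. Under this code the nine four-fold boxes are CTN, GTN, TCN, CCN,
ACN, GCN, CGN, GGN and AGN — AGN is one four-codon serine family here,
unlike the standard code — and every remaining sense codon belongs to a
two-codon family, so the two/four split is exhaustive. Stop codons (TAA,
TAG), codons containing ambiguous bases and incomplete trailing codons are
excluded entirely (all three positions); the TA box therefore contributes
only its sense codons. The implementation classifies by codon prefix; the
test suite cross-checks all 64 codons against an independent
implementation of the genetic code (seqinr, numcode 5).

Two pooling choices are deliberate. Counts are pooled across genes before
the ratio is taken (one skew per genome per class) rather than averaging
per-gene skews — the ratio of sums is the maximum-likelihood composition
of the class, and short genes would otherwise dominate the variance. And
skews are computed alignment-free from annotated CDSs, not from a filtered
multiple alignment; this removes the dependence on external aligners and
block filters at the cost of small numeric differences from
alignment-based values (hypervariable regions are not masked here).

Outliers follow the far-out fence rule: a value is flagged when beyond
Q1 − k·IQR or Q3 + k·IQR with k = 3 by default. Quartiles use linear
interpolation between order statistics (R's default type 7; no method is
stated in the source literature, so the common default is pinned and
tested against a longhand oracle). "Beyond" is strict: a value exactly on
a fence is not flagged, a boundary case pinned by test. With fewer than
four finite values no outliers are reported (a warning is raised); when
all values are equal the IQR is zero and any deviant value is beyond the
collapsed fences.

## The synthetic-data generator

`simulate_genome()` produces annotated GenBank/FASTA fixtures whose true
gene order, architecture and composition are known, so every stage is
testable without downloads. Defaults emulate a typical ~15.5 kb
springtail mitogenome: the Pancrustacea arrangement; internal codon
counts per PCG sized like real genes (~3700 codons in total, `cox1` 512
down to `atp8` 52); a start-codon plan with 6 canonical ATG, TTG on
`nad4L` and ATT elsewhere; 9 partial and 4 complete stops; one long
intergenic spacer (592 bp ahead of `nad1`) and a 33 bp `rrnL`/`trnV`
overlap; AT-rich RNA/spacer composition (~71% AT); and per-class skew
targets with positive J-strand and negative N-strand CG asymmetry whose
magnitudes grow from first positions to four-fold third positions. The
per-class jitter of `simulate_genome_set()` (SD 0.03/0.05/0.12/0.25 for
positions 1/2, two-fold and four-fold third positions) reproduces the
qualitative dispersion ranking 4-fold > 2-fold > second > first observed
across real taxa; the ranking, not the SD values, is the modelled fact.

PCG sequences are built codon-wise. Third-position bases are exact iid
draws from the two-fold/four-fold class targets. Codon prefixes are drawn
from a product distribution over first/second-position vectors, with
stop-forming TA prefixes redrawn; because that redraw depletes T at
position 1 and A at position 2, the sampling vectors are first calibrated
by iterative proportional fitting so the *realized* position-1/2 marginals
equal the targets in expectation. The planned start codons are the one
deterministic (non-target) contribution to the class counts; recovery
tests subtract them before standardizing. Parameter recovery is then
assessed against exact multinomial sampling noise: per-class skews of a
default-size genome sit within 3 standard errors of their targets.

One overlap constraint is structural: an overlap is only feasible when at
least one side is a sequence-unconstrained feature (tRNA/rRNA/control
region), because two codon-constrained genes cannot share bases without
violating one of their plans; a plan requesting a PCG–PCG overlap is
rejected. Real atp8/atp6-style overlaps (shared bases in different
reading frames) are therefore not emulated. Other realism limits: RNA
genes are random sequence (no secondary structure, so a tRNA-folding
annotator would not re-discover them); internal codons are not
constrained to any proteome, only to compositional targets; genomes in a
set are independent, with no phylogenetic correlation; and no sequencing
artefacts (Ns, truncations) are produced unless edited in. Passing tests
on these fixtures therefore demonstrate correctness of the *measurement*
machinery, not that real annotations are error-free.

All randomness flows through R's generator seeded once per spec
(`seed` field); the RNG state of the caller is saved and restored, and a
fixed seed yields byte-identical output files (the GenBank writer uses a
fixed LOCUS date for this reason).

## Problem sizes and determinism

The shipped checks use desk-scale sizes chosen to exercise the
mathematics rather than the hardware: 200 random edit scripts on the
38-element order, 100 random signed circular orders of 4–8 genes for the
brute-force comparison, genomes of ~3700 codons for skew recovery, and an
8-genome set for outlier detection. `scripts/acceptance.R` recomputes all
of these from scratch under a caller-supplied seed. The skew-recovery
statistic is a maximum of 16 approximately standard-normal deviates; its
3-SE bound is a property of the generator, not a fitted tolerance, and
like any stochastic bound it is exceeded by chance in a few percent of
seeds.

## Known limitations

* Rearrangement detection is descriptive (minimal displaced set under a
  fixed tie-break), not a rearrangement-distance model; DCJ/HP distances
  and ancestral-arrangement reconstruction are out of scope.
* Signature matching presumes a complete query; a genome that is both
  incomplete and rearranged relative to a signature model will usually
  fall through to `novel`.
* Skew values computed alignment-free will differ slightly from
  alignment-filtered published ranges; they are comparable within a
  data set processed by this package, which is the analysis the outlier
  rule needs.
* De-novo annotation, read assembly, alignment, phylogenetic inference
  and selection (dN/dS) analyses are deliberately not implemented;
  mitorder starts from an annotation and ends at plot-ready tables.
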
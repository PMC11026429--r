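---
title: "Phasing and dating allopolyploid subgenomes from synonymous divergence"
author: "ksphase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phasing and dating allopolyploid subgenomes from synonymous divergence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Many plant genomes are allopolyploids: they arose by hybridization between
two diverged species, so each haploid complement carries two parental
subgenomes. Long after the event, the two subgenomes can still be told
apart by their divergence to a related diploid reference — chromosomes
inherited from the parent closer to the reference show systematically
lower synonymous divergence (Ks) than chromosomes from the other parent.
`ksphase` implements this reconstruction end to end for the hypotetraploid
crucifer case (2n = 30, i.e. n = 15 against an ancestral base of x = 8):

1. estimate Ks per duplicate gene pair and per gene–ortholog pair (NG86),
2. filter orthogroups to unambiguous (paralog pair, reference ortholog)
   triples,
3. aggregate Ks by chromosome and split the chromosomes into two
   subgenomes,
4. convert Ks peaks into divergence times via T = Ks/(2µ),
5. replay the karyotype history (whole-genome duplication, nested
   chromosome insertion, inversions) as symbolic genomic-block algebra,
6. estimate genome size from a k-mer multiplicity histogram,

plus a synthetic allotetraploid generator so that every stage can be
validated against known ground truth without any external download.

```{r, eval = FALSE}
library(ksphase)
report <- run_pipeline(pipeline_config(seed = 1))
report$phase$sizes      # list(A = 8, B = 7) on the default scenario
```

## The Ks estimator (NG86)

The estimator is the Nei–Gojobori (1986) counting method with equal
pathway weighting and Jukes–Cantor correction.

*Sites.* For a sense codon, each of the three positions contributes a
synonymous-site fraction: the number of the three possible single
nucleotide changes that preserve the amino acid, divided by the number of
changes that do not create a stop codon (stop targets leave the
denominator). The per-sequence sums are averaged across the two sequences,
S = (S1 + S2)/2, and N = 3·(codons used) − S.

*Differences.* For a codon column differing at k ≤ 3 positions, the k!
orderings of single-nucleotide steps are averaged; each step is classified
synonymous or nonsynonymous, and orderings that pass through a stop codon
are excluded from the average. If every ordering is blocked, the column is
skipped with a warning.

*Correction.* pS = Sd/S and pN = Nd/N are converted to rates with the
Jukes–Cantor map d = −(3/4)·ln(1 − 4p/3), defined for p < 0.75; a pair at
or beyond that bound is flagged `saturated` and its Ks is not finite.
Records also carry `too_short` (no usable codon column) and `undefined`
(S = 0, e.g. an all-Met/Trp alignment) flags; downstream summaries use
`ok` records only, which is this package's explicit resolution of how
failed estimates are treated before medians are taken.

Codon columns containing gaps or ambiguous bases in either sequence are
skipped pairwise (complete-codon deletion), which keeps S and N symmetric
between the sequences. Columns containing stop codons are skipped with a
warning by default; `strict_stops = TRUE` rejects the pair instead.

This estimator replaces a maximum-likelihood codon-model estimator
(yn00-style) deliberately: NG86 is fully specified by counting rules, so
it can be verified *exactly* against a brute-force enumerator (the test
suite does this for 1000 random codon pairs), and at the divergence scale
that matters here (Ks ≤ 0.15) the difference between counting and ML
estimators is far below the precision of the downstream medians.

## The synthetic allotetraploid generator

The generator is the package's ground-truth instrument, and its defaults
*are* the study conditions: 15 chromosomes, 8 assigned to subgenome A and
7 to subgenome B (chromosomes 1, 3, 5, 7, 8, 10, 13, 14 versus 2, 4, 6,
9, 11, 12, 15), ortholog divergence to the reference diploid Ks = 0.05
(A) and 0.09 (B), homeolog (paralog) divergence Ks = 0.102, 50 genes per
chromosome, 300 codons per gene.

*Event process.* A random stop-free ancestor is drawn uniformly over the
61 sense codons. A Poisson number of substitution events with mean
ks·S(ancestor) is applied; each event picks uniformly among the single
nucleotide changes that are synonymous for the *current* sequence.
Multiple hits, including back-substitutions, arise naturally, which is
exactly what the Jukes–Cantor correction must undo; nonsynonymous changes
are never applied, so the protein is invariant by construction and dN is
structurally zero. Events per synonymous site are calibrated: the rate a
position receives is proportional to its fractional site count, so the
expected events per site equals ks uniformly across degeneracy classes.

*Trios.* Each orthogroup needs three sequences (reference copy, focal A
copy, focal B copy) whose three pairwise divergences equal the scenario
levels simultaneously. Applying divergence to one lineage per pair cannot
satisfy three pairwise constraints at once, so the generator evolves the
three copies on an additive star tree with branch lengths

* bA = (ksA + ksP − ksB)/2,
* bB = (ksB + ksP − ksA)/2,
* bR = (ksA + ksB − ksP)/2,

which reproduce every pairwise expectation exactly. The scenario
constructor rejects level combinations violating the triangle condition
(all branches ≥ 0). For the defaults this gives bA = 0.031, bB = 0.071,
bR = 0.019 — the reference diploid sits closest to the subgenome-A
parent, as it should.

*Placement.* A copies are dealt round-robin across subgenome-A
chromosomes and B copies across subgenome-B chromosomes; the number of
orthogroups is `genes_per_chromosome × max(#A, #B)`, so
`genes_per_chromosome` is a per-chromosome minimum (the smaller subgenome
receives proportionally more genes per chromosome). With a single
subgenome (degenerate test scenarios), the homeless copy is placed across
all chromosomes while keeping its nominal divergence level.

*What the generator does not emulate* — codon-usage bias, indels,
selection, GC drift, rate heterogeneity among genes, gene loss/dropout,
and read errors. Passing the recovery tests therefore shows that the
estimator and phaser are correct and calibrated under the assumed
generative model, not that they are robust to every artifact of real
annotations and alignments.

*A note on the preset levels.* Ages sometimes quoted for this system
(4.2 Mya alongside Ks 0.05; 7.2 Mya alongside Ks 0.09) are not consistent
with T = Ks/(2µ) applied to those rounded levels, which date to 3.8 and
6.9 Mya — presumably unrounded medians were dated. The scenario takes Ks
levels, not times, and this package always reports formula-exact ages
rather than reproducing rounded literature ages.

## Subgenome phasing

Per chromosome, the phaser takes the **median** Ks of its genes against
the reference (medians, not means, because the chromosome-level summaries
this analysis rests on are medians, and medians resist the long right
tail of per-gene Ks estimates). Chromosomes with fewer than `min_genes`
(default 10) usable records are reported but left unassigned.

The two-cluster split is exact and seed-free: medians are sorted and all
n − 1 contiguous splits are scored by total within-cluster sum of squared
deviations. In one dimension the optimal bipartition is always contiguous
in sorted order, so this is the global optimum over all 2^(n−1) − 1
bipartitions — the test suite asserts the equivalence by brute force up
to n = 15. An iterative 2-means would find the same optimum only up to
initialization; the exact split removes that source of nondeterminism.
The lower-Ks cluster is labeled subgenome A.

Whether two subgenomes are really present is itself a question the data
must answer, so the partition carries an explicit ambiguity rule: the gap
between clusters is
compared to the pooled within-cluster IQR, and if `gap <
ambiguity_ratio × pooled IQR` (default ratio 1), labels are withheld.
Identical medians are always ambiguous. The `homeolog_consistency` check
closes the loop: with a correct partition, the two copies of every
paralog pair should fall into different subgenomes (fraction 1.0 on clean
synthetic data; ~8/15 expected under random labels for an 8/7 split).

## Dating

T (years) = Ks/(2µ) with µ = 6.51648×10⁻⁹ synonymous substitutions per
site per year (a Brassicaceae rate). The factor 2 accounts for
substitutions accruing on both lineages since the split. The default peak
estimator is the sample median, the convention under which WGD ages in
this literature are quoted; a Gaussian-KDE mode (Silverman bandwidth,
evaluated on [0, 0.75]) is provided for distributions where "peak" should
mean the mode. Ages are reported raw and rounded half-up to 0.1 Mya for
display; rounded values are never used in further computation.

## Genomic-block karyotype algebra

Karyotypes are written in a one-line-per-chromosome text format,
`ID: [-]BLOCK ... | ... .`, with `|` marking the centromere. The block
alphabet is the 22-block crucifer convention: A–X with the K–L and M–N
associations each treated as a single block (written `KL`, `MN`) and
block W split into halves `Wa`/`Wb` — the only reading under which "all
22 blocks duplicated" and the printed chromosome compositions are
mutually consistent.

Two presets ship with the package. `ACK_Cardamineae_n8` encodes the
eight ancestral chromosomes (AK1 = A+B+C, AK2 = D+E, AK3 = F+G+H,
AK4 = I+J, AK5 = KL+MN, AK6/8 = V+Wa+Q+R, AK7 = S+T+U,
AK8/6 = O+P+Wb+X). Centromere placement: AK8/6 carries its centromere
between P and Wb (required by the fusion geometry below); AK2's
centromere is terminal after E; the remaining presets place the
centromere between the block groups of the two arms. `R_aquatica_n15`
encodes the reconstructed allotetraploid karyotype: six homeologous
pairs, the unfused AK2 and AK8/6 homeologues, and the fusion chromosome
`O P -E -D Wb X`.

Three operators drive the reconstruction. `whole_genome_duplication`
duplicates every chromosome (ids suffixed `_1`/`_2`).
`nested_chromosome_insertion` splices the donor's full block list into
the recipient's (internal) centromere, removing the donor: n drops by
one and block content is conserved; with the donor inverted, its blocks
are reversed with flipped signs, which is how AK2 (D E) becomes the
`-E -D` core of the fusion chromosome. The fused centromere is placed at
the donor's centromere mapped through its orientation, reflecting
retention of the donor centromere at the insertion site.
`invert_segment` models paracentric inversions (and refuses to span the
centromere in paracentric mode).

`match_ancestral` classifies chromosomes as shared or derived by block
*content* (order- and orientation-insensitive, with Wa/Wb matching only
their own half). Content matching is deliberate: comparative maps treat
chromosomes as shared despite within-chromosome inversions, so inversions
must not break the shared call — they are detectable separately with the
inversion operator. A derived chromosome
is tested for the NCI signature: its content is the disjoint union of
two ancestral chromosomes, with the donor's full content contiguous and
strictly internal (recipient blocks on both flanks). The donor may be
the recipient's own homeologue (both map to the same ancestral id),
which matters after a WGD. Internally inverted donor segments are
accepted, since inversions post-dating the insertion are expected.

The exact inversion breakpoints inside the fusion chromosome are below
block granularity and are not modeled; the preset encodes final block
order only.

## k-mer genome sizing

`count_kmers` counts canonical k-mers (the lexicographic minimum of a
window and its reverse complement — strand-symmetric counting, matching
standard k-mer counters) by packing windows into 2-bit-per-base doubles,
exact up to k = 26. `find_peak` automates what is often done by eye:
after a centered 3-bin moving average, the peak is the largest smoothed
count at multiplicities strictly above an error cutoff (default 3); ties
are broken by the larger raw count, then the lower multiplicity, so an
isolated spike is its own peak. Genome size = total k-mer instances /
peak depth, with the error-region mass (multiplicity ≤ cutoff) excluded
from the numerator by default; both totals are reported.

On an exact tiling (c identical copies of a genome of length L) the
estimator returns L − k + 1 exactly — the small-k bias relative to L is
inherent to the definition and documented rather than corrected. On
sampled reads of length ℓ the expected peak is coverage × (ℓ−k+1)/ℓ
(interior k-mers only appear in reads covering all k bases), so the
estimate of a 1 Mb genome at 30× with 100 b reads and k = 21 lands
within ~4–5% of the truth, limited by the discreteness of the peak.

## Response utilities

`call_degs` applies strict thresholds (FDR < 0.01, |log2FC| > 1 by
default — a gene exactly at a threshold is not called, following the
strict inequalities of the convention it implements).
`classify_timing` is set algebra over two contrast gene sets (early =
first only, throughout = both, late = second only), and
`deg_timing_report` keeps the up/down directions separate, yielding six
classes. Differential-expression inference itself (dispersion, GLM) is
out of scope: the tables of per-gene log2FC/FDR are inputs. The
dissection index DI = perimeter/√area is unit-free, scale-invariant and
minimized by a circle at 2√π; inputs violating the isoperimetric bound
draw a warning since no planar shape can produce them.

## Numerical and design choices

* **Determinism.** Every stochastic function takes an explicit seed and
  restores the caller's RNG state; a single pipeline seed derives
  per-stage seeds by label hashing (`derive_seed`), all below 2³¹.
  Identical configuration implies byte-identical outputs.
* **Saturation guard.** Simulation levels must satisfy Ks < 0.75 (the
  Jukes–Cantor domain bound); the estimator flags rather than errors at
  the record level.
* **Filter interpretation.** "Duplicated in the focal species" is read
  as *exactly two* focal copies (configurable), because downstream Ks
  needs unambiguous pairs; diploids absent from an orthogroup fail the
  single-copy test ("conserved as single copy" implies presence). The
  reference diploid is a criterion field, so phasing can use any
  diploid.
* **Problem sizes.** The validation suite runs the default scenario
  (15 chromosomes × ≥50 genes × 300 codons) across 20 seeds, 1000-pair
  estimator cohorts per divergence level, and a 1 Mb / 30× read set for
  k-mer sizing — sizes chosen so the statistical claims (±0.01 medians,
  <3% bias, <5% size error) are testable with comfortable margins.

## Limitations

* NG86 ignores transition/transversion bias and codon frequencies; at
  Ks ≫ 0.3 it underestimates divergence relative to ML estimators. The
  analyses here live at Ks ≤ 0.15, where the difference is negligible.
* The phaser assumes exactly two subgenomes (k = 2); higher polyploids
  and synteny- or k-mer-composition-based phasing are out of scope.
* The karyotype algebra works at block granularity: translocations and
  fissions beyond NCI/inversion, and sequence-level synteny, are not
  modeled.
* The k-mer sizer assumes error-free, uniform coverage; heterozygosity
  and repeat-structure modeling (mixture fits to the spectrum) are out
  of scope, so real-read estimates inherit the usual biases of the
  total/peak method.
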
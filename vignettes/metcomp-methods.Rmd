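---
title: "Methods: RIP quantitation, orthology classes and effector screening in metcomp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: RIP quantitation, orthology classes and effector screening in metcomp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metcomp)
library(dplyr)
```

metcomp implements the downstream analysis layer of a three-species fungal
comparative-genomics study. This vignette documents the models and procedures,
the parameters that matter, what the synthetic-data generator does and does
not emulate, and the numerical choices made where conventions genuinely
diverge.

## Coordinate and alphabet conventions

Two coordinate conventions meet at the package boundary: BED-like interval
sets are 0-based half-open, alignment-coordinate tables (show-coords-style)
are 1-based inclusive. Each reader preserves its format's native convention;
all internal arithmetic is 0-based half-open, and `bed_to_onebased()` /
`onebased_to_bed()` convert explicitly. Sequence case is normalised to upper
on read: repeat masking is carried by interval sets, never by letter case, so
there is a single source of truth for what is repetitive. Nucleotide sequences
are restricted to A/C/G/T/N (gaps additionally allowed in alignments),
proteins to the 20 residues plus X; violations are rejected at parse time with
the offending sequence and offset, or masked to N/X when the caller opts in.

## Assembly statistics

The N50 pair follows the cumulative-half convention: scaffolds are ranked by
length descending (ties broken by identifier so the statistic is independent
of input order), and the N50 length is the length of the first scaffold at
which the cumulative sum reaches *at least* half the assembly size — the
ceiling-style reading, which is the dominant one and the only one consistent
with reporting both a small rank and a large length for a scaffold-level
assembly. The rank is reported alongside the length because comparative tables
for fungal assemblies conventionally print both.

GC% is `100·(G+C)/(A+C+G+T)`: N is excluded from both numerator and
denominator, so ambiguous scaffold gaps do not dilute the estimate. Published
GC values do not always state their N handling; recomputations should
therefore be compared within about ±0.05 percentage points, which covers
either choice at typical N fractions. Gene density is genes per Mbp to one
decimal. Repeat coverage takes the union of the (possibly overlapping,
possibly fragmented) intervals — via `IRanges::reduce()` — so double-annotated
bases count once, and coverage is invariant under splitting an interval in
two; both properties are asserted in the test suite.

## RIP indices

RIP (repeat-induced point mutation) converts C→T in CpA context (equivalently
G→A in TpG on the other strand), enriching TpA and depleting CpA/TpG. Two
quantitation routes are implemented.

The *index route* needs no alignment: overlapping dinucleotides are counted on
a single strand, pairs containing N skipped, and never across segment
boundaries when the genome is partitioned into repetitive (interval union) and
non-repetitive (complement) fractions. TpA/ApT is the frequency of the RIP
product over a non-RIP control; both dinucleotides are reverse-complement
palindromes, so one strand suffices — an invariance the tests check
explicitly. CpA is pooled with its reverse complement TpG for the target
frequency. A zero ApT count flags the ratio undefined rather than erroring:
short degenerate segments are expected in real partitions.

## deRIP consensus

The deRIP model reconstructs a repeat family's putative pre-RIP ancestor from
its alignment. Per column:

1. if the column contains both C and T, and at least one row carries A at its
   next non-gap position (the downstream RIP context), the polymorphism is
   RIP-consistent and the model takes C;
2. symmetrically, a column with both G and A where some row carries T at its
   previous non-gap position takes G;
3. otherwise the majority base wins, gaps excluded, with ties broken in the
   fixed order C > G > T > A — preferring the RIP-susceptible base, so the
   reconstruction is conservative in the same direction as the reversion
   rules.

Columns whose majority character is the gap are dropped from the model (the
gapless consensus retains a column-aligned copy as an attribute, so mutation
classification can reuse the model without re-aligning). Because the model
never chooses T over C or A over G in a RIP-consistent column, its GC content
is bounded below by the plain majority consensus — a property the suite
asserts on fuzzed alignments.

Under a pure RIP process with at least one unmutated copy surviving per
column, this recovers the ancestor exactly (an acceptance property). Under
background noise it is deliberately conservative: a spurious C in an all-T
column with downstream-A evidence triggers a false reversion. On the
generator's default conditions this costs about 2% of positions and, because
false reversions feed mutation classification, shifts some counts into the
non-CpA classes — deflating dominance, never inflating it. Consumers wanting
the noise-free behaviour can classify against a known reference model instead
of the internal consensus.

## RIP mutation classes and dominance

Every row-versus-model substitution at a column where the model has C and the
row has T is classed CpY↔TpY by the model's *next* non-gap base Y; the
reverse-complement case (model G, row A) is classed through the model's
*previous* non-gap base X (X=T ⇒ CpA↔TpA, X=G ⇒ CpC↔TpC, X=C ⇒ CpG↔TpG,
X=A ⇒ CpT↔TpT). All other substitutions, and RIP-type transitions with no
flanking base or an N context, count as `other_mutations`. Indels are never
counted. The per-family dominance is

$$\mathrm{dominance} = \frac{n_{CpA\leftrightarrow TpA}}{n_{CpC\leftrightarrow TpC} + n_{CpG\leftrightarrow TpG} + n_{CpT\leftrightarrow TpT}}$$

with a positive numerator over a zero denominator flagged infinite (a genuine
outcome for small, purely CpA-mutated families) and 0/0 flagged undefined.
Scores of 1 or more mark families whose C→T mutation is CpA-dominated, the
RIP-typical signature. Two aggregation conventions exist for the genome-level
score; metcomp pools the class counts across families and takes the ratio of
sums, rather than averaging per-family ratios, because pooling is
well-defined in the presence of infinite family scores and weights families
by their mutation load. The "total RIP-like mutations" is the sum of all four
CpN↔TpN classes. No minimum-length filter is applied to families by default —
RIP is thought to need several hundred bp of duplicated sequence, but
assemblies fragment long repeats into short families, so the per-family table
carries `avg_length_bp` and leaves filtering to the caller.

## Orthology classes

From a three-species group table, the label set is a partition:
*divergent:s* (members in s only, of any number — species-specific genes with
no orthologs in either comparator), *expanded:s* (present in all three with a
strict single maximum in s), *shared* (all three, no strict maximum), and
*ambiguous* (exactly two species). Requiring presence in all three for
"expanded" keeps divergent and expanded disjoint; two-species groups fit
neither concept and are deliberately left unresolved rather than forced into
one. Per-species summaries count divergent *proteins* (not groups) and, for
expanded groups, both the group count and the expanded species' member count,
because published comparisons quote both. Ortholog inference output may omit
proteins with no hits entirely; `add_singleton_groups()` turns roster proteins
absent from the table into one-member divergent groups when an explicit
roster is supplied — without a roster the table is taken at face value.

## Effector screen

Motifs are written with fixed residues, bracketed classes and X (any residue);
class members are canonicalised by sorting so spelling variants compile
identically. X in a pattern matches the 20 standard residues but never the
ambiguity letter X in a sequence. All overlapping match positions are
reported; presence is collapsed per protein × motif. Scanning runs over the
full precursor (signal peptide included), matching the common whole-proteome
screening practice; a post-cleavage scan would need reliable cleavage sites
for every protein, which secretion predictors do not guarantee. The shipped
registry holds the six motifs with published candidate counts in this system
([YFW]XC, [LI]XAR, RXLR, CHXC, KECXD, YXSL[RK]); larger registries load from
YAML rather than being hard-coded.

A *candidate effector* is a protein passing every active criterion; the
default is secreted ∧ motif-positive with no length cap, because that is how
the candidate set is defined in the source analyses, while the ≤300 aa cap
belongs to the divergent-effector characterisation. Tightening criteria can
only shrink the candidate set (asserted as a property). Proteins missing from
the secretion table are treated as not secreted, with a message — silently
dropping them would bias candidate counts invisibly.

Molecular weight uses standard average residue masses plus one water
(75.07 Da for free glycine). The isoelectric point solves for zero
Henderson–Hasselbalch net charge over the EMBOSS pKa set (N-terminus 8.6,
C-terminus 3.6; side chains K 10.8, R 12.5, H 6.5, D 3.9, E 4.1, C 8.5,
Y 10.1) by bisection on pH ∈ [0, 14] to 0.01. Net charge is strictly
decreasing in pH (each term is a decreasing logistic), so the root exists and
is unique; the suite asserts the monotonicity that guarantees bisection
correctness.

## MAT typing

Thallism is a pure function of the presence set of the four recognised MAT
genes. Any MAT1-1-* gene establishes the MAT1-1 (alpha-box) idiomorph; MAT1-2
establishes the HMG-box idiomorph; both ⇒ putative homothallism, one ⇒ the
corresponding putative heterothallism, none ⇒ indeterminate. "Putative"
because presence of both idiomorphs licenses self-fertility only
genomically — functional mating is not inferable here. Completeness of the
MAT1-1 idiomorph (all of MAT1-1-1/2/3) is reported separately with the
missing members listed, since isolates with an altered idiomorph (e.g.
missing MAT1-1-2) are biologically meaningful intermediate cases. Presence is
an input, typically from orthology or annotation; homology search is upstream
and out of scope.

## The synthetic-data generator

The generator emulates the statistical structure the analyses consume, not
the biology that produced it:

* **Repeat families** — a uniform-random ancestor; per copy, RIP applied
  first (each CpA's C→T and TpG's G→A independently with probability
  `rip_rate`, eligibility read from the ancestor), then background
  transitions (probability `bg_rate` per site). No indels, so alignments are
  column-trivial and ground-truth mutation coordinates are unambiguous;
  re-evaluating RIP eligibility after background mutation is deliberately not
  modelled for the same reason.
* **Proteomes** — core groups (one gene per species, 2% residue divergence
  between species variants), divergent genes (one species only), expanded
  groups (`expansion_size` inparalogs in one species, one elsewhere). A
  fraction of proteins get a synthetic signal-peptide prefix (M + 2 charged +
  10 hydrophobic + an A-x-A cleavage site; cleavage after residue 16) with a
  matching positive secretion row; motifs are planted downstream of residue
  30. Background sequence is scrubbed of chance motif matches (the first
  residue of any unplanned match window is re-drawn from non-motif residues
  until the proteome is clean, never touching a planted window): short motifs
  match random sequence at high rates, and without scrubbing the planted
  candidate set would not be a usable ground truth. Real proteomes are *not*
  scrubbed — recovery tests show the classification logic is correct, not
  that motif matches in real data are effectors.
* **Genomes** — random-background scaffolds with family copies embedded at
  recorded non-overlapping positions until the target repeat fraction is
  approximated; the interval annotation equals the embedding record exactly.

Defaults (3 × ~200 genes, 12 families × 8 copies × 600 bp, `rip_rate` 0.2
over `bg_rate` 0.01, 200 kb genomes in 8 scaffolds at 3% repeat content, 25%
secreted, 30% motif-planted) give clearly RIP-positive repetitive fractions
(TpA/ApT ≈ 1.3 against ≈ 1.0 background, pooled dominance ≈ 2) at
interactive runtimes; family lengths sit inside the 45–1225 bp range typical
of de novo repeat families in fragmented fungal assemblies. What the
generator does not emulate: repeat taxonomy, indels and alignment error,
codon structure, realistic signal-peptide physics, paralog-specific
divergence rates. Tests passing on synthetic bundles therefore validate the
analysis layer's correctness and calibration behaviour, not predictions
about any particular genome.

All randomness flows through per-stage integer streams derived from one
master seed, so a given seed yields byte-identical bundles across platforms.

## Verification strategy and problem sizes

Each contribution is checked against an independent route: dinucleotide
counting and motif scanning against positional brute-force oracles; RIP
classification against a per-position oracle over 200 seeded small families
(≤ 50 bp × ≤ 10 copies); deRIP against exact ancestor recovery under pure
RIP; dominance against strict monotonicity over a planted-rate grid
({0, 0.05, 0.1, 0.2, 0.4} at background 0.01); orthology and effector
classification against exact recovery of planted sets over 20 seeds. These
sizes keep the default suite under a minute while exercising every rule
branch; the generator scales to larger conditions by configuration when more
statistical resolution is wanted.

## Known limitations

Dominance classification against the internal deRIP model inherits the
model's conservative false reversions under background noise (see above).
The ortholog reader targets the canonical wide ProteinOrtho-style table; raw
predictor report dialects (SignalP native output, RepeatMasker `.out`) are
out of scope and expected as simplified TSVs. Published candidate-effector
counts depend on the exact upstream secretome and supplementary tables of
the original analyses; with those inputs transcribed into the expected
formats, the acceptance tests recompute the published counts from scratch.
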
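---
title: "OrthoTrace: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{OrthoTrace: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(OrthoTrace)
```

## The problem

Comparative functional genetics leans on an assumption that is rarely
checked: that a gene essential in one species has a conserved, present
ortholog doing the same job in its relatives.  Testing that assumption at
scale means calling ortholog *presence or absence* for hundreds of genes
across a clade of genome assemblies — and doing it carefully, because the
naive failure modes all point the same way.  A gene can look absent
because the assembly broke inside the locus (a contig-end truncation), because
the locus is split over two short contigs, or because the protein has
diverged past the sensitivity of a similarity search, while the gene is in
fact present and functional.  OrthoTrace implements a layered calling
procedure designed around exactly these failure modes, together with the
two statistical companions such a study needs: a McDonald–Kreitman (MK)
test of selective neutrality for a focal gene, and shared-control
estimation statistics for fertility assays of knockout genotypes.

## The calling pipeline

**Stage 1 — reciprocal best hits.**  For each focal gene, the
representative protein (the longest CDS per gene; annotation isoform
choice is not standardized across assemblies, so one representative is a
deliberate simplification) is searched against the target proteome with
an exact Smith–Waterman local aligner (BLOSUM62, affine gaps 11/1 — the
familiar BLASTp defaults).  If the rank-1 hit passes the score and
coverage thresholds, the subject is searched back against the reference
proteome; the gene is `PRESENT_RBBH` only if the reverse rank-1 hit is the
original gene.  Rank-1 ties in either direction are treated as failures
(`ambiguous_tie`) and pushed to stage 2: a paralog that ties its ortholog
is precisely the situation reciprocity cannot resolve.  The engine is
exact rather than seeded-heuristic; at the proteome sizes this package
targets (hundreds of genes, not whole genomes) exactness is affordable and
buys deterministic, order-stable results.  An adapter
(`readBlastTab()`) accepts BLAST `-outfmt 6` tables for users who want to
swap in an external engine.

**Stage 2 — synteny.**  Every preliminary absence is re-examined in its
expected genomic neighborhood.  Up to three flanking genes per side (the
anchor set) are located in the target by the same reciprocal criterion —
anchors must RBBH back, so we never anchor on a paralog.  The block
between the innermost located anchors defines where the missing gene
ought to be.  Anchor order and orientation are *not* required to be
conserved, only co-location on one contig: requiring collinearity would
convert every local inversion into a false absence.  The gene's CDS
(nucleotide) and protein are then re-searched against the inter-anchor
interval and against every contig that carries a located anchor.  A hit
covering ≥ 0.8 of the CDS rescues the gene; partial hits on two or more
contigs whose merged query coverage reaches 0.8 count as a split-gene
rescue.  The nucleotide route matters: synonymous sites keep nucleotide
identity serviceable long after protein identity has collapsed below what
a protein search can rank reliably.

Classification of the remaining absences is total: rescued →
`PRESENT_RESCUED`; retained synteny (both sides co-located) →
`ABSENT_SYNTENY`; evidence stopping at a contig edge without both sides
co-located → `UNRESOLVED_CONTIG_END`; otherwise `ABSENT_NO_SYNTENY`.
`UNRESOLVED_CONTIG_END` is deliberately neither present nor absent —
headline absence counts exclude it by default (a switch includes it).

**Stage 3 — in-silico validation.**  For absences with retained synteny,
the inter-anchor interval (the "amplicon", by analogy with PCR across a
syntenic block) is extracted and scanned: a nucleotide search for the CDS
and a six-frame translation search for the protein.  No hit above
thresholds gives `VALIDATED_ABSENT`; intervals longer than `maxAmplicon`
are skipped as `NOT_VALIDATED` (the electronic analogue of a gap too large
to amplify); any hit flags a contradiction instead of silently passing.

**Confidence tiers.**  A validated absence is `VALIDATED`.  Otherwise an
absence is `HIGH` confidence when the same gene has a present ortholog in
a species at least as divergent from the reference — if the search found
the gene across a deeper divergence, failure at a shallower one is
unlikely to be a sensitivity artifact.  Absences confined to the deepest
lineages, with no deeper witness, are `LOW`.  Lineage support can be read
per absence or per gene; the two differ when a gene is absent from several
species at different depths, so `tierAbsences()` reports both (`tier` and
`gene_support`).

### Thresholds

| parameter | default | meaning |
|---|---|---|
| `minScoreProtein` | 60 | raw SW score a forward protein hit must reach |
| `minCoverage` | 0.5 | query coverage of a credible forward hit |
| `minIdentity` | off | optional identity filter (a ≥ 25% rule can be enabled to mimic precomputed-ortholog imports) |
| `minScoreNt` | 50 | raw score for nucleotide (rescue/validation) hits |
| `rescueCoverage` | 0.8 | merged CDS coverage that rescues an absence |
| `maxAmplicon` | 50 kb | largest interval submitted to validation |
| `endMargin` | 20 kb | distance to a contig edge that counts as "at the end" |

Percent identity is identical columns over aligned columns *including*
gap columns — definitions vary across tools, so ours is pinned down here
and in the `alignLocal()` documentation.  Scores are floored at zero (a
true local alignment may be empty); raw scores rather than E-values are
thresholded, which keeps the engine free of database-size corrections.
The score/coverage defaults were chosen once against the synthetic clade
regime described below (random unrelated proteins score far below 60;
genuine orthologs at ≤ 40% protein distance score far above) and are
exposed in `orthologThresholds()` rather than hard-coded.

## The synthetic clade forge

`forgeClade()` derives one genome per species from a forged reference,
with divergence controlled by an amino-acid substitution rate per MY
(default 0.002/site/MY, i.e. expected protein identity `exp(-0.002 d)`:
≈ 0.87 at 70 MY, a conservative-protein regime).  Substitutions follow a
simple BLOSUM62-derived exchangeability bias; synonymous codon changes run
at three times the amino-acid-changing rate; intergenic sequence mutates
at the synonymous-scale rate.  Whole-codon indels are supported but off by
default.  This is an identity-gradient generator, not a substitution
model: the pipeline consumes identities and coverages, so realism beyond
the gradient (codon usage, rate heterogeneity, transposable elements,
chromosome-scale rearrangement) would add cost without adding test power.
Consequently, passing the planted-event suite shows the *logic* of the
pipeline is right under controlled divergence; it does not certify
performance on real assemblies with repeat content and annotation noise.

Planted events mirror the observed failure modes: `lost` excises the gene
body plus 50 bp margins and leaves the flanks adjacent; a
`split_across_contigs` gene is cut mid-CDS onto two contigs and left
unannotated (assembly breaks inside a locus usually take the annotation
with them); an `at_contig_end` gene keeps only its proximal half at a
contig edge, the distal half lost to the assembly gap; a
`diverged_extreme` gene receives one-step nonsynonymous replacements that
collapse protein identity to ≈ 20% while nucleotide identity stays near
73% — recoverable by the nucleotide route only.  Each event carries its
expected final call in the truth ledger, so end-to-end tests are exact
comparisons, not tolerances.  The same seed yields byte-identical output.

## McDonald–Kreitman test

Changes are tabulated per codon column against a supplied common-ancestor
sequence (ancestral reconstruction itself is out of scope; a parsimony
fallback over ingroup consensus / sister / outgroup is provided, masking
irreconcilable sites).  A monomorphic ingroup codon differing from the
ancestor is a fixed, lineage-specific change; two or more ingroup alleles
are polymorphic, each minor allele classified against the major one.
Multi-step codon differences are averaged with equal weight over all
shortest mutational pathways that avoid stop codons, giving fractional
synonymous/nonsynonymous contributions; columns with gaps, ambiguity,
ingroup stops, or no stop-free pathway are excluded and counted.

Polymorphic changes below 12% frequency are excluded by default — the
standard guard against slightly deleterious alleles still segregating —
with a strict `<`, so a site at exactly 12% is retained.  Frequency is
*minor-allele* frequency of the sampled sequences: the outgroup-free,
conservative reading (a derived-allele reading would need polarization
that the ancestor cannot always supply); the cutoff and the reading are
both exposed as arguments.  The 2×2 table (Dn, Ds, Pn, Ps) keeps its
fractional values for NI `(Pn/Ps)/(Dn/Ds)` and `alpha = 1 − NI` (reported
`NA` whenever a denominator is zero), and is rounded to nearest integers
for the two-tailed Fisher exact test, which sums hypergeometric point
probabilities not exceeding the observed one (relative slack `1e-7` for
floating-point ties, the convention base R also uses; the all-zero table
reports p = 1).  Calibration is checked by planting neutral,
proportional counts: across 500 seeded replicates mean alpha must sit
within ±0.05 of zero and the rejection rate at p < 0.05 at or below 0.07.

## Estimation statistics

Fertility assays compare each genotype to one shared wild-type control.
`effectSizes()` reports the mean difference in adult progeny per fly with
a 95% BCa bootstrap interval (5000 independent per-group resamples;
bias-correction from the fraction of resampled deltas below the observed
one, acceleration from the delete-one jackknife over both groups pooled)
and a permutation p-value on |mean difference| with the add-one rule,
10 000 reshuffles by default — enough that a true p below 10⁻⁴ is
reportable as `< 1/(n_perm+1)` rather than truncated at a coarser bound.
Significance follows the estimation-graphics convention: an effect is
called when zero lies outside the interval.  No multiplicity correction
is applied across genotypes (the shared-control design reports each
comparison on its own terms).  Degenerate cases are explicit: all-constant
groups yield a zero-width interval with a warning, and a degenerate bias
correction falls back to the percentile interval with a warning.  The
resampling protocol (one `sample.int` call for the control index matrix,
then one for the group) is documented so an independent implementation
reproduces intervals exactly from the same seed; BCa coverage is verified
empirically (93–97% over 1000 normal-pair replicates).  Negative-binomial
progeny counts in the forge mirror the overdispersion such assays show;
a "sterile" genotype is all-zero, which makes the effect size exactly
minus the control mean — a useful fixed point for tests.

## Problem sizes and determinism

The shipped tests and the acceptance script run at desk scale, chosen as
the smallest sizes that exercise every code path: a 40-gene, 5-species
clade with eight planted events for the end-to-end checks; 200 random
short pairs against an independent Gotoh oracle for the aligner; every
2×2 table with margins ≤ 30 against full enumeration for the Fisher test
(164 176 tables); 500 replicates for MK calibration; 1000 replicates for
BCa coverage.  Genome-scale runs (hundreds of genes against whole
assemblies) are the same code on bigger inputs, with the external-engine
adapter available where exact alignment would be the bottleneck.  Every
stochastic step takes an explicit seed, and derived sub-streams keep
seeds below 2³¹.

## Known limitations

* Orthology is one-to-one by construction; many-to-many families and
  tree-reconciliation orthology are out of scope, and a recent duplicate
  will (correctly, but conservatively) break reciprocity and land in the
  synteny stage.
* The rescue search runs within located blocks and anchor contigs, not
  genome-wide; a gene translocated far from its neighborhood is reported
  absent with retained synteny — the validation stage would catch it only
  if it moved inside the amplicon.
* The MK implementation assumes an in-frame codon alignment and a
  supplied ancestor; alignment and ancestral-state uncertainty are not
  propagated.
* The forge does not emulate annotation errors on *conserved* genes
  (missing models, chimeras), so the pipeline's robustness to those comes
  only from the nucleotide rescue route.
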
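---
title: "Detecting rapidly evolving genes between two transcriptomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting rapidly evolving genes between two transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kaksflow)
```

## The problem

When two closely related species have recently diverged into contrasting
habitats, the genes that drove the divergence are expected to show an
elevated ratio of nonsynonymous (amino-acid changing) to synonymous
(silent) substitution rates. Writing Ka for the nonsynonymous rate per
nonsynonymous site and Ks for the synonymous rate per synonymous site,
Ka/Ks > 1 is the classic signature of positive selection, Ka/Ks near 0
of purifying selection, and values in between of relaxed constraint.

`kaksflow` implements the complete screen for such genes from a pair of
assembled transcriptomes: read cleaning, coding-region extraction,
reciprocal-best-hit (BBH) orthology with strict paralog filtering,
codon-aware alignment, Ka/Ks estimation, Fisher-exact validity testing,
GO-category enrichment of the positively selected set, and RPKM-based
expression concordance between a control and a stress condition. A
codon-substitution simulator with planted ground truth drives all
validation: every stage can be audited against what was planted.

## The estimators

Two estimators are implemented, deliberately at different points on the
simplicity/realism spectrum, so that one can serve as an oracle for the
other.

**NG86 counting.** For each codon, the expected number of synonymous
sites is obtained by enumerating all nine single-nucleotide changes;
changes that would create a stop codon are excluded from the
denominator (so, for example, TTT has S = 1/3 of a synonymous site
because only TTT→TTC is silent). Differences between codons separated
by more than one nucleotide are resolved by averaging equally over all
minimal substitution paths through sense codons; paths through stop
codons are dropped whenever at least one stop-free path exists. The raw
proportions ps = Sd/S and pn = Nd/N are corrected for multiple hits
with the Jukes–Cantor formula d = −(3/4)·ln(1 − 4p/3), undefined when
the logarithm's argument is non-positive.

**YN00 approximate ML.** The Yang–Nielsen style estimator accounts for
two realities the counting method ignores: transition/transversion bias
(κ) and unequal codon usage. κ is estimated from the
fourfold-degenerate and nondegenerate codon positions using the Kimura
two-parameter correction on each class (the transition/transversion
distance ratio at such sites estimates κ/2). Site counts are then
weighted by κ and by F3×4 position-specific nucleotide frequencies;
substitution counts weight the minimal paths by the codon model
(target-nucleotide frequency × κ for transitions × ω for nonsynonymous
steps), and the ω used in the weighting is iterated to a fixed point
(tolerance 1e-6, cap 100 iterations; non-convergence is flagged on the
result rather than raised). Distances apply the Kimura two-parameter
correction separately within the synonymous and nonsynonymous site
classes. In the κ = 1, uniform-frequency limit the site computation
reduces algebraically to NG86, which is the cross-check the test suite
enforces.

**Classification.** Each retained pair is placed in one of six
categories: `positive` (both rates defined, Ks > 0, Ka/Ks > 1),
`weak_purifying` (ratio in (0.5, 1]; the boundary reading is that a
ratio of exactly 1 is not positive), `purifying` ((0, 0.5]), `ka_only`
(Ka > 0 but Ks undefined or zero; the ratio is reported as undefined
rather than infinite), `ks_only` (symmetric), and `incalculable`.
A two-sided Fisher exact test on the table [[Sd, S−Sd], [Nd, N−Nd]]
(fractional counts rounded half away from zero) accompanies every
estimate as a validity check.

## The simulator

The generating model is GY94-style: a continuous-time Markov chain on
the 61 sense codons in which only single-nucleotide changes have
positive rate, with rate proportional to the target codon's frequency,
multiplied by κ for transitions and by ω for nonsynonymous changes;
changes into stop codons are forbidden. The chain is scaled so one unit
of divergence t equals one expected substitution per codon at
stationarity, the ancestor is drawn from the codon frequencies, and the
two lineages evolve independently for t/2 each. The simulator was
chosen to match the assumptions of the YN00 estimator so that parameter
recovery is a fair test of the estimator rather than of model mismatch.

The simulator records every realized event (synonymous/nonsynonymous ×
transition/transversion), which enables two strong invariant checks:
at small t the realized counts must equal the Hamming decomposition of
the output pair, and under the neutral symmetric model the realized
synonymous fraction must match the flux share enumerable directly from
the genetic code.

**What the fixture emulates — and what it does not.** The fixture
generator plants ortholog pairs on an ω grid, paralog decoys (deeply
diverged duplicates whose expected Ks far exceeds 0.1), stop-codon
contaminants, short-overlap and low-coverage truncations, GO labels
with one category enriched among ω > 1 pairs, and per-species
control/stress abundances with a subset of genes stress-induced.
Reads are drawn gene-proportionally to abundance × length with uniform
starts, either strand, and independent substitution errors. The
simulator does not generate indels, assembly chimeras, splice variants,
heterozygosity, or coverage biases, so passing the planted-truth audits
demonstrates the correctness of the pipeline's logic, not robustness to
every artifact of real transcriptome assemblies.

## Parameter choices

| parameter | default | rationale |
|---|---|---|
| ortholog divergence t | 0.05 subst/codon | keeps expected Ks ≈ 0.05 for predominantly synonymous pairs, safely inside the Ks ≤ 0.1 retention regime the screen targets |
| decoy divergence t | 1.0 | expected Ks well above 0.1, so decoys must fall to the Ks filter |
| pair length | 280–380 codons | matches transcript-scale CDS (~1 kb) and gives each pair enough substitutions for stable rates |
| κ (generator) | 2 | typical plant nuclear transcriptome transition bias |
| min ORF | 150 nt | conventional floor for a credible coding region |
| BBH min raw score | 100 | calibrated on simulated sets: unrelated proteins of this length score < 60 under BLOSUM62/affine 11-1, true orthologs score in the hundreds |
| overlap filter | > 150 bp, strict | pairs at exactly 150 bp are excluded |
| coverage filter | ≥ 0.90 of **both** sequences, boundary inclusive | the stricter of the two readings of "90% coverage" |
| gap-column filter | > 0.20 of columns | reproducible stand-in for a manual "ambiguous alignment" check |
| Ks filter | > 0.1, strict | Ks = 0.10 is retained |
| regulation call | \|log2 ratio\| ≥ 1, pseudo-count 0.1 RPKM | a declared convention — the two-fold rule — not an inferred one |
| QC | > 8 Ns, > 50% bases ≤ Q5, one base > 80% of the read | literal strict-inequality reading of the cleaning rules; the complexity proxy is a deliberate simple substitute for DUST-style scoring |

## Numerical and design decisions

* **ORF choice.** Without an external protein database, frame selection
  by best database hit is not reproducible; the longest ATG-initiated
  stop-free ORF over all six frames is used instead, with deterministic
  tie-breaks (frame order, then leftmost start).
* **Alignment.** Heuristic database search is replaced by exact
  Smith–Waterman (BBH scoring) and Needleman–Wunsch (codon-alignment
  guide) under BLOSUM62 with affine gaps 11/1, via
  `Biostrings::pairwiseAlignment`. E-values are not computed; the raw
  score threshold plays that role at desk scale. Codon alignments are
  obtained by back-translating the protein alignment, so frameshifts
  cannot arise by construction.
* **Aggregate recovery statistic.** Replicate studies summarise ω as
  `mean(Ka)/mean(Ks)` over replicates ("pooled"), not as the mean of
  per-pair ratios: a per-pair ratio is a ratio estimator whose
  small-sample bias is positive and grows as the expected synonymous
  count shrinks (at ω = 2 and t = 0.1 only ~4 synonymous events are
  expected per 300-codon pair, and the mean ratio overshoots by ~25%
  while the pooled estimate stays within a few percent). The mean of
  per-pair ratios is still used where only monotonicity in ω is
  asserted.
* **Degenerate inputs.** Identical sequences give Sd = Nd = 0,
  Ka = Ks = 0, an undefined ratio and the `incalculable` category;
  saturated proportions make the corrected distance undefined rather
  than clamped; pairs whose Ks is undefined are retained through the
  Ks filter and routed to `ka_only`/`incalculable`.
* **Read mapping.** The mismatch-limited mapper is exact (no heuristics
  in the *result*): pigeonhole seeding guarantees every placement with
  at most `max_mismatch` mismatches is enumerated, reads tied between
  genes are discarded as ambiguous, and ties within a gene stay with
  the gene. There is no indel handling — adequate for substitution-only
  simulated reads, a stated limitation for real data.
* **Determinism.** Every stochastic function requires an explicit seed
  and a pipeline rerun with the same configuration and seed is
  byte-identical.

## Problem sizes used in validation

The shipped validation suites use 200 replicate pairs of 300 codons at
t = 0.1 for parameter recovery and false-positive control, 100
replicates of 500 codons for the estimator-agreement check, a
30-pair planted fixture for the filter audit, and 50,000 simulated
reads per condition for expression recovery. These sizes were chosen so
that Monte-Carlo error is several times smaller than the tolerances
being asserted.

## Known limitations

* YN00 here follows the published approximate method in structure but
  resolves the remaining freedom (path weighting, κ pooling across the
  two degeneracy classes) by explicit, tested conventions; it is not a
  line-for-line reimplementation of any particular program, and full
  ML codon models (branch/site models, confidence intervals on ω) are
  out of scope.
* GO enrichment treats categories as flat labels: no ontology-graph
  propagation, and raw p-values by default (a Benjamini–Hochberg column
  is optional) since the screen is exploratory.
* RPKM uses the full transcript length as the exon region, which is the
  right convention for single-exon transcript contigs but not for
  genomic alignments.
* The expression stage has no replicates and therefore no dispersion
  estimation; calls are threshold-based, as appropriate for a
  single-library screen.
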
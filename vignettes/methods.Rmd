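---
title: "Methods: congenic-strain multi-omics mapping of CYP-mediated resistance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: congenic-strain multi-omics mapping of CYP-mediated resistance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the statistical and algorithmic
choices behind each stage, the parameters that matter, what the synthetic
data generator does and does not emulate, and the known limitations.

## The congenic design

Three strains are compared against a reference genome (LVP): a susceptible
recipient (ROCK), a resistant donor (SP), and a congenic strain (CKR)
produced by introgressing the SP resistance loci into the ROCK background.
Because CKR inherits only selected SP segments, a signal shared by SP and
CKR but absent from ROCK is enriched for true resistance factors on two
axes at once: genomic position (inside introgressed blocks) and molecular
phenotype (expression or protein level).

## Variant patterns

Sites are filtered on phred-scaled confidence with the boundary kept at
equality: QUAL exactly 30 is retained, because only sites *below* the
threshold are discarded. This off-by-one is stated explicitly since it
silently changes downstream SNP counts.

Each site is assigned one of four homozygous pattern codes — `a`
(ROCK differs from SP = CKR), `b` (SP differs), `c` (CKR differs), `d`
(all equal) — and is `uninformative` if any strain is heterozygous or
missing. The resistance-associated pattern is code `a` with SP and CKR
homozygous-alternate and ROCK homozygous-reference; since the VCF REF
allele is the reference-strain allele, this enforces "different from both
ROCK and the reference" by construction. Multi-allelic records are split
into biallelic sites before classification.

The effect annotator is deliberately minimal: codon-level translate-and-
compare for CDS SNPs (strand-aware; translation uses the standard code
without initiator-codon special-casing, so single-codon comparisons are
well defined), positional classes otherwise (exonic-upstream-of-CDS is
5'; 3' UTR and intron collapse into one class, mirroring how the effect
categories are tabulated). When a SNP hits several transcripts the most
severe class is kept (non-synonymous > synonymous > 5' > 3'/intron).
Coding indels are bucketed as non-synonymous with detail `indel`. This is
not a reimplementation of a full effect predictor: splice-site and
regulatory classes are out of scope.

## Locus scan

Resistance SNPs are counted in non-overlapping tiling windows (default
10 Mb) — tiling rather than sliding because the scan is presented as
counts per window. A window seeds a locus only when its count strictly
exceeds the threshold (default 100 per 10 Mb); a count of exactly 100 does
not. Adjacent supra-threshold windows merge into one locus. Raising the
threshold can only shrink the covered region, though it can split one
locus into two, so monotonicity is stated (and tested) in terms of
coverage, not locus count. No permutation null is computed; the threshold
is a density heuristic, not a significance level.

## Differential expression

Genes enter testing only if their CPM exceeds 1 in at least 4 of the
compared samples and they have at least one count in each strain (a gene
absent from one strain entirely is untestable and removed).

Between-sample normalization is trimmed mean of M-values (TMM),
implemented from its published definition: per-gene log-ratios against a
reference column (the sample whose upper-quartile CPM is closest to the
mean upper quartile), doubly trimmed 30% on M and 5% on A, averaged with
delta-method weights, and rescaled to geometric mean 1. The test suite
cross-checks the factors against an independent implementation to within
5%; exact equality is not promised because reference-column tie-breaks
differ.

Testing uses a two-group negative-binomial exact test rather than a GLM:
counts are scaled to a common effective library size (library size x TMM
factor, geometric mean) and rounded to pseudo-counts; a common dispersion
is estimated by conditional maximum likelihood; per-gene dispersions are
moderated by weighted-likelihood empirical Bayes (gene conditional
likelihood plus `prior_n = 10` times the average likelihood, maximized on
a 61-point dispersion grid spanning the common value x 2^±6); and the
p-value is the exact conditional probability-mass test on the two group
totals. The rounding step is a documented approximation (the alternative,
quantile-matching pseudo-counts, adds complexity without changing any
tested property). The reported log2 fold-change uses a 0.5 pseudo-count
guard for display; the test itself never sees the guard. Significance is
|log2FC| >= 1 and Benjamini-Hochberg FDR <= 0.01, with the positive sign
meaning higher expression in the first-named (resistant) strain.

Calibration and power are tested by simulation: under the global null the
fraction of genes at FDR <= 0.01 stays below 2% averaged over seeds; with
planted log2FC = 2 at 4 vs 4 replicates and dispersion 0.05, sensitivity
exceeds 0.9 with an observed false-discovery proportion at most 0.05.

## TMT proteomics

Shared peptides are razor-assigned to the candidate protein with the most
distinct peptides, ties broken by lexicographically smallest protein id —
a stated, deterministic tie-break. Protein abundance is the sum of PSM
signal-to-noise per channel (rollup conserves each channel's total S/N
exactly), then every channel is scaled so all totals equal the mean raw
total ("normalization on total peptide amount"); the order
rollup-then-normalize is a documented choice. Differential abundance is a
two-sided two-sample t-test on log2(normalized abundance + 1) with
*pooled* variance: channels of one TMT mixture share a noise model, and
the Welch approximation is unstable at 3-4 channels per group (df can
drop to ~2). No multiple-testing correction is applied by default,
mirroring the raw p <= 0.05 criterion of small-scale TMT designs; a BH
switch is available. Isotope-impurity correction is out of scope (vendor-
and lot-specific).

## Variant-informed proteome database

Strain variants are applied at genome level (REF alleles verified against
the genome, overlapping variants rejected), then CDSs are extracted
strand-aware, spliced and translated; this genome-first order makes
intronic variants harmless by construction. Translation stops at the
first stop codon; a stop before the annotated end truncates the protein
and sets a `premature_stop` flag. Per gene, the longest isoform is kept
(ties to the lexicographically smallest transcript id). Only the standard
genetic code is supported.

## Integration and concordance

Transcript and protein results join per gene in a full outer join;
proteins that resolve to no annotated gene are kept under their accession
with a null gene id. Pearson correlation of log2 fold-changes is computed
only over genes quantified in both layers — a convention that tends to
overestimate concordance (absent-in-one-layer genes are excluded), kept
deliberately for comparability with dual-quantified reporting.

## The six-hypothesis engine

The classifier encodes six mechanisms of CYP-mediated resistance:

| | mechanism | evidence required |
|---|---|---|
| H1 | coding variant in a CYP | resistance-associated non-synonymous SNP in a CYP (no expression change required; a flag records whether one exists) |
| H2 | CYP promoter mutation | CYP transcript **and** protein up in **both** resistant strains |
| H3 | CYP duplication | same evidence as H2 (expression data cannot separate the two); clustered members reported as candidate duplication units |
| H4 | coding variant in a switch | resistance-associated non-synonymous SNP in a TF or lncRNA |
| H5 | switch promoter mutation | switch transcript up in both strains or down in both (repressors count; opposite directions in the two strains are treated as inconsistent with shared inheritance and excluded) |
| H6 | CYP protein stabilization | both layers quantified, protein up in both strains, transcript **not** up in both |

"Switch" membership comes from the annotation's `gene_class` (TF or
lncRNA), supplied as input — identifying transcription factors is
curation, not computation. H2/H3 membership excludes H6 by construction.
Accession-only proteins passing the H6 expression pattern are reported
but not listed as gene candidates, since they cannot be deduplicated or
positioned.

CYP clusters are single-linkage chains of H2/H3 CYPs on one chromosome
with inter-span gaps of at most 100 kb; the gap is a package default (the
clusters are named, not distance-defined, in the source material), and
only clusters of two or more genes are reported.

The locus filter passes a gene if its span intersects any mapped locus.
Two hypotheses are exempt: H3, because a duplication is invisible in a
SNP-density chromosome scan, and H6, because protein stabilization needs
no cis-linked DNA change at the CYP. Genes on unplaced scaffolds are
retained and flagged `unfilterable`. Consolidation deduplicates by exact
gene id across hypotheses and reports per-hypothesis counts, the union,
and the H4+H5 "switch" union; the post-filter list is always a subset of
the pre-filter list.

## The synthetic data generator

The generator emulates the congenic design's *downstream products*, not
its raw data: homozygous genotype calls across the three strains,
negative-binomial gene counts, and PSM-level TMT S/N tables. Defaults are
the study conditions: three chromosomes at 310/474/410 Mb, two
introgressed blocks (chr1:100-130 Mb and chr3:310-340 Mb, the causal
locus inside the chromosome-3 block), donor-specific SNPs at 20/Mb
(hom-alt in SP genome-wide, in CKR only inside blocks), ancestral
background divergence at 1/Mb shared by all three strains, 2% injected
heterozygous calls to exercise the homozygous-only filter, 4/4/4 RNA
replicates, the 4/3/3 ROCK/SP/CKR TMT channel layout, NB dispersion 0.05,
and log-normal protein noise with CV 20%.

Three defaults deserve justification. The planted transcript effect is
log2FC = 3, the magnitude the up-regulated CYPs actually show (observed
range ~1.7-4.5). Protein effects are the transcript effects damped by a
concordance factor of 0.5, matching the observed protein/transcript
fold-change ratio of dual-quantified CYPs (~0.5); stabilized CYPs instead
get the full protein effect with zero transcript effect. And 200 genes
are simulated per chromosome so that planted effects are ~3% of the
simulated proteome: with many fewer genes, the planted up-regulation
inflates resistant-channel totals and total-amount normalization visibly
attenuates every ratio — an artifact of a too-small proteome, not a
feature of the design.

Genome and transcript sequences are generated only when the configured
genome is small (<= 50 Mb total, or on request): the coordinate-level
stages (patterns, locus scan, expression, proteomics, classification)
never need sequence, and sequence-level stages (effect annotation,
proteome construction) are exercised on scaled-down genomes. Simulated
reference CDSs are made stop-free so translation artifacts do not
confound sequence-level tests.

What the generator does **not** emulate: read-level noise and mapping
bias, linkage and recombination beyond fixed introgression blocks,
residual heterozygosity structure of real selected strains (the 2% het
rate is a placeholder, not an inference), MS spectral noise, shared
peptides at realistic rates, batch effects, and gene-length or GC biases
in counts. Passing tests therefore demonstrate correctness of the
algorithms under the stated generative model, not robustness to every
artifact of real sequencing or MS data.

## Problem sizes and determinism

The test suite and the acceptance script run simulations at the sizes
above (600 genes, ~25,000 variant sites, ~510 proteins per run; 20 seeds
for recovery rates, 50 for locus-scan recovery), chosen so the full suite
completes in minutes on one CPU while keeping every planted-signal check
at the study's own design scale. All randomness flows from a single
integer seed per run; identical configuration and seed give byte-identical
datasets.

## Known limitations

* The NB exact test is not numerically identical to any specific GLM
  implementation; agreement is at the level of calibration and power, by
  design.
* The proteomics p-values are plain t-tests; spectral-search engines
  compute theirs differently, so absolute p-values are not comparable
  across tools.
* The effect annotator reports one class per SNP (most severe across
  transcripts), a stated decision; per-transcript reporting would change
  category counts.
* Candidate classification is only as good as the supplied `gene_class`
  curation; a mislabelled transcription factor silently moves between
  hypothesis sets.
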
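# congenicomics

Multi-omics candidate-gene mapping of cytochrome P450 (CYP) mediated
pyrethroid resistance in congenic mosquito strains.

## The problem

Pyrethroid-resistant *Aedes aegypti* overexpress detoxifying CYPs, but the
mutations *causing* that overexpression are hard to pin down: comparing an
unrelated resistant strain with a susceptible one yields hundreds of
differences, almost all irrelevant. A congenic design sharpens the picture.
Starting from a susceptible recipient strain (ROCK) and a resistant donor
strain (SP), repeated backcrossing with selection produces a congenic
strain (CKR) that carries only the SP resistance loci in an otherwise ROCK
background. Any variant or expression difference shared by SP **and** CKR
relative to ROCK is then a strong resistance candidate, and the introgressed
blocks themselves light up as peaks of strain-specific SNP density.

`congenicomics` implements that analysis end to end as a tested R package:

* **Variant patterns** — quality filtering (QUAL >= 30), per-site genotype
  pattern classification across ROCK/SP/CKR (codes `a`-`d`), and selection
  of the resistance-associated pattern: hom-alt in SP and CKR, hom-ref in
  ROCK and the LVP reference. A minimal codon-level effect annotator
  classifies selected SNPs as non-synonymous, synonymous, 5' or 3'/intron.
* **Locus scan** — counts of resistance SNPs in 10-Mb windows; windows with
  more than 100 SNPs seed resistance loci, adjacent hot windows merge.
* **Differential expression** — CPM > 1 in >= 4 samples filtering, TMM
  normalization, a negative-binomial exact test with empirical-Bayes
  moderated tagwise dispersion, Benjamini-Hochberg FDR, and the
  |log2FC| >= 1 & FDR <= 0.01 significance rule.
* **TMT proteomics** — razor + unique peptide assignment, signal-to-noise
  rollup to protein abundance, total-peptide-amount normalization, and
  p <= 0.05 two-sample t-tests on log2 abundances.
* **Variant-informed proteome database** — strain variants substituted into
  the reference genome, strand-aware CDS extraction and translation, and
  longest-isoform-per-gene selection.
* **Integration** — full outer join of transcript and protein layers per
  gene, with Pearson correlation of log2 fold-changes over dual-quantified
  genes.
* **Hypothesis engine** — classifies every gene under six mechanistic
  hypotheses for CYP-mediated resistance (H1 CYP coding variant; H2 CYP
  promoter mutation; H3 CYP duplication; H4 coding variant in a regulatory
  "switch", i.e. a transcription factor or lncRNA; H5 switch promoter
  mutation; H6 CYP protein stabilization), detects clustered CYPs,
  filters candidates by mapped loci (duplication and stabilization
  candidates are exempt) and consolidates a deduplicated candidate list.
* **Synthetic data generator** — a seeded simulator of the whole congenic
  design (introgressed blocks, genotypes, NB counts, TMT PSM tables,
  sequences) with recorded ground truth, so every stage is testable
  without raw sequencing or mass-spectrometry data.

## Worked example

The packaged summary table of significantly up-regulated CYPs (transcript
and protein log2 fold-changes for SP/ROCK and CKR/ROCK) feeds the
hypothesis classifier directly:

```r
library(congenicomics)

j <- cyp_summary_as_joined()
sets <- classify_candidates(j$joined, NULL, j$catalog)
nrow(sets$H2)                          # CYPs up in both layers, both strains
#> [1] 10
nrow(sets$H6)                          # protein-up without transcript-up
#> [1] 5
sets$protein_only_accessions           # up in both strains, unannotated gene
#> [1] "EAT33129.1"
```

Ten CYPs are up-regulated at both transcript and protein level in both
resistant strains (the H2/H3 candidates, among them CYP9J26-28, CYP9M5/9M6
and CYP6AA6/6BB2, which form three tight clusters), five annotated CYPs are
up as protein only (the H6 protein-stabilization candidates), and one
further protein-only CYP is known only by an external accession.

Consolidating the packaged per-hypothesis candidate table reproduces the
headline candidate counts:

```r
cs <- example_candidate_sets()
consolidate(cs, "pre_filter")$n_candidates    # all six hypotheses, deduplicated
#> [1] 139
consolidate(cs, "post_filter")$n_switch       # H4+H5 switches after locus filter
#> [1] 65
```

The synthetic generator exercises the full pipeline with known truth:

```r
sim <- simulate_congenic_design(sim_config(seed = 1))
snps <- select_resistance_snps(sim$variants)
loci <- call_loci(window_counts(snps, sim$config$chromosome_lengths))
loci[, c("chrom", "start", "end", "peak_count")]
#>   chrom   start     end peak_count
#> 1  chr1 1.0e+08 1.3e+08        194
#> 2  chr3 3.1e+08 3.4e+08        192
```

Both called loci coincide with the planted introgression blocks
(chr1:100-130 Mb, chr3:310-340 Mb).

## Scope

Read alignment, variant calling, spectral search and figure styling are
upstream/downstream of this package and out of scope; inputs are VCF,
GFF3, FASTA, a gene-level count TSV and a PSM-level TMT TSV.
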
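Package: congenicomics
Title: Congenic-Strain Multi-Omics Mapping of CYP-Mediated Insecticide Resistance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for mapping cytochrome P450 (CYP) mediated
    pyrethroid resistance with congenic mosquito strains. Filters and
    classifies per-site genotype patterns across a susceptible recipient
    strain (ROCK), a resistant donor strain (SP) and a congenic
    introgression strain (CKR) to select resistance-associated homozygous
    SNPs; maps resistance loci from windowed SNP densities; performs
    gene-level RNA-seq differential expression (CPM filtering, TMM
    normalization, negative-binomial exact tests, Benjamini-Hochberg FDR);
    rolls up TMT peptide-spectrum-match signal-to-noise to protein
    abundances with razor-peptide assignment and total-amount
    normalization; builds strain-specific variant-informed protein
    databases; joins transcript and protein layers with Pearson
    fold-change concordance; and classifies candidate resistance genes
    under six mechanistic hypotheses with CYP cluster detection and
    locus-based filtering. Ships a synthetic congenic-introgression data
    generator with recorded ground truth so every stage is testable
    without raw sequencing or mass-spectrometry data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings,
    vcfR,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
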
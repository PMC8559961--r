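#' Construct a table of variant sites
#'
#' Builds the canonical per-site table used throughout the package: one row
#' per biallelic site with phred-scaled quality and one genotype column per
#' study strain.  The reference strain (LVP) carries the REF allele by
#' construction and is therefore implicitly homozygous-reference.
#'
#' @param chrom Chromosome/contig names.
#' @param pos 1-based positions (>= 1).
#' @param ref,alt Reference and alternate alleles (single bases for SNPs;
#'   longer strings for indels).
#' @param qual Phred-scaled site confidence (>= 0).
#' @param ROCK,SP,CKR Genotype state of each strain, one of `"hom_ref"`,
#'   `"het"`, `"hom_alt"`, `"missing"`.
#' @return A `data.frame` of class `variant_sites` with columns `chrom`,
#'   `pos`, `ref`, `alt`, `qual`, `ROCK`, `SP`, `CKR`.
#' @export
variant_sites <- function(chrom, pos, ref, alt, qual, ROCK, SP, CKR) {
  n <- length(pos)
  rec <- function(x) if (length(x) == 1L && n != 1L) rep_len(x, n) else x
  chrom <- rec(chrom); ref <- rec(ref); alt <- rec(alt); qual <- rec(qual)
  ROCK <- rec(ROCK); SP <- rec(SP); CKR <- rec(CKR)
  sites <- data.frame(
    chrom = as.character(chrom), pos = as.integer(pos),
    ref = as.character(ref), alt = as.character(alt),
    qual = as.numeric(qual),
    ROCK = as.character(ROCK), SP = as.character(SP), CKR = as.character(CKR),
    stringsAsFactors = FALSE
  )
  validate_variant_sites(sites)
}

GT_STATES <- c("hom_ref", "het", "hom_alt", "missing")
STUDY_STRAINS <- c("ROCK", "SP", "CKR")

validate_variant_sites <- function(sites) {
  stopifnot(is.data.frame(sites))
  missing_cols <- setdiff(c("chrom", "pos", "ref", "alt", "qual", STUDY_STRAINS),
                          names(sites))
  if (length(missing_cols))
    stop("variant site table lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (any(sites$pos < 1L)) stop("variant positions must be >= 1")
  if (any(sites$qual < 0)) stop("QUAL must be >= 0")
  for (s in STUDY_STRAINS) {
    bad <- !(sites[[s]] %in% GT_STATES)
    if (any(bad))
      stop("unknown genotype state for strain ", s, ": ",
           paste(unique(sites[[s]][bad]), collapse = ", "))
  }
  class(sites) <- unique(c("variant_sites", class(sites)))
  sites
}

#' Filter variant sites on phred-scaled quality
#'
#' Removes sites whose QUAL is below `min_qual`.  The boundary is kept at
#' equality: a site with QUAL exactly equal to the threshold is retained,
#' because only sites with confidence strictly lower than the threshold are
#' discarded.  Order is preserved and the operation is idempotent.
#'
#' @param sites A `variant_sites` table.
#' @param min_qual Minimum phred-scaled quality (default 30).
#' @return The subset of `sites` with `qual >= min_qual`.
#' @export
filter_quality <- function(sites, min_qual = 30) {
  if (!is.numeric(min_qual) || length(min_qual) != 1L || min_qual < 0)
    stop("min_qual must be a single non-negative number")
  sites <- validate_variant_sites(sites)
  out <- sites[sites$qual >= min_qual, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify the cross-strain genotype pattern of each site
#'
#' Assigns every site one of four homozygous-pattern codes, comparing the
#' susceptible recipient strain (ROCK), the resistant donor strain (SP) and
#' the congenic introgression strain (CKR):
#'
#' * `a`: ROCK differs from SP = CKR
#' * `b`: SP differs from ROCK = CKR
#' * `c`: CKR differs from ROCK = SP
#' * `d`: all three strains identical
#'
#' Codes are only assigned when all three strains are homozygous and called;
#' any heterozygous or missing genotype makes the site `uninformative`.
#' A site is flagged resistance-associated when it shows the congenic
#' introgression signature: homozygous-alternate in both resistant strains
#' (SP and CKR) and homozygous-reference in ROCK (code `a` with ROCK on the
#' reference allele, which is the LVP allele by VCF construction).
#'
#' @param sites A `variant_sites` table.
#' @return `sites` with columns `code` (factor-free character, one of
#'   `a`, `b`, `c`, `d`, `uninformative`) and `resistance_associated`
#'   (logical) appended.
#' @export
classify_genotype_pattern <- function(sites) {
  sites <- validate_variant_sites(sites)
  r <- sites$ROCK; s <- sites$SP; c_ <- sites$CKR
  hom <- function(g) g %in% c("hom_ref", "hom_alt")
  all_hom <- hom(r) & hom(s) & hom(c_)
  code <- rep("uninformative", nrow(sites))
  code[all_hom & s == c_ & r != s] <- "a"
  code[all_hom & r == c_ & s != r] <- "b"
  code[all_hom & r == s & c_ != r] <- "c"
  code[all_hom & r == s & s == c_] <- "d"
  sites$code <- code
  sites$resistance_associated <-
    code == "a" & s == "hom_alt" & c_ == "hom_alt" & r == "hom_ref"
  sites
}

#' Select resistance-associated homozygous SNPs
#'
#' Composition of the quality filter and the genotype-pattern classifier:
#' keeps exactly the sites that pass QUAL filtering and carry the
#' resistance-associated pattern (hom-alt in SP and CKR, hom-ref in ROCK and
#' hence in the LVP reference).
#'
#' @inheritParams filter_quality
#' @return The classified subset of resistance-associated sites, with a
#'   `"per_chrom"` attribute giving the per-chromosome site counts.
#' @export
select_resistance_snps <- function(sites, min_qual = 30) {
  kept <- classify_genotype_pattern(filter_quality(sites, min_qual))
  out <- kept[kept$resistance_associated, , drop = FALSE]
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "per_chrom") <- table(factor(out$chrom, levels = unique(out$chrom)))
  out
}

EFFECT_SEVERITY <- c("non_synonymous", "synonymous", "five_prime",
                     "three_prime_or_intron", "intergenic")

#' Annotate the predicted coding effect of variants
#'
#' A minimal positional/codon-level effect annotator.  SNPs falling in a CDS
#' are translated in place (strand-aware) and classified `synonymous` or
#' `non_synonymous` with an amino-acid-change detail (e.g. `"A2D"`); exonic
#' positions upstream of the CDS are `five_prime`; 3' UTR and intronic
#' positions collapse into `three_prime_or_intron`; everything else is
#' `intergenic`.  Coding indels are bucketed as `non_synonymous` with detail
#' `"indel"`.  When a variant hits several overlapping transcripts the most
#' severe category is reported (non_synonymous > synonymous > five_prime >
#' three_prime_or_intron > intergenic).
#'
#' @param sites A `variant_sites` table.
#' @param annotation A [gene_annotation] object.
#' @param genome_seq Named `DNAStringSet` (or named character vector) of
#'   chromosome sequences.
#' @return `sites` with columns `effect`, `effect_gene` and `effect_detail`
#'   appended.
#' @export
annotate_effect <- function(sites, annotation, genome_seq) {
  sites <- validate_variant_sites(sites)
  annotation <- validate_gene_annotation(annotation)
  if (is.character(genome_seq)) genome_seq <- Biostrings::DNAStringSet(genome_seq)
  bad_chrom <- setdiff(unique(sites$chrom), names(genome_seq))
  if (length(bad_chrom))
    stop("site on contig absent from the genome: ", paste(bad_chrom, collapse = ", "))

  tx_index <- build_transcript_index(annotation)
  n <- nrow(sites)
  eff <- character(n); gene <- rep(NA_character_, n); detail <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    res <- effect_one_site(sites$chrom[i], sites$pos[i], sites$ref[i],
                           sites$alt[i], tx_index, genome_seq)
    eff[i] <- res$category; gene[i] <- res$gene_id; detail[i] <- res$detail
  }
  sites$effect <- eff
  sites$effect_gene <- gene
  sites$effect_detail <- detail
  sites
}

# Precompute per-transcript spliced CDS coordinates (in transcription order)
# and exon/CDS interval sets; validates CDS length %% 3.
build_transcript_index <- function(annotation) {
  genes <- annotation$genes
  txs <- annotation$transcripts
  feats <- annotation$features
  idx <- vector("list", nrow(txs))
  for (i in seq_len(nrow(txs))) {
    tx <- txs$tx_id[i]
    g <- genes[genes$gene_id == txs$gene_id[i], , drop = FALSE]
    f <- feats[feats$tx_id == tx, , drop = FALSE]
    ex <- f[f$type == "exon", , drop = FALSE]
    cds <- f[f$type == "CDS", , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    cds <- cds[order(cds$start), , drop = FALSE]
    cds_len <- sum(cds$end - cds$start + 1L)
    if (nrow(cds) && cds_len %% 3L != 0L)
      stop("CDS length of transcript ", tx, " is not a multiple of 3")
    # genomic positions of spliced CDS in transcription order
    cds_pos <- unlist(lapply(seq_len(nrow(cds)),
                             function(k) seq.int(cds$start[k], cds$end[k])))
    strand <- g$strand[1]
    if (identical(strand, "-")) cds_pos <- rev(cds_pos)
    idx[[i]] <- list(tx_id = tx, gene_id = g$gene_id[1], chrom = g$chrom[1],
                     strand = strand, gene_start = g$start[1], gene_end = g$end[1],
                     exons = ex[, c("start", "end"), drop = FALSE],
                     cds = cds[, c("start", "end"), drop = FALSE],
                     cds_pos = cds_pos)
  }
  idx
}

effect_one_site <- function(chrom, pos, ref, alt, tx_index, genome_seq) {
  best <- list(category = "intergenic", gene_id = NA_character_, detail = NA_character_)
  rank <- function(cat) match(cat, EFFECT_SEVERITY)
  is_indel <- nchar(ref) != nchar(alt)
  for (tx in tx_index) {
    if (tx$chrom != chrom || pos < tx$gene_start || pos > tx$gene_end) next
    in_cds <- length(tx$cds_pos) && pos %in% tx$cds_pos
    if (in_cds) {
      if (is_indel) {
        cand <- list(category = "non_synonymous", gene_id = tx$gene_id, detail = "indel")
      } else {
        cand <- classify_cds_snp(tx, chrom, pos, alt, genome_seq)
      }
    } else {
      in_exon <- any(pos >= tx$exons$start & pos <= tx$exons$end)
      if (in_exon && length(tx$cds_pos)) {
        # transcription-order comparison against the CDS start
        cds_first <- tx$cds_pos[1]
        upstream <- if (tx$strand == "-") pos > cds_first else pos < cds_first
        cand <- list(category = if (upstream) "five_prime" else "three_prime_or_intron",
                     gene_id = tx$gene_id, detail = NA_character_)
      } else {
        # intron (or exon of a non-coding transcript)
        cand <- list(category = "three_prime_or_intron", gene_id = tx$gene_id,
                     detail = NA_character_)
      }
    }
    if (rank(cand$category) < rank(best$category)) best <- cand
  }
  best
}

classify_cds_snp <- function(tx, chrom, pos, alt, genome_seq) {
  i <- match(pos, tx$cds_pos)              # 1-based index along the spliced CDS
  codon_idx <- (i - 1L) %/% 3L
  codon_pos <- tx$cds_pos[(codon_idx * 3L + 1L):(codon_idx * 3L + 3L)]
  base_at <- function(p, alt_at = NA) {
    b <- as.character(Biostrings::subseq(genome_seq[[chrom]], p, p))
    if (!is.na(alt_at) && p == alt_at) b <- alt
    if (tx$strand == "-")
      b <- as.character(Biostrings::complement(Biostrings::DNAString(b)))
    b
  }
  ref_codon <- paste0(vapply(codon_pos, base_at, ""))
  alt_codon <- paste0(vapply(codon_pos, base_at, "", alt_at = pos))
  ref_codon <- paste(ref_codon, collapse = "")
  alt_codon <- paste(alt_codon, collapse = "")
  tr <- function(codon) as.character(Biostrings::translate(
    Biostrings::DNAString(codon), no.init.codon = TRUE))
  aa_ref <- tr(ref_codon)
  aa_alt <- tr(alt_codon)
  if (aa_ref == aa_alt) {
    list(category = "synonymous", gene_id = tx$gene_id,
         detail = paste0(aa_ref, codon_idx + 1L, aa_alt))
  } else {
    list(category = "non_synonymous", gene_id = tx$gene_id,
         detail = paste0(aa_ref, codon_idx + 1L, aa_alt))
  }
}
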
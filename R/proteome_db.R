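#' Substitute strain-specific variants into a reference genome
#'
#' Applies homozygous-alternate variants of one strain to the reference
#' sequence: SNP bases are replaced in place; indels splice the alternate
#' allele in for the reference allele.  Every variant's REF allele is
#' checked against the genome and a mismatch is an error naming the site.
#' Overlapping variants are rejected.
#'
#' @param genome_seq Named `DNAStringSet` (or named character vector).
#' @param variants `data.frame` with columns `chrom`, `pos`, `ref`, `alt`
#'   (only the variants already restricted to the strain of interest).
#' @return A named `DNAStringSet` of the strain-specific genome.
#' @export
apply_variants <- function(genome_seq, variants) {
  if (is.character(genome_seq)) genome_seq <- Biostrings::DNAStringSet(genome_seq)
  out <- as.character(genome_seq)
  if (nrow(variants) == 0) return(Biostrings::DNAStringSet(out))
  for (ch in unique(variants$chrom)) {
    v <- variants[variants$chrom == ch, , drop = FALSE]
    v <- v[order(v$pos), , drop = FALSE]
    ends <- v$pos + nchar(v$ref) - 1L
    if (nrow(v) > 1 && any(v$pos[-1] <= ends[-nrow(v)]))
      stop("overlapping variants on ", ch)
    seq_ch <- out[[ch]]
    obs <- substring(seq_ch, v$pos, ends)
    bad <- obs != v$ref
    if (any(bad))
      stop("REF allele mismatch at ", ch, ":", v$pos[which(bad)[1]],
           " (genome has ", obs[which(bad)[1]], ", variant says ",
           v$ref[which(bad)[1]], ")")
    # rebuild right-to-left so earlier coordinates stay valid
    for (i in rev(seq_len(nrow(v)))) {
      seq_ch <- paste0(substring(seq_ch, 1L, v$pos[i] - 1L), v$alt[i],
                       substring(seq_ch, ends[i] + 1L, nchar(seq_ch)))
    }
    out[[ch]] <- seq_ch
  }
  Biostrings::DNAStringSet(out)
}

#' Extract spliced CDS sequences and translate them
#'
#' For every transcript, concatenates its CDS intervals strand-aware
#' (reverse-complemented on the minus strand), translates with the standard
#' genetic code, and truncates at the first stop codon.  A stop before the
#' annotated end (e.g. introduced by a substituted variant) sets a
#' `premature_stop` flag; ambiguous codons translate to `X`.
#'
#' @param genome_seq Named `DNAStringSet` (reference or strain-specific).
#' @param annotation A [gene_annotation] object.
#' @return `data.frame`: `tx_id`, `gene_id`, `protein` (amino-acid string,
#'   stop excluded), `aa_length`, `premature_stop`.
#' @export
extract_and_translate <- function(genome_seq, annotation) {
  if (is.character(genome_seq)) genome_seq <- Biostrings::DNAStringSet(genome_seq)
  annotation <- validate_gene_annotation(annotation)
  idx <- build_transcript_index(annotation)
  res <- lapply(idx, function(tx) {
    if (!length(tx$cds_pos)) return(NULL)
    cds <- paste(vapply(seq_len(nrow(tx$cds)), function(k)
      as.character(Biostrings::subseq(genome_seq[[tx$chrom]],
                                      tx$cds$start[k], tx$cds$end[k])), ""),
      collapse = "")
    if (tx$strand == "-")
      cds <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                             no.init.codon = TRUE,
                                             if.fuzzy.codon = "X"))
    n_codons <- nchar(aa)
    stop_at <- regexpr("*", aa, fixed = TRUE)
    premature <- FALSE
    if (stop_at > 0) {
      premature <- stop_at < n_codons
      aa <- substring(aa, 1L, stop_at - 1L)
    }
    data.frame(tx_id = tx$tx_id, gene_id = tx$gene_id, protein = aa,
               aa_length = nchar(aa), premature_stop = premature,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Keep the longest protein isoform per gene
#'
#' @param proteins Output of [extract_and_translate()].
#' @return One row per gene: the longest isoform, ties broken by the
#'   lexicographically smallest transcript id.
#' @export
longest_isoform <- function(proteins) {
  ord <- order(proteins$gene_id, -proteins$aa_length, proteins$tx_id)
  p <- proteins[ord, , drop = FALSE]
  out <- p[!duplicated(p$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a strain-specific variant-informed protein database
#'
#' End-to-end convenience: substitute the strain's homozygous variants into
#' the reference genome, extract and translate all annotated CDSs, and keep
#' the longest isoform of each gene.
#'
#' @inheritParams apply_variants
#' @param annotation A [gene_annotation] object.
#' @param strain Strain label recorded in FASTA headers.
#' @param fasta_path Optional output path; when given, protein FASTA is
#'   written with headers `>gene_id|transcript_id strain=NAME`.
#' @return The longest-isoform protein `data.frame` (invisibly returns the
#'   path attribute when written).
#' @export
build_proteome_db <- function(genome_seq, variants, annotation, strain,
                              fasta_path = NULL) {
  strain_genome <- apply_variants(genome_seq, variants)
  prot <- longest_isoform(extract_and_translate(strain_genome, annotation))
  if (!is.null(fasta_path)) {
    aa <- Biostrings::AAStringSet(prot$protein)
    names(aa) <- sprintf("%s|%s strain=%s", prot$gene_id, prot$tx_id, strain)
    Biostrings::writeXStringSet(aa, fasta_path)
    attr(prot, "fasta_path") <- fasta_path
  }
  prot
}
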
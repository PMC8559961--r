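GT_CODE <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1", missing = "./.")

#' Write variant sites as a VCF v4.2 file
#'
#' Emits a minimal plain-text VCF with QUAL and per-strain GT fields
#' (ROCK, SP, CKR sample columns); genotypes are encoded `0/0`, `0/1`,
#' `1/1` or `./.`.
#'
#' @param sites A `variant_sites` table.
#' @param path Output path.
#' @param chrom_lengths Optional named vector used to write contig header
#'   lines.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(sites, path, chrom_lengths = NULL) {
  sites <- validate_variant_sites(sites)
  header <- c("##fileformat=VCFv4.2",
              "##source=congenicomics",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
  if (!is.null(chrom_lengths))
    header <- c(header, sprintf("##contig=<ID=%s,length=%d>",
                                names(chrom_lengths),
                                as.integer(chrom_lengths)))
  header <- c(header, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                              "FILTER", "INFO", "FORMAT", STUDY_STRAINS),
                            collapse = "\t"))
  body <- paste(sites$chrom, sites$pos, ".", sites$ref, sites$alt,
                format(sites$qual, trim = TRUE), ".", ".", "GT",
                GT_CODE[sites$ROCK], GT_CODE[sites$SP], GT_CODE[sites$CKR],
                sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a VCF into a variant site table
#'
#' Parses GT and QUAL; multi-allelic records are split into biallelic
#' sites (each ALT allele becomes its own site, genotypes collapsed onto
#' carrying that allele homozygously / heterozygously).
#'
#' @param path VCF file with ROCK, SP and CKR sample columns.
#' @return A `variant_sites` table.
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (!all(STUDY_STRAINS %in% colnames(gt)))
    stop("VCF must contain sample columns ", paste(STUDY_STRAINS, collapse = ", "))
  decode <- function(g, allele) {
    g <- gsub("|", "/", g, fixed = TRUE)
    out <- rep("missing", length(g))
    a <- as.character(allele)
    out[g == "0/0"] <- "hom_ref"
    out[g == paste0(a, "/", a)] <- "hom_alt"
    het <- grepl("/", g, fixed = TRUE) & !g %in% c("0/0", paste0(a, "/", a)) &
      !grepl("\\.", g) &
      vapply(strsplit(g, "/", fixed = TRUE),
             function(x) any(x == a) | any(x == "0"), NA)
    out[het] <- "het"
    out
  }
  rows <- list()
  alts <- strsplit(as.character(fix[, "ALT"]), ",", fixed = TRUE)
  for (i in seq_len(nrow(fix))) {
    for (k in seq_along(alts[[i]])) {
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
        ref = fix[i, "REF"], alt = alts[[i]][k],
        qual = as.numeric(fix[i, "QUAL"]),
        ROCK = decode(gt[i, "ROCK"], k),
        SP = decode(gt[i, "SP"], k),
        CKR = decode(gt[i, "CKR"], k),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  validate_variant_sites(out)
}

#' Write a synthetic dataset to disk
#'
#' Emits the simulated dataset as standard plain-text files: VCF (one file,
#' ROCK/SP/CKR sample columns), GFF3 annotation, counts TSV plus sample
#' map, PSM TSV plus channel map, truth JSON and - when sequences were
#' generated - genome and spliced-transcript FASTA.  All files round-trip
#' through the package's own readers (see [read_dataset()]).
#'
#' @param sim A `congenic_sim` from [simulate_congenic_design()].
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of the paths written, invisibly.
#' @export
write_dataset <- function(sim, out_dir) {
  stopifnot(inherits(sim, "congenic_sim"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  paths <- c(vcf = p("variants.vcf"), gff = p("annotation.gff3"),
             counts = p("counts.tsv"), samples = p("samples.tsv"),
             psms = p("psms.tsv"), channels = p("channels.tsv"),
             truth = p("truth.json"))
  write_vcf(sim$variants, paths[["vcf"]],
            chrom_lengths = sim$config$chromosome_lengths)
  write_gff3(sim$annotation, paths[["gff"]])
  write_counts_tsv(sim$counts, paths[["counts"]], paths[["samples"]])
  write_psm_tsv(sim$psms, paths[["psms"]], paths[["channels"]])
  truth <- sim$truth
  truth$transcript_lfc <- as.list(truth$transcript_lfc)
  truth$protein_lfc <- as.list(truth$protein_lfc)
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "columns")
  if (!is.null(sim$sequences)) {
    paths <- c(paths, genome = p("genome.fa"), transcripts = p("transcripts.fa"))
    Biostrings::writeXStringSet(sim$sequences, paths[["genome"]])
    Biostrings::writeXStringSet(spliced_transcripts(sim$sequences, sim$annotation),
                                paths[["transcripts"]])
  }
  invisible(paths)
}

#' Extract spliced transcript sequences
#'
#' Concatenates exon sequences per transcript, reverse-complementing on
#' the minus strand.
#'
#' @param genome_seq Named `DNAStringSet`.
#' @param annotation A [gene_annotation].
#' @return A named `DNAStringSet` of transcript sequences.
#' @export
spliced_transcripts <- function(genome_seq, annotation) {
  idx <- build_transcript_index(annotation)
  seqs <- vapply(idx, function(tx) {
    s <- paste(vapply(seq_len(nrow(tx$exons)), function(k)
      as.character(Biostrings::subseq(genome_seq[[tx$chrom]],
                                      tx$exons$start[k], tx$exons$end[k])), ""),
      collapse = "")
    if (tx$strand == "-")
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    s
  }, "")
  names(seqs) <- vapply(idx, `[[`, "", "tx_id")
  Biostrings::DNAStringSet(seqs)
}

#' Read a synthetic dataset back from disk
#'
#' Counterpart of [write_dataset()].
#'
#' @param dir Directory written by [write_dataset()].
#' @return A list with `variants`, `annotation`, `counts`, `psms`, `truth`
#'   and (when present) `sequences`.
#' @export
read_dataset <- function(dir) {
  p <- function(f) file.path(dir, f)
  truth <- jsonlite::read_json(p("truth.json"), simplifyVector = TRUE)
  truth$transcript_lfc <- unlist(truth$transcript_lfc)
  truth$protein_lfc <- unlist(truth$protein_lfc)
  out <- list(
    variants = read_vcf(p("variants.vcf")),
    annotation = read_gff3(p("annotation.gff3")),
    counts = read_counts_tsv(p("counts.tsv"), p("samples.tsv")),
    psms = read_psm_tsv(p("psms.tsv"), p("channels.tsv")),
    truth = truth
  )
  if (file.exists(p("genome.fa")))
    out$sequences <- Biostrings::readDNAStringSet(p("genome.fa"))
  out
}
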
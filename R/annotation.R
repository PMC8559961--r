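#' Construct a gene annotation object
#'
#' Lightweight container for gene models: a gene table (coordinates, strand,
#' functional class), a transcript table and a per-transcript feature table
#' (exon and CDS intervals).  Coordinates are 1-based inclusive, matching
#' GFF3.  The gene class vocabulary drives the hypothesis engine: `CYP`
#' (cytochrome P450), `TF` (transcription factor), `lncRNA` (long non-coding
#' RNA) and `other`; TF and lncRNA genes together form the candidate
#' regulatory "switch" class.
#'
#' @param genes `data.frame` with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand` (`"+"`/`"-"`), `gene_class`; optional `cyp_name`.
#' @param transcripts `data.frame` with columns `tx_id`, `gene_id`.
#' @param features `data.frame` with columns `tx_id`, `type`
#'   (`"exon"`/`"CDS"`), `start`, `end`.
#' @return A list of class `gene_annotation`.
#' @export
gene_annotation <- function(genes, transcripts, features) {
  if (is.null(genes$cyp_name)) genes$cyp_name <- NA_character_
  ann <- structure(list(genes = genes, transcripts = transcripts,
                        features = features),
                   class = "gene_annotation")
  validate_gene_annotation(ann)
}

GENE_CLASSES <- c("CYP", "TF", "lncRNA", "other")

validate_gene_annotation <- function(ann) {
  stopifnot(inherits(ann, "gene_annotation") || is.list(ann))
  g <- ann$genes
  need <- setdiff(c("gene_id", "chrom", "start", "end", "strand", "gene_class"),
                  names(g))
  if (length(need)) stop("gene table lacks column(s): ", paste(need, collapse = ", "))
  if (anyDuplicated(g$gene_id)) stop("duplicate gene ids in annotation")
  bad <- !(g$gene_class %in% GENE_CLASSES)
  if (any(bad)) stop("unknown gene_class: ", paste(unique(g$gene_class[bad]), collapse = ", "))
  if (any(g$end < g$start)) stop("gene end < start")
  f <- ann$features
  if (nrow(f) && any(!f$type %in% c("exon", "CDS")))
    stop("feature types must be exon or CDS")
  class(ann) <- "gene_annotation"
  ann
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat("gene_annotation:", nrow(x$genes), "genes,", nrow(x$transcripts),
      "transcripts on", length(unique(x$genes$chrom)), "contig(s)\n")
  print(table(x$genes$gene_class))
  invisible(x)
}

#' Write a gene annotation to GFF3
#'
#' Emits gene, mRNA, exon and CDS features with `ID`/`Parent` links and the
#' package's `gene_class` (and optional `cyp_name`) attributes on gene rows.
#'
#' @param annotation A [gene_annotation] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(annotation, path) {
  annotation <- validate_gene_annotation(annotation)
  g <- annotation$genes; t <- annotation$transcripts; f <- annotation$features
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(g))) {
    attrs <- sprintf("ID=%s;gene_class=%s", g$gene_id[i], g$gene_class[i])
    if (!is.na(g$cyp_name[i])) attrs <- paste0(attrs, ";cyp_name=", g$cyp_name[i])
    lines <- c(lines, paste(g$chrom[i], "congenicomics", "gene", g$start[i],
                            g$end[i], ".", g$strand[i], ".", attrs, sep = "\t"))
    for (tx in t$tx_id[t$gene_id == g$gene_id[i]]) {
      ftx <- f[f$tx_id == tx, , drop = FALSE]
      lines <- c(lines, paste(g$chrom[i], "congenicomics", "mRNA",
                              min(ftx$start), max(ftx$end), ".", g$strand[i], ".",
                              sprintf("ID=%s;Parent=%s", tx, g$gene_id[i]),
                              sep = "\t"))
      for (k in seq_len(nrow(ftx))) {
        phase <- if (ftx$type[k] == "CDS") "0" else "."
        lines <- c(lines, paste(g$chrom[i], "congenicomics", ftx$type[k],
                                ftx$start[k], ftx$end[k], ".", g$strand[i], phase,
                                sprintf("Parent=%s", tx), sep = "\t"))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene annotation from GFF3
#'
#' @param path GFF3 file with gene/mRNA/exon/CDS features carrying
#'   `ID`/`Parent` and (on genes) `gene_class` attributes.
#' @return A [gene_annotation] object.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  gene_rows <- df[df$type == "gene", , drop = FALSE]
  genes <- data.frame(
    gene_id = as.character(gene_rows$ID),
    chrom = as.character(gene_rows$seqnames),
    start = gene_rows$start, end = gene_rows$end,
    strand = as.character(gene_rows$strand),
    gene_class = if ("gene_class" %in% names(gene_rows))
      as.character(gene_rows$gene_class) else "other",
    cyp_name = if ("cyp_name" %in% names(gene_rows))
      as.character(gene_rows$cyp_name) else NA_character_,
    stringsAsFactors = FALSE
  )
  mrna <- df[df$type == "mRNA", , drop = FALSE]
  parent_of <- function(x) vapply(x, function(p) as.character(p)[1], "")
  transcripts <- data.frame(
    tx_id = as.character(mrna$ID),
    gene_id = parent_of(mrna$Parent),
    stringsAsFactors = FALSE
  )
  frows <- df[df$type %in% c("exon", "CDS"), , drop = FALSE]
  features <- data.frame(
    tx_id = parent_of(frows$Parent),
    type = as.character(frows$type),
    start = frows$start, end = frows$end,
    stringsAsFactors = FALSE
  )
  gene_annotation(genes, transcripts, features)
}
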
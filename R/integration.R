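#' Join transcript-level and protein-level results per gene
#'
#' Full outer join of the RNA-seq differential-expression records and the
#' protein quantification records on gene id, producing one row per gene
#' (or per accession-only protein) with both layers' fold-changes and
#' significance calls for the SP/ROCK and CKR/ROCK comparisons and a
#' `layer_presence` flag (`both`, `transcript_only`, `protein_only`).
#' Proteins that do not resolve to an annotated gene keep a null `gene_id`
#' and are retained under their accession.
#'
#' @param de_sp,de_ckr DE `data.frame`s from [test_de()] for the SP/ROCK
#'   and CKR/ROCK comparisons (or compatible tables with `gene_id`,
#'   `log2fc`, `call`).
#' @param prot_sp,prot_ckr Protein `data.frame`s from [test_protein_de()]
#'   for the same comparisons (with `protein`, `log2_ratio`, `call`).
#' @param id_map Optional `data.frame` (`protein`, `gene_id`) resolving
#'   protein ids to gene ids; `NA` gene_id marks unannotated proteins.
#'   By default protein ids are assumed to be gene ids already.
#' @param gene_info Optional `data.frame` (`gene_id`, `gene_class`,
#'   `chrom`, `start`, `end`) merged onto the result.
#' @return `data.frame` of class `joined_layers`: `gene_id`, `accession`,
#'   `gene_class`, `chrom`, `start`, `end`, `mrna_lfc_sp`, `mrna_call_sp`,
#'   `mrna_lfc_ckr`, `mrna_call_ckr`, `prot_lfc_sp`, `prot_call_sp`,
#'   `prot_lfc_ckr`, `prot_call_ckr`, `layer_presence`; the attribute
#'   `"layer_counts"` holds the both/transcript_only/protein_only tally.
#' @export
join_layers <- function(de_sp, de_ckr, prot_sp, prot_ckr, id_map = NULL,
                        gene_info = NULL) {
  tx <- merge(
    stats::setNames(de_sp[, c("gene_id", "log2fc", "call")],
                    c("gene_id", "mrna_lfc_sp", "mrna_call_sp")),
    stats::setNames(de_ckr[, c("gene_id", "log2fc", "call")],
                    c("gene_id", "mrna_lfc_ckr", "mrna_call_ckr")),
    by = "gene_id", all = TRUE)
  if (anyDuplicated(tx$gene_id)) stop("duplicate gene ids in transcript layer")

  pr <- merge(
    stats::setNames(prot_sp[, c("protein", "log2_ratio", "call")],
                    c("protein", "prot_lfc_sp", "prot_call_sp")),
    stats::setNames(prot_ckr[, c("protein", "log2_ratio", "call")],
                    c("protein", "prot_lfc_ckr", "prot_call_ckr")),
    by = "protein", all = TRUE)
  if (anyDuplicated(pr$protein)) stop("duplicate protein ids in protein layer")
  if (is.null(id_map)) {
    pr$gene_id <- pr$protein
  } else {
    pr$gene_id <- id_map$gene_id[match(pr$protein, id_map$protein)]
  }
  pr$accession <- pr$protein
  # unannotated proteins join on their accession so they survive the outer join
  pr$join_id <- ifelse(is.na(pr$gene_id), paste0("accession:", pr$accession),
                       pr$gene_id)
  tx$join_id <- tx$gene_id
  joined <- merge(tx, pr[, setdiff(names(pr), c("protein", "gene_id"))],
                  by = "join_id", all = TRUE)
  joined$gene_id <- ifelse(startsWith(joined$join_id, "accession:"),
                           NA_character_, joined$join_id)
  joined$join_id <- NULL
  has_tx <- !is.na(joined$mrna_lfc_sp) | !is.na(joined$mrna_lfc_ckr) |
    !is.na(joined$mrna_call_sp) | !is.na(joined$mrna_call_ckr)
  has_pr <- !is.na(joined$prot_lfc_sp) | !is.na(joined$prot_lfc_ckr) |
    !is.na(joined$prot_call_sp) | !is.na(joined$prot_call_ckr)
  joined$layer_presence <- ifelse(has_tx & has_pr, "both",
                                  ifelse(has_tx, "transcript_only", "protein_only"))
  if (!is.null(gene_info)) {
    joined <- merge(joined, gene_info, by = "gene_id", all.x = TRUE)
  } else {
    joined$gene_class <- NA_character_
    joined$chrom <- NA_character_; joined$start <- NA_real_; joined$end <- NA_real_
  }
  joined <- joined[order(is.na(joined$gene_id), joined$gene_id, joined$accession), ,
                   drop = FALSE]
  rownames(joined) <- NULL
  attr(joined, "layer_counts") <- table(factor(
    joined$layer_presence, levels = c("both", "transcript_only", "protein_only")))
  class(joined) <- c("joined_layers", class(joined))
  joined
}

#' Pearson correlation of transcript vs protein fold-changes
#'
#' Pearson r between transcript and protein log2 fold-changes over genes
#' quantified in both layers, with the least-squares regression line.  Only
#' dual-layer genes enter, which tends to overestimate the concordance of
#' the full gene complement -- the convention is kept for comparability
#' with dual-quantified reporting.
#'
#' @param joined A `joined_layers` table (or any data.frame with the two
#'   fold-change columns).
#' @param comparison `"SP"` or `"CKR"` (which strain-vs-ROCK pair to use).
#' @param subset Optional logical vector selecting rows (e.g.
#'   `joined$gene_class == "CYP"`).
#' @return A list: `r`, `slope`, `intercept`, `n`, and `defined` (FALSE
#'   when either coordinate has zero variance, in which case `r` is `NA`).
#' @export
pearson_logfc <- function(joined, comparison = c("SP", "CKR"), subset = NULL) {
  comparison <- match.arg(comparison)
  xcol <- if (comparison == "SP") "mrna_lfc_sp" else "mrna_lfc_ckr"
  ycol <- if (comparison == "SP") "prot_lfc_sp" else "prot_lfc_ckr"
  df <- as.data.frame(joined)
  if (!is.null(subset)) df <- df[which(subset), , drop = FALSE]
  ok <- stats::complete.cases(df[, c(xcol, ycol)])
  x <- df[[xcol]][ok]; y <- df[[ycol]][ok]
  if (length(x) < 3) stop("need >= 3 dual-layer records (got ", length(x), ")")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, slope = NA_real_, intercept = NA_real_,
                n = length(x), defined = FALSE))
  fit <- stats::lm(y ~ x)
  list(r = stats::cor(x, y), slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]), n = length(x), defined = TRUE)
}
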
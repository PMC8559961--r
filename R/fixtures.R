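#' Packaged worked-example tables
#'
#' Three small published summary tables ship with the package as worked
#' examples for the hypothesis engine and the resolution analysis:
#'
#' * `cyp_overexpression_summary`: per-CYP transcript and protein log2
#'   fold-changes (SP/ROCK and CKR/ROCK) of the significantly up-regulated
#'   CYPs; a blank (NA) cell means no significant change in that layer and
#'   comparison.  One entry is an accession-only protein with no annotated
#'   gene.
#' * `strain_resolution_counts`: numbers of differential hits found using
#'   the donor strain alone, the congenic strain alone, and both.
#' * `candidate_hypotheses`: the per-hypothesis candidate gene lists with
#'   each gene's locus-filter verdict and unplaced-scaffold flag.
#'
#' @param name One of `"cyp_overexpression_summary"`,
#'   `"strain_resolution_counts"`, `"candidate_hypotheses"`.
#' @return A `data.frame`.
#' @export
load_example_table <- function(name = c("cyp_overexpression_summary",
                                        "strain_resolution_counts",
                                        "candidate_hypotheses")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".tsv"),
                      package = "congenicomics", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Joined transcript/protein layers from the CYP summary table
#'
#' Converts the packaged CYP fold-change summary into the `joined_layers`
#' shape consumed by [classify_candidates()]: a populated fold-change cell
#' means a significant `up` call (all planted values in this table are
#' positive), an NA cell in an otherwise-quantified gene means `ns`.
#' Annotated genes were quantified in both layers; the accession-only
#' protein is `protein_only`.
#'
#' @return A list: `joined` (data.frame in `joined_layers` layout) and
#'   `catalog` (minimal gene catalog: every entry a CYP on an unspecified
#'   chromosome).
#' @export
cyp_summary_as_joined <- function() {
  t2 <- load_example_table("cyp_overexpression_summary")
  annotated <- !grepl("\\.", t2$accession)   # accession-only ids carry a dot
  call_of <- function(v, quantified) ifelse(!quantified, NA_character_,
                                            ifelse(!is.na(v) & v > 0, "up", "ns"))
  joined <- data.frame(
    gene_id = ifelse(annotated, t2$accession, NA_character_),
    accession = t2$accession,
    gene_class = "CYP",
    chrom = NA_character_, start = NA_real_, end = NA_real_,
    mrna_lfc_sp = t2$mrna_sp, mrna_call_sp = call_of(t2$mrna_sp, annotated),
    mrna_lfc_ckr = t2$mrna_ckr, mrna_call_ckr = call_of(t2$mrna_ckr, annotated),
    prot_lfc_sp = t2$prot_sp, prot_call_sp = call_of(t2$prot_sp, TRUE),
    prot_lfc_ckr = t2$prot_ckr, prot_call_ckr = call_of(t2$prot_ckr, TRUE),
    layer_presence = ifelse(annotated, "both", "protein_only"),
    stringsAsFactors = FALSE)
  catalog <- data.frame(gene_id = t2$accession[annotated],
                        gene_class = "CYP",
                        chrom = NA_character_, start = NA_real_, end = NA_real_,
                        unplaced = TRUE,
                        cyp_name = t2$cyp_name[annotated],
                        stringsAsFactors = FALSE)
  list(joined = joined, catalog = catalog)
}

#' Candidate sets from the packaged per-hypothesis candidate table
#'
#' Reads the packaged candidate list and assembles a `candidate_sets`
#' object (via [candidate_sets_from_tables()]) whose `filter_status`
#' encodes each gene's published locus-filter verdict, ready for
#' [consolidate()].
#'
#' @return A `candidate_sets` object.
#' @export
example_candidate_sets <- function() {
  t5 <- load_example_table("candidate_hypotheses")
  tables <- lapply(split(t5, t5$hypothesis), function(df) {
    data.frame(gene_id = df$gene_id, gene_class = df$gene_class,
               unplaced = df$unplaced, passed_filter = df$passed_filter,
               stringsAsFactors = FALSE)
  })
  candidate_sets_from_tables(tables[c("H1", "H2", "H3", "H4", "H5", "H6")])
}
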
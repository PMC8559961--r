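#' Six mechanistic hypotheses for CYP-mediated resistance
#'
#' The candidate classifier screens every gene against six mechanistic
#' hypotheses for elevated CYP-mediated detoxification in the resistant
#' strains:
#'
#' * **H1** - amino-acid variant in a CYP itself: CYPs carrying a
#'   resistance-associated non-synonymous SNP (no expression change
#'   required; an expression-change flag is recorded).
#' * **H2** - promoter mutation of a CYP: CYP up-regulated at transcript
#'   AND protein level in BOTH resistant strains.
#' * **H3** - CYP gene duplication: same expression signature as H2 (the
#'   two differ only in mechanism, which expression data cannot separate);
#'   tightly clustered H2/H3 CYPs are additionally reported as candidate
#'   duplication units.
#' * **H4** - coding variant in a regulatory "switch": transcription factor
#'   or lncRNA with a resistance-associated non-synonymous SNP.
#' * **H5** - promoter mutation of a switch: TF/lncRNA transcript
#'   up-regulated in both resistant strains or down-regulated in both
#'   (repressors count too).
#' * **H6** - CYP protein stabilization: CYP quantified in both layers,
#'   protein up in both strains, but transcript NOT up in both.
#'
#' @name hypotheses
NULL

SWITCH_CLASSES <- c("TF", "lncRNA")

candidate_frame <- function(gene_ids, catalog, note) {
  idx <- match(gene_ids, catalog$gene_id)
  data.frame(gene_id = gene_ids,
             gene_class = catalog$gene_class[idx],
             chrom = catalog$chrom[idx],
             start = catalog$start[idx], end = catalog$end[idx],
             unplaced = if (!is.null(catalog$unplaced)) catalog$unplaced[idx]
                        else is.na(catalog$chrom[idx]),
             note = rep(note, length(gene_ids)),
             filter_status = rep(NA_character_, length(gene_ids)),
             stringsAsFactors = FALSE)
}

#' Classify candidate resistance genes under the six hypotheses
#'
#' @param joined A `joined_layers` table from [join_layers()] (calls for
#'   SP/ROCK and CKR/ROCK in both layers).
#' @param snps Annotated resistance SNPs: output of
#'   [select_resistance_snps()] run through [annotate_effect()] (needs
#'   `resistance_associated`, `effect`, `effect_gene`).  May have zero rows.
#' @param gene_catalog `data.frame` with `gene_id`, `gene_class`, `chrom`,
#'   `start`, `end` (optionally `unplaced`); genes missing a class are
#'   skipped with a warning.
#' @return A list of class `candidate_sets` with elements `H1`..`H6`
#'   (candidate data.frames), `protein_only_accessions` (accession-only
#'   proteins up in both strains that lack an annotated gene, reported but
#'   not candidates) and `h1_expression_flag` (per-H1-gene logical, TRUE if
#'   the gene also shows an expression change).
#' @seealso [hypotheses]
#' @export
classify_candidates <- function(joined, snps, gene_catalog) {
  joined <- as.data.frame(joined)
  no_class <- is.na(gene_catalog$gene_class)
  if (any(no_class)) {
    warning("skipping ", sum(no_class), " gene(s) without gene_class")
    gene_catalog <- gene_catalog[!no_class, , drop = FALSE]
  }
  cls <- function(ids) gene_catalog$gene_class[match(ids, gene_catalog$gene_id)]

  up <- function(x) !is.na(x) & x == "up"
  down <- function(x) !is.na(x) & x == "down"
  tx_up_both <- up(joined$mrna_call_sp) & up(joined$mrna_call_ckr)
  tx_down_both <- down(joined$mrna_call_sp) & down(joined$mrna_call_ckr)
  prot_up_both <- up(joined$prot_call_sp) & up(joined$prot_call_ckr)
  jcls <- cls(joined$gene_id)

  # H2/H3: CYP up in both layers, both strains
  h23_ids <- sort(joined$gene_id[!is.na(joined$gene_id) & jcls == "CYP" &
                                   tx_up_both & prot_up_both])
  # H6: both layers quantified, protein up in both, transcript not up in both
  h6_mask <- !is.na(joined$gene_id) & jcls == "CYP" &
    joined$layer_presence == "both" & prot_up_both & !tx_up_both
  h6_ids <- sort(joined$gene_id[h6_mask])
  # accession-only proteins up in both strains (unannotated; reported only)
  acc_mask <- is.na(joined$gene_id) & prot_up_both
  accessions <- sort(joined$accession[acc_mask])

  # SNP-driven hypotheses
  ns_genes <- character(0)
  if (!is.null(snps) && nrow(snps)) {
    ns <- snps$resistance_associated & !is.na(snps$effect) &
      snps$effect == "non_synonymous" & !is.na(snps$effect_gene)
    ns_genes <- unique(snps$effect_gene[ns])
  }
  h1_ids <- sort(ns_genes[cls(ns_genes) %in% "CYP"])
  h4_ids <- sort(ns_genes[cls(ns_genes) %in% SWITCH_CLASSES])

  # H5: switch transcript altered in the same direction in both strains
  h5_mask <- !is.na(joined$gene_id) & jcls %in% SWITCH_CLASSES &
    (tx_up_both | tx_down_both)
  h5_ids <- sort(joined$gene_id[h5_mask])

  h1_flag <- stats::setNames(
    h1_ids %in% joined$gene_id[tx_up_both | tx_down_both | prot_up_both],
    h1_ids)
  sets <- list(
    H1 = candidate_frame(h1_ids, gene_catalog, "non-synonymous resistance SNP in CYP"),
    H2 = candidate_frame(h23_ids, gene_catalog, "CYP up in both layers, both strains"),
    H3 = candidate_frame(h23_ids, gene_catalog, "CYP up in both layers, both strains (duplication reading)"),
    H4 = candidate_frame(h4_ids, gene_catalog, "non-synonymous resistance SNP in switch"),
    H5 = candidate_frame(h5_ids, gene_catalog, "switch transcript altered in both strains"),
    H6 = candidate_frame(h6_ids, gene_catalog, "CYP protein up without transcript up (stabilization)"),
    protein_only_accessions = accessions,
    h1_expression_flag = h1_flag
  )
  class(sets) <- "candidate_sets"
  sets
}

#' Assemble candidate sets from precomputed gene lists
#'
#' Builds a `candidate_sets` object directly from per-hypothesis gene
#' tables (e.g. a published candidate table), including an optional
#' locus-filter verdict per gene, so that [consolidate()] can be applied to
#' externally curated lists.
#'
#' @param tables Named list `H1`..`H6` of `data.frame`s with at least
#'   `gene_id`; optional `gene_class`, `chrom`, `start`, `end`, `unplaced`,
#'   `passed_filter` (logical).
#' @return A `candidate_sets` object (with `filter_status` set where
#'   `passed_filter` was given).
#' @export
candidate_sets_from_tables <- function(tables) {
  sets <- lapply(names(tables), function(h) {
    t <- tables[[h]]
    df <- data.frame(gene_id = t$gene_id,
                     gene_class = t$gene_class %||% NA_character_,
                     chrom = t$chrom %||% NA_character_,
                     start = t$start %||% NA_real_, end = t$end %||% NA_real_,
                     unplaced = t$unplaced %||% FALSE,
                     note = paste0("curated ", h),
                     filter_status = NA_character_,
                     stringsAsFactors = FALSE)
    if (!is.null(t$passed_filter)) {
      df$filter_status <- ifelse(t$passed_filter, "pass", "fail")
      df$filter_status[df$unplaced] <- "unfilterable"
      if (h %in% c("H3", "H6")) df$filter_status <- "exempt"
    }
    df
  })
  names(sets) <- names(tables)
  sets$protein_only_accessions <- character(0)
  sets$h1_expression_flag <- logical(0)
  class(sets) <- "candidate_sets"
  sets
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Detect clusters of co-regulated CYPs
#'
#' Single-linkage grouping of the H2/H3 CYPs: genes on the same chromosome
#' whose spans are within `max_gap` bp of the next gene's span are chained
#' into one cluster; only clusters of two or more genes are reported.
#' Tight clusters of jointly up-regulated CYPs are the footprint a tandem
#' duplication would leave in expression data.
#'
#' @param gene_ids Gene ids to cluster (typically `sets$H2$gene_id`).
#' @param gene_catalog `data.frame` with `gene_id`, `chrom`, `start`,
#'   `end` (and optionally `cyp_name`).
#' @param max_gap Maximum allowed gap between successive gene spans in bp
#'   (default 1e5).
#' @return A list of character vectors (cluster members, named by
#'   `cyp_name` when available, values are gene ids).
#' @export
detect_cyp_clusters <- function(gene_ids, gene_catalog, max_gap = 1e5) {
  g <- gene_catalog[match(gene_ids, gene_catalog$gene_id), , drop = FALSE]
  g <- g[!is.na(g$chrom), , drop = FALSE]
  g <- g[order(g$chrom, g$start), , drop = FALSE]
  clusters <- list()
  current <- character(0); last_end <- -Inf; last_chrom <- ""
  flush <- function() {
    if (length(current) >= 2) clusters[[length(clusters) + 1L]] <<- current
  }
  for (i in seq_len(nrow(g))) {
    if (g$chrom[i] == last_chrom && g$start[i] - last_end <= max_gap) {
      current <- c(current, g$gene_id[i])
      last_end <- max(last_end, g$end[i])
    } else {
      flush()
      current <- g$gene_id[i]
      last_end <- g$end[i]
    }
    last_chrom <- g$chrom[i]
  }
  flush()
  if (!is.null(gene_catalog$cyp_name)) {
    clusters <- lapply(clusters, function(ids) {
      nm <- gene_catalog$cyp_name[match(ids, gene_catalog$gene_id)]
      stats::setNames(ids, nm)
    })
  }
  clusters
}

#' Filter candidates by mapped resistance loci
#'
#' Marks each candidate gene by whether its span intersects any mapped
#' resistance locus.  Two hypotheses are exempt from the positional filter:
#' H3 (a duplication is invisible in a SNP-density chromosome scan) and H6
#' (protein stabilization needs no cis-linked DNA change at the CYP, so no
#' positional filtering can be applied).  Genes on unplaced scaffolds have
#' no usable coordinates and are retained with status `unfilterable`.
#'
#' @param sets A `candidate_sets` object.
#' @param loci A `locus_intervals` table (from [call_loci()] or
#'   [locus_intervals()]); may have zero rows.
#' @return `sets` with `filter_status` filled in (`pass`, `fail`, `exempt`,
#'   `unfilterable`).
#' @export
filter_by_loci <- function(sets, loci) {
  stopifnot(inherits(sets, "candidate_sets"))
  hits_locus <- function(chrom, start, end) {
    if (nrow(loci) == 0) return(FALSE)
    any(loci$chrom == chrom & loci$start <= end & loci$end >= start)
  }
  for (h in c("H1", "H2", "H3", "H4", "H5", "H6")) {
    df <- sets[[h]]
    if (!nrow(df)) next
    if (h %in% c("H3", "H6")) {
      df$filter_status <- "exempt"
    } else {
      status <- character(nrow(df))
      for (i in seq_len(nrow(df))) {
        if (isTRUE(df$unplaced[i])) {
          status[i] <- "unfilterable"
        } else if (is.na(df$chrom[i]) || is.na(df$start[i])) {
          stop("gene ", df$gene_id[i], " has no coordinates and is not ",
               "flagged as unplaced")
        } else {
          status[i] <- if (hits_locus(df$chrom[i], df$start[i], df$end[i]))
            "pass" else "fail"
        }
      }
      df$filter_status <- status
    }
    sets[[h]] <- df
  }
  sets
}

#' Consolidate candidate sets into a deduplicated gene list
#'
#' Union over the six hypotheses with exact gene-id deduplication.  At
#' stage `post_filter` only genes whose `filter_status` is `pass`, `exempt`
#' or `unfilterable` are kept (so the post-filter list is always a subset
#' of the pre-filter list).  Reported alongside the union are
#' per-hypothesis counts and the size of the H4 + H5 "switch" union.
#'
#' @param sets A `candidate_sets` object (locus-filtered for
#'   `post_filter`).
#' @param stage `"pre_filter"` or `"post_filter"`.
#' @return A list: `stage`, `per_hypothesis` (named counts), `genes`
#'   (deduplicated ids ordered by chrom, position, id), `n_candidates`,
#'   `switch_genes` (H4 + H5 union) and `n_switch`.
#' @export
consolidate <- function(sets, stage = c("pre_filter", "post_filter")) {
  stopifnot(inherits(sets, "candidate_sets"))
  stage <- match.arg(stage)
  hyp <- c("H1", "H2", "H3", "H4", "H5", "H6")
  pick <- function(df) {
    if (!nrow(df)) return(df)
    if (stage == "post_filter") {
      if (all(is.na(df$filter_status)))
        stop("post_filter requested but filter_by_loci() has not been applied")
      df <- df[df$filter_status %in% c("pass", "exempt", "unfilterable"), ,
               drop = FALSE]
    }
    df
  }
  kept <- lapply(sets[hyp], pick)
  all_df <- do.call(rbind, kept)
  dedup <- all_df[!duplicated(all_df$gene_id), , drop = FALSE]
  dedup <- dedup[order(dedup$chrom, dedup$start, dedup$gene_id, na.last = TRUE), ,
                 drop = FALSE]
  switch_ids <- sort(unique(c(kept$H4$gene_id, kept$H5$gene_id)))
  list(stage = stage,
       per_hypothesis = vapply(kept, nrow, integer(1)),
       genes = dedup$gene_id,
       n_candidates = nrow(dedup),
       switch_genes = switch_ids,
       n_switch = length(switch_ids))
}

#' Resolution gain from congenic and multi-strain comparisons
#'
#' Given the number of hits found with the donor strain alone (`sp`), with
#' the congenic strain alone (`ckr`), and shared by both (`both`), returns
#' the fold gains in resolution: `sp / ckr` (what a congenic strain buys
#' over an unrelated resistant strain) and `sp / both` (what requiring
#' concordance of both resistant strains buys).
#'
#' @param sp,ckr,both Hit counts (vectors recycle).
#' @return `data.frame` with `congenic_gain` and `multistrain_gain`,
#'   rounded to one decimal.
#' @export
resolution_gain <- function(sp, ckr, both) {
  data.frame(congenic_gain = round(sp / ckr, 1),
             multistrain_gain = round(sp / both, 1))
}
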
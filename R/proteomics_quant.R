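#' Construct a PSM-level TMT quantification table
#'
#' One row per peptide-spectrum match with the peptide sequence, its
#' candidate protein ids (semicolon-separated for shared peptides) and one
#' reporter signal-to-noise (S/N) column per TMT channel.
#'
#' @param peptide Peptide sequences.
#' @param proteins Character vector of candidate protein ids per PSM,
#'   semicolon-separated when the peptide is shared.
#' @param sn Numeric matrix of S/N values, one column per channel (column
#'   names are channel ids).
#' @param channel_strain Named character vector mapping channel id to strain.
#' @return A list of class `psm_table` with elements `psm` (data.frame) and
#'   `channel_strain`.
#' @export
psm_table <- function(peptide, proteins, sn, channel_strain) {
  sn <- as.matrix(sn)
  rownames(sn) <- NULL
  if (any(sn < 0)) stop("S/N values must be non-negative")
  if (is.null(colnames(sn))) stop("S/N matrix needs channel ids as colnames")
  if (!setequal(names(channel_strain), colnames(sn)))
    stop("channel_strain must name every S/N column")
  if (any(!nzchar(proteins)))
    stop("every PSM needs at least one candidate protein")
  structure(list(
    psm = data.frame(peptide = as.character(peptide),
                     proteins = as.character(proteins),
                     sn, check.names = FALSE, stringsAsFactors = FALSE),
    channel_strain = channel_strain[colnames(sn)]
  ), class = "psm_table")
}

channel_cols <- function(psms) names(psms$channel_strain)

#' Razor assignment of shared peptides
#'
#' Resolves each shared peptide to a single protein: the candidate with the
#' largest number of distinct peptides mapping to it (counting all candidate
#' relations), with ties broken by the lexicographically smallest protein
#' id.  Unique peptides keep their only candidate.  Both razor and unique
#' peptides then contribute to quantitation.  The assignment depends only
#' on the peptide-protein map, so it is deterministic and invariant to row
#' order.
#'
#' @param psms A `psm_table`.
#' @return The `psm_table` with a single-protein `protein` column added and
#'   a logical `unique_peptide` column.
#' @export
assign_razor <- function(psms) {
  stopifnot(inherits(psms, "psm_table"))
  cand <- strsplit(psms$psm$proteins, ";", fixed = TRUE)
  if (any(lengths(cand) == 0)) stop("PSM with empty candidate protein list")
  # distinct peptides per candidate protein
  pep_prot <- unique(data.frame(
    peptide = rep(psms$psm$peptide, lengths(cand)),
    protein = unlist(cand), stringsAsFactors = FALSE))
  n_pep <- table(pep_prot$protein)
  pick <- vapply(cand, function(p) {
    counts <- as.integer(n_pep[p])
    p <- p[order(-counts, p)]
    p[1]
  }, "")
  psms$psm$protein <- pick
  psms$psm$unique_peptide <- lengths(cand) == 1L
  psms
}

#' Roll PSM signal-to-noise up to protein abundances
#'
#' Per protein and channel, abundance is the sum of S/N over the protein's
#' razor-assigned PSMs, so each channel's total S/N is conserved exactly
#' across the rollup.
#'
#' @param psms A razor-assigned `psm_table` (see [assign_razor()]).
#' @return A list of class `protein_quant`: `abundance` (proteins x
#'   channels raw summed S/N), `normalized` (NULL until
#'   [normalize_total()]), `peptides` (per-protein distinct and unique
#'   peptide counts) and `channel_strain`.
#' @export
rollup <- function(psms) {
  stopifnot(inherits(psms, "psm_table"))
  if (is.null(psms$psm$protein))
    psms <- assign_razor(psms)
  ch <- channel_cols(psms)
  sn <- as.matrix(psms$psm[, ch, drop = FALSE])
  ab <- rowsum(sn, group = psms$psm$protein)
  pep <- psms$psm[, c("protein", "peptide", "unique_peptide")]
  n_pep <- tapply(pep$peptide, pep$protein, function(x) length(unique(x)))
  n_unique <- tapply(pep$unique_peptide, pep$protein, sum)
  ord <- order(rownames(ab))
  structure(list(
    abundance = ab[ord, , drop = FALSE],
    normalized = NULL,
    peptides = data.frame(protein = rownames(ab)[ord],
                          n_peptides = as.integer(n_pep[rownames(ab)[ord]]),
                          n_unique_peptides = as.integer(n_unique[rownames(ab)[ord]]),
                          stringsAsFactors = FALSE),
    channel_strain = psms$channel_strain
  ), class = "protein_quant")
}

#' Total-peptide-amount channel normalization
#'
#' Scales every channel so that all channel totals equal the mean raw
#' channel total; within-channel relative abundances are untouched and the
#' operation is idempotent.
#'
#' @param quant A `protein_quant` from [rollup()].
#' @return `quant` with the `normalized` matrix filled in.
#' @export
normalize_total <- function(quant) {
  stopifnot(inherits(quant, "protein_quant"))
  tot <- colSums(quant$abundance)
  if (any(tot == 0))
    stop("channel(s) with zero total abundance: ",
         paste(colnames(quant$abundance)[tot == 0], collapse = ", "))
  target <- mean(tot)
  quant$normalized <- sweep(quant$abundance, 2, target / tot, "*")
  quant
}

#' Two-strain differential protein abundance
#'
#' Log2 ratio of group means of normalized abundance, with a two-sided
#' two-sample t-test on log2(normalized abundance + 1).  Mirroring the
#' study design, no multiple-testing correction is applied by default (the
#' significance criterion is raw p <= 0.05); set `adjust = "BH"` to use FDR
#' instead.
#'
#' @param quant A normalized `protein_quant` (see [normalize_total()]).
#' @param strain_a,strain_b Strains to compare (ratios are a/b).
#' @param p_max Significance threshold on the (possibly adjusted) p-value
#'   (default 0.05).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return `data.frame`: `protein`, `comparison`, `log2_ratio`, `pvalue`,
#'   `call` (`up`/`down`/`ns`), `n_peptides`, `n_unique_peptides`.
#' @export
test_protein_de <- function(quant, strain_a, strain_b, p_max = 0.05,
                            adjust = c("none", "BH")) {
  stopifnot(inherits(quant, "protein_quant"))
  adjust <- match.arg(adjust)
  if (is.null(quant$normalized)) quant <- normalize_total(quant)
  st <- quant$channel_strain
  ia <- which(st == strain_a); ib <- which(st == strain_b)
  if (length(ia) < 2 || length(ib) < 2)
    stop("need >= 2 channels per strain (got ", length(ia), " and ", length(ib), ")")
  x <- quant$normalized
  la <- log2(x[, ia, drop = FALSE] + 1)
  lb <- log2(x[, ib, drop = FALSE] + 1)
  # pooled-variance Student t: channels of one TMT mixture share a noise
  # model, and Welch's df approximation is unstable at 3-4 channels
  pval <- vapply(seq_len(nrow(x)), function(i) {
    if (stats::sd(la[i, ]) == 0 && stats::sd(lb[i, ]) == 0) return(1)
    stats::t.test(la[i, ], lb[i, ], var.equal = TRUE)$p.value
  }, numeric(1))
  ratio <- log2(rowMeans(x[, ia, drop = FALSE]) /
                  rowMeans(x[, ib, drop = FALSE]))
  p_eff <- if (adjust == "BH") stats::p.adjust(pval, "BH") else pval
  call <- rep("ns", length(pval))
  call[p_eff <= p_max & ratio > 0] <- "up"
  call[p_eff <= p_max & ratio < 0] <- "down"
  data.frame(protein = rownames(x),
             comparison = paste0(strain_a, "/", strain_b),
             log2_ratio = ratio, pvalue = pval, call = call,
             n_peptides = quant$peptides$n_peptides,
             n_unique_peptides = quant$peptides$n_unique_peptides,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Read / write PSM tables as TSV
#'
#' Layout: `peptide`, `proteins` (semicolon-separated candidates), then one
#' S/N column per channel; the channel-to-strain map travels in a companion
#' TSV (`channel`, `strain`).
#'
#' @param psms A `psm_table`.
#' @param path,map_path Paths for the PSM TSV and channel map TSV.
#' @return `write_psm_tsv`: the paths, invisibly. `read_psm_tsv`: a
#'   `psm_table`.
#' @export
write_psm_tsv <- function(psms, path, map_path) {
  keep <- c("peptide", "proteins", channel_cols(psms))
  utils::write.table(psms$psm[, keep], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(channel = names(psms$channel_strain),
                                strain = unname(psms$channel_strain)),
                     map_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(path, map_path))
}

#' @rdname write_psm_tsv
#' @export
read_psm_tsv <- function(path, map_path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  map <- utils::read.delim(map_path, stringsAsFactors = FALSE)
  ch <- setdiff(names(df), c("peptide", "proteins"))
  psm_table(df$peptide, df$proteins, as.matrix(df[, ch, drop = FALSE]),
            stats::setNames(map$strain, map$channel))
}
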
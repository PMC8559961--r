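#' Construct a count matrix with a sample-to-strain map
#'
#' @param counts Non-negative integer matrix, genes in rows (rownames = gene
#'   ids), samples in columns (colnames = sample ids).
#' @param strain Character vector mapping each sample (column) to a strain;
#'   recycled names from `colnames(counts)` if unnamed.
#' @return A list of class `count_matrix` with elements `counts` and
#'   `strain`.
#' @export
count_matrix <- function(counts, strain) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (is.null(rownames(counts))) stop("counts need gene ids as rownames")
  if (is.null(colnames(counts))) stop("counts need sample ids as colnames")
  if (is.null(names(strain))) names(strain) <- colnames(counts)
  if (!setequal(names(strain), colnames(counts)))
    stop("every sample must be mapped to exactly one strain")
  strain <- strain[colnames(counts)]
  structure(list(counts = counts, strain = strain), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "genes x", ncol(x$counts), "samples\n")
  print(table(x$strain))
  invisible(x)
}

#' Counts per million
#'
#' Scales each sample (column) so its entries sum to one million.
#'
#' @param counts A `count_matrix` or plain numeric matrix.
#' @return A numeric matrix of CPM values with the input dimnames.
#' @export
cpm <- function(counts) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else as.matrix(counts)
  tot <- colSums(m)
  zero <- tot == 0
  if (any(zero))
    stop("sample(s) with zero total count: ",
         paste(colnames(m)[zero], collapse = ", "))
  sweep(m, 2, tot, "/") * 1e6
}

#' Expression filter for differential testing
#'
#' Retains genes with CPM strictly greater than `cpm_min` in at least
#' `min_samples` of the samples belonging to the two compared strains, and
#' additionally drops genes with zero total count in either strain (a gene
#' entirely absent from one strain cannot be tested meaningfully).
#' Deterministic, order-preserving and idempotent.
#'
#' @param counts A `count_matrix`.
#' @param strains Character vector of the strains being compared; defaults
#'   to all strains present.
#' @param cpm_min CPM threshold (exclusive; default 1).
#' @param min_samples Minimum number of qualifying samples (default 4).
#' @return A filtered `count_matrix` restricted to the samples of `strains`.
#' @export
filter_genes <- function(counts, strains = NULL, cpm_min = 1, min_samples = 4) {
  stopifnot(inherits(counts, "count_matrix"))
  if (is.null(strains)) strains <- unique(counts$strain)
  keep_samples <- counts$strain %in% strains
  m <- counts$counts[, keep_samples, drop = FALSE]
  st <- counts$strain[keep_samples]
  if (min_samples > ncol(m))
    stop("min_samples (", min_samples, ") exceeds available samples (", ncol(m), ")")
  x <- cpm(m)
  enough <- rowSums(x > cpm_min) >= min_samples
  present_everywhere <- Reduce(`&`, lapply(strains, function(s)
    rowSums(m[, st == s, drop = FALSE]) > 0))
  keep <- enough & present_everywhere
  count_matrix(m[keep, , drop = FALSE], st)
}

#' Trimmed mean of M-values normalization factors
#'
#' Computes between-sample scaling factors by the TMM method: per-gene
#' log-ratios (M) and log-abundances (A) of each sample against a reference
#' column are doubly trimmed (30% on M, 5% on A by default) and the
#' remaining M-values averaged with inverse-variance (delta-method) weights.
#' The reference column is the sample whose upper-quartile CPM is closest to
#' the mean upper quartile.  Factors are rescaled to have geometric mean 1,
#' so they express relative, not absolute, composition corrections.
#'
#' @param counts A `count_matrix` or numeric matrix (ideally pre-filtered;
#'   all-zero gene rows are rejected).
#' @param trim_m,trim_a Two-sided trim fractions for M and A (defaults 0.30
#'   and 0.05).
#' @return Named numeric vector of normalization factors, one per sample.
#' @export
tmm_factors <- function(counts, trim_m = 0.30, trim_a = 0.05) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else as.matrix(counts)
  if (any(rowSums(m) == 0))
    stop("all-zero gene rows present; run filter_genes() first")
  lib <- colSums(m)
  uq <- apply(sweep(m, 2, lib, "/"), 2, stats::quantile, probs = 0.75)
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(m)), function(k) {
    tmm_pair(m[, k], m[, ref], lib[k], lib[ref], trim_m, trim_a)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(m)
  f
}

tmm_pair <- function(obs, ref, n_obs, n_ref, trim_m, trim_a) {
  ok <- obs > 0 & ref > 0
  obs <- obs[ok]; ref <- ref[ok]
  if (!length(obs)) return(1)
  p_obs <- obs / n_obs; p_ref <- ref / n_ref
  M <- log2(p_obs / p_ref)
  A <- 0.5 * log2(p_obs * p_ref)
  if (max(abs(M)) < 1e-10) return(1)   # identical relative profiles
  w <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  n <- length(M)
  lo_m <- floor(n * trim_m) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1; hi_a <- n + 1 - lo_a
  rM <- rank(M, ties.method = "first"); rA <- rank(A, ties.method = "first")
  keep <- rM >= lo_m & rM <= hi_m & rA >= lo_a & rA <= hi_a
  if (!any(keep)) return(1)
  2^(sum(w[keep] * M[keep]) / sum(w[keep]))
}

# Conditional negative-binomial log-likelihood (terms in the dispersion
# only) for one group of equal-library-size counts, summed over genes.
# z: genes x samples matrix; r = 1/dispersion.
cond_loglik_group <- function(z, r) {
  n <- ncol(z)
  tot <- rowSums(z)
  rowSums(lgamma(z + r)) - lgamma(tot + n * r) + lgamma(n * r) - n * lgamma(r)
}

estimate_common_dispersion <- function(z_by_group) {
  nll <- function(log_phi) {
    r <- 1 / exp(log_phi)
    -sum(vapply(z_by_group, function(z) sum(cond_loglik_group(z, r)), numeric(1)))
  }
  opt <- stats::optimize(nll, interval = log(c(1e-6, 20)))
  exp(opt$minimum)
}

estimate_tagwise_dispersion <- function(z_by_group, common, prior_n = 10,
                                        grid_length = 61, grid_range = c(-6, 6)) {
  phi_grid <- common * 2^seq(grid_range[1], grid_range[2], length.out = grid_length)
  G <- nrow(z_by_group[[1]])
  ll <- matrix(0, G, length(phi_grid))
  for (j in seq_along(phi_grid)) {
    r <- 1 / phi_grid[j]
    for (z in z_by_group) ll[, j] <- ll[, j] + cond_loglik_group(z, r)
  }
  shared <- colMeans(ll)
  post <- ll + prior_n * matrix(shared, G, length(phi_grid), byrow = TRUE)
  phi_grid[max.col(post, ties.method = "first")]
}

# Exact conditional two-group NB test: probability-mass method (all outcomes
# at most as probable as the observed split contribute to p).
nb_exact_pvalue <- function(za, zb, na, nb, phi) {
  z <- za + zb
  if (z == 0) return(1)
  phi <- max(phi, 1e-8)
  ra <- na / phi; rb <- nb / phi
  x <- 0:z
  lp <- lgamma(x + ra) - lgamma(x + 1) + lgamma(z - x + rb) - lgamma(z - x + 1)
  lp <- lp - max(lp)
  p <- exp(lp); p <- p / sum(p)
  obs <- p[za + 1]
  min(1, sum(p[p <= obs * (1 + 1e-10)]))
}

#' Negative-binomial exact test for two-strain differential expression
#'
#' Tests each gene for differential expression between two strains on raw
#' counts.  Library sizes are equalized by scaling each sample's counts to
#' the geometric-mean effective library size (library size times TMM
#' factor) and rounding, giving pseudo-counts on a common scale.  A common
#' negative-binomial dispersion is estimated by conditional maximum
#' likelihood and moderated per gene by weighted-likelihood empirical Bayes
#' (gene likelihood plus `prior_n` times the average likelihood, maximized
#' on a dispersion grid).  Each gene's p-value is from the exact
#' conditional test on the two group totals; FDR is Benjamini-Hochberg
#' across tested genes.  The reported log2 fold-change is the ratio of
#' group mean pseudo-counts with a 0.5 guard (display only; the test never
#' sees the guard), with positive values meaning higher expression in
#' `strain_a` (conventionally the resistant strain).
#'
#' @param counts A filtered `count_matrix` containing both strains.
#' @param strain_a,strain_b Strains to compare (fold-changes are a/b).
#' @param lfc_min Minimum |log2 FC| for an up/down call (default 1).
#' @param fdr_max Maximum FDR for an up/down call (default 0.01).
#' @param prior_n Weight of the shared likelihood in tagwise dispersion
#'   moderation (default 10).
#' @return A `data.frame`: `gene_id`, `comparison`, `log2fc`, `pvalue`,
#'   `fdr`, `call` (`up`/`down`/`ns`), `dispersion`.
#' @export
test_de <- function(counts, strain_a, strain_b, lfc_min = 1, fdr_max = 0.01,
                    prior_n = 10) {
  stopifnot(inherits(counts, "count_matrix"))
  sel <- counts$strain %in% c(strain_a, strain_b)
  m <- counts$counts[, sel, drop = FALSE]
  st <- counts$strain[sel]
  na <- sum(st == strain_a); nb <- sum(st == strain_b)
  if (na < 2 || nb < 2)
    stop("need >= 2 replicates per strain (got ", na, " and ", nb, ")")
  lib <- colSums(m)
  eff <- lib * tmm_factors(m)
  common_size <- exp(mean(log(eff)))
  pseudo <- round(sweep(m, 2, common_size / eff, "*"))
  za <- pseudo[, st == strain_a, drop = FALSE]
  zb <- pseudo[, st == strain_b, drop = FALSE]
  groups <- list(za, zb)
  phi0 <- estimate_common_dispersion(groups)
  phi <- estimate_tagwise_dispersion(groups, phi0, prior_n = prior_n)
  ta <- rowSums(za); tb <- rowSums(zb)
  pval <- vapply(seq_len(nrow(pseudo)), function(g)
    nb_exact_pvalue(ta[g], tb[g], na, nb, phi[g]), numeric(1))
  mean_a <- ta / na; mean_b <- tb / nb
  lfc <- log2((mean_a + 0.5) / (mean_b + 0.5))
  fdr <- stats::p.adjust(pval, method = "BH")
  call <- rep("ns", length(pval))
  call[lfc >= lfc_min & fdr <= fdr_max] <- "up"
  call[lfc <= -lfc_min & fdr <= fdr_max] <- "down"
  data.frame(gene_id = rownames(m),
             comparison = paste0(strain_a, "/", strain_b),
             log2fc = lfc, pvalue = pval, fdr = fdr, call = call,
             dispersion = phi, row.names = NULL, stringsAsFactors = FALSE)
}

#' Read / write count matrices as TSV
#'
#' The TSV layout is gene ids in the first column and one column per
#' sample; the sample-to-strain map travels in a two-column companion TSV
#' (`sample`, `strain`).
#'
#' @param counts A `count_matrix`.
#' @param path,map_path Paths of the count TSV and the sample map TSV.
#' @return `write_counts_tsv`: the paths, invisibly.  `read_counts_tsv`:
#'   a `count_matrix`.
#' @export
write_counts_tsv <- function(counts, path, map_path) {
  df <- data.frame(gene_id = rownames(counts$counts), counts$counts,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample = names(counts$strain),
                                strain = unname(counts$strain)),
                     map_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(path, map_path))
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path, map_path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  map <- utils::read.delim(map_path, stringsAsFactors = FALSE)
  count_matrix(m, stats::setNames(map$strain, map$sample))
}
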
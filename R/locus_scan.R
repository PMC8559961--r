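#' Count SNPs in fixed genomic windows
#'
#' Tiles each chromosome with non-overlapping half-open windows
#' `[k*w, (k+1)*w)` (0-based; equivalently positions `k*w + 1 .. (k+1)*w`
#' 1-based) and counts the SNPs falling in each.  A site at 1-based position
#' `p` belongs to window `floor((p - 1) / w) + 1`.  The default window of
#' 10 Mb matches the resolution at which congenic introgression blocks show
#' up as SNP-density peaks.
#'
#' @param snps A `variant_sites` table (typically the output of
#'   [select_resistance_snps()]); only `chrom` and `pos` are used.
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp).
#' @param window_size Window width in bp (default 1e7).
#' @return A `data.frame` of class `window_counts` with columns `chrom`,
#'   `window` (1-based index), `start`, `end` (1-based inclusive, last window
#'   clipped to the chromosome) and `count`.
#' @export
window_counts <- function(snps, chrom_lengths, window_size = 1e7) {
  if (!is.numeric(window_size) || window_size <= 0)
    stop("window_size must be > 0")
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths))))
    stop("chrom_lengths must be named")
  out <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    nw <- ceiling(len / window_size)
    pos <- snps$pos[snps$chrom == ch]
    over <- pos > len
    if (any(over))
      stop("SNP position beyond chromosome ", ch, " length: ",
           paste(utils::head(pos[over], 3), collapse = ", "))
    w <- floor((pos - 1) / window_size) + 1L
    counts <- tabulate(w, nbins = nw)
    data.frame(chrom = ch, window = seq_len(nw),
               start = (seq_len(nw) - 1) * window_size + 1,
               end = pmin(seq_len(nw) * window_size, len),
               count = counts, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  class(res) <- c("window_counts", class(res))
  res
}

#' Call resistance loci from windowed SNP counts
#'
#' Windows whose count strictly exceeds `threshold` seed loci; runs of
#' adjacent supra-threshold windows on the same chromosome are merged into a
#' single locus interval.  The default threshold of 100 SNPs per 10 Mb
#' window reflects the density at which introgressed donor blocks stand out
#' against background strain divergence; a window with exactly `threshold`
#' SNPs is not a seed.  Raising the threshold can only remove loci, never
#' add them.
#'
#' @param windows Output of [window_counts()].
#' @param threshold Minimum (exclusive) SNP count for a window to seed a
#'   locus (default 100).
#' @return `data.frame` of class `locus_intervals` with columns `chrom`,
#'   `start`, `end` (1-based inclusive, window-aligned), `peak_count` and
#'   `total_snps`; zero rows when no window exceeds the threshold.
#' @export
call_loci <- function(windows, threshold = 100) {
  if (!is.numeric(threshold) || threshold < 0) stop("threshold must be >= 0")
  res <- list()
  for (ch in unique(windows$chrom)) {
    w <- windows[windows$chrom == ch, , drop = FALSE]
    w <- w[order(w$window), , drop = FALSE]
    hot <- w$count > threshold
    if (!any(hot)) next
    runs <- rle(hot)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (k in which(runs$values)) {
      i <- starts[k]:ends[k]
      res[[length(res) + 1L]] <- data.frame(
        chrom = ch, start = w$start[i[1]], end = w$end[i[length(i)]],
        peak_count = max(w$count[i]), total_snps = sum(w$count[i]),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               peak_count = integer(), total_snps = integer(),
               stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("locus_intervals", class(out))
  out
}

#' Build a locus interval table from explicit coordinates
#'
#' Helper for supplying curated resistance-locus intervals (e.g. regions
#' shaded on a chromosome scan) to [filter_by_loci()] without re-running the
#' window scan.
#'
#' @param chrom,start,end Vectors of equal length; 1-based inclusive bp.
#' @return A `locus_intervals` data.frame.
#' @export
locus_intervals <- function(chrom, start, end) {
  stopifnot(length(chrom) == length(start), length(start) == length(end))
  if (any(end <= start)) stop("locus end must exceed start")
  out <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                    end = as.numeric(end),
                    peak_count = rep(NA_integer_, length(chrom)),
                    total_snps = rep(NA_integer_, length(chrom)),
                    stringsAsFactors = FALSE)
  class(out) <- c("locus_intervals", class(out))
  out
}

#' Write window counts as TSV and called loci as BED
#'
#' @param windows Output of [window_counts()].
#' @param loci Output of [call_loci()].
#' @param tsv_path,bed_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, the paths written.
#' @export
write_locus_scan <- function(windows, loci, tsv_path = NULL, bed_path = NULL) {
  if (!is.null(tsv_path))
    utils::write.table(as.data.frame(windows)[, c("chrom", "start", "end", "count")],
                       tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bed_path)) {
    bed <- data.frame(chrom = loci$chrom, start = loci$start - 1, end = loci$end,
                      name = sprintf("locus_%d", seq_len(nrow(loci))),
                      score = loci$peak_count)
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(c(tsv_path, bed_path))
}
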
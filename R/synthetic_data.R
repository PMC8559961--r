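#' Configure a synthetic congenic-introgression simulation
#'
#' Defines the study design the generator emulates: a susceptible recipient
#' strain (ROCK), a resistant donor strain (SP) and a congenic strain (CKR)
#' carrying SP-derived introgressed blocks in a ROCK background, all called
#' against an LVP-like reference.  Defaults reproduce the study-scale
#' conditions: three chromosomes at Aedes-genome scale, two introgressed
#' blocks (one per mapped resistance locus) with the causal locus inside
#' the chromosome-3 block, ten transcriptionally up-regulated CYPs, five
#' protein-stabilized CYPs, one causal regulatory switch, 4/4/4 RNA-seq
#' replicates and the 4/3/3 ROCK/SP/CKR TMT channel layout.
#'
#' @param chromosome_lengths Named vector of chromosome lengths in bp.
#' @param n_genes_per_chrom Genes simulated per chromosome.
#' @param donor_snp_density Expected donor(SP)-specific SNPs per Mb
#'   (Poisson rate; these are hom-alt in SP genome-wide and hom-alt in CKR
#'   only inside introgressed blocks).
#' @param background_divergence Expected ROCK-vs-reference SNPs per Mb
#'   (ancestral colony divergence shared by all three study strains;
#'   irrelevant to resistance).
#' @param introgressed_blocks `data.frame` (`chrom`, `start`, `end`), bp,
#'   1-based inclusive; non-overlapping and inside their chromosomes.
#' @param causal_locus Optional length-3 list/vector (`chrom`, `start`,
#'   `end`) contained in some introgressed block; the causal switch gene is
#'   placed inside it.
#' @param n_regulated_cyps CYPs with planted transcript (and concordant
#'   protein) up-regulation in both resistant strains.
#' @param n_stabilized_cyps CYPs with planted protein-only up-regulation
#'   (transcript effect exactly 0).
#' @param planted_log2fc Target transcript log2 fold-change of planted
#'   effects (resistant vs ROCK).
#' @param protein_concordance Fraction (0-1) of the transcript effect
#'   propagated to protein level for regulated genes.
#' @param rna_replicates,tmt_channels Named per-strain counts (>= 2 each).
#' @param nb_mean_log_range Range (log2) of baseline negative-binomial
#'   means.
#' @param nb_dispersion Negative-binomial dispersion (> 0).
#' @param psm_per_protein Maximum PSMs per protein (drawn uniformly from
#'   1..psm_per_protein).
#' @param protein_cv Log-normal coefficient of variation of protein S/N.
#' @param het_rate Probability a site gets one genotype flipped to
#'   heterozygous (exercises the homozygous-only filter).
#' @param emit_sequences `TRUE`, `FALSE` or `"auto"` (generate genome and
#'   transcript sequences only when the total genome is <= 50 Mb).
#' @param seed Integer seed; identical config + seed gives identical data.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(chromosome_lengths = c(chr1 = 310e6, chr2 = 474e6, chr3 = 410e6),
                       n_genes_per_chrom = 200,
                       donor_snp_density = 20,
                       background_divergence = 1,
                       introgressed_blocks = data.frame(
                         chrom = c("chr1", "chr3"),
                         start = c(100e6, 310e6),
                         end = c(130e6, 340e6)),
                       causal_locus = list(chrom = "chr3", start = 310e6, end = 320e6),
                       n_regulated_cyps = 10,
                       n_stabilized_cyps = 5,
                       planted_log2fc = 3,
                       protein_concordance = 0.5,
                       rna_replicates = c(ROCK = 4, SP = 4, CKR = 4),
                       tmt_channels = c(ROCK = 4, SP = 3, CKR = 3),
                       nb_mean_log_range = c(3, 10),
                       nb_dispersion = 0.05,
                       psm_per_protein = 5,
                       protein_cv = 0.2,
                       het_rate = 0.02,
                       emit_sequences = "auto",
                       seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  cl <- cfg$chromosome_lengths
  if (is.null(names(cl))) stop("chromosome_lengths must be named")
  b <- cfg$introgressed_blocks
  if (!is.null(b) && nrow(b)) {
    for (i in seq_len(nrow(b))) {
      if (!b$chrom[i] %in% names(cl))
        stop("introgressed_blocks: unknown chromosome ", b$chrom[i])
      if (b$start[i] < 1 || b$end[i] > cl[[b$chrom[i]]] || b$start[i] >= b$end[i])
        stop("introgressed_blocks: block ", b$chrom[i], ":", b$start[i], "-",
             b$end[i], " lies outside its chromosome")
    }
    for (ch in unique(b$chrom)) {
      bb <- b[b$chrom == ch, , drop = FALSE]
      bb <- bb[order(bb$start), , drop = FALSE]
      if (nrow(bb) > 1 && any(bb$start[-1] <= bb$end[-nrow(bb)]))
        stop("introgressed_blocks: overlapping blocks on ", ch)
    }
  }
  if (!is.null(cfg$causal_locus)) {
    loc <- cfg$causal_locus
    inside <- !is.null(b) && nrow(b) &&
      any(b$chrom == loc$chrom & b$start <= loc$start & b$end >= loc$end)
    if (!inside)
      stop("causal_locus: must be contained in an introgressed block")
  }
  if (cfg$protein_concordance < 0 || cfg$protein_concordance > 1)
    stop("protein_concordance: must be in [0, 1]")
  if (cfg$nb_dispersion <= 0) stop("nb_dispersion: must be > 0")
  if (any(cfg$rna_replicates < 2))
    stop("rna_replicates: need >= 2 replicates per strain")
  if (any(cfg$tmt_channels < 2))
    stop("tmt_channels: need >= 2 channels per strain")
  if (cfg$psm_per_protein < 1) stop("psm_per_protein: must be >= 1")
  for (f in c("donor_snp_density", "background_divergence", "het_rate",
              "protein_cv"))
    if (cfg[[f]] < 0) stop(f, ": must be >= 0")
  cfg
}

in_any_block <- function(chrom, pos, blocks) {
  if (is.null(blocks) || !nrow(blocks)) return(rep(FALSE, length(pos)))
  out <- rep(FALSE, length(pos))
  for (i in seq_len(nrow(blocks))) {
    out <- out | (chrom == blocks$chrom[i] & pos >= blocks$start[i] &
                    pos <= blocks$end[i])
  }
  out
}

#' Simulate a complete congenic-strain multi-omics dataset
#'
#' Generates, from one [sim_config()], every downstream product the
#' pipeline consumes: per-strain variant genotypes (donor-specific SNPs
#' hom-alt in SP genome-wide and in CKR only inside introgressed blocks;
#' background ROCK-vs-reference divergence; a configurable rate of
#' heterozygous calls), a gene annotation with CYP/TF/lncRNA classes, an
#' RNA-seq count matrix with negative-binomial noise and planted fold
#' changes, a PSM-level TMT table whose protein effects are the transcript
#' effects scaled by `protein_concordance` (except stabilized CYPs:
#' protein-only effect), optional genome/transcript sequences, and a
#' ground-truth record.
#'
#' @param config A [sim_config()].
#' @return A list of class `congenic_sim`: `variants` (a `variant_sites`
#'   table), `annotation` ([gene_annotation]), `sequences` (named
#'   `DNAStringSet` or `NULL`), `counts` (`count_matrix`), `psms`
#'   (`psm_table`) and `truth` (list; see Details).
#' @details The `truth` record holds the realized `blocks`, `causal_locus`,
#'   `switch_id`, `regulated_cyp_ids`, `stabilized_cyp_ids`, per-gene true
#'   transcript and protein log2 fold-changes (`transcript_lfc`,
#'   `protein_lfc`; identical for SP/ROCK and CKR/ROCK by the inheritance
#'   design), and the per-site table `site_pattern` with the constructed
#'   pattern `code`, `resistance_associated` label and `passes_qual` flag.
#' @export
simulate_congenic_design <- function(config = sim_config()) {
  config <- validate_sim_config(config)
  set.seed(config$seed)
  cl <- config$chromosome_lengths

  ann <- simulate_annotation(config)
  ann <- ensure_switch_in_locus(ann, config)
  genes <- ann$genes

  truth_fx <- plant_effects(config, genes)
  variants <- simulate_variants(config)

  emit <- config$emit_sequences
  if (identical(emit, "auto")) emit <- sum(cl) <= 50e6
  sequences <- NULL
  if (isTRUE(emit)) {
    sequences <- simulate_genome(config, ann)
    # make VCF REF alleles agree with the emitted genome
    for (i in seq_len(nrow(variants))) {
      b <- as.character(Biostrings::subseq(sequences[[variants$chrom[i]]],
                                           variants$pos[i], variants$pos[i]))
      variants$ref[i] <- b
      variants$alt[i] <- sample(setdiff(c("A", "C", "G", "T"), b), 1)
    }
  }

  counts <- simulate_counts(config, genes, truth_fx$transcript_lfc)
  psms <- simulate_psms(config, genes, truth_fx$protein_lfc)

  truth <- list(
    blocks = config$introgressed_blocks,
    causal_locus = config$causal_locus,
    switch_id = truth_fx$switch_id,
    regulated_cyp_ids = truth_fx$regulated_cyp_ids,
    stabilized_cyp_ids = truth_fx$stabilized_cyp_ids,
    transcript_lfc = truth_fx$transcript_lfc,
    protein_lfc = truth_fx$protein_lfc,
    site_pattern = variants[, c("chrom", "pos", "code", "resistance_associated",
                                "passes_qual")]
  )
  variants <- validate_variant_sites(
    variants[, c("chrom", "pos", "ref", "alt", "qual", "ROCK", "SP", "CKR")])
  structure(list(variants = variants, annotation = ann, sequences = sequences,
                 counts = counts, psms = psms, truth = truth,
                 config = config),
            class = "congenic_sim")
}

# Gene models: non-overlapping genes per chromosome, 1-2 transcripts with
# 2-3 exons, CDS a multiple of 3.  Class mix fixed: ~25% CYP, ~15% TF,
# ~15% lncRNA, rest other.
simulate_annotation <- function(config) {
  cl <- config$chromosome_lengths
  n <- config$n_genes_per_chrom
  chrom <- rep(names(cl), each = n)
  slot <- floor(unname(cl[chrom]) / n)
  gene_len <- pmin(slot - 200, 6000)
  k <- rep(seq_len(n), length(cl))
  offset <- vapply(pmax(slot - gene_len - 100, 1),
                   function(m) sample.int(m, 1), 1L)
  start <- (k - 1) * slot + offset
  end <- start + gene_len - 1
  ngene <- length(start)
  genes <- data.frame(
    gene_id = sprintf("GENE%05d", seq_len(ngene)),
    chrom = chrom, start = start, end = end,
    strand = sample(c("+", "-"), ngene, replace = TRUE),
    gene_class = sample(GENE_CLASSES, ngene, replace = TRUE,
                        prob = c(0.25, 0.15, 0.15, 0.45)),
    cyp_name = NA_character_, stringsAsFactors = FALSE)
  cyps <- which(genes$gene_class == "CYP")
  genes$cyp_name[cyps] <- sprintf("CYP9X%d", seq_along(cyps))
  transcripts <- data.frame(tx_id = paste0(genes$gene_id, ".t1"),
                            gene_id = genes$gene_id, stringsAsFactors = FALSE)
  # two exons with one intron; CDS occupies the interior of each exon
  # (leaving UTR margins, padded to a codon boundary); lncRNAs get no CDS
  len <- end - start + 1
  e1s <- start;                e1e <- start + floor(len * 0.4)
  e2s <- start + floor(len * 0.6); e2e <- end
  utr <- 120L
  c1s <- e1s + utr; c1e <- e1e
  c2s <- e2s;       c2e_raw <- e2e - utr
  c2e <- c2e_raw - ((c1e - c1s + 1) + (c2e_raw - c2s + 1)) %% 3
  tx <- transcripts$tx_id
  coding <- genes$gene_class != "lncRNA"
  features <- rbind(
    data.frame(tx_id = rep(tx, 2), type = "exon",
               start = c(e1s, e2s), end = c(e1e, e2e),
               stringsAsFactors = FALSE),
    data.frame(tx_id = rep(tx[coding], 2), type = "CDS",
               start = c(c1s[coding], c2s[coding]),
               end = c(c1e[coding], c2e[coding]),
               stringsAsFactors = FALSE))
  gene_annotation(genes, transcripts, features)
}

# The congenic design puts the causal regulatory switch inside the causal
# locus; if the random class assignment left no TF there, reclassify a gene
# inside the locus as TF (or, for a locus smaller than the gene grid,
# relocate the nearest gene into it).
ensure_switch_in_locus <- function(ann, config) {
  if (is.null(config$causal_locus)) return(ann)
  loc <- config$causal_locus
  g <- ann$genes
  in_loc <- g$chrom == loc$chrom & g$start >= loc$start & g$end <= loc$end
  if (any(in_loc & g$gene_class == "TF")) return(ann)
  if (any(in_loc)) {
    pick <- sample(which(in_loc), 1)
    g$gene_class[pick] <- "TF"
    g$cyp_name[pick] <- NA_character_
  } else {
    cand <- which(g$chrom == loc$chrom)
    if (!length(cand)) stop("causal_locus chromosome has no genes")
    pick <- cand[which.min(abs(g$start[cand] - loc$start))]
    span <- g$end[pick] - g$start[pick]
    new_start <- floor((loc$start + loc$end - span) / 2)
    delta <- new_start - g$start[pick]
    g$start[pick] <- g$start[pick] + delta
    g$end[pick] <- g$end[pick] + delta
    tx_ids <- ann$transcripts$tx_id[ann$transcripts$gene_id == g$gene_id[pick]]
    sel <- ann$features$tx_id %in% tx_ids
    ann$features$start[sel] <- ann$features$start[sel] + delta
    ann$features$end[sel] <- ann$features$end[sel] + delta
    g$gene_class[pick] <- "TF"
    g$cyp_name[pick] <- NA_character_
  }
  ann$genes <- g
  ann
}

# pick the planted-effect genes and record true fold changes
plant_effects <- function(config, genes) {
  cyp_ids <- genes$gene_id[genes$gene_class == "CYP"]
  tf_ids <- genes$gene_id[genes$gene_class == "TF"]
  need <- config$n_regulated_cyps + config$n_stabilized_cyps
  if (length(cyp_ids) < need)
    stop("not enough CYP genes simulated (", length(cyp_ids), ") for ",
         need, " planted effects; raise n_genes_per_chrom")
  regulated <- sample(cyp_ids, config$n_regulated_cyps)
  stabilized <- sample(setdiff(cyp_ids, regulated), config$n_stabilized_cyps)

  switch_id <- NA_character_
  if (!is.null(config$causal_locus)) {
    loc <- config$causal_locus
    in_loc <- genes$gene_class == "TF" & genes$chrom == loc$chrom &
      genes$start >= loc$start & genes$end <= loc$end
    if (any(in_loc)) switch_id <- sample(genes$gene_id[in_loc], 1)
  }
  tx <- stats::setNames(rep(0, nrow(genes)), genes$gene_id)
  pr <- tx
  tx[regulated] <- config$planted_log2fc
  pr[regulated] <- config$planted_log2fc * config$protein_concordance
  pr[stabilized] <- config$planted_log2fc
  if (!is.na(switch_id)) {
    tx[switch_id] <- config$planted_log2fc
    pr[switch_id] <- config$planted_log2fc * config$protein_concordance
  }
  list(regulated_cyp_ids = sort(regulated),
       stabilized_cyp_ids = sort(stabilized),
       switch_id = switch_id, transcript_lfc = tx, protein_lfc = pr)
}

simulate_variants <- function(config) {
  cl <- config$chromosome_lengths
  blocks <- config$introgressed_blocks
  rows <- list()
  for (ch in names(cl)) {
    len <- cl[[ch]]
    n_donor <- stats::rpois(1, config$donor_snp_density * len / 1e6)
    n_bg <- stats::rpois(1, config$background_divergence * len / 1e6)
    pos_d <- sort(sample.int(len, n_donor))
    pos_b <- sort(sample.int(len, n_bg))
    if (n_donor) {
      inb <- in_any_block(ch, pos_d, blocks)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch, pos = pos_d, origin = "donor",
        ROCK = "hom_ref", SP = "hom_alt",
        CKR = ifelse(inb, "hom_alt", "hom_ref"),
        stringsAsFactors = FALSE)
    }
    if (n_bg) {
      # ancestral ROCK-vs-reference divergence is shared by all three
      # study strains (they derive from the same colony stock)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch, pos = pos_b, origin = "background",
        ROCK = "hom_alt", SP = "hom_alt", CKR = "hom_alt",
        stringsAsFactors = FALSE)
    }
  }
  v <- do.call(rbind, rows)
  v <- v[!duplicated(v[, c("chrom", "pos")]), , drop = FALSE]
  v <- v[order(v$chrom, v$pos), , drop = FALSE]
  n <- nrow(v)
  # heterozygous injection: one random strain per affected site
  het <- stats::runif(n) < config$het_rate
  which_strain <- sample(STUDY_STRAINS, n, replace = TRUE)
  for (s in STUDY_STRAINS) v[[s]][het & which_strain == s] <- "het"
  v$qual <- round(stats::rgamma(n, shape = 4, scale = 15), 1)
  v$passes_qual <- v$qual >= 30
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  v$ref <- ref; v$alt <- unname(alt)
  # constructed pattern labels (the generator's own bookkeeping, kept as
  # ground truth for the pattern classifier)
  hom <- function(g) g %in% c("hom_ref", "hom_alt")
  all_hom <- hom(v$ROCK) & hom(v$SP) & hom(v$CKR)
  code <- rep("uninformative", n)
  code[all_hom & v$SP == v$CKR & v$ROCK != v$SP] <- "a"
  code[all_hom & v$ROCK == v$CKR & v$SP != v$ROCK] <- "b"
  code[all_hom & v$ROCK == v$SP & v$CKR != v$ROCK] <- "c"
  code[all_hom & v$ROCK == v$SP & v$SP == v$CKR] <- "d"
  v$code <- code
  v$resistance_associated <- code == "a" & v$SP == "hom_alt" &
    v$CKR == "hom_alt" & v$ROCK == "hom_ref"
  rownames(v) <- NULL
  v
}

simulate_genome <- function(config, ann) {
  cl <- config$chromosome_lengths
  seqs <- lapply(names(cl), function(ch)
    paste(sample(c("A", "C", "G", "T"), cl[[ch]], replace = TRUE),
          collapse = ""))
  names(seqs) <- names(cl)
  genome <- Biostrings::DNAStringSet(unlist(seqs))
  # rewrite CDS regions codon-by-codon so reference proteins are stop-free
  sense_codons <- setdiff(names(Biostrings::GENETIC_CODE),
                          c("TAA", "TAG", "TGA"))
  idx <- build_transcript_index(ann)
  chars <- lapply(as.character(genome), function(s) strsplit(s, "")[[1]])
  for (tx in idx) {
    np <- length(tx$cds_pos)
    if (!np) next
    n_codon <- np / 3
    codons <- c("ATG", sample(sense_codons, n_codon - 2, replace = TRUE), "TAA")
    bases <- strsplit(paste(codons, collapse = ""), "")[[1]]
    # cds_pos is in transcription order; on the minus strand the genome
    # carries the complement of the sense base at each of those positions
    if (tx$strand == "-") bases <- chartr("ACGT", "TGCA", bases)
    chars[[tx$chrom]][tx$cds_pos] <- bases
  }
  Biostrings::DNAStringSet(vapply(chars, paste, "", collapse = ""))
}

simulate_counts <- function(config, genes, transcript_lfc) {
  reps <- config$rna_replicates
  strains <- rep(names(reps), reps)
  samples <- paste0(strains, "_", unlist(lapply(reps, seq_len)))
  base_mu <- 2^stats::runif(nrow(genes), config$nb_mean_log_range[1],
                            config$nb_mean_log_range[2])
  lfc <- transcript_lfc[genes$gene_id]
  m <- matrix(0L, nrow(genes), length(samples),
              dimnames = list(genes$gene_id, samples))
  for (j in seq_along(samples)) {
    mu <- base_mu * if (strains[j] == "ROCK") 1 else 2^lfc
    m[, j] <- stats::rnbinom(nrow(genes), mu = mu, size = 1 / config$nb_dispersion)
  }
  count_matrix(m, stats::setNames(strains, samples))
}

simulate_psms <- function(config, genes, protein_lfc) {
  ch_cfg <- config$tmt_channels
  strains <- rep(names(ch_cfg), ch_cfg)
  channels <- paste0("ch_", strains, "_", unlist(lapply(ch_cfg, seq_len)))
  prot_genes <- genes$gene_id[genes$gene_class != "lncRNA"]
  np <- length(prot_genes)
  nc <- length(channels)
  sdlog <- sqrt(log(1 + config$protein_cv^2))
  base <- stats::rlnorm(np, meanlog = log(200), sdlog = 1)
  n_psm <- sample.int(config$psm_per_protein, np, replace = TRUE)
  idx <- rep.int(seq_len(np), n_psm)          # protein index per PSM row
  total <- length(idx)
  # per-protein Dirichlet(1,...) split of abundance across its PSMs
  share <- stats::rexp(total)
  share <- share / rep.int(as.vector(rowsum(share, idx)), n_psm)
  # protein x channel effect: resistant strains carry the planted effect
  eff <- 2^outer(protein_lfc[prot_genes],
                 as.numeric(strains != "ROCK"), `*`)
  noise <- matrix(stats::rlnorm(total * nc, meanlog = -sdlog^2 / 2,
                                sdlog = sdlog), total, nc)
  sn <- (share * base[idx]) * eff[idx, , drop = FALSE] * noise
  colnames(sn) <- channels
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  peptides <- do.call(paste0, as.data.frame(
    matrix(sample(aa, total * 12, replace = TRUE), total, 12)))
  psm_table(peptides, prot_genes[idx], sn,
            stats::setNames(strains, channels))
}

#' @export
print.congenic_sim <- function(x, ...) {
  cat("congenic_sim:", nrow(x$variants), "variant sites,",
      nrow(x$annotation$genes), "genes,",
      ncol(x$counts$counts), "RNA samples,",
      length(x$psms$channel_strain), "TMT channels\n")
  invisible(x)
}
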
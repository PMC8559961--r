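# Shared builders for the test suite.  Everything is generated in code at
# test time; no binary fixtures.

# Scaled-down simulation with sequences (total genome 4.5 Mb -> sequences
# are emitted), used by sequence-level and round-trip tests.
mini_config <- function(seed = 1, ...) {
  defaults <- list(
    chromosome_lengths = c(chr1 = 1.5e6, chr2 = 1.5e6, chr3 = 1.5e6),
    n_genes_per_chrom = 40,
    donor_snp_density = 200,
    background_divergence = 20,
    introgressed_blocks = data.frame(chrom = "chr3", start = 4e5, end = 1.1e6),
    causal_locus = list(chrom = "chr3", start = 5e5, end = 1e6),
    n_regulated_cyps = 4, n_stabilized_cyps = 2,
    seed = seed)
  do.call(sim_config, utils::modifyList(defaults, list(...), keep.null = TRUE))
}

# Small random multi-gene annotation + genome on one 21 kb contig;
# two exons per gene, CDS a codon multiple, random strand.
toy_gene_set <- function(seed = 1, n_gene = 8) {
  set.seed(seed)
  slot <- 2500
  genes <- data.frame(gene_id = sprintf("g%02d", seq_len(n_gene)), chrom = "ctg",
                      start = (seq_len(n_gene) - 1) * slot + 100,
                      end = (seq_len(n_gene) - 1) * slot + 1500,
                      strand = sample(c("+", "-"), n_gene, TRUE),
                      gene_class = "other", cyp_name = NA_character_,
                      stringsAsFactors = FALSE)
  tx <- data.frame(tx_id = paste0(genes$gene_id, ".t1"), gene_id = genes$gene_id,
                   stringsAsFactors = FALSE)
  feats <- do.call(rbind, lapply(seq_len(n_gene), function(i) {
    s <- genes$start[i]; e <- genes$end[i]
    e1 <- c(s, s + 500); e2 <- c(s + 800, e)
    c1 <- c(e1[1] + 100, e1[2]); c2 <- c(e2[1], e2[2] - 100)
    pad <- (c1[2] - c1[1] + 1 + c2[2] - c2[1] + 1) %% 3
    c2[2] <- c2[2] - pad
    rbind(data.frame(tx_id = tx$tx_id[i], type = "exon",
                     start = c(e1[1], e2[1]), end = c(e1[2], e2[2])),
          data.frame(tx_id = tx$tx_id[i], type = "CDS",
                     start = c(c1[1], c2[1]), end = c(c1[2], c2[2])))
  }))
  ann <- gene_annotation(genes, tx, feats)
  genome <- Biostrings::DNAStringSet(
    c(ctg = paste(sample(c("A", "C", "G", "T"), 21000, TRUE), collapse = "")))
  list(ann = ann, genome = genome)
}

# Independent translate-and-diff oracle: classify one SNP by mutating the
# spliced CDS string directly and translating whole CDSs with Biostrings.
# Returns "non_synonymous"/"synonymous" for coding sites, NA otherwise.
oracle_effect <- function(ann, genome, chrom, pos, alt) {
  for (i in seq_len(nrow(ann$transcripts))) {
    tx_id <- ann$transcripts$tx_id[i]
    g <- ann$genes[ann$genes$gene_id == ann$transcripts$gene_id[i], ]
    if (g$chrom != chrom) next
    cds <- ann$features[ann$features$tx_id == tx_id &
                          ann$features$type == "CDS", , drop = FALSE]
    if (!nrow(cds)) next
    cds <- cds[order(cds$start), , drop = FALSE]
    cds_pos <- unlist(lapply(seq_len(nrow(cds)),
                             function(k) seq.int(cds$start[k], cds$end[k])))
    if (g$strand == "-") cds_pos <- rev(cds_pos)
    j <- match(pos, cds_pos)
    if (is.na(j)) next
    bases <- vapply(cds_pos, function(p)
      as.character(Biostrings::subseq(genome[[chrom]], p, p)), "")
    if (g$strand == "-") bases <- chartr("ACGT", "TGCA", bases)
    ref_cds <- paste(bases, collapse = "")
    bases[j] <- if (g$strand == "-") chartr("ACGT", "TGCA", alt) else alt
    alt_cds <- paste(bases, collapse = "")
    tr <- function(s) as.character(
      Biostrings::translate(Biostrings::DNAString(s), no.init.codon = TRUE,
                            if.fuzzy.codon = "X"))
    return(if (tr(ref_cds) == tr(alt_cds)) "synonymous" else "non_synonymous")
  }
  NA_character_
}

# Two-group count matrix with optional planted log2 effects in group A.
toy_count_matrix <- function(seed, n_genes = 500, n_a = 4, n_b = 4,
                             dispersion = 0.05, lfc = rep(0, n_genes),
                             mean_log_range = c(4, 10)) {
  set.seed(seed)
  mu <- 2^stats::runif(n_genes, mean_log_range[1], mean_log_range[2])
  m <- cbind(
    matrix(stats::rnbinom(n_genes * n_a, mu = mu * 2^lfc, size = 1 / dispersion),
           n_genes),
    matrix(stats::rnbinom(n_genes * n_b, mu = mu, size = 1 / dispersion),
           n_genes))
  rownames(m) <- sprintf("g%04d", seq_len(n_genes))
  colnames(m) <- c(paste0("A", seq_len(n_a)), paste0("B", seq_len(n_b)))
  count_matrix(m, stats::setNames(rep(c("A", "B"), c(n_a, n_b)), colnames(m)))
}

# Full synthetic pipeline: DE on both comparisons, protein quant, join,
# classification, locus scan and filtering.  Returns what the end-to-end
# recovery checks need.
run_full_pipeline <- function(sim) {
  genes <- sim$annotation$genes
  de_sp <- test_de(filter_genes(sim$counts, c("SP", "ROCK")), "SP", "ROCK")
  de_ck <- test_de(filter_genes(sim$counts, c("CKR", "ROCK")), "CKR", "ROCK")
  q <- normalize_total(rollup(assign_razor(sim$psms)))
  p_sp <- test_protein_de(q, "SP", "ROCK")
  p_ck <- test_protein_de(q, "CKR", "ROCK")
  joined <- join_layers(de_sp, de_ck, p_sp, p_ck,
                        gene_info = genes[, c("gene_id", "gene_class",
                                              "chrom", "start", "end")])
  snps <- select_resistance_snps(sim$variants)
  loci <- call_loci(window_counts(snps, sim$config$chromosome_lengths))
  sets <- filter_by_loci(classify_candidates(joined, NULL, genes), loci)
  list(joined = joined, sets = sets, loci = loci, snps = snps)
}

# Did the pipeline recover all planted signals of one simulation?
e2e_recovered <- function(sim, res) {
  tr <- sim$truth
  h5_post <- res$sets$H5$gene_id[res$sets$H5$filter_status %in%
                                   c("pass", "exempt", "unfilterable")]
  c(switch_in_h5 = tr$switch_id %in% h5_post,
    cyps_in_h23 = all(tr$regulated_cyp_ids %in% res$sets$H2$gene_id),
    stabilized_in_h6 = all(tr$stabilized_cyp_ids %in% res$sets$H6$gene_id))
}
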
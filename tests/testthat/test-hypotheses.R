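mk_joined <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    defaults <- list(gene_id = NA_character_, accession = NA_character_,
                     gene_class = NA_character_, chrom = NA_character_,
                     start = NA_real_, end = NA_real_,
                     mrna_lfc_sp = NA_real_, mrna_call_sp = NA_character_,
                     mrna_lfc_ckr = NA_real_, mrna_call_ckr = NA_character_,
                     prot_lfc_sp = NA_real_, prot_call_sp = NA_character_,
                     prot_lfc_ckr = NA_real_, prot_call_ckr = NA_character_,
                     layer_presence = "both")
    as.data.frame(utils::modifyList(defaults, r), stringsAsFactors = FALSE)
  }))
}

toy_catalog <- data.frame(
  gene_id = c("cypA", "cypB", "cypC", "tf1", "lnc1", "oth1"),
  gene_class = c("CYP", "CYP", "CYP", "TF", "lncRNA", "other"),
  chrom = "chr1", start = c(1, 10, 20, 30, 40, 50) * 1e6,
  end = c(1, 10, 20, 30, 40, 50) * 1e6 + 1e4,
  unplaced = FALSE, stringsAsFactors = FALSE)

test_that("expression hypotheses classify the canonical patterns", {
  joined <- mk_joined(
    # up in both layers, both strains -> H2/H3
    list(gene_id = "cypA", accession = "cypA", gene_class = "CYP",
         mrna_call_sp = "up", mrna_call_ckr = "up",
         prot_call_sp = "up", prot_call_ckr = "up"),
    # protein up in both, transcript up in SP only -> H6
    list(gene_id = "cypB", accession = "cypB", gene_class = "CYP",
         mrna_call_sp = "up", mrna_call_ckr = "ns",
         prot_call_sp = "up", prot_call_ckr = "up"),
    # up in SP only in both layers -> no hypothesis
    list(gene_id = "cypC", accession = "cypC", gene_class = "CYP",
         mrna_call_sp = "up", mrna_call_ckr = "ns",
         prot_call_sp = "up", prot_call_ckr = "ns"),
    # switch transcript down in both strains -> H5 (repressors count)
    list(gene_id = "tf1", accession = "tf1", gene_class = "TF",
         mrna_call_sp = "down", mrna_call_ckr = "down",
         layer_presence = "transcript_only"),
    # lncRNA up in both strains -> H5
    list(gene_id = "lnc1", accession = "lnc1", gene_class = "lncRNA",
         mrna_call_sp = "up", mrna_call_ckr = "up",
         layer_presence = "transcript_only"),
    # accession-only protein up in both -> reported, not a candidate
    list(accession = "XP_9.1", prot_call_sp = "up", prot_call_ckr = "up",
         layer_presence = "protein_only"))
  sets <- classify_candidates(joined, NULL, toy_catalog)
  expect_equal(sets$H2$gene_id, "cypA")
  expect_equal(sets$H3$gene_id, "cypA")
  expect_equal(sets$H6$gene_id, "cypB")
  expect_equal(sort(sets$H5$gene_id), c("lnc1", "tf1"))
  expect_equal(nrow(sets$H1), 0)
  expect_equal(nrow(sets$H4), 0)
  expect_equal(sets$protein_only_accessions, "XP_9.1")
  # H2/H3 and H6 are disjoint by construction
  expect_length(intersect(sets$H2$gene_id, sets$H6$gene_id), 0)
})

test_that("SNP-driven hypotheses H1 and H4 use non-synonymous resistance SNPs", {
  snps <- data.frame(
    chrom = "chr1", pos = c(100, 200, 300, 400),
    resistance_associated = c(TRUE, TRUE, TRUE, FALSE),
    effect = c("non_synonymous", "non_synonymous", "synonymous",
               "non_synonymous"),
    effect_gene = c("cypA", "tf1", "cypB", "lnc1"), stringsAsFactors = FALSE)
  joined <- mk_joined(list(gene_id = "cypA", accession = "cypA",
                           gene_class = "CYP"))
  sets <- classify_candidates(joined, snps, toy_catalog)
  expect_equal(sets$H1$gene_id, "cypA")   # CYP, ns, resistance-associated
  expect_equal(sets$H4$gene_id, "tf1")    # switch, ns
  # synonymous and non-resistance sites contribute nothing
  expect_false("cypB" %in% sets$H1$gene_id)
  expect_false("lnc1" %in% sets$H4$gene_id)
  expect_named(sets$h1_expression_flag, "cypA")
})

test_that("classification is invariant to input row order", {
  joined <- mk_joined(
    list(gene_id = "cypA", accession = "cypA", gene_class = "CYP",
         mrna_call_sp = "up", mrna_call_ckr = "up",
         prot_call_sp = "up", prot_call_ckr = "up"),
    list(gene_id = "tf1", accession = "tf1", gene_class = "TF",
         mrna_call_sp = "up", mrna_call_ckr = "up"))
  a <- classify_candidates(joined, NULL, toy_catalog)
  b <- classify_candidates(joined[rev(seq_len(nrow(joined))), ], NULL,
                           toy_catalog)
  expect_equal(a$H2, b$H2)
  expect_equal(a$H5, b$H5)
})

test_that("CYP cluster detection chains neighbours within the gap limit", {
  cat <- data.frame(
    gene_id = paste0("c", 1:6),
    gene_class = "CYP",
    chrom = c("chr3", "chr3", "chr3", "chr3", "chr1", "chr1"),
    start = c(1e6, 1.05e6, 1.11e6, 5e6, 1e6, 1.02e6),
    end = c(1.01e6, 1.06e6, 1.12e6, 5.01e6, 1.01e6, 1.03e6),
    cyp_name = paste0("CYP", 1:6), stringsAsFactors = FALSE)
  cl <- detect_cyp_clusters(cat$gene_id, cat, max_gap = 1e5)
  members <- lapply(cl, function(x) sort(unname(x)))
  expect_length(members, 2)
  expect_true(any(vapply(members, identical, NA, c("c1", "c2", "c3"))))
  expect_true(any(vapply(members, identical, NA, c("c5", "c6"))))
  # genes on different chromosomes never cluster
  cat2 <- cat; cat2$chrom <- paste0("chr", 1:6)
  expect_length(detect_cyp_clusters(cat2$gene_id, cat2, max_gap = 1e9), 0)
})

test_that("the three published CYP neighbourhoods are recovered as clusters", {
  # coordinates emulate the named neighbourhoods: a three-gene CYP9J run,
  # the CYP9M pair and the CYP6AA/6BB pair, with the other three isolated
  t2 <- load_example_table("cyp_overexpression_summary")
  acc <- function(nm) t2$accession[t2$cyp_name == nm]
  cat <- data.frame(
    gene_id = vapply(c("CYP9J26", "CYP9J27", "CYP9J28", "CYP9M5", "CYP9M6",
                       "CYP6AA6", "CYP6BB2", "CYP9AE1", "CYP9J10", "CYP9J17"),
                     acc, ""),
    gene_class = "CYP",
    chrom = c("chr3", "chr3", "chr3", "chr3", "chr3", "chr1", "chr1",
              "chr2", "chr3", "chr3"),
    start = c(316.0e6, 316.05e6, 316.12e6, 250.0e6, 250.06e6,
              280.0e6, 280.07e6, 100e6, 310e6, 312e6),
    end = c(316.04e6, 316.09e6, 316.16e6, 250.04e6, 250.10e6,
            280.04e6, 280.11e6, 100.04e6, 310.04e6, 312.04e6),
    cyp_name = c("CYP9J26", "CYP9J27", "CYP9J28", "CYP9M5", "CYP9M6",
                 "CYP6AA6", "CYP6BB2", "CYP9AE1", "CYP9J10", "CYP9J17"),
    stringsAsFactors = FALSE)
  cl <- detect_cyp_clusters(cat$gene_id, cat, max_gap = 1e5)
  names_of <- function(x) sort(names(x))
  got <- lapply(cl, names_of)
  expect_length(got, 3)
  expect_true(any(vapply(got, identical, NA, c("CYP9J26", "CYP9J27", "CYP9J28"))))
  expect_true(any(vapply(got, identical, NA, c("CYP9M5", "CYP9M6"))))
  expect_true(any(vapply(got, identical, NA, c("CYP6AA6", "CYP6BB2"))))
})

test_that("locus filtering passes, fails, exempts and flags correctly", {
  loci <- locus_intervals(c("chr1", "chr1", "chr3", "chr3"),
                          c(40e6, 300e6, 310e6, 330e6),
                          c(250e6, 310e6, 320e6, 360e6))
  tables <- list(
    H1 = data.frame(gene_id = "cyp_in", gene_class = "CYP", chrom = "chr1",
                    start = 100e6, end = 100.01e6, unplaced = FALSE),
    H2 = data.frame(gene_id = "cyp_chr2", gene_class = "CYP", chrom = "chr2",
                    start = 100e6, end = 100.01e6, unplaced = FALSE),
    H3 = data.frame(gene_id = "cyp_dup", gene_class = "CYP", chrom = "chr2",
                    start = 1e6, end = 1.01e6, unplaced = FALSE),
    H4 = data.frame(gene_id = "tf_unplaced", gene_class = "TF",
                    chrom = NA_character_, start = NA_real_, end = NA_real_,
                    unplaced = TRUE),
    H5 = data.frame(gene_id = "tf_out", gene_class = "TF", chrom = "chr1",
                    start = 10e6, end = 10.01e6, unplaced = FALSE),
    H6 = data.frame(gene_id = "cyp_stab", gene_class = "CYP", chrom = "chr2",
                    start = 2e6, end = 2.01e6, unplaced = FALSE))
  sets <- filter_by_loci(candidate_sets_from_tables(tables), loci)
  expect_equal(sets$H1$filter_status, "pass")          # inside chr1 40-250 Mb
  expect_equal(sets$H2$filter_status, "fail")          # no locus on chr2
  expect_equal(sets$H3$filter_status, "exempt")        # duplications invisible
  expect_equal(sets$H4$filter_status, "unfilterable")  # unplaced scaffold
  expect_equal(sets$H5$filter_status, "fail")          # chr1 but outside loci
  expect_equal(sets$H6$filter_status, "exempt")        # stabilization unfilterable
  # empty locus list: only exempt/unfilterable genes survive post-filter
  sets0 <- filter_by_loci(candidate_sets_from_tables(tables),
                          locus_intervals(character(), numeric(), numeric()))
  post <- consolidate(sets0, "post_filter")
  expect_equal(sort(post$genes), c("cyp_dup", "cyp_stab", "tf_unplaced"))
  # genes without coordinates that are not unplaced are an error
  bad <- tables
  bad$H1$chrom <- NA_character_; bad$H1$start <- NA_real_
  expect_error(filter_by_loci(candidate_sets_from_tables(bad), loci),
               "no coordinates")
})

test_that("consolidation deduplicates and never grows after filtering", {
  tables <- list(
    H1 = data.frame(gene_id = c("a", "b"), unplaced = FALSE,
                    passed_filter = c(TRUE, FALSE)),
    H2 = data.frame(gene_id = "c", unplaced = FALSE, passed_filter = FALSE),
    H3 = data.frame(gene_id = "c", unplaced = FALSE, passed_filter = FALSE),
    H4 = data.frame(gene_id = c("a", "d"), unplaced = FALSE,
                    passed_filter = c(TRUE, FALSE)),
    H5 = data.frame(gene_id = c("d", "e"), unplaced = FALSE,
                    passed_filter = c(FALSE, TRUE)),
    H6 = data.frame(gene_id = "f", unplaced = FALSE, passed_filter = FALSE))
  sets <- candidate_sets_from_tables(tables)
  pre <- consolidate(sets, "pre_filter")
  expect_equal(pre$n_candidates, 6)                       # {a..f}
  expect_equal(unname(pre$per_hypothesis),
               c(2L, 1L, 1L, 2L, 2L, 1L))
  expect_equal(pre$n_switch, 3)                           # {a, d, e}
  post <- consolidate(sets, "post_filter")
  # a (H1 pass), c (H3 exempt), e (H5 pass), f (H6 exempt)
  expect_equal(sort(post$genes), c("a", "c", "e", "f"))
  expect_true(all(post$genes %in% pre$genes))
  expect_equal(post$n_switch, 2)                          # {a, e}
  # brute-force union oracle on the pre-filter stage
  expect_equal(pre$n_candidates,
               length(unique(unlist(lapply(tables, `[[`, "gene_id")))))
  # unfiltered sets cannot be consolidated post-filter
  raw <- candidate_sets_from_tables(lapply(tables, function(t)
    t[, c("gene_id", "unplaced")]))
  expect_error(consolidate(raw, "post_filter"), "filter_by_loci")
})

test_that("planted switch, regulated and stabilized CYPs are recovered end-to-end", {
  ok <- 0
  for (s in seq_len(3)) {
    sim <- simulate_congenic_design(sim_config(seed = 70 + s))
    res <- run_full_pipeline(sim)
    if (all(e2e_recovered(sim, res))) ok <- ok + 1
  }
  expect_gte(ok, 2)
})
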
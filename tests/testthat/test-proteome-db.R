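test_that("variant substitution matches a naive per-base oracle", {
  set.seed(1)
  g <- Biostrings::DNAStringSet(c(
    c1 = paste(sample(c("A", "C", "G", "T"), 5000, TRUE), collapse = "")))
  expect_equal(as.character(apply_variants(g, data.frame(
    chrom = character(), pos = integer(), ref = character(),
    alt = character()))), as.character(g))
  # one SNP changes exactly one position
  ref10 <- as.character(Biostrings::subseq(g[["c1"]], 10, 10))
  alt10 <- setdiff(c("A", "C", "G", "T"), ref10)[1]
  one <- apply_variants(g, data.frame(chrom = "c1", pos = 10,
                                      ref = ref10, alt = alt10))
  diff_at <- which(strsplit(as.character(one[["c1"]]), "")[[1]] !=
                     strsplit(as.character(g[["c1"]]), "")[[1]])
  expect_equal(diff_at, 10L)
  # 100 random SNPs vs naive character-vector substitution
  pos <- sample.int(5000, 100)
  ref <- vapply(pos, function(p)
    as.character(Biostrings::subseq(g[["c1"]], p, p)), "")
  alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  got <- apply_variants(g, data.frame(chrom = "c1", pos = pos,
                                      ref = ref, alt = alt))
  naive <- strsplit(as.character(g[["c1"]]), "")[[1]]
  naive[pos] <- alt
  expect_equal(as.character(got[["c1"]]), paste(naive, collapse = ""))
})

test_that("bad variants are rejected with the offending site named", {
  g <- Biostrings::DNAStringSet(c(c1 = "ACGTACGTAC"))
  expect_error(apply_variants(g, data.frame(chrom = "c1", pos = 2,
                                            ref = "G", alt = "T")),
               "c1:2")
  expect_error(apply_variants(g, data.frame(chrom = "c1", pos = c(2, 3),
                                            ref = c("CG", "GT"),
                                            alt = c("C", "G"))),
               "overlapping")
})

test_that("translation handles both strands and premature stops", {
  mk_ann <- function(strand) {
    gene_annotation(
      data.frame(gene_id = "g1", chrom = "c", start = 1, end = 30,
                 strand = strand, gene_class = "other",
                 cyp_name = NA_character_),
      data.frame(tx_id = "g1.t1", gene_id = "g1"),
      rbind(data.frame(tx_id = "g1.t1", type = "exon", start = 1, end = 30),
            data.frame(tx_id = "g1.t1", type = "CDS", start = 11, end = 19)))
  }
  genome <- Biostrings::DNAStringSet(c(c = paste0("AAAAAAAAAA", "ATGGCTTAA",
                                                  "AAAAAAAAAAA")))
  prot <- extract_and_translate(genome, mk_ann("+"))
  expect_equal(prot$protein, "MA")
  expect_false(prot$premature_stop)
  # two-exon minus-strand gene: sense CDS "ATGGCTTCATAA" (-> MAS) split as
  # revcomp("ATGGC") = GCCAT at 19..23 and revcomp("TTCATAA") = TTATGAA at
  # 5..11; transcription runs from the higher-coordinate exon down
  minus_genome <- Biostrings::DNAStringSet(c(c = paste0(
    "AAAA", "TTATGAA", "CCCCCCC", "GCCAT", "AAAAAAA")))
  minus_ann <- gene_annotation(
    data.frame(gene_id = "g1", chrom = "c", start = 1, end = 30, strand = "-",
               gene_class = "other", cyp_name = NA_character_),
    data.frame(tx_id = "g1.t1", gene_id = "g1"),
    rbind(data.frame(tx_id = "g1.t1", type = "exon", start = c(5, 19),
                     end = c(11, 23)),
          data.frame(tx_id = "g1.t1", type = "CDS", start = c(5, 19),
                     end = c(11, 23))))
  mprot <- extract_and_translate(minus_genome, minus_ann)
  expect_equal(mprot$protein, "MAS")
  expect_false(mprot$premature_stop)
  # premature stop introduced by a variant truncates and flags
  stop_genome <- Biostrings::DNAStringSet(c(c = paste0(
    "AAAAAAAAAA", "ATGTAATAA", "AAAAAAAAAAA")))
  sprot <- extract_and_translate(stop_genome, mk_ann("+"))
  expect_equal(sprot$protein, "M")
  expect_true(sprot$premature_stop)
})

test_that("minus-strand translation equals the hand-built oracle", {
  # CDS on minus strand at 11..19; genome there is revcomp(ATGGCTTAA)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString("ATGGCTTAA")))
  genome <- Biostrings::DNAStringSet(c(c = paste0("AAAAAAAAAA", rc,
                                                  "AAAAAAAAAAA")))
  ann <- gene_annotation(
    data.frame(gene_id = "g1", chrom = "c", start = 1, end = 30, strand = "-",
               gene_class = "other", cyp_name = NA_character_),
    data.frame(tx_id = "g1.t1", gene_id = "g1"),
    rbind(data.frame(tx_id = "g1.t1", type = "exon", start = 1, end = 30),
          data.frame(tx_id = "g1.t1", type = "CDS", start = 11, end = 19)))
  expect_equal(extract_and_translate(genome, ann)$protein, "MA")
})

test_that("longest isoform selection keeps one protein per gene", {
  prot <- data.frame(
    tx_id = c("t1", "t2", "t3", "t4", "t5"),
    gene_id = c("gA", "gA", "gB", "gC", "gC"),
    protein = c(strrep("M", 120), strrep("M", 200), "MAAA",
                strrep("K", 50), strrep("Q", 50)),
    aa_length = c(120, 200, 4, 50, 50),
    premature_stop = FALSE, stringsAsFactors = FALSE)
  out <- longest_isoform(prot)
  expect_equal(nrow(out), 3)
  expect_equal(out$tx_id[out$gene_id == "gA"], "t2")    # longest wins
  expect_equal(out$tx_id[out$gene_id == "gB"], "t3")    # single isoform
  expect_equal(out$tx_id[out$gene_id == "gC"], "t4")    # tie -> lexical
  expect_equal(anyDuplicated(out$gene_id), 0L)
})

test_that("a zero-variant strain database equals the reference database", {
  toy <- toy_gene_set(seed = 3)
  novar <- data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character())
  fa1 <- withr::local_tempfile(fileext = ".fa")
  fa2 <- withr::local_tempfile(fileext = ".fa")
  db_ref <- build_proteome_db(toy$genome, novar, toy$ann, "REF", fa1)
  db_strain <- build_proteome_db(toy$genome, novar, toy$ann, "REF", fa2)
  expect_equal(db_ref$protein, db_strain$protein)
  expect_identical(readLines(fa1), readLines(fa2))     # byte-identical
  # determinism: repeated construction gives identical output
  expect_equal(build_proteome_db(toy$genome, novar, toy$ann, "REF"), db_ref,
               ignore_attr = TRUE)
})

test_that("strain variants flow through to the protein database", {
  toy <- toy_gene_set(seed = 4)
  ref_db <- build_proteome_db(
    toy$genome, data.frame(chrom = character(), pos = integer(),
                           ref = character(), alt = character()),
    toy$ann, "REF")
  # find a SNP the translate-and-diff oracle calls non-synonymous, located
  # before the first stop codon so it survives into the truncated protein
  cds1 <- toy$ann$features[toy$ann$features$tx_id == "g01.t1" &
                             toy$ann$features$type == "CDS", ]
  cds1 <- cds1[order(cds1$start), ]
  cds_pos <- unlist(lapply(seq_len(nrow(cds1)),
                           function(k) seq.int(cds1$start[k], cds1$end[k])))
  if (toy$ann$genes$strand[toy$ann$genes$gene_id == "g01"] == "-")
    cds_pos <- rev(cds_pos)
  aa_len <- ref_db$aa_length[ref_db$gene_id == "g01"]
  candidates <- cds_pos[seq_len(min(3 * aa_len, length(cds_pos)))]
  found <- FALSE
  for (pos in candidates) {
    ref <- as.character(Biostrings::subseq(toy$genome[["ctg"]], pos, pos))
    alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
    if (identical(oracle_effect(toy$ann, toy$genome, "ctg", pos, alt),
                  "non_synonymous")) { found <- TRUE; break }
  }
  expect_true(found)
  db <- build_proteome_db(toy$genome,
                          data.frame(chrom = "ctg", pos = pos, ref = ref,
                                     alt = alt), toy$ann, "SP")
  expect_equal(anyDuplicated(db$gene_id), 0L)
  expect_equal(db$gene_id, ref_db$gene_id)
  expect_false(identical(db$protein[db$gene_id == "g01"],
                         ref_db$protein[ref_db$gene_id == "g01"]))
  expect_identical(db$protein[db$gene_id != "g01"],
                   ref_db$protein[ref_db$gene_id != "g01"])
})
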
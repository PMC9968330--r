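test_that("the transcriptome generator is deterministic under a fixed seed", {
  a <- generate_transcriptome(n_transcripts = 50, seed = 1)
  b <- generate_transcriptome(n_transcripts = 50, seed = 1)
  expect_identical(a, b)
  c_ <- generate_transcriptome(n_transcripts = 50, seed = 2)
  expect_false(identical(a$transcripts$sequence, c_$transcripts$sequence))
})

test_that("planted ORFs are recovered verbatim by enumeration", {
  d <- generate_transcriptome(n_transcripts = 60, seed = 3)
  orfs <- enumerate_orfs(d$transcripts)
  man <- d$manifest[!is.na(d$manifest$orf_protein), ]
  expect_gt(nrow(man), 0)
  for (i in seq_len(nrow(man))) {
    hit <- orfs$transcript_id == man$transcript_id[i] &
      orfs$start_nt == man$orf_start_nt[i] &
      orfs$end_nt == man$orf_end_nt[i]
    expect_equal(sum(hit), 1)
    expect_equal(orfs$protein[hit], man$orf_protein[i])
    expect_equal(orfs$frame[hit], man$orf_frame[i])
  }
})

test_that("orf_rate 0 plants nothing", {
  d <- generate_transcriptome(n_transcripts = 20, orf_rate = 0, seed = 4)
  expect_true(all(is.na(d$manifest$orf_protein)))
})

test_that("infeasible ORF/length combinations are rejected", {
  expect_error(generate_transcriptome(n_transcripts = 5,
                                      length_range = c(60, 80),
                                      orf_len_aa = c(40, 80), seed = 1),
               "too short")
})

test_that("expression lands every transcript in its designed bin", {
  d <- generate_transcriptome(n_transcripts = 80, seed = 5)
  e <- generate_expression(d$transcripts,
                           bin_design = c(non_expressed = 0.3, low = 0.2,
                                          high = 0.5), seed = 6)
  expect_equal(as.vector(table(e$bins$bin)[c("non_expressed", "low",
                                             "high")]),
               c(24, 16, 40))
  got <- bin_expression(e$tpm)
  expect_equal(got$bin[match(e$bins$transcript_id, got$transcript_id)],
               e$bins$bin)
  # deterministic for a fixed seed
  expect_identical(e, generate_expression(d$transcripts,
                                          bin_design = c(non_expressed = 0.3,
                                                         low = 0.2,
                                                         high = 0.5),
                                          seed = 6))
})

test_that("an all-high design produces an empty decoy database", {
  d <- generate_transcriptome(n_transcripts = 20, seed = 7)
  e <- generate_expression(d$transcripts,
                           bin_design = c(non_expressed = 0, low = 0,
                                          high = 1), seed = 8)
  db <- build_search_databases(d$transcripts, bin_expression(e$tpm))
  expect_equal(sum(db$role == "decoy"), 0)
  expect_gt(sum(db$role == "target"), 0)
})

test_that("generated peptides carry unambiguous provenance", {
  d <- generate_transcriptome(n_transcripts = 60, seed = 9)
  e <- generate_expression(d$transcripts, seed = 10)
  pr <- generate_proteome(seed = 11)
  pep <- generate_peptides(d, e$bins, pr, n_lnc = 40, n_canonical = 20,
                           n_unmatched = 10, seed = 12)
  db <- build_search_databases(d$transcripts, bin_expression(e$tpm))
  prov <- classify_peptide_provenance(pep$sequence, pr,
                                      db[db$role == "target", ])
  expect_equal(prov, pep$provenance_truth)
  expect_true(all(nchar(pep$sequence) %in% 8:11))
  # n_unmatched = 0 -> no unmatched calls
  pep0 <- generate_peptides(d, e$bins, pr, n_lnc = 10, n_canonical = 5,
                            n_unmatched = 0, seed = 13)
  expect_false(any(pep0$provenance_truth == "unmatched"))
})

test_that("regulation flags are allocated exactly to the proportions", {
  d <- generate_transcriptome(n_transcripts = 60, seed = 14)
  e <- generate_expression(d$transcripts, seed = 15)
  pr <- generate_proteome(seed = 16)
  pep <- generate_peptides(d, e$bins, pr, n_lnc = 60, n_canonical = 30,
                           n_unmatched = 10, seed = 17)
  s <- summarize_regulation(pep$regulation_flag)
  expect_equal(s$percent[s$class == "up"], 10)
  expect_equal(s$percent[s$class == "down"], 32)
  expect_equal(s$percent[s$class == "unchanged"], 58)
})

test_that("peak designs are recovered exactly by classification", {
  d <- generate_transcriptome(n_transcripts = 50, seed = 18)
  pk <- generate_peaks(d$annotation, direct_fraction = 0.8,
                       associated_fraction = 0.1, seed = 19)
  calls <- classify_gene_targets(d$annotation, pk$peaks,
                                 reference_genes = pk$host_genes)
  expect_equal(calls$class[match(pk$expected$gene_id, calls$gene_id)],
               pk$expected$class)
  s <- summarize_target_fractions(calls)
  expect_equal(s$n, as.vector(table(pk$expected$class)[c("direct",
                                                         "associated",
                                                         "none")]))
})

test_that("a zero direct fraction forces all-none designs", {
  d <- generate_transcriptome(n_transcripts = 20, seed = 20)
  expect_warning(pk <- generate_peaks(d$annotation, direct_fraction = 0,
                                      associated_fraction = 0.2,
                                      seed = 21), "impossible")
  expect_true(all(pk$expected$class == "none"))
  expect_equal(nrow(pk$peaks), 0)
  calls <- classify_gene_targets(d$annotation, pk$peaks)
  expect_true(all(calls$class == "none"))
})

test_that("a full dataset writes standard files that round-trip", {
  dir <- withr::local_tempdir()
  ds <- simulate_lncpep_dataset(seed = 5, n_transcripts = 30,
                                out_dir = dir, n_lnc = 10,
                                n_canonical = 5, n_unmatched = 2)
  expect_true(all(file.exists(file.path(dir,
    c("transcripts.fa", "annotation.tsv", "tpm.tsv", "peptides.tsv",
      "proteome.fa", "peaks.bed", "manifest.json")))))
  ann <- read_annotation_tsv(file.path(dir, "annotation.tsv"))
  tx <- read_transcript_fasta(file.path(dir, "transcripts.fa"),
                              annotation = ann)
  expect_equal(tx, ds$transcriptome$transcripts)
  tpm <- read_expression_tsv(file.path(dir, "tpm.tsv"))
  expect_equal(bin_expression(tpm)$bin[match(ds$expression$bins$transcript_id,
                                             tpm$transcript_id)],
               ds$expression$bins$bin)
  peaks <- read_peaks_bed(file.path(dir, "peaks.bed"))
  expect_equal(peaks[c("chrom", "start", "end")],
               ds$peaks$peaks[c("chrom", "start", "end")],
               ignore_attr = TRUE)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  expect_equal(man$seed, 5)
  expect_equal(nrow(man$transcripts), 30)
})
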
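planted_orf <- function(protein, id = "src") {
  tx <- make_orf_transcript(protein, id = id)
  orfs <- enumerate_orfs(tx)
  list(tx = tx, orf = orfs[orfs$protein == protein, ])
}

test_that("flanked segments carry 8 natural residues each side at 24-nt flanks", {
  f <- planted_orf("MITDPGTVPRGPSHFSRLPLGGWAEDG")
  seg <- extract_flanked_segment("RGPSHFSRL", f$orf, f$tx)
  expect_equal(seg$protein, "ITDPGTVPRGPSHFSRLPLGGWAED")
  expect_equal(seg$upstream_aa, "ITDPGTVP")
  expect_equal(nchar(seg$nt_segment), 75)
  # the upstream flank encodes 24 nt
  expect_equal(3 * nchar(seg$upstream_aa), 24)
  expect_equal(translate_dna(seg$nt_segment, 0),
               paste0(seg$upstream_aa, seg$peptide, seg$downstream_aa))
})

test_that("flanks truncate at the ORF stop and start", {
  # downstream truncated to 7 residues by the ORF's stop codon
  f <- planted_orf("MCDKAFLKLKYLRLHERIYSGKKPY")
  seg <- extract_flanked_segment("KYLRLHERI", f$orf, f$tx)
  expect_equal(seg$protein, "CDKAFLKLKYLRLHERIYSGKKPY")
  expect_equal(seg$downstream_aa, "YSGKKPY")
  # peptide starting at the ORF Met: zero upstream residues
  f2 <- planted_orf("MKLHGFDSAWERTYIPQN")
  seg2 <- extract_flanked_segment("MKLHGFDSA", f2$orf, f2$tx)
  expect_equal(seg2$upstream_aa, "")
  expect_equal(seg2$downstream_aa, "WERTYIPQ")
})

test_that("flank truncation arithmetic holds across random designs", {
  set.seed(55)
  for (i in 1:25) {
    n_aa <- sample(12:40, 1)
    prot <- paste0("M", paste0(sample(strsplit("ACDEFGHIKLMNPQRSTVWY",
                                               "")[[1]],
                                      n_aa - 1, replace = TRUE),
                               collapse = ""))
    f <- planted_orf(prot)
    len <- sample(8:11, 1)
    p0 <- sample.int(n_aa - len + 1, 1) - 1
    pep <- substr(prot, p0 + 1, p0 + len)
    seg <- suppressWarnings(extract_flanked_segment(pep, f$orf, f$tx))
    # leftmost occurrence governs the flank arithmetic
    p0 <- regexpr(pep, prot, fixed = TRUE)[1] - 1
    expect_equal(nchar(seg$protein),
                 len + min(8, p0) + min(8, n_aa - p0 - len))
    expect_equal(translate_dna(seg$nt_segment, 0), seg$protein)
    expect_false(grepl("*", seg$protein, fixed = TRUE))
  }
})

test_that("segment extraction rejects absent and warns on repeated peptides", {
  f <- planted_orf("MITDPGTVPRGPSHFSRLPLGGWAEDG")
  expect_error(extract_flanked_segment("WWWWWWWW", f$orf, f$tx),
               "not found")
  f2 <- planted_orf("MAAKLMWRTAAKLMWRTD")
  expect_warning(seg <- extract_flanked_segment("AAKLMWRT", f2$orf, f2$tx),
                 "leftmost")
  expect_equal(seg$upstream_aa, "M")  # leftmost occurrence used
})

test_that("cassette assembly is additive and preserves every peptide", {
  f1 <- planted_orf("MITDPGTVPRGPSHFSRLPLGGWAEDG", "s1")
  f2 <- planted_orf("MCDKAFLKLKYLRLHERIYSGKKPY", "s2")
  s1 <- extract_flanked_segment("RGPSHFSRL", f1$orf, f1$tx)
  s2 <- extract_flanked_segment("KYLRLHERI", f2$orf, f2$tx)
  cas <- assemble_cassette(list(s1, s2))
  expect_equal(cas$length_nt,
               nchar(cas$leader_nt) + nchar(s1$nt_segment) +
                 nchar(s2$nt_segment))
  expect_equal(cas$cassette_nt,
               paste0(cas$leader_nt, s1$nt_segment, s2$nt_segment))
  # translating after the Kozak reproduces leader + segment proteins
  expect_equal(cas$cassette_protein,
               paste0(translate_dna(tpa_leader_default(), 0),
                      s1$protein, s2$protein))
})

test_that("a 20-segment cassette reproduces all 20 planted peptides", {
  set.seed(66)
  peps <- character(20)
  segs <- vector("list", 20)
  for (k in 1:20) {
    prot <- paste0("M", paste0(sample(strsplit("ACDEFGHIKLMNPQRSTVWY",
                                               "")[[1]],
                                      25, replace = TRUE), collapse = ""))
    f <- planted_orf(prot, sprintf("tx%02d", k))
    peps[k] <- substr(prot, 8, 16)
    segs[[k]] <- suppressWarnings(
      extract_flanked_segment(peps[k], f$orf, f$tx))
  }
  cas <- assemble_cassette(segs)
  for (k in 1:20)
    expect_true(grepl(peps[k], cas$cassette_protein, fixed = TRUE))
  expect_false(grepl("*", cas$cassette_protein, fixed = TRUE))
})

test_that("junction stop codons are warned, never edited", {
  bad <- list(peptide = "K", upstream_aa = "", downstream_aa = "",
              protein = "K*", nt_segment = "AAATAA")
  expect_warning(cas <- assemble_cassette(list(bad)), "stop codon")
  expect_true(grepl("TAA", cas$cassette_nt, fixed = TRUE))
})

test_that("cloning amplicons drop the stop and keep 30 nt upstream", {
  # 30-nt ORF (incl. stop) with >= 30 nt upstream context -> 57-nt amplicon
  prot9 <- "MKLHGFDSA"
  tx <- make_tx(paste0(random_dna(40), rt_fixed(prot9), "TAA",
                       random_dna(10)))
  orfs <- enumerate_orfs(tx)
  orf <- orfs[orfs$protein == prot9, ]
  amp <- cloning_amplicon(orf, tx)
  expect_equal(nchar(amp), 30 - 3 + 30)
  # translated in frame 0 from position upstream_nt, the amplicon
  # reproduces the ORF protein
  expect_equal(translate_dna(substr(amp, 31, nchar(amp)), 0), prot9)

  # ORF at the transcript start: amplicon is the ORF minus its stop
  tx2 <- make_tx(paste0(rt_fixed(prot9), "TAA"))
  orf2 <- enumerate_orfs(tx2)
  amp2 <- cloning_amplicon(orf2, tx2)
  expect_equal(amp2, rt_fixed(prot9))

  # stopless ORFs cannot be amplified "minus the STOP codon"
  tx3 <- make_tx("ATGAAAAAA")
  orf3 <- enumerate_orfs(tx3, require_stop = FALSE)
  expect_error(cloning_amplicon(orf3[orf3$frame == 0, ], tx3), "stop")
})
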
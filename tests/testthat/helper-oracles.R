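# Independent oracles and fixture builders shared across tests.

GC_TABLE <- as.character(Biostrings::GENETIC_CODE)
names(GC_TABLE) <- names(Biostrings::GENETIC_CODE)

aa_of <- function(codon) {
  if (grepl("N", codon)) return("X")
  unname(GC_TABLE[codon])
}

# Brute-force ORF scan: test every position for ATG, walk codon by codon to
# the first stop. Positional, one ORF at a time — independent of the
# vectorised implementation.
oracle_orfs <- function(dna, require_stop = TRUE) {
  L <- nchar(dna)
  rows <- list()
  for (s in seq_len(max(0L, L - 2L))) {
    if (substr(dna, s, s + 2L) != "ATG") next
    pos <- s
    prot <- character(0)
    stopped <- FALSE
    while (pos + 2L <= L) {
      cod <- substr(dna, pos, pos + 2L)
      if (cod %in% c("TAA", "TAG", "TGA")) { stopped <- TRUE; break }
      prot <- c(prot, aa_of(cod))
      pos <- pos + 3L
    }
    end1 <- if (stopped) pos + 3L else pos  # 1-based position after ORF
    if (!stopped && require_stop) next
    rows[[length(rows) + 1L]] <- data.frame(
      frame = (s - 1L) %% 3L, start_nt = s - 1L, end_nt = end1 - 1L,
      protein = paste0(prot, collapse = ""),
      length_aa = length(prot), has_stop = stopped,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(frame = integer(), start_nt = integer(),
                      end_nt = integer(), protein = character(),
                      length_aa = integer(), has_stop = logical()))
  out <- out[order(out$frame, out$start_nt), , drop = FALSE]
  rownames(out) <- NULL
  out
}

random_dna <- function(n) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Deterministic reverse translation: one fixed codon per amino acid.
RT_CODON <- vapply(split(names(GC_TABLE), GC_TABLE), `[`, character(1), 1L)
rt_fixed <- function(protein) {
  paste0(RT_CODON[strsplit(protein, "")[[1]]], collapse = "")
}

# A transcript whose single planted ORF encodes `protein` (plus stop),
# embedded between `up` and `down` context.
make_orf_transcript <- function(protein, id = "t1", up = "GGGGG",
                                down = "CCCCC", stop = "TAA") {
  seq <- paste0(up, rt_fixed(protein), stop, down)
  transcript_table(id, paste0("g_", id), "chrT", "+", 0, nchar(seq), seq)
}

make_tx <- function(seqs, ids = sprintf("t%d", seq_along(seqs))) {
  transcript_table(ids, paste0("g_", ids), "chrT", "+",
                   0, nchar(seqs), seqs)
}
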
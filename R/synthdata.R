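#' Seeded synthetic-data generators with a ground-truth manifest
#'
#' These generators emulate, at desk scale, the inputs the pipeline
#' consumes: lncRNA transcripts carrying planted ATG-to-stop smORFs (mostly
#' under 100 residues), a TPM table spanning the three expression bins
#' across two conditions, MHC-sized peptides of known provenance, ChIP-seq
#' peaks placed inside or outside TSS windows, and a canonical proteome.
#' Every planted feature is recorded in a manifest so downstream calls can
#' be checked against ground truth.
#'
#' @name synthdata
#' @keywords internal
NULL

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# codons per amino acid, from the standard code (stops excluded)
.codons_by_aa <- local({
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), as.character(gc))[.AA20]
})

# reverse-translate a protein with uniformly random synonymous codons
.rt_protein <- function(protein) {
  aa <- strsplit(protein, "")[[1]]
  paste0(vapply(.codons_by_aa[aa], function(cs)
    cs[sample.int(length(cs), 1L)], character(1)), collapse = "")
}

.random_dna <- function(n) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.random_protein <- function(n) {
  paste0(sample(.AA20, n, replace = TRUE), collapse = "")
}

# integer allocation of n by proportions, largest remainder
.allocate <- function(n, props) {
  raw <- n * props / sum(props)
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  as.integer(base)
}

#' Generate a synthetic lncRNA transcriptome with planted smORFs
#'
#' Background sequence is uniform over A/C/G/T; a fraction `orf_rate` of
#' transcripts carries one planted ORF (start Met, stop-free body, stop
#' codon) whose protein length is drawn from `orf_len_aa` — by default 20-80
#' residues, the sub-100-residue smORF regime. Genes are placed one per
#' transcript on a single synthetic chromosome, spaced so that promoter
#' windows of neighbouring genes can never interact.
#'
#' @param n_transcripts Number of transcripts (>= 1).
#' @param length_range Transcript length range in nt (min, max).
#' @param orf_rate Fraction of transcripts with a planted ORF.
#' @param orf_len_aa Planted ORF protein length range in residues.
#' @param gene_gap Genomic gap between consecutive genes in nt.
#' @param seed Integer seed.
#' @return List with `transcripts` (transcript table), `annotation`
#'   (gene-level data.frame) and `manifest` (per-transcript planted-ORF
#'   record: `orf_frame`, `orf_start_nt`, `orf_end_nt`, `orf_protein`; NA
#'   when none planted).
#' @export
generate_transcriptome <- function(n_transcripts = 100L,
                                   length_range = c(300L, 900L),
                                   orf_rate = 0.7,
                                   orf_len_aa = c(20L, 80L),
                                   gene_gap = 10000L,
                                   seed = 1L) {
  if (n_transcripts < 1L) stop("need at least one transcript", call. = FALSE)
  max_orf_nt <- 3L * (max(orf_len_aa) + 1L)
  if (max_orf_nt + 3L > min(length_range))
    stop("length_range too short for the requested ORF lengths",
         call. = FALSE)
  set.seed(seed)
  ids <- sprintf("LNC%04d", seq_len(n_transcripts))
  lens <- sample(seq(length_range[1], length_range[2]), n_transcripts,
                 replace = TRUE)
  has_orf <- stats::runif(n_transcripts) < orf_rate
  orf_frame <- rep(NA_integer_, n_transcripts)
  orf_start <- rep(NA_integer_, n_transcripts)
  orf_end <- rep(NA_integer_, n_transcripts)
  orf_protein <- rep(NA_character_, n_transcripts)
  seqs <- character(n_transcripts)
  for (i in seq_len(n_transcripts)) {
    if (!has_orf[i]) { seqs[i] <- .random_dna(lens[i]); next }
    n_aa <- sample(seq(orf_len_aa[1], orf_len_aa[2]), 1L)
    prot <- paste0("M", .random_protein(n_aa - 1L))
    orf_nt <- paste0(.rt_protein(prot),
                     sample(c("TAA", "TAG", "TGA"), 1L))
    bg <- lens[i] - nchar(orf_nt)
    up <- sample.int(bg + 1L, 1L) - 1L
    seqs[i] <- paste0(.random_dna(up), orf_nt, .random_dna(bg - up))
    orf_start[i] <- up
    orf_end[i] <- up + nchar(orf_nt)
    orf_frame[i] <- up %% 3L
    orf_protein[i] <- prot
  }
  strand <- sample(c("+", "-"), n_transcripts, replace = TRUE)
  g_start <- 5000 + cumsum(c(0, utils::head(lens + gene_gap, -1)))
  tx <- transcript_table(
    transcript_id = ids, gene_id = sub("^LNC", "LNCG", ids),
    chrom = "chrSim1", strand = strand,
    genomic_start = g_start, genomic_end = g_start + lens,
    sequence = seqs
  )
  annotation <- data.frame(
    gene_id = tx$gene_id, chrom = tx$chrom, strand = tx$strand,
    genomic_start = tx$genomic_start, genomic_end = tx$genomic_end,
    stringsAsFactors = FALSE
  )
  manifest <- data.frame(
    transcript_id = ids, gene_id = tx$gene_id,
    orf_frame = orf_frame, orf_start_nt = orf_start,
    orf_end_nt = orf_end, orf_protein = orf_protein,
    stringsAsFactors = FALSE
  )
  list(transcripts = tx, annotation = annotation, manifest = manifest)
}

#' Generate a synthetic canonical proteome
#'
#' @param n_proteins Number of proteins.
#' @param length_range Protein length range in residues.
#' @param seed Integer seed.
#' @return data.frame with `protein_id`, `sequence`.
#' @export
generate_proteome <- function(n_proteins = 20L,
                              length_range = c(150L, 400L), seed = 1L) {
  set.seed(seed)
  lens <- sample(seq(length_range[1], length_range[2]), n_proteins,
                 replace = TRUE)
  data.frame(
    protein_id = sprintf("SP%03d", seq_len(n_proteins)),
    sequence = vapply(lens, .random_protein, character(1)),
    stringsAsFactors = FALSE
  )
}

#' Generate a TPM table that lands each transcript in a designed bin
#'
#' Transcripts are assigned to the three expression bins by exact
#' largest-remainder allocation of `bin_design`, and TPM values are drawn so
#' the per-transcript maximum across all samples falls inside the designed
#' bin: zeros for non-expressed, (0.55, 0.95) for low, and >= 1.05 for
#' high. A fraction of high-bin transcripts is up- or down-regulated in the
#' second condition by `effect_fold`, always staying inside the bin.
#'
#' @param transcripts Transcript table (only ids are used).
#' @param bin_design Named proportions over `non_expressed`, `low`, `high`;
#'   must sum to 1.
#' @param conditions Two condition labels.
#' @param n_reps Replicates per condition.
#' @param regulated_props Proportions of high-bin transcripts up/down/
#'   unchanged in the second condition.
#' @param effect_fold Fold change applied to regulated transcripts.
#' @param seed Integer seed.
#' @return List with `tpm` (data.frame: `transcript_id` plus
#'   `<condition>_rep<j>` columns) and `bins` (designed bin per transcript).
#' @export
generate_expression <- function(transcripts,
                                bin_design = c(non_expressed = 0.3,
                                               low = 0.2, high = 0.5),
                                conditions = c("DMSO", "PRMT5i"),
                                n_reps = 3L,
                                regulated_props = c(up = 0.2, down = 0.2,
                                                    unchanged = 0.6),
                                effect_fold = 3,
                                seed = 1L) {
  if (abs(sum(bin_design) - 1) > 1e-9)
    stop("bin_design proportions must sum to 1", call. = FALSE)
  if (length(conditions) != 2L)
    stop("exactly two conditions are expected", call. = FALSE)
  set.seed(seed)
  ids <- transcripts$transcript_id
  n <- length(ids)
  counts <- .allocate(n, bin_design[c("non_expressed", "low", "high")])
  bins <- sample(rep(c("non_expressed", "low", "high"), counts))
  cols <- as.vector(outer(conditions, seq_len(n_reps),
                          function(c, j) sprintf("%s_rep%d", c, j)))
  mat <- matrix(0, nrow = n, ncol = length(cols),
                dimnames = list(NULL, cols))
  is_c2 <- grepl(paste0("^", conditions[2], "_"), cols)
  low_i <- which(bins == "low")
  if (length(low_i))
    mat[low_i, ] <- stats::runif(length(low_i) * length(cols), 0.55, 0.95)
  high_i <- which(bins == "high")
  if (length(high_i)) {
    reg <- sample(rep(c("up", "down", "unchanged"),
                      .allocate(length(high_i),
                                regulated_props[c("up", "down",
                                                  "unchanged")])))
    base <- stats::runif(length(high_i), 1.5, 30)
    for (k in seq_along(high_i)) {
      noise <- stats::runif(length(cols), 0.9, 1.1)
      v <- base[k] * noise
      if (reg[k] == "up") v[is_c2] <- v[is_c2] * effect_fold
      if (reg[k] == "down") v[is_c2] <- pmax(1.05, v[is_c2] / effect_fold)
      mat[high_i[k], ] <- v
    }
  }
  tpm <- data.frame(transcript_id = ids, mat, check.names = FALSE,
                    stringsAsFactors = FALSE)
  list(tpm = tpm,
       bins = data.frame(transcript_id = ids, bin = bins,
                         stringsAsFactors = FALSE))
}

# substring drawn from a protein, of length len
.sample_substring <- function(protein, len) {
  start <- sample.int(nchar(protein) - len + 1L, 1L)
  substr(protein, start, start + len - 1L)
}

#' Generate an MS peptide table of known provenance
#'
#' lncRNA-origin peptides are 8-11-mer substrings (mode 9, mean 9.0) of
#' planted ORF proteins on expressed (low/high) transcripts; canonical
#' contaminants are substrings of the canonical proteome; unmatched
#' peptides are random strings occurring in neither. Cross-contamination is
#' rejected by resampling, so intended provenance is unambiguous.
#' Regulation flags are allocated exactly to `regulation_props`.
#'
#' @param transcriptome Output of [generate_transcriptome()].
#' @param bins `bins` data.frame from [generate_expression()].
#' @param proteome Canonical proteome data.frame
#'   ([generate_proteome()]).
#' @param n_lnc,n_canonical,n_unmatched Peptide counts per intended class.
#' @param regulation_props Proportions over up/down/unchanged.
#' @param length_probs Sampling weights for lengths 8-11.
#' @param seed Integer seed.
#' @return data.frame with `sequence`, `provenance_truth`,
#'   `source_transcript`, `regulation_flag` and two abundance columns.
#' @export
generate_peptides <- function(transcriptome, bins, proteome,
                              n_lnc = 60L, n_canonical = 30L,
                              n_unmatched = 10L,
                              regulation_props = c(up = 0.10, down = 0.32,
                                                   unchanged = 0.58),
                              length_probs = c(`8` = 0.25, `9` = 0.55,
                                               `10` = 0.15, `11` = 0.05),
                              seed = 1L) {
  set.seed(seed)
  man <- transcriptome$manifest
  expressed <- bins$transcript_id[bins$bin %in% c("low", "high")]
  src <- man[!is.na(man$orf_protein) & man$transcript_id %in% expressed &
               nchar(man$orf_protein) >= 11L, , drop = FALSE]
  if (n_lnc > 0L && !nrow(src))
    stop("no expressed planted ORFs to draw lncRNA peptides from",
         call. = FALSE)
  can_hay <- .haystack(proteome$sequence)
  # expressed transcripts' full 3-frame translations: the target database
  # superset used to keep canonical/unmatched peptides out of it
  expr_tx <- transcriptome$transcripts[
    transcriptome$transcripts$transcript_id %in% expressed, , drop = FALSE]
  lnc_hay <- if (nrow(expr_tx))
    .haystack(three_frame_translate(expr_tx)$protein) else ""

  draw_len <- function() as.integer(sample(names(length_probs), 1L,
                                           prob = length_probs))
  draw_set <- function(n, sampler, keep) {
    out <- character(0); src_id <- character(0); tries <- 0L
    while (length(out) < n) {
      tries <- tries + 1L
      if (tries > 200L * max(1L, n))
        stop("could not draw enough peptides under the rejection rules",
             call. = FALSE)
      cand <- sampler()
      if (keep(cand$pep) && !cand$pep %in% out) {
        out <- c(out, cand$pep); src_id <- c(src_id, cand$src)
      }
    }
    list(pep = out, src = src_id)
  }

  lnc <- draw_set(n_lnc, function() {
    i <- sample.int(nrow(src), 1L)
    list(pep = .sample_substring(src$orf_protein[i], draw_len()),
         src = src$transcript_id[i])
  }, function(p) !grepl(p, can_hay, fixed = TRUE))
  can <- draw_set(n_canonical, function() {
    i <- sample.int(nrow(proteome), 1L)
    list(pep = .sample_substring(proteome$sequence[i], draw_len()),
         src = proteome$protein_id[i])
  }, function(p) !grepl(p, lnc_hay, fixed = TRUE))
  unm <- draw_set(n_unmatched, function() {
    list(pep = .random_protein(draw_len()), src = NA_character_)
  }, function(p) !grepl(p, lnc_hay, fixed = TRUE) &&
       !grepl(p, can_hay, fixed = TRUE))

  n_total <- n_lnc + n_canonical + n_unmatched
  flags <- sample(rep(c("up", "down", "unchanged"),
                      .allocate(n_total,
                                regulation_props[c("up", "down",
                                                   "unchanged")])))
  base <- stats::rlnorm(n_total, meanlog = 10, sdlog = 1)
  fold <- ifelse(flags == "up", 2.5, ifelse(flags == "down", 0.4, 1)) *
    stats::runif(n_total, 0.95, 1.05)
  data.frame(
    sequence = c(lnc$pep, can$pep, unm$pep),
    provenance_truth = rep(c("lncRNA_unique", "canonical", "unmatched"),
                           c(n_lnc, n_canonical, n_unmatched)),
    source_transcript = c(lnc$src, can$src, unm$src),
    regulation_flag = flags,
    abund_ctrl = base,
    abund_treated = base * fold,
    stringsAsFactors = FALSE
  )
}

#' Generate ChIP-seq peaks realising a designed target-class split
#'
#' Designed direct genes receive a peak strictly inside their TSS window.
#' Designed associated genes receive no window peak; instead a synthetic
#' host gene is emitted that spans the lncRNA gene and carries a peak at its
#' own (distant) TSS, so the host scores direct and the contained lncRNA
#' scores associated — the geometry of an lncRNA lying within another
#' transcription-factor target gene. Remaining genes stay peak-free. If the
#' direct fraction is zero no reference can score direct, so no associated
#' calls are possible and the associated fraction is ignored with a
#' warning.
#'
#' @param annotation Gene annotation from [generate_transcriptome()].
#' @param direct_fraction,associated_fraction Designed fractions (sum <=
#'   1).
#' @param half_width TSS window half-width the design must respect.
#' @param seed Integer seed.
#' @return List with `peaks` (data.frame `chrom`, `start`, `end`,
#'   `peak_id`), `host_genes` (reference annotation for associated calls)
#'   and `expected` (designed class per gene).
#' @export
generate_peaks <- function(annotation, direct_fraction = 0.8,
                           associated_fraction = 0.1, half_width = 500L,
                           seed = 1L) {
  if (direct_fraction + associated_fraction > 1 + 1e-9 ||
      direct_fraction < 0 || associated_fraction < 0)
    stop("class fractions must be non-negative and sum to at most 1",
         call. = FALSE)
  set.seed(seed)
  n <- nrow(annotation)
  counts <- .allocate(n, c(direct_fraction, associated_fraction,
                           1 - direct_fraction - associated_fraction))
  if (counts[1] == 0L && counts[2] > 0L) {
    warning("no direct genes designed; associated calls are impossible ",
            "and the associated fraction is ignored", call. = FALSE)
    counts[3] <- counts[3] + counts[2]
    counts[2] <- 0L
  }
  cls <- sample(rep(c("direct", "associated", "none"), counts))
  tss <- ifelse(annotation$strand == "+", annotation$genomic_start,
                annotation$genomic_end - 1)
  direct_i <- which(cls == "direct")
  assoc_i <- which(cls == "associated")
  if (length(assoc_i) && min(annotation$genomic_start[assoc_i]) < 3500)
    stop("gene placement too close to the chromosome start to fit host genes",
         call. = FALSE)
  peaks <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), stringsAsFactors = FALSE)
  if (length(direct_i)) {
    centre <- tss[direct_i] +
      sample(seq(-half_width + 60L, half_width - 60L), length(direct_i),
             replace = TRUE)
    peaks <- rbind(peaks, data.frame(
      chrom = annotation$chrom[direct_i],
      start = pmax(0, centre - 50), end = centre + 50,
      stringsAsFactors = FALSE))
  }
  host_genes <- data.frame(gene_id = character(0), chrom = character(0),
                           strand = character(0), genomic_start = numeric(0),
                           genomic_end = numeric(0), stringsAsFactors = FALSE)
  if (length(assoc_i)) {
    host_genes <- data.frame(
      gene_id = paste0("HOST_", annotation$gene_id[assoc_i]),
      chrom = annotation$chrom[assoc_i],
      strand = "+",
      genomic_start = annotation$genomic_start[assoc_i] - 3000,
      genomic_end = annotation$genomic_end[assoc_i] + 3000,
      stringsAsFactors = FALSE
    )
    peaks <- rbind(peaks, data.frame(
      chrom = host_genes$chrom,
      start = host_genes$genomic_start - 40,
      end = host_genes$genomic_start + 60,
      stringsAsFactors = FALSE))
  }
  if (nrow(peaks)) peaks$peak_id <- sprintf("peak_%d", seq_len(nrow(peaks)))
  else peaks$peak_id <- character(0)
  # design audit: no peak may stray into the window of a non-direct gene
  win <- data.frame(gene_id = annotation$gene_id,
                    lo = pmax(0, tss - half_width), hi = tss + half_width)
  for (j in which(cls != "direct")) {
    inside <- peaks$start < win$hi[j] & peaks$end > win$lo[j] &
      peaks$chrom == annotation$chrom[j]
    if (any(inside))
      stop("design infeasible: a peak falls inside the window of gene ",
           annotation$gene_id[j], call. = FALSE)
  }
  list(peaks = peaks, host_genes = host_genes,
       expected = data.frame(gene_id = annotation$gene_id, class = cls,
                             stringsAsFactors = FALSE))
}

#' Generate a complete synthetic dataset, optionally written to disk
#'
#' Orchestrates all generators under sub-seeds derived from `seed` and,
#' when `out_dir` is given, writes standard files: transcript FASTA,
#' annotation TSV, TPM TSV, peak BED, canonical proteome FASTA, peptide TSV
#' and a JSON truth manifest.
#'
#' @param seed Integer master seed.
#' @param n_transcripts Number of lncRNA transcripts.
#' @param out_dir Optional output directory (created if missing).
#' @param ... Passed on to [generate_peptides()] (counts, proportions).
#' @return List with `transcriptome`, `proteome`, `expression`, `peptides`,
#'   `peaks`.
#' @export
simulate_lncpep_dataset <- function(seed = 1L, n_transcripts = 100L,
                                    out_dir = NULL, ...) {
  txome <- generate_transcriptome(n_transcripts = n_transcripts, seed = seed)
  proteome <- generate_proteome(seed = seed + 1L)
  expr <- generate_expression(txome$transcripts, seed = seed + 2L)
  peptides <- generate_peptides(txome, expr$bins, proteome,
                                seed = seed + 3L, ...)
  peaks <- generate_peaks(txome$annotation, seed = seed + 4L)
  out <- list(transcriptome = txome, proteome = proteome,
              expression = expr, peptides = peptides, peaks = peaks)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    tx <- txome$transcripts
    write_fasta(stats::setNames(tx$sequence, tx$transcript_id),
                file.path(out_dir, "transcripts.fa"), type = "dna")
    utils::write.table(tx[c("transcript_id", "gene_id", "chrom", "strand",
                            "genomic_start", "genomic_end")],
                       file.path(out_dir, "annotation.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(expr$tpm, file.path(out_dir, "tpm.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(peptides, file.path(out_dir, "peptides.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_fasta(stats::setNames(proteome$sequence, proteome$protein_id),
                file.path(out_dir, "proteome.fa"), type = "protein")
    utils::write.table(
      cbind(peaks$peaks[c("chrom", "start", "end", "peak_id")]),
      file.path(out_dir, "peaks.bed"), sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE)
    utils::write.table(peaks$host_genes,
                       file.path(out_dir, "host_genes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    manifest <- list(seed = seed,
                     transcripts = txome$manifest,
                     bins = expr$bins,
                     peptides = peptides[c("sequence", "provenance_truth",
                                           "source_transcript",
                                           "regulation_flag")],
                     target_classes = peaks$expected)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  out
}
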
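#' Sequence primitives: translation, three-frame translation, ORF enumeration
#'
#' @name seqcore
#' @keywords internal
NULL

# Codon -> amino acid lookup built once from the standard genetic code.
# Stops render '*'; any codon containing N renders 'X'.
.codon_table <- local({
  gc <- Biostrings::GENETIC_CODE
  tab <- as.character(gc)
  names(tab) <- names(gc)
  tab
})

.STOP_CODONS <- c("TAA", "TAG", "TGA")

.check_dna <- function(dna) {
  if (!is.character(dna) || length(dna) != 1L || is.na(dna))
    stop("`dna` must be a single character string", call. = FALSE)
  bad <- regexpr("[^ACGTN]", dna)
  if (bad > 0L)
    stop(sprintf("invalid nucleotide '%s' at position %d",
                 substr(dna, bad, bad), bad), call. = FALSE)
  invisible(dna)
}

#' Translate a DNA string in a given frame
#'
#' Standard-genetic-code translation of the codons starting at `frame`
#' nucleotides from the 5' end. Stop codons are rendered `*`; any codon
#' containing `N` is rendered `X`; a trailing partial codon is dropped.
#'
#' @param dna Single DNA string over `A,C,G,T,N` (sense strand, 5'->3').
#' @param frame Integer offset 0, 1 or 2.
#' @return Single amino-acid string (possibly empty).
#' @examples
#' translate_dna("ATGTTT", 0)   # "MF"
#' translate_dna("AATGTTT", 1)  # "MF"
#' translate_dna("ATGTAA", 0)   # "M*"
#' @export
translate_dna <- function(dna, frame = 0L) {
  .check_dna(dna)
  frame <- as.integer(frame)
  if (length(frame) != 1L || is.na(frame) || frame < 0L || frame > 2L)
    stop("`frame` must be 0, 1 or 2", call. = FALSE)
  n <- nchar(dna)
  n_codon <- (n - frame) %/% 3L
  if (n_codon <= 0L) return("")
  starts <- frame + 1L + 3L * (seq_len(n_codon) - 1L)
  codons <- substring(dna, starts, starts + 2L)
  aa <- .codon_table[codons]
  aa[is.na(aa)] <- "X"  # codons containing N
  paste0(aa, collapse = "")
}

.check_transcripts <- function(transcripts) {
  req <- c("transcript_id", "gene_id", "chrom", "strand",
           "genomic_start", "genomic_end", "sequence")
  if (!is.data.frame(transcripts) || !all(req %in% names(transcripts)))
    stop("`transcripts` must be a data.frame with columns: ",
         paste(req, collapse = ", "), call. = FALSE)
  if (any(!nzchar(transcripts$sequence)))
    stop("transcript sequences must be non-empty", call. = FALSE)
  if (any(transcripts$genomic_end <= transcripts$genomic_start))
    stop("genomic_end must exceed genomic_start", call. = FALSE)
  if (any(!transcripts$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'", call. = FALSE)
  invisible(transcripts)
}

#' Construct a transcript table
#'
#' The transcript container used throughout the pipeline: one row per
#' transcript, with 0-based half-open genomic coordinates and the spliced
#' sense-strand sequence. The TSS is derivable per row: `genomic_start` on
#' the plus strand, `genomic_end - 1` on the minus strand.
#'
#' @param transcript_id,gene_id,chrom Character vectors.
#' @param strand `"+"` or `"-"` per transcript.
#' @param genomic_start,genomic_end 0-based half-open genomic coordinates.
#' @param sequence DNA strings over `A,C,G,T,N`, 5'->3' sense orientation.
#' @return A validated `data.frame`.
#' @export
transcript_table <- function(transcript_id, gene_id, chrom, strand,
                             genomic_start, genomic_end, sequence) {
  tx <- data.frame(
    transcript_id = as.character(transcript_id),
    gene_id = as.character(gene_id),
    chrom = as.character(chrom),
    strand = as.character(strand),
    genomic_start = as.numeric(genomic_start),
    genomic_end = as.numeric(genomic_end),
    sequence = toupper(as.character(sequence)),
    stringsAsFactors = FALSE
  )
  for (s in tx$sequence) .check_dna(s)
  .check_transcripts(tx)
}

#' Transcription start site of each transcript
#'
#' @param transcripts Transcript table (see [transcript_table()]).
#' @return Numeric vector of 0-based TSS positions (strand-aware).
#' @export
transcript_tss <- function(transcripts) {
  .check_transcripts(transcripts)
  ifelse(transcripts$strand == "+",
         transcripts$genomic_start,
         transcripts$genomic_end - 1)
}

#' Three-frame translation of a transcript
#'
#' Translates the sense strand in frames 0, 1 and 2 (no reverse-complement
#' frames). Each protein has length `floor((L - frame) / 3)`.
#'
#' @param transcripts Transcript table; each row is translated.
#' @return data.frame with columns `transcript_id`, `frame`, `protein`.
#' @export
three_frame_translate <- function(transcripts) {
  .check_transcripts(transcripts)
  out <- do.call(rbind, lapply(seq_len(nrow(transcripts)), function(i) {
    data.frame(
      transcript_id = transcripts$transcript_id[i],
      frame = 0:2,
      protein = vapply(0:2, function(f)
        translate_dna(transcripts$sequence[i], f), character(1)),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

#' Enumerate ATG-to-stop open reading frames on a transcript
#'
#' For every start codon in every sense frame, reports the ORF ending at the
#' first downstream in-frame stop codon. Nested ORFs sharing a stop are all
#' reported. ORFs running off the 3' end are reported only when
#' `require_stop = FALSE` (with `has_stop = FALSE`). Coordinates are 0-based
#' half-open on the transcript; `end_nt` is the position after the stop codon
#' when a stop terminates the ORF. The reported `protein` excludes the stop.
#'
#' @param transcripts Transcript table.
#' @param require_stop Drop ORFs lacking an in-frame stop (default `TRUE`).
#' @param min_aa Minimum protein length in residues (default 1).
#' @param start_codons Codons accepted as initiators (default `"ATG"`; may be
#'   extended to near-cognate starts).
#' @return data.frame with columns `transcript_id`, `frame`, `start_nt`,
#'   `end_nt`, `protein`, `length_aa`, `has_stop`, sorted by
#'   (transcript, frame, start_nt).
#' @examples
#' tx <- transcript_table("t1", "g1", "chr1", "+", 0, 9, "ATGAAATGA")
#' enumerate_orfs(tx)  # one ORF, protein "MK"
#' @export
enumerate_orfs <- function(transcripts, require_stop = TRUE, min_aa = 1L,
                           start_codons = "ATG") {
  .check_transcripts(transcripts)
  res <- lapply(seq_len(nrow(transcripts)), function(i) {
    seq_i <- transcripts$sequence[i]
    id <- transcripts$transcript_id[i]
    L <- nchar(seq_i)
    per_frame <- lapply(0:2, function(f) {
      n_codon <- (L - f) %/% 3L
      if (n_codon < 1L) return(NULL)
      pos <- f + 1L + 3L * (seq_len(n_codon) - 1L)
      codons <- substring(seq_i, pos, pos + 2L)
      starts <- which(codons %in% start_codons)
      if (!length(starts)) return(NULL)
      stops <- which(codons %in% .STOP_CODONS)
      # first stop at or after each start (a start codon is never a stop)
      nxt <- if (length(stops))
        stops[findInterval(starts, stops, left.open = TRUE) + 1L]
      else rep(NA_integer_, length(starts))
      has_stop <- !is.na(nxt)
      if (require_stop) {
        keep <- has_stop
        starts <- starts[keep]; nxt <- nxt[keep]; has_stop <- has_stop[keep]
        if (!length(starts)) return(NULL)
      }
      end_codon <- ifelse(has_stop, nxt, n_codon)  # inclusive codon index
      start_nt <- f + 3L * (starts - 1L)
      end_nt <- f + 3L * end_codon
      length_aa <- ifelse(has_stop,
                          (end_nt - start_nt) / 3L - 1L,
                          (end_nt - start_nt) / 3L)
      protein <- vapply(seq_along(starts), function(k) {
        aa <- .codon_table[codons[seq(starts[k],
                                      starts[k] + length_aa[k] - 1L)]]
        aa[is.na(aa)] <- "X"
        paste0(aa, collapse = "")
      }, character(1))
      data.frame(transcript_id = id, frame = f,
                 start_nt = start_nt, end_nt = end_nt,
                 protein = protein, length_aa = length_aa,
                 has_stop = has_stop, stringsAsFactors = FALSE)
    })
    do.call(rbind, per_frame)
  })
  out <- do.call(rbind, res)
  if (is.null(out) || !nrow(out))
    return(data.frame(transcript_id = character(), frame = integer(),
                      start_nt = integer(), end_nt = integer(),
                      protein = character(), length_aa = integer(),
                      has_stop = logical(), stringsAsFactors = FALSE))
  out <- out[out$length_aa >= min_aa, , drop = FALSE]
  out <- out[order(out$transcript_id, out$frame, out$start_nt), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Average residue masses (Da), standard amino-acid composition.
.residue_mass <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132
)
.WATER_MASS <- 18.0153

#' Theoretical average molecular weight of a polypeptide, in kDa
#'
#' Sum of standard average residue masses plus one water, divided by 1000.
#'
#' @param protein Amino-acid string over the 20-letter alphabet (no `*`).
#' @return Mass in kDa (numeric).
#' @examples
#' round(protein_mw_kda("M"), 3)  # 0.149
#' @export
protein_mw_kda <- function(protein) {
  if (!is.character(protein) || length(protein) != 1L || is.na(protein) ||
      !nzchar(protein))
    stop("`protein` must be a non-empty amino-acid string", call. = FALSE)
  aa <- strsplit(protein, "")[[1]]
  unknown <- setdiff(aa, names(.residue_mass))
  if (length(unknown))
    stop("unknown residue(s): ", paste(unique(unknown), collapse = ", "),
         call. = FALSE)
  (sum(.residue_mass[aa]) + .WATER_MASS) / 1000
}
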
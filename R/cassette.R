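#' Poly-antigen cassette and ORF cloning-construct design
#'
#' Each selected MHC peptide is carried into the cassette together with its
#' natural flanking coding sequence (24 nt, i.e. 8 residues, either side by
#' default), bounded by the source ORF: flanks truncate at the ORF's start
#' methionine and stop codon. Segments are concatenated behind a Kozak
#' sequence and a tPA secretion-leader CDS. The cloning amplicon for an ORF
#' is the ORF minus its stop codon plus 30 nt of upstream transcript
#' sequence (to retain any endogenous ribosome binding site), leaving the 3'
#' end in frame with a downstream tag.
#'
#' @name cassette
#' @keywords internal
NULL

#' Default tPA secretion-leader CDS
#'
#' CDS of the standard 23-residue human tissue plasminogen activator signal
#' peptide, commonly fused to vectored-vaccine antigens. Supplied as a
#' default; any in-frame leader can be passed to [assemble_cassette()].
#'
#' @return Single DNA string (69 nt).
#' @export
tpa_leader_default <- function() {
  paste0("ATGGATGCAATGAAGAGAGGGCTCTGCTGTGTGCTGCTGCTGTGTGGAGCAGTCTTC",
         "GTTTCGCCCAGC")
}

#' Extract a peptide's natural flanked segment from its source ORF
#'
#' Takes `flank_nt / 3` natural residues either side of the peptide within
#' the ORF's reading frame, truncating where the ORF protein ends (at its
#' start Met or stop codon). The nucleotide segment is copied verbatim from
#' the source transcript, so `translate_dna(nt_segment, 0)` reproduces
#' `upstream_aa + peptide + downstream_aa`.
#'
#' @param peptide Peptide sequence (e.g. a 9-mer MHC ligand).
#' @param orf One-row data.frame from [enumerate_orfs()] (the source ORF).
#' @param transcripts Transcript table containing the ORF's transcript.
#' @param flank_nt Flank width in nt each side; divisible by 3 (default 24).
#' @return List with `peptide`, `upstream_aa`, `downstream_aa`, `protein`
#'   (the concatenation) and `nt_segment`.
#' @export
extract_flanked_segment <- function(peptide, orf, transcripts,
                                    flank_nt = 24L) {
  .check_peptides(peptide)
  if (flank_nt %% 3L != 0L)
    stop("`flank_nt` must be divisible by 3", call. = FALSE)
  if (nrow(orf) != 1L)
    stop("`orf` must be a single ORF candidate row", call. = FALSE)
  seq_i <- transcripts$sequence[match(orf$transcript_id,
                                      transcripts$transcript_id)]
  if (is.na(seq_i))
    stop("ORF transcript absent from transcript table", call. = FALSE)
  hits <- gregexpr(peptide, orf$protein, fixed = TRUE)[[1]]
  if (hits[1] == -1L)
    stop("peptide not found in the ORF protein", call. = FALSE)
  if (length(hits) > 1L)
    warning("peptide occurs ", length(hits),
            " times in the ORF protein; using the leftmost occurrence",
            call. = FALSE)
  p0 <- hits[1] - 1L                      # 0-based residue offset in ORF
  flank_aa <- flank_nt %/% 3L
  up_aa <- min(flank_aa, p0)
  down_aa <- min(flank_aa, orf$length_aa - (p0 + nchar(peptide)))
  seg_aa_start <- p0 - up_aa              # 0-based, within ORF protein
  seg_aa_len <- up_aa + nchar(peptide) + down_aa
  nt_from <- orf$start_nt + 3L * seg_aa_start      # 0-based on transcript
  nt_to <- nt_from + 3L * seg_aa_len
  nt_segment <- substr(seq_i, nt_from + 1L, nt_to)
  list(
    peptide = peptide,
    upstream_aa = substr(orf$protein, seg_aa_start + 1L, p0),
    downstream_aa = substr(orf$protein, p0 + nchar(peptide) + 1L,
                           seg_aa_start + seg_aa_len),
    protein = substr(orf$protein, seg_aa_start + 1L,
                     seg_aa_start + seg_aa_len),
    nt_segment = nt_segment
  )
}

#' Assemble the poly-antigen cassette
#'
#' Concatenates the flanked segments, in the given order, behind the Kozak
#' sequence and the tPA leader CDS. A stop codon arising in the reading
#' frame across a segment junction is reported as a warning (junction
#' index), never auto-edited.
#'
#' @param segments List of flanked segments from
#'   [extract_flanked_segment()].
#' @param kozak Kozak sequence placed 5' of the leader (default
#'   `"GCCACC"`).
#' @param tpa_leader Leader CDS, length divisible by 3 (default
#'   [tpa_leader_default()]).
#' @return List with `segments`, `leader_nt` (kozak + leader),
#'   `cassette_nt`, `cassette_protein` (leader peptide + segment proteins,
#'   translated from the leader ATG) and `length_nt`.
#' @export
assemble_cassette <- function(segments, kozak = "GCCACC",
                              tpa_leader = tpa_leader_default()) {
  if (!length(segments)) stop("no segments to assemble", call. = FALSE)
  .check_dna(kozak); .check_dna(tpa_leader)
  if (nchar(tpa_leader) %% 3L != 0L)
    stop("leader CDS length must be divisible by 3", call. = FALSE)
  seg_nt <- vapply(segments, `[[`, character(1), "nt_segment")
  if (any(nchar(seg_nt) %% 3L != 0L))
    stop("every segment must be a whole number of codons", call. = FALSE)
  insert_nt <- paste0(seg_nt, collapse = "")
  insert_protein <- translate_dna(paste0(tpa_leader, insert_nt), 0)
  if (grepl("*", insert_protein, fixed = TRUE)) {
    # locate which junction (or segment) introduced the stop
    stop_aa <- regexpr("*", insert_protein, fixed = TRUE)
    aa_bounds <- cumsum(c(nchar(tpa_leader), nchar(seg_nt)) / 3)
    junction <- findInterval(stop_aa - 1, aa_bounds)
    warning("in-frame stop codon at cassette junction ", junction,
            call. = FALSE)
  }
  leader_nt <- paste0(kozak, tpa_leader)
  cassette_nt <- paste0(leader_nt, insert_nt)
  list(segments = segments,
       leader_nt = leader_nt,
       cassette_nt = cassette_nt,
       cassette_protein = insert_protein,
       length_nt = nchar(cassette_nt))
}

#' Cloning amplicon for an ORF-FLAG construct
#'
#' The amplified region spans up to `upstream_nt` nt of natural transcript
#' sequence 5' of the ORF (truncated at the transcript start) through the
#' ORF minus its stop codon, so the product stays in frame with a 3' tag.
#'
#' @param orf One-row [enumerate_orfs()] data.frame; must have a stop codon
#'   (`has_stop`), which is dropped from the product.
#' @param transcripts Transcript table containing the ORF's transcript.
#' @param upstream_nt Upstream context to include (default 30).
#' @return Single DNA string.
#' @export
cloning_amplicon <- function(orf, transcripts, upstream_nt = 30L) {
  if (nrow(orf) != 1L)
    stop("`orf` must be a single ORF candidate row", call. = FALSE)
  if (!isTRUE(orf$has_stop))
    stop("ORF has no stop codon; cannot amplify 'minus the STOP codon'",
         call. = FALSE)
  seq_i <- transcripts$sequence[match(orf$transcript_id,
                                      transcripts$transcript_id)]
  if (is.na(seq_i))
    stop("ORF transcript absent from transcript table", call. = FALSE)
  from <- max(0L, orf$start_nt - upstream_nt)       # 0-based
  substr(seq_i, from + 1L, orf$end_nt - 3L)
}
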
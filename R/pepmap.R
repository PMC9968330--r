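#' Peptide provenance, ORF assignment and repertoire summaries
#'
#' MS-identified peptides are matched by exact substring search against the
#' canonical proteome and the lncRNA target database; peptides found only in
#' the lncRNA database are the "lncRNA-derived" set, and candidate source
#' ORFs are attached by containment in enumerated ORF proteins.
#'
#' @name pepmap
#' @keywords internal
NULL

.check_peptides <- function(peptides) {
  if (!is.character(peptides) || !length(peptides))
    stop("peptides must be a character vector", call. = FALSE)
  bad <- grepl("[^ACDEFGHIKLMNPQRSTVWY]", peptides)
  if (any(bad))
    stop("invalid residue in peptide(s): ",
         paste(utils::head(peptides[bad], 5), collapse = ", "),
         call. = FALSE)
  if (any(!nzchar(peptides)))
    stop("empty peptide sequence", call. = FALSE)
  invisible(peptides)
}

# Concatenate subject sequences with a separator that can never occur in a
# peptide, so one fixed-string search covers the whole database.
.haystack <- function(seqs) paste(seqs, collapse = "-")

.collapse_il <- function(x) chartr("I", "L", x)

#' Classify peptide provenance
#'
#' Substring search of each peptide against the canonical proteome and the
#' lncRNA target database. Canonical evidence dominates: a peptide found in
#' both is `shared`, counted with the canonical repertoire, so
#' `lncRNA_unique` means derived from lncRNA genes only.
#'
#' @param peptides Character vector of peptide sequences.
#' @param canonical Canonical proteome data.frame (see
#'   [read_proteome_fasta()]) or character vector of protein sequences.
#' @param lnc_targets Target database entries ([build_search_databases()]
#'   output, target rows) or character vector of entry sequences.
#' @param collapse_il Treat I and L as equivalent (MS cannot distinguish
#'   them); default `FALSE`.
#' @return Character vector over `canonical`, `lncRNA_unique`, `shared`,
#'   `unmatched`.
#' @export
classify_peptide_provenance <- function(peptides, canonical, lnc_targets,
                                        collapse_il = FALSE) {
  .check_peptides(peptides)
  can_seqs <- if (is.data.frame(canonical)) canonical$sequence else canonical
  lnc_seqs <- if (is.data.frame(lnc_targets)) lnc_targets$protein_segment
              else lnc_targets
  can_hay <- .haystack(can_seqs)
  lnc_hay <- .haystack(lnc_seqs)
  probe <- peptides
  if (collapse_il) {
    can_hay <- .collapse_il(can_hay)
    lnc_hay <- .collapse_il(lnc_hay)
    probe <- .collapse_il(probe)
  }
  in_can <- vapply(probe, function(p) grepl(p, can_hay, fixed = TRUE),
                   logical(1), USE.NAMES = FALSE)
  in_lnc <- vapply(probe, function(p) grepl(p, lnc_hay, fixed = TRUE),
                   logical(1), USE.NAMES = FALSE)
  out <- rep("unmatched", length(peptides))
  out[in_can & !in_lnc] <- "canonical"
  out[!in_can & in_lnc] <- "lncRNA_unique"
  out[in_can & in_lnc] <- "shared"
  out
}

#' Candidate source ORFs for a peptide
#'
#' All ATG-to-stop ORFs (across all supplied transcripts) whose polypeptide
#' contains the peptide, sorted by (transcript, frame, start).
#'
#' @param peptide Single peptide sequence.
#' @param transcripts Transcript table.
#' @param orfs Optional precomputed [enumerate_orfs()] output (avoids
#'   re-enumeration when mapping many peptides).
#' @return data.frame of ORF candidates (possibly empty).
#' @export
assign_orfs_to_peptide <- function(peptide, transcripts, orfs = NULL) {
  .check_peptides(peptide)
  if (length(peptide) != 1L)
    stop("one peptide at a time; see `peptide_report()` for batches",
         call. = FALSE)
  if (is.null(orfs)) orfs <- enumerate_orfs(transcripts)
  hit <- grepl(peptide, orfs$protein, fixed = TRUE)
  out <- orfs[hit, , drop = FALSE]
  out <- out[order(out$transcript_id, out$frame, out$start_nt), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-peptide provenance and ORF report
#'
#' @param peptides Character vector of peptides.
#' @param canonical,lnc_targets,collapse_il As in
#'   [classify_peptide_provenance()].
#' @param transcripts Transcript table used for ORF assignment.
#' @return data.frame with one row per peptide: `sequence`, `provenance`,
#'   `n_orfs`, and the best (first) ORF's coordinates.
#' @export
peptide_report <- function(peptides, canonical, lnc_targets, transcripts,
                           collapse_il = FALSE) {
  prov <- classify_peptide_provenance(peptides, canonical, lnc_targets,
                                      collapse_il = collapse_il)
  orfs <- enumerate_orfs(transcripts)
  per <- lapply(peptides, assign_orfs_to_peptide,
                transcripts = transcripts, orfs = orfs)
  data.frame(
    sequence = peptides,
    provenance = prov,
    n_orfs = vapply(per, nrow, integer(1)),
    orf_transcript_id = vapply(per, function(d)
      if (nrow(d)) d$transcript_id[1] else NA_character_, character(1)),
    orf_frame = vapply(per, function(d)
      if (nrow(d)) d$frame[1] else NA_integer_, integer(1)),
    orf_start_nt = vapply(per, function(d)
      if (nrow(d)) d$start_nt[1] else NA_integer_, integer(1)),
    orf_end_nt = vapply(per, function(d)
      if (nrow(d)) d$end_nt[1] else NA_integer_, integer(1)),
    stringsAsFactors = FALSE
  )
}

#' Peptide length distribution and mean length
#'
#' @param peptides Non-empty character vector of peptide sequences.
#' @return List with `counts` (named integer vector, count per length) and
#'   `mean_length` (arithmetic mean, 1 decimal).
#' @export
peptide_length_distribution <- function(peptides) {
  .check_peptides(peptides)
  len <- nchar(peptides)
  counts <- table(len)
  list(counts = stats::setNames(as.integer(counts), names(counts)),
       mean_length = round(mean(len), 1))
}

#' Normalise an abundance matrix to the row mean
#'
#' Each value is divided by its row's mean, so every output row has mean 1.
#'
#' @param mat Numeric matrix (rows: peptides or transcripts; columns:
#'   samples). Each row must have a strictly positive mean.
#' @return Matrix of the same shape.
#' @export
normalize_to_mean <- function(mat) {
  mat <- as.matrix(mat)
  if (!is.numeric(mat)) stop("matrix must be numeric", call. = FALSE)
  rm_ <- rowMeans(mat)
  bad <- which(!(rm_ > 0))
  if (length(bad)) {
    lab <- if (!is.null(rownames(mat))) rownames(mat)[bad[1]] else bad[1]
    stop("row ", lab, " has non-positive mean; cannot normalise",
         call. = FALSE)
  }
  mat / rm_
}

#' Summarise peptide regulation calls
#'
#' Aggregates externally-computed significance calls (the pipeline does not
#' compute differential abundance itself).
#'
#' @param flags Character vector over `up`, `down`, `unchanged` (no missing
#'   values).
#' @return data.frame with one row per class: `class`, `n`, `percent`.
#' @export
summarize_regulation <- function(flags) {
  if (!length(flags) || anyNA(flags))
    stop("every peptide needs a regulation flag", call. = FALSE)
  bad <- setdiff(unique(flags), c("up", "down", "unchanged"))
  if (length(bad))
    stop("invalid regulation flag(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  lev <- c("up", "down", "unchanged")
  n <- vapply(lev, function(l) sum(flags == l), integer(1))
  data.frame(class = lev, n = n, percent = 100 * n / length(flags),
             stringsAsFactors = FALSE, row.names = NULL)
}
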
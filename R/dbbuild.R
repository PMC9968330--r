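#' Expression-gated target/decoy search-database construction
#'
#' Transcripts are binned on TPM: non-expressed (TPM = 0), weakly expressed
#' ("low", 0.5 < TPM < 1.0) and expressed ("high", TPM >= 1.0). Low/high
#' transcripts feed the target database; the translated non-expressed set is
#' the decoy database; the undefined interval (0, 0.5] is excluded from both.
#'
#' @name dbbuild
#' @keywords internal
NULL

#' Bin transcripts by summary TPM
#'
#' The per-transcript summary is the maximum TPM across samples by default
#' ("detectable in any sample"), switchable to the mean. Bins:
#' `summary_tpm <= zero_eps` -> `non_expressed`; `(low_lo, low_hi)` ->
#' `low`; `>= low_hi` -> `high`; the remaining gap `(zero_eps, low_lo]` ->
#' `unassigned` (excluded from both databases).
#'
#' @param expression data.frame with `transcript_id` plus one numeric column
#'   per sample (see [read_expression_tsv()]).
#' @param thresholds List with `zero_eps` (default 1e-9, absorbs quantifier
#'   float noise), `low_lo` (0.5) and `low_hi` (1.0).
#' @param aggregator `"max"` (default) or `"mean"` across samples.
#' @return data.frame with `transcript_id`, `summary_tpm`, `bin`.
#' @export
bin_expression <- function(expression,
                           thresholds = list(zero_eps = 1e-9,
                                             low_lo = 0.5, low_hi = 1.0),
                           aggregator = c("max", "mean")) {
  aggregator <- match.arg(aggregator)
  if (!"transcript_id" %in% names(expression))
    stop("expression table needs a transcript_id column", call. = FALSE)
  th <- utils::modifyList(list(zero_eps = 1e-9, low_lo = 0.5, low_hi = 1.0),
                          as.list(thresholds))
  samp <- setdiff(names(expression), "transcript_id")
  if (!length(samp))
    stop("expression table has no sample columns", call. = FALSE)
  mat <- as.matrix(expression[samp])
  storage.mode(mat) <- "numeric"
  if (anyNA(mat)) stop("TPM values must not be missing", call. = FALSE)
  if (any(mat < 0)) stop("TPM values must be non-negative", call. = FALSE)
  summary_tpm <- if (aggregator == "max") apply(mat, 1, max)
                 else rowMeans(mat)
  bin <- rep("unassigned", nrow(expression))
  bin[summary_tpm <= th$zero_eps] <- "non_expressed"
  bin[summary_tpm > th$low_lo & summary_tpm < th$low_hi] <- "low"
  bin[summary_tpm >= th$low_hi] <- "high"
  data.frame(transcript_id = expression$transcript_id,
             summary_tpm = summary_tpm, bin = bin,
             stringsAsFactors = FALSE, row.names = NULL)
}

# Maximal stop-free segments of a frame translation, with their 1-based
# segment index among segments meeting min_aa.
.frame_segments <- function(protein, min_aa) {
  segs <- strsplit(protein, "*", fixed = TRUE)[[1]]
  segs <- segs[nchar(segs) >= min_aa]
  segs
}

#' Build target and decoy search databases
#'
#' Every low/high ("expressed at detectable levels") transcript contributes,
#' per sense frame, each maximal stop-free segment of its frame translation
#' of length >= `min_segment_aa` as a target entry; non-expressed
#' transcripts contribute identically-constructed decoy entries; unassigned
#' transcripts contribute nothing. Transcripts present in the expression
#' table but absent from the transcript table are skipped with a warning and
#' counted in `attr(, "report")`.
#'
#' @param transcripts Transcript table.
#' @param binned Output of [bin_expression()].
#' @param min_segment_aa Minimum segment length in residues (default 7, the
#'   shortest plausible MHC class I ligand).
#' @return data.frame of database entries (`entry_id`, `transcript_id`,
#'   `frame`, `segment`, `role`, `protein_segment`) with a `report`
#'   attribute counting skipped transcripts.
#' @export
build_search_databases <- function(transcripts, binned, min_segment_aa = 7L) {
  .check_transcripts(transcripts)
  if (!all(c("transcript_id", "bin") %in% names(binned)))
    stop("`binned` must come from bin_expression()", call. = FALSE)
  missing_ids <- setdiff(binned$transcript_id, transcripts$transcript_id)
  if (length(missing_ids))
    warning(length(missing_ids),
            " transcript(s) in the expression table absent from the FASTA; skipped",
            call. = FALSE)
  use <- binned[binned$bin %in% c("low", "high", "non_expressed") &
                  binned$transcript_id %in% transcripts$transcript_id, ,
                drop = FALSE]
  rows <- lapply(seq_len(nrow(use)), function(i) {
    id <- use$transcript_id[i]
    role <- if (use$bin[i] == "non_expressed") "decoy" else "target"
    seq_i <- transcripts$sequence[match(id, transcripts$transcript_id)]
    per_frame <- lapply(0:2, function(f) {
      segs <- .frame_segments(translate_dna(seq_i, f), min_segment_aa)
      if (!length(segs)) return(NULL)
      data.frame(transcript_id = id, frame = f,
                 segment = seq_along(segs), role = role,
                 protein_segment = segs, stringsAsFactors = FALSE)
    })
    do.call(rbind, per_frame)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(transcript_id = character(), frame = integer(),
                      segment = integer(), role = character(),
                      protein_segment = character(), stringsAsFactors = FALSE)
  out$entry_id <- sprintf("%s|F%d|S%d", out$transcript_id, out$frame,
                          out$segment)
  out <- out[c("entry_id", "transcript_id", "frame", "segment", "role",
               "protein_segment")]
  rownames(out) <- NULL
  attr(out, "report") <- list(n_skipped = length(missing_ids),
                              skipped_ids = missing_ids)
  out
}

#' Write database entries to FASTA
#'
#' Headers are `<transcript_id>|F<frame>|S<segment>`, with decoy entries
#' carrying `decoy_prefix`. Round-trips losslessly through
#' [read_database_fasta()].
#'
#' @param entries Output of [build_search_databases()] (any subset).
#' @param path Output FASTA path.
#' @param decoy_prefix Header prefix marking decoys (default `"DECOY_"`).
#' @return Invisibly, `path`.
#' @export
write_database_fasta <- function(entries, path, decoy_prefix = "DECOY_") {
  if (!nrow(entries)) {
    warning("writing an empty database FASTA", call. = FALSE)
    file.create(path)
    return(invisible(path))
  }
  headers <- ifelse(entries$role == "decoy",
                    paste0(decoy_prefix, entries$entry_id),
                    entries$entry_id)
  seqs <- entries$protein_segment
  names(seqs) <- headers
  write_fasta(seqs, path, type = "protein")
  invisible(path)
}

#' Read a database FASTA written by [write_database_fasta()]
#'
#' @param path FASTA path.
#' @param decoy_prefix Prefix identifying decoy entries.
#' @return data.frame with the same columns as [build_search_databases()].
#' @export
read_database_fasta <- function(path, decoy_prefix = "DECOY_") {
  if (file.size(path) == 0)
    return(data.frame(entry_id = character(), transcript_id = character(),
                      frame = integer(), segment = integer(),
                      role = character(), protein_segment = character(),
                      stringsAsFactors = FALSE))
  prot <- read_proteome_fasta(path)
  is_decoy <- startsWith(prot$protein_id, decoy_prefix)
  entry_id <- ifelse(is_decoy,
                     substring(prot$protein_id, nchar(decoy_prefix) + 1L),
                     prot$protein_id)
  parts <- strsplit(entry_id, "|", fixed = TRUE)
  data.frame(
    entry_id = entry_id,
    transcript_id = vapply(parts, function(p)
      paste(p[seq_len(length(p) - 2L)], collapse = "|"), character(1)),
    frame = as.integer(sub("^F", "", vapply(parts, function(p)
      p[length(p) - 1L], character(1)))),
    segment = as.integer(sub("^S", "", vapply(parts, function(p)
      p[length(p)], character(1)))),
    role = ifelse(is_decoy, "decoy", "target"),
    protein_segment = prot$sequence,
    stringsAsFactors = FALSE
  )
}
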
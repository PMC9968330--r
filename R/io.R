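#' File readers and writers for the pipeline's standard formats
#'
#' FASTA goes through Biostrings; BED and GTF through rtracklayer. All
#' genomic coordinates are converted to the package's internal 0-based
#' half-open convention at the parser boundary (GTF and GRanges are 1-based
#' closed; BED is already 0-based half-open).
#'
#' @name lncpep-io
#' @keywords internal
NULL

#' Read transcript sequences from a FASTA file
#'
#' Sequence names are taken up to the first whitespace. Gene ids and
#' coordinates, if not supplied via `annotation`, default to one gene per
#' transcript on a placeholder chromosome.
#'
#' @param path FASTA file of transcript (or protein-coding) sequences.
#' @param annotation Optional annotation data.frame (from
#'   [read_annotation_tsv()] or [read_annotation_gtf()]) with columns
#'   `transcript_id`, `gene_id`, `chrom`, `strand`, `genomic_start`,
#'   `genomic_end`; joined on `transcript_id`.
#' @return Transcript table (see [transcript_table()]).
#' @export
read_transcript_fasta <- function(path, annotation = NULL) {
  ss <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  seqs <- as.character(ss)
  if (is.null(annotation)) {
    transcript_table(
      transcript_id = ids,
      gene_id = ids,
      chrom = "unplaced",
      strand = "+",
      genomic_start = 0,
      genomic_end = nchar(seqs),
      sequence = seqs
    )
  } else {
    m <- match(ids, annotation$transcript_id)
    if (anyNA(m))
      stop("transcripts missing from annotation: ",
           paste(utils::head(ids[is.na(m)], 5), collapse = ", "),
           call. = FALSE)
    transcript_table(
      transcript_id = ids,
      gene_id = annotation$gene_id[m],
      chrom = annotation$chrom[m],
      strand = annotation$strand[m],
      genomic_start = annotation$genomic_start[m],
      genomic_end = annotation$genomic_end[m],
      sequence = seqs
    )
  }
}

#' Read a protein FASTA (canonical proteome)
#'
#' @param path FASTA file of amino-acid sequences.
#' @return data.frame with columns `protein_id`, `sequence`.
#' @export
read_proteome_fasta <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  data.frame(protein_id = sub("\\s.*$", "", names(ss)),
             sequence = as.character(ss),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write sequences to FASTA
#'
#' @param sequences Named character vector (names become headers).
#' @param path Output path.
#' @param type `"dna"` or `"protein"`.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(sequences, path, type = c("dna", "protein")) {
  type <- match.arg(type)
  ss <- if (type == "dna") Biostrings::DNAStringSet(sequences)
        else Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(ss, filepath = path)
  invisible(path)
}

#' Read a minimal 6-column annotation TSV
#'
#' Columns (with header): `transcript_id`, `gene_id`, `chrom`, `strand`,
#' `genomic_start`, `genomic_end`; coordinates 0-based half-open.
#'
#' @param path TSV path.
#' @return Annotation data.frame.
#' @export
read_annotation_tsv <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("transcript_id", "gene_id", "chrom", "strand",
           "genomic_start", "genomic_end")
  if (!all(req %in% names(ann)))
    stop("annotation TSV must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  ann[req]
}

#' Read transcript annotation from a GTF file
#'
#' Keeps `transcript` features; converts 1-based closed GTF coordinates to
#' 0-based half-open.
#'
#' @param path GTF path.
#' @return Annotation data.frame as in [read_annotation_tsv()].
#' @export
read_annotation_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "transcript"]
  data.frame(
    transcript_id = as.character(gr$transcript_id),
    gene_id = as.character(gr$gene_id),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    genomic_start = GenomicRanges::start(gr) - 1,
    genomic_end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

#' Read ChIP-seq peak intervals from BED
#'
#' BED is 0-based half-open; coordinates pass through unchanged. Multiple
#' files (e.g. several cell lines) are pooled.
#'
#' @param paths One or more BED3+ paths.
#' @return data.frame with columns `chrom`, `start`, `end`, `peak_id`.
#' @export
read_peaks_bed <- function(paths) {
  peaks <- do.call(rbind, lapply(paths, function(p) {
    gr <- rtracklayer::import(p, format = "bed")
    data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
               start = GenomicRanges::start(gr) - 1,
               end = GenomicRanges::end(gr),
               stringsAsFactors = FALSE)
  }))
  peaks$peak_id <- sprintf("peak_%d", seq_len(nrow(peaks)))
  peaks
}

#' Read a per-transcript expression (TPM) table
#'
#' @param path TSV with a `transcript_id` column and one numeric column per
#'   sample.
#' @return data.frame with `transcript_id` plus sample columns.
#' @export
read_expression_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"transcript_id" %in% names(tab))
    stop("expression TSV must have a transcript_id column", call. = FALSE)
  tab
}

#' Read an MS peptide list
#'
#' @param path TSV with a `sequence` column, optional abundance columns and
#'   an optional `regulation_flag` column (`up`/`down`/`unchanged`).
#' @return data.frame.
#' @export
read_peptides_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"sequence" %in% names(tab))
    stop("peptide TSV must have a sequence column", call. = FALSE)
  tab
}
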
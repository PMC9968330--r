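#' Transcription-factor target classification from ChIP-seq peaks
#'
#' A gene is a potential direct target when a peak falls inside the 1000-bp
#' window centred on its TSS (500 bp either side, half-open); an lncRNA gene
#' with no window peak is "associated" when its boundaries overlap, or are
#' contained within, the boundaries of a direct-target gene on either
#' strand. Interval arithmetic goes through GenomicRanges; all coordinates
#' here are 0-based half-open and are shifted to 1-based closed at the
#' GRanges boundary.
#'
#' @name regclass
#' @keywords internal
NULL

.check_genes <- function(genes) {
  req <- c("gene_id", "chrom", "strand", "genomic_start", "genomic_end")
  if (!is.data.frame(genes) || !all(req %in% names(genes)))
    stop("gene annotation needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  if (any(is.na(genes$strand)) || any(!genes$strand %in% c("+", "-")))
    stop("every gene needs strand '+' or '-'", call. = FALSE)
  invisible(genes)
}

#' Promoter window around a gene's TSS
#'
#' The TSS is strand-aware (`genomic_start` on `+`, `genomic_end - 1` on
#' `-`); the window is `[tss - half_width, tss + half_width)` clamped at the
#' chromosome start, i.e. 1000 nt wide at the default.
#'
#' @param genes Gene annotation data.frame (`gene_id`, `chrom`, `strand`,
#'   `genomic_start`, `genomic_end`; 0-based half-open).
#' @param half_width Half window width in nt (default 500).
#' @return data.frame with `gene_id`, `chrom`, `tss`, `window_start`,
#'   `window_end` (0-based half-open).
#' @export
tss_window <- function(genes, half_width = 500L) {
  .check_genes(genes)
  tss <- ifelse(genes$strand == "+", genes$genomic_start,
                genes$genomic_end - 1)
  data.frame(gene_id = genes$gene_id,
             chrom = genes$chrom,
             tss = tss,
             window_start = pmax(0, tss - half_width),
             window_end = tss + half_width,
             stringsAsFactors = FALSE, row.names = NULL)
}

# 0-based half-open -> GRanges (1-based closed), strand-blind.
.as_granges0 <- function(chrom, start0, end0) {
  GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start0 + 1, end = end0)
  )
}

#' Classify genes as direct / associated / no target
#'
#' Direct: any pooled peak shares >= 1 nt with the gene's TSS window.
#' Associated: not direct, but the gene's boundaries intersect or lie within
#' the boundaries of a direct-scoring gene (strand-blind). Precedence is
#' direct > associated > none. The reference set for "associated" is built
#' by applying the same peak rule to `reference_genes` (defaults to the
#' query genes themselves); a gene never scores associated by overlapping
#' itself.
#'
#' @param genes lncRNA gene annotation data.frame.
#' @param peaks Peak data.frame (`chrom`, `start`, `end`, optional
#'   `peak_id`), pooled across tracks. Peaks on chromosomes absent from the
#'   annotation are ignored with a warning.
#' @param reference_genes Optional annotation of additional genes screened
#'   for direct-target status as overlap references.
#' @param half_width TSS window half-width in nt (default 500).
#' @return data.frame with `gene_id`, `tss`, `window_start`, `window_end`,
#'   `class` and `evidence` (peak ids for direct calls, the direct gene's id
#'   for associated calls).
#' @export
classify_gene_targets <- function(genes, peaks, reference_genes = NULL,
                                  half_width = 500L) {
  .check_genes(genes)
  if (!all(c("chrom", "start", "end") %in% names(peaks)))
    stop("peaks need columns chrom, start, end", call. = FALSE)
  if (is.null(peaks$peak_id))
    peaks$peak_id <- sprintf("peak_%d", seq_len(nrow(peaks)))
  req <- c("gene_id", "chrom", "strand", "genomic_start", "genomic_end")
  all_genes <- genes[req]
  if (!is.null(reference_genes)) {
    .check_genes(reference_genes)
    extra <- reference_genes[!reference_genes$gene_id %in% genes$gene_id, ,
                             drop = FALSE]
    all_genes <- rbind(all_genes, extra[req])
  }
  known <- unique(all_genes$chrom)
  off <- !peaks$chrom %in% known
  if (any(off)) {
    warning(sum(off), " peak(s) on chromosomes absent from the annotation; ignored",
            call. = FALSE)
    peaks <- peaks[!off, , drop = FALSE]
  }

  win <- tss_window(all_genes, half_width = half_width)
  win_gr <- .as_granges0(win$chrom, win$window_start, win$window_end)
  peak_gr <- .as_granges0(peaks$chrom, peaks$start, peaks$end)
  hits <- GenomicRanges::findOverlaps(win_gr, peak_gr, minoverlap = 1L)
  direct_idx <- unique(S4Vectors::queryHits(hits))
  direct_all <- all_genes$gene_id[direct_idx]

  peak_evidence <- vapply(seq_len(nrow(all_genes)), function(i) {
    ph <- S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == i]
    paste(peaks$peak_id[ph], collapse = ",")
  }, character(1))

  # direct genes' full boundaries, the reference for "associated"
  ref <- all_genes[all_genes$gene_id %in% direct_all, , drop = FALSE]
  ref_gr <- .as_granges0(ref$chrom, ref$genomic_start, ref$genomic_end)
  gene_gr <- .as_granges0(genes$chrom, genes$genomic_start, genes$genomic_end)
  ov <- GenomicRanges::findOverlaps(gene_gr, ref_gr, minoverlap = 1L)
  qh <- S4Vectors::queryHits(ov)
  sh <- S4Vectors::subjectHits(ov)
  self <- genes$gene_id[qh] == ref$gene_id[sh]
  qh <- qh[!self]; sh <- sh[!self]

  m <- match(genes$gene_id, all_genes$gene_id)
  is_direct <- genes$gene_id %in% direct_all
  cls <- rep("none", nrow(genes))
  cls[is_direct] <- "direct"
  assoc_host <- vapply(seq_len(nrow(genes)), function(i) {
    hosts <- ref$gene_id[sh[qh == i]]
    if (length(hosts)) paste(sort(unique(hosts)), collapse = ",") else ""
  }, character(1))
  cls[!is_direct & nzchar(assoc_host)] <- "associated"

  evidence <- character(nrow(genes))
  evidence[cls == "direct"] <- peak_evidence[m][cls == "direct"]
  evidence[cls == "associated"] <- assoc_host[cls == "associated"]

  out <- win[m, c("gene_id", "tss", "window_start", "window_end")]
  out$class <- cls
  out$evidence <- evidence
  rownames(out) <- NULL
  out
}

#' Class fractions of target calls
#'
#' @param calls Output of [classify_gene_targets()].
#' @return data.frame with `class`, `n`, `percent` (1 decimal) for direct,
#'   associated and none.
#' @export
summarize_target_fractions <- function(calls) {
  if (!nrow(calls)) stop("no target calls to summarise", call. = FALSE)
  lev <- c("direct", "associated", "none")
  n <- vapply(lev, function(l) sum(calls$class == l), integer(1))
  data.frame(class = lev, n = n,
             percent = round(100 * n / nrow(calls), 1),
             stringsAsFactors = FALSE, row.names = NULL)
}
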
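#' Vaccine-candidate shortlisting
#'
#' Candidates are filtered on three criteria — predicted MHC class I
#' binding (percentile rank from an external predictor, lower = stronger),
#' expression of the source lncRNA in normal thymocytes (low expression
#' favours escape from central tolerance), and significance of the source
#' lncRNA's differential regulation under PRMT5 inhibition — then ranked
#' lexicographically. Thresholds are mandatory configuration: the field
#' offers no universal cut-offs, so none are silently assumed.
#'
#' @param annotations data.frame with columns `peptide`,
#'   `predicted_affinity_rank`, `thymus_expression`, `regulation_q` (all
#'   present for every candidate).
#' @param thresholds List with `affinity_rank_max`, `thymus_max`, `q_max`;
#'   all three required.
#' @param n Number of peptides to shortlist (>= 1). If fewer candidates
#'   survive the thresholds, the shorter list is returned with a warning.
#' @return data.frame: the top `n` survivors ordered by (affinity rank,
#'   thymus expression, q), ties broken by peptide string.
#' @export
rank_vaccine_candidates <- function(annotations, thresholds, n = 20L) {
  req <- c("peptide", "predicted_affinity_rank", "thymus_expression",
           "regulation_q")
  if (!is.data.frame(annotations) || !all(req %in% names(annotations)))
    stop("annotations need columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  if (anyNA(annotations[req]))
    stop("all three criteria must be present for every candidate",
         call. = FALSE)
  th_req <- c("affinity_rank_max", "thymus_max", "q_max")
  if (!is.list(thresholds) || !all(th_req %in% names(thresholds)))
    stop("thresholds must supply: ", paste(th_req, collapse = ", "),
         call. = FALSE)
  if (n < 1L) stop("`n` must be >= 1", call. = FALSE)
  keep <- annotations$predicted_affinity_rank <= thresholds$affinity_rank_max &
    annotations$thymus_expression <= thresholds$thymus_max &
    annotations$regulation_q <= thresholds$q_max
  surv <- annotations[keep, , drop = FALSE]
  surv <- surv[order(surv$predicted_affinity_rank, surv$thymus_expression,
                     surv$regulation_q, surv$peptide), , drop = FALSE]
  if (nrow(surv) < n)
    warning("only ", nrow(surv), " candidate(s) satisfy the thresholds ",
            "(requested ", n, ")", call. = FALSE)
  out <- utils::head(surv, n)
  rownames(out) <- NULL
  out
}
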
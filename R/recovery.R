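#' Planted-truth recovery metrics
#'
#' Compares pipeline output against the simulator's truth set: precision and
#' recall of line-specific variant detection, of gene deletion/duplication
#' calling, and the type confusion matrix plus breakpoint errors of
#' structural-variant calling. These are the end-to-end validation
#' quantities of the synthetic-panel study.
#'
#' @name recovery
NULL

prec_recall <- function(pred, truth) {
  tp <- length(intersect(pred, truth))
  list(precision = if (length(pred)) tp / length(pred) else NA_real_,
       recall = if (length(truth)) tp / length(truth) else NA_real_,
       n_pred = length(pred), n_truth = length(truth))
}

#' @rdname recovery
#' @param panel A `panel_matrix`.
#' @param truth A [truth_set()].
#' @return `evaluate_line_specific()`: list with `precision`, `recall`,
#'   `n_pred`, `n_truth` over (sample, site) line-specific assignments.
#' @export
evaluate_line_specific <- function(panel, truth) {
  ls <- line_specific_variants(panel)
  pred <- unlist(lapply(names(ls), function(s) {
    st <- rbind(ls[[s]]$snps, ls[[s]]$indels)
    if (!nrow(st)) return(character(0))
    paste(s, st$chrom, st$pos, st$ref, st$alt)
  }))
  tv <- truth$variants
  tls <- tv[isTRUE_vec(tv$line_specific), , drop = FALSE]
  tr <- paste(tls$sample, tls$chrom, tls$pos, tls$ref, tls$alt)
  prec_recall(pred, tr)
}

#' @rdname recovery
#' @param events Gene event table after control exclusion (`sample`,
#'   `gene_id`, `event`).
#' @return `evaluate_gene_events()`: list with per-event-type precision and
#'   recall.
#' @export
evaluate_gene_events <- function(events, truth) {
  out <- lapply(c("deletion", "duplication"), function(ev) {
    pred <- paste(events$sample[events$event == ev],
                  events$gene_id[events$event == ev])
    te <- truth$gene_events
    tr <- paste(te$sample[te$event == ev], te$gene_id[te$event == ev])
    prec_recall(pred, tr)
  })
  names(out) <- c("deletion", "duplication")
  out
}

#' @rdname recovery
#' @param calls SV call data.frame (with `sample` column) after filtering.
#' @param match_tol Maximum breakpoint distance for matching a call to a
#'   planted event.
#' @return `evaluate_sv()`: list with `confusion` (truth type x called type
#'   matrix), `n_unmatched_calls`, `n_missed_truth`, and `breakpoint_errors`
#'   (data.frame with per-matched-event `errA`, `errB`).
#' @export
evaluate_sv <- function(calls, truth, match_tol = 1000) {
  types <- c("CTX", "ITX", "INV")
  conf <- matrix(0L, 3, 3, dimnames = list(truth = types, called = types))
  sv <- truth$sv_events
  # calls carry mates in canonical (chromosome, position) order; put the
  # planted events in the same frame before matching
  if (nrow(sv)) {
    swap <- sv$chromB < sv$chromA |
      (sv$chromB == sv$chromA & sv$posB < sv$posA)
    if (any(swap)) {
      tmp <- sv[swap, c("chromA", "posA")]
      sv[swap, c("chromA", "posA")] <- sv[swap, c("chromB", "posB")]
      sv[swap, c("chromB", "posB")] <- tmp
    }
  }
  matched_call <- rep(FALSE, nrow(calls))
  errs <- list()
  missed <- 0L
  for (i in seq_len(nrow(sv))) {
    e <- sv[i, ]
    cand <- which(!matched_call &
                    calls$sample == e$sample &
                    calls$chromA == e$chromA & calls$chromB == e$chromB &
                    abs(calls$posA - e$posA) <= match_tol &
                    abs(calls$posB - e$posB) <= match_tol)
    if (!length(cand)) {
      missed <- missed + 1L
      next
    }
    j <- cand[which.min(abs(calls$posA[cand] - e$posA))]
    matched_call[j] <- TRUE
    conf[e$type, calls$sv_type[j]] <- conf[e$type, calls$sv_type[j]] + 1L
    errs[[length(errs) + 1L]] <- data.frame(
      truth_type = e$type, called_type = calls$sv_type[j],
      errA = abs(calls$posA[j] - e$posA),
      errB = abs(calls$posB[j] - e$posB))
  }
  list(confusion = conf,
       n_unmatched_calls = sum(!matched_call),
       n_missed_truth = missed,
       breakpoint_errors = if (length(errs)) do.call(rbind, errs) else
         data.frame(truth_type = character(0), called_type = character(0),
                    errA = integer(0), errB = integer(0)))
}

#' @rdname recovery
#' @param effects Annotation from [annotate_panel()].
#' @return `evaluate_forced_effects()`: list with `n_truth`, `n_correct` and
#'   `confusion` (table of planted vs annotated class) over the
#'   construction-forced coding variants.
#' @export
evaluate_forced_effects <- function(panel, effects, truth) {
  tv <- truth$variants
  tf <- tv[!is.na(tv$effect), , drop = FALSE]
  tf <- tf[!duplicated(paste(tf$chrom, tf$pos, tf$ref, tf$alt)), ,
           drop = FALSE]
  key_sites <- paste(panel$sites$chrom, panel$sites$pos, panel$sites$ref,
                     panel$sites$alt)
  idx <- match(paste(tf$chrom, tf$pos, tf$ref, tf$alt), key_sites)
  ann <- effects$effect[idx]
  list(n_truth = nrow(tf),
       n_correct = sum(ann == tf$effect, na.rm = TRUE),
       confusion = table(planted = tf$effect, annotated = ann))
}
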
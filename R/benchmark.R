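#' Segment-matching parameters
#'
#' @param min_overlap Minimum residue overlap between a predicted and an
#'   annotated segment for a true-positive match (default 3).  Structure-
#'   derived TM boundaries are not reliable at per-residue level, so
#'   over-strict overlap criteria are deliberately avoided.
#' @param exclude_signal_fp Discard unmatched predicted segments that
#'   overlap an annotated signal-peptide region by at least
#'   `min_overlap`, counting them neither as TP nor FP (default `TRUE`):
#'   signal peptides are biophysically TM-helix-like, so calling them is
#'   not an error of the hydrophobicity model.
#' @return List of class `match_params`.
#' @export
match_params <- function(min_overlap = 3L, exclude_signal_fp = TRUE) {
  if (min_overlap < 1) stop("min_overlap must be >= 1")
  structure(list(min_overlap = as.integer(min_overlap),
                 exclude_signal_fp = isTRUE(exclude_signal_fp)),
            class = "match_params")
}

.check_segment_list <- function(segs, what) {
  if (!is.data.frame(segs) || !all(c("start", "end") %in% names(segs)))
    stop(what, " must be a data frame with start and end columns")
  if (!nrow(segs)) return(invisible(segs))
  if (any(segs$end < segs$start))
    stop(what, " contains an interval with end < start")
  if (is.unsorted(segs$start, strictly = TRUE) ||
      any(segs$start[-1] <= segs$end[-nrow(segs)]))
    stop(what, " segments must be sorted by start and non-overlapping")
  invisible(segs)
}

.overlap_len <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2) + 1L)
}

#' Match predicted against annotated TM segments
#'
#' One-to-one matching: every predicted/annotated pair overlapping by at
#' least `min_overlap` residues is a candidate; candidates are accepted
#' greedily in descending overlap order (ties broken by earlier annotated
#' start, then earlier predicted start), and each segment joins at most
#' one pair.  Unmatched annotated segments are false negatives; unmatched
#' predicted segments are false positives, unless they overlap an
#' annotated signal-peptide region by at least `min_overlap`, in which
#' case they are discarded (neither TP nor FP) when
#' `exclude_signal_fp` is set.
#'
#' The greedy rule mirrors a fully automated, conservative evaluation:
#' with closely spaced "twin peak" helices it can link one predicted
#' segment to the larger of two annotated overlaps and leave a
#' technically false FP behind -- such cases are surfaced in the
#' per-record report rather than resolved by special-casing.
#'
#' @param predicted,annotated Segment data frames (`start`, `end`),
#'   sorted, non-overlapping within themselves.
#' @param signal_regions Annotated signal-peptide intervals (same form).
#' @param params A [match_params].
#' @return List with data frames `tp` (`pred_start`, `pred_end`,
#'   `ann_start`, `ann_end`, `overlap`), `fp`, `fn`, `discarded`.
#' @examples
#' match_segments(data.frame(start = 10, end = 30),
#'                data.frame(start = 12, end = 28))$tp
#' @export
match_segments <- function(predicted, annotated,
                           signal_regions = data.frame(start = integer(),
                                                       end = integer()),
                           params = match_params()) {
  .check_segment_list(predicted, "predicted")
  .check_segment_list(annotated, "annotated")
  .check_segment_list(signal_regions, "signal_regions")
  np <- nrow(predicted); na <- nrow(annotated)
  cand <- NULL
  if (np && na) {
    grid <- expand.grid(p = seq_len(np), a = seq_len(na))
    ov <- .overlap_len(predicted$start[grid$p], predicted$end[grid$p],
                       annotated$start[grid$a], annotated$end[grid$a])
    keep <- ov >= params$min_overlap
    cand <- data.frame(p = grid$p[keep], a = grid$a[keep], overlap = ov[keep])
  }
  p_used <- rep(FALSE, np); a_used <- rep(FALSE, na)
  tp_rows <- list()
  if (!is.null(cand) && nrow(cand)) {
    ord <- order(-cand$overlap, annotated$start[cand$a],
                 predicted$start[cand$p])
    for (k in ord) {
      p <- cand$p[k]; a <- cand$a[k]
      if (p_used[p] || a_used[a]) next
      p_used[p] <- TRUE; a_used[a] <- TRUE
      tp_rows[[length(tp_rows) + 1L]] <-
        data.frame(pred_start = predicted$start[p], pred_end = predicted$end[p],
                   ann_start = annotated$start[a], ann_end = annotated$end[a],
                   overlap = cand$overlap[k])
    }
  }
  tp <- if (length(tp_rows)) do.call(rbind, tp_rows) else
    data.frame(pred_start = integer(), pred_end = integer(),
               ann_start = integer(), ann_end = integer(),
               overlap = integer())
  unmatched_p <- which(!p_used)
  discard <- rep(FALSE, length(unmatched_p))
  if (params$exclude_signal_fp && nrow(signal_regions) && length(unmatched_p)) {
    for (k in seq_along(unmatched_p)) {
      p <- unmatched_p[k]
      ov <- .overlap_len(predicted$start[p], predicted$end[p],
                         signal_regions$start, signal_regions$end)
      discard[k] <- any(ov >= params$min_overlap)
    }
  }
  list(tp = tp,
       fp = predicted[unmatched_p[!discard], c("start", "end"), drop = FALSE],
       fn = annotated[!a_used, c("start", "end"), drop = FALSE],
       discarded = predicted[unmatched_p[discard], c("start", "end"),
                             drop = FALSE])
}

#' Confusion counts for per-segment evaluation
#'
#' `confusion_counts()` builds the bookkeeping object from raw counts;
#' `tally_matches()` derives it from a [match_segments] result.  By
#' construction `tp + fn = n_annotated` and `tp + fp = n_predicted`
#' (discarded signal-peptide hits are excluded from `n_predicted`).
#'
#' @param tp,fp,fn Non-negative integer counts.
#' @param discarded Number of predicted segments discarded as
#'   signal-peptide hits.
#' @return List of class `confusion_counts` with elements `tp`, `fp`,
#'   `fn`, `discarded`, `n_annotated`, `n_predicted`.
#' @export
confusion_counts <- function(tp, fp, fn, discarded = 0L) {
  if (any(c(tp, fp, fn, discarded) < 0)) stop("counts must be non-negative")
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn), discarded = as.integer(discarded),
                 n_annotated = as.integer(tp + fn),
                 n_predicted = as.integer(tp + fp)),
            class = "confusion_counts")
}

#' @rdname confusion_counts
#' @param match Result of [match_segments].
#' @export
tally_matches <- function(match) {
  confusion_counts(nrow(match$tp), nrow(match$fp), nrow(match$fn),
                   nrow(match$discarded))
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("Per-segment confusion counts\n")
  cat(sprintf("  annotated %d, predicted %d (+%d signal-discarded)\n",
              x$n_annotated, x$n_predicted, x$discarded))
  cat(sprintf("  TP %d  FP %d  FN %d\n", x$tp, x$fp, x$fn))
  invisible(x)
}

#' Recall and precision from confusion counts
#'
#' Standard per-segment definitions: `recall = TP / (TP + FN)` and
#' `precision = TP / (TP + FP)`.  An undefined ratio (zero denominator)
#' is reported as `NA` rather than 0.
#'
#' @param counts A [confusion_counts] (or list with `tp`, `fp`, `fn`).
#' @return List of class `metrics` with elements `recall`, `precision`.
#' @examples
#' compute_metrics(confusion_counts(tp = 2882, fp = 190, fn = 136))
#' @export
compute_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  if (any(c(tp, fp, fn) < 0)) stop("counts must be non-negative")
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  structure(list(recall = recall, precision = precision), class = "metrics")
}

#' @export
print.metrics <- function(x, ...) {
  cat(sprintf("recall %s  precision %s\n",
              ifelse(is.na(x$recall), "-", sprintf("%.3f", x$recall)),
              ifelse(is.na(x$precision), "-", sprintf("%.3f", x$precision))))
  invisible(x)
}

#' Per-protein TM identification table
#'
#' Tabulates, per ground-truth class, how many records the predictor
#' classified TM versus non-TM, with percentages of the class total.
#' `classification_percentages()` is the underlying arithmetic for a
#' single row.
#'
#' @param truth Character vector of ground-truth classes per record
#'   (e.g. `"TM"`, `"globular"`, `"signal"`).
#' @param classification Character vector of predicted classes (`"TM"` /
#'   `"non-TM"`).
#' @return Data frame with one row per truth class: `class`, `total`,
#'   `tm`, `nontm`, `pct_tm`, `pct_nontm` (percentages of `total`).
#' @export
protein_table <- function(truth, classification) {
  stopifnot(length(truth) == length(classification))
  classes <- unique(truth)
  rows <- lapply(classes, function(cl) {
    sel <- truth == cl
    pc <- classification_percentages(sum(classification[sel] == "TM"),
                                     sum(classification[sel] != "TM"))
    data.frame(class = cl, total = sum(sel), tm = pc$tm, nontm = pc$nontm,
               pct_tm = pc$pct_tm, pct_nontm = pc$pct_nontm)
  })
  do.call(rbind, rows)
}

#' @rdname protein_table
#' @param tm,nontm Counts of records classified TM and non-TM.
#' @export
classification_percentages <- function(tm, nontm) {
  total <- tm + nontm
  list(tm = tm, nontm = nontm, total = total,
       pct_tm = if (total > 0) 100 * tm / total else NA_real_,
       pct_nontm = if (total > 0) 100 * nontm / total else NA_real_)
}

#' Evaluate the predictor on a labeled dataset
#'
#' Runs [das_predict] on every record, extracts annotated helical
#' segments (labels H/h) and signal regions (label S) from the topology
#' annotation, applies the minimum-overlap matching rule per record, and
#' aggregates per-segment confusion counts, recall/precision, the
#' per-protein TM identification table, and a per-record report.
#' Beta-barrel labels (B/b) are ignored entirely: the method detects
#' alpha-helical segments only.  Records whose annotation length does not
#' match the sequence are skipped and listed in the `skipped` element.
#'
#' @param records Labeled record data frame (from [read_labeled_fasta]
#'   or [synth_dataset]).
#' @param library Reference library.
#' @param matrix A [pair_score_matrix].
#' @param window Odd integer window length.
#' @param caller A [caller_params].
#' @param matching A [match_params].
#' @param verbose Print progress to standard error.
#' @return List of class `das_evaluation`: `counts`
#'   ([confusion_counts]), `metrics`, `protein_table`, `per_record`
#'   (data frame), `fn_histogram`, `skipped`.
#' @export
evaluate_dataset <- function(records, library, matrix = pair_score_matrix(),
                             window = 15L, caller = caller_params(),
                             matching = match_params(), verbose = FALSE) {
  stopifnot(is.data.frame(records),
            all(c("id", "seq", "labels") %in% names(records)))
  n <- nrow(records)
  rows <- vector("list", n)
  skipped <- character()
  for (i in seq_len(n)) {
    rec <- records[i, , drop = FALSE]
    if (nchar(rec$labels) != nchar(rec$seq)) {
      skipped <- c(skipped, rec$id)
      if (verbose)
        message("skipping ", rec$id, ": annotation/sequence length mismatch")
      next
    }
    ann <- annotation_segments(rec$labels, c("H", "h"))
    sig <- annotation_segments(rec$labels, "S")
    truth <- if (nrow(ann)) "TM" else if (nrow(sig)) "signal" else "globular"
    pred <- das_predict(rec, library, matrix, window, caller)
    m <- match_segments(pred$segments[, c("start", "end"), drop = FALSE],
                        ann, sig, matching)
    cc <- tally_matches(m)
    rows[[i]] <- data.frame(id = rec$id, class = truth,
                            n_annotated = cc$n_annotated,
                            n_predicted = nrow(pred$segments),
                            tp = cc$tp, fp = cc$fp, fn = cc$fn,
                            discarded = cc$discarded,
                            classification = pred$classification,
                            quality = pred$quality,
                            twin_peak = any(pred$segments$twin_peak),
                            signal_warning =
                              any(pred$segments$possible_signal_peptide))
    if (verbose && i %% 20L == 0L) message("evaluated ", i, "/", n)
  }
  per_record <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(per_record))
    stop("no evaluable records in dataset")
  rownames(per_record) <- NULL
  counts <- confusion_counts(sum(per_record$tp), sum(per_record$fp),
                             sum(per_record$fn), sum(per_record$discarded))
  structure(list(counts = counts, metrics = compute_metrics(counts),
                 protein_table = protein_table(per_record$class,
                                               per_record$classification),
                 per_record = per_record,
                 fn_histogram = fn_multiplicity(per_record),
                 skipped = skipped),
            class = "das_evaluation")
}

#' Histogram of missed-segment multiplicity
#'
#' Counts, over proteins with at least one false negative, how many
#' proteins miss exactly `k` annotated segments -- missing a single
#' segment is the typical failure mode, and the histogram total
#' `sum(k * count)` equals the overall FN count by construction.
#'
#' @param per_record Per-record report from [evaluate_dataset] (needs an
#'   `fn` column).
#' @return Named integer vector mapping `k` to the number of proteins
#'   with exactly `k` false negatives; empty when there are none.
#' @export
fn_multiplicity <- function(per_record) {
  fns <- per_record$fn[per_record$fn > 0]
  if (!length(fns)) return(stats::setNames(integer(), character()))
  tab <- table(fns)
  stats::setNames(as.integer(tab), names(tab))
}

#' @export
print.das_evaluation <- function(x, ...) {
  print(x$counts)
  print(x$metrics)
  cat("\nPer-protein TM identification:\n")
  pt <- x$protein_table
  for (i in seq_len(nrow(pt)))
    cat(sprintf("  %-9s %4d total: %4d TM (%.1f%%), %4d non-TM (%.1f%%)\n",
                pt$class[i], pt$total[i], pt$tm[i], pt$pct_tm[i],
                pt$nontm[i], pt$pct_nontm[i]))
  if (length(x$fn_histogram)) {
    cat("\nMissed-segment multiplicity (k FN : proteins):",
        paste(sprintf("%s:%d", names(x$fn_histogram), x$fn_histogram),
              collapse = "  "), "\n")
  }
  if (length(x$skipped))
    cat("\nSkipped records:", paste(x$skipped, collapse = ", "), "\n")
  invisible(x)
}

#' Write evaluation reports as TSV
#'
#' @param evaluation A `das_evaluation`.
#' @param per_record_path,summary_path Output paths (either may be
#'   `NULL` to skip).
#' @export
write_evaluation_tsv <- function(evaluation, per_record_path = NULL,
                                 summary_path = NULL) {
  if (!is.null(per_record_path))
    utils::write.table(evaluation$per_record, per_record_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(summary_path)) {
    cc <- evaluation$counts; mm <- evaluation$metrics
    lines <- c("quantity\tvalue",
               sprintf("annotated_segments\t%d", cc$n_annotated),
               sprintf("predicted_segments\t%d", cc$n_predicted),
               sprintf("tp\t%d", cc$tp), sprintf("fp\t%d", cc$fp),
               sprintf("fn\t%d", cc$fn),
               sprintf("signal_discarded\t%d", cc$discarded),
               sprintf("recall\t%.3f", mm$recall),
               sprintf("precision\t%.3f", mm$precision))
    writeLines(lines, summary_path)
  }
  invisible(evaluation)
}
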
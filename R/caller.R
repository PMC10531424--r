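#' Segment-calling parameters
#'
#' Bundles the thresholds governing how a global DAS profile is turned
#' into predicted transmembrane segments and a TM/non-TM call.
#'
#' @param cutoff Profile score above which a residue is called TM
#'   (default 2.5, i.e. 2.5 times the random-background pair score).
#' @param signal_window A segment starting within this many N-terminal
#'   residues gets a "possible signal peptide" warning (default 25).
#' @param twin_gap Two consecutive segments separated by at most this
#'   many linker residues both get a "twin peak" warning (default 4).
#' @param mode `"trusted"` computes the quality value only when the
#'   decision needs it (exactly one segment); `"unconditional"` always
#'   computes it.
#' @param quality_threshold Minimum quality for a single-segment query to
#'   be classified TM (default 3.0).
#' @param plot_cap Upper y-axis bound used by fixed-scale profile plots
#'   (default 5).
#' @param signal_rule Whether the signal-peptide warning tests the
#'   segment `"start"` (default) or the `"peak"` position against
#'   `signal_window`.
#' @return List of class `caller_params`.
#' @export
caller_params <- function(cutoff = 2.5, signal_window = 25L, twin_gap = 4L,
                          mode = c("trusted", "unconditional"),
                          quality_threshold = 3.0, plot_cap = 5,
                          signal_rule = c("start", "peak")) {
  mode <- match.arg(mode)
  signal_rule <- match.arg(signal_rule)
  if (cutoff <= 0) stop("cutoff must be positive")
  if (signal_window < 1) stop("signal_window must be >= 1")
  if (twin_gap < 0) stop("twin_gap must be >= 0")
  if (plot_cap < cutoff) stop("plot_cap must be >= cutoff")
  structure(list(cutoff = cutoff, signal_window = as.integer(signal_window),
                 twin_gap = as.integer(twin_gap), mode = mode,
                 quality_threshold = quality_threshold, plot_cap = plot_cap,
                 signal_rule = signal_rule),
            class = "caller_params")
}

.empty_segments <- function() {
  data.frame(start = integer(), end = integer(), peak = numeric(),
             mean_excess = numeric(), peak_pos = integer(),
             possible_signal_peptide = logical(), twin_peak = logical())
}

#' Call transmembrane segments from a global DAS profile
#'
#' Predicted segments are exactly the maximal runs of consecutive
#' positions with profile score `>= cutoff` (the boundary is inclusive).
#' No minimum length is imposed and runs are never merged: very short
#' predicted segments can be real hits, and over-strict post-filtering is
#' left to the user, guided by the attached warnings.
#'
#' @param profile A `score_profile` (typically from [das_profile]).
#' @param params A [caller_params].
#' @return Data frame of segments, sorted by `start`: `start`, `end`
#'   (1-based inclusive), `peak` (maximum profile value inside), `
#'   mean_excess` (mean of profile minus cutoff inside), `peak_pos`,
#'   and logical warning columns `possible_signal_peptide`, `twin_peak`
#'   (filled in by [annotate_warnings]).
#' @examples
#' p <- c(1, 3, 3, 1, 1, 3, 1)
#' call_segments(p, caller_params())[, c("start", "end")]
#' @export
call_segments <- function(profile, params = caller_params()) {
  stopifnot(length(profile) >= 1L)
  above <- as.numeric(profile) >= params$cutoff
  if (!any(above)) return(.empty_segments())
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  starts <- starts[keep]; ends <- ends[keep]
  peak <- mean_excess <- numeric(length(starts))
  peak_pos <- integer(length(starts))
  for (s in seq_along(starts)) {
    vals <- as.numeric(profile)[starts[s]:ends[s]]
    peak[s] <- max(vals)
    peak_pos[s] <- starts[s] + which.max(vals) - 1L
    mean_excess[s] <- mean(vals - params$cutoff)
  }
  segs <- data.frame(start = starts, end = ends, peak = peak,
                     mean_excess = mean_excess, peak_pos = peak_pos,
                     possible_signal_peptide = FALSE, twin_peak = FALSE)
  annotate_warnings(segs, params)
}

#' Attach advisory warnings to called segments
#'
#' Adds `possible_signal_peptide` to any segment starting within the
#' N-terminal `signal_window` residues (signal peptides are
#' biophysically TM-helix-like and are flagged rather than suppressed),
#' and `twin_peak` to both members of any consecutive pair whose linker
#' (`next start - previous end - 1`) is at most `twin_gap` residues.
#' Warnings never alter the segment list or the classification; the user
#' makes the final decision.
#'
#' @param segments Segment data frame, sorted and non-overlapping.
#' @param params A [caller_params].
#' @return The segment data frame with warning columns filled in.
#' @export
annotate_warnings <- function(segments, params = caller_params()) {
  if (!nrow(segments)) return(segments)
  if (is.unsorted(segments$start, strictly = TRUE) ||
      any(segments$start[-1] <= segments$end[-nrow(segments)]))
    stop("segments must be sorted by start and non-overlapping")
  anchor <- if (params$signal_rule == "start") segments$start else
    segments$peak_pos
  segments$possible_signal_peptide <- anchor <= params$signal_window
  segments$twin_peak <- FALSE
  if (nrow(segments) > 1L) {
    gap <- segments$start[-1] - segments$end[-nrow(segments)] - 1L
    twin <- gap <= params$twin_gap
    segments$twin_peak[-1] <- twin
    segments$twin_peak[-nrow(segments)] <-
      segments$twin_peak[-nrow(segments)] | twin
  }
  segments
}

#' Prediction quality value
#'
#' A scalar summary of prediction strength: the maximum segment peak.
#' It matters most for queries with exactly one predicted segment, where
#' it alone decides the TM/non-TM classification.
#'
#' @param profile The score profile the segments were called from.
#' @param segments Called segment data frame (at least one row).
#' @param params A [caller_params].
#' @return Numeric scalar.
#' @export
quality_value <- function(profile, segments, params = caller_params()) {
  if (!nrow(segments))
    stop("quality value undefined: no predicted segments")
  max(segments$peak)
}

#' Classify a protein as TM or non-TM
#'
#' Two or more predicted segments classify the protein as TM; none as
#' non-TM; with exactly one segment the quality value decides
#' (`TM` iff `quality >= quality_threshold`).
#'
#' @param segments Called segment data frame.
#' @param quality Quality value; required in the single-segment case.
#' @param params A [caller_params].
#' @return `"TM"` or `"non-TM"`.
#' @export
classify_protein <- function(segments, quality = NA_real_,
                             params = caller_params()) {
  n <- nrow(segments)
  if (n == 0L) return("non-TM")
  if (n >= 2L) return("TM")
  if (is.na(quality))
    stop("classification of a single-segment query requires a quality value")
  if (quality >= params$quality_threshold) "TM" else "non-TM"
}

#' Predict transmembrane segments for one query sequence
#'
#' Runs the full pipeline: global DAS profile against the reference
#' library, segment calling at the cutoff, warning annotation, quality
#' value (always in unconditional mode, only for single-segment queries
#' in trusted mode), and TM/non-TM classification.  Deterministic for
#' fixed inputs.
#'
#' @param query Residue string or one-row record data frame.
#' @param library A reference library ([load_library] / [synth_library]).
#' @param matrix A [pair_score_matrix] (default built from
#'   Kyte-Doolittle).
#' @param window Odd integer window length (default 15).
#' @param params A [caller_params].
#' @return Object of class `das_prediction`: `id`, `segments` (data
#'   frame), `classification`, `quality` (`NA` when not computed),
#'   `profile`, `mode`, `params`, `window`.
#' @examples
#' lib <- synth_library(size = 8, seed = 11)
#' q <- synth_tm_protein(n_segments = 2, seed = 42)
#' das_predict(q, lib)
#' @export
das_predict <- function(query, library, matrix = pair_score_matrix(),
                        window = 15L, params = caller_params()) {
  q <- .as_residues(query)
  profile <- das_profile(query, library, matrix, window)
  segments <- call_segments(profile, params)
  quality <- NA_real_
  if (nrow(segments) >= 1L &&
      (params$mode == "unconditional" || nrow(segments) == 1L))
    quality <- quality_value(profile, segments, params)
  classification <- classify_protein(segments, quality, params)
  structure(list(id = q$id, segments = segments,
                 classification = classification, quality = quality,
                 profile = profile, mode = params$mode, params = params,
                 window = as.integer(window)),
            class = "das_prediction")
}

#' @export
print.das_prediction <- function(x, ...) {
  cat("DAS prediction for ", if (is.na(x$id)) "<unnamed>" else x$id,
      ": ", x$classification, sep = "")
  if (!is.na(x$quality)) cat(" (quality ", format(x$quality, digits = 3), ")",
                             sep = "")
  cat("\n")
  if (nrow(x$segments)) {
    for (i in seq_len(nrow(x$segments))) {
      s <- x$segments[i, ]
      w <- c(if (s$possible_signal_peptide) "possible signal peptide",
             if (s$twin_peak) "twin peak")
      cat(sprintf("  TM segment %d: %d-%d  peak %.2f%s\n", i, s$start, s$end,
                  s$peak,
                  if (length(w)) paste0("  [", paste(w, collapse = "; "), "]")
                  else ""))
    }
  } else cat("  no TM segments above cutoff\n")
  invisible(x)
}

.warning_string <- function(segments) {
  vapply(seq_len(nrow(segments)), function(i) {
    w <- c(if (segments$possible_signal_peptide[i]) "possible_signal_peptide",
           if (segments$twin_peak[i]) "twin_peak")
    if (length(w)) paste(w, collapse = ",") else "-"
  }, "")
}

#' Write a prediction as short-form TSV
#'
#' One row per predicted segment (or one row with empty segment fields
#' for a segment-free query) with columns `id`, `classification`,
#' `quality`, `segment`, `start`, `end`, `peak`, `warnings`.
#'
#' @param prediction A `das_prediction`.
#' @param path Output path, `""` for standard output, or `NULL` to only
#'   return the formatted lines.
#' @param header Whether to emit the column header line.
#' @export
write_prediction_tsv <- function(prediction, path = "", header = TRUE) {
  segs <- prediction$segments
  qual <- if (is.na(prediction$quality)) "-" else
    sprintf("%.3f", prediction$quality)
  if (nrow(segs)) {
    rows <- sprintf("%s\t%s\t%s\t%d\t%d\t%d\t%.3f\t%s",
                    prediction$id, prediction$classification, qual,
                    seq_len(nrow(segs)), segs$start, segs$end, segs$peak,
                    .warning_string(segs))
  } else {
    rows <- sprintf("%s\t%s\t%s\t-\t-\t-\t-\t-", prediction$id,
                    prediction$classification, qual)
  }
  if (header)
    rows <- c("id\tclassification\tquality\tsegment\tstart\tend\tpeak\twarnings",
              rows)
  if (is.null(path)) return(invisible(rows))
  if (identical(path, "")) writeLines(rows) else writeLines(rows, path)
  invisible(rows)
}

#' Plot a DAS score profile
#'
#' Line plot of the global DAS profile with the segment-calling cutoff as
#' a red dotted horizontal line and called segments shaded.  `"fixed"`
#' scaling clamps the y-axis to `[0, plot_cap]` so profiles of different
#' proteins are directly comparable; `"free"` scaling fits the data.
#'
#' @param profile A `score_profile`.
#' @param segments Called segments (optional, for shading).
#' @param params A [caller_params].
#' @param scaling `"free"` or `"fixed"`.
#' @param file Optional output file; the device is chosen from the
#'   extension (`.svg` or `.png`).
#' @param main Plot title.
#' @return Invisibly, a list with the `ylim` used and the `file` written
#'   (if any).
#' @export
render_profile <- function(profile, segments = NULL,
                           params = caller_params(),
                           scaling = c("free", "fixed"), file = NULL,
                           main = "DAS profile") {
  scaling <- match.arg(scaling)
  stopifnot(length(profile) >= 1L)
  ylim <- if (scaling == "fixed") c(0, params$plot_cap) else
    c(0, max(max(profile), params$cutoff) * 1.05)
  if (!is.null(file)) {
    ext <- tolower(tools::file_ext(file))
    switch(ext,
           svg = grDevices::svg(file, width = 8, height = 4.5),
           png = grDevices::png(file, width = 960, height = 540),
           stop("unsupported plot format: ", ext))
    on.exit(grDevices::dev.off())
  }
  vals <- pmin(as.numeric(profile), ylim[2])
  graphics::plot(seq_along(vals), vals, type = "l", lwd = 2, ylim = ylim,
                 xlab = "residue position", ylab = "DAS score", main = main)
  if (!is.null(segments) && nrow(segments))
    graphics::rect(segments$start - 0.5, ylim[1], segments$end + 0.5,
                   ylim[2], col = grDevices::adjustcolor("steelblue", 0.2),
                   border = NA)
  graphics::abline(h = params$cutoff, col = "red", lty = 3, lwd = 2)
  invisible(list(ylim = ylim, file = file))
}
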
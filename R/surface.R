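#' Dense alignment surface between two sequences
#'
#' Computes the gapless dot-plot style comparison matrix `S[i, j]`: the
#' mean pair score over a diagonal window of length `window` centered on
#' query position `i` and reference position `j`,
#' `S[i, j] = mean_k M(query[i + k], reference[j + k])` for
#' `k = -w, ..., +w` with `w = (window - 1) / 2`, restricted to offsets
#' where both positions exist (the window shrinks at sequence ends rather
#' than being zero-padded, so termini are not biased downwards -- the
#' signal-peptide warning operates in the first 25 residues).
#' Intersections of two transmembrane segments show up as dense
#' high-scoring blocks on this surface.
#'
#' @param query,reference Residue strings, or single rows of a
#'   [read_fasta] data frame.
#' @param matrix A [pair_score_matrix].
#' @param window Odd positive integer window length (default 15, a
#'   typical transmembrane helix core span).
#' @return Object of class `alignment_surface`: `S` (numeric matrix,
#'   query positions x reference positions), `window`, `query_id`,
#'   `reference_id`.
#' @examples
#' m <- pair_score_matrix()
#' s <- alignment_surface("MKTLLILVLLII", "GGLLILVAGG", m, window = 5)
#' dim(s$S)
#' @export
alignment_surface <- function(query, reference, matrix, window = 15L) {
  q <- .as_residues(query)
  r <- .as_residues(reference)
  if (!is.numeric(window) || length(window) != 1L || window < 1L ||
      window %% 2L != 1L)
    stop("window must be an odd integer >= 1")
  qi <- .residue_index(matrix, q$seq)
  ri <- .residue_index(matrix, r$seq)
  P <- matrix$scores[qi, ri, drop = FALSE]
  Lq <- length(qi); Lr <- length(ri)
  w <- (window - 1L) %/% 2L
  S <- matrix(0, Lq, Lr)
  cnt <- matrix(0L, Lq, Lr)
  for (k in -w:w) {
    i0 <- max(1L, 1L - k); i1 <- min(Lq, Lq - k)
    j0 <- max(1L, 1L - k); j1 <- min(Lr, Lr - k)
    if (i0 > i1 || j0 > j1) next
    S[i0:i1, j0:j1] <- S[i0:i1, j0:j1] + P[(i0:i1) + k, (j0:j1) + k]
    cnt[i0:i1, j0:j1] <- cnt[i0:i1, j0:j1] + 1L
  }
  S <- S / cnt
  structure(list(S = S, window = as.integer(window),
                 query_id = q$id, reference_id = r$id),
            class = "alignment_surface")
}

.as_residues <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1L, all(c("id", "seq") %in% names(x)))
    list(id = x$id, seq = toupper(x$seq))
  } else if (is.character(x) && length(x) == 1L) {
    list(id = NA_character_, seq = toupper(x))
  } else stop("expected a residue string or a one-row record data frame")
}

#' @export
print.alignment_surface <- function(x, ...) {
  cat("Dense alignment surface ", nrow(x$S), " x ", ncol(x$S),
      " (window ", x$window, ")\n", sep = "")
  invisible(x)
}

#' Score profiles projected from an alignment surface
#'
#' `cumulative_profile()` projects the surface onto one axis as the plain
#' mean over the partner axis, `c[i] = mean_j S[i, j]` -- a high-precision
#' windowed hydrophobicity curve for that sequence.
#' `cross_weighted_profile()` projects onto the query axis with each
#' reference column weighted by the reference's own cumulative score,
#' `C[i] = sum_j S[i, j] c_r[j] / sum_j c_r[j]`, which emphasizes query
#' alignment against the partner's transmembrane regions; if every
#' reference column score is zero the profile is all zero.
#'
#' @param surface An [alignment_surface].
#' @param axis Which axis to project onto.
#' @return Numeric vector of per-residue scores with attribute
#'   `provenance`, class `score_profile`.
#' @export
cumulative_profile <- function(surface, axis = c("query", "reference")) {
  stopifnot(inherits(surface, "alignment_surface"))
  axis <- match.arg(axis)
  p <- if (axis == "query") rowMeans(surface$S) else colMeans(surface$S)
  .score_profile(unname(p), "single-comparison cumulative")
}

#' @rdname cumulative_profile
#' @export
cross_weighted_profile <- function(surface) {
  stopifnot(inherits(surface, "alignment_surface"))
  cr <- colMeans(surface$S)
  sw <- sum(cr)
  p <- if (sw == 0) rep(0, nrow(surface$S)) else
    as.vector(surface$S %*% cr) / sw
  .score_profile(unname(p), "cross-weighted")
}

.score_profile <- function(values, provenance) {
  structure(as.numeric(values), provenance = provenance,
            class = "score_profile")
}

#' @export
print.score_profile <- function(x, ...) {
  cat("Score profile (", attr(x, "provenance"), "), length ", length(x),
      ", max ", format(max(x), digits = 4), "\n", sep = "")
  invisible(x)
}

#' Global DAS profile of a query against a reference library
#'
#' The per-residue score that is thresholded to call transmembrane
#' segments: the arithmetic mean, over reference library members, of the
#' cross-weighted cumulative score profile of the query/member alignment
#' surface.  A library member whose id equals the query id is excluded
#' from the average, so library members can themselves be scored without
#' a trivial self-match.
#'
#' @param query Residue string or one-row record data frame.
#' @param library A [load_library] object, or a data frame of records
#'   with columns `id` and `seq`.
#' @param matrix A [pair_score_matrix].
#' @param window Odd integer window length (default 15).
#' @return `score_profile` of length `nchar(query)`, provenance
#'   `"global average"`.
#' @examples
#' lib <- synth_library(size = 8, seed = 11)
#' m <- pair_score_matrix()
#' d <- das_profile("MKTLLILVLLAVILIIGGSARDK", lib, m)
#' max(d)
#' @export
das_profile <- function(query, library, matrix, window = 15L) {
  members <- .library_records(library)
  q <- .as_residues(query)
  if (!is.na(q$id)) members <- members[members$id != q$id, , drop = FALSE]
  if (!nrow(members))
    stop("reference library is empty after self-exclusion")
  # canonical member order: the average is then bit-identical under any
  # permutation of the library
  members <- members[order(members$id, method = "radix"), , drop = FALSE]
  acc <- NULL
  for (i in seq_len(nrow(members))) {
    cw <- cross_weighted_profile(
      alignment_surface(q$seq, members$seq[i], matrix, window))
    acc <- if (is.null(acc)) cw else acc + cw
  }
  .score_profile(acc / nrow(members), "global average")
}

.library_records <- function(library) {
  if (inherits(library, "ref_library")) return(library$records)
  if (is.data.frame(library) && all(c("id", "seq") %in% names(library)))
    return(library)
  stop("library must be a ref_library or a data frame with id and seq")
}

#' Export a score profile as TSV
#'
#' Writes one row per residue: `position`, `residue`, `score`.
#'
#' @param profile A `score_profile`.
#' @param seq The residue string the profile was computed for.
#' @param path Output path.
#' @export
write_profile_tsv <- function(profile, seq, path) {
  stopifnot(length(profile) == nchar(seq))
  d <- data.frame(position = seq_along(profile),
                  residue = strsplit(toupper(seq), "")[[1]],
                  score = as.numeric(profile))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
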
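# Independent brute-force reference implementations used as oracles.
# These deliberately avoid the package's vectorized code paths: plain
# nested loops computing everything from first principles.

# Toy 3-letter alphabet shared by the exhaustive profile tests.
toy_letters <- c("A", "G", "L")
toy_values <- c(A = 0.2, G = 0, L = 1)
toy_background <- c(A = 1, G = 1, L = 1) / 3
toy_scale <- function() hydro_scale(toy_values, "toy")
toy_matrix <- function()
  pair_score_matrix(toy_scale(), toy_background, ambiguity = character())

# All sequences over `letters` of exactly length L.
all_strings <- function(letters, L) {
  if (L == 1) return(letters)
  apply(do.call(expand.grid,
                c(rep(list(letters), L), stringsAsFactors = FALSE)),
        1, paste, collapse = "")
}

# Windowed diagonal surface by naive triple loop.
oracle_surface <- function(q, r, scores, window) {
  qc <- strsplit(q, "")[[1]]; rc <- strsplit(r, "")[[1]]
  Lq <- length(qc); Lr <- length(rc)
  w <- (window - 1) / 2
  S <- matrix(0, Lq, Lr)
  for (i in seq_len(Lq)) for (j in seq_len(Lr)) {
    acc <- 0; cnt <- 0
    for (k in -w:w) {
      if (i + k >= 1 && i + k <= Lq && j + k >= 1 && j + k <= Lr) {
        acc <- acc + scores[qc[i + k], rc[j + k]]
        cnt <- cnt + 1
      }
    }
    S[i, j] <- acc / cnt
  }
  S
}

# Global profile from first principles: normalization, constant,
# surface, column means, weighted projection, average over references.
oracle_das_profile <- function(q, refs, values, background, window) {
  n <- (values - min(values)) / (max(values) - min(values))
  nbar <- sum(background[names(n)] * n)
  cc <- 1 / nbar^2
  scores <- cc * outer(n, n)
  dimnames(scores) <- list(names(n), names(n))
  Lq <- nchar(q)
  total <- rep(0, Lq)
  for (r in refs) {
    S <- oracle_surface(q, r, scores, window)
    cr <- apply(S, 2, mean)
    prof <- if (sum(cr) == 0) rep(0, Lq) else {
      p <- rep(0, Lq)
      for (i in seq_len(Lq)) p[i] <- sum(S[i, ] * cr) / sum(cr)
      p
    }
    total <- total + prof
  }
  total / length(refs)
}

# Segment extraction by linear scan (position-by-position).
oracle_segments <- function(labels, classes) {
  chars <- strsplit(labels, "")[[1]]
  starts <- ends <- integer()
  open <- FALSE
  for (i in seq_along(chars)) {
    if (chars[i] %in% classes) {
      if (!open) { starts <- c(starts, i); open <- TRUE }
    } else if (open) { ends <- c(ends, i - 1L); open <- FALSE }
  }
  if (open) ends <- c(ends, length(chars))
  data.frame(start = starts, end = ends)
}

# Greedy one-to-one matcher by repeated max-extraction over an explicit
# candidate table (same rule as the package, independent mechanics).
oracle_match_counts <- function(predicted, annotated, signal_regions = NULL,
                                min_overlap = 3, exclude_signal = TRUE) {
  ov1 <- function(s1, e1, s2, e2) max(0, min(e1, e2) - max(s1, s2) + 1)
  np <- nrow(predicted); na <- nrow(annotated)
  cand <- list()
  if (np && na) {
    for (p in seq_len(np)) for (a in seq_len(na)) {
      o <- ov1(predicted$start[p], predicted$end[p],
               annotated$start[a], annotated$end[a])
      if (o >= min_overlap)
        cand[[length(cand) + 1L]] <- c(p = p, a = a, o = o)
    }
  }
  p_used <- rep(FALSE, np); a_used <- rep(FALSE, na)
  tp <- 0L
  while (length(cand)) {
    best <- 1L
    for (k in seq_along(cand)) {
      ck <- cand[[k]]; cb <- cand[[best]]
      better <- ck["o"] > cb["o"] ||
        (ck["o"] == cb["o"] &&
           (annotated$start[ck["a"]] < annotated$start[cb["a"]] ||
              (annotated$start[ck["a"]] == annotated$start[cb["a"]] &&
                 predicted$start[ck["p"]] < predicted$start[cb["p"]])))
      if (better) best <- k
    }
    cb <- cand[[best]]
    tp <- tp + 1L
    p_used[cb["p"]] <- TRUE; a_used[cb["a"]] <- TRUE
    cand <- Filter(function(ck) !p_used[ck["p"]] && !a_used[ck["a"]], cand)
  }
  discarded <- 0L
  fp <- 0L
  for (p in which(!p_used)) {
    is_sig <- FALSE
    if (exclude_signal && !is.null(signal_regions) && nrow(signal_regions)) {
      for (s in seq_len(nrow(signal_regions))) {
        if (ov1(predicted$start[p], predicted$end[p], signal_regions$start[s],
                signal_regions$end[s]) >= min_overlap) is_sig <- TRUE
      }
    }
    if (is_sig) discarded <- discarded + 1L else fp <- fp + 1L
  }
  list(tp = tp, fp = fp, fn = sum(!a_used), discarded = discarded)
}

# Maximal runs of TRUE in a logical vector as a segment data frame.
occupancy_segments <- function(bits) {
  if (!any(bits)) return(data.frame(start = integer(), end = integer()))
  r <- rle(bits)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

# Random sorted non-overlapping segment list on positions 1..L.
random_segments <- function(L, p = 0.4) {
  occupancy_segments(stats::runif(L) < p)
}

# Small shared fixtures (built once per test run).
shared_matrix <- pair_score_matrix()
shared_library <- synth_library(size = 8, seed = 11)
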
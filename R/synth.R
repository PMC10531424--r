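# Run expr under a local RNG seeded with `seed`, restoring global RNG state.
.with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.draw_len <- function(range) {
  if (range[1] > range[2]) stop("invalid length range: lower > upper")
  if (any(range < 1)) stop("length bounds must be positive")
  sample(range[1]:range[2], 1L)
}

#' Parameters for the synthetic protein generators
#'
#' The generators plant the sequence architecture the predictor is built
#' to detect: membrane-spanning stretches of roughly 15-30 predominantly
#' hydrophobic residues separated by polar loops.  The composition
#' weights deliberately caricature real membrane proteins -- strongly
#' hydrophobic segments, strongly polar loops -- because the synthetic
#' data exist to give tests unambiguous ground truth, not to imitate
#' natural k-mer statistics.
#'
#' @param n_segments Integer range for the number of TM segments per
#'   generated TM protein.
#' @param segment_length Integer range of planted TM segment lengths
#'   (residues).
#' @param loop_length Integer range of inter-segment loop lengths.
#' @param globular_length Integer range of globular protein lengths.
#' @param hydrophobic_weights Residue sampling weights inside planted
#'   segments (I/L/V/F/A/M-dominated).
#' @param hydrophilic_weights Residue sampling weights inside loops
#'   (D/E/K/R/N/Q/S/T/G/P-dominated).
#' @param background_weights Residue weights for globular bodies
#'   (database-background frequencies).
#' @param seed Default seed for generators called without an explicit one.
#' @return List of class `generator_params`.
#' @export
generator_params <- function(n_segments = c(1L, 7L),
                             segment_length = c(15L, 30L),
                             loop_length = c(10L, 60L),
                             globular_length = c(120L, 400L),
                             hydrophobic_weights = c(I = 0.30, L = 0.28,
                                                     V = 0.20, F = 0.10,
                                                     M = 0.07, A = 0.05),
                             hydrophilic_weights = c(D = 0.12, E = 0.13,
                                                     K = 0.12, R = 0.10,
                                                     N = 0.09, Q = 0.09,
                                                     S = 0.10, T = 0.08,
                                                     G = 0.10, P = 0.07),
                             background_weights = residue_frequencies(),
                             seed = 1L) {
  for (r in list(n_segments, segment_length, loop_length, globular_length)) {
    if (length(r) != 2L || any(r < 1) || r[1] > r[2])
      stop("length ranges must be positive with lower <= upper")
  }
  for (w in list(hydrophobic_weights, hydrophilic_weights,
                 background_weights)) {
    if (is.null(names(w)) || any(w < 0) || abs(sum(w) - 1) > 1e-9)
      stop("weight tables must be named, non-negative and sum to 1")
  }
  structure(list(n_segments = as.integer(n_segments),
                 segment_length = as.integer(segment_length),
                 loop_length = as.integer(loop_length),
                 globular_length = as.integer(globular_length),
                 hydrophobic_weights = hydrophobic_weights,
                 hydrophilic_weights = hydrophilic_weights,
                 background_weights = background_weights,
                 seed = as.integer(seed)),
            class = "generator_params")
}

.sample_residues <- function(n, weights) {
  paste(sample(names(weights), n, replace = TRUE, prob = weights),
        collapse = "")
}

#' Generate a synthetic multi-spanning TM protein
#'
#' Alternating loop/segment architecture: polar loops (labeled
#' alternately `1` and `2`, mimicking intracellular/extracellular sides)
#' flank hydrophobic segments labeled `H`.  Deterministic for a fixed
#' seed.
#'
#' @param params A [generator_params].
#' @param n_segments Number of TM segments; drawn from
#'   `params$n_segments` when `NULL`.
#' @param seed RNG seed (defaults to `params$seed`).
#' @param id Record id.
#' @return One-row data frame with columns `id`, `desc`, `seq`, `labels`.
#' @examples
#' p <- synth_tm_protein(n_segments = 2, seed = 7)
#' annotation_segments(p$labels, c("H", "h"))
#' @export
synth_tm_protein <- function(params = generator_params(), n_segments = NULL,
                             seed = params$seed, id = NULL) {
  .with_seed(seed, {
    if (is.null(n_segments)) n_segments <- .draw_len(params$n_segments)
    if (n_segments < 1) stop("n_segments must be >= 1")
    side <- sample(c("1", "2"), 1L)
    seq_parts <- lab_parts <- character()
    for (s in seq_len(n_segments)) {
      nl <- .draw_len(params$loop_length)
      seq_parts <- c(seq_parts,
                     .sample_residues(nl, params$hydrophilic_weights))
      lab_parts <- c(lab_parts, strrep(side, nl))
      side <- if (side == "1") "2" else "1"
      ns <- .draw_len(params$segment_length)
      seq_parts <- c(seq_parts,
                     .sample_residues(ns, params$hydrophobic_weights))
      lab_parts <- c(lab_parts, strrep("H", ns))
    }
    nl <- .draw_len(params$loop_length)
    seq_parts <- c(seq_parts, .sample_residues(nl, params$hydrophilic_weights))
    lab_parts <- c(lab_parts, strrep(side, nl))
    if (is.null(id)) id <- sprintf("synTM_seed%d", seed)
    data.frame(id = id, desc = sprintf("synthetic TM protein, %d segments",
                                       n_segments),
               seq = paste(seq_parts, collapse = ""),
               labels = paste(lab_parts, collapse = ""),
               stringsAsFactors = FALSE)
  })
}

# Longest run of strongly hydrophobic residues (I/L/V/F/M) in a string.
.max_hydrophobic_run <- function(seq) {
  chars <- strsplit(seq, "")[[1]] %in% c("I", "L", "V", "F", "M")
  if (!any(chars)) return(0L)
  r <- rle(chars)
  max(r$lengths[r$values])
}

.sample_globular_body <- function(n, params, max_run = 8L, retries = 200L) {
  for (t in seq_len(retries)) {
    s <- .sample_residues(n, params$background_weights)
    if (.max_hydrophobic_run(s) <= max_run) return(s)
  }
  stop("globular generator failed: could not avoid hydrophobic runs after ",
       retries, " attempts")
}

#' Generate a synthetic globular (non-TM) protein
#'
#' Residues are drawn from background database frequencies, with
#' rejection sampling enforcing that no run of 9 or more consecutive
#' strongly hydrophobic residues (I/L/V/F/M) occurs, so the generator can
#' never accidentally plant a TM-like stretch.  All labels are `1`.
#'
#' @inheritParams synth_tm_protein
#' @param length Sequence length; drawn from `params$globular_length`
#'   when `NULL`.
#' @return One-row data frame (`id`, `desc`, `seq`, `labels`).
#' @export
synth_globular <- function(params = generator_params(), length = NULL,
                           seed = params$seed, id = NULL) {
  .with_seed(seed, {
    if (is.null(length)) length <- .draw_len(params$globular_length)
    if (length < 1) stop("length must be >= 1")
    s <- .sample_globular_body(length, params)
    if (is.null(id)) id <- sprintf("synGLOB_seed%d", seed)
    data.frame(id = id, desc = "synthetic globular protein",
               seq = s, labels = strrep("1", length),
               stringsAsFactors = FALSE)
  })
}

#' Generate a synthetic signal-peptide protein
#'
#' A cleavable-signal-like architecture: an optional short polar
#' N-terminal stretch (0-4 residues, labeled `1`), a hydrophobic core of
#' 7-15 residues labeled `S` (so the S-run starts within the first 5
#' positions), then a globular body.  Signal peptides are biophysically
#' TM-helix-like, which is exactly the confound this class exists to
#' exercise.
#'
#' @inheritParams synth_globular
#' @param body_length Length of the globular body; drawn from
#'   `params$globular_length` when `NULL`.
#' @return One-row data frame (`id`, `desc`, `seq`, `labels`).
#' @export
synth_signal_protein <- function(params = generator_params(),
                                 body_length = NULL, seed = params$seed,
                                 id = NULL) {
  .with_seed(seed, {
    if (is.null(body_length)) body_length <- .draw_len(params$globular_length)
    n_pre <- sample(0:4, 1L)
    n_sig <- sample(7:15, 1L)
    pre <- if (n_pre > 0)
      .sample_residues(n_pre, params$hydrophilic_weights) else ""
    sig <- .sample_residues(n_sig, params$hydrophobic_weights)
    body <- .sample_globular_body(body_length, params)
    if (is.null(id)) id <- sprintf("synSIG_seed%d", seed)
    data.frame(id = id, desc = "synthetic signal-peptide protein",
               seq = paste0(pre, sig, body),
               labels = paste0(strrep("1", n_pre), strrep("S", n_sig),
                               strrep("1", body_length)),
               stringsAsFactors = FALSE)
  })
}

#' Generate a mixed labeled dataset
#'
#' Seeded, shuffled concatenation of synthetic TM, globular and
#' signal-peptide proteins; the ground truth is fully recoverable from
#' the topology labels via [annotation_segments].
#'
#' @param params A [generator_params].
#' @param n_tm,n_globular,n_signal Number of records of each class.
#' @param seed Master seed; every record derives its own seed from it.
#' @param path Optional output path; when given, the dataset is also
#'   written as labeled FASTA.
#' @return Data frame of labeled records (`id`, `desc`, `seq`, `labels`).
#' @examples
#' d <- synth_dataset(n_tm = 2, n_globular = 2, n_signal = 1, seed = 5)
#' d$id
#' @export
synth_dataset <- function(params = generator_params(), n_tm = 0L,
                          n_globular = 0L, n_signal = 0L,
                          seed = params$seed, path = NULL) {
  stopifnot(n_tm >= 0, n_globular >= 0, n_signal >= 0)
  n <- n_tm + n_globular + n_signal
  recs <- .with_seed(seed, {
    sub_seeds <- sample.int(.Machine$integer.max - 1L, max(n, 1L))
    out <- vector("list", n)
    k <- 0L
    for (i in seq_len(n_tm)) {
      k <- k + 1L
      out[[k]] <- synth_tm_protein(params, seed = sub_seeds[k],
                                   id = sprintf("tm_%03d", i))
    }
    for (i in seq_len(n_globular)) {
      k <- k + 1L
      out[[k]] <- synth_globular(params, seed = sub_seeds[k],
                                 id = sprintf("glob_%03d", i))
    }
    for (i in seq_len(n_signal)) {
      k <- k + 1L
      out[[k]] <- synth_signal_protein(params, seed = sub_seeds[k],
                                       id = sprintf("sig_%03d", i))
    }
    if (n == 0L)
      data.frame(id = character(), desc = character(), seq = character(),
                 labels = character(), stringsAsFactors = FALSE)
    else do.call(rbind, out)[sample.int(n), , drop = FALSE]
  })
  rownames(recs) <- NULL
  if (!is.null(path)) write_labeled_fasta(recs, path)
  recs
}

#' Generate a synthetic reference library
#'
#' `size` multi-spanning synthetic TM proteins.  Reference library
#' members emulate polytopic membrane proteins -- many membrane passes
#' (4-7 here) joined by short loops -- because the pipeline averages the
#' query's cross-weighted profile over these sequences and the reference
#' weighting is only informative when the references themselves are
#' TM-dense, as real polytopic proteins (cytochrome oxidase and
#' cytochrome bd subunits, transporters) are.  Loop lengths are
#' therefore drawn from 8-25 residues for library members, overriding
#' the looser default used for query-side TM proteins.
#'
#' For a fixed seed the libraries are nested by prefix: the first 8
#' members of the size-16 library are the size-8 library, and so on, so
#' library size acts purely as a speed/accuracy knob.
#'
#' @param params A [generator_params].
#' @param size Library size, one of 8, 16, 24, 32.
#' @param seed Master seed.
#' @return A `ref_library` (see [load_library]).
#' @export
synth_library <- function(params = generator_params(), size = 8L,
                          seed = params$seed) {
  if (!size %in% c(8L, 16L, 24L, 32L))
    stop("library size must be one of 8, 16, 24, 32")
  lib_params <- params
  lib_params$loop_length <- c(8L, 25L)
  member_seeds <- .with_seed(seed, sample.int(.Machine$integer.max - 1L, 32L))
  recs <- do.call(rbind, lapply(seq_len(size), function(i) {
    n_seg <- .with_seed(member_seeds[i], sample(4:7, 1L))
    synth_tm_protein(lib_params, n_segments = n_seg, seed = member_seeds[i],
                     id = sprintf("synlib_%02d", i))
  }))
  rownames(recs) <- NULL
  .ref_library(recs, size = size,
               name = sprintf("synthetic TM library (seed %d)", seed))
}
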
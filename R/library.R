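LIBRARY_SIZES <- c(8L, 16L, 24L, 32L)

.ref_library <- function(records, size, name) {
  if (nrow(records) != size)
    stop("library member count (", nrow(records),
         ") does not match nominal size (", size, ")")
  if (anyDuplicated(records$id))
    stop("reference library has duplicate member id(s): ",
         paste(unique(records$id[duplicated(records$id)]), collapse = ", "))
  structure(list(records = records, size = as.integer(size), name = name),
            class = "ref_library")
}

#' Load a reference library of TM protein sequences
#'
#' Every query is compared against a small library of multi-spanning
#' transmembrane proteins.  Libraries come in nested sizes 8, 16, 24 and
#' 32 -- the first `size` records of the source FASTA -- so that the
#' larger sizes, kept for backwards compatibility, are strict supersets
#' of the smaller ones.  The smallest (8) library is recommended:
#' runtime grows linearly with size and larger libraries do not buy a
#' matching accuracy gain.
#'
#' The bundled default (`system.file("extdata",
#' "tm_library_synthetic.fasta", package = "dastm")`) is a synthetic
#' stand-in library of 32 generated multi-spanning TM sequences; any
#' FASTA of trusted TM proteins can be substituted via `source`.
#'
#' @param source Path to a FASTA file; `NULL` for the bundled synthetic
#'   library.
#' @param size Library size, one of 8, 16, 24, 32 (default 8).
#' @return Object of class `ref_library`: `records` (data frame `id`,
#'   `desc`, `seq`), `size`, `name`.
#' @examples
#' lib <- load_library(size = 8)
#' lib$records$id
#' @export
load_library <- function(source = NULL, size = 8L) {
  if (!size %in% LIBRARY_SIZES)
    stop("library size must be one of ", paste(LIBRARY_SIZES, collapse = ", "))
  if (is.null(source)) {
    source <- system.file("extdata", "tm_library_synthetic.fasta",
                          package = "dastm")
    name <- "bundled synthetic TM library"
  } else name <- basename(source)
  recs <- read_fasta(source)
  if (nrow(recs) < size)
    stop("library source has ", nrow(recs), " records, fewer than the ",
         "requested size ", size)
  .ref_library(recs[seq_len(size), , drop = FALSE], size = size, name = name)
}

#' @export
print.ref_library <- function(x, ...) {
  cat("Reference TM library: ", x$name, " (", x$size, " members)\n", sep = "")
  cat(" ", paste(x$records$id, collapse = ", "), "\n")
  invisible(x)
}

#' Validate a reference library against itself
#'
#' A usable library must consist of sequences the method itself
#' recognizes as transmembrane: each member is predicted against the
#' remaining members (self-exclusion leaves `size - 1` comparators) and
#' must yield at least one called segment.  The report carries one row
#' per member; the library passes when every member does.
#'
#' @param library A `ref_library`.
#' @param matrix A [pair_score_matrix].
#' @param window Odd integer window length.
#' @param params A [caller_params].
#' @return Data frame with columns `id`, `n_segments`, `ok` and
#'   attributes `passes` (logical) and `notes`.
#' @export
validate_library <- function(library, matrix = pair_score_matrix(),
                             window = 15L, params = caller_params()) {
  recs <- .library_records(library)
  n <- nrow(recs)
  if (n < 2L) {
    rep <- data.frame(id = recs$id, n_segments = NA_integer_, ok = FALSE)
    attr(rep, "passes") <- FALSE
    attr(rep, "notes") <- "single-member library: self-exclusion leaves an empty comparator set"
    return(rep)
  }
  n_seg <- integer(n)
  for (i in seq_len(n)) {
    prof <- das_profile(recs[i, , drop = FALSE], recs, matrix, window)
    n_seg[i] <- nrow(call_segments(prof, params))
  }
  rep <- data.frame(id = recs$id, n_segments = n_seg, ok = n_seg >= 1L)
  attr(rep, "passes") <- all(rep$ok)
  attr(rep, "notes") <- if (all(rep$ok)) "all members recalled as TM" else
    paste("members with no called segment:",
          paste(recs$id[!rep$ok], collapse = ", "))
  rep
}
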
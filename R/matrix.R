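AMBIGUITY_LETTERS <- c("X", "B", "Z", "U", "O")

#' Build the hydrophobicity pair scoring matrix
#'
#' The dense alignment surface is computed under a substitution table that
#' scores residue pairs by joint hydrophobicity rather than evolutionary
#' exchangeability: `M(a, b) = c * n(a) * n(b)`, where `n` is the
#' min-max-normalized hydrophobicity of the scale and the constant `c` is
#' fixed so that the background-weighted mean score is exactly 1,
#' `sum_a sum_b f(a) f(b) M(a, b) = 1`.  Profile scores are therefore
#' expressed as multiples of the expectation for a random residue pair,
#' which is what makes the segment-calling cutoff of 2.5 interpretable as
#' "2.5 times the random background".
#'
#' Ambiguity letters (X, B, Z, U, O by default, minus any letter the scale
#' itself defines) score as if their normalized hydrophobicity were the
#' background-weighted mean of `n`, so degenerate real-world sequences
#' never abort a prediction run.
#'
#' @param scale A [hydro_scale] (default Kyte-Doolittle).
#' @param background Named numeric vector of residue frequencies covering
#'   every scale letter; positive, summing to 1 (default
#'   [residue_frequencies]).
#' @param ambiguity Character vector of extra letters scored at the
#'   background-mean hydrophobicity.
#' @return Object of class `pair_matrix`: `scores` (square numeric matrix
#'   over scale + ambiguity letters), `letters`, `ambiguity`, `background`,
#'   `constant` (the normalization constant c), `scale_name`.
#' @examples
#' m <- pair_score_matrix()
#' m$scores["I", "L"]
#' # background-weighted mean score is 1 by construction:
#' f <- residue_frequencies()
#' sum(outer(f, f) * m$scores[names(f), names(f)])
#' @export
pair_score_matrix <- function(scale = hydro_scale(kyte_doolittle(), "kyte-doolittle"),
                              background = residue_frequencies(),
                              ambiguity = AMBIGUITY_LETTERS) {
  stopifnot(inherits(scale, "hydro_scale"))
  letters <- names(scale$values)
  if (is.null(names(background)))
    stop("background frequencies must be named")
  missing <- setdiff(letters, names(background))
  if (length(missing))
    stop("background frequencies missing for residue(s): ",
         paste(missing, collapse = ", "))
  f <- background[letters]
  if (any(f <= 0)) stop("background frequencies must be positive")
  if (abs(sum(f) - 1) > 1e-9)
    stop("background frequencies must sum to 1 (got ", format(sum(f)), ")")

  n <- normalized_values(scale)
  nbar <- sum(f * n)                       # background-mean hydrophobicity
  if (nbar <= 0)
    stop("degenerate background: mean normalized hydrophobicity is 0")
  const <- 1 / nbar^2                      # forces sum f(a) f(b) M(a,b) = 1

  ambiguity <- setdiff(ambiguity, letters)
  n_all <- c(n, stats::setNames(rep(nbar, length(ambiguity)), ambiguity))
  scores <- const * outer(n_all, n_all)
  dimnames(scores) <- list(names(n_all), names(n_all))

  structure(list(scores = scores, letters = letters, ambiguity = ambiguity,
                 background = f, constant = const, nbar = nbar,
                 scale_name = scale$name),
            class = "pair_matrix")
}

#' @export
print.pair_matrix <- function(x, ...) {
  cat("Hydrophobicity pair scoring matrix (", x$scale_name, ")\n", sep = "")
  cat("  alphabet:", paste(x$letters, collapse = ""),
      " ambiguity:", paste(x$ambiguity, collapse = ""), "\n")
  cat("  normalization constant c =", format(x$constant, digits = 6),
      "; background-mean score = 1\n")
  invisible(x)
}

#' Serialize / deserialize a pair scoring matrix as text triples
#'
#' Writes one `A B score` triple per line (upper triangle only, the matrix
#' is symmetric) for audit or substitution of an externally derived table.
#' `read_pair_matrix()` restores a scoring-capable `pair_matrix`; the
#' background and normalization metadata are carried in `#`-prefixed
#' header comments.
#'
#' @param matrix A `pair_matrix`.
#' @param path Output (input) file path.
#' @return `read_pair_matrix` returns a `pair_matrix`.
#' @export
write_pair_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "pair_matrix"))
  s <- matrix$scores
  ln <- rownames(s)
  rows <- c(sprintf("# pair scoring matrix: %s", matrix$scale_name),
            sprintf("# constant %.*g", 17, matrix$constant),
            sprintf("# ambiguity %s", paste(matrix$ambiguity, collapse = "")))
  for (i in seq_along(ln)) for (j in i:length(ln))
    rows <- c(rows, sprintf("%s %s %.*g", ln[i], ln[j], 17, s[i, j]))
  writeLines(rows, path)
  invisible(path)
}

#' @rdname write_pair_matrix
#' @export
read_pair_matrix <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  body <- grep("^#", lines, value = TRUE, invert = TRUE)
  body <- body[nzchar(trimws(body))]
  parts <- strsplit(trimws(body), "[[:space:]]+")
  if (any(lengths(parts) != 3L))
    stop("malformed matrix file: expected 'A B score' triples")
  a <- vapply(parts, `[[`, "", 1L)
  b <- vapply(parts, `[[`, "", 2L)
  v <- as.numeric(vapply(parts, `[[`, "", 3L))
  if (any(is.na(v))) stop("malformed matrix file: non-numeric score")
  letters <- sort(unique(c(a, b)))
  s <- matrix(NA_real_, length(letters), length(letters),
              dimnames = list(letters, letters))
  s[cbind(a, b)] <- v
  s[cbind(b, a)] <- v
  if (anyNA(s)) stop("malformed matrix file: incomplete pair coverage")
  amb <- sub("^# ambiguity ?", "", grep("^# ambiguity", hdr, value = TRUE))
  amb <- if (length(amb)) strsplit(amb, "")[[1]] else character()
  cst <- sub("^# constant ", "", grep("^# constant", hdr, value = TRUE))
  structure(list(scores = s, letters = setdiff(letters, amb),
                 ambiguity = amb, background = NULL,
                 constant = if (length(cst)) as.numeric(cst) else NA_real_,
                 nbar = NA_real_, scale_name = "from-file"),
            class = "pair_matrix")
}

# Score lookup for a residue string: indices into the matrix, with any
# letter outside the table treated as the first ambiguity letter.
.residue_index <- function(matrix, residues) {
  chars <- strsplit(residues, "")[[1]]
  ln <- rownames(matrix$scores)
  idx <- match(chars, ln)
  if (anyNA(idx)) {
    if (!length(matrix$ambiguity))
      stop("residue letter(s) not in scoring matrix: ",
           paste(unique(chars[is.na(idx)]), collapse = ", "))
    idx[is.na(idx)] <- match(matrix$ambiguity[1], ln)
  }
  idx
}
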
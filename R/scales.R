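#' Amino acid hydrophobicity scales and background frequencies
#'
#' `kyte_doolittle()` returns the Kyte-Doolittle hydropathy index for the
#' 20 standard residues (positive = hydrophobic).  `residue_frequencies()`
#' returns background amino acid frequencies typical of a large
#' well-curated protein sequence database, used to normalize the pair
#' scoring matrix so that the expected score of two random residues is 1.
#'
#' @return Named numeric vector over one-letter residue codes.
#' @examples
#' kyte_doolittle()["I"]   # most hydrophobic, 4.5
#' sum(residue_frequencies())
#' @export
kyte_doolittle <- function() {
  c(A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
    Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
    L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
    S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2)
}

#' @rdname kyte_doolittle
#' @export
residue_frequencies <- function() {
  f <- c(A = 0.0826, R = 0.0553, N = 0.0406, D = 0.0546, C = 0.0137,
         Q = 0.0393, E = 0.0674, G = 0.0708, H = 0.0227, I = 0.0593,
         L = 0.0965, K = 0.0582, M = 0.0241, F = 0.0386, P = 0.0473,
         S = 0.0664, T = 0.0534, W = 0.0110, Y = 0.0292, V = 0.0686)
  f / sum(f)
}

#' Construct a hydrophobicity scale object
#'
#' A scale is a named numeric vector of per-residue hydrophobicity values
#' over an arbitrary alphabet (the 20 standard residues for real use, or a
#' reduced toy alphabet for testing).  Scoring uses the min-max-normalized
#' values, so only relative hydrophobicities matter.
#'
#' @param values Named numeric vector, one value per residue letter.
#' @param name Short identifier for the scale.
#' @return Object of class `hydro_scale` with elements `values`, `name`.
#' @examples
#' sc <- hydro_scale(kyte_doolittle(), "kyte-doolittle")
#' range(normalized_values(sc))
#' @export
hydro_scale <- function(values, name = "custom") {
  if (is.null(names(values)) || any(!nzchar(names(values))))
    stop("scale values must be a named vector of residue letters")
  if (anyDuplicated(names(values)))
    stop("duplicate residue letters in scale")
  if (any(!is.finite(values)))
    stop("scale values must be finite")
  if (length(values) < 2L)
    stop("scale must cover at least two residue letters")
  if (diff(range(values)) == 0)
    stop("degenerate scale: all hydrophobicity values are equal, ",
         "min-max normalization is undefined")
  structure(list(values = values, name = name), class = "hydro_scale")
}

#' @rdname hydro_scale
#' @param scale A `hydro_scale` object.
#' @export
normalized_values <- function(scale) {
  stopifnot(inherits(scale, "hydro_scale"))
  v <- scale$values
  (v - min(v)) / (max(v) - min(v))
}

#' @export
print.hydro_scale <- function(x, ...) {
  cat("Hydrophobicity scale:", x$name, "(", length(x$values), "letters )\n")
  print(round(x$values, 3))
  invisible(x)
}
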
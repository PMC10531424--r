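RESIDUE_LETTERS <- c("A","C","D","E","F","G","H","I","K","L",
                     "M","N","P","Q","R","S","T","V","W","Y")
LABEL_LETTERS <- c("H", "h", "B", "b", "S", "1", "2", "U")

# Read raw text lines from a path, connection, or literal text containing
# newlines; strips \r so both \n and \r\n files parse.
.source_lines <- function(source) {
  if (inherits(source, "connection")) {
    lines <- readLines(source, warn = FALSE)
  } else if (is.character(source) && length(source) == 1L &&
             !grepl("\n", source, fixed = TRUE)) {
    if (!file.exists(source)) stop("cannot read input: ", source)
    lines <- readLines(source, warn = FALSE)
  } else {
    lines <- unlist(strsplit(source, "\n", fixed = TRUE), use.names = FALSE)
  }
  sub("\r$", "", lines)
}

#' Read and write protein FASTA files
#'
#' `read_fasta()` parses FASTA into a data frame of sequence records with
#' one row per record, preserving file order.  Sequences are uppercased;
#' the 20 standard residue letters plus the ambiguity letters X, B, Z, U,
#' O are accepted, anything else is a format error reported with its
#' record and position.  `write_fasta()` writes the records back out; a
#' write/read round trip is the identity on normalized records.
#'
#' @param source Path, connection, or FASTA text (with embedded newlines).
#' @param records Data frame with columns `id`, `desc`, `seq`.
#' @param path Output file path.
#' @param width Line-wrap width for sequence output.
#' @return `read_fasta` returns a data frame with character columns `id`,
#'   `desc` and `seq`.
#' @examples
#' recs <- read_fasta(">A first\nMKTLLILV\n>B\nGGSA\n")
#' recs$seq
#' @export
read_fasta <- function(source) {
  lines <- .source_lines(source)
  .parse_fasta_lines(lines)
}

.parse_fasta_lines <- function(lines) {
  payload <- lines[nzchar(trimws(lines))]
  if (!length(payload)) stop("no records: input contains no FASTA data")
  if (!startsWith(payload[1], ">"))
    stop("FASTA format error: sequence line before any header")
  con <- textConnection(lines)
  on.exit(close(con))
  raw <- seqinr::read.fasta(con, seqtype = "AA", as.string = TRUE,
                            forceDNAtolower = FALSE)
  if (!length(raw)) stop("no records: input contains no FASTA data")
  ids <- vapply(raw, attr, "", "name")
  annot <- vapply(raw, attr, "", "Annot")
  desc <- sub("^>\\S*\\s*", "", annot)
  seqs <- toupper(vapply(raw, as.character, ""))
  recs <- data.frame(id = unname(ids), desc = unname(desc),
                     seq = unname(seqs), stringsAsFactors = FALSE)
  if (any(!nzchar(recs$id))) stop("FASTA format error: empty record id")
  if (anyDuplicated(recs$id))
    stop("FASTA format error: duplicate record id(s): ",
         paste(unique(recs$id[duplicated(recs$id)]), collapse = ", "))
  if (any(!nzchar(recs$seq)))
    stop("FASTA format error: empty sequence for record ",
         recs$id[!nzchar(recs$seq)][1])
  .check_residues(recs)
  recs
}

.check_residues <- function(recs) {
  ok <- c(RESIDUE_LETTERS, AMBIGUITY_LETTERS)
  for (i in seq_len(nrow(recs))) {
    chars <- strsplit(recs$seq[i], "")[[1]]
    bad <- which(!(chars %in% ok))
    if (length(bad))
      stop("FASTA format error: illegal residue character '", chars[bad[1]],
           "' at position ", bad[1], " of record ", recs$id[i])
  }
  invisible(recs)
}

#' @rdname read_fasta
#' @export
write_fasta <- function(records, path, width = 60L) {
  stopifnot(is.data.frame(records), all(c("id", "seq") %in% names(records)))
  desc <- if ("desc" %in% names(records)) records$desc else rep("", nrow(records))
  out <- character()
  for (i in seq_len(nrow(records))) {
    hdr <- if (nzchar(desc[i])) paste(records$id[i], desc[i]) else records$id[i]
    out <- c(out, paste0(">", hdr), .wrap_seq(records$seq[i], width))
  }
  writeLines(out, path)
  invisible(path)
}

.wrap_seq <- function(s, width) {
  n <- nchar(s)
  starts <- seq(1L, n, by = width)
  substring(s, starts, pmin(starts + width - 1L, n))
}

#' Read and write labeled FASTA (sequence plus per-residue topology)
#'
#' Labeled FASTA pairs every sequence with a six-state topology string of
#' equal length: H/h helical TM, B/b beta TM, S signal peptide, 1
#' intracellular, 2 extracellular, U unknown/unresolved.  Each record is a
#' header line followed by the sequence block and then the label block;
#' either block may be wrapped over multiple lines, so the payload is
#' concatenated and split at its midpoint (an odd payload length is a
#' format error -- the two halves must match exactly).
#'
#' @inheritParams read_fasta
#' @return `read_labeled_fasta` returns a data frame with columns `id`,
#'   `desc`, `seq`, `labels`.
#' @examples
#' d <- read_labeled_fasta(">A\nMKTLLILV\n22HHHHHH\n")
#' d$labels
#' @export
read_labeled_fasta <- function(source) {
  lines <- .source_lines(source)
  payload <- lines[nzchar(trimws(lines))]
  if (!length(payload)) stop("no records: input contains no FASTA data")
  if (!startsWith(payload[1], ">"))
    stop("labeled FASTA format error: sequence line before any header")
  is_hdr <- startsWith(payload, ">")
  rec_id <- cumsum(is_hdr)
  headers <- sub("^>", "", payload[is_hdr])
  ids <- sub("\\s.*$", "", headers)
  desc <- sub("^\\S*\\s*", "", headers)
  n <- length(headers)
  seqs <- labels <- character(n)
  for (r in seq_len(n)) {
    body <- paste(gsub("[[:space:]]", "", payload[!is_hdr & rec_id == r]),
                  collapse = "")
    if (!nzchar(body))
      stop("labeled FASTA format error: empty record ", ids[r])
    if (nchar(body) %% 2L != 0L)
      stop("labeled FASTA format error: sequence/label length mismatch ",
           "for record ", ids[r])
    half <- nchar(body) %/% 2L
    seqs[r] <- toupper(substr(body, 1L, half))
    labels[r] <- substr(body, half + 1L, nchar(body))
    chars <- strsplit(labels[r], "")[[1]]
    bad <- which(!(chars %in% LABEL_LETTERS))
    if (length(bad))
      stop("labeled FASTA format error: illegal topology label '",
           chars[bad[1]], "' at position ", bad[1], " of record ", ids[r])
  }
  recs <- data.frame(id = ids, desc = desc, seq = seqs, labels = labels,
                     stringsAsFactors = FALSE)
  if (anyDuplicated(recs$id))
    stop("labeled FASTA format error: duplicate record id(s): ",
         paste(unique(recs$id[duplicated(recs$id)]), collapse = ", "))
  .check_residues(recs)
  recs
}

#' @rdname read_labeled_fasta
#' @export
write_labeled_fasta <- function(records, path, width = 60L) {
  stopifnot(is.data.frame(records),
            all(c("id", "seq", "labels") %in% names(records)))
  if (any(nchar(records$seq) != nchar(records$labels)))
    stop("sequence/label length mismatch in records to write")
  desc <- if ("desc" %in% names(records)) records$desc else rep("", nrow(records))
  out <- character()
  for (i in seq_len(nrow(records))) {
    hdr <- if (nzchar(desc[i])) paste(records$id[i], desc[i]) else records$id[i]
    out <- c(out, paste0(">", hdr),
             .wrap_seq(records$seq[i], width),
             .wrap_seq(records$labels[i], width))
  }
  writeLines(out, path)
  invisible(path)
}

#' Extract annotated segment intervals from a topology label string
#'
#' Returns the maximal runs of positions whose label belongs to the
#' requested classes, as 1-based inclusive intervals.  Requesting both
#' cases of a letter (for example `c("H", "h")`) merges them into one
#' class, since membership is tested per position.
#'
#' @param labels Topology label string (six-state alphabet).
#' @param classes Character vector of label letters defining the class.
#' @return Data frame with integer columns `start`, `end`, sorted and
#'   non-overlapping; zero rows when no position matches.
#' @examples
#' annotation_segments("22HHH11hh2", c("H", "h"))
#' @export
annotation_segments <- function(labels, classes = c("H", "h")) {
  stopifnot(is.character(labels), length(labels) == 1L, length(classes) >= 1L)
  chars <- strsplit(labels, "")[[1]]
  member <- chars %in% classes
  if (!any(member))
    return(data.frame(start = integer(), end = integer()))
  r <- rle(member)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}
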
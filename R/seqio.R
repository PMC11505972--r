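#' @importFrom rlang abort
#' @importFrom tibble tibble
NULL

# IUPAC nucleotide alphabet accepted on input. Anything outside A/C/G/T is
# treated as a mismatch during alignment matching, but tolerated here because
# Sanger base callers routinely emit ambiguity codes.
IUPAC_DNA <- c("A", "C", "G", "T", "N",
               "M", "R", "W", "S", "Y", "K", "V", "H", "D", "B")

abort_io <- function(msg, ...) {
  abort(msg, class = c("sangerstitch_io_error", "sangerstitch_error"), ...)
}

abort_usage <- function(msg, ...) {
  abort(msg, class = c("sangerstitch_usage_error", "sangerstitch_error"), ...)
}

#' Normalize raw sequence text
#'
#' Uppercases and strips whitespace, line breaks, and digits (so sequence text
#' copied from numbered viewers is tolerated), then validates that every
#' remaining character is an IUPAC nucleotide code.
#'
#' @param x Character scalar of raw sequence text.
#' @param path Optional source path, used in error messages.
#' @return A normalized sequence string.
#' @examples
#' normalize_sequence("ac gt\n10 ACGT")
#' @export
normalize_sequence <- function(x, path = NULL) {
  stopifnot(is.character(x))
  x <- toupper(gsub("[[:space:][:digit:]]", "", paste(x, collapse = "")))
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  bad <- which(!(chars %in% IUPAC_DNA))
  if (length(bad) > 0) {
    where <- if (is.null(path)) "sequence" else paste0("'", path, "'")
    abort_io(sprintf(
      "invalid character '%s' at position %d in %s (expected IUPAC DNA codes)",
      chars[bad[1]], bad[1], where))
  }
  x
}

infer_format <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) > 0 && startsWith(first, ">")) "fasta" else "txt"
}

#' Read a single DNA sequence from a plain-text file
#'
#' Supports the three dialects produced by sequencing facilities and common
#' editors: `fasta` (single record; header discarded), and `seq`/`txt` (bare
#' sequence text, possibly wrapped or numbered). `auto` infers fasta from a
#' leading `>`.
#'
#' @param path Path to the sequence file.
#' @param format One of `"auto"`, `"seq"`, `"fasta"`, `"txt"`.
#' @return A normalized sequence string (uppercase, whitespace/digits removed).
#' @seealso [write_sequence()], [read_sanger_reads()]
#' @export
read_sequence <- function(path, format = c("auto", "seq", "fasta", "txt")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort_io(sprintf("cannot read sequence file '%s': no such file", path))
  }
  lines <- readLines(path, warn = FALSE)
  if (format == "auto") {
    format <- if (length(lines) > 0 && startsWith(lines[1], ">")) "fasta" else "txt"
  }
  if (format == "fasta") {
    headers <- which(startsWith(lines, ">"))
    if (length(headers) > 1) {
      abort_io(sprintf(
        "multi-record fasta in '%s': %d records found, exactly one expected",
        path, length(headers)))
    }
    if (length(headers) == 1) lines <- lines[-headers]
  }
  seq <- normalize_sequence(paste(lines, collapse = ""), path = path)
  if (nchar(seq) == 0) {
    abort_io(sprintf("empty sequence in '%s' after normalization", path))
  }
  seq
}

#' Write a DNA sequence to a plain-text file
#'
#' `fasta` output gets a single header line derived from the file stem and the
#' sequence wrapped at 60 columns; `seq` and `txt` output the bare sequence
#' with a single trailing newline. [read_sequence()] round-trips all three.
#'
#' @param seq Sequence string (non-empty).
#' @param path Output path.
#' @param format One of `"seq"`, `"fasta"`, `"txt"`.
#' @param name Header name for fasta output; defaults to the file stem.
#' @return `path`, invisibly.
#' @export
write_sequence <- function(seq, path, format = c("seq", "fasta", "txt"),
                           name = NULL) {
  format <- match.arg(format)
  stopifnot(is.character(seq), length(seq) == 1)
  if (nchar(seq) == 0) abort_io("refusing to write an empty sequence")
  lines <- if (format == "fasta") {
    if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
    c(paste0(">", name), wrap_sequence(seq, 60L))
  } else {
    seq
  }
  tryCatch(writeLines(lines, path),
           error = function(e) abort_io(sprintf(
             "cannot write sequence to '%s': %s", path, conditionMessage(e))))
  invisible(path)
}

wrap_sequence <- function(seq, width) {
  n <- nchar(seq)
  starts <- seq.int(1L, n, by = width)
  substring(seq, starts, pmin(starts + width - 1L, n))
}

#' Reverse complement
#'
#' Watson-Crick complement in reversed order; IUPAC ambiguity codes are
#' complemented by Biostrings (N stays N). An involution: applying it twice
#' returns the input.
#'
#' @param seq Sequence string over the IUPAC alphabet.
#' @return The reverse-complemented sequence string.
#' @examples
#' reverse_complement("AACG") # "CGTT"
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1)
  if (nchar(seq) == 0) return(seq)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Read an ordered set of Sanger reads into a tibble
#'
#' The order of `paths` is the merge order (the order walking primers were
#' designed); each read carries its sequencing direction, `"F"` (forward) or
#' `"R"` (reverse).
#'
#' @param paths Character vector of sequence file paths, in merge order.
#' @param directions Character vector of `"F"`/`"R"`, one per path.
#' @param format Input format passed to [read_sequence()].
#' @return A tibble with columns `source`, `direction`, `sequence`, `length`,
#'   one row per read in order.
#' @export
read_sanger_reads <- function(paths, directions,
                              format = c("auto", "seq", "fasta", "txt")) {
  format <- match.arg(format)
  if (length(paths) != length(directions)) {
    abort_usage("`paths` and `directions` must have the same length")
  }
  directions <- validate_directions(directions)
  seqs <- vapply(paths, read_sequence, character(1), format = format,
                 USE.NAMES = FALSE)
  tibble(source = as.character(paths), direction = directions,
         sequence = seqs, length = nchar(seqs))
}

validate_directions <- function(directions) {
  directions <- toupper(as.character(directions))
  bad <- which(!(directions %in% c("F", "R")))
  if (length(bad) > 0) {
    abort_usage(sprintf(
      "direction must be 'F' or 'R', got '%s' for read %d",
      directions[bad[1]], bad[1]))
  }
  directions
}
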
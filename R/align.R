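#' Affine-gap scoring scheme for global alignment
#'
#' Defaults mirror the EMBOSS needle DNA defaults (EDNAFULL-like): match +5,
#' mismatch -4, gap opening 10, gap extension 0.5, end gaps free. A gap of
#' length L costs `gap_open + (L - 1) * gap_extend` (the opening penalty
#' covers the first gapped position), the convention used by needle and by
#' Biopython's PairwiseAligner.
#'
#' End gaps — the unaligned overhangs where one read extends past the other —
#' are not penalized by default, matching needle's `endweight=false` default.
#' This matters for overlap detection: walking reads share only a terminal
#' overlap, and penalizing their long overhangs rewards alignments that
#' scatter the overlap into a mosaic of short gapped segments instead of one
#' contiguous block.
#'
#' @param match Score for an identical A/C/G/T pair (must exceed `mismatch`).
#' @param mismatch Score for any other residue pair, including pairs involving
#'   ambiguity codes.
#' @param gap_open Penalty (non-negative) for opening a gap.
#' @param gap_extend Penalty (non-negative, at most `gap_open`) per additional
#'   gapped position.
#' @param penalize_end_gaps If `TRUE`, leading/trailing gaps are charged like
#'   interior gaps (needle's `endweight=true`).
#' @return A `scoring_scheme` object.
#' @export
scoring_scheme <- function(match = 5, mismatch = -4,
                           gap_open = 10, gap_extend = 0.5,
                           penalize_end_gaps = FALSE) {
  stopifnot(is.numeric(match), is.numeric(mismatch),
            is.numeric(gap_open), is.numeric(gap_extend),
            is.logical(penalize_end_gaps), length(penalize_end_gaps) == 1)
  if (match <= mismatch) abort_usage("match score must exceed mismatch score")
  if (gap_open < gap_extend || gap_extend < 0) {
    abort_usage("need gap_open >= gap_extend >= 0")
  }
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend,
                 penalize_end_gaps = penalize_end_gaps),
            class = "scoring_scheme")
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat(sprintf("<scoring_scheme> match %+g, mismatch %+g, gap open %g, gap extend %g, end gaps %s\n",
              x$match, x$mismatch, x$gap_open, x$gap_extend,
              if (x$penalize_end_gaps) "penalized" else "free"))
  invisible(x)
}

# Substitution matrix over the IUPAC alphabet: +match only for identical
# A/C/G/T pairs; everything else (including N vs N) scores as mismatch.
iupac_substitution_matrix <- function(scoring) {
  ab <- IUPAC_DNA
  mat <- matrix(scoring$mismatch, length(ab), length(ab),
                dimnames = list(ab, ab))
  for (b in c("A", "C", "G", "T")) mat[b, b] <- scoring$match
  mat
}

match_line_of <- function(ga, gb) {
  a <- strsplit(ga, "", fixed = TRUE)[[1]]
  b <- strsplit(gb, "", fixed = TRUE)[[1]]
  out <- rep(".", length(a))
  out[a == "-" | b == "-"] <- " "
  out[a == b & a %in% c("A", "C", "G", "T")] <- "|"
  paste(out, collapse = "")
}

#' Global (Needleman-Wunsch) pairwise alignment
#'
#' End-to-end optimal alignment of two sequences under an affine-gap scoring
#' scheme, computed by Biostrings' dynamic-programming aligner. With the
#' default scheme end gaps are free (see [scoring_scheme()]), so the alignment
#' spans both sequences in full but unaligned overhangs cost nothing — the
#' needle-default behavior that keeps a terminal overlap in one contiguous
#' block. Tie-breaking among co-optimal alignments follows Biostrings'
#' deterministic traceback, so identical inputs always yield identical
#' alignments.
#'
#' @param a,b Sequence strings (non-empty, IUPAC alphabet).
#' @param scoring A [scoring_scheme()].
#' @return A `pairwise_alignment` object: gapped rows `gapped_a`/`gapped_b`, a
#'   `match_line` over `|` (identity), `.` (mismatch), and space (gap), the
#'   alignment `score`, and identity/gap statistics. Columns where either
#'   residue is not a plain A/C/G/T count as mismatches.
#' @examples
#' aln <- global_align("AAAAACCCCC", "CCCCCGGGGG")
#' glance(aln)
#' @export
global_align <- function(a, b, scoring = scoring_scheme()) {
  stopifnot(inherits(scoring, "scoring_scheme"))
  for (s in list(a, b)) {
    if (!is.character(s) || length(s) != 1 || nchar(s) == 0) {
      abort_usage("global_align requires two non-empty sequence strings")
    }
  }
  a <- toupper(a); b <- toupper(b)
  aln <- Biostrings::pairwiseAlignment(
    a, b,
    type = if (scoring$penalize_end_gaps) "global" else "overlap",
    substitutionMatrix = iupac_substitution_matrix(scoring),
    gapOpening = scoring$gap_open - scoring$gap_extend,
    gapExtension = scoring$gap_extend)
  if (scoring$penalize_end_gaps) {
    ga <- as.character(Biostrings::alignedPattern(aln))
    gb <- as.character(Biostrings::alignedSubject(aln))
  } else {
    # ends-free mode: Biostrings reports only the aligned core; reattach the
    # unaligned overhangs as free end-gap columns so the full inputs are
    # recoverable from the gapped rows
    core_a <- as.character(Biostrings::alignedPattern(aln))
    core_b <- as.character(Biostrings::alignedSubject(aln))
    pr <- Biostrings::pattern(aln); sr <- Biostrings::subject(aln)
    a_left <- substr(a, 1, BiocGenerics::start(pr) - 1)
    a_right <- substr(a, BiocGenerics::end(pr) + 1, nchar(a))
    b_left <- substr(b, 1, BiocGenerics::start(sr) - 1)
    b_right <- substr(b, BiocGenerics::end(sr) + 1, nchar(b))
    ga <- paste0(a_left, strrep("-", nchar(b_left)), core_a,
                 a_right, strrep("-", nchar(b_right)))
    gb <- paste0(strrep("-", nchar(a_left)), b_left, core_b,
                 strrep("-", nchar(a_right)), b_right)
  }
  new_pairwise_alignment(ga, gb, Biostrings::score(aln), scoring)
}

new_pairwise_alignment <- function(gapped_a, gapped_b, score, scoring) {
  ml <- match_line_of(gapped_a, gapped_b)
  cols <- strsplit(ml, "", fixed = TRUE)[[1]]
  len <- length(cols)
  id <- sum(cols == "|")
  gaps <- sum(cols == " ")
  structure(list(
    gapped_a = gapped_a, gapped_b = gapped_b, match_line = ml,
    score = score, identity_count = id,
    identity_pct = 100 * id / len, gap_count = gaps,
    alignment_length = len, scoring = scoring),
    class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("<pairwise_alignment> length %d, identity %d/%d (%.1f%%), gaps %d, score %.1f\n",
              x$alignment_length, x$identity_count, x$alignment_length,
              x$identity_pct, x$gap_count, x$score))
  invisible(x)
}

#' Alignment summary statistics
#'
#' @param aln A `pairwise_alignment`.
#' @return A one-row tibble with `identity_pct`, `identity_count`,
#'   `gap_count`, `alignment_length`, and `score`.
#' @export
alignment_stats <- function(aln) {
  stopifnot(inherits(aln, "pairwise_alignment"))
  tibble(identity_pct = aln$identity_pct,
         identity_count = aln$identity_count,
         gap_count = aln$gap_count,
         alignment_length = aln$alignment_length,
         score = aln$score)
}

#' @rdname alignment_stats
#' @param x A `pairwise_alignment`.
#' @param ... Unused.
#' @export
glance.pairwise_alignment <- function(x, ...) alignment_stats(x)

#' Per-column view of a pairwise alignment
#'
#' @param x A `pairwise_alignment`.
#' @param ... Unused.
#' @return A tibble with one row per alignment column: `column` (1-based),
#'   residues `a` and `b`, the `match` character, and the 1-based ungapped
#'   positions `a_pos`/`b_pos` (NA at gap columns).
#' @export
tidy.pairwise_alignment <- function(x, ...) {
  a <- strsplit(x$gapped_a, "", fixed = TRUE)[[1]]
  b <- strsplit(x$gapped_b, "", fixed = TRUE)[[1]]
  m <- strsplit(x$match_line, "", fixed = TRUE)[[1]]
  a_pos <- cumsum(a != "-"); a_pos[a == "-"] <- NA_integer_
  b_pos <- cumsum(b != "-"); b_pos[b == "-"] <- NA_integer_
  tibble(column = seq_along(a), a = a, b = b, match = m,
         a_pos = as.integer(a_pos), b_pos = as.integer(b_pos))
}

#' Locate the first run of n consecutive matching bases
#'
#' Scans the alignment's match line for the leftmost window of `n` consecutive
#' identity columns. Because a run of matches contains no gaps, the window's
#' span is `n` in alignment space and in both ungapped sequences. A run broken
#' by a single gap or mismatch does not qualify.
#'
#' @param aln A `pairwise_alignment`.
#' @param n Required run length (>= 1).
#' @return A `match_run` with 0-based half-open coordinates (`aln_start`,
#'   `aln_end`, `a_start`, `a_end`, `b_start`, `b_end`), or `NULL` if no such
#'   window exists.
#' @export
find_n_consecutive <- function(aln, n) {
  stopifnot(inherits(aln, "pairwise_alignment"))
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < 1 || n != floor(n)) {
    abort_usage("`n` must be a single integer >= 1")
  }
  n <- as.integer(n)
  cols <- strsplit(aln$match_line, "", fixed = TRUE)[[1]]
  r <- rle(cols == "|")
  ends <- cumsum(r$lengths)
  hit <- which(r$values & r$lengths >= n)
  if (length(hit) == 0) return(NULL)
  aln_start <- ends[hit[1]] - r$lengths[hit[1]]  # 0-based start of the run
  a_chars <- strsplit(aln$gapped_a, "", fixed = TRUE)[[1]]
  b_chars <- strsplit(aln$gapped_b, "", fixed = TRUE)[[1]]
  a_start <- sum(a_chars[seq_len(aln_start)] != "-")
  b_start <- sum(b_chars[seq_len(aln_start)] != "-")
  structure(list(n = n,
                 aln_start = aln_start, aln_end = aln_start + n,
                 a_start = a_start, a_end = a_start + n,
                 b_start = b_start, b_end = b_start + n),
            class = "match_run")
}

longest_match_run <- function(aln) {
  r <- rle(strsplit(aln$match_line, "", fixed = TRUE)[[1]] == "|")
  if (!any(r$values)) 0L else max(r$lengths[r$values])
}

#' @export
print.match_run <- function(x, ...) {
  cat(sprintf("<match_run> %d consecutive matches at alignment column %d (a %d-%d, b %d-%d, 0-based)\n",
              x$n, x$aln_start, x$a_start, x$a_end, x$b_start, x$b_end))
  invisible(x)
}

#' Format an alignment as an EMBOSS needle (srspair) style report
#'
#' Plain-text report with a `#`-prefixed header (sequence names, scoring,
#' Length/Identity/Gaps/Score statistics) followed by 50-column alignment
#' blocks. Coordinates in the blocks are 1-based inclusive ungapped positions,
#' the needle convention; gap characters do not advance them.
#'
#' @param aln A `pairwise_alignment`.
#' @param name_a,name_b Display names for the two sequences.
#' @param scoring The [scoring_scheme()] used (defaults to the one stored in
#'   the alignment).
#' @return The report as a single character string.
#' @export
format_needle_srspair <- function(aln, name_a = "seq_a", name_b = "seq_b",
                                  scoring = aln$scoring) {
  stopifnot(inherits(aln, "pairwise_alignment"))
  len <- aln$alignment_length
  pct <- function(k) sprintf("%4.1f", 100 * k / len)
  stat_line <- function(label, k) {
    sprintf("%-18s%d/%d (%s%%)", label, k, len, pct(k))
  }
  header <- c(
    "########################################",
    "# Program: sangerstitch",
    paste0("# Rundate: ", format(Sys.time(), "%a %d %b %Y %H:%M:%S")),
    "# Align_format: srspair",
    "########################################",
    "",
    "#=======================================",
    "#",
    "# Aligned_sequences: 2",
    paste0("# 1: ", name_a),
    paste0("# 2: ", name_b),
    sprintf("# Matrix: match %+g / mismatch %+g", scoring$match, scoring$mismatch),
    sprintf("# Gap_penalty: %.1f", scoring$gap_open),
    sprintf("# Extend_penalty: %.1f", scoring$gap_extend),
    "#",
    sprintf("# Length: %d", len),
    stat_line("# Identity:", aln$identity_count),
    stat_line("# Gaps:", aln$gap_count),
    sprintf("# Score: %.1f", aln$score),
    "#",
    "#=======================================",
    "")
  paste(c(header, srspair_blocks(aln, name_a, name_b), ""), collapse = "\n")
}

srspair_blocks <- function(aln, name_a, name_b, width = 50L) {
  a <- strsplit(aln$gapped_a, "", fixed = TRUE)[[1]]
  b <- strsplit(aln$gapped_b, "", fixed = TRUE)[[1]]
  m <- strsplit(aln$match_line, "", fixed = TRUE)[[1]]
  len <- length(a)
  # truncate names as needle does so columns stay aligned
  nm_a <- substr(name_a, 1, 13); nm_b <- substr(name_b, 1, 13)
  starts <- seq.int(1L, len, by = width)
  a_done <- 0L; b_done <- 0L
  out <- character(0)
  for (s in starts) {
    e <- min(s + width - 1L, len)
    a_blk <- a[s:e]; b_blk <- b[s:e]
    a_n <- sum(a_blk != "-"); b_n <- sum(b_blk != "-")
    a_from <- if (a_n > 0) a_done + 1L else a_done
    b_from <- if (b_n > 0) b_done + 1L else b_done
    a_done <- a_done + a_n; b_done <- b_done + b_n
    out <- c(out,
      sprintf("%-13s %6d %s %6d", nm_a, a_from, paste(a_blk, collapse = ""), a_done),
      sprintf("%-13s %6s %s", "", "", paste(m[s:e], collapse = "")),
      sprintf("%-13s %6d %s %6d", nm_b, b_from, paste(b_blk, collapse = ""), b_done),
      "")
  }
  out
}

#' Plot identity along a pairwise alignment
#'
#' Fraction of identity columns in sliding windows along the alignment, with
#' gap columns marked as a rug. Useful for eyeballing where two reads agree
#' and where their overlap sits.
#'
#' @param object A `pairwise_alignment`.
#' @param window Window width in alignment columns.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pairwise_alignment <- function(object, window = 25L, ...) {
  d <- tidy(object)
  is_id <- as.integer(d$match == "|")
  k <- min(window, nrow(d))
  frac <- stats::filter(is_id, rep(1 / k, k), sides = 2)
  df <- tibble(column = d$column, identity = as.numeric(frac))
  gaps <- d[d$match == " ", , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$column, y = .data$identity)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_rug(data = gaps, ggplot2::aes(x = .data$column),
                      inherit.aes = FALSE, sides = "b", alpha = 0.5) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "alignment column",
                  y = sprintf("identity (window = %d)", k)) +
    ggplot2::theme_minimal()
}
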
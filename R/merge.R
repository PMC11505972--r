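#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
#' @importFrom rlang .data
NULL

abort_overlap <- function(msg, ...) {
  abort(msg, class = c("sangerstitch_overlap_error", "sangerstitch_error"), ...)
}

MIN_CONSECUTIVE <- 10L
MAX_CONSECUTIVE <- 1000L

#' Merge parameters
#'
#' @param consecutive_matches Length n of the first uninterrupted run of
#'   identical aligned bases required to declare the overlap between two
#'   adjacent reads (default 50; allowed range 10-1000). Lower it (e.g. to 35
#'   or 40) to rescue pairs whose true overlap is shorter than 50 bases.
#' @param scoring A [scoring_scheme()].
#' @return A `merge_params` object.
#' @export
merge_params <- function(consecutive_matches = 50L,
                         scoring = scoring_scheme()) {
  n <- check_and_convert(consecutive_matches)
  stopifnot(inherits(scoring, "scoring_scheme"))
  structure(list(consecutive_matches = n, scoring = scoring),
            class = "merge_params")
}

#' Validate the Consecutive Matches parameter
#'
#' Parses and range-checks the run-length parameter n: a positive integer in
#' \[10, 1000\]. Below ~10, spurious runs between unrelated ~700-base reads
#' become probable, so shorter values are rejected.
#'
#' @param raw_value The raw value (string or number).
#' @return The validated integer n.
#' @export
check_and_convert <- function(raw_value) {
  n <- suppressWarnings(as.numeric(raw_value))
  if (length(n) != 1 || is.na(n) || n != floor(n)) {
    abort_usage(sprintf(
      "Consecutive Matches must be an integer, got '%s'", as.character(raw_value)))
  }
  if (n < MIN_CONSECUTIVE || n > MAX_CONSECUTIVE) {
    abort_usage(sprintf(
      "Consecutive Matches must be between %d and %d, got %d",
      MIN_CONSECUTIVE, MAX_CONSECUTIVE, as.integer(n)))
  }
  as.integer(n)
}

#' Check that a read set is large enough to merge
#'
#' @param reads A data frame of reads (one row per read).
#' @return `reads`, invisibly, if at least two reads are present.
#' @export
check_file_list_count <- function(reads) {
  k <- if (is.data.frame(reads)) nrow(reads) else length(reads)
  if (k < 2) {
    abort_usage(sprintf(
      "need at least two sequence files to merge, got %d", k))
  }
  invisible(reads)
}

#' Convert all reads to the forward strand
#'
#' Reads flagged `R` are reverse-complemented so that every read is collinear
#' with the target sequence; order is preserved.
#'
#' @param reads A data frame with columns `sequence` and `direction`.
#' @return `reads` with an added character column `forward`.
#' @export
forwardize <- function(reads) {
  stopifnot(is.data.frame(reads),
            all(c("sequence", "direction") %in% names(reads)))
  dirs <- validate_directions(reads$direction)
  fwd <- ifelse(dirs == "F", reads$sequence,
                vapply(reads$sequence, reverse_complement, character(1),
                       USE.NAMES = FALSE))
  dplyr::mutate(tibble::as_tibble(reads), forward = fwd)
}

#' Align an adjacent pair and derive its splice boundary
#'
#' Globally aligns the forwardized previous and next reads, locates the first
#' run of n consecutive matching bases, and converts the run into splice
#' coordinates: the previous read contributes everything up to and including
#' the run (`prev_cut = run end in prev`), the next read contributes from its
#' run end onward (`next_cut = run end in next`). The overlap run is thus
#' taken once, from the previous read; inside the run the two reads are
#' identical, so the choice of donor is observationally neutral.
#'
#' @param prev,nxt Forwardized sequence strings.
#' @param params A [merge_params()].
#' @param prev_name,next_name Display names used in errors and reports.
#' @return A `boundary_pair`: `prev_cut`, `next_cut` (0-based; `prev_cut`
#'   exclusive end in prev, `next_cut` inclusive start in next), the
#'   `match_run`, and the underlying `pairwise_alignment`.
#' @export
align_to_get_boundaries <- function(prev, nxt, params = merge_params(),
                                    prev_name = "prev", next_name = "next") {
  stopifnot(inherits(params, "merge_params"))
  n <- params$consecutive_matches
  if (nchar(prev) < n || nchar(nxt) < n) {
    abort_usage(sprintf(
      "both sequences must be at least n = %d bases long (%s: %d, %s: %d)",
      n, prev_name, nchar(prev), next_name, nchar(nxt)))
  }
  aln <- global_align(prev, nxt, params$scoring)
  run <- find_n_consecutive(aln, n)
  if (is.null(run)) {
    abort_overlap(sprintf(
      paste0("insufficient overlap between '%s' and '%s': no run of %d ",
             "consecutive matching bases (longest observed: %d); if these ",
             "reads do overlap, lower the Consecutive Matches parameter ",
             "(e.g. to 35 or 40)"),
      prev_name, next_name, n, longest_match_run(aln)))
  }
  structure(list(prev_cut = run$a_end, next_cut = run$b_end,
                 run = run, alignment = aln,
                 prev_name = prev_name, next_name = next_name),
            class = "boundary_pair")
}

#' @export
print.boundary_pair <- function(x, ...) {
  cat(sprintf("<boundary_pair> %s[..%d) + %s[%d..) via %d-match run\n",
              x$prev_name, x$prev_cut, x$next_name, x$next_cut, x$run$n))
  invisible(x)
}

#' Splice forwardized reads at their boundaries
#'
#' Iteratively concatenates `forward_seqs[[1]][1:prev_cut_1]` with each
#' following read from its `next_cut` onward, so each overlap region appears
#' exactly once in the merged sequence.
#'
#' @param forward_seqs Character vector of forwardized sequences, in order.
#' @param boundaries A data frame with columns `prev_cut`/`next_cut` (0-based,
#'   as produced by [align_to_get_boundaries()]), or a list of
#'   `boundary_pair` objects; one per adjacent pair.
#' @return The merged sequence string.
#' @export
splice <- function(forward_seqs, boundaries) {
  if (is.data.frame(boundaries)) {
    prev_cut <- boundaries$prev_cut; next_cut <- boundaries$next_cut
  } else {
    prev_cut <- vapply(boundaries, `[[`, numeric(1), "prev_cut")
    next_cut <- vapply(boundaries, `[[`, numeric(1), "next_cut")
  }
  k <- length(forward_seqs)
  if (length(prev_cut) != k - 1) {
    abort_usage(sprintf("expected %d boundaries for %d reads, got %d",
                        k - 1, k, length(prev_cut)))
  }
  for (i in seq_len(k - 1)) {
    if (prev_cut[i] < 1 || prev_cut[i] > nchar(forward_seqs[i]) ||
        next_cut[i] < 0 || next_cut[i] > nchar(forward_seqs[i + 1])) {
      abort(sprintf("boundary %d out of range for its sequences", i),
            class = c("sangerstitch_internal_error", "sangerstitch_error"))
    }
  }
  merged <- substr(forward_seqs[1], 1, prev_cut[1])
  for (i in seq_len(k - 1)) {
    piece <- substring(forward_seqs[i + 1], next_cut[i] + 1)
    if (i < k - 1) piece <- substr(piece, 1, prev_cut[i + 1] - next_cut[i])
    merged <- paste0(merged, piece)
  }
  merged
}

read_display_names <- function(reads) {
  if ("source" %in% names(reads)) {
    nm <- sub("\\.[^.]*$", "", basename(reads$source))
  } else {
    nm <- sprintf("read_%d", seq_len(nrow(reads)))
  }
  make.unique(nm, sep = "_")
}

#' Merge an ordered set of Sanger walking reads
#'
#' The pipeline core: validates the read set, forwardizes reverse reads,
#' globally aligns each adjacent pair in input order, locates the first run of
#' `consecutive_matches` identical aligned bases to define each splice
#' boundary, and stitches the full-length sequence. The read order is the
#' experimental walking order supplied by the user; it is never inferred.
#'
#' @param reads A data frame with columns `sequence` and `direction` (`"F"` or
#'   `"R"`), optionally `source` (used for display names); one row per read in
#'   merge order. Typically from [read_sanger_reads()] or
#'   [simulate_walking_reads()].
#' @param consecutive_matches Run length n (default 50); see [merge_params()].
#' @param scoring A [scoring_scheme()].
#' @return A `sanger_merge` object with components `merged` (the sequence
#'   string), `boundaries` (tibble, one row per adjacent pair), `forwardized`,
#'   `alignments`, `reports` (srspair texts), `log_text`, `reads`, `params`.
#'   Use [tidy()] for the boundary table, [glance()] for a one-row summary,
#'   and [autoplot()] for a read-layout sketch.
#' @examples
#' reads <- tibble::tibble(
#'   sequence = c("AAAAACCCCCGGGGG", "CCCCCGGGGGTTTTT"),
#'   direction = c("F", "F"))
#' fit <- merge_sanger(reads, consecutive_matches = 10)
#' fit$merged
#' @export
merge_sanger <- function(reads, consecutive_matches = 50L,
                         scoring = scoring_scheme()) {
  params <- if (inherits(consecutive_matches, "merge_params")) {
    consecutive_matches
  } else {
    merge_params(consecutive_matches, scoring)
  }
  stopifnot(is.data.frame(reads))
  check_file_list_count(reads)
  if (!all(c("sequence", "direction") %in% names(reads))) {
    abort_usage("`reads` must have columns `sequence` and `direction`")
  }
  log <- character(0)
  note <- function(fmt, ...) {
    log <<- c(log, paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S  "),
                          sprintf(fmt, ...)))
  }
  nm <- read_display_names(reads)
  note("merging %d reads, Consecutive Matches = %d", nrow(reads),
       params$consecutive_matches)
  for (i in seq_len(nrow(reads))) {
    src <- if ("source" %in% names(reads)) reads$source[i] else "<in-memory>"
    note("read %d (%s, %s): %s [%d bases]", i, nm[i], reads$direction[i],
         src, nchar(reads$sequence[i]))
  }
  reads_f <- forwardize(reads)
  note("forwardized %d reverse read(s)", sum(reads_f$direction == "R"))

  k <- nrow(reads_f)
  pairs <- vector("list", k - 1)
  for (i in seq_len(k - 1)) {
    bp <- withCallingHandlers(
      align_to_get_boundaries(reads_f$forward[i], reads_f$forward[i + 1],
                              params, nm[i], nm[i + 1]),
      sangerstitch_overlap_error = function(e) {
        note("pair %d (%s vs %s): FAILED: %s", i, nm[i], nm[i + 1],
             conditionMessage(e))
      })
    aln <- bp$alignment
    note(paste0("pair %d (%s vs %s): identity %d/%d (%.1f%%), gaps %d, ",
                "run at alignment column %d, prev_cut %d, next_cut %d"),
         i, nm[i], nm[i + 1], aln$identity_count, aln$alignment_length,
         aln$identity_pct, aln$gap_count, bp$run$aln_start, bp$prev_cut,
         bp$next_cut)
    pairs[[i]] <- bp
  }

  boundaries <- purrr::map_dfr(seq_along(pairs), function(i) {
    bp <- pairs[[i]]; aln <- bp$alignment
    tibble(pair = i, prev_name = bp$prev_name, next_name = bp$next_name,
           prev_cut = bp$prev_cut, next_cut = bp$next_cut,
           run_aln_start = bp$run$aln_start,
           run_a_start = bp$run$a_start, run_b_start = bp$run$b_start,
           identity_pct = aln$identity_pct, identity_count = aln$identity_count,
           gap_count = aln$gap_count, alignment_length = aln$alignment_length,
           score = aln$score)
  })

  merged <- splice(reads_f$forward, boundaries)
  note("merged sequence length: %d", nchar(merged))
  note("merged sequence:")
  log <- c(log, wrap_sequence(merged, 60L))

  reports <- vapply(pairs, function(bp) {
    format_needle_srspair(bp$alignment, bp$prev_name, bp$next_name,
                          params$scoring)
  }, character(1))

  structure(list(merged = merged, boundaries = boundaries,
                 forwardized = reads_f$forward, alignments =
                   lapply(pairs, `[[`, "alignment"),
                 reports = reports, log_text = paste(log, collapse = "\n"),
                 reads = reads_f, read_names = nm, params = params),
            class = "sanger_merge")
}

#' @export
print.sanger_merge <- function(x, ...) {
  cat(sprintf("<sanger_merge> %d reads -> %d bases (n = %d)\n",
              nrow(x$reads), nchar(x$merged), x$params$consecutive_matches))
  print(x$boundaries[, c("pair", "prev_name", "next_name", "prev_cut",
                         "next_cut", "identity_pct", "gap_count")])
  invisible(x)
}

#' Tidy the splice boundaries of a merge
#'
#' @param x A `sanger_merge`.
#' @param ... Unused.
#' @return The boundary tibble: one row per adjacent pair with splice cuts
#'   (0-based: `prev_cut` is the exclusive end of the previous read's
#'   contribution, `next_cut` the inclusive start of the next read's),
#'   match-run coordinates, and per-pair alignment statistics.
#' @export
tidy.sanger_merge <- function(x, ...) x$boundaries

#' One-row summary of a merge
#'
#' @param x A `sanger_merge`.
#' @param ... Unused.
#' @return A one-row tibble: read count, merged length, the n used, and the
#'   worst per-pair identity observed.
#' @export
glance.sanger_merge <- function(x, ...) {
  tibble(n_reads = nrow(x$reads), merged_length = nchar(x$merged),
         consecutive_matches = x$params$consecutive_matches,
         min_pair_identity_pct = min(x$boundaries$identity_pct),
         total_gap_columns = sum(x$boundaries$gap_count))
}

#' Sketch the layout of merged reads
#'
#' Draws each forwardized read as a horizontal segment at its position in the
#' merged sequence, with the spliced contribution emphasised, so overlaps and
#' cut points are visible at a glance.
#'
#' @param object A `sanger_merge`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sanger_merge <- function(object, ...) {
  k <- length(object$forwardized)
  lens <- nchar(object$forwardized)
  offset <- c(0, cumsum(object$boundaries$prev_cut -
                          object$boundaries$next_cut))
  contrib_from <- c(0, object$boundaries$next_cut)
  contrib_to <- c(object$boundaries$prev_cut, lens[k])
  d <- tibble(
    read = factor(object$read_names, levels = rev(object$read_names)),
    start = offset, end = offset + lens,
    used_from = offset + contrib_from, used_to = offset + contrib_to)
  ggplot2::ggplot(d, ggplot2::aes(y = .data$read)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$start, xend = .data$end,
                                       yend = .data$read),
                          linewidth = 1, alpha = 0.35) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$used_from,
                                       xend = .data$used_to,
                                       yend = .data$read),
                          linewidth = 3) +
    ggplot2::labs(x = "position in merged sequence (bases)", y = NULL,
                  title = sprintf("%d reads merged into %d bases",
                                  k, nchar(object$merged))) +
    ggplot2::theme_minimal()
}

#' Write the run artifacts of a merge
#'
#' Creates a folder named `merged_sequence` plus a `YYYYMMDDHHMMSS` timestamp
#' inside `first_input_dir` and writes the run log, one forwardized sequence
#' per read, one srspair alignment report per adjacent pair
#' (`<prev>_vs_<next>.needle`), and the merged sequence (`merged.seq`, seq
#' format). If the folder already exists (two runs within one second), a
#' `_1`, `_2`, ... suffix is appended rather than overwriting.
#'
#' @param result A `sanger_merge`.
#' @param first_input_dir Directory receiving the run folder; conventionally
#'   the directory of the first input file.
#' @param clock Timestamp for the folder name (default now).
#' @return The created directory path, invisibly.
#' @export
write_run_artifacts <- function(result, first_input_dir,
                                clock = Sys.time()) {
  stopifnot(inherits(result, "sanger_merge"))
  if (!dir.exists(first_input_dir)) {
    abort_io(sprintf("output directory '%s' does not exist", first_input_dir))
  }
  stamp <- format(clock, "%Y%m%d%H%M%S")
  base <- file.path(first_input_dir, paste0("merged_sequence", stamp))
  out <- base
  i <- 0
  while (dir.exists(out)) {
    i <- i + 1
    out <- paste0(base, "_", i)
  }
  if (!dir.create(out, recursive = TRUE)) {
    abort_io(sprintf("cannot create output folder '%s'", out))
  }
  writeLines(result$log_text, file.path(out, "log.txt"))
  for (j in seq_along(result$forwardized)) {
    write_sequence(result$forwardized[j],
                   file.path(out, sprintf("%s_forwardized.seq",
                                          result$read_names[j])),
                   format = "seq")
  }
  b <- result$boundaries
  for (j in seq_along(result$reports)) {
    writeLines(result$reports[j],
               file.path(out, sprintf("%s_vs_%s.needle",
                                      b$prev_name[j], b$next_name[j])))
  }
  write_sequence(result$merged, file.path(out, "merged.seq"), format = "seq")
  invisible(out)
}
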
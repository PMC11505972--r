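# Synthetic walking-sequencing data with ground truth, so every pipeline
# property is testable without real trace files.

with_seed_ <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Generate a uniform random reference sequence
#'
#' Bases drawn i.i.d. uniformly over A/C/G/T; the same seed always yields the
#' same sequence, and the caller's RNG state is left untouched.
#'
#' @param length Reference length in bases (>= 1).
#' @param seed Integer seed (optional; without it the current RNG stream is
#'   used).
#' @return The reference sequence string.
#' @export
random_reference <- function(length, seed = NULL) {
  if (!is.numeric(length) || length < 1) {
    abort_usage("reference length must be >= 1")
  }
  with_seed_(seed, paste(
    sample(c("A", "C", "G", "T"), as.integer(length), replace = TRUE),
    collapse = ""))
}

#' Simulate a Sanger primer-walking read set
#'
#' Tiles a reference with reads of `read_length` whose consecutive overlaps
#' are drawn uniformly from `overlap_range`, emulating walking sequencing
#' where each new primer sits 200-300 bases before the end of the previous
#' read. Reads flagged `R` are stored reverse-complemented, as a
#' reverse-strand trace's base caller would emit them. Reads running past the
#' reference end are clipped to it. Optional substitution errors are injected
#' only within a terminal window of each read (the end-of-trace region where
#' Sanger signal degrades), with every error position recorded; ground-truth
#' splice coordinates are recorded before error injection.
#'
#' @param reference_length Reference length in bases (ignored if `reference`
#'   is supplied).
#' @param n_reads Number of reads to tile.
#' @param read_length Read length in bases (typical Sanger: 700-900).
#' @param overlap_range Length-2 integer vector, inclusive bounds for the
#'   overlap between consecutive reads (typical walking design: 200-300).
#' @param directions Character vector of `"F"`/`"R"` per read, recycled;
#'   default alternates F, R.
#' @param end_error_rate Per-base substitution probability inside each read's
#'   terminal window (default 0 = error-free).
#' @param error_window Width of the terminal window, in bases, at the forward-
#'   orientation end of each read.
#' @param seed Integer seed for reproducibility.
#' @param reference Optional reference sequence string to tile instead of a
#'   random one.
#' @return A `walking_sim` object: `reference`, `reads` (tibble directly
#'   consumable by [merge_sanger()], with synthetic `source` names),
#'   `layout` (per-read reference offsets, 0-based half-open),
#'   `truth_boundaries` (per-pair ground-truth `prev_cut`/`next_cut`),
#'   and `errors` (injected substitutions with read and reference positions).
#' @examples
#' sim <- simulate_walking_reads(reference_length = 2000, n_reads = 3,
#'                               read_length = 800, seed = 1)
#' fit <- merge_sanger(sim$reads)
#' identical(fit$merged, sim$reference)
#' @export
simulate_walking_reads <- function(reference_length = 2000L,
                                   n_reads = 4L,
                                   read_length = 800L,
                                   overlap_range = c(200L, 300L),
                                   directions = NULL,
                                   end_error_rate = 0,
                                   error_window = 10L,
                                   seed = NULL,
                                   reference = NULL) {
  stopifnot(length(overlap_range) == 2)
  overlap_range <- as.integer(sort(overlap_range))
  if (overlap_range[1] < 1) abort_usage("overlap_min must be >= 1")
  if (overlap_range[2] >= read_length) {
    abort_usage("infeasible geometry: overlap_max must be < read_length")
  }
  if (is.null(directions)) {
    directions <- rep(c("F", "R"), length.out = n_reads)
  }
  directions <- validate_directions(rep(directions, length.out = n_reads))

  with_seed_(seed, {
    if (is.null(reference)) reference <- random_reference(reference_length)
    reference_length <- nchar(reference)

    overlaps <- if (n_reads > 1) {
      # index-based draw: sample(x) on a length-1 x would sample from 1:x
      choices <- seq.int(overlap_range[1], overlap_range[2])
      choices[sample.int(length(choices), n_reads - 1, replace = TRUE)]
    } else integer(0)
    starts <- cumsum(c(0L, read_length - overlaps))
    if (any(starts >= reference_length)) {
      abort_usage("infeasible geometry: reads cannot span the reference")
    }
    ends <- pmin(starts + read_length, reference_length)
    fwd <- substring(reference, starts + 1L, ends)
    lens <- ends - starts

    # ground truth before any error injection: take all of prev, then next
    # from where prev ends (next_cut = residual overlap, capped at next's
    # length for reads fully contained in their predecessor's window)
    truth <- if (n_reads > 1) {
      tibble(pair = seq_len(n_reads - 1),
             overlap = pmax(0L, pmin(ends[-n_reads], ends[-1]) - starts[-1]),
             prev_cut = lens[-n_reads],
             next_cut = pmin(pmax(0L, ends[-n_reads] - starts[-1]),
                             lens[-1]))
    } else {
      tibble(pair = integer(0), overlap = integer(0),
             prev_cut = integer(0), next_cut = integer(0))
    }

    errors <- tibble(read = integer(0), pos = integer(0),
                     ref_pos = integer(0), from = character(0),
                     to = character(0))
    if (end_error_rate > 0 && error_window > 0) {
      bases <- c("A", "C", "G", "T")
      for (i in seq_len(n_reads)) {
        win <- seq.int(max(1L, lens[i] - error_window + 1L), lens[i])
        hit <- win[stats::runif(length(win)) < end_error_rate]
        for (p in hit) {
          orig <- substr(fwd[i], p, p)
          sub <- sample(setdiff(bases, orig), 1)
          substr(fwd[i], p, p) <- sub
          errors <- dplyr::bind_rows(errors, tibble(
            read = i, pos = p, ref_pos = starts[i] + p,
            from = orig, to = sub))
        }
      }
    }

    stored <- ifelse(directions == "F", fwd,
                     vapply(fwd, reverse_complement, character(1),
                            USE.NAMES = FALSE))
    reads <- tibble(source = sprintf("read_%d", seq_len(n_reads)),
                    direction = directions, sequence = stored,
                    length = lens)
    structure(list(reference = reference, reads = reads,
                   layout = tibble(read = seq_len(n_reads), start = starts,
                                   end = ends, length = lens,
                                   direction = directions),
                   truth_boundaries = truth, errors = errors,
                   spanned = substr(reference, 1, max(ends))),
              class = "walking_sim")
  })
}

#' @export
print.walking_sim <- function(x, ...) {
  cat(sprintf("<walking_sim> %d reads (%s) tiling a %d-base reference, span %d bases\n",
              nrow(x$reads), paste(x$reads$direction, collapse = ""),
              nchar(x$reference), nchar(x$spanned)))
  invisible(x)
}

#' Write simulated reads and ground truth to disk
#'
#' Writes one sequence file per read plus the reference and a plain-text
#' `truth.txt` listing per-read offsets, ground-truth splice boundaries, and
#' injected error positions. Filenames are prefixed `synthetic_` to mark them
#' as simulated data.
#'
#' @param sim A `walking_sim`.
#' @param dir Output directory (created if missing).
#' @param format Sequence file format: `"seq"`, `"fasta"`, or `"txt"`.
#' @return The `reads` tibble with `source` replaced by the written paths,
#'   ready for [read_sanger_reads()] or the command-line front end.
#' @export
write_simulated_reads <- function(sim, dir, format = c("seq", "fasta", "txt")) {
  stopifnot(inherits(sim, "walking_sim"))
  format <- match.arg(format)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ext <- if (format == "fasta") "fasta" else format
  paths <- file.path(dir, sprintf("synthetic_read_%d.%s",
                                  seq_len(nrow(sim$reads)), ext))
  for (i in seq_len(nrow(sim$reads))) {
    write_sequence(sim$reads$sequence[i], paths[i], format = format)
  }
  ref_path <- file.path(dir, paste0("synthetic_reference.", ext))
  write_sequence(sim$reference, ref_path, format = format)
  truth <- c(
    sprintf("reference: %s (%d bases)", ref_path, nchar(sim$reference)),
    "layout (0-based half-open reference offsets):",
    sprintf("  read %d [%s]: %d-%d", sim$layout$read, sim$layout$direction,
            sim$layout$start, sim$layout$end),
    "truth boundaries (0-based cuts):",
    if (nrow(sim$truth_boundaries) > 0) {
      sprintf("  pair %d: overlap %d, prev_cut %d, next_cut %d",
              sim$truth_boundaries$pair, sim$truth_boundaries$overlap,
              sim$truth_boundaries$prev_cut, sim$truth_boundaries$next_cut)
    } else "  (single read)",
    "injected errors (1-based position in forward-orientation read):",
    if (nrow(sim$errors) > 0) {
      sprintf("  read %d pos %d (ref %d): %s->%s", sim$errors$read,
              sim$errors$pos, sim$errors$ref_pos, sim$errors$from,
              sim$errors$to)
    } else "  none")
  writeLines(truth, file.path(dir, "truth.txt"))
  dplyr::mutate(sim$reads, source = paths)
}
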
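# Independent oracles used to cross-check the aligner and run detection.

# Exhaustive enumeration of every global alignment (every monotone column
# sequence; no memoization) under affine gap costs: a gap of length L costs
# gap_open + (L - 1) * gap_extend. End gaps follow the scheme: free by
# default (needle endweight=false semantics: one free leading gap run, and
# everything after either sequence is exhausted is a free trailing run),
# or charged like interior gaps when penalize_end_gaps is set.
# Feasible for sequences up to ~length 6.
#
# States: 0 start, 1 after a residue column, 2 interior gap in the A row
# (consuming B), 3 interior gap in the B row (consuming A), 4 free leading
# gap in the A row, 5 free leading gap in the B row.
oracle_align_score <- function(a, b, sc = scoring_scheme()) {
  A <- strsplit(a, "", fixed = TRUE)[[1]]
  B <- strsplit(b, "", fixed = TRUE)[[1]]
  na <- length(A); nb <- length(B)
  acgt <- c("A", "C", "G", "T")
  free_ends <- !sc$penalize_end_gaps
  rec <- function(i, j, state) {
    if (i > na && j > nb) return(0)
    if (free_ends && (i > na || j > nb)) return(0) # free trailing run
    best <- -Inf
    if (i > na) { # must gap out the rest of B in the A row (charged)
      rest <- nb - j + 1L
      pen <- if (state == 2L) rest * sc$gap_extend
             else sc$gap_open + (rest - 1L) * sc$gap_extend
      return(-pen)
    }
    if (j > nb) {
      rest <- na - i + 1L
      pen <- if (state == 3L) rest * sc$gap_extend
             else sc$gap_open + (rest - 1L) * sc$gap_extend
      return(-pen)
    }
    s <- if (A[i] == B[j] && A[i] %in% acgt) sc$match else sc$mismatch
    best <- max(best, s + rec(i + 1L, j + 1L, 1L))
    # gap in the A row, consuming B[j]
    pen <- if (state == 2L) sc$gap_extend
           else if (free_ends && state %in% c(0L, 4L)) 0
           else sc$gap_open
    nxt <- if (free_ends && state %in% c(0L, 4L)) 4L else 2L
    best <- max(best, rec(i, j + 1L, nxt) - pen)
    # gap in the B row, consuming A[i]
    pen <- if (state == 3L) sc$gap_extend
           else if (free_ends && state %in% c(0L, 5L)) 0
           else sc$gap_open
    nxt <- if (free_ends && state %in% c(0L, 5L)) 5L else 3L
    best <- max(best, rec(i + 1L, j, nxt) - pen)
    best
  }
  rec(1L, 1L, 0L)
}

# Naive linear scan for the first window of n consecutive '|' columns;
# returns the 0-based start column or NULL.
oracle_first_run_start <- function(match_line, n) {
  cols <- strsplit(match_line, "", fixed = TRUE)[[1]] == "|"
  if (length(cols) < n) return(NULL)
  for (i in seq_len(length(cols) - n + 1L)) {
    if (all(cols[i:(i + n - 1L)])) return(i - 1L)
  }
  NULL
}

random_seq <- function(k) {
  paste(sample(c("A", "C", "G", "T"), k, replace = TRUE), collapse = "")
}

# A noisy copy of `seq`: point substitutions plus occasional 1-base indels,
# for generating non-trivial alignments.
mutate_seq <- function(seq, sub_rate = 0.1, indel_rate = 0.02) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bases <- c("A", "C", "G", "T")
  out <- character(0)
  for (ch in chars) {
    r <- stats::runif(1)
    if (r < indel_rate / 2) next                      # deletion
    if (r < indel_rate) out <- c(out, sample(bases, 1)) # insertion before
    out <- c(out,
             if (stats::runif(1) < sub_rate) sample(setdiff(bases, ch), 1)
             else ch)
  }
  if (length(out) == 0) out <- sample(bases, 1)
  paste(out, collapse = "")
}

degap <- function(x) gsub("-", "", x, fixed = TRUE)
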
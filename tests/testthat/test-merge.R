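test_that("read-set size and Consecutive Matches validation", {
  two <- tibble::tibble(sequence = c("ACGT", "ACGT"), direction = c("F", "F"))
  expect_invisible(check_file_list_count(two))
  expect_error(check_file_list_count(two[1, ]), "at least two",
               class = "sangerstitch_usage_error")
  expect_error(check_file_list_count(two[0, ]), "at least two",
               class = "sangerstitch_usage_error")

  expect_identical(check_and_convert("50"), 50L)
  expect_identical(check_and_convert("35"), 35L)
  expect_identical(check_and_convert(40), 40L)
  for (bad in list("abc", "0", "-5", "50.5", "9", "1001")) {
    expect_error(check_and_convert(bad), class = "sangerstitch_usage_error")
  }
})

test_that("forwardize reverse-complements R reads and preserves order", {
  reads <- tibble::tibble(sequence = c("ACGT", "ACGT", "AACC"),
                          direction = c("F", "R", "R"))
  out <- forwardize(reads)
  expect_identical(out$forward, c("ACGT", "ACGT", "GGTT"))
  expect_identical(out$sequence, reads$sequence)
})

test_that("align_to_get_boundaries derives splice cuts from the first run", {
  prev <- paste0(strrep("A", 10), strrep("C", 10))
  nxt <- paste0(strrep("C", 10), strrep("G", 10))
  bp <- align_to_get_boundaries(prev, nxt, merge_params(10))
  expect_identical(bp$prev_cut, 20L) # run ends at prev's end
  expect_identical(bp$next_cut, 10L) # next contributes from its run end
  expect_identical(bp$run$a_start, 10L)
  expect_identical(bp$run$b_start, 0L)

  # total overlap: a sequence against itself
  s <- random_seq(40)
  bp2 <- align_to_get_boundaries(s, s, merge_params(40))
  expect_identical(bp2$prev_cut, 40L)
  expect_identical(bp2$next_cut, 40L)
})

test_that("insufficient overlap raises a diagnostic overlap error", {
  err <- expect_error(
    align_to_get_boundaries(strrep("A", 60), strrep("T", 60),
                            merge_params(50), "first", "second"),
    class = "sangerstitch_overlap_error")
  expect_match(conditionMessage(err), "first")
  expect_match(conditionMessage(err), "second")
  expect_match(conditionMessage(err), "50")
  expect_match(conditionMessage(err), "longest observed: 0")
  expect_match(conditionMessage(err), "lower the Consecutive Matches")

  # too-short inputs are a precondition failure, not an overlap failure
  expect_error(align_to_get_boundaries("ACGT", strrep("A", 60),
                                       merge_params(50)),
               class = "sangerstitch_usage_error")
})

test_that("splice concatenates contributions with each overlap taken once", {
  expect_identical(
    splice(c("AAAAACCCCC", "CCCCCGGGGG"),
           tibble::tibble(prev_cut = 10, next_cut = 5)),
    "AAAAACCCCCGGGGG")
  # three fragments tiled from a reference with known cuts
  ref <- "AAACCCGGGTTTACGACG"
  frags <- c(substr(ref, 1, 9), substr(ref, 4, 15), substr(ref, 10, 18))
  b <- tibble::tibble(prev_cut = c(9, 12), next_cut = c(6, 6))
  expect_identical(splice(frags, b), ref)
  # out-of-range boundary is an internal-consistency error
  expect_error(splice(c("ACGT", "ACGT"),
                      tibble::tibble(prev_cut = 9, next_cut = 1)),
               class = "sangerstitch_internal_error")
  expect_error(splice(c("ACGT", "ACGT", "ACGT"),
                      tibble::tibble(prev_cut = 2, next_cut = 1)),
               class = "sangerstitch_usage_error")
})

test_that("merge_sanger reconstructs the reference from simulated reads", {
  sim <- simulate_walking_reads(reference_length = 2000, n_reads = 4,
                                read_length = 800,
                                directions = c("F", "R", "F", "R"),
                                seed = 301)
  fit <- merge_sanger(sim$reads)
  expect_identical(fit$merged, sim$spanned)
  expect_identical(nrow(fit$boundaries), 3L)
  expect_length(fit$reports, 3L)
  expect_match(fit$log_text, "merged sequence length")
  expect_identical(glance(fit)$merged_length, nchar(sim$spanned))
  expect_identical(tidy(fit), fit$boundaries)
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("merging two identical forward reads returns the read itself", {
  s <- random_seq(120)
  reads <- tibble::tibble(sequence = c(s, s), direction = c("F", "F"))
  fit <- merge_sanger(reads, consecutive_matches = 50)
  expect_identical(fit$merged, s)
})

test_that("a non-overlapping pair fails naming the pair at fault", {
  sim <- simulate_walking_reads(reference_length = 1200, n_reads = 2,
                                read_length = 500, overlap_range = c(80, 90),
                                seed = 5)
  unrelated <- random_reference(500, seed = 99)
  reads <- dplyr::bind_rows(
    sim$reads,
    tibble::tibble(source = "stray", direction = "F", sequence = unrelated,
                   length = 500L))
  err <- expect_error(merge_sanger(reads, 50),
                      class = "sangerstitch_overlap_error")
  expect_match(conditionMessage(err), "read_2")
  expect_match(conditionMessage(err), "stray")
})

test_that("merging is composable: pairwise first equals one-shot", {
  sim <- simulate_walking_reads(reference_length = 1500, n_reads = 3,
                                read_length = 600,
                                overlap_range = c(100, 150),
                                directions = c("F", "R", "F"), seed = 17)
  one_shot <- merge_sanger(sim$reads, 50)
  first_two <- merge_sanger(sim$reads[1:2, ], 50)
  rest <- dplyr::bind_rows(
    tibble::tibble(source = "partial", direction = "F",
                   sequence = first_two$merged,
                   length = nchar(first_two$merged)),
    sim$reads[3, ])
  staged <- merge_sanger(rest, 50)
  expect_identical(staged$merged, one_shot$merged)
})

test_that("merged output is invariant to flipping a read's strand", {
  set.seed(71)
  for (i in 1:5) {
    sim <- simulate_walking_reads(reference_length = 900, n_reads = 3,
                                  read_length = 400,
                                  overlap_range = c(80, 120),
                                  directions = "F",
                                  seed = 1000 + i)
    flipped <- sim$reads
    j <- sample(nrow(flipped), 1)
    flipped$sequence[j] <- reverse_complement(flipped$sequence[j])
    flipped$direction[j] <- "R"
    expect_identical(merge_sanger(flipped, 50)$merged,
                     merge_sanger(sim$reads, 50)$merged)
  }
})

test_that("overlap threshold is sharp and rescuable by lowering n", {
  # reads short enough that a 49-base overlap outscores spurious scattered
  # matches between the unique flanks under the default scoring
  ref <- random_reference(400, seed = 12)
  reads49 <- tibble::tibble(
    sequence = c(substr(ref, 1, 200), substr(ref, 152, 400)),
    direction = c("F", "F"))
  expect_error(merge_sanger(reads49, 50),
               class = "sangerstitch_overlap_error")
  rescued <- merge_sanger(reads49, 40)
  expect_identical(rescued$merged, ref)
  # overlap of exactly n merges
  reads50 <- tibble::tibble(
    sequence = c(substr(ref, 1, 201), substr(ref, 152, 400)),
    direction = c("F", "F"))
  expect_identical(merge_sanger(reads50, 50)$merged, ref)
})

test_that("end-window errors outside the splice path do not corrupt output", {
  hits <- 0L
  for (s in 1:10) {
    sim <- simulate_walking_reads(reference_length = 1600, n_reads = 3,
                                  read_length = 700,
                                  overlap_range = c(150, 200),
                                  directions = c("F", "R", "F"),
                                  end_error_rate = 0.5, error_window = 10,
                                  seed = 4000 + s)
    fit <- merge_sanger(sim$reads, 50)
    b <- fit$boundaries
    # reference positions the splice path takes from each read
    included <- function(read, pos) {
      if (read < nrow(sim$reads)) {
        from <- if (read == 1) 0L else b$next_cut[read - 1]
        pos > from & pos <= b$prev_cut[read]
      } else {
        pos > b$next_cut[read - 1]
      }
    }
    inc <- mapply(included, sim$errors$read, sim$errors$pos)
    merged_chars <- strsplit(fit$merged, "")[[1]]
    ref_chars <- strsplit(sim$reference, "")[[1]]
    excluded_ref <- sim$errors$ref_pos[!inc]
    clean <- setdiff(seq_along(merged_chars), sim$errors$ref_pos[inc])
    expect_identical(merged_chars[clean],
                     ref_chars[clean])
    if (any(inc)) {
      expect_identical(merged_chars[sim$errors$ref_pos[inc]],
                       sim$errors$to[inc])
      hits <- hits + 1L
    }
    expect_false(any(merged_chars[excluded_ref] != ref_chars[excluded_ref]))
  }
  expect_gt(nrow(sim$errors), 0) # the generator did inject errors
})

test_that("run artifacts follow the timestamped folder contract", {
  d <- withr::local_tempdir()
  sim <- simulate_walking_reads(reference_length = 1000, n_reads = 3,
                                read_length = 450,
                                overlap_range = c(100, 150), seed = 9)
  fit <- merge_sanger(sim$reads, 50)
  clock <- as.POSIXct("2024-09-12 08:26:41", tz = "UTC")
  out <- write_run_artifacts(fit, d, clock = clock)
  expect_identical(basename(out), "merged_sequence20240912082641")
  files <- list.files(out)
  expect_length(files, 1 + 3 + 2 + 1) # log + forwardized + reports + merged
  expect_length(grep("_forwardized\\.seq$", files), 3L)
  expect_length(grep("\\.needle$", files), 2L)
  expect_true("log.txt" %in% files)
  expect_identical(read_sequence(file.path(out, "merged.seq")), fit$merged)
  fw <- read_sequence(file.path(out, "read_2_forwardized.seq"))
  expect_identical(fw, fit$forwardized[2])

  # a second run in the same second never overwrites
  out2 <- write_run_artifacts(fit, d, clock = clock)
  expect_identical(basename(out2), "merged_sequence20240912082641_1")

  # srspair statistics in the saved report agree with alignment_stats
  rep1 <- readLines(file.path(out, grep("\\.needle$", files, value = TRUE)[1]))
  st <- alignment_stats(fit$alignments[[1]])
  expect_true(sprintf("# Identity:       %d/%d (%s%%)", st$identity_count,
                      st$alignment_length,
                      sprintf("%4.1f", st$identity_pct)) %in% rep1)
})
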
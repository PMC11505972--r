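# sangerstitch

Merge overlapping Sanger sequencing reads from a primer-walking experiment
into one full-length sequence.

## The problem

A single Sanger sequencing reaction reliably calls roughly 700–1000 bases,
after which signal quality decays. To verify a cloned gene longer than one
read, labs do *walking* sequencing: each new sequencing primer is designed in
the good-signal region 200–300 bases before the end of the previous read, so
consecutive reads overlap by a few hundred bases. The resulting read files
(plain-text `seq`, `fasta`, or `txt`; some sequenced on the reverse strand)
must be stitched into one sequence before comparison with the expected gene.

`sangerstitch` automates the stitching:

1. **Forwardize** — reads flagged `R` (reverse strand) are
   reverse-complemented so all reads are collinear with the target.
2. **Align** — each adjacent pair in the user-supplied walking order is
   globally aligned (Needleman–Wunsch with affine gaps; end gaps free, the
   EMBOSS needle default). Default scores: match +5, mismatch −4, gap open
   10, gap extend 0.5.
3. **Locate the overlap** — the splice boundary is the *first* run of
   *n* consecutive identical aligned bases (the **Consecutive Matches**
   parameter, default *n* = 50). Writing the run's end as position
   *a* in the previous read and *b* in the next read, the merged sequence
   takes `prev[1..a]` followed by `next[b+1..]` — everything before and
   including the matching region from the previous read, everything after it
   from the next read, whose mid-reaction signal is better there.
4. **Splice and report** — the merged sequence is emitted together with
   needle-style (srspair) alignment reports for every adjacent pair,
   forwardized intermediates, and a timestamped run log, so every merge
   decision can be audited.

If two reads truly overlap by fewer than 50 bases, the pair can be rescued by
lowering `consecutive_matches` (e.g. to 35 or 40), merging that pair alone,
and then merging its result with the remaining reads — staged merging is
byte-identical to one-shot merging on compatible sets.

## Worked example

Simulate a walking experiment (4 reads of 800 bases, overlaps 200–300,
alternating forward/reverse) and merge it back:

```r
library(sangerstitch)

sim <- simulate_walking_reads(reference_length = 2000, n_reads = 4,
                              read_length = 800, overlap_range = c(200, 300),
                              directions = c("F", "R", "F", "R"), seed = 42)
fit <- merge_sanger(sim$reads, consecutive_matches = 50)
fit
#> <sanger_merge> 4 reads -> 2000 bases (n = 50)
#> # A tibble: 3 × 7
#>    pair prev_name next_name prev_cut next_cut identity_pct gap_count
#>   <int> <chr>     <chr>        <int>    <int>        <dbl>     <int>
#> 1     1 read_1    read_2         585       50         19.9      1070
#> 2     2 read_2    read_3         606       50         18.0      1112
#> 3     3 read_3    read_4         624       50         24.9       683

identical(fit$merged, sim$reference)
#> [1] TRUE
```

Each boundary row says where the previous read's contribution ends
(`prev_cut`, 0-based exclusive) and where the next read's begins
(`next_cut`): pair 1 found its 50-base match run ending at position 585 of
read 1 and position 50 of read 2. `identity_pct` and `gap_count` describe the
full pairwise alignment in needle's convention — free end-gap columns from
the non-overlapping flanks are counted, which is why identity over the whole
alignment is low even though the detected overlap itself is a perfect run.

`tidy(fit)` returns the full boundary table, `glance(fit)` a one-row
summary, `autoplot(fit)` a read-layout sketch, and
`write_run_artifacts(fit, dir)` the `merged_sequence<YYYYMMDDHHMMSS>` folder
with the log, forwardized reads, per-pair `.needle` reports, and
`merged.seq`.

With read files on disk the same run is:

```r
reads <- read_sanger_reads(c("first.seq", "second.seq", "third.seq"),
                           directions = c("F", "R", "F"))
fit <- merge_sanger(reads)
write_sequence(fit$merged, "merged.fasta", format = "fasta")
```

or from the shell, via the bundled front end (exit codes 0/2/3/4 for
success / usage / I-O / insufficient overlap):

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/merge_sanger.R", package = "sangerstitch"))')" \
  --in first.seq:F --in second.seq:R --in third.seq:F \
  --out merged.seq --matches 50 --summary
```

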
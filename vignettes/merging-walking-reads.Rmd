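---
title: "Merging Sanger walking reads: model, parameters, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Merging Sanger walking reads: model, parameters, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sangerstitch)
```

## The merging model

A walking-sequencing experiment produces an *ordered* set of reads
$r_1, \dots, r_k$: each new sequencing primer is placed in the good-signal
region a couple of hundred bases before the end of the previous read, so
consecutive reads overlap and the order is experimental knowledge, not
something to infer. Reads sequenced on the reverse strand are recorded as
their reverse complement and must be flipped back ("forwardized") before
merging.

For each adjacent pair $(r_i, r_{i+1})$ (both forwardized), the package
computes a global pairwise alignment and scans its match line for the
**first** run of $n$ consecutive identical aligned bases. A run of matches
contains no gaps, so it occupies $n$ positions in both reads; write its end
as $a_i$ in $r_i$ and $b_i$ in $r_{i+1}$. The merged sequence is then

$$ r_1[1..a_1] \;\Vert\; r_2[b_1\!+\!1..a_2] \;\Vert\; \dots \;\Vert\;
   r_k[b_{k-1}\!+\!1..\,] $$

each overlap region appearing exactly once. The biochemical rationale: once
$n$ bases match consecutively, the previous read is approaching its end,
where Sanger signal degrades, while the next read is still in its
well-resolved middle — so everything up to and including the matching region
is taken from the previous read and everything after it from the next.

Two modelling choices here were genuinely open and are worth stating:

* **Run donor.** Inside the matching run the two reads are identical by
  construction, so taking the run from the previous read (as above) or the
  next is observationally neutral; taking it from the previous read makes
  the splice a single left-to-right pass. This is the package's choice; it
  becomes observable only if a sequencing error falls inside the run itself.
* **First run, not longest.** The boundary is the *first* qualifying run.
  The earliest boundary hands over to the next read as soon as the evidence
  threshold is met, keeping more of the merged sequence in each read's
  high-quality middle. A run broken by a single mismatch or gap column does
  not qualify — "consecutive" is strict.

## Alignment and scoring

Pairwise alignment is end-to-end (Needleman–Wunsch) with affine gaps,
delegated to `Biostrings::pairwiseAlignment()`. The default
`scoring_scheme()` is match $+5$, mismatch $-4$, gap open $10$, gap extend
$0.5$ — the EMBOSS needle DNA defaults — with a gap of length $L$ costing
$10 + 0.5(L-1)$.

**End gaps are free by default** (`penalize_end_gaps = FALSE`), matching
needle's `endweight=false` default. This is load-bearing for overlap
detection. Adjacent walking reads share only a terminal overlap; their
remaining flanks are unrelated sequence. If the long end gaps spanning those
flanks were charged, the optimal alignment shifts to a mosaic that scatters
the overlap into many short gapped segments — cheap 0.5-per-base gap
extension plus occasional spurious matches outscores one contiguous block
flanked by two expensive end gaps — and no $n$-run survives. With free end
gaps the contiguous overlap is optimal whenever its match score exceeds what
spurious scattered matching of the flanks can earn. The implementation uses
Biostrings' ends-free mode and re-attaches the unaligned overhangs as
explicit end-gap columns, so de-gapping either alignment row always
reproduces the full input read.

Consequence, stated as a limitation: spurious-match score grows with flank
length, so a *short* true overlap is only recovered when the unique flanks
are not too long. At the default scores the package's own sharpness tests
exercise a 49-base overlap with ~150–200-base flanks (rescued at
$n = 40$, refused at $n = 50$); the same 49-base overlap between two
full-length 800-base reads is not recoverable by global alignment under
these scores, whatever $n$. For such cases the scoring is exposed
(`scoring_scheme()`, CLI flags `--match`, `--mismatch`, `--gap-open`,
`--gap-extend`): raising the gap-extension penalty suppresses the mosaic
alternative.

Other alignment conventions:

* Comparison is case-insensitive; any column involving a character outside
  A/C/G/T (N or another IUPAC ambiguity code) counts as a mismatch, both in
  scoring and in the match line. Ambiguity codes are accepted on input
  because Sanger base callers emit them; they are never silently rewritten.
* Tie-breaking among co-optimal alignments follows Biostrings'
  deterministic traceback: the same inputs always give the same alignment
  and therefore the same report. Inside a true overlap, run detection is
  insensitive to which co-optimal arrangement is returned.
* Internally all coordinates are 0-based half-open; the srspair report
  writer is the single place where needle's 1-based inclusive convention
  appears.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `consecutive_matches` ($n$) | 50 | run length declaring an overlap; bases |
| `match` / `mismatch` | +5 / −4 | per-column scores |
| `gap_open` / `gap_extend` | 10 / 0.5 | affine gap penalties |
| `penalize_end_gaps` | `FALSE` | charge end gaps like interior gaps |

$n$ is accepted in $[10, 1000]$. The floor of 10 is deliberate: between two
unrelated ~700-base flanks the expected number of chance shared 10-mers is
no longer negligible, so smaller $n$ invites spurious boundaries. Lowering
$n$ to 35–40 is the intended rescue for genuinely short overlaps (merge the
weak pair alone, then merge its result with the rest — staged and one-shot
merging are byte-identical on compatible sets, which the test suite asserts).

## Degenerate inputs and failure behavior

Fewer than two reads, a missing direction, an unparsable $n$, or a read
shorter than $n$ are refused up front with typed errors. When no $n$-run
exists in a pair, the error names the pair, reports the longest run
observed, and suggests lowering the parameter. The CLI maps these classes to
stable exit codes (0 success, 2 usage, 3 I/O, 4 insufficient overlap) and
leaves no partial output file behind on failure. Run-artifact folders are
named `merged_sequence` + `YYYYMMDDHHMMSS`; a second run within the same
second gets a `_1`, `_2`, … suffix rather than overwriting.

## The synthetic-data generator

`simulate_walking_reads()` emulates the *geometry* of walking sequencing:
a uniform random A/C/G/T reference is tiled by reads of fixed length whose
consecutive overlaps are drawn uniformly from a range (defaults: 800-base
reads, 200–300-base overlaps, the dimensions of a typical walking design
over a ~2 kb insert). Reads flagged `R` are stored reverse-complemented, as
a reverse-strand trace's base caller would emit them. A read running past
the reference end is clipped to it — the final walking reaction simply runs
off the end of the insert — which can make the last read a suffix of its
predecessor's window; merging handles that case naturally. Ground-truth
splice coordinates are recorded before any error injection, so tests can
verify reconstruction exactly.

The error model is substitutions only, confined to a terminal window of each
read (default 10 bases, in forward orientation), imitating end-of-trace
signal decay; every injected position is recorded. Indels are deliberately
excluded from the error model's exactness assertions because an indel inside
an overlap changes the coordinate ground truth itself.

What the generator does **not** emulate — and what passing tests therefore
do not show about real data: chromatogram traces and base-quality values
(inputs here are plain text, as in the workflow this package supports),
base-caller miscalls in the middle of a read, homopolymer slippage,
non-uniform base composition, and vector/adapter contamination. The
generator validates the merging logic, not the sequencing chemistry.

## Problem sizes used in validation

The package's checks run at the scale the method is designed for: the
headline round-trip check simulates a 2000-base reference with four 800-base
reads (overlaps 200–300, directions F,R,F,R), merges at $n = 50$, and
requires the merged-vs-reference global alignment to show 100% identity and
0 gap columns. The aligner is cross-checked against an independent
exhaustive enumeration of all global alignments on 500 random pairs of
length ≤ 6; run detection against a naive match-line scan on 1000 random
alignments; strand invariance and reverse-complement involution on 100
random cases each. These sizes were chosen so the full suite exercises every
property at meaningful scale while remaining quick to run.

## Known limitations

* Read order is taken from the user, never inferred; a wrong order fails
  with an insufficient-overlap error rather than being repaired.
* One pass, two reads at a time: no consensus calling from >2× coverage and
  no quality-weighted resolution of disagreements inside overlaps — inside
  a detected run there is nothing to resolve, and outside it the donor rule
  decides.
* Short overlaps between long reads may be undetectable at the default
  scores (see the scoring section); the parameters are exposed for exactly
  this case.
* Multi-record FASTA input is rejected rather than split: one file is one
  read.
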
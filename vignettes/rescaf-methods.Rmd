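---
title: "Methods: disassemble-reassemble scaffolding with long reads"
author: "rescaf developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disassemble-reassemble scaffolding with long reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rescaf)
```

## The problem

Draft genome assemblies routinely contain structural errors — misjoins,
relocations, inversions — that no amount of base-level polishing can fix.
Single-molecule long reads (Oxford Nanopore, PacBio), once error-corrected,
are long enough to certify the local structure of an assembly: if many reads
align contiguously and almost completely inside a region of the draft, that
region is structurally trustworthy; if reads consistently break at a
position, the draft is suspect there.

`rescaf` exploits this in two stages:

1. **Disassemble.** Align error-corrected long reads to the draft (the
   package consumes the aligner's tabular block output; it does not run an
   aligner).  Keep only *validated* regions — intervals supported by reads
   that align almost entirely and without structural disagreement — and
   discard the rest.
2. **Reassemble.** Re-order and re-orient the validated segments using
   reads that bridge segment ends, by solving a maximum weighted
   alternating path cover on a breakpoint-style graph, then emit scaffold
   sequences with the bridging reads' own bases filling the junction gaps.

## Alignment model and validation thresholds

An aligner's output for one (draft sequence, read) pair is a chain of
aligned blocks $(DL_i, DR_i, RL_i, RR_i)$: draft interval aligned to read
interval.  The package:

* trims overlaps between consecutive blocks by cutting back the left ends
  of the right-hand block, advancing draft and read coordinates by the same
  amount (the larger of the two overlaps) so the block diagonal is
  preserved;
* closes small inter-block gaps by global Needleman–Wunsch alignment
  (match $+1$, mismatch $-1$, gap $-1$; linear gaps).  The scheme is the
  simplest edit-distance-like choice — the method's decisions depend only
  on gap *lengths*, not on the closing alignment's quality — and is
  configurable.  Gaps longer than 5000 bp per side are not closed (the
  quadratic cost is refused and the chain is split instead);
* treats read coordinates stepping backwards (micro-inversions) as chain
  breaks rather than overlaps to trim.

A resulting alignment segment is kept iff

* every consecutive block pair has $|g_1 - g_2| \le 30$, where $g_1$ is the
  draft-side and $g_2$ the read-side gap length — concordant gaps mean
  base-level noise, discordant gaps mean structural disagreement; and
* the aligned fraction of the read is **strictly greater** than $0.99$.
  The strictness follows the defining wording ("larger than"); the boundary
  case is pinned by a unit test.

Validated intervals overlapping by at least $\delta = 50$ bp are merged
(transitive closure); thinner overlaps are considered untrustworthy, and
the later interval is truncated at the earlier one's end so that validated
segments are always disjoint.  All three thresholds are tunable via
`validation_config()`; the defaults are the working values above.

Extraction is verbatim (`simple`) by default.  A `consensus` mode realigns
each supporting read onto its interval (banded global alignment) and takes
a per-column majority vote, ties going to the draft base and a gap majority
deleting the column; read insertions never create new columns.  Majority
voting is deliberately minimal — partial-order alignment or
quality-weighted consensus is out of scope.

## The scaffold graph and the alternating path cover

Each validated segment becomes two vertices — tail (5') and head (3') —
joined by a *dashed* edge of weight 0.  A read **bridges** two segments
when it has validated-quality alignments (same thresholds, with the
aligned fraction computed over the hit's read span) to a terminal window
of both segments, in compatible read order and orientation.  The terminal
window is the outermost $\min(500\,\mathrm{bp}, 20\%)$ of the segment:
interior hits indicate repeats, not junctions.  Bridges between the same
unordered vertex pair whose junction gap lengths agree within 100 bp are
merged into one *solid* edge weighted by the number of distinct supporting
reads; when dissimilar geometries survive, only the best-supported one is
kept (ties: larger median junction identity, then smallest read id), and
discarded geometries are not reconsidered later.

A scaffold is an alternating path — dashed, solid, …, dashed — and a
*cover* is a set of vertex-disjoint alternating paths using every vertex
and every dashed edge exactly once (each segment appears in exactly one
scaffold, exactly once).  The objective is the total solid weight.  The
decision version of this problem is NP-complete (reduction from
Hamiltonian path; `hamiltonian_reduction()` implements the construction as
a test generator), so the package solves it approximately:

1. find an exact maximum-weight matching $M^*$ over the solid edges alone;
2. add the dashed edges; components are now paths and cycles;
3. break each cycle.

The default cycle-breaking (`relaxed`) removes the smallest-weight solid
edge of each cycle once, with ties broken lexicographically on the sorted
vertex pair so output is deterministic.  If a cycle has $k_i$ solid edges
and $k_{\min} = \min_i k_i$, the output satisfies
$ALG \ge M^* (k_{\min}-1)/k_{\min}$, and since any cover is a matching
after deleting its dashed edges, $OPT \le M^*$; hence
$OPT/ALG \le k_{\min}/(k_{\min}-1) \le 2$.  An `iterative` variant instead
marks the smallest cycle edge ineligible and re-runs the matching until no
cycle remains.  As implemented it keeps the best acyclic solution seen
across rounds (each round's cycle-broken matching is itself feasible), so
it is never worse than the relaxed variant by construction; re-matching
may additionally recover weight the one-shot removal loses.  Ineligible
edges are excluded from the matching outright — an explicit $-1$ weight
would violate the positive-weight premise of the model, and exclusion
reproduces the intended effect.

Matching is exact: subset dynamic programming over each connected
component of the solid subgraph (components above 22 vertices are refused;
production instances are far sparser).  `brute_force_cover()` is an
independent exact oracle — exhaustive search over matchings whose union
with the dashed edges is acyclic, which is precisely the set of feasible
covers — capped at 8 segments and used throughout the test suite.

## Reassembly

Walking each path, a segment traversed tail-to-head is emitted forward,
head-to-tail reverse complemented; the two walk directions give
reverse-complementary scaffolds and the canonical direction starts at the
lexicographically smaller segment id.  Each junction is filled from
exactly one bridging read — the one with the highest mean junction
identity (ties: longest junction span, then read id) — keeping output
deterministic even when several reads span the gap; multi-read gap
consensus is deliberately not attempted.  A negative junction distance
trims the overlap off the start of the right-hand segment instead of
inserting sequence.  No padding characters are ever inserted: every
emitted base comes from a validated segment or a real read.

## The synthetic-data module

The simulator states the world the tests run in:

* **Genome**: uniform random A/C/G/T; circular genomes are simulated as
  linear (circularity only affects external reference-comparison
  evaluation, which is out of scope).
* **Structural corruption** (`mutate_assembly()`): the genome is cut
  $N-1$ times; with $m$ cuts to go and $L$ bases remaining, the cut point
  is uniform on $[l, L/(m+1)]$ measured from the left end of the remaining
  suffix — $L$ is interpreted as the *remaining* length, matching the
  recursive phrasing of the protocol, and this guarantees every piece is
  at least $l$ bp.  Pieces are shuffled uniformly (the identity permutation
  is allowed), each is reverse complemented with probability 0.5 (the
  protocol leaves "some" unquantified), and each is corrupted base-wise
  with default per-base probabilities of 2% insertion, 2% deletion and 2%
  mismatch — interpreted as per-position event probabilities, at most one
  event per reference position, single-base insertions (the protocol does
  not specify an event-length distribution).  The truth layout of every
  piece (source interval, strand, output order) is returned for
  evaluation.
* **Reads** (`simulate_reads()`): uniform start positions, strand flipped
  with probability 0.5, residual errors at 0.5% (split equally across
  event types) standing in for already-corrected reads; coverage is hit
  within 5% by drawing reads until the base budget is met.

**Read lengths.** The calibration targets are a mean of 4070 bp and an
upper quartile of 6231 bp.  No single lognormal can satisfy both: for a
lognormal, $\mathrm{mean}/Q_3 = \exp(\sigma^2/2 - z_{0.75}\sigma) \ge
0.797$ for all $\sigma$, while the targets require $4070/6231 = 0.653$,
and truncation does not close the gap.  The targets demand a distribution
with a large population of short reads next to a moderate full-length
mode — exactly what error correction produces, since correctors trim and
split raw reads.  Lengths are therefore modelled as a two-component
lognormal mixture: a fragment component fixed at meanlog $\log 1200$,
sdlog 0.6, and a full-length component with sdlog 0.35 whose location and
mixture weight are solved numerically (`calibrate_length_model()`) so the
mixture mean and upper quartile hit the targets exactly; the solved
defaults ($w \approx 0.479$, full-length meanlog $\approx 8.717$) are
frozen as package constants and a unit test keeps them in sync with the
solver.

**What the simulator does not model** — and therefore what a green test
does not establish: realistic base-composition bias, homopolymer-biased
error profiles, quality scores, genomic repeats (uniform random genomes
are essentially repeat-free, so bridging is never confounded by repeats),
and chimeric reads.  Structural-correction results on this synthetic world
are a best case; the thresholds exist precisely because real alignments
are messier.

**The toy truth aligner** (`truth_alignments()`) converts simulation truth
into the aligned-block table an aligner would produce, by intersecting
read source intervals with piece source intervals.  Coordinates are exact
only when no simulated indels shift them (mismatch-only corruption is
fine); with indels an external aligner's coords file is the supported
input.  This keeps the whole pipeline testable offline while exercising
every stage downstream of alignment.

## Numerical and degenerate-input choices

* All internal coordinates are 0-based half-open; the coords dialect on
  disk is 1-based inclusive with reverse-strand rows carrying a descending
  query interval.
* Banded global alignment is used where the diagonal is known (consensus,
  calibration realignment); the band is the length difference plus a
  6-sigma allowance for the indel random walk, and the traceback errors
  out loudly if it ever leaves the band.
* Seeds: every simulator entry point takes a seed and restores the
  caller's RNG state; identical seeds give byte-identical outputs.
* Degenerate inputs: empty block tables, reads with no alignments, graphs
  with no solid edges, and single-segment paths (emitted as standalone
  scaffolds) are all well-defined and covered by tests.
* A read aligning twice to the same junction contributes one support unit
  (repeat protection); a read touching $k > 2$ segments yields the $k-1$
  consecutive bridges.

## Known limitations

* The exact matching component limit (22 vertices per solid component) is
  ample for bacterial-scale instances but a blossom-algorithm backend
  would be needed for dense metazoan-scale graphs.
* Consensus extraction is column-majority only and ignores read
  insertions.
* The evaluator scores piece-level adjacency and orientation against the
  simulated truth; it is a stand-in for reference-comparison tools, not a
  reimplementation of their relocation/inversion calling.
* Validation against the "smaller of the two sequences" (useful when reads
  are longer than fragmented contigs) is available via
  `validation_config(fraction_basis = "smaller")` but off by default.

## A worked example

```{r example, eval = FALSE}
genome <- setNames(random_genome(100000, seed = 11), "ref")
mut <- mutate_assembly(genome, mutation_config(
  n_pieces = 5, min_piece_len = 10000,
  ins_rate = 0, del_rate = 0, mis_rate = 0, seed = 12))
sim <- simulate_reads(genome, read_sim_config(
  coverage = 25, residual_error_rate = 0, seed = 13))
blocks <- truth_alignments(sim$truth, mut$layout, nchar(sim$reads))
res <- run_pipeline(mut$draft, sim$reads, blocks)
evaluate_scaffolds(res, mut$layout)
```

On this stated world the pipeline validates one segment per piece,
recovers all four true adjacencies with the correct orientations, and
emits a single scaffold whose sequence matches the reference substring it
covers; the acceptance suite (`tests/testthat/test-acceptance.R`) and the
report script (`scripts/acceptance.R`) compute the corresponding
quantities at full scale.
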
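---
title: "Bin-based token-existence filtering of seed locations: model and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bin-based token-existence filtering of seed locations: model and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedsieve)
```

## The problem

Seed-and-extend read mappers find candidate locations for a read by exact
k-mer (seed) lookup, then verify each candidate with an edit-distance
alignment. The candidate list is dominated by locations that fail
verification, and alignment is by far the most expensive step, so a cheap
pre-alignment test that discards hopeless candidates — without ever
discarding a correct one — directly reduces mapping time. `seedsieve`
implements such a filter, designed around access patterns that also map
naturally onto processing-in-memory hardware, together with the scaffolding
needed to evaluate it: a minimal mapper, a planted-read simulator, and an
analytic cost model of the in-memory realization.

## The filter

The reference is divided into `t` *bins* of fixed stride
`ceil(genome_length / t)`, each extended by `overlap` bases so consecutive
bins share sequence. Each bin `x` carries a bitvector `b_x` of `4^n` bits:
bit `k` is 1 iff the token (DNA word of length `n`, default 5) with base-4
code `k` occurs in the bin. For a read `r` of length `L` and a candidate
location `z`, the *accumulation sum* `Sum_z` counts, over the
`L - n + 1` token occurrences of `r` (duplicates counted per occurrence),
the existence bits in the bin containing `z`. The location passes iff

```
Sum_z >= max(0, (L - (n - 1)) - ceil(L * e) * n)
```

where `e` is the alignment error tolerance. The threshold's logic: a read
matching within `ceil(L*e)` edit errors keeps, in the worst case, all but
`ceil(L*e) * n` of its tokens intact (each substitution or deletion corrupts
at most `n` consecutive tokens, an insertion at most `n - 1`; the worst case
places every error in a disjoint token set), and every intact token of a
contained match must be present in the bin. Consequently a location whose
bin contains a true match can never fall below the threshold: the filter has
**zero false positives** within the error budget. The converse does not
hold — a bin can reach the threshold from unrelated token occurrences (the
degenerate example is a poly-A read scoring `L - n + 1` against a bin with a
single `AAAAA`) — so passing locations still require verification, and the
filter's quality is measured by its *false negative rate* (passing locations
that fail verification, over all passing locations) and by the *average read
existence* (fraction of all bins a read passes, averaged over reads; lower
is better).

## Parameters and defaults

* **Token size `n` = 5.** The discriminative power of an existence bit in a
  bin of a few hundred bases falls off sharply below 5 (nearly every 4-mer
  occurs by chance); each increment quadruples the `4^n t / 8`-byte
  footprint. At genome scale (`450 * 2^16` bins) the n = 5 index is
  `footprint_bytes(450 * 2^16, 5) / 1e9` ≈ 3.77 GB.
* **Error tolerance `e` = 0.05**, the conventional short-read alignment
  budget; at `L = 100` the threshold is `compute_threshold(100, 5, 0.05)` =
  71 of 96 tokens.
* **Bin overlap.** The guarantee requires the whole matching segment to lie
  in one bin. A read of length `L` may gain up to `ceil(L*e)` reference
  bases through deletions, so the weakest sufficient overlap is
  `default_overlap(L, e) = L + ceil(L*e) - 1` (104 for `L = 100`,
  `e = 0.05`). Overlap is configurable; smaller values void the guarantee
  and `map_reads()` refuses them.
* **Stride / bin count.** More bins mean smaller bins, fewer chance token
  hits, lower read existence and FN rate, at linearly more memory. The
  mapping experiments here use stride 150 (bin width 254); sweeps cover
  64–1024 bins at desk scale.

## Numerical and boundary choices

* Coordinates are 0-based half-open everywhere; tokens encode as big-endian
  base-4 with A=0, C=1, G=2, T=3.
* Ties pass: `Sum_z == threshold` is a pass, as the worst case is
  attainable.
* If the threshold expression is non-positive (high `e`, short reads) it
  clamps to 0 with a warning: every location passes, preserving correctness
  while signalling that the token budget cannot discriminate.
* Reference tokens overlapping non-ACGT characters are never marked present
  (conservative). Ambiguous *read* bases are budgeted as worst-case
  substitutions: each contributes its `n` covering tokens as zero and lowers
  the threshold by `n`, so N-containing true reads still pass.
* The last bin of each record is truncated at the record end; bins never
  span record boundaries in multi-record references, so no phantom tokens
  appear across chromosome junctions.
* Reads shorter than `n` are rejected rather than silently passed.
* Strand: the filter scores exactly the query string it is given; the
  harness queries the reverse complement separately and tags candidates
  with strand.

### Candidate projection and the boundary guard

The harness projects each seed hit back to a candidate *read start*
`z = hit - seed_offset` and filters the bin `floor(z / stride)`. Indels
upstream of a seed shift `z` by up to `k = ceil(L*e)` bases relative to the
true segment start, so a candidate can land in the bin *after* the one
containing its match; the bin of `z` then misses up to `k` leading tokens
and can — rarely, at the worst-case error placement — fall below the
threshold even though verification (which aligns against the window
`[z - k, z + L + k)`) succeeds. `map_reads()` therefore applies a *boundary
guard*: when `z mod stride < k`, the previous bin is also evaluated and the
candidate passes if either bin passes. With `overlap >= L + k - 1` one can
show every segment within edit distance `k` of the read inside the
verifier's window is wholly contained in one of the two bins, which restores
the zero-false-positive guarantee end to end (the pure per-bin rule remains
available as `filter_read_locations()` and via
`map_reads(..., boundary_guard = FALSE)`). The guard touches only
candidates within `k` bases of a bin boundary (about `k / stride` ≈ 3% of
candidates at the defaults) and can only enlarge the passing set, so the
false-negative cost is marginal.

## The hardware-path model

The index is laid out token-major: one stored row holds one token's
existence bit across consecutive bins, so a single row fetch serves many
bins at once. `filter_bin_window()` is the functional model of that path —
`w` per-bin accumulators updated in lockstep, one `fetch_token_row()` per
token occurrence — and is bit-identical to per-bin evaluation for every `w`.
`estimate_cost()` is the corresponding schedule-only cost model: per touched
window (a window is skipped when none of its bins holds a candidate),
`L - n + 1` row activations; `ceil(w / row_bits_per_cycle)` lockstep cycles
per activation plus one compare/writeback per window; `ceil(bins/8)` bitmask
bytes per window. No DRAM timing, energy, or area is modeled — costs are
abstract row-fetch cycles, so only *relative* statements (e.g. widening the
window never increases activations) are meaningful; wall-clock speedups are
hardware- and data-dependent and out of scope.

## What the simulator emulates — and what it does not

`random_genome()` draws i.i.d. uniform ACGT; `plant_reads()` samples reads
at uniform positions and strands and applies exact counts of substitutions,
insertions and deletions at uniform positions, keeping `L` fixed (a
deletion extends the source window, an insertion shrinks it), with the
truth table retained. This gives planted ground truth for exact
false-negative/false-positive accounting, and it reproduces the qualitative
parameter trends (read existence rising with `e`, falling with bin count).
It does **not** reproduce real-genome token statistics: repeats, GC skew
and low-complexity regions make real bins far more token-dense than uniform
ones, and real candidate lists depend on a production mapper's seeding.
Absolute FN rates and read-existence values measured here therefore do not
transfer to real data; the zero-false-positive property, the oracle
equivalences and the monotone trends do, because they are
distribution-free.

## Problem sizes used in the checks

The shipped checks run at desk scale, chosen to exercise every guarantee
while staying cheap: the zero-false-positive suite plants 1000 reads of
100 bp carrying 0–5 mixed errors on a 1 Mbp uniform reference (stride-150
bins, overlap 104); oracle equivalence compares every index bit and
window accumulation sum against naive substring search on fifty 10 kb
references and the verifier against a full-DP oracle on 500 read/window
pairs; the parameter sweep covers `n ∈ {4, 5}`, 64–1024 bins and
`e ∈ [0, 0.05]` on a 200 kb reference with 40 planted plus 40 random
reads.

## Known limitations

* The mapping harness is an evaluation scaffold, not a production mapper:
  fixed-offset non-overlapping seeds, no paired ends, no base qualities, no
  SAM semantics.
* One index serves one `(n, stride, overlap)` configuration; changing
  parameters means rebuilding.
* Token sizes are capped at 15 (4^n indexable in a double); practical sizes
  are 4–6.
* The in-memory model treats the whole bin window as a single lockstep
  unit; finer vault-level decompositions would change constants, not the
  monotone structure.
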
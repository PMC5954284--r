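# seedsieve

Pre-alignment filtering of candidate seed locations for seed-and-extend DNA
read mapping, for people building or evaluating read mappers and
pre-alignment accelerators.

Seed-and-extend mappers look up exact seed matches to get candidate
locations, then verify each candidate with an expensive edit-distance
alignment — and most candidates fail. `seedsieve` implements a bin-based
token-existence filter that discards hopeless candidates *before*
alignment, with a guarantee of zero false positives within the alignment
error budget, plus everything needed to study it: a minimal seed-and-extend
harness, a planted-read simulator with known ground truth, an analytic cost
model of a processing-in-memory realization, and a command-line interface.

## The filter in brief

The reference is cut into `t` overlapping bins (stride
`s = ceil(G/t)`, each extended by `overlap` bases). Bin `x` stores a
bitvector `b_x` of `4^n` bits — bit `k` is 1 iff the length-`n` token with
base-4 code `k` (A=0, C=1, G=2, T=3) occurs in the bin. For a read `r` of
length `L` at candidate location `z`, the accumulation sum

    Sum_z = Σ over the L − n + 1 token occurrences of r
            of the token's existence bit in bin(z)

is compared against the error-tolerant threshold

    threshold = max(0, (L − (n − 1)) − ceil(L·e)·n)

where `e` is the alignment error tolerance. Each of the `ceil(L·e)`
tolerated edit errors corrupts at most `n` tokens, so a true match within
the budget always keeps at least `threshold` tokens intact and present in
its bin: locations below the threshold can be discarded with **zero false
positives**. Passing locations still need verification; filter quality is
measured by the false-negative rate (passing locations that fail
verification) and the average read existence (fraction of bins a read
passes — lower is better).

## Worked example

The canonical toy: a 100-base genome in five stride-20 bins (overlap 8),
where bin 2 contains the token `GACAG` but not `TTTTT`:

```r
library(seedsieve)

fx  <- worked_example_fixture()
idx <- build_index(fx$genome, fx$binning, fx$codec)
idx
#> <token_index> 'toy': 1024 tokens (n = 5) x 5 bins; 111 bits set; raw footprint 640 bytes
existence_bit(idx, encode_token("GACAG", fx$codec), 2)
#> [1] 1
existence_bit(idx, encode_token("TTTTT", fx$codec), 2)
#> [1] 0
```

A full evaluation run on simulated data — 50 planted 100 bp reads with 0–5
errors on a 200 kb random reference, stride-150 bins, `n = 5`, `e = 0.05`
(threshold `compute_threshold(100, 5, 0.05)` = 71 of 96 tokens):

```r
genome  <- random_genome(200000, seed = 1)
sim     <- plant_reads(genome, 50, 100, substitutions = rep(0:4, 10),
                       deletions = rep(c(0, 1), 25), seed = 2)
binning <- binning_from_stride(genome, 150, default_overlap(100, 0.05))
index   <- build_index(genome, binning, token_codec(5))
cfg     <- filter_config(5, 0.05)

res <- map_reads(sim$reads, genome, index, cfg)
res
#> <map_result> filter on: 64 accepted mapping(s) from 75 candidate location(s)
#> <filter_evaluation> pass: 64 (mapped: 64), reject: 11; FN rate 0, FP count 0
```

Reading the output: seeds produced 75 candidate locations; the filter
passed 64 and rejected 11; every passing candidate verified (false-negative
rate 0 here) and — the guarantee — none of the 11 rejected candidates would
have verified (false-positive count 0), so only 64 of 75 alignments were
actually needed. `glance(res)` returns these tallies as a one-row tibble,
`tidy(res)` the per-candidate table, `autoplot(res)` a decision/outcome
plot. `parameter_sweep()` sweeps `n`, bin count and `e` and has an
`autoplot()` method; `average_read_existence(sim$reads, index, cfg)` gives
the per-read fraction of passing bins (`5.2e-4` in this run).

A thin CLI over the same functions ships in `inst/cli/seedsieve`
(`build-index`, `filter`, `map`, `simulate`, `sweep`, `pim-estimate`); the
binary index format is documented byte-exactly in
`inst/doc-format/index-format.md`.

## Scope

The harness is an evaluation scaffold, not a production mapper (no paired
ends, base qualities, or SAM semantics); the cost model counts abstract row
activations and lockstep cycles, not DRAM timing. Absolute filter metrics
on uniform-random references do not transfer to real genomes (repeats and
skewed composition change token statistics); the zero-false-positive
property and the monotone parameter trends are distribution-free and do.
See the vignette `vignettes/seed-location-filtering.Rmd` for the model,
design decisions and limitations in full.
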
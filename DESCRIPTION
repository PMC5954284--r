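Package: seedsieve
Title: Bin-Based Token-Existence Filtering of Seed Locations for Read Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Pre-alignment filtering of candidate seed locations for
    seed-and-extend DNA read mapping. Builds per-bin token-existence
    bitvector indexes over a reference genome, scores candidate locations
    by an accumulation sum of read-token existence bits with an
    error-tolerant threshold (guaranteeing zero false positives within the
    stated edit-error budget), and evaluates the filter inside a minimal
    seed-and-extend mapping harness with planted-read simulations. Also
    provides a simplified analytic cost model of a processing-in-memory
    realization of the filter (row activations, lockstep cycles, bitmask
    traffic).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    tibble,
    tidyr,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
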
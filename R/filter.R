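#' Filter configuration: token size and error tolerance
#'
#' @param token_size Token length `n` (>= 1).
#' @param error_tolerance Alignment error tolerance `e` in `[0, 1)`: the
#'   fraction of a read's length allowed as edit errors (substitutions,
#'   insertions, deletions) for an alignment to count as a match. `e = 0.05`
#'   is the value in common use for short-read mapping.
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(token_size = 5, error_tolerance = 0.05) {
  token_size <- as.integer(token_size)
  if (is.na(token_size) || token_size < 1L) stop("token_size must be >= 1")
  e <- as.numeric(error_tolerance)
  if (is.na(e) || e < 0 || e >= 1) stop("error_tolerance must lie in [0, 1)")
  structure(list(token_size = token_size, error_tolerance = e),
            class = "filter_config")
}

#' @export
print.filter_config <- function(x, ...) {
  cat("<filter_config> token size n = ", x$token_size,
      ", error tolerance e = ", x$error_tolerance, "\n", sep = "")
  invisible(x)
}

#' Extract all overlapping tokens of a read
#'
#' Returns the `L - n + 1` length-`n` windows of the read in order, one row
#' per occurrence (duplicated tokens appear once per occurrence — the
#' accumulation sum counts occurrences, not distinct tokens). Tokens
#' containing a non-ACGT character are flagged ambiguous and carry an `NA`
#' code.
#'
#' @param read Read sequence (single string) or a list/row with `seq`.
#' @param n Token size.
#' @return Tibble with columns `position` (0-based offset in the read),
#'   `token`, `code`, `ambiguous`.
#' @examples
#' extract_tokens("GACAGT", 5)
#' @export
extract_tokens <- function(read, n) {
  seq <- read_seq_string(read)
  L <- nchar(seq)
  if (L < n) {
    stop("read of length ", L, " is shorter than the token size ", n)
  }
  codec <- token_codec(n)
  codes <- scan_token_codes(seq, codec)
  pos <- seq_len(L - n + 1) - 1
  tibble::tibble(
    position = pos,
    token = substring(seq, pos + 1, pos + n),
    code = codes,
    ambiguous = is.na(codes)
  )
}

#' Maximum number of allowable edit errors for a read
#'
#' `ceil(L * e)`: the error budget implied by an alignment error tolerance
#' `e` for a read of length `L`.
#'
#' @param L Read length in bases (>= 1).
#' @param e Error tolerance in `[0, 1)`.
#' @return Integer error count.
#' @examples
#' allowable_errors(100, 0.05)  # 5
#' allowable_errors(104, 0.05)  # 6
#' @export
allowable_errors <- function(L, e) {
  if (any(L < 1)) stop("read length must be >= 1")
  if (any(e < 0 | e >= 1)) stop("error tolerance must lie in [0, 1)")
  as.integer(ceiling(L * e))
}

#' Accumulation-sum threshold
#'
#' A read of length `L` contains `L - (n - 1)` tokens. Each edit error can,
#' in the worst case, corrupt `n` consecutive tokens, and the worst case
#' places each of the `ceil(L*e)` allowable errors in a disjoint set of
#' tokens; every token not touched by an error must still be present in a
#' bin that matches. Hence the threshold
#'
#' \deqn{\max(0,\; (L - (n-1)) - \lceil L e \rceil \cdot n)}
#'
#' A location passes when its accumulation sum is greater than or equal to
#' this value, which is what makes the filter free of false positives within
#' the error budget. When the expression is non-positive the threshold
#' clamps to 0 (every location passes) and a warning is emitted: the token
#' budget cannot discriminate at that tolerance.
#'
#' @inheritParams allowable_errors
#' @param n Token size.
#' @return Integer threshold >= 0.
#' @examples
#' compute_threshold(100, 5, 0.05)  # 71
#' compute_threshold(100, 5, 0)     # 96
#' @export
compute_threshold <- function(L, n, e) {
  if (any(L < n)) stop("read length must be >= token size")
  raw <- (L - (n - 1)) - allowable_errors(L, e) * n
  if (any(raw <= 0)) {
    warning("accumulation-sum threshold clamped to 0 (pass-all): ",
            "error tolerance too high for this read length and token size")
  }
  as.integer(pmax(0, raw))
}

# Per-read precomputation shared by all bins: token codes and the
# ambiguity-adjusted threshold. Each read token containing a non-ACGT base
# contributes 0 to every sum, and each ambiguous *base* is budgeted as one
# extra worst-case substitution (threshold drops by n per ambiguous base),
# which preserves the zero-false-positive guarantee for N-containing reads.
read_filter_profile <- function(read, cfg) {
  seq <- read_seq_string(read)
  n <- cfg$token_size
  L <- nchar(seq)
  if (L < n) stop("read of length ", L, " is shorter than the token size ", n)
  codec <- token_codec(n)
  codes <- scan_token_codes(seq, codec)
  n_ambig_bases <- L - sum(strsplit(seq, "", fixed = TRUE)[[1]] %in% names(BASE_CODES))
  k <- allowable_errors(L, cfg$error_tolerance) + n_ambig_bases
  threshold <- max(0L, as.integer((L - (n - 1)) - k * n))
  list(seq = seq, L = L, codes = codes[!is.na(codes)],
       n_tokens = L - n + 1L, threshold = threshold)
}

#' Accumulation sum of a read against one bin
#'
#' Sums, over the read's token occurrences, the existence bit of each token
#' in the given bin (`Sum_z` for any location `z` in that bin). The location
#' passes when the sum reaches the error-tolerant threshold of
#' [compute_threshold()] (ties pass). Ambiguous read tokens contribute 0 and
#' lower the threshold (see [compute_threshold()] details).
#'
#' @param read Read sequence (single string).
#' @param index A [build_index()] token index.
#' @param bin 0-based bin number.
#' @param cfg A [filter_config()]; its token size must match the index.
#' @return One-row tibble: `bin`, `sum`, `threshold`, `passed`.
#' @examples
#' fx <- worked_example_fixture()
#' idx <- build_index(fx$genome, fx$binning, fx$codec)
#' accumulation_sum(fx$read, idx, 2, filter_config(5, 0.05))
#' @export
accumulation_sum <- function(read, index, bin, cfg) {
  check_cfg_index(cfg, index)
  if (length(bin) != 1L || bin < 0 || bin >= index$binning$num_bins) {
    stop("bin number out of range [0, t)")
  }
  prof <- read_filter_profile(read, cfg)
  s <- accumulation_sum_profile(prof, index, bin)
  tibble::tibble(bin = bin, sum = s, threshold = prof$threshold,
                 passed = s >= prof$threshold)
}

accumulation_sum_profile <- function(prof, index, bin) {
  if (!length(prof$codes)) return(0L)
  sum(index$bits[prof$codes + 1, bin + 1])
}

check_cfg_index <- function(cfg, index) {
  stopifnot(inherits(cfg, "filter_config"), inherits(index, "token_index"))
  if (cfg$token_size != index$codec$token_size) {
    stop("configuration error: filter token size (", cfg$token_size,
         ") differs from index token size (", index$codec$token_size, ")")
  }
  invisible(TRUE)
}

#' Filter candidate seed locations for one read
#'
#' For each candidate location `z` (a 0-based global position interpreted as
#' the read's candidate starting location) the filter evaluates the
#' accumulation sum of the read against the bin containing `z`; the
#' location's pass bit is that bin's pass flag. Each distinct bin is
#' evaluated once and the result is shared by all locations that fall in it.
#' Output row order matches input order.
#'
#' @param read Read sequence (single string) or a one-row tibble with
#'   `read_id` and `seq`.
#' @param locations Numeric vector of candidate 0-based locations.
#' @param index A [build_index()] token index.
#' @param cfg A [filter_config()].
#' @param read_id Identifier recorded in the output (default taken from
#'   `read` when it has one, else `"read"`).
#' @return The seed-location filter bitmask: a tibble with one row per
#'   candidate, columns `read_id`, `location`, `bin`, `sum`, `threshold`,
#'   `pass` (integer 0/1).
#' @export
filter_read_locations <- function(read, locations, index, cfg, read_id = NULL) {
  check_cfg_index(cfg, index)
  if (is.null(read_id)) read_id <- read_id_string(read)
  locations <- as.numeric(locations)
  if (!length(locations)) {
    return(tibble::tibble(read_id = character(), location = numeric(),
                          bin = numeric(), sum = integer(),
                          threshold = integer(), pass = integer()))
  }
  bad <- which(is.na(locations) | locations < 0 |
                 locations >= index$binning$genome_length)
  if (length(bad)) {
    stop("invalid candidate location at entry ", bad[1], ": ",
         locations[bad[1]])
  }
  prof <- read_filter_profile(read, cfg)
  bins <- bin_of_location(locations, index$binning)
  ub <- unique(bins)
  sums <- vapply(ub, function(b) accumulation_sum_profile(prof, index, b),
                 numeric(1))
  s <- sums[match(bins, ub)]
  tibble::tibble(
    read_id = read_id,
    location = locations,
    bin = bins,
    sum = as.integer(s),
    threshold = prof$threshold,
    pass = as.integer(s >= prof$threshold)
  )
}

#' Evaluate one read against a window of consecutive bins, token by token
#'
#' The functional model of the lockstep hardware path: for each token
#' occurrence of the read, one row fetch ([fetch_token_row()]) yields that
#' token's existence bits across the whole window, and per-bin accumulators
#' are updated in lockstep; afterwards every accumulator is compared against
#' the threshold. Results are semantically identical to calling
#' [accumulation_sum()] bin by bin — the window width changes the schedule,
#' never the values.
#'
#' @inheritParams accumulation_sum
#' @param bin_start First bin of the window (0-based).
#' @param w Window width in bins.
#' @return Tibble with one row per bin in the window: `bin`, `sum`,
#'   `threshold`, `passed`.
#' @export
filter_bin_window <- function(read, index, bin_start, w, cfg) {
  check_cfg_index(cfg, index)
  if (w < 1) stop("window width w must be >= 1")
  if (bin_start < 0 || bin_start + w > index$binning$num_bins) {
    stop("bin window out of range [0, t)")
  }
  prof <- read_filter_profile(read, cfg)
  acc <- integer(w)
  for (code in prof$codes) {
    acc <- acc + fetch_token_row(index, code, bin_start, w)
  }
  tibble::tibble(
    bin = bin_start + seq_len(w) - 1,
    sum = acc,
    threshold = prof$threshold,
    passed = acc >= prof$threshold
  )
}

#' Export a seed-location filter bitmask
#'
#' `write_bitmask_tsv()` writes the tibble returned by
#' [filter_read_locations()] as TSV (columns `read_id`, `location`, `bin`,
#' `sum`, `threshold`, `pass`). `bitmask_to_bed()` converts the passing
#' entries to BED intervals `[z, z + L)`.
#'
#' @param bitmask Tibble from [filter_read_locations()].
#' @param path Output path.
#' @param read_length Read length used for the BED interval end.
#' @param chrom Chromosome name for the BED output.
#' @return `write_bitmask_tsv()`: `path` invisibly; `bitmask_to_bed()`: a
#'   tibble with `chrom`, `start`, `end`, `name`.
#' @export
write_bitmask_tsv <- function(bitmask, path) {
  utils::write.table(bitmask, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_bitmask_tsv
#' @export
bitmask_to_bed <- function(bitmask, read_length, chrom = "ref") {
  passing <- bitmask[bitmask$pass == 1L, , drop = FALSE]
  tibble::tibble(
    chrom = chrom,
    start = passing$location,
    end = passing$location + read_length,
    name = passing$read_id
  )
}

# Accept either a plain string or anything with a $seq field.
read_seq_string <- function(read) {
  if (is.character(read) && length(read) == 1L) return(toupper(read))
  if (!is.null(read$seq)) {
    s <- read$seq
    if (length(s) != 1L) stop("expected a single read sequence")
    return(toupper(as.character(s)))
  }
  stop("read must be a single string or have a 'seq' field")
}

read_id_string <- function(read) {
  if (is.list(read) && !is.null(read$read_id) && length(read$read_id) == 1L) {
    return(as.character(read$read_id))
  }
  "read"
}
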
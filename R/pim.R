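#' Configuration of the in-memory filter cost model
#'
#' Abstract parameters of a processing-in-memory realization: `w` logic
#' modules process `w` consecutive bins (a *bin window*) in lockstep, one
#' token row fetch feeding all of them per cycle; the memory row bandwidth
#' caps how many existence bits move per cycle; filter bitmasks accumulate
#' in a fixed logic-layer buffer before being drained.
#'
#' @param bin_window Bin window width `w` in bins (>= 1).
#' @param row_bits_per_cycle Bits copied from a memory row per cycle
#'   (default 4096, the HBM2-class figure); must be >= `bin_window`.
#' @param bitmask_buffer_bytes Bitmask buffer capacity (default 512 KiB).
#' @return Object of class `pim_config`.
#' @export
pim_config <- function(bin_window = 4096, row_bits_per_cycle = 4096,
                       bitmask_buffer_bytes = 524288) {
  if (bin_window < 1 || row_bits_per_cycle < 1 || bitmask_buffer_bytes < 1) {
    stop("all pim_config parameters must be >= 1")
  }
  if (bin_window > row_bits_per_cycle) {
    stop("bin_window w must not exceed row_bits_per_cycle")
  }
  structure(
    list(bin_window = bin_window, row_bits_per_cycle = row_bits_per_cycle,
         bitmask_buffer_bytes = bitmask_buffer_bytes),
    class = "pim_config"
  )
}

#' @export
print.pim_config <- function(x, ...) {
  cat("<pim_config> bin window w = ", x$bin_window, ", row bandwidth ",
      x$row_bits_per_cycle, " bits/cycle, bitmask buffer ",
      x$bitmask_buffer_bytes, " bytes\n", sep = "")
  invisible(x)
}

#' Bin windows containing at least one candidate location
#'
#' Window `i` covers bins `[i*w, (i+1)*w)`; only windows holding a candidate
#' seed location need to be processed — a span of consecutive empty bins is
#' skipped entirely.
#'
#' @param locations Numeric vector of candidate 0-based genome locations.
#' @param binning A [make_binning()] configuration.
#' @param w Bin window width.
#' @return Sorted numeric vector of 0-based window indices (empty when there
#'   are no candidates).
#' @export
windows_touched <- function(locations, binning, w) {
  stopifnot(inherits(binning, "binning_config"))
  if (w < 1) stop("window width w must be >= 1")
  if (!length(locations)) return(numeric(0))
  bins <- bin_of_location(locations, binning)
  sort(unique(floor(bins / w)))
}

#' Analytic cost of filtering one read's candidates in memory
#'
#' Schedule-only model (no DRAM timing): for every touched bin window, each
#' of the read's `L - n + 1` token occurrences costs one row activation; the
#' lockstep pipeline spends `ceil(w / row_bits_per_cycle)` cycles per row
#' fetch plus one compare/writeback cycle per window; each touched window
#' emits `ceil(bins_in_window / 8)` bitmask bytes. Functional results are
#' identical for every `w` (see [filter_bin_window()]); only these counts
#' change.
#'
#' @param read_length Read length `L`.
#' @param n Token size.
#' @param locations Candidate 0-based genome locations.
#' @param binning A [make_binning()] configuration.
#' @param pim A [pim_config()].
#' @return One-row tibble of class `cost_report`: `windows_processed`,
#'   `row_activations`, `lockstep_cycles`, `bitmask_bytes`,
#'   `bitmask_buffer_fills`.
#' @export
estimate_cost <- function(read_length, n, locations, binning, pim) {
  stopifnot(inherits(pim, "pim_config"))
  if (read_length < n) stop("read length must be >= token size")
  w <- pim$bin_window
  wins <- windows_touched(locations, binning, w)
  tokens <- read_length - n + 1
  nwin <- length(wins)
  # last window may hold fewer than w bins
  bins_in <- pmin(w, binning$num_bins - wins * w)
  row_activations <- tokens * nwin
  cycles_per_fetch <- ceiling(w / pim$row_bits_per_cycle)
  lockstep_cycles <- row_activations * cycles_per_fetch + nwin
  bitmask_bytes <- sum(ceiling(bins_in / 8))
  structure(
    tibble::tibble(
      windows_processed = nwin,
      row_activations = row_activations,
      lockstep_cycles = lockstep_cycles,
      bitmask_bytes = bitmask_bytes,
      bitmask_buffer_fills = ceiling(bitmask_bytes / pim$bitmask_buffer_bytes)
    ),
    class = c("cost_report", class(tibble::tibble()))
  )
}

#' Write a cost report as JSON
#'
#' @param report A [estimate_cost()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cost_json <- function(report, path) {
  jsonlite::write_json(as.list(tibble::as_tibble(report)[1, ]), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Analytic hardware parameters
#'
#' `bitvector_length()` is the per-bin bitvector length in bits, `4^n` (one
#' existence bit per possible token). `accumulator_bits()` is the width of
#' each lockstep accumulator, `ceil(log2(read_length))` bits — enough to
#' hold the maximum accumulation sum `L - n + 1` of a length-`L` read.
#'
#' @param token_size Token length `n`.
#' @param read_length Read length `L`.
#' @return An integer (bits).
#' @examples
#' bitvector_length(5)   # 1024
#' accumulator_bits(100) # 7
#' @export
bitvector_length <- function(token_size) {
  if (any(token_size < 1)) stop("token_size must be >= 1")
  4^token_size
}

#' @rdname bitvector_length
#' @export
accumulator_bits <- function(read_length) {
  if (any(read_length < 1)) stop("read_length must be >= 1")
  as.integer(ceiling(log2(read_length)))
}
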
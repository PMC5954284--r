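#' Divide a genome into overlapping bins
#'
#' The reference is cut into `num_bins` bins of fixed stride
#' `ceil(genome_length / num_bins)`; each bin additionally extends `overlap`
#' bases past its stride so that consecutive bins share `overlap` bases.
#' Bin `i` covers global positions `[i*stride, min(i*stride + stride +
#' overlap, record_end))`. The overlap is what lets a whole read (plus any
#' bases gained through deletions) sit inside a single bin, which is the
#' containment the accumulation-sum filter relies on: any window of
#' `overlap + 1` or fewer bases starting at `z` lies entirely inside bin
#' `floor(z / stride)`.
#'
#' For a multi-record genome every record is binned independently with the
#' same stride and overlap (bins never span record boundaries, so no phantom
#' tokens appear across chromosome junctions); bins are numbered
#' consecutively across records, and the realized total may exceed the
#' requested `num_bins` by up to one bin per record.
#'
#' @param genome A [genome_sequence()], or a single genome length in bases.
#' @param num_bins Requested number of bins `t` (>= 1).
#' @param overlap Bases shared between consecutive bins (>= 0). The default
#'   that guarantees containment for reads of length `L` under error
#'   tolerance `e` is `default_overlap(L, e)`.
#' @return An object of class `binning_config`: fields `stride`, `overlap`,
#'   `bin_width` (= stride + overlap), `num_bins` (realized total `t`),
#'   `genome_length`, and a tibble `records` with per-record `name`,
#'   `offset`, `length`, `bin_offset`, `num_bins`.
#' @examples
#' b <- make_binning(1000, 10, overlap = 99)
#' b$stride     # 100
#' b$bin_width  # 199
#' @export
make_binning <- function(genome, num_bins, overlap = 0) {
  if (inherits(genome, "genome_sequence")) {
    lens <- genome$lengths
    nms <- genome$names
    offs <- genome$offsets
  } else {
    lens <- as.numeric(genome)
    if (length(lens) != 1L || is.na(lens) || lens < 1) {
      stop("genome must be a genome_sequence or a single positive length")
    }
    nms <- "genome"
    offs <- 0
  }
  total <- sum(lens)
  num_bins <- as.numeric(num_bins)
  if (num_bins < 1) stop("num_bins must be >= 1")
  if (total < num_bins) {
    stop("configuration error: genome length (", total,
         ") is smaller than the requested number of bins (", num_bins, ")")
  }
  overlap <- as.numeric(overlap)
  if (overlap < 0) stop("overlap must be >= 0")
  stride <- ceiling(total / num_bins)
  rec_bins <- pmax(1, ceiling(lens / stride))
  structure(
    list(
      stride = stride,
      overlap = overlap,
      bin_width = stride + overlap,
      num_bins = sum(rec_bins),
      genome_length = total,
      records = tibble::tibble(
        name = nms,
        offset = offs,
        length = lens,
        bin_offset = cumsum(c(0, rec_bins[-length(rec_bins)])),
        num_bins = rec_bins
      )
    ),
    class = "binning_config"
  )
}

#' @rdname make_binning
#' @param stride Bin stride in bases; `binning_from_stride()` derives the bin
#'   count as `ceil(genome_length / stride)` per record.
#' @export
binning_from_stride <- function(genome, stride, overlap = 0) {
  stride <- as.numeric(stride)
  if (stride < 1) stop("stride must be >= 1")
  overlap <- as.numeric(overlap)
  if (overlap < 0) stop("overlap must be >= 0")
  if (inherits(genome, "genome_sequence")) {
    lens <- genome$lengths
    nms <- genome$names
    offs <- genome$offsets
  } else {
    lens <- as.numeric(genome)
    if (length(lens) != 1L || is.na(lens) || lens < 1) {
      stop("genome must be a genome_sequence or a single positive length")
    }
    nms <- "genome"
    offs <- 0
  }
  rec_bins <- pmax(1, ceiling(lens / stride))
  structure(
    list(
      stride = stride,
      overlap = overlap,
      bin_width = stride + overlap,
      num_bins = sum(rec_bins),
      genome_length = sum(lens),
      records = tibble::tibble(
        name = nms,
        offset = offs,
        length = lens,
        bin_offset = cumsum(c(0, rec_bins[-length(rec_bins)])),
        num_bins = rec_bins
      )
    ),
    class = "binning_config"
  )
}

#' Default bin overlap for a read length and error tolerance
#'
#' `max_read_length + ceil(max_read_length * e) - 1`: the weakest overlap for
#' which a read window, lengthened by up to `ceil(L*e)` reference bases
#' through deletions, is still contained in the bin of its starting location.
#'
#' @param max_read_length Longest read the filter must contain, bases.
#' @param e Alignment error tolerance in `[0, 1)`.
#' @return Overlap in bases.
#' @export
default_overlap <- function(max_read_length, e) {
  max_read_length + allowable_errors(max_read_length, e) - 1
}

#' @export
print.binning_config <- function(x, ...) {
  cat("<binning_config> t = ", format(x$num_bins, big.mark = ","),
      " bins, stride ", x$stride, ", overlap ", x$overlap,
      " (bin width ", x$bin_width, ") over ",
      format(x$genome_length, big.mark = ","), " bases, ",
      nrow(x$records), " record(s)\n", sep = "")
  invisible(x)
}

#' Bin containing a genome location
#'
#' Returns the (0-based) bin number whose stride interval contains global
#' 0-based location `z`: within a record, `bin_offset + floor(local / stride)`.
#' Because bins overlap, `z` may also fall inside the previous bin's extent;
#' this function always returns the anchoring (stride) bin, the bin that
#' contains the whole window `[z, z + overlap + 1)` (clipped to the record).
#'
#' @param z Numeric vector of global 0-based locations.
#' @param binning A [make_binning()] configuration.
#' @return Numeric vector of 0-based bin numbers.
#' @examples
#' b <- make_binning(1000, 10, overlap = 99)
#' bin_of_location(c(0, 199, 200, 250), b)  # 0 1 2 2
#' @export
bin_of_location <- function(z, binning) {
  stopifnot(inherits(binning, "binning_config"))
  z <- as.numeric(z)
  if (anyNA(z) || any(z < 0 | z >= binning$genome_length)) {
    stop("location out of range [0, genome_length)")
  }
  rec <- findInterval(z, binning$records$offset)
  local <- z - binning$records$offset[rec]
  binning$records$bin_offset[rec] + floor(local / binning$stride)
}

# Global [start, end) interval of 0-based bin numbers (vectorized).
bin_interval <- function(bin, binning) {
  if (anyNA(bin) || any(bin < 0 | bin >= binning$num_bins)) {
    stop("bin number out of range [0, t)")
  }
  recs <- binning$records
  rec <- findInterval(bin, recs$bin_offset)
  local <- bin - recs$bin_offset[rec]
  start <- recs$offset[rec] + local * binning$stride
  end <- pmin(start + binning$bin_width, recs$offset[rec] + recs$length[rec])
  list(start = start, end = end)
}

# The DNA string covered by one bin.
bin_sequence <- function(genome, binning, bin) {
  iv <- bin_interval(bin, binning)
  rec <- findInterval(bin, binning$records$bin_offset)
  local_start <- iv$start - genome$offsets[rec]
  local_end <- iv$end - genome$offsets[rec]
  substr(genome$seqs[rec], local_start + 1, local_end)
}
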
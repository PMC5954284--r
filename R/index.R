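#' Build the per-bin token-existence bitvector index
#'
#' Scans the reference once and records, for every bin `x` and every possible
#' token of length `n`, whether that token occurs as a substring of the bin's
#' sequence. The result is a `4^n x t` bit matrix: row `k` is the existence
#' bit of the token with code `k` across all `t` bins (so fetching one row
#' yields one token's bit across many consecutive bins, mirroring how the
#' bitvectors would be laid out along a memory row in hardware). Tokens that
#' overlap a non-ACGT reference character set no bits.
#'
#' @param genome A [genome_sequence()].
#' @param binning A [make_binning()] configuration for the same genome; its
#'   `bin_width` must be at least the token size.
#' @param codec A [token_codec()].
#' @param genome_name Label stored with the index.
#' @return An object of class `token_index` with fields `binning`, `codec`,
#'   `bits` (logical `4^n x t` matrix), `genome_name`, `version`.
#' @examples
#' fx <- worked_example_fixture()
#' idx <- build_index(fx$genome, fx$binning, fx$codec)
#' existence_bit(idx, encode_token("GACAG", fx$codec), 2)
#' @export
build_index <- function(genome, binning, codec, genome_name = genome$names[1]) {
  stopifnot(inherits(genome, "genome_sequence"),
            inherits(binning, "binning_config"),
            inherits(codec, "token_codec"))
  n <- codec$token_size
  if (binning$bin_width < n) {
    stop("configuration error: bin_width (", binning$bin_width,
         ") is smaller than the token size (", n, ")")
  }
  if (binning$genome_length != genome$genome_length) {
    stop("binning was built for a genome of different length")
  }
  stride <- binning$stride
  width <- binning$bin_width
  bits <- matrix(FALSE, nrow = codec$n_tokens, ncol = binning$num_bins)
  # A token at local position p lies in every bin b with
  # b*stride <= p and p + n <= b*stride + width; that is at most
  # 1 + floor((width - n) / stride) bins per position.
  max_back <- floor((width - n) / stride)
  for (r in seq_along(genome$seqs)) {
    codes <- scan_token_codes(genome$seqs[r], codec)
    if (!length(codes)) next
    p <- which(!is.na(codes)) - 1  # 0-based local positions of clean tokens
    codes <- codes[p + 1]
    anchor <- floor(p / stride)
    bin_offset <- binning$records$bin_offset[r]
    for (j in 0:max_back) {
      b <- anchor - j
      keep <- b >= 0 & (b * stride + width >= p + n)
      if (!any(keep)) next
      bits[cbind(codes[keep] + 1, bin_offset + b[keep] + 1)] <- TRUE
    }
  }
  structure(
    list(binning = binning, codec = codec, bits = bits,
         genome_name = as.character(genome_name), version = 1L),
    class = "token_index"
  )
}

#' @export
print.token_index <- function(x, ...) {
  cat("<token_index> '", x$genome_name, "': ", x$codec$n_tokens,
      " tokens (n = ", x$codec$token_size, ") x ",
      format(x$binning$num_bins, big.mark = ","), " bins; ",
      format(sum(x$bits), big.mark = ","), " bits set; raw footprint ",
      format(footprint_bytes(x$binning$num_bins, x$codec$token_size),
             big.mark = ","), " bytes\n", sep = "")
  invisible(x)
}

#' Query existence bits
#'
#' `existence_bit()` reads the bit of one token in one bin;
#' `fetch_token_row()` reads one token's bits across a window of `w`
#' consecutive bins (the row-granularity access pattern of the in-memory
#' realization). Both are pure reads; both are vectorized over `token_code`
#' / `bin`.
#'
#' @param index A [build_index()] result.
#' @param token_code Integer code(s) in `[0, 4^n)` (see [encode_token()]).
#' @param bin 0-based bin number(s) in `[0, t)`.
#' @param bin_start First bin of the window (0-based).
#' @param w Window width in bins (>= 1).
#' @return `existence_bit()`: integer 0/1 vector. `fetch_token_row()`:
#'   integer 0/1 vector of length `w`, bins `bin_start` to
#'   `bin_start + w - 1` in order.
#' @export
existence_bit <- function(index, token_code, bin) {
  stopifnot(inherits(index, "token_index"))
  if (anyNA(token_code) || any(token_code < 0 | token_code >= index$codec$n_tokens)) {
    stop("token code out of range [0, 4^n)")
  }
  if (anyNA(bin) || any(bin < 0 | bin >= index$binning$num_bins)) {
    stop("bin number out of range [0, t)")
  }
  as.integer(index$bits[cbind(token_code + 1, bin + 1)])
}

#' @rdname existence_bit
#' @export
fetch_token_row <- function(index, token_code, bin_start, w) {
  stopifnot(inherits(index, "token_index"), length(token_code) == 1L)
  if (w < 1) stop("window width w must be >= 1")
  if (bin_start < 0 || bin_start + w > index$binning$num_bins) {
    stop("bin window [", bin_start, ", ", bin_start + w, ") out of range [0, ",
         index$binning$num_bins, ")")
  }
  if (token_code < 0 || token_code >= index$codec$n_tokens) {
    stop("token code out of range [0, 4^n)")
  }
  as.integer(index$bits[token_code + 1, (bin_start + 1):(bin_start + w)])
}

#' Raw memory footprint of an index configuration
#'
#' One bitvector of `4^n` bits per bin: `num_bins * 4^token_size / 8` bytes,
#' before any per-row byte padding or file header.
#'
#' @param num_bins Number of bins `t`.
#' @param token_size Token length `n`.
#' @return Footprint in bytes (numeric; may exceed 2^31).
#' @examples
#' footprint_bytes(450 * 2^16, 5) / 1e9  # ~3.77 GB
#' @export
footprint_bytes <- function(num_bins, token_size) {
  if (any(num_bins < 1) || any(token_size < 1)) {
    stop("num_bins and token_size must be >= 1")
  }
  num_bins * 4^token_size / 8
}

INDEX_MAGIC <- charToRaw("SSIX")
INDEX_FORMAT_VERSION <- 1L

#' Save / load a token index
#'
#' The on-disk format is a little-endian binary file: the magic bytes
#' `SSIX`, a format version, the codec and binning metadata (including the
#' per-record layout of a multi-record genome), then the bit matrix packed
#' token-major — `4^n` rows of `ceil(t/8)` bytes, each row byte-padded, so a
#' row of the file is one token's existence bits across all bins. The full
#' byte layout is documented in `inst/doc-format/index-format.md`.
#' `load_index(save_index(x))` is bit-identical to `x`.
#'
#' @param index A `token_index`.
#' @param path File path.
#' @return `save_index()`: `path` invisibly. `load_index()`: a `token_index`.
#' @export
save_index <- function(index, path) {
  stopifnot(inherits(index, "token_index"))
  con <- file(path, "wb")
  on.exit(close(con))
  wint <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wdbl <- function(x) writeBin(as.numeric(x), con, size = 8L, endian = "little")
  wstr <- function(s) {
    raw <- charToRaw(s)
    wint(length(raw))
    writeBin(raw, con)
  }
  writeBin(INDEX_MAGIC, con)
  wint(index$version)
  wint(index$codec$token_size)
  b <- index$binning
  wdbl(b$num_bins); wdbl(b$stride); wdbl(b$overlap); wdbl(b$genome_length)
  wstr(index$genome_name)
  wint(nrow(b$records))
  for (r in seq_len(nrow(b$records))) {
    wstr(b$records$name[r])
    wdbl(b$records$length[r])
    wdbl(b$records$num_bins[r])
  }
  t <- b$num_bins
  bytes_per_row <- ceiling(t / 8)
  pad <- bytes_per_row * 8 - t
  m <- index$bits
  if (pad > 0) m <- cbind(m, matrix(FALSE, nrow(m), pad))
  writeBin(packBits(as.vector(t(m)), type = "raw"), con)
  invisible(path)
}

#' @rdname save_index
#' @export
load_index <- function(path) {
  if (!file.exists(path)) stop("index file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  corrupt <- function(why) stop("corrupt index file (", why, "): ", path)
  rint <- function() {
    x <- readBin(con, "integer", size = 4L, endian = "little")
    if (length(x) != 1L) corrupt("truncated header")
    x
  }
  rdbl <- function() {
    x <- readBin(con, "numeric", size = 8L, endian = "little")
    if (length(x) != 1L) corrupt("truncated header")
    x
  }
  rstr <- function() {
    len <- rint()
    if (len < 0 || len > 1e6) corrupt("bad string length")
    raw <- readBin(con, "raw", n = len)
    if (length(raw) != len) corrupt("truncated header")
    rawToChar(raw)
  }
  magic <- readBin(con, "raw", n = 4L)
  if (length(magic) != 4L || !identical(magic, INDEX_MAGIC)) corrupt("bad magic bytes")
  version <- rint()
  if (version != INDEX_FORMAT_VERSION) corrupt(paste0("unsupported version ", version))
  token_size <- rint()
  if (token_size < 1L || token_size > 15L) corrupt("bad token size")
  num_bins <- rdbl(); stride <- rdbl(); overlap <- rdbl(); genome_length <- rdbl()
  genome_name <- rstr()
  n_records <- rint()
  if (n_records < 1L || n_records > 1e6) corrupt("bad record count")
  rec_name <- character(n_records)
  rec_len <- numeric(n_records)
  rec_bins <- numeric(n_records)
  for (r in seq_len(n_records)) {
    rec_name[r] <- rstr()
    rec_len[r] <- rdbl()
    rec_bins[r] <- rdbl()
  }
  if (sum(rec_len) != genome_length) corrupt("record lengths disagree with genome length")
  if (sum(rec_bins) != num_bins) corrupt("record bin counts disagree with total")
  binning <- structure(
    list(
      stride = stride, overlap = overlap, bin_width = stride + overlap,
      num_bins = num_bins, genome_length = genome_length,
      records = tibble::tibble(
        name = rec_name,
        offset = cumsum(c(0, rec_len[-n_records])),
        length = rec_len,
        bin_offset = cumsum(c(0, rec_bins[-n_records])),
        num_bins = rec_bins
      )
    ),
    class = "binning_config"
  )
  codec <- token_codec(token_size)
  bytes_per_row <- ceiling(num_bins / 8)
  payload <- readBin(con, "raw", n = codec$n_tokens * bytes_per_row + 1)
  if (length(payload) != codec$n_tokens * bytes_per_row) {
    corrupt("bit payload has wrong size")
  }
  unpacked <- as.logical(rawToBits(payload))
  m <- matrix(unpacked, nrow = bytes_per_row * 8, ncol = codec$n_tokens)
  bits <- t(m)[, seq_len(num_bins), drop = FALSE]
  structure(
    list(binning = binning, codec = codec, bits = bits,
         genome_name = genome_name, version = version),
    class = "token_index"
  )
}
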
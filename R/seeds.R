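#' Build an exact-match k-mer seed index over the forward strand
#'
#' A stand-in for a read mapper's hash table: every `seed_length`-mer of the
#' reference (forward strand, per record, never spanning record boundaries)
#' is stored with its sorted list of global 0-based locations. Seeds that
#' overlap non-ACGT characters are not indexed.
#'
#' @param genome A [genome_sequence()].
#' @param seed_length Seed k-mer length (1..15; default 12).
#' @return An object of class `seed_index`.
#' @examples
#' si <- build_seed_index(genome_sequence("ACGTACGT"), 4)
#' seed_locations(si, "ACGT")  # 0 4
#' @export
build_seed_index <- function(genome, seed_length = 12) {
  stopifnot(inherits(genome, "genome_sequence"))
  seed_length <- as.integer(seed_length)
  if (is.na(seed_length) || seed_length < 1L || seed_length > 15L) {
    stop("seed_length must be in 1..15")
  }
  codec <- token_codec(seed_length)
  codes_all <- numeric(0)
  pos_all <- numeric(0)
  for (r in seq_along(genome$seqs)) {
    codes <- scan_token_codes(genome$seqs[r], codec)
    if (!length(codes)) next
    keep <- !is.na(codes)
    codes_all <- c(codes_all, codes[keep])
    pos_all <- c(pos_all, genome$offsets[r] + which(keep) - 1)
  }
  ord <- order(codes_all, pos_all)
  codes_sorted <- codes_all[ord]
  pos_sorted <- pos_all[ord]
  uniq <- unique(codes_sorted)
  # first occurrence of each unique code in the sorted vector
  first <- c(1, which(diff(codes_sorted) != 0) + 1)
  structure(
    list(seed_length = seed_length, codec = codec,
         codes = uniq, first = first,
         count = diff(c(first, length(codes_sorted) + 1)),
         positions = pos_sorted,
         n_seeds = length(codes_sorted)),
    class = "seed_index"
  )
}

#' @export
print.seed_index <- function(x, ...) {
  cat("<seed_index> k = ", x$seed_length, ": ",
      format(x$n_seeds, big.mark = ","), " indexed positions, ",
      format(length(x$codes), big.mark = ","), " distinct seeds\n", sep = "")
  invisible(x)
}

#' Look up the genome locations of one seed
#'
#' @param seed_index A [build_seed_index()] result.
#' @param seed Seed string of length `seed_length` (non-ACGT characters give
#'   no hits).
#' @return Sorted numeric vector of global 0-based locations (possibly
#'   empty).
#' @export
seed_locations <- function(seed_index, seed) {
  stopifnot(inherits(seed_index, "seed_index"))
  code <- encode_token(seed, seed_index$codec, ambiguous_na = TRUE)
  seed_locations_code(seed_index, code)
}

seed_locations_code <- function(seed_index, code) {
  if (is.na(code)) return(numeric(0))
  i <- match(code, seed_index$codes)
  if (is.na(i)) return(numeric(0))
  from <- seed_index$first[i]
  seed_index$positions[from:(from + seed_index$count[i] - 1)]
}

#' Reverse complement of a DNA string
#'
#' @param seq A single DNA string (IUPAC codes allowed).
#' @return The reverse complement as a string.
#' @export
reverse_complement <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Candidate mapping locations of a read from its seeds
#'
#' Takes `num_seeds` non-overlapping seeds from the read at fixed offsets
#' `0, seed_length, 2*seed_length, ...`, looks each up in the seed index and
#' projects every hit back to a candidate read-start location
#' `z = hit - offset`. The reverse-complemented read is processed
#' symmetrically and reported with strand `"-"` (its `z` is the start of the
#' reverse-complement on the forward reference). Hits projecting to a
#' negative start are dropped; `(location, strand)` pairs are deduplicated
#' (first contributing seed kept).
#'
#' @param read Read sequence (single string, or a row with `read_id`,
#'   `seq`).
#' @param seed_index A [build_seed_index()] result.
#' @param num_seeds Number of seeds per strand; default
#'   `floor(L / seed_length)` (all non-overlapping seeds).
#' @param read_id Identifier for the output.
#' @return Tibble with columns `read_id`, `location`, `strand`,
#'   `seed_offset`.
#' @export
candidate_locations <- function(read, seed_index, num_seeds = NULL,
                                read_id = NULL) {
  stopifnot(inherits(seed_index, "seed_index"))
  seq <- read_seq_string(read)
  if (is.null(read_id)) read_id <- read_id_string(read)
  L <- nchar(seq)
  sl <- seed_index$seed_length
  if (is.null(num_seeds)) num_seeds <- L %/% sl
  if (num_seeds < 1 || L < num_seeds * sl) {
    stop("read of length ", L, " is too short for ", num_seeds,
         " seeds of length ", sl)
  }
  one_strand <- function(s, strand) {
    codes <- scan_token_codes(s, seed_index$codec)
    offsets <- (seq_len(num_seeds) - 1) * sl
    out <- lapply(offsets, function(off) {
      hits <- seed_locations_code(seed_index, codes[off + 1])
      z <- hits - off
      z <- z[z >= 0]
      if (!length(z)) return(NULL)
      tibble::tibble(location = z, strand = strand, seed_offset = off)
    })
    dplyr::bind_rows(out)
  }
  res <- dplyr::bind_rows(
    one_strand(seq, "+"),
    one_strand(reverse_complement(seq), "-")
  )
  if (!nrow(res)) {
    return(tibble::tibble(read_id = character(), location = numeric(),
                          strand = character(), seed_offset = numeric()))
  }
  res <- dplyr::distinct(res, .data$location, .data$strand,
                         .keep_all = TRUE)
  res <- dplyr::arrange(res, .data$strand, .data$location)
  tibble::tibble(read_id = read_id, res)
}
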
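#' Verify a candidate location by semi-global edit distance
#'
#' The verification step of the seed-and-extend loop: the read is aligned
#' end-to-end against the reference window `[z - k, z + L + k)` (clipped to
#' the containing record), where `k = allowable_errors(L, e)` slack on each
#' side absorbs indel-induced shifts of the candidate start. The distance is
#' the unit-cost semi-global edit distance (free reference ends, minimum
#' over end positions); the location is accepted when the distance is at
#' most `k` — the same error budget the filter's threshold tolerates.
#'
#' @param read Read sequence (single string or anything with `$seq`).
#' @param genome A [genome_sequence()].
#' @param z Candidate 0-based starting location of the read.
#' @param e Error tolerance in `[0, 1)`.
#' @return One-row tibble: `location`, `edit_distance`, `accepted`.
#' @examples
#' g <- genome_sequence("ACGTACGTACGTACGT")
#' verify_alignment("GTACGTAC", g, 2, 0.1)
#' @export
verify_alignment <- function(read, genome, z, e) {
  stopifnot(inherits(genome, "genome_sequence"))
  seq <- read_seq_string(read)
  L <- nchar(seq)
  if (length(z) != 1L || is.na(z) || z < 0 || z >= genome$genome_length) {
    stop("candidate location out of range [0, genome_length)")
  }
  k <- allowable_errors(L, e)
  rec <- record_of_location(genome, z)
  local <- z - genome$offsets[rec]
  win_start <- max(0, local - k)
  window <- substr(genome$seqs[rec], win_start + 1,
                   min(local + L + k, genome$lengths[rec]))
  d <- .semiglobal_edit_distance(seq, window)
  tibble::tibble(location = z, edit_distance = d, accepted = d <= k)
}
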
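#' Construct a genome sequence object
#'
#' A genome is one or more named DNA sequences (chromosomes/contigs) laid out
#' on a single 0-based global coordinate axis: record `i` occupies
#' `[offset[i], offset[i] + length[i])`. Sequences are uppercased on
#' construction; characters outside `A`, `C`, `G`, `T` are kept verbatim and
#' treated as ambiguous by all token operations.
#'
#' @param seqs Character vector of DNA sequences (one element per record).
#' @param names Record names; defaults to `seq1`, `seq2`, ...
#' @return An object of class `genome_sequence` with fields `names`, `seqs`,
#'   `lengths`, `offsets` (0-based global start of each record) and
#'   `genome_length` (total bases).
#' @examples
#' g <- genome_sequence("ACGTACGTAA", "toy")
#' g$genome_length
#' @export
genome_sequence <- function(seqs, names = NULL) {
  if (length(seqs) < 1L) stop("genome must contain at least one sequence")
  seqs <- toupper(as.character(seqs))
  lens <- unname(nchar(seqs))
  if (any(lens < 1L)) stop("every genome record must have length >= 1")
  if (is.null(names)) {
    names <- if (!is.null(base::names(seqs))) base::names(seqs) else paste0("seq", seq_along(seqs))
  }
  structure(
    list(
      names = as.character(names),
      seqs = unname(seqs),
      lengths = as.numeric(lens),
      offsets = cumsum(c(0, lens[-length(lens)])),
      genome_length = sum(as.numeric(lens))
    ),
    class = "genome_sequence"
  )
}

#' @export
print.genome_sequence <- function(x, ...) {
  cat("<genome_sequence> ", length(x$seqs), " record(s), ",
      format(x$genome_length, big.mark = ","), " bases\n", sep = "")
  for (i in seq_along(x$seqs)) {
    cat("  ", x$names[i], ": ", format(x$lengths[i], big.mark = ","),
        " bases at global offset ", x$offsets[i], "\n", sep = "")
  }
  invisible(x)
}

#' Read a reference genome from FASTA
#'
#' Multi-record FASTA is allowed; records are placed end-to-end on the global
#' coordinate axis (binning never spans record boundaries, see
#' [make_binning()]).
#'
#' @param path Path to a FASTA file.
#' @return A [genome_sequence()] object.
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) < 1L) stop("FASTA file contains no records: ", path)
  nm <- sub("\\s.*$", "", names(set))
  genome_sequence(as.character(set), nm)
}

#' Write a genome to FASTA
#'
#' @param genome A [genome_sequence()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  stopifnot(inherits(genome, "genome_sequence"))
  set <- Biostrings::DNAStringSet(genome$seqs)
  names(set) <- genome$names
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

# Record index (1-based) containing global 0-based position z.
record_of_location <- function(genome, z) {
  findInterval(z, genome$offsets)
}

# Extract genome[z, z + width) as a string, clipped to the containing record.
# Used by the verifier; windows never span record boundaries.
genome_window <- function(genome, z, width) {
  rec <- record_of_location(genome, z)
  local <- z - genome$offsets[rec]
  end <- min(local + width, genome$lengths[rec])
  substr(genome$seqs[rec], local + 1, end)
}
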
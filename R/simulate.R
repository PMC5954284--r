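#' Generate a uniform-random reference genome
#'
#' Bases are i.i.d. uniform over ACGT; deterministic for a given seed (the
#' caller's RNG state is left untouched).
#'
#' @param length Genome length in bases (>= 1).
#' @param seed Integer RNG seed.
#' @param name Record name.
#' @return A [genome_sequence()] with one record.
#' @export
random_genome <- function(length, seed = 1L, name = "random") {
  if (length < 1) stop("genome length must be >= 1")
  withr::with_seed(seed, {
    genome_sequence(
      paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
            collapse = ""),
      name
    )
  })
}

#' Plant reads with controlled errors at known positions
#'
#' Samples each read from a uniform random position on a uniform random
#' strand, then mutates it with exactly the configured number of
#' substitutions, insertions and deletions, placed uniformly without
#' replacement. Read length stays fixed at `read_length`: a deletion removes
#' a read base and the window extends one extra reference base; an insertion
#' adds a random base and the window shrinks by one. The returned truth
#' table records the planted start, strand, reference span and error
#' counts, so false negatives/positives can be scored without re-deriving
#' ground truth.
#'
#' @param genome A [genome_sequence()].
#' @param n_reads Number of reads.
#' @param read_length Read length `L` (all reads; default 100).
#' @param substitutions,insertions,deletions Per-read error counts; each
#'   either a single value or a vector of length `n_reads`.
#' @param rc_fraction Fraction of reads planted on the reverse strand
#'   (default 0.5).
#' @param seed Integer RNG seed.
#' @return List with `reads` (tibble `read_id`, `seq`) and `truth` (tibble
#'   `read_id`, `true_location` — 0-based start of the source window on the
#'   forward reference —, `strand`, `ref_span`, `substitutions`,
#'   `insertions`, `deletions`, `n_errors`).
#' @export
plant_reads <- function(genome, n_reads, read_length = 100,
                        substitutions = 0, insertions = 0, deletions = 0,
                        rc_fraction = 0.5, seed = 1L) {
  stopifnot(inherits(genome, "genome_sequence"))
  rep_n <- function(x, what) {
    x <- as.integer(x)
    if (length(x) == 1L) x <- rep(x, n_reads)
    if (length(x) != n_reads || anyNA(x) || any(x < 0)) {
      stop(what, " must be a non-negative count or a vector of length n_reads")
    }
    x
  }
  subs <- rep_n(substitutions, "substitutions")
  ins <- rep_n(insertions, "insertions")
  del <- rep_n(deletions, "deletions")
  if (any(ins + del > read_length)) stop("more indels than read bases")
  if (any(read_length - ins < 0)) stop("infeasible error configuration")
  span <- read_length + del - ins
  if (any(span < 1) || any(span > max(genome$lengths))) {
    stop("infeasible configuration: reference span outside genome record")
  }
  bases <- c("A", "C", "G", "T")
  withr::with_seed(seed, {
    reads <- character(n_reads)
    pos <- numeric(n_reads)
    strand <- ifelse(stats::runif(n_reads) < rc_fraction, "-", "+")
    # sample records proportionally to the positions they can host
    for (i in seq_len(n_reads)) {
      capacity <- pmax(0, genome$lengths - span[i] + 1)
      if (sum(capacity) < 1) stop("no genome record can host a read of span ", span[i])
      rec <- sample.int(length(capacity), 1, prob = capacity)
      p <- sample.int(capacity[rec], 1) - 1  # 0-based local start
      segment <- substr(genome$seqs[rec], p + 1, p + span[i])
      q <- if (strand[i] == "-") reverse_complement(segment) else segment
      chars <- strsplit(q, "", fixed = TRUE)[[1]]
      # deletions: drop d read bases
      if (del[i] > 0) {
        chars <- chars[-sample.int(length(chars), del[i])]
      }
      # insertions: add random bases at random junctions
      if (ins[i] > 0) {
        at <- sort(sample.int(length(chars) + 1, ins[i], replace = TRUE))
        for (j in seq_along(at)) {
          a <- at[j] + j - 1  # account for previously inserted bases
          chars <- append(chars, sample(bases, 1), after = a - 1)
        }
      }
      # substitutions: change to a different base
      if (subs[i] > 0) {
        at <- sample.int(length(chars), subs[i])
        for (a in at) {
          chars[a] <- sample(setdiff(bases, chars[a]), 1)
        }
      }
      stopifnot(length(chars) == read_length)
      reads[i] <- paste(chars, collapse = "")
      pos[i] <- genome$offsets[rec] + p
    }
    ids <- sprintf("read%04d", seq_len(n_reads))
    list(
      reads = tibble::tibble(read_id = ids, seq = reads),
      truth = tibble::tibble(
        read_id = ids, true_location = pos, strand = strand,
        ref_span = span, substitutions = subs, insertions = ins,
        deletions = del, n_errors = subs + ins + del
      )
    )
  })
}

#' Tiny worked-example fixture
#'
#' A deterministic 100-base toy genome binned with stride 20 and overlap 8
#' (token size 5), built so that bin 2 contains the token `GACAG` but not
#' `TTTTT` — the canonical illustration of the existence-bit semantics —
#' plus a short read drawn from bin 2. Used in documentation and tests.
#'
#' @return List with `genome`, `binning`, `codec`, `read` (a string from
#'   bin 2's interval) and `read_location` (its 0-based start).
#' @export
worked_example_fixture <- function() {
  # bins (stride 20, overlap 8): bin 0 [0,28) bin 1 [20,48) bin 2 [40,68)
  # bin 3 [60,88) bin 4 [80,100). GACAG sits at position 50 (inside bin 2);
  # TTTTT appears only at position 5 (bins 0 only reach it).
  g <- paste0(
    "ACGGATTTTT", "CAGGCCAATC",  # [0,20)
    "GTACCAGTGA", "CCTAAGGACT",  # [20,40)
    "AATCGGTCCA", "GACAGCTTAC",  # [40,60)
    "GGATCCAGTA", "CAATGGCTTA",  # [60,80)
    "CCGGAATTCA", "GGCCTTAGCA"   # [80,100)
  )
  genome <- genome_sequence(g, "toy")
  binning <- make_binning(genome, num_bins = 5, overlap = 8)
  list(
    genome = genome,
    binning = binning,
    codec = token_codec(5),
    read = substr(g, 48 + 1, 48 + 12),  # "CAGACAGCTTAC"
    read_location = 48
  )
}

#' Write reads as FASTQ
#'
#' Constant dummy qualities (`I`, Phred 40); the simulator does not model
#' base quality.
#'
#' @param reads Tibble with `read_id`, `seq` (e.g. from [plant_reads()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reads_fastq <- function(reads, path) {
  reads <- as_read_tibble(reads)
  set <- Biostrings::DNAStringSet(reads$seq)
  names(set) <- reads$read_id
  qual <- Biostrings::PhredQuality(
    vapply(nchar(reads$seq), function(l) strrep("I", l), character(1))
  )
  qset <- Biostrings::QualityScaledDNAStringSet(set, qual)
  Biostrings::writeQualityScaledXStringSet(qset, path)
  invisible(path)
}

#' Read sequences from FASTQ or FASTA
#'
#' @param path Input path.
#' @param format `"fastq"` or `"fasta"`; guessed from the extension by
#'   default.
#' @return Tibble with `read_id`, `seq`.
#' @export
read_reads <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.f(ast)?q(\\.gz)?$", path, ignore.case = TRUE)) {
      "fastq"
    } else {
      "fasta"
    }
  }
  set <- Biostrings::readDNAStringSet(path, format = format)
  tibble::tibble(
    read_id = sub("\\s.*$", "", names(set)),
    seq = unname(toupper(as.character(set)))
  )
}

#' Write a truth table as TSV
#'
#' @param truth Truth tibble from [plant_reads()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Mixed per-read error compositions
#'
#' Assigns each read a total error count cycling through
#' `0, 1, ..., max_errors` and splits each total uniformly at random among
#' substitutions, insertions and deletions — the standard planted-error
#' design for exercising a filter across its whole tolerated error range.
#'
#' @param n_reads Number of reads.
#' @param max_errors Largest per-read error count (the filter's budget
#'   `ceil(L*e)` in the matched design).
#' @param seed Integer RNG seed.
#' @return Tibble with columns `substitutions`, `insertions`, `deletions`,
#'   `n_errors`; pass the first three to [plant_reads()].
#' @export
mixed_error_counts <- function(n_reads, max_errors, seed = 1L) {
  k <- rep(0:max_errors, length.out = n_reads)
  withr::with_seed(seed, {
    split <- vapply(k, function(ki) {
      if (ki == 0) return(c(0, 0, 0))
      tabulate(sample.int(3, ki, replace = TRUE), nbins = 3)
    }, numeric(3))
  })
  tibble::tibble(
    substitutions = as.integer(split[1, ]),
    insertions = as.integer(split[2, ]),
    deletions = as.integer(split[3, ]),
    n_errors = as.integer(k)
  )
}
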
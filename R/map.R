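#' Map reads with a minimal seed-and-extend loop around the filter
#'
#' For every read: look up candidate locations from non-overlapping seeds on
#' both strands ([candidate_locations()]), filter them through the bin
#' accumulation-sum test, and verify with the semi-global edit-distance
#' aligner ([verify_alignment()]). With `use_filter = TRUE` only passing
#' candidates would be aligned; the harness nevertheless verifies every
#' candidate so that the filter's confusion tallies (including would-be
#' false positives) can be measured exactly.
#'
#' Candidates within `k = ceil(L*e)` bases of their bin's left (stride)
#' boundary are additionally checked against the previous bin (`boundary
#' guard`): an indel-shifted candidate start can precede its bin's start by
#' up to `k` bases, and with `overlap >= L + k - 1` the matching segment is
#' then provably contained in one of the two bins, which preserves the
#' zero-false-positive guarantee end to end. Disable with
#' `boundary_guard = FALSE` to study the unguarded per-bin rule.
#'
#' @param reads Tibble with columns `read_id` and `seq`, or a (optionally
#'   named) character vector of read sequences.
#' @param genome A [genome_sequence()].
#' @param index A [build_index()] token index over `genome`.
#' @param cfg A [filter_config()]; token size must match the index, and each
#'   read must satisfy `L + ceil(L*e) <= overlap + 1` so a read plus
#'   worst-case deletions fits in one bin.
#' @param use_filter If `FALSE`, every candidate is verified and reported
#'   (the unfiltered baseline).
#' @param seed_index Optional prebuilt [build_seed_index()]; otherwise built
#'   here with `seed_length`.
#' @param seed_length,num_seeds Seeding parameters (see
#'   [candidate_locations()]).
#' @param boundary_guard Apply the previous-bin guard described above.
#' @return An object of class `map_result`: list with `mappings` (tibble
#'   `read_id`, `location`, `strand`, `edit_distance` of accepted
#'   locations), `candidates` (per-candidate tibble with `bin`, `sum`,
#'   `threshold`, `pass`, `edit_distance`, `mapped`), `evaluation` (a
#'   [evaluate_filter()] object) and `use_filter`.
#' @export
map_reads <- function(reads, genome, index, cfg, use_filter = TRUE,
                      seed_index = NULL, seed_length = 12, num_seeds = NULL,
                      boundary_guard = TRUE) {
  stopifnot(inherits(genome, "genome_sequence"))
  check_cfg_index(cfg, index)
  reads <- as_read_tibble(reads)
  if (is.null(seed_index)) seed_index <- build_seed_index(genome, seed_length)
  e <- cfg$error_tolerance
  binning <- index$binning
  rows <- vector("list", nrow(reads))
  for (i in seq_len(nrow(reads))) {
    seq <- toupper(reads$seq[i])
    L <- nchar(seq)
    k <- allowable_errors(L, e)
    if (L + k > binning$overlap + 1) {
      stop("configuration error: read length ", L, " plus error budget ", k,
           " exceeds overlap + 1 (", binning$overlap + 1,
           "); increase the bin overlap (see default_overlap())")
    }
    cands <- candidate_locations(reads[i, ], seed_index, num_seeds = num_seeds)
    if (!nrow(cands)) next
    profiles <- list("+" = read_filter_profile(seq, cfg))
    queries <- list("+" = seq)
    if (any(cands$strand == "-")) {
      rc <- reverse_complement(seq)
      queries[["-"]] <- rc
      profiles[["-"]] <- read_filter_profile(rc, cfg)
    }
    per_strand <- lapply(split(cands, cands$strand), function(cs) {
      st <- cs$strand[1]
      prof <- profiles[[st]]
      fl <- filter_locations_guarded(prof, cs$location, index, k,
                                     guard = boundary_guard)
      d <- vapply(cs$location, function(z) {
        rec <- record_of_location(genome, z)
        local <- z - genome$offsets[rec]
        win <- substr(genome$seqs[rec], max(0, local - k) + 1,
                      min(local + L + k, genome$lengths[rec]))
        .semiglobal_edit_distance(queries[[st]], win)
      }, integer(1))
      tibble::tibble(
        read_id = cs$read_id, location = cs$location, strand = cs$strand,
        bin = fl$bin, sum = fl$sum, threshold = prof$threshold,
        pass = fl$pass, edit_distance = d, mapped = d <= k
      )
    })
    rows[[i]] <- dplyr::bind_rows(per_strand)
  }
  candidates <- dplyr::bind_rows(rows)
  if (!nrow(candidates)) {
    candidates <- tibble::tibble(
      read_id = character(), location = numeric(), strand = character(),
      bin = numeric(), sum = integer(), threshold = integer(),
      pass = integer(), edit_distance = integer(), mapped = logical()
    )
  }
  accepted <- if (use_filter) {
    candidates[candidates$pass == 1L & candidates$mapped, , drop = FALSE]
  } else {
    candidates[candidates$mapped, , drop = FALSE]
  }
  evaluation <- evaluate_filter(
    n_pass = sum(candidates$pass == 1L),
    n_pass_and_map = sum(candidates$pass == 1L & candidates$mapped),
    n_reject = sum(candidates$pass == 0L),
    n_reject_but_map = sum(candidates$pass == 0L & candidates$mapped)
  )
  structure(
    list(
      mappings = candidates_to_mappings(accepted),
      candidates = candidates,
      evaluation = evaluation,
      use_filter = use_filter
    ),
    class = "map_result"
  )
}

candidates_to_mappings <- function(accepted) {
  tibble::tibble(
    read_id = accepted$read_id,
    location = accepted$location,
    strand = accepted$strand,
    edit_distance = accepted$edit_distance
  )
}

# Pass bits for candidate locations of one read profile, with the optional
# previous-bin boundary guard. Each distinct bin is evaluated once.
filter_locations_guarded <- function(prof, locations, index, k, guard = TRUE) {
  binning <- index$binning
  bins <- bin_of_location(locations, binning)
  cache <- new.env(parent = emptyenv())
  bin_sum <- function(b) {
    key <- as.character(b)
    if (is.null(cache[[key]])) {
      cache[[key]] <- accumulation_sum_profile(prof, index, b)
    }
    cache[[key]]
  }
  sums <- vapply(bins, bin_sum, numeric(1))
  pass <- sums >= prof$threshold
  if (guard && k > 0) {
    recs <- binning$records
    rec <- findInterval(locations, recs$offset)
    local <- locations - recs$offset[rec]
    need <- !pass & (local %% binning$stride) < k &
      bins > recs$bin_offset[rec]
    for (j in which(need)) {
      pass[j] <- bin_sum(bins[j] - 1) >= prof$threshold
    }
  }
  list(bin = bins, sum = as.integer(sums), pass = as.integer(pass))
}

#' @export
print.map_result <- function(x, ...) {
  ev <- x$evaluation
  cat("<map_result> filter ", if (x$use_filter) "on" else "off", ": ",
      nrow(x$mappings), " accepted mapping(s) from ",
      nrow(x$candidates), " candidate location(s)\n", sep = "")
  print(ev)
  invisible(x)
}

#' Filter confusion metrics
#'
#' Builds the evaluation record from the four candidate tallies. The false
#' negative rate is the ratio of locations that passed the filter but did
#' not result in a mapping over all locations that passed; the false
#' positive count is the number of locations the filter rejected that would
#' have mapped (guaranteed 0 within the error budget).
#'
#' @param n_pass Candidates that passed the filter.
#' @param n_pass_and_map Passing candidates that verified (mapped).
#' @param n_reject Candidates rejected by the filter.
#' @param n_reject_but_map Rejected candidates that would have mapped.
#' @return Object of class `filter_evaluation`: the tallies plus
#'   `false_negative_rate`, `false_positive_count` and `fn_rate_defined`
#'   (`FALSE` when nothing passed, in which case the rate is reported as 0).
#' @examples
#' evaluate_filter(10, 6, 90, 0)  # FN rate 0.4
#' @export
evaluate_filter <- function(n_pass, n_pass_and_map, n_reject,
                            n_reject_but_map) {
  stopifnot(n_pass >= n_pass_and_map, n_reject >= n_reject_but_map)
  structure(
    list(
      n_pass = n_pass,
      n_pass_and_map = n_pass_and_map,
      n_reject = n_reject,
      n_reject_but_map = n_reject_but_map,
      false_negative_rate = if (n_pass > 0) (n_pass - n_pass_and_map) / n_pass else 0,
      fn_rate_defined = n_pass > 0,
      false_positive_count = n_reject_but_map
    ),
    class = "filter_evaluation"
  )
}

#' @export
print.filter_evaluation <- function(x, ...) {
  cat("<filter_evaluation> pass: ", x$n_pass, " (mapped: ", x$n_pass_and_map,
      "), reject: ", x$n_reject, "; FN rate ",
      signif(x$false_negative_rate, 4),
      if (!x$fn_rate_defined) " (undefined: nothing passed)" else "",
      ", FP count ", x$false_positive_count, "\n", sep = "")
  invisible(x)
}

#' Average read existence
#'
#' For each read, the fraction of all `t` bins whose accumulation sum passes
#' the threshold; averaged over the read set. A lower value means the filter
#' confines each read to fewer bins — the headline measure of filtering
#' effectiveness as parameters vary.
#'
#' @param reads Tibble with `read_id`/`seq`, or character vector.
#' @param index A [build_index()] token index.
#' @param cfg A [filter_config()].
#' @return A single fraction in `[0, 1]`.
#' @export
average_read_existence <- function(reads, index, cfg) {
  check_cfg_index(cfg, index)
  reads <- as_read_tibble(reads)
  if (!nrow(reads)) stop("read set must be nonempty")
  fracs <- vapply(reads$seq, function(s) {
    prof <- read_filter_profile(s, cfg)
    sums <- if (length(prof$codes)) {
      colSums(index$bits[prof$codes + 1, , drop = FALSE])
    } else {
      numeric(index$binning$num_bins)
    }
    mean(sums >= prof$threshold)
  }, numeric(1), USE.NAMES = FALSE)
  mean(fracs)
}

#' Sweep filter parameters over a grid
#'
#' Re-runs index construction, filtering and mapping for every combination
#' of token size `n`, bin count `num_bins` and error tolerance `e`, and
#' reports average read existence, false negative rate, false positive
#' count and the raw index footprint — the desk-scale analogue of the
#' parameter-sensitivity methodology.
#'
#' @param genome A [genome_sequence()].
#' @param reads Tibble with `read_id`/`seq`, or character vector.
#' @param grid Data frame with columns `n`, `num_bins`, `e` (one row per
#'   configuration), e.g. from [tidyr::expand_grid()].
#' @param seed_length Seed length for candidate generation.
#' @param overlap Bin overlap; default `default_overlap(max L, max e)` so
#'   one index per `(n, num_bins)` serves all tolerances in the grid.
#' @return A tibble of class `sweep_result`: the grid columns plus
#'   `stride`, `overlap`, `average_read_existence`, `false_negative_rate`,
#'   `false_positive_count`, `n_pass`, `n_candidates`, `footprint_bytes`.
#' @export
parameter_sweep <- function(genome, reads, grid, seed_length = 12,
                            overlap = NULL) {
  stopifnot(inherits(genome, "genome_sequence"))
  grid <- tibble::as_tibble(grid)
  if (!nrow(grid)) stop("parameter grid must be nonempty")
  stopifnot(all(c("n", "num_bins", "e") %in% names(grid)))
  reads <- as_read_tibble(reads)
  max_L <- max(nchar(reads$seq))
  if (is.null(overlap)) overlap <- default_overlap(max_L, max(grid$e))
  seed_index <- build_seed_index(genome, seed_length)
  index_cache <- new.env(parent = emptyenv())
  get_index <- function(n, num_bins) {
    key <- paste(n, num_bins)
    if (is.null(index_cache[[key]])) {
      binning <- make_binning(genome, num_bins, overlap)
      index_cache[[key]] <- build_index(genome, binning, token_codec(n))
    }
    index_cache[[key]]
  }
  out <- lapply(seq_len(nrow(grid)), function(i) {
    n <- grid$n[i]; num_bins <- grid$num_bins[i]; e <- grid$e[i]
    index <- get_index(n, num_bins)
    cfg <- filter_config(n, e)
    are <- average_read_existence(reads, index, cfg)
    mr <- map_reads(reads, genome, index, cfg, use_filter = TRUE,
                    seed_index = seed_index)
    ev <- mr$evaluation
    tibble::tibble(
      n = n, num_bins = num_bins, e = e,
      stride = index$binning$stride, overlap = index$binning$overlap,
      average_read_existence = are,
      false_negative_rate = ev$false_negative_rate,
      false_positive_count = ev$false_positive_count,
      n_pass = ev$n_pass,
      n_candidates = ev$n_pass + ev$n_reject,
      footprint_bytes = footprint_bytes(num_bins, n)
    )
  })
  res <- dplyr::bind_rows(out)
  class(res) <- c("sweep_result", class(res))
  res
}

as_read_tibble <- function(reads) {
  if (is.character(reads)) {
    ids <- if (!is.null(names(reads))) names(reads) else
      paste0("read", seq_along(reads))
    return(tibble::tibble(read_id = ids, seq = toupper(unname(reads))))
  }
  reads <- tibble::as_tibble(reads)
  if (!all(c("read_id", "seq") %in% names(reads))) {
    stop("reads must have 'read_id' and 'seq' columns")
  }
  reads$seq <- toupper(reads$seq)
  reads
}

#' Write mappings / metrics
#'
#' `write_mappings_tsv()` writes the accepted mappings of a [map_reads()]
#' result as TSV (`read_id`, `location`, `strand`, `edit_distance`);
#' `write_metrics_json()` writes the evaluation as JSON.
#'
#' @param result A `map_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mappings_tsv <- function(result, path) {
  stopifnot(inherits(result, "map_result"))
  utils::write.table(result$mappings, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_mappings_tsv
#' @export
write_metrics_json <- function(result, path) {
  stopifnot(inherits(result, "map_result"))
  ev <- result$evaluation
  jsonlite::write_json(
    list(
      n_candidates = ev$n_pass + ev$n_reject,
      n_pass = ev$n_pass, n_pass_and_map = ev$n_pass_and_map,
      n_reject = ev$n_reject, n_reject_but_map = ev$n_reject_but_map,
      false_negative_rate = ev$false_negative_rate,
      false_positive_count = ev$false_positive_count,
      verifications_with_filter = ev$n_pass,
      verifications_without_filter = ev$n_pass + ev$n_reject
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read an external candidate list
#'
#' TSV with columns `read_id`, `location` (0-based), `strand` — the
#' interchange format for candidate seed locations produced by an external
#' mapper.
#'
#' @param path TSV path.
#' @return Tibble with those columns.
#' @export
read_candidates_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "numeric", "character"))
  if (!all(c("read_id", "location", "strand") %in% names(df))) {
    stop("candidate TSV must have columns read_id, location, strand")
  }
  tibble::as_tibble(df)
}
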
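# Independent oracles used across the suite. These deliberately avoid the
# package's own scanning/DP code paths: substring membership goes through
# grepl(fixed = TRUE) on the bin string, counting goes through per-window
# string comparison, and edit distance through a vectorized full-DP
# recurrence in R (the package verifier is a plain rolling-row DP in C++).

# Existence-bit oracle: 4^n x t matrix of naive substring membership.
naive_index_bits <- function(genome, binning, codec) {
  n <- codec$token_size
  tokens <- decode_token(seq_len(codec$n_tokens) - 1, codec)
  bits <- matrix(FALSE, nrow = codec$n_tokens, ncol = binning$num_bins)
  for (b in seq_len(binning$num_bins) - 1) {
    bs <- seedsieve:::bin_sequence(genome, binning, b)
    bits[, b + 1] <- vapply(tokens, function(tok) grepl(tok, bs, fixed = TRUE),
                            logical(1), USE.NAMES = FALSE)
  }
  bits
}

# Accumulation-sum oracle: count read-token occurrences (duplicates counted
# per occurrence) that are substrings of the bin's sequence.
naive_accumulation <- function(read, bin_seq, n) {
  L <- nchar(read)
  windows <- substring(read, 1:(L - n + 1), n:L)
  clean <- !grepl("[^ACGT]", windows)
  sum(vapply(windows[clean], function(w) grepl(w, bin_seq, fixed = TRUE),
             logical(1)))
}

# Semi-global unit-cost edit distance, full DP vectorized per row with the
# cummin resolution of the in-row insertion dependency.
sg_edit_oracle <- function(pattern, text) {
  p <- strsplit(pattern, "", fixed = TRUE)[[1]]
  tx <- strsplit(text, "", fixed = TRUE)[[1]]
  m <- length(p)
  n <- length(tx)
  if (m == 0) return(0L)
  if (n == 0) return(m)
  prev <- rep(0, n + 1)
  for (i in seq_len(m)) {
    sub <- prev[1:n] + (p[i] != tx)
    del <- prev[2:(n + 1)] + 1
    a <- c(prev[1] + 1, pmin(sub, del))
    prev <- (0:n) + cummin(a - (0:n))
  }
  as.integer(min(prev))
}

# All occurrences of a pattern in a subject, overlapping included.
naive_occurrences <- function(pattern, subject) {
  k <- nchar(pattern)
  L <- nchar(subject)
  if (L < k) return(numeric(0))
  starts <- 1:(L - k + 1)
  starts[substring(subject, starts, starts + k - 1) == pattern] - 1
}

# Random DNA string outside the package's generator.
rand_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# Mutate a string with k random substitutions (test-local, independent of
# plant_reads).
mutate_subs <- function(seq, k) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  at <- sample.int(length(ch), k)
  for (a in at) ch[a] <- sample(setdiff(c("A", "C", "G", "T"), ch[a]), 1)
  paste(ch, collapse = "")
}
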
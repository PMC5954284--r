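test_that("extract_tokens returns every overlapping window in order", {
  tk <- extract_tokens("GACAGT", 5)
  expect_equal(tk$token, c("GACAG", "ACAGT"))
  expect_equal(tk$position, c(0, 1))

  # a read of 104 A's yields 100 AAAAA occurrences
  tk2 <- extract_tokens(strrep("A", 104), 5)
  expect_equal(nrow(tk2), 100)
  expect_true(all(tk2$token == "AAAAA"))

  # occurrence count is L - (n - 1) for random reads
  set.seed(8)
  for (L in c(20, 57, 100)) {
    expect_equal(nrow(extract_tokens(rand_dna(L), 5)), L - 4)
  }
  expect_error(extract_tokens("ACG", 5), "shorter")
})

test_that("extract_tokens flags ambiguous windows", {
  tk <- extract_tokens("ACGTNACG", 4)
  expect_equal(tk$ambiguous, c(FALSE, rep(TRUE, 4)))
  expect_true(all(is.na(tk$code[tk$ambiguous])))
})

test_that("allowable errors is the ceiling of L times e", {
  expect_equal(allowable_errors(100, 0.05), 5L)
  expect_equal(allowable_errors(104, 0.05), 6L)
  expect_equal(allowable_errors(100, 0), 0L)
  expect_equal(allowable_errors(7, 0.05), 1L)
  expect_error(allowable_errors(0, 0.05))
  expect_error(allowable_errors(100, 1))
})

test_that("threshold subtracts worst-case token destruction and clamps at 0", {
  expect_equal(compute_threshold(100, 5, 0.05), 71L)
  # zero tolerated errors: every token must exist
  for (L in c(10, 50, 100)) {
    expect_equal(compute_threshold(L, 5, 0), L - 5L + 1L)
  }
  expect_warning(th <- compute_threshold(100, 5, 0.2), "clamped")
  expect_equal(th, 0L)
})

test_that("threshold is non-increasing in the error tolerance", {
  es <- seq(0, 0.2, by = 0.01)
  th <- suppressWarnings(vapply(es, function(e) compute_threshold(100, 5, e),
                                integer(1)))
  expect_true(all(diff(th) <= 0))
  th2 <- suppressWarnings(vapply(es, function(e) compute_threshold(63, 4, e),
                                 integer(1)))
  expect_true(all(diff(th2) <= 0))
})

test_that("accumulation sum counts per-occurrence existence bits", {
  # an all-A read against a bin whose only read-token present is AAAAA:
  # all 100 occurrences hit the single existing token
  g <- genome_sequence(paste0(strrep("G", 150), "AAAAA", strrep("G", 150)))
  idx <- build_index(g, make_binning(g, 1, 0), token_codec(5))
  res <- accumulation_sum(strrep("A", 104), idx, 0, filter_config(5, 0.05))
  expect_equal(res$sum, 100L)
  expect_equal(res$threshold, 70L)   # (104 - 4) - 6 * 5
  expect_true(res$passed)

  # all-A read against an all-G bin is rejected at small e
  gG <- genome_sequence(strrep("G", 300))
  idxG <- build_index(gG, make_binning(gG, 1, 0), token_codec(5))
  resG <- accumulation_sum(strrep("A", 100), idxG, 0, filter_config(5, 0.05))
  expect_equal(resG$sum, 0L)
  expect_false(resG$passed)
})

test_that("a read exactly present in a bin reaches the maximal sum", {
  g <- random_genome(400, seed = 31)
  idx <- build_index(g, make_binning(g, 2, 110), token_codec(5))
  read <- substr(g$seqs[1], 41, 140)  # inside bin 0
  for (e in c(0, 0.02, 0.05, 0.1)) {
    res <- accumulation_sum(read, idx, 0, filter_config(5, e))
    expect_equal(res$sum, 96L)  # L - n + 1
    expect_true(res$passed)
  }
})

test_that("accumulation sums match the naive substring-count oracle", {
  set.seed(77)
  g <- random_genome(2000, seed = 55)
  binning <- make_binning(g, 8, 60)
  codec <- token_codec(4)
  idx <- build_index(g, binning, codec)
  cfg <- filter_config(4, 0.05)
  for (rep in 1:6) {
    read <- if (rep %% 2) rand_dna(60) else
      substr(g$seqs[1], 300 * rep, 300 * rep + 59)
    for (b in c(0, 3, 7)) {
      res <- accumulation_sum(read, idx, b, cfg)
      expect_equal(res$sum,
                   naive_accumulation(read, seedsieve:::bin_sequence(g, binning, b), 4))
    }
  }
})

test_that("ambiguous read bases contribute zero and relax the threshold", {
  g <- random_genome(500, seed = 13)
  idx <- build_index(g, make_binning(g, 1, 0), token_codec(5))
  clean <- substr(g$seqs[1], 101, 200)
  withN <- paste0(substr(clean, 1, 49), "N", substr(clean, 51, 100))
  cfg <- filter_config(5, 0.05)
  res_clean <- accumulation_sum(clean, idx, 0, cfg)
  res_n <- accumulation_sum(withN, idx, 0, cfg)
  # one ambiguous base kills its 5 covering tokens and lowers the threshold by 5
  expect_equal(res_n$threshold, res_clean$threshold - 5L)
  expect_equal(res_n$sum, res_clean$sum - 5L)
  expect_true(res_n$passed)  # an N-containing true read still passes
})

test_that("filter_read_locations shares bin evaluations and keeps order", {
  g <- random_genome(3000, seed = 41)
  binning <- make_binning(g, 10, 110)
  idx <- build_index(g, binning, token_codec(5))
  cfg <- filter_config(5, 0.05)
  read <- substr(g$seqs[1], 901, 1000)  # planted at z = 900
  locs <- c(900, 10, 905, 2500, 11)
  bm <- filter_read_locations(read, locs, idx, cfg, read_id = "r1")
  expect_equal(bm$location, locs)        # output order matches input order
  expect_equal(bm$pass[1], 1L)           # verbatim plant passes
  expect_equal(bm$pass[3], 1L)           # same bin as the plant
  # two locations in the same bin get identical results
  same_bin <- bm$bin == bm$bin[2]
  expect_true(length(unique(bm$sum[same_bin])) == 1)
  # per-location agreement with independent evaluation
  for (i in seq_along(locs)) {
    solo <- accumulation_sum(read, idx, bin_of_location(locs[i], binning), cfg)
    expect_equal(bm$sum[i], solo$sum)
    expect_equal(bm$pass[i], as.integer(solo$passed))
  }
  expect_error(filter_read_locations(read, c(5, -1), idx, cfg),
               "entry 2")
  expect_equal(nrow(filter_read_locations(read, numeric(0), idx, cfg)), 0)
})

test_that("windowed lockstep evaluation equals per-bin evaluation for all w", {
  g <- random_genome(2500, seed = 99)
  idx <- build_index(g, make_binning(g, 12, 80), token_codec(4))
  cfg <- filter_config(4, 0.03)
  read <- substr(g$seqs[1], 1001, 1070)
  per_bin <- dplyr::bind_rows(lapply(0:11, function(b)
    accumulation_sum(read, idx, b, cfg)))
  for (w in c(1, 3, 12)) {
    got <- dplyr::bind_rows(lapply(seq(0, 11, by = w), function(s)
      filter_bin_window(read, idx, s, min(w, 12 - s), cfg)))
    expect_equal(got$sum, per_bin$sum)
    expect_equal(got$passed, per_bin$passed)
  }
  expect_error(filter_bin_window(read, idx, 8, 5, cfg), "out of range")
})

test_that("the passing set grows monotonically with the error tolerance", {
  g <- random_genome(4000, seed = 17)
  binning <- make_binning(g, 16, 110)
  idx <- build_index(g, binning, token_codec(5))
  set.seed(3)
  read <- mutate_subs(substr(g$seqs[1], 2001, 2100), 3)
  locs <- seq(0, 3999, by = 97)
  prev_pass <- NULL
  for (e in c(0, 0.01, 0.03, 0.05, 0.08)) {
    bm <- filter_read_locations(read, locs, idx, filter_config(5, e))
    if (!is.null(prev_pass)) expect_true(all(bm$pass >= prev_pass))
    prev_pass <- bm$pass
  }
})

test_that("bitmask export writes TSV and BED faithfully", {
  fx <- worked_example_fixture()
  idx <- build_index(fx$genome, fx$binning, fx$codec)
  bm <- filter_read_locations(fx$read, c(fx$read_location, 0), idx,
                              filter_config(5, 0.1), read_id = "toy")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_bitmask_tsv(bm, tsv)
  back <- utils::read.table(tsv, header = TRUE, sep = "\t")
  expect_equal(back$location, bm$location)
  expect_equal(back$pass, bm$pass)
  bed <- bitmask_to_bed(bm, read_length = nchar(fx$read))
  expect_true(all(bed$end - bed$start == nchar(fx$read)))
  expect_equal(nrow(bed), sum(bm$pass))
})

test_that("reads shorter than the token size are rejected", {
  fx <- worked_example_fixture()
  idx <- build_index(fx$genome, fx$binning, fx$codec)
  expect_error(accumulation_sum("ACG", idx, 0, filter_config(5, 0)),
               "shorter")
  expect_error(filter_config(5, 1), "\\[0, 1\\)")
  expect_error(
    accumulation_sum("ACGTACGT", idx, 0, filter_config(4, 0)),
    "token size"
  )
})
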
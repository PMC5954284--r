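test_that("seed index stores every exact k-mer location", {
  si <- build_seed_index(genome_sequence("ACGTACGT"), 4)
  expect_equal(seed_locations(si, "ACGT"), c(0, 4))
  expect_equal(seed_locations(si, "TTTT"), numeric(0))
  # conservation: total stored positions == L - k + 1 on an ACGT-only genome
  g <- random_genome(800, seed = 4)
  si2 <- build_seed_index(g, 6)
  expect_equal(si2$n_seeds, 800 - 6 + 1)
  expect_equal(sum(si2$count), si2$n_seeds)
  # every stored location hosts the seed verbatim
  some <- si2$codes[c(1, 10, 50)]
  for (code in some) {
    tok <- decode_token(code, si2$codec)
    for (z in seed_locations(si2, tok)) {
      expect_equal(substr(g$seqs[1], z + 1, z + 6), tok)
    }
  }
})

test_that("candidate locations match a brute-force seed scan", {
  set.seed(20)
  g <- random_genome(3000, seed = 61)
  si <- build_seed_index(g, 8)
  read <- substr(g$seqs[1], 1501, 1560)
  cands <- candidate_locations(read, si, read_id = "r")
  # truth location must be present on the forward strand
  expect_true(any(cands$location == 1500 & cands$strand == "+"))
  # brute force: every seed occurrence projected back to read start
  expected <- sort(unique(unlist(lapply(0:6, function(i) {
    seed <- substr(read, i * 8 + 1, i * 8 + 8)
    hits <- naive_occurrences(seed, g$seqs[1])
    hits[hits - i * 8 >= 0] - i * 8
  }))))
  got_fwd <- sort(cands$location[cands$strand == "+"])
  expect_equal(got_fwd, expected)
  expect_error(candidate_locations("ACGT", si), "too short")
})

test_that("reverse-strand candidates locate reverse-complemented plants", {
  g <- random_genome(2000, seed = 71)
  si <- build_seed_index(g, 10)
  segment <- substr(g$seqs[1], 701, 800)
  read <- reverse_complement(segment)
  cands <- candidate_locations(read, si, read_id = "rc")
  expect_true(any(cands$location == 700 & cands$strand == "-"))
})

test_that("semi-global verification matches the full-DP oracle", {
  g <- random_genome(1000, seed = 81)
  read <- substr(g$seqs[1], 201, 300)
  v <- verify_alignment(read, g, 200, 0.05)
  expect_equal(v$edit_distance, 0L)
  expect_true(v$accepted)
  set.seed(5)
  one_sub <- mutate_subs(read, 1)
  expect_equal(verify_alignment(one_sub, g, 200, 0.05)$edit_distance, 1L)
  # randomized agreement, near and far matches
  for (rep in 1:25) {
    pat <- if (rep %% 2) rand_dna(60) else mutate_subs(substr(g$seqs[1], 501, 560), rep %% 7)
    win_start <- sample(0:900, 1)
    txt <- substr(g$seqs[1], win_start + 1, win_start + 70)
    expect_equal(
      seedsieve:::.semiglobal_edit_distance(pat, txt),
      sg_edit_oracle(pat, txt)
    )
  }
})

test_that("filter-on and filter-off mapping accept identical locations", {
  g <- random_genome(60000, seed = 91)
  sim <- plant_reads(g, 40, 100,
                     substitutions = rep(0:3, 10),
                     deletions = rep(c(0, 1), 20),
                     seed = 17)
  cfg <- filter_config(5, 0.05)
  binning <- binning_from_stride(g, 150, default_overlap(100, 0.05))
  idx <- build_index(g, binning, token_codec(5))
  si <- build_seed_index(g, 12)
  on <- map_reads(sim$reads, g, idx, cfg, use_filter = TRUE, seed_index = si)
  off <- map_reads(sim$reads, g, idx, cfg, use_filter = FALSE, seed_index = si)
  key <- function(m) paste(m$read_id, m$location, m$strand)
  expect_setequal(key(on$mappings), key(off$mappings))
  expect_equal(on$evaluation$false_positive_count, 0)
  # filter never increases the verification load
  expect_lte(on$evaluation$n_pass,
             on$evaluation$n_pass + on$evaluation$n_reject)
  # every planted read is recovered at (or, after indel shifts of the
  # projected start, within the error budget of) its true location
  recovered <- vapply(seq_len(nrow(sim$truth)), function(i) {
    tr <- sim$truth[i, ]
    hits <- on$mappings[on$mappings$read_id == tr$read_id &
                          on$mappings$strand == tr$strand, ]
    any(abs(hits$location - tr$true_location) <= tr$n_errors)
  }, logical(1))
  expect_true(all(recovered))
})

test_that("decoy candidates (shared seeds, no true match) never map", {
  g <- random_genome(50000, seed = 23)
  set.seed(29)
  # reads borrow one genuine 12-mer seed and append random tails
  decoys <- vapply(1:15, function(i) {
    p <- sample(0:(50000 - 12), 1)
    paste0(substr(g$seqs[1], p + 1, p + 12), rand_dna(88))
  }, character(1))
  cfg <- filter_config(5, 0.05)
  binning <- binning_from_stride(g, 150, default_overlap(100, 0.05))
  idx <- build_index(g, binning, token_codec(5))
  res <- map_reads(decoys, g, idx, cfg)
  expect_gt(nrow(res$candidates), 0)   # seeds do produce candidates
  expect_equal(res$evaluation$n_pass_and_map, 0)
  expect_equal(nrow(res$mappings), 0)
})

test_that("evaluation rates follow their definitions", {
  ev <- evaluate_filter(10, 6, 90, 0)
  expect_equal(ev$false_negative_rate, 0.4)
  expect_equal(ev$false_positive_count, 0)
  expect_equal(evaluate_filter(8, 8, 2, 0)$false_negative_rate, 0)
  empty <- evaluate_filter(0, 0, 5, 0)
  expect_equal(empty$false_negative_rate, 0)
  expect_false(empty$fn_rate_defined)
  expect_error(evaluate_filter(5, 6, 0, 0))
})

test_that("average read existence behaves on degenerate references", {
  # all-A read over an all-A genome: every bin passes
  gA <- genome_sequence(strrep("A", 1000))
  idxA <- build_index(gA, make_binning(gA, 10, 110), token_codec(5))
  expect_equal(average_read_existence(strrep("A", 100), idxA,
                                      filter_config(5, 0.05)), 1)
  # a read present in exactly one bin of a 10-bin genome at e = 0
  g <- random_genome(1000, seed = 37)
  idx <- build_index(g, make_binning(g, 10, 0), token_codec(5))
  read <- substr(g$seqs[1], 301, 400)  # bin 3 verbatim
  expect_equal(average_read_existence(read, idx, filter_config(5, 0)), 0.1)
  expect_error(average_read_existence(character(0), idx, filter_config(5, 0)),
               "nonempty")
})

test_that("mapping enforces the containment precondition", {
  g <- random_genome(5000, seed = 43)
  idx <- build_index(g, binning_from_stride(g, 150, 50), token_codec(5))
  sim <- plant_reads(g, 2, 100, seed = 3)
  expect_error(
    map_reads(sim$reads, g, idx, filter_config(5, 0.05)),
    "configuration error"
  )
})

test_that("map results expose tidy, glance and autoplot interfaces", {
  g <- random_genome(20000, seed = 53)
  sim <- plant_reads(g, 8, 100, substitutions = 1, seed = 7)
  idx <- build_index(g, binning_from_stride(g, 150, 104), token_codec(5))
  res <- map_reads(sim$reads, g, idx, filter_config(5, 0.05))
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("read_id", "location", "bin", "sum", "pass", "mapped")
                  %in% names(td)))
  gl <- glance(res)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$false_positive_count, 0)
  expect_s3_class(autoplot(res), "ggplot")
  expect_equal(tidy(res$evaluation)$value[tidy(res$evaluation)$metric == "n_pass"],
               gl$n_pass)
})
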
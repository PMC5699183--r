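test_that("binning applies a strict inequality at the threshold", {
  k <- 15L
  km40 <- random_dna(k)
  km35 <- random_dna(k)
  pool <- c(rep(paste0("AA", km40), 40), rep(paste0(km35, "TT"), 35))
  s <- kmer_sketch(pool, k = k, width = 2^16, depth = 3L)
  res <- bin_reads(read_set(c("hi", "lo"), c(km40, km35)), s,
                   threshold = 35, keep_pairs = FALSE)
  expect_equal(res$reads$read_id, "hi")  # 40 > 35 kept, 35 == 35 dropped
  expect_equal(res$counts$qualifying, 1L)

  expect_error(bin_reads(read_set("a", "ACGT"), s, threshold = 0), "> 0")
})

test_that("retained set matches brute-force exact-table selection", {
  set.seed(41)
  k <- 21L
  nuc <- random_dna(4000)
  org <- random_dna(1200)
  # organelle at 20x the nuclear depth (nuclear ~2x)
  reads <- c(tile_reads(nuc, 80, 100L), circular_reads(org, 480, 100L))
  reads <- sample(reads)
  rs <- read_set(sprintf("r%d", seq_along(reads)), reads)
  s <- kmer_sketch(rs, k = k, width = 2^18, depth = 3L)

  exact <- r_exact_counts(reads, k)
  threshold <- 10
  truth_keep <- r_max_kmer_count(reads, k, exact) > threshold
  res <- bin_reads(rs, s, threshold, keep_pairs = FALSE)
  expect_setequal(res$reads$read_id, rs$read_id[truth_keep])
})

test_that("sketch collisions never cause false negatives, and threshold is monotone", {
  set.seed(42)
  k <- 15L
  for (rep_i in 1:5) {
    nuc <- random_dna(1500)
    org <- random_dna(500)
    reads <- c(tile_reads(nuc, 30, 60L), circular_reads(org, 150, 60L))
    rs <- read_set(sprintf("r%d", seq_along(reads)), reads)
    # cramped sketch: plenty of collisions
    s <- kmer_sketch(rs, k = k, width = 512L, depth = 2L, seed = rep_i)
    exact <- r_exact_counts(reads, k)
    truth_max <- r_max_kmer_count(reads, k, exact)
    for (thr in c(5, 12, 20)) {
      kept <- bin_reads(rs, s, thr, keep_pairs = FALSE)$reads$read_id
      must_keep <- rs$read_id[truth_max > thr]
      expect_true(all(must_keep %in% kept))
    }
    kept_lo <- bin_reads(rs, s, 5, keep_pairs = FALSE)$reads$read_id
    kept_hi <- bin_reads(rs, s, 20, keep_pairs = FALSE)$reads$read_id
    expect_true(all(kept_hi %in% kept_lo))
  }
})

test_that("pair rescue keeps the whole pair when either mate qualifies", {
  k <- 15L
  hot <- random_dna(k)
  pool <- c(rep(hot, 50), "ACGTACGTACGTACGTACGT")
  s <- kmer_sketch(pool, k = k, width = 2^16, depth = 3L)
  rs <- read_set(c("p/1", "p/2"), c(hot, "ACGTACGTACGTACGTACGT"),
                 mate = c(1L, 2L), pair_id = c(1L, 1L))
  with_rescue <- bin_reads(rs, s, threshold = 10, keep_pairs = TRUE)
  expect_equal(n_reads(with_rescue$reads), 2L)
  expect_equal(with_rescue$counts$rescued_mates, 1L)
  without <- bin_reads(rs, s, threshold = 10, keep_pairs = FALSE)
  expect_equal(without$reads$read_id, "p/1")
})
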
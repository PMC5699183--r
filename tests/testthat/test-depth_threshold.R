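test_that("depth_profile recovers constructed coverage and truncates long anchors", {
  set.seed(31)
  g <- random_dna(2000)
  # exact 10x: every offset divisible by 10 covered once per phase
  starts <- as.vector(outer(seq(1, 1901, by = 100), 0:9 * 10, "+"))
  starts <- starts[starts <= 1901]
  reads <- substring(g, starts, starts + 99)
  dp <- depth_profile(reads, g)
  expect_equal(length(dp$depths), 2000L)
  interior <- dp$depths[150:1850]
  expect_true(all(interior >= 9L & interior <= 10L))
  expect_equal(stats::median(interior), 10)

  long_anchor <- paste0(g, random_dna(98001))  # 100,001 bp total
  dp2 <- depth_profile(reads[1:20], long_anchor)
  expect_equal(length(dp2$depths), 100000L)

  expect_warning(dp0 <- depth_profile(read_set(character(), character()), g),
                 "empty read stream")
  expect_true(all(dp0$depths == 0L))
})

test_that("nd_threshold matches the documented trimmed-mean convention", {
  mk <- function(depths) structure(list(contig_id = "x",
                                        depths = as.integer(depths)),
                                   class = "depth_profile")
  # constant profile: trimmed mean is the constant, value is factor times it
  nd <- nd_threshold(mk(rep(10L, 1000L)))
  expect_equal(nd$trimmed_mean, 10)
  expect_equal(nd$value, 50)
  # all depths non-zero: slice holds about half the positions
  expect_equal(nd$n, 501L)

  nd2 <- nd_threshold(mk(c(0, 0, 4, 4, 4, 4)))
  expect_equal(nd2$value, 20)

  # brute-force oracle for the documented inclusive-floor convention
  oracle <- function(depths, factor = 5) {
    nz <- sort(depths[depths > 0])
    m <- length(nz)
    idx <- (floor(0.25 * (m - 1)):floor(0.75 * (m - 1))) + 1
    factor * mean(nz[idx])
  }
  d <- sample(c(rep(0L, 50), 1:100))
  expect_equal(nd_threshold(mk(d))$value, oracle(d))
  expect_equal(nd_threshold(mk(1:100))$value, 5 * mean(25:75))

  expect_error(nd_threshold(mk(rep(0L, 10))), "manually")

  # scale equivariance and zero-invariance
  set.seed(32)
  d <- rpois(500, 12)
  v <- nd_threshold(mk(d))$value
  expect_equal(nd_threshold(mk(3L * d))$value, 3 * v)
  expect_equal(nd_threshold(mk(c(d, rep(0L, 200))))$value, v)
})

test_that("depth/k-mer-depth conversions follow N = M*L/(L-k+1)", {
  expect_equal(genome_depth_from_kmer_depth(70, 100, 31), 100)
  expect_equal(genome_depth_from_kmer_depth(7, 50, 1), 7)  # k=1: N == M
  expect_error(genome_depth_from_kmer_depth(5, 30, 31), "k < L \\+ 1")

  set.seed(33)
  for (i in 1:200) {
    L <- sample(31:300, 1)
    k <- sample(1:31, 1)
    M <- runif(1, 0.1, 500)
    N <- genome_depth_from_kmer_depth(M, L, k)
    expect_equal(kmer_depth_from_genome_depth(N, L, k), M, tolerance = 1e-12)
  }

  nd <- nd_threshold_manual(50)
  nd <- kmer_threshold_from_nd(nd, 100, 31)
  expect_equal(nd$kmer_threshold, 35)
  nd1 <- kmer_threshold_from_nd(nd_threshold_manual(50), 100, 1)
  expect_equal(nd1$kmer_threshold, nd1$value)
  # conversion never raises the threshold
  for (k in c(1, 15, 31)) {
    expect_lte(kmer_threshold_from_nd(nd_threshold_manual(80), 100,
                                      k)$kmer_threshold, 80)
  }
})

test_that("effective_read_length is the modal length with smaller-value ties", {
  expect_equal(effective_read_length(rep(strrep("A", 100), 5)), 100L)
  mixed <- c(rep(strrep("A", 100), 9), strrep("A", 40))
  expect_equal(effective_read_length(mixed), 100L)
  tie <- c(rep(strrep("A", 50), 3), rep(strrep("A", 70), 3))
  expect_equal(effective_read_length(tie), 50L)
  expect_error(effective_read_length(character()), "empty")
})

test_that("threshold over simulated constant coverage sits near factor x depth", {
  set.seed(34)
  g <- random_dna(20000)
  D <- 20
  reads <- tile_reads(g, n = round(20000 * D / 100), len = 100L)
  nd <- nd_threshold(depth_profile(reads, g))
  expect_gt(nd$value / D, 4.5)
  expect_lt(nd$value / D, 5.5)
})
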
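test_that("canonical_kmer picks the smaller strand and is idempotent", {
  expect_equal(canonical_kmer("ACGT"), "ACGT")  # own reverse complement
  expect_equal(canonical_kmer("TTTT"), "AAAA")
  expect_error(canonical_kmer("ACNG"), "A,C,G,T")

  set.seed(21)
  ks <- vapply(1:50, function(i) random_dna(sample(3:15, 1)), "")
  expect_equal(canonical_kmer(canonical_kmer(ks)), canonical_kmer(ks))
  expect_equal(canonical_kmer(ks), r_canonical(ks))  # independent oracle
})

test_that("sketch insertion follows the N-skipping window rule", {
  s <- kmer_sketch("ACGTACGT", k = 4L, width = 4096L, depth = 3L)
  expect_equal(kmer_estimate(s, "ACGT"), 2L)
  expect_equal(s$n_inserted, 5)  # 5 windows, none with N

  sN <- kmer_sketch("ACGNACGT", k = 4L, width = 4096L, depth = 3L)
  expect_equal(sN$n_inserted, 1)  # only the final ACGT window is N-free

  expect_warning(kmer_sketch("ACG", k = 31L, width = 64L), "read length")
  expect_error(kmer_sketch("ACGT", k = 32L), "between 1 and 31")
})

test_that("estimates are one-sided against the exact table, exact without collisions", {
  set.seed(22)
  genome <- random_dna(3000)
  reads <- tile_reads(genome, 500, len = 80L)
  k <- 15L
  exact <- r_exact_counts(reads, k)

  wide <- kmer_sketch(reads, k = k, width = 2^18, depth = 3L, seed = 5L)
  est <- kmer_estimate(wide, names(exact))
  expect_true(all(est >= as.integer(exact)))
  expect_true(mean(est == as.integer(exact)) > 0.999)

  # adversarially tiny sketch: still one-sided, some strict overestimates
  tiny <- kmer_sketch(reads, k = k, width = 2L, depth = 2L, seed = 5L)
  est_tiny <- kmer_estimate(tiny, names(exact))
  expect_true(all(est_tiny >= as.integer(exact)))
  expect_true(any(est_tiny > as.integer(exact)))

  # never-inserted k-mer in a collision-free sketch
  absent <- setdiff(c("AAAAAAAAAAAAAAA", "CCCCCCCCCCCCCCC"), names(exact))
  expect_equal(kmer_estimate(wide, absent[1]), 0L)

  expect_error(kmer_estimate(wide, "ACGT"), "length")
  expect_error(kmer_estimate(wide, strrep("N", k)), "outside")
})

test_that("strand symmetry and determinism hold", {
  set.seed(23)
  reads <- vapply(1:100, function(i) random_dna(60), "")
  s1 <- kmer_sketch(reads, k = 11L, width = 2^14, depth = 3L, seed = 9L)
  s2 <- kmer_sketch(sample(reads), k = 11L, width = 2^14, depth = 3L, seed = 9L)
  expect_identical(s1$counters, s2$counters)

  kms <- vapply(1:30, function(i) random_dna(11), "")
  expect_equal(kmer_estimate(s1, kms), kmer_estimate(s1, r_revcomp(kms)))
})

test_that("max_kmer_count equals the brute-force window maximum", {
  set.seed(24)
  genome <- random_dna(2000)
  reads <- tile_reads(genome, 300, len = 70L)
  k <- 17L
  s <- kmer_sketch(reads, k = k, width = 2^18, depth = 3L, seed = 2L)

  expect_equal(max_kmer_count(s, substr(genome, 1, k - 1L)), 0L)

  exact <- r_exact_counts(reads, k)
  probe <- tile_reads(genome, 40, len = 70L)
  expect_equal(max_kmer_count(s, probe), r_max_kmer_count(probe, k, exact))

  # single-window read whose k-mer occurs 12 times elsewhere in the pool
  km <- random_dna(k)
  pool <- c(reads, rep(paste0("T", km, "A"), 12))
  s2 <- kmer_sketch(pool, k = k, width = 2^18, depth = 3L, seed = 2L)
  expect_equal(max_kmer_count(s2, km), 12L)
})

test_that("sketches serialise to flat binary files and back", {
  dir <- withr::local_tempdir()
  s <- kmer_sketch(c("ACGTACGTGG", "TTACGGA"), k = 5L, width = 256L,
                   depth = 4L, seed = 42L)
  p <- file.path(dir, "pool.cms")
  sketch_save(s, p)
  s2 <- sketch_load(p)
  expect_identical(s2[c("k", "width", "depth", "seed")],
                   s[c("k", "width", "depth", "seed")])
  expect_identical(s2$counters, s$counters)
  expect_equal(s2$n_inserted, s$n_inserted)
})
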
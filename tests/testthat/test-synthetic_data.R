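test_that("synthetic_spec enforces its invariants", {
  expect_error(synthetic_spec(copy_ratio = 1), "copy_ratio")
  expect_error(synthetic_spec(error_rate = 0.2), "error_rate")
  expect_error(synthetic_spec(nuclear_length = 200, organelle_length = 200,
                              insert_mean = 300), "insert_mean")
  expect_error(synthetic_spec(numt_count = 1, numt_length = 20000),
               "numt_length")
})

test_that("simulation matches its stated copy-number world and is reproducible", {
  spec <- synthetic_spec(nuclear_length = 50000L, organelle_length = 16000L,
                         copy_ratio = 20, nuclear_depth = 10, seed = 77L)
  sim <- simulate_dataset(spec)
  lab <- sim$truth$labels
  n_org <- sum(lab$origin == "organelle")
  n_nuc <- sum(lab$origin != "organelle")
  ratio <- n_org / n_nuc
  expected <- 20 * 16000 / 50000
  se <- expected * sqrt(1 / n_org + 1 / n_nuc)
  expect_lt(abs(ratio - expected), max(3 * se, 0.05))

  sim2 <- simulate_dataset(spec)
  expect_identical(sim2$reads, sim$reads)
  expect_identical(sim2$truth$organelle_seq, sim$truth$organelle_seq)

  # labels partition the pairs; every read belongs to a labelled pair
  expect_equal(nrow(lab), n_reads(sim$reads) / 2L)
  expect_true(all(lab$origin %in% c("nuclear", "organelle", "numt")))

  # circular sampling: some fragments wrap the origin
  org_lab <- lab[lab$origin == "organelle", ]
  expect_gt(sum(org_lab$end > spec$organelle_length), 0L)

  # mean depth ratio over the two genomes recovers the copy ratio
  L <- spec$read_length
  d_org <- 2 * L * n_org / spec$organelle_length
  d_nuc <- 2 * L * n_nuc / spec$nuclear_length
  expect_lt(abs(d_org / d_nuc - 20), 1)
})

test_that("files written by the simulator round-trip and include truth outputs", {
  dir <- withr::local_tempdir()
  spec <- synthetic_spec(nuclear_length = 3000L, organelle_length = 900L,
                         copy_ratio = 15, nuclear_depth = 4,
                         insert_mean = 250L, seed = 5L)
  sim <- simulate_dataset(spec, out_dir = dir)
  expect_true(all(file.exists(sim$files)))
  back <- read_fastq(sim$files[["r1"]], sim$files[["r2"]])
  expect_equal(back$bases, sim$reads$bases)
  truth <- read_fasta(sim$files[["truth_fasta"]])
  expect_equal(truth$bases[truth$contig_id == "organelle"],
               sim$truth$organelle_seq)
})

test_that("NUMT insertions are verbatim organelle copies with labelled reads", {
  spec <- synthetic_spec(nuclear_length = 20000L, organelle_length = 5000L,
                         copy_ratio = 12, nuclear_depth = 8,
                         numt_count = 2L, numt_length = 600L, seed = 9L)
  sim <- simulate_dataset(spec)
  nt <- sim$truth$numt_table
  expect_equal(nrow(nt), 2L)
  for (j in 1:2) {
    ins <- substr(sim$truth$nuclear_seq, nt$nuclear_start[j], nt$nuclear_end[j])
    src <- substr(sim$truth$organelle_seq, nt$organelle_start[j],
                  nt$organelle_end[j])
    expect_equal(ins, src)
  }
  expect_gt(sum(sim$truth$labels$origin == "numt"), 0L)
})

test_that("score_recovery handles rotation, strand and off-target candidates", {
  spec <- synthetic_spec(nuclear_length = 4000L, organelle_length = 2000L,
                         copy_ratio = 10, nuclear_depth = 5,
                         insert_mean = 250L, error_rate = 0, seed = 13L)
  sim <- simulate_dataset(spec)
  org <- sim$truth$organelle_seq
  rot <- paste0(substr(org, 1001, 2000), substr(org, 1, 1000))
  expect_equal(score_recovery(rot, sim$truth),
               list(identity = 100, coverage = 100))
  expect_equal(score_recovery(revcomp(org), sim$truth)$identity, 100)

  nuc_frag <- substr(sim$truth$nuclear_seq, 1, 1500)
  off <- score_recovery(nuc_frag, sim$truth)
  expect_lt(off$coverage, 5)

  expect_equal(score_recovery("", sim$truth), list(identity = 0, coverage = 0))

  # a few substitutions lower identity but not coverage
  mut <- rot
  for (p in c(100L, 900L, 1500L))
    substr(mut, p, p) <- chartr("ACGT", "CATG", substr(mut, p, p))
  sc <- score_recovery(mut, sim$truth)
  expect_gte(sc$identity, 99.8 - 0.15)
  expect_lt(sc$identity, 100)
  expect_equal(sc$coverage, 100)
})
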
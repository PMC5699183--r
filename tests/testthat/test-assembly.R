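test_that("assembly_config validates its k list", {
  expect_error(assembly_config(k_list = c(21L, 21L)), "increasing")
  expect_error(assembly_config(k_list = c(20L, 41L)), "odd")
  expect_equal(assembly_config()$k_list, c(21L, 41L, 61L))
})

test_that("error-free tilings reassemble to the source sequence", {
  set.seed(51)
  g <- random_dna(2000)
  contigs <- assemble(full_tiling(g))
  expect_equal(nrow(contigs), 1L)
  expect_true(contigs$bases %in% c(g, revcomp(g)))

  g2 <- random_dna(2000)
  both <- assemble(sample(c(full_tiling(g), full_tiling(g2))))
  expect_gte(nrow(both), 2L)
  hits <- vapply(both$bases[1:2], function(ctg)
    grepl(ctg, g, fixed = TRUE) || grepl(ctg, revcomp(g), fixed = TRUE) ||
      grepl(ctg, g2, fixed = TRUE) || grepl(ctg, revcomp(g2), fixed = TRUE),
    logical(1))
  expect_true(all(hits))

  expect_equal(nrow(assemble(character())), 0L)
})

test_that("contig k-mers come from the read pool and output ignores read order", {
  set.seed(52)
  g <- random_dna(1500)
  reads <- tile_reads(g, 450, 100L)  # 30x
  a1 <- assemble(reads)
  a2 <- assemble(rev(reads))
  expect_identical(a1$bases, a2$bases)

  pool_kmers <- names(r_exact_counts(reads, 21L))
  for (ctg in a1$bases) {
    n <- nchar(ctg)
    w <- r_canonical(substring(ctg, 1:(n - 20L), 21:n))
    expect_true(all(w %in% pool_kmers))
  }
})

test_that("a circular genome at high depth yields one near-complete contig with a k-1 terminus", {
  set.seed(53)
  circ <- random_dna(5000)
  reads <- circular_reads(circ, 1500, 100L)  # 30x
  contigs <- assemble(reads)
  longest <- contigs$bases[1]
  expect_gte(nchar(longest), 0.99 * 5000)
  # runs once around the circle: contained in the doubled genome
  doubled <- paste0(circ, circ)
  expect_true(grepl(longest, doubled, fixed = TRUE) ||
                grepl(longest, revcomp(doubled), fixed = TRUE))
  circ_res <- check_circularity(longest)
  expect_true(circ_res$is_circular)
  expect_equal(nchar(circ_res$trimmed$bases), 5000L)
})

test_that("the external assembler adapter parses output and propagates failures", {
  dir <- withr::local_tempdir()
  fixture <- file.path(dir, "fixture.fa")
  write_fasta(contig_set(c("x", "y"), c(random_dna(300), random_dna(250))),
              fixture)
  r1 <- file.path(dir, "r1.fq")
  writeLines(c("@a", "ACGT", "+", "IIII"), r1)

  got <- run_external_assembler(r1, paste("cp", fixture, "{out}"))
  expect_equal(got$contig_id, c("x", "y"))
  expect_equal(got$source, rep("external", 2))

  expect_error(run_external_assembler(r1, "false # {out}"), "exit")
  expect_error(run_external_assembler(r1, "true # {out}"), "no output")
  expect_warning(run_external_assembler(r1, "touch {out}"), "empty")
})
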
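test_that("select_candidate picks by length with documented tie-breaks", {
  set.seed(61)
  ctg <- contig_set(c("a", "b", "c"),
                    c(random_dna(16000), random_dna(3000), random_dna(900)))
  expect_equal(select_candidate(ctg)$contig_id, "a")

  tie <- contig_set(c("t1", "t2"), c("TTTTAAAA", "AAAATTTT"))
  expect_equal(select_candidate(tie)$bases, "AAAATTTT")

  ann <- list(b = data.frame(subject_id = "mito", bit_score = 500))
  expect_equal(select_candidate(ctg, "annotated", ann)$contig_id, "b")
  expect_warning(got <- select_candidate(ctg, "annotated", list()),
                 "falling back")
  expect_equal(got$contig_id, "a")

  expect_error(select_candidate(contig_set(character(), character())),
               "zero contigs")
})

test_that("check_circularity finds engineered terminal overlaps and nothing else", {
  set.seed(62)
  S <- random_dna(5000)
  res <- check_circularity(paste0(S, substr(S, 1, 80)))
  expect_true(res$is_circular)
  expect_equal(res$overlap_length, 80L)
  expect_equal(res$trimmed$bases, S)

  expect_false(check_circularity(S)$is_circular)

  # 30 bp engineered overlap below the 50 bp minimum
  expect_false(check_circularity(paste0(S, substr(S, 1, 30)))$is_circular)

  # tolerated mismatches within the overlap (2% of 200 = 4)
  ov <- substr(S, 1, 200)
  substr(ov, 50, 50) <- "A"; substr(ov, 120, 120) <- "C"
  res_mm <- check_circularity(paste0(S, ov))
  expect_true(res_mm$is_circular)

  expect_warning(short <- check_circularity(random_dna(90)), "too short")
  expect_false(short$is_circular)

  # trimming is idempotent
  expect_false(check_circularity(res$trimmed)$is_circular)
})

test_that("trimmed circular candidates match the reference under rotation and strand", {
  set.seed(63)
  circ <- random_dna(3000)
  doubled <- paste0(circ, circ)
  contig <- substr(doubled, 500, 500 + 3000 + 74)  # rotated, 75 bp overlap
  res <- check_circularity(contig)
  expect_true(res$is_circular)
  expect_equal(nchar(res$trimmed$bases), 3000L)
  expect_true(grepl(res$trimmed$bases, doubled, fixed = TRUE))
  rc <- check_circularity(revcomp(contig))
  expect_true(grepl(rc$trimmed$bases, revcomp(doubled), fixed = TRUE))
})

test_that("validate_candidate compares depths over a shared span", {
  set.seed(64)
  nuc <- random_dna(6000)
  org <- random_dna(2000)
  reads <- c(tile_reads(nuc, 300, 100L),      # ~5x
             circular_reads(org, 2000, 100L)) # ~100x
  rep20 <- validate_candidate(reads, org, nuc)
  expect_gt(rep20$depth_ratio, 10)
  expect_equal(rep20$verdict, "supported")
  expect_equal(length(rep20$nuclear_profile$depths), 2000L)

  # self-comparison: ratio ~ 1, unsupported
  self <- validate_candidate(tile_reads(nuc, 300, 100L),
                             substr(nuc, 1, 2000), nuc)
  expect_lt(abs(self$depth_ratio - 1), 0.35)
  expect_equal(self$verdict, "unsupported")

  # nothing maps to the nuclear anchor
  none <- validate_candidate(circular_reads(org, 50, 100L), org,
                             random_dna(3000))
  expect_equal(none$verdict, "unsupported")
  expect_match(none$diagnostic, "no reads mapped")

  dir <- withr::local_tempdir()
  tsv <- file.path(dir, "depth.tsv")
  write_depth_comparison(rep20, tsv)
  tab <- read.delim(tsv)
  expect_named(tab, c("position", "candidate_depth", "nuclear_depth"))
  expect_equal(nrow(tab), 2000L)
})

test_that("annotation hooks are optional, parsed, capped at 10 and sorted by bit-score", {
  dir <- withr::local_tempdir()
  ctg <- contig_set("c1", random_dna(500))

  hits <- data.frame(q = "c1", s = sprintf("ref%02d", 1:12), pid = 99.0,
                     alen = 450L, e = 1e-50, bs = c(101:109, 60, 60, 50))
  mock <- file.path(dir, "hits.tsv")
  write.table(hits, mock, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  res <- annotation_hook(ctg, paste("cp", mock, "{out_tsv}"))
  expect_named(res, "c1")
  expect_equal(nrow(res$c1), 10L)
  expect_equal(res$c1$bit_score, sort(res$c1$bit_score, decreasing = TRUE))
  expect_equal(res$c1$subject_id[1], "ref09")

  # bit-score ties: stable order by subject id
  tied <- res$c1[res$c1$bit_score == 60, ]
  expect_equal(tied$subject_id, "ref10")  # tie broken by subject id

  expect_warning(empty <- annotation_hook(ctg, NULL), "no annotation hook")
  expect_length(empty, 0L)
  expect_warning(failed <- annotation_hook(ctg, "false # {query_fasta} {out_tsv}"),
                 "failed")
  expect_length(failed, 0L)
})
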
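# Fixture builders and independent oracles. The oracles deliberately avoid
# the package's k-mer machinery: reverse complements via chartr, window
# enumeration via substring.

r_revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

r_canonical <- function(kmers) {
  rc <- r_revcomp(kmers)
  ifelse(kmers <= rc, kmers, rc)
}

# exact canonical k-mer counts by brute-force enumeration (N-free windows)
r_exact_counts <- function(seqs, k) {
  all <- unlist(lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character())
    w <- substring(s, 1:(n - k + 1), k:n)
    w[!grepl("N", w, fixed = TRUE)]
  }))
  if (length(all) == 0) return(integer())
  table(r_canonical(all))
}

# brute-force per-read maximum true k-mer count against a count table
r_max_kmer_count <- function(seqs, k, counts) {
  vapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(0L)
    w <- substring(s, 1:(n - k + 1), k:n)
    w <- w[!grepl("N", w, fixed = TRUE)]
    if (length(w) == 0) return(0L)
    m <- counts[r_canonical(w)]
    m[is.na(m)] <- 0L
    as.integer(max(m))
  }, integer(1), USE.NAMES = FALSE)
}

# reads with uniform random starts over a linear genome
tile_reads <- function(genome, n, len = 100L) {
  glen <- nchar(genome)
  starts <- sample.int(glen - len + 1L, n, replace = TRUE)
  substring(genome, starts, starts + len - 1L)
}

# reads covering every offset `reps` times (deterministic full tiling)
full_tiling <- function(genome, len = 100L, step = 7L, reps = 2L) {
  glen <- nchar(genome)
  starts <- rep(unique(c(seq(1L, glen - len + 1L, by = step),
                         glen - len + 1L)), reps)
  substring(genome, starts, starts + len - 1L)
}

# reads from a circular genome (fragments may wrap the origin)
circular_reads <- function(genome, n, len = 100L) {
  glen <- nchar(genome)
  starts <- sample.int(glen, n, replace = TRUE)
  substring(paste0(genome, genome), starts, starts + len - 1L)
}

write_fastq_lines <- function(path, ids, seqs, quals = NULL) {
  if (is.null(quals)) quals <- strrep("I", nchar(seqs))
  writeLines(c(rbind(paste0("@", ids), seqs, "+", quals)), path)
}
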
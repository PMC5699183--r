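#' Canonical form of k-mers
#'
#' The canonical form of a k-mer is the lexicographically smaller of the
#' k-mer and its reverse complement, making counting strand-symmetric:
#' shotgun reads come from both strands, and the depth argument that drives
#' read binning assumes strand-pooled counts.
#'
#' @param kmer character vector of k-mers over `{A,C,G,T}`.
#' @return character vector of canonical k-mers (idempotent).
#' @export
#' @examples
#' canonical_kmer(c("ACGT", "TTTT"))
canonical_kmer <- function(kmer) {
  stopifnot(is.character(kmer), length(kmer) > 0)
  if (any(grepl("[^ACGT]", kmer)))
    stop("k-mers must contain only {A,C,G,T} (no N)")
  rc <- revcomp(kmer)
  ifelse(kmer <= rc, kmer, rc)
}

#' Count canonical k-mers of a read pool in a Count-Min Sketch
#'
#' Every N-free length-`k` window of every read is canonicalised and
#' inserted once. A Count-Min Sketch keeps `depth` rows of `width` counters
#' under independent seeded hash functions; a query returns the minimum of
#' the addressed counters, so estimates are never below the true count
#' (one-sided error). Collisions can only inflate counts, which for read
#' binning means false positives (extra nuclear reads) but never lost
#' organelle reads.
#'
#' The 2-bit encoding used before hashing restricts `k` to at most 31
#' (default 31). For real WGS pools a width of `2^26` is a reasonable
#' setting; the package default of `2^22` suits desk-scale data.
#'
#' @param reads a [read_set()] or character vector of sequences.
#' @param k k-mer size in bp (1--31).
#' @param width counters per row.
#' @param depth number of rows (hash functions).
#' @param seed integer seed from which the row hash functions are derived;
#'   recorded in the sketch for reproducibility.
#' @return a `kmer_sketch` object.
#' @export
kmer_sketch <- function(reads, k = 31L, width = 2^22, depth = 3L, seed = 1L) {
  reads <- as_read_set(reads)
  k <- as.integer(k); width <- as.integer(width); depth <- as.integer(depth)
  stopifnot(k >= 1L, width >= 1L, depth >= 1L)
  built <- cms_build_cpp(reads$bases, k, width, depth, as.integer(seed))
  if (built$n_inserted == 0)
    warning("no k-mers inserted: k = ", k,
            " may exceed every read length (or the read set is empty)")
  structure(list(k = k, width = width, depth = depth, seed = as.integer(seed),
                 counters = built$counters, n_inserted = built$n_inserted),
            class = "kmer_sketch")
}

#' @export
print.kmer_sketch <- function(x, ...) {
  cat(sprintf("kmer_sketch: k=%d, %d x %d counters, seed %d, %.0f insertions\n",
              x$k, x$depth, x$width, x$seed, x$n_inserted))
  invisible(x)
}

#' Estimated count of k-mers
#'
#' Minimum over the sketch rows of the addressed counters. Always greater
#' than or equal to the true canonical count; equal when no row collides.
#'
#' @param sketch a [kmer_sketch()].
#' @param kmers character vector of length-`k` k-mers over `{A,C,G,T}`.
#' @return integer vector of estimates.
#' @export
kmer_estimate <- function(sketch, kmers) {
  stopifnot(inherits(sketch, "kmer_sketch"))
  cms_estimate_cpp(sketch$counters, sketch$k, sketch$width, sketch$depth,
                   sketch$seed, kmers)
}

#' Maximum k-mer count within each read
#'
#' For each read, the maximum sketch estimate over all its N-free length-`k`
#' windows; 0 for reads with no valid window (e.g. shorter than `k`). This
#' is the per-read statistic compared against the binning threshold.
#'
#' @param sketch a [kmer_sketch()].
#' @param reads a [read_set()] or character vector.
#' @return integer vector, one value per read.
#' @export
max_kmer_count <- function(sketch, reads) {
  stopifnot(inherits(sketch, "kmer_sketch"))
  reads <- as_read_set(reads)
  cms_max_per_read_cpp(sketch$counters, sketch$k, sketch$width, sketch$depth,
                       sketch$seed, reads$bases)
}

#' Exact canonical k-mer counts (test oracle)
#'
#' Exact multiset multiplicities of canonical k-mers across a read pool,
#' held in memory: the independent oracle against which the sketch's
#' one-sided error is verified. Desk-scale only.
#'
#' @param reads a [read_set()] or character vector.
#' @param k k-mer size (1--31).
#' @return data.frame with columns `kmer` and `count`.
#' @export
exact_kmer_counts <- function(reads, k = 31L) {
  reads <- as_read_set(reads)
  res <- exact_kmer_counts_cpp(reads$bases, as.integer(k))
  data.frame(kmer = res$kmer, count = res$count, stringsAsFactors = FALSE)
}

#' Serialise a sketch to a flat binary file
#'
#' Self-describing header (magic, k, width, depth, seed, insertion count)
#' followed by the raw counter grid.
#'
#' @param sketch a [kmer_sketch()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
sketch_save <- function(sketch, path) {
  stopifnot(inherits(sketch, "kmer_sketch"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("CMSK"), con)
  writeBin(c(1L, sketch$k, sketch$width, sketch$depth, sketch$seed), con,
           size = 4L, endian = "little")
  writeBin(as.numeric(sketch$n_inserted), con, size = 8L, endian = "little")
  writeBin(sketch$counters, con, size = 4L, endian = "little")
  invisible(path)
}

#' Load a sketch written by [sketch_save()]
#' @param path file written by [sketch_save()].
#' @return a `kmer_sketch`.
#' @export
sketch_load <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 4L))
  if (magic != "CMSK") stop("not a sketch file: ", path)
  hdr <- readBin(con, "integer", 5L, size = 4L, endian = "little")
  if (hdr[1] != 1L) stop("unsupported sketch file version ", hdr[1])
  n_ins <- readBin(con, "numeric", 1L, size = 8L, endian = "little")
  counters <- readBin(con, "integer", as.numeric(hdr[3]) * hdr[4],
                      size = 4L, endian = "little")
  structure(list(k = hdr[2], width = hdr[3], depth = hdr[4], seed = hdr[5],
                 counters = counters, n_inserted = n_ins),
            class = "kmer_sketch")
}
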
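#' Per-position read depth over an anchor contig
#'
#' Maps reads to the anchor with the built-in mapper (exact 21-mer seeding,
#' diagonal voting, ungapped verification, single best placement per read)
#' and counts reads covering each position. Only the first 100,000 bp of
#' the anchor are profiled -- enough to determine the depth, and it bounds
#' the cost on long contigs. The built-in mapper produces depth only; an
#' external mapper can substitute by supplying a precomputed profile
#' downstream.
#'
#' @param reads a [read_set()] or character vector of sequences.
#' @param anchor a one-row [contig_set()] or a single DNA string.
#' @param max_length anchor truncation length in bp (default 100000).
#' @param seed_len exact-match seed length for the mapper.
#' @param max_mismatch_frac maximum mismatch fraction accepted at
#'   verification.
#' @param min_overlap minimum read/anchor overlap in bp for a placement to
#'   count.
#' @return a `depth_profile`: list with `contig_id` and integer `depths`
#'   (one per anchor position, 0-based positions in file outputs).
#' @export
depth_profile <- function(reads, anchor, max_length = 100000L,
                          seed_len = 21L, max_mismatch_frac = 0.2,
                          min_overlap = 25L) {
  reads <- as_read_set(reads)
  if (inherits(anchor, "contig_set")) {
    stopifnot(nrow(anchor) == 1L)
    contig_id <- anchor$contig_id
    seq <- anchor$bases
  } else {
    stopifnot(is.character(anchor), length(anchor) == 1L)
    contig_id <- "anchor"
    seq <- toupper(anchor)
  }
  if (!nzchar(seq)) stop("anchor contig is empty")
  seq <- substr(seq, 1L, max_length)
  if (nrow(reads) == 0L) {
    warning("empty read stream: depth profile is all zeros")
    depths <- integer(nchar(seq))
  } else {
    depths <- map_depth_cpp(seq, reads$bases, as.integer(seed_len),
                            max_mismatch_frac, as.integer(min_overlap))
  }
  structure(list(contig_id = contig_id, depths = depths),
            class = "depth_profile")
}

#' @export
print.depth_profile <- function(x, ...) {
  cat(sprintf("depth_profile over '%s': %d positions, mean depth %.2f\n",
              x$contig_id, length(x$depths), mean(x$depths)))
  invisible(x)
}

#' Nuclear depth (ND) threshold from a depth profile
#'
#' The ND threshold is `factor` times the mean of the non-zero per-base
#' depths lying between the 25th and 75th percentiles of their sorted
#' order. With `m` sorted non-zero depths the slice runs from index
#' `floor(0.25 * (m - 1))` to `floor(0.75 * (m - 1))` (0-based, inclusive),
#' so when every position is covered the slice holds about half the contig
#' length. The default factor of 5 sits between the nuclear depth and the
#' lowest organelle copy number reported in the literature (10x); organisms
#' with unusually few organelle copies call for a manual threshold instead.
#'
#' @param profile a [depth_profile()].
#' @param factor multiplier applied to the trimmed mean (default 5).
#' @return an `nd_threshold`: list with `value` (`factor * trimmed_mean`),
#'   `trimmed_mean`, `n` (slice length), `factor`, and `kmer_threshold`
#'   (NA until [kmer_threshold_from_nd()] fills it).
#' @export
nd_threshold <- function(profile, factor = 5) {
  stopifnot(inherits(profile, "depth_profile"), factor > 0)
  nz <- sort(profile$depths[profile$depths > 0L])
  m <- length(nz)
  if (m == 0L)
    stop("all depths are zero; supply the threshold manually ",
         "(nd_threshold_manual() or --nd-threshold)")
  lo <- floor(0.25 * (m - 1)) + 1L
  hi <- floor(0.75 * (m - 1)) + 1L
  slice <- nz[lo:hi]
  tm <- mean(slice)
  structure(list(value = factor * tm, trimmed_mean = tm,
                 n = length(slice), factor = factor,
                 kmer_threshold = NA_real_),
            class = "nd_threshold")
}

#' Manually specified ND threshold
#'
#' Wraps a user-chosen read-depth threshold in the same object produced by
#' [nd_threshold()], for organisms where the automatic estimate is
#' unsuitable (the value should sit slightly above the nuclear depth times
#' the factor's intent).
#'
#' @param value threshold in read-depth units.
#' @param factor nominal factor recorded for reporting.
#' @return an `nd_threshold`.
#' @export
nd_threshold_manual <- function(value, factor = 5) {
  stopifnot(is.numeric(value), value > 0)
  structure(list(value = value, trimmed_mean = value / factor,
                 n = NA_integer_, factor = factor,
                 kmer_threshold = NA_real_),
            class = "nd_threshold")
}

#' @export
print.nd_threshold <- function(x, ...) {
  cat(sprintf(
    "nd_threshold: value %.3f (trimmed mean %.3f x factor %g, n = %s)",
    x$value, x$trimmed_mean, x$factor, format(x$n)))
  if (!is.na(x$kmer_threshold))
    cat(sprintf("; k-mer threshold %.3f", x$kmer_threshold))
  cat("\n")
  invisible(x)
}

#' Convert k-mer depth to genome depth
#'
#' Genome depth `N` and k-mer depth `M` are related by
#' `N = M * L / (L - k + 1)` where `L` is the read length: a read of length
#' `L` contributes `L - k + 1` k-mers, so k-mer depth underestimates genome
#' depth by that factor. Requires `k < L + 1`.
#'
#' @param M k-mer depth (pool-wide k-mer count).
#' @param L read length in bp.
#' @param k k-mer size in bp.
#' @return genome depth `N`.
#' @export
#' @examples
#' genome_depth_from_kmer_depth(70, 100, 31)  # 100
genome_depth_from_kmer_depth <- function(M, L, k) {
  stopifnot(is.numeric(M), is.numeric(L), is.numeric(k))
  if (any(k > L)) stop("k must satisfy k < L + 1")
  M * L / (L - k + 1)
}

#' Convert genome depth to k-mer depth (inverse of
#' [genome_depth_from_kmer_depth()])
#'
#' @param N genome depth.
#' @inheritParams genome_depth_from_kmer_depth
#' @return k-mer depth `M = N * (L - k + 1) / L`.
#' @export
kmer_depth_from_genome_depth <- function(N, L, k) {
  stopifnot(is.numeric(N), is.numeric(L), is.numeric(k))
  if (any(k > L)) stop("k must satisfy k < L + 1")
  N * (L - k + 1) / L
}

#' Express an ND threshold in k-mer-count units
#'
#' Binning compares per-read maximum k-mer counts against the threshold;
#' converting the read-depth threshold into k-mer-count units (the inverse
#' depth relation) keeps the comparison in consistent units. The conversion
#' always lowers the threshold (since `(L - k + 1) / L <= 1`), so it is the
#' conservative, recall-favouring choice.
#'
#' @param nd an [nd_threshold()].
#' @inheritParams genome_depth_from_kmer_depth
#' @return the `nd_threshold` with `kmer_threshold` filled in.
#' @export
kmer_threshold_from_nd <- function(nd, L, k) {
  stopifnot(inherits(nd, "nd_threshold"))
  nd$kmer_threshold <- kmer_depth_from_genome_depth(nd$value, L, k)
  nd
}

#' Effective read length of a pool
#'
#' Modal post-trimming read length over a sample of at most `sample_size`
#' reads; ties break to the smaller length (the conservative choice for the
#' threshold conversion). This is the `L` of the depth/k-mer-depth
#' relation.
#'
#' @param reads a [read_set()] or character vector.
#' @param sample_size maximum number of reads inspected.
#' @return integer modal read length.
#' @export
effective_read_length <- function(reads, sample_size = 100000L) {
  reads <- as_read_set(reads)
  if (nrow(reads) == 0L) stop("cannot determine read length of an empty pool")
  lens <- nchar(reads$bases[seq_len(min(nrow(reads), sample_size))])
  tab <- table(lens)
  modes <- as.integer(names(tab)[tab == max(tab)])
  min(modes)
}
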
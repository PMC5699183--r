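#' Estimate per-contig genome depth from a k-mer sketch
#'
#' Median sketch count over (a sample of) each contig's k-mer windows,
#' converted from k-mer-depth to genome-depth units. A cheap, mapping-free
#' depth estimate used to pick a nuclear anchor among initial contigs.
#'
#' @param sketch a [kmer_sketch()] built over the read pool.
#' @param contigs a [contig_set()].
#' @param L effective read length of the pool (for the unit conversion).
#' @param n_windows maximum windows sampled per contig.
#' @return numeric vector of estimated genome depths, one per contig.
#' @export
contig_kmer_depth <- function(sketch, contigs, L, n_windows = 300L) {
  stopifnot(inherits(sketch, "kmer_sketch"), inherits(contigs, "contig_set"))
  k <- sketch$k
  vapply(contigs$bases, function(seq) {
    n <- nchar(seq) - k + 1L
    if (n < 1L) return(NA_real_)
    starts <- unique(round(seq(1L, n, length.out = min(n, n_windows))))
    kmers <- substring(seq, starts, starts + k - 1L)
    kmers <- kmers[!grepl("N", kmers, fixed = TRUE)]
    if (length(kmers) == 0L) return(NA_real_)
    m <- stats::median(kmer_estimate(sketch, kmers))
    genome_depth_from_kmer_depth(m, L, k)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Choose the nuclear anchor among initial-assembly contigs
#'
#' The classical rule -- the longest contig is nuclear -- holds when the
#' nuclear genome dwarfs the organelle, so that some nuclear contig always
#' outgrows the organelle. On small or fragmented assemblies the organelle
#' itself can be the longest contig, which would push the depth threshold
#' to organelle levels and empty the bin. This selector therefore takes the
#' longest contig whose estimated depth is *typical*: within
#' `depth_factor` times the length-weighted median depth across contigs
#' (most assembled bases are nuclear, so the typical depth is the nuclear
#' depth). If no contig qualifies it falls back to the longest, with a
#' warning.
#'
#' @param contigs a non-empty [contig_set()].
#' @param depths estimated genome depth per contig
#'   ([contig_kmer_depth()]).
#' @param depth_factor tolerance above the typical depth (default 3;
#'   intentionally below the threshold factor 5, so anything organelle-like
#'   at >= 10x nuclear depth is excluded while ordinary repeats pass).
#' @return a one-row [contig_set()].
#' @export
select_anchor <- function(contigs, depths, depth_factor = 3) {
  stopifnot(inherits(contigs, "contig_set"), nrow(contigs) > 0L,
            length(depths) == nrow(contigs))
  lens <- nchar(contigs$bases)
  ok <- !is.na(depths)
  if (!any(ok)) return(select_candidate(contigs, "longest"))
  ord <- order(depths[ok])
  w <- cumsum(lens[ok][ord]) / sum(lens[ok][ord])
  typical <- depths[ok][ord][which(w >= 0.5)[1]]
  eligible <- ok & depths <= depth_factor * typical
  if (!any(eligible)) {
    warning("no contig has typical depth; falling back to the longest")
    return(select_candidate(contigs, "longest"))
  }
  pool <- contigs[eligible, , drop = FALSE]
  out <- select_candidate(pool, "longest")
  out
}
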
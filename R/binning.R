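#' Bin reads by maximum k-mer frequency
#'
#' Retains the subset of reads containing at least one k-mer whose sketch
#' count is strictly greater than the threshold -- the high-copy-number
#' pool. Because sketch estimates never underestimate, every read whose
#' true maximum k-mer count exceeds the threshold is retained: sketching
#' can add nuclear false positives (harmless small contigs downstream) but
#' never lose organelle reads.
#'
#' With `keep_pairs` (the default) a whole pair is retained when either
#' mate qualifies: the mate of an organelle read is almost surely organelle
#' too, and keeping it improves assembler connectivity.
#'
#' @param reads a [read_set()]; the same (post-trim) pool the sketch was
#'   built over.
#' @param sketch a [kmer_sketch()] built over `reads`.
#' @param threshold positive k-mer-count threshold (see
#'   [kmer_threshold_from_nd()]); comparison is strict (`> threshold`).
#' @param keep_pairs retain the full pair when either mate qualifies.
#' @return list with `reads` (retained `read_set`) and `counts` (`input`,
#'   `retained`, `qualifying`, `rescued_mates`).
#' @export
bin_reads <- function(reads, sketch, threshold, keep_pairs = TRUE) {
  reads <- as_read_set(reads)
  stopifnot(inherits(sketch, "kmer_sketch"))
  if (!is.numeric(threshold) || threshold <= 0)
    stop("threshold must be > 0")
  maxc <- max_kmer_count(sketch, reads)
  qualifies <- maxc > threshold
  keep <- qualifies
  if (keep_pairs && any(qualifies)) {
    qualifying_pairs <- unique(reads$pair_id[qualifies & reads$mate > 0L])
    keep <- keep | (reads$mate > 0L & reads$pair_id %in% qualifying_pairs)
  }
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(reads = out,
       counts = list(input = nrow(reads),
                     retained = nrow(out),
                     qualifying = sum(qualifies),
                     rescued_mates = sum(keep & !qualifies)))
}
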
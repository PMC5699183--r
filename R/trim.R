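#' Trimming configuration
#'
#' Controls the built-in 3' adapter/quality trimmer. Adapter matching is an
#' exact match of an adapter prefix at the read 3' end with a minimum
#' overlap of 8 bp and no mismatches; this keeps trimming deterministic and
#' testable. No adapter sequences are assumed by default -- if none are
#' supplied, adapter matching is skipped and only quality/length filtering
#' applies.
#'
#' @param adapter_sequences character vector of adapter sequences (5'->3').
#' @param min_length minimum surviving read length in bp (default 30).
#' @param quality_cutoff Phred score below which 3' tail bases are trimmed
#'   (default 2).
#' @param min_adapter_overlap minimum exact adapter overlap in bp.
#' @return a `trim_config` list.
#' @export
trim_config <- function(adapter_sequences = character(),
                        min_length = 30L,
                        quality_cutoff = 2L,
                        min_adapter_overlap = 8L) {
  stopifnot(min_length >= 1L, min_adapter_overlap >= 1L, quality_cutoff >= 0L)
  adapter_sequences <- toupper(adapter_sequences)
  if (length(adapter_sequences) && any(grepl("[^ACGT]", adapter_sequences)))
    stop("adapter sequences must be over {A,C,G,T}")
  structure(list(adapter_sequences = adapter_sequences,
                 min_length = as.integer(min_length),
                 quality_cutoff = as.integer(quality_cutoff),
                 min_adapter_overlap = as.integer(min_adapter_overlap)),
            class = "trim_config")
}

#' Trim a single read
#'
#' Removes a 3' adapter contamination (exact prefix-of-adapter match at the
#' read end) and then a low-quality 3' tail. A read shorter than
#' `cfg$min_length` after trimming is discarded, signalled by returning
#' `NULL` (a valid outcome, not an error).
#'
#' @param read one-row [read_set()].
#' @param cfg a [trim_config()].
#' @return the trimmed one-row `read_set`, or `NULL` if discarded.
#' @export
trim_read <- function(read, cfg = trim_config()) {
  stopifnot(inherits(read, "read_set"), nrow(read) == 1L)
  out <- trim_read_set(read, cfg)
  if (nrow(out) == 0L) NULL else out
}

# vectorised trimming; drops discarded rows, resets orphaned mates to unpaired
trim_read_set <- function(reads, cfg) {
  if (nrow(reads) == 0L) return(reads)
  tr <- trim_reads_cpp(reads$bases, reads$quals, cfg$adapter_sequences,
                       cfg$min_adapter_overlap, cfg$quality_cutoff)
  reads$bases <- tr$bases
  reads$quals <- tr$quals
  keep <- nchar(reads$bases) >= cfg$min_length
  out <- reads[keep, , drop = FALSE]
  # a survivor whose mate was discarded becomes an unpaired singleton
  n_orphaned <- 0L
  if (nrow(out) > 0L && any(out$mate > 0L)) {
    mates_per_pair <- table(out$pair_id[out$mate > 0L])
    orphan <- out$mate > 0L &
      as.vector(mates_per_pair[as.character(out$pair_id)]) == 1L
    out$mate[orphan] <- 0L
    n_orphaned <- sum(orphan)
  }
  rownames(out) <- NULL
  attr(out, "n_orphaned") <- n_orphaned
  out
}

#' Preprocess a read set: trim, filter, and keep orphans as singletons
#'
#' Applies [trim_read()] to every read. When exactly one mate of a pair is
#' discarded, the survivor is kept as an unpaired singleton (maximising
#' recall of high-copy reads rather than dropping the pair).
#'
#' @param reads a [read_set()].
#' @param cfg a [trim_config()].
#' @return list with `reads` (the surviving `read_set`) and `counts`
#'   (`input`, `output`, `discarded`, `orphaned` read counts).
#' @export
preprocess <- function(reads, cfg = trim_config()) {
  stopifnot(inherits(reads, "read_set"))
  n_in <- nrow(reads)
  out <- trim_read_set(reads, cfg)
  list(reads = out,
       counts = list(input = n_in,
                     output = nrow(out),
                     discarded = n_in - nrow(out),
                     orphaned = attr(out, "n_orphaned") %||% 0L))
}
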
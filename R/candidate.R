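#' Select the candidate organelle contig
#'
#' By default the longest contig: in a high-frequency-k-mer assembly the
#' long nuclear genome is not assembled, so the longest contig is expected
#' to be the organelle. In `annotated` mode the longest contig with a hit
#' from a user-supplied annotation result (see [annotation_hook()]) is
#' chosen instead, falling back to the longest with a warning when no
#' annotation is available or nothing hits.
#'
#' @param contigs a non-empty [contig_set()].
#' @param mode `"longest"` or `"annotated"`.
#' @param annotations named list (contig_id -> hit table) as returned by
#'   [annotation_hook()]; used in `annotated` mode.
#' @return a one-row [contig_set()]. Length ties break to the
#'   lexicographically smaller sequence.
#' @export
select_candidate <- function(contigs, mode = c("longest", "annotated"),
                             annotations = NULL) {
  stopifnot(inherits(contigs, "contig_set"))
  if (nrow(contigs) == 0L) stop("cannot select a candidate from zero contigs")
  mode <- match.arg(mode)
  pool <- contigs
  if (mode == "annotated") {
    hit_ids <- names(annotations)[vapply(annotations, function(h)
      !is.null(h) && nrow(h) > 0L, logical(1))]
    if (length(hit_ids) == 0L) {
      warning("no annotation hits available; falling back to longest contig")
    } else {
      pool <- contigs[contigs$contig_id %in% hit_ids, , drop = FALSE]
      if (nrow(pool) == 0L) {
        warning("annotation hits match no contig id; falling back to longest")
        pool <- contigs
      }
    }
  }
  ord <- order(-nchar(pool$bases), pool$bases)
  out <- pool[ord[1], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Test a contig for circularity and trim the duplicated terminus
#'
#' A contig assembled once around a circular molecule carries a duplicated
#' terminal overlap: its first bases reappear at its end. Overlap lengths
#' from `min(floor(length/2), max_scan)` down to `min_overlap` are scanned
#' for the longest prefix/suffix match with at most `max_mismatch_frac`
#' mismatches; on success the suffix copy is cut. A 50 bp minimum overlap
#' makes chance matches on random sequence astronomically unlikely while
#' the 2% mismatch allowance tolerates end-of-assembly errors.
#'
#' @param contig a one-row [contig_set()] or a single DNA string.
#' @param min_overlap minimum overlap length in bp (default 50).
#' @param max_mismatch_frac maximum mismatch fraction within the overlap.
#' @param max_scan largest overlap length scanned (default 2000).
#' @return a `circularity_result`: list with `is_circular`,
#'   `overlap_length` and `trimmed` (one-row `contig_set`; the input,
#'   untrimmed, when not circular).
#' @export
check_circularity <- function(contig, min_overlap = 50L,
                              max_mismatch_frac = 0.02, max_scan = 2000L) {
  if (!inherits(contig, "contig_set"))
    contig <- contig_set("contig", contig)
  stopifnot(nrow(contig) == 1L)
  seq <- contig$bases
  n <- nchar(seq)
  not_circular <- structure(list(is_circular = FALSE, overlap_length = 0L,
                                 trimmed = contig),
                            class = "circularity_result")
  if (n <= 2L * min_overlap) {
    warning("contig of ", n, " bp is too short for a circularity test at ",
            "min_overlap ", min_overlap)
    return(not_circular)
  }
  x <- charToRaw(seq)
  hi <- min(n %/% 2L, max_scan)
  for (ov in seq(hi, min_overlap)) {
    mm <- sum(x[seq_len(ov)] != x[(n - ov + 1L):n])
    if (mm <= floor(max_mismatch_frac * ov)) {
      trimmed <- contig
      trimmed$bases <- substr(seq, 1L, n - ov)
      return(structure(list(is_circular = TRUE, overlap_length = as.integer(ov),
                            trimmed = trimmed),
                       class = "circularity_result"))
    }
  }
  not_circular
}

#' @export
print.circularity_result <- function(x, ...) {
  if (x$is_circular)
    cat(sprintf("circular: %d bp terminal overlap trimmed -> %d bp\n",
                x$overlap_length, nchar(x$trimmed$bases)))
  else cat("not circular (no terminal overlap found)\n")
  invisible(x)
}

#' Validate a candidate by depth comparison against the nuclear background
#'
#' Maps the reads to the candidate and to a same-length section of the
#' nuclear anchor and compares mean depths. A depth ratio around the
#' organelle copy number (10--100x) supports an organelle origin; the
#' verdict is `"supported"` when the ratio reaches `support_ratio`.
#'
#' @param reads a [read_set()] (the full preprocessed pool).
#' @param candidate one-row [contig_set()] or DNA string.
#' @param nuclear_anchor one-row [contig_set()] or DNA string (the longest
#'   contig of the initial assembly). If shorter than the candidate, the
#'   whole anchor is used.
#' @param support_ratio minimum depth ratio for a `"supported"` verdict.
#' @return a `validation_report`: list with `candidate_mean_depth`,
#'   `nuclear_mean_depth`, `depth_ratio`, both profiles, `verdict` and a
#'   `diagnostic` string when degenerate.
#' @export
validate_candidate <- function(reads, candidate, nuclear_anchor,
                               support_ratio = 5) {
  reads <- as_read_set(reads)
  if (!inherits(candidate, "contig_set"))
    candidate <- contig_set("candidate", candidate)
  if (!inherits(nuclear_anchor, "contig_set"))
    nuclear_anchor <- contig_set("nuclear_anchor", nuclear_anchor)
  span <- min(nchar(candidate$bases), nchar(nuclear_anchor$bases))
  cand_prof <- depth_profile(reads, candidate)
  nuc <- nuclear_anchor
  nuc$bases <- substr(nuc$bases, 1L, span)
  nuc_prof <- depth_profile(reads, nuc)
  cmd <- mean(cand_prof$depths)
  nmd <- mean(nuc_prof$depths)
  diagnostic <- NULL
  if (nmd == 0) {
    diagnostic <- "no reads mapped to the nuclear anchor; ratio undefined"
    ratio <- NA_real_
    verdict <- "unsupported"
  } else {
    ratio <- cmd / nmd
    verdict <- if (ratio >= support_ratio) "supported" else "unsupported"
  }
  structure(list(candidate_mean_depth = cmd, nuclear_mean_depth = nmd,
                 depth_ratio = ratio, candidate_profile = cand_prof,
                 nuclear_profile = nuc_prof, verdict = verdict,
                 support_ratio = support_ratio, diagnostic = diagnostic),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(
    "validation: candidate depth %.2f vs nuclear %.2f (ratio %s) -> %s\n",
    x$candidate_mean_depth, x$nuclear_mean_depth,
    ifelse(is.na(x$depth_ratio), "NA", sprintf("%.2f", x$depth_ratio)),
    x$verdict))
  if (!is.null(x$diagnostic)) cat("  note:", x$diagnostic, "\n")
  invisible(x)
}

#' Write the depth-comparison table of a validation report
#'
#' Tabular depth data (position, candidate depth, nuclear depth) -- the
#' testable form of the validation graph; plotting is left to the user.
#'
#' @param report a [validate_candidate()] result.
#' @param path output TSV.
#' @return invisibly, `path`.
#' @export
write_depth_comparison <- function(report, path) {
  stopifnot(inherits(report, "validation_report"))
  n <- max(length(report$candidate_profile$depths),
           length(report$nuclear_profile$depths))
  pad <- function(v) c(v, rep(NA_integer_, n - length(v)))
  df <- data.frame(position = seq_len(n) - 1L,
                   candidate_depth = pad(report$candidate_profile$depths),
                   nuclear_depth = pad(report$nuclear_profile$depths))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run an external annotation hook over contigs
#'
#' Optional, pluggable annotation (e.g. a BLAST search against organelle
#' references): the template's `{query_fasta}` and `{out_tsv}` placeholders
#' are substituted, the command is run, and the standard 6-column tabular
#' output (query id, subject id, percent identity, alignment length,
#' e-value, bit-score) is parsed. Up to 10 hits per contig are kept, sorted
#' by descending bit-score (ties: subject id). Failures degrade to a
#' warning and an empty mapping -- annotation is never required, keeping
#' the method reference-free.
#'
#' @param contigs a [contig_set()].
#' @param hook_spec shell command template with `{query_fasta}` and
#'   `{out_tsv}`, or `NULL`/`NA` for "no hook".
#' @param max_hits hits retained per contig.
#' @return named list: contig_id -> data.frame of hits (possibly empty).
#' @export
annotation_hook <- function(contigs, hook_spec, max_hits = 10L) {
  stopifnot(inherits(contigs, "contig_set"))
  empty <- stats::setNames(vector("list", 0L), character())
  if (is.null(hook_spec) || is.na(hook_spec) || !nzchar(hook_spec)) {
    warning("no annotation hook supplied; returning an empty mapping")
    return(empty)
  }
  query <- tempfile(fileext = ".fa")
  out_tsv <- tempfile(fileext = ".tsv")
  write_fasta(contigs, query)
  cmd <- gsub("{query_fasta}", query, hook_spec, fixed = TRUE)
  cmd <- gsub("{out_tsv}", out_tsv, cmd, fixed = TRUE)
  res <- suppressWarnings(system(cmd, intern = TRUE))
  status <- attr(res, "status") %||% 0L
  if (status != 0L || !file.exists(out_tsv)) {
    warning("annotation hook failed (exit ", status, "); ignoring annotation")
    return(empty)
  }
  tab <- tryCatch(
    utils::read.table(out_tsv, sep = "\t", stringsAsFactors = FALSE,
                      col.names = c("query_id", "subject_id", "pct_identity",
                                    "align_length", "evalue", "bit_score")),
    error = function(e) NULL)
  if (is.null(tab) || nrow(tab) == 0L) return(empty)
  split_hits <- split(tab, tab$query_id)
  lapply(split_hits, function(h) {
    h <- h[order(-h$bit_score, h$subject_id), , drop = FALSE]
    rownames(h) <- NULL
    utils::head(h, max_hits)
  })
}
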
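#' Read FASTQ files into a read set
#'
#' Parses 4-line FASTQ records (Phred+33), transparently decompressing gzip
#' (detected by the magic bytes, not the file name). When `paired_path` is
#' given the two files are read in lockstep and mates are linked by
#' position, as produced by standard paired-end runs; the two files must
#' contain equal record counts and matching identifiers up to a `/1`//`/2`
#' or whitespace-delimited mate tag.
#'
#' @param path FASTQ file (plain or gzip).
#' @param paired_path optional second FASTQ with the mates of `path`.
#' @return a [read_set()]; paired reads carry `mate` 1/2 and a shared
#'   `pair_id`.
#' @export
read_fastq <- function(path, paired_path = NULL) {
  r1 <- parse_one_fastq(path)
  if (is.null(paired_path)) {
    return(read_set(r1$id, r1$bases, r1$quals, mate = 0L))
  }
  r2 <- parse_one_fastq(paired_path)
  if (length(r1$id) != length(r2$id))
    stop("pairing error: ", path, " has ", length(r1$id), " records but ",
         paired_path, " has ", length(r2$id))
  mism <- strip_mate_suffix(r1$id) != strip_mate_suffix(r2$id)
  if (any(mism))
    stop("pairing error: read ids disagree at record ", which(mism)[1])
  n <- length(r1$id)
  read_set(c(rbind(r1$id, r2$id)),
           c(rbind(r1$bases, r2$bases)),
           c(rbind(r1$quals, r2$quals)),
           mate = rep(c(1L, 2L), n),
           pair_id = rep(seq_len(n), each = 2L))
}

is_gzip <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 2L)
  length(magic) == 2L && magic[1] == as.raw(0x1f) && magic[2] == as.raw(0x8b)
}

parse_one_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  con <- if (is_gzip(path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  if (length(lines) %% 4L != 0L)
    stop("malformed FASTQ ", path, ": line count ", length(lines),
         " is not a multiple of 4")
  if (length(lines) == 0L)
    return(list(id = character(), bases = character(), quals = character()))
  hdr <- lines[seq(1L, length(lines), by = 4L)]
  bases <- lines[seq(2L, length(lines), by = 4L)]
  quals <- lines[seq(4L, length(lines), by = 4L)]
  bad_hdr <- !startsWith(hdr, "@")
  if (any(bad_hdr))
    stop("malformed FASTQ ", path, ": record ", which(bad_hdr)[1],
         " does not start with '@'")
  bad_len <- nchar(bases) != nchar(quals)
  if (any(bad_len))
    stop("malformed FASTQ ", path, ": record ", which(bad_len)[1],
         " has ", nchar(bases)[which(bad_len)[1]], " bases but ",
         nchar(quals)[which(bad_len)[1]], " quality values")
  list(id = sub("^@", "", hdr), bases = bases, quals = quals)
}

#' Write a read set as FASTQ
#'
#' Paired mates and unpaired reads can be split into separate files, the
#' layout expected by downstream assemblers.
#'
#' @param reads a [read_set()].
#' @param path output FASTQ (gzip if the name ends in `.gz`).
#' @param path2 optional: mates with `mate == 2` go here (and `mate == 1`
#'   to `path`); unpaired reads go to `singleton_path` if given, else to
#'   `path`.
#' @param singleton_path optional FASTQ for unpaired reads.
#' @return invisibly, the vector of files written.
#' @export
write_fastq <- function(reads, path, path2 = NULL, singleton_path = NULL) {
  stopifnot(inherits(reads, "read_set"))
  written <- character()
  emit <- function(sub, p) {
    con <- if (grepl("\\.gz$", p)) gzfile(p, "wt") else file(p, "wt")
    on.exit(close(con))
    if (nrow(sub) > 0)
      writeLines(c(rbind(paste0("@", sub$read_id), sub$bases, "+", sub$quals)),
                 con)
    else writeLines(character(), con)
    written <<- c(written, p)
  }
  if (is.null(path2)) {
    emit(reads, path)
  } else {
    emit(reads[reads$mate == 1L, , drop = FALSE], path)
    emit(reads[reads$mate == 2L, , drop = FALSE], path2)
    singles <- reads[reads$mate == 0L, , drop = FALSE]
    if (!is.null(singleton_path)) emit(singles, singleton_path)
    else if (nrow(singles) > 0)
      warning(nrow(singles), " unpaired reads appended to ", path)
  }
  invisible(written)
}

#' Construct a contig set
#'
#' Assembled sequences with their provenance: a `data.frame` with columns
#' `contig_id`, `bases`, `mean_depth` (NA until a depth profile is
#' computed) and `source` (`"built_in"` or `"external"`).
#'
#' @param contig_id character ids.
#' @param bases character DNA sequences (non-empty, `{A,C,G,T}`).
#' @param mean_depth numeric, recycled.
#' @param source character, recycled.
#' @return a `contig_set` (also a `data.frame`).
#' @export
contig_set <- function(contig_id, bases, mean_depth = NA_real_,
                       source = "built_in") {
  stopifnot(is.character(contig_id), is.character(bases),
            length(contig_id) == length(bases))
  if (length(bases) > 0 && any(!nzchar(bases)))
    stop("contig sequences must be non-empty")
  out <- data.frame(contig_id = contig_id, bases = toupper(bases),
                    mean_depth = rep_len(as.numeric(mean_depth), length(bases)),
                    source = rep_len(source, length(bases)),
                    stringsAsFactors = FALSE)
  class(out) <- c("contig_set", "data.frame")
  out
}

#' @export
print.contig_set <- function(x, ...) {
  cat("contig_set with", nrow(x), "contigs")
  if (nrow(x) > 0)
    cat("; lengths", paste(utils::head(nchar(x$bases), 5), collapse = ", "),
        if (nrow(x) > 5) "...")
  cat("\n")
  invisible(x)
}

#' Write contigs to FASTA
#'
#' Standard FASTA via Biostrings, input order preserved, 70-column wrapping.
#' An empty contig set produces an empty (but valid) file.
#'
#' @param contigs a [contig_set()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_fasta <- function(contigs, path) {
  stopifnot(inherits(contigs, "contig_set"))
  set <- Biostrings::DNAStringSet(contigs$bases)
  names(set) <- contigs$contig_id
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Read a FASTA file into a contig set
#'
#' @param path FASTA file (plain or gzip).
#' @param source provenance label to attach.
#' @return a [contig_set()].
#' @export
read_fasta <- function(path, source = "external") {
  set <- Biostrings::readDNAStringSet(path)
  contig_set(names(set) %||% character(), as.character(set), source = source)
}
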
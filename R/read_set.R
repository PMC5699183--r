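#' Construct a read set
#'
#' A `read_set` is the package's in-memory container for sequencing reads: a
#' `data.frame` with one row per read and columns `read_id`, `bases`,
#' `quals` (Phred+33 string, same length as `bases`), `mate` (0 for
#' unpaired, 1 or 2 for the two mates of a pair) and `pair_id` (integer
#' shared by the two mates of a pair, unique otherwise). Bases are
#' case-normalised on construction and characters outside `{A,C,G,T,N}` are
#' mapped to `N` with a warning.
#'
#' @param read_id character vector of read identifiers.
#' @param bases character vector of DNA sequences.
#' @param quals character vector of Phred+33 quality strings; defaults to
#'   constant Phred 35.
#' @param mate integer vector (0, 1 or 2), recycled.
#' @param pair_id integer vector grouping mates; defaults to one group per
#'   row (all unpaired).
#' @return a `read_set` (also a `data.frame`).
#' @export
#' @examples
#' rs <- read_set(c("r1", "r2"), c("ACGTACGT", "TTTTACGT"))
#' n_reads(rs)
read_set <- function(read_id, bases, quals = NULL, mate = 0L, pair_id = NULL) {
  stopifnot(is.character(read_id), is.character(bases),
            length(read_id) == length(bases))
  bases <- normalize_bases(bases)
  if (is.null(quals))
    quals <- vapply(nchar(bases), function(n)
      strrep(rawToChar(as.raw(35L + 33L)), n), character(1))
  if (any(nchar(quals) != nchar(bases)))
    stop("quality strings must have the same length as the bases")
  mate <- rep_len(as.integer(mate), length(bases))
  if (is.null(pair_id)) pair_id <- seq_along(bases)
  out <- data.frame(read_id = read_id, bases = bases, quals = quals,
                    mate = mate, pair_id = as.integer(pair_id),
                    stringsAsFactors = FALSE)
  class(out) <- c("read_set", "data.frame")
  out
}

#' Number of reads in a read set
#' @param x a `read_set`.
#' @return integer read count.
#' @export
n_reads <- function(x) nrow(x)

#' @export
print.read_set <- function(x, ...) {
  cat("read_set with", nrow(x), "reads (",
      sum(x$mate > 0L), "paired,", sum(x$mate == 0L), "unpaired )\n")
  if (nrow(x) > 0) print(utils::head(as.data.frame(x), 3))
  invisible(x)
}

# strip a trailing mate tag: "/1", "/2", or a whitespace-delimited suffix
strip_mate_suffix <- function(id) {
  sub("/[12]$", "", sub("\\s.*$", "", id))
}

as_read_set <- function(x) {
  if (inherits(x, "read_set")) return(x)
  if (is.character(x))
    return(read_set(sprintf("read_%d", seq_along(x)), x))
  stop("cannot interpret object of class ", paste(class(x), collapse = "/"),
       " as a read_set")
}
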
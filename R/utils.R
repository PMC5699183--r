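#' Reverse complement of DNA strings
#'
#' Vectorised over a character vector; preserves `N`.
#'
#' @param x character vector of DNA sequences over `{A,C,G,T,N}`.
#' @return character vector of reverse complements.
#' @export
#' @examples
#' revcomp(c("ACGT", "TTTA"))
revcomp <- function(x) {
  stopifnot(is.character(x))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Random DNA sequence with uniform base composition
#'
#' @param n sequence length in bp.
#' @return a single DNA string.
#' @export
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# normalise bases on ingest: upper-case, anything outside {A,C,G,T,N} -> N
normalize_bases <- function(bases, warn = TRUE) {
  bases <- toupper(bases)
  bad <- grepl("[^ACGTN]", bases)
  if (any(bad)) {
    if (warn)
      warning(sum(bad), " read(s) contained characters outside {A,C,G,T,N}; ",
              "mapped to N")
    bases[bad] <- gsub("[^ACGTN]", "N", bases[bad])
  }
  bases
}

# %||% as in rlang, kept internal
`%||%` <- function(a, b) if (is.null(a)) b else a
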
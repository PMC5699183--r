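#' Assembly configuration
#'
#' Parameters of the built-in iterative-k de Bruijn unitig assembler. The
#' k list must be strictly increasing and odd (odd k rules out palindromic
#' k-mers, which would break canonical graph traversal). `min_kmer_count`
#' of 2 suppresses singleton sequencing-error k-mers. For reference, the
#' external-assembler presets used in real deployments are 21/49/77/105 for
#' the initial whole-pool assembly and 20/40/60/80/100 for the post-binning
#' assembly.
#'
#' @param k_list strictly increasing odd k-mer sizes (default 21, 41, 61).
#' @param min_kmer_count minimum read-support count for a k-mer to enter
#'   the graph (default 2).
#' @param min_contig_length minimum emitted contig length in bp (default
#'   200).
#' @param tip_rounds rounds of short-tip removal per k.
#' @return an `assembly_config` list.
#' @export
assembly_config <- function(k_list = c(21L, 41L, 61L),
                            min_kmer_count = 2L,
                            min_contig_length = 200L,
                            tip_rounds = 3L) {
  k_list <- as.integer(k_list)
  if (any(diff(k_list) <= 0L)) stop("k_list must be strictly increasing")
  if (any(k_list %% 2L == 0L)) stop("all k in k_list must be odd")
  structure(list(k_list = k_list,
                 min_kmer_count = as.integer(min_kmer_count),
                 min_contig_length = as.integer(min_contig_length),
                 tip_rounds = as.integer(tip_rounds)),
            class = "assembly_config")
}

#' Assemble reads into contigs (built-in assembler)
#'
#' A deliberately simple unitig assembler: per k it keeps canonical k-mers
#' seen at least `min_kmer_count` times, pops tips shorter than `2k`, and
#' collapses unbranched paths. Unitigs of each k re-enter the next, larger
#' k as pseudo-reads whose k-mers are kept unconditionally (the
#' iterative-k strategy), letting contigs grow across stretches where
#' direct read support at large k is thin. No scaffolding, bubble popping
#' or paired-end resolution: sufficient for the small, high-depth organelle
#' read subsets this pipeline produces, and fully deterministic --
#' including under read-order permutation. Real deployments may substitute
#' [run_external_assembler()].
#'
#' A perfectly covered circular genome emits a single unitig that runs once
#' around the circle plus a duplicated `k - 1` bp terminus, which is what
#' [check_circularity()] later detects and trims.
#'
#' @param reads a [read_set()] or character vector; empty input yields an
#'   empty contig set.
#' @param cfg an [assembly_config()].
#' @return a [contig_set()] sorted by length descending (ties:
#'   lexicographically smaller sequence first), `source = "built_in"`.
#' @export
assemble <- function(reads, cfg = assembly_config()) {
  reads <- as_read_set(reads)
  stopifnot(inherits(cfg, "assembly_config"))
  unitigs <- character()
  for (k in cfg$k_list)
    unitigs <- assemble_k_cpp(reads$bases, unitigs, k, cfg$min_kmer_count,
                              cfg$tip_rounds)
  unitigs <- unitigs[nchar(unitigs) >= cfg$min_contig_length]
  unitigs <- unitigs[order(-nchar(unitigs), unitigs)]
  contig_set(sprintf("contig_%d", seq_along(unitigs)), unitigs,
             source = "built_in")
}

#' Run an external assembler through a command template
#'
#' Substitutes `{r1}`, `{r2}` (optional) and `{out}` in the template, runs
#' it through the shell, and parses the FASTA written to `{out}` into
#' contigs with `source = "external"`; e.g.
#' `"megahit -1 {r1} -2 {r2} -o tmp && cp tmp/final.contigs.fa {out}"`.
#'
#' @param r1 path to reads (FASTQ), substituted for `{r1}`.
#' @param template shell command template containing `{r1}` and `{out}`.
#' @param r2 optional mate file for `{r2}`.
#' @param out_fasta path the tool must write; defaults to a temp file.
#' @return a [contig_set()]; empty output FASTA yields an empty set with a
#'   warning.
#' @export
run_external_assembler <- function(r1, template, r2 = NULL,
                                   out_fasta = tempfile(fileext = ".fa")) {
  cmd <- gsub("{r1}", r1, template, fixed = TRUE)
  if (!is.null(r2)) cmd <- gsub("{r2}", r2, cmd, fixed = TRUE)
  cmd <- gsub("{out}", out_fasta, cmd, fixed = TRUE)
  res <- suppressWarnings(system(cmd, intern = TRUE))
  status <- attr(res, "status") %||% 0L
  if (status != 0L)
    stop("external assembler failed (exit ", status, "): ",
         paste(res, collapse = "\n"))
  if (!file.exists(out_fasta))
    stop("external assembler produced no output at ", out_fasta)
  contigs <- read_fasta(out_fasta, source = "external")
  if (nrow(contigs) == 0L)
    warning("external assembler produced an empty FASTA")
  contigs
}
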
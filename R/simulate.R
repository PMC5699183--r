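#' Specification of a synthetic WGS dataset
#'
#' The stated world of the simulator: a random nuclear sequence plus a
#' random circular organelle sequence present at `copy_ratio` times the
#' nuclear depth (organelles sit at 10--100 copies per cell; the default
#' ratio of 20 lies inside that range). Reads are uniform paired-end with
#' i.i.d. substitution errors; no indels, GC bias or platform quirks (see
#' the methods vignette for what this does and does not exercise).
#' Optionally, `numt_count` verbatim organelle fragments are copied into
#' the nuclear sequence to emulate NUMTs -- nuclear insertions of
#' mitochondrial DNA, the worst-case (100% identity) form of that
#' contamination.
#'
#' @param nuclear_length nuclear genome length in bp.
#' @param organelle_length circular organelle genome length in bp.
#' @param copy_ratio organelle depth / nuclear depth (> 1).
#' @param nuclear_depth mean nuclear read depth (x).
#' @param read_length read length in bp.
#' @param insert_mean,insert_sd fragment (insert) size distribution in bp.
#' @param error_rate per-base substitution probability (0 <= e < 0.1).
#' @param numt_count number of NUMT insertions.
#' @param numt_length length of each NUMT in bp.
#' @param seed integer RNG seed; the whole dataset is reproducible from it.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(nuclear_length = 50000L, organelle_length = 16000L,
                           copy_ratio = 20, nuclear_depth = 10,
                           read_length = 100L, insert_mean = 300L,
                           insert_sd = 30, error_rate = 0.005,
                           numt_count = 0L, numt_length = 500L, seed = 1L) {
  stopifnot(copy_ratio > 1, nuclear_length > 0, organelle_length > 0,
            read_length > 0, insert_mean >= read_length,
            error_rate >= 0, error_rate < 0.1,
            numt_count >= 0, numt_length > 0)
  if (insert_mean > nuclear_length || insert_mean > organelle_length)
    stop("infeasible spec: insert_mean exceeds a genome length")
  if (numt_count > 0 && numt_length > organelle_length)
    stop("numt_length exceeds the organelle length")
  structure(list(nuclear_length = as.integer(nuclear_length),
                 organelle_length = as.integer(organelle_length),
                 copy_ratio = copy_ratio, nuclear_depth = nuclear_depth,
                 read_length = as.integer(read_length),
                 insert_mean = as.integer(insert_mean), insert_sd = insert_sd,
                 error_rate = error_rate, numt_count = as.integer(numt_count),
                 numt_length = as.integer(numt_length),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# i.i.d. substitution errors; each error draws uniformly among the 3 others
add_errors <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0) return(seqs)
  bases <- c("A", "C", "G", "T")
  n_err <- stats::rbinom(length(seqs), nchar(seqs), rate)
  for (i in which(n_err > 0)) {
    s <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    pos <- sample.int(length(s), n_err[i])
    for (p in pos) s[p] <- sample(bases[bases != s[p]], 1L)
    seqs[i] <- paste(s, collapse = "")
  }
  seqs
}

#' Simulate a labelled synthetic WGS dataset
#'
#' Draws fragments uniformly from the nuclear sequence and -- treating the
#' organelle as circular, so fragments may wrap the origin -- from the
#' organelle, with fragment counts proportional to length x depth. Each
#' fragment yields a forward R1 and reverse-complemented R2 of
#' `read_length` bp, with substitution errors and constant Phred 35
#' qualities. Every read carries a truth label (`nuclear`, `organelle` or
#' `numt`) tied to its sampled coordinates.
#'
#' @param spec a [synthetic_spec()].
#' @param out_dir optional directory; when given, paired gzip FASTQ, a
#'   truth FASTA and a truth label TSV are written there.
#' @return list with `reads` (a [read_set()]), `truth` (a
#'   `synthetic_truth`: `nuclear_seq`, `organelle_seq`, `numt_table`,
#'   per-read `labels`) and `files` (paths written, or `NULL`).
#' @export
simulate_dataset <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(spec$seed)

  nuclear <- random_dna(spec$nuclear_length)
  organelle <- random_dna(spec$organelle_length)

  numt_table <- data.frame(nuclear_start = integer(), nuclear_end = integer(),
                           organelle_start = integer(),
                           organelle_end = integer())
  if (spec$numt_count > 0) {
    for (j in seq_len(spec$numt_count)) {
      src <- sample.int(spec$organelle_length - spec$numt_length + 1L, 1L)
      dst <- sample.int(spec$nuclear_length - spec$numt_length + 1L, 1L)
      substr(nuclear, dst, dst + spec$numt_length - 1L) <-
        substr(organelle, src, src + spec$numt_length - 1L)
      numt_table[j, ] <- c(dst, dst + spec$numt_length - 1L,
                           src, src + spec$numt_length - 1L)
    }
  }

  L <- spec$read_length
  n_nuc <- round(spec$nuclear_length * spec$nuclear_depth / (2 * L))
  n_org <- round(spec$organelle_length * spec$nuclear_depth *
                   spec$copy_ratio / (2 * L))

  draw_fragments <- function(n, genome, circular) {
    glen <- nchar(genome)
    ins <- pmin(glen, pmax(L, round(stats::rnorm(n, spec$insert_mean,
                                                 spec$insert_sd))))
    if (circular) {
      start <- sample.int(glen, n, replace = TRUE)
      frag <- substring(paste0(genome, genome), start, start + ins - 1L)
    } else {
      start <- floor(stats::runif(n) * (glen - ins + 1)) + 1L
      frag <- substring(genome, start, start + ins - 1L)
    }
    list(start = start, ins = ins, frag = frag)
  }

  fn <- draw_fragments(n_nuc, nuclear, circular = FALSE)
  fo <- draw_fragments(n_org, organelle, circular = TRUE)

  overlaps_numt <- function(start, end) {
    if (nrow(numt_table) == 0L) return(rep(FALSE, length(start)))
    hit <- rep(FALSE, length(start))
    for (j in seq_len(nrow(numt_table)))
      hit <- hit | (start <= numt_table$nuclear_end[j] &
                      end >= numt_table$nuclear_start[j])
    hit
  }
  nuc_label <- ifelse(overlaps_numt(fn$start, fn$start + fn$ins - 1L),
                      "numt", "nuclear")

  frag <- c(fn$frag, fo$frag)
  ins <- c(fn$ins, fo$ins)
  start <- c(fn$start, fo$start)
  label <- c(nuc_label, rep("organelle", n_org))
  n <- length(frag)

  r1 <- add_errors(substr(frag, 1L, L), spec$error_rate)
  r2 <- add_errors(revcomp(substring(frag, ins - L + 1L, ins)),
                   spec$error_rate)

  ids <- sprintf("sim_%06d", seq_len(n))
  reads <- read_set(c(rbind(paste0(ids, "/1"), paste0(ids, "/2"))),
                    c(rbind(r1, r2)),
                    mate = rep(c(1L, 2L), n),
                    pair_id = rep(seq_len(n), each = 2L))
  labels <- data.frame(read_id = ids, origin = label, start = start,
                       end = start + ins - 1L, stringsAsFactors = FALSE)

  truth <- structure(list(nuclear_seq = nuclear, organelle_seq = organelle,
                          numt_table = numt_table, labels = labels,
                          spec = spec),
                     class = "synthetic_truth")

  files <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    f1 <- file.path(out_dir, "reads_R1.fastq.gz")
    f2 <- file.path(out_dir, "reads_R2.fastq.gz")
    write_fastq(reads, f1, f2)
    ft <- file.path(out_dir, "truth.fasta")
    write_fasta(contig_set(c("nuclear", "organelle"),
                           c(nuclear, organelle), source = "built_in"), ft)
    fl <- file.path(out_dir, "truth_labels.tsv")
    utils::write.table(labels, fl, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(r1 = f1, r2 = f2, truth_fasta = ft, labels = fl)
  }
  list(reads = reads, truth = truth, files = files)
}

#' Score a candidate against the simulated organelle truth
#'
#' Locates the candidate on the doubled organelle sequence (handling
#' rotation and strand), then scores identity and coverage. An exact
#' substring hit gives 100% identity directly; otherwise 200 bp chunks of
#' the candidate anchor a majority rotation offset and the candidate is
#' compared base-by-base against the rotated reference. Substitution-only
#' scoring -- adequate because both the simulator and the built-in
#' assembler are indel-free.
#'
#' @param candidate one-row [contig_set()] or DNA string (empty gives
#'   zeros).
#' @param truth a `synthetic_truth` from [simulate_dataset()].
#' @return list with `identity` and `coverage`, both percentages of the
#'   organelle genome.
#' @export
score_recovery <- function(candidate, truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  seq <- if (inherits(candidate, "contig_set")) {
    if (nrow(candidate) == 0L) "" else candidate$bases[1]
  } else as.character(candidate)
  nc <- nchar(seq)
  if (is.na(nc) || nc == 0L) return(list(identity = 0, coverage = 0))
  org <- truth$organelle_seq
  lo <- nchar(org)
  doubled <- paste0(org, org)
  for (s in c(seq, revcomp(seq))) {
    if (nc <= 2L * lo && regexpr(s, doubled, fixed = TRUE) > 0)
      return(list(identity = 100, coverage = 100 * min(nc, lo) / lo))
  }
  tripled <- paste0(doubled, org)
  best <- list(identity = 0, coverage = 0)
  for (s in c(seq, revcomp(seq))) {
    starts <- seq(1L, max(1L, nc - 200L + 1L), by = 200L)
    offs <- integer()
    for (st in starts) {
      chunk <- substr(s, st, min(nc, st + 199L))
      if (nchar(chunk) < 50L) next
      p <- regexpr(chunk, doubled, fixed = TRUE)
      if (p > 0) offs <- c(offs, (p - st) %% lo)
    }
    if (length(offs) == 0L) next
    off <- as.integer(names(sort(table(offs), decreasing = TRUE))[1])
    ref_rot <- substr(tripled, off + 1L, off + nc)
    cmp_len <- min(nc, nchar(ref_rot))
    a <- charToRaw(substr(s, 1L, cmp_len))
    b <- charToRaw(substr(ref_rot, 1L, cmp_len))
    ident <- 100 * sum(a == b) / cmp_len
    cov <- 100 * min(cmp_len, lo) / lo
    if (ident > best$identity ||
        (ident == best$identity && cov > best$coverage))
      best <- list(identity = ident, coverage = cov)
  }
  best
}
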
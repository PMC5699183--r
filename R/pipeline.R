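#' Run the full organelle extraction pipeline
#'
#' Orchestrates the five stages end to end: (1) trim reads and assemble the
#' whole pool, (2) map reads back to the longest contig -- assumed nuclear
#' -- and derive the nuclear depth (ND) threshold from its depth profile,
#' (3) count k-mers (default k = 31) in a Count-Min Sketch and keep only
#' reads with at least one k-mer above the threshold, (4) reassemble the
#' retained pool and pick the candidate contig, (5) circularity-trim and
#' depth-validate it. Supplying `anchor` skips the initial assembly;
#' supplying `nd_threshold` skips both the initial assembly and the
#' mapping (the report records them as skipped) -- this is also the escape
#' hatch for organisms whose copy number defies the automatic estimate.
#'
#' @param reads a [read_set()], or path to a FASTQ file (`reads2` then
#'   optionally names the mate file).
#' @param out_dir output directory; intermediate and final files are kept
#'   there (`candidate.fasta`, `circularity.json`, `depth_comparison.tsv`,
#'   `binned_reads.fastq.gz`, `report.json`).
#' @param reads2 optional mate FASTQ path when `reads` is a path.
#' @param anchor optional nuclear anchor: a [contig_set()], DNA string or
#'   FASTA path.
#' @param nd_threshold optional manual ND threshold (read-depth units).
#' @param factor ND threshold multiplier (default 5).
#' @param k k-mer size for counting/binning (default 31).
#' @param sketch_width,sketch_depth Count-Min Sketch dimensions.
#' @param trim_cfg a [trim_config()].
#' @param assembly_cfg an [assembly_config()] used for both assemblies; the
#'   second assembly raises `min_kmer_count` to at least a quarter of the
#'   k-mer threshold to suppress recurrent error k-mers at organelle depth
#'   (see the methods vignette).
#' @param depth_conversion convert the ND threshold into k-mer-count units
#'   before binning (default TRUE, the unit-consistent reading); FALSE
#'   compares raw k-mer counts against the unconverted threshold. Both are
#'   conservative: conversion lowers the threshold, raising recall.
#' @param keep_pairs retain full pairs when either mate qualifies.
#' @param mode candidate selection mode, `"longest"` or `"annotated"`.
#' @param hook_spec annotation hook template for `annotated` mode (see
#'   [annotation_hook()]).
#' @param support_ratio depth ratio needed for a `"supported"` verdict.
#' @param seed seed for the sketch hash functions.
#' @return a `pipeline_report` list: per-stage parameters/counts/status,
#'   the `candidate` contig, `circularity` and `validation` results, and
#'   the output file paths. Also written as `report.json`.
#' @export
run_pipeline <- function(reads, out_dir, reads2 = NULL, anchor = NULL,
                         nd_threshold = NULL, factor = 5, k = 31L,
                         sketch_width = 2^22, sketch_depth = 3L,
                         trim_cfg = trim_config(),
                         assembly_cfg = assembly_config(),
                         depth_conversion = TRUE, keep_pairs = TRUE,
                         mode = "longest", hook_spec = NULL,
                         support_ratio = 5, seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(parameters = list(factor = factor, k = k,
                                   sketch_width = sketch_width,
                                   sketch_depth = sketch_depth,
                                   depth_conversion = depth_conversion,
                                   keep_pairs = keep_pairs, mode = mode,
                                   support_ratio = support_ratio,
                                   seed = seed),
                 stages = list())
  note <- function(stage, ...) {
    report$stages[[stage]] <<- list(...)
    write_report(report, out_dir)
  }
  fail <- function(stage, msg) stop("pipeline stage '", stage, "': ", msg,
                                    call. = FALSE)

  # -- stage 0: input -------------------------------------------------------
  if (is.character(reads) && length(reads) == 1L && file.exists(reads))
    reads <- read_fastq(reads, reads2)
  reads <- as_read_set(reads)
  if (nrow(reads) == 0L) fail("input", "no reads supplied")

  # -- stage 1: preprocess --------------------------------------------------
  pp <- preprocess(reads, trim_cfg)
  note("preprocess", status = "run", counts = pp$counts,
       min_length = trim_cfg$min_length)
  if (nrow(pp$reads) == 0L)
    fail("preprocess", "no reads survived trimming")

  # -- stage 2: k-mer sketch ------------------------------------------------
  L <- effective_read_length(pp$reads)
  if (k > L) fail("sketch", paste0("k = ", k, " exceeds read length ", L))
  sketch <- kmer_sketch(pp$reads, k = k, width = sketch_width,
                        depth = sketch_depth, seed = seed)
  note("sketch", status = "run", k = k, width = sketch$width,
       depth = sketch$depth, seed = seed, read_length = L,
       n_inserted = sketch$n_inserted)

  # -- stage 3: anchor (initial assembly) -----------------------------------
  nd <- NULL
  anchor_contig <- NULL
  if (!is.null(nd_threshold)) {
    nd <- nd_threshold_manual(nd_threshold, factor)
    note("initial_assembly", status = "skipped",
         reason = "nd_threshold supplied")
    note("depth_profile", status = "skipped",
         reason = "nd_threshold supplied")
  }
  if (is.null(anchor) && is.null(nd)) {
    initial <- assemble(pp$reads, assembly_cfg)
    if (nrow(initial) == 0L)
      fail("initial_assembly",
           "no contigs assembled; supply --anchor or --nd-threshold")
    depths <- contig_kmer_depth(sketch, initial, L)
    anchor_contig <- select_anchor(initial, depths)
    anchor_contig$contig_id <- "nuclear_anchor"
    write_fasta(initial, file.path(out_dir, "initial_assembly.fasta"))
    note("initial_assembly", status = "run", n_contigs = nrow(initial),
         anchor_length = nchar(anchor_contig$bases),
         anchor_est_depth = depths[match(anchor_contig$bases,
                                         initial$bases)])
  } else if (!is.null(anchor)) {
    anchor_contig <- if (inherits(anchor, "contig_set")) {
      anchor[1, , drop = FALSE]
    } else if (is.character(anchor) && file.exists(anchor)) {
      read_fasta(anchor)[1, , drop = FALSE]
    } else contig_set("nuclear_anchor", as.character(anchor))
    note("initial_assembly", status = "skipped", reason = "anchor supplied")
  }

  # -- stage 4: depth profile + ND threshold + binning ----------------------
  if (is.null(nd)) {
    profile <- depth_profile(pp$reads, anchor_contig)
    nd <- tryCatch(nd_threshold(profile, factor),
                   error = function(e) fail("depth_profile",
                                            conditionMessage(e)))
    note("depth_profile", status = "run",
         anchor_positions = length(profile$depths),
         trimmed_mean = nd$trimmed_mean, n = nd$n, value = nd$value)
  }
  nd <- kmer_threshold_from_nd(nd, L, k)
  threshold <- if (depth_conversion) nd$kmer_threshold else nd$value
  binned <- bin_reads(pp$reads, sketch, threshold, keep_pairs)
  note("binning", status = "run", threshold = threshold,
       nd_value = nd$value, counts = binned$counts)
  if (nrow(binned$reads) == 0L)
    fail("binning", paste0("no reads above threshold ",
                           format(threshold),
                           "; consider a lower --nd-threshold"))
  write_fastq(binned$reads, file.path(out_dir, "binned_reads.fastq.gz"))

  # -- stage 5: second assembly + candidate ---------------------------------
  cfg2 <- assembly_cfg
  cfg2$min_kmer_count <- max(cfg2$min_kmer_count,
                             as.integer(ceiling(threshold / 4)))
  contigs <- assemble(binned$reads, cfg2)
  if (nrow(contigs) == 0L)
    fail("assembly",
         "binned reads assembled into no contigs; consider a lower threshold")
  write_fasta(contigs, file.path(out_dir, "assembly.fasta"))
  note("assembly", status = "run", n_contigs = nrow(contigs),
       min_kmer_count = cfg2$min_kmer_count,
       k_list = cfg2$k_list)

  annotations <- NULL
  if (identical(mode, "annotated"))
    annotations <- annotation_hook(contigs, hook_spec)
  candidate <- select_candidate(contigs, mode, annotations)
  candidate$contig_id <- "organelle_candidate"

  # -- stage 6: circularity + validation ------------------------------------
  circ <- check_circularity(candidate)
  cand_final <- circ$trimmed
  write_fasta(cand_final, file.path(out_dir, "candidate.fasta"))
  jsonlite::write_json(list(is_circular = circ$is_circular,
                            overlap_length = circ$overlap_length,
                            length = nchar(cand_final$bases)),
                       file.path(out_dir, "circularity.json"),
                       auto_unbox = TRUE)
  note("circularity", status = "run", is_circular = circ$is_circular,
       overlap_length = circ$overlap_length,
       candidate_length = nchar(cand_final$bases))

  if (is.null(anchor_contig)) {
    cand_prof <- depth_profile(pp$reads, cand_final)
    validation <- structure(
      list(candidate_mean_depth = mean(cand_prof$depths),
           nuclear_mean_depth = NA_real_, depth_ratio = NA_real_,
           candidate_profile = cand_prof,
           nuclear_profile = structure(list(contig_id = "none",
                                            depths = integer()),
                                       class = "depth_profile"),
           verdict = "unsupported", support_ratio = support_ratio,
           diagnostic = paste("no nuclear anchor available",
                              "(manual nd_threshold run);",
                              "depth comparison skipped")),
      class = "validation_report")
    cand_final$mean_depth <- validation$candidate_mean_depth
    note("validation", status = "partial",
         candidate_mean_depth = validation$candidate_mean_depth,
         reason = validation$diagnostic)
  } else {
    validation <- validate_candidate(pp$reads, cand_final, anchor_contig,
                                     support_ratio)
    cand_final$mean_depth <- validation$candidate_mean_depth
    write_depth_comparison(validation,
                           file.path(out_dir, "depth_comparison.tsv"))
    note("validation", status = "run",
         candidate_mean_depth = validation$candidate_mean_depth,
         nuclear_mean_depth = validation$nuclear_mean_depth,
         depth_ratio = validation$depth_ratio, verdict = validation$verdict)
  }

  report$candidate <- cand_final
  report$circularity <- circ
  report$validation <- validation
  report$files <- file.path(out_dir,
                            c("candidate.fasta", "circularity.json",
                              "depth_comparison.tsv", "report.json"))
  class(report) <- "pipeline_report"
  write_report(report, out_dir)
  invisible(report)
}

write_report <- function(report, out_dir) {
  serialisable <- list(parameters = report$parameters,
                       stages = report$stages)
  if (!is.null(report$validation))
    serialisable$summary <- list(
      candidate_length = nchar(report$candidate$bases),
      is_circular = report$circularity$is_circular,
      depth_ratio = report$validation$depth_ratio,
      verdict = report$validation$verdict)
  jsonlite::write_json(serialisable, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  invisible(NULL)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline_report\n")
  for (s in names(x$stages))
    cat(sprintf("  %-18s %s\n", s, x$stages[[s]]$status))
  if (!is.null(x$candidate)) {
    cat(sprintf("  candidate: %d bp, %scircular, depth ratio %s (%s)\n",
                nchar(x$candidate$bases),
                if (x$circularity$is_circular) "" else "not ",
                ifelse(is.na(x$validation$depth_ratio), "NA",
                       sprintf("%.1f", x$validation$depth_ratio)),
                x$validation$verdict))
  }
  invisible(x)
}
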
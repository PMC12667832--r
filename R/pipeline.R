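#' Read a FASTQ/FASTA file of long reads
#'
#' FASTQ input keeps per-base qualities ([Biostrings] quality-scaled set);
#' FASTA input gets uniform quality 40 and downstream base-quality filters
#' become inert (a message is emitted). With `validate = TRUE` the FASTQ
#' structure is checked record by record and the first offending record is
#' reported by number.
#'
#' @param path Input file.
#' @param format `"fastq"` or `"fasta"` (guessed from the extension by
#'   default).
#' @param validate Check FASTQ structure first.
#' @return A [Biostrings::QualityScaledDNAStringSet].
#' @export
readReads <- function(path, format = NULL, validate = FALSE) {
  if (!file.exists(path)) stop("input file not found: ", path)
  if (is.null(format))
    format <- if (grepl("\\.(fa|fasta)(\\.gz)?$", path)) "fasta" else "fastq"
  if (format == "fasta") {
    s <- Biostrings::readDNAStringSet(path)
    message("FASTA input: no base qualities; quality filters are inert")
    return(Biostrings::QualityScaledDNAStringSet(
      s, Biostrings::PhredQuality(vapply(nchar(as.character(s)), function(l)
        rawToChar(as.raw(rep(40L + 33L, l))), ""))))
  }
  if (validate) .validateFastq(path)
  Biostrings::readQualityScaledDNAStringSet(path)
}

.validateFastq <- function(path) {
  lines <- readLines(path)
  nl <- length(lines)
  if (nl %% 4L != 0L)
    stop(sprintf("malformed FASTQ: truncated record %d (line count %d not a multiple of 4)",
                 nl %/% 4L + 1L, nl))
  for (r in seq_len(nl %/% 4L)) {
    i <- (r - 1L) * 4L
    if (!startsWith(lines[i + 1L], "@") || !startsWith(lines[i + 3L], "+") ||
        nchar(lines[i + 2L]) != nchar(lines[i + 4L]) ||
        nchar(lines[i + 2L]) == 0L)
      stop(sprintf("malformed FASTQ: record %d", r))
  }
  invisible(TRUE)
}

#' Write reads as FASTQ
#'
#' @param reads A [Biostrings::QualityScaledDNAStringSet].
#' @param path Output file (plain text; `.gz` for gzip).
#' @return Invisibly `path`.
#' @export
writeReads <- function(reads, path) {
  Biostrings::writeQualityScaledXStringSet(reads, path,
                                           compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Default pipeline configuration
#'
#' All tunables of the simulation, overlap, phasing, correction and T2T
#' stages, with their defaults. `runPipeline()` merges user overrides into
#' this list and rejects unknown keys.
#'
#' @return Named list of parameters.
#' @export
pcConfig <- function() {
  list(
    # simulation
    ref_length = 100000L, ploidy = 2L, het_rate = 0.001,
    depth = 30, length_mean = 9000, length_sd = 2500,
    sub_rate = 0.005, ins_rate = 0.0025, del_rate = 0.0025,
    recurrent_sites = 50L, rho = 0.5, hp_multiplier = 2, hp_min_run = 4L,
    # overlap
    k = 15L, window = 10L, min_overlap_len = 1000L, max_div = 0.15,
    band = 48L, max_indel = 10L, truth_overlaps = FALSE,
    # phasing
    min_alt = 2L, q_threshold = 10L, run_len_threshold = 4L, min_shared = 8L,
    min_shared1 = 2L, max_conflict = 1L,
    iso_support_threshold = 28L, grouped_support_threshold = 2L,
    # correction
    min_depth = 3L, min_ratio = 0.5, rounds = 2L,
    # telomere / t2t
    telomere_motif = "TTAGGG", telomere_window = 1000L,
    telomere_density = 0.4, max_tip_len = 50000L, min_cov = 10,
    min_anchor = 10000L, max_gap = 1000000L,
    # run
    seed = 1L, threads = 1L)
}

.mergeConfig <- function(overrides) {
  cfg <- pcConfig()
  if (length(overrides)) {
    unknown <- setdiff(names(overrides), names(cfg))
    if (length(unknown))
      stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
    cfg[names(overrides)] <- overrides
  }
  cfg
}

#' Run the simulate / overlap / correct / evaluate pipeline
#'
#' Executes the full pipeline into an artifact directory: simulation (unless
#' `input` is given), correction (overlap, pileup, filters, LCG phasing,
#' classification, support selection, consensus), truth-based evaluation
#' (when simulating) and a manifest. Identical configuration and seed yield
#' byte-identical artifacts and manifest hashes.
#'
#' Artifacts: `config.yaml` (effective configuration), `reads.fastq` (input,
#' when simulated), `truth.tsv` + `recurrent.json` (truth ledger),
#' `corrected.fastq`, `report.tsv` (per read), `sites.tsv` (per candidate
#' site), `overlaps.paf`, `evaluation.tsv`, `manifest.json` (file names,
#' md5 hashes, stage counts).
#'
#' @param config Named list of overrides of [pcConfig()], or a path to a
#'   YAML file of the same shape.
#' @param outDir Output directory (created; must be writable).
#' @param input Optional FASTQ path: correct these reads instead of
#'   simulating.
#' @return Invisibly, the manifest as a list.
#' @export
runPipeline <- function(config = list(), outDir, input = NULL) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  cfg <- .mergeConfig(config)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outDir)) stop("cannot create output directory: ", outDir)
  yaml::write_yaml(cfg, file.path(outDir, "config.yaml"))
  artifacts <- c("config.yaml")
  counts <- list()

  truth <- NULL; haps <- NULL
  if (is.null(input)) {
    set.seed(cfg$seed)
    haps <- simulateHaplotypes(cfg$ref_length, cfg$ploidy, cfg$het_rate)
    sim <- simulateReads(haps, depth = cfg$depth, lengthMean = cfg$length_mean,
                         lengthSd = cfg$length_sd,
                         model = errorModel(cfg$sub_rate, cfg$ins_rate,
                                            cfg$del_rate, cfg$recurrent_sites,
                                            cfg$rho, cfg$hp_multiplier,
                                            cfg$hp_min_run))
    reads <- simReads(sim)
    truth <- simTruth(sim)
    writeReads(reads, file.path(outDir, "reads.fastq"))
    write.table(truth@reads, file.path(outDir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(sites = truth@recurrentSites,
           reads = lapply(truth@recurrentReads, function(i)
             truth@reads$read_id[i])),
      file.path(outDir, "recurrent.json"), auto_unbox = FALSE, digits = NA)
    artifacts <- c(artifacts, "reads.fastq", "truth.tsv", "recurrent.json")
    counts$reads <- length(reads)
  } else {
    reads <- readReads(input, validate = TRUE)
    counts$reads <- length(reads)
  }

  res <- correctReads(reads, rounds = cfg$rounds, threads = cfg$threads,
                      truth = if (cfg$truth_overlaps) truth else NULL,
                      k = cfg$k, window = cfg$window,
                      minOverlapLen = cfg$min_overlap_len,
                      maxDiv = cfg$max_div, band = cfg$band,
                      maxIndel = cfg$max_indel, minAlt = cfg$min_alt,
                      qThreshold = cfg$q_threshold,
                      runLen = cfg$run_len_threshold,
                      minShared = cfg$min_shared,
                      minShared1 = cfg$min_shared1,
                      maxConflict = cfg$max_conflict,
                      isoSupportThreshold = cfg$iso_support_threshold,
                      groupedSupportThreshold = cfg$grouped_support_threshold,
                      minDepth = cfg$min_depth, minRatio = cfg$min_ratio)
  writeReads(res$reads, file.path(outDir, "corrected.fastq"))
  write.table(res$report, file.path(outDir, "report.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(res$sites, file.path(outDir, "sites.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  ovl <- findReadOverlaps(res$reads, k = cfg$k, window = cfg$window,
                          minOverlapLen = cfg$min_overlap_len,
                          maxDiv = cfg$max_div, band = cfg$band,
                          maxIndel = cfg$max_indel)
  writePAF(ovl, file.path(outDir, "overlaps.paf"))
  artifacts <- c(artifacts, "corrected.fastq", "report.tsv", "sites.tsv",
                 "overlaps.paf")
  counts$sites <- nrow(res$sites)
  counts$informative <- sum(res$sites$class == "informative")
  counts$errors <- sum(res$sites$class == "error")
  counts$masked <- sum(res$sites$class == "masked")
  counts$edits <- sum(res$report$edits)
  message(sprintf("correct: %d reads, %d sites (%d informative / %d error / %d masked), %d edits",
                  counts$reads, counts$sites, counts$informative,
                  counts$errors, counts$masked, counts$edits))

  if (!is.null(truth)) {
    ev <- evaluateCorrection(res$reads, truth, haps,
                             hpRun = cfg$run_len_threshold)
    write.table(ev, file.path(outDir, "evaluation.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    artifacts <- c(artifacts, "evaluation.tsv")
    counts$zero_error_fraction <- mean(ev$zero_error)
    message(sprintf("evaluate: %.1f%% of reads error-free outside homopolymers",
                    100 * mean(ev$zero_error)))
  }

  manifest <- list(
    artifacts = lapply(setNames(artifacts, artifacts), function(f)
      list(md5 = unname(tools::md5sum(file.path(outDir, f))))),
    counts = counts)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
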
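#' Error model for read simulation
#'
#' Parameters of the sequencing-error process used by [simulateReads()].
#' Random substitution/insertion/deletion errors are applied per base; inside
#' homopolymer runs of at least `hpMinRun` bases all three rates are
#' multiplied by `hpMultiplier`, mimicking the elevated homopolymer error
#' rate of nanopore reads. On top of the random errors, `recurrentSites`
#' reference positions receive a fixed wrong allele that every covering read
#' reproduces with probability `rho` — the position-recurrent error structure
#' that breaks the random-error assumption of HiFi-style correction.
#'
#' Base qualities: correct bases get Phred `qCorrect`; erroneous bases get
#' Phred `qError` with probability `qErrorProb` (else `qCorrect`), so the
#' base-quality filter is exercised both ways.
#'
#' @param subRate,insRate,delRate Per-base error probabilities.
#' @param recurrentSites Number of recurrent error sites to plant.
#' @param rho Probability that a read covering a recurrent site carries the
#'   planted allele.
#' @param hpMultiplier Error-rate multiplier inside homopolymer runs.
#' @param hpMinRun Minimum run length counting as a homopolymer.
#' @param qCorrect,qError,qErrorProb Quality model (see above).
#' @return A named list of validated parameters with class
#'   `"phasecor_error_model"`.
#' @export
errorModel <- function(subRate = 0.005, insRate = 0.0025, delRate = 0.0025,
                       recurrentSites = 50L, rho = 0.5,
                       hpMultiplier = 2, hpMinRun = 4L,
                       qCorrect = 25L, qError = 8L, qErrorProb = 0.5) {
  rates <- c(subRate, insRate, delRate)
  if (any(rates < 0) || any(rates > 1))
    stop("error rates must lie in [0, 1]")
  if (rho <= 0 || rho > 1) stop("rho must lie in (0, 1]")
  if (hpMultiplier < 1) stop("hpMultiplier must be >= 1")
  if (recurrentSites < 0) stop("recurrentSites must be >= 0")
  structure(list(subRate = subRate, insRate = insRate, delRate = delRate,
                 recurrentSites = as.integer(recurrentSites), rho = rho,
                 hpMultiplier = hpMultiplier, hpMinRun = as.integer(hpMinRun),
                 qCorrect = as.integer(qCorrect), qError = as.integer(qError),
                 qErrorProb = qErrorProb),
            class = "phasecor_error_model")
}

#' Simulate a haplotype set
#'
#' Draws a random reference of length `refLength` and derives `ploidy`
#' haplotypes by planting independent heterozygous substitutions at rate
#' `hetRate` per base (positions and alternative alleles drawn uniformly).
#' Substitution-only variants keep all haplotypes in the reference coordinate
#' system, which makes the truth ledger exact.
#'
#' @param refLength Reference length in bp (>= 1000).
#' @param ploidy Number of haplotypes (>= 1).
#' @param hetRate Per-base heterozygosity in `[0, 0.05]`.
#' @param seed Optional integer seed (`set.seed`).
#' @return A [HaplotypeSet].
#' @examples
#' haps <- simulateHaplotypes(2000, ploidy = 2, hetRate = 0.01, seed = 1)
#' nrow(variants(haps))
#' @export
simulateHaplotypes <- function(refLength, ploidy = 2L, hetRate = 0.001,
                               seed = NULL) {
  if (length(refLength) != 1L || refLength < 1000)
    stop("refLength must be a single value >= 1000")
  if (ploidy < 1L) stop("ploidy must be a positive integer")
  if (hetRate < 0 || hetRate > 0.05) stop("hetRate must lie in [0, 0.05]")
  if (!is.null(seed)) set.seed(seed)
  bases <- c("A", "C", "G", "T")
  refv <- sample(bases, refLength, replace = TRUE)
  ref <- paste(refv, collapse = "")
  haps <- character(ploidy)
  vars <- vector("list", ploidy)
  for (h in seq_len(ploidy)) {
    nv <- rbinom(1L, as.integer(refLength), hetRate)
    if (nv > 0L) {
      pos <- sort(sample.int(refLength, nv)) - 1L
      refA <- refv[pos + 1L]
      alt <- vapply(refA, function(b) sample(setdiff(bases, b), 1L), "")
      hv <- refv
      hv[pos + 1L] <- alt
      haps[h] <- paste(hv, collapse = "")
      vars[[h]] <- data.frame(hap = h, pos = pos, ref = refA, alt = alt,
                              row.names = NULL, stringsAsFactors = FALSE)
    } else {
      haps[h] <- ref
      vars[[h]] <- data.frame(hap = integer(), pos = integer(),
                              ref = character(), alt = character(),
                              stringsAsFactors = FALSE)
    }
  }
  new("HaplotypeSet", reference = ref,
      haplotypes = Biostrings::DNAStringSet(haps),
      variants = do.call(rbind, vars), ploidy = as.integer(ploidy))
}

#' Positions where haplotypes differ (true heterozygous sites)
#'
#' @param haps A [HaplotypeSet].
#' @return Sorted integer vector of 0-based reference positions at which not
#'   all haplotypes carry the same base.
#' @export
hetPositions <- function(haps) {
  stopifnot(is(haps, "HaplotypeSet"))
  v <- haps@variants
  if (!nrow(v)) return(integer())
  het <- vapply(split(v, v$pos), function(d) {
    # a position is heterozygous unless every haplotype carries the same alt
    nrow(d) < haps@ploidy || length(unique(d$alt)) > 1L
  }, logical(1))
  sort(as.integer(names(het)[het]))
}

#' Simulate noisy long reads with recurrent errors
#'
#' Reads are drawn uniformly from the haplotypes and positions, with
#' truncated-normal lengths (floor 500 bp) and a 50% chance of being emitted
#' reverse-complemented. Planted recurrent sites carry the identical wrong
#' allele in every affected read (probability `rho` per covering read);
#' random errors follow the [errorModel()]. The returned truth ledger is
#' complete: per-read origin, per-read error positions, an exact base-level
#' origin map, and the recurrent-site catalogue with affected reads.
#'
#' Recurrent sites are placed at least 50 bp away from any true variant so
#' that truth classification is unambiguous.
#'
#' @param haps A [HaplotypeSet].
#' @param depth Total expected coverage of the reference (across all
#'   haplotypes; >= 1).
#' @param lengthMean,lengthSd Read length distribution (truncated normal,
#'   floor 500 bp).
#' @param model An [errorModel()].
#' @param seed Optional integer seed.
#' @return A [SimulatedReads] object.
#' @export
simulateReads <- function(haps, depth = 30, lengthMean = 9000, lengthSd = 2500,
                          model = errorModel(), seed = NULL) {
  stopifnot(is(haps, "HaplotypeSet"))
  if (depth < 1) stop("depth must be >= 1")
  hapLen <- nchar(haps@reference)
  if (lengthMean > hapLen) stop("lengthMean exceeds haplotype length")
  if (!is.null(seed)) set.seed(seed)

  total <- depth * hapLen
  n_guess <- ceiling(total / max(500, lengthMean)) * 2L + 20L
  lens <- pmin(hapLen, pmax(500L, as.integer(round(rnorm(n_guess, lengthMean, lengthSd)))))
  n <- which(cumsum(as.numeric(lens)) >= total)[1L]
  if (is.na(n)) n <- n_guess
  lens <- lens[seq_len(n)]
  hap_idx <- sample.int(haps@ploidy, n, replace = TRUE)
  starts <- as.integer(floor(runif(n, 0, hapLen - lens + 1)))
  strands <- rbinom(n, 1L, 0.5)

  # recurrent sites: on the shared (non-variant) backbone, >= 50 bp from any
  # true variant
  rec_pos <- integer()
  rec_alt <- character()
  if (model$recurrentSites > 0L) {
    banned <- unique(unlist(lapply(haps@variants$pos, function(p)
      seq.int(max(0L, p - 50L), min(hapLen - 1L, p + 50L)))))
    avail <- setdiff(seq_len(hapLen) - 1L, banned)
    if (length(avail) < model$recurrentSites)
      stop("not enough variant-free positions for the requested recurrent sites")
    rec_pos <- sort(sample(avail, model$recurrentSites))
    refb <- substring(haps@reference, rec_pos + 1L, rec_pos + 1L)
    bases <- c("A", "C", "G", "T")
    rec_alt <- vapply(refb, function(b) sample(setdiff(bases, b), 1L), "")
  }

  sim <- .pc_sim_reads(as.character(haps@haplotypes), hap_idx, starts, lens,
                       strands, model$subRate, model$insRate, model$delRate,
                       model$hpMultiplier, model$hpMinRun,
                       model$qCorrect, model$qError, model$qErrorProb,
                       rec_pos, rec_alt, model$rho)

  ids <- sprintf("read%05d", seq_len(n))
  quals <- vapply(sim$qual, function(q) rawToChar(as.raw(q + 33L)), "")
  reads <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(setNames(sim$seq, ids)),
    Biostrings::PhredQuality(quals))

  origin_map <- .originMaps(sim, lens, strands, starts)

  truth <- new("SimTruth",
    reads = data.frame(read_id = ids, hap = hap_idx, start = starts,
                       end = starts + lens, strand = ifelse(strands == 1L, "-", "+"),
                       stringsAsFactors = FALSE),
    recurrentSites = if (length(rec_pos))
      data.frame(pos = rec_pos,
                 ref = substring(haps@reference, rec_pos + 1L, rec_pos + 1L),
                 alt = rec_alt, row.names = NULL, stringsAsFactors = FALSE)
      else data.frame(pos = integer(), ref = character(), alt = character(),
                      stringsAsFactors = FALSE),
    recurrentReads = sim$rec_reads,
    randomErrors = lapply(seq_len(n), function(i)
      data.frame(pos = sim$err_pos[[i]], kind = sim$err_kind[[i]],
                 stringsAsFactors = FALSE)),
    originMap = origin_map)

  new("SimulatedReads", reads = reads, truth = truth)
}

# Exact per-base origin offsets, reconstructed from the emitted error records.
# Events are recorded in pre-reverse-complement (construction) order except
# that positions of 'S'/'R'/'I'/'D' were flipped for minus reads; rebuild in
# construction order first, then flip.
.originMaps <- function(sim, lens, strands, starts) {
  lapply(seq_along(lens), function(i) {
    outlen <- nchar(sim$seq[[i]])
    pos <- sim$err_pos[[i]]
    kind <- sim$err_kind[[i]]
    if (strands[i] == 1L) pos <- outlen - 1L - pos    # back to construction frame
    o <- integer(outlen)
    ins_at <- sort(pos[kind == "I"])
    del_at <- sort(pos[kind == "D"])                  # construction-frame out pos
    # walk: origin offset advanced per consumed origin base
    map <- integer(outlen)
    oi <- 0L; di <- 1L
    ii <- 1L
    for (p in seq_len(outlen) - 1L) {
      while (di <= length(del_at) && del_at[di] == p && (di <= length(del_at))) {
        # deletions recorded at the position of the *next* emitted base; each
        # one consumed an origin base before this output base
        oi <- oi + 1L
        di <- di + 1L
      }
      if (ii <= length(ins_at) && ins_at[ii] == p) {
        map[p + 1L] <- NA_integer_
        ii <- ii + 1L
      } else {
        map[p + 1L] <- oi
        oi <- oi + 1L
      }
    }
    if (strands[i] == 1L) map <- rev(map)
    map + starts[i]
  })
}

#' Evaluate corrected reads against the simulation truth
#'
#' Aligns each corrected read to the substring of its origin haplotype and
#' counts residual mismatches and indel bases. With `maskHomopolymers`,
#' residual counting excludes positions inside (or immediately adjacent to)
#' homopolymer runs of at least `hpRun` bases on the origin, where nanopore
#' errors concentrate and correction is not expected to resolve them.
#'
#' @param reads Corrected reads (a [Biostrings::QualityScaledDNAStringSet],
#'   `DNAStringSet`, or named character vector); names must exist in `truth`.
#' @param truth The [SimTruth] ledger.
#' @param haps The [HaplotypeSet] the reads were simulated from.
#' @param maskHomopolymers Logical: exclude homopolymer positions.
#' @param hpRun Minimum run length for masking.
#' @param band Alignment band width.
#' @return A `data.frame` with one row per read: `read_id`, `n_mismatch`,
#'   `n_indel`, `n_masked` (differences excluded by the homopolymer mask),
#'   `origin_len`, `residual_rate`, `zero_error`.
#' @export
evaluateCorrection <- function(reads, truth, haps, maskHomopolymers = TRUE,
                               hpRun = 4L, band = 100L) {
  stopifnot(is(truth, "SimTruth"), is(haps, "HaplotypeSet"))
  ids <- names(reads)
  seqs <- as.character(reads)
  if (is.null(ids)) stop("reads must be named")
  tr <- truth@reads
  missing <- setdiff(ids, tr$read_id)
  if (length(missing))
    stop("unknown read id(s): ", paste(head(missing, 3L), collapse = ", "))
  idx <- match(ids, tr$read_id)
  hapsq <- as.character(haps@haplotypes)
  res <- lapply(seq_along(ids), function(i) {
    r <- tr[idx[i], ]
    origin <- substring(hapsq[r$hap], r$start + 1L, r$end)
    s <- seqs[[i]]
    if (r$strand == "-") s <- .pc_revcomp(s)
    if (identical(s, origin))
      return(data.frame(read_id = ids[i], n_mismatch = 0L, n_indel = 0L,
                        n_masked = 0L, origin_len = nchar(origin),
                        stringsAsFactors = FALSE))
    aln <- .pc_align_pair(origin, s, band)
    d <- aln$diffs
    masked <- rep(FALSE, nrow(d))
    if (maskHomopolymers && nrow(d)) {
      hp <- .pc_hp_mask(origin, hpRun, TRUE)
      masked <- hp[pmin(nchar(origin), d$tpos + 1L)]
    }
    keep <- d[!masked, , drop = FALSE]
    data.frame(read_id = ids[i],
               n_mismatch = sum(keep$kind == "S"),
               n_indel = sum(keep$len[keep$kind != "S"]),
               n_masked = sum(d$len[masked]),
               origin_len = nchar(origin), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$residual_rate <- (out$n_mismatch + out$n_indel) / out$origin_len
  out$zero_error <- out$n_mismatch + out$n_indel == 0L
  out
}
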
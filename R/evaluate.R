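#' Compare site classifications against the simulation truth
#'
#' Maps every candidate site of the per-read site table (read coordinates)
#' back to reference coordinates through the exact origin map of the truth
#' ledger, labels it as planted recurrent error site, true heterozygous
#' site, or other (random-error coincidence), and summarises how the
#' classifier treated each group. Masked sites are excluded from the
#' summary rates: masking is a separate, deliberate filter, and a masked
#' site is neither selected against supports nor counted as informative.
#'
#' @param sites The per-site `data.frame` from [correctReads()] (`$sites`).
#' @param truth The [SimTruth] ledger.
#' @param haps The [HaplotypeSet].
#' @return A list with `sites` (the table with `gpos` and `truth` columns)
#'   and `summary`: recurrent/het site counts and the fraction classified
#'   error resp. informative, plus the HiFi-style baseline count of
#'   recurrent sites it would call informative.
#' @export
evaluateClassification <- function(sites, truth, haps) {
  stopifnot(is(truth, "SimTruth"), is(haps, "HaplotypeSet"))
  tr <- truth@reads
  idx <- match(sites$target_id, tr$read_id)
  if (anyNA(idx)) stop("site table references unknown read ids")
  gpos <- vapply(seq_len(nrow(sites)), function(i) {
    m <- truth@originMap[[idx[i]]]
    p <- sites$pos[i] + 1L
    if (p >= 1L && p <= length(m)) m[p] else NA_integer_
  }, integer(1))
  rec <- truth@recurrentSites$pos
  het <- hetPositions(haps)
  lab <- rep("other", nrow(sites))
  lab[gpos %in% rec] <- "recurrent"
  lab[gpos %in% het] <- "het"
  sites$gpos <- gpos
  sites$truth <- lab
  unmasked <- sites$mask == "none"
  r <- sites[lab == "recurrent" & unmasked, , drop = FALSE]
  h <- sites[lab == "het" & unmasked, , drop = FALSE]
  baseline_inf <- sum(r$n1 >= 2L)
  list(sites = sites,
       summary = list(
         recurrent_n = nrow(r),
         recurrent_error_frac = if (nrow(r)) mean(r$class == "error") else NA_real_,
         recurrent_informative = sum(r$class == "informative"),
         het_n = nrow(h),
         het_informative_frac = if (nrow(h)) mean(h$class == "informative") else NA_real_,
         baseline_recurrent_informative = baseline_inf))
}

#' Haplotype purity of selected supports
#'
#' For every target read covering at least `minHet` true heterozygous sites,
#' checks the haplotype of origin of each kept support. Reports both the raw
#' origin purity and the number of \emph{corrupting} supports: kept supports
#' from another haplotype whose shared origin interval with the target
#' contains a heterozygous site (supports whose shared interval is free of
#' het sites are sequence-identical to the target's haplotype there and
#' cannot corrupt it).
#'
#' @param supports Named list of kept support ids per target (from
#'   [correctReads()]).
#' @param truth The [SimTruth] ledger.
#' @param haps The [HaplotypeSet].
#' @param minHet Minimum covered het sites for a target to enter the check.
#' @return A list: `targets` evaluated, `supports_total`, `same_hap`,
#'   `other_hap`, `corrupting`, `purity` (same-haplotype fraction) and
#'   `corrupting_frac`.
#' @export
evaluateSupportPurity <- function(supports, truth, haps, minHet = 2L) {
  stopifnot(is(truth, "SimTruth"), is(haps, "HaplotypeSet"))
  tr <- truth@reads
  het <- hetPositions(haps)
  n_same <- n_other <- n_corr <- 0L
  n_targets <- 0L
  for (tid in names(supports)) {
    ti <- match(tid, tr$read_id)
    hcov <- het[het >= tr$start[ti] & het < tr$end[ti]]
    if (length(hcov) < minHet) next
    n_targets <- n_targets + 1L
    for (sid in supports[[tid]]) {
      si <- match(sid, tr$read_id)
      if (tr$hap[si] == tr$hap[ti]) { n_same <- n_same + 1L; next }
      n_other <- n_other + 1L
      a <- max(tr$start[ti], tr$start[si]); b <- min(tr$end[ti], tr$end[si])
      if (any(het >= a & het < b)) n_corr <- n_corr + 1L
    }
  }
  tot <- n_same + n_other
  list(targets = n_targets, supports_total = tot, same_hap = n_same,
       other_hap = n_other, corrupting = n_corr,
       purity = if (tot) n_same / tot else NA_real_,
       corrupting_frac = if (tot) n_corr / tot else NA_real_)
}

#' Run one replicate of the simulation benchmark
#'
#' Simulates a diploid read set at the package's default study conditions
#' (100 kb reference, heterozygosity 1e-3, 30x coverage, 1% random errors,
#' 50 recurrent sites at recurrence 0.5), corrects it with the default
#' pipeline, and scores the result against the truth ledger: classification
#' of planted recurrent sites and of true heterozygous sites (first-round
#' tables, i.e. on the raw reads), the HiFi-style baseline contrast, support
#' purity, the fraction of reads corrected to zero errors outside
#' homopolymer runs, and the mean residual error rate.
#'
#' @param seed Integer seed for the replicate.
#' @param refLength,ploidy,hetRate,depth Simulation scale.
#' @param rawEval Also align the uncorrected reads to their origins to
#'   measure the pre-correction residual rate (the costly part of the
#'   evaluation; the planted error rate does not vary between replicates,
#'   so a subset of replicates suffices for the fold change).
#' @param ... Passed to [correctReads()].
#' @return One-row `data.frame` of summary metrics.
#' @export
benchmarkCorrection <- function(seed, refLength = 100000, ploidy = 2L,
                                hetRate = 0.001, depth = 30,
                                rawEval = TRUE, ...) {
  haps <- simulateHaplotypes(refLength, ploidy, hetRate, seed = seed)
  sim <- simulateReads(haps, depth = depth, seed = seed + 500000L)
  reads <- simReads(sim)
  truth <- simTruth(sim)
  cr <- correctReads(reads, ...)
  ec <- evaluateClassification(cr$sites, truth, haps)
  pu <- evaluateSupportPurity(cr$supports, truth, haps)
  ev <- evaluateCorrection(cr$reads, truth, haps)
  raw <- if (rawEval) mean(evaluateCorrection(reads, truth, haps)$residual_rate)
         else NA_real_
  s <- ec$summary
  data.frame(
    seed = seed,
    reads = length(reads),
    rec_n = s$recurrent_n,
    rec_error = round(s$recurrent_n * s$recurrent_error_frac),
    rec_informative = s$recurrent_informative,
    baseline_rec_informative = s$baseline_recurrent_informative,
    het_n = s$het_n,
    het_informative = round(s$het_n * s$het_informative_frac),
    purity = pu$purity,
    corrupting = pu$corrupting,
    supports_total = pu$supports_total,
    zero_error_frac = mean(ev$zero_error),
    residual = mean(ev$residual_rate),
    residual_raw = raw)
}
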
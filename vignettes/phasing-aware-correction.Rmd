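---
title: "Phasing-aware error correction of noisy long reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phasing-aware error correction of noisy long reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Consensus-based error correction of long reads rests on a simple assumption:
sequencing errors are rare and random, so a difference seen in several
overlapping reads at the same position marks a true variant, while a
difference seen in one read is an error. That assumption holds approximately
for circular-consensus (HiFi-class) data. Nanopore Simplex reads break it:
a fraction of their errors is *recurrent* — the same wrong base appears in
many reads at the same genomic position, typically flagged by depressed base
qualities. A correction pipeline built on the random-error assumption then
mistakes recurrent errors for heterozygous sites, rejects the very reads it
should be using as supports, and leaves most reads uncorrected.

`phasecor` implements the phasing-based remedy: true heterozygous sites lie
on haplotypes, so they are *in phase* with their neighbours, while a
recurrent error is carried by a random subset of reads and is in phase with
nothing. Jointly phasing the candidate sites of each read therefore
separates variants from recurrent errors, and only reads agreeing with the
target at the surviving (informative) sites are used for consensus.

## The model and the dynamic program

For a target read $R$, every overlapping read is aligned to it and each
position where at least two reads carry the identical alternative allele
becomes a candidate site. At site $S[i]$, read $k$ has phase

$$S[i][k] \in \{0, 1, *\}$$

— matching $R$ (0), differing from $R$ (1), or not covering the site
($*$). Two sites are *compatible* when every read phased at both has the
same phase at both. The size of the largest compatible chain ending at site
$i$ follows the recurrence

$$\mathrm{LCG}(i) = \max_{j<i,\; S[j] \leftrightarrow S[i]} \mathrm{LCG}(j) + 1 ,$$

computed with $O(N^2)$ pairwise checks and $O(N)$ score/predecessor
storage. Traceback from high scores downwards groups sites into clusters;
grouped sites supported by at least two reads on each side are informative,
isolated sites are errors unless exceptionally supported, and only reads
with phase 0 or $*$ at every informative site become supports for windowed
consensus correction.

Three site filters precede the dynamic program, mirroring the error
structure of nanopore data: candidate sites inside (or adjacent to)
homopolymer runs are discarded; sites whose phase split coincides exactly
with sequencing strand are discarded; and bases below Phred 10 are treated
as potential errors and removed from the site computation.

## What the compatibility predicate needs beyond its textbook form

The predicate above is exact on complete, error-free phase matrices. On
realistic pileups — partial coverage, 1% residual differences, quality
masking — the literal form admits pathological chains, and the package adds
guards (each individually switchable; setting `minShared = 0`,
`minShared1 = 0`, `maxConflict = 0` restores the literal predicate):

* **`minShared` (default 8)** — at least this many reads must be phased at
  both sites. Without it, coverage-sparse site pairs are vacuously
  compatible.
* **`minShared1` (default 2)** — at least this many of the agreeing reads
  must be phase 1 at *both* sites. Linkage between two variants is
  evidenced by reads carrying both alternative alleles; agreement made
  only of phase-0 reads says nothing (two unrelated error sites whose
  carriers do not see each other's position would otherwise chain).
* **`maxConflict` (default 1)** — one disagreeing read is tolerated when
  backed by five co-phase-1 reads per conflict. A single read with a
  sequencing error on a variant position otherwise unlinks a true het from
  its neighbours, capping het recovery at roughly the per-site probability
  that no read errs there ($\approx 95\%$ at 1% error and 30× depth).
* **Cluster profile consistency** — chains only guarantee compatibility
  with the predecessor, so a cluster can pick up sites that conflict with
  the phasing as a whole. Each cluster defines a profile (majority phase
  per read); member sites disagreeing with it beyond `clusterTol` are
  demoted, clusters whose profile does not split the reads (at least
  `minorFrac` on each side) are dissolved (an "everyone differs" chain is
  the target's own error run, not linked variants), and traceback branches
  are merged into the cluster they run into only when they agree with its
  profile.
* **Minor-side fraction (`minorFrac`, default 0.1)** — an informative site
  must place at least a tenth of its phased reads on the minor side. A
  true variant partitions reads by haplotype ($\approx 1/\mathrm{ploidy}$
  per side); a site whose minor side is one or two chance matches of the
  target's own error is never a variant.

The isolated-site support threshold (`isoSupportThreshold`, default 28)
deserves its own note. A recurrent error whose planted allele is carried by
the target itself splits the covering reads roughly in half — exactly like
a het — but stays isolated because its carrier set is random. Its support
at 30× is 15–17 reads, so any threshold below ~20 readmits precisely the
artefacts the method exists to remove. True variants are recovered through
clustering; the isolated path is a deliberate long-shot reserved for
exceptional support.

## Consensus: windows, not columns

The correction step is plurality voting, but over *windows*, not columns.
Differences of the selected supports are clustered (gap ≤ `mergeGap` = 3,
anchored only on positions where at least two supports differ), and each
support spanning a window votes with the subsequence its alignment implies
there. Voting on sequence content makes the outcome independent of how
equivalent alignments represent a dense difference region — per-column
voting fragments the same physical difference across representations and
stalls.

Quality matters twice. A voter with any base below Phred 10 in the window
is set aside. And an allele whose carrier pool is enriched in such
low-quality carriers (≥ 20%, at least two) is treated as a sequencing
artefact: it can neither win a window nor defend it. This resolves the
regime where a recurrent allele holds the numerical majority of the local
reads — counts alone cannot tell truth from artefact there, but the
basecaller's quality depression can.

The vote threshold is a majority (`minRatio = 0.5`) with ties retained in
favour of the target and a floor of `minDepth = 3` votes. At recurrence
0.5, a wrong allele holds ~35–40% of the confident votes at a
target-carried site; a 60% bar leaves such errors in place indefinitely,
while a majority bar converges over the (default two) correction rounds,
each of which re-overlaps the partially corrected reads.

## Alignment engineering

Overlap candidates come from minimizer sketching (k = 15, window 10) and
diagonal chaining; the median chain diagonal projects the overlap to the
read ends. Because that projection is exact only up to indel drift, the
banded aligner (band 48, covering 3.5σ of indel drift at 1% error over
9 kb reads plus projection error) runs in free-end-gap ("dovetail") mode
with a 32 bp soft margin on any window boundary not pinned to a read end,
and reports the aligned subrange itself. Indels are left-aligned — and
re-left-aligned after the mirror transform that lets one pairwise alignment
feed the pileups of both reads, since mirroring a left-aligned indel
right-aligns it; without re-canonicalisation the two orientations anchor
the same physical indel at different positions and split consensus votes by
strand. Indels longer than 10 bp split an overlap in two. For site calling
(not for consensus), 15 bp at each overlap boundary are trimmed, and a read
with a lone difference within 3 bp of a site is phased `*` there rather
than 0 — single-read wobble in indel placement is not evidence of
agreement. Differences at positions where two or more reads differ are
exempt from that ambiguity window, so conflicts between nearby candidate
sites stay visible.

## The simulator

`simulateHaplotypes()` draws a uniform random reference and plants
independent substitutions per haplotype (default heterozygosity $10^{-3}$),
keeping all haplotypes in the reference coordinate frame.
`simulateReads()` samples read start positions and haplotypes uniformly,
lengths from a truncated normal (default mean 9 kb, sd 2.5 kb, floor
500 bp — a scaled-down long-read length profile appropriate to the 100 kb
default reference), reverse-complements half the reads, and applies two
error layers: 50 recurrent sites (placed ≥ 50 bp from any variant so truth
labels are unambiguous) whose fixed wrong allele each covering read copies
with probability ρ = 0.5, and random substitutions/insertions/deletions
totalling 1% (0.5% / 0.25% / 0.25%), doubled inside homopolymer runs of
four or more bases. Correct bases get Phred 25; erroneous bases get Phred 8
with probability one half — so the quality filter sees both flagged and
unflagged errors. The truth ledger records, per read, the origin interval
and strand, every random error, an exact per-base origin map, and the
carrier list of every recurrent site.

What the simulator does *not* model: context-dependent error hotspots
beyond homopolymers, chimeric or adapter-bearing reads, length-quality
correlation, and structural variation between haplotypes (variants are
SNV-only, which keeps coordinates shared and truth exact). Passing the
simulation benchmarks therefore demonstrates the algorithmic behaviour —
discrimination of recurrent errors from linked variants under a controlled
error process — not performance on any particular real instrument's reads.

## Benchmark scales and honest limits

The packaged benchmark (`benchmarkCorrection()`, also driven by the test
suite and `scripts/acceptance.R`) uses a 100 kb diploid reference at 30×
— about 335 reads per replicate; the test suite runs 20 replicates and the
acceptance script 6. Typical results per replicate: ≥ 98–99.5% of planted
recurrent sites classified as errors while the bundled HiFi-style baseline
classifies essentially all of them informative (a 40–200-fold difference),
~97% of heterozygous candidate sites informative, support purity ~99%,
85–94% of reads corrected to zero non-homopolymer errors, and a ~100-fold
drop in mean residual error.

Three structural effects keep some of these short of perfection, and they
are worth naming because they are properties of the study design rather
than bugs:

* **Linear-genome coverage taper.** Reads are sampled uniformly on a
  linear reference, so coverage falls to zero at the outer ~1 kb of each
  end. Errors there lack the `minDepth` witnesses to fix and het sites
  lack phased neighbours; reads touching the ends dominate the residual
  tail.
* **Errors on variants.** With 1% errors and ~15 same-haplotype reads per
  site, a few percent of het sites have a read error on the variant
  position itself; the conflict tolerance recovers most but not all.
* **Heavy recurrent sites.** At ρ = 0.5, individual sites draw carrier
  fractions well above one half by chance; in low-coverage stretches the
  true allele can fall below the vote floor, and two recurrent sites
  planted within a few bases of each other fragment the window vote.

Support "purity" is reported as the fraction of kept supports whose read
truly originates from the target's haplotype. It cannot reach 100% under
this design: a wrong-haplotype read whose overlap with the target contains
no heterozygous site is sequence-identical to the target's haplotype over
the shared interval and is rightly kept (it cannot corrupt anything —
the `corrupting` counter tracks the harmful subset, which the noise-free
safety test requires to be zero), and a het site masked as a homopolymer
occasionally lets a distinguishable wrong-haplotype read through.

## Telomere-aware tip preservation and dual-scaffolding

Two small assembly-side strategies round out the package, in deliberately
toy-scale form on explicit graph/contig objects. `cleanTips()` removes
short, low-coverage dead-end nodes from a unitig graph, iterating to a
fixpoint in ascending node-id order — but never removes a node whose
telomere flag is set (`flagTelomeres()` scans node ends for ≥ 40%
motif-covered terminal windows, default motif `TTAGGG`, scanning both
strands), because genuine chromosome ends present as tips and silent
removal drops telomeres from assemblies. `dualScaffold()` anchors each
contig of one haplotype onto the other by minimizer chaining (ambiguous
anchors — second hit on a different contig with ≥ half the chain weight —
are left alone); two contigs anchored co-linearly on one companion contig
are joined with an N-gap equal to the inter-anchor distance (floor 1 bp),
refused when the spanned companion region contains `N`s or the companion is
itself broken there. Plans serialise to AGP 2.1 and graphs to GFA 1.0.

## Numerical and procedural choices

* Coordinates are 0-based half-open throughout; AGP output follows AGP's
  1-based inclusive convention.
* DP ties go to the largest predecessor index; traceback visits sites by
  decreasing score, larger index first — both for determinism.
* Consensus edits apply right-to-left; edited bases get quality
  `min(40, 10 + 2 × votes)`.
* Per-read correction is independent and RNG-free, so `threads > 1`
  (forked workers, deterministic merge order) is byte-identical to serial.
* FASTA input (no qualities) is accepted; all bases are treated as
  Phred 40 and the quality filters become inert, with a message.
* Degenerate inputs: empty read sets, reads without overlaps, and
  zero-site tables flow through every stage and return empty/identity
  results.

## Parameters at a glance

| parameter | default | meaning |
|---|---|---|
| `k`, `window` | 15, 10 | minimizer sketch |
| `minOverlapLen` | 1000 bp | minimum usable overlap |
| `maxDiv` | 0.15 | alignment divergence cut |
| `band` | 48 | alignment band half-width |
| `maxIndel` | 10 bp | larger indels split the overlap |
| `minAlt` | 2 | reads sharing the identical alternative allele for a candidate site |
| `qThreshold` | 10 | Phred floor for phased bases and votes |
| `runLen` | 4 | homopolymer mask run length |
| `minShared` / `minShared1` / `maxConflict` | 8 / 2 / 1 | compatibility guards |
| `isoSupportThreshold` | 28 | support needed by an isolated site |
| `groupedSupportThreshold` | 2 | support needed by a grouped site |
| `minDepth` / `minRatio` | 3 / 0.5 | consensus vote floor and majority |
| `mergeGap` | 3 bp | difference-cluster window gap |
| `rounds` | 2 | correction rounds |
| telomere `motif`/`window`/`minDensity` | TTAGGG / 1000 / 0.4 | tip flagging |
| `minAnchor` / `maxGap` | 10 kb / 1 Mb | dual-scaffold anchoring |
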
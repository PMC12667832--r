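Package: phasecor
Title: Phasing-Aware Error Correction of Noisy Long Reads
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Joint haplotype phasing and identification of recurrent
    sequencing errors in noisy long reads (Oxford Nanopore Simplex style).
    Candidate heterozygous sites on a target read are phased against all
    overlapping reads and clustered with a largest-compatible-group dynamic
    program; sites incompatible with the local phasing are recognised as
    recurrent sequencing errors, so that haplotype-consistent supporting
    reads can be selected for consensus correction. Ships a diploid/polyploid
    read simulator with position-recurrent error structure and a complete
    truth ledger, minimizer-based overlap detection with banded alignment,
    and simplified telomere-aware tip preservation and dual-scaffolding
    strategies for telomere-to-telomere assembly, together with PAF, GFA and
    AGP import/export.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    parallel,
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
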
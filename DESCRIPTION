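Package: cloneCN
Title: Clone-Specific Copy Number and Breakpoint Inference from Bulk Tumour Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Joint inference of normal/tumour-clone mixture proportions,
    clone- and allele-specific segment copy numbers, and clone-specific
    copy numbers of rearrangement breakpoints from whole-genome sequencing
    read counts. The genome is modelled as a factor graph in which
    transition factors between adjacent segments penalise unconnected
    segment ends (telomeres), with rearrangement breakpoints allowed to
    absorb copy-number change; posterior inference uses structured
    variational expectation-maximisation with an exact sum-product chain
    update. Includes a breakpoint-naive hidden Markov model baseline with
    greedy post-hoc breakpoint assignment, a genome-evolution simulator
    producing ground-truthed clone mixtures, and evaluation utilities for
    accuracy scoring, clone tracking, and tumour-chromosome assembly.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Rcpp,
    jsonlite,
    yaml,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
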
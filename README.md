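# cloneCN

Clone-specific copy number and breakpoint inference from bulk tumour
whole-genome sequencing.

## What it does, and for whom

Bulk tumour sequencing measures an unlabelled mixture of normal cells and
ancestrally related tumour clones. For analysts working with binned read
counts and structural-variant calls, cloneCN jointly infers:

* the mixture fractions of normal cells and up to two tumour clones,
* clone- and allele-specific integer copy numbers per genome segment, and
* clone-specific integer copy numbers of rearrangement breakpoints —
  i.e. how many chromosomes in each clone carry each junction.

The genome is modelled as a chain of segments whose adjacent copy numbers
are coupled through *telomere-counting* transition factors: a candidate
configuration pays $e^{-\lambda t}$ where $t$ is the number of segment
ends left unconnected. Without a breakpoint at a boundary,
$t(c,c') = |c - c'|$ (summed over clones and alleles); a breakpoint with
orientation $o$ and copy number $b$ interposed at the boundary absorbs
copy change, $t(c,c',b,o) = |c - c' - o\,b|$ on the allele it phases to.
Segment read counts enter through a negative-binomial-mixture emission
with mean $\mu_n = l_n \sum_m h_m c_{nm}$ (effective length $\times$
depth-weighted copies) plus a beta-binomial allele-ratio term. Inference
is structured variational EM: exact sum-product on the segment chain,
discrete posterior updates for each breakpoint, and quasi-Newton point
estimates of the per-clone haploid depths $h$, coordinate-ascending an
evidence lower bound (ELBO). A breakpoint-naive HMM baseline with greedy
post-hoc breakpoint assignment, a genome-evolution simulator with exact
ground truth, and evaluation/clone-tracking/chromosome-assembly utilities
round out the package. See the vignette
(`vignettes/clone-copy-number-model.Rmd`) for the full model description.

## Worked example

Simulate a ground-truthed two-clone mixture (50% normal, descendant clone
30% of the tumour, 40X), fit it, and score against the truth:

```r
library(cloneCN)

sim <- simulateMixture(seed = 7, normalFraction = 0.5, descendantFraction = 0.3,
                       nEvents = 30,
                       chromLengths = setNames(rep(3e7, 5), paste0("chr", 1:5)))
fit <- fitCloneCN(sim$segments, sim$breakpoints)
fit
#> CloneCNFit (breakpoint mode): 300 segments, 26 breakpoints
#>   mixture fractions: 0.431 0.400 0.169
#>   haploid depths:    0.04886 0.03805 0.0133
#>   ELBO -5267.0347 after 8 cycles (converged)
```

The haploid depths are reads per nucleotide per copy for (normal,
ancestral, descendant); as cell fractions, `fit@h / sum(fit@h)` gives
(0.49, 0.38, 0.13) against the simulated (0.50, 0.35, 0.15). The printed
mixture fractions are read-mass fractions $\rho_m = h_m S_m / \sum h_j S_j$.

```r
scoreFit(fit, sim$truth)[, 1:4]
#>   segmentAccuracy breakpointAccuracy normalFractionAbsError minorCloneFractionAbsError
#> 1       0.8166667          0.3461538             0.01241736                 0.01731593
```

82% of this small genome gets the exact clone- and allele-specific copy
numbers of both tumour clones; the mixture fractions are recovered within
2 points. Per-breakpoint calls come with posterior confidence and clonal
prevalence (the tumour fraction carrying the junction):

```r
head(breakpointCopyNumber(fit)[, c("id", "cn_1", "cn_2", "cn_3", "maxProb")], 4)
#>       id cn_1 cn_2 cn_3   maxProb
#> 1 bp_001    0    1    1 0.9986389
#> 2 bp_002    0    0    0 0.9993221
#> 3 bp_003    0    0    1 0.9989941
#> 4 bp_004    0    1    1 0.9986542
head(breakpointPrevalence(fit), 4)
#>    bp_001    bp_002    bp_003    bp_004
#> 1.0000000 0.0000000 0.2973102 1.0000000
```

`bp_003` is called descendant-specific (carried by ~30% of tumour cells);
`bp_002` is a balanced junction the copy-number signal cannot support.
Downstream utilities: `fitCloneCNNaive()` (baseline HMM + greedy
breakpoints), `selectConfidentSubclonal()`, `classifyClonalDynamics()`
(clone tracking across samples), `assembleChromosome()` (walking divergent
segments through subclonal junctions), and `writeFitResults()` /
`readSegmentTable()` etc. for the TSV/JSON interfaces. A command-line
dispatcher over these functions is installed at
`inst/scripts/clonecn.R`.

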
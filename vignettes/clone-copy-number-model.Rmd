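---
title: "Joint inference of clone mixtures, segment and breakpoint copy number"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint inference of clone mixtures, segment and breakpoint copy number}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Bulk whole-genome sequencing of a tumour measures an admixture of normal
cells and one or more tumour clones. Read depth along the genome carries
the signal of segmental copy-number change, allele-specific read counts
carry the signal of allelic imbalance, and discordant read pairs nominate
rearrangement breakpoints — tumour-specific adjacencies between segment
ends. cloneCN jointly infers, from binned read counts and a list of
predicted breakpoints:

* mixture fractions of normal cells and (up to) two tumour clones,
* clone- and allele-specific integer copy numbers for every segment, and
* clone-specific integer copy numbers for every breakpoint.

# The model

## Observation model

The genome is partitioned into regular bins (default 500 kb), further split
so that every breakend coincides with a segment boundary. For segment $n$
with bias-adjusted effective length $l_n$, the expected read count is a
linear combination over clones $m$ of haploid read depths $h_m$ (reads per
nucleotide contributed by one copy of a segment in clone $m$) and total
copy numbers $c_{nm}$:

$$\mu_n = l_n \sum_m h_m c_{nm}.$$

Counts are modelled by a two-component negative binomial mixture sharing
the mean $\mu_n$ (a low-variance bulk component and a higher-variance
component for noisy bins), the allele-A fraction of allele-informative
reads by a beta-binomial whose mean is the depth-weighted allele-copy
ratio, and a small flat outlier component over the joint (total, allele)
observation absorbs segments no copy-number state explains. Because
copy-number states are enumerated as per-clone (major, minor) pairs while
phased allele counts identify a particular haplotype, the allele term is a
symmetric two-component mixture over the two assignments of state alleles
to data alleles.

The normal clone is fixed at one copy of each allele. Tumour-clone states
enumerate (major, minor) pairs with major $\ge$ minor and total at most
`cMax` (default 5, giving 12 states per clone and 144 joint states for two
tumour clones); bulk data carry little information about specific states
above this total.

## Genome-graph prior

Adjacent segments are coupled by transition factors
$f = e^{-\lambda t}$, where $t$ counts *telomeres* — segment ends left
unconnected by a candidate configuration. Without a breakpoint at the
boundary, $t(c, c') = |c - c'|$ summed over clones and alleles (alleles
aligned major-to-major; for sorted pairs this alignment is always
optimal). A breakpoint with orientation $o$ interposed at the boundary can
absorb copy change on one allele:
$t(c, c', b, o) = \min_\ell\left(|c_\ell - c'_\ell - o\,b| +
|c_{-\ell} - c'_{-\ell}|\right)$ per clone, with the minimum-telomere
allele carrying the junction, because the allele phase of breakpoints is
unobserved. The factors are deliberately un-normalised, following the
factor-graph formulation; chromosome ends break the chain.

### Choice of the telomere penalty

`lambda` defaults to 4. This is larger than the smallest value that makes
the factors informative, for a structural reason: with un-normalised
factors, a solution that collapses one clone's haploid depth to zero frees
that clone's dimension of the chain, and summing over its now
unconstrained paths adds roughly $N \log(1 + k e^{-2\lambda})$ nats to the
evidence ($k$ the number of neighbouring states one unit away). At
$\lambda = 1$ this "volume bonus" is about 0.4 nats per segment — larger
than the per-segment likelihood signal of a minor clone — and the
degenerate solution wins the ELBO on kilosegment problems. At
$\lambda \ge 2$ the bonus is negligible; 4 leaves a comfortable margin
while costing nothing at true copy-number steps, which are absorbed by
their interposed breakpoints once the breakpoint posterior sharpens.

## Structured variational inference

The posterior over segment copies $C$, breakpoint copies $B$, depths $h$
and likelihood parameters $\theta$ is approximated by
$q(C)\,\prod_k q_k(b_k)\,q(h)\,q(\theta)$ with point-mass $q(h), q(\theta)$.
Coordinate ascent iterates:

1. **q(C)**: with the transition factors replaced by their expectation
   under $q_k$, $q(C)$ is a chain; exact single and pairwise marginals
   come from scaled forward–backward sum-product (compiled code).
2. **q_k**: each breakpoint posterior is refreshed from the pairwise
   marginals at the boundaries carrying its breakends,
   $\log q_k(b) \propto \sum \gamma_n(c, c') \log f(c, c', b \mid o, \lambda)$.
3. **h (and optionally θ)**: point estimates maximise the
   $\gamma$-weighted expected emission log-likelihood by L-BFGS-B with
   $h \ge 0$. The quasi-Newton search runs on the total-count part of the
   objective (exact when allele counts are absent, and fast because states
   collapse to distinct total-copy combinations); the candidate is
   accepted only if the full expected emission log-likelihood — allele
   terms included — does not decrease. This is a generalised-EM step: the
   ELBO can only go up, which the monotonicity tests verify. Dispersion
   parameters are treated as fixed hyperparameters by default
   (`fitTheta = FALSE`); they are weakly identified at desk scale and
   refitting them rarely changes the copy-number calls, but the same
   guarded update refits them when enabled.

The ELBO is tracked after each of the three updates. With $q(C)$ set to
the exact chain posterior the ELBO equals the chain log-partition plus the
breakpoint-posterior entropies, which makes the bookkeeping cheap and
exact.

## Initialisation

Variational inference here is sensitive to initialisation, so restarts
matter more than iteration count. Candidate starting depths come from a
robust scan of the per-segment depth histogram: pairs (normal depth $h_0$,
total tumour haploid depth $h_T$) are scored by how well the integer
lattice $2h_0 + c\,h_T$ explains the observed depths, with truncated
residuals so subclonal and noisy segments cannot dominate, and a mild
parsimony penalty on implied copy levels that breaks the halved-spacing
(doubled-ploidy) alias. Because depth alone identifies $h_0$ only up to
shifts of $h_T/2$, each candidate is expanded over that lattice ambiguity
and the full model — allele ratios and transitions included — picks the
register by ELBO. Each start runs a few pilot cycles (default 4); the best
two continue to convergence (relative ELBO change below `tol`, default
1e-6, or `maxIter` cycles). A blind grid over normal fraction, clone split
and ploidy guesses is kept as a fallback for degenerate depth histograms.

Ties in the final maximum-marginal states are broken toward lower total
copy number and lower clone index; the state enumeration is sorted so the
first maximum implements this deterministically. The whole fit is a
deterministic function of its inputs.

## Mixture fractions

The fit reports both haploid depths $h$ and mixture fractions
$\rho_m = h_m S_m / \sum_j h_j S_j$ with $S_m = \sum_n l_n c_{nm}$ —
$\rho$ is the fraction of sequenced mass attributable to each clone.
Because $h_m$ is proportional to the number of cells of clone $m$, the
*cell* fraction estimate is $h_m / \sum_j h_j$; evaluation against the
simulator's cell fractions uses this quantity.

# The baseline

`fitCloneCNNaive()` runs the identical pipeline with breakpoint copies
clamped to zero (`bMax = 0`), i.e. a breakpoint-naive HMM, then assigns
breakpoint copies post hoc: per breakpoint and clone, the copy number in
`0..bMax` minimising the summed telomere count at its two breakend
boundaries, ties to the smaller value, breakpoints visited in input order.
The per-clone objective is separable, so the greedy answer never exceeds
the all-zero telomere count.

# The simulator

`simulateMixture()` generates ground-truthed datasets in two stages.

**Histories.** Duplication, deletion and balanced rearrangement events are
applied to an initially diploid genome on a two-clone phylogeny: trunk
events are shared, branch events are private to the descendant clone
(clones are labelled by lineage, not size, so an ancestral/descendant
mixture of $x/1-x$ is distinct from the reverse). Event endpoints live on
the bin grid, so simulated breakends always coincide with segment
boundaries. Per-history knobs (duplication/deletion balance, whole-
chromosome event rate, descendant share of events, focal event sizes of
5–40% of a chromosome) are drawn at random, each proposal is replayed, and
the best of `nProposals` (default 100) histories under squared error on
(target tumour ploidy, target divergent proportion) is kept — a
score-and-resample scheme. Replay is purely additive (single copies of one
allele), so the stored truth is exactly reproducible from the event list,
and junction multiplicity is 1 on carrying clones; deletion events are
only placed where the chosen allele has a copy to lose, and stacked
duplications are capped at total copy 6 to reflect the rarity of
high-level amplification at bin scale.

**Counts.** Given cell fractions (normal fraction, descendant fraction of
the tumour) and a coverage (default 40X, converted to read pairs per
nucleotide assuming 2x100 bp pairs), haploid depths are
$h_m = d/2 \cdot \rho^{cell}_m$ and counts are drawn from the same
likelihood family the model fits: negative binomial mixture totals,
beta-binomial allele counts over a fraction (default 0.2) of
allele-informative pairs, and flat outliers at the outlier weight.

**Default noise levels.** Inverse-dispersions (2000, 100) with 5% weight
on the heavy component give count noise of about 2% CV at 500-kb bins
plus a heavy tail, matching GC-corrected bin counts from a typical 40X
genome; allele over-dispersion 0.002 gives phased-block allele-fraction
scatter of about 2%. These defaults are the simulator's definition of
realistic data and are used as-is by the recovery experiments.

**What the simulator does not emulate.** GC/mappability bias along the
genome (effective lengths are exact by construction; the pluggable bias
model is exercised only in unit tests), replication-timing waves,
breakpoint-caller artefacts other than optional uniform false positives,
subclonal structure deeper than two tumour clones, and real read-level
phenomena (the aligned-read re-sampling pathway used for full-scale
benchmarking against a deep source genome is out of scope here). Passing
recovery tests therefore demonstrate correctness of the inference under
the stated generative assumptions, not performance on real sequencing
artefacts.

# Evaluation utilities

`scoreFit()` reports length-weighted clone-specific segment accuracy under
the best tumour-label permutation (labels are inherently exchangeable),
exact per-clone breakpoint accuracy, and absolute/relative errors of
normal fraction, minor clone fraction, mean tumour ploidy and divergent
proportion. `breakpointPrevalence()` and `classifyClonalDynamics()`
implement clone tracking across samples (ascending / descending / stable /
conflicting, with a small tolerance, default 0.02, defining "unchanged").
`selectConfidentSubclonal()` applies the segment-smoothing and filtering
rules (drop < 100 kb, merge equal-divergence runs, keep >= 1 Mb with total
copy <= 4) before nominating subclonal breakpoints, and
`assembleChromosome()` greedily walks divergent merged segments through
subclonal junctions, in both directions from a seed, terminating at the
first revisit with a cycle flag.

# Numerical choices

* Forward–backward runs in scaled linear space; emissions are shifted by
  their row maximum, so chains of thousands of segments are stable.
* All-zero emission columns (no feasible state) raise an error rather
  than propagating NaN.
* The M-step uses central-difference gradients with step
  $10^{-6}\max(|h|, 10^{-4})$, tight enough to match closed-form optima
  to about 1e-6 relative.
* Beta-binomial and negative-binomial log-pmfs hoist the
  observation-dependent `lgamma` terms out of the state loop, which is
  what makes the 144-state emission matrix cheap.
* Problem sizes in the recovery experiments are 1000 x 500 kb segments,
  20 replicates per condition, chosen to estimate median accuracies
  stably on a single CPU.

# Known limitations

* Two tumour clones at most; the chain state space grows quadratically in
  clones.
* Balanced rearrangements carry junctions without copy change; the
  telomere factor assigns them one telomere per carried copy, so the
  model prefers zero copies for them and true balanced junction copies
  are systematically missed. Their truth is retained by the simulator, so
  reported breakpoint accuracies honestly include these misses.
* The breakpoint-to-allele phasing rule (minimum-telomere allele) is a
  heuristic; a wrong phase can cost accuracy at adjacent imbalanced
  segments.
* Interval-level identifiability limits remain: 50/50 tumour mixtures
  and doubled-ploidy registers can tie in the ELBO, in which case the
  parsimony preferences decide.
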
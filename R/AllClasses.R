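#' @import methods
#' @importFrom stats optim rbinom rpois rnbinom rbeta runif dnbinom dpois
#'   dbinom setNames aggregate
#' @importFrom utils read.delim write.table head tail modifyList
#' @useDynLib cloneCN, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Likelihood parameters for segment read-count emissions
#'
#' Container for the global parameters \eqn{\theta} of the read-count
#' emission model: the count family (Poisson, negative binomial, or a
#' two-component negative binomial mixture sharing a common mean), the
#' beta-binomial over-dispersion of the allele-ratio model, and the weight
#' and log-density of a flat outlier component mixed into the emission.
#'
#' @slot family one of \code{"poisson"}, \code{"negbin"},
#'   \code{"negbin_mixture"}.
#' @slot nbInvDispersion inverse-dispersion (\code{size}) of each negative
#'   binomial component; variance is \eqn{\mu + \mu^2/r}. Length 1 for
#'   \code{"negbin"}, 2 for \code{"negbin_mixture"}.
#' @slot nbMixWeight mixture weight of the second (high-variance) component.
#' @slot alleleDispersion beta-binomial over-dispersion \eqn{\rho \in [0,1)};
#'   0 recovers the binomial.
#' @slot outlierWeight prior weight of the flat outlier component.
#' @slot outlierLogDensity log-density of the outlier component; \code{NA}
#'   derives a per-segment value from the data scale.
#' @export
setClass("LikelihoodParams", representation(
  family = "character",
  nbInvDispersion = "numeric",
  nbMixWeight = "numeric",
  alleleDispersion = "numeric",
  outlierWeight = "numeric",
  outlierLogDensity = "numeric"
))

setValidity("LikelihoodParams", function(object) {
  msg <- character()
  if (!object@family %in% c("poisson", "negbin", "negbin_mixture"))
    msg <- c(msg, "family must be poisson, negbin or negbin_mixture")
  if (any(object@nbInvDispersion <= 0)) msg <- c(msg, "inverse-dispersions must be > 0")
  if (object@family == "negbin" && length(object@nbInvDispersion) < 1)
    msg <- c(msg, "negbin needs one inverse-dispersion")
  if (object@family == "negbin_mixture" && length(object@nbInvDispersion) != 2)
    msg <- c(msg, "negbin_mixture needs two inverse-dispersions")
  if (object@nbMixWeight < 0 || object@nbMixWeight > 1)
    msg <- c(msg, "nbMixWeight must lie in [0,1]")
  if (object@alleleDispersion < 0 || object@alleleDispersion >= 1)
    msg <- c(msg, "alleleDispersion must lie in [0,1)")
  if (object@outlierWeight < 0 || object@outlierWeight >= 1)
    msg <- c(msg, "outlierWeight must lie in [0,1)")
  if (length(msg)) msg else TRUE
})

#' Construct emission-model parameters
#'
#' @param family count model family; default a two-component negative
#'   binomial mixture, which fits the over-dispersion of real bin counts
#'   better than a single component.
#' @param nbInvDispersion inverse-dispersion per component.
#' @param nbMixWeight weight of the high-variance component.
#' @param alleleDispersion beta-binomial over-dispersion in [0,1).
#' @param outlierWeight weight of the flat outlier component.
#' @param outlierLogDensity log-density of the outlier component
#'   (\code{NA} = derived from the data scale).
#' @return a \linkS4class{LikelihoodParams} object.
#' @examples
#' likelihoodParams(family = "poisson", outlierWeight = 0)
#' @export
likelihoodParams <- function(family = c("negbin_mixture", "negbin", "poisson"),
                             nbInvDispersion = NULL,
                             nbMixWeight = 0.05,
                             alleleDispersion = 0.002,
                             outlierWeight = 0.01,
                             outlierLogDensity = NA_real_) {
  family <- match.arg(family)
  if (is.null(nbInvDispersion)) {
    nbInvDispersion <- switch(family,
      poisson = numeric(0),
      negbin = 2000,
      negbin_mixture = c(2000, 100))
  }
  new("LikelihoodParams", family = family,
      nbInvDispersion = as.numeric(nbInvDispersion),
      nbMixWeight = as.numeric(nbMixWeight),
      alleleDispersion = as.numeric(alleleDispersion),
      outlierWeight = as.numeric(outlierWeight),
      outlierLogDensity = as.numeric(outlierLogDensity))
}

#' Configuration of the clone copy-number model fit
#'
#' @slot lambda telomere penalty; transition factors are
#'   \eqn{e^{-\lambda t}} in the implied telomere count \eqn{t}.
#' @slot cMax cap on per-clone total (allele-sum) copy number.
#' @slot bMax cap on per-clone breakpoint copy number.
#' @slot nTumour number of tumour clones (1 or 2).
#' @slot params \linkS4class{LikelihoodParams}.
#' @slot tol relative ELBO convergence tolerance.
#' @slot maxIter maximum coordinate-ascent cycles per restart.
#' @slot pilotIter cycles run for every restart before the best is continued.
#' @slot normalFractions,cloneSplits,ploidyGuesses initialisation grid over
#'   candidate normal fractions, descendant-within-tumour splits, and
#'   tumour ploidies used to scale the starting haploid depths.
#' @slot fitTheta also refit dispersion parameters in the M-step.
#' @slot seed integer recorded for provenance (the fit itself is
#'   deterministic).
#' @export
setClass("CloneCNConfig", representation(
  lambda = "numeric", cMax = "integer", bMax = "integer",
  nTumour = "integer", params = "LikelihoodParams",
  tol = "numeric", maxIter = "integer", pilotIter = "integer",
  normalFractions = "numeric", cloneSplits = "numeric",
  ploidyGuesses = "numeric", keepRestarts = "integer",
  fitTheta = "logical", seed = "integer"
))

setValidity("CloneCNConfig", function(object) {
  msg <- character()
  if (object@lambda < 0) msg <- c(msg, "lambda must be >= 0")
  if (object@cMax < 1) msg <- c(msg, "cMax must be >= 1")
  if (object@bMax < 0) msg <- c(msg, "bMax must be >= 0")
  if (!object@nTumour %in% 1:2) msg <- c(msg, "nTumour must be 1 or 2")
  if (any(object@normalFractions <= 0 | object@normalFractions >= 1))
    msg <- c(msg, "normalFractions must lie in (0,1)")
  if (length(msg)) msg else TRUE
})

#' Construct a fit configuration
#'
#' @param lambda telomere penalty (default 4). With un-normalised
#'   transition factors a clone whose haploid depth collapses to zero gains
#'   a path-volume bonus of roughly \eqn{N \log(1 + k e^{-2\lambda})};
#'   the default keeps that bonus negligible while true copy-number steps
#'   remain cheap because interposed breakpoints absorb them.
#' @param cMax per-clone total copy-number cap (default 5; higher states are
#'   rarely inferable from bulk data).
#' @param bMax per-clone breakpoint copy-number cap (default 2).
#' @param nTumour number of tumour clones, 1 or 2 (default 2; the chain
#'   state space grows quadratically with clones, capping the model at two
#'   tumour clones plus normal).
#' @param params emission parameters (\code{\link{likelihoodParams}()}).
#' @param tol relative ELBO change declaring convergence (default 1e-6).
#' @param maxIter maximum coordinate-ascent cycles (default 100).
#' @param pilotIter cycles given to each restart before the best-ELBO
#'   restarts are continued to convergence (default 5).
#' @param keepRestarts number of best pilot restarts run to convergence
#'   (default 3).
#' @param normalFractions,cloneSplits,ploidyGuesses initialisation grid;
#'   starting depths are scaled so the observed genome-wide read depth
#'   matches a mixture of diploid normal and tumour at the guessed ploidy.
#' @param fitTheta refit dispersions in the M-step (default FALSE).
#' @param seed provenance seed (the fit is deterministic).
#' @return a \linkS4class{CloneCNConfig}.
#' @export
cloneCNConfig <- function(lambda = 4, cMax = 5L, bMax = 2L, nTumour = 2L,
                          params = likelihoodParams(),
                          tol = 1e-6, maxIter = 100L, pilotIter = 4L,
                          keepRestarts = 2L,
                          normalFractions = c(0.2, 0.4, 0.6),
                          cloneSplits = 0.25,
                          ploidyGuesses = c(2, 2.75),
                          fitTheta = FALSE, seed = 1L) {
  new("CloneCNConfig", lambda = as.numeric(lambda), cMax = as.integer(cMax),
      bMax = as.integer(bMax), nTumour = as.integer(nTumour), params = params,
      tol = as.numeric(tol), maxIter = as.integer(maxIter),
      pilotIter = as.integer(pilotIter),
      normalFractions = as.numeric(normalFractions),
      cloneSplits = as.numeric(cloneSplits),
      ploidyGuesses = as.numeric(ploidyGuesses),
      keepRestarts = as.integer(keepRestarts),
      fitTheta = isTRUE(fitTheta), seed = as.integer(seed))
}

#' Result of a clone copy-number fit
#'
#' @slot segments \code{GRanges} of the input segments with matrix columns
#'   \code{major} and \code{minor} (one column per clone) holding the
#'   maximum-marginal allele-specific copy numbers.
#' @slot breakpoints data.frame of breakpoints with per-clone copy-number
#'   columns \code{cn_1}, \code{cn_2}, ... and posterior columns.
#' @slot h per-clone haploid read depths (reads per nucleotide per copy);
#'   clone 1 is normal.
#' @slot rho mixture fractions derived from \code{h} and the fitted genome
#'   masses.
#' @slot elbo final evidence lower bound.
#' @slot elboTrace ELBO recorded after every coordinate update of the
#'   selected restart.
#' @slot iterations coordinate-ascent cycles used.
#' @slot converged logical.
#' @slot mode \code{"breakpoint"} or \code{"naive"}.
#' @slot posthoc greedy post-hoc breakpoint assignments (naive mode).
#' @slot config the \linkS4class{CloneCNConfig} used.
#' @slot diagnostics list (restart ELBOs, warnings).
#' @export
setClass("CloneCNFit", representation(
  segments = "GRanges", breakpoints = "data.frame",
  h = "numeric", rho = "numeric",
  elbo = "numeric", elboTrace = "numeric",
  iterations = "integer", converged = "logical",
  mode = "character", posthoc = "data.frame",
  config = "CloneCNConfig", diagnostics = "list"
))

#' Ground truth emitted by the genome-evolution simulator
#'
#' @slot segments \code{GRanges} with matrix columns \code{major},
#'   \code{minor} (phased allele copies per clone: normal, ancestral,
#'   descendant).
#' @slot breakpoints data.frame with per-clone true copy columns.
#' @slot chromLengths named chromosome lengths (bp).
#' @slot binSize segment bin size (bp).
#' @slot normalFraction fraction of normal cells.
#' @slot descendantFraction descendant clone fraction within the tumour.
#' @slot cellFractions cell fractions (normal, ancestral, descendant).
#' @slot h per-clone haploid depths implied by the simulated coverage.
#' @slot ploidy realised mean tumour ploidy.
#' @slot divergentProportion realised fraction of the genome with divergent
#'   clone copy number.
#' @slot events event history (replayable).
#' @slot seed simulation seed.
#' @export
setClass("SimulatedTruth", representation(
  segments = "GRanges", breakpoints = "data.frame",
  chromLengths = "numeric", binSize = "numeric",
  normalFraction = "numeric", descendantFraction = "numeric",
  cellFractions = "numeric", h = "numeric",
  ploidy = "numeric", divergentProportion = "numeric",
  events = "data.frame", seed = "integer"
))

#' @describeIn CloneCNFit-class per-clone haploid read depths
#' @param object a fit
#' @export
setGeneric("haploidDepths", function(object) standardGeneric("haploidDepths"))
setMethod("haploidDepths", "CloneCNFit", function(object) object@h)

#' @describeIn CloneCNFit-class mixture fractions (normal first)
#' @export
setGeneric("mixtureFractions", function(object) standardGeneric("mixtureFractions"))
setMethod("mixtureFractions", "CloneCNFit", function(object) object@rho)
setMethod("mixtureFractions", "SimulatedTruth", function(object) object@cellFractions)

#' @describeIn CloneCNFit-class segment copy numbers as GRanges
#' @export
setGeneric("segmentCopyNumber", function(object) standardGeneric("segmentCopyNumber"))
setMethod("segmentCopyNumber", "CloneCNFit", function(object) object@segments)
setMethod("segmentCopyNumber", "SimulatedTruth", function(object) object@segments)

#' @describeIn CloneCNFit-class breakpoint copy-number table
#' @export
setGeneric("breakpointCopyNumber", function(object) standardGeneric("breakpointCopyNumber"))
setMethod("breakpointCopyNumber", "CloneCNFit", function(object) object@breakpoints)
setMethod("breakpointCopyNumber", "SimulatedTruth", function(object) object@breakpoints)

#' @describeIn CloneCNFit-class final evidence lower bound
#' @export
setGeneric("fitELBO", function(object) standardGeneric("fitELBO"))
setMethod("fitELBO", "CloneCNFit", function(object) object@elbo)

setMethod("show", "CloneCNFit", function(object) {
  cat(sprintf("CloneCNFit (%s mode): %d segments, %d breakpoints\n",
              object@mode, length(object@segments), nrow(object@breakpoints)))
  cat("  mixture fractions:", paste(sprintf("%.3f", object@rho), collapse = " "), "\n")
  cat("  haploid depths:   ", paste(sprintf("%.4g", object@h), collapse = " "), "\n")
  cat(sprintf("  ELBO %.4f after %d cycles (%sconverged)\n", object@elbo,
              object@iterations, if (object@converged) "" else "not "))
})

setMethod("show", "SimulatedTruth", function(object) {
  cat(sprintf("SimulatedTruth: %d segments, %d breakpoints, %d events\n",
              length(object@segments), nrow(object@breakpoints), nrow(object@events)))
  cat(sprintf("  fractions (normal/anc/desc): %s\n",
              paste(sprintf("%.3f", object@cellFractions), collapse = " ")))
  cat(sprintf("  tumour ploidy %.3f, divergent proportion %.3f\n",
              object@ploidy, object@divergentProportion))
})
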
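# Emission models: read counts given clone copy numbers and haploid depths.

logSumExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Expected read count of a segment
#'
#' The expected count is a linear combination of (effective) segment length,
#' clone-specific copy number, and clone-specific haploid read depth, summed
#' over clones: \eqn{\mu = l \sum_m h_m c_m}.
#'
#' @param l segment (effective) length in bp.
#' @param cn per-clone total copy numbers (vector, or matrix with one row
#'   per state and one column per clone).
#' @param h per-clone haploid depths (reads per nucleotide per copy).
#' @return expected count(s).
#' @examples
#' expectedReadCount(1000, c(2, 1), c(0.01, 0.02)) # 40
#' @export
expectedReadCount <- function(l, cn, h) {
  if (is.matrix(cn)) {
    stopifnot(ncol(cn) == length(h))
    as.numeric(l) * as.numeric(cn %*% h)
  } else {
    stopifnot(length(cn) == length(h))
    as.numeric(l) * sum(h * cn)
  }
}

nbLogPmf <- function(x, mu, size) {
  # dnbinom_mu; mu == 0 handled as a point mass at zero
  out <- dnbinom(x, size = size, mu = pmax(mu, 0), log = TRUE)
  zero <- mu <= 0
  if (any(zero)) out[zero] <- ifelse(x[zero] == 0, 0, -Inf)
  out
}

countCoreLogLik <- function(x, mu, params) {
  fam <- params@family
  if (fam == "poisson") {
    ll <- dpois(x, lambda = mu, log = TRUE)
    zero <- mu <= 0
    if (any(zero)) ll[zero] <- ifelse(x[zero] == 0, 0, -Inf)
    return(ll)
  }
  if (fam == "negbin") return(nbLogPmf(x, mu, params@nbInvDispersion[1]))
  w2 <- params@nbMixWeight
  l1 <- nbLogPmf(x, mu, params@nbInvDispersion[1])
  l2 <- nbLogPmf(x, mu, params@nbInvDispersion[2])
  if (w2 <= 0) return(l1)
  if (w2 >= 1) return(l2)
  m <- pmax(l1, l2)
  ifelse(is.finite(m),
         m + log((1 - w2) * exp(l1 - m) + w2 * exp(l2 - m)),
         m)
}

#' Log-likelihood of a total read count
#'
#' Poisson, negative binomial, or two-component negative binomial mixture
#' (components share the mean \eqn{\mu}), optionally further mixed with a
#' flat outlier component of weight \code{outlierWeight}.
#'
#' @param x observed count(s), non-negative integers.
#' @param mu expected count(s) from \code{\link{expectedReadCount}}.
#' @param params \linkS4class{LikelihoodParams}.
#' @param outlierLogDensity overrides \code{params@outlierLogDensity}.
#' @return log-probability, vectorised over \code{x}/\code{mu}.
#' @export
totalCountLogLik <- function(x, mu, params = likelihoodParams(),
                             outlierLogDensity = NULL) {
  if (any(x < 0)) stop("counts must be non-negative")
  ll <- countCoreLogLik(x, mu, params)
  w <- params@outlierWeight
  if (w > 0) {
    od <- if (!is.null(outlierLogDensity)) outlierLogDensity
          else params@outlierLogDensity
    if (any(is.na(od))) stop("outlierLogDensity required when outlierWeight > 0")
    m <- pmax(ll, od)
    ll <- ifelse(is.finite(m),
                 m + log((1 - w) * exp(ll - m) + w * exp(od - m)),
                 m)
  }
  ll
}

betaBinLogPmf <- function(x, n, p, rho) {
  # beta-binomial with mean p and over-dispersion rho; rho -> 0 is binomial
  if (rho <= 0) return(dbinom(x, n, pmin(pmax(p, 0), 1), log = TRUE))
  s <- (1 - rho) / rho
  a <- p * s; b <- (1 - p) * s
  eps <- 1e-12
  ifelse(p <= 0, ifelse(x == 0, 0, -Inf),
  ifelse(p >= 1, ifelse(x == n, 0, -Inf),
    lchoose(n, x) + lbeta(x + a, n - x + b) - lbeta(a, b)))
}

#' Allele-ratio log-likelihood
#'
#' Beta-binomial log-probability of the allele-A count out of the total
#' allele-informative count, with mean
#' \eqn{p = \sum_m h_m c^A_m / \sum_m h_m (c^A_m + c^B_m)} (0.5 when the
#' denominator vanishes) and over-dispersion
#' \code{params@alleleDispersion}.
#'
#' @param xa,xb allele A/B read counts.
#' @param cnA,cnB per-clone allele copy numbers (vectors over clones, or
#'   matrices states x clones).
#' @param h per-clone haploid depths.
#' @param params \linkS4class{LikelihoodParams}.
#' @return log-probability (0 when \code{xa + xb == 0}).
#' @export
alleleLogLik <- function(xa, xb, cnA, cnB, h, params = likelihoodParams()) {
  if (is.matrix(cnA)) {
    num <- as.numeric(cnA %*% h); den <- as.numeric((cnA + cnB) %*% h)
  } else {
    num <- sum(h * cnA); den <- sum(h * (cnA + cnB))
  }
  p <- ifelse(den > 0, num / den, 0.5)
  n <- xa + xb
  out <- betaBinLogPmf(xa, n, p, params@alleleDispersion)
  out[n == 0] <- 0
  out
}

#' Full emission log-likelihood of a segment
#'
#' Sum of the total-count log-likelihood at the bias-adjusted effective
#' length and the allele-ratio log-likelihood. Because copy-number states
#' are enumerated with major >= minor per clone while the measured allele-A
#' count is phased, the allele term is a symmetric two-component phase
#' mixture over the two assignments of state alleles to data alleles.
#'
#' @param x,xa,xb total and allele read counts of the segment.
#' @param leff effective length (bp).
#' @param stateA,stateB per-clone allele copies of the state (vectors over
#'   clones, normal included).
#' @param h per-clone haploid depths.
#' @param params \linkS4class{LikelihoodParams}.
#' @param phaseMixture use the symmetric phase mixture for the allele term
#'   (default TRUE; FALSE matches \code{\link{alleleLogLik}} exactly).
#' @param outlierLogDensity log-density of the flat outlier component;
#'   defaults to a scale set by the segment's own observed depth.
#' @return log-probability.
#' @export
emissionLogLik <- function(x, xa, xb, leff, stateA, stateB, h,
                           params = likelihoodParams(), phaseMixture = TRUE,
                           outlierLogDensity = NULL) {
  mu <- expectedReadCount(leff, stateA + stateB, h)
  od <- if (!is.null(outlierLogDensity)) outlierLogDensity
        else params@outlierLogDensity
  if (is.na(od) && params@outlierWeight > 0)
    od <- defaultOutlierLogDensity(leff, (x + 1) / leff) - log(xa + xb + 1)
  tot <- totalCountLogLik(x, mu, stripOutlier(params))
  if (xa + xb == 0) {
    al <- 0
  } else if (phaseMixture) {
    al <- logSumExp(c(alleleLogLik(xa, xb, stateA, stateB, h, params),
                      alleleLogLik(xa, xb, stateB, stateA, h, params))) - log(2)
  } else {
    al <- alleleLogLik(xa, xb, stateA, stateB, h, params)
  }
  core <- tot + al
  w <- params@outlierWeight
  if (w > 0) logSumExp(c(log(1 - w) + core, log(w) + od)) else core
}

stripOutlier <- function(params) {
  p <- params
  p@outlierWeight <- 0
  p
}

# Flat density over total counts spanning roughly ten times the typical
# count range of the segment at the observed genome-wide depth. A function
# of the data only (never of the parameters being optimised), so it cannot
# attract the depth estimates. The full outlier component used in the
# emission is flat over the joint (total, allele) observation, i.e. this
# minus log(xa + xb + 1).
defaultOutlierLogDensity <- function(leff, depth) {
  -log(10 * (leff * depth + 10))
}
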
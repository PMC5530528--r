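# Chain construction and structured variational updates.
#
# The variational posterior factorises as q(C) q(h) q(theta) prod_k q_k(b_k):
# q(C) is a per-chromosome chain (an HMM after expectation of the transition
# factors under q_k), q_k are discrete distributions over joint per-clone
# breakpoint copies, and h, theta carry point estimates.

#' Build the internal chain model
#'
#' Assembles the data vectors, copy-number state space, telomere tensors and
#' breakend-to-boundary mapping used by the variational updates. Breakends
#' are interposed at the segment boundary their position coincides with; at
#' most one breakend is kept per boundary (later ones are dropped with a
#' warning).
#'
#' @param segments GRanges with metadata columns \code{readcount},
#'   \code{allele_a_readcount}, \code{allele_b_readcount} (optional) and
#'   \code{effective_length} (optional, defaults to width).
#' @param breakpoints breakpoint table (\code{\link{normalizeBreakpoints}}).
#' @param config \linkS4class{CloneCNConfig}.
#' @return an opaque model list consumed by \code{\link{buildChain}},
#'   \code{\link{sumProduct}} and \code{\link{fitCloneCN}}.
#' @export
makeChainModel <- function(segments, breakpoints = NULL, config = cloneCNConfig()) {
  ord <- order(match(as.character(GenomicRanges::seqnames(segments)),
                     GenomeInfoDb::seqlevels(segments)),
               GenomicRanges::start(segments))
  if (!identical(ord, seq_along(segments)))
    segments <- segments[ord]
  mc <- S4Vectors::mcols(segments)
  if (is.null(mc$readcount)) stop("segments need a readcount column")
  x <- as.numeric(mc$readcount)
  xa <- if (!is.null(mc$allele_a_readcount)) as.numeric(mc$allele_a_readcount) else numeric(length(x))
  xb <- if (!is.null(mc$allele_b_readcount)) as.numeric(mc$allele_b_readcount) else numeric(length(x))
  leff <- if (!is.null(mc$effective_length)) as.numeric(mc$effective_length)
          else as.numeric(GenomicRanges::width(segments))
  chrom <- as.character(GenomicRanges::seqnames(segments))
  chains <- split(seq_along(segments), factor(chrom, levels = unique(chrom)))
  for (idx in chains) {
    if (any(diff(segStart0(segments)[idx]) <= 0))
      stop("segments must be sorted and non-overlapping within chromosome")
  }
  states <- enumerateCNStates(config@cMax, config@nTumour)
  bStates <- enumerateBreakpointStates(config@bMax, config@nTumour)
  bp <- normalizeBreakpoints(breakpoints)

  # boundary map: boundary i of a chain sits between segments idx[i], idx[i+1]
  boundaryKey <- character(0)
  boundaryChain <- integer(0); boundaryPos <- integer(0)
  for (ci in seq_along(chains)) {
    idx <- chains[[ci]]
    if (length(idx) < 2) next
    left <- idx[-length(idx)]
    # boundary exists only where segments abut
    key <- posKey(chrom[left], segEnd0(segments)[left])
    boundaryKey <- c(boundaryKey, key)
    boundaryChain <- c(boundaryChain, rep(ci, length(left)))
    boundaryPos <- c(boundaryPos, seq_along(left))
  }
  bmap <- data.frame(key = boundaryKey, chain = boundaryChain,
                     pos = boundaryPos,
                     bpRow = rep(NA_integer_, length(boundaryKey)),
                     orientation = rep(NA_integer_, length(boundaryKey)),
                     stringsAsFactors = FALSE)
  if (nrow(bp)) {
    for (r in seq_len(nrow(bp))) {
      for (e in 1:2) {
        key <- posKey(bp[[paste0("chrom_", e)]][r], bp[[paste0("position_", e)]][r])
        j <- match(key, bmap$key)
        if (is.na(j)) next
        if (!is.na(bmap$bpRow[j])) {
          warning(sprintf("boundary %s already carries a breakend; ignoring breakend of breakpoint %s",
                          key, bp$id[r]))
          next
        }
        bmap$bpRow[j] <- r
        bmap$orientation[j] <- bp[[paste0("orientation_", e)]][r]
      }
    }
  }
  dhat <- sum(x) / sum(leff)   # observed genome-wide depth, a data constant
  list(segments = segments, x = x, xa = xa, xb = xb, leff = leff,
       outlierLogDens = defaultOutlierLogDensity(leff, dhat) - log(xa + xb + 1),
       l = as.numeric(GenomicRanges::width(segments)),
       chrom = chrom, chains = chains, states = states, bStates = bStates,
       tPlain = plainTelomereMatrix(states),
       tBpPlus = breakpointTelomereArray(states, bStates, +1),
       tBpMinus = breakpointTelomereArray(states, bStates, -1),
       # S^2 x B matrices for fast expectation contractions
       tBpPlusMat = vapply(breakpointTelomereArray(states, bStates, +1),
                           as.numeric, numeric(nrow(states)^2)),
       tBpMinusMat = vapply(breakpointTelomereArray(states, bStates, -1),
                            as.numeric, numeric(nrow(states)^2)),
       boundaries = bmap, breakpoints = bp, config = config)
}

emissionMatrix <- function(model, h, params = model$config@params) {
  famCode <- match(params@family, c("poisson", "negbin", "negbin_mixture")) - 1L
  od <- if (is.na(params@outlierLogDensity)) model$outlierLogDens
        else rep(params@outlierLogDensity, length(model$x))
  cpp_emission_matrix(model$x, model$xa, model$xb, model$leff, model$states,
                      h, famCode,
                      if (length(params@nbInvDispersion)) params@nbInvDispersion else 1,
                      params@nbMixWeight, params@alleleDispersion,
                      params@outlierWeight, od)
}

#' Build the chain terms of q(C)
#'
#' Emission terms are the segment emission log-likelihoods; transition terms
#' at breakend-free boundaries are \eqn{-\lambda t(c, c')} and at breakend
#' boundaries the expectation of \eqn{\log f(c, c', b | o, \lambda)} under
#' the current breakpoint posterior \eqn{q_k}.
#'
#' @param model from \code{\link{makeChainModel}}.
#' @param qks list (one per breakpoint row) of probability vectors over the
#'   joint breakpoint states; \code{NULL} for uniform.
#' @param h per-clone haploid depths.
#' @param params emission parameters (default from config).
#' @return list with per-chain emission/transition structures.
#' @export
buildChain <- function(model, qks = NULL, h, params = model$config@params) {
  lambda <- model$config@lambda
  nB <- nrow(model$bStates)
  if (is.null(qks))
    qks <- rep(list(rep(1 / nB, nB)), nrow(model$breakpoints))
  logEmit <- emissionMatrix(model, h, params)
  plainLog <- -lambda * model$tPlain
  transMats <- list(exp(plainLog))
  logTransMats <- list(plainLog)
  bmap <- model$boundaries
  bmap$matIdx <- rep(1L, nrow(bmap))
  act <- which(!is.na(bmap$bpRow))
  S <- nrow(model$states)
  for (j in act) {
    tMat <- if (bmap$orientation[j] == 1) model$tBpPlusMat else model$tBpMinusMat
    q <- qks[[bmap$bpRow[j]]]
    lm <- matrix(-lambda * (tMat %*% q), S, S)
    transMats[[length(transMats) + 1]] <- exp(lm)
    logTransMats[[length(logTransMats) + 1]] <- lm
    bmap$matIdx[j] <- length(transMats)
  }
  list(logEmit = logEmit, transMats = transMats, logTransMats = logTransMats,
       boundaries = bmap, qks = qks, h = h, params = params)
}

#' Sum-product (forward-backward) on the chain
#'
#' Computes single and pairwise posterior marginals of q(C) and the
#' log-partition of each chromosome chain, in scaled linear space.
#'
#' @param model from \code{\link{makeChainModel}}.
#' @param chain from \code{\link{buildChain}}.
#' @param pairAll also return pairwise marginals for breakend-free
#'   boundaries (used by tests; memory-heavy for long chains).
#' @return list: \code{gamma} (segments x states), \code{logZ},
#'   \code{eTrans} (expected transition score), \code{pairs} (list indexed
#'   by global boundary row of pairwise marginal matrices, breakend
#'   boundaries always included), \code{eEmis}.
#' @export
sumProduct <- function(model, chain, pairAll = FALSE) {
  S <- nrow(model$states)
  N <- length(model$x)
  gamma <- matrix(0, N, S)
  logZ <- 0; eTrans <- 0
  pairs <- vector("list", nrow(chain$boundaries))
  for (ci in seq_along(model$chains)) {
    idx <- model$chains[[ci]]
    brows <- which(chain$boundaries$chain == ci)
    transIdx <- chain$boundaries$matIdx[brows]
    wantLocal <- if (pairAll) seq_along(brows)
                 else which(!is.na(chain$boundaries$bpRow[brows]))
    fb <- cpp_chain_fb(chain$logEmit[idx, , drop = FALSE],
                       chain$transMats, chain$logTransMats,
                       as.integer(transIdx), as.integer(wantLocal))
    gamma[idx, ] <- fb$gamma
    logZ <- logZ + fb$logZ
    eTrans <- eTrans + fb$eTrans
    for (k in seq_along(wantLocal))
      pairs[[brows[wantLocal[k]]]] <- fb$pairs[[k]]
  }
  eEmis <- sum(gamma * chain$logEmit)
  list(gamma = gamma, logZ = logZ, eTrans = eTrans, pairs = pairs,
       eEmis = eEmis)
}

qkEntropy <- function(q) {
  q <- q[q > 0]
  -sum(q * log(q))
}

# Expected log transition factor per joint breakpoint state for breakpoint
# row k, summed over the boundaries carrying its breakends.
breakpointScores <- function(model, fb, k) {
  lambda <- model$config@lambda
  rows <- which(model$boundaries$bpRow == k)
  sc <- numeric(nrow(model$bStates))
  for (j in rows) {
    P <- fb$pairs[[j]]
    if (is.null(P)) next
    tMat <- if (model$boundaries$orientation[j] == 1) model$tBpPlusMat else model$tBpMinusMat
    sc <- sc - lambda * as.numeric(crossprod(tMat, as.numeric(P)))
  }
  sc
}

#' Variational update of one breakpoint's copy-number posterior
#'
#' \eqn{q_k(b) \propto \exp \sum_{n: k_n = k} \sum_{c, c'}
#' \gamma_n(c, c') \log f(c, c', b | o, \lambda)}.
#'
#' @param model chain model.
#' @param fb result of \code{\link{sumProduct}} (pairwise marginals at the
#'   breakpoint's boundaries are required).
#' @param k breakpoint row index.
#' @return list: \code{q} (probability vector over joint breakpoint
#'   states), \code{score} (the expected log-factor vector).
#' @export
updateBreakpointPosterior <- function(model, fb, k) {
  sc <- breakpointScores(model, fb, k)
  q <- exp(sc - logSumExp(sc))
  list(q = q / sum(q), score = sc)
}

#' M-step update of haploid depths (and optionally dispersions)
#'
#' Maximises \eqn{\sum_n \sum_c \gamma_n(c) \log p(x_n | c, h, l_n, \theta)}
#' by quasi-Newton ascent (L-BFGS-B, \eqn{h \ge 0}). The search runs on the
#' total-count part of the objective (exact when allele counts are absent);
#' the candidate is accepted only if the full expected emission
#' log-likelihood does not decrease, so the update never lowers the ELBO.
#'
#' @param model chain model.
#' @param gamma single marginals (segments x states).
#' @param h current haploid depths.
#' @param params current \linkS4class{LikelihoodParams}.
#' @param fitTheta also refit negative-binomial inverse-dispersions.
#' @param maxit L-BFGS-B iteration cap.
#' @param currentObjective full expected emission log-likelihood at
#'   (\code{h}, \code{params}) if already computed (saves one evaluation).
#' @return list: \code{h}, \code{params}, \code{objective} (full expected
#'   emission log-likelihood at the returned values), \code{improved}.
#' @export
updateDepths <- function(model, gamma, h, params = model$config@params,
                         fitTheta = model$config@fitTheta, maxit = 50L,
                         currentObjective = NULL) {
  states <- model$states
  tot <- totalCopies(states)
  tkey <- apply(tot, 1, paste, collapse = ",")
  uk <- !duplicated(tkey)
  tau <- tot[uk, , drop = FALSE]
  G <- outer(tkey, tkey[uk], "==") * 1
  W <- gamma %*% G                       # N x J weights on total-copy combos
  M <- length(h)
  famCode <- match(params@family, c("poisson", "negbin", "negbin_mixture")) - 1L
  od <- if (is.na(params@outlierLogDensity)) model$outlierLogDens
        else rep(params@outlierLogDensity, length(model$x))

  surrogate <- function(par) {
    hh <- par[seq_len(M)]
    pp <- params
    if (fitTheta && length(params@nbInvDispersion))
      pp@nbInvDispersion <- exp(par[-seq_len(M)])
    val <- cpp_weighted_total_loglik(
      model$x, model$leff, as.numeric(tau %*% hh), W, famCode,
      if (length(pp@nbInvDispersion)) pp@nbInvDispersion else 1,
      pp@nbMixWeight, pp@outlierWeight, od, 1e-10)
    if (!is.finite(val)) return(1e12)
    -val
  }
  exactObjective <- function(hh, pp) sum(gamma * emissionMatrix(model, hh, pp))

  par0 <- h
  lower <- rep(0, M)
  if (fitTheta && length(params@nbInvDispersion)) {
    par0 <- c(par0, log(params@nbInvDispersion))
    lower <- c(lower, rep(log(1e-3), length(params@nbInvDispersion)))
  }
  cur <- if (!is.null(currentObjective)) currentObjective
         else exactObjective(h, params)
  surrogateGrad <- function(par) {
    # central differences at a step fine enough for 1e-6-level optima
    vapply(seq_along(par), function(i) {
      hstep <- 1e-6 * max(abs(par[i]), 1e-4)
      up <- par; up[i] <- par[i] + hstep
      dn <- par; dn[i] <- max(par[i] - hstep, lower[i])
      (surrogate(up) - surrogate(dn)) / (up[i] - dn[i])
    }, numeric(1))
  }
  opt <- tryCatch(
    optim(par0, surrogate, gr = surrogateGrad, method = "L-BFGS-B",
          lower = lower, control = list(maxit = maxit, factr = 1e3)),
    error = function(e) NULL)
  if (is.null(opt))
    return(list(h = h, params = params, objective = cur, improved = FALSE))
  hNew <- opt$par[seq_len(M)]
  pNew <- params
  if (fitTheta && length(params@nbInvDispersion))
    pNew@nbInvDispersion <- exp(opt$par[-seq_len(M)])
  new <- exactObjective(hNew, pNew)
  if (is.finite(new) && new > cur)
    list(h = hNew, params = pNew, objective = new, improved = TRUE)
  else
    list(h = h, params = params, objective = cur, improved = FALSE)
}

#' Evidence lower bound of the current variational state
#'
#' With q(C) set to the exact chain posterior given the current breakpoint
#' posteriors and point estimates, the ELBO reduces to the chain
#' log-partition plus the entropies of the \eqn{q_k} (delta-factor
#' entropies are constant and omitted).
#'
#' @param model chain model.
#' @param h haploid depths.
#' @param qks list of breakpoint posteriors (\code{NULL} = uniform).
#' @param params emission parameters.
#' @return list: \code{elbo}, \code{fb} (sum-product result),
#'   \code{chain}.
#' @export
computeELBO <- function(model, h, qks = NULL, params = model$config@params) {
  chain <- buildChain(model, qks, h, params)
  fb <- sumProduct(model, chain)
  elbo <- fb$logZ + sum(vapply(chain$qks, qkEntropy, numeric(1)))
  list(elbo = elbo, fb = fb, chain = chain)
}
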
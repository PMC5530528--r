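# Coordinate-ascent driver: fit mixture, segment and breakpoint copy number.

# Candidate (normal depth, total tumour haploid depth) pairs scored by how
# well integer copy levels 2*h0 + c*hT explain the per-segment depths, with
# residuals truncated so subclonal/noisy segments cannot dominate. The best
# distinct candidates seed the restarts.
depthInitCandidates <- function(model, nCandidates = 4L, cMax = 8L) {
  d <- model$x / model$leff
  w <- model$leff / mean(model$leff)
  dbar <- sum(model$x) / sum(model$leff)
  h0s <- dbar * seq(0.025, 0.45, length.out = 24)
  hTs <- dbar * seq(0.05, 0.55, length.out = 40)
  cap <- (0.04 * dbar)^2
  grid <- expand.grid(h0 = h0s, hT = hTs)
  score <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    h0 <- grid$h0[i]; hT <- grid$hT[i]
    cc <- pmin(pmax(round((d - 2 * h0) / hT), 0), cMax)
    resid <- d - 2 * h0 - cc * hT
    # preference for parsimonious (lower) copy levels breaks the
    # halved-spacing (doubled-ploidy) degeneracy
    score[i] <- sum(w * pmin(resid^2, cap)) + 0.1 * cap * sum(w * cc)
  }
  ord <- order(score)
  chosen <- list()
  for (i in ord) {
    if (length(chosen) >= nCandidates) break
    ok <- all(vapply(chosen, function(ch) {
      abs(ch$h0 - grid$h0[i]) > 0.12 * dbar * 0.5 ||
        abs(ch$hT - grid$hT[i]) > 0.1 * dbar * 0.5
    }, logical(1)))
    if (ok) chosen[[length(chosen) + 1]] <- list(h0 = grid$h0[i], hT = grid$hT[i])
  }
  chosen
}

initialDepths <- function(model, normalFraction, cloneSplit, ploidyGuess = 2) {
  d <- sum(model$x) / sum(model$leff)   # reads per nucleotide, total
  nT <- model$config@nTumour
  scale <- d / (2 * normalFraction + ploidyGuess * (1 - normalFraction))
  if (nT == 1L) {
    h <- c(normalFraction, 1 - normalFraction) * scale
  } else {
    h <- c(normalFraction,
           (1 - normalFraction) * (1 - cloneSplit),
           (1 - normalFraction) * cloneSplit) * scale
  }
  pmax(h, 1e-12)
}

# One coordinate-ascent cycle; returns updated state with ELBO recordings.
ascentCycle <- function(model, state) {
  chain <- buildChain(model, state$qks, state$h, state$params)
  fb <- sumProduct(model, chain)
  HqC <- fb$logZ - fb$eEmis - fb$eTrans
  elboA <- fb$logZ + sum(vapply(chain$qks, qkEntropy, numeric(1)))
  trace <- c(state$trace, elboA)

  # breakpoint posterior updates (exact coordinate ascent)
  qks <- chain$qks
  dTrans <- 0; dEnt <- 0
  if (length(qks)) {
    for (k in seq_along(qks)) {
      up <- updateBreakpointPosterior(model, fb, k)
      dTrans <- dTrans + sum(up$q * up$score) - sum(qks[[k]] * up$score)
      dEnt <- dEnt + qkEntropy(up$q) - qkEntropy(qks[[k]])
      qks[[k]] <- up$q
    }
  }
  elboB <- elboA + dTrans + dEnt
  trace <- c(trace, elboB)

  # depth (and optional dispersion) update, guarded to never decrease
  up <- updateDepths(model, fb$gamma, state$h, state$params,
                     fitTheta = model$config@fitTheta, maxit = 6L,
                     currentObjective = fb$eEmis)
  elboC <- elboB + (up$objective - fb$eEmis)
  trace <- c(trace, elboC)

  list(h = up$h, params = up$params, qks = qks, trace = trace,
       elbo = elboC, gamma = fb$gamma, fb = fb, improvedH = up$improved)
}

runAscent <- function(model, state, nCycles, tol) {
  converged <- FALSE
  cycles <- state$cycles %||% 0
  for (it in seq_len(nCycles)) {
    prev <- state$elbo
    keep <- state[c("h", "params", "qks", "trace", "elbo")]
    state <- ascentCycle(model, keep)
    cycles <- cycles + 1
    if (!is.null(prev) && is.finite(prev)) {
      rel <- abs(state$elbo - prev) / max(1, abs(state$elbo))
      if (rel < tol) { converged <- TRUE; break }
    }
  }
  state$cycles <- cycles
  state$converged <- converged
  state
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit the clone mixture and copy-number model
#'
#' Structured variational expectation-maximisation: cycles of (i) exact
#' sum-product update of the segment copy-number chain q(C), (ii) updates of
#' every breakpoint copy-number posterior q_k, and (iii) a quasi-Newton
#' point-estimate update of the haploid depths h (and optionally the
#' dispersion parameters), iterated until the relative ELBO change falls
#' below \code{tol}. Each candidate initialisation from the configured grid
#' is run for \code{pilotIter} cycles and the best-ELBO restart is continued
#' to convergence. The fit is deterministic given its inputs.
#'
#' @param segments GRanges with \code{readcount}, optional allele counts
#'   and \code{effective_length} metadata columns.
#' @param breakpoints breakpoint table (may be \code{NULL} or empty).
#' @param config \linkS4class{CloneCNConfig}.
#' @return a \linkS4class{CloneCNFit}.
#' @export
fitCloneCN <- function(segments, breakpoints = NULL, config = cloneCNConfig()) {
  model <- makeChainModel(segments, breakpoints, config)
  splits <- if (config@nTumour == 2L) config@cloneSplits else 0
  dbar <- sum(model$x) / sum(model$leff)
  cand <- depthInitCandidates(model, nCandidates = 2L)
  # the integer-level lattice leaves h0 identified only up to shifts of
  # hT/2; expand each candidate and let the full model (allele ratios,
  # transitions) pick the right register by ELBO
  pairs <- list()
  for (ch in cand) for (k in 0:2) {
    h0 <- ch$h0 - k * ch$hT / 2
    nf <- 2 * h0 / dbar
    if (h0 > 1e-4 * dbar && nf > 0.05 && nf < 0.95)
      pairs[[length(pairs) + 1]] <- list(h0 = h0, hT = ch$hT)
  }
  inits <- list()
  for (ch in pairs) for (cs in splits) {
    h <- if (config@nTumour == 1L) c(ch$h0, ch$hT)
         else c(ch$h0, ch$hT * (1 - cs), ch$hT * cs)
    inits[[length(inits) + 1]] <- pmax(h, 1e-12)
  }
  inits <- inits[!duplicated(vapply(inits, function(h)
    paste(signif(h, 4), collapse = ","), character(1)))]
  if (!length(inits)) {
    # blind grid fallback when depth modes are degenerate
    grid <- unique(expand.grid(nf = config@normalFractions, cs = splits,
                               pg = config@ploidyGuesses))
    for (g in seq_len(nrow(grid)))
      inits[[length(inits) + 1]] <- initialDepths(model, grid$nf[g], grid$cs[g], grid$pg[g])
  }
  nB <- nrow(model$bStates)
  restarts <- vector("list", length(inits))
  for (g in seq_along(inits)) {
    st <- list(h = inits[[g]],
               params = config@params,
               qks = rep(list(rep(1 / nB, nB)), nrow(model$breakpoints)),
               trace = numeric(0), elbo = NULL)
    restarts[[g]] <- runAscent(model, st, config@pilotIter, config@tol)
  }
  elbos <- vapply(restarts, function(s) s$elbo, numeric(1))
  keep <- head(order(elbos, decreasing = TRUE), max(config@keepRestarts, 1L))
  finals <- lapply(keep, function(g) {
    s <- restarts[[g]]
    if (!s$converged && s$cycles < config@maxIter)
      s <- runAscent(model, s, config@maxIter - s$cycles, config@tol)
    s
  })
  fElbos <- vapply(finals, function(s) s$elbo, numeric(1))
  best <- keep[which.max(fElbos)]
  state <- finals[[which.max(fElbos)]]
  if (!state$converged)
    warning("coordinate ascent did not converge; reporting best state")
  buildFit(model, state, mode = "breakpoint",
           diagnostics = list(restartELBOs = elbos, bestRestart = best,
                              grid = grid))
}

buildFit <- function(model, state, mode, diagnostics = list()) {
  # final E-step at the converged parameters for reporting
  final <- computeELBO(model, state$h, state$qks, state$params)
  gamma <- final$fb$gamma
  pick <- max.col(gamma, ties.method = "first")  # states pre-sorted for ties
  st <- model$states
  nClone <- ncol(st) / 2
  segs <- model$segments
  S4Vectors::mcols(segs)$major <- st[pick, majorCols(st), drop = FALSE]
  S4Vectors::mcols(segs)$minor <- st[pick, minorCols(st), drop = FALSE]
  colnames(S4Vectors::mcols(segs)$major) <- paste0("clone_", seq_len(nClone))
  colnames(S4Vectors::mcols(segs)$minor) <- paste0("clone_", seq_len(nClone))
  S4Vectors::mcols(segs)$maxMarginalProb <- gamma[cbind(seq_len(nrow(gamma)), pick)]

  tot <- totalCopies(st)[pick, , drop = FALSE]
  mass <- as.numeric(t(tot) %*% model$l)      # S_m = sum_n l_n c_nm
  hS <- state$h * mass
  rho <- if (sum(hS) > 0) hS / sum(hS) else rep(NA_real_, nClone)

  bp <- model$breakpoints
  if (nrow(bp)) {
    qm <- do.call(rbind, state$qks)
    bpick <- max.col(qm, ties.method = "first")  # bStates sorted: ties -> smaller b
    cn <- model$bStates[bpick, , drop = FALSE]
    colnames(cn) <- paste0("cn_", seq_len(nClone))
    bp <- cbind(bp, as.data.frame(cn))
    bp$maxProb <- qm[cbind(seq_len(nrow(qm)), bpick)]
  }
  new("CloneCNFit", segments = segs, breakpoints = bp,
      h = state$h, rho = rho,
      elbo = final$elbo, elboTrace = c(state$trace, final$elbo),
      iterations = as.integer(state$cycles %||% 0L),
      converged = isTRUE(state$converged), mode = mode,
      posthoc = data.frame(), config = model$config,
      diagnostics = diagnostics)
}
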
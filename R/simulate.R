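# Genome-evolution simulator: ground-truthed two-clone mixtures.
#
# Histories are sequences of duplication, deletion and balanced
# rearrangement events applied to an initially diploid genome on a
# two-clone phylogeny (trunk events shared by both tumour clones,
# branch events private to the descendant). Histories are proposed at
# random, scored by the squared distance of realised (tumour ploidy,
# divergent proportion) from their targets, and the best of R proposals is
# kept (score-and-resample). Event endpoints live on the segment-bin grid,
# so every simulated breakend coincides with a segment boundary.

defaultChromLengths <- function(nChrom = 10, chromLength = 5e7) {
  setNames(rep(chromLength, nChrom), paste0("chr", seq_len(nChrom)))
}

#' Replay an event history into clone copy-number profiles
#'
#' Replay is deterministic: events add or subtract single copies of one
#' allele over bin-aligned intervals, so the stored truth is always exactly
#' reproducible from the history.
#'
#' @param events data.frame with columns \code{kind} (duplication,
#'   deletion, balanced), \code{lineage} (shared, descendant),
#'   \code{chrom}, \code{startBin}, \code{endBin}, \code{allele},
#'   \code{chrom2}, \code{bin2}, \code{wholeChrom}.
#' @param chromLengths named chromosome lengths.
#' @param binSize bin size (bp).
#' @return list: \code{cn} (bins x 4 matrix: ancestral/descendant x
#'   allele 1/2), \code{bins} data.frame, \code{breakpoints} truth table,
#'   \code{ploidy}, \code{divergentProportion}.
#' @export
replayHistory <- function(events, chromLengths, binSize = 5e5) {
  nBins <- ceiling(chromLengths / binSize)
  offset <- cumsum(c(0, head(nBins, -1)))
  names(offset) <- names(chromLengths)
  total <- sum(nBins)
  cn <- matrix(1L, total, 4,
               dimnames = list(NULL, c("anc_1", "anc_2", "desc_1", "desc_2")))
  bins <- data.frame(
    chrom = rep(names(chromLengths), nBins),
    bin = unlist(lapply(nBins, function(k) seq_len(k) - 1)),
    stringsAsFactors = FALSE)
  bins$start <- bins$bin * binSize
  bins$end <- pmin(bins$start + binSize, chromLengths[bins$chrom])
  nEv <- nrow(events)
  bId <- character(nEv); bC1 <- character(nEv); bP1 <- numeric(nEv)
  bO1 <- integer(nEv); bC2 <- character(nEv); bP2 <- numeric(nEv)
  bO2 <- integer(nEv); bAnc <- integer(nEv); bKind <- character(nEv)
  bLin <- character(nEv); hasBp <- logical(nEv)
  for (r in seq_len(nEv)) {
    kind <- events$kind[r]; lineage <- events$lineage[r]
    shared <- lineage == "shared"
    if (kind == "balanced") {
      hasBp[r] <- TRUE
      bId[r] <- sprintf("bp_%03d", r)
      bC1[r] <- events$chrom[r]; bP1[r] <- events$startBin[r] * binSize; bO1[r] <- 1L
      bC2[r] <- events$chrom2[r]; bP2[r] <- events$bin2[r] * binSize; bO2[r] <- -1L
      bAnc[r] <- as.integer(shared); bKind[r] <- kind; bLin[r] <- lineage
      next
    }
    idx <- offset[events$chrom[r]] + seq.int(events$startBin[r] + 1, events$endBin[r])
    delta <- if (kind == "duplication") 1L else -1L
    cols <- if (shared) c(events$allele[r], events$allele[r] + 2L)
            else events$allele[r] + 2L
    cn[idx, cols] <- cn[idx, cols] + delta
    if (any(cn[idx, cols] < 0)) stop("invalid history: negative copy number")
    if (!events$wholeChrom[r]) {
      # junction: duplication joins interval end back to its start;
      # deletion joins flank before start to flank after end
      hasBp[r] <- TRUE
      bId[r] <- sprintf("bp_%03d", r)
      bC1[r] <- events$chrom[r]; bC2[r] <- events$chrom[r]
      if (kind == "duplication") {
        bP1[r] <- events$endBin[r] * binSize; bP2[r] <- events$startBin[r] * binSize
      } else {
        bP1[r] <- events$startBin[r] * binSize; bP2[r] <- events$endBin[r] * binSize
      }
      bO1[r] <- 1L; bO2[r] <- -1L
      bAnc[r] <- as.integer(shared); bKind[r] <- kind; bLin[r] <- lineage
    }
  }
  bp <- data.frame(id = bId[hasBp], chrom_1 = bC1[hasBp], position_1 = bP1[hasBp],
                   orientation_1 = bO1[hasBp], chrom_2 = bC2[hasBp],
                   position_2 = bP2[hasBp], orientation_2 = bO2[hasBp],
                   cn_anc = bAnc[hasBp], cn_desc = rep(1L, sum(hasBp)),
                   kind = bKind[hasBp], lineage = bLin[hasBp],
                   stringsAsFactors = FALSE)
  w <- bins$end - bins$start
  ploidyAnc <- sum((cn[, "anc_1"] + cn[, "anc_2"]) * w) / sum(w)
  ploidyDesc <- sum((cn[, "desc_1"] + cn[, "desc_2"]) * w) / sum(w)
  divergent <- sum(w * (cn[, "anc_1"] != cn[, "desc_1"] |
                        cn[, "anc_2"] != cn[, "desc_2"])) / sum(w)
  list(cn = cn, bins = bins, breakpoints = bp,
       ploidy = mean(c(ploidyAnc, ploidyDesc)),
       divergentProportion = divergent)
}

proposeHistory <- function(nEvents, chromLengths, binSize, maxTotalCopy = 6L) {
  nBins <- ceiling(chromLengths / binSize)
  chroms <- names(chromLengths)
  pDup <- runif(1, 0.35, 0.65)
  pBal <- 0.2
  pWhole <- runif(1, 0.05, 0.3)
  descShare <- runif(1, 0.25, 0.6)
  nDesc <- round(descShare * nEvents)
  lineage <- rep("shared", nEvents)
  if (nDesc > 0) lineage[sample.int(nEvents, min(nDesc, nEvents))] <- "descendant"
  used <- character(0)   # occupied boundary keys chrom:bin
  cnSim <- matrix(1L, sum(nBins), 4)
  offset <- cumsum(c(0, head(nBins, -1))); names(offset) <- chroms
  kindV <- character(nEvents); chromV <- character(nEvents)
  sBinV <- integer(nEvents); eBinV <- integer(nEvents)
  alleleV <- rep(NA_integer_, nEvents); chrom2V <- rep(NA_character_, nEvents)
  bin2V <- rep(NA_integer_, nEvents); wholeV <- logical(nEvents)
  placedV <- logical(nEvents)
  for (i in seq_len(nEvents)) {
    for (try in 1:25) {
      u <- runif(1)
      kind <- if (u < pBal) "balanced" else if (u < pBal + pDup) "duplication" else "deletion"
      if (kind == "balanced") {
        c1 <- sample(chroms, 1); c2 <- sample(chroms, 1)
        if (nBins[c1] < 3 || nBins[c2] < 3) next
        b1 <- sample.int(nBins[c1] - 1, 1); b2 <- sample.int(nBins[c2] - 1, 1)
        k1 <- paste0(c1, ":", b1); k2 <- paste0(c2, ":", b2)
        if (k1 == k2 || k1 %in% used || k2 %in% used) next
        kindV[i] <- kind; chromV[i] <- c1; sBinV[i] <- b1; eBinV[i] <- b1
        chrom2V[i] <- c2; bin2V[i] <- b2
        used <- c(used, k1, k2)
        placedV[i] <- TRUE; break
      }
      ch <- sample(chroms, 1)
      nb <- nBins[ch]
      whole <- runif(1) < pWhole
      if (whole) {
        sBin <- 0; eBin <- nb
      } else {
        if (nb < 4) next
        lenBins <- max(1, round(runif(1, 0.05, 0.4) * nb))
        if (lenBins > nb - 2) next
        sBin <- sample.int(nb - lenBins - 1, 1)   # interior boundaries
        eBin <- sBin + lenBins
        k1 <- paste0(ch, ":", sBin); k2 <- paste0(ch, ":", eBin)
        if (k1 %in% used || k2 %in% used) next
      }
      idx <- offset[ch] + seq.int(sBin + 1, eBin)
      cols <- if (lineage[i] == "shared") 1:4 else 3:4
      placed <- FALSE
      for (al in sample(1:2)) {
        cc <- intersect(cols, c(al, al + 2))
        ok <- if (kind == "deletion") all(cnSim[idx, cc] >= 1)
              else {
                tots <- cnSim[idx, intersect(cols, c(1, 3)), drop = FALSE] +
                        cnSim[idx, intersect(cols, c(2, 4)), drop = FALSE]
                max(tots) < maxTotalCopy
              }
        if (ok) {
          delta <- if (kind == "duplication") 1L else -1L
          cnSim[idx, cc] <- cnSim[idx, cc] + delta
          kindV[i] <- kind; chromV[i] <- ch; sBinV[i] <- sBin; eBinV[i] <- eBin
          alleleV[i] <- al; wholeV[i] <- whole
          if (!whole) used <- c(used, paste0(ch, ":", sBin), paste0(ch, ":", eBin))
          placed <- TRUE
          break
        }
      }
      if (placed) { placedV[i] <- TRUE; break }
    }
  }
  data.frame(kind = kindV, lineage = lineage, chrom = chromV, startBin = sBinV,
             endBin = eBinV, allele = alleleV, chrom2 = chrom2V, bin2 = bin2V,
             wholeChrom = wholeV, stringsAsFactors = FALSE)[placedV, ]
}

#' Sample a scored evolutionary history
#'
#' Proposes \code{nProposals} random histories, replays each, scores the
#' realised tumour ploidy and divergent proportion against the targets by
#' squared error, and keeps the best.
#'
#' @param nEvents events per history (default 50).
#' @param targetPloidy target mean tumour ploidy.
#' @param targetDivergent target divergent genome proportion.
#' @param normalFraction fraction of normal cells.
#' @param descendantFraction descendant clone fraction within the tumour.
#' @param chromLengths named chromosome lengths (default 10 x 50 Mb).
#' @param binSize segment bin size (default 500 kb).
#' @param nProposals proposals scored (default 100).
#' @param seed RNG seed; the returned truth is a deterministic function of
#'   the arguments.
#' @return a \linkS4class{SimulatedTruth} (haploid depths are filled in by
#'   \code{\link{simulateReadCounts}}).
#' @export
sampleHistory <- function(nEvents = 50, targetPloidy = 2.5, targetDivergent = 0.2,
                          normalFraction = 0.5, descendantFraction = 0.3,
                          chromLengths = defaultChromLengths(), binSize = 5e5,
                          nProposals = 100, seed = 1L) {
  withr::with_seed(seed, {
    best <- NULL; bestScore <- Inf; bestEvents <- NULL
    for (r in seq_len(max(nProposals, 1))) {
      ev <- if (nEvents > 0) proposeHistory(nEvents, chromLengths, binSize)
            else data.frame()
      rp <- replayHistory(
        if (is.null(ev)) data.frame() else ev, chromLengths, binSize)
      score <- (rp$ploidy - targetPloidy)^2 + (rp$divergentProportion - targetDivergent)^2
      if (score < bestScore) { bestScore <- score; best <- rp; bestEvents <- ev }
      if (nEvents == 0) break
    }
  })
  if (bestScore > 0.1^2 * 2 && nEvents > 0)
    warning("history targets not closely attained; returning best-scoring proposal")
  buildTruth(best, bestEvents, chromLengths, binSize,
             normalFraction, descendantFraction, seed)
}

buildTruth <- function(rp, events, chromLengths, binSize,
                       normalFraction, descendantFraction, seed) {
  segs <- grFromZeroBased(rp$bins$chrom, rp$bins$start, rp$bins$end,
                          seqlengths = chromLengths)
  major <- cbind(clone_1 = 1L, clone_2 = rp$cn[, "anc_1"], clone_3 = rp$cn[, "desc_1"])
  minor <- cbind(clone_1 = 1L, clone_2 = rp$cn[, "anc_2"], clone_3 = rp$cn[, "desc_2"])
  S4Vectors::mcols(segs)$major <- major   # phased allele 1
  S4Vectors::mcols(segs)$minor <- minor   # phased allele 2
  S4Vectors::mcols(segs)$length <- GenomicRanges::width(segs)
  cf <- c(normal = normalFraction,
          ancestral = (1 - normalFraction) * (1 - descendantFraction),
          descendant = (1 - normalFraction) * descendantFraction)
  bp <- rp$breakpoints
  if (nrow(bp)) {
    bp$cn_1 <- 0L
    bp$cn_2 <- bp$cn_anc
    bp$cn_3 <- bp$cn_desc
  }
  new("SimulatedTruth", segments = segs, breakpoints = bp,
      chromLengths = unlist(chromLengths), binSize = binSize,
      normalFraction = normalFraction, descendantFraction = descendantFraction,
      cellFractions = cf, h = rep(NA_real_, 3),
      ploidy = rp$ploidy, divergentProportion = rp$divergentProportion,
      events = if (is.null(events)) data.frame() else events, seed = as.integer(seed))
}

#' Simulate segment read counts from a truth
#'
#' Draws per-segment total counts from the configured likelihood family at
#' the expected count implied by the true copy numbers and the haploid
#' depths derived from coverage and cell fractions, then allele counts from
#' the beta-binomial allele model. Outliers are drawn from the same flat
#' component the likelihood uses. The breakpoint table lists the true
#' breakpoints, optionally plus false positives at unused boundaries.
#'
#' @param truth a \linkS4class{SimulatedTruth}.
#' @param coverage haploid-equivalent genome coverage (X); converted to
#'   read pairs per nucleotide assuming 2 x 100 bp pairs.
#' @param params \linkS4class{LikelihoodParams} used as the generative
#'   model.
#' @param alleleRate fraction of read pairs informative for allele phase.
#' @param fpRate expected false-positive breakpoints per true breakpoint.
#' @param seed RNG seed.
#' @return list: \code{segments} (GRanges with count columns),
#'   \code{breakpoints} (input table for fitting), \code{truth} (with
#'   haploid depths filled).
#' @export
simulateReadCounts <- function(truth, coverage = 40, params = likelihoodParams(),
                               alleleRate = 0.2, fpRate = 0, seed = 1L) {
  d <- coverage / 200                     # read pairs per nucleotide, diploid
  h <- d / 2 * truth@cellFractions
  names(h) <- NULL
  segs <- truth@segments
  mc <- S4Vectors::mcols(segs)
  tot <- mc$major + mc$minor
  alleleA <- mc$major
  l <- as.numeric(GenomicRanges::width(segs))
  mu <- l * as.numeric(tot %*% h)
  pA <- ifelse(mu > 0, l * as.numeric(alleleA %*% h) / mu, 0.5)
  n <- length(segs)
  withr::with_seed(seed, {
    x <- switch(params@family,
      poisson = rpois(n, mu),
      negbin = rnbinom(n, size = params@nbInvDispersion[1], mu = mu),
      negbin_mixture = {
        comp <- rbinom(n, 1, params@nbMixWeight) + 1
        rnbinom(n, size = params@nbInvDispersion[comp], mu = mu)
      })
    isOut <- rep(FALSE, n)
    if (params@outlierWeight > 0) {
      K <- 10 * (l * 2 * sum(h) + 10)
      isOut <- rbinom(n, 1, params@outlierWeight) == 1
      x[isOut] <- floor(runif(sum(isOut)) * K[isOut])
    }
    nab <- rbinom(n, x, alleleRate)
    rho <- params@alleleDispersion
    if (rho > 0) {
      s <- (1 - rho) / rho
      pDraw <- rbeta(n, pmax(pA * s, 1e-9), pmax((1 - pA) * s, 1e-9))
    } else pDraw <- pA
    xa <- rbinom(n, nab, pDraw)
    # outliers are flat over the joint (total, allele) observation
    xa[isOut] <- floor(runif(sum(isOut)) * (nab[isOut] + 1))
    cols <- c("id", "chrom_1", "position_1", "orientation_1",
              "chrom_2", "position_2", "orientation_2")
    bpFit <- if (nrow(truth@breakpoints)) truth@breakpoints[, cols]
             else truth@breakpoints
    if (fpRate > 0 && nrow(bpFit)) {
      nFp <- rpois(1, fpRate * nrow(bpFit))
      if (nFp > 0) bpFit <- rbind(bpFit, randomFalseBreakpoints(truth, nFp))
    }
  })
  S4Vectors::mcols(segs)$readcount <- as.integer(x)
  S4Vectors::mcols(segs)$allele_a_readcount <- as.integer(xa)
  S4Vectors::mcols(segs)$allele_b_readcount <- as.integer(nab - xa)
  S4Vectors::mcols(segs)$effective_length <- l
  truth@h <- h
  rownames(bpFit) <- NULL
  list(segments = segs, breakpoints = bpFit, truth = truth)
}

randomFalseBreakpoints <- function(truth, nFp) {
  chroms <- names(truth@chromLengths)
  nBins <- ceiling(truth@chromLengths / truth@binSize)
  usedKeys <- with(truth@breakpoints,
                   c(posKey(chrom_1, position_1), posKey(chrom_2, position_2)))
  out <- list()
  while (length(out) < nFp) {
    c1 <- sample(chroms, 1); c2 <- sample(chroms, 1)
    p1 <- sample.int(nBins[c1] - 1, 1) * truth@binSize
    p2 <- sample.int(nBins[c2] - 1, 1) * truth@binSize
    k <- c(posKey(c1, p1), posKey(c2, p2))
    if (any(k %in% usedKeys) || k[1] == k[2]) next
    usedKeys <- c(usedKeys, k)
    out[[length(out) + 1]] <- data.frame(
      id = sprintf("fp_%03d", length(out) + 1),
      chrom_1 = c1, position_1 = p1, orientation_1 = sample(c(-1L, 1L), 1),
      chrom_2 = c2, position_2 = p2, orientation_2 = sample(c(-1L, 1L), 1),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Simulate a complete ground-truthed dataset
#'
#' Convenience wrapper: \code{\link{sampleHistory}} followed by
#' \code{\link{simulateReadCounts}}. All arguments of both are accepted.
#'
#' @param seed RNG seed driving both stages.
#' @param coverage,params,alleleRate,fpRate passed to
#'   \code{\link{simulateReadCounts}}.
#' @param ... passed to \code{\link{sampleHistory}}.
#' @return list: \code{segments}, \code{breakpoints}, \code{truth}.
#' @export
simulateMixture <- function(seed = 1L, coverage = 40, params = likelihoodParams(),
                            alleleRate = 0.2, fpRate = 0, ...) {
  truth <- sampleHistory(..., seed = seed)
  simulateReadCounts(truth, coverage = coverage, params = params,
                     alleleRate = alleleRate, fpRate = fpRate,
                     seed = seed + 1000L)
}
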
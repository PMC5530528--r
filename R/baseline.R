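# Breakpoint-naive baseline: the same chain with breakpoint copy number
# clamped to zero, followed by greedy post-hoc breakpoint assignment.

#' Fit the breakpoint-naive baseline model
#'
#' Runs the identical variational pipeline with breakpoint copy number
#' clamped to zero (\code{bMax = 0}), so every boundary uses the plain
#' telomere transition factor, then assigns breakpoint copy numbers post
#' hoc with \code{\link{greedyBreakpointCopies}}.
#'
#' @inheritParams fitCloneCN
#' @return a \linkS4class{CloneCNFit} with \code{mode = "naive"} and the
#'   greedy assignments in the \code{posthoc} slot (also merged into the
#'   breakpoint table's \code{cn_*} columns).
#' @export
fitCloneCNNaive <- function(segments, breakpoints = NULL, config = cloneCNConfig()) {
  cfg0 <- config
  cfg0@bMax <- 0L
  fit <- fitCloneCN(segments, breakpoints, cfg0)
  fit@mode <- "naive"
  fit@config <- config
  bp <- normalizeBreakpoints(breakpoints)
  if (nrow(bp)) {
    ph <- greedyBreakpointCopies(fit@segments, bp, bMax = config@bMax)
    fit@posthoc <- ph
    nClone <- ncol(S4Vectors::mcols(fit@segments)$major)
    for (m in seq_len(nClone))
      fit@breakpoints[[paste0("cn_", m)]] <- ph[[paste0("cn_", m)]]
  }
  fit
}

boundaryStateLookup <- function(segments) {
  chrom <- as.character(GenomicRanges::seqnames(segments))
  major <- S4Vectors::mcols(segments)$major
  minor <- S4Vectors::mcols(segments)$minor
  key <- posKey(chrom, segEnd0(segments))
  nextKey <- posKey(chrom, segStart0(segments))
  list(chrom = chrom, major = major, minor = minor,
       endKey = key, startKey = nextKey)
}

# telomere count at one boundary for fixed flanking copies and per-clone b
boundaryTelomeres <- function(lhMajor, lhMinor, rhMajor, rhMinor, b, o) {
  t <- 0
  for (m in seq_along(b)) {
    onMajor <- abs(lhMajor[m] - rhMajor[m] - o * b[m]) + abs(lhMinor[m] - rhMinor[m])
    onMinor <- abs(lhMajor[m] - rhMajor[m]) + abs(lhMinor[m] - rhMinor[m] - o * b[m])
    t <- t + min(onMajor, onMinor)
  }
  t
}

#' Greedy post-hoc breakpoint copy-number assignment
#'
#' Given fixed integer segment copy numbers, assigns each breakpoint, per
#' clone independently, the copy number in \code{0..bMax} that minimises
#' the summed telomere count at its two breakend boundaries (exhaustive per
#' breakpoint, greedy over breakpoints in input order; ties take the
#' smaller copy number). Breakends that do not coincide with an internal
#' segment boundary contribute nothing.
#'
#' @param segments GRanges with \code{major}/\code{minor} matrix columns
#'   (as in a \linkS4class{CloneCNFit}).
#' @param breakpoints breakpoint table.
#' @param bMax per-clone cap.
#' @return data.frame with breakpoint id, per-clone \code{cn_m}, and the
#'   summed boundary telomere count before (\code{t0}) and after
#'   (\code{t1}) assignment.
#' @export
greedyBreakpointCopies <- function(segments, breakpoints, bMax = 2L) {
  bp <- normalizeBreakpoints(breakpoints)
  lk <- boundaryStateLookup(segments)
  nClone <- ncol(lk$major)
  out <- data.frame(id = bp$id, stringsAsFactors = FALSE)
  cn <- matrix(0L, nrow(bp), nClone)
  t0 <- numeric(nrow(bp)); t1 <- numeric(nrow(bp))
  for (r in seq_len(nrow(bp))) {
    ends <- list()
    for (e in 1:2) {
      key <- posKey(bp[[paste0("chrom_", e)]][r], bp[[paste0("position_", e)]][r])
      li <- match(key, lk$endKey); ri <- match(key, lk$startKey)
      if (is.na(li) || is.na(ri)) next
      if (lk$chrom[li] != lk$chrom[ri]) next
      ends[[length(ends) + 1]] <- list(li = li, ri = ri,
                                       o = bp[[paste0("orientation_", e)]][r])
    }
    bestB <- rep(0L, nClone)
    for (m in seq_len(nClone)) {
      cost <- vapply(0:bMax, function(bv) {
        sum(vapply(ends, function(en) {
          bVec <- rep(0L, nClone); bVec[m] <- bv
          boundaryTelomeres(lk$major[en$li, ], lk$minor[en$li, ],
                            lk$major[en$ri, ], lk$minor[en$ri, ], bVec, en$o)
        }, numeric(1)))
      }, numeric(1))
      bestB[m] <- which.min(cost) - 1L   # which.min takes first -> smaller b
    }
    zero <- rep(0L, nClone)
    tAt <- function(bv) sum(vapply(ends, function(en)
      boundaryTelomeres(lk$major[en$li, ], lk$minor[en$li, ],
                        lk$major[en$ri, ], lk$minor[en$ri, ], bv, en$o), numeric(1)))
    t0[r] <- tAt(zero)
    t1[r] <- tAt(bestB)
    cn[r, ] <- bestB
  }
  for (m in seq_len(nClone)) out[[paste0("cn_", m)]] <- cn[, m]
  out$t0 <- t0; out$t1 <- t1
  out
}
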
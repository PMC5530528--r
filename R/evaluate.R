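# Accuracy scoring against simulated truth, clone tracking, and
# tumour-chromosome assembly from subclonal breakpoints.

sortedPairs <- function(major, minor) {
  list(hi = pmax(major, minor), lo = pmin(major, minor))
}

#' Score a fit against simulated truth
#'
#' Length-weighted proportion of the genome with correct clone-specific
#' (allele-sorted) copy number under the best permutation of tumour clone
#' labels; proportion of breakpoints with exactly correct per-clone copy
#' number under the same permutation; and relative/absolute errors of the
#' normal fraction, minor clone fraction, mean tumour ploidy and divergent
#' proportion.
#'
#' @param fit a \linkS4class{CloneCNFit}.
#' @param truth a \linkS4class{SimulatedTruth} on the same segmentation.
#' @return one-row data.frame.
#' @export
scoreFit <- function(fit, truth) {
  fs <- fit@segments; ts <- truth@segments
  if (length(fs) != length(ts) ||
      any(GenomicRanges::start(fs) != GenomicRanges::start(ts)) ||
      any(as.character(GenomicRanges::seqnames(fs)) != as.character(GenomicRanges::seqnames(ts))))
    stop("fit and truth use different segmentations")
  w <- as.numeric(GenomicRanges::width(fs))
  fM <- S4Vectors::mcols(fs)$major; fm <- S4Vectors::mcols(fs)$minor
  tM <- S4Vectors::mcols(ts)$major; tm <- S4Vectors::mcols(ts)$minor
  nTf <- ncol(fM) - 1
  tumourT <- 2:3
  perms <- if (nTf == 1) list(c(2, 2)) else list(c(2, 3), c(3, 2))

  f <- sortedPairs(fM, fm); t_ <- sortedPairs(tM, tm)
  accFor <- function(perm) {
    ok <- rep(TRUE, length(fs))
    for (j in seq_along(tumourT)) {
      tc <- tumourT[j]; fc <- perm[j]
      ok <- ok & f$hi[, fc] == t_$hi[, tc] & f$lo[, fc] == t_$lo[, tc]
    }
    sum(w[ok]) / sum(w)
  }
  accs <- vapply(perms, accFor, numeric(1))
  best <- which.max(accs)
  perm <- perms[[best]]

  bpAcc <- NA_real_
  tb <- truth@breakpoints; fb <- fit@breakpoints
  if (nrow(tb) && nrow(fb) && all(paste0("cn_", 2:3) %in% names(tb))) {
    m <- match(tb$id, fb$id)
    okbp <- vapply(seq_len(nrow(tb)), function(r) {
      if (is.na(m[r])) return(FALSE)
      all(vapply(seq_along(tumourT), function(j) {
        fcol <- paste0("cn_", perm[j]); tcol <- paste0("cn_", tumourT[j])
        fb[[fcol]][m[r]] == tb[[tcol]][r]
      }, logical(1)))
    }, logical(1))
    bpAcc <- mean(okbp)
  }

  # haploid depths are proportional to cell counts, so cell fractions are
  # h / sum(h); rho is the read-mass fraction and differs when ploidy != 2
  cfE <- fit@h / sum(fit@h)
  cf <- truth@cellFractions
  relerr <- function(e, s) if (s != 0) abs(e - s) / s else abs(e - s)
  nfE <- cfE[1]; nfS <- cf[[1]]
  minorE <- if (nTf == 1) min(cfE[-1]) else min(cfE[2:3])
  minorS <- min(cf[2:3])

  tumTotF <- (fM + fm)[, perm, drop = FALSE]
  ploidyE <- mean(colSums(tumTotF * w) / sum(w))
  divE <- sum(w * (f$hi[, perm[1]] != f$hi[, perm[2]] |
                   f$lo[, perm[1]] != f$lo[, perm[2]])) / sum(w)

  data.frame(
    segmentAccuracy = accs[best],
    breakpointAccuracy = bpAcc,
    normalFractionError = relerr(nfE, nfS),
    normalFractionAbsError = abs(nfE - nfS),
    minorCloneFractionError = relerr(minorE, minorS),
    minorCloneFractionAbsError = abs(minorE - minorS),
    ploidyError = relerr(ploidyE, truth@ploidy),
    divergentProportionError = relerr(divE, truth@divergentProportion),
    permutation = paste(perm, collapse = ","))
}

#' Clonal prevalence of each breakpoint
#'
#' The prevalence of a breakpoint is the tumour fraction carrying it:
#' \eqn{\sum_{m: b_{km} > 0} \rho_m / \sum_{tumour\,m} \rho_m}.
#'
#' @param fit a \linkS4class{CloneCNFit}.
#' @return named numeric vector (by breakpoint id).
#' @export
breakpointPrevalence <- function(fit) {
  bp <- fit@breakpoints
  if (!nrow(bp)) return(setNames(numeric(0), character(0)))
  rho <- fit@rho
  tum <- seq_along(rho)[-1]
  cn <- as.matrix(bp[, paste0("cn_", tum), drop = FALSE])
  prev <- as.numeric((cn > 0) %*% rho[tum]) / sum(rho[tum])
  setNames(prev, bp$id)
}

#' Classify clonal dynamics of breakpoints across samples
#'
#' Compares breakpoint clonal prevalence in a reference sample against two
#' replicate follow-up samples: ascending if prevalence rises in both,
#' descending if it falls in both, stable if unchanged (within \code{tol})
#' in at least one, conflicting otherwise. Breakpoints missing from a
#' sample count as prevalence zero.
#'
#' @param s1,s2a,s2b named prevalence vectors
#'   (\code{\link{breakpointPrevalence}}) or \linkS4class{CloneCNFit}s.
#' @param tol prevalence change regarded as no change (default 0.02).
#' @return data.frame with id, the three prevalences, and \code{label}.
#' @export
classifyClonalDynamics <- function(s1, s2a, s2b, tol = 0.02) {
  toPrev <- function(x) if (is(x, "CloneCNFit")) breakpointPrevalence(x) else x
  s1 <- toPrev(s1); s2a <- toPrev(s2a); s2b <- toPrev(s2b)
  ids <- unique(c(names(s1), names(s2a), names(s2b)))
  at <- function(v, id) ifelse(id %in% names(v), v[id], 0)
  p1 <- at(s1, ids); pa <- at(s2a, ids); pb <- at(s2b, ids)
  da <- pa - p1; db <- pb - p1
  label <- ifelse(da > tol & db > tol, "ascending",
           ifelse(da < -tol & db < -tol, "descending",
           ifelse(abs(da) <= tol | abs(db) <= tol, "stable", "conflicting")))
  data.frame(id = ids, prev_s1 = as.numeric(p1), prev_s2a = as.numeric(pa),
             prev_s2b = as.numeric(pb), label = label, stringsAsFactors = FALSE)
}

#' Merge adjacent segments with identical clone copy-number divergence
#'
#' Drops segments shorter than \code{smoothLength}, then merges runs of
#' adjacent segments whose inter-clone allele-copy difference is identical.
#'
#' @param fit a \linkS4class{CloneCNFit} with two tumour clones.
#' @param smoothLength minimum segment length retained before merging.
#' @return data.frame of merged segments with divergence annotation.
#' @export
mergeDivergentSegments <- function(fit, smoothLength = 1e5) {
  segs <- fit@segments
  keep <- GenomicRanges::width(segs) >= smoothLength
  segs <- segs[keep]
  M <- S4Vectors::mcols(segs)$major; m <- S4Vectors::mcols(segs)$minor
  chrom <- as.character(GenomicRanges::seqnames(segs))
  dM <- M[, 2] - M[, 3]; dm <- m[, 2] - m[, 3]
  key <- paste(chrom, dM, dm)
  run <- cumsum(c(TRUE, key[-1] != key[-length(key)]))
  s0 <- segStart0(segs); e0 <- segEnd0(segs)
  tot2 <- M[, 2] + m[, 2]; tot3 <- M[, 3] + m[, 3]
  out <- data.frame(
    chrom = tapply(chrom, run, `[`, 1),
    start = as.numeric(tapply(s0, run, min)),
    end = as.numeric(tapply(e0, run, max)),
    dMajor = as.numeric(tapply(dM, run, `[`, 1)),
    dMinor = as.numeric(tapply(dm, run, `[`, 1)),
    maxTotal = as.numeric(tapply(pmax(tot2, tot3), run, max)),
    stringsAsFactors = FALSE)
  out$length <- out$end - out$start
  out$divergent <- out$dMajor != 0 | out$dMinor != 0
  rownames(out) <- NULL
  out
}

#' Select high-confidence subclonal breakpoints
#'
#' After smoothing (<\code{smoothLength} segments dropped) and merging of
#' equal-divergence runs, keeps breakpoints that are predicted subclonal
#' (tumour-clone copy numbers differ, at least one positive) and whose both
#' breakends adjoin a merged divergent segment of length at least
#' \code{minLength} with total copy number at most \code{maxCopy}.
#'
#' @param fit a \linkS4class{CloneCNFit}.
#' @param smoothLength segment smoothing threshold (default 100 kb).
#' @param minLength minimum merged segment length (default 1 Mb).
#' @param maxCopy maximum total copy number of supporting segments.
#' @return the filtered breakpoint data.frame.
#' @export
selectConfidentSubclonal <- function(fit, smoothLength = 1e5, minLength = 1e6,
                                     maxCopy = 4) {
  bp <- fit@breakpoints
  if (!nrow(bp)) return(bp)
  merged <- mergeDivergentSegments(fit, smoothLength)
  keptSegs <- merged[merged$divergent & merged$length >= minLength &
                     merged$maxTotal <= maxCopy, , drop = FALSE]
  sub <- bp$cn_2 != bp$cn_3 & (bp$cn_2 > 0 | bp$cn_3 > 0)
  adjoins <- function(chrom, pos) {
    any(keptSegs$chrom == chrom & keptSegs$start <= pos & keptSegs$end >= pos)
  }
  ok <- vapply(seq_len(nrow(bp)), function(r) {
    sub[r] &&
      adjoins(bp$chrom_1[r], bp$position_1[r]) &&
      adjoins(bp$chrom_2[r], bp$position_2[r])
  }, logical(1))
  bp[ok, , drop = FALSE]
}

#' Assemble a tumour chromosome from subclonal breakpoints
#'
#' Greedy walk linking clonally divergent merged segments through subclonal
#' breakpoints, extending in both directions from a seed segment until no
#' qualifying outgoing breakend remains; revisiting a segment terminates
#' the walk and flags a cycle. Deterministic given breakpoint input order.
#'
#' @param fit a \linkS4class{CloneCNFit}.
#' @param seedSegment row index into the divergent merged segments (see
#'   \code{\link{mergeDivergentSegments}}; only rows with
#'   \code{divergent == TRUE} are eligible).
#' @param smoothLength,minLength,maxCopy as in
#'   \code{\link{selectConfidentSubclonal}}.
#' @return data.frame of the walk: segment coordinates and orientation in
#'   assembly order, with attribute \code{cycle}.
#' @export
assembleChromosome <- function(fit, seedSegment, smoothLength = 1e5,
                               minLength = 1e6, maxCopy = 4) {
  merged <- mergeDivergentSegments(fit, smoothLength)
  segsAll <- merged[merged$divergent & merged$length >= minLength &
                    merged$maxTotal <= maxCopy, , drop = FALSE]
  rownames(segsAll) <- NULL
  if (seedSegment < 1 || seedSegment > nrow(segsAll))
    stop("seedSegment out of range of divergent segments")
  bp <- selectConfidentSubclonal(fit, smoothLength, minLength, maxCopy)

  attachedSeg <- function(chrom, pos, o) {
    hit <- if (o == 1)
      which(segsAll$chrom == chrom & segsAll$start < pos & segsAll$end >= pos)
    else
      which(segsAll$chrom == chrom & segsAll$start <= pos & segsAll$end > pos)
    if (length(hit)) hit[1] else NA_integer_
  }
  exitBreakend <- function(segIdx, side, usedBp) {
    wantO <- if (side == "right") 1L else -1L
    for (r in seq_len(nrow(bp))) {
      if (bp$id[r] %in% usedBp) next
      for (e in 1:2) {
        o <- bp[[paste0("orientation_", e)]][r]
        if (o != wantO) next
        at <- attachedSeg(bp[[paste0("chrom_", e)]][r],
                          bp[[paste0("position_", e)]][r], o)
        if (!is.na(at) && at == segIdx)
          return(list(row = r, end = e))
      }
    }
    NULL
  }
  walk <- function(startIdx, startSide, dir, visited = startIdx,
                   used = character(0)) {
    out <- list()
    cur <- startIdx; side <- startSide
    cycle <- FALSE
    repeat {
      hit <- exitBreakend(cur, side, used)
      if (is.null(hit)) break
      used <- c(used, bp$id[hit$row])
      pe <- if (hit$end == 1) 2 else 1
      po <- bp[[paste0("orientation_", pe)]][hit$row]
      nxt <- attachedSeg(bp[[paste0("chrom_", pe)]][hit$row],
                         bp[[paste0("position_", pe)]][hit$row], po)
      if (is.na(nxt)) break
      if (nxt %in% visited) { cycle <- TRUE; break }
      visited <- c(visited, nxt)
      if (dir == "right") {
        orient <- if (po == -1) "+" else "-"
        side <- if (po == -1) "right" else "left"
      } else {
        orient <- if (po == 1) "+" else "-"
        side <- if (po == 1) "left" else "right"
      }
      out[[length(out) + 1]] <- data.frame(segIdx = nxt, orientation = orient,
                                           via = bp$id[hit$row],
                                           stringsAsFactors = FALSE)
      cur <- nxt
    }
    list(steps = out, cycle = cycle, visited = visited, used = used)
  }
  right <- walk(seedSegment, "right", "right")
  left <- walk(seedSegment, "left", "left",
               visited = right$visited, used = right$used)
  steps <- c(rev(left$steps),
             list(data.frame(segIdx = seedSegment, orientation = "+",
                             via = NA_character_, stringsAsFactors = FALSE)),
             right$steps)
  res <- do.call(rbind, steps)
  res <- cbind(res, segsAll[res$segIdx, c("chrom", "start", "end", "dMajor", "dMinor")])
  rownames(res) <- NULL
  attr(res, "cycle") <- left$cycle || right$cycle
  res
}
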
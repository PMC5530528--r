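# Copy-number state space and telomere transition factors.
#
# A state holds per-clone, per-allele copy numbers for one segment. The
# normal clone is fixed at one copy of each allele; tumour-clone states are
# enumerated as (major, minor) pairs with major >= minor and total <= cMax.
# Transition factors between adjacent segments are exp(-lambda * t) where t
# counts the segment ends left unconnected (telomeres) by a candidate
# configuration of segment and breakpoint copy number.

#' Enumerate the copy-number state space
#'
#' @param cMax cap on per-clone total copy number.
#' @param nTumour number of tumour clones (1 or 2).
#' @return integer matrix with one row per state and columns
#'   \code{major_m}, \code{minor_m} per clone (clone 1 = normal, fixed at
#'   1/1). Rows are ordered by grand total then per-clone totals so that
#'   first-maximum tie-breaking prefers lower copy numbers and lower clone
#'   indices.
#' @export
enumerateCNStates <- function(cMax = 5L, nTumour = 2L) {
  stopifnot(cMax >= 1, nTumour %in% 1:2)
  pairs <- do.call(rbind, lapply(0:cMax, function(tot) {
    minor <- 0:(tot %/% 2)
    cbind(major = tot - minor, minor = minor)
  }))
  pairs <- pairs[order(pairs[, 1] + pairs[, 2], pairs[, 1]), , drop = FALSE]
  if (nTumour == 1L) {
    st <- cbind(major_1 = 1L, minor_1 = 1L,
                major_2 = pairs[, 1], minor_2 = pairs[, 2])
  } else {
    i <- rep(seq_len(nrow(pairs)), each = nrow(pairs))
    j <- rep(seq_len(nrow(pairs)), times = nrow(pairs))
    st <- cbind(major_1 = 1L, minor_1 = 1L,
                major_2 = pairs[i, 1], minor_2 = pairs[i, 2],
                major_3 = pairs[j, 1], minor_3 = pairs[j, 2])
  }
  tot <- totalCopies(st)
  ord <- do.call(order, c(list(rowSums(tot)), lapply(seq_len(ncol(tot)), function(k) tot[, k]),
                          lapply(seq(3, ncol(st), by = 2), function(k) st[, k])))
  st <- st[ord, , drop = FALSE]
  storage.mode(st) <- "integer"
  rownames(st) <- NULL
  st
}

majorCols <- function(states) seq(1, ncol(states), by = 2)
minorCols <- function(states) seq(2, ncol(states), by = 2)

totalCopies <- function(states) {
  states[, majorCols(states), drop = FALSE] + states[, minorCols(states), drop = FALSE]
}

#' Telomere count between adjacent segments without a breakpoint
#'
#' The number of unconnected segment ends implied by a change in copy
#' number: summed over clones and alleles, the absolute copy difference.
#'
#' @param cn,cnPrime states as vectors of per-clone (major, minor) copies.
#' @return non-negative integer.
#' @examples
#' telomereCountPlain(c(1, 1, 2, 1), c(1, 1, 1, 1)) # 1
#' @export
telomereCountPlain <- function(cn, cnPrime) {
  stopifnot(length(cn) == length(cnPrime))
  sum(abs(cn - cnPrime))
}

#' Telomere count at a breakpoint-coincident boundary
#'
#' A breakpoint with orientation \code{o} and per-clone copy number
#' \code{b} absorbs copy-number change on one allele:
#' per clone the breakpoint is scored against each allele and the
#' minimum-telomere allele is used, \eqn{t = \min_\ell (|c_\ell - c'_\ell -
#' o b| + |c_{-\ell} - c'_{-\ell}|)}, summed over clones.
#'
#' @param cn,cnPrime states as per-clone (major, minor) vectors.
#' @param b per-clone breakpoint copy numbers (normal clone included,
#'   conventionally 0).
#' @param o breakend orientation, +1 or -1.
#' @return non-negative integer.
#' @examples
#' # deletion start: copies 2 -> 1 fully explained by one junction copy
#' telomereCountBreakpoint(c(1, 1, 1, 1), c(1, 1, 1, 0), b = c(0, 1), o = 1)
#' @export
telomereCountBreakpoint <- function(cn, cnPrime, b, o) {
  stopifnot(o %in% c(-1, 1), length(cn) == length(cnPrime),
            length(b) * 2 == length(cn), all(b >= 0))
  t <- 0
  for (m in seq_along(b)) {
    a <- cn[2 * m - 1]; mi <- cn[2 * m]
    ap <- cnPrime[2 * m - 1]; mip <- cnPrime[2 * m]
    onMajor <- abs(a - ap - o * b[m]) + abs(mi - mip)
    onMinor <- abs(a - ap) + abs(mi - mip - o * b[m])
    t <- t + min(onMajor, onMinor)
  }
  t
}

#' Transition factor from a telomere count
#'
#' @param t telomere count (non-negative).
#' @param lambda penalty rate (>= 0).
#' @return un-normalised factor \eqn{e^{-\lambda t}} in (0, 1].
#' @export
transitionFactor <- function(t, lambda = 1) {
  stopifnot(lambda >= 0, all(t >= 0))
  exp(-lambda * t)
}

# S x S matrix of plain telomere counts between all state pairs.
plainTelomereMatrix <- function(states) {
  t <- matrix(0, nrow(states), nrow(states))
  for (k in seq_len(ncol(states)))
    t <- t + abs(outer(states[, k], states[, k], "-"))
  t
}

# Enumerate joint breakpoint states (per tumour clone 0..bMax); normal 0.
enumerateBreakpointStates <- function(bMax = 2L, nTumour = 2L) {
  if (nTumour == 1L) {
    b <- cbind(b_1 = 0L, b_2 = 0:bMax)
  } else {
    g <- expand.grid(b_2 = 0:bMax, b_3 = 0:bMax)
    g <- g[order(g$b_2 + g$b_3, g$b_2), ]
    b <- cbind(b_1 = 0L, b_2 = g$b_2, b_3 = g$b_3)
  }
  storage.mode(b) <- "integer"
  rownames(b) <- NULL
  b
}

# For one orientation, list over joint breakpoint states of S x S telomere
# matrices with the per-clone minimum-allele assignment.
breakpointTelomereArray <- function(states, bStates, o) {
  nClone <- ncol(states) / 2
  lapply(seq_len(nrow(bStates)), function(bi) {
    t <- matrix(0, nrow(states), nrow(states))
    for (m in seq_len(nClone)) {
      a <- states[, 2 * m - 1]; mi <- states[, 2 * m]
      bm <- bStates[bi, m]
      dMaj <- abs(outer(a, a, "-") - o * bm) + abs(outer(mi, mi, "-"))
      dMin <- abs(outer(a, a, "-")) + abs(outer(mi, mi, "-") - o * bm)
      t <- t + pmin(dMaj, dMin)
    }
    t
  })
}
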
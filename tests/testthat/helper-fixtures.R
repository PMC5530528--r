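# Shared fixtures and independent oracles.

# tiny partitioned genome with count columns filled from explicit vectors
makeCountedSegments <- function(chromLengths, binSize, x, xa = NULL, xb = NULL,
                                breakpoints = NULL) {
  gr <- partitionGenome(chromLengths, breakpoints, binSize)
  S4Vectors::mcols(gr)$readcount <- as.integer(x)
  S4Vectors::mcols(gr)$allele_a_readcount <- if (is.null(xa)) 0L else as.integer(xa)
  S4Vectors::mcols(gr)$allele_b_readcount <- if (is.null(xb)) 0L else as.integer(xb)
  S4Vectors::mcols(gr)$effective_length <- GenomicRanges::width(gr)
  gr
}

# brute-force chain marginals by exhaustive enumeration of S^N paths
enumerateChainMarginals <- function(logEmit, logTransList) {
  N <- nrow(logEmit); S <- ncol(logEmit)
  conf <- as.matrix(expand.grid(rep(list(seq_len(S)), N)))
  score <- numeric(nrow(conf))
  for (n in seq_len(N)) score <- score + logEmit[n, conf[, n]]
  for (n in seq_len(N - 1)) {
    lt <- logTransList[[n]]
    score <- score + lt[cbind(conf[, n], conf[, n + 1])]
  }
  lz <- max(score) + log(sum(exp(score - max(score))))
  p <- exp(score - lz)
  singles <- matrix(0, N, S)
  for (n in seq_len(N))
    singles[n, ] <- vapply(seq_len(S), function(s) sum(p[conf[, n] == s]), numeric(1))
  pairs <- lapply(seq_len(N - 1), function(n) {
    out <- matrix(0, S, S)
    for (i in seq_len(S)) for (j in seq_len(S))
      out[i, j] <- sum(p[conf[, n] == i & conf[, n + 1] == j])
    out
  })
  list(singles = singles, pairs = pairs, logZ = lz)
}

# small two-clone simulated dataset for fast fitting tests
smallSim <- function(seed, nEvents = 10, nChrom = 3, chromLen = 1e7,
                     normalFraction = 0.5, descendantFraction = 0.3,
                     coverage = 40, nProposals = 25) {
  # small genomes cannot always reach the default history targets; the
  # resulting warning is expected here
  suppressWarnings(
    simulateMixture(seed = seed, nEvents = nEvents,
                    chromLengths = stats::setNames(rep(chromLen, nChrom),
                                                   paste0("chr", seq_len(nChrom))),
                    normalFraction = normalFraction,
                    descendantFraction = descendantFraction,
                    coverage = coverage, nProposals = nProposals))
}

# wrap truth into a CloneCNFit-shaped object for evaluation tests
fitFromTruth <- function(truth, permute = FALSE) {
  segs <- truth@segments
  mc <- S4Vectors::mcols(segs)
  major <- mc$major; minor <- mc$minor
  if (permute) { major <- major[, c(1, 3, 2)]; minor <- minor[, c(1, 3, 2)] }
  # store allele-sorted copies as a fit would
  S4Vectors::mcols(segs)$major <- pmax(major, minor)
  S4Vectors::mcols(segs)$minor <- pmin(major, minor)
  bp <- truth@breakpoints
  if (nrow(bp)) {
    cn <- bp[, c("cn_1", "cn_2", "cn_3")]
    if (permute) cn <- cn[, c(1, 3, 2)]
    bp$cn_1 <- cn[[1]]; bp$cn_2 <- cn[[2]]; bp$cn_3 <- cn[[3]]
  }
  h <- truth@h
  if (permute) h <- h[c(1, 3, 2)]
  tot <- S4Vectors::mcols(segs)$major + S4Vectors::mcols(segs)$minor
  mass <- as.numeric(t(tot) %*% as.numeric(GenomicRanges::width(segs)))
  rho <- h * mass / sum(h * mass)
  new("CloneCNFit", segments = segs, breakpoints = bp, h = h, rho = rho,
      elbo = 0, elboTrace = numeric(0), iterations = 0L, converged = TRUE,
      mode = "breakpoint", posthoc = data.frame(), config = cloneCNConfig(),
      diagnostics = list())
}
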
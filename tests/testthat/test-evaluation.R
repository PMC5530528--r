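test_that("scoring a perfect result gives unit accuracy and zero errors", {
  truth <- sampleHistory(nEvents = 10, chromLengths = c(chr1 = 1e7, chr2 = 1e7),
                         nProposals = 20, seed = 9)
  truth <- simulateReadCounts(truth, seed = 2)$truth   # fills haploid depths
  fit <- fitFromTruth(truth)
  s <- scoreFit(fit, truth)
  expect_equal(s$segmentAccuracy, 1)
  expect_equal(s$breakpointAccuracy, 1)
  expect_equal(s$normalFractionAbsError, 0, tolerance = 1e-12)
  expect_equal(s$minorCloneFractionAbsError, 0, tolerance = 1e-12)
  expect_equal(s$ploidyError, 0, tolerance = 1e-12)
  expect_equal(s$divergentProportionError, 0, tolerance = 1e-12)

  # swapping tumour clone labels changes nothing
  s2 <- scoreFit(fitFromTruth(truth, permute = TRUE), truth)
  expect_equal(s2$segmentAccuracy, 1)
  expect_equal(s2$breakpointAccuracy, 1)
  expect_equal(s2$minorCloneFractionAbsError, 0, tolerance = 1e-12)
})

test_that("scoring matches a hand-computed five-segment report", {
  gr <- partitionGenome(c(chr1 = 5e6), binSize = 1e6)
  tMajor <- cbind(1L, c(1L, 2L, 2L, 3L, 1L), c(1L, 2L, 1L, 3L, 1L))
  tMinor <- cbind(1L, c(1L, 1L, 1L, 1L, 0L), c(1L, 1L, 1L, 1L, 0L))
  truthSegs <- gr
  S4Vectors::mcols(truthSegs)$major <- tMajor
  S4Vectors::mcols(truthSegs)$minor <- tMinor
  w <- rep(1e6, 5)
  divergent <- 1 / 5                          # only segment 3 differs
  ploidy <- mean(c(sum((tMajor + tMinor)[, 2]) / 5, sum((tMajor + tMinor)[, 3]) / 5))
  truth <- new("SimulatedTruth", segments = truthSegs,
               breakpoints = data.frame(), chromLengths = c(chr1 = 5e6),
               binSize = 1e6, normalFraction = 0.5, descendantFraction = 0.4,
               cellFractions = c(normal = 0.5, ancestral = 0.3, descendant = 0.2),
               h = c(0.05, 0.03, 0.02), ploidy = ploidy,
               divergentProportion = divergent, events = data.frame(), seed = 1L)
  fitSegs <- gr
  fMajor <- tMajor; fMajor[5, 2] <- 2L        # one wrong segment, clone 2
  S4Vectors::mcols(fitSegs)$major <- fMajor
  S4Vectors::mcols(fitSegs)$minor <- tMinor
  fit <- new("CloneCNFit", segments = fitSegs, breakpoints = data.frame(),
             h = c(0.045, 0.033, 0.022), rho = c(0.4, 0.36, 0.24),
             elbo = 0, elboTrace = numeric(0), iterations = 1L,
             converged = TRUE, mode = "breakpoint", posthoc = data.frame(),
             config = cloneCNConfig(), diagnostics = list())
  s <- scoreFit(fit, truth)
  expect_equal(s$segmentAccuracy, 4 / 5)
  cf <- c(0.045, 0.033, 0.022) / 0.1
  expect_equal(s$normalFractionAbsError, abs(cf[1] - 0.5), tolerance = 1e-12)
  expect_equal(s$minorCloneFractionAbsError, abs(cf[3] - 0.2), tolerance = 1e-12)
  # mismatched segmentation is rejected
  expect_error(scoreFit(fit, sampleHistory(nEvents = 0,
    chromLengths = c(chr1 = 4e6), seed = 1)), "segmentation")
})

test_that("clonal dynamics classification follows both replicates", {
  s1 <- c(k1 = 0.1, k2 = 0.6, k3 = 0.5, k4 = 0.3)
  s2a <- c(k1 = 0.6, k2 = 0.1, k3 = 0.5, k4 = 0.6)
  s2b <- c(k1 = 0.7, k2 = 0.2, k3 = 0.9, k4 = 0.1)
  d <- classifyClonalDynamics(s1, s2a, s2b)
  expect_equal(d$label[match(c("k1", "k2", "k3", "k4"), d$id)],
               c("ascending", "descending", "stable", "conflicting"))
  # a breakpoint absent from a sample counts as prevalence zero
  d2 <- classifyClonalDynamics(c(k9 = 0.5), s2a, s2b)
  expect_equal(d2$prev_s1[d2$id == "k1"], 0)
})

confidentFixture <- function() {
  # chr1: 10 x 500kb segments; a 0.5 Mb divergent island and a 2 Mb block
  gr <- partitionGenome(c(chr1 = 5e6, chr2 = 5e6), binSize = 5e5)
  n <- length(gr)
  major <- cbind(rep(1L, n), rep(2L, n), rep(2L, n))
  minor <- cbind(rep(1L, n), rep(1L, n), rep(1L, n))
  major[2, 3] <- 3L                 # 0.5 Mb divergent island (chr1 bin 2)
  major[5:8, 3] <- 3L               # 2 Mb divergent block (chr1 bins 5..8)
  fitSegs <- gr
  S4Vectors::mcols(fitSegs)$major <- major
  S4Vectors::mcols(fitSegs)$minor <- minor
  bp <- data.frame(id = c("small", "big", "clonal"),
                   chrom_1 = "chr1", position_1 = c(5e5, 2e6, 15e5),
                   orientation_1 = c(1L, 1L, 1L),
                   chrom_2 = "chr1", position_2 = c(1e6, 4e6, 45e5),
                   orientation_2 = c(-1L, -1L, -1L),
                   cn_1 = 0L, cn_2 = c(0L, 0L, 1L), cn_3 = c(1L, 1L, 1L))
  new("CloneCNFit", segments = fitSegs, breakpoints = bp,
      h = c(0.05, 0.04, 0.01), rho = c(0.45, 0.4, 0.15), elbo = 0,
      elboTrace = numeric(0), iterations = 1L, converged = TRUE,
      mode = "breakpoint", posthoc = data.frame(), config = cloneCNConfig(),
      diagnostics = list())
}

test_that("confident subclonal breakpoints need long low-copy divergent flanks", {
  fit <- confidentFixture()
  sel <- selectConfidentSubclonal(fit)
  expect_true("big" %in% sel$id)       # 2 Mb divergent flanks, copies <= 4
  expect_false("small" %in% sel$id)    # 0.5 Mb island fails the length filter
  expect_false("clonal" %in% sel$id)   # equal clone copies: not subclonal
})

test_that("breakpoint prevalence weights carrying clones", {
  fit <- confidentFixture()
  prev <- breakpointPrevalence(fit)
  rho <- fit@rho
  expect_equal(unname(prev["big"]), rho[3] / sum(rho[2:3]))
  expect_equal(unname(prev["clonal"]), 1)
})

assemblyFixture <- function() {
  # three divergent 2 Mb blocks on chr1/chr2/chr3 joined by two subclonal
  # translocations: chr1 block end -> chr2 block start -> chr3 block start
  gr <- partitionGenome(c(chr1 = 4e6, chr2 = 4e6, chr3 = 4e6), binSize = 5e5)
  n <- length(gr)
  chrom <- as.character(GenomicRanges::seqnames(gr))
  bin <- (GenomicRanges::start(gr) - 1) / 5e5
  major <- cbind(rep(1L, n), rep(2L, n), rep(2L, n))
  minor <- cbind(rep(1L, n), rep(1L, n), rep(1L, n))
  divv <- (chrom == "chr1" & bin >= 4) | (chrom == "chr2" & bin < 4) |
          (chrom == "chr3" & bin >= 2 & bin < 6)
  major[divv, 3] <- 3L
  S4Vectors::mcols(gr)$major <- major
  S4Vectors::mcols(gr)$minor <- minor
  bp <- data.frame(id = c("t1", "t2"),
                   chrom_1 = c("chr1", "chr2"), position_1 = c(4e6, 2e6),
                   orientation_1 = c(1L, 1L),
                   chrom_2 = c("chr2", "chr3"), position_2 = c(0, 1e6),
                   orientation_2 = c(-1L, -1L), cn_1 = 0L,
                   cn_2 = c(0L, 0L), cn_3 = c(1L, 1L))
  new("CloneCNFit", segments = gr, breakpoints = bp,
      h = c(0.05, 0.04, 0.01), rho = c(0.45, 0.4, 0.15), elbo = 0,
      elboTrace = numeric(0), iterations = 1L, converged = TRUE,
      mode = "breakpoint", posthoc = data.frame(), config = cloneCNConfig(),
      diagnostics = list())
}

test_that("chromosome assembly walks subclonal junctions between divergent blocks", {
  fit <- assemblyFixture()
  merged <- mergeDivergentSegments(fit)
  divRows <- which(merged$divergent & merged$length >= 1e6 & merged$maxTotal <= 4)
  seedIdx <- which(merged[divRows, "chrom"] == "chr2")[1]
  segsAll <- merged[divRows, ]
  walk <- assembleChromosome(fit, seedSegment = seedIdx)
  expect_equal(nrow(walk), 3)
  expect_equal(walk$chrom, c("chr1", "chr2", "chr3"))
  expect_equal(walk$orientation, c("+", "+", "+"))

  # a seed with no qualifying breakends stays alone
  fit2 <- fit
  fit2@breakpoints <- fit@breakpoints[0, ]
  walk2 <- assembleChromosome(fit2, seedSegment = seedIdx)
  expect_equal(nrow(walk2), 1)
})

test_that("cyclic walks terminate at the first revisit and are flagged", {
  fit <- assemblyFixture()
  # add a junction from the chr3 block end back to the chr1 block start
  back <- data.frame(id = "t3", chrom_1 = "chr3", position_1 = 3e6,
                     orientation_1 = 1L, chrom_2 = "chr1", position_2 = 2e6,
                     orientation_2 = -1L, cn_1 = 0L, cn_2 = 0L, cn_3 = 1L)
  fit@breakpoints <- rbind(fit@breakpoints, back)
  merged <- mergeDivergentSegments(fit)
  divRows <- which(merged$divergent & merged$length >= 1e6 & merged$maxTotal <= 4)
  seedIdx <- which(merged[divRows, "chrom"] == "chr2")[1]
  walk <- assembleChromosome(fit, seedSegment = seedIdx)
  expect_true(attr(walk, "cycle"))
  expect_lte(nrow(walk), 3)
})
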
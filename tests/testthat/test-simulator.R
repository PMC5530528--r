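test_that("histories replay deterministically and match stored truth", {
  t1 <- sampleHistory(nEvents = 10, chromLengths = c(chr1 = 1e7, chr2 = 1e7),
                      nProposals = 20, seed = 9)
  t2 <- sampleHistory(nEvents = 10, chromLengths = c(chr1 = 1e7, chr2 = 1e7),
                      nProposals = 20, seed = 9)
  expect_identical(S4Vectors::mcols(t1@segments)$major,
                   S4Vectors::mcols(t2@segments)$major)
  expect_identical(t1@breakpoints, t2@breakpoints)
  # replaying the stored event history reproduces the stored copy numbers
  rp <- replayHistory(t1@events, t1@chromLengths, t1@binSize)
  mc <- S4Vectors::mcols(t1@segments)
  expect_equal(unname(cbind(mc$major[, 2], mc$minor[, 2], mc$major[, 3], mc$minor[, 3])),
               unname(rp$cn[, c("anc_1", "anc_2", "desc_1", "desc_2")]))
  expect_equal(t1@ploidy, rp$ploidy)
  expect_equal(t1@divergentProportion, rp$divergentProportion)
})

test_that("degenerate histories give diploid truth", {
  t0 <- sampleHistory(nEvents = 0, chromLengths = c(chr1 = 5e6), seed = 2)
  mc <- S4Vectors::mcols(t0@segments)
  expect_true(all(mc$major == 1L) && all(mc$minor == 1L))
  expect_equal(t0@ploidy, 2)
  expect_equal(t0@divergentProportion, 0)
  expect_equal(nrow(t0@breakpoints), 0)
})

test_that("an ancestral whole-chromosome duplication is shared by both clones", {
  ev <- data.frame(kind = "duplication", lineage = "shared", chrom = "chr1",
                   startBin = 0, endBin = 10, allele = 1L,
                   chrom2 = NA_character_, bin2 = NA_integer_, wholeChrom = TRUE,
                   stringsAsFactors = FALSE)
  rp <- replayHistory(ev, c(chr1 = 5e6, chr2 = 5e6), binSize = 5e5)
  onChr1 <- rp$bins$chrom == "chr1"
  tots <- rp$cn[, "anc_1"] + rp$cn[, "anc_2"]
  expect_true(all(tots[onChr1] == 3))
  expect_true(all((rp$cn[, "desc_1"] + rp$cn[, "desc_2"])[onChr1] == 3))
  expect_equal(rp$divergentProportion, 0)
  expect_equal(nrow(rp$breakpoints), 0)   # whole-chromosome events: no junction
})

test_that("unbalanced events couple breakpoints to copy steps, balanced do not", {
  t1 <- sampleHistory(nEvents = 15, chromLengths = c(chr1 = 2e7, chr2 = 2e7),
                      nProposals = 30, seed = 14)
  bp <- t1@breakpoints
  mc <- S4Vectors::mcols(t1@segments)
  key <- sprintf("%s:%.0f", as.character(GenomicRanges::seqnames(t1@segments)),
                 GenomicRanges::end(t1@segments))
  for (r in seq_len(nrow(bp))) {
    for (e in 1:2) {
      k <- sprintf("%s:%.0f", bp[[paste0("chrom_", e)]][r], bp[[paste0("position_", e)]][r])
      li <- match(k, key)
      if (is.na(li) || li == length(t1@segments)) next
      dTot <- abs(mc$major[li + 1, 2:3] + mc$minor[li + 1, 2:3] -
                  mc$major[li, 2:3] - mc$minor[li, 2:3])
      if (bp$kind[r] == "balanced") {
        expect_equal(sum(dTot), 0)
      }
    }
    if (bp$kind[r] != "balanced") {
      # at least one breakend shows a copy step in a carrying clone
      steps <- vapply(1:2, function(e) {
        k <- sprintf("%s:%.0f", bp[[paste0("chrom_", e)]][r], bp[[paste0("position_", e)]][r])
        li <- match(k, key)
        if (is.na(li) || li == length(t1@segments)) return(0)
        sum(abs(mc$major[li + 1, 2:3] - mc$major[li, 2:3]) +
            abs(mc$minor[li + 1, 2:3] - mc$minor[li, 2:3]))
      }, numeric(1))
      expect_true(sum(steps) > 0)
    }
  }
})

test_that("history re-sampling calibrates to its targets", {
  hits <- vapply(1:20, function(sd) {
    tr <- sampleHistory(nEvents = 50, targetPloidy = 2.5, targetDivergent = 0.2,
                        nProposals = 100, seed = sd)
    abs(tr@ploidy - 2.5) <= 0.1 && abs(tr@divergentProportion - 0.2) <= 0.1
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("simulated counts match their generative law and are reproducible", {
  # law of large numbers at Poisson mean 100
  truth <- sampleHistory(nEvents = 0,
                         chromLengths = setNames(rep(5e8, 10), paste0("chr", 1:10)),
                         binSize = 5e5, seed = 1)
  pois <- likelihoodParams(family = "poisson", outlierWeight = 0)
  cov100 <- 100 * 200 / 5e5   # coverage such that mu = l * coverage/200 = 100
  simA <- simulateReadCounts(truth, coverage = cov100, params = pois,
                             alleleRate = 0, seed = 4)
  x <- S4Vectors::mcols(simA$segments)$readcount
  expect_equal(length(x), 10000)
  expect_lt(abs(mean(x) - 100) / 100, 0.01)

  # byte-identical outputs under a fixed seed
  t2 <- suppressWarnings(sampleHistory(nEvents = 8, chromLengths = c(chr1 = 1e7),
                                       seed = 6, nProposals = 10))
  s1 <- simulateReadCounts(t2, seed = 11)
  s2 <- simulateReadCounts(t2, seed = 11)
  expect_identical(S4Vectors::mcols(s1$segments), S4Vectors::mcols(s2$segments))
  expect_identical(s1$breakpoints, s2$breakpoints)

  # descendant fraction zero is distributionally single-clone
  t3 <- suppressWarnings(sampleHistory(nEvents = 8,
                                       chromLengths = c(chr1 = 1e7, chr2 = 1e7),
                                       descendantFraction = 0, seed = 3,
                                       nProposals = 10))
  s3 <- simulateReadCounts(t3, seed = 5)
  fit <- fitCloneCN(s3$segments, s3$breakpoints, cloneCNConfig())
  cellFrac <- fit@h / sum(fit@h)
  expect_lt(min(cellFrac[2:3]), 0.06)

  # false positives appear at unused boundaries with fp ids
  s4 <- simulateReadCounts(t2, fpRate = 1, seed = 8)
  expect_true(any(grepl("^fp_", s4$breakpoints$id)))
})
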
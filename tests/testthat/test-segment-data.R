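test_that("partitioning tiles chromosomes exactly at bins and breakends", {
  gr <- partitionGenome(c(chr1 = 3000), binSize = 1000)
  expect_equal(length(gr), 3)
  expect_equal(GenomicRanges::start(gr) - 1, c(0, 1000, 2000))
  expect_equal(GenomicRanges::end(gr), c(1000, 2000, 3000))

  bp <- data.frame(id = "b1", chrom_1 = "chr1", position_1 = 1500,
                   orientation_1 = 1L, chrom_2 = "chr1", position_2 = 2500,
                   orientation_2 = -1L)
  gr2 <- partitionGenome(c(chr1 = 3000), bp, binSize = 1000)
  expect_true(1500 %in% GenomicRanges::end(gr2))
  expect_true(all(S4Vectors::mcols(gr2)$isBreakendBoundaryRight[GenomicRanges::end(gr2) %in% c(1500, 2500)]))

  # random breakends always land on boundaries; tiling is exact
  withr::with_seed(42, {
    lens <- c(a = 5.3e6, b = 2.7e6)
    pos <- data.frame(chrom = sample(names(lens), 5, replace = TRUE))
    pos$p <- floor(runif(5) * (lens[pos$chrom] - 2)) + 1
    bps <- data.frame(id = paste0("k", 1:5),
                      chrom_1 = pos$chrom[c(1, 2, 3, 4, 5)], position_1 = pos$p,
                      orientation_1 = 1L, chrom_2 = "a",
                      position_2 = seq(1e6, 1.4e6, by = 1e5) + 13,
                      orientation_2 = -1L)
    gr3 <- partitionGenome(lens, bps, binSize = 5e5)
    bounds <- sprintf("%s:%.0f", as.character(GenomicRanges::seqnames(gr3)),
                      GenomicRanges::end(gr3))
    for (e in 1:2) {
      k <- sprintf("%s:%.0f", bps[[paste0("chrom_", e)]], bps[[paste0("position_", e)]])
      expect_true(all(k %in% bounds))
    }
    for (ch in names(lens)) {
      w <- GenomicRanges::width(gr3[GenomicRanges::seqnames(gr3) == ch])
      expect_equal(sum(w), unname(lens[ch]))
    }
  })

  expect_error(partitionGenome(c(chr1 = 1000),
    data.frame(id = "x", chrom_1 = "chr1", position_1 = 2000, orientation_1 = 1L,
               chrom_2 = "chr1", position_2 = 10, orientation_2 = -1L), 500),
    "outside chromosome bounds")
})

test_that("read-pair counting requires full containment and counts pairs once", {
  segs <- partitionGenome(c(chr1 = 3000), binSize = 1000)
  frags <- data.frame(chrom = "chr1",
                      start = c(rep(100, 10), 950),
                      end = c(rep(400, 10), 1100))
  frags <- frags[order(frags$start), ]
  out <- countReadPairs(frags, segs)
  expect_equal(S4Vectors::mcols(out)$readcount, c(10L, 0L, 0L))

  withr::with_seed(7, {
    st <- floor(runif(1000) * 2800)
    frg <- data.frame(chrom = "chr1", start = st, end = st + 200)
    frg <- frg[order(frg$start), ]
    got <- S4Vectors::mcols(countReadPairs(frg, segs))$readcount
    # brute-force containment oracle
    want <- vapply(seq_along(segs), function(i) {
      s0 <- GenomicRanges::start(segs)[i] - 1; e0 <- GenomicRanges::end(segs)[i]
      sum(frg$start >= s0 & frg$end <= e0)
    }, numeric(1))
    expect_equal(got, as.integer(want))
    expect_true(sum(got) <= nrow(frg))
  })

  expect_error(countReadPairs(data.frame(chrom = "chr1", start = c(500, 100),
                                         end = c(700, 300)), segs),
               "coordinate-sorted")
})

test_that("BAM input counts proper pairs via fragment spans", {
  skip_if_not_installed("Rsamtools")
  sam <- file.path(tempdir(), "toy.sam")
  lines <- c("@HD\tVN:1.6\tSO:coordinate", "@SQ\tSN:chr1\tLN:3000")
  mk <- function(name, pos, mpos, isize, flag, flag2) {
    c(paste(name, flag, "chr1", pos, 60, "50M", "=", mpos, isize,
            paste(rep("A", 50), collapse = ""), "*", sep = "\t"),
      paste(name, flag2, "chr1", mpos, 60, "50M", "=", pos, -isize,
            paste(rep("A", 50), collapse = ""), "*", sep = "\t"))
  }
  reads <- c(mk("p1", 101, 251, 200, 99, 147),   # fully inside segment 1
             mk("p2", 901, 1051, 200, 99, 147))  # straddles 1000 boundary
  ord <- c(1, 3, 2, 4)
  writeLines(c(lines, c(reads)[ord]), sam)
  bam <- Rsamtools::asBam(sam, file.path(tempdir(), "toy"), overwrite = TRUE)
  segs <- partitionGenome(c(chr1 = 3000), binSize = 1000)
  out <- countReadPairs(bam, segs)
  expect_equal(S4Vectors::mcols(out)$readcount, c(1L, 0L, 0L))
})

test_that("haplotype block counts aggregate by midpoint", {
  segs <- partitionGenome(c(chr1 = 2000), binSize = 1000)
  blocks <- data.frame(chrom = "chr1", start = 100, end = 300,
                       allele_1 = 30, allele_2 = 20)
  out <- aggregateAlleleCounts(blocks, segs)
  expect_equal(S4Vectors::mcols(out)$allele_a_readcount, c(30L, 0L))
  expect_equal(S4Vectors::mcols(out)$allele_b_readcount, c(20L, 0L))

  straddle <- data.frame(chrom = "chr1", start = 900, end = 1300,
                         allele_1 = 5, allele_2 = 7)
  out2 <- aggregateAlleleCounts(straddle, segs)  # midpoint 1100 -> segment 2
  expect_equal(S4Vectors::mcols(out2)$allele_a_readcount, c(0L, 5L))

  withr::with_seed(11, {
    st <- floor(runif(50) * 1900)
    bl <- data.frame(chrom = "chr1", start = st, end = st + 80,
                     allele_1 = rpois(50, 20), allele_2 = rpois(50, 15))
    got <- S4Vectors::mcols(aggregateAlleleCounts(bl, segs))
    mid <- floor((bl$start + bl$end) / 2)
    seg2 <- mid >= 1000
    expect_equal(got$allele_a_readcount,
                 as.integer(c(sum(bl$allele_1[!seg2]), sum(bl$allele_1[seg2]))))
    expect_equal(got$allele_b_readcount,
                 as.integer(c(sum(bl$allele_2[!seg2]), sum(bl$allele_2[seg2]))))
  })
})

test_that("effective length sums per-position bias weights", {
  gr <- partitionGenome(c(chr1 = 1000), binSize = 1000)
  expect_equal(effectiveLengths(gr), 1000)
  expect_equal(effectiveLengths(gr, bias = 0.5), 500)
  sine <- function(chrom, pos) 1 + 0.5 * sin(pos / 50)
  direct <- sum(1 + 0.5 * sin((0:999) / 50))
  expect_equal(effectiveLengths(gr, bias = sine), direct, tolerance = 1e-12)
  expect_error(effectiveLengths(gr, bias = function(c, p) rep(-1, length(p))),
               "non-negative")
})

test_that("raw copy numbers follow the depth/allele-ratio convention", {
  gr <- partitionGenome(c(chr1 = 1000), binSize = 1000)
  S4Vectors::mcols(gr)$readcount <- 40
  S4Vectors::mcols(gr)$effective_length <- 1000
  S4Vectors::mcols(gr)$allele_a_readcount <- 20
  S4Vectors::mcols(gr)$allele_b_readcount <- 20
  r <- rawCopyNumbers(gr, h = c(0.01, 0.005, 0.005))
  expect_equal(r$raw_total, 2)
  expect_equal(r$raw_major, 1)
  expect_equal(r$raw_minor, 1)

  # pure diploid normal signal gives raw total zero
  S4Vectors::mcols(gr)$readcount <- 2 * 0.01 * 1000
  expect_equal(rawCopyNumbers(gr, h = c(0.01, 0.005, 0.005))$raw_total, 0)

  # simulator consistency: raw totals track sum_m h_m c_nm / h_T
  sim <- smallSim(21)
  h <- sim$truth@h
  r2 <- rawCopyNumbers(sim$segments, h)
  tm <- S4Vectors::mcols(sim$truth@segments)
  tumTot <- as.numeric((tm$major[, 2:3] + tm$minor[, 2:3]) %*% h[2:3]) / sum(h[2:3])
  expect_true(mean(abs(r2$raw_total - tumTot)) < 0.2)
})
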
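# Chain construction, sum-product, and the variational updates.

tinyModel <- function(seed = 1, nSeg = 6, cMax = 4, bMax = 2,
                      boundaries = c(2, 4), coverage = 40) {
  cfg <- cloneCNConfig(cMax = cMax, bMax = bMax, nTumour = 1L,
                       params = likelihoodParams())
  binSize <- 1000
  bp <- NULL
  if (length(boundaries)) {
    bp <- data.frame(id = paste0("k", seq_along(boundaries)),
                     chrom_1 = "chr1", position_1 = boundaries * binSize,
                     orientation_1 = rep(c(1L, -1L), length.out = length(boundaries)),
                     chrom_2 = "chr2", position_2 = seq_along(boundaries) * binSize,
                     orientation_2 = -1L)
  }
  withr::with_seed(seed, {
    x1 <- rpois(nSeg, 0.2 * binSize * runif(nSeg, 0.5, 1.5))
    x2 <- rpois(3, 0.2 * binSize)
    segs <- makeCountedSegments(c(chr1 = nSeg * binSize, chr2 = 3 * binSize),
                                binSize, c(x1, x2),
                                xa = rpois(nSeg + 3, 20), xb = rpois(nSeg + 3, 20),
                                breakpoints = bp)
  })
  makeChainModel(segs, bp, cfg)
}

test_that("chain transition terms are breakpoint-posterior expectations", {
  model <- tinyModel()
  nB <- nrow(model$bStates)
  lambda <- model$config@lambda
  # point-mass posterior: transition equals log f at that breakpoint state
  qks <- list(c(0, 1, 0), c(1, 0, 0))
  ch <- buildChain(model, qks, h = c(0.05, 0.05))
  j <- which(!is.na(ch$boundaries$bpRow))[1]
  o <- ch$boundaries$orientation[j]
  tArr <- if (o == 1) model$tBpPlus else model$tBpMinus
  expect_equal(ch$logTransMats[[ch$boundaries$matIdx[j]]], -lambda * tArr[[2]])

  # no breakpoints: every boundary carries the plain factor
  model0 <- tinyModel(boundaries = integer(0))
  ch0 <- buildChain(model0, NULL, h = c(0.05, 0.05))
  expect_true(all(ch0$boundaries$matIdx == 1))
  expect_equal(ch0$logTransMats[[1]], -lambda * model0$tPlain)

  # random posterior: matches the explicit sum over breakpoint states
  withr::with_seed(4, q <- {
    v <- runif(nB); v / sum(v)
  })
  ch2 <- buildChain(model, list(q, q), h = c(0.05, 0.05))
  direct <- Reduce(`+`, Map(`*`, q, tArr))
  expect_equal(ch2$logTransMats[[ch2$boundaries$matIdx[j]]], -lambda * direct,
               tolerance = 1e-12)
})

test_that("sum-product handles degenerate chains", {
  cfg <- cloneCNConfig(nTumour = 1L)
  segs <- makeCountedSegments(c(chr1 = 1000), 1000, x = 95, xa = 20, xb = 22)
  model <- makeChainModel(segs, NULL, cfg)
  ch <- buildChain(model, NULL, h = c(0.05, 0.05))
  fb <- sumProduct(model, ch)
  expect_equal(as.numeric(fb$gamma),
               as.numeric(exp(ch$logEmit - cloneCN:::logSumExp(ch$logEmit))),
               tolerance = 1e-12)
  expect_equal(fb$logZ, cloneCN:::logSumExp(ch$logEmit), tolerance = 1e-10)

  # uniform emissions and transitions give uniform marginals
  model2 <- tinyModel(boundaries = integer(0))
  ch2 <- buildChain(model2, NULL, h = c(0.05, 0.05))
  S <- nrow(model2$states)
  ch2$logEmit[] <- 0
  ch2$transMats[[1]][] <- 1
  ch2$logTransMats[[1]][] <- 0
  fb2 <- sumProduct(model2, ch2)
  expect_equal(as.numeric(fb2$gamma), rep(1 / S, length(fb2$gamma)),
               tolerance = 1e-12)
})

test_that("breakpoint posterior updates follow the pairwise marginals", {
  model <- tinyModel(nSeg = 4, boundaries = 2)
  S <- nrow(model$states)
  st <- model$states
  j <- which(!is.na(model$boundaries$bpRow))[1]
  o <- model$boundaries$orientation[j]
  # point mass on a copy drop of one on the major allele across the boundary
  iFrom <- which(st[, 3] == 2 & st[, 4] == 1)[1]
  iTo <- which(st[, 3] == 1 & st[, 4] == 1)[1]
  P <- matrix(0, S, S); P[iFrom, iTo] <- 1
  fb <- list(pairs = setNames(vector("list", nrow(model$boundaries)), NULL))
  fb$pairs[[j]] <- P
  up <- updateBreakpointPosterior(model, fb, k = model$boundaries$bpRow[j])
  expect_equal(unname(model$bStates[which.max(up$q), 2]), 1L)  # b = 1 explains it
  # no copy change: zero copies win
  P2 <- matrix(0, S, S); P2[iFrom, iFrom] <- 1
  fb$pairs[[j]] <- P2
  up2 <- updateBreakpointPosterior(model, fb, k = model$boundaries$bpRow[j])
  expect_equal(unname(model$bStates[which.max(up2$q), 2]), 0L)
  # random marginals match a direct evaluation of the update formula
  withr::with_seed(8, { P3 <- matrix(runif(S * S), S, S); P3 <- P3 / sum(P3) })
  fb$pairs[[j]] <- P3
  up3 <- updateBreakpointPosterior(model, fb, k = model$boundaries$bpRow[j])
  lambda <- model$config@lambda
  direct <- vapply(seq_len(nrow(model$bStates)), function(bi) {
    s <- 0
    for (a in seq_len(S)) for (b in seq_len(S))
      s <- s + P3[a, b] * (-lambda) *
        telomereCountBreakpoint(st[a, ], st[b, ], model$bStates[bi, ], o)
    s
  }, numeric(1))
  expect_equal(up3$q, exp(direct) / sum(exp(direct)), tolerance = 1e-10)
})

test_that("depth update matches the closed-form Poisson solution", {
  # single clone, point-mass marginals: h maximising the Poisson likelihood
  # is sum(x) / sum(l c)
  withr::with_seed(12, {
    n <- 40
    l <- runif(n, 1e3, 1e4)
    cn <- sample(1:4, n, replace = TRUE)
    hTrue <- 0.03
    x <- rpois(n, l * cn * hTrue)
  })
  states <- cbind(major = 1:4, minor = 0L)   # one clone, totals 1..4
  gamma <- matrix(0, n, 4); gamma[cbind(seq_len(n), cn)] <- 1
  cfg <- cloneCNConfig(params = likelihoodParams(family = "poisson",
                                                 outlierWeight = 0))
  model <- list(x = x, leff = l, xa = numeric(n), xb = numeric(n),
                states = states, outlierLogDens = rep(0, n), config = cfg)
  up <- updateDepths(model, gamma, h = 0.01, params = cfg@params,
                     fitTheta = FALSE, maxit = 60)
  closed <- sum(x) / sum(l * cn)
  expect_equal(up$h, closed, tolerance = 1e-6)

  # flat objective (all mass on zero copies, zero counts): h untouched
  gamma0 <- matrix(0, n, 4)
  states0 <- cbind(major = c(0L, 1L, 2L, 3L), minor = 0L)
  gamma0[, 1] <- 1
  model0 <- list(x = numeric(n), leff = l, xa = numeric(n), xb = numeric(n),
                 states = states0, outlierLogDens = rep(0, n), config = cfg)
  up0 <- updateDepths(model0, gamma0, h = 0.02, params = cfg@params,
                      fitTheta = FALSE, maxit = 30)
  expect_equal(up0$h, 0.02)

  # depth recovery from truth-informed marginals on a simulated mixture
  sim <- smallSim(41, nEvents = 25, nChrom = 5, chromLen = 5e7)
  cfg2 <- cloneCNConfig()
  m2 <- makeChainModel(sim$segments, sim$breakpoints, cfg2)
  fb <- computeELBO(m2, sim$truth@h)$fb
  up2 <- updateDepths(m2, fb$gamma, sim$truth@h, maxit = 40)
  expect_true(all(abs(up2$h - sim$truth@h) / sim$truth@h < 0.05))
})

test_that("the ELBO lower-bounds the enumerated evidence", {
  model <- tinyModel(nSeg = 3, cMax = 2, bMax = 1, boundaries = 2)
  # restrict to chromosome 1 only for enumeration simplicity
  cfg <- model$config
  segs <- model$segments[model$chrom == "chr1"]
  bp <- model$breakpoints
  model <- makeChainModel(segs, bp, cfg)
  h <- c(0.05, 0.05)
  S <- nrow(model$states); N <- length(model$x)
  lambda <- cfg@lambda
  logEmit <- cloneCN:::emissionMatrix(model, h)
  st <- model$states
  bS <- model$bStates
  j <- which(!is.na(model$boundaries$bpRow))
  conf <- as.matrix(expand.grid(rep(list(seq_len(S)), N)))
  evid <- -Inf
  for (bi in seq_len(nrow(bS))) {
    sc <- numeric(nrow(conf))
    for (n in seq_len(N)) sc <- sc + logEmit[n, conf[, n]]
    for (bd in seq_len(N - 1)) {
      o <- model$boundaries$orientation[bd]
      for (r in seq_len(nrow(conf))) {
        a <- conf[r, bd]; b <- conf[r, bd + 1]
        t <- if (bd %in% j)
          telomereCountBreakpoint(st[a, ], st[b, ], bS[bi, ], o)
        else telomereCountPlain(st[a, ], st[b, ])
        sc[r] <- sc[r] - lambda * t
      }
    }
    evid <- cloneCN:::logSumExp(c(evid, cloneCN:::logSumExp(sc)))
  }
  for (trial in 1:3) {
    withr::with_seed(trial, q <- { v <- runif(nrow(bS)); v / sum(v) })
    el <- computeELBO(model, h, qks = list(q))$elbo
    expect_lte(el, evid + 1e-9)
  }
})
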
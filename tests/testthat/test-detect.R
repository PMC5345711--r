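# thresholds reused across detector tests (small but real)
localThresholds <- function(cross, alpha = 0.05, B = 80, seed = 17) {
  estimateThresholds(cross, alpha, nPermutations = B, seed = seed)
}

test_that("the bootstrap k0 selection applies the tie rule", {
  sel <- mbpqtl:::.selectK0
  expect_equal(sel(c(0.1, 0.3, 0.2, 0.9, 0.4)), 4L)   # unique argmax
  expect_equal(sel(c(0.1, 0.9, 0.3, 0.2, 0.9)), 3L)   # ties {2,5} -> 3
  expect_equal(sel(rep(1, 8)), 4L)                    # full tie -> (1+p)/2
  expect_equal(sel(rep(0, 3)), 2L)                    # no exceedance ever
})

test_that("MBP claims QTL from the original data at lambda_k0(alpha)", {
  map <- tinyMap(L = 8, nChr = 2)
  spec <- makeEffectSpec(map, "m2", p = 3, nzeCounts = 1,
                         targetH2Range = c(0.15, 0.15), seed = 2)
  cross <- makeCross(N = 80, p = 3, L = 8, seed = 3, spec = spec)
  ts <- localThresholds(cross)
  res <- mbpDetect(cross, ts, B = 60, seed = 5)
  expect_s4_class(res$frequency, "BootstrapFrequency")
  expect_true(all(res$frequency@fk >= 0 & res$frequency@fk <= 1))
  expect_identical(res$frequency@B, 60L)
  # strong single-effect QTL is found
  expect_true(res$detection@claimed[2])
  # claim consistency: statistic is the original best-k0 stat vs lambda(alpha)
  sc <- scanGenome(cross)
  l <- 2; k0 <- res$detection@k0[l]
  expect_equal(res$detection@statistic[l], scanStats(sc)[l, k0])
  expect_equal(res$detection@threshold[l], ts@lambdaAlpha[k0])
  # bootstrap reproducibility
  res2 <- mbpDetect(cross, ts, B = 60, seed = 5)
  expect_identical(res$frequency@fk, res2$frequency@fk)
  expect_error(mbpDetect(cross, ts, B = 0), "bootstrap")
})

test_that("All claims exactly loci whose full statistic clears lambda_p", {
  cross <- makeCross(N = 50, p = 3, L = 6, seed = 8)
  ts <- localThresholds(cross)
  sc <- scanGenome(cross)
  det <- allDetect(sc, ts)
  expect_equal(det@claimed, scanStats(sc)[, 3] > ts@lambdaAlpha[3])
  # boundary: a statistic exactly at the threshold is not claimed
  la <- ts@lambdaAlpha
  la[3] <- max(scanStats(sc)[, 3])
  tsEdge <- initialize(ts, lambdaAlpha = la,
                       lambdaBeta = pmax(ts@lambdaBeta, la))
  detEdge <- allDetect(sc, tsEdge)
  expect_false(detEdge@claimed[which.max(scanStats(sc)[, 3])])
})

test_that("Indv claims loci and traits from individual-effect exceedance", {
  cross <- makeCross(N = 50, p = 3, L = 6, seed = 9)
  ts <- localThresholds(cross)
  sc <- scanGenome(cross)
  # below tau everywhere: nothing claimed
  tsHigh <- ts; tsHigh@tauAlpha <- max(sc@indiv) + 1
  expect_false(any(indvDetect(sc, tsHigh)@claimed))
  # exactly one (locus, trait) above tau
  tsOne <- ts
  tsOne@tauAlpha <- max(sc@indiv) - 1e-9
  det <- indvDetect(sc, tsOne)
  hit <- which(sc@indiv == max(sc@indiv), arr.ind = TRUE)
  expect_equal(which(det@claimed), unname(hit[1, "row"]))
  expect_equal(det@traitSets[[hit[1, "row"]]], unname(hit[1, "col"]))
})

test_that("Seq stops at the first significant step and records survivors", {
  # one huge effect among nulls: claimed with that single effect surviving
  map <- tinyMap(L = 8, nChr = 2)
  spec <- makeEffectSpec(map, "m6", p = 4, nzeCounts = 1,
                         targetH2Range = c(0.3, 0.3), seed = 3)
  cross <- makeCross(N = 80, p = 4, L = 8, seed = 4, spec = spec)
  ts <- localThresholds(cross)
  det <- seqDetect(scanGenome(cross), ts)
  expect_true(det@claimed[6])
  k <- which(spec@effects[1, ] != 0)
  expect_equal(det@traitSets[[6]], k)
  expect_equal(det@k0[6], 1L)
  # p = 1 equivalence with All
  c1 <- makeCross(N = 50, p = 1, L = 6, seed = 10)
  t1 <- localThresholds(c1)
  s1 <- scanGenome(c1)
  expect_equal(seqDetect(s1, t1)@claimed, allDetect(s1, t1)@claimed)
})

test_that("BICdelta elimination responds to the penalty as expected", {
  cross <- makeCross(N = 50, p = 3, L = 6, seed = 11)
  sc <- scanGenome(cross)
  expect_warning(det0 <- bicdeltaDetect(sc, 0), "penalty")
  expect_true(all(det0@claimed))
  expect_true(all(lengths(det0@traitSets) >= 1))
  detInf <- bicdeltaDetect(sc, 1e9)
  expect_false(any(detInf@claimed))
  expect_true(all(lengths(detInf@traitSets) == 0))
  # retained count is where elimination first stalls
  ts <- localThresholds(cross)
  det <- bicdeltaDetect(sc, ts)
  d <- sc@bestk - cbind(0, sc@bestk[, -3])
  for (l in 1:6) {
    h <- which(d[l, ] > ts@bicPenalty)
    expect_equal(det@k0[l], if (length(h)) max(h) else 0L)
  }
})

test_that("every detection satisfies the claim/threshold contract", {
  cross <- makeCross(N = 50, p = 4, L = 6, seed = 12)
  ts <- localThresholds(cross)
  for (m in c("All", "MBP", "Indv", "Seq", "BICdelta")) {
    det <- detectQTL(cross, m, ts, B = 30, seed = 2)
    expect_identical(det@claimed, det@statistic > det@threshold)
    expect_identical(det@method, m)
  }
})
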
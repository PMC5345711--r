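test_that("joint LRT equals the factorized-likelihood oracle", {
  # hand-sized p = 2, N = 8
  x <- c(0.5, -0.5, 0.5, 0.5, -0.5, -0.5, 0.5, -0.5)
  Y <- cbind(c(1.2, 0.3, -0.4, 2.1, 0.0, -1.1, 0.7, 0.9),
             c(0.2, 1.3, 0.4, -0.1, 1.0, 0.1, -0.7, 0.4))
  for (act in list(1L, 2L, 1:2))
    expect_equal(lrtJoint(x, Y, act), oracleLRT(x, Y, act),
                 tolerance = 1e-8)

  # larger random instances over all active-set sizes
  withr::local_seed(21)
  for (rep in 1:3) {
    N <- 40; p <- 5
    x <- sample(c(0.5, -0.5), N, replace = TRUE)
    Y <- matrix(rnorm(N * p), N, p) %*% chol(0.5 + 0.5 * diag(p))
    for (act in list(3L, c(2L, 5L), c(1L, 3L, 4L), 1:5))
      expect_equal(lrtJoint(x, Y, act), oracleLRT(x, Y, act),
                   tolerance = 1e-8)
  }
})

test_that("monomorphic loci score zero with a warning", {
  Y <- matrix(rnorm(40), 20, 2)
  expect_warning(T0 <- lrtJoint(rep(0.5, 20), Y), "monomorphic")
  expect_equal(T0, 0)
})

test_that("backward elimination matches exhaustive single-removal search", {
  withr::local_seed(31)
  for (p in 2:4) {
    for (rep in 1:4) {
      N <- 30
      x <- sample(c(0.5, -0.5), N, replace = TRUE)
      Y <- matrix(rnorm(N * p), N, p)
      Y[, 1] <- Y[, 1] + x * rnorm(1)
      got <- backwardEliminate(x, Y)
      want <- oracleBackward(x, Y)
      expect_equal(got$order, want$order)
      expect_equal(got$bestk, want$bestk, tolerance = 1e-8)
    }
  }
  # p = 1: nothing to eliminate
  x <- sample(c(0.5, -0.5), 30, replace = TRUE)
  Y <- matrix(rnorm(30), 30, 1)
  be <- backwardEliminate(x, Y)
  expect_equal(be$bestk, lrtJoint(x, Y, 1L))
})

test_that("best-k statistics are nested and nonnegative", {
  withr::local_seed(41)
  for (rep in 1:5) {
    cross <- makeCross(N = 50, p = 6, seed = rep)
    sc <- scanGenome(cross)
    expect_true(all(scanStats(sc) >= 0))
    expect_true(all(apply(scanStats(sc), 1, function(r)
      all(diff(r) >= -1e-8))))
    # each row's elimination order is a permutation of the traits
    expect_true(all(apply(eliminationOrder(sc), 1, function(o)
      identical(sort(o), 1:6))))
  }
})

test_that("null joint LRT is asymptotically chi-square in the set size", {
  withr::local_seed(51)
  N <- 200; nsim <- 400
  for (k in c(1L, 3L)) {
    stats <- replicate(nsim, {
      x <- sample(c(0.5, -0.5), N, replace = TRUE)
      Y <- matrix(rnorm(N * 4), N, 4)
      lrtJoint(x, Y, seq_len(k))
    })
    q95 <- unname(quantile(stats, 0.95))
    ref <- qchisq(0.95, df = k)
    # 3x the Monte-Carlo SE of an empirical 95th percentile, plus a small
    # finite-N allowance
    mcSE <- sqrt(0.05 * 0.95 / nsim) / dchisq(ref, df = k)
    expect_lt(abs(q95 - ref), 3 * mcSE + 0.3)
  }
})

test_that("genome scans are locus-independent and reduce to one locus", {
  cross <- makeCross(N = 50, p = 3, L = 6, seed = 5)
  sc <- scanGenome(cross)
  be <- backwardEliminate(genotypes(cross)[, 4], phenotypes(cross))
  expect_equal(scanStats(sc)[4, ], be$bestk)
  expect_equal(eliminationOrder(sc)[4, ], be$order)

  # permuting locus order permutes scan rows identically
  perm <- c(3, 1, 6, 2, 5, 4)
  sc2 <- scanGenome(genotypes(cross)[, perm], phenotypes(cross))
  expect_equal(scanStats(sc2), scanStats(sc)[perm, ])
})

test_that("individual- and single-effect statistics verify by refit", {
  cross <- makeCross(N = 60, p = 4, seed = 6)
  et <- effectTests(cross)
  x <- genotypes(cross)[, 2]
  Y <- phenotypes(cross)
  Tfull <- lrtJoint(x, Y)
  for (k in 1:4) {
    expect_equal(et$indiv[2, k], Tfull - lrtJoint(x, Y, setdiff(1:4, k)),
                 tolerance = 1e-8)
    expect_equal(et$single[2, k], lrtJoint(x, Y, k), tolerance = 1e-8)
  }

  # p = 1: indiv, single and joint coincide
  c1 <- makeCross(N = 40, p = 1, seed = 7)
  e1 <- effectTests(c1)
  j1 <- vapply(seq_len(nLoci(c1)), function(l)
    lrtJoint(genotypes(c1)[, l], phenotypes(c1)), 0)
  expect_equal(drop(e1$indiv), j1, tolerance = 1e-8)
  expect_equal(drop(e1$single), j1, tolerance = 1e-8)
})

test_that("single-effect tests approach univariate scans for independent traits", {
  withr::local_seed(61)
  N <- 500
  map <- tinyMap()
  g <- simulateRILGenotypes(map, N, 8)
  Y <- simulateTraits(g, nullEffectSpec(4, Sigma = diag(4)), 9)
  et <- effectTests(qtlCross(g, Y, map))
  x <- g[, 3]
  uni <- vapply(1:4, function(k) {
    r0 <- sum(resid(lm(Y[, k] ~ 1))^2)
    r1 <- sum(resid(lm(Y[, k] ~ x))^2)
    N * log(r0 / r1)
  }, 0)
  # agreement is asymptotic in N; allow O(p/N)-scale slack on the statistic
  expect_lt(max(abs(et$single[3, ] - uni)), 1.5)
})

test_that("conditional effect tests reduce to their limiting cases", {
  cross <- makeCross(N = 60, p = 4, seed = 10)
  x <- genotypes(cross)[, 1]
  Y <- phenotypes(cross)
  et <- effectTests(cross)
  # empty trivial set: the individual-effect test
  expect_equal(lrtGivenTrivial(x, Y, 2, integer()), et$indiv[1, 2],
               tolerance = 1e-8)
  # everything else trivial: the single-effect test
  expect_equal(lrtGivenTrivial(x, Y, 2, c(1L, 3L, 4L)), et$single[1, 2],
               tolerance = 1e-8)
  # difference-of-joint-fits identity
  expect_equal(lrtGivenTrivial(x, Y, 3, 4L),
               lrtJoint(x, Y, 1:3) - lrtJoint(x, Y, c(1L, 2L)),
               tolerance = 1e-8)
  expect_error(lrtGivenTrivial(x, Y, 2, c(2L, 3L)), "trivial")
})
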
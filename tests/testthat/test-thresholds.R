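# synthetic PermutationNull from explicit records
fakeNull <- function(bestk, step = bestk, indiv = apply(bestk, 1, max),
                     single = indiv) {
  new("PermutationNull", bestkMax = bestk, stepMax = step,
      indivMax = indiv, singleMax = single,
      nPermutations = nrow(bestk), seed = 0L)
}

test_that("permutation records are deterministic and correctly shaped", {
  cross <- makeCross(N = 40, p = 3, L = 6, seed = 2)
  n1 <- permutationNull(cross, 1, seed = 5)
  expect_equal(dim(n1@bestkMax), c(1L, 3L))
  n2 <- permutationNull(cross, 25, seed = 5)
  expect_identical(n2@bestkMax, permutationNull(cross, 25, 5)@bestkMax)
  expect_false(identical(n2@bestkMax,
                         permutationNull(cross, 25, 6)@bestkMax))
})

test_that("single-trait permutation maxima match a univariate oracle", {
  cross <- makeCross(N = 40, p = 1, L = 6, seed = 3)
  B <- 20
  nul <- permutationNull(cross, B, seed = 9)
  # replay the same permutation stream with plain lm() scans
  X <- genotypes(cross); y <- phenotypes(cross)[, 1]
  N <- nrow(X)
  set.seed(9)
  want <- vapply(seq_len(B), function(b) {
    Xp <- X[sample.int(N), , drop = FALSE]
    max(vapply(seq_len(ncol(Xp)), function(l) {
      r0 <- sum(resid(lm(y ~ 1))^2)
      r1 <- sum(resid(lm(y ~ Xp[, l]))^2)
      N * log(r0 / r1)
    }, 0))
  }, 0)
  expect_equal(drop(nul@bestkMax), want, tolerance = 1e-8)
  # with one trait, individual = single = joint records
  expect_equal(nul@indivMax, drop(nul@bestkMax), tolerance = 1e-8)
  expect_equal(nul@singleMax, drop(nul@bestkMax), tolerance = 1e-8)
})

test_that("lambda(alpha) is the conservative order statistic", {
  recs <- matrix(c(seq_len(1000) / 10, seq_len(1000)), 1000, 2)
  nul <- fakeNull(recs)
  expect_equal(lambdaAlpha(nul, 0.05), c(sort(recs[, 1])[950], 950))
  # alpha near 1: the smallest recorded maximum
  expect_equal(lambdaAlpha(nul, 0.9995), c(0.1, 1))
  # constant records
  nulC <- fakeNull(matrix(7, 50, 3))
  expect_equal(lambdaAlpha(nulC, 0.05), rep(7, 3))
  expect_error(lambdaAlpha(nul, 1.2), "alpha")
  expect_warning(lambdaAlpha(fakeNull(matrix(1:10, 10, 1)), 0.05),
                 "coarse")
})

test_that("joint calibration solves the per-family level beta", {
  # one trait: beta = alpha and lambda(beta) = lambda(alpha)
  withr::local_seed(71)
  one <- fakeNull(matrix(rchisq(1000, 3), 1000, 1))
  lb <- lambdaBeta(one, 0.05)
  expect_equal(lb$beta, 0.05, tolerance = 1e-9)
  expect_equal(lb$lambda, lambdaAlpha(one, 0.05))

  # perfectly dependent columns: joint = marginal, beta = alpha
  v <- rchisq(1000, 3)
  dep <- fakeNull(cbind(v, v * 2 + 1, v^2))
  expect_equal(lambdaBeta(dep, 0.05)$beta, 0.05, tolerance = 1e-9)

  # independent columns: beta approaches the Sidak level 1-(1-a)^(1/p)
  B <- 4000; p <- 4
  ind <- fakeNull(matrix(rchisq(B * p, 5), B, p))
  beta <- lambdaBeta(ind, 0.05)$beta
  sidak <- 1 - (1 - 0.05)^(1 / p)
  expect_lt(abs(beta - sidak), 0.006)

  # dominance and empirical joint coverage on the records themselves
  lb <- lambdaBeta(ind, 0.05)
  la <- lambdaAlpha(ind, 0.05)
  expect_true(all(lb$lambda >= la - 1e-12))
  cover <- mean(apply(sweep(ind@bestkMax, 2, lb$lambda, "<="), 1, all))
  expect_gte(cover, 0.95)
})

test_that("tau, sequential and penalty thresholds behave as quantiles", {
  cross <- makeCross(N = 40, p = 3, L = 6, seed = 4)
  nul <- permutationNull(cross, 60, seed = 2)
  # quantile monotonicity in alpha
  expect_gte(tauAlpha(nul, 0.02), tauAlpha(nul, 0.10))
  expect_true(all(lambdaAlpha(nul, 0.02) >= lambdaAlpha(nul, 0.10)))
  expect_gte(bicPenalty(nul, 0.02), bicPenalty(nul, 0.10))
  expect_true(all(seqThresholds(nul, 0.05) >= 0))

  # penalty is the (1 - alpha) order statistic of the forward-selection
  # maxima, and those maxima dominate every per-trait statistic
  fk <- fakeNull(matrix(rchisq(200, 2), 200, 1),
                 single = sort(rchisq(200, 4)))
  expect_equal(bicPenalty(fk, 0.05), fk@singleMax[190])

  # one trait: tau and the sequential threshold equal lambda_1
  c1 <- makeCross(N = 40, p = 1, L = 6, seed = 5)
  n1 <- permutationNull(c1, 40, seed = 3)
  expect_equal(tauAlpha(n1, 0.05), lambdaAlpha(n1, 0.05)[1])
  expect_equal(seqThresholds(n1, 0.05), unname(lambdaAlpha(n1, 0.05)))
})

test_that("the assembled threshold set satisfies its invariants", {
  cross <- makeCross(N = 40, p = 4, L = 6, seed = 6)
  ts <- estimateThresholds(cross, 0.05, nPermutations = 60, seed = 11)
  expect_s4_class(ts, "ThresholdSet")
  expect_lte(ts@beta, 0.05)
  expect_true(all(ts@lambdaBeta >= ts@lambdaAlpha - 1e-12))
  expect_identical(ts@nPermutations, 60L)
  # bit-exact reproducibility under the seed
  ts2 <- estimateThresholds(cross, 0.05, nPermutations = 60, seed = 11)
  expect_identical(ts@lambdaAlpha, ts2@lambdaAlpha)
  expect_identical(ts@seqThresholds, ts2@seqThresholds)
})
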
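test_that("path enumeration respects propensity pruning and ordering", {
  bd2 <- makeFixture("bd_x0_2")
  expect_equal(enumeratePaths(bd2$system, bd2$x0, c(1L, 1L)),
    list(c(1L, 2L), c(2L, 1L)))
  # from extinction the death-first route is blocked
  bd0 <- makeFixture("bd_x0_0")
  expect_equal(enumeratePaths(bd0$system, bd0$x0, c(1L, 1L)),
    list(c(1L, 2L)))
  expect_equal(enumeratePaths(bd0$system, bd0$x0, c(0L, 0L)),
    list(integer(0)))
  expect_equal(length(enumeratePaths(bd2$system, bd2$x0, c(3L, 2L))),
    choose(5, 2))
  expect_error(enumeratePaths(bd2$system, bd2$x0, c(6L, 6L), cap = 10),
    "overflow")
})

test_that("pathChain records exit and along-chain rates of the worked example", {
  bd2 <- makeFixture("bd_x0_2")
  ch <- pathChain(bd2$system, bd2$x0, c(1L, 2L, 2L, 2L))
  expect_equal(ch@alpha, c(1.2, 1.3, 1.2, 1.1, 1.0))
  expect_equal(ch@beta, c(1.0, 0.3, 0.2, 0.1))
  expect_equal(ch@states[5, ], c(1L, 3L))
  bd0 <- makeFixture("bd_x0_0")
  expect_error(pathChain(bd0$system, bd0$x0, c(2L, 1L)), "zero propensity")
})

test_that("the two-state closed form matches its divided difference", {
  ch <- makeChain(alpha = c(1.0, 1.1), beta = 1.0)
  sol <- pathChainSolve(ch, times = 1)
  expect_equal(sol$probs[2, 1], (exp(-1.0) - exp(-1.1)) / 0.1,
    tolerance = 1e-13)
  expect_equal(sol$probs[1, 1], exp(-1.0), tolerance = 1e-14)
  # at t = 0+ the mass is still on the first state
  sol0 <- pathChainSolve(ch, times = 1e-14)
  expect_equal(sol0$probs[, 1], c(ch@initialMass, 0), tolerance = 1e-12)
})

test_that("equal exit rates give the degenerate t-exponential limit", {
  ch <- makeChain(alpha = c(0.8, 0.8), beta = 0.6, C = 0.9)
  tt <- c(0.5, 2, 6)
  sol <- pathChainSolve(ch, times = tt)
  expect_all_close(sol$probs[2, ], 0.9 * 0.6 * tt * exp(-0.8 * tt), 1e-13)
  expect_all_close(sol$probs[2, ], odeChainProbs(ch, tt)[2, ], 1e-10)
})

test_that("closed-form chain probabilities match the ODE oracle", {
  set.seed(31)
  tt <- c(0.5, 1, 3, 8)
  for (i in 1:10) {
    m <- sample(3:6, 1)
    alpha <- round(runif(m, 0.3, 2), 2)
    if (i %% 2 == 0) alpha[2] <- alpha[1]    # force repeated rates
    beta <- round(runif(m - 1, 0.05, 1), 2) * pmin(alpha[-m], 1)
    ch <- makeChain(alpha, pmin(beta, alpha[-m]))
    sol <- pathChainSolve(ch, tt)
    expect_all_close(sol$probs, odeChainProbs(ch, tt), 1e-10)
    expect_all_close(colSums(sol$probs) + sol$sink, ch@initialMass, 1e-10)
    expect_true(all(sol$probs >= -1e-12))
  }
})

test_that("long chains fall back to the matrix-exponential route", {
  m <- 60
  ch <- makeChain(alpha = seq(0.5, 1.5, length.out = m),
    beta = rep(0.4, m - 1))
  sol <- pathChainSolve(ch, times = c(1, 5))
  expect_equal(sol$method, "matrix-exponential")
  expect_all_close(sol$probs, odeChainProbs(ch, c(1, 5)), 1e-9)
})

test_that("states decompose exactly into their path chains", {
  bd2 <- makeFixture("bd_x0_2")
  times <- c(0.5, 1, 5)
  # single-firing state: one path, identical to the CME recursion base case
  dec1 <- decomposeState(bd2$system, bd2$x0, c(1L, 0L), times)
  expect_equal(dec1$nPaths, 1L)
  expect_lt(dec1$maxAbsDiff, 1e-10)
  dec <- decomposeState(bd2$system, bd2$x0, c(2L, 1L), times)
  expect_equal(dec$nPaths, 3L)
  expect_lt(dec$maxAbsDiff, 1e-8)
  # each path's terminal probability is a non-negative summand of the total
  paths <- enumeratePaths(bd2$system, bd2$x0, c(2L, 1L))
  for (p in paths) {
    term <- pathChainSolve(pathChain(bd2$system, bd2$x0, p), times)$probs[4, ]
    expect_true(all(term >= -1e-14))
    expect_true(all(term <= dec$cmeProb + 1e-10))
  }
})

test_that("the origin's decomposition is the bare exponential decay", {
  bd2 <- makeFixture("bd_x0_2")
  dec <- decomposeState(bd2$system, bd2$x0, c(0L, 0L), times = c(1, 4))
  expect_all_close(dec$pathSum, exp(-1.2 * c(1, 4)), 1e-12)
  expect_lt(dec$maxAbsDiff, 1e-10)
})
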
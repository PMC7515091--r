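test_that("gammaMap reconstructs populations from firing records", {
  bd <- makeFixture("bd_x0_2")
  expect_equal(gammaMap(bd$system, bd$x0, c(3L, 1L)), 4L)
  expect_equal(gammaMap(bd$system, bd$x0, c(0L, 0L)), bd$x0)
  # a death at population zero is outside the lattice
  bd0 <- makeFixture("bd_x0_0")
  expect_null(gammaMap(bd0$system, bd0$x0, c(0L, 1L)))
  expect_error(gammaMap(bd0$system, bd0$x0, c(1L, 1L, 1L)), "per reaction")
  expect_error(gammaMap(bd0$system, c(1L, 1L), c(0L, 0L)), "per species")
})

test_that("gammaMap is additive over single firings", {
  dm <- makeFixture("dimerization_toy")
  set.seed(11)
  for (i in 1:50) {
    r <- as.integer(rpois(2, 2))
    x <- gammaMap(dm$system, dm$x0, r)
    if (is.null(x)) next
    for (n in 1:2) {
      xn <- gammaMap(dm$system, dm$x0, r + as.integer(1:2 == n))
      if (!is.null(xn))
        expect_equal(xn, x + netStoich(dm$system)[n, ])
    }
  }
})

test_that("gammaPullback finds every preimage and round-trips", {
  bd <- makeFixture("bd_x0_0")
  expect_equal(gammaPullback(bd$system, bd$x0, 1L, maxTotal = 3),
    rbind(c(1L, 0L), c(2L, 1L)))
  # arithmetic oracle: r1 - r2 = 1 with r1 + r2 <= 5
  expect_equal(gammaPullback(bd$system, bd$x0, 1L, maxTotal = 5),
    rbind(c(1L, 0L), c(2L, 1L), c(3L, 2L)))
  expect_equal(gammaPullback(bd$system, bd$x0, bd$x0, maxTotal = 0),
    rbind(c(0L, 0L)))
  pre <- gammaPullback(bd$system, bd$x0, 3L, maxTotal = 7)
  expect_gt(nrow(pre), 1L)  # Gamma is not injective in r
  for (i in seq_len(nrow(pre)))
    expect_equal(gammaMap(bd$system, bd$x0, pre[i, ]), 3L)
})

test_that("mass-action propensities follow the binomial convention", {
  bd <- makeFixture("bd_x0_0")
  expect_equal(speciesPropensity(bd$system, 7L, n = 1), 1.0)   # no reactants
  expect_equal(speciesPropensity(bd$system, 0L, n = 2), 0.0)
  expect_equal(speciesPropensity(bd$system, 5L, n = 2), 0.5)   # cd * x
  dm <- makeFixture("dimerization_toy")
  expect_equal(speciesPropensity(dm$system, c(4L, 0L), n = 2), 0.1 * choose(4, 2))
  expect_equal(speciesPropensity(dm$system, c(1L, 5L), n = 2), 0.0)
  expect_error(speciesPropensity(bd$system, 1L, n = 3), "invalid reaction")
})

test_that("reaction propensities are the species law pulled back by Gamma", {
  bd <- makeFixture("bd_x0_0")
  expect_equal(reactionPropensity(bd$system, bd$x0, c(2L, 1L), n = 2), 0.1)
  expect_equal(reactionPropensity(bd$system, bd$x0, c(0L, 0L), n = 2), 0.0)
  # Gamma image outside the lattice: all propensities vanish
  expect_equal(reactionPropensity(bd$system, bd$x0, c(0L, 1L)), c(0, 0))
  set.seed(21)
  for (i in 1:25) {
    r <- as.integer(rpois(2, 3))
    x <- gammaMap(bd$system, bd$x0, r)
    expected <- if (is.null(x)) c(0, 0) else speciesPropensity(bd$system, x)
    expect_equal(reactionPropensity(bd$system, bd$x0, r), expected)
  }
})

test_that("total propensity matches the worked generator diagonals", {
  expect_equal(totalPropensity(bdSystem(1.0, 0.1), 2L, c(0L, 0L)), 1.2)
  expect_equal(totalPropensity(bdSystem(1.0, 0.1), 0L, c(0L, 0L)), 1.0)
  pb <- makeFixture("pure_birth")
  for (k in 0:5)
    expect_equal(totalPropensity(pb$system, pb$x0, k), 1.0)
})

test_that("custom propensity hooks override mass action by name", {
  bd <- makeFixture("bd_x0_0")
  sys <- setPropensityHook(bd$system, "death", function(x) 0.5 * x[1]^2)
  expect_equal(speciesPropensity(sys, 3L, n = 2), 4.5)
  expect_equal(speciesPropensity(sys, 3L, n = 1), 1.0)
  expect_error(setPropensityHook(bd$system, "lysis", identity),
    "unknown reaction")
})

test_that("ReactionSystem validity rejects inconsistent definitions", {
  expect_error(ReactionSystem("X", rbind(0L), rbind(1L), -1.0), "positive")
  expect_error(ReactionSystem("X", rbind(c(0L, 0L)), rbind(c(1L, 0L)), 1.0),
    "must be")
  expect_error(ReactionSystem(character(0), matrix(0L, 1, 0),
    matrix(0L, 1, 0), 1.0), "at least one species")
})
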
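test_that("the solve starts from a point mass and conserves probability", {
  bd <- makeFixture("bd_x0_0")
  d <- solveReactionCME(bd$system, bd$x0, times = c(1e-12, 1, 5, 10),
    eps = 1e-8)
  expect_equal(stateProbability(d, c(0L, 0L))[1], 1, tolerance = 1e-9)
  expect_all_close(colSums(probabilities(d)) + tailMass(d), 1, 1e-10)
  expect_lt(max(tailMass(d)), 1e-8)
})

test_that("pure-birth firing counts are exactly Poisson", {
  pb <- makeFixture("pure_birth")
  d <- solveReactionCME(pb$system, pb$x0, times = 1, eps = 1e-12)
  expect_equal(stateProbability(d, 0L)[1], exp(-1), tolerance = 1e-12)
  sm <- shellMasses(d)
  expect_all_close(sm[, 1], dpois(0:(nrow(sm) - 1L), 1), 1e-12)
})

test_that("truncation failure is reported with the residual tail", {
  bd <- makeFixture("bd_x0_0")
  expect_error(
    solveReactionCME(bd$system, bd$x0, times = 10, eps = 1e-8, MMax = 16L),
    "tail mass")
})

test_that("shell tails are monotone and the outflow identity holds", {
  for (fx in c("bd_x0_0", "bd_x0_2", "dimerization_toy", "toggle_toy")) {
    f <- makeFixture(fx)
    d <- solveReactionCME(f$system, f$x0, times = c(2.5, 5), eps = 1e-8)
    M <- truncationDepth(d@generator@space)
    psis <- vapply(0:(M - 1L), function(m) tailBeyond(d, m)[2L], numeric(1))
    expect_true(all(diff(psis) <= 1e-12), info = fx)
    for (m in 1:3) {
      id <- tailMassIdentity(d, m = m, time = 5)
      expect_lt(abs(id$diff), 1e-6)
    }
  }
  # before anything can fire, both flux and tail vanish
  bd <- makeFixture("bd_x0_0")
  d0 <- solveReactionCME(bd$system, bd$x0, times = c(1e-14, 5), eps = 1e-8)
  id0 <- tailMassIdentity(d0, m = 2, time = 1e-14)
  expect_lt(abs(id0$phi), 1e-12)
  expect_lt(abs(id0$psi), 1e-12)
})

test_that("push-forward agrees with the direct species FSP solve", {
  bd <- makeFixture("bd_x0_0")
  times <- c(1, 5, 10)
  sp <- pushForward(solveReactionCME(bd$system, bd$x0, times, eps = 1e-8))
  fsp <- solveSpeciesFSP(bd$system, bd$x0, times, eps = 1e-8)
  for (x in 0:40)
    expect_all_close(speciesProbability(sp, x), speciesProbability(fsp, x),
      2e-8)
  expect_gte(min(colSums(fsp@probs)), 1 - 1e-8)
})

test_that("push-forward groups the full pull-back of each population", {
  bd <- makeFixture("bd_x0_0")
  d <- solveReactionCME(bd$system, bd$x0, times = 10, eps = 1e-10)
  sp <- pushForward(d)
  pre <- gammaPullback(bd$system, bd$x0, 1L,
    maxTotal = truncationDepth(d@generator@space))
  direct <- 0
  for (i in seq_len(nrow(pre))) direct <- direct + stateProbability(d, pre[i, ])
  expect_equal(direct, speciesProbability(sp, 1L)[1], tolerance = 1e-12)
})

test_that("reaction-count partial sums approach the species probability from below", {
  bd <- makeFixture("bd_x0_0")
  d <- solveReactionCME(bd$system, bd$x0, times = 10, eps = 1e-10)
  pz1 <- speciesProbability(pushForward(d), 1L)[1]
  partial <- cumsum(c(stateProbability(d, c(1L, 0L))[1],
    stateProbability(d, c(2L, 1L))[1],
    stateProbability(d, c(3L, 2L))[1]))
  expect_true(all(diff(partial) >= 0))
  expect_true(all(partial <= pz1 + 1e-10))
})

test_that("an absorbed origin stays a point mass in the species solve", {
  sys <- ReactionSystem("X", rbind(1L), rbind(0L), 0.1, "death")
  fsp <- solveSpeciesFSP(sys, 0L, times = c(1, 10), eps = 1e-10)
  expect_equal(speciesProbability(fsp, 0L), c(1, 1), tolerance = 1e-12)
  expect_equal(nrow(fsp@states), 1L)
})

test_that("pure-birth push-forward is the shifted Poisson law", {
  pb <- makeFixture("pure_birth")
  sp <- pushForward(solveReactionCME(pb$system, pb$x0, times = 2, eps = 1e-12))
  for (k in 0:10)
    expect_equal(speciesProbability(sp, k)[1], dpois(k, 2),
      tolerance = 1e-11)
})

test_that("sub-unit initial mass scales the whole solution", {
  bd <- makeFixture("bd_x0_0")
  d1 <- solveReactionCME(bd$system, bd$x0, times = 3, eps = 1e-10, C = 1)
  dh <- solveReactionCME(bd$system, bd$x0, times = 3, eps = 1e-10, C = 0.5)
  expect_all_close(probabilities(dh), 0.5 * probabilities(d1), 1e-12)
  expect_all_close(colSums(probabilities(dh)) + tailMass(dh), 0.5, 1e-10)
})
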
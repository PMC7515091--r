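test_that("shell expansion matches brute-force reachability", {
  bd0 <- makeFixture("bd_x0_0")
  expect_equal(shellSizes(expandShells(bd0$system, bd0$x0, 4)),
    c(1L, 1L, 2L, 2L, 3L))
  bd2 <- makeFixture("bd_x0_2")
  sp2 <- expandShells(bd2$system, bd2$x0, 3)
  expect_equal(shellSizes(sp2), c(1L, 2L, 3L, 3L))
  # (0,3) is pruned: its Gamma image would be population -1
  expect_false("0,3" %in% apply(countStates(sp2), 1, paste, collapse = ","))
  for (fx in c("dimerization_toy", "toggle_toy", "pure_birth")) {
    f <- makeFixture(fx)
    expect_equal(shellSizes(expandShells(f$system, f$x0, 5)),
      bruteShellSizes(f$system, f$x0, 5), info = fx)
  }
})

test_that("an absorbing origin yields empty shells", {
  # only a death reaction, starting from extinction
  sys <- ReactionSystem("X", rbind(1L), rbind(0L), 0.1, "death")
  expect_equal(shellSizes(expandShells(sys, 0L, 3)), c(1L, 0L, 0L, 0L))
})

test_that("shell sizes are invariant under reaction relabeling", {
  bd <- makeFixture("bd_x0_2")
  swapped <- ReactionSystem("X", rbind(1L, 0L), rbind(0L, 1L),
    c(0.1, 1.0), c("death", "birth"))
  for (M in c(3, 6))
    expect_equal(shellSizes(expandShells(bd$system, bd$x0, M)),
      shellSizes(expandShells(swapped, bd$x0, M)))
})

test_that("generator entries match the worked birth-death matrix", {
  bd <- makeFixture("bd_x0_2")
  space <- expandShells(bd$system, bd$x0, 3)
  gen <- buildGenerator(space)
  keys <- apply(countStates(space), 1, paste, collapse = ",")
  A <- as.matrix(gen@Astar)
  expect_equal(A[match("0,0", keys), match("0,0", keys)], -1.2)  # -cb - 2cd
  expect_equal(A[match("1,1", keys), match("1,0", keys)], 0.3)   # 3cd into (1,1)
  expect_equal(A[match("1,0", keys), match("0,0", keys)], 1.0)   # cb
  expect_equal(A[match("1,1", keys), match("1,1", keys)], -1.2)
  expect_equal(Matrix::diag(gen@Astar), -gen@alpha)
})

test_that("the shell-ordered generator is strictly lower triangular with spectrum -alpha", {
  for (fx in fixtureNames()) {
    f <- makeFixture(fx)
    gen <- buildGenerator(expandShells(f$system, f$x0, 8))
    expect_true(verifyTriangular(gen)$ok, info = fx)
    ev <- sort(Re(eigen(as.matrix(gen@Astar), only.values = TRUE)$values))
    expect_all_close(ev, sort(-gen@alpha), 1e-9)
  }
})

test_that("triangularity violations are detected and located", {
  bd <- makeFixture("bd_x0_0")
  gen <- buildGenerator(expandShells(bd$system, bd$x0, 4))
  A <- as.matrix(gen@Astar)
  A[1, 3] <- 0.5  # inject an upward (backward-in-shell) rate
  rep <- verifyTriangular(Matrix::Matrix(A, sparse = TRUE))
  expect_false(rep$ok)
  expect_equal(rep$violations$row, 1)
  expect_equal(rep$violations$col, 3)
})

test_that("inflow entries correspond exactly to single-firing predecessors", {
  f <- makeFixture("toggle_toy")
  space <- expandShells(f$system, f$x0, 6)
  gen <- buildGenerator(space)
  A <- as.matrix(gen@Astar)
  st <- countStates(space)
  for (i in seq_len(nrow(st))) {
    src <- which(A[i, ] > 0)
    for (j in src) {
      step <- st[i, ] - st[j, ]
      expect_equal(sum(step), 1L)
      n <- which(step == 1L)
      expect_equal(A[i, j], reactionPropensity(f$system, f$x0, st[j, ], n))
    }
  }
})

test_that("the state index dump reports shells and Gamma images", {
  bd <- makeFixture("bd_x0_2")
  space <- expandShells(bd$system, bd$x0, 2)
  df <- writeStateIndex(space, file = tempfile(fileext = ".tsv"))
  expect_equal(nrow(df), sum(shellSizes(space)))
  expect_equal(df$gamma_population[df$state == "1,1"], "2")
  expect_equal(df$shell, c(0L, 1L, 1L, 2L, 2L, 2L))
})
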
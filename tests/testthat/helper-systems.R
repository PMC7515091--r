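# Shared builders and independent oracles for the test suite.

bdSystem <- function(cb, cd) {
  ReactionSystem(
    speciesNames = "X",
    reactantStoich = rbind(0L, 1L),
    productStoich = rbind(1L, 0L),
    rateConstants = c(cb, cd),
    reactionNames = c("birth", "death"))
}

# A path chain with prescribed rates, detached from any kinetics: states
# are successive firings of a single dummy reaction.  Used to probe the
# closed-form engine on arbitrary (alpha, beta) configurations.
makeChain <- function(alpha, beta, C = 1) {
  m <- length(alpha)
  stopifnot(length(beta) == m - 1L)
  sys <- ReactionSystem("X", rbind(0L), rbind(1L), 1.0, "step")
  new("PathChain",
    states = matrix(0:(m - 1L), ncol = 1L),
    reactionSequence = rep(1L, m - 1L),
    initialMass = C,
    alpha = as.numeric(alpha),
    beta = as.numeric(beta),
    x0 = 0L,
    system = sys)
}

# Independent ODE oracle for a path chain: lsoda on the (m+1)-state
# generator (states plus sink) at tight tolerance.
odeChainProbs <- function(chain, times) {
  A <- chainGenerator(chain)
  m <- chainLength(chain)
  u0 <- numeric(m + 1L)
  u0[1L] <- chain@initialMass
  sol <- deSolve::ode(y = u0, times = c(0, times),
    func = function(t, y, p) list(as.vector(A %*% y)),
    rtol = 1e-12, atol = 1e-14)
  t(unname(sol[-1L, 1L + seq_len(m), drop = FALSE]))
}

# Brute-force reaction-count shell sizes: enumerate the full integer grid
# up to depth M and keep states reachable through positive-propensity
# predecessors, never consulting expandShells.
bruteShellSizes <- function(system, x0, M) {
  nr <- numReactions(system)
  reach <- list("0" = integer(nr))
  names(reach) <- paste(integer(nr), collapse = ",")
  sizes <- integer(M + 1L)
  sizes[1L] <- 1L
  frontier <- list(integer(nr))
  for (m in seq_len(M)) {
    nxt <- list()
    for (r in frontier) {
      for (n in seq_len(nr)) {
        if (reactionPropensity(system, x0, r, n) > 0) {
          rp <- r
          rp[n] <- rp[n] + 1L
          key <- paste(rp, collapse = ",")
          if (is.null(nxt[[key]])) nxt[[key]] <- rp
        }
      }
    }
    sizes[m + 1L] <- length(nxt)
    frontier <- unname(nxt)
  }
  sizes
}

expect_all_close <- function(a, b, tol) {
  expect_lt(max(abs(a - b)), tol)
}
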
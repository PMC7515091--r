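#' Run the full property-check battery on the built-in fixtures
#'
#' Exercises, on every requested fixture, the structural and analytical
#' identities the framework rests on: strict lower-triangularity of the
#' shell-ordered generator and the equality of its spectrum with the
#' negated exit rates; probability conservation of the truncated solve;
#' the shell conservation/outflow identity; the decomposition of
#' reaction-count states into path chains; single-gate and cascade
#' dominance of the gating bounds; and agreement of a seeded SSA ensemble
#' with the solved species distribution (at the Monte-Carlo rate).
#' Margins are reported per check; nothing is raised on failure.
#'
#' @param fixtures character vector of fixture names.
#' @param t evaluation time for the distribution checks.
#' @param eps truncation tolerance.
#' @param M shell depth for the structural checks.
#' @param nSSA trajectories for the SSA check (its tolerance scales as
#'   `3 * sqrt(#states / nSSA)`).
#' @param seed master seed for the SSA check.
#' @return data.frame with columns `fixture`, `check`, `pass`, `margin`.
#' @examples
#' validateAll(fixtures = "bd_x0_2", t = 2, nSSA = 200)
#' @export
validateAll <- function(fixtures = fixtureNames(), t = 5, eps = 1e-8,
                        M = 8L, nSSA = 2000L, seed = 1L) {
  rows <- list()
  add <- function(fixture, check, pass, margin) {
    rows[[length(rows) + 1L]] <<- data.frame(fixture = fixture,
      check = check, pass = pass, margin = margin)
  }
  for (fx in fixtures) {
    f <- makeFixture(fx)
    space <- expandShells(f$system, f$x0, M)
    gen <- buildGenerator(space)
    tri <- verifyTriangular(gen)
    add(fx, "generator lower-triangular", tri$ok,
      -nrow(tri$violations))
    specErr <- max(abs(sort(eigen(as.matrix(gen@Astar),
      only.values = TRUE)$values) - sort(-gen@alpha)))
    add(fx, "spectrum equals -alpha", specErr <= 1e-9, 1e-9 - specErr)
    dist <- solveReactionCME(f$system, f$x0, times = c(t / 2, t), eps = eps)
    consErr <- max(abs(colSums(dist@probs) + dist@tailMass - 1))
    add(fx, "conservation", consErr <= 1e-10, 1e-10 - consErr)
    mono <- diff(vapply(0:(dist@generator@space@M - 1L), function(m)
      tailBeyond(dist, m)[2L], numeric(1)))
    add(fx, "tail monotone in shell", all(mono <= 1e-12), -max(c(mono, 0)))
    idErr <- abs(tailMassIdentity(dist, m = min(3L,
      dist@generator@space@M - 1L))$diff)
    add(fx, "shell outflow identity", idErr <= 1e-6, 1e-6 - idErr)
    r <- dist@generator@space@states[sum(dist@generator@space@shellSizes[1:3]), ]
    dec <- decomposeState(f$system, f$x0, r, times = c(t / 2, t))
    add(fx, "path-chain decomposition", dec$maxAbsDiff <= 1e-8,
      1e-8 - dec$maxAbsDiff)
    ch <- .longestChain(f$system, f$x0, depth = 4L)
    if (!is.null(ch)) {
      vb <- verifyBound(ch, times = seq(t / 20, t, length.out = 20))
      add(fx, "cascade bound dominance", vb$pointwiseOk && vb$integralOk,
        min(c(vb$pointwise$margin, vb$integral$margin)))
    }
    emp <- ensembleDistribution(f$system, f$x0, t = t, n = nSSA, seed = seed)
    sp <- pushForward(dist)
    tv <- tvDistance(emp, sp)
    tolTV <- 3 * sqrt(nrow(sp@states) / nSSA)
    add(fx, "SSA agreement (TV)", tv <= tolTV, tolTV - tv)
  }
  do.call(rbind, rows)
}

# A depth-step admissible chain found greedily (largest propensity first);
# NULL when the origin is absorbing.
.longestChain <- function(system, x0, depth = 4L) {
  r <- integer(numReactions(system))
  seq <- integer(0)
  for (k in seq_len(depth)) {
    a <- reactionPropensity(system, x0, r)
    if (all(a <= 0)) break
    n <- which.max(a)
    seq <- c(seq, n)
    r[n] <- r[n] + 1L
  }
  if (length(seq) < 2L) NULL else pathChain(system, x0, seq)
}
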
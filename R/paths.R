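#' Enumerate admissible paths from the origin to a reaction-count state
#'
#' An admissible path is a sequence of reaction-count states in which each
#' step increments exactly one firing count.  All paths of length
#' `sum(r) + 1` from the origin to `r` whose every transition has positive
#' propensity are returned as reaction-index sequences, in lexicographic
#' order; zero-propensity transitions are pruned since their chains carry
#' no probability.  The number of paths grows multinomially, so a hard cap
#' guards the enumeration.
#'
#' @param system a [ReactionSystem-class].
#' @param x0 initial population state.
#' @param r target reaction-count state.
#' @param cap maximum number of paths before an overflow error.
#' @return List of integer reaction-index sequences (a single empty
#'   sequence for `r = 0`).
#' @examples
#' bd <- makeFixture("bd_x0_2")
#' enumeratePaths(bd$system, bd$x0, c(1, 1))  # birth-death and death-birth
#' @export
enumeratePaths <- function(system, x0, r, cap = 1e5) {
  x0 <- .checkSpeciesState(system, x0, "x0")
  r <- .checkCountState(system, r)
  count <- 0L
  recurse <- function(r) {
    if (all(r == 0L)) return(list(integer(0)))
    out <- list()
    for (n in which(r > 0L)) {
      pred <- r
      pred[n] <- pred[n] - 1L
      if (reactionPropensity(system, x0, pred, n) <= 0) next
      for (p in recurse(pred)) {
        count <<- count + 1L
        if (count > cap)
          stop("path enumeration overflow: more than ", cap, " paths")
        out[[length(out) + 1L]] <- c(p, n)
      }
    }
    out
  }
  paths <- recurse(r)
  if (length(paths) > 1L) {
    m <- do.call(rbind, paths)
    paths <- paths[.lexOrder(m)]
  }
  paths
}

#' Build a path chain from a reaction firing sequence
#'
#' Walks the firing sequence from the origin, recording each visited
#' reaction-count state, its total exit rate \eqn{\alpha}, and the
#' along-chain rate \eqn{\beta} of each step (the propensity of the firing
#' reaction at the source state).  Every off-path transition is implicitly
#' absorbed by the chain's sink.
#'
#' @param system a [ReactionSystem-class].
#' @param x0 initial population state.
#' @param reactions integer vector of reaction indices fired in order
#'   (empty for the single-state path at the origin).
#' @param C initial mass on the first state, in (0, 1].
#' @return A [PathChain-class].
#' @examples
#' bd <- makeFixture("bd_x0_2")
#' pathChain(bd$system, bd$x0, c(1, 2, 2, 2))  # Example chain to (1, 3)
#' @export
pathChain <- function(system, x0, reactions, C = 1) {
  x0 <- .checkSpeciesState(system, x0, "x0")
  reactions <- as.integer(reactions)
  nr <- numReactions(system)
  if (length(reactions) && (any(reactions < 1L) || any(reactions > nr)))
    stop("reaction indices must lie in 1..", nr)
  m <- length(reactions) + 1L
  states <- matrix(0L, m, nr)
  alpha <- numeric(m)
  beta <- numeric(max(m - 1L, 0L))
  r <- integer(nr)
  alpha[1L] <- totalPropensity(system, x0, r)
  for (k in seq_along(reactions)) {
    n <- reactions[k]
    beta[k] <- reactionPropensity(system, x0, r, n)
    if (beta[k] <= 0)
      stop(sprintf("step %d (reaction %d) has zero propensity: not admissible",
        k, n))
    r[n] <- r[n] + 1L
    states[k + 1L, ] <- r
    alpha[k + 1L] <- totalPropensity(system, x0, r)
  }
  new("PathChain", states = states, reactionSequence = reactions, initialMass = C,
    alpha = alpha, beta = beta, x0 = x0, system = system)
}

#' @rdname pathChain
#' @param chain a `PathChain`.
#' @export
chainLength <- function(chain) nrow(chain@states)

setMethod("show", "PathChain", function(object) {
  m <- chainLength(object)
  cat(sprintf("PathChain: %d states, C = %g\n", m, object@initialMass))
  cat("  path:", paste(apply(object@states, 1L, .key1), collapse = " -> "),
    "\n")
  if (m > 1L)
    cat("  reactions:", paste(object@reactionSequence, collapse = ","),
      " beta:", paste(signif(object@beta, 6), collapse = ","), "\n")
  cat("  alpha:", paste(signif(object@alpha, 6), collapse = ","), "\n")
})

#' The (m+1)-state generator of a path chain including its sink
#'
#' Diagonal entries are the full exit rates \eqn{-\alpha(g_k)}, the
#' subdiagonal carries the along-chain rates \eqn{\beta}, and the last row
#' is the sink collecting all remaining outflow.  Used by the numerical
#' fallback and as the independent ODE oracle for the closed forms.
#'
#' @param chain a [PathChain-class].
#' @return Dense `(m+1) x (m+1)` matrix.
#' @export
chainGenerator <- function(chain) {
  m <- chainLength(chain)
  A <- matrix(0, m + 1L, m + 1L)
  diag(A)[seq_len(m)] <- -chain@alpha
  if (m > 1L)
    A[cbind(2:m, 1:(m - 1L))] <- chain@beta
  off <- chain@alpha - c(chain@beta, 0)  # residual outflow into the sink
  A[m + 1L, seq_len(m)] <- off
  A
}

#' Solve a path chain in closed form
#'
#' The first state decays as \eqn{C e^{-\alpha(g_1) t}}; each subsequent
#' state is the convolution
#' \eqn{p(g_k, t) = \beta(g_{k-1}, g_k) \int_0^t e^{-\alpha(g_k)(t-s)}
#' p(g_{k-1}, s)\,ds}, evaluated exactly in the exponential-polynomial
#' algebra.  The sink takes the conservation complement, so state masses
#' plus sink equal `C` at every time.  Chains longer than
#' `closedFormLimit` states switch to a matrix-exponential solve of the
#' chain generator (the closed form is still exact there, but its term
#' count and factorials grow with depth).
#'
#' @param chain a [PathChain-class].
#' @param times strictly increasing non-negative grid.
#' @param closedFormLimit maximum chain length solved symbolically.
#' @return A list with `times`, `probs` (states x times), `sink`,
#'   `polys` (list of [ExpPolynomial-class], or `NULL` for the numerical
#'   route) and `method`.
#' @examples
#' bd <- makeFixture("bd_x0_2")
#' sol <- pathChainSolve(pathChain(bd$system, bd$x0, c(1, 2, 2, 2)),
#'   times = c(1, 5, 10))
#' sol$probs[5, ]  # p(X_g(t) = (1,3))
#' @export
pathChainSolve <- function(chain, times, closedFormLimit = 50L) {
  times <- .checkTimes(times)
  m <- chainLength(chain)
  if (m <= closedFormLimit) {
    polys <- vector("list", m)
    polys[[1L]] <- expPolynomial(chain@initialMass, 0L, chain@alpha[1L])
    if (m > 1L)
      for (k in 2:m)
        polys[[k]] <- epConvolve(polys[[k - 1L]], a = chain@alpha[k],
          beta = chain@beta[k - 1L])
    probs <- do.call(rbind, lapply(polys, epEval, t = times))
    method <- "closed-form"
  } else {
    A <- chainGenerator(chain)
    u0 <- numeric(m + 1L)
    u0[1L] <- chain@initialMass
    probs <- .propagateGrid(A, u0, times)[seq_len(m), , drop = FALSE]
    polys <- NULL
    method <- "matrix-exponential"
  }
  list(times = times, probs = probs, sink = chain@initialMass - colSums(probs),
    polys = polys, method = method)
}

#' Decompose a reaction-count state into its path chains
#'
#' Any reaction-count state is reached through one of finitely many
#' admissible paths, and its CME probability is exactly the sum of the
#' terminal probabilities of the corresponding independent path chains
#' (each started with full mass 1; sub-chains are not renormalised).  Both
#' sides of the identity are computed independently — the path chains in
#' the closed-form algebra, the CME by the truncated-generator solve — and
#' their maximum absolute difference is reported.
#'
#' @param system a [ReactionSystem-class].
#' @param x0 initial population state.
#' @param r target reaction-count state.
#' @param times strictly increasing non-negative grid.
#' @param eps truncation tolerance for the CME side.
#' @param cap path-enumeration cap.
#' @return List with `times`, `pathSum`, `cmeProb`, `maxAbsDiff` and
#'   `nPaths`.
#' @export
decomposeState <- function(system, x0, r, times, eps = 1e-12, cap = 1e5) {
  times <- .checkTimes(times)
  r <- .checkCountState(system, r)
  paths <- enumeratePaths(system, x0, r, cap = cap)
  if (!length(paths))
    stop("state ", .key1(r), " is not reachable")
  pathSum <- numeric(length(times))
  for (p in paths) {
    sol <- pathChainSolve(pathChain(system, x0, p), times)
    pathSum <- pathSum + sol$probs[nrow(sol$probs), ]
  }
  dist <- solveReactionCME(system, x0, times, eps = eps,
    M0 = max(8L, sum(r)))
  cmeProb <- stateProbability(dist, r)
  list(times = times, pathSum = pathSum, cmeProb = cmeProb,
    maxAbsDiff = max(abs(pathSum - cmeProb)), nPaths = length(paths))
}
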
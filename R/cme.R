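# Linear propagation of du/dt = A u.
#
# Two routes, both accurate to ~1e-13: dense scaling-and-squaring matrix
# exponential (Matrix::expm) for small systems, and uniformization
# (Poisson-weighted power series with the tail cut below 1e-16) for large
# sparse ones.  Both are applied stepwise over the output grid, caching
# exponentials per unique step length.

.DENSE_LIMIT <- 700L

.expAtv <- function(A, dt, u, cache = NULL) {
  n <- length(u)
  if (n <= .DENSE_LIMIT) {
    key <- sprintf("e%.17g", dt)
    E <- if (!is.null(cache)) cache[[key]] else NULL
    if (is.null(E)) {
      E <- as.matrix(Matrix::expm(A * dt))
      if (!is.null(cache)) cache[[key]] <- E
    }
    return(drop(E %*% u))
  }
  .uniformize(A, dt, u)
}

.uniformize <- function(A, dt, u, tol = 1e-16) {
  lam <- max(-min(Matrix::diag(A)), max(abs(A@x), 0))
  if (lam * dt == 0) return(u)
  K <- stats::qpois(tol, lam * dt, lower.tail = FALSE) + 10L
  w <- u
  res <- stats::dpois(0, lam * dt) * w
  for (k in seq_len(K)) {
    w <- w + as.vector(A %*% w) / lam
    res <- res + stats::dpois(k, lam * dt) * w
  }
  res
}

.propagateGrid <- function(A, u0, times) {
  out <- matrix(0, length(u0), length(times))
  cache <- new.env(parent = emptyenv())
  tprev <- 0
  u <- u0
  for (k in seq_along(times)) {
    dt <- times[k] - tprev
    if (dt > 0) u <- .expAtv(A, dt, u, cache)
    out[, k] <- u
    tprev <- times[k]
  }
  out
}

.checkTimes <- function(times) {
  times <- as.numeric(times)
  if (length(times) == 0 || any(times < 0) ||
      is.unsorted(times, strictly = TRUE))
    stop("times must be a strictly increasing non-negative grid")
  times
}

#' Solve the reaction-counts CME with a certified truncation tail
#'
#' Places mass `C` on the origin (no reaction has fired at time zero) and
#' integrates the forward equation on the shell-truncated lower-triangular
#' generator.  The truncation depth starts at `M0` shells and doubles
#' until the tail mass — the probability of having fired more than `M`
#' reactions — is below `eps` at every output time; forward-only flow
#' makes the tail largest at the final time, which is asserted rather than
#' assumed.  Because probability never flows backwards, the retained state
#' probabilities are exact up to propagation round-off: deepening the
#' truncation only adds states.
#'
#' @param system a [ReactionSystem-class].
#' @param x0 initial population state.
#' @param times strictly increasing non-negative time grid.
#' @param eps truncation tolerance in (0, 1).
#' @param C initial mass on the origin in (0, 1]; 1 solves the full CME,
#'   smaller values support sub-chain reuse.
#' @param M0 starting truncation depth.
#' @param MMax hard cap on the truncation depth.
#' @param stateCap hard cap on the number of retained states.
#' @return A [ReactionDistribution-class].
#' @examples
#' bd <- makeFixture("bd_x0_0")
#' d <- solveReactionCME(bd$system, bd$x0, times = c(1, 5, 10), eps = 1e-8)
#' max(tailMass(d))
#' @export
solveReactionCME <- function(system, x0, times, eps = 1e-8, C = 1,
                             M0 = 8L, MMax = 64L, stateCap = 2e6) {
  times <- .checkTimes(times)
  stopifnot(eps > 0, eps < 1, C > 0, C <= 1)
  M <- as.integer(M0)
  repeat {
    space <- expandShells(system, x0, M)
    if (nrow(space@states) > stateCap)
      stop("state cap exceeded at M = ", M)
    gen <- buildGenerator(space)
    u0 <- numeric(nrow(space@states))
    u0[1L] <- C
    probs <- .propagateGrid(gen@Astar, u0, times)
    probs[probs < 0 & probs > -1e-12] <- 0
    tail <- pmax(C - colSums(probs), 0)
    saturated <- space@shellSizes[M + 1L] == 0L  # space is finite: tail exact 0
    if (max(tail) < eps || saturated) break
    if (M >= MMax)
      stop(sprintf(
        "truncation failed: tail mass %.3e at depth M = %d (eps = %.1e)",
        max(tail), M, eps))
    M <- min(2L * M, as.integer(MMax))
  }
  if (which.max(tail) != length(times) && max(tail) > 0)
    stopifnot(max(tail) < eps)  # tail must still be certified everywhere
  new("ReactionDistribution", generator = gen, times = times, probs = probs,
    tailMass = tail, initialMass = C, eps = eps)
}

#' @rdname ReactionDistribution-class
#' @param x a `ReactionDistribution`.
#' @export
tailMass <- function(x) x@tailMass

#' @rdname ReactionDistribution-class
#' @export
probabilities <- function(x) x@probs

#' Probability of one reaction-count state over the grid
#'
#' @param dist a [ReactionDistribution-class].
#' @param r reaction-count state.
#' @return Numeric vector over `dist@times`; zero if `r` was pruned or
#'   lies beyond the truncation.
#' @export
stateProbability <- function(dist, r) {
  r <- .checkCountState(dist@generator@space@system, r)
  keys <- .stateKeys(dist@generator@space@states)
  i <- match(.key1(r), keys)
  if (is.na(i)) rep(0, length(dist@times)) else dist@probs[i, ]
}

#' Probability mass per shell and cumulative tails
#'
#' `shellMasses()` sums state probabilities within each shell;
#' `tailBeyond()` returns \eqn{\psi_{m+1}(t)}, the probability of having
#' fired more than `m` reactions (deeper retained shells plus the
#' truncation tail).
#'
#' @param dist a [ReactionDistribution-class].
#' @param m shell index.
#' @return `shellMasses()`: matrix `(M+1) x times`; `tailBeyond()`:
#'   numeric vector over the grid.
#' @export
shellMasses <- function(dist) {
  sh <- dist@generator@space@shell
  M <- dist@generator@space@M
  out <- matrix(0, M + 1L, length(dist@times))
  agg <- rowsum(dist@probs, sh)
  out[as.integer(rownames(agg)) + 1L, ] <- agg
  out
}

#' @rdname shellMasses
#' @export
tailBeyond <- function(dist, m) {
  sh <- dist@generator@space@shell
  keep <- sh <= m
  pmax(dist@initialMass - colSums(dist@probs[keep, , drop = FALSE]), 0)
}

#' Exact time-integrals of state probabilities
#'
#' Computes \eqn{\int_0^t p(R(s) = r)\,ds} for every retained state by a
#' matrix exponential of the augmented generator
#' \eqn{[[A^*, u_0], [0, 0]]}, whose top-right block is the exact integral
#' of the semigroup applied to the initial vector — no quadrature error.
#'
#' @param dist a [ReactionDistribution-class].
#' @param time upper integration limit.
#' @return Numeric vector of per-state integrals.
#' @export
integratedProbabilities <- function(dist, time) {
  A <- dist@generator@Astar
  n <- nrow(A)
  u0 <- numeric(n)
  u0[1L] <- dist@initialMass
  B <- rbind(cbind(A, u0), 0)
  v <- numeric(n + 1L)
  v[n + 1L] <- 1
  drop(.expAtv(B, time, v))[seq_len(n)]
}

#' Conservation/outflow identity between a shell and its tail
#'
#' The probability that more than `m` reactions have fired by time `t`
#' equals the probability flux that has crossed shell `m`:
#' \eqn{\phi_m = \sum_{r \in \nabla_m} \alpha(x_0, r)
#'   \int_0^t p(R(s) = r)\,ds} must equal
#' \eqn{\psi_{m+1} = \sum_{m' > m} \sum_{r \in \nabla_{m'}} p(R(t) = r)}.
#' Both sides are computed independently (exact augmented-exponential
#' integrals versus summed state probabilities) so their difference
#' measures solver consistency.
#'
#' @param dist a [ReactionDistribution-class].
#' @param m shell index, `m < M`.
#' @param time evaluation time; must be one of `dist@times` (defaults to
#'   the last).
#' @return List with `phi`, `psi` and `diff = phi - psi`.
#' @export
tailMassIdentity <- function(dist, m, time = max(dist@times)) {
  space <- dist@generator@space
  stopifnot(m >= 0, m < space@M)
  k <- match(time, dist@times)
  if (is.na(k)) stop("time must be one of the solved grid times")
  ints <- integratedProbabilities(dist, time)
  inShell <- space@shell == m
  phi <- sum(dist@generator@alpha[inShell] * ints[inShell])
  psi <- tailBeyond(dist, m)[k]
  list(phi = phi, psi = psi, diff = phi - psi)
}

setMethod("show", "ReactionDistribution", function(object) {
  cat(sprintf(
    "ReactionDistribution: %d states, %d times in [%g, %g]\n",
    nrow(object@probs), length(object@times),
    min(object@times), max(object@times)))
  cat(sprintf("  truncation depth M = %d, max tail mass %.3e (eps = %.1e)\n",
    object@generator@space@M, max(object@tailMass), object@eps))
})

# ---- push-forward to species counts -----------------------------------

#' Push a reaction-count distribution forward to species counts
#'
#' Groups the retained reaction-count states by their population image
#' under the Gamma map and sums their probabilities:
#' \eqn{p(X(t) = x) = \sum_{r \in \Gamma^{-1}(x_0, x)} p(R(t) = r)}.
#' The species probabilities are approached from below; the deficit is
#' bounded by the reaction-count truncation tail.
#'
#' @param dist a [ReactionDistribution-class].
#' @return A [SpeciesDistribution-class].
#' @export
pushForward <- function(dist) {
  space <- dist@generator@space
  img <- t(apply(space@states, 1L, function(r)
    gammaMap(space@system, space@x0, r)))
  if (numSpecies(space@system) == 1L) img <- matrix(as.integer(img), ncol = 1L)
  keys <- .stateKeys(img)
  uniq <- !duplicated(keys)
  xs <- img[uniq, , drop = FALSE]
  ord <- .lexOrder(xs)
  xs <- xs[ord, , drop = FALSE]
  grp <- match(keys, .stateKeys(xs))
  probs <- rowsum(dist@probs, grp)
  out <- matrix(0, nrow(xs), length(dist@times))
  out[as.integer(rownames(probs)), ] <- probs
  new("SpeciesDistribution", states = xs, times = dist@times, probs = out,
    truncationError = max(dist@tailMass))
}

#' Probability of one population state over the grid
#'
#' @param dist a [SpeciesDistribution-class].
#' @param x population state.
#' @return Numeric vector over `dist@times`.
#' @export
speciesProbability <- function(dist, x) {
  x <- as.integer(x)
  i <- match(.key1(x), .stateKeys(dist@states))
  if (is.na(i)) rep(0, length(dist@times)) else dist@probs[i, ]
}

setMethod("show", "SpeciesDistribution", function(object) {
  cat(sprintf(
    "SpeciesDistribution: %d population states, %d times, truncation error <= %.3e\n",
    nrow(object@states), length(object@times), object@truncationError))
})

# ---- direct species-counts FSP oracle ---------------------------------

#' Solve the species-counts CME directly by finite state projection
#'
#' The classical population-counts CME solved on a truncated species
#' state space: states reachable from `x0` in at most `N` firings are
#' enumerated through positive-propensity transitions, the generator
#' keeps full exit rates on the diagonal (mass stepping outside the
#' projection is lost, and tracked), and `N` doubles until the lost mass
#' is below `eps` at every output time.  Serves as the independent
#' cross-check for [pushForward()].
#'
#' @inheritParams solveReactionCME
#' @param N0 starting expansion depth.
#' @param NMax hard cap on the expansion depth.
#' @return A [SpeciesDistribution-class].
#' @export
solveSpeciesFSP <- function(system, x0, times, eps = 1e-8,
                            N0 = 8L, NMax = 4096L, stateCap = 2e6) {
  times <- .checkTimes(times)
  stopifnot(eps > 0, eps < 1)
  x0 <- .checkSpeciesState(system, x0, "x0")
  N <- as.integer(N0)
  repeat {
    states <- .expandSpecies(system, x0, N, stateCap)
    A <- .speciesGenerator(system, states)
    u0 <- numeric(nrow(states))
    u0[match(.key1(x0), .stateKeys(states))] <- 1
    probs <- .propagateGrid(A, u0, times)
    probs[probs < 0 & probs > -1e-12] <- 0
    lost <- pmax(1 - colSums(probs), 0)
    if (max(lost) < eps || attr(states, "saturated")) break
    if (N >= NMax)
      stop(sprintf("FSP truncation failed: lost mass %.3e at depth N = %d",
        max(lost), N))
    N <- min(2L * N, NMax)
  }
  new("SpeciesDistribution", states = .stripAttr(states), times = times,
    probs = probs, truncationError = max(lost))
}

.stripAttr <- function(m) {
  attr(m, "saturated") <- NULL
  m
}

# Species states reachable from x0 within N positive-propensity firings.
.expandSpecies <- function(system, x0, N, stateCap) {
  seen <- new.env(parent = emptyenv())
  assign(.key1(x0), TRUE, envir = seen)
  all <- list(matrix(x0, 1L))
  frontier <- matrix(x0, 1L)
  saturated <- FALSE
  for (step in seq_len(N)) {
    nxt <- list()
    for (i in seq_len(nrow(frontier))) {
      x <- frontier[i, ]
      a <- .propensityVec(system, x)
      for (n in which(a > 0)) {
        xp <- x + system@netStoich[n, ]
        if (any(xp < 0)) next
        k <- .key1(xp)
        if (!exists(k, envir = seen, inherits = FALSE)) {
          assign(k, TRUE, envir = seen)
          nxt[[length(nxt) + 1L]] <- xp
        }
      }
    }
    if (!length(nxt)) {
      saturated <- TRUE
      break
    }
    frontier <- do.call(rbind, nxt)
    all[[length(all) + 1L]] <- frontier
    if (sum(vapply(all, nrow, integer(1))) > stateCap)
      stop("species state cap exceeded")
  }
  m <- do.call(rbind, all)
  storage.mode(m) <- "integer"
  m <- m[.lexOrder(m), , drop = FALSE]
  attr(m, "saturated") <- saturated
  m
}

.speciesGenerator <- function(system, states) {
  n <- nrow(states)
  idx <- seq_len(n)
  names(idx) <- .stateKeys(states)
  ii <- jj <- integer(0)
  xx <- numeric(0)
  dg <- numeric(n)
  for (j in seq_len(n)) {
    x <- states[j, ]
    a <- .propensityVec(system, x)
    dg[j] <- -sum(a)
    for (nn in which(a > 0)) {
      xp <- x + system@netStoich[nn, ]
      if (any(xp < 0)) next
      i <- idx[.key1(xp)]
      if (!is.na(i)) {
        ii <- c(ii, i); jj <- c(jj, j); xx <- c(xx, a[nn])
      }
    }
  }
  Matrix::sparseMatrix(i = c(ii, seq_len(n)), j = c(jj, seq_len(n)),
    x = c(xx, dg), dims = c(n, n))
}
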
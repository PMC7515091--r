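# Stochastic simulation (Gillespie direct method) over reaction counts.
#
# Reproducibility: trajectories draw from L'Ecuyer-CMRG substreams.  The
# master seed initialises the first stream; trajectory i uses the i-th
# stream obtained by parallel::nextRNGStream, so ensembles are
# reproducible independently of execution order and the key schedule is
# (master seed, trajectory index).

.streamState <- function(seed) {
  old <- globalenv()$.Random.seed
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  suppressWarnings(set.seed(as.integer(seed), kind = "L'Ecuyer-CMRG"))
  globalenv()$.Random.seed
}

.withStream <- function(state, expr) {
  old <- globalenv()$.Random.seed
  assign(".Random.seed", state, envir = globalenv())
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

# Direct-method SSA using the current RNG state.  Right-continuous
# convention: a jump at exactly tEnd is included.
.ssaOne <- function(system, x0, tEnd) {
  nr <- numReactions(system)
  r <- integer(nr)
  x <- x0
  tcur <- 0
  jumpTimes <- numeric(0)
  reactionIndices <- integer(0)
  repeat {
    a <- .propensityVec(system, x)
    atot <- sum(a)
    if (atot <= 0) break
    tau <- -log(stats::runif(1)) / atot
    if (tcur + tau > tEnd) break
    tcur <- tcur + tau
    n <- min(findInterval(stats::runif(1) * atot, cumsum(a)) + 1L, nr)
    r[n] <- r[n] + 1L
    x <- x + system@netStoich[n, ]
    jumpTimes <- c(jumpTimes, tcur)
    reactionIndices <- c(reactionIndices, n)
  }
  list(jumpTimes = jumpTimes, reactionIndices = reactionIndices,
    reactionCounts = r, species = x)
}

#' Simulate one trajectory of the reaction-counts process
#'
#' Gillespie's direct method: exponential waiting times at the total
#' propensity, the firing reaction chosen with probability
#' \eqn{\alpha_n / \alpha}.  The trajectory is the cumulative tally of
#' firings; the species path is reconstructed through the Gamma map.
#' Identical seeds give identical trajectories.
#'
#' @param system a [ReactionSystem-class].
#' @param x0 initial population state.
#' @param tEnd simulation horizon.
#' @param seed integer master seed.
#' @return A list with `jumpTimes`, `reactionIndices`, terminal
#'   `reactionCounts` and `species`, and the `seed`.
#' @examples
#' bd <- makeFixture("bd_x0_0")
#' simulateSSA(bd$system, bd$x0, tEnd = 5, seed = 1)$reactionCounts
#' @export
simulateSSA <- function(system, x0, tEnd, seed) {
  x0 <- .checkSpeciesState(system, x0, "x0")
  stopifnot(tEnd >= 0)
  out <- .withStream(.streamState(seed), .ssaOne(system, x0, tEnd))
  out$seed <- as.integer(seed)
  out
}

#' Empirical distribution from an SSA ensemble
#'
#' Runs `n` independent trajectories to time `t` (one RNG substream per
#' trajectory, derived from the master seed) and tabulates the terminal
#' reaction-count states and their pushed-forward species states, with
#' binomial standard errors \eqn{\sqrt{\hat p(1-\hat p)/n}}.
#'
#' @param system a [ReactionSystem-class].
#' @param x0 initial population state.
#' @param t query time.
#' @param n number of trajectories.
#' @param seed integer master seed.
#' @return An [EmpiricalDistribution-class].
#' @examples
#' bd <- makeFixture("bd_x0_0")
#' emp <- ensembleDistribution(bd$system, bd$x0, t = 2, n = 500, seed = 7)
#' head(emp@speciesCounts)
#' @export
ensembleDistribution <- function(system, x0, t, n, seed) {
  x0 <- .checkSpeciesState(system, x0, "x0")
  stopifnot(t >= 0, n >= 1)
  n <- as.integer(n)
  state <- .streamState(seed)
  nr <- numReactions(system)
  terminals <- matrix(0L, n, nr)
  for (i in seq_len(n)) {
    terminals[i, ] <- .withStream(state,
      .ssaOne(system, x0, t))$reactionCounts
    state <- parallel::nextRNGStream(state)
  }
  species <- matrix(rep(x0, each = n), n) + terminals %*% system@netStoich
  new("EmpiricalDistribution",
    reactionCounts = .tabulateStates(terminals, n),
    speciesCounts = .tabulateStates(species, n),
    n = n, time = as.numeric(t), seed = as.integer(seed))
}

.tabulateStates <- function(m, n) {
  storage.mode(m) <- "integer"
  keys <- .stateKeys(m)
  tab <- table(keys)
  uniq <- m[!duplicated(keys), , drop = FALSE]
  uniq <- uniq[.lexOrder(uniq), , drop = FALSE]
  ukeys <- .stateKeys(uniq)
  cnt <- as.integer(tab[ukeys])
  p <- cnt / n
  data.frame(state = ukeys, count = cnt, freq = p,
    se = sqrt(p * (1 - p) / n), stringsAsFactors = FALSE)
}

setMethod("show", "EmpiricalDistribution", function(object) {
  cat(sprintf(
    "EmpiricalDistribution: %d trajectories at t = %g (seed %d)\n",
    object@n, object@time, object@seed))
  cat(sprintf("  %d distinct reaction-count states, %d species states\n",
    nrow(object@reactionCounts), nrow(object@speciesCounts)))
})

#' Total-variation distance between an SSA ensemble and a solved species
#' distribution
#'
#' @param emp an [EmpiricalDistribution-class].
#' @param dist a [SpeciesDistribution-class] containing `emp@time` in its
#'   grid.
#' @return Total-variation distance (half the L1 difference, with solver
#'   truncation mass counted as unmatched).
#' @export
tvDistance <- function(emp, dist) {
  k <- match(emp@time, dist@times)
  if (is.na(k)) stop("ensemble time not in the solved grid")
  solved <- dist@probs[, k]
  names(solved) <- .stateKeys(dist@states)
  keys <- union(names(solved), emp@speciesCounts$state)
  p <- solved[keys]
  p[is.na(p)] <- 0
  q <- emp@speciesCounts$freq[match(keys, emp@speciesCounts$state)]
  q[is.na(q)] <- 0
  (sum(abs(p - q)) + (1 - sum(solved))) / 2
}
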
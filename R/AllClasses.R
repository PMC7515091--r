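#' @import methods
#' @importFrom Matrix sparseMatrix expm
NULL

#' Reaction network with stochastic mass-action kinetics
#'
#' A `ReactionSystem` holds the species labels, the reactant and product
#' stoichiometry matrices (one row per reaction, one column per species),
#' and the mass-action rate constants.  The net stoichiometric vector of
#' reaction \eqn{n} is the difference of product and reactant rows; it is
#' stored explicitly and checked by the validity method.  Propensities
#' follow the stochastic mass-action convention
#' \eqn{a_n(x) = c_n \prod_i \binom{x_i}{s_{ni}}}{a_n(x) = c_n prod_i choose(x_i, s_ni)}
#' with \eqn{s} the reactant stoichiometry; a reaction may instead carry a
#' custom propensity hook registered by name (see [setPropensityHook()]).
#'
#' @slot speciesNames character vector of species labels.
#' @slot reactionNames character vector of reaction labels.
#' @slot reactantStoich,productStoich non-negative integer matrices,
#'   `Nr x Ns`.
#' @slot netStoich integer matrix, `productStoich - reactantStoich`.
#' @slot rateConstants positive numeric vector of length `Nr`, units 1/time
#'   (bimolecular constants are taken as already volume-scaled).
#' @slot propensityHooks named list of functions `function(x) rate`, keyed
#'   by reaction name; empty by default.
#'
#' @seealso [ReactionSystem()] for the constructor,
#'   [readReactionSystem()] for file input.
#' @export
setClass("ReactionSystem",
  slots = c(
    speciesNames    = "character",
    reactionNames   = "character",
    reactantStoich  = "matrix",
    productStoich   = "matrix",
    netStoich       = "matrix",
    rateConstants   = "numeric",
    propensityHooks = "list"
  )
)

setValidity("ReactionSystem", function(object) {
  ns <- length(object@speciesNames)
  nr <- length(object@reactionNames)
  msg <- character(0)
  if (ns < 1L) msg <- c(msg, "at least one species is required")
  if (nr < 1L) msg <- c(msg, "at least one reaction is required")
  for (nm in c("reactantStoich", "productStoich", "netStoich")) {
    m <- slot(object, nm)
    if (!identical(dim(m), c(nr, ns)))
      msg <- c(msg, sprintf("%s must be %d x %d", nm, nr, ns))
    if (!is.numeric(m) || any(m != round(m)))
      msg <- c(msg, sprintf("%s must be integer-valued", nm))
  }
  if (any(object@reactantStoich < 0) || any(object@productStoich < 0))
    msg <- c(msg, "stoichiometry matrices must be non-negative")
  if (!all(object@netStoich == object@productStoich - object@reactantStoich))
    msg <- c(msg, "netStoich must equal productStoich - reactantStoich")
  if (length(object@rateConstants) != nr || any(object@rateConstants <= 0))
    msg <- c(msg, "rateConstants must be positive, one per reaction")
  if (anyDuplicated(object@reactionNames))
    msg <- c(msg, "reaction names must be unique")
  hooks <- object@propensityHooks
  if (length(hooks) &&
      (is.null(names(hooks)) || !all(names(hooks) %in% object@reactionNames) ||
       !all(vapply(hooks, is.function, logical(1)))))
    msg <- c(msg, "propensityHooks must be functions named after reactions")
  if (length(msg)) msg else TRUE
})

#' Shell-blocked enumeration of the reachable reaction-count lattice
#'
#' The reaction-count state space partitions into shells: shell \eqn{m}
#' holds the states reachable in exactly \eqn{m} firings from the origin,
#' i.e. those with total count \eqn{\|r\|_1 = m}.  An `OrderedStateSpace`
#' stores the states of shells \eqn{0..M} as rows of an integer matrix,
#' blocked by shell and ordered lexicographically within each shell, so the
#' row order is deterministic and the one-step generator is strictly lower
#' triangular.  Only states reached through positive-propensity transitions
#' are retained; states whose species image would go negative carry zero
#' probability and are pruned.
#'
#' @slot states integer matrix, one reaction-count state per row.
#' @slot shell integer vector giving each row's shell index (total count).
#' @slot shellSizes integer vector of length `M + 1`, states per shell.
#' @slot M truncation depth (maximum total firing count retained).
#' @slot x0 the initial species population the enumeration was built for.
#' @slot system the [ReactionSystem-class] enumerated.
#'
#' @seealso [expandShells()]
#' @export
setClass("OrderedStateSpace",
  slots = c(
    states     = "matrix",
    shell      = "integer",
    shellSizes = "integer",
    M          = "integer",
    x0         = "integer",
    system     = "ReactionSystem"
  )
)

setValidity("OrderedStateSpace", function(object) {
  msg <- character(0)
  n <- nrow(object@states)
  if (length(object@shell) != n)
    msg <- c(msg, "shell must have one entry per state")
  if (n > 0 && !all(rowSums(object@states) == object@shell))
    msg <- c(msg, "shell index must equal the state's total count")
  if (length(object@shellSizes) != object@M + 1L)
    msg <- c(msg, "shellSizes must have M + 1 entries")
  if (sum(object@shellSizes) != n)
    msg <- c(msg, "shellSizes must sum to the number of states")
  if (n == 0 || object@shell[1L] != 0L || any(object@states[1L, ] != 0L))
    msg <- c(msg, "shell 0 must be the origin")
  if (is.unsorted(object@shell))
    msg <- c(msg, "states must be blocked by shell")
  if (length(msg)) msg else TRUE
})

#' Lower-triangular rate generator over an ordered reaction-count space
#'
#' Holds the truncated generator \eqn{A^*} of the reaction-counts CME as a
#' sparse matrix over the shell-blocked state order: the diagonal entry of
#' state \eqn{r} is \eqn{-\alpha(x_0, r)} (its full exit rate, including
#' transitions that leave the truncation), and the off-diagonal entry
#' (row \eqn{r + 1_n}, column \eqn{r}) is \eqn{\alpha_n(x_0, r)}.  Because
#' every transition increments the total count, the matrix is strictly
#' lower triangular off the diagonal; [verifyTriangular()] asserts this
#' rather than assuming it.  Column sums are \eqn{\le 0}: mass that steps
#' past the deepest retained shell is lost to the (implicit) truncation
#' tail.
#'
#' @slot Astar sparse `dgCMatrix` generator.
#' @slot alpha numeric vector of total exit rates, `alpha == -diag(Astar)`.
#' @slot space the [OrderedStateSpace-class] the matrix is indexed by.
#'
#' @seealso [buildGenerator()]
#' @export
setClass("RateGenerator",
  slots = c(
    Astar = "Matrix",
    alpha = "numeric",
    space = "OrderedStateSpace"
  )
)

setValidity("RateGenerator", function(object) {
  msg <- character(0)
  n <- nrow(object@space@states)
  if (!identical(dim(object@Astar), c(n, n)))
    msg <- c(msg, "Astar dimension must match the state space")
  d <- Matrix::diag(object@Astar)
  if (any(d > 0))
    msg <- c(msg, "diagonal entries must be <= 0")
  if (length(object@alpha) != n || any(abs(object@alpha + d) > 1e-12 * pmax(1, object@alpha)))
    msg <- c(msg, "alpha must equal -diag(Astar)")
  if (any(Matrix::colSums(object@Astar) > 1e-10))
    msg <- c(msg, "column sums must be <= 0 (probability may only flow out)")
  if (length(msg)) msg else TRUE
})

#' Transient solution of the reaction-counts CME
#'
#' Probabilities of every retained reaction-count state on a time grid,
#' together with the truncation tail mass \eqn{\psi(t)} (the probability
#' that the process has stepped beyond the deepest retained shell).  At
#' every time, `colSums(probs) + tailMass == C` where `C` is the initial
#' mass placed on the origin (1 for the full CME; smaller values are used
#' when solving sub-chains).
#'
#' @slot generator the [RateGenerator-class] that was integrated.
#' @slot times increasing non-negative time grid.
#' @slot probs numeric matrix, states x times.
#' @slot tailMass numeric vector, per-time truncation tail.
#' @slot initialMass initial mass on the origin (the C of the solve).
#' @slot eps truncation tolerance the solve was certified against.
#'
#' @seealso [solveReactionCME()]
#' @export
setClass("ReactionDistribution",
  slots = c(
    generator = "RateGenerator",
    times     = "numeric",
    probs     = "matrix",
    tailMass  = "numeric",
    initialMass = "numeric",
    eps       = "numeric"
  )
)

setValidity("ReactionDistribution", function(object) {
  msg <- character(0)
  nt <- length(object@times)
  if (is.unsorted(object@times, strictly = TRUE) || any(object@times < 0))
    msg <- c(msg, "times must be strictly increasing and non-negative")
  if (ncol(object@probs) != nt || length(object@tailMass) != nt)
    msg <- c(msg, "probs/tailMass must match the time grid")
  if (nrow(object@probs) != nrow(object@generator@space@states))
    msg <- c(msg, "probs must have one row per state")
  if (any(object@probs < -1e-10) || any(object@probs > 1 + 1e-10))
    msg <- c(msg, "probabilities must lie in [0, 1]")
  cons <- abs(colSums(object@probs) + object@tailMass - object@initialMass)
  if (any(cons > 1e-8))
    msg <- c(msg, "probability + tail mass must equal C at every time")
  if (length(msg)) msg else TRUE
})

#' Distribution over species population states
#'
#' A species-counts distribution on a time grid, either obtained by pushing
#' a reaction-count distribution forward through the Gamma map
#' ([pushForward()]) or solved directly by finite state projection
#' ([solveSpeciesFSP()]).  Probabilities sum to at most 1; the deficit is
#' bounded by `truncationError`.
#'
#' @slot states integer matrix of population states, one per row.
#' @slot times increasing non-negative time grid.
#' @slot probs numeric matrix, states x times.
#' @slot truncationError upper bound on the probability mass missing from
#'   the enumerated states (at any grid time).
#'
#' @export
setClass("SpeciesDistribution",
  slots = c(
    states          = "matrix",
    times           = "numeric",
    probs           = "matrix",
    truncationError = "numeric"
  )
)

setValidity("SpeciesDistribution", function(object) {
  msg <- character(0)
  if (nrow(object@probs) != nrow(object@states) ||
      ncol(object@probs) != length(object@times))
    msg <- c(msg, "probs must be states x times")
  if (any(object@probs < -1e-10) || any(object@probs > 1 + 1e-10))
    msg <- c(msg, "probabilities must lie in [0, 1]")
  s <- colSums(object@probs)
  if (any(s > 1 + 1e-8))
    msg <- c(msg, "probabilities must sum to at most 1")
  if (any(s < 1 - object@truncationError - 1e-8))
    msg <- c(msg, "probability deficit exceeds the declared truncation error")
  if (length(msg)) msg else TRUE
})

#' Exponential polynomial \eqn{\sum_j c_j t^{k_j} e^{-\lambda_j t}}
#'
#' The closed-form algebra behind path-chain probabilities: each term is a
#' coefficient, a non-negative integer power of `t`, and a non-negative
#' decay rate.  The class is closed under the convolution
#' \eqn{\int_0^t e^{-a(t-s)} f(s)\,ds}, under products with
#' \eqn{(1 - e^{-at})} factors, and under exact antiderivatives, which is
#' all the path-chain and cascade-bound machinery needs.  Rates closer than
#' a relative `1e-12` are merged (producing higher powers of `t`) to avoid
#' catastrophic cancellation in near-degenerate divided differences.
#'
#' @slot coef numeric coefficients.
#' @slot power non-negative integer powers of `t`.
#' @slot rate non-negative decay rates.
#'
#' @seealso [expPolynomial()], [epEval()], [epConvolve()], [epIntegral()]
#' @export
setClass("ExpPolynomial",
  slots = c(coef = "numeric", power = "integer", rate = "numeric")
)

setValidity("ExpPolynomial", function(object) {
  msg <- character(0)
  n <- length(object@coef)
  if (length(object@power) != n || length(object@rate) != n)
    msg <- c(msg, "coef, power and rate must have equal length")
  if (any(object@power < 0L)) msg <- c(msg, "powers must be non-negative")
  if (any(object@rate < 0)) msg <- c(msg, "rates must be non-negative")
  if (length(msg)) msg else TRUE
})

#' A continuous-time Markov chain restricted to one admissible path
#'
#' An admissible path is a sequence of reaction-count states in which
#' consecutive states differ by a single firing.  The associated path chain
#' is the CTMC whose states are the path states plus an absorbing sink
#' collecting every off-path transition: state \eqn{g_k} is exited at its
#' full rate \eqn{\alpha(g_k)} while probability enters the next state at
#' rate \eqn{\beta(g_{k-1}, g_k) = \alpha_n(g_{k-1})}, the propensity of
#' the firing that makes the step (so \eqn{\beta \le \alpha} at each
#' state).  The initial mass `C` sits on the first state; retained state
#' probabilities plus the sink always sum to `C`.
#'
#' @slot states integer matrix of path states (rows), consecutive rows
#'   differing by one unit firing.
#' @slot reactionSequence integer vector of the firing reaction indices
#'   (length `nrow(states) - 1`).
#' @slot initialMass initial probability mass C in (0, 1].
#' @slot alpha total exit rate at each path state.
#' @slot beta along-chain transition rate for each step.
#' @slot x0 initial species population.
#' @slot system the underlying [ReactionSystem-class].
#'
#' @seealso [pathChain()], [pathChainSolve()], [cascadeUpperBound()]
#' @export
setClass("PathChain",
  slots = c(
    states           = "matrix",
    reactionSequence = "integer",
    initialMass      = "numeric",
    alpha            = "numeric",
    beta             = "numeric",
    x0               = "integer",
    system           = "ReactionSystem"
  )
)

setValidity("PathChain", function(object) {
  msg <- character(0)
  m <- nrow(object@states)
  if (m < 1L) msg <- c(msg, "a path needs at least one state")
  if (length(object@reactionSequence) != m - 1L)
    msg <- c(msg, "reactionSequence must have one entry per step")
  if (length(object@alpha) != m || length(object@beta) != max(m - 1L, 0L))
    msg <- c(msg, "alpha/beta lengths must match the path")
  if (m > 1L) {
    step <- object@states[-1L, , drop = FALSE] - object@states[-m, , drop = FALSE]
    if (any(rowSums(step) != 1L) || any(step < 0L))
      msg <- c(msg, "consecutive states must differ by exactly one firing")
    if (any(object@beta > object@alpha[-m] + 1e-12))
      msg <- c(msg, "beta must not exceed the exit rate of the source state")
    if (any(object@beta < 0)) msg <- c(msg, "beta must be non-negative")
  }
  if (length(object@initialMass) != 1L || object@initialMass <= 0 || object@initialMass > 1)
    msg <- c(msg, "C must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' Cascade of gated/un-gated bounds on a path probability
#'
#' Level functions \eqn{u_1, \dots, u_m} of the gating cascade:
#' \eqn{u_1 \equiv C} and
#' \eqn{u_n(t) = \frac{\beta(g_{n-1},g_n)}{\alpha(g_{n-1})}
#'   (1 - e^{-\alpha(g_{n-1}) t})\, u_{n-1}(t)}.
#' The top level bounds the terminal path probability from above; every
#' level is non-negative and non-decreasing in `t`.
#'
#' @slot chain the bounded [PathChain-class].
#' @slot levels list of [ExpPolynomial-class] level functions.
#' @slot times evaluation grid.
#' @slot values numeric matrix, levels x times.
#'
#' @seealso [cascadeUpperBound()], [verifyBound()]
#' @export
setClass("CascadeBound",
  slots = c(
    chain  = "PathChain",
    levels = "list",
    times  = "numeric",
    values = "matrix"
  )
)

#' Empirical distribution from an SSA ensemble
#'
#' Tabulated terminal states of `n` independent stochastic simulation
#' trajectories queried at a fixed time, over both reaction-count and
#' (pushed-forward) species states, with binomial standard errors.
#'
#' @slot reactionCounts data.frame with columns `state` (comma-joined
#'   counts), `count`, `freq`, `se`.
#' @slot speciesCounts data.frame in the same layout over populations.
#' @slot n number of trajectories.
#' @slot time query time.
#' @slot seed master seed.
#'
#' @seealso [ensembleDistribution()]
#' @export
setClass("EmpiricalDistribution",
  slots = c(
    reactionCounts = "data.frame",
    speciesCounts  = "data.frame",
    n              = "integer",
    time           = "numeric",
    seed           = "integer"
  )
)
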
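#' Construct a reaction network
#'
#' Builds a [ReactionSystem-class] from stoichiometry matrices and
#' mass-action rate constants.  Rows index reactions, columns index
#' species; the net stoichiometric vector of each reaction is computed as
#' product minus reactant row.
#'
#' @param speciesNames character vector of species labels.
#' @param reactantStoich,productStoich non-negative integer matrices,
#'   `Nr x Ns` (a vector is accepted for a single reaction).
#' @param rateConstants positive numeric vector, one per reaction.
#' @param reactionNames optional character vector of reaction labels;
#'   defaults to `R1, R2, ...`.
#'
#' @return A validated [ReactionSystem-class].
#' @examples
#' bd <- ReactionSystem(
#'   speciesNames = "X",
#'   reactantStoich = rbind(0, 1),
#'   productStoich = rbind(1, 0),
#'   rateConstants = c(1.0, 0.1),
#'   reactionNames = c("birth", "death")
#' )
#' netStoich(bd)
#' @export
ReactionSystem <- function(speciesNames, reactantStoich, productStoich,
                           rateConstants, reactionNames = NULL) {
  reactantStoich <- .asStoich(reactantStoich, length(speciesNames))
  productStoich <- .asStoich(productStoich, length(speciesNames))
  if (is.null(reactionNames))
    reactionNames <- paste0("R", seq_len(nrow(reactantStoich)))
  new("ReactionSystem",
    speciesNames = as.character(speciesNames),
    reactionNames = as.character(reactionNames),
    reactantStoich = reactantStoich,
    productStoich = productStoich,
    netStoich = productStoich - reactantStoich,
    rateConstants = as.numeric(rateConstants),
    propensityHooks = list())
}

.asStoich <- function(m, ns) {
  if (is.vector(m)) m <- matrix(m, ncol = ns)
  storage.mode(m) <- "integer"
  dimnames(m) <- NULL
  m
}

#' Register a custom propensity for one reaction
#'
#' Replaces the stochastic mass-action law of a single reaction with a
#' user-supplied function of the population vector.  Model files stay
#' mass-action only; hooks are attached programmatically.
#'
#' @param system a [ReactionSystem-class].
#' @param reactionName name of the reaction to override.
#' @param fun function `function(x) rate` returning a non-negative scalar.
#' @return The modified system.
#' @export
setPropensityHook <- function(system, reactionName, fun) {
  stopifnot(is(system, "ReactionSystem"), is.function(fun))
  if (!reactionName %in% system@reactionNames)
    stop("unknown reaction: ", reactionName)
  system@propensityHooks[[reactionName]] <- fun
  validObject(system)
  system
}

# ---- accessors --------------------------------------------------------

#' @rdname ReactionSystem
#' @param x,object a `ReactionSystem`.
#' @export
numSpecies <- function(x) length(x@speciesNames)

#' @rdname ReactionSystem
#' @export
numReactions <- function(x) length(x@reactionNames)

#' @rdname ReactionSystem
#' @export
speciesNames <- function(x) x@speciesNames

#' @rdname ReactionSystem
#' @export
reactionNames <- function(x) x@reactionNames

#' @rdname ReactionSystem
#' @export
netStoich <- function(x) x@netStoich

#' @rdname ReactionSystem
#' @export
rateConstants <- function(x) x@rateConstants

setMethod("show", "ReactionSystem", function(object) {
  cat(sprintf("ReactionSystem: %d species (%s), %d reactions\n",
    numSpecies(object), paste(object@speciesNames, collapse = ", "),
    numReactions(object)))
  for (n in seq_along(object@reactionNames)) {
    lhs <- .sideLabel(object@reactantStoich[n, ], object@speciesNames)
    rhs <- .sideLabel(object@productStoich[n, ], object@speciesNames)
    hook <- if (object@reactionNames[n] %in% names(object@propensityHooks))
      " [custom propensity]" else ""
    cat(sprintf("  %s: %s -> %s   c = %g%s\n",
      object@reactionNames[n], lhs, rhs, object@rateConstants[n], hook))
  }
})

.sideLabel <- function(s, names) {
  i <- which(s > 0)
  if (!length(i)) return("0")
  paste(ifelse(s[i] > 1L, paste0(s[i], " "), ""), names[i],
    sep = "", collapse = " + ")
}

# ---- state checks -----------------------------------------------------

.checkSpeciesState <- function(system, x, what = "x") {
  x <- as.integer(x)
  if (length(x) != numSpecies(system))
    stop(what, " must have one entry per species")
  if (any(x < 0)) stop(what, " must be a non-negative population vector")
  x
}

.checkCountState <- function(system, r, what = "r") {
  r <- as.integer(r)
  if (length(r) != numReactions(system))
    stop(what, " must have one entry per reaction")
  if (any(r < 0)) stop(what, " must be a non-negative count vector")
  r
}

# ---- Gamma map and pull-back ------------------------------------------

#' Map reaction counts to the species population they produce
#'
#' Given the initial population `x0` and the number of times each reaction
#' has fired, the current population is
#' \eqn{x_0 + \sum_n \nu_n r_n}.  If any entry of that vector is negative
#' the firing record is inconsistent with non-negative populations and the
#' map returns `NULL` (the explicit "outside the population lattice"
#' marker); a negative-population state is never returned.
#'
#' @param system a [ReactionSystem-class].
#' @param x0 non-negative integer population vector.
#' @param r non-negative integer reaction-count vector.
#' @return Integer population vector, or `NULL` if any coordinate would be
#'   negative.
#' @examples
#' bd <- makeFixture("bd_x0_2")
#' gammaMap(bd$system, bd$x0, c(3, 1))  # 2 + 3 - 1 = 4
#' @export
gammaMap <- function(system, x0, r) {
  x0 <- .checkSpeciesState(system, x0, "x0")
  r <- .checkCountState(system, r)
  x <- x0 + as.integer(drop(r %*% system@netStoich))
  if (any(x < 0)) NULL else x
}

#' Pull a population state back to its reaction-count preimages
#'
#' Enumerates every reaction-count state `r` with total count at most
#' `maxTotal` whose image under [gammaMap()] equals `x`.  The Gamma map is
#' rarely injective (several firing records produce the same population),
#' so the result is a set, returned as a lexicographically sorted integer
#' matrix with one state per row.
#'
#' @inheritParams gammaMap
#' @param x target population state.
#' @param maxTotal maximum total firing count to search.
#' @return Integer matrix (possibly zero rows), one count state per row.
#' @examples
#' bd <- makeFixture("bd_x0_0")
#' gammaPullback(bd$system, bd$x0, 1, maxTotal = 5)
#' @export
gammaPullback <- function(system, x0, x, maxTotal) {
  x0 <- .checkSpeciesState(system, x0, "x0")
  x <- .checkSpeciesState(system, x)
  stopifnot(maxTotal >= 0)
  nr <- numReactions(system)
  if ((maxTotal + 1)^nr > 2e6)
    stop("pull-back enumeration too large; reduce maxTotal")
  grid <- as.matrix(expand.grid(rep(list(0:maxTotal), nr)))
  storage.mode(grid) <- "integer"
  dimnames(grid) <- NULL
  grid <- grid[rowSums(grid) <= maxTotal, , drop = FALSE]
  img <- matrix(rep(x0, each = nrow(grid)), nrow(grid)) +
    grid %*% system@netStoich
  hit <- rowSums(img < 0) == 0 &
    rowSums(img != matrix(rep(x, each = nrow(grid)), nrow(grid))) == 0
  out <- grid[hit, , drop = FALSE]
  out[.lexOrder(out), , drop = FALSE]
}

# ---- propensities -----------------------------------------------------

#' Propensity functions
#'
#' `speciesPropensity()` evaluates the firing rate of reaction `n` at a
#' population state under the stochastic mass-action law
#' \eqn{a_n(x) = c_n \prod_i \binom{x_i}{s_{ni}}} (zero whenever a reactant
#' is under-stocked), or a registered custom hook.
#' `reactionPropensity()` is its pull-back to reaction-count states: the
#' value at the Gamma image of `r`, or 0 when that image lies outside the
#' population lattice.  `totalPropensity()` sums the pull-back over all
#' reactions; it vanishes exactly at absorbing states.
#'
#' @param system a [ReactionSystem-class].
#' @param x population state.
#' @param x0 initial population state.
#' @param r reaction-count state.
#' @param n reaction index in `1..Nr` (omit for all reactions).
#' @return Non-negative rate(s).
#' @examples
#' bd <- makeFixture("bd_x0_0")
#' speciesPropensity(bd$system, x = 5, n = 2)     # 0.1 * 5
#' reactionPropensity(bd$system, bd$x0, c(2, 1), n = 2)
#' totalPropensity(bd$system, bd$x0, c(0, 0))
#' @export
speciesPropensity <- function(system, x, n = NULL) {
  x <- .checkSpeciesState(system, x)
  a <- .propensityVec(system, x)
  if (is.null(n)) return(a)
  if (!is.numeric(n) || any(n < 1) || any(n > numReactions(system)))
    stop("invalid reaction index")
  a[n]
}

# All-reaction mass-action propensity vector at a population state; hooks
# override per reaction.  No input validation: hot path.
.propensityVec <- function(system, x) {
  s <- system@reactantStoich
  a <- system@rateConstants
  for (n in seq_along(a)) a[n] <- a[n] * prod(choose(x, s[n, ]))
  hooks <- system@propensityHooks
  if (length(hooks))
    for (nm in names(hooks))
      a[match(nm, system@reactionNames)] <- hooks[[nm]](x)
  a
}

#' @rdname speciesPropensity
#' @export
reactionPropensity <- function(system, x0, r, n = NULL) {
  x <- gammaMap(system, x0, r)
  if (is.null(x)) {
    z <- numeric(if (is.null(n)) numReactions(system) else length(n))
    return(z)
  }
  speciesPropensity(system, x, n)
}

#' @rdname speciesPropensity
#' @export
totalPropensity <- function(system, x0, r) {
  sum(reactionPropensity(system, x0, r))
}
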
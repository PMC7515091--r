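#' Enumerate the reachable reaction-count state space in shells
#'
#' Breadth-first expansion of the reaction-count lattice from the origin:
#' shell `m` contains the states with total firing count `m` that are
#' reachable through positive-propensity transitions.  A successor
#' `r + 1n` is added only when the pulled-back propensity
#' \eqn{\alpha_n(x_0, r)} is positive; states whose species image would go
#' negative carry zero probability and are never stored.  Within each
#' shell, states are ordered lexicographically, so the enumeration is
#' deterministic and byte-reproducible.
#'
#' @param system a [ReactionSystem-class].
#' @param x0 initial population state.
#' @param M truncation depth (number of shells beyond the origin).
#' @return An [OrderedStateSpace-class].
#' @examples
#' bd <- makeFixture("bd_x0_0")
#' shellSizes(expandShells(bd$system, bd$x0, M = 4))  # 1 1 2 2 3
#' @export
expandShells <- function(system, x0, M) {
  x0 <- .checkSpeciesState(system, x0, "x0")
  M <- as.integer(M)
  stopifnot(M >= 0L)
  nr <- numReactions(system)
  shells <- vector("list", M + 1L)
  shells[[1L]] <- matrix(0L, 1L, nr)
  if (M > 0L) {
    for (m in seq_len(M)) {
      cur <- shells[[m]]
      if (nrow(cur) == 0L) {
        shells[[m + 1L]] <- matrix(0L, 0L, nr)
        next
      }
      succ <- vector("list", nrow(cur))
      for (i in seq_len(nrow(cur))) {
        r <- cur[i, ]
        a <- reactionPropensity(system, x0, r)
        live <- which(a > 0)
        if (length(live)) {
          s <- matrix(rep(r, each = length(live)), length(live))
          s[cbind(seq_along(live), live)] <- s[cbind(seq_along(live), live)] + 1L
          succ[[i]] <- s
        }
      }
      succ <- do.call(rbind, succ)
      shells[[m + 1L]] <- if (is.null(succ)) matrix(0L, 0L, nr)
        else .uniqueSortedRows(succ)
    }
  }
  sizes <- vapply(shells, nrow, integer(1))
  new("OrderedStateSpace",
    states = do.call(rbind, shells),
    shell = rep(seq_along(sizes) - 1L, sizes),
    shellSizes = sizes,
    M = M,
    x0 = x0,
    system = system)
}

#' @rdname OrderedStateSpace-class
#' @param x an `OrderedStateSpace`.
#' @export
shellSizes <- function(x) x@shellSizes

#' @rdname OrderedStateSpace-class
#' @export
countStates <- function(x) x@states

#' @rdname OrderedStateSpace-class
#' @export
truncationDepth <- function(x) x@M

setMethod("show", "OrderedStateSpace", function(object) {
  cat(sprintf(
    "OrderedStateSpace: %d reaction-count states in shells 0..%d (x0 = %s)\n",
    nrow(object@states), object@M, .key1(object@x0)))
  cat("  shell sizes:", paste(object@shellSizes, collapse = " "), "\n")
})

#' Dump a state index as TSV
#'
#' Writes one row per retained reaction-count state with its shell, the
#' comma-joined firing counts, and the comma-joined population reached
#' through the Gamma map.
#'
#' @param space an [OrderedStateSpace-class].
#' @param file path or connection passed to [utils::write.table()].
#' @return The data.frame, invisibly.
#' @export
writeStateIndex <- function(space, file = stdout()) {
  gam <- apply(space@states, 1L, function(r)
    .key1(gammaMap(space@system, space@x0, r)))
  df <- data.frame(shell = space@shell,
    state = .stateKeys(space@states),
    gamma_population = gam)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Assemble the lower-triangular reaction-counts generator
#'
#' Builds the truncated generator of the reaction-counts CME over the
#' shell-blocked state order of `space`: the off-diagonal entry
#' (row `r + 1n`, column `r`) is \eqn{\alpha_n(x_0, r)} and the diagonal
#' entry of `r` is minus its total exit rate \eqn{-\alpha(x_0, r)}.
#' Transitions stepping past the deepest retained shell appear only in the
#' diagonal (as outflow to the truncation tail); they are never redirected.
#'
#' @param space an [OrderedStateSpace-class].
#' @return A [RateGenerator-class].
#' @examples
#' bd <- makeFixture("bd_x0_2")
#' gen <- buildGenerator(expandShells(bd$system, bd$x0, 3))
#' Matrix::diag(gen@Astar)[1]  # -(cb + 2 cd) = -1.2
#' @export
buildGenerator <- function(space) {
  system <- space@system
  x0 <- space@x0
  n <- nrow(space@states)
  keys <- .stateKeys(space@states)
  idx <- seq_len(n)
  names(idx) <- keys
  ii <- jj <- integer(0)
  xx <- numeric(0)
  alpha <- numeric(n)
  for (j in seq_len(n)) {
    r <- space@states[j, ]
    a <- reactionPropensity(system, x0, r)
    alpha[j] <- sum(a)
    live <- which(a > 0)
    for (nn in live) {
      rp <- r
      rp[nn] <- rp[nn] + 1L
      i <- idx[.key1(rp)]
      if (!is.na(i)) {   # inside truncation; otherwise diagonal-only outflow
        ii <- c(ii, i); jj <- c(jj, j); xx <- c(xx, a[nn])
      }
    }
  }
  A <- Matrix::sparseMatrix(i = c(ii, seq_len(n)), j = c(jj, seq_len(n)),
    x = c(xx, -alpha), dims = c(n, n))
  new("RateGenerator", Astar = A, alpha = alpha, space = space)
}

#' Check strict lower-triangularity of a generator
#'
#' The shell-blocked order makes every one-firing transition point from a
#' shell to the next, so all off-diagonal rates must lie strictly below
#' the diagonal.  This is asserted, not assumed: the return value reports
#' any offending entries.
#'
#' @param gen a [RateGenerator-class] (or a bare matrix to check against
#'   an assumed ordering).
#' @return A list with `ok` (logical) and `violations` (data.frame of
#'   row, col, value for entries on the wrong side).
#' @export
verifyTriangular <- function(gen) {
  A <- if (is(gen, "RateGenerator")) gen@Astar else gen
  A <- methods::as(methods::as(A, "CsparseMatrix"), "generalMatrix")
  tri <- methods::as(A, "TsparseMatrix")
  i <- tri@i + 1L
  j <- tri@j + 1L
  bad <- which(i < j & tri@x != 0)
  list(ok = length(bad) == 0L,
    violations = data.frame(row = i[bad], col = j[bad], value = tri@x[bad]))
}

setMethod("show", "RateGenerator", function(object) {
  cat(sprintf("RateGenerator: %d x %d sparse lower-triangular generator\n",
    nrow(object@Astar), ncol(object@Astar)))
  cat(sprintf("  %d transition rates, max exit rate %g\n",
    length(object@Astar@x) - nrow(object@Astar), max(object@alpha)))
})
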
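#' Built-in toy reaction networks
#'
#' Fully specified small systems used throughout the examples, tests and
#' validation battery:
#' \describe{
#'   \item{`bd_x0_0`}{birth-death `0 -> X` (cb = 1.0), `X -> 0`
#'     (cd = 0.1), starting population 0.}
#'   \item{`bd_x0_2`}{the same rates starting from population 2.}
#'   \item{`bd_case1`, `bd_case2`, `bd_case3`}{birth-death from
#'     population 2 with (cb, cd) = (1.0, 0.15), (1.0, 0.2) and
#'     (2.0, 0.15).}
#'   \item{`pure_birth`}{single reaction `0 -> X` at rate 1.0: total
#'     firings are exactly Poisson(t).}
#'   \item{`dimerization_toy`}{`0 -> X` (1.0) and `X + X -> D` (0.1)
#'     from (X, D) = (2, 0): a bimolecular propensity.}
#'   \item{`toggle_toy`}{`A -> B` (1.0) and `B -> A` (0.8) from
#'     (A, B) = (2, 0): a conversion cycle whose species space is finite
#'     while the reaction-count space is not.}
#' }
#'
#' @param name fixture label.
#' @return List with `system` (a [ReactionSystem-class]) and `x0`.
#' @examples
#' makeFixture("bd_x0_0")$system
#' @export
makeFixture <- function(name) {
  bd <- function(cb, cd, x0) {
    list(system = ReactionSystem(
      speciesNames = "X",
      reactantStoich = rbind(0L, 1L),
      productStoich = rbind(1L, 0L),
      rateConstants = c(cb, cd),
      reactionNames = c("birth", "death")),
      x0 = as.integer(x0))
  }
  switch(name,
    bd_x0_0  = bd(1.0, 0.1, 0L),
    bd_x0_2  = bd(1.0, 0.1, 2L),
    bd_case1 = bd(1.0, 0.15, 2L),
    bd_case2 = bd(1.0, 0.2, 2L),
    bd_case3 = bd(2.0, 0.15, 2L),
    pure_birth = list(system = ReactionSystem(
      speciesNames = "X",
      reactantStoich = rbind(0L),
      productStoich = rbind(1L),
      rateConstants = 1.0,
      reactionNames = "birth"), x0 = 0L),
    dimerization_toy = list(system = ReactionSystem(
      speciesNames = c("X", "D"),
      reactantStoich = rbind(c(0L, 0L), c(2L, 0L)),
      productStoich = rbind(c(1L, 0L), c(0L, 1L)),
      rateConstants = c(1.0, 0.1),
      reactionNames = c("birth", "dimerize")), x0 = c(2L, 0L)),
    toggle_toy = list(system = ReactionSystem(
      speciesNames = c("A", "B"),
      reactantStoich = rbind(c(1L, 0L), c(0L, 1L)),
      productStoich = rbind(c(0L, 1L), c(1L, 0L)),
      rateConstants = c(1.0, 0.8),
      reactionNames = c("toB", "toA")), x0 = c(2L, 0L)),
    stop("unknown fixture name: ", name)
  )
}

#' @rdname makeFixture
#' @export
fixtureNames <- function() {
  c("bd_x0_0", "bd_x0_2", "bd_case1", "bd_case2", "bd_case3",
    "pure_birth", "dimerization_toy", "toggle_toy")
}
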
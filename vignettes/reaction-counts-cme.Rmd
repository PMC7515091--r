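---
title: "Reaction-count state spaces, path chains, and gating bounds"
author: "rxnpaths"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reaction-count state spaces, path chains, and gating bounds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rxnpaths)
```

## The model

A well-mixed reaction network with $N_s$ species and $N_r$ mass-action
reactions is a continuous-time Markov chain $Z(t)$ on population vectors
$x \in \Omega \subset \mathbb{N}_0^{N_s}$.  Reaction $n$ has net
stoichiometry $\nu_n$ and stochastic mass-action propensity
$a_n(x) = c_n \prod_i \binom{x_i}{s_{ni}}$, with $s$ the reactant
stoichiometry and $c_n > 0$ a rate constant in units of 1/time
(bimolecular constants are taken as already volume-scaled).  The
probability law solves the chemical master equation (CME).

This package works primarily in the *reaction-count* coordinates: the
state $r \in \Lambda \subset \mathbb{N}_0^{N_r}$ records how many times
each reaction has fired.  Given the initial population $x_0$, the
current population is the affine image
$$\Gamma(x_0, r) = x_0 + \textstyle\sum_n \nu_n r_n,$$
and the propensities pull back as
$\alpha_n(x_0, r) = a_n(\Gamma(x_0, r))$ when the image is a valid
population, zero otherwise.  Firing reaction $n$ increments $r_n$ by
one, so *every* transition increases the total count $\|r\|_1$: the
process only steps forward.  Two structural consequences drive the whole
package:

* the lattice partitions into **shells** $\nabla_m$ of states reachable
  in exactly $m$ firings, and under a shell-blocked order the truncated
  generator $A^*$ is strictly lower triangular, with spectrum equal to
  the negated total exit rates $-\alpha(x_0, r)$ on its diagonal;
* probabilities of retained states are unaffected by truncation depth
  (nothing flows backwards), so truncation only loses the tail mass
  $\psi(t)$, which is certified directly.

Species-level answers are recovered by the push-forward
$p(X(t) = x) = \sum_{r \in \Gamma^{-1}(x_0, x)} p(R(t) = r)$, and an
independent finite-state-projection (FSP) solver for the species CME
(`solveSpeciesFSP()`) cross-checks that identity.

```{r quick}
bd <- makeFixture("bd_x0_0")            # birth-death, cb = 1.0, cd = 0.1
d <- solveReactionCME(bd$system, bd$x0, times = c(1, 5, 10), eps = 1e-8)
d
max(abs(speciesProbability(pushForward(d), 1L) -
        speciesProbability(solveSpeciesFSP(bd$system, bd$x0,
          c(1, 5, 10), 1e-8), 1L)))
```

## Tunable parameters

* `eps` (dimensionless, default `1e-8`): the certified bound on the
  truncation tail at every output time.  The solver starts at depth
  `M0 = 8` shells and doubles `M` until `max(tailMass) < eps`, up to
  `MMax = 64` shells or `stateCap = 2e6` states; beyond the cap it
  raises an error reporting the residual tail rather than returning an
  uncertified answer.  One depth serves the whole grid: with
  forward-only flow the tail is largest at the final time, which is
  asserted on the computed tail, not assumed.
* `C` (mass, default 1): the initial probability placed on the origin.
  The full CME requires a unit point mass; values below 1 are exposed
  because sub-chains started from accumulated gate mass reuse the same
  machinery without renormalising.
* `times`: any strictly increasing non-negative grid; probabilities at
  `t = 0` are the point mass on the origin.
* `cap` (paths, default `1e5`): admissible-path enumeration is
  multinomial in the target's counts and fails loudly at the cap.
* `closedFormLimit` (default 50 states): chains longer than this switch
  from the symbolic engine to a matrix-exponential solve of the chain
  generator.

## Numerical choices

**Propagation.** The linear system $\dot u = A^* u$ is integrated by a
dense scaling-and-squaring matrix exponential for up to 700 states
(cached per unique grid step) and by uniformization — the
Poisson-weighted power series of the shifted generator, tail cut below
$10^{-16}$ — for larger sparse systems.  Both are spectrally stable on
these generators and deliver the $10^{-10}$ conservation the class
validity demands.  Nested quadrature of the recursive convolution
solution is avoided entirely: it accumulates error with depth, while the
matrix exponential is mathematically identical to that recursion.

**Exact time-integrals.** The shell conservation/outflow identity
$\phi_m = \psi_{m+1}$ equates the flux
$\sum_{r \in \nabla_m} \alpha(x_0,r) \int_0^t p(R(s) = r)\,ds$ with the
mass beyond shell $m$.  The integrals are computed *exactly* by
exponentiating the augmented matrix
$\left[\begin{smallmatrix}A & u_0\\ 0 & 0\end{smallmatrix}\right]$,
whose top-right block is $\int_0^t e^{As} u_0\,ds$ — a closed form we
prefer over adaptive quadrature on an interpolated trajectory, which
would cap the check's resolution at the quadrature tolerance.

```{r lemma}
tailMassIdentity(d, m = 3, time = 5)
```

**The exponential-polynomial engine.** Path-chain probabilities live in
the family $\sum_j c_j t^{k_j} e^{-\lambda_j t}$, which is closed under
the chain convolution $\beta \int_0^t e^{-a(t-s)} f(s)\,ds$.  Repeated
exit rates *must* occur (a birth-death path that revisits a population
revisits its exit rate), so rates equal within a relative $10^{-12}$
are merged and produce $t^k$ terms — the exact degenerate limit — in
place of near-singular divided differences.  The conditioning boundary
is worth stating: for rates that are close but *not* equal (gaps below
roughly $10^{-2}$ at powers $\ge 3$) the divided-difference
coefficients grow like $\mu^{-(k+1)}$ and cancellation caps the
absolute accuracy near $10^{-7}$.  Mass-action chains have rate gaps
that are integer multiples of the rate constants, so they sit on either
side of that sliver; the chain-generator matrix exponential
(`chainGenerator()` + the numerical route) is the fallback for anything
in between.  Within its regime the engine agrees with a stiff ODE
oracle to $10^{-13}$.

**Determinism and tie-breaks.** Shells are enumerated breadth-first and
sorted lexicographically within each shell; outputs are
byte-reproducible.  States whose $\Gamma$ image would be a negative
population are never stored: the inherited propensity gives them zero
probability, so retaining them (as the zero-propensity reading of the
state space would) changes nothing but the state count.  Successors are
created only through positive-propensity edges for the same reason.

**Degenerate inputs.** An absorbing origin yields empty shells and an
exactly conserved point mass; a saturated (finite) state space
terminates the truncation loop with zero tail regardless of `eps`;
`t = 0` grids, single-state paths, and sub-unit initial mass are all
exercised in the test suite.

## Path chains and the decomposition

An admissible path $g = (g_1, \dots, g_m)$ steps by single firings.  Its
path chain keeps the path states plus one absorbing sink: state $g_k$
is left at its full exit rate $\alpha(g_k)$ while mass enters $g_{k+1}$
at $\beta(g_k, g_{k+1}) = \alpha_n(g_k)$, the propensity of the firing
that makes the step.  The first state decays as $C e^{-\alpha(g_1) t}$
and each subsequent state is one convolution.  Summing the terminal
probability over *all* admissible paths from the origin to $r$
reconstructs $p(R(t) = r)$ exactly — the decomposition identity that the
package verifies on every fixture:

```{r decomp}
bd2 <- makeFixture("bd_x0_2")
decomposeState(bd2$system, bd2$x0, c(2L, 1L), times = c(0.5, 1, 5))[
  c("maxAbsDiff", "nPaths")]
```

## Gating bounds, and one cautionary observation

Gating a chain at position $j$ freezes its outflow so the horizon's
inflow accumulates to
$C_j = \beta(g_{j-1}, g_j) \int_0^{\Delta t} p(\cdot = g_{j-1})\,ds$;
un-gating restarts a fresh chain from that mass.  Cascading this at
every transition yields the closed-form levels
$u_1 \equiv C$, $u_n(t) = \frac{\beta(g_{n-1},g_n)}{\alpha(g_{n-1})}
(1 - e^{-\alpha(g_{n-1}) t})\, u_{n-1}(t)$, computed exactly in the
exponential-polynomial algebra.  Two dominance statements are checked by
`verifyBound()`:

* **time-integral dominance** at interior states — the integrated
  occupancy under the level-$(k-1)$ un-gated chain dominates the
  original's.  This holds on every fixture and on 100 seeded random
  chains in the test suite;
* **pointwise dominance** of the terminal level $u_m(t)$ over the exact
  path probability.  This is the plotted claim; it holds at all 1000
  grid points in all four worked parameter cases, and the package
  checks it empirically rather than citing it as proved.

One stronger statement that is sometimes quoted — that after a *single*
gate at $g_2$ the un-gated chain dominates the original *pointwise* at
every later state — is **false** in general, and the package
deliberately reports rather than asserts it.  The counterexample is the
package's own worked chain (birth-death from population 2, horizon
$\Delta t = 10$): the un-gated chain decays from the gate state at rate
$\alpha(g_2) = 1.3$ while the original chain's slowest mode is $1.2$,
so the original overtakes the un-gated chain at later times
(margin $\approx -10^{-2}$ by $t = 4$, confirmed independently by the
closed form and a stiff ODE solve agreeing to $10^{-15}$).  The
integrated form at $g_2$ is unaffected, and so are the cascade bounds
above, whose levels drop the terminal decay altogether.

```{r gate}
ch <- pathChain(bd2$system, bd2$x0, c(1, 2, 2, 2))   # to state (1, 3)
gateConstant(ch, j = 2, dt = 10)                     # (1/1.2)(1 - e^{-12})
vb <- verifyBound(ch, times = seq(0.01, 10, length.out = 200))
c(pointwise = min(vb$pointwise$margin), integral = min(vb$integral$margin))
sg <- verifySingleGate(ch, times = seq(0.5, 10, length.out = 20))
c(integralOk = sg$integralOk, pointwiseOk = sg$pointwiseOk)
```

## The stochastic simulation oracle

`simulateSSA()` is the direct-method Gillespie sampler in reaction-count
coordinates: exponential waiting times at the total propensity, the
firing reaction chosen in proportion to its propensity, species
reconstructed through $\Gamma$.  Snapshots use the right-continuous
convention.  Ensembles draw one L'Ecuyer-CMRG substream per trajectory
index, derived from the master seed, so results are reproducible
independently of execution order.  The Monte-Carlo route is the
package's distribution-free cross-check: at $10^5$ trajectories the
total-variation distance to the solved species law sits near
$4 \times 10^{-3}$, within the $3\sigma$ binomial envelope.

## What the fixtures emulate — and what they do not

The bundled fixtures are the worked birth-death systems (population 0
or 2; rate pairs $(1.0, 0.1)$, $(1.0, 0.15)$, $(1.0, 0.2)$,
$(2.0, 0.15)$), a pure-birth network whose firing count is exactly
Poisson$(c_b t)$ (the closed-form anchor for the solver), a
dimerization toy with a genuinely bimolecular propensity, and a
two-species conversion cycle whose species space is finite while its
reaction-count space is not.  They exercise boundary-pinned states,
pruning, non-injective $\Gamma$, and degenerate rate ties.  They do
*not* emulate stiff multi-scale networks, high-dimensional lattices
(the shell count grows polynomially with $N_r$ and the path count
multinomially), or time-varying kinetics — passing tests say nothing
about those regimes.

Problem sizes in the tests and the acceptance script were chosen to
keep every identity at its analytical tolerance while the full battery
completes in about a minute: truncation depths up to 64 shells
($\approx 10^3$ states for the birth-death systems), decomposition over
the first five shells (17 states, $\le 10$ paths each), bound
verification at 1000 grid points, and $10^5$ SSA trajectories.

## Known limitations

* Stationary distributions are out of scope: the reaction-count process
  never stops stepping forward, so only transient (finite-time)
  questions are posed to it.
* Time-dependent propensities and reverse-time/inference uses are not
  supported.
* Path enumeration is exact and therefore exponential in depth; the cap
  makes the failure explicit instead of silent.
* Custom propensity hooks step outside the mass-action guarantees; the
  enumeration trusts them to vanish wherever the population lattice is
  left (mass action enforces this automatically).
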
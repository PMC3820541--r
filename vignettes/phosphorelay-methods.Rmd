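---
title: "Methods: steady-state shape, noise and timing of four-layered phosphorelays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: steady-state shape, noise and timing of four-layered phosphorelays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosphorelay)
```

## The model

A four-layered phosphorelay passes a phosphoryl group down the chain
HK -> REC -> Hpt -> RR. The sensor histidine kinase HK autophosphorylates at
rate `ks`, which stands in for the signal; the phosphorylated fraction of
the terminal response regulator RR is the output. The aspartate-bearing
layers (REC, RR) can lose their phosphoryl group by hydrolysis (rates
`kh1`, `kh2`), and each of the three transfer interfaces may also run in
reverse (`k2r`, `k3r`, `k4r`). Under mass action this gives the ODE system
with transfer fluxes

```
J2 = k2 [HK~P][REC]  - k2r [HK][REC~P]
J3 = k3 [REC~P][Hpt] - k3r [REC][Hpt~P]
J4 = k4 [Hpt~P][RR]  - k4r [RR~P][Hpt]
```

plus `ks [HK]` at the top and the two hydrolysis sinks. Protein totals per
layer are conserved (one conservation law per layer). Units are arbitrary
but coherent (concentration and time); the package never assumes a
particular magnitude, and worked examples span rate constants from `1e-2`
to `1e5` and totals from `1e-4` to `10`.

Turning the three reverse transfers and two hydrolyses on or off gives
`2^5 = 32` topologies, enumerated by `relay_topologies()`. The id order
follows the published pairings for the 18 ids that appear in print; the 14
remaining ids are fixed by the unique block structure consistent with all
of them (four blocks of eight by hydrolysis pattern, a fixed
reverse-transfer order within each block). This assignment is re-verified
programmatically at package load.

## Responsiveness

A relay is *responsive* when its steady-state output actually varies with
the signal. Phosphoryl groups must be able to leave the output layer and
then exit the relay: the structural rule is `h2 = 1` or
(`h1 = 1` and `r3 = 1` and `r4 = 1`), leaving 18 responsive and 14
non-responsive topologies. `responsiveness_screen()` confirms the rule
numerically: it integrates the ODE to steady state at two signals six
decades apart (defaults `1e-6` and `1`, generic unit rates and totals) and
calls the relay responsive when the outputs differ by more than 1% of the
RR total. Predicate and screen agree on all 32 topologies; for variants
with additional first-order losses the rule generalizes recursively (an
extra drain at a layer acts as a sink exactly like hydrolysis does).

## The steady-state map and its exact treatment

At steady state the flux balances are triangular when read from the bottom
layer up: given the output level `rr = [RR~P]`, the RR balance fixes
`[Hpt~P]` by one linear equation, the Hpt balance then fixes `[REC~P]`, the
REC balance fixes `[HK~P]`, and the HK balance yields the signal. This
gives the exact map `ks = f(rr)` (the inverse of the signal-response
curve) in closed form per level — no root finding and no integration. Each
intermediate must land inside `[0, total]`; the first response level where
this fails is the maximal response `alpha`, located by bisection on the
feasibility boundary to a relative tolerance of `1e-10`. `alpha` equals
the large-signal limit of the steady-state output (tested against stiff
ODE integration at `ks = 1e6` to `1e-4` relative).

Curves are sampled on the standard grid `0, alpha/100, ..., 0.95 alpha`
(96 points, including zero; the grid convention is documented here because
a 95-point variant without the origin would be equally defensible). Every
grid point is cross-checked in the test suite against ODE steady states to
`1e-6` relative.

The same elimination covers three model variants exactly, because an
additional first-order loss at any layer only adds a linear drain term to
that layer's balance: protein turnover (dilution `delta` on every species,
production `delta * total` of each unphosphorylated form, so the stated
totals are the steady-state totals), HK~P auto-dephosphorylation, and
Hpt~P auto-dephosphorylation. The bifunctional-HK variant couples the top
two conservation classes through the HK.REC~P complex; there the
elimination retains one scalar root problem per response level (bisected
to machine precision), which is still far cheaper and more accurate than
integrating the ODE per signal. Only the encounter-complex variant falls
back to fully numerical curves (`variant_steady_curve()`).

## Classifying hyperbolic versus sigmoidal curves

A hyperbolic signal-response curve is concave throughout; a sigmoidal one
starts convex and inflects. The sign of the second derivative of the
response at zero signal therefore separates the two. The package computes
that curvature exactly: the elimination uses only rational operations, so
propagating second-order Taylor jets (value, first, second derivative with
respect to `rr`) through it yields `f'(0)` and `f''(0)` to machine
precision, and the inverse-function rule gives
`d^2 R / d ks^2 |_0 = -f''(0) / f'(0)^3`. No finite-difference step is
involved, which keeps the sign test robust even for curvatures of order
`1e-3` in poorly scaled instances. (For the bifunctional variant, whose
map contains an inner root solve, the derivatives at zero use high-order
one-sided differences on a response grid of `1e-4 alpha`.) Degenerate
instances with `f'(0) <= 0` are rejected as indeterminate.

The second, independent classifier estimates the second derivative
numerically along the whole curve: central differences on a uniform
200-point signal grid spanning `[0, f(0.95 alpha)]`, with a sign change
counted only when two consecutive points agree on each side — single-point
numerical flips are ignored. The two classifiers agree on the vast
majority of sampled instances (enforced at 95% per topology in the tests);
disagreements concentrate where the inflection sits far into the
compressed upper end of the uniform signal grid.

Sigmoidality has analytic necessary conditions: `kh1 > 0`, `k2 > k2r`,
and (`k3r > k3` or `k3r * k4r > k3 * k4`), with `k3r > 0` required as
well; all inequalities strict, ties classed hyperbolic. The third
condition is the contrapositive of the exact forcing statement — the
curvature at zero is negative whenever `k3 > k3r` *and*
`k3 k4 > k3r k4r` — and it genuinely compares rate products: an additive
comparison of the sums (`k3r + k4r` versus `k3 + k4`), which is a
tempting simplification, is falsified by relays without output
hydrolysis whose bottom interface runs strongly in reverse (the suite
carries instances, verified sigmoidal by exact curvature, by ODE finite
differences and by whole-curve sign change, with both sum disjuncts
false and `k3r k4r` two orders of magnitude above `k3 k4`). Violating
any condition forces negative curvature at zero — this implication is
property-tested over random draws, and no surveyed sigmoidal instance
may violate the predicate (a single counterexample fails the suite).

Steepness is summarized by the Hill coefficient
`nH = log(81) / log(input90 / input10)`, with the 10%- and 90%-of-alpha
signals evaluated exactly through `f` where available, by monotone (Hyman)
spline interpolation on sampled curves otherwise. Michaelis-Menten and
Hill reference shapes recover `nH = 1, 2, 4` to `1e-6`.

## Parameter-space sampling

The sampler draws log-uniformly: bimolecular transfer rates over
`[1e-2, 1e2]` with forward and reverse drawn i.i.d., first-order
hydrolysis rates over `[1e-3, 1e1]`, totals over `[1e-1, 1e1]` (one shared
draw in the default equal-totals mode, four independent draws otherwise),
1000 sets per topology. Log-uniform weighting treats each decade equally —
the natural prior for rate constants spread over orders of magnitude — and
i.i.d. forward/reverse draws make ratio-based criteria scale-free. These
ranges were fixed once as the package's study conditions.

What the generator emulates: broad, biologically plausible kinetic
diversity with no correlation structure between parameters. What it does
not emulate: the original curated per-parameter literature ranges behind
the published survey, which are not reproducible from the main text. The
structural results are insensitive to this (forced zeros stay at exactly
0% sigmoidal under any ranges; topologies 14 and 30 carry the two largest
sigmoidal fractions and sit closest to an even split), but threshold
counts are not: under the package's default ranges six topologies — 14,
16, 26, 29, 30 and 32 — exceed 2% sigmoidality, whereas the published
survey reports only the four with reverse transfer at both lower
interfaces above that threshold. Passing surveys here therefore
demonstrate the structural ordering, not the literal published
percentages.

## Intrinsic noise at small copy number

For noise the relay is mapped onto a continuous-time Markov chain on
molecule counts: each layer total is represented by `N` molecules
(default 10), counts are `g x` with `g = N / total` (the `N_A V` system
size), bimolecular rate constants are divided by `g`, first-order rates
are untouched. Conservation leaves a 4-tuple of phospho-counts, i.e.
`(N+1)^4 = 14641` states at `N = 10`. The stationary distribution solves
`pi Q = 0` restricted to the communicating class reachable from the empty
state (breadth-first search on the positivity pattern; the pattern is
signal-independent for positive signals and is reused across a grid).

The solve is a two-stage hybrid. Compiled Gauss-Seidel sweeping of the
balance equations — the iterative scheme probabilistic model checkers
use — handles well-mixed chains in well under a second, warm-started from
a product-of-binomials approximation centered on the deterministic steady
state (and, along a signal grid, from the previous grid point). Stiff
relays, however — rates spread over several decades, or no hydrolysis at
the output layer — mix so slowly that iterative sweeps can stall at a
deceptively small residual while still far from the solution, and direct
sparse LU of the whole 4-D lattice generator is ruled out by catastrophic
fill-in. When the sweeps miss the residual tolerance (`1e-12` of the
largest exit rate) the solve therefore falls through to an exact direct
block elimination over RR~P levels: the chain is quasi-birth-death in the
output count, so Schur complements accumulate level by level and the
stationary vector follows by substitution, anchored at the end of the
level range expected (from the deterministic mean) to carry the mass and
re-anchored at the other end if the residual disagrees. The direct path
reproduces deterministic means to six digits on chains where plain
iteration returns errors of order one. A Gillespie direct-method
simulator (compiled, driven by R's RNG so `set.seed()` governs it)
provides an independent stochastic cross-check of the stationary
moments.

Regime comparisons use *matched pairs*: both members share every drawn
rate and total, and only the forward/reverse orientation at the REC-Hpt
and Hpt-RR interfaces is flipped (forward-dominant gives the hyperbolic
member, reverse-dominant the sigmoidal one — the relay's documented tuning
knob), with both labels verified by classification. Unmatched draws would
let the maximal response, which varies over orders of magnitude between
draws, dominate the coefficient of variation. Noise is evaluated at
signals producing matched response fractions (10% to 90% of each
member's own maximal response) and summarized as the median SD/mean of
the phospho-RR fraction: matching by operating point is essential,
because a grid spaced in raw signal lands most of a sigmoidal member's
points in its compressed saturated top end, where noise is lowest, and
the within-pair comparison would then contrast different operating
regimes rather than regimes of curve shape.

## Step-response timing

The switching time is measured from an exact steady state: the basal
operating point is the response level `b * alpha` (b = 0.2, 0.5, 0.8),
whose full state the elimination provides directly, and the basal signal
is `ks* = f(b * alpha)`. A stated basal signal "level of 0.2 alpha" mixes
units (alpha is a response level), so the package reads it as the signal
*producing* that response — the dimensionally consistent choice, flagged
here as an interpretation. The signal then steps by ±10%, the stiff ODE
runs in doubling segments (state carried forward, so early transients are
never re-integrated), and the switching time is the first moment after
which the output stays within 1% of the net change around the new steady
state, confirmed over a doubled horizon. The returned time is stable to
1% under output-grid refinement. The step is applied to the signal, not
the response target, matching the input-step reading of the protocol.

## Numerical choices, sizes and degenerate inputs

* ODE work uses `deSolve::lsoda` with `rtol 1e-10 / atol 1e-12 x scale`
  for steady-state oracles and `1e-8 / 1e-11 x scale` for timing runs;
  steady state is declared when the derivative norm drops below
  `1e-9 x (largest total)` (oracles) with doubling horizons.
* All bisections (alpha, curve inversion, signal inversion) are monotone
  with explicit feasible/infeasible invariants; exact zeros are returned
  at `rr = 0` rather than computed.
* Degenerate instances — required rates at zero, `f'(0) <= 0`,
  non-responsive structures — raise errors rather than returning
  placeholder numbers; surveys count and exclude such failures.
* Test problem sizes: surveys of 1000 draws per topology (3 seeds for the
  threshold count), 200 random instances x 10 grid points for the
  elimination-vs-ODE oracle, `N = 10` and `20` for the count-chain
  convergence check, 10 matched pairs per topology for noise, 100 draws
  per regime for timing. These sizes are the package's chosen study
  conditions and give stable results at fixed seeds.

## Known limitations

* The published per-topology sigmoidality percentages depend on curated
  sampling ranges that are not recoverable from the main text; only
  structural zeros, ordering and near-even splits are reproducible here
  (see the sampling section).
* Step-response timing contrasts between regimes are likewise
  range-dependent: under the package's default ranges the
  tunable-topology timing pattern reported for curated parameter sets
  does not reproduce (the tests compute and document the observed
  pattern), whereas the noise contrast is robust.
* The symbolic closed form of the curve polynomials and of the
  curvature-at-zero expression is deliberately not reconstructed; the
  exact elimination plus jet differentiation computes the same quantities
  without the algebra.
* The count-chain analysis requires equal layer totals (a single system
  size cannot map unequal totals to a common copy number) and the simple
  monofunctional model.
* The encounter-complex variant models complexes on the forward transfer
  steps alongside the elementary channel, so zero extra rates reduce
  exactly to the simple model; the replacement form (no elementary
  channel) is obtained by zeroing the elementary forward rates.
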
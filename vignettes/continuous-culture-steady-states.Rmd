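---
title: "Steady states of continuous cell cultures: model, methods and numerical choices"
author: "chemofba"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Steady states of continuous cell cultures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemofba)
```

## The model

`chemofba` couples a constraint-based model of intracellular metabolism to
the two macroscopic balances of a continuous (chemostat or perfusion)
bioreactor:

$$\frac{dX}{dt} = (\mu - \phi D)\,X, \qquad
  \frac{ds_i}{dt} = -u_i X - (s_i - c_i) D,$$

where $X$ is the cell density (gDW/L), $s_i$ the culture concentration of
metabolite $i$ (mM), $c_i$ its feed concentration, $D$ the dilution rate
(1/h), $\phi \in (0,1]$ the bleeding coefficient (the fraction of cells that
actually leaves with the outflow; $\phi = 1$ is the classical chemostat),
$\mu$ the effective growth rate and $u_i$ the cell-specific exchange rate
(mmol/gDW/h, positive for consumption).

Inside the cell, fluxes $r_k$ satisfy quasi-steady-state balances at every
metabolite, including a growth-independent maintenance drain $e_i$ and a
biomass demand $y_i z$ where $z$ is the biomass synthesis rate:

$$\sum_k N_{ik} r_k + u_i = e_i + y_i z .$$

Two further constraint families close the cell model. A molecular-crowding
(enzyme cost) budget bounds the cost-weighted sum of split fluxes,
$\sum_k (\alpha_k^+ r_k^+ + \alpha_k^- r_k^-) \le C$, representing the
finite enzymatic capacity of the cell; and reversibility bounds restrict
flux signs. Nutrient uptake is bounded by transporter kinetics, $u_i \le
V_i$, and by what the culture can actually supply. In steady state the
supply bound takes the form

$$u_i \le \min\{V_i,\; c_i/\xi\}, \qquad \xi = X/D,$$

which is the pivotal observation the package is built on: every
steady-state property of the culture is a function of the single composite
variable $\xi$, the inverse of the cell-specific perfusion rate (CSPR).
The cell is assumed to maximize $z$ subject to all constraints; among
growth-optimal flux vectors the one of minimum crowding cost is selected
(a lexicographic, two-stage linear program, `solve_fba()`).

The steady-state procedure (`scan_steady_states()`) is then: solve the LP
at each $\xi$ to get $z^*(\xi)$ and $u^*(\xi)$; recover concentrations
$s_i^* = c_i - u_i^* \xi$; apply the toxicity model to get
$\mu^*(\xi)$; and read off the operating point from
$D^* = \mu^*/\phi,\; X^* = \xi \mu^*/\phi$. Two toxicity mechanisms are
supported (`toxicity_spec()`): a linear death rate
$\mu = z - \sum_j \tau_j s_j$, and multiplicative hyperbolic yield factors
$\mu = z \prod_j (1 + s_j/K_j)^{-1}$ of the kind used for lactate and
ammonia inhibition.

Two landmarks summarize feasibility: the washout rate
$D_{\max} = \mu^*(0)/\phi$ (`washout_rate()`), above which only the
cell-free state survives, and the medium depth $\xi_m$ (`find_xi_max()`),
the largest $\xi$ at which the maintenance demand can still be met, located
by bisection on LP feasibility.

Because $u^*, s^*, \mu^*$ depend on $\phi$ not at all, and $D^*, X^*$ only
through the factor $1/\phi$, the parametric curve $(\phi D^*, \phi X^*)$ is
invariant across perfusion systems: a chemostat experiment characterizes
every perfusion system with the same cell line and medium. The test suite
asserts this invariance for $\phi \in \{0.3, 0.5, 1\}$.

## Stability and bifurcation structure

A steady state is unstable precisely where $\mu^*(\xi)$ is locally
increasing, and stable otherwise; `classify_stability()` applies this
criterion with centered finite differences, and
`jacobian_eigen_check()` cross-validates it by computing the eigenvalues of
the numerically differentiated Jacobian of the full dynamical system at the
point (for low-dimensional models). Plateaus are classified stable: the
borderline case with a vanishing slope is not resolved further, since any
nonzero tolerance makes the call arbitrary there anyway.

Since $z^*(\xi)$ is provably non-increasing (a consequence of the nested
feasible sets: raising $\xi$ only tightens the uptake bounds — asserted on
the toy network and on randomized fixtures), any increase of $\mu^*$ must
come from toxicity relief: as $\xi$ grows, secreted waste per unit medium
falls, and $\mu^*$ can rise. This is the mechanism behind multistability.
`build_diagram()` partitions the scan into stability branches, finds fold
points at local extrema of $D^*(\xi)$, and reports dilution-rate windows in
which several branches coexist; the trivial washout branch ($X = 0$ at any
$D$) is kept as metadata. With the default toy parameters the structure is:
exactly two folds, one window, three coexisting states in its interior (two
stable, one unstable), and the hysteresis loop that follows from it.

## The toy network as an oracle

The built-in overflow-metabolism network (`toy_params()`,
`toy_as_generic_model()`) has four metabolites: substrate S, intermediate
P, energy currency E, waste W. Glycolysis-like conversion S → P + $N_F$ E
competes with respiration-like oxidation P → $N_R$ E, capped at
$r_{\max}$; surplus P leaves as toxic waste W. Every steady-state quantity
has a closed form:

$$u = \min\{V, c/\xi\},\quad r = \min\{u, r_{\max}\},\quad v = r - u,$$
$$s^* = c - \min\{V\xi, c\},\quad
  w^* = \max\{0, c - s^* - r_{\max}\xi\},\quad
  z = (N_F u + N_R r - e)/y,$$

with thresholds $\xi_0 = c/V$ (nutrient excess ends), $\xi_{sec} =
c/r_{\max}$ (secretion stops) and $\xi_m = c(N_F + N_R)/e$ (maintenance
fails). Defaults are literature-scale mammalian values ($N_F = 2$, $N_R =
38$, $r_{\max} = 0.45$, $V = 0.5$, $e = 1.0625$ mmol/gDW/h, $y = 348$
mmol/gDW, $c = 15$ mM, $\tau = 0.0022$ h⁻¹mM⁻¹, 0.9 ng dry weight per
cell). The respiratory cap is deliberately realized through the crowding
budget (cost $C/r_{\max}$ on respiration only) so that the cost-constraint
code path is exercised by every toy solve; an alternative encoding through
a hard uptake bound is kept for differential testing, and the suite checks
the two agree to $10^{-9}$.

These closed forms are the package's primary oracle: the acceptance suite
requires the generic LP pipeline to match them to $10^{-8}$ (absolute,
model units) at 200 values of $\xi$. With the default parameters the
multistable window computed by the package is narrow and sits just below
the washout rate ($D$ between about 1.10 and 1.17 day⁻¹) — the window's
*location* is parameter-sensitive, and only its qualitative structure (two
folds, three coexisting states, path dependence) should be read as the
robust prediction.

## What the fixture generator emulates — and what it does not

`generate_fixture()` produces three topologies: the toy network itself;
random linear chains (one substrate, one terminal energy yield) whose
optimum has a one-line closed form used for differential testing; and
randomized overflow networks drawn within the toy parameter invariants
($N_F < N_R$, $e/(N_F+N_R) \le r_{\max} \le V$). These fixtures exercise
feasibility boundaries, phase changes and the monotonicity theorem, but
they do not emulate genome-scale features: no alternate optima beyond the
cheap/costly two-path structure, no reversible internal cycles, no
compartments, no realistic cost spectra. Passing tests therefore validate
the machinery — LP correctness, the $\xi$ parameterization, stability
logic, integration — not the biological fidelity of any particular
network reconstruction.

## Dynamics

`simulate_culture()` integrates the two balances with an instantaneous FBA
solve at every step (dynamic FBA). Two numerical choices matter:

* **Transient uptake bound.** The steady-state bound $c_i D/X$ is an
  identity only at equilibrium. During transients the package bounds uptake
  by what is actually available over the step,
  $u_i \le \min\{V_i,\; s_i/(Xh) + c_i D/X\}$ with $h$ the current step
  size: the stock plus the feed inflow. The inflow term is essential — a
  pure stock bound $s_i/(Xh)$ makes the depleted-substrate concentration
  proportional to $h$ (a boundary layer that forces the step controller
  into $\sim 10^{-4}$ h steps indefinitely), whereas with the inflow term
  the $s_i = 0$ limit reproduces the steady coupling exactly and the
  integrator relaxes back to full steps after a depletion front passes.

* **Integrator.** Explicit adaptive Heun (trapezoidal predictor-corrector)
  with step halving on negative-concentration overshoot and on local error
  above `rtol` (default $10^{-4}$ relative). The right-hand side is only
  piecewise smooth — the LP optimum switches vertices at phase boundaries —
  so a high-order smooth integrator would gain nothing between switches and
  would misbehave across them; an adaptive low-order method with rejection
  is the appropriate tool. Terminal states of feasible constant-$D$ runs
  are required (in the acceptance suite) to land within 1% of the
  steady-state curve, and halving the output step must move terminal
  density by less than 0.1%.

If the LP becomes infeasible mid-run (maintenance unmet), the cell enters a
death branch ($z = 0$, exchanges zero, $\mu$ from the toxicity mechanism at
$z = 0$); the event is logged and integration continues. Washout is logged
when $X$ falls below $10^{-12}$ of the inoculum.

`path_dependence_experiment()` packages the protocol pair that demonstrates
hysteresis: a constant target dilution rate applied to a small inoculum
lands on the low-density branch, while a slow ramp through sub-window rates
first converges to the (there unique) high-density branch and then tracks
it into the window. Swapping initial conditions shows each branch is
locally attracting.

## Numerical choices and tolerances

* **LP solver.** A dense two-phase primal simplex with Bland's rule
  (`solve_lp()`), written for the small, curated networks this package
  targets (tens of reactions). Equalities are handled directly; finite
  upper bounds become explicit rows. Optimality/feasibility tolerance
  $10^{-9}$ on reduced costs and the phase-1 objective; pivot tolerance
  $10^{-11}$. The test suite cross-checks it against brute-force vertex
  enumeration on every small fixture and against an independent solver on
  random dense programs. Genome-scale models want a sparse industrial LP
  code and are out of scope.
* **Lexicographic pin.** The second stage fixes $z$ within $10^{-11}$
  relative. A looser pin visibly leaks into secreted-flux coordinates
  (the slack is amplified by $\xi\, y/N_R$), which is why the pin sits two
  orders below the documented oracle-equivalence bound of $10^{-8}$.
* **Constraint residual tolerance** for `validate_solution()`: $10^{-6}$
  absolute in model units.
* **$\xi$ grid.** Geometric from $\xi_m \times 10^{-4}$ to $\xi_m$ plus the
  $\xi = 0$ limit point (80 points by default), with up to 4 rounds of
  midpoint refinement around phase-signature changes, feasibility edges
  and sign changes of $d\mu^*/d\xi$.
* **$\xi = 0$ conventions.** The uptake bound at $\xi = 0$ is $V_i$ when
  $c_i > 0$ and $0$ when $c_i = 0$ ($0/0 := 0$): a metabolite absent from
  the feed can never be consumed, and one fed at infinite concentration
  (water, protons, oxygen) is bounded by kinetics alone.
* **Active-exchange threshold** $\varepsilon_u = 10^{-6} \times \max V$
  over bounded exchanges (scale-aware zero test) decides which metabolites
  count as secreted or limiting in a phase signature; phase boundaries are
  then bisected to $10^{-6}$ relative $\xi$ precision. How "limiting" is
  thresholded is a genuine free choice; tying it to the kinetic scale keeps
  the signature invariant under unit changes.
* **Stability threshold** $\varepsilon_{slope} = 10^{-4} \mu^*(0)/\xi_m$;
  folds are sharpened by golden-section search on $\mu^*(\xi)$ to
  $10^{-5}$ relative precision.
* **Problem sizes in the shipped tests**: scans of ~100 grid points,
  dynamic runs of a few thousand culture hours, 20 random fixtures for the
  monotonicity property, 200 oracle points — sizes chosen so the full suite
  documents the method's behavior while running in about two minutes on a
  single core.

## Degenerate inputs

Zero maintenance makes every $\xi$ feasible; `find_xi_max()` then reports
`Inf` after probing a configurable upper bound. A medium too poor to cover
maintenance even at vanishing density fails at $\xi = 0$ and is reported as
the degenerate "depth ≤ 0" case. Toxicity can push $\mu^*$ below zero;
such points stay on the curve flagged `realizable = FALSE` (they
correspond to no steady state with $D \ge 0$ and $X > 0$, but they shape
the curve's geometry). An unbounded growth direction (a cost-free,
bound-free exchange loop) is a modeling error and raises a hard error
naming the offending direction rather than returning a number.

## Known limitations

No gas-phase mass transfer is modeled, so predictions hold only while
oxygen (or CO₂ removal) is not limiting. Intracellular kinetics and
regulation are absent by construction; flux variability at the optimum is
resolved by the minimum-cost rule, not explored. The dense simplex and the
brute-force cross-checks are deliberate small-model tools. Finally, the
toy parameter set places the multistable window within a few percent of
washout; quantitative window edges should be re-derived for any real cell
line and medium rather than read off the toy defaults.
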
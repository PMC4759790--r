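---
title: "Bursting noise in a genetic toggle switch: models and numerical methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bursting noise in a genetic toggle switch: models and numerical methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(burstswitch)
```

## The biological problem

mRNA is short-lived relative to the protein it encodes. While a transcript
exists, ribosomes translate it at a high rate; when it degrades, production
stops. The number of proteins made from one transcript is therefore random
— a race between translation (rate $\gamma B$) and mRNA decay (rate
$\gamma$) whose outcome is geometric with mean $B$ — and protein
production arrives in *bursts*. How this bursting noise survives (or is
destroyed by) successive levels of model coarse-graining is the question
this package is built to study, using a symmetric two-gene toggle switch
as the test bed.

## The model hierarchy

All engines share one parameter object (`model_params()`), with time in
cell cycles and abundances in molecules:

| engine | state | production of X |
|---|---|---|
| `FM` | mRNA + protein | transcription at $a_X$, translation at $\gamma B$ per mRNA |
| `GB` | protein only | bursts at $a_X$, geometric size, mean $B$ |
| `CB` | protein only | bursts at $a_X$, constant size $B$ |
| `NB` | protein only | single proteins at rate $B\,a_X$ |
| `DA-GB` | concentrations | Itô SDE (Kramers–Moyal expansion of GB) |
| `PDMP` | mRNA mode + concentrations | $\dot x = \gamma b$ while the X-mode is occupied |
| `PDMP-SN` | concentrations | instantaneous $\mathrm{Exp}(b)$ bursts at $a_X$ |

with $a_X = K\,(r_0 + r f(N_Y))$, $f(N) = 1/(1+(N/K)^n)$ for the toggle,
protein degradation $\gamma_0$ everywhere, and $b = B/K$ the burst size in
concentration units (0.15 for the default preset). The `ecoli_table1`
preset carries literature *E. coli* estimates ($B=30$, $\gamma=30$,
$\gamma_0=1$, $r=6/100$, $r_0=1/150$, $K=200$, $n=3$); one of its sources
normalises by a burst size of 39 molecules where the tabulated value is
30 — we follow the tabulated 30 throughout.

The diffusion approximation's coefficients are fixed by the first two jump
moments of the GB chain,
$$v_x = \frac{B a_X - \gamma_0 K x}{K},\qquad
  D_x = \frac{a_X (2B^2+B) + \gamma_0 K x}{K^2},$$
where $2B^2+B$ is the second moment of the geometric burst law. The unit
tests verify both against brute-force moment estimation from the GB
simulator, which is the authority for these forms.

The three-state PDMP keeps the mRNA occupancy (no transcript / one X
transcript / one Y transcript) as a Markov mode: entering the X-mode at
rate $a_X$, leaving at rate $\gamma$, producing at rate $\gamma b$ while
inside. Because at most one transcript is represented, the production flux
is reduced by the probability of the empty mode, a bias of order
$a/\gamma$ that vanishes in the shot-noise limit $\gamma\to\infty$, where
each visit leaves behind an $\mathrm{Exp}(b)$ concentration increment.
The exponential distribution is the continuum analogue of the geometric
burst law — at the default burst statistics the Jensen–Shannon distance
between the negative-binomial and binned-Gamma frozen-rate stationary laws
is 0.011, against 0.85 for the no-burst Poisson reduction.

### The three-way switch

The multi-switch variant replaces the repressive Hill function by a
product of shifted Hill factors,
$$a(N_\text{self}, N_\text{other}) = q_0
  \Bigl(1 + \frac{r_1}{1+(N_\text{self}/K_1)^{n_1}}\Bigr)
  \Bigl(1 + \frac{r_2}{1+(N_\text{other}/K_2)^{n_2}}\Bigr),$$
with $q_0=4$, $r_1=-4/5$ (self-activation: the factor grows from
$1+r_1 = 1/5$ to 1 with the gene's own protein), $r_2 = 7/3$
(cross-repression), $n_1=3$, $n_2=1$, $K_1=160$, $K_2=320$. In the
$\lambda$-fold shifted-Hill notation common for self-activating toggle
circuits these correspond to a 5-fold activation and a 0.3-fold
repression ($r = 1/\lambda - 1$). Under the deterministic
(no-burst) limit this rate function is tristable — attractors near
$(322, 65)$, $(224, 224)$ and $(65, 322)$ molecules, protein scale
$B q_0 (1+r_2) = 400$ — which is the structural signature the package
tests; bursting engines lose the central state.

## Stochastic machinery and its numerical choices

**Exact simulation.** All discrete engines use the direct Gillespie
method with on-the-fly propensity recomputation (4–8 channels; a
dependency graph would buy nothing). The PDMP's time-dependent 0-state
exit rates are sampled by thinning against the exact propensity supremum
(for the toggle $K(r_0+r)$; for the three-way form
$q_0\max(1,1+r_1)\max(1,1+r_2)$ — an analytic bound, so no safety
inflation is needed). All randomness flows through R's RNG: a seed plus a
parameter set reproduces any trajectory bit-for-bit.

**Stationary histograms** are time-weighted (not event-weighted)
occupancies on unit molecule bins $0\ldots900$, continuous engines binned
through $N = \mathrm{round}(Kx)$; burn-in defaults to 50 cycles.
Piecewise-deterministic flows are sampled every `dt_occ` (default 0.005)
cycles between events. Because single runs of the bistable switch mix
between basins only on the switching timescale, `symmetrize = TRUE`
averages a histogram with its transpose — exact in law for the symmetric
circuit — and is used whenever a two-mode stationary law is wanted at
desk scale.

A practical warning for Jensen–Shannon comparisons: with $\sim10^4$
populated unit bins, two finite-sample estimates of the *same* law have a
JS noise floor that decays only like the square root of the run length
(about 0.14 at $10^4$ cycles at the default preset). The model-ranking
tests therefore use $2\times10^4$-cycle runs, where every inequality the
package asserts holds with a clear margin above the floor; the absolute
JS values still sit on that floor and should not be read as converged
distances. For tight closed-form comparisons (JS $<5\times10^{-3}$) the
suite uses one-species frozen-rate scenarios with $4\times10^5$-cycle
runs, where the floor is far below the threshold. The finite-$\gamma$
PDMP's agreement with the shot-noise limit is asserted as monotone
convergence in $\gamma$ (plus a closed bound at $\gamma=1000$) rather
than at a fixed small distance at $\gamma=300$: the single-transcript
truncation biases the production flux by a factor $1-O(a/\gamma)$, which
at $\gamma=300$ already exceeds such a tolerance regardless of run
length.

**Mean first switching times.** Switching is first passage to the
symmetric boundary, $N_Y \ge N_X$ for discrete states and $y \ge x$ for
concentrations ("reach or cross": bursts overshoot the diagonal).
Censoring at the horizon `t_cap` (default 2000 cycles) is always reported
and flagged; a censored-majority run certifies a lower bound, which is
how the no-burst engine's $>1000$-cycle stability is established. During
shared exponential decay the ratio $y/x$ is invariant, so continuous
engines only test the boundary at burst events (and, for the finite-
$\gamma$ PDMP, via the closed-form crossing time inside the Y-mode).

**Backward equation.** In the shot-noise limit the MFST surface solves a
linear integro-differential equation on the open half-plane
$\Omega=\{x>y\}$: advection $-\gamma_0(x\partial_x + y\partial_y)T$, plus
for each species a burst term $a(\cdot)\,(E_Z[T(\cdot+Z)]-T)$ with
$Z\sim\mathrm{Exp}(b)$ and $T\equiv 0$ wherever a y-burst lands at
$y\ge x$; right-hand side $-1$. Discretisation choices that matter:

* the burst expectation integrates the exponential kernel *exactly*
  against a piecewise-linear representation of $T$ along grid lines (the
  only quadrature error is the linear ansatz); the kernel is truncated at
  $10b$ with its $4.5\times10^{-5}$ tail lumped by constant
  extrapolation, as is the tail beyond the truncation box (the flow
  points inward, so the box edge only receives kernel weight);
* advection is discretised *along characteristics* (semi-Lagrangian:
  each node backtracks one cell along its own decay ray, with linear
  interpolation transverse to it). Coordinate-wise upwinding would leak
  probability into the exit boundary and systematically depress $T$;
* diagonal grid nodes carry the *interior limit* of $T$ — the surface is
  discontinuous at the boundary (its inside limit is the $\sim 1/a_Y$
  wait for the next exiting burst, not 0), and pinning zero there acts as
  a spurious absorbing layer;
* the scheme is first order; by default the solver runs at $h$ and $2h$
  and returns the Richardson extrapolation $2T_h - T_{2h}$ (within $2h$
  of the diagonal the plain $T_h$ values are kept). At the default
  $h=0.05$, $[0,4]^2$ box this reproduces shot-noise Monte Carlo within
  a few percent per probe cell, and enlarging the box moves interior
  values by $\sim 10^{-3}$ relative — the "no boundary condition"
  self-consistency.

The solver is restricted to toggle regulation, mirroring its role; the
finite-$\gamma$ three-state backward system is covered by Monte Carlo
only.

**Quasi-potentials.** In the weak-noise limit $b\to 0$ the stationary law
takes the WKB form $p_s \sim e^{-S_0(x,y)/b}$, and $S_0$ solves
$H(x,y,\nabla S_0)=0$ with the bursting Hamiltonian
$$H = \tilde a_X \frac{p_x}{1-p_x} + \tilde a_Y \frac{p_y}{1-p_y}
      - \gamma_0 x p_x - \gamma_0 y p_y, \qquad \tilde a_i = b\,a_i,$$
defined for momenta $p_i<1$ (requests beyond raise a domain error, not
NaN). Expanding the kernel transform $p/(1-p) = p + p^2 + p^3 + \cdots$
shows the diffusion approximation — whose Hamiltonian is
$\sum_i v_i p_i + (K D_i/2B) p_i^2$ on the same $e^{-S_0/b}$ scale —
agrees only to quadratic order; the cubic and higher terms are the
signature of the exponential burst tails, and they make the bursting
quasi-potential strictly *shallower* at large protein numbers (verified
by direct minimisation at endpoints beyond the attractor).

$S_0$ is computed by a geometric minimum action method: paths from the
attractor are relaxed under arc-length reparametrisation, and the
momentum at each node is recovered by a one-dimensional root-find of
$H(x, \theta\hat e)=0$ along the local direction of travel $\hat e$
(segments moving with the deterministic flow cost nothing; an admissible-
domain guard caps $\theta$ below the kernel divergence, reporting
endpoints that would need $p\ge1$ as unreachable). This ray ansatz avoids
the Legendre transform of the non-quadratic Hamiltonian; it is exact in
one dimension and for gradient diffusions (both closed-form oracles in
the test suite pass at $10^{-4}$ relative error or better), and for
non-gradient dynamics it is a variational approximation from below whose
residual the package treats as part of the method, not hidden. Defaults:
straight-line initial path, 128 nodes, stagnation tolerance $10^{-6}$;
the stagnation test is strict, so surfaces and tests use documented
smaller budgets (32–64 nodes, a handful of outer cycles) where 1–2%
accuracy suffices. Each surface is reported relative to its own
attractor, and `exp(-S0/b)` is exported as the WKB density estimate
(mode locations, not heights, are the meaningful output).

## What the synthetic scenarios do and do not establish

The packaged fixtures are frozen-regulation reductions (constant
transcription rate, one relevant species) whose stationary laws are
available in closed form — negative binomial for geometric bursts, Gamma
for exponential bursts, Poisson for the no-burst chain — plus a
constructed trimodal histogram for the mode detector. They pin down the
burst bookkeeping exactly, but they cannot validate regulation-coupled
behaviour; that is covered by the cross-engine consistency checks
(jump-moment oracles, FD-vs-Monte-Carlo, exchange symmetry, flux
balance) at the default presets. A green suite therefore establishes
that every engine realises its stated law and that the engines agree
where the theory says they must — not that the parameter values describe
any particular organism.

## Known limitations

* The finite-$\gamma$ PDMP caps mRNA at one molecule per species by
  construction; its flux deficit relative to the FM is $O(a/\gamma)$ and
  is documented behaviour, not a defect.
* Euler–Maruyama with reflection at zero (|x| after the step) preserves
  the stationary law better than truncation for weak noise near the
  boundary, but both are ad-hoc; the underlying SDE is only meaningful
  at large $K$ anyway.
* Histogram occupancy of deterministic flow segments is sampled at
  `dt_occ`, not integrated per bin in closed form; at the defaults the
  induced error is far below the Monte-Carlo floor.
* The gMAM ray ansatz under-estimates the action for strongly rotational
  dynamics; for the toggle's basin structure the bias is small compared
  with the PDMP-vs-diffusion differences it is used to demonstrate.
* Dimerisation, explicit genetic states and cell division are outside
  the scope of the model family.
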
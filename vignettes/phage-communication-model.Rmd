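---
title: "Modelling the evolution of arbitrium communication in temperate phages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the evolution of arbitrium communication in temperate phages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The biological question

Temperate bacteriophages of the SPbeta group secrete a small signalling
peptide ("arbitrium") on infection and read its extracellular
concentration when deciding between the lytic cycle (immediate burst of
progeny) and the lysogenic cycle (dormant integration into the host).
Because every infection adds a fixed increment of peptide, the
concentration tracks how many infections have occurred, i.e. how much of
the susceptible host pool has already been consumed. **arbitrium** is a
simulation and analysis toolkit for the eco-evolutionary dynamics of
this decision: under which ecological regimes is communication favoured,
and which communication strategy is evolutionarily stable?

## The model

A well-mixed system of susceptible bacteria $S$, per-variant lysogens
$L_i$ and free phages $P_i$, and the signal concentration $A$. Bacteria
grow logistically (rate $r$, capacity $K$); phages adsorb at rate $a$,
infect successfully with probability $b$, and each successful infection
either lysogenises (probability $\varphi_i(A)$) or lyses the cell
immediately, releasing $B$ phages. Lysogens are induced at rate
$\alpha$, free phages decay at rate $\delta$, the signal is taken up and
degraded by cells at rate $u$, and each infection adds $c$ to $A$.
Lysogens are immune to superinfection; adsorption to any cell removes
the phage.

The package works in the nondimensionalised variables $s = S/K$,
$l = L/K$, $p = bP/K$, $\hat A = A/(cK)$, $\tau = rt$, under which the
dynamics close over five dimensionless parameters: the effective burst
size $\hat B = bB$, scaled adsorption rate $\hat a = aK/r$, scaled decay
rate $\hat\delta = \delta/r$, scaled induction rate
$\hat\alpha = \alpha/r$, and scaled uptake rate $\hat u = uK/r$
(defaults 2, 10, 0.01, $10^{-3}$, 0.1). This scaling is verified in the
test suite by comparing the scaled right-hand side against an
independently coded dimensional system mapped through the
transformation, to $10^{-12}$ relative tolerance. With $r = 1\,h^{-1}$,
scaled time is in hours. The signal unit $cK$ is the concentration
reached when all $K$ initial cells have been infected once, so $\hat A$
reads directly as "fraction of the host pool already infected" during a
fast epidemic.

The lysis-lysogeny response is a step function
(`lysogeny_propensity()`): variant $i$ is fully lytic while
$\hat A < \theta_i$ and lysogenises with propensity $\phi_{max,i}$ once
$\hat A \ge \theta_i$. The boundary is closed at $\theta$ so that
$\theta = 0$ reproduces a constant, signal-independent propensity; the
constant-propensity ("bet-hedging") scenario is the
$\theta \equiv 0$ slice of the communication scenario.

### Mutation

Phage replication mutates the two traits independently with probability
$\mu$ per trait (default 0.01): a fraction $\mu$ of each variant's burst
output moves to its nearest neighbours on the regular trait grid, split
equally where two neighbours exist; at a grid boundary the outward
half-flux stays with the source variant, so the operator conserves
phage number exactly (asserted to $10^{-14}$ for every test input). The
operator is applied to both burst terms (induction and lytic bursts),
the propensity axis first; the axis operators commute, so the order is
immaterial. The kernel shape and the rate are package choices, and both
are configurable.

### Serial passaging

Equilibrium analysis (`find_equilibria()`) shows why passaging is the
interesting regime: for realistic parameters the only stable state has
every susceptible cell infected (the classifier labels it
`lysogen_only_type_ii`), where no further lysis-lysogeny decisions are
taken and the signal is constant, defeating the purpose of
communication. Selection on communication therefore requires repeated
perturbation. `run_serial_passaging()` initialises a fresh host
population at carrying capacity with a small phage inoculum (default
total $10^{-5}\hat B$ in scaled units, the image of
$\Sigma P_i = 10^{-5} K B$), integrates one episode of duration $T$,
transfers a fraction $D$ (default 0.01) into fresh hosts, and repeats.
Two protocols are provided: phage-only transfer (the default; preserves
variant frequencies exactly, which the tests assert at $10^{-14}$) and
full-sample transfer, which also carries diluted susceptibles, lysogens
and signal. Fresh cells are *added* at capacity in the full-sample
protocol; a config switch (`full_sample_cap`) instead caps the total
bacterial inoculum at capacity — either reading of "transfer into a
fresh host population" is defensible, so both are provided. The two
protocols select neighbouring strategies (one 0.005 grid step apart at
defaults).

An evolutionary steady state is declared when the L1 distance between
consecutive end-of-episode phage frequency vectors stays below
$10^{-6}$ for 10 consecutive episodes (cap 2000 episodes). Under
carrying-capacity noise this criterion is inapplicable — the
distribution fluctuates around its stationary value — so noisy runs
integrate a fixed number of episodes (1000 by default) and
`steady_state_frequencies()` estimates the stationary distribution as
the time-average of the final quarter of episodes; for deterministic
runs it is the final episode's vector.

### Carrying-capacity noise

`draw_carrying_capacity()` draws each episode's capacity from a gamma
distribution with mean 1 and shape $1/\mathrm{CV}^2$, so CV = 1 is the
exponential distribution and CV = 0 returns exactly 1 without consuming
random numbers. All noise in a run flows from one seed, with the
episode capacities drawn up-front so that shortening or lengthening a
run never changes earlier draws.

## ESS theory

Two analytic approximations are implemented. For bet-hedgers,
`phi_star_closed_form()` evaluates
$\phi^* = 1 - (bB)^{-1}\log(BK/P_0)$, clamped to $[0,1]$ with a flag
(the raw value is negative at the default burst size). For
communicators, `theta_star_closed_form()` evaluates
$\theta^*/(cK) = 1/(2 - (bB)^{-1})$, which decreases from 1 at
$bB = 1$ towards $1/2$ for highly infective phages — the "switch when
half the hosts are infected" prediction.

The numerical ESS machinery implements the best-response construction
directly. `epidemic_duration()` locates the collapse time $T_E$ of a
monomorphic resident epidemic (first passage of $s$ below
$10^{-3}k$, found by root-finding on a densely sampled trajectory).
`invader_lysogen_yield()` integrates the linearised rare-invader
equations on the frozen resident background and returns lysogens
produced per initial invader phage — the invader fitness proxy when
episodes are long, validated against a full nonlinear two-variant
simulation with the invader at relative frequency $10^{-8}$ (agreement
to 0.1%). `optimal_invader_trait()` maximises this yield (coarse grid
plus local refinement), and `ess_fixed_point()` iterates trait
$\mapsto$ best response with damping (bisection fallback) until the
strategy is its own best reply.

Numerical points worth knowing:

* For switching residents the susceptible population need not collapse
  (once $\hat A \ge \theta$ every infection lysogenises and the
  epidemic stalls with hosts left over); the invasion window then falls
  back to the episode duration $T$, which is what passaging truncates
  it to anyway.
* The resident background is re-sampled on $[0, T_E]$ after the
  collapse time is known. At $\hat B = 100$ the epidemic lasts
  $\approx 0.03$ time units, and sampling it at the episode scale
  would alias the switching time badly; with the adaptive window the
  fixed point lands within $5\times 10^{-4}$ of the closed form.
* The invader equations are integrated piecewise between the times the
  background signal crosses the invader's threshold, so each piece has
  a smooth right-hand side; integrating across the step discontinuity
  makes adaptive solvers grind.

At the default burst size $\hat B = 2$ the fixed point gives
$\theta^{ESS} \approx 0.62$ — below the closed-form 2/3, because signal
uptake during the (slow, at this burst size) epidemic depresses the
concentration relative to the infected fraction. This matters when
reading grid-based simulation outcomes: on the 0.05 trait grid the two
neighbours of 0.62 acquire nearly equal steady-state mass (within ~7%
relative), and the package's converged runs peak at
$(\phi_{max}, \theta) = (1, 0.60)$ at $T = 12$. The corresponding
fixed point for the propensity axis reproduces the simulated
bet-hedging optimum ($\phi^{ESS} = 0.038$ vs the grid's 0.04).

The closed form for $\phi^*$ should be treated as a small-$\hat B$
approximation: at large effective burst sizes it predicts
near-complete lysogeny, while both the rare-invader yield calculation
and direct competition show that low propensities keep winning (a
$\phi = 0.065$ variant eliminates $\phi \ge 0.3$ variants decisively at
$\hat B \approx 500$). The package therefore reports the closed form
alongside the realized simulation outcome and leaves the comparison to
the user; the fixed-point calculator is the reliable predictor across
the parameter range.

## Numerical choices

* **Integrator.** Episodes are integrated with `deSolve::lsoda` at
  `rtol = 1e-8`, `atol = 1e-12`, with the right-hand side compiled in C
  (the reference R implementation is retained and the two are asserted
  equal to near machine precision). The system is stiff after the
  epidemic collapse — adsorption turns over free phages at rate
  $\hat a n \approx 10$ while induction replenishes them at
  $10^{-3}$ — so a stiffness-switching multistep method is much
  cheaper than an explicit Runge-Kutta scheme. Halving the tolerances
  moves episode endpoints by less than $10^{-6}$ (unit-scale), and the
  selected variants in mutation-free competitions are unchanged at
  `rtol = 1e-10`.
* **Negativity.** The step-function switch makes the right-hand side
  discontinuous, and the solver's local error can leave components a
  hair below zero. End-of-episode states clip negative excursions up to
  $10^{-9}$ (six orders below any dynamical scale here) and error on
  anything larger.
* **Extinction.** A run whose total phage density falls below
  $10^{-30}$ is reported extinct rather than erroring; this also keeps
  denormalised numbers out of the arithmetic.
* **Ties.** `dominant_variant()` breaks frequency ties towards lower
  $\phi_{max}$, then lower $\theta$ — arbitrary but fixed.
* **Problem sizes.** The package's own experiment defaults are the
  study-scale settings: 101-variant propensity grids, 441-variant
  communication grids, 2000-episode caps, 1000-episode noisy runs. The
  compiled right-hand side makes these fast (a converged 441-variant
  run at $T = 12$ takes seconds to low minutes); the test suite runs
  the full-size experiments directly, except that the randomized
  parameter sweeps use 3-10 sets rather than the study's 500.

## What the simulations do and do not show

The generator produces exactly the idealised study conditions:
deterministic well-mixed dynamics, instantaneous lysis, a sharp step
response, immediate signal release on infection, and episode-wise
gamma noise on the carrying capacity as the only stochasticity. Passing
tests therefore validate the implementation of this model, not the
biology of any real phage: latent periods, gradual response curves,
spatial structure, lysogen-produced signal and demographic noise are
all outside the model class (deliberately, matching the source study's
scope). The two-regime selection structure (lytic dominance for short
passage intervals, a fixed non-trivial strategy for long ones) and the
robustness of communication to capacity noise are properties of the
model that the test suite reproduces end-to-end.

## Session info

```{r, eval = FALSE}
sessionInfo()
```
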
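---
title: "Model-based design of fentanyl PCA: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based design of fentanyl PCA: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fentapca)
```

## The model and its assumptions

`fentapca` simulates intravenous fentanyl with a linear mammillary
three-compartment model plus a first-order effect-site compartment. The
state is the amount vector $(a_1, a_2, a_3)$ in µg (central, fast
peripheral, slow peripheral) and the effect-site concentration $C_e$ in
ng/mL:

$$
\begin{aligned}
\dot a_1 &= -(k_{10}+k_{12}+k_{13})\,a_1 + k_{21} a_2 + k_{31} a_3 + u(t)\\
\dot a_2 &= k_{12} a_1 - k_{21} a_2\\
\dot a_3 &= k_{13} a_1 - k_{31} a_3\\
\dot C_e &= k_{e0}\,(a_1/V_c - C_e)
\end{aligned}
$$

with $u(t)$ the zero-order infusion rate (µg/min) into the central
compartment and plasma concentration $C_p = a_1/V_c$. The effect compartment
carries a *concentration*, not an amount, so $k_{e0}$ appears exactly as
written and no effect-site volume is introduced; the effect site receives
negligible mass, which is the standard biophase idealisation.

The model is linear and time-invariant: responses superpose across dose
events, concentrations scale proportionally with dose, and the amount
subsystem conserves mass up to first-order elimination
($\mathrm{d}(a_1+a_2+a_3)/\mathrm{d}t = -k_{10} a_1$). The test suite
asserts all three properties directly.

Everything is deterministic. Interindividual and residual variability are
set to zero by construction: the simulator propagates point estimates, which
is the appropriate tool for *designing* a dosing scheme (the design question
is "what does the typical-parameter curve do", not "what is the population
spread"). Consequently nothing here predicts the variability of real
patients, only the central tendency under the assumed parameters.

## Parameters and units

| parameter | default | units | meaning |
|---|---|---|---|
| `v_central` | 26.6 | L | central distribution volume |
| `k10` | 0.0332 | 1/min | elimination from central |
| `k12`, `k21` | 0.172, 0.1 | 1/min | central ↔ fast peripheral |
| `k13`, `k31` | 0.131, 0.0177 | 1/min | central ↔ slow peripheral |
| `ke0` | 0.147 | 1/min | effect-site equilibration |
| `mec` | 0.23 | ng/mL | lower window bound (minimal effective concentration) |
| `upper` | 2.0 | ng/mL | upper window bound |

Amounts are µg, volumes L, time min; µg/L is numerically ng/mL, so the only
unit conversion anywhere is µg/h → µg/min for pump rates. The fentanyl
defaults are literature point estimates for a typical adult and are used
unscaled for every simulated subject; no covariate (weight, age) model is
applied. The upper window bound is the package's configurable default for
"concentrations where opioid side effects become a concern"; the lower bound
is the classic fentanyl MEC. The default window reference is the effect-site
concentration, which drives analgesia with the equilibration lag; a flag
switches to plasma, and after the distribution phase the two give similar
crossing times.

## Exact event-driven propagation

Between dose events the system is linear with constant forcing, so instead
of stepping an ODE solver we propagate with the matrix exponential of the
augmented $5\times5$ system (the constant rate $u$ is absorbed as a fifth
state with $\dot u = 0$):

$$x(t+\Delta t) = \exp\!\left(\begin{bmatrix} A & e_1\\ 0 & 0\end{bmatrix}
\Delta t\right) \begin{bmatrix} x(t)\\ u\end{bmatrix}.$$

This is the exact solution: results are bit-stable, independent of the
output grid, and a simulated "step" of 50 000 min is as accurate as one of
0.1 min (the steady-state tests exploit exactly this). The augmented
transition matrix does not depend on the rate, so one `Matrix::expm` call
per distinct step length serves an entire simulation; an adaptive ODE
integration (`deSolve::lsoda` at `rtol = 1e-11`) is kept in the test suite
as an independent oracle and agrees to relative error below $10^{-6}$ on
100 random parameter/regimen draws.

Numerical details worth knowing:

* Boluses are instantaneous additions to $a_1$. At a bolus time the stored
  plasma value is the post-bolus right limit; $C_e$ is continuous
  everywhere.
* Simultaneous events are applied rate-change first, then bolus.
* Output times are the union of the regular grid (default 0.1 min) and all
  event times; near-duplicate times are merged at $10^{-9}$ min.
* The exponential of a Metzler matrix is non-negative; entries are clamped
  at the $-10^{-9}$ roundoff level so states never go negative.
* `concentration_at()` re-propagates from the nearest earlier breakpoint
  rather than interpolating, so off-grid queries are exact too.

## Dosing programs and the PCA pump

A `regimen()` combines scheduled events (boluses, infusion segments in µg/h
over half-open intervals, open-ended segments allowed), a PCA program
(demand dose, lockout, basal schedule) and a rescue list. The lockout is
measured from the last *granted* demand — the pump convention; rejected
presses do not restart the clock.

Patient demand behaviour is not part of the model, so it is supplied as a
policy: `none` (the deterministic base case used for the concentration-curve
figures and for regimen design), `worst_case` (continuous pressing; grants
exactly every lockout interval — the upper envelope of what the pump can
deliver) and `poisson` (a seeded homogeneous Poisson process of attempts,
for sensitivity studies; bit-reproducible from its seed, and the caller's
RNG stream is left untouched). Rescue boluses are explicit user events
because pain — the trigger for rescue in practice — is not simulated.

## Window metrics

`window_metrics()` reads compliance quantities off a simulated series:
the first downward crossing of the MEC after the first dose (absolute and
relative to that dose), total time below the MEC and above the upper bound,
the peak with its time, and the list of maximal sub-MEC ("undertreated")
intervals. Crossings are located by bisection *on the exact propagator*
within the grid interval that brackets a sign change, to a tolerance of
$10^{-4}$ min, and all durations are sums of crossing-time differences —
never grid-point counts — so metrics are invariant to the simulation grid.
Peaks are refined the same way with `optimize()` over the bracketing smooth
intervals, with stored breakpoint values compared as candidates because a
plasma peak can sit exactly at a bolus instant.

One caveat is inherited from bracketing: a dip shorter than one grid
interval that both enters and leaves the band between two adjacent grid
points would be missed. With the default 0.1-min grid and rate constants of
order 0.3 /min or slower, concentrations cannot turn around that fast, so
this is theoretical; it is why the default grid is finer than the
equilibration timescale.

## The regimen search

The design step is an explicit exhaustive search, because the clinical
intent ("keep the concentration above the MEC and below the side-effect
bound, with as little drug as possible") does not by itself fix a candidate
set or objective. `search_space()` enumerates (initial rate, step-down
time, subsequent rate) triples over user-supplied grids, on top of a fixed
loading (default: 50 µg infused over the 10 min before the end of surgery)
and fixed PCA settings. Feasibility is judged on the *no-demand* scenario —
demand boluses only push the concentration up, so a schedule that complies
without them complies with them, and the base case stays deterministic.
Among feasible candidates the smallest total scheduled dose over the
horizon wins; ties break by lower peak reference concentration, then by
ascending (initial rate, step-down time, subsequent rate), making the
result independent of enumeration order. If nothing is feasible the result
says so and reports the least-violating candidate with its violation time.

Because the compliance constraint only involves the window up to the last
constraint time, candidates are simulated only that far; the dose objective
over the full horizon is computed arithmetically from the schedule.

With the default parameters and window, a noteworthy (and load-bearing)
result: a 20 µg/h first-hour basal under the standard loading lets the
effect-site concentration cross the MEC at $t \approx 39.4$ min, and the
minimal compliant initial rate on a 5-µg/h grid is 25 µg/h. The curve
hovers within 0.007 ng/mL of the MEC from ~39 to ~90 min, so this
infeasibility is marginal — at plotting resolution the 20 µg/h curve and
the MEC line coincide through the whole first hour — but the exact
propagator resolves it. Near-threshold readouts like this are extremely
sensitive to the parameter point; a few percent on `ke0` or `v_central`
moves the crossing by tens of minutes. That sensitivity is a property of
grazing trajectories, not of the numerics (which are exact given the
parameters), and is the main caveat when comparing crossing times against
figure-derived expectations.

## Scenario defaults

The built-in scenarios place the time origin at the end of surgery. The
demand-only program gives its 50 µg as a true bolus at $t = -10$ min; the
model-based program loads the same 50 µg as a zero-order infusion over
$[-10, 0)$ (300 µg/h), which is how such a loading is actually programmed
and avoids the bolus overshoot. Both default to demand policy `none` and no
rescue boluses: the base curves describe the *programs*, with patient
behaviour layered on explicitly when wanted.

## Problem sizes used in the tests

The suite simulates at grid steps between 0.05 and 10 min over horizons of
60 min to 48 h; the oracle-agreement check uses 100 random systems on a
120-min horizon; the search tests use up to 121 candidates. These sizes were
chosen so each test isolates one property at full numerical fidelity — the
propagation being exact, longer horizons add nothing but runtime.

## Known limitations

* Linear PK only: no nonlinearity, no covariates, no variability — the
  simulator characterises a typical-parameter subject, not a population.
* Analgesia itself is not modelled: the MEC is a fixed threshold, pain
  scores and rescue triggers are outside the model, and demand policies are
  stylised behaviour models, not data-fitted ones.
* The upper window bound is a configurable convention; feasibility
  conclusions near either bound inherit the parameter sensitivity discussed
  above.
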
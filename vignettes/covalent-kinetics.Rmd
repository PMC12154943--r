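---
title: "Modeling covalent inhibition with rapidly exchanging intermediates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling covalent inhibition with rapidly exchanging intermediates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(covkin)
```

## The model and its assumptions

covkin simulates Markovian mass-action reaction networks and layers a
covalent-inhibition analysis on top. A scheme is a list of species (with
initial concentrations in μM and role tags) and transitions (with positive
integer stoichiometric coefficients and rate constants in s⁻¹·μM^(1−Σν)).
The rate law is assembled in matrix form: with source and target
stoichiometry matrices `N_src` and `N_tgt` (one row per transition, one
column per species) and `N = N_tgt − N_src`, the concentration derivative is
the row vector of per-transition fluxes — each flux being the rate constant
times the product of source concentrations raised to their coefficients —
multiplied by `N`. This supports arbitrary stoichiometry (ν > 1 works, e.g.
dimerizations, although none of the built-in schemes needs it) but
deliberately excludes non-mass-action rate laws, time-dependent "constants",
compartments, and SBML import.

The built-in schemes encode one biological idea: the noncovalent complex of
an irreversible inhibitor is not a single state but a fast equilibrium
between a nonreactive conformation `E··I` (the only one assumed able to
dissociate) and a reactive conformation `E·I` from which the covalent adduct
`E–I` forms. When the exchange rates `kr`, `knr` are fast relative to
binding, dissociation and reaction, the five-species scheme reduces exactly
to a two-step scheme with reactive probability `pr = kr/(kr + knr)`,
apparent dissociation rate `koffapp = (1 − pr)·koff` and apparent
inactivation rate `kinactapp = pr·kinact` (`reduce_params()`). The package
treats both representations as first-class and verifies numerically that
they produce indistinguishable covalent occupancy when the timescale
separation holds (the tests require max |ΔCO| ≤ 10⁻³ when
`kr + knr` exceeds the other rates by ≥ 10³; measured agreement is ~10⁻⁵).
`reduce_params()` reports the separation ratio so users can judge validity:
the reduction degrades as the ratio approaches 1.

Assumptions worth keeping in mind: only the nonreactive conformation
dissociates; the covalent step is strictly irreversible (reversible-covalent
chemistry is out of scope); there is no substrate competition, enzyme
degradation or resynthesis; and dose-response readouts are noncompetitive
proxies of covalent occupancy.

## Parameters, units and defaults

All concentrations are μM, times s, bimolecular rates μM⁻¹s⁻¹. Stop times
supplied in hours at the protocol/CLI boundary are converted to seconds on
load. The worked-example parameter set used throughout the documentation —
`[E]0 = 10⁻³ μM (1 nM)`, `[I]0 = 1 μM`, `kon = 10⁻² μM⁻¹s⁻¹`,
`koff = 10⁻² s⁻¹`, `kinact = 10⁻⁴ s⁻¹`, `pr = 0.5` — sits in the regime
typical of covalent inhibitors, `kinact ≪ koff < kon·[I]0`, with the enzyme
three orders of magnitude below the doses so the inhibitor is the saturating
species. `dose_rate()` warns when inputs leave this regime, because the
pseudo-first-order analysis it implements degrades there (see below).

Conformational exchange in the expanded schemes is physically on the
microsecond scale; numerically nothing is gained by integrating six orders of
magnitude of stiffness, so the reproduction experiments set
`kr + knr` to 10³–10⁴ × the fastest slow rate, which is already deep in the
rapid-equilibrium limit (the reduction error scales as the inverse
separation ratio) while keeping LSODA cheap.

## Numerical choices

* **Integrator** — `deSolve::lsoda` with `rtol = 10⁻⁸`, `atol = 10⁻¹² μM`.
  LSODA's automatic stiff/non-stiff switching fits these systems, which are
  stiff by construction when conformational exchange is fast.
* **Output grid** — 400 log-spaced points from 10⁻² s to the end time
  (preceded by t = 0, where the returned row equals the initial
  concentrations exactly); dense enough for fitting, cheap to integrate.
* **Negativity guard** — excursions within `atol + rtol·max|C₀|` below zero
  are clipped to 0; anything larger is an error, not a warning.
* **Conservation check** — conserved moieties are found as non-negative
  integer vectors in the null space of `N` (exact Gauss-Jordan elimination
  plus recombination); every trajectory is checked to hold them constant to
  within 10·rtol relative, with a warning (escalatable to an error) on
  violation. Moieties are diagnostic only; they are never enforced during
  integration.
* **Linear-scheme oracle** — for schemes whose every transition consumes one
  molecule of one species, the exact solution is computed by
  eigen-decomposition of the rate matrix. The tests integrate dozens of
  random such schemes (rates spanning six decades) and require pointwise
  agreement within 10·rtol; the random generator rejects rate matrices with
  eigenvector condition number above 10⁷, where "exact" would itself be
  ill-conditioned.
* **Residence time** — computed as a mean exit time: initialize the system
  entirely in the nonreactive complex, remove association transitions so
  nothing rebinds, and accumulate the time integral of the bound fraction as
  an auxiliary quadrature state of the ODE system. Integration doubles its
  end time until the bound fraction falls below 10⁻⁶ and then adds the
  analytic exponential tail of the local slowest mode. A mean-exit-time
  estimator was chosen over fitting the occupancy decay because it is
  assumption-free about the number of modes; the two agree under rapid
  pre-equilibrium, where τ = 1/(koff·(1 − pr)) (verified to ~10⁻¹³ relative
  on a 5 × 5 grid of koff ∈ [10⁻⁴, 10⁻¹] s⁻¹, pr ∈ [0, 0.9]). Schemes with
  no dissociation pathway are detected and refused rather than integrated
  forever.
* **Optimizers** — all fits are Levenberg–Marquardt (minpack.lm) with
  analytic-formula initial guesses: kobs from the time to half-plateau,
  KIapp from the dose at half-maximal kobs, Hill n from 1, amplitude from
  the maximal response. Everything is deterministic; there are no random
  restarts. The Hill EC50 is fitted on its natural scale with a zero lower
  bound (a log reparameterization defeats the symbolic differentiation used
  by the nls machinery). Uncertainties come from the Jacobian-based
  covariance approximation and are flagged as approximate.

## The dose-rate and dose-response workflows

`dose_rate()` reproduces the conventional scoring pipeline: integrate the
full ODEs (bimolecular step included) at each dose, fit
`CO(t) = 1 − e^(−kobs·t)` by unweighted least squares over the full trace,
then fit the Michaelis–Menten analog. Default dose grid: 8 log-spaced doses
spanning 0.1–10× the analytic KIapp — brackets the half-maximum and the
plateau. Default end time: 5/kobs at the smallest dose, so every trace rises
essentially to completion; a warning fires if CO at the smallest dose stays
below 0.05. The kobs fitting window is the full simulated course, matching
the generic description of the assay; no early-time truncation is applied.

`dose_response()` integrates the full ODEs per dose and reads CO at the stop
time tDR, attaching the analytic amplitude `1 − e^(−kinactapp·tDR)`, the
auxiliary `η = ln((1 + e^(−kinactapp·tDR))/2)` (computed with
`log1p`/`expm1`, so it is accurate for kinactapp·tDR from 10⁻¹² up), and the
analytic `EC50 = −KIapp·η/(kinactapp·tDR + η)`. Default dose grid: 50
log-spaced doses spanning 10⁻²–10²× the analytic EC50. The identity behind
the derivation — plugging kobs = −η/tDR into the growth factor yields
exactly half the amplitude — is tested to machine precision.

Three boundaries of validity are worth stating explicitly, because the
package's own tests probe them:

* The analytic EC50 assumes the pseudo-first-order Michaelis–Menten form of
  kobs. It matches the ODE-simulated midpoint to well under 5% in the
  well-mixed regime (the worked-example parameters), but fails badly —
  ~80% — when the enzyme concentration approaches the doses
  ([E]0 = 1 μM), where depletion of free inhibitor turns the dose-response
  into a stoichiometric titration. Interestingly, in the slow-association
  regime (kon·[I]0 < kinactapp) the *midpoint* is still predicted to ~0.4%
  even though the curve *shape* deviates strongly (the fitted Hill n rises
  to ~1.46): with binding rate-limiting, the occupancy growth is nearly
  single-exponential at every dose, so the half-maximum relation holds at
  the midpoint while the wings steepen.
* Fitted Hill coefficients with amplitude and EC50 fixed analytically are
  grid-sensitive in the depletion regime. With
  [E]0 = 1 μM the fitted n ranges from ~0.6 to ~2.0 as the dose-grid
  endpoints move, because the fixed analytic EC50 sits far from the true
  midpoint; the package's default grid yields 0.89. Away from depletion the
  fitted n is stable to the second decimal across grids.
* The kobs workflow itself is mis-specified when `koffapp ≲ kinactapp`
  (e.g. pr → 1 with koffapp → 0): the per-dose kinetics become a sequential
  two-step process whose slow eigenvalue is min(kon·[I]0, kinactapp), not a
  Michaelis–Menten hyperbola, and the fitted KIapp acquires a 20–30% bias
  regardless of rate magnitudes. This is why `dose_rate()` carries the
  regime warning, and why the fitted KIapp reproduces its analytic pr → 0
  limit (Kd) to ~0.1% but overshoots the pr → 1 limit (kinact/kon). The
  linearity of fitted kinactapp in pr is exact to ~0.1% across pr ∈ [0.1,
  0.9], the range where the workflow's assumptions hold.

## Global fitting and identifiability

`global_fit()` embeds ODE solves of the reduced scheme in a least-squares
objective over an entire dose × time covalent-occupancy surface.
Covalent occupancy depends on the rate constants only through
(kon, koffapp, kinactapp); with kon fixed, the free triple {Kd, pr, kinact}
is therefore constrained only up to a one-dimensional manifold
(koffapp and kinactapp fixed, pr free). The implementation makes this
visible rather than hiding it: starting values are derived from the data by
a per-dose kobs pre-analysis and a Michaelis–Menten-analog fit, unfolded
with a neutral pr = 0.5 (or the fixed pr when supplied); the fit reports a
pr–kinact correlation diagnostic (≈ −0.98 on the reference surface) and the
full correlation matrix. Fixing pr — for example to a value predicted by
molecular simulation — renders Kd and kinact identifiable from a single
curve, and the tests recover them to better than 2% from deliberately
perturbed starting values. Requests with both kr and knr free are refused
outright: occupancy data carry no information about the exchange rates
beyond their ratio. Internally, rates and affinities are fitted on the log
scale and pr on the logit scale, so positivity and [0, 1] bounds hold by
construction.

## What the simulations emulate — and what they do not

All reference experiments use noiseless, deterministic ODE output: they
emulate ideal, well-mixed in-vitro kinetics with a perfectly proportional
covalent-occupancy readout and no measurement error. Passing tests
demonstrate the internal consistency of the kinetic theory and the
correctness of the numerics; they do not demonstrate robustness to assay
noise, pipetting error in dose series, substrate competition, inhibitor
degradation, or intracellular target resynthesis — none of which are
modeled. Stochastic (Gillespie) simulation is likewise out of scope: at the
copy numbers of in-vitro kinetics the deterministic limit is appropriate,
and the linear-scheme eigen oracle already provides an exact independent
check of the integrator.

## Problem sizes

The test-suite experiments use sizes chosen to exercise every claim while
keeping a full run in the tens of seconds: 50 random linear schemes for the
oracle property, a 5 × 5 (koff, pr) residence-time grid, 8-dose rate
workflows, 50-dose response curves, and a 6-dose × 20-timepoint surface for
global-fit recovery. The figure-reproduction experiments
(`reproduce_figure()`) complete in well under a minute each.

## Known limitations

* Stoichiometric coefficients are positive integers; fractional or
  concentration-dependent stoichiometry is rejected.
* The Hill fit refuses non-monotone responses instead of attempting robust
  regression; noisy experimental curves may need pre-smoothing or the
  global-fit route.
* The fitted Hill n is exposed as a curve-shape descriptor only; no
  mechanistic meaning (cooperativity or otherwise) is claimed for n ≠ 1 in
  irreversible kinetics, where asymmetric causes (inhibitor depletion,
  slow association) dominate.
* Covariance estimates are first-order Jacobian approximations; for
  near-degenerate fits (see the identifiability discussion) they indicate
  direction, not calibrated confidence intervals.
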
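---
title: "Constructing thermodynamically consistent kinetic models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing thermodynamically consistent kinetic models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kineticizer)
```

## The construction problem

A kinetic model of metabolism must satisfy several kinds of consistency at
once.  Quantities shared by several reactions — metabolite concentrations,
stationary fluxes, equilibrium constants — must take a single value
everywhere they appear.  Stationary fluxes must balance at every internal
metabolite, `N v = 0`.  Equilibrium constants, being exponentials of
chemical-potential differences, must satisfy the Wegscheider conditions: the
sum of `ln k_eq` along any closed reaction loop vanishes, compactly
`Kᵀ ln k_eq = 0` with `K` a null-space matrix of the internal stoichiometric
matrix.  Within each rate law, the kinetic constants must obey the Haldane
relationship tying them to the reaction's equilibrium constant.  And every
flux direction must agree with its thermodynamic force
`ln(k_eq/Γ)`, where `Γ` is the mass-action ratio at the operating state.

Fitting all of these simultaneously on sparse, noisy data is hopeless as a
single optimisation.  The package instead layers the construction so each
stage fixes a set of shared quantities and hands them to the next stage as
hard constraints.  The final enzyme-level rescaling then actualises the
predefined steady state without disturbing anything already fixed, because
each rate law is homogeneous of degree one in its velocity parameter `u`.

## Stage choices and their rationale

### Geometric flux balancing

`geometric_fba()` maximises the growth objective by LP, pins the optimum,
minimises `Σ|v|` (split positive/negative parts), and removes residual
degeneracy by iteratively centring each flux inside its flux-variability
range until the ranges collapse (below `1e-9` mM/s).  The minimal-total-flux
principle acts as a regulariser that makes the distribution identifiable;
the centring step makes it *unique* and symmetric (a balanced diamond splits
0.5/0.5 rather than an arbitrary vertex).  All LPs use a bounded-variable
simplex with Bland's smallest-index rule, so the solution path is
deterministic and independent of reaction ordering.  Flux data enter as
bounds `value·(1±r)`; `r` defaults to 0.1 when a bundle does not state
bounds.  Infeasible bound sets are reported as an irreducible conflicting
set found by a deletion filter, not silently relaxed.

### Subnetwork export

Reactions with `|v|` at or below the cutoff (default 0: only exactly
vanishing fluxes) are removed, negative-flux reactions are reversed in both
stoichiometry and flux, and orphaned species are dropped.  A positive cutoff
triggers a warning that flux balancing must be re-run on the reduced
network, since deleting small nonzero fluxes breaks stationarity; the
`kineticize()` wrapper does this re-run automatically.

### Thermodynamic balancing

Concentrations are completed pragmatically and then held fixed: unknown
intracellular species get the median of the known intracellular values,
unknown extracellular species the extracellular median (R's median
convention — the mean of the central pair for even counts).  Protons,
inorganic phosphate and boundary species are flagged as fixed
concentrations.

Equilibrium constants are then adjusted in log-space by box-constrained
least squares subject to `Kᵀ x = 0`: transport reactions are pinned at
`k_eq = 1` (a transporter moves matter, not standard chemical potential),
measured values are hard equalities, and each flux-carrying unknown is boxed
between `1.1·Γ` (the 10% force margin, so the force stays strictly positive
in the flux direction) and an upper bound of `1e6`.  The least-squares
target for unknowns is `10·Γ` — one order of magnitude of driving force,
comfortably inside the box; the printed upper bound in the source material
for this workflow is ambiguous, and `1e6` on the mM scale spans the
physiological range of reaction free energies.  Conflicts — a measured
`k_eq` below `1.1·Γ` for a flux-carrying reaction, or fixed values that
jointly violate a loop condition — are errors, because measured equilibrium
constants are treated as exact fixed points, not soft data.  The active-set
quadratic-programming solver enforces the equalities to machine precision,
which is why the Wegscheider residuals in the test suite sit at `1e-15`
rather than at the `1e-8` acceptance tolerance.

### Parameter balancing

Each reaction is balanced independently in the basis
`x = (ln k_cat⁺, ln K_M,i)`; `ln k_cat⁻` is the dependent combination
`ln k_cat⁺ − ln k_eq + Σ_i n_i ln K_M,i`, so with `k_eq` fixed every prior,
pseudo value and datum is a linear Gaussian term in `x` and the posterior
mode is a small box-constrained convex quadratic programme (mode = median in
log-space; geometric SDs from the posterior covariance).  Decomposing the
network this way is exact, not an approximation: the only quantities shared
between reactions are `k_eq` and the concentrations, and both are already
fixed.

Priors (log-normal, medians/geometric SDs): `k_cat⁺`, `k_cat⁻` 10 /s × 10;
`K_M` 0.1 mM × 10; a pseudo value on the velocity constant
`√(k_cat⁺ k_cat⁻)` of 10 /s × 10 expresses prior knowledge about the
dependent direction.  These are deliberately wide — they regularise without
dominating a datum of geometric SD ≤ 2.  Box bounds `1e-4 ≤ k_cat ≤ 1e4` /s
and `1e-4 ≤ K_M ≤ 1e3` mM keep pathological modes out.  Every participant
lacking a `K_M` datum receives a pseudo-datum equal to its steady-state
concentration (geometric SD 1.5) — the classic initialisation that centres
saturation at the operating point.  Allosteric modifier constants bypass
balancing entirely and are taken from the data bundle as supplied, since no
thermodynamic constraint ties them to the rest.

One substantive convention deserves a note: the Haldane relationship is
implemented in the form dictated by the common modular rate law itself,
`k_cat⁺/k_cat⁻ = k_eq · Π_i K_M,i^{-n_i}` (signed `n_i`, products
positive) — equivalently the textbook
`K_eq = (V_f K_{M,P})/(V_r K_{M,S})` for a uni-uni reaction.  Any other
sign convention would break the identity "rate = 0 exactly when `Γ = k_eq`",
which the test suite asserts.

### Rate laws and rescaling

The common modular law's denominator enumerates enzyme binding states of a
random-order mechanism; molecularities are `|n_i|`.  Biomass, growth and
lipid-production reactions (flagged by name patterns, configurable) get
clamped linlog laws with default elasticities `ε_i = |n_i|` for substrates
and 0 for products — linlog needs a reference state, which the construction
state provides, and the clamp at zero prevents negative production rates
when substrates are strongly depleted.  Regulation multiplies rates by
`c/(c+K_A)` per activator and `K_I/(c+K_I)` per inhibitor; cooperative
(Hill) regulation is not modelled, matching the hyperbolic constants
available from database averages.  Because all preceding stages guarantee
`sign(rate_j(c*)) = sign(v_j)`, the rescaling `u_j ← u_j·v_j/rate_j(c*)` is
well-defined and positive; it must run *after* any regulation is attached,
which is why `apply_regulation()` clears the `rescaled` flag.

## Analyses

Conserved moieties (e.g. ATP + ADP) make the raw Jacobian singular, so
stability and control analysis run on the reduced system: independent
species are chosen by pivoted QR of the dynamic stoichiometric matrix and
the link matrix `L` (with `N_dyn = L N_R`) maps independent changes to the
full vector.  Elasticities are analytic closed-form derivatives of the rate
laws (validated against central differences in the tests).  Control
coefficients come from the standard matrix identities
`C_S = −L (N_R E L)⁻¹ N_R`, `C_J = I + E C_S`; scaled variants are
normalised by steady-state fluxes and concentrations, and both the
summation and connectivity theorems are asserted on every fixture.  Overall
control per reaction is the root sum of squares of its scaled flux-control
column, with the top 5% (rounded up, ties broken by reaction id) flagged
high-control.  Both unscaled and scaled matrices are reported, since the two
are useful for different displays; the ranking uses the scaled form.

Steady states are located by damped Newton on the reduced system with an
ODE-relaxation fallback; the stationarity tolerance defaults to `1e-9` mM/s
— a loose tolerance here is known to let a regulated model drift away from
its constructed state, so the default is strict.  Perturbation simulations
multiply a boundary concentration at `t = 0` and integrate the stiff system
with an adaptive backward-Euler scheme (analytic-Jacobian Newton inner
solves, step-doubling error control, `rtol = 1e-6`).  First order is
adequate because the integrator's role is relaxation towards attractors,
not trajectory quadrature; backward Euler also preserves moiety totals
exactly.  With `restore_at` set, the perturbation is removed at that time
and the diagnostic reports whether the state returns to the reference within
`relax_tol` (default `1e-6` relative), mirroring the perturb-and-relax test
of stability.

## The synthetic world

`make_fixture()` generates six topologies (linear chain, diamond, parallel
cycle, multi-compartment transporter chain, ATP/ADP moiety pathway, and a
feedback-inhibited chain) in which every consistency condition holds exactly
by construction:

* `ln k_eq = −N_intᵀ μ` from chemical potentials of the internal species, so
  the loop conditions are identities; transport reactions' potential sums
  are constrained to zero, making their `k_eq` exactly 1.
* Potentials and internal concentrations are found jointly by a feasibility
  LP that gives every reaction a randomised positive force margin (at least
  `ln 1.1 + 0.05`); the driving force for through-pathways comes from the
  fixed boundary concentrations — substrate-rich medium in (24.5 mM, the
  extracellular median of the data this workflow was built around),
  product-poor out.  Internal concentrations centre on the intracellular
  median 0.549 mM.
* `K_M` are drawn log-normally around the participant's concentration,
  `k_cat⁺` around 10 /s, `k_cat⁻` set by Haldane; target fluxes are exact
  rational routings (unit pathway flux, symmetric 0.5/0.5 splits), and `u`
  is rescaled so the true model actualises them.

The data bundle is the truth after Bernoulli masking and multiplicative
log-normal noise.  Two deliberate departures from naive noising reflect how
the pipeline treats data: measured `k_eq` are generated from *noisy
potentials* (with the transport component projected out), so they remain
mutually Wegscheider-consistent and direction-consistent — the pipeline
takes them as hard constraints, as a curated, internally consistent set
would be; and noise-free bundles carry exact flux bounds (`r = 0`) while
noisy bundles use `r = 0.1`, because with slack bounds the growth-maximising
LP correctly sits at the upper bound rather than at the generating value.
Concentration and flux tables are complete (they are the predefined frame
of the construction); masking applies to the kinetic and thermodynamic
constants.

What the generator does **not** emulate: genome-scale topology and its
degeneracy, isoenzymes, correlated measurement error across laboratories,
pH/ionic-strength corrections to equilibrium constants, and cooperative
regulation.  A green test suite therefore establishes that the machinery is
correct and internally consistent on networks where ground truth is known —
not that a genome-scale reconstruction with real data will yield a stable or
accurate model.

## Numerical choices

* Null spaces by SVD with threshold `1e-10 × max σ` (robust for
  rank-deficient `N`).
* LP: dense two-phase bounded-variable simplex, Bland's rule (deterministic,
  cycling-free), warm starts for flux-variability scans.
* QP: primal active-set with feasible iterates; equalities in every KKT
  solve, hence loop conditions at machine precision.
* ODE: adaptive backward Euler, Newton inner solves with analytic Jacobians,
  positivity by step rejection.
* Steady state: damped Newton, tolerance `1e-9` mM/s, ODE fallback.
* Degenerate inputs: empty reactions, unknown ids, non-positive constants,
  sign conflicts and Wegscheider-violating data all raise typed errors
  early, with the offending ids in the message.

## Known limitations

* The sign-feasibility test assigns free potentials to boundary species;
  pathways driven by boundary turnover are feasible even though a
  potential assignment restricted to internal species would not exist.
  This matches the physics (such loops are driven, not futile) but differs
  from a strictly internal reading of the force condition.
* Measured equilibrium constants are exact constraints; there is no soft
  mode for reconciling an inconsistent measured set.
* Regulation is hyperbolic only; enzyme mass balances, compartment volumes
  and pH dependence are out of scope.
* The SBML layer covers core Level 2/3 with explicit kinetic laws and a
  restricted MathML vocabulary; SBML packages (fbc, layout) are not read.
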
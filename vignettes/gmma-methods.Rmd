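---
title: "Global multi-method analysis of binding isotherms: models, numerics and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Global multi-method analysis of binding isotherms: models, numerics and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gmma)
```

## The interaction model

A `binding_model` describes a reversible interacting system by its
components and its complex species. Every complex carries

* an integer stoichiometry vector over the components (the stoichiometry
  is a *model* property, never a fitted quantity);
* a cumulative association constant, stored and fitted as log₁₀β against a
  1 M standard state (dimensionless). Fitting on the log scale keeps the
  optimization scale-free over the pM–mM affinity range and makes
  Gaussian parameter errors a reasonable approximation;
* a cumulative molar enthalpy ΔH (kcal/mol, relative to the free
  components), a sedimentation coefficient s (Svedberg) and an anisotropy
  r.

Free components are implicit species with log₁₀β = 0 and ΔH = 0. Units
throughout: molar concentrations, kcal/mol energies,
R = 1.987·10⁻³ kcal mol⁻¹ K⁻¹.

For a component with two identical binding sites the package supports a
microscopic parameterization: a per-site constant k and a cooperativity
factor α, converted to the stored macroscopic constants by the statistical
factors K1 = 2k and K2 = αk/2. Because the statistical-factor convention
is not universal, cooperativity free energies are always reported in
*both* conventions: the raw macroscopic ΔΔG = ΔG(step 2) − ΔG(step 1)
(which equals −RT ln(1/4) ≈ +0.82 kcal/mol for independent identical
sites at 298 K), and the corrected ΔΔG = −RT ln(10)·log₁₀α, which is zero
for independent sites. `cooperativity()` returns both.

## Solving the equilibrium

All forward models rest on one operation: given totals per component,
find the free concentrations satisfying mass action and mass balance. The
solver iterates damped Newton steps on *log* free concentrations —
positivity is automatic, and the iteration is well-conditioned across the
twelve orders of magnitude of β the package is meant to cover. Details
that matter:

* initialization at free = totals (always an upper bound on the solution);
* Newton steps capped at 4 natural-log units, then halved while the
  maximum relative mass-balance error does not decrease;
* convergence declared at relative mass-balance error < 10⁻¹²
  (non-convergence after 200 iterations is an error, never a silent
  result);
* within an isotherm series consecutive compositions warm-start each
  other; a warm start that fails to converge triggers one cold restart.

Compositions with a zero total are handled by eliminating the absent
component and every species containing it before the solve.

## Technique forward models

**ITC.** A perfusion-cell titration is book-kept injection by injection:
after injecting volume v the pre-injection cell concentrations are diluted
by (1 − v/V₀) and injectant enters at (v/V₀) of the syringe
concentration. With the cell enthalpy content H(i) = V₀ Σ ΔH_S [S](i),
the raw heat of injection i is q = H(i) − H(i−1) + (v/V₀)(H(i)+H(i−1))/2;
the mean-value term restores the heat of material displaced from the
sensed volume. Heats are normalized by the *nominal* moles of injectant.
There is no "n" value: concentration errors and inactive material are
separate per-experiment parameters — a bounded concentration-error factor
γ per component and an incompetent fraction in [0, 1] — which can be
linked across experiments. Two- and three-component cells (displacement
and competition titrations) go through the same general solve.

**SPR.** Steady-state surface binding is a 1:1 Langmuir in the *free*
analyte concentration of the injected mixture. The preferred competition
mode uses the surface purely as a probe of free analyte: a direct series
is fitted first (`spr_calibrate()`), and mixture responses are then read
through that calibration, with a warning when the free concentration
leaves the calibrated range. Multivalent surface models are rejected by
design — heterogeneous surface binding cannot be turned into a reliable
solution-affinity probe.

**SV isotherms.** The signal-weighted average sedimentation coefficient
s_w = Σ ε_S c_S s_S / Σ ε_S c_S with species signal coefficients additive
over composition, ε_S = Σ_j ε_j ν_jS. Boundary-level sedimentation
modeling is out of scope; the tags `se`/`sv` are recognized and rejected
with a clear error so that session files from richer ecosystems fail
loudly rather than silently.

**Anisotropy.** Population-weighted over probe-containing species;
equal quantum yields across bound states are the default (then intensity
weighting equals population weighting), per-species yield ratios are
optional locals.

**Generic linear signal.** baseline + Σ coeff_S·c_S covers quenching,
absorbance, fast-exchange chemical shifts and similar linear observables.

Every technique has a baseline/offset local parameter (default 0,
optionally fitted).

## The global objective

χ²_glob = Σ_e w_e Σ_i ((f_ei − y_ei)/σ_ei)². Default weights are
w_e = 1, i.e. maximum-likelihood weighting under the stated σ; because
very dissimilar data-set sizes can let one technique dominate, an
`"equal_experiment"` preset w_e = mean(N)/N_e is provided, and the
`weight_scan()` tool quantifies how sensitive any conclusion is to the
choice. The reduced χ² divides by N_eff − P with N_eff = Σ w_e N_e and P
the number of free parameters *after* link resolution (a linked group
counts once); this keeps E[χ²_r] ≈ 1 for correct σ at unit weights.

Bounds are enforced by transformation (log for one-sided, logit for
two-sided), not penalties, so every optimizer works on an unconstrained
vector. Marquardt–Levenberg (via minpack.lm) is the default; simplex
restarts once from its converged point; simulated annealing uses
exponential cooling, requires a seed, and is polished by a local search.
A fit never returns a point above its start, and the per-experiment χ²
decomposition is exact by construction.

## Statistics

* **Covariance** comes from the numerical Jacobian of the weighted
  residual vector at the optimum (forward differences, relative step
  10⁻⁶), scaled by the reduced χ²; singular curvature falls back to a
  pseudo-inverse with a warning.
* **Profile projections** fix one or two parameters on a grid and
  re-optimize all others, warm-starting each node from its neighbor
  (serpentine order in 2-D). The confidence threshold is
  χ²_crit = χ²_min (1 + p/(N_eff−P) F(p, N_eff−P; CL)). Nodes whose
  re-optimization fails are marked invalid, never interpolated. Grids for
  K-type parameters should be log-spaced (they are, by default, since the
  parameters themselves are log₁₀β).
* **Monte-Carlo intervals** resimulate data as best-fit model plus
  Gaussian noise at the experimental σ and refit each replicate *from the
  best-fit start*. Starting at the best fit is deliberate and documented
  as mildly anti-conservative (replicates cannot escape to distant local
  minima); it is what keeps 500 replicates affordable on a desk machine.
* **Consistency test.** The cross-validation construction is a design
  choice of this package: for each subgroup g, the model is fitted
  without g, g is fitted alone (with only the parameters g can inform
  left free), and the jointly constrained fit is compared against the
  split description χ²_leaveout + χ²_own by an F-ratio on the parameters
  released by the split. This is the classical nested-model F test
  assembled from the two cross-validation fits; simulation (200 suites in
  the test suite) confirms a type-I rate at or below the nominal α. The
  χ² of g's data under the leave-out parameters is reported alongside as
  the direct cross-validation diagnostic.
* **Information report.** A parameter is perturbed by its 1σ and each
  experiment's χ² increase is evaluated with that experiment's free
  locals re-optimized. Individual entries can be negative (the global
  best fit is a compromise); techniques with no physical sensitivity to
  the parameter are exactly zero.

## Experimental-design tools

Concentration maps evaluate signal, fractional signal contributions or
fractional species populations (relative to a reference component) on a
log₁₀-spaced 2-D grid over two components, all others fixed. Feasibility
cropping assumes mixtures are made in one step from the component stocks
plus buffer, so a node is feasible iff Σ c_j/stock_j ≤ 1 and the mapped
signal lies in the requested window; when several signals exist, cropping
applies to the single mapped signal. Serial-dilution planning is out of
scope. The differential mode reports |∂(signal)/∂(log parameter)| by
central differences — parameters already on a log scale are stepped
additively, linear-scale parameters multiplicatively. "Log-equidistant"
trajectory sampling interpolates linearly in the map's log₁₀ coordinates
along the segment, endpoints included. Mixing recipes are exact by
construction (v = cV/stock) and the trajectory → recipe → composition
round trip reproduces targets to machine precision.

## The synthetic-data generator and what passing tests mean

`simulate_experiment()` adds i.i.d. Gaussian noise of per-point σ to the
forward model; no noise model is prescribed by the techniques themselves,
and Gaussian per-point noise is the assumption already implicit in the
χ² objective. `make_fixture_suite()` fixes the study conditions used
throughout the tests: a two-site system A + B ⇌ AB ⇌ ABB with
log₁₀K1 = 6.5, log₁₀K2 = 5.5 (moderate negative cooperativity, Kd 0.32
and 3.2 µM), step enthalpies −8 and −12 kcal/mol, s = 2.6/2.3/4.1/5.6 S —
values chosen once as typical of a mid-sized protein–protein system — and
11 data sets over four techniques (one SPR competition isotherm, four ITC
titrations at 5–40 µM cell concentrations, five s_w isotherms from
dilution and titration series, one anisotropy titration) at 1% of each
data set's signal range as noise.

The generator emulates the *structure* of real multi-method data —
heterogeneous observables, per-technique nuisance parameters, dissimilar
data-set sizes — but not its pathologies: no systematic baseline drift,
no correlated noise, no thermogram-integration artifacts, no surface
degradation, no concentration mislabeling beyond the explicit γ
parameters. Passing the recovery and contour tests therefore demonstrates
the correctness and statistical calibration of the *analysis chain*, not
that any real data set of this size will determine its parameters equally
well.

Problem sizes used by the test suite were chosen to exercise every code
path at desk scale: 100 random models against independent oracles for the
solver, the 146-point demo suite for recovery and for the (K1, K2)
contour-area comparison (13×13 to 17×17 profile grids spanning 8
curvature-based σ), 200 simulated three-subgroup suites for the
consistency test's type-I rate, and 500 Monte-Carlo replicates on a
10-point linear-response set.

## Known limitations

* Kinetics are out of scope everywhere: no rate constants, no
  time-resolved SPR, no boundary-level sedimentation modeling.
* The equilibrium solver assumes a single stable composition; systems
  engineered to have near-degenerate solutions (extreme β with exactly
  compensating stoichiometries) will converge slowly or error.
* Monte-Carlo refits from the best-fit start understate multimodal
  uncertainty (see above).
* The consistency test needs every subgroup to be individually fittable
  for the parameters it can inform; tiny subgroups are skipped with a
  warning.
* File formats are a transparent text dialect (YAML model/session files,
  tab-separated isotherms with typed headers); vendor and legacy binary
  formats are not read.
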
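---
title: "Random-coil pressure coefficients: models, fitting and correction"
author: "hpcoil maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Random-coil pressure coefficients: models, fitting and correction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hpcoil)
```

## The problem

Hydrostatic pressure shifts the conformational equilibria of proteins in
solution, and chemical shifts are the most precisely observable NMR readout
of those changes. But pressure also moves the resonances of a completely
disordered chain — mostly by compressing the hydrogen bonds of backbone
amide groups — so a raw pressure response mixes a "trivial" random-coil
baseline with the structurally or functionally interesting part. The remedy
used throughout high-pressure NMR is subtractive: measure the pressure
response of residue X in a random-coil model peptide (Ac-Gly-Gly-X-Ala-NH2),
and subtract those coefficients from per-residue protein data.

hpcoil packages the measured backbone amide ¹⁵N and ¹H pressure coefficients
of the 20 canonical residues (0.1–200 MPa, 283 K, pH 6.7, 800 MHz; His at
pH 4.0 and 8.5, Pro as cis and trans isomers) together with the models that
make them usable.

## The quadratic pressure-shift model

Over the experimentally accessible range the shift of a random-coil amide is
captured by a second-order Taylor expansion about atmospheric pressure
$p_0 = 0.1$ MPa:

$$\delta(p) = \delta_0 + B_1\,\Delta p + B_2\,\Delta p^2, \qquad
  \Delta p = \frac{p - p_0}{1000}\ \text{GPa}.$$

`predict_shift()` evaluates it; `fit_quadratic()` recovers
$(\delta_0, B_1, B_2)$ from a measured series. The model is *linear* in its
parameters, so the fit is solved in closed form (weighted linear least
squares). The iterative scaled Levenberg–Marquardt minimisation
historically applied to this model converges to exactly this solution, so
nothing is lost by solving directly. Numerical choices:

* the design matrix uses $\Delta p$ centred at `p0` and expressed in GPa,
  which keeps the normal equations well-conditioned over 0.1–200 MPa and
  yields coefficients directly in the tabulated units;
* fits are unweighted by default (the reference tables state no weighting);
  inverse-variance weights are accepted;
* standard errors are the parameter covariance scaled by residual variance;
  with exactly three points the quadratic interpolates and errors are
  reported as `NA` rather than zero.

All values are stored at the printed two-decimal precision — the raw
spectra behind the tables were never published, so no re-derivation is
attempted. `table_mean()` averages over *all* rows of one nucleus (22 for
¹⁵N including both His pH forms and both Pro isomers; 19 for ¹H): that
membership convention reproduces all four published mean coefficients at
two-decimal rounding, and is locked by tests.

## The multistate thermodynamic model

When a residue exchanges rapidly between $N$ conformational states
($|\Delta\omega_{ij}\tau_{ij}| \ll 1$; `check_fast_exchange()` evaluates the
product against a configurable threshold, default 0.1 as a concrete reading
of "much less than one"), the observed shift is the population-weighted
average

$$\delta(p) = \sum_{i=1}^{N} \langle\delta_i\rangle\, p_i', \qquad
  p_i' = \frac{1}{Z}\exp\!\left(-\frac{G_i^0 + V_i^0\,\Delta p +
  \tfrac12\beta_i^0\,\Delta p^2}{RT}\right),$$

with $G_i^0$ (J/mol) the state free energy at $(p_0, T_0)$, $V_i^0$
(mL/mol) its partial molar volume difference and $\beta_i^0$
(mL mol⁻¹ MPa⁻¹) its compressibility factor. Keeping energy in J/mol,
volume in mL/mol and pressure in MPa makes the exponent dimensionless with
no conversion constants (1 mL·MPa = 1 J). We treat $p_i'$ as the
*normalised* population $\exp(\cdot)/Z$ — the only reading under which the
observable is a probability-weighted average. Populations are computed by
subtracting the largest exponent before exponentiating (log-sum-exp), so
extreme free energies cannot overflow; a genuinely non-finite exponent is an
error naming the offending state. Temperature defaults to 283 K, the
temperature of the reference measurements.

### Linking the two models

`taylor_coefficients()` gives the quadratic coefficients the ensemble would
show near $p_0$, analytically. With population averages
$\langle\cdot\rangle$ at $p_0$:

$$B_1^{\text{(per MPa)}} = -\frac{\mathrm{Cov}(\delta, V)}{RT}, \qquad
  2B_2^{\text{(per MPa}^2)} =
  \frac{\big\langle(\delta - \langle\delta\rangle)(V - \langle
  V\rangle)^2\big\rangle}{(RT)^2} - \frac{\mathrm{Cov}(\delta,\beta)}{RT},$$

then scaled by $10^3$ and $10^6$ into the per-GPa units of the tables. The
derivation differentiates the Boltzmann weights directly; the
second-derivative term is the third mixed central moment of $(\delta, V, V)$
minus the compressibility covariance. The tests verify the expressions
against Richardson-extrapolated central differences of `ensemble_shift()` on
100 seeded random 2- and 3-state models at a relative tolerance of 1e−6.
Two numerical notes the test design depends on:

* at the default $p_0 = 0.1$ MPa a centred difference is boxed in by the
  $p \ge 0$ domain ($h \le 0.1$ MPa) and cannot beat a ~1e−5 error floor;
  the oracle therefore uses models with $p_0 = 10$ MPa and $h = 0.5$ MPa,
  where it reaches ~1e−7. The analytic result itself is exact at any $p_0$.
* for a two-state model symmetric at $p_0$ (equal populations) the
  transition is *steepest* at $p_0$: the sigmoid has its inflection there,
  so the curvature is zero at $p_0$ and maximal some tens of MPa into the
  transition. The generator tests assert that slope property.

## Two-state fitting and identifiability

`fit_two_state()` estimates $(\delta_A, \delta_B, \Delta G^0, \Delta V^0$,
optionally $\Delta\beta^0)$ by nonlinear least squares. Starts are a
deterministic grid — $\Delta G^0 \in \{-5, 0, 5\}$ kJ/mol $\times$
$\Delta V^0 \in \{-100, -25, 25\}$ mL/mol, state shifts initialised from the
series endpoints — each polished by BFGS plus Nelder–Mead; the lowest sum of
squares wins (first best on ties within 1e−10), and failure of every start
is a hard error rather than a silent local optimum. The returned model is
canonicalised so state A carries the smaller shift, which removes the
label-switching ambiguity ($\Delta$-parameters flip sign under relabelling).

A shallow two-state transition over 0.1–200 MPa is experimentally
indistinguishable from a quadratic baseline. Rather than report meaningless
thermodynamic parameters, the fit compares its residual sum of squares with
the 3-parameter quadratic fit by a partial F-test (5% level; SSEs at the
numerical zero floor are treated as ties) and sets `quadratic_sufficient`
when the extra parameters buy nothing. Simulated-recovery tests show
$\Delta V^0$ recovered within ±20% at the experimental noise level
(σ = 0.01 ppm, 16 points) for a 2 kJ/mol, −50 mL/mol transition.

## The correction pipeline

`correct_tracks()` runs per residue: fit the quadratic model to the track,
look up the matching random-coil entry (His defaults to pH 4.0, Pro to
trans; both overridable per track), and form
$\Delta B_k = B_k^{\text{obs}} - B_k^{\text{ref}}$ with the significance
score

$$z_k = \frac{|\Delta B_k|}{\sqrt{SE_{\text{obs}}^2 + SE_{\text{ref}}^2}}$$

(errors combined in quadrature, assuming independence; the reference SEs
are the tabulated fit standard deviations). A track is flagged when
$z_1 > 2$ by default. Choices worth knowing:

* the flag is driven by $B_1$ only; $B_2$ differences are reported with
  their own score but not flagged by default, because the tabulated $B_2$
  errors are about five-fold larger — both thresholds are configurable;
* $\delta_0$ differences are never flagged: absolute random-coil shifts
  depend on sequence context the model peptides do not capture, and the
  correction concerns the pressure response only;
* the z > 2 rule is this package's own convention — the source data define
  no significance threshold for "structurally important";
* unresolvable residue/nucleus combinations (e.g. Pro ¹H, which has no
  observable amide proton) are reported as skipped with a reason, never
  dropped silently.

`residual_curve()` gives the pointwise alternative: observed shift minus
the reference prediction, leaving a constant offset where $\delta_0$
differs and noise where the residue is purely random-coil.

## What the generator emulates — and what it does not

`simulate_series()`, `simulate_reference_panel()` and
`simulate_two_state()` produce series with the statistical structure of the
underlying experiment:

* **Grid**: 9 evenly spaced pressures over 0.1–200 MPa. The source tables
  do not print their grid; 9 points mirrors typical high-pressure NMR
  titrations and the density of the published per-residue figures. It is a
  documented assumption, configurable everywhere.
* **Noise**: i.i.d. Gaussian with σ = 0.01 ppm (¹⁵N) and 0.001 ppm (¹H) —
  the shift reading errors stated for the reference tables. Constant
  variance across pressure is assumed; the true per-point error profile is
  unreported. Shift reading error is digitisation/fit dominated, hence
  Gaussian.
* **Seeding**: all randomness flows through the config seed, which uses a
  private RNG stream and leaves the caller's `.Random.seed` untouched.
  σ = 0 is allowed and composes with `fit_quadratic()` to an exact
  round trip for all 41 entries.

The generator does **not** emulate peak overlap, assignment errors,
pressure-dependent linewidths, buffer pK shifts with pressure, or
temperature/pH dependence of the coefficients. A green simulation test
therefore establishes correctness of the numerics and calibration of the
statistics under the stated noise model — not robustness to spectral
artefacts.

Two calibration facts the test suite documents deliberately:

* with 9-point tracks the z-score uses a residual-variance estimate with
  6 degrees of freedom, which inflates the ¹⁵N null flag rate above the
  normal-tail 4.55% (a t₆ effect), while the quadrature reference term
  deflates the ¹H rate below it; over the mixed 41-entry panel the observed
  null rate is consistent with the nominal level within Monte-Carlo error,
  and that is the level at which the null test is run;
* the 95% coverage check of $\hat\delta_0 \pm 1.96\,SE$ runs on 33-point
  series: at dof = 6 normal-theory intervals genuinely cover only ~90%,
  which is a property of short series, not a defect of the estimator.

## Known limitations

* Backbone amides only; no side-chain nuclei, no temperature coefficients,
  no pH titration curves.
* The reference values carry the conditions of their measurement (283 K,
  pH 6.7, Tris buffer); applying them to proteins measured elsewhere in
  condition space adds systematic error the package does not model.
* No lineshape or relaxation-dispersion modelling: everything assumes fast
  exchange.
* No peak picking or resonance assignment; inputs are already-tracked
  per-residue series. NMR-STAR ingestion is future work.
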
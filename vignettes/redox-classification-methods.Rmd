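---
title: "Methods: free-energy estimation and redox classification of disulfide bonds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: free-energy estimation and redox classification of disulfide bonds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(redoxbond)
```

## The problem and the model

A disulfide bond's biological role tracks its reduction potential:
oxidoreductases cleave only bonds with relatively high potentials, so
bonds inside the literature window of −330 to −89 mV are candidates for a
functional (catalytic or allosteric) role, while typical structural bonds
sit below −470 mV. `redoxbond` turns per-replica non-equilibrium
alchemical work values for the disulfide → dithiol transformation into
exactly that classification.

The physical backbone is the Crooks fluctuation theorem (CFT). For a
switching protocol run in both directions at inverse temperature
β = 1/(k~B~T),

$$\frac{P_F(W)}{P_B(-W)} = e^{\beta (W - \Delta G)},$$

where forward work distributions are sampled on the oxidized → reduced
path (λ: 0 → 1) and backward ones on the reverse path. Backward work sets
are stored exactly as produced on their own path; negation into the
forward frame (W̃ = −W~B~) happens inside the estimators only, keeping
raw data faithful to the simulation output.

### Estimators

**Crooks Gaussian Intersection (CGI).** If both work distributions are
Gaussian, the CFT forces them to share a variance, and ΔG is the
abscissa where the two densities intersect. We fit N(μ~f~, σ~f~²) to the
forward works and N(μ~r~, σ~r~²) to the negated backward works and solve

$$\left(\tfrac{1}{\sigma_f^2}-\tfrac{1}{\sigma_r^2}\right)x^2
 - 2\left(\tfrac{\mu_f}{\sigma_f^2}-\tfrac{\mu_r}{\sigma_r^2}\right)x
 + \tfrac{\mu_f^2}{\sigma_f^2}-\tfrac{\mu_r^2}{\sigma_r^2}
 - 2\ln\tfrac{\sigma_r}{\sigma_f} = 0.$$

Root selection is a genuine design choice because the quadratic has two
roots: we prefer the real root between the two fitted means (the
physically meaningful intersection lies between the modes); if both or
neither root lands there, the root nearest the midpoint is used and a
warning flag is set in the diagnostics, and complex roots fall back to
the midpoint with the same flag. In the equal-variance limit the equation
degenerates to a linear one whose solution is exactly (μ~f~ + μ~r~)/2,
which the implementation returns without any root finding (no
cancellation noise).

**Bennett acceptance ratio (BAR).** The maximum-likelihood estimate
solves, with f(t) = 1/(1+e^t^) and M = ln(n~F~/n~B~),

$$g(\Delta G) = \sum_i f\!\big(M + \beta(W_{F,i} - \Delta G)\big)
             - \sum_j f\!\big(-M + \beta(\Delta G - \tilde W_j)\big) = 0.$$

g is strictly monotone *increasing* in ΔG (it runs from −n~B~ to +n~F~),
so the root is unique; we bracket it by the range of all works widened by
50 kJ/mol and solve with Brent's method to 10⁻⁸ kJ/mol. The Fermi
function is evaluated via `plogis`, which is stable in both tails, so
widely separated distributions degrade gracefully (the root is still
found, but the overlap diagnostics expose that it is meaningless).

**Uncertainty.** The only uncertainty channel is a paired nonparametric
bootstrap: each direction is resampled with replacement independently and
the estimator re-run (default 1000 resamples; the minimum accepted is
100). This choice keeps CGI and BAR uncertainties directly comparable;
an analytic BAR variance is deliberately out of scope. The bootstrap is
deterministic given its seed and restores the caller's RNG state.

**Diagnostics.** Both estimators assume usable overlap between the
forward and negated-backward distributions. Every estimate carries the
closed-form Bhattacharyya coefficient of the two fitted Gaussians, the
gap between fitted means (twice the dissipation for CFT-consistent
data), and per-direction one-sample Kolmogorov–Smirnov normality
p-values. The KS test plugs in the fitted parameters, which makes it an
approximate screen rather than an exact test; it is documented as such.

### From ΔG to a role

The reduction potential follows the two-electron Nernst relation
E⁰ = −ΔG/(nF) with n = 2 and F = 96.485 kJ mol⁻¹ V⁻¹ (so
E(mV) = −ΔG/0.19297). The raw potential is then calibrated linearly to
the experimental scale; the default model is E~corr~ = 1.5·E~cal~ − 43 mV,
the published calibration of this protocol class. The packaged LOXL2
reference table is internally consistent with an intercept of −47 mV
rather than the printed −43 (every corrected value in it reproduces with
−47 to the printed precision, none with −43); the package defaults to the
printed formula and exposes the intercept as a parameter, and the tests
that reproduce the table use the table-consistent value. Classification
is applied to the **corrected** potential — the reference table's role
assignments are only reproducible on that scale — with an inclusive
functional window [−330, −89] mV and a two-way outcome: anything outside
the window is structural. Potentials between −470 and −330 mV are
reported with a gray-zone flag rather than a third class, matching how
such intermediate values are treated in practice. Catalytic-versus-
allosteric subtyping of functional bonds is user-supplied metadata
(domain context), not computed: it derives from deletion-construct
experiments, not from the potential itself.

Units are kJ/mol throughout the estimation layer; the only conversion is
at the Nernst boundary (mV). Temperature defaults to 300 K with
k~B~ = 0.0083145 kJ mol⁻¹ K⁻¹.

## The synthetic-data generator

`cft_model()` / `sample_cft_works()` generate the unique Gaussian pair
satisfying the CFT at a known ΔG: forward works from
N(ΔG + βσ²/2, σ²) and backward works stored as the negated draws of
N(ΔG − βσ²/2, σ²). Dissipation is therefore parameterized by σ alone —
there is no independent dissipation dial. Defaults mirror a realistic
study design: 500 replicas per direction per bond at 300 K, 17 bonds per
panel, ground-truth free energies spanning 17–50 kJ/mol (the range of
typical disulfide reduction works). Work-distribution widths of real
protein disulfides are only available graphically in the source studies,
so σ defaults to 4 kJ/mol with 2–8 kJ/mol treated as the plausible band
in the recovery tests; this is a modelling choice, not a measured value.

What the generator does *not* emulate: time correlation between replicas
drawn from a finite equilibrium trajectory, anharmonic work tails, drift
from incomplete equilibration, and λ-schedule artifacts. Passing
recovery tests on this generator therefore demonstrates correctness of
the estimators under their own assumptions (Gaussian, independent,
CFT-consistent work), not robustness to real-data pathologies — overlap
and normality diagnostics exist precisely because real work sets violate
these assumptions.

`synth_dhdl()` produces dH/dλ curves whose trapezoidal integral equals a
prescribed work exactly (a sinusoidal base plus seeded noise, closed by a
constant shift — exact because the λ path has unit measure), which lets
the integration and I/O layers be tested against the estimators
end-to-end.

## Hybrid-topology construction

The alchemical transformation needs a residue description valid at both
end states. `build_hybrid_residue()` consumes two user-supplied
templates — the disulfide-bonded half-cystine (state A) and the free
cysteine (state B) — and emits the hybrid residue CYD: the thiol
hydrogen, absent in state A, is represented by a dummy atom HUD (zero
charge, a designated zero-Lennard-Jones type, no bonded terms at λ = 0;
a full hydrogen at λ = 1), and two virtual sites VC and VS are added,
position-constrained to the CB and S atoms and interaction-free in both
states. Cross-residue terms of a bonded pair — the S1–S2 bond, both
CB–S–S angles, and every dihedral whose central bond is S1–S2 — exist in
state A only; the dihedral set is enumerated from the templates'
connectivity (all four-atom paths through S1–S2) rather than synthesized
from multiplicity rules, because the source protocol does not enumerate
which dihedrals it retained.

Design constraints worth stating explicitly: hybrid atom order follows
the cysteine template with HUD in the thiol slot, and the two templates
must agree on the ordering of their shared atoms — this is what makes
both end-state projections reproduce their template *field-for-field*,
which is the module's central invariant (checked by
`validate_state_equivalence()` and by golden-file tests). The writer's
dialect is a documented, versioned subset of an itp-style grammar with
A/B columns; numbers are serialized with 17 significant digits so the
write/read round trip is exact, and a frozen golden file pins the
grammar. Force-field parameters are consumed from template files; the
packaged templates are synthetic toys that mimic the relevant entries —
no force field is redistributed.

## Structure analysis

`detect_disulfides()` applies the standard geometric rule: cysteine
SG–SG distance at most 2.5 Å (a bonded disulfide sits near 2.05 Å), on
the first model with the highest-occupancy altloc, pairing greedily by
increasing distance so each cysteine joins at most one bond (verified
against exhaustive minimum-weight matching in tests). Bond-to-site
distances use the SG midpoint as the bond's location — the choice of
reference point is not fixed by convention, so per-SG distances are also
reported. Secondary structure is consumed as an H/E/L annotation, never
computed. The distance–potential association uses Spearman rank
correlation (monotonicity, not linearity, is the claim of interest).

## Numerical choices and degenerate inputs

* Duplicate λ values in a dH/dλ series are an error, never averaged;
  series must be strictly monotone in their direction of travel.
* Work sets reject non-finite values at construction; tied values are
  legitimate (bootstrap resamples create them routinely).
* Zero-sd (degenerate) work sets are an error for CGI and the overlap
  report; BAR handles them, and a fully degenerate bootstrap returns an
  SE of exactly 0.
* Estimator failures inside the bootstrap are tolerated up to 10% of
  resamples, then reported as an error with the failure count.
* CSV work tables serialize at 17 significant digits; read∘write is the
  identity on doubles.

## Problem sizes used by the test suite

The recovery grid runs both estimators over ΔG ∈ {10, 30, 50} kJ/mol ×
σ ∈ {2, 4, 8} kJ/mol × 20 seeds at 500 replicas per direction (bootstrap
SEs at 100 resamples), and the end-to-end panel check uses 17 bonds ×
500 replicas — the full study scale. Bootstrap-calibration and
moment-recovery tests use 200 regenerated datasets and 10⁵ draws
respectively. These sizes were chosen so the whole suite completes in
about a minute on a single core while keeping every check at or above
the sampling scale it speaks for.

## Known limitations

* The Gaussian work model is both the generator and the CGI assumption;
  CGI's accuracy on strongly non-Gaussian real work data is not
  established here (BAR is the safer default in that regime, and the
  reference analyses likewise report BAR values).
* The KS normality screen reuses fitted parameters (anti-conservative).
* No autocorrelation handling: replicas are treated as independent.
* The calibration is a fixed linear map; its transferability beyond the
  protocol it was fitted on is the user's responsibility.
* Jarzynski averaging, MBAR/multistate estimation, pKa/electrostatics
  and any MD execution are out of scope.
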
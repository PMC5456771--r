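---
title: "Hyperelastic characterization of tracheal tissues: models, pipeline and design choices"
author: "tracheamech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hyperelastic characterization of tracheal tissues}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tracheamech)
```

## The mechanical problem

The trachea is a composite organ: stiff C-shaped cartilage rings hold the
lumen open, the trachealis muscle closes the posterior gap, and connective
tissue bridges consecutive rings. Scaffolds for trachea tissue engineering
must match the stiffness of each constituent, which is what motivates
characterizing the three tissues separately under uniaxial tension.

All three tissues are modelled as isotropic, incompressible, hyperelastic
solids. Incompressibility is justified by the high water content of the
tissues; isotropy is a simplification (fibrous soft tissues are in general
anisotropic) that keeps the constitutive equations identifiable from a
single loading direction. Both assumptions are discussed under
*Limitations* below.

## From machine output to stress and stretch

A tensile test yields force $T$ (N) versus crosshead displacement
$\Delta L$ (mm). With the preload-referenced gauge length $L_0$ and
reference cross-section $A_0$:

$$\lambda = \frac{L_0 + \Delta L}{L_0}, \qquad
  \sigma = \frac{T}{A_0}\lambda ,$$

the second expression being the Cauchy (true) stress of an incompressible
specimen, whose current cross-section is $A_0/\lambda$. N and mm² give MPa
directly, and the package keeps that unit convention everywhere: stress-like
model coefficients are in MPa.

**Preload referencing.** The protocol defines the reference length at a
0.1 N preload. `preload_reference()` makes the first sample at or above the
preload the new origin and discards earlier samples. `record_to_curve()`
then subtracts the force carried at that reference sample before computing
stress. Subtracting the *force* (rather than a constant stress offset)
makes $\sigma(1) = 0$ exact and lets a noiseless simulated record
round-trip to its generating stress function to machine precision — the
invariant the processing tests enforce. The residual bias relative to
treating the preload as part of the tissue stress is below
$0.1\,(\lambda-1)/A_0$ MPa, negligible at the areas used here.

**Monotonicity.** Non-increasing displacement samples (machine jitter) are
dropped with a diagnostic count rather than failing the record.

## The constitutive models

For an isotropic incompressible material under uniaxial tension the
invariants reduce to $I_1 = \lambda^2 + 2/\lambda$,
$I_2 = 2\lambda + 1/\lambda^2$, $I_3 = 1$, and the axial Cauchy stress
derives from the strain energy $W$ as

$$\sigma = \lambda_1\frac{\partial W}{\partial\lambda_1}
         - \lambda_3\frac{\partial W}{\partial\lambda_3}
         = 2\Big(\lambda^2-\frac1\lambda\Big)
           \Big(\frac{\partial W}{\partial I_1}
              + \frac1\lambda\frac{\partial W}{\partial I_2}\Big).$$

Seven strain-energy functions are registered (`hyperelastic_models()`),
with coefficients named `a1, a2, ...` in the order they appear in $W$:

| model | $W$ | uniaxial $\sigma$ |
|---|---|---|
| Neo-Hookean | $a_1(I_1-3)$ | $2a_1(\lambda^2-1/\lambda)$ |
| Mooney-Rivlin | $a_1(I_1-3)+a_2(I_2-3)$ | $2(\lambda^2-1/\lambda)(a_1+a_2/\lambda)$ |
| Yeoh | $\sum_{i=1}^3 a_i(I_1-3)^i$ | $2(\lambda^2-1/\lambda)\,[a_1+2a_2(I_1-3)+3a_3(I_1-3)^2]$ |
| Fung | $\frac{a_1}{2a_2}(e^{a_2(I_1-3)}-1)$ | $a_1(\lambda^2-1/\lambda)e^{a_2(I_1-3)}$ |
| Humphrey | $a_1(e^{a_2(I_1-3)}-1)$ | $2a_1a_2(\lambda^2-1/\lambda)e^{a_2(I_1-3)}$ |
| Ogden (3 terms) | $\sum_n \frac{a_{2n-1}}{a_{2n}}(\sum_i\lambda_i^{a_{2n}}-3)$ | $\sum_n a_{2n-1}(\lambda^{a_{2n}}-\lambda^{-a_{2n}/2})$ |
| Veronda-Westmann | $a_1(e^{a_2(I_1-3)}-1)-\frac{a_1a_2}{2}(I_2-3)$ | $2a_1a_2(\lambda^2-1/\lambda)(e^{a_2(I_1-3)}-\frac{1}{2\lambda})$ |

The stress columns are re-derived from the $W$ definitions; published
uniaxial stress tables for these models are not always internally
consistent (kinematic prefactors are easy to lose in typesetting), so the
package trusts the derivation and verifies it mechanically: every closed
form is checked against `cauchy_stress_fd()`, a central-finite-difference
evaluation of $\lambda_1\,\partial W/\partial\lambda_1 -
\lambda_3\,\partial W/\partial\lambda_3$ that shares only the $W$
definitions. The oracle agrees with the closed forms to better than
$10^{-5}$ relative error over random parameter draws, and the initial
tangent moduli ($d\sigma/d\lambda$ at $\lambda=1$: $6a_1$ for
Neo-Hookean/Yeoh, $6(a_1{+}a_2)$ for Mooney-Rivlin, $3a_1$ for Fung,
$6a_1a_2$ for Humphrey, $3a_1a_2$ for Veronda-Westmann,
$\tfrac32\sum a_{2n-1}a_{2n}$ for Ogden) are checked the same way.

Two structural identities are useful and tested: Fung$(a_1,a_2)$ ≡
Humphrey$(a_1/2a_2,\,a_2)$ pointwise, and Yeoh/Mooney-Rivlin/Ogden all nest
the Neo-Hookean solid.

## Fitting and model ranking

`hyperfit()` minimises the sum of squared stress residuals over the curve's
stretch grid with the Levenberg–Marquardt algorithm (`minpack.lm::nls.lm`,
`ftol = ptol = 1e-12`, 300 iterations, box constraints keeping exponents in
a numerically safe range). Exponential arguments are clipped at 60 to guard
overflow during exploration.

Nonlinear least squares on exponential and high-order polynomial models is
multimodal, so the optimiser is restarted from 16 seeded initial vectors:
one deterministic heuristic anchored on the curve's small-strain modulus
$E_0$ (e.g. $a_1 = E_0/6$ for invariant-linear models) and 15 random draws
spreading stress-like coefficients over $\pm(0.1\text{–}10)\times E_0/6$
and exponents log-uniformly over $[0.1, 20]$ — a spread that covers the
coefficient magnitudes observed for these tissues (0.06–12 MPa). With a
fixed seed the whole fit is bit-reproducible.

`r_squared()` uses the mean-anchored definition
$1-\mathrm{SS}_{res}/\mathrm{SS}_{tot}$, the convention of standard
curve-fitting toolboxes. `fit_all_models()` ranks models by $R^2$ rounded
to 0.001 (the precision such tables are printed at), breaking ties in
favour of fewer parameters — a nested superset that merely matches its
subset should not outrank it.

The three-term Ogden model deserves a caveat: six coefficients fitted to a
single smooth ~50-point curve are structurally unidentifiable (many
coefficient vectors give the same curve). Its fit is therefore assessed at
the curve level (residual RMS, $R^2$), never at the coefficient level, and
its `converged` flag frequently stays `FALSE` because the optimum plateau
has a non-vanishing gradient tolerance — that is reported honestly rather
than suppressed.

**Linear modulus.** Cartilage is quasi-linear up to $\lambda = 1.2$
($R^2 \ge 0.999$ on the reconstructed mean curve), so its stiffness is
summarised by a Young's modulus: the OLS slope of $\sigma$ on engineering
strain $\lambda-1$ with a free intercept. The free intercept makes the
slope insensitive to how the preload offset was handled; at these strains
the distinction between engineering-strain and stretch regressors is nil.

## Cohort statistics

Per-donor stiffness is the mean of that donor's specimen moduli (three
specimens per tissue), so inference is at the donor level and no
mixed-effects structure is needed. Groups are compared by a two-way ANOVA
of modulus on age group × sex. The cohort is unbalanced (13 young / 17
old), so Type II sums of squares are used (`car::Anova`); with a weak
interaction — which is what the data show — Type II is the conventional
choice, and for balanced designs it reduces to the classical decomposition
(property-tested against explicit mean-contrast formulas). Normality is
screened with the Shapiro–Wilk test plus Q-Q coordinates; the significance
level is fixed at 0.05. Three tissues are tested without multiple-testing
correction, matching the original analysis; reports note this.

Age groups are the two disjoint donor bands, young 18–36 and old 49–65
years; ages between the bands are rejected rather than silently binned.

## The synthetic cohort generator

No donor-level measurements are publicly available, so the generator
(`cohort_config()`, `generate_cohort()`) emulates the cohort the analysis
expects, and its defaults *are* the study conditions:

* **Composition**: 30 donors — 13 young (5 F, 8 M) and 17 old (7 F, 10 M),
  ages uniform within the bands; 3 specimens per tissue per donor.
* **Mean curves**: per-tissue ground truth is the reported Yeoh coefficient
  set of each tissue (cartilage 3.583/−2.534/12.020; smooth muscle
  0.063/0.394/−0.171; connective 0.257/0.483/−0.148 MPa).
* **Between-donor heterogeneity**: one positive multiplicative stiffness
  scale per donor × tissue (curve shape preserved — group differences are
  reported as stiffness shifts, not shape changes). The scale is lognormal,
  chosen for positivity at the large coefficient-of-variation targets
  (~0.43–0.49); its moments are matched so that the cartilage modulus
  scale × E_base has exactly the reported group moments (young
  13.30 ± 5.72 MPa, old 20.71 ± 10.17 MPa), with E_base the linear modulus
  of the ground-truth cartilage curve over [1, 1.2]. Soft tissues, for
  which no moduli are printed, get unit young-group mean with CV 0.40 and
  an old/young ratio of 1.35 (connective) and 1.10 (smooth muscle) —
  ordering the age sensitivity as connective > smooth muscle, with smooth
  muscle least age-sensitive.
* **Geometry**: gauge lengths from the reported per-tissue distributions
  (4.13 ± 1.81, 6.37 ± 1.91, 1.60 ± 0.33 mm, truncated positive).
  Cross-sections are documented fixture choices (cartilage 5 ± 1.5 mm²,
  soft tissues 3 ± 1 mm²): no cross-sections are printed anywhere, and they
  only scale forces — they cancel out of every stress.
* **Records**: stretch grid [1, λ_max] step 0.01 (λ_max 1.2 for cartilage,
  1.5 for soft tissues), force = preload + σA₀/λ + Gaussian noise with SD
  = 1% of the record's peak model force. The preload-holding reference
  sample is noise-free (a servo holds the set-point), which keeps the
  preload crossing — and hence the stretch grid — exact; noise then
  perturbs stresses, which is the error mode that matters downstream. A
  short sub-preload lead-in is prepended so the preload-referencing logic
  is always exercised. The noise magnitude is a fixture parameter, not a
  calibrated value: no stress-dispersion numbers are printed for the soft
  tissues.

Everything is deterministic given `seed` (mandatory, no wall-clock
default): regenerating a cohort gives byte-identical CSVs, and generation
restores the caller's RNG state.

**What the generator does not emulate**: failure and rupture, hysteresis
and preconditioning evolution, strain-rate effects, within-donor specimen
heterogeneity beyond force noise, anisotropy, and any age-related *shape*
change of the curves. Passing tests therefore demonstrate that the
pipeline recovers what this generative structure contains — multiplicative
stiffness differences under realistic noise and cohort sizes — not that
real tracheal data satisfy the model.

## Averaging and problem sizes

Curves are averaged on the uniform grid [1, λ_max] step 0.01 (51 points for
soft tissues, 21 for cartilage) — fine enough to resolve the curvature over
both ranges; the original acquisition grid is machine-specific, which is
why resampling (linear interpolation, no extrapolation) precedes
averaging. Averaging is two-stage — specimens within donor, then donors —
so each donor contributes equally. Curves that do not reach λ_max are
excluded from the average with a warning rather than failing the run.
Statistical acceptance checks use the full default cohort (30 donors, 3
specimens each) and, for the age-effect detection rate, 50 independently
seeded cohorts — sizes at which the whole suite runs in seconds.

## Known limitations

* The isotropy and incompressibility assumptions are inherited from the
  modelling tradition for these tissues; transversely isotropic or
  compressible formulations are out of scope.
* One detection-rate expectation is not met by design: with the reported
  group moments (13.30 ± 5.72 vs 20.71 ± 10.17 MPa at n = 13/17) the
  two-sided power of the age-effect test is ≈ 0.68, so the pipeline flags
  p < 0.05 in about two thirds of seeded cohorts, not more. That is a
  property of the stated effect size and sample sizes, and the package
  reports it rather than inflating the effect to pass.
* The pooled overall cartilage modulus (16.92 ± 8.76 MPa as printed)
  depends on the real per-donor data and on an averaging convention that
  is ambiguous (the printed group means at n = 13/17 average to 17.50);
  the package adopts per-donor slopes averaged within group and does not
  target the pooled number.
* Fitted coefficients carry no uncertainty quantification (no confidence
  intervals, no AIC/BIC selection); ranking is by $R^2$ alone, as in the
  original workflow.
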
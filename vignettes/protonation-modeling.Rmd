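---
title: "Modeling the proton-binding capacity of soluble bio-organic substances"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the proton-binding capacity of soluble bio-organic substances}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protofit)
```

## The chemical problem

Soluble bio-organic substances (SBOs) are polydisperse macromolecular
mixtures recovered from treated municipal biowaste.  Like humic
substances, they carry carboxylic, phenolic and nitrogen functional
groups of widely varying acid strength, so a titration curve of an SBO is
the superposition of many overlapping protonation equilibria.  The
package models that curve with a small number of *site classes*: each
class is a weak r-protic acid with cumulative protonation constants
$\beta_r = [\mathrm{AH}_r]/([\mathrm{A}][\mathrm{H}^+]^r)$ and a
concentration expressed per gram of dry matter.  Absolute charges are not
tracked — only the protonation level $r$ — because every computed quantity
(species fractions, bound protons, titration curves) depends only on $r$.
All constants are *conditional*: they refer to the working medium (0.1
mol/L background electrolyte, 25 °C) on the free-concentration scale,
$\mathrm{pH} = -\log_{10}[\mathrm{H}^+]$.  No activity-coefficient or
electrostatic (Donnan/Debye–Hückel) correction is applied, and the
protonation parameters are assumed independent of the dissociation
degree.

Three canonical structures are supported.  Models I and II are
"diprotic-like": one site carries two cumulative constants and a single
shared concentration, optionally flanked by one (Model I) or one to two
(Model II) monoprotic sites.  Model III is a discrete-site model: every
site is monoprotic with an independent constant.  Arbitrary custom
structures are also allowed.

## Speciation and the proton condition

For one site, the fraction of the state carrying $r$ protons is
$\alpha_r = \beta_r [\mathrm{H}]^r / \sum_j \beta_j [\mathrm{H}]^j$ with
$\beta_0 = 1$.  The implementation works on $\log_{10}$ terms and
subtracts the per-point maximum before exponentiating, so fractions are
well-defined for any finite pH (they normalize to 1 within $10^{-12}$
over pH $[-2, 16]$, which the tests assert).  The mean protons bound per
site is $\bar n = \sum_r r\,\alpha_r$, and its pH derivative is
$-\ln 10 \cdot \mathrm{Var}(r)$ — the variance of the bound-proton
number — which the solver and the fit Jacobian reuse.

Free $[\mathrm{H}^+]$ at a titration point solves the proton condition

$$ [\mathrm{H}^+] - K_w/[\mathrm{H}^+] + \sum_i C_i \bar n_i(\mathrm{pH})
   = T_H, $$

under the **fully protonated reference convention**: sites enter the
balance carrying all their protons, and $T_H$ counts strong acid added,
minus strong base, plus the protons delivered with the sites.  The excess
KOH used to dissolve the sample and the HCl used to acidify it to the
starting pH fold into one net strong-acid term `c_strong_acid`, which the
fit can optionally refine.  The left side is strictly decreasing in pH,
so the root is unique; it is found by a Newton iteration with an analytic
derivative, safeguarded by bisection on the bracket pH $[-2, 16]$
(convergence to $10^{-13}$ in pH, vectorized across titration points).  A
composition with no root in the bracket raises an infeasibility error.
The solver is verified against an independent plain-bisection oracle on
randomly generated 1–5-site models.

Simulated titrations dilute every analytical total by $v_0/(v_0+v)$ and
add titrant as $c_T v/(v_0+v)$; pH is therefore strictly increasing in
added base, which the tests check point-wise.

## Electrode model and calibration

The cell EMF is modeled as $E = E^0 - s\,\mathrm{pH} + j_a[\mathrm{H}^+]$:
a Nernstian term plus an acidic junction potential.  This functional form
is the convention of classical electrode-calibration refinement programs;
no alkaline junction term is used.  The slope defaults to the theoretical
59.16 mV/decade at 25 °C and is *not* refined by default — the typical
calibration refines $E^0$, $j_a$ and $K_w$ — though slope refinement is
available.  $pK_w$ defaults to 13.78, a standard conditional value at
25 °C and $I = 0.1$ mol/L; it is configurable and refinable, since the
working value in any particular laboratory setup is itself an outcome of
calibration.  Calibration requires at least 10 points and, when $K_w$ is
refined, an alkaline branch past the equivalence point; it shares the
weighting and least-squares stack of the main fit so the two stages use
identical conventions.

## Weighting and the fit statistic

Each point is weighted $w_i = 1/s_i^2$ with
$s_i^2 = \sigma_E^2 + (\partial E/\partial v)_i^2\,\sigma_V^2$, where the
defaults $\sigma_E = 0.1$ mV and $\sigma_V = 0.001$ mL are the instrument
resolutions of the emulated titration setup.  The local slope is
estimated by centered finite differences on the *observed* curve
(one-sided at the ends), so steep equivalence-region points are
down-weighted.  Unit weighting is available.  The model-comparison
statistic is the weighted standard deviation of the fit,
$\sigma = \sqrt{\sum_i w_i r_i^2/(n-p)}$: 0 for a perfect fit, and close
to 1 when the residual scatter matches the assumed error model — a
property verified by a Monte-Carlo consistency test.

## Parameter refinement

`fit_protonation_model()` minimizes the weighted error-squares sum on EMF
with a Levenberg–Marquardt iteration (`minpack.lm`).  Cumulative
constants are refined directly in $\log_{10}$; site concentrations are
refined as $\log_{10}$ of mmol/g so positivity is structural.  The
residual Jacobian is analytic, obtained from the implicit-function
theorem on the proton condition
($\partial \mathrm{pH}/\partial\theta = -(\partial f/\partial\theta)/
(\partial f/\partial \mathrm{pH})$), which makes noise-free
self-consistency sharp: refitting data simulated from any of the bundled
parameter sets recovers every parameter within $10^{-6}$.  Standard
deviations come from the inverse weighted normal-equations matrix scaled
by $\sigma$ (concentration uncertainties by the delta method).
Parameters whose constants fall more than one log unit outside the
observed pH window, or whose dispersion is not estimable, are flagged as
not determined by the data.

A pH-window mask supports the staged diprotic protocol: refine the
diprotic site on pH 2.8–6.5, then widen to 10.5 and add one monoprotic
site (`fit_model_I_staged()`).  The added alkaline site is treated as the
boundary toward Model II territory, so the staged recipe emits a Model I
structure with the extra site rather than inventing a third canonical
form.  A deterministic multi-start option (±1 log unit around the
guesses) guards against secondary minima; initial guesses can also be
auto-seeded from the buffer intensity of the observed curve
(`initial_site_guesses()`), a deliberately rough but reproducible
heuristic.  Exact numerical compatibility with the classical refinement
programs in this field is a non-goal: the algorithmic spirit (linearized
mass-balance least squares on EMF) is retained, their internals are not
reproduced.

## Functional-group breakdown

Sites with stepwise $\log K < 7$ are pooled as carboxylic, the rest as
phenolic; the threshold is configurable (the humic-substances literature
also uses 8) and the comparison is strictly `<`.  Each protonation step
contributes its site's concentration once, so the two pools always sum to
$\sum_i n_i C_i$ regardless of the threshold — an exact conservation the
tests exploit.  For diprotic sites both steps are classified by their own
stepwise constant; the canonical use of the classification, however, is
on discrete (Model III) fits.

NMR mole fractions convert to mmol/g of carbon as
$C_i \cdot \%C_{EA} / 1.20011$.  The denominator is kept exactly as
published for this conversion rather than recomputed from the IUPAC
atomic weight (which would give 1.2011), so that reported pool sizes are
reproduced; nitrogen uses IUPAC 14.007.  The balances
$\mathrm{COY} = \mathrm{COOH} + \mathrm{CONR}$ and
$\mathrm{N} = \mathrm{NR} + \mathrm{CONR}$ then yield the amide and
non-amide pools, with negative components rejected as inconsistent
inputs.  Note that applying the conversion to the *rounded* published
composition tables does not exactly reproduce the published COY/PhOY
pools (the original computation evidently used unrounded NMR fractions);
the package computes from whatever inputs it is given and does not
force-match.  Report values are rounded with `round_report()` — decimal
half-to-even after suppressing binary representation noise — because
plain `round()` can flip a printed last digit when a sum lands one ulp
off an exact half.

## Synthetic data

`make_sbo_titration()` emulates the reference design: 25 mL of 0.5 g/L
SBO in 0.1 mol/L TEACl, acidified to pH 3, titrated with 0.1 mol/L KOH to
pH 11.5, 50–120 points (default 80) uniform in titrant volume.  Noise is
independent Gaussian per point with SD equal to the instrument
resolutions (0.1 mV on EMF, 0.001 mL on delivered volume); the EMF is
computed at the true delivered volume while the nominal volume is
recorded, which is exactly the error structure the propagated weights
assume.  Generation is bit-reproducible per seed and leaves the global
RNG untouched; the generating truth travels in the dataset attributes for
recovery studies.  What the generator does **not** emulate: titration
hysteresis between forward and reverse runs (a conformational effect
described qualitatively but never quantified — reverse schedules can only
be generated under the same equilibrium model), electrode drift, CO₂
contamination, equilibration kinetics, and any point-density adaptation
to the local slope.  Passing recovery tests therefore demonstrates
statistical identifiability under the stated error model, not robustness
to those real-data effects.

## Numerical choices and problem sizes

Solver tolerances: $10^{-13}$ in pH for the proton condition; LM runs
with `ftol = ptol = 1e-15` so noise-free refits are limited by the
residual floor, not the stopping rule.  The test-suite study sizes are
chosen to be statistically meaningful at desk scale: 1000 random models
for the solver-vs-bisection check, 50 seeded replicates of the four-site
discrete design (80 points each) for stochastic parameter recovery
(median $|\Delta \log K| < 0.05$, median relative concentration error
< 5 %), 200 replicates of a one-site design for the $\sigma$-consistency
check (mean in $[0.9, 1.1]$), and 60 replicates for electrode-bias
checks.

## Known limitations

* Conditional constants only — results do not transfer across ionic
  strengths or media without recalibration.
* The published weighted standard deviations of the original fits
  (1.43–3.03) cannot be reproduced because the raw titration data are not
  deposited; the bundled parameter sets carry them as reference metadata
  only.
* Metal-ion complexation, micellar aggregation above the CMC, and
  $K(\alpha)$ models where constants depend on the dissociation degree
  (NICA, Högfeldt) are out of scope.
* The logK < 7 classification is an operational convention, not an
  assignment of constants to specific chemical moieties: nitrogen bases
  overlap both pools, which is precisely why the NMR balance is needed.
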
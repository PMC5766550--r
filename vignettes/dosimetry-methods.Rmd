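---
title: "Methods: from mouse biodistribution to predicted human dose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from mouse biodistribution to predicted human dose}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cudosim)
```

`cudosim` predicts human organ absorbed doses for a ⁶⁴Cu-labelled antibody
tracer from mouse biodistribution measurements. This vignette is the
package's own account of the science: the model at each stage, the
parameters that matter, what the synthetic data generator does and does not
emulate, and the numerical decisions taken where the methodology is
genuinely open.

## The dosimetry chain

The pipeline is a composition of four linear operators applied to per-organ
uptake data, with the injected activity normalised to 1.

**Quantification.** A gamma-counter measurement becomes percent injected
dose per gram:
$$\%ID/g = 100\,\frac{(\text{raw} - \text{background})\cdot
2^{t/T_{1/2}\,[\text{if corrected}]}}{\text{injected counts}\cdot m_\text{organ}}.$$
Decay correction is a first-class state, not a convention: every table
carries a `decay_corrected` flag, `decay_correct()`/`decay_uncorrect()` are
exact inverses, and downstream stages convert automatically. This matters
because reporting conventions differ between ex-vivo counting (usually
decay-corrected to injection) and PET time-activity plots (often not), and
because cumulated activity must be computed on the *physically decaying*
signal.

**Time integration.** The time-integrated activity (residence time) of a
source organ is the trapezoidal integral of its non-decay-corrected
fraction-of-injected-activity curve, plus a tail beyond the last sample:

* a `(0, 0)` anchor is prepended — the tracer is injected intravenously at
  $t = 0$, so organ activity starts at zero. For a hypothetical curve with
  $f(0) > 0$ sampled from $t = \varepsilon$ this anchor introduces a
  deficit of order $\varepsilon f(0)/2$, which vanishes under refinement;
  the tests assert the pure-decay closed form $T_{1/2}/\ln 2 = 18.32$ h at
  $10^{-3}$ relative tolerance on a 0.01 h grid for exactly this reason.
* the default tail, `physical_decay`, freezes biology after the last sample
  and lets only physical decay act: contribution $A_\text{last}/\lambda$
  with $\lambda = \ln 2 / T_{1/2}$. This is the conservative
  (dose-overestimating) standard when late kinetics are unmeasured. `zero`
  truncates; `fitted_exp` fits a biological clearance rate log-linearly to
  the last ≥ 2 *decay-corrected* points (floored at zero — fitting the raw
  points would double-count physical decay) and uses
  $A_\text{last}/(\lambda + \lambda_\text{fit})$. For non-increasing late
  data the three tails are ordered `zero` ≤ `fitted_exp` ≤
  `physical_decay`, which the tests assert.

No organ can outlive the isotope: every residence time is checked against
the pure-decay bound $1.443\,T_{1/2}$ and a violation warns about
inconsistent input.

**Interspecies scaling.** Mouse %ID/g becomes a human-equivalent whole-organ
fraction by relative organ mass:
$$(\%ID/\text{organ})_\text{human} = (\%ID/g)_\text{mouse}\times
M_\text{body,mouse}\times\frac{M_\text{organ,human}}{M_\text{body,human}}.$$
This is the standard relative-organ-mass extrapolation for antibody
tracers; it scales amplitudes only and deliberately applies no allometric
time scaling. It is isolated in `kirschner_scale()` so an alternative (for
example, dropping the body-mass ratio) can be swapped without touching the
rest of the chain. Because the operator is linear and pointwise, scaling
commutes with time integration — asserted by test — so the choice of
scaling before or after integration is immaterial. Measured compartments
without a phantom counterpart (the tumor) cannot be scaled; they are
excluded with a warning and reported separately. The heart ROI of an intact
IgG is dominated by circulating blood, so `heart` (and `blood`) map onto
the `heart_contents` source region by default (`default_source_map()`).

**MIRD dose and weighting.** Organ dose coefficients are
$D_T = \sum_S \tau_S\, S(T \leftarrow S)$, with S values consumed as data
(mSv/MBq·h). Effective dose uses the ICRP-60 weights (gonads 0.20; red
marrow, colon, lungs, stomach 0.12; bladder, breasts, liver, esophagus,
thyroid 0.05; skin, bone surface 0.01; remainder 0.05 as the
organ-mass-weighted mean of adrenals, brain, small intestine, kidneys,
muscle, pancreas, spleen and uterus). The effective dose equivalent uses
the ICRP-26 weights (gonads 0.25, breasts 0.15, red marrow and lungs 0.12,
thyroid and bone surface 0.03) plus 0.06 for each of the five highest-dose
remaining organs. Aliases connect reported organs to scheme tissues: the
colon dose is the mass-weighted ULI/LLI combination, the thymus stands in
for the esophagus, gonads resolve to the testes of the adult-male phantom
(falling back to ovaries), and "osteogenic cells" are the bone surface.
Missing tissues count as zero *with a warning*; weights that do not close
to unity are an error, ties for the dose-limiting organ break
lexicographically, and `total_body` is never treated as an organ.

On the packaged published organ-dose table for the blocked PET/CT arm these
two operations reproduce the printed effective-dose rows within 1.5% (see
`scripts/acceptance.R` and the acceptance tests). The published record
itself swaps the two labels in one place — its results text attaches
"effective dose" to the values its table prints under "Effective Dose
Equivalent" — and the package follows the table, whose labelling our
recomputation confirms as the internally consistent one.

**Administrable activity.** Each regulatory limit divided by its governing
coefficient gives an activity: organ limits (150 mSv annual, 50 mSv single
study) divide by the maximum organ dose coefficient, whole-body limits
(50/30 mSv) divide by the effective dose. All four are reported and the
binding minimum is flagged, because published "annual" figures for this
tracer class arithmetically correspond to the 50 mSv *single-study organ*
limit — reporting every combination makes the interpretation explicit
rather than guessed.

## The synthetic cohort generator

The generator exists so that every downstream stage is testable with known
ground truth; its defaults encode the emulated study design: 7.4 MBq
injected, 23 g mice, four animals per cohort, PET sampling at
{1, 2, 4, 18, 24, 48} h and necropsy sampling at {1, 12, 24, 48} h, isotope
half-life 12.7 h.

**Kinetic form.** Each organ's biology-only curve is a sum of normalised
rise-and-clear (Bateman) components
$A\,(e^{-\lambda_c t} - e^{-\lambda_u t})/\max_s(\cdot)$ with
$\lambda_u > \lambda_c \ge 0$; with $\lambda_c = 0$ a component saturates
towards its amplitude. A single component reproduces monotone
rise-then-clear profiles (clearance organs), but a receptor-rich xenograft
accumulating an antibody over 48 h shows an early perfusion signal followed
by near-linear accumulation, which no single Bateman curve matches within
the calibration budget; the xenograft therefore uses two additive
components, an early vascular transient and a slow receptor-driven
accumulation. Measurement noise is multiplicative lognormal with shape
`noise_sigma` (default 0.10, matching the ~5–15% SD/mean ratios typical of
replicate biodistribution data); %ID/g is positive with roughly
proportional error, which makes a lognormal the natural choice.

**Blocking.** Pre-administering the non-radioactive antibody saturates the
receptor; in the generator this is a per-organ amplitude factor
$\beta \in [0,1]$. The shipped defaults carry $\beta < 1$ not only for the
receptor-bearing tumor and spleen but also mildly for heart and liver,
because the reported blocked-cohort uptake is significantly lower there
too (less receptor-mediated hepatic handling, more tracer remaining in
circulation is *not* emulated mechanistically — the factor is purely
phenomenological).

**Calibration.** The default kinetics are fixed, versioned sets whose
noise-free curves pass within ±15% of reported uptake anchors — for the
xenograft model (decay-corrected): heart/liver/spleen at 48 h and tumor at
4/24/48 h in both cohorts; for the humanised melanoma model
(non-decay-corrected): heart/liver/spleen at 24 h, tumor at 24/48 h, and
every organ below 0.5 %ID/g by 48 h. The calibrated parameters achieve ≤ 6%
on every anchor (asserted in the acceptance tests). Calibration was done
once, by least-maximum-relative-error fitting against the anchors, and is
not a tuning surface.

**What the generator does not emulate.** No image formation: no partial
volume effects (the optional per-organ recovery coefficient defaults to 1
because no coefficients are published), no ROI delineation error, no
scanner calibration drift. No inter-animal kinetic heterogeneity beyond
i.i.d. multiplicative noise, no tumor growth over the imaging window, no
receptor internalisation dynamics. Passing tests on synthetic data
therefore demonstrate the *correctness of the computational chain*, not the
biological fidelity of any particular curve.

## The shipped S-value fixture

Re-deriving phantom Monte Carlo transport is out of scope; S values are
input data. Because no published ⁶⁴Cu tabulation ships with the package,
the fixture `svalues_cu64_adult_male_synthetic.csv` is *synthetic*:
constructed from per-decay energy bookkeeping (non-penetrating 0.125 MeV;
photon 0.185 MeV), self-dose
$S = (\Delta_{np} + \phi\,\Delta_\gamma)/m$ with a mass-scaled photon
absorbed fraction, a dedicated wall-from-contents term for the heart, and
small geometry-factored photon cross terms. These are physically plausible
magnitudes, adequate for the qualitative headline (the liver, with by far
the largest scaled residence time among solid organs, is dose-limiting)
and for exact-linearity and oracle tests — they are **not** a substitute
for a validated tabulation in production use, where users should supply
their own matrix via `read_svalue_matrix()`.

## Numerical choices and degenerate inputs

* Trapezoid via `pracma::trapz`; refinement error decreases monotonically
  (asserted), $O(\Delta t^2)$ on smooth curves.
* Problem sizes in the test suite: dense grids of $10^4$ points for
  closed-form checks, 5×5 random S matrices for the brute-force oracle,
  2–4 animals per synthetic cohort — the whole suite runs in seconds.
* Exactly one of counts or %ID/g per measurement row; both or neither is an
  error, not a guess.
* An organ fraction above 1 (more than the injected dose) warns and is
  propagated, never clipped.
* A missing whole-body curve yields a zero remainder-of-body residence time
  with a warning; nothing is imputed.
* Single-value uptake-ratio inputs return an `NA` uncertainty (a standard
  deviation of one value is undefined).
* Pooled-variance (classical Student) rather than Welch t test, matching
  the emulated analysis convention.
* Seeds: `generate_cohort()` is a pure function of its configuration
  including the seed; the RNG state of the session is left untouched
  (`withr::with_seed`).

## Limitations

The mouse-to-human extrapolation ignores species differences in antibody
kinetics (FcRn recycling, target-mediated disposition); the remainder-organ
conventions follow the pre-2007 ICRP schemes because those are what the
emulated workflow used; the shipped phantom is an adult male only; and the
dose-limiting-organ call on synthetic defaults depends on the synthetic S
values as discussed above.
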
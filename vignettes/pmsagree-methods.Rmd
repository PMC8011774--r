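---
title: "Estimating mean systemic filling pressure and comparing its two bedside surrogates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating mean systemic filling pressure and comparing its two bedside surrogates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmsagree)
```

## The physiology being modelled

In Guyton's description of the circulation, venous return is driven by the
gradient between mean systemic filling pressure (Pms) and right atrial
pressure (RAP), against a resistance to venous return (RVR):

$$ VR = \frac{P_{ms} - RAP}{RVR}, $$

and in steady state venous return equals cardiac output. Pms is the
pressure the whole systemic circulation would equilibrate to at zero flow;
it indexes effective intravascular volume, which makes it clinically
attractive and experimentally awkward — you cannot stop a patient's
circulation to read it off.

Two bedside surrogates are implemented here.

**The analogue, Pmsa.** Parkin's algorithm maps one hemodynamic snapshot
to an analogue pressure

$$ P_{msa} = 0.96\,RAP + 0.04\,MAP + c \cdot CO, $$

where the anthropometric constant
$c = 0.038\,(94.17 + 0.193\,\text{age}) / (4.5 \cdot 0.99^{\text{age}-15}
\cdot BSA_{DuBois})$ carries an age- and size-dependent vascular
resistance scale ($BSA_{DuBois} = 0.007184\,h^{0.725}\,w^{0.425}$, h in
cm, w in kg). The pressure weights sum to one, so `pmsa(r, r, 0) = r`:
at zero flow with arterial and venous pressures equilibrated the analogue
reduces to that common pressure, which is exactly the definition of Pms.
CO enters in L/min; with indexed or mL-scale flow the `c * CO` term is
dimensionally wrong and yields non-physiologic values, so the package
validates flow inputs at load time and lets CI be reconciled against
`CO / BSA` within a configurable 5% tolerance. Age below 15 years is
rejected rather than extrapolated: the decay term `0.99^(age-15)` is
anchored at 15 and the formula has no provenance below it.

**The reference, Pms-Insp.** Inspiratory holds at stepwise airway plateau
pressures (5, 10, 15, 20, 25, 30 cm H2O, each held at least 12 s, 2 min
apart) load the right atrium: RAP rises, venous return falls, and each
hold contributes one (RAP, CI) point that — because the steady state must
lie on the venous return line — traces that line. Ordinary least squares
of flow on RAP, extrapolated to zero flow, gives the x-intercept
$-a/b$, the RAP at which venous return would cease: Pms-Insp. The fit is
deliberately plain OLS with no weighting. A non-negative slope is refused
(`pms_nonphysiologic_fit`) rather than silently extrapolated to a
meaningless intercept, as are designs with fewer than three points or no
RAP spread. The flow axis defaults to cardiac index, as venous return
curves are conventionally drawn; fitting CO instead rescales both
coefficients by BSA and provably leaves the intercept unchanged (asserted
in the tests).

## Agreement statistics

`run_study()` reproduces a complete method-comparison analysis, overall
and stratified by vasopressor use:

* **Bland–Altman**: differences are taken as `pmsa - pms_insp`, so a
  negative bias means the analogue reads low. Precision is the SD of the
  differences and the limits of agreement are `bias ± 1.96 SD`. The bias
  is tested against zero with a one-sample t test (normality of the
  differences is screened, advisorily only, by a Kolmogorov–Smirnov
  statistic against a moment-fitted normal). Proportional bias is the OLS
  slope of difference on pairwise mean.
* **ICC**: two-way mixed model, absolute agreement, computed from the
  two-way ANOVA mean squares. Both ICC(A,1) and the average-measures
  ICC(A,k) are reported — the headline value is average-measures — with
  McGraw–Wong F-distribution confidence bounds (average-measures bounds by
  Spearman–Brown step-up) and the p-value of `F = MSR/MSE` on
  `(n-1, (n-1)(k-1))` df. Identical columns give ICC exactly 1; zero
  between-subject variance leaves the ICC undefined and is an error, not
  a number.
* **Rank tests**: the paired signed-rank and two-group rank-sum tests use
  exact two-sided p-values for small samples (n ≤ 25). Without ties the
  exact distributions of base R are used; with ties, where base R falls
  back to an approximation, the exact null distribution of the mid-rank
  statistic is built by generating-function convolution (doubled ranks
  keep everything integer), which matches full enumeration over sign
  assignments / group labelings exactly. Zero differences are dropped and
  counted; an all-zero sample returns p = 1 by convention, flagged.
  Larger samples use the tie-corrected normal approximation with
  continuity correction.
* **Conversion coefficient**: the mean ± SD of the per-subject ratios
  `pms_insp / pmsa`; the reciprocal of the mean, rounded to two decimals,
  is the factor by which the analogue underestimates (or overestimates)
  the reference.
* **Coefficient of variance**: `100 · SD/mean`. Published COV values for
  this comparison are not mutually consistent with any single choice of
  numerator and denominator, so the definition is explicit and
  configurable; the report default relates the SD of the paired
  differences to the mean of all paired measurements, and the report
  records which definition was used.
* **ICC power**: the post-hoc power of the F-based test that the ICC
  exceeds a null value uses the Walter–Eliasziw–Donner construction:
  `MSB/MSW ~ C(rho) F(n-1, n(k-1))` with `C(rho) = 1 + k rho/(1-rho)`,
  so the two-tailed power is a rescaled F tail probability. At
  `icc_alt = icc_null` it returns exactly alpha, and it is monotone in n.
* No multiplicity correction is applied anywhere, matching the analysis
  this package reproduces.
* **Instrument QC**: a thermodilution calibration triplet is accepted only
  if no measurement deviates from the triplet mean by more than 10%.

Reported tables round pressures and limits of agreement to 2 decimals,
bias to 3, and ICC to 2; the underlying objects keep full precision.

## The virtual-patient simulator

`simulate_cohort()` exists so that every stage — snapshot Pmsa, stream
processing, hold extraction, curve fitting, the full agreement report —
can be tested against known truth without any recorded data.

Each virtual patient is a Guytonian circulation: a venous return line with
true `pms_true` and `rvr`, a saturating cardiac function curve
$CO = CO_{max}\,(1 - e^{-s\,(RAP - RAP_0)/CO_{max}})$, and
`MAP = RAP + CO * SVR`. Inspiratory holds shift the cardiac function
curve rightward by `transmission × Pplateau × 0.7355` mmHg (plateau
pressures are set in cm H2O but the circulation works in mmHg; the
conversion lives in one constant). The steady state is the intersection
of the two curves (closed form for the linear-heart option used in
closed-form tests, `uniroot` to 1e-10 otherwise), so the noiseless hold
points are *exactly* collinear with x-intercept `pms_true` — the
geometry, not the fitting code, guarantees recovery, which is what makes
the zero-noise tests machine-precision checks of the whole chain. A
plateau that pushes the heart curve past `pms_true` collapses the
circulation; such points are excluded and flagged, and a patient with
fewer than three usable holds is redrawn, as such a patient could not
have contributed a curve to a real study either.

Default parameter ranges are chosen to land the cohort on the marginal
distributions of a sedated post-cardiac-surgery ICU population: age
35–78 y, height 156–191 cm, weight 61–110 kg, baseline RAP 3–7 mmHg,
baseline CI 2.2–3.4 L/min/m2, SVR 9–15 mmHg·min/L, which puts true Pms at
roughly 7–17 mmHg and MAP at 55–90 mmHg. The airway-to-RAP transmission
fraction (0.35–0.55) is unknown in patients and is treated purely as a
simulator knob. The cardiac function curve is parameterized by its
*local* Starling slope at the operating point (1.2–2.0 L/min per mmHg)
rather than by an unstressed intercept, because that slope is what sets
how far RAP travels over the hold schedule; these values reproduce the
5–6 mmHg RAP excursion typical of published example curves and keep the
regression well conditioned.

By default each patient satisfies `RVR = c + 0.04 · SVR`. Substituting
`MAP = RAP + CO·SVR` into the analogue shows why this matters:

$$ P_{msa} = RAP + (c + 0.04\,SVR)\,CO, \qquad
   P_{ms} = RAP + RVR \cdot CO, $$

so under the identity the analogue equals true Pms *exactly* at any
noiseless steady state — verified to machine precision in the tests — and
any deviation `rvr_mismatch_sd > 0` injects a method bias of known sign.
This is also the honest limitation of the default cohort: real paired
data scatter far more than simulated data (published precisions are near
1.9 mmHg against ~0.3 mmHg here), precisely because real circulations do
not obey the identity. Passing tests on the default simulator therefore
demonstrates correctness of the estimators and statistics, not clinical
interchangeability of the methods.

**Noise model.** Monitor noise is per-sample: additive Gaussian on
pressures (defaults 0.5 mmHg RAP, 1.0 mmHg MAP), mean-preserving
multiplicative lognormal on CO (CV 5%). A hold-level read-out is the mean
of the final 3 s of the hold (the settled plateau; the settling time
constant is ~1.5 s, so the tail sits within a fraction of a percent of
the asymptote), and its noise shrinks by the square root of the number of
averaged samples. This matters for the intercept: noise on RAP is
regressor noise, and un-averaged it would attenuate the fitted slope
(classical errors-in-variables) and bias Pms-Insp upward by roughly
`(Pms − mean RAP) · var(noise)/var(RAP)` — on the order of 0.2 mmHg at
0.5 mmHg raw noise, but under 0.05 mmHg once the 3-s averaging of the
actual read-out process is modelled. The Monte-Carlo test (28 cohorts of
18, ~500 replicates) bounds the absolute mean recovery error at
0.2 mmHg.

All randomness flows from a single integer seed in `sim_config()`; a
fixed seed makes cohorts, streams and JSON reports bit-reproducible
(asserted byte-for-byte in the tests).

## Numerical and design choices

* Hold summarization uses the final 3 s of each hold; within-hold nadir
  or end-hold alternatives would be defensible too, so the window is a
  parameter rather than a constant.
* The realtime Pmsa monitor uses a 30 s trailing mean (configurable); the
  value paired with Pms-Insp is the smoothed value at the last sample
  before the hold's tag, since the maneuver itself perturbs the inputs.
* Exact rank-test p-values double the smaller tail (including the
  observed point mass) and cap at 1, matching base R's convention so the
  tied and untied paths agree where both exist.
* Protocol screening (`validate_protocol`) is advisory: missing plateau
  steps, short holds, ≥ 1000 mL tidal volumes and irregular intervals are
  findings, never mutations of the data; only conditions that invalidate
  a fit (slope sign, < 3 points) are errors.
* Error signalling is by classed conditions (`pms_data_format`,
  `pms_protocol_violation`, `pms_circulatory_collapse`, ...) so pipelines
  can distinguish bad files from bad physiology.

## Problem sizes

The test suite simulates cohorts of 18 (the study scale), uses 500-replicate
Monte-Carlo checks for estimator consistency and ICC confidence-interval
coverage (n = 200 subjects per replicate for the latter), and enumerates
rank-test null distributions fully up to n = 8; the whole suite runs in
well under a minute on one core.

## Known limitations

* The simulator's heart–lung interaction is a constant transmission
  fraction; PEEP effects, pleural-pressure gradients and left/right output
  differences during holds are not modelled.
* The analogue's constant `c` is taken as given; the package does not
  re-derive or refit it.
* Agreement on simulated defaults is optimistic by construction (see
  above); conclusions about real patients require real paired data, for
  which the CSV readers and the `pms report` pipeline are the entry
  point.
* No trend analysis (fluid challenge, passive leg raise) is implemented;
  the comparison is of paired static estimates.
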
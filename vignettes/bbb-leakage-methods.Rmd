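---
title: "Methods: sparse-DCE Patlak leakage mapping and cohort analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sparse-DCE Patlak leakage mapping and cohort analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bbbleak)
```

# The measurement model

## From signal to concentration

Gadolinium shortens tissue T1 in proportion to its local concentration,

$$\frac{1}{T_{1,\text{post}}} = \frac{1}{T_{1,\text{pre}}} + r_1 C,$$

so a pre/post pair of quantitative T1 maps gives
$C = (1/T_{1,\text{post}} - 1/T_{1,\text{pre}})/r_1$ directly
(`concentration_from_t1()`, T1 in ms converted to seconds internally, C in
mmol/L). The relaxivity default is $r_1 = 4.5\ \mathrm{L\,mmol^{-1}s^{-1}}$,
a literature-typical value for gadobutrol at high field; it is a plain
parameter (`relaxometry_params()`) because the correct value depends on
agent and field strength. Negative concentrations arise from noise and are
deliberately **kept**: clipping at zero would bias every downstream Patlak
slope upward. They are counted in a QC summary instead, and voxels with
nonpositive T1 are invalidated rather than converted.

For the dynamic series the package uses the linearized low-concentration
conversion $\Delta R_1(t) = (S(t)/\bar S_0 - 1)/(T_{10}\,k)$ with $\bar S_0$
the pre-injection baseline mean and $k$ a sequence scaling constant
(`concentration_from_dynamic()`). The full spoiled-gradient-echo signal
equation is not modelled: the linear map is exactly invertible, which makes
every conversion testable against its inverse, and at the sub-millimolar
tissue concentrations of subtle leakage the linearization error is far below
measurement noise. Whole blood is converted to plasma by
$C_p = C_b/(1-\mathrm{Hct})$.

## The Patlak model

For a tissue in which contrast transfer across the barrier is effectively
irreversible over the experiment,

$$C_t(t) = K_i \int_0^t C_p(\tau)\,d\tau + v_p\,C_p(t).$$

Dividing by $C_p(t)$ linearizes this: plotting $y = C_t/C_p$ against the
"stretched time" $x = \int_0^t C_p\,d\tau \,/\, C_p(t)$ puts the data on a
line with slope $K_i$ (min⁻¹, the leakage rate) and intercept $v_p$ (the
plasma volume fraction). `patlak_transform()` builds these coordinates and
`fit_patlak()` / `fit_patlak_volume()` fit them by unweighted ordinary least
squares — the plain graphical Patlak estimator. No nonnegativity constraint
is imposed: negative estimates are data, and the ROI trimming stage is the
designed place to handle them.

Numerical choices that matter:

* **The plasma integral** (`integrate_vif()`) is the exact integral of the
  piecewise-linear interpolant through the VIF samples — the value any
  trapezoidal rule on a refined grid converges to — so it is additive over
  subintervals to rounding error, and the forward simulator
  (`forward_tissue_curve()`) uses the *same* integral. Noise-free
  forward-plus-fit round trips are therefore exact to machine precision,
  which the tests assert at 10⁻⁹ and better. Extrapolation beyond the last
  sample is refused, never silent.
* **Fit window**: pre-injection samples are always excluded; samples with
  $C_p$ at or below 1% of the plasma peak are excluded to avoid ratio
  blow-up near arrival; dynamic and late T1-map samples are both included by
  default (`patlak_fit_config()`), since the sparse protocol's premise is
  that the two late points anchor the slope while the early dynamic points
  pin the intercept. Whether the original analysis fit on dynamic + sparse
  points jointly or on sparse points only is not derivable from the study
  description, so both are supported (`use_dynamic`, `use_t1map`).
* **Vectorization**: the Patlak abscissa and window are shared by every
  voxel of a study, so the volume fit standardizes the arithmetic order to
  reproduce the scalar fit bit for bit (asserted on phantoms); voxels with
  non-finite samples fall back to the per-voxel path, and failed fits are
  flagged invalid rather than zeroed.
* Fits with fewer than two included points, or a degenerate abscissa, are
  invalid by definition.

## ROI summarization

Per ROI the physiological measure is the mean voxel $K_i$ (and $v_p$) after
an outlier correction that retains values inside the central 95% interval of
the ROI's own distribution. Two readings of "95% interval" are implemented:
the default is the percentile interval $[P_{2.5}, P_{97.5}]$ with
linear-interpolation (type 7) quantiles, fixed and documented for
bit-reproducibility; a mean ± 1.96 SD variant is available
(`trimmed_mean_95(method = "sd")`), and the choice is recorded in the output
metadata. The percentile reading is the default because a confidence
interval *of the mean* would retain almost nothing at ROI voxel counts and
cannot be the intended voxel-level correction. $K_i$ and $v_p$ are trimmed
independently — they are separate physiological measures, and a voxel may be
an outlier in one but not the other.

One consequence worth stating plainly: a central-95% trim can neutralize at
most 2.5% one-sided contamination. The tests plant gross corruption at and
below that level and verify recovery; above it, the upper percentile itself
is dragged into the contaminated block and no percentile trim can help.

## Clinical scoring

Blood pressure: repeated automated office measurements; the summary is the
arithmetic mean of the **last five** (`summarize_bp()`, requiring ≥ 5), by
which time the seated pressure has settled. The summary MAP averages the
device-reported per-measurement MAPs rather than recomputing from summary
SBP/DBP. Hypertension is SBP ≥ 135 or DBP ≥ 85 mm Hg (inclusive) or
antihypertensive medication; subgroups are NT, CHT (medicated, both
pressures below threshold — "controlled" reuses the same 135/85 thresholds,
as no second threshold is defined), UHT− (high, unmedicated) and UHT+ (high
despite medication).

The global cSVD burden score sums four independent binary points: deep-WMH
Fazekas ≥ 2 or irregular periventricular hyperintensities extending into
deep WM; ≥ 1 lacune; ≥ 1 basal-ganglia microbleed; basal-ganglia PVS grade
≥ 1 (count ≥ 11 in the slice with most PVS, graded 0: ≤ 10, 1: 11–25,
2: 26–40, 3: ≥ 41). All boundaries are inclusive exactly as written. The
tests enumerate the full rating space and check the score against an
independent rule-by-rule evaluation.

## Cohort statistics

Each model is an OLS regression of a z-scored outcome on z-scored predictors
(binary predictors coded 0/1 first), so the reported exposure coefficient is
standardized and comparable across ROIs and measures; the raw-scale
coefficient is also emitted. The design grid is
{Ki, vp} × {total GM, total WM, cortical GM, deep GM, extra parcels} ×
{status, SBP, DBP, MAP} × {no rotation, BMI, alcohol use, smoking history,
hematocrit, antihypertensive medication, cholesterol medication, cSVD
score}, always adjusted for age and male sex. Missing data are omitted
per model; rank deficiency is an error naming the collinear columns, not a
silent drop. No multiple-testing correction is applied across the grid by
default (each cell is reported at α = 0.05, matching the design this
implements); a Benjamini–Hochberg column is available but off by default.

Subject outliers follow the conjunctive rule |deleted studentized residual|
> 3.5 **and** Cook's distance > 1. Diagnostics come from the standard
hat-matrix identities (`stats::rstudent`, `stats::cooks.distance`) and are
validated in the tests against a brute-force leave-one-out refit oracle at
10⁻¹⁰ on every row. By default an outlier flagged in any base
(age+sex-adjusted) model is excluded study-wide — mirroring a design in
which whole subjects, not model-specific points, are removed — with a
per-model alternative (`analysis_config(outlier_scope = "model")`).

Subgroup contrasts use one-way ANOVA with Tukey HSD post hoc tests
(studentized-range adjustment), and the pooled comparison of CHT against
UHT− ∪ UHT+ is a two-sided equal-variance Student t test — with two groups
and the usual equal-variance assumption a two-group ANOVA would be
equivalent, so the t test is chosen for its directional readout.

# The synthetic-data generators

The generators exist so every stage above is testable against known truth.

**Schedule** (`default_schedule()`): three pre-injection baseline volumes
12 s apart, a dynamic sample every 12 s to 3 minutes post injection, and two
late T1-map samples at 5 and 25 minutes post injection.
`dense_schedule()` provides a conventional 30-s-interval design out to
25 min used purely as a comparison arm.

**VIF** (`simulate_vif()`): a gamma-variate first-pass bolus plus a
biexponentially decaying recirculation tail — the standard literature shape
— scaled to a whole-blood peak of 3 mM by default (a typical value for a
small compact bolus; the study protocol does not pin the peak, so it is a
config parameter inside the plausible 2–5 mM band). Plasma concentration is
blood/(1 − Hct), Hct 0.45 by default.

**Phantoms** (`simulate_phantom()`): contiguous tissue slabs (cortical GM,
deep GM, WM by default) whose voxels follow the forward Patlak curve of
their region truth plus i.i.d. Gaussian concentration noise, default sd
0.002 mM. Default truths — Ki 1.5 × 10⁻³ / 1.0 × 10⁻³ / 4 × 10⁻⁴ min⁻¹, vp
2.5 / 2.0 / 1.0% — are literature-typical for subtle BBB leakage; no
magnitudes are printed in the study description, so these are package
defaults, exposed in `ground_truth_region()`. At this noise level the
per-voxel Ki standard error on the sparse schedule is ≈ 2 × 10⁻⁴ min⁻¹,
so region-level trimmed means over a few hundred voxels recover truth to
well under 10%, and the sparse design's voxelwise Ki correlates above 0.9
with the dense design's — both properties are asserted in the tests rather
than only claimed here.

**Cohorts** (`simulate_cohort()`): 19 NT / 12 CHT / 5 UHT− / 5 UHT+ by
default, matching the analyzed group structure. Each subject receives seven
BP measurements whose last-five mean is constructed to equal the subgroup's
sampled target exactly, so generated cohorts classify back into exactly the
configured groups; per-measurement MAP uses the oscillometric convention
DBP + (SBP − DBP)/3, which is needed only for synthesis (real device MAPs
are taken as reported). True regional Ki is affine in summarized MAP with a
configurable slope per region, plus an additive male−female difference and
Gaussian ROI measurement noise (defaults: slope 1.2 × 10⁻⁵ min⁻¹ per mm Hg
in cortical GM only, sex effect 1 × 10⁻⁴ min⁻¹, noise sd 2 × 10⁻⁴ min⁻¹).
These defaults were set by a power calculation, not by tuning: with the
subgroup BP ranges used, cohort MAP has sd ≈ 10–11 mm Hg, so the planted
cortical signal is ≈ 1.3 × 10⁻⁴ min⁻¹ against 2 × 10⁻⁴ noise — a partial
correlation near 0.5, i.e. a subtle effect that a 41-subject study detects
with roughly 95% power at α = 0.05. Total GM is the 0.8/0.2 mix of the
observed cortical and deep GM values, so a cortical effect echoes into total
GM, as anatomy dictates. cSVD markers are drawn at deliberately mild
prevalences (most subjects score 0–1), reflecting an early-disease
population. Configurations whose BP sampling ranges cannot produce their
subgroup's classification (e.g. "uncontrolled" capped below 135/85) are
rejected up front.

## What the generators do *not* emulate

No MR signal equation, B1 inhomogeneity, motion, registration error or
realistic anatomy; phantom regions are slabs, not folded cortex; cohort
covariates are independent draws, whereas real cardiovascular covariates
are correlated with pressure and age; concentration noise is additive
Gaussian, not Rician on signal magnitude (a defensible approximation in the
concentration/T1 domain where this pipeline starts, and the noise model is
stated so its limits are visible). Passing tests therefore demonstrate the
*computational* correctness and statistical calibration of the chain — they
do not validate acquisition physics or segmentation, which this package
consumes as inputs.

# Problem sizes and determinism

The shipped tests run phantoms at 10×10×10 voxels, voxel-design comparisons
at 1000 voxels, and cohort simulations at n = 41 with 100–150 replicates —
sizes chosen so the whole suite exercises every guarantee in a few minutes
on a laptop while keeping Monte-Carlo bands (e.g. a false-positive rate
checked against [2.5%, 7.5%] at a nominal 5%) tight enough to be meaningful.
All generators are pure functions of their parameters and an integer seed,
restore the caller's RNG state, and the analysis report is byte-identical
across reruns on identical input.

# Known limitations

* The Patlak model ignores backflux; over ~25 minutes this is the standard
  assumption for intact-to-subtly-leaky barriers, but it underestimates
  Ki where leakage is frank.
* Unweighted OLS treats all included points equally; a weights hook exists
  (`PatlakPoints$weights` in the transform output) but no error-in-x
  modelling is attempted.
* The linearized dynamic-signal conversion assumes low concentration; blood
  VIFs measured from raw dynamic signal would need the full signal equation,
  which is out of scope (the VIF is consumed as concentration).
* "95% CI" outlier correction is an interpretation (percentile interval);
  the SD variant is provided because the original wording is ambiguous.
* With five-subject subgroups, Tukey-adjusted contrasts have limited power;
  the pooled comparison exists precisely to mitigate that.
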
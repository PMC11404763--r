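# bbbleak

Quantifying subtle blood–brain barrier (BBB) leakage from sparsely sampled
dynamic contrast-enhanced (DCE) MRI, and relating it to blood pressure at
cohort level.

## The problem

Chronic hypertension is suspected to impair the blood–brain barrier before
any overt tissue damage is visible. The leakage involved is tiny — influx
rate constants on the order of 10⁻⁴–10⁻³ min⁻¹ — so a sensitive protocol
trades dense temporal sampling for a long acquisition window: a short
dynamic series for a few minutes after a compact gadolinium bolus, plus two
late quantitative T1 maps, the last roughly 25 minutes after injection. This
package implements the full downstream analysis of such a protocol:

1. **Relaxometry** — convert pre/post-contrast T1 maps (ms) or
   baseline-normalized dynamic signals to gadolinium concentration via
   `C = (1/T1_post − 1/T1_pre)/r1`, and whole-blood to plasma concentration
   via `C_p = C_b/(1 − Hct)`.
2. **Patlak graphical analysis** — per voxel, plot
   `y(t) = C_t(t)/C_p(t)` against `x(t) = ∫₀ᵗ C_p dτ / C_p(t)`; for an
   irreversible-uptake tissue the points fall on a line whose slope is the
   leakage rate **Ki** (min⁻¹) and whose intercept is the plasma volume
   fraction **vp**. Ordinary least squares per voxel yields the leakage maps.
3. **ROI summaries** — mean Ki and vp over tissue ROIs (total GM, total WM,
   cortical GM, deep GM, plus user-supplied parcels) with an outlier
   correction that retains values inside the central 95% of each ROI's own
   distribution.
4. **Clinical scores** — blood-pressure summarization (mean of the last five
   repeated measurements), hypertension classification (SBP ≥ 135 or
   DBP ≥ 85 mm Hg or antihypertensive medication), subgroup assignment
   (NT / CHT / UHT− / UHT+), PVS grading and the 0–4 global cSVD burden
   score.
5. **Cohort statistics** — multivariable linear regressions of standardized
   Ki/vp on hypertension status and on SBP/DBP/MAP, adjusted for age and sex
   with one-at-a-time covariate rotation; subject outlier exclusion
   (|deleted studentized residual| > 3.5 AND Cook's distance > 1); subgroup
   ANOVA with Tukey post hoc tests; pooled CHT-vs-UHT comparison.
6. **Synthetic data** — digital phantoms, vascular input functions and full
   cohorts with known ground truth, so that every stage is testable without
   patient data.

It is written for imaging scientists and statisticians who need a tested,
reproducible reference implementation of this analysis chain, or a
ground-truth simulation environment to plan similar studies.

## Worked example

```r
library(bbbleak)

# a 10x10x10 digital phantom on the sparse schedule, with measurement noise
sched <- default_schedule()
ph    <- simulate_phantom(sched, shape = c(10, 10, 10), seed = 1)
maps  <- fit_patlak_volume(ph$concentration, ph$vif, mask = ph$labels > 0)
maps
#> <leakage_maps> grid 10x10x10; 1000 valid fits; median Ki 0.000994 min^-1, median vp 0.02

summarize_rois(maps, ph$labels)[, c("roi", "mean_ki", "mean_vp", "n_total")]
#>           roi  mean_ki mean_vp n_total
#> 1    total_gm 0.001209  0.0221     700
#> 2    total_wm 0.000398  0.0100     300
#> 3 cortical_gm 0.001494  0.0250     300
#> 4     deep_gm 0.000999  0.0200     400
```

The trimmed ROI means recover the generating truths (cortical GM Ki
1.5 × 10⁻³, deep GM 1.0 × 10⁻³, WM 4 × 10⁻⁴ min⁻¹; vp 2.5 / 2.0 / 1.0%)
to well within the per-voxel noise.

```r
# a 41-subject cohort (19 NT / 12 CHT / 5 UHT- / 5 UHT+) with a planted
# MAP -> Ki slope in cortical grey matter only
sim <- simulate_cohort(cohort_config(seed = 1))
rep <- run_full_analysis(sim$cohort, sim$roi)
r   <- rep$regressions
r[r$rotation == "none" & r$exposure == "map" & r$measure == "ki",
  c("roi", "beta_std", "p_value", "n_used", "significant")]
#>             roi beta_std  p_value n_used significant
#> 25  cortical_gm   0.6254 1.67e-05     41        TRUE
#> 57      deep_gm   0.0669 6.73e-01     41       FALSE
#> 89     total_gm   0.6590 3.98e-06     41        TRUE
#> 121    total_wm  -0.0534 7.15e-01     41       FALSE
```

`beta_std` is the standardized exposure coefficient: the planted cortical
effect (and its echo in total GM, which contains cortical GM) is detected;
deep GM and WM, where nothing was planted, are null. The subgroup section of
the report carries the ANOVA/Tukey tables and the pooled comparison:

```r
rep$subgroup[["cortical_gm.ki"]]$pooled_uht
#> t = -3.75, p = 0.0013, direction "CHT lower"
```

— medically controlled subjects show lower leakage than the pooled
uncontrolled groups, as the generator's pressure effect implies.

A thin command-line wrapper over the same functions is installed at
`inst/cli/bbbleak` (subcommands `simulate-phantom`, `simulate-cohort`,
`concentration`, `fit-patlak`, `roi-stats`, `score-cohort`, `analyze`).

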
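# mbrfit

Automated growth-rate determination from high-throughput microbioreactor
backscatter time series.

Microbioreactor systems (e.g. the 48-well BioLector) record a backscatter
(BS) signal as an online biomass proxy every few minutes for dozens of
parallel cultivations. The maximum specific growth rate μ — the key
biological-fitness metric in strain screening — must be fitted on the
*exponential* part of each curve only, and finding that window by hand does
not scale and is not reproducible.

mbrfit automates the whole chain, per well:

1. **Blank & error** — the blank is the mean of the pre-growth readings and
   the additive measurement error σ their standard deviation (fixed-count or
   adaptive below-LOD prefix).
2. **Blanking** — readings minus blank, with propagated constant error
   δ = √(σ² + σ²/n_pre).
3. **LOQ** — fitting starts where the blanked signal first exceeds the
   user-defined limit of quantification.
4. **Exponential-phase detection** — starting from the full curve tail, the
   last measurement is removed iteratively until three criteria hold:
   adjusted R² of the fit > 0.99, the last biomass increase exceeds the
   previous one, and neither increase is negative.
5. **Rate** — weighted linear regression of ln(biomass) on time
   (weights (c_X/δ)², i.e. inverse squared transformed errors), slope = μ
   in 1/h with a Student-t 95% CI; a weighted non-linear fit of
   c(t) = c₀·e^(μt) serves as cross-check.

Plate-scale batch processing, replicate aggregation, comparison against
reference rates (Dev[%] = |1 − μ_auto/μ_ref|·100), result CSVs, diagnostic
plots, and a synthetic growth-curve simulator with known ground truth
(lag / exponential / diauxic / stationary phases, additive Gaussian noise)
are included. Everything is deterministic given the input and seeds.

## Worked example

Single well — simulate a *C. glutamicum*-like batch (0.46 1/h between 15 h
and 24 h, 9-min cycles, additive noise 0.4 a.u.), then recover the rate:

```r
library(mbrfit)

curve   <- simulate_curve(curve_spec(seed = 42))
blanked <- apply_blank(curve, policy = "adaptive")
det     <- detect_growth(blanked, loq = 4, nlr = TRUE)
det
#> <mbr_detection> converged after 41 trailing-point removals
#>   window: cycles 131-160 (19.50-23.85 h), 30 points
#> <mbr_fit WLR>  mu = 0.4654 1/h  (95% CI 0.4564-0.4745)  adj R2 = 0.9974  n = 30
#> <mbr_fit NLR>  mu = 0.4664 1/h  (95% CI 0.4573-0.4754)  adj R2 = 0.9981  n = 30
```

The detection converged: 41 trailing (stationary-phase) measurements were
removed, the accepted window covers the exponential phase (19.5–23.85 h),
and the weighted linear and non-linear estimates agree within 0.3% — the
true rate 0.46 lies inside both CIs. `tidy(det)` returns the per-iteration
criteria trace, `glance(det)` a one-row summary, `autoplot(det)` the
annotated curve.

Whole plate with replicate groups and a literature comparison:

```r
sim <- simulate_plate(6, list(
  wildtype = curve_spec(),
  mutant   = curve_spec(mu1 = 0.30, t_phase1_end = 29, t_total = 32)), seed = 7)

res <- process_plate(sim$plate, loq = 4, blank_policy = "adaptive")
res[, c("well_id", "strain", "status", "mu", "ci_low", "ci_high")]
#>   well_id strain   status    mu ci_low ci_high
#> 1 A01     wildtype ok     0.469  0.457   0.480
#> 2 A02     mutant   ok     0.298  0.293   0.303
#> 3 A03     wildtype ok     0.459  0.447   0.471
#> 4 A04     mutant   ok     0.297  0.291   0.303
#> 5 A05     wildtype ok     0.461  0.450   0.471
#> 6 A06     mutant   ok     0.294  0.288   0.299

aggregate_replicates(res, reference = tibble::tibble(
  strain = c("wildtype", "mutant"), mu_lit = c(0.43, 0.32)))
#>   strain   n_replicates mu_mean   mu_sd mu_mean_2dp status mu_lit dev_pct
#> 1 mutant              3   0.296 0.00203        0.3  ok       0.32    7.42
#> 2 wildtype            3   0.463 0.00526        0.46 ok       0.43    7.61
```

Each replicate's rate is recovered near its truth (0.46 / 0.30), replicate
means are reported at full precision with a two-decimal presentation
column, and `dev_pct` is the percent deviation from the supplied reference
rates.

The bundled panel of 23 genome-reduced *C. glutamicum* strains compares
automated against manually evaluated rates:

```r
panel <- cglutamicum_panel()
sum(deviation_percent(panel$mu_auto, panel$mu_lit) <= 10)
#> [1] 13
```

## Command line

A thin wrapper over the same functions lives in `inst/cli/mbrfit.R`:

```sh
Rscript inst/cli/mbrfit.R simulate --out plate.csv --n-wells 48 --seed 1
Rscript inst/cli/mbrfit.R fit     --input plate.csv --well A01 --loq 4
Rscript inst/cli/mbrfit.R plate   --input plate.csv --loq 4 --out results/
```

Exit codes: 0 converged, 2 bad input, 3 no exponential phase. Input
dialects: wide CSV (`time_h` column plus one column per well) and
BioLector-style spreadsheets (`--dialect biolector_xlsx`).

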
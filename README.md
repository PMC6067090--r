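# halleymort

Halley-pooled mortality age trajectories and congenital-risk frailty models.

## The problem

After birth, human mortality falls by three to four orders of magnitude
before reaching its lifetime minimum around age 10 — far faster than it
later rises in old age.  `halleymort` is for epidemiologists and
demographers who want to trace and model that decline in cause-of-death
data.  It builds age-specific mortality trajectories from WHO Mortality
Database ICD-10 flat files by **Halley pooling** — summing deaths and
populations over many countries and calendar years into one "large
population", so that rare-cause, old-age cells contain non-zero counts —
and fits two parametric laws to the force of mortality μ(x):

* the **inverse proportion** μ(x) = μ₁/x (log–log slope −1), fitted through
  a model ladder: quadratic log–log fit (curvature test), linear fit (slope
  γ with 95% CI, R², adjusted R̄², test of γ = −1), and the slope-fixed
  one-parameter fit with closed-form scale estimator
  ln μ₁ = mean(ln μᵢ + ln xᵢ) and bespoke coefficient of determination
  R_b² = 1 − SS_resid/SS_total, compared by nested F tests;
* the **bent curve** μ(x) = μ₁(1 − e^(−r_max·x))/x implied by a truncated
  reciprocal (log-uniform) distribution f(r) ≅ c/r of fixed congenital
  individual risk: flat below ~1/r_max years, inverse-proportional above,
  fitted by deterministic log-scale RSS minimisation.

A bundled cohort microsimulator generates data under exactly that
generative model (log-uniform risks, exponential lifetimes, WHO-dialect
tabulation with detailed infant age intervals) and closes the loop with
parameter-recovery experiments.  Extreme-age summaries (first-day rate,
lifetime minimum, [90,95)-year rate, and their ratios) round out the
pipeline.

## Worked example

Simulate a rare-cause cohort under the congenital-risk model — 5% of a
million births carry a log-uniform risk with upper limit r_max = 2.9/yr —
run it through tabulation, pooling and every fit:

```r
library(halleymort)
cfg <- simulation_config(n = 1e6, r_min = 1e-8, r_max = 2.9,
                         carrier_fraction = 0.05, seed = 42)
rep <- recovery_experiment(cfg, window = c(0, 10))
print(rep)
#> Recovery experiment (reciprocal risks, n = 1000000 x 1 cell(s), seed 42)
#>   deaths pooled below 95 y: 16062
#>   gamma_hat = -0.3654, 95% CI (-0.5170, -0.2137), covers -1: FALSE
#>   Rb2 (inverse proportion) = -1.6593; quadratic delta = -0.0753 (p = 0.00038)
#>   bent curve: mu1 = 26549, r_max = 3.043 (rel. error +4.9%)
```

Read: with r_max = 2.9 the trajectory is *bent* — flat below
1/r_max ≈ 0.34 years — so over [0, 10) it is nowhere near an inverse
proportion (slope −0.37, negative R_b², significant curvature), yet the
two-parameter bent-curve fit recovers the generative r_max to within 5%.
Re-running with risks far above 1/x across the window (say r_max = 1e4)
flips the verdict: slope within a few percent of −1 and R_b² above 0.99 —
the two regimes the model predicts.

The package also reproduces published distributional summaries of the
extreme-age ratios (first-day/minimum and old-age/minimum) for nine
European countries:

```r
print(ratio_summary(eu9_extreme_reference()))
#> Extreme-age ratio summary over 18 country-years
#>   Ratio A (first day / minimum): mean 5236, SD 1745
#>   Ratio B ([90,95) / minimum):   mean 2416, SD 1146
#>   normality (ks): p_A = 0.259, p_B = 0.223
#>   one-sided paired t (mean B < mean A): p = 5.97e-06
```

The childhood decline (Ratio A) is significantly larger than the old-age
rise (Ratio B): p < 0.0001.

To analyse real WHO extracts, point `run_pipeline()` at the files:

```r
run_pipeline(list(deaths = "Morticd10_part1.txt",
                  population = "census_population.csv",
                  causes = "Q00-Q07"),
             output_dir = "reports")
```

which writes the rate table, the upper-age model-ladder sweep, the
bent-curve fit, per-country-year extremes and plot-ready trajectory tables
as tab-separated files.

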
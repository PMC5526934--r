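# caribouViability

Demographic viability analysis of boreal caribou (*Rangifer tarandus
caribou*) under landscape disturbance, for wildlife biologists and
land-management analysts working with the two data streams these programmes
actually produce: GPS-collar telemetry of adult females and late-winter
aerial classification surveys.

The package takes both streams through the full analysis:

1. **Survival** — annual adult-female survival per population and
   biological year (1 April–31 March) by the staggered-entry Kaplan–Meier
   estimator, S&#770; = ∏(1 − d&#8348;/n&#8348;), with right-censoring at the
   last known-alive location and a ≥ 6 monitored-females filter.
2. **Recruitment** — calf per adult-female ratios from survey counts, with
   unclassified adults apportioned by the observed sex ratio when < 10% are
   unclassified and by a 65/35 female/male assumption otherwise, a ≥ 50
   individuals filter, and the *previous* year's disturbance attached to
   each survey.
3. **Vital-rate models** — weighted binomial mixed models (logit link,
   population random intercept, `lme4`):
   logit(S) = β₀ + β_D·D + β_P·P and
   logit(R) = β₀ + β_D·D₍t−1₎ + β_{P²}·P², where `D` is the proportion of
   the range disturbed and `P` the proportion of potentially productive
   forest stands. Coefficient intervals come from a parametric bootstrap.
4. **Viability** — the finite annual rate of change of the female segment,
   λ_f = S_f / (1 − R_f) with R_f = (R/2)/(1 + R/2), the withstand
   threshold D\*(P) solving λ_f = 1, and a 95%-confidence lower limit from
   10,000 coefficient simulations.
5. **Succession** — stand height/canopy development (OLS with age²,
   productivity and their interaction) and the post-disturbance deciduous
   pulse (penalized-spline GAM), with the treed/vegetated cover
   corrections.
6. **Synthetic data** — a generator that emulates all four input tables
   with the statistical structure the pipeline assumes, so everything runs
   and is testable with no field data.

## Worked example

Build the vital-rate models from known logit-scale coefficients (here the
published estimates) and ask what a landscape disturbed over 35% of its
area means for a herd:

```r
library(caribouViability)

surv <- vital_rate_model("survival",    beta = c(1.67, -0.77, 1.22),
                         se = c(0.29, 0.29, 0.54))
rec  <- vital_rate_model("recruitment", beta = c(-0.15, -5.05, 2.41),
                         se = c(0.59, 0.14, 1.22))

predict_rate(rec, D = 0.35, P = 0.21)   # 0.140  calves per female
predict_rate(rec, D = 0.35, P = 0.85)   # 0.456
lambda_f(predict_rate(surv, 0.35, 0.21), predict_rate(rec, 0.35, 0.21))  # 0.899
lambda_f(predict_rate(surv, 0.35, 0.85), predict_rate(rec, 0.35, 0.85))  # 1.129

for (p in c(0.21, 0.5, 0.85)) {
  d_mean <- mean_threshold(surv, rec, p)
  d_95   <- confident_threshold(surv, rec, p, n_sim = 10000, seed = 1)
  cat(sprintf("P = %.2f : D*_mean = %.3f, D*_95 = %.3f\n",
              p, as.numeric(d_mean), d_95))
}
#> P = 0.21 : D*_mean = 0.137, D*_95 = 0.000
#> P = 0.50 : D*_mean = 0.299, D*_95 = 0.060
#> P = 0.85 : D*_mean = 0.579, D*_95 = 0.214
```

Read: at 35% disturbance a low-productivity range (P = 0.21) produces only
0.14 calves per female and a declining female segment (λ_f ≈ 0.90), while a
highly productive range (P = 0.85) still grows (λ_f ≈ 1.13). The
point-estimate withstand threshold rises from ~14% to ~58% disturbance
across that productivity span; demanding 95% confidence of at least
stability lowers those limits to 0% and ~21%.

The same machinery runs end to end from raw tables (or fully synthetic
data) with one call:

```r
cfg <- pipeline_config(out_dir = "run1", generator = generator_config(),
                       seed = 1)
report <- run_pipeline(cfg)   # writes CSV/TSV/JSON artefacts + filter log
plot(report$viability)
```

Identical configuration and seed give byte-identical outputs. See the
methods vignette (`vignettes/caribou-viability-methods.Rmd`) for the model
assumptions, numerical choices and known limitations.

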
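# lipokin

Lipoprotein metabolism indicators for cardiovascular risk prediction.

ApoB-containing lipoproteins (VLDL, IDL, LDL) are produced by the liver,
shrink through lipolysis by lipoprotein lipase (LPL, extrahepatic) and
hepatic lipase (HL), attach to the liver and are taken up. A measured
particle-size profile — an NMR-style table of subclass concentrations —
implicitly records the balance of these processes. `lipokin` inverts a
steady-state population-balance model of the size distribution to recover
the process rates behind a single profile, reduces them to dimensionless
**lipoprotein metabolism indicators**, and asks whether two of them improve
ten-year cardiovascular risk prediction over conventional risk factors.

## The model

Particle concentrations `c_i` on a discrete size grid (largest bin `n`)
satisfy the steady-state balance

```
(lambda_i + a_i) c_i = P_i + lambda_{i+1} c_{i+1}
```

where `P_i` is the hepatic production flux into bin `i` (log-normal in
diameter), `lambda_i = k_lpl f_L(d_i) + k_hl f_H(d_i)` is the lipolysis
rate (one-bin shrink per event; LPL acts on large, HL on small particles)
and `a_i = k_att g(d_i)` the liver-attachment rate. The solution follows by
downward recursion from the largest bin. Fitting the model to an observed
subclass profile (sum of squared relative residuals, multi-start L-BFGS-B
over log-parameters) recovers the canonical rate constants, from which all
process fluxes over the three class ranges (VLDL–LDL, VLDL only, IDL–LDL)
and their 45 pairwise ratios follow. The two named indicators are

* `VLDL_E` — the VLDL LPL-lipolysis flux divided by the particle influx
  into the VLDL range (extrahepatic lipolysis per incoming particle);
* `VLDL_H` — the average of the mean HL rate constant over VLDL and the
  VLDL liver-attachment flux, each divided by the VLDL production flux
  (hepatic turnover per produced particle).

Both are invariant to the overall scale non-identifiability of a
steady-state fit.

Downstream, a squared-hinge (L2-norm) Gaussian-kernel SVM risk score is
built by a grouped forward-selection protocol (six classical risk
variables with age and sex forced, two cholesterol markers, then
indicators that add test-split AUC and pass an r² < 0.25 collinearity
screen), Platt-calibrated to probabilities, and compared across nested
models with DeLong tests, net reclassification improvement (NRI, 6%/20%
cutoffs), integrated discrimination improvement (IDI) and an
intermediate-risk subgroup analysis. A fully synthetic cohort generator
(Framingham-style marginals, configurable logistic outcome model with a
~7.3% ten-year event rate in which low `VLDL_E`/`VLDL_H` raise risk)
makes every stage testable without restricted data.

## Worked example

```r
library(lipokin)
g <- size_grid()                                   # 60 log bins, 19-80 nm
truth <- kinetic_params(f_prod_total = 17, prod_mu = 45, prod_sigma = 0.3,
                        k_lpl = 1.5, k_hl = 0.01, k_att = 0.005)
obs <- simulate_observed_profile(truth, g, noise_cv = 0.08, seed = 42)
obs
#> Particle profile (nmol/L):
#>   ldl_small  ldl_medium   ldl_large         idl  vldl_small vldl_medium
#>    626.0607    684.4276    457.7661    847.1900    208.5855    122.7875
#>  vldl_large
#>      9.5251

fit <- fit_kinetics(obs)
fit
#> Kinetic model fit (canonical, f_prod_total = 1)
#> f_prod_total      prod_mu   prod_sigma        k_lpl         k_hl        k_att
#>    1.000e+00    4.201e+01    3.718e-01    7.683e-02    1.136e-03    2.456e-04
#>        k_upt
#>    2.456e-04
#> objective 0.00327  (start 3, 7/10 starts converged)
```

The fitted rates are the true ones divided by the true production flux
(canonical form): e.g. `k_lpl` 0.0768 vs 1.5/17 = 0.088, recovered through
8% measurement noise. Indicators follow directly:

```r
indicator_set(fit$params, grid = g)
#> VLDL_E = 19.68   VLDL_H = 0.04755
#> 45 process-pair ratios ( 0 undefined )
```

Evaluation statistics use the same conventions as the published tables —
for instance a two-sided z-test from an AUC difference and its standard
error:

```r
roc_auc(c(0.8, 0.6, 0.6, 0.5), c(1, 1, 0, 0))
#> AUC 0.8750 (SE 0.1768), improvement from random 0.3750
round(delong_ztest(0.0177, 0.00637)$p, 4)
#> [1] 0.0055
```

An end-to-end synthetic analysis — generate a cohort, fit every profile,
select markers, write the four comparison tables — is one call:

```r
res <- run_pipeline(pipeline_config(out_dir = "out", seed = 1,
                                    n_subjects = 2000))
```

or, from a shell, `inst/exec/lipokin run-all --seed 1 --out-dir out` (the
subcommands `simulate-cohort`, `fit-profiles`, `compute-indicators`,
`select-markers`, `evaluate` run the stages separately).

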
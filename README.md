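# impbench

Missing values are routinely filled in ("imputed") before a dataset is
analysed, and imputation methods are almost always validated under ideal
conditions. `impbench` is for the other case: it measures how imputation
quality degrades when the data contain **high-leverage outliers** or
**misclassified categories** — the situations a data producer actually
faces. It is aimed at biostatisticians and survey methodologists who need
to choose (or defend) an imputation method for contaminated real-world
data.

The package provides, as one framework:

- a mixed-type data model (continuous / semi-continuous / binary /
  categorical / count columns, CSV + YAML schema on disk) with strict
  missingness bookkeeping;
- two synthetic study populations — a bivariate Gaussian (AGE, INCOME)
  population with rank-MAR missingness in INCOME and four-corner leverage
  outliers, and a lognormal energy-consumption model
  `energy = exp(2 + I(type=1) − 0.1·log(runtime) + ε)` with flipped type
  labels — plus MCD-based robust outlier flagging and MCAR/MAR amputation
  that protects contaminated rows;
- nine imputers: mean/median/mode, random hotdeck, Gower-distance kNN,
  predictive mean matching (Bayesian regression, type-2 matching),
  midastouch (donor sampling with probability `ω_i d_ij^{−κ}`,
  `κ(R²) = (50R²/(1+δ−R²))^{3/8}`), robust chained regression (IRMI, MM
  estimators per response scale), iterative random forests, and
  bootstrap boosted trees with predictive mean matching;
- evaluation statistics: MAPE, NRMSE (variance-standardized at the scored
  cells), correlation distortion `‖R−R̃‖_F/(D−1)`, false classification
  rate, PCA-loading differences, estimator bias/variance/RMSE, coverage
  rates, Rubin's rules with `T = W̄ + (1+1/m)B`, accuracy and F1;
- config-driven study harnesses with common random numbers, so method
  contrasts are paired and every printed aggregate is recomputable from
  the emitted per-replicate table.

## Worked example

Simulate the income population, plant 40 leverage outliers, ampute 30% of
the incomes of the clean rows (missingness increasing with AGE), impute
with four methods, and estimate the mean income with a 95% interval:

```r
library(impbench)
cfg <- study_config("income_outliers",
                    methods = c("complete_case", "knn", "pmm", "irmi"),
                    contamination = c(0, 40), replications = 100, m = 5, seed = 7)
res <- run_outlier_study(cfg)
res
#> study_result (income_outliers): 100 replicates, methods: complete_case, knn, pmm, irmi
#>          method contamination        bias  variance     rmse coverage
#> 1 complete_case             0 -2.80672720  1.837426 3.116912     0.48
#> 2           knn             0  0.05123211  1.686450 1.299644     0.96
#> 3           pmm             0  0.04276511  1.650254 1.285334     0.98
#> 4          irmi             0  0.11022816  1.711745 1.312972     0.97
#> 5 complete_case            40 -2.73447063  2.428036 3.147279     0.64
#> 6           knn            40 -0.06184503 16.922600 4.114174     0.76
#> 7           pmm            40 -0.03174462 18.853533 4.342182     0.88
#> 8          irmi            40  0.14119796  2.287113 1.518898     1.00
```

Reading the table: the true mean income is 1500. With no contamination
(`contamination = 0`), the three imputers are unbiased with RMSE ≈ 1.3 and
near-nominal coverage, while the complete-case mean is biased (−2.8)
because dropping MAR-missing rows removes mostly high-age, high-income
cases. With 40 outliers, the RMSE of kNN and PMM roughly triples (the
outliers corrupt their donor models), whereas robust IRMI barely moves
(1.31 → 1.52) and keeps full coverage — the headline result the framework
is built to measure.

A command-line wrapper for ad-hoc use lives at `inst/cli/impbench.R`
(subcommands `simulate`, `impute`, `evaluate`, `study`).

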
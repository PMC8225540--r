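# covscreen

Machine-learning covariate screening for population pharmacokinetic (PopPK)
models, packaged as a fully self-contained simulation benchmark.

## The problem

Covariate model building is one of the slowest steps of population PK
analysis: stepwise covariate modeling (SCM) refits a nonlinear mixed-effects
(NLME) model for every candidate covariate-parameter relationship in every
forward/backward round. A much cheaper alternative is to (1) fit only the
covariate-free *base* model, (2) extract each subject's empirical Bayes
estimate (EBE) of clearance, and (3) let a machine-learning regressor predict
those clearance EBEs from all candidate covariates, ranking covariates by
permutation importance. `covscreen` implements both routes and the simulation
machinery to compare them.

The true model is a one-compartment oral PK model with first-order
absorption, linear elimination and bioavailability 1:

    C(t) = D*ka / (V*ka - CL) * (exp(-CL/V * t) - exp(-ka * t))

with log-normal inter-individual variability on V, CL and ka
(`V_i = V_pop*exp(eta_1)`, etc.; omega^2 = 0.2, 0.2, 0.3), exponential
residual error (sigma^2 = 0.15), population values `V = 10 L`, `CL = 1 L/h`,
`ka = 1 1/h`, and covariate effects on clearance only:

    CL_i = CL_pop * exp(eta_2) * prod(1 + CAT_i*beta1) * prod((COT_i/med(COT))^beta2)

(linear effects for binary categorical covariates, power for continuous).
Benchmark scenarios cross six covariate configurations (1-4 true and 2-15
false covariates) with two effect-size bands (<20% / >40%) and three
correlation bands (<0.3 / 0.3-0.6 / >0.6) for 36 scenarios, plus two
sparse-sampling scenarios (7a, 7b) with only 2-3 observations per subject
that sharply raise the EBE eta-shrinkage `1 - sd(eta_hat)/omega`.

What the package provides:

* **scenarios/simulate** - scenario grid, correlated covariate generation
  (Gaussian copula, log-normal margins), effect-size calibration, and
  NONMEM-style dataset simulation/IO (`build_scenario_grid()`,
  `simulate_dataset()`, `write_dataset()`).
* **nlme** - from-scratch Laplace-approximation NLME estimation with an
  Rcpp core (`fit_population()`), clearance EBEs and eta-shrinkage
  (`compute_ebes()`, `eta_shrinkage()`), likelihood-ratio tests
  (`lrt_pvalue()`).
* **screening** - random-forest, linear/RBF support-vector, and
  two-hidden-layer neural-network regressors with scenario-level
  hyper-parameter grid search and normalized permutation importance
  (`screen_covariates()`, `permutation_importance()`).
* **selection** - top-M, order-of-importance, and minimum-of-importance
  selection rules, accuracy-maximizing threshold calibration, and a full
  SCM comparator with forward inclusion (p < 0.05) and backward elimination
  (p > 0.01) over linear/power/exponential/piecewise forms (`scm_search()`).
* **evaluate** - confusion counts under both true-positive definitions,
  F1/accuracy, pooled ROC curves and AUROC with qualitative bands
  (`roc_curve()`, `f1_score()`).
* **pipeline** - end-to-end orchestration with deterministic per-stage seed
  derivation (`run_scenario()`, `run_benchmark()`), plus a thin CLI at
  `inst/cli/covscreen.R`.

## Worked example

```r
library(covscreen)

grid <- build_scenario_grid()
names(grid) <- sapply(grid, `[[`, "name")
spec <- grid[["2b"]]          # 1 true CAT + 1 true COT, high effects

res <- run_scenario(spec, methods = "rf",
                    approaches = c("top_m", "order"),
                    n_replicates = 5, master_seed = 101)
res
#> <scenario_result 2b> 5 replicates (5 converged)
#>   mean CL shrinkage: 6.3%
#>   rf         AUROC 1.000; mean F1 top_m=1.00 order=1.00
```

Reading: across 5 simulated populations of 100 subjects, the random-forest
importance ranking separates the two true covariates from the two false ones
perfectly (pooled AUROC 1.0), and both the top-M rule (M = number of true
covariates) and the order-of-importance rule recover exactly the true
covariate set (mean F1 = 1). The base-model clearance EBEs carry ~6%
eta-shrinkage under the standard 5-time sampling design.

One replicate's importance table:

```r
res$results$rf$scores[[1]]
#>   covariate     raw_diff       score
#> 1      CAT1  0.317355213 0.233144155
#> 2      COT1  1.039294601 0.763514987
#> 3      CAF1  0.004547568 0.003340858
#> 4      COF1 -0.023565561 0.000000000
```

The two true covariates absorb >99% of the normalized importance.

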
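# svyord

Survey-weighted ordinal regression under outcome-dependent sampling (ODS).

When an expensive exposure can only be measured on a subsample drawn *by
outcome category* — `n_k` of the `N_k` cohort members with `Y = k`, the
ordinal generalization of a case-control study — standard ordinal
regression is no longer innocuous: whether unweighted maximum likelihood
still estimates the cohort slopes depends on which ordinal logit you
model. svyord implements the four standard families

| family | model |
|---|---|
| `sm` | stereotype: `ln(pi_{K+1-j}/pi_1) = alpha_j + phi_j beta'x`, scores `phi` estimated, `phi_1 = 1`, `phi_K = 0` |
| `ac` | adjacent-category logit: `ln(pi_{k+1}/pi_k) = alpha_k + beta'x` |
| `cr` | continuation-ratio logit: `logit Pr(Y > k | Y >= k) = alpha_k + beta'x` |
| `cm` | cumulative logit (proportional odds): `logit Pr(Y <= k) = alpha_k + beta'x` |

and, for each:

* unweighted ML and inverse-sampling-fraction **weighted pseudo-likelihood**
  fits (`ord_fit`), by damped Newton on analytic scores/information;
* **design-based standard errors** by influence-function linearization
  (`design_cov`), plus delta-method inference for the stereotype products
  `phi_k * beta_j` (`delta_phi_beta`);
* the analytic ODS results: Bayes-reweighted sampled-data probabilities
  (`sampled_probs`), the SM/AC intercept-offset representation
  (`sampled_intercepts`, offsets `ln` of sampling-fraction ratios, slopes
  and scores untouched — hence unweighted SM/AC slopes are consistent
  under ODS), and the CR equal-upper-fractions special case
  (`cr_special_case_check`);
* a **Monte Carlo engine** (`ods_scenario`, `calibrate_truth`,
  `run_study`) that generates cohorts from a latent ordinal probit model,
  calibrates per-family true parameters by ML projection on a 10^6-row
  cohort, replicates cohort → ODS sample → fit, and reports RB
  (percent mean relative bias), RE (percent relative error of reported
  SEs versus the empirical SD), ESE, and RRMSE (weighted/unweighted RMSE
  ratio).

## Worked example

80% of the cohort in the lowest category (scenario L5), cumulative-logit
model, 200 replicates of cohort (N = 10,000) → ODS (80 per category) →
unweighted and weighted fits:

```r
library(svyord)
sc    <- ods_scenario("L5", K = 5)
truth <- calibrate_truth(sc, families = "cm", M = 3e5, seed = 20240901)
study <- run_study(sc, ord_family("cm", 5, 2), truth$params$cm,
                   R = 200, seed = 11)
summary(study)
#>    param  truth   RB_u  RE_u ESE_u RB_w   RE_w ESE_w RRMSE
#> 1 alpha1  1.980 -147.6 10.86 0.211 2.15 -1.318 0.303 0.104
#> 2 alpha2  2.356  -96.2  3.34 0.220 2.01 -2.503 0.309 0.137
#> 3 alpha3  2.836  -67.1  1.73 0.227 1.85 -2.587 0.314 0.166
#> 4 alpha4  3.607  -46.2  5.30 0.233 1.53 -0.732 0.321 0.193
#> 5  beta1 -1.813  -33.3 -5.61 0.345 5.80 -7.454 0.523 0.765
#> 6  beta2  0.881  -33.3 -4.46 0.196 1.50 -2.501 0.277 0.787
```

Reading: unweighted cumulative-logit slopes are biased toward zero by
about a third (`RB_u` ≈ −33%) and the intercepts are badly distorted;
the weighted fit removes the bias (`RB_w` a few percent, within Monte
Carlo error at R = 200), its design-based SEs track the empirical SD
(`RE_w` small), and `RRMSE < 1` shows the weighted estimator also wins
on root mean squared error in this skewed design. (The truth column was
calibrated at M = 3e5 here; the full-scale run uses M = 1e6.)

Single fits work on plain data too:

```r
dat <- read_ordinal_table("cohort.csv", outcome_col = "grade",
                          covariate_cols = c("x1", "x2"), weight_col = "w")
fit <- ord_fit(ord_family("cm", K = dat$K, p = dat$p), dat)
design_cov(fit, dat)          # model- and design-based SEs
```

Command-line entry points (`cli_fit`, `cli_simulate`, `cli_calibrate`)
write full-precision JSON/CSV artifacts with the seed and configuration
embedded, e.g.

```sh
Rscript -e 'svyord::cli_simulate()' --scenario L5 --K 5 --family cm \
  --reps 200 --seed 11 --out results/
```

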
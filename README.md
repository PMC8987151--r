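# kmsacohort

Survival-adjusted burden-of-illness analysis for matched administrative-claims
cohorts.

## The problem

When an exposure kills — hyperkalemia (serum K⁺ > 5.0 mmol/L) in new-onset
chronic kidney disease is the motivating case — the exposed cohort's shorter
survival contaminates any naive annual cost comparison: excluding decedents
selects the healthy, and dividing by observed follow-up divides by a quantity
the exposure itself shortened. kmsacohort implements the standard fix for
interval-partitioned cost data, the **Kaplan-Meier sample average (KMSA)**
estimator, inside a complete, reproducible claims pipeline for
epidemiologists and health-economics analysts:

1. new-onset cohort identification (ICD-10 prefix code sets, washout,
   age and continuous-enrollment rules),
2. two-stage matching — coarse 1:30 on sex / diagnosis year / age, then
   greedy 1:1 on the logit propensity score with a caliper — with
   standardized-difference balance diagnostics,
3. Kaplan-Meier, log-rank, and Cox proportional-hazards mortality analysis,
4. KMSA estimation of annual costs (six components × inpatient/outpatient)
   and healthcare resource use, with paired-bootstrap percentile CIs, and
5. two pair-level sensitivity analyses (malignancy exclusion,
   12-month survivors only).

The estimator: with follow-up cut into twelve 30-day intervals,

&nbsp;&nbsp;&nbsp;&nbsp;Ĉ = Σₖ Ŝ(30(k−1)) · C̄ₖ,

where Ŝ is the cohort's product-limit survival curve and C̄ₖ is the mean
outcome accrued in interval k among patients alive and enrolled at its start.
With no deaths, Ĉ reduces exactly to the plain mean of annual totals.

Because real claims of this kind are access-restricted, the package ships a
**synthetic claims generator** as a first-class module: enrollment spans with
a death mechanism, coded diagnoses and prescriptions, confounded cohort
membership, and a cost process with a sharp month-1 inpatient spike — with
closed-form ground truth (`truth_mean_annual_cost()`, true hazard ratio) so
the entire pipeline is validated by parameter recovery.

## Worked example

```r
library(kmsacohort)

cfg <- sim_config(n_patients = 3000, hk_fraction = 0.15, rng_seed = 11)
sim <- simulate_population(cfg)
report <- run_pipeline(
  sim$data,
  analysis_config(seed = 5,
                  bootstrap = bootstrap_config(n_iterations = 500, seed = 5)))
print(report)
#> <study_report>
#> # A tibble: 7 × 2
#>   step                        n
#>   <chr>                   <int>
#> 1 new_onset_ckd            2877
#> 2 hk_with_event             404
#> 3 non_hk_candidates        2473
#> 4 hk_enrollment_filtered    402
#> 5 coarse_pool_controls     2153
#> 6 hk_with_coarse_controls   402
#> 7 matched_pairs             402
#>   12m mortality: HK 41.3% vs control 11.4%, HR 4.41 [3.18, 6.11]
#>   annual cost (KMSA): HK ¥56785 [53466, 60273] vs control ¥20920 [19387, 22471]; diff ¥35865
#>   balance: 38/38 covariates |d| <= 0.10 post-match
```

Reading the output: of 3,000 simulated patients, 2,877 qualify as new-onset
CKD; 402 hyperkalemia members survive the enrollment filter and all match
1:1 to controls. Twelve-month mortality is 41.3% vs 11.4% (Cox HR 4.41,
95% CI 3.18–6.11 — the generator's true HR is 5), and the survival-weighted
annual cost difference is ¥35,865 against a closed-form generator truth of
¥57,188 − ¥20,500 = ¥36,688. All 38 matching covariates sit within the
|d| ≤ 0.10 balance convention after matching.

Pieces are ordinary tibbles: `report$kmsa` (one row per outcome with
per-cohort estimates, CIs and bootstrap p), `report$balance_pre` /
`report$balance_post`, `report$mortality`, `report$monthly`;
`tidy()` / `glance()` work on the fitted objects and
`autoplot(report$survival$km_hk)`, `plot_monthly_costs(report)`,
`plot_balance(report)` give the standard figures.

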
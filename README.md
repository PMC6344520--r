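# motionstack

Head motion during resting-state fMRI is not random: heavier subjects move
more, and many psychological characteristics correlate with motion too.
Because motion artifacts survive preprocessing and bias connectivity
estimates, knowing *which* subject characteristics predict motion — and
whether psychological predictors carry any signal beyond what they share
with physical ones — matters for anyone analyzing resting-state cohorts.
`motionstack` is an R package for that analysis: it computes per-scan
motion summaries from realignment parameters, estimates how much motion
variance a predictor set explains with a stacked machine-learning ensemble
inside repeated nested cross-validation, aggregates variable importance
across learners, and partitions explained variance by residualizing
psychological predictors on the physical block. A latent-factor synthetic
cohort generator provides ground-truth data for calibration and testing.

## The model in brief

* **Outcome**: `y = log(mean ENORM)`, where `ENORM_t = ||p_{t+1} - p_t||_2`
  over the six rigid-body realignment parameters (rotations in degrees,
  translations in mm, AFNI convention). Framewise displacement (the L1
  norm of the same differences) is computed alongside; the two subject-level
  means correlate > 0.99.
* **Learners**: elastic net, principal component regression, partial least
  squares, RBF support-vector regression, random forest, and a
  conditional-inference-style forest — each tuned by inner k-fold CV with
  random search and the one-standard-error rule.
* **Stacking**: prediction = Σ wᵢ · predᵢ with
  wᵢ ∝ max(R²ᵢ, 0), where R²ᵢ is learner i's inner-CV expected
  out-of-sample R² (squared correlation of observed and pooled
  cross-validated predictions).
* **Evaluation**: repeated nested CV; pooled outer-fold predictions give
  one R² per repeat; results are reported as mean ± 1.96·SD across
  repeats.
* **Variable importance**: learner-specific importances (standardized
  coefficients, permutation OOB-MSE increase, loess-filter R²), min–max
  scaled to 0–100 per learner, combined with the stacking weights.
* **Variance partitioning**: models are fit on physical, psychological,
  combined, and *residualized psychological* predictor sets (each
  psychological variable replaced by its OLS residual on the physical
  block).

See `vignettes/head-motion-stacking.Rmd` for assumptions, parameter
defaults, and design rationale.

## Worked example

```r
library(motionstack)

# a synthetic cohort with the default study conditions:
# 464 subjects, 15 physical + 105 psychological predictors,
# physical-block population R2 = 0.11
cohort <- generate_cohort(cohort_spec(seed = 1))

plan <- cv_plan(k_inner = 5, k_outer = 5, n_repeats = 5,
                n_search = c(ENET = 6, PCR = 6, PLS = 4, SVR = 4,
                             RF = 3, CF = 3),
                seed = 43,
                control = learner_control(num_trees = 100,
                                          max_components = 12))

table <- knn_impute(cohort$features, k = 5)
phys <- summarize_repeats(nested_cv(table, cohort$outcome, plan,
                                    subset = "physical"))
psy  <- summarize_repeats(nested_cv(table, cohort$outcome, plan,
                                    subset = "psychological"))
resid <- summarize_repeats(nested_cv(table, cohort$outcome, plan,
                                     subset = "residualized"))
print(phys); print(psy); print(resid)
```

Output from this exact configuration:

```
<study_summary> 5 repeats: R2 = 0.056 (95% CI 0.043 to 0.069)
top variables: body_water, weight, bmi, waist_hip_ratio, arm_impedance
<study_summary> 5 repeats: R2 = 0.022 (95% CI 0.009 to 0.036)
top variables: psych_drug_09, psych_drug_10, psych_drug_04, psych_drug_01, ...
<study_summary> 5 repeats: R2 = 0.001 (95% CI -0.002 to 0.003)
```

Reading: the physical block carries real predictive signal (this
particular cohort draw realizes a best-linear R² below its 0.11 population
target, and pooling predictions across outer folds is conservative — see
the vignette); the psychological block explains a clearly smaller but
non-null share; and after residualizing on the physical block its interval
straddles zero — the psychological signal is shared variance, which is the
phenomenon the pipeline is built to detect. The anchor variables (`weight`,
`bmi`) sit at the top of the stacked importance ranking, and the
drug-construct variables dominate the psychological model, mirroring the
expected structure.

Motion metrics from an AFNI-style `.1D` file:

```r
mp <- read_motion_params("subject01.1D")   # T x 6, '#' comments ignored
s <- summarize_motion(mp)
s$mean_enorm; s$mean_fd; s$log_mean_enorm
```

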
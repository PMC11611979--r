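# slowdcm

Effective-connectivity analysis of **motor fatigability** in the cortical
motor network.  Tapping as fast as possible for 30 s slows down reliably
("motor slowing"), yet BOLD activity in the primary sensorimotor cortex
(SM1), dorsal premotor cortex (PMd) and supplementary motor area (SMA)
*increases* while speed falls.  `slowdcm` asks which directed
interactions explain that pattern — in particular whether a release of
SM1 **self-inhibition** is required — using dynamic causal modelling
(DCM) end to end:

* the tapping paradigm's trial schedules, GLM regressors (with
  orthogonalized parametric modulators) and DCM inputs;
* a **two-state** neuronal model (excitatory + inhibitory population per
  region) obeying
  `ẋ = (A + Σ uⱼ B⁽ʲ⁾) x + C u`,
  with log-scaled rates so between-region connections stay excitatory
  and self-connections stay inhibitory, coupled to a balloon–Windkessel
  hemodynamic model (compiled RK4 integrator);
* **variational-Laplace inversion** per subject and model, returning MAP
  estimates and a free-energy approximation to log model evidence
  (exact for linear-Gaussian reductions);
* the **180-model space** in 8 families (top-down / bottom-up /
  selective premotor / null, each with and without SM1 self-modulation;
  36/36/12/6 models per self level);
* family-level **random-effects Bayesian model selection**, a 0.95
  decisiveness check, and **Bayesian model averaging** with an Occam's
  window of 0.05;
* group-level Bonferroni-corrected t-tests on the averaged modulatory
  parameters and a stepwise regression against each subject's
  behavioural slowing slope;
* a fully seeded **synthetic-cohort generator** (24 subjects, 2 runs ×
  360 volumes at TR 2.5 s by default) so every stage is testable from
  known ground truth.

See `vignettes/motor-slowing-dcm.Rmd` for the model equations, priors,
numerical choices and validation design.

## Worked example

```r
library(slowdcm)

cfg <- pipeline_config(n_subjects = 4, space = "reduced", seed = 3,
                       n_draws = 1e5, max_iter = 24,
                       design = design_config(n_runs = 1))
res <- run_pipeline(cfg)

round(res$bms$exceedance, 3)
#> bottom_up-selfSM1 bottom_up+selfSM1      null-selfSM1      null+selfSM1
#>             0.056             0.094             0.056             0.095
#> selective-selfSM1 selective+selfSM1  top_down-selfSM1  top_down+selfSM1
#>             0.192             0.171             0.145             0.191

res$decision$decisive
#> [1] FALSE

res$ttests[1:2, c("parameter", "mean", "t", "p_bonferroni")]
#>    parameter       mean         t p_bonferroni
#> 1 B:SMA->SM1  0.3290084  8.480125    0.0206581
#> 2 B:self-SM1 -0.2180357 -2.856025    0.3887267

round(res$behaviour$lmm$slope, 3)
#> [1] -0.111
```

Reading: with only 4 synthetic subjects no family reaches the 0.95
decisiveness threshold (the generating top-down + SM1-self family is
among the highest), so parameters are averaged over the whole space;
the averaged SMA→SM1 modulation and the negative SM1 self-modulation
are recovered, and tapping speed declines by ~0.11 normalized units per
10 s bin.  Larger cohorts sharpen all of this — `pipeline_config()`
defaults to 24 subjects and the full 180-model space.

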
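---
title: "Effective connectivity of motor slowing: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Effective connectivity of motor slowing: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific question

Tapping as fast as possible for 30 s produces a reliable decline in
tapping speed — *motor slowing*, an objective marker of performance
fatigability.  Paradoxically, BOLD activity in the primary sensorimotor
cortex (SM1), dorsal premotor cortex (PMd) and supplementary motor area
(SMA) *rises* while speed falls.  `slowdcm` implements a complete
effective-connectivity analysis of this phenomenon: a dynamic causal
model (DCM) of the SM1–PMd–SMA network driven by the tapping paradigm's
inputs, inverted per subject over a 180-model space, compared at the
family level, averaged across models, and related to the behavioural
slowing each subject shows.  Because the package is built around a
synthetic-cohort generator with known ground truth, every stage can be
validated by parameter- and family-recovery experiments rather than by
eyeballing.

## The generative model

### Neuronal dynamics

Neural activity follows the bilinear state-space form

$$\dot x = \Big(A + \sum_j u_j B^{(j)}\Big) x + C u,$$

in its *two-state* variant: each region holds an excitatory (E) and an
inhibitory (I) population.  Between-region connections couple E
populations and are strictly excitatory; within a region the I
population is driven by its E population and feeds back inhibition.
Rates are log-scaled so sign constraints hold for every parameter value:

* between-region rate: $a_0 \exp(A_{ij} + u_{\mathrm{mod}} B_{ij})$,
  always positive (excitatory), with $a_0 = 0.2$ Hz;
* self-inhibition gain: $g_{IE} \exp(A_{ii} + u_{\mathrm{mod}} B_{ii})$,
  always applied with a negative sign (inhibitory), $g_{IE} = 1$ Hz.

A negative modulatory self-weight $B_{ii}$ therefore means that
self-inhibition is *released* as the slowing input ramps up — the
candidate mechanism for the rising BOLD signal, and the package's
default ground truth gives SM1 a self-modulation of $-0.4$.  The
remaining constants (E decay 1 Hz, I decay 0.5 Hz, E→I drive
0.5 Hz) were fixed once so that the network remains stable over the
whole ±2 SD range of the shrinkage priors; the property suite sweeps
that range and checks boundedness over a full 900 s run.

### Inputs

Two external inputs drive the network, both at microtime resolution
(TR/16 by default):

* a **driving input**: a boxcar spanning every tapping epoch (constant
  drive from upstream areas while the task is on), entering via $C$ at
  PMd and/or SMA — never SM1;
* a **modulatory input**: a within-trial staircase rising in 5 s bins
  (levels $k/6$, six levels over a 30 s slowing trial, two over a 10 s
  control trial), identical for every subject.  It is not mean-centred
  by default, preserving its "linear increase" reading; a centring flag
  exists.  A session-long-constant driving option exists too, but is
  not the default because a constant that never switches off is not
  identifiable against baseline.

### Hemodynamics

Each region's E activity drives a standard balloon–Windkessel model
(signal decay 0.64 s⁻¹, feedback 0.32 s⁻¹, transit time 2 s with a
per-region estimable log-scaling, stiffness 0.32, resting extraction
0.4, resting volume fraction 0.04), read out as percent BOLD signal
change.  Flow, volume and deoxyhemoglobin are integrated in log space
so they stay positive at any step size.  Integration is fixed-step RK4
at TR/16 (≈0.156 s); the compiled integrator is cross-checked against
an adaptive solver (`deSolve::lsoda` at tolerance 1e−12) on the same
vector field, and halving the step changes noise-free BOLD by less
than 0.1 % of its range.

## Experiment design and regressors

The schedule builder reproduces the paradigm: two 900 s runs of 360
volumes (TR 2.5 s), each with two blocks of four 30 s slowing trials
and four 10 s control trials (order counterbalanced across runs and
alternating across subjects), every trial preceded by a 2–3 s
uniformly jittered get-ready cue and followed by a 30 s break, and a
20 s implicit baseline after each block.  Infeasible configurations
fail loudly.

GLM-style regressors (tapping, parametric modulation of tapping,
recovery, parametric modulation of recovery, get-ready) are built as
microtime boxcars/staircases, convolved with the canonical double-gamma
HRF (peak gamma shape 6, undershoot shape 16, ratio 6, 32 s kernel)
and sampled at the TR.  Parametric modulators are residualized against
their parent regressor **after** convolution by default, so the final
design columns are exactly orthogonal (inner product 0 to machine
precision); this matches how design matrices are orthogonalized in
common practice, and an option performs the residualization on the raw
microtime staircase instead.  The recovery modulator ramps only over
breaks that follow 30 s trials.

## Model space and families

All 180 models share a fully bidirectional endogenous A-matrix and
differ only in (i) which connections the slowing input modulates and
(ii) where the driving input enters (PMd, SMA or both).  Four cores —
top-down (premotor→SM1), bottom-up (SM1→premotor), selective
(one bidirectional SM1↔premotor pair, always with the involved
premotor self-modulation) and null — are crossed with the joint
SMA↔PMd interaction modulation, the three driving targets, and the
presence of SM1 self-modulation, giving families of 36/36/12/6 models
per SM1-self level.  In "both-connection" top-down/bottom-up variants
the two premotor self-modulations switch jointly; per-area
combinations would break these counts.  The enumeration is validated
against the counts and against pairwise uniqueness of the masks.

## Inversion

Each subject-model pair is inverted by variational Laplace: Gauss–
Newton ascent on the free energy with finite-difference prediction
Jacobians, Gaussian shrinkage priors (variance 1/16 on endogenous,
self and transit parameters, 1/4 on modulatory and driving weights,
all means 0; masked parameters get zero variance), and per-region
noise log-precisions optimized under a broad Gaussian hyperprior
(mean 0, variance 16).  Steps that fail to raise the free energy are
halved and ultimately rejected, so the accepted trajectory is
non-decreasing; convergence is declared at ΔF < 0.01 nats (iteration
cap 128 by default).  Singular curvature is ridge-regularized with a
warning.  For a linear forward model with fixed noise precision the
converged free energy equals the closed-form log evidence — the suite
checks agreement to 1e−3 nats — because the Laplace approximation is
exact there.

During inversion the forward model integrates at TR/8 (the microtime
inputs are thinned by 2).  This halves the cost of every Jacobian
column while remaining inside the integrator's convergence envelope;
the data themselves are always generated at TR/16.

## Model comparison and averaging

Family-level random-effects BMS first pools each subject's member-model
evidences into a family evidence by a log-mean-exp (a uniform
within-family prior, so the per-model prior mass is inversely
proportional to family size and the 36-model families cannot outvote
the 6-model family by bulk alone), then fits a variational Dirichlet
over the 8 family frequencies.  Exceedance probabilities come from
seeded Monte-Carlo draws of the fitted Dirichlet (10⁶ by default).
Under identical evidences every family's exceedance is 1/8 by
symmetry, which the suite verifies.

If no family exceeds the 0.95 decisiveness threshold, parameters are
averaged across the *whole* space by BMA, exactly as the study design
prescribes for that scenario; otherwise averaging is restricted to the
winning family.  The Occam's window is a posterior-odds cutoff: models
within a factor `occam = 0.05` of the best model's posterior
probability are retained.  Subject-level weights are the RFX
responsibilities (family responsibility × within-family posterior);
fixed-effects softmax weights are used when no BMS result is supplied
(e.g. single-subject analyses).  The deterministic mode computes exact
weighted means (and is tested against a brute-force oracle); a seeded
sampling mode draws the model identity per subject instead.  Whether
the original analysis drew subject-wise model assignments or used
group weights is not stated anywhere we could check, so both are
provided with the deterministic average as default.

## Group inference

Averaged modulatory parameters are tested against zero with one-sample
t-tests, Bonferroni-corrected over the tested set (every connection
modulated in any window model).  The brain–behaviour link is a
forward-backward stepwise OLS regression of each subject's behavioural
slowing score — the fitted slope of control-normalized speed over 10 s
bins in slowing trials, a scalar the package defines explicitly since
no standard definition exists — on those parameters, with entry/removal
thresholds 0.05/0.10 (common defaults).  Cook's distance and leverage
are always reported alongside any selected model, because such
associations can hinge on single subjects.

## The synthetic cohort: what it does and does not emulate

The generator draws per-subject parameters around the configured
population means (between-subject SD 0.1), simulates both runs at the
scan TR with white measurement noise at SNR 1 (noise SD = noise-free
signal SD), and produces tapping speeds whose within-trial decline is
`link_intercept + Σ link_weights × true B + noise` — deliberately a
simple linear bridge, because the brain–behaviour link in the analysis
is itself only a regression.  The default link weight of 0.25 on the
SM1 self-modulation gives a population-mean slowing slope of −0.1 per
bin.  Everything derives from one master seed and regenerates bit for
bit.

Not emulated: head motion, physiological (cardiac/respiratory) noise,
scanner drift, voxel geometry and spatial smoothing, regional
variation in hemodynamics beyond transit time, and any nonlinear or
non-stationary behaviour of real cortex.  Passing recovery tests
therefore show that the *pipeline* is correct and well-calibrated for
data generated by its own model class at realistic noise levels — not
that real fMRI obeys this model.

## Problem sizes in the validation suite

Recovery experiments are scaled to stay informative while remaining
routine to run: sign-recovery uses 50 single-subject replicates over
the 12-model selective family with SM1 self-modulation; family
recovery uses 20 cohorts of 10 subjects over an 8-model
family-representative space (one core model per family, driving input
to both premotor areas); both use one 360-volume run per subject.
These sizes are the package's validation design; the full 180-model,
24-subject, two-run analysis is available through
`run_pipeline(pipeline_config(space = "full"))`.

## Known limitations

* Gradients are finite-difference; a complex-step or adjoint scheme
  would be faster and smoother for large spaces.
* The noise model is white; serial correlations in real fMRI would
  make the free energies optimistic.
* Priors are package defaults, not a reproduction of any particular
  SPM release's priors, so numerical identity with SPM results is not
  expected — recovery behaviour, not number-matching, is the
  validation target.
* Protected exceedance probabilities and hierarchical (parametric
  empirical Bayes) group models are out of scope.
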
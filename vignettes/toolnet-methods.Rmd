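---
title: "Decoding and effective connectivity of pantomimed tool use: models and methods"
author: "toolnet authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding and effective connectivity of pantomimed tool use: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toolnet)
```

# The experiment this package models

`toolnet` implements, end to end, the analysis of a delayed-pantomime fMRI
experiment. On every trial a participant hears a verbal cue (1 s) naming one
of four pantomimes — grasp-to-move or grasp-to-use, with scissors or an axe —
waits through a 9 s planning delay, executes the pantomime for 2.5 s on an
auditory go signal, and rests through an 11.5 s inter-trial interval. A run
holds 16 trials (4 per condition) between 16 s and 20 s baselines: 420 s,
i.e. 210 volumes at TR = 2 s. A session has 8 runs; the study has 17
subjects.

The two scientific questions the analysis chain addresses are:

1. **Where is action and goal information encoded?** Multivoxel patterns in
   eight tool-network ROIs (pMTG, SMG, PMv, aIPS, PMd, SPOC, SPL, M1; 12-mm
   spheres, coordinates shipped in `inst/extdata/rois_mvpa.tsv`) are decoded
   for *action* information (move vs use within a tool) and, by cross-tool
   cross-decoding, for tool-invariant *goal* information.
2. **How do ventral and dorsolateral streams interact during execution?**
   A three-node dynamic causal model (pMTG, aIPS, PMv) asks which
   connections the grasp-to-use task modulates, using random-effects
   Bayesian model selection over a 15-model space.

Because no public data accompany the study, the package is driven by a
synthetic generator whose defaults encode the study's design exactly; real
events tables and ROI time series can be substituted at the same interfaces.

# The synthetic BOLD generator

For each ROI, phase and condition the generator draws a voxel pattern

$$p(\text{action}, \text{tool}) = g_a\, a(\text{action}, \text{tool}) + g_g\, s(\text{action})\, g_0,$$

where the four $a$ vectors and $g_0$ are orthonormal (drawn once per
subject via the QR decomposition of a Gaussian matrix), and
$s(\text{move}) = +1$, $s(\text{use}) = -1$. The $a$ vectors are a
*tool-specific action code*: they separate move from use within a tool but
share nothing across tools. The single axis $g_0$ is a *tool-invariant goal
code*: it is the only component that can transfer across tools, so
cross-decoding accuracy is at chance exactly when $g_g = 0$.

The run signal is the sum over trials and phases of (phase boxcar ⊛
canonical HRF) × pattern; noise is stationary AR(1) (marginal sd `sigma`,
lag-1 correlation `ar1_rho`) plus slow cosine drift with periods above
128 s, independent across voxels.

Which (ROI, phase) cells carry which code is set by the encoding profile.
The default profile reproduces the study's reported significance map:
action information in every ROI at execution and in all but M1 at planning;
goal information in pMTG, aIPS, SPL and SPOC at planning and in pMTG, aIPS,
SPL, SMG and PMv at execution; no condition information at the cue.

## Calibration choices

The study reports decoding accuracies only graphically, so the gain
magnitudes are calibration choices, fixed once:

* `sigma = 1`, `ar1_rho = 0.3`, `drift_amplitude = 1`;
* `action_gain = 0.5`, `goal_gain = 0.55` at execution;
* `planning_scale = 0.35` multiplies both gains at planning.

The planning rescaling exists because the 9-s planning regressor carries
several times the energy of the 2.5-s execution regressor; equal pattern
amplitudes would put planning decoding at ceiling. With these values,
group-mean decoding in signal-carrying cells sits near 75–82% for both
phases — mid-range, comfortably above chance but far from ceiling, which is
where the group tests are informative.

Between-subject variability: pattern bases are redrawn per subject and the
gains are jittered by ±20% (uniform, per subject × ROI × phase), giving the
random-effects structure that the group t-tests assume.

What the generator does **not** emulate: spatial voxel correlations,
physiological (cardiac/respiratory) noise, motion artefacts, or any
anatomical structure. Passing tests therefore show that the analysis chain
is correct and well calibrated under its own assumptions, not that the
original biological effects are reproduced.

# Trial-wise GLM (beta series)

The design matrix has one regressor of interest per trial and phase — cue,
planning and execution boxcars (1 / 9 / 2.5 s) convolved with a unit-peak
double-gamma HRF — for all trials of all runs in a single
least-squares-all model: 16 × 3 × 8 = 384 regressors of interest. Planning
is modelled as the full 9-s epoch (`planning_as_impulse = TRUE` switches to
an event). Per run, the nuisance block holds an intercept, a discrete-cosine
high-pass basis (128 s cutoff, the filtering the scanner pipeline would
apply), optional motion parameters, and — when error trials are flagged — a
pooled error regressor; error trials never reach the decoder. Estimation is
ordinary least squares via the Cholesky factor of the normal equations, with
an explicit rank check that names collinear columns. Residual AR modelling
is deliberately omitted (decoding consumes betas, not t-values; the default
is raw betas, as the choice between raw and scaled patterns is immaterial to
a linear decoder with shrinkage).

# Decoding

Decoding is shrinkage LDA under leave-one-run-out cross-validation, after
per-run trial balancing (each condition subsampled to the run's minimum
count, seeded).

* **Action**: train and test move-vs-use separately per tool on the
  held-out run; report the mean of the two tools' accuracies.
* **Goal**: train move-vs-use on one tool's trials from the training runs,
  test on the *other* tool's trials of the held-out run; average both
  directions and all folds. Training and test sets thus never share a run
  — the study does not state whether its cross-decoding respected run
  folds, and keeping the fold geometry preserves independence.

The pooled within-class covariance is shrunk toward its average-variance
diagonal; the default intensity is the Ledoit–Wolf analytic value, and a
fixed λ is available for exact reproducibility of small fixtures. Exact
ties on the discriminant boundary go to the first class level. Cue-phase
patterns are extractable but not part of the headline outputs.

# Group inference

Each ROI × phase × comparison cell is tested against chance (50%) with a
one-tailed one-sample t-test across subjects (accuracies enter
untransformed), and the Benjamini–Yekutieli step-up procedure controls the
FDR at q = 0.05 jointly across the whole family — 8 ROIs × 2 comparisons ×
2 phases = 32 tests by default (`family = "per_phase"` corrects each phase
separately; whether the original correction family included the cue phase
is not stated, and the cue is excluded here). BY rather than BH because the
accuracies of overlapping ROIs and nested comparisons are arbitrarily
dependent.

# Dynamic causal modelling

## Forward model

Neural dynamics are bilinear, $\dot z = (A + u_{task} B)\, z + C u_{drive}$,
over the ordered nodes (pMTG, aIPS, PMv). The driving input $u_{drive}$ is
the auditory instruction stream — the 1-s verbal cue of every trial plus
the 0.5-s go signal at every execution onset — entering pMTG only. The
modulatory input $u_{task}$ is the boxcar of grasp-to-use execution epochs,
so the non-use executions provide the unmodulated propagation baseline that
makes B identifiable. Each node's neural state drives a standard
balloon–Windkessel haemodynamic cascade (κ = 0.64 s⁻¹, γ = 0.32 s⁻¹,
τ = 2.0 s, α = 0.32, ρ = 0.4, V₀ = 0.04 — literature defaults, fixed
throughout) and the usual nonlinear BOLD observation equation. Integration
is fixed-step RK4 at dt = 0.05 s (convergence-checked: halving dt moves the
output by < 10⁻⁴ relative), implemented in C++, sampled at TR.

## Model space

The study tested fifteen modulatory patterns but lists them only
graphically. The shipped fixture (`inst/extdata/dcm_model_space.tsv`,
user-replaceable without code changes) enumerates the fifteen non-empty
combinations of four modulation elements: ventral→dorsal forward
(pMTG→aIPS with pMTG→PMv), dorsal→ventral backward (aIPS→pMTG with
PMv→pMTG), and the two within-dorsolateral directions (aIPS→PMv, PMv→aIPS)
separately. Model 1 modulates all six directed connections — matching the
description of the reported winning model — and the remaining fourteen are
an explicit, documented approximation of the original space.

## Inversion and evidence

Free parameters are the six off-diagonal intrinsic couplings
(prior N(0, 0.5²)), small deviations of the self-connections around the
−0.5 s⁻¹ baseline (N(0, 0.05²)), the supported modulatory weights
(N(0, 1²)) and the pMTG driving weight (N(0, 1²)); haemodynamics stay
fixed, which keeps the inverse problem identifiable at this scale — a
documented simplification relative to full variational-Laplace toolboxes.
MAP estimation solves the penalised least-squares problem by
Levenberg–Marquardt, re-estimating the per-node noise variances between
passes, from two deterministic starts: the prior mean, and a
deconvolution-plus-regression estimate (Wiener deconvolution of each node
to an approximate neural signal, then ridge regression of its derivative
on the bilinear terms — the neural equation is linear in A, B, C given the
states). The log evidence is a Laplace approximation with Gauss–Newton
curvature; a model with no free parameters degenerates cleanly to prior =
posterior. Unstable intrinsic matrices (any resting eigenvalue ≥ 0) and
state blow-ups are rejected, and the optimiser is steered away from them by
a penalty.

## Model selection and group tests

Random-effects BMS follows the variational Dirichlet scheme (uniform
prior, one count per model): posterior model frequencies per subject,
Dirichlet counts over the population, and exceedance probabilities by
Monte Carlo sampling of the posterior Dirichlet (10⁶ draws, seeded; only
the two-model case has a closed form). Connection parameters of the
winning model are tested against zero with two-sided one-sample t-tests
under BY-FDR. Because the intrinsic-connectivity report of the original
study is ambiguous between A alone and task-average coupling, `dcm_fit`
exposes A and B separately so either summary can be formed.

## Synthetic DCM ground truth

`default_dcm_truth()` uses asymmetric intrinsic couplings (0.05–0.25 s⁻¹)
— symmetric coupling would make the three nodes' states near-collinear and
the modulated connections mutually unidentifiable — with all six
modulations positive (0.2–0.35 s⁻¹) and a unit drive into pMTG. Subjects
jitter every nonzero coupling by ±20% (self-decay held fixed), and white
observation noise is scaled per node to a chosen signal-to-noise ratio.
The high-SNR validation condition is SNR = 20 (signal sd / noise sd): at
that ratio the full model space is decisively discriminable, while at
SNR ≈ 10 the weakest modulatory weight no longer repays its complexity
cost and a reduced model can win — a useful reminder that failure to
detect a modulation is not evidence of its absence.
The study's real-data exceedance (0.7903 for the full model) cannot be
reproduced without the unavailable scans; the package instead verifies
*recovery*: on data generated from the full-modulation model at high SNR,
BMS must select it decisively, and at zero noise the coupling parameters
must come back within a few percent.

# Problem sizes in the shipped tests

The test suite keeps the full experimental structure (17 subjects, 8 runs,
16 trials, 32-test family, 15 models) and scales only the per-ROI voxel
count, which the design leaves free: 24 voxels for the null-calibration
replicates, 60 for the significance-map replicates, 100 (the package
default, standing in for the ≈250 voxels of a 12-mm sphere at 3-mm
resolution) elsewhere. DCM validation simulates one 420-s run per subject
rather than the eight concatenated runs of the original session; this is
the package's desk-scale default for synthetic validation and is stated on
the relevant functions.

# Known limitations

* The generator's noise is temporally AR(1) and spatially white; real
  multivoxel noise is spatially structured, which typically *reduces*
  effective decodable signal for a fixed amplitude.
* The DCM engine estimates neural coupling only; haemodynamic parameters
  are fixed and shared across nodes, so regional haemodynamic variability
  would be absorbed into coupling estimates on real data.
* Models 2–15 of the modulatory space are an approximation of a figure;
  conclusions about specific reduced models depend on the fixture.
* The Laplace/Gauss–Newton evidence is coarser than a full variational
  free-energy scheme; it is validated here by model recovery, not by
  equivalence to any toolbox.
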
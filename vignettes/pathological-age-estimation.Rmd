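---
title: "Estimating brain pathological age with a correlation-criterion deviation search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating brain pathological age with a correlation-criterion deviation search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathage)
```

## The model

Neurodegeneration behaves like accelerated brain aging: in Alzheimer's
disease (AD) and its prodromal stage (mild cognitive impairment, MCI),
structures such as the hippocampus lose volume faster than in normal
aging. Conventional "brain age" pipelines regress chronological age $y$ on
imaging features $x$ and read the prediction $\hat y$ as the brain's age,
training by minimising a distance such as
$\lVert \hat y - y \rVert$. But if disease advances brain aging by some
per-class offset, chronological age is the wrong training label: the label
itself carries none of the class structure the estimate is meant to
expose.

This package instead assumes that subjects of diagnostic class $k$
(ordinal codes $0,\dots,K-1$ in severity order: NC $<$ MCI $<$ AD) have a
class deviation $d_k$ (in years) between their real age and their
*pathological* age. For a candidate deviation vector
$d = (d_0,\dots,d_{K-1})$:

1. an epsilon support vector regression (SVR) is trained on the training
   set with labels $y_i + d_{k(i)}$;
2. validation-set ages are predicted;
3. the candidate is scored by the fitness
   $\lambda(d) = \mathrm{corr}(\hat y_{\mathrm{val}},\,
   y_{\mathrm{label}})$, the Pearson correlation between predicted ages
   and the ordinal class codes.

The search enumerates a grid of candidates (every class range
$[d_k^{\min}, d_k^{\max}]$, common step) and returns the maximiser
$d^\ast$. A subject's **brain pathological age** is their real age plus
their class's optimal deviation, $y + d^\ast_{k}$, and $d^\ast_k$ itself
estimates the extent of accelerated aging in class $k$. The correlation
criterion is used instead of an error criterion because correlation with
the class code — not closeness to chronological age — is what makes an
age variant useful for staging disease; correlation is also invariant to
the scale and offset of the predictions, so it measures separability
rather than calibration.

The traditional estimator is retained as the baseline
(`run_baseline()`): an SVR trained on real ages, whose
epsilon-insensitive loss realises the classical error-minimisation
criterion.

## Tunable parameters

* **Deviation ranges** (`deviation_grid()`): prior knowledge puts
  disease-related deviations within roughly a decade, so the conventional
  ranges are $[-10, 10]$ years per class for two-class problems and
  $[-8, 8]$ for three-class problems (the candidate count is the product
  of per-class grid sizes, so three-class searches use the narrower
  range).
* **Step** (years, default 1): the resolution of the search. A step of
  0.1 is supported; cost scales as $(\mathrm{range}/\mathrm{step}+1)^K$.
* **Kernel** (`age_estimator_config()`): `linear`, `polynomial` or
  `gaussian`. Published comparisons favour the linear kernel for
  two-feature hippocampal volume data; `compare_kernels()` reruns the
  whole protocol per kernel on identical splits for a paired comparison.
* **SVR hyperparameters**: cost 1, epsilon tube 0.1 years, polynomial
  degree 3, kernel width $\gamma = 1/(p \cdot \overline{\mathrm{Var}}(x))$
  on the features as passed to the solver. These are the canonical
  defaults of an epsilon-SVR implementation, pinned explicitly so results
  do not drift with library versions.
* **Split policy** (`split_policy()`): train/validation/test fractions
  default to (0.6, 0.2, 0.2), stratified by class. The validation set
  must support a stable correlation estimate, and the test set stays
  untouched by the argmax.
* **Repeats** (`repeat_experiment()`, default 10): the protocol repeats
  the random split, search and test scoring; repeat $r$ uses seed
  `policy$seed + r - 1`, so any repeat is reproducible in isolation.

## Feature standardization

Features are z-scored on training statistics before entering the solver
(`standardize = TRUE`, the default), and targets are never scaled, so
`epsilon` keeps its meaning in years. This is a numerical choice, not a
modelling one: hippocampal volumes are orders of magnitude larger than
ages, and on that raw scale the quadratic-program solver hits its
termination tolerance far from the optimum (we observed predictions from
two mathematically equivalent parametrizations of the same linear-kernel
problem differing by more than eight years). For the linear and gaussian
kernels standardization is a reparametrization of the same function
class; for the polynomial kernel it changes the geometry, which is why
the flag exists (`standardize = FALSE` feeds raw features).

A useful consequence: with unscaled targets, libsvm's epsilon-SVR dual is
*exactly* invariant under a common shift of all training labels (the
equality constraint cancels the shift in the objective), so predictions
are translation-equivariant to machine precision. The package's
shift-invariance tests lean on this.

## The synthetic cohort generator

Restricted-access feature tables cannot ship with a package, so
`generate_cohort()` draws cohorts with the statistical structure the
method assumes:

* ages are truncated-normal per class (defaults mirror a balanced
  hippocampus dataset: three classes of 411 subjects, ages 65–85, class
  mean ages 76.09/75.36/75.50 years, SDs 4.696/7.635/7.245 before
  truncation — realized SDs are smaller, which we accept);
* latent brain age is `age + class_accel[k] + eta`, with jitter `eta`
  (SD 1 year by default) so brain age is not a deterministic function of
  age; the default true accelerations (0, 4, 8) years are an arbitrary
  documented choice of the same order as published deviation estimates;
* each volume feature declines linearly with brain age
  (slope 3 units/year by default; linear decline is the dominant pattern
  reported for normal aging), with residual SD 5 units and bilateral
  noise correlation 0.8 between left and right volumes; volumes are
  clipped at a small positive floor.

What the generator does **not** emulate: feature-specific disease
effects (e.g. asymmetric left/right atrophy), nonlinear atrophy
trajectories, covariates (sex, education), longitudinal structure, and
measurement artefacts. The omission of feature-specific class effects is
consequential — see the next section.

## Identifiability: what the search can and cannot recover here

Two structural facts shape how search output should be read.

**Only deviation differences are identified.** Because the SVR is
translation-equivariant in its labels and the Pearson correlation is
shift-invariant, $\lambda(d) = \lambda(d + c\mathbf{1})$ for any common
shift $c$: the fitness surface is constant along the all-ones direction.
The signed values of recovered deviations therefore depend on a
convention. The package breaks exact fitness ties by the smallest
Euclidean norm of the deviation vector, then by enumeration order, which
selects a minimum-norm representative reproducibly; in floating point the
diagonal is level only to solver precision, so the realized representative
also reflects fit noise.

**With a linear kernel and a single latent factor, nothing else is
identified either.** A linear-kernel SVR prediction is affine in the
features, so the validation fitness depends on the fitted coefficients
only through their direction. In the generator above, *all* class
information enters the features through one scalar (latent brain age):
the cross-covariance between features and any shifted label
$y + d_{k}$ is proportional to the same vector for every candidate $d$.
Consequently the *expected* fitness is the same for every candidate whose
fitted slope has the correct sign — empirically the surface is a flat
plateau over most of the grid, with a sign cliff where
$\mathrm{Var}(y) + \mathrm{cov}_k(d_k, \Delta_k)$ changes sign — and the
argmax within the plateau is sampling noise. On such data the search
recovers the *ordering* of the true accelerations at roughly chance
rates, and the package's acceptance suite records this honestly rather
than asserting a recovery the data cannot support. Recovering per-class
deviations from two-feature data requires class information to enter the
features through more than one direction (for real hippocampal data,
e.g., asymmetric atrophy) or a nonlinear kernel whose predictions are not
affine in the features. Passing tests on this generator therefore
demonstrate the machinery (argmax consistency, zero dominance, shift
invariance, protocol integrity), not deviation recovery on real cohorts.

## Numerical choices

* Truncated-normal ages are drawn by inverse-CDF sampling and clamped to
  the range to guard against quantile roundoff at the tails.
* A candidate whose model predicts a constant on the validation set has
  undefined correlation; it scores $-\infty$ in the surface instead of
  aborting the search. At the criterion layer the same situation is a
  classed error (`pathage_degenerate_error`), never a silent 0 — a silent
  0 would let degenerate fits masquerade as mid-grid candidates.
* When every training target fits inside the epsilon tube of a constant,
  the solver reports an empty model; the package returns the optimal
  constant fit (the target mean) in that case.
* The best model is refitted once at the optimal candidate rather than
  cached for every candidate, trading a single extra fit for memory.
* Correlations are reported signed. Published tables typically show
  magnitudes; `correlation_report(..., abs = TRUE)` matches that
  presentation.
* Deviation significance is a per-class two-sided one-sample t-test of
  the recovered deviations against zero across repeats — the natural
  construction when each repeat contributes one deviation per class. A
  class recovered identically in every repeat has zero variance and is
  flagged degenerate (`NA` with an attribute) rather than given an
  arbitrary p-value.

## Problem sizes used by the test suite

The unit suite runs on cohorts of 20–60 subjects per class with small
grids (steps 1–2, ranges within ±2), chosen so the full suite completes
in seconds while still exercising every code path; the end-to-end
acceptance checks use full-size cohorts (411 per class) with step-2
grids. All simulations are seeded; the generator and the split policy
never touch the caller's RNG stream.

## Known limitations

* Exhaustive enumeration only; the cost is exponential in the number of
  classes. Smarter optimizers would change the estimator's statistical
  behaviour (the argmax of a noisy surface) and are out of scope.
* The ordering $d_0 < d_1 < d_2$ is an empirical observation in published
  work, not a constraint; the package never enforces it.
* Whether the baseline should train on all classes or on normal controls
  only differs between traditional pipelines; both are provided
  (`baseline_train = "all"` or `"nc"`), defaulting to all classes.
* The correlation criterion is linear; ranked or nonlinear dependency
  measures are not implemented.
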
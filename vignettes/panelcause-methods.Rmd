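---
title: "Forecasting interventions versus predicting outcomes in cross-lagged panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forecasting interventions versus predicting outcomes in cross-lagged panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelcause)
```

## The model

`panelcause` works with a bivariate linear Gaussian structural causal
model for a cross-lagged panel design: two variables, conventionally $X$
(in the running example, mean-centered blood insulin in mcIU/ml) and $Y$
(mean-centered blood glucose in mg/dl), measured at $T$ equally spaced
waves. The data-generating recursion is

$$
X_{t+1} = c_{xx} X_t + c_{xy} Y_t + \varepsilon_{x,t+1}, \qquad
Y_{t+1} = c_{yx} X_t + c_{yy} Y_t + \varepsilon_{y,t+1},
$$

with time-stable autoregressive coefficients $c_{xx}, c_{yy}$,
cross-lagged coefficients $c_{xy}$ ($Y_t \to X_{t+1}$) and $c_{yx}$
($X_t \to Y_{t+1}$), and independent Gaussian innovations with
time-stable variances $\psi_{xx}, \psi_{yy}$ for $t \ge 2$. The wave-1
pair is exogenous with free (co)variances
$\psi_{x_1x_1}, \psi_{y_1y_1}, \psi_{x_1y_1}$; the covariance is drawn as
a bidirected edge because it stands for an unobserved common cause of the
initial conditions. All variables are mean-centered, so intercepts are
zero throughout (non-zero intercepts are accepted for generality).

`build_crosslagged()` assembles this model as an explicit DAG with
coefficients (`model_spec`), and `implied_moments()` computes its reduced
form: with coefficient matrix $C$ and error covariance $\Psi$,

$$
\mu = (I - C)^{-1} b, \qquad
\Sigma = (I - C)^{-1} \Psi (I - C)^{-\top}.
$$

Everything else in the package is a functional of $(\mu, \Sigma)$ for a
suitably modified model.

The worked example ships as `insulin_glucose_params()`; its wave-1
(co)variances are the long-run equilibrium of the dynamics, which
`stationary_initial_covariance()` verifies by solving the discrete
Lyapunov equation $\Sigma_1 = A \Sigma_1 A^\top + Q$ exactly (via
vectorization; the solver refuses lag matrices with spectral radius
$\ge 1$). The example system is stable with eigenvalue moduli 0.93 and
0.32 — persistent, which matters later for estimation.

## Forecast versus prediction

The package's central distinction:

* **Forecast after an intervention.** `apply_do()` performs graph
  surgery for $do(X_2 = x_2)$: all edges into $X_2$ are deleted, its
  error variance and covariances set to zero, and its intercept set to
  $x_2$ — every unit in the population gets the same value, detached
  from its causes, while all other mechanisms stay intact (modularity).
  `interventional_distribution()` is then simply the implied joint of
  the mutilated model. For the example,
  $E(Y_3 \mid do(X_2 = 11.48)) = c_{yx} \cdot 11.48 = -6.89$.
* **Prediction from an observation.** `condition_on()` applies exact
  Gaussian conditioning (Schur complement) to the *unmutilated* joint.
  Observing $X_2 = 11.48$ predicts
  $E(Y_3 \mid X_2 = 11.48) = 1.71 \cdot 11.48 \approx 19.7$, with the
  positive slope driven by backdoor association through the history of
  the process, not by the (negative) causal effect.

The two answers differ in sign because the population regression slope
of $Y_3$ on $X_2$ mixes the direct effect $c_{yx}$ with spurious
backdoor contributions. `backdoor_paths()` enumerates those paths,
`d_separated()` tests blocking (on the latent expansion of the graph,
where each bidirected edge becomes an explicit common parent), and
`minimal_adjustment_sets()` returns all inclusion-minimal backdoor
adjustment sets — for the example, $\{Y_2\}$ is the smallest, and
`population_regression()` adjusted for any returned set recovers
$c_{yx} = -0.6$ exactly.

Second moments behave oppositely: intervening *destabilizes* the
self-regulating system (the forecast variance of $Y_3$ rises from 632.93
to 951.43, independent of the chosen level), while observing *sharpens*
prediction (632.93 → 245.71 → 40.00 as more waves are observed). Both
invariances-in-the-level are exact consequences of linearity and are
verified numerically in the tests.

## Acceptable ranges and optimal dosing

`success_probability()` evaluates
$P(\text{lower} < Y_3 < \text{upper})$ under any of these Gaussian
distributions. Ranges are stored in model units: the example uses the
euglycemic band 60–180 mg/dl centered at 100, i.e. $[-40, 80]$ in the
mean-centered metric; the package does not hard-code clinical values.

Because the outcome mean is affine in the level of the treated (or
observed) variable while the variance is level-free, the optimal level
has the closed form
$\text{level}^\ast = (\text{midpoint} - \text{offset})/\text{slope}$.
`optimal_level()` uses it, but first verifies the affine/constant
premise numerically at probe levels and cross-checks the result against
a bounded numerical maximization (agreement required to $10^{-4}$);
a target with no influence on the outcome raises a flat-objective error
rather than returning an arbitrary level. For the example the optimal
dose is $do(X_2 = -33.33)$ with success probability 94.8%, whereas the
value one would *wish to observe* is $X_2 = 11.67$; applying the
observational optimum as a dose costs 9.3 percentage points.

## Unobserved heterogeneity and person-specific forecasts

With `heterogeneity = TRUE` the model gains additive random intercepts
$\eta_x, \eta_y$ — latent, person-constant inputs with free covariance
matrix ($\psi_{\eta_x\eta_x} = 5$, $\psi_{\eta_y\eta_y} = 10$,
$\psi_{\eta_x\eta_y} = 2.5$ in the example). Loadings on waves
$t \ge 2$ are fixed at 1 (setting the latent scale and expressing time
stability); the four wave-1 loadings are free and, in the example, equal
the long-run accumulation matrix $(I - A)^{-1}$ of the dynamics, so the
process starts in its person-specific equilibrium. The wave-1 error
(co)variances keep their homogeneous values, with the intercepts
entering wave 1 only through the free loadings; this convention
reproduces the example's inflated stationary moments
($V(Y_t) = 3822.93$, $SD(X_t) = 26.30$ for $t \ge 2$) exactly.

`person_specific_interventional()` conditions the interventional
distribution on known latent values $\eta_x = z_x, \eta_y = z_y$. Three
consequences, all reproduced in the tests:

* the person-specific interventional mean shifts linearly in
  $(z_x, z_y)$, but the ATE is person-free (the $z$ terms cancel in any
  contrast of levels);
* learning the person's intercepts drops the forecast variance from
  5939.03 to 951.43 — exactly the homogeneous interventional variance,
  because the latent contribution is removed;
* optimal doses are person-specific ($-104.92$, $-33.33$, $38.25$ for
  the three illustrative individuals one SD below, at, and above the
  latent means) while the attainable maximum (94.8%) is shared, since
  only the mean, not the variance, depends on the person.

Backdoor identification changes character here: no observed adjustment
set exists (the latent intercepts confound every route into the
treatment and cannot be blocked downstream), and every latent-admitting
minimal set involves at least one intercept. The package therefore
identifies interventional quantities by direct computation on the
parameterized model rather than by covariate adjustment; the general
matrix identification criteria for linear DAG models are cited in the
field but not reimplemented here.

A note on the illustrative individuals: their latent values are the
printed two-decimal standard deviations ($\pm 2.24, \pm 3.16$), not
$\sqrt 5$ and $\sqrt{10}$; the package stores the printed values since
they define the worked case (the difference is below 0.12 in the
person-specific mean).

## The simulator

`simulate_panel()` draws i.i.d. persons from the exact data-generating
process: latent intercepts from their bivariate normal, the wave-1 pair
from its ($\eta$-shifted) bivariate normal, later waves by the
structural recursion (implemented equivalently through the reduced
form). Randomness is split into substreams derived from the master seed
(latents / wave 1 / one per later wave) so that homogeneous,
heterogeneous, and intervened runs with the same seed share innovations
and differ only where the model differs. Identical seed and parameters
give bitwise identical output. The generator emulates exactly what the
analytic machinery assumes — linear dynamics, Gaussian errors, no
missingness, equal spacing, no measurement error — so simulation-based
agreement with the closed forms validates the algebra, not the model's
realism for any particular empirical system. Time-varying confounding,
autocorrelated residuals, or measurement error would all break the
correspondence and are intentionally out of scope.

Default study sizes in the test suite: 200,000 persons for Monte-Carlo
moment checks (3-standard-error bands), 5,000 for estimation recovery,
smaller sizes for unit-level checks; these are the sizes at which the
checked contrasts are well resolved at desk scale.

## Estimation

`fit_crosslagged_ml()` minimizes the normal-theory covariance
discrepancy
$F(\theta) = \ln|\Sigma(\theta)| + \mathrm{tr}(S\Sigma(\theta)^{-1}) -
\ln|S| - p$
over the constrained parameterization (9 parameters homogeneous, 16
with random intercepts); $F \ge 0$ with equality iff
$\Sigma(\theta) = S$. Starting values are data-driven but
truth-agnostic: pooled OLS on the lagged regressions, and for the
random-intercept variant within-person (fixed-effects) OLS for the
dynamics, the long-run matrix $(I - \hat A)^{-1}$ for the wave-1
loadings, and the covariance of back-projected person means for the
latent block, plus jittered replicates. Convergence tolerance is
$10^{-12}$ relative on the objective; the reported `converged` flag
means the objective is stable under a polish restart.

The homogeneous model is comfortably identified and recovery of the
lagged coefficients at $n = 5000$ is well within Wald bands. The
random-intercept variant is *locally identified but weakly*: the
Jacobian of the implied moments has full rank, with a condition number
around $10^7$ — a near-flat ridge trades wave-1 error (co)variances
against latent loadings, a direct consequence of the persistent
dynamics (eigenvalue 0.93) mimicking a random intercept over only four
waves. Two numerical choices follow. First, standard errors come from
the curvature of the smooth discrepancy surface (the admissibility
penalty is excluded from differencing), since the optimum can sit on
the boundary of the parameter space where penalty cliffs corrupt finite
differences. Second, Hessian eigenvalues that are numerically zero or
negative are floored, so flat directions yield honestly enormous
standard errors rather than failures. Recovery checks therefore focus
on the well-resolved quantities — lagged coefficients, and the latent
(co)variances whose Wald bands reflect the weak identification.

`predict_latents()` computes empirical-Bayes (conditional-mean) latent
scores $\hat z = \Sigma_{\eta o}\Sigma_{oo}^{-1}(y - \mu_o)$; they are
shrunken toward zero by the model's signal-to-noise ratio, and the
tests verify the empirical shrinkage slope against the model-implied
one.

## Numerical conventions

* Variable order is fixed — latents first, then wave-major observed
  ($X_1, Y_1, X_2, Y_2, \dots$) — so all matrices are deterministic and
  serializable.
* PSD checks allow eigenvalues down to $-10^{-8}$ (relative);
  conditioning clamps round-off-negative variances at zero.
* Intervened coordinates keep exact zero covariance rows; conditioning
  on a degenerate coordinate is vacuous when the stated value matches
  the point mass and an error otherwise — no silent pseudo-inversion.
* Comparisons against printed reference values use half a unit in the
  last printed decimal; the printed optimal dose appears both as
  $-33.34$ and $-33.33$ in the source material (the exact value is
  $-33.\overline{3}$), so dose comparisons allow $\pm 0.01$.
* Wave-1 moments may be given explicitly or requested as the Lyapunov
  solution (`stationary_init = TRUE`); a regression test confirms the
  two agree for the shipped example.

## Limitations

Nonlinear or non-Gaussian mechanisms, time-varying coefficients,
unequally spaced or continuous-time dynamics, missing data, measurement
error, counterfactual (cross-world) queries, and soft interventions are
out of scope. Identification here is by direct computation on a known,
correctly specified model; with real data the causal structure is an
assumption, and the sensitivity and specification tests that would
probe it are not part of this package.
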
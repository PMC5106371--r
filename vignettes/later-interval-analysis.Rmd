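---
title: "Modelling self-paced inter-movement intervals with LATER"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling self-paced inter-movement intervals with LATER}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

## The model

When a person performs a self-paced, repetitive action -- tapping a finger,
repeating a syllable -- each movement can be treated as the outcome of a
decision. The LATER family of race models (linear approach to threshold with
ergodic rate) describes that decision as a signal that rises linearly from a
baseline at a rate drawn fresh on every trial from a normal distribution
$N(\mu_r, \sigma_r^2)$, and triggers the movement when it reaches a threshold
at distance $\theta$ above baseline. The inter-movement interval is then

$$T = \theta / r, \qquad r \sim N(\mu_r, \sigma_r^2),$$

so the *promptness* $1/T$ is normally distributed with mean
$\mu_p = \mu_r/\theta$ and SD $\sigma_p = \sigma_r/\theta$. A variable whose
reciprocal is Gaussian is called **recinormal**. Two consequences drive the
whole analysis:

1. **Reciprobit linearity.** Plot interval quantiles on a reciprocal-time
   abscissa ($-1/t$, so that time still increases to the right and reaches 0
   at $t=\infty$) against the probit of cumulative probability, and a
   recinormal sample falls on a straight line with slope $1/\sigma_p$ and
   ordinate-intercept $k = \mu_p/\sigma_p$ at the infinite-time axis.
2. **Two signatures of change.** If a manipulation reduces the
   baseline-to-threshold distance $\theta$ (a shorter race), both $\mu_p$
   and $\sigma_p$ scale by the same factor: the reciprobit line *swivels*
   about its fixed infinite-time intercept. If instead the mean rate of rise
   $\mu_r$ changes, only $\mu_p$ moves: the line *shifts* along the time
   axis at constant slope.

Only two of $(\theta, \mu_r, \sigma_r)$ are identifiable from interval data;
the package convention sets $\theta = 1$ in the baseline condition, so a
threshold change is reported as the dimensionless ratio
$\theta_\text{stim}/\theta_\text{pre} = \mu_{p,\text{pre}}/\mu_{p,\text{stim}}$.
A ratio below 1 means the race was shortened -- behaviour accelerated beyond
the intended pace.

## Likelihood and fitting

All fitting happens on the promptness scale, where the model is Gaussian and
the MLE is closed form: $\hat\mu_p = \overline{1/t}$,
$\hat\sigma_p^2 = \overline{(1/t - \hat\mu_p)^2}$ (divisor $n$). Reported
log-likelihoods are on the *interval* scale, including the change-of-variables
Jacobian $-2\sum\log t_i$, so values are comparable across all models fitted
to the same intervals.

The promptness normal is left untruncated: mass at or below zero promptness
corresponds to "no response within finite time" and is ignored by the
likelihood, the classic treatment in this literature. This keeps the MLE
exact. The regime analysed here ($\mu_p/\sigma_p \approx 6.7$ at a CV of
0.15) puts negligible mass near the boundary; as a guard, parameter objects
raise a `near_boundary` flag (not an error) when $\mu_p/\sigma_p < 2$, i.e.
when more than about 2.3% of promptness mass is non-positive and the
untruncated approximation starts to bite.

### The four two-condition models

`fit_joint()` fits pre- and stimulation-window intervals jointly under four
nested parameterisations:

| model | constraint | parameters |
|---|---|---|
| null | everything shared | 2 |
| shift | $\sigma_p$ shared (common slope) | 3 |
| swivel | $\mu_p/\sigma_p$ shared (common intercept) | 3 |
| unconstrained | none | 4 |

Null, shift and unconstrained have closed-form MLEs. The swivel model is
maximised along its one-dimensional profile in the shared intercept $k_0$:
for fixed $k_0$ the per-condition $\hat\sigma$ solves the quadratic
$n\sigma^2 + k_0 S_1 \sigma - S_2 = 0$ (with $S_1 = \sum p_i$,
$S_2 = \sum p_i^2$), whose positive root is unique. The outer search
evaluates the profile on a 40-point log-spaced grid over $k_0 \in [0.5, 50]$
and refines the bracketing subinterval by Brent's method to a $k_0$
tolerance of $10^{-10}$. A profile maximum at the boundary of the search
interval returns the best iterate with a warning. The test suite verifies
the optimizer against an exhaustive grid search of the three-dimensional
swivel likelihood (separable over conditions at fixed $k_0$) to a relative
log-likelihood gap below $10^{-6}$.

Model comparison uses $\mathrm{BIC} = -2\ell + k\ln n$ with $n$ the total
interval count across both conditions -- the sample size of the joint
likelihood, the standard convention when a single likelihood spans both
samples. Winner margins are labelled with the Kass--Raftery bands, half-open
as $(0,2]$ weak, $(2,6]$ substantial, $(6,10]$ strong, $>10$ very strong.

### Threshold ratio and bootstrap

Under the fitted swivel model `threshold_ratio()` returns
$\mu_{p,\text{pre}}/\mu_{p,\text{stim}}$, asserting that the
$\sigma_p$ ratio agrees within optimizer tolerance (they are equal exactly
at the constraint). `bootstrap_ratio()` resamples intervals with replacement
*within* each condition -- condition membership is fixed by the stimulation
protocol, so condition sizes are preserved -- refits the swivel model, and
reports the percentile CI (2.5/97.5 centiles at the default level).
Percentile rather than BCa: it is the simplest reproducible choice given
that nothing more specific is required of the interval; BCa is a possible
extension. Resamples on which the fit fails (e.g. degenerate draws) are
redrawn, up to ten times the requested resample count. The whole procedure
is deterministic given its seed.

### The early-response mixture

Some blocks show a minor population of unusually fast responses -- a second,
steeper limb at the fast end of the reciprobit plot. `fit_early_mixture()`
fits a free two-component normal mixture on the promptness scale by EM,
initialised by splitting the sample at its 85th percentile (the early
component is by definition minor, so the upper promptness tail seeds it).
Convergence is declared when the log-likelihood gain drops below $10^{-8}$,
capped at 500 iterations; monotonicity of the EM objective is tested. The
component with the larger $\mu_p$ is labelled early; if it carries at least
half the mass the labels are swapped (early stays the minor component) and
the fit is flagged `relabelled`. If the mixture fails to beat the
single-component fit, the single fit is returned with `weight_early = 0` and
`single_component = TRUE`. A shared-intercept (constrained) mixture would be
an alternative parameterisation; the free mixture was chosen because it
makes no mechanistic assumption about the early population, at the cost of
two extra parameters -- a sensitivity analysis hook rather than a settled
question.

## The simulator and what it emulates

`simulate_experiment()` generates a block of self-paced alternating
movements with an abrupt condition switch: events accrue sequentially,
$t_{k+1} = t_k + T_k$, with $T_k$ drawn from baseline promptness parameters
while $t_k$ is before stimulation onset and from stimulation parameters
once $t_k$ enters the stimulation window. Defaults are the study
conditions: baseline frequency 2.96 Hz, threshold factor 0.65 in the
stimulated manual condition (0.56 vocal). The promptness CV of 0.15 is a
fixture choice -- interval dispersion is not pinned down by any reported
value -- and is recorded in every manifest. Stimulation is a pure swivel by
default (both promptness parameters divided by the threshold factor,
preserving the intercept exactly, by construction); a shift mode rescales
only $\mu_p$, for model-selection calibration. Nonpositive rate draws are
rejected and redrawn -- the simplest exactly documentable scheme, matching
the untruncated likelihood's "no response" interpretation.

Two realistic nuisances are modelled. Exactly one interval straddles the
stimulation onset (drawn under baseline parameters); the windowing rules
discard it rather than split it. Optional frame quantization rounds *event
times* (not intervals) to the nearest multiple of the frame step -- 40 ms
for standard 25 frame/s clinical video -- so quantization error accumulates
along the stream as it does in real video annotation. Quantized data are
fitted with the same continuous likelihood; an interval-censored likelihood
is deliberately out of scope, and the quantization-robustness check in the
acceptance suite quantifies the (small) resulting bias at the study
conditions instead.

What the simulator does *not* emulate: drift in the self-chosen pace,
serial correlation between successive intervals, movement-duration overlap,
detection/annotation error beyond frame quantization, and any
patient-to-patient heterogeneity beyond what the caller builds from
multiple configs. Passing tests therefore demonstrate that the estimators
recover the truth under the model's own assumptions at realistic parameter
values -- not that real clinical recordings satisfy those assumptions.

## The interval pipeline

`events_to_intervals()` labels successive differences of one block's event
times. Window membership is half-open: an event at exactly the onset
belongs to the stimulation window, $[\text{onset}, \text{offset}]$, and the
pre window is $[\text{onset} - w, \text{onset})$ with $w$ defaulting to the
stimulation duration so the two conditions are comparable in exposure. An
interval is kept only if both bounding events lie in the same window;
everything else is discarded and counted, and the counts satisfy
$n_\text{pre} + n_\text{stim} + n_\text{discarded} = n_\text{events} - 1$
on every block. Deterministic boundary behaviour was preferred over any
interpolation of straddling intervals.

`frequency_stats()` summarises instantaneous frequency ($1/T$, Hz) per
patient x effector x condition cell and tests the stimulation effect with
an ordinary-least-squares ANOVA (condition, effector, patient and
interactions as categorical predictors) plus Bonferroni-adjusted
pooled-variance t tests per cell. The OLS model is a deliberate
fixed-effects approximation of a mixed model with patient as a random
factor: with the very small patient counts typical of intracranial work a
random-effect variance is ill-estimated, so patient enters as a fixed
factor and the report header flags the approximation. Cells below the
minimum size are excluded with a warning, never silently.

## Problem sizes and numerical choices

The test and acceptance runs use sizes at which every check completes
comfortably on a single core: grid-search oracles at $n \le 50$ per
dataset; parameter recovery and model-selection calibration at 2000
intervals per condition over 20 seeded replicates; bootstrap coverage at
150 intervals per condition with 1000 resamples over 100 replicates;
consistency checks at up to 100,000 simulated trials. Sufficient-statistic
likelihood evaluation makes a single swivel fit sub-millisecond, which is
what makes the coverage simulation cheap. Ties in the reciprobit transform
are collapsed to the mean of their Hazen plotting positions
$(i - 0.5)/n$ -- a convention chosen to keep extreme probits finite; none
of the standard plotting positions is canonical for this analysis, and the
choice only affects the plot, not the likelihood fits.

## Known limitations

* The untruncated promptness likelihood is exact only away from the zero
  boundary; heavily dispersed data ($\mu_p/\sigma_p < 2$) trip the validity
  flag and deserve a truncated or censored treatment this package does not
  provide.
* Frame-quantized data are fitted with the continuous likelihood; at 40 ms
  and ~3 Hz the induced ratio bias is below the acceptance tolerance, but
  coarser sampling or faster behaviour would need an interval-censored
  likelihood.
* The frequency ANOVA is a fixed-effects approximation; its F statistics
  are not comparable to a random-effects (REML) analysis and are not meant
  to reproduce one.
* Only two-condition designs are supported (pre vs stimulation); three or
  more conditions, hierarchical pooling across patients, and mixtures with
  more than two components are out of scope.
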
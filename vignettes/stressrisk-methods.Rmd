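---
title: "Methods: hierarchical Bayesian estimation of risk attitudes, loss aversion and consistency under acute stress"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hierarchical Bayesian estimation of risk attitudes, loss aversion and consistency under acute stress}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Whether acute stress changes how people make risky monetary decisions cannot
be settled by the raw probability of gambling: that single number confounds
at least three distinct processes — how strongly the utility of money
saturates (risk attitude), how much more losses weigh than gains (loss
aversion), and how deterministically choices track utility differences
(consistency). `stressrisk` implements a task and model family that
separates the three, estimates them hierarchically across a cohort, and
tests whether a within-subject stress manipulation (or the cortisol response
it provokes) moves any of them.

## Choice model

Each trial offers a 50/50 gamble against a guaranteed amount. Outcomes are
valued by a two-branch power utility,

$$u(x^+) = p\,x^{\rho}, \qquad u(x^-) = -p\,\lambda\,(-x)^{\rho},$$

with a single curvature $\rho$ shared across gains and losses and a
multiplicative loss weight $\lambda$. The gamble's utility is the sum of its
two equiprobable branch utilities; the guaranteed utility uses $p = 1$.
Choice follows a softmax (logistic) rule,

$$P(\text{gamble}) = \bigl(1 + e^{-\mu\,(u_g - u_s)}\bigr)^{-1},$$

where $\mu \ge 0$ is the consistency (inverse temperature): $\mu = 0$ is
coin-flipping, large $\mu$ near-deterministic choice. The task deliberately
uses only the probabilities 0.5 and 1, eliminating probability weighting and
ambiguity from the model by design; there is no temporal or learning
component. Note that $\mu$ multiplies a utility difference measured in
(dollars)$^{\rho}$: its absolute scale is relative to the task's stake
sizes and is not portable across designs with different dollar ranges.

Session-level parameters arise from log-additive subject effects,

$$\theta_{i,j} = \exp\!\bigl(\theta_i + m_j\,\Delta\theta_{Si} +
\mathrm{Day}_j\,\Delta\theta_{Di}\bigr),$$

applied componentwise to $(\rho, \lambda, \mu)$. The modulator $m_j$ is
either the binary stress indicator of session $j$ (the *condition* model,
Model 1) or the session's $\Delta$Cortisol value (the *covariate* model,
Model 2). The exponential keeps every session parameter strictly positive
for any finite effects. Subject-level baselines and effects are Gaussian
across the cohort:

$$\theta_i \sim N(\theta_M, \theta_V), \quad
\Delta\theta_{Si} \sim N(\Delta\theta_{SM}, \Delta\theta_{SV}), \quad
\Delta\theta_{Di} \sim N(\Delta\theta_{DM}, \Delta\theta_{DV}).$$

The trial likelihood is Bernoulli in the softmax probability, evaluated in
log-sigmoid form with per-trial probabilities clipped to
$[10^{-12}, 1-10^{-12}]$ — at consistency values around 25 the logits on
saturated trials exceed 700 and naive exponentials overflow; the clip also
keeps the posterior density finite everywhere, which matters only in the
extreme tails and is documented here rather than hidden.

## Task generator

`generate_trial_set()` draws 120 gain-loss trials (gain vs. loss gamble
against a guaranteed \$0) and 30 gain-only trials (positive-or-zero gamble
against a smaller guaranteed amount) on a \$0.25 grid — gains \$2–12,
loss magnitudes \$1–6, gain-only gains \$3–12 with guaranteed fractions
0.3–0.7 — with unique value triples (duplicates are redrawn, bounded) and a
seeded random presentation order. The two families jointly identify the
three parameters: gain-only trials pin down $\rho$ via certainty
equivalents, gain-loss trials then separate $\lambda$, and trial-to-trial
stochasticity identifies $\mu$.

One design quantity deserves emphasis: for a consistent agent
($\mu \approx 26$) a trial carries information about $\mu$ only if its
choice probability is away from 0 and 1, i.e. if
$|\mu \, \Delta u| \lesssim 3$, a band of width about \$0.6 in the gain
around the indifference line $g = \lambda^{1/\rho} l$. Independently
uniform draws on the stated ranges place only ~6% of trials in that band,
leaving $\mu$ nearly unidentified. The generator therefore *anchors* a
configurable fraction of gain-loss gains near the indifference line at
reference parameters ($\rho = 0.92$, $\lambda = 2.2$) with ±\$0.25 jitter,
and pins a fraction of gain-only guaranteed amounts to the gamble's
certainty equivalent ($0.5^{1/\rho} \approx 0.47$ of the gain).
`design_informativeness()` measures the calibration: the default design
(anchored fractions 0.65 / 0.8) keeps 35–40% of trials informative at the
reference parameters. The validation design used for parameter recovery
(`recovery_study_config()`) raises the anchored fractions to 0.9, because
a recovery study's purpose is a sharp group-level target; with the looser
default design the group consistency parameter is recovered with a
systematic 10–15% downward attenuation that we traced to weak per-session
information, not to the sampler (the posterior matches an independent JAGS
implementation of the identical model) nor to the priors (halving or
quartering the SD prior scale changes nothing).

## Synthetic cohort

`simulate_study()` emulates the full design: 120 subjects split evenly
across the four crossed groups (SS, SC, CS, CC; a most-even split with a
warning when the cohort size is not divisible by 4), 64 female / 56 male at
the default size, two sessions per subject (Day 1, Day 2), an independent
150-trial set per subject-day by default (`shared_trials` reproduces a
fixed-set variant), simulated choices with realized outcomes, a four-sample
cortisol panel per subject-day, and the payment rule (\$30 endowment plus
the summed outcomes of 15 randomly selected trials). One master seed spawns
named substreams (`design`, `population`, `trials/…`, `choices/…`,
`cortisol/…`, `payment/…`) so any component can be regenerated alone.

Generator defaults are the task-typical values: baselines
$e^{\theta_M} = (0.92,\ 2.22,\ 25.9)$ with population SDs
$(0.24,\ 0.84,\ 0.87)$ on the log scale, zero mean stress and day effects,
and effect SDs of 0.1 — effect heterogeneity is not separately reported for
this design, so a small nonzero default keeps the generative model honest
without drowning the means. Cortisol panels use group-by-day mean
baseline-to-pre-task changes of (SS) 0.17/0.11, (SC) 0.10/0.01, (CS)
−0.01/0.16, (CC) −0.05/−0.01 concentration units for Day 1/Day 2,
linearly interpolated across the four timepoints, with additive Gaussian
timepoint noise (SD 0.03) and a baseline SD of 0.03 around a mean of 0.15.
Concentrations are floored at 0.01. The panel's units are treated as opaque
"concentration units" matching the magnitudes above; typical salivary
cortisol is reported in µg/dL, and the transform below is not
unit-invariant, so the 0.5 offset is applied in these native units.

What the simulator does *not* emulate: cortisol pharmacokinetics or
circadian structure beyond the linear drift implicit in the group means;
non-response trials (the real task had a 2 s response window; loaders drop
missing choices with a logged count, but the generator produces complete
sessions); any within-session learning or fatigue. Passing recovery tests
therefore demonstrates that the *estimator* is faithful to the *model*, not
that the model captures every feature of real behavior.

## Cortisol preprocessing

The covariate is the change from the baseline (sample 1) to the pre-task
(sample 3) concentration, passed through a modified log,
$\Delta\text{Cortisol} = \log(\Delta_{\text{raw}} + 0.5) - \log(0.5)$,
which reduces positive skew while mapping zero change to zero; it requires
$\Delta_{\text{raw}} > -0.5$ and inverts exactly
($\exp(v) \cdot 0.5 - 0.5$). The covariate enters Model 2 in raw
modified-log units (a `standardize` flag offers z-scoring; the worked
reconstructions at covariate values −0.04 and 0.20 are consistent with raw
units, which decided the default).

Subjects with extreme overall cortisol are screened out before covariate
analyses: a subject is excluded when their mean concentration across all
samples exceeds the rest of the cohort's mean by more than 30 leave-one-out
standard deviations. The leave-one-out form is deliberate: with an
inclusive SD, one extreme subject among $n$ peers can reach at most about
$\sqrt{n}$ SDs, so a 30-SD rule could never fire. The rule is one-sided
(high side only) and single-pass — re-running it on the kept set removes
nobody.

## Estimation

`fit_hierarchical()` samples the full posterior over
$\{\theta_M, \theta_V, \Delta\theta_{SM}, \Delta\theta_{SV},
\Delta\theta_{DM}, \Delta\theta_{DV}\}$ (covariate analogues in Model 2)
and all subject deviates. Priors are weakly informative on the log scale —
baseline means $N(0, 5)$, effect means $N(0, 2)$, SDs half-$N(0, 2)$ — and
configurable through `prior_config()`; the recovery results are insensitive
to the SD scale over 0.25–2. The subject level is parameterized
non-centered (deviate = mean + SD × standard normal), which is the
mathematically identical form of the population equations with better
sampling geometry when subjects are weakly informed.

The sampler is a compiled adaptive Metropolis-within-Gibbs scheme with
three additions chosen for this posterior's geometry:

* **Scalar adaptive updates** for every subject deviate and hyperparameter
  (Robbins–Monro adaptation of log proposal scales toward 0.44 acceptance,
  warmup only), with per-trial power terms $g^{\rho}$ cached and recomputed
  only when a proposal touches $\rho$.
* **Joint mean-vector proposals** (Haario-style, covariance learned during
  warmup; one 3-d block per mean vector plus one 9-d block over all means,
  several rounds per sweep): the posterior correlates $\rho$ with $\lambda$
  along the indifference line, $\rho$ with $\mu$ through the utility scale,
  and baselines with effect means through the group structure, and scalar
  updates alone crawl along those ridges.
* **Interweaving (ASIS)** for each (mean, SD) pair: subject deviates are
  re-expressed in centered form (which is exactly what the likelihood
  sees), the mean is Gibbs-updated and the SD Metropolis-updated under the
  Gaussian population density and the priors at fixed centered values, then
  mapped back. This costs no likelihood evaluations and fixes the slow
  mixing of the SD hyperparameters that the non-centered form alone shows
  when subjects are strongly data-informed (300 trials each).

Chains are initialized at a complete-pooling maximum-likelihood estimate of
$(\rho, \lambda, \mu)$ plus chain-specific jitter, and each chain runs on
its own seeded RNG substream, making fits bit-reproducible for a given
seed. The study-scale configuration is 4 chains × 3000 warmup × 3000 kept
(12,000 draws per parameter); the desk-scale configuration (4 × 500 × 500)
is used for recovery validation and interactive work, where mean
group-level split-Rhat values land near 1.1 and all recovery targets are
insensitive to doubling the run length.

## Diagnostics, intervals, reconstruction

* `rhat()` implements split-chain potential scale reduction; the default
  applies it to rank-normalized draws (the modern robust variant, bounded
  on fully separated chains), with the classic formula available.
  Zero-variance chains yield `NA` rather than an error.
* `credible_interval()` returns central (equal-tailed) quantile intervals.
* `max_level_excluding_zero()` returns the largest central level whose
  interval excludes zero, $2\,|\hat F(0) - 0.5|$ with $\le$-counting at
  ties, capped at $(n-1)/n$ with the resolution reported as an attribute.
* `reconstruct_params()` reports natural-scale parameters by exponentiating
  posterior means of the group-level means (baseline; Day 2 adds the day
  effect; stress adds the stress effect; `cortisol_at = x` scales the
  covariate effect). Posterior means, not medians, are used throughout for
  consistency with the reconstruction convention.

## Validation by parameter recovery

With no deposited raw data, correctness is argued by simulation.
`run_parameter_recovery()` generates a reduced cohort — 30 subjects × 2
days × 150 trials, baselines at $(0.92, 2.22, 25.9)$, population SDs 0.05
and effect SDs 0.02 (small, so the group target is sharp), zero stress
effects — and refits Model 1 at desk scale. In the `day` variant the
generating day effects move Day-2 $\lambda$ to 2.57 and $\mu$ to 34.3
(log-ratio effects), with the $\rho$ day effect zero. Across seeds the
reconstructed baselines land within ~2% ($\rho$, $\lambda$) and ~6%
($\mu$) of truth, day-effect intervals for $\lambda$ and $\mu$ exclude
zero, and the (truly zero) stress-effect intervals contain zero.
`scripts/acceptance.R` reruns exactly this computation from a command-line
seed. Problem sizes were chosen so a full validation (two fits) completes
in a few minutes on one core; the analysis scripts accept `--full` for
study-scale runs.

## Known limitations

* $\mu$ is design-relative (see above); comparisons across tasks with
  different stake grids are not meaningful without rescaling.
* The sampler is a random-walk family scheme: it needs the joint/ASIS
  machinery above to mix at the sizes used here, and very large cohorts
  would be better served by a gradient-based backend; the draws contract
  (`sr_fit`) is backend-agnostic.
* Effect-heterogeneity SDs ($\Delta\theta_{SV}$ etc.) are weakly identified
  in a two-session design and their posteriors lean on the prior; the
  reported effects are the means, which are robust to this.
* The leave-one-out exclusion rule and the anchored task design are
  package-level interpretations of under-specified procedures; both are
  flagged where they matter and controlled by configuration.
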
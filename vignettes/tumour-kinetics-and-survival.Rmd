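---
title: "Tumour growth kinetics metrics and survival: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tumour growth kinetics metrics and survival: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tgmetrics)
```

## The question

Longitudinal tumour burden in solid-tumour trials is summarised by the
RECIST sum of longest diameters (SLD, cm), measured on a fixed scan
schedule until progressive disease. Fitting a decay/re-growth model to
these series yields per-patient metrics — decay rate (DR), re-growth rate
(GR), time to tumour re-growth (TTG) — that have been proposed as
predictors of overall survival (OS) and as early-development decision
tools. Two distinct uses must be separated:

* **individual risk** — does a patient's metric predict *that patient's*
  survival? Here the time taken to *estimate* the metric matters: TTG and
  GR are only known once the whole pre-progression series has been
  observed, so correlating them with OS from treatment start builds in a
  guarantee-time (time-dependent) bias.
* **group risk** — given two historical arms, can arm-level summaries of
  the metrics predict the hazard ratio of a future head-to-head trial?
  Here full time courses are legitimately available.

The package implements both analyses, a forward/reverse alignment device
that removes the individual-risk bias, and a synthetic-cohort generator so
the whole pipeline is testable without any proprietary trial data.

## The kinetic model

SLD is modelled as

$$\mathrm{SLD}(t) = A\,(e^{-Bt} + e^{Ct} - 1), \qquad A, B, C > 0,$$

with $t$ in weeks: exponential shrinkage at rate $B$ superimposed on
exponential re-growth at rate $C$. The curve has a unique minimum at

$$t_p = \frac{\log B - \log C}{B + C},$$

negative when $B < C$ (the fitted profile grows monotonically on study).
In forward time $B$ is DR and $C$ is GR, and TTG is $t_p$ clamped to
$[0, \text{observation span}]$. The model-predicted percent change at
week 8, $100(e^{-8B} + e^{8C} - 2)$, is independent of $A$.

*Clamping convention.* Nothing pins $t_p$ inside the observed window for
monotone profiles, so `derive_metrics()` clamps it to the span and flags
the clamp (`tp_clamped`). This keeps TTG well defined and bounded; it is a
package convention, not a property of the model.

*Units.* Weeks are canonical internally (scan schedules are 6- or
8-weekly); summaries convert to months as `weeks * 7 / 30.4375`.

## Population fit

`fit_population()` places the model in a nonlinear mixed-effects frame:
log-normal inter-individual variability on $(A, B, C)$ with diagonal
covariance, additive Gaussian residual error on the cm scale. Patients
need a pre-treatment scan and at least one on-treatment scan; exclusions
are reported, never silent. Two-point patients are retained by default —
shrinkage makes them estimable — and a `min_points` setting can demand
more.

Estimation is a two-stage penalised scheme. Each patient's log-parameters
minimise

$$J_i(p) = \sum_j \frac{(y_{ij} - f(t_{ij}; e^p))^2}{2\sigma^2}
         + \sum_k \frac{(p_k - \mu_k)^2}{2\omega_k^2},$$

by a Levenberg-damped Gauss–Newton solver (compiled, analytic gradients,
log-scale box constraints that keep the exponentials finite). The
population parameters are then obtained in two stages: moment updates of
$(\mu, \omega^2, \sigma)$ from the per-patient modes with first-order
curvature corrections (which stop shrinkage from collapsing the
variances), followed by direct maximisation of the Laplace-approximate
marginal likelihood with the modes profiled out (Nelder–Mead with simplex
restarts). The second stage exists because pure moment iteration stalls on
near-degenerate cohorts (e.g. no true inter-individual variability): the
variance estimate collapses geometrically while the fixed effects creep,
and the iteration freezes short of the optimum. Direct maximisation does
not have this failure mode, and on a noise-free homogeneous cohort the
generating parameters are recovered to better than 0.1%.

Numerical details that matter:

* starting values are seed-free heuristics ($A$ from the baseline scan,
  $B$ and $C$ from log-linear slopes on either side of the observed
  nadir), with a population-start and a swapped-rate start per patient on
  the first pass to dodge local minima of the biexponential;
* $\sigma$ is floored at $10^{-4}$ cm and each $\omega_k^2$ at $10^{-6}$
  so noise-free data remain well posed;
* SLD values below 0.1 cm are floored at 0.1 cm with a warning (RECIST
  minimum-measurable convention);
* moment iterations stop at a relative tolerance of $10^{-6}$ or 200
  iterations; non-convergence is flagged on the returned object, not
  hidden.

`eb_estimate()` exposes the per-patient penalised fit (the empirical Bayes
mode) for a new series under a fitted population; it is deterministic and
matches a brute-force grid-plus-polish optimisation of the same objective
to $10^{-4}$ in the tests.

This estimator is *not* claimed to be numerically identical to
FOCE/`nlme`; it is a reproducible first-order approximation adequate at
the data density of the emulated trials (3–13 scans per patient).

## Forward and reverse alignment

Forward alignment indexes each series from treatment start and correlates
metrics with OS. Reverse alignment reflects each series about its last
included scan — the progression scan, since imaging stops at progression —
so the progression scan becomes time 0 and the clock runs backwards on a
non-negative axis; the same fitting code applies, and the phase roles swap
(the first-phase rate now estimates GR, the second-phase rate DR). The
turning point of the reverse fit is the time to nadir (TTN), and
TTG = span − TTN. The reverse outcome is post-progression survival,
OS − PFS, with the OS censoring indicator carried over.

Two conventions are worth stating because the underlying protocols leave
them open. The imaging origin for reversal is the last scan (not the
recorded PFS date; the small gap between the two is ignored). Patients
whose progression event was death itself have no post-progression time and
no imaging beyond progression; they are flagged and excluded from
reverse-alignment survival analysis, with the exclusion count always
reported.

One structural fact deserves emphasis: the biexponential family is **not
closed under time reflection**. If $f(t)$ follows the model, then
$f(T - s)$ is a three-exponential-amplitude curve that the model can only
approximate, so a reverse fit is a genuine re-approximation, not a
re-parameterisation, and reverse-fit parameters are *not* algebraically
the swapped forward parameters even on noise-free data. The package treats
the role swap as the interpretive convention it is; the tests document the
quantitative gap rather than paper over it.

## Concordance probability and bootstrap

Individual risk is quantified by a model-based pairwise concordance
probability (CP) in the Gönen–Heller style: with Cox linear predictor
$\eta_i = \beta x_i$, each unordered pair contributes
$1/(1 + e^{\eta_\text{better} - \eta_\text{other}})$, where "better" is
pre-specified per metric — higher TTG is better, lower GR is better — and
tied covariates contribute 1/2. CP = 0.5 means no consistent relationship;
$\beta = 0$ gives exactly 0.5 for any cohort. Because the benefit
direction is pre-specified, a fitted coefficient whose sign contradicts
expectation yields CP < 0.5, which the unsigned estimator cannot express;
when the fitted sign matches expectation the signed and standard
estimators coincide. CP is computed on the same data that produced
$\beta$ (apparent CP, no cross-validation), ties are handled by Efron's
method in the Cox fit, and the metric enters on its natural scale.

Uncertainty comes from a patient-level percentile bootstrap (default
1,000 resamples at the original cohort size; Cox fit and CP recomputed per
replicate); a metric is called significant when the 95% interval excludes
0.5. No multiplicity correction is applied — each metric is reported with
its own interval. Percentile rather than BCa is the simplest method
consistent with a plain "bootstrapped samples" prescription.

## Group risk: resampled test trials

`simulate_test_trials()` draws 1,000 head-to-head test trials by sampling
patients with replacement from two historical arms at the emulated trial's
exact arm sizes (110 test, 112 reference by default), carrying each
patient's full record intact. Per replicate it computes the PFS hazard
ratio and the ratios of arm-mean GR and arm-mean TTG, oriented so that
values below 1 favour the test arm (GR: test/reference; TTG:
reference/test). These oriented ratios are reported as *proxies* for the
predicted OS hazard ratio — the analysis scheme treats them on the HR
scale without a formal surrogacy model, and the package labels them as
such. Metrics come from a single population fit per arm (fit once,
resample patients); refitting the mixed model inside every replicate would
multiply the cost a thousandfold for no change in the resampling logic.
The squared Pearson correlation between the TTG and GR ratios across
replicates measures how interchangeable the two metrics are as trial-level
predictors.

## The synthetic cohort generator

`generate_cohort()` emulates a phase III comparator arm: log-normal
$(A, B, C)$; scans every 6 or 8 weeks up to a maximum follow-up, with
optional uniform jitter; additive $N(0, \sigma^2)$ noise floored at
0.1 cm; progression at the first scan whose SLD reaches $1.2\times$ the
running nadir (a RECIST-1.0-like rule on SLD only); imaging truncated at
progression; a small per-interval probability of death during imaging
(the "progression by death" subset); post-progression survival either
**null** (exponential, independent of kinetics) or **linked**
(log-hazard linear in true GR and TTG); administrative censoring on both
endpoints.

The presets in `nsclc_arm_spec()` were calibrated once against the
published arm-level summaries of three NSCLC comparator arms and then
frozen:

| preset | scans | baseline SLD | median PFS | extras |
|---|---|---|---|---|
| docetaxel-like | 8-weekly | ~8.3 cm | ~3.7 months | OS−PFS median ~5.2 months |
| erlotinib-like | 6-weekly | ~8 cm | ~4.1 months | short OS follow-up; OS median typically not estimable |
| paclitaxel/carboplatin-like | 8-weekly | ~10.7 cm | ~7 months | deeper response (week-8 change ~ −15%) |

Log-scale SDs are 0.4–0.45 for $A$ and 0.5 for the rates;
$\sigma = 0.3$ cm. Death-during-imaging probabilities were set so that
well under 10% of progression events are deaths, matching the published
pattern in which imaging drop-out is overwhelmingly treatment
discontinuation rather than death (the package's `dropout_assessment()`
reproduces this check).

**What the generator does and does not emulate.** It reproduces the
schedule structure, baseline burden, progression-triggered drop-out,
censoring patterns and marginal survival scales of the real arms. It does
not reproduce real-data features such as non-target/new-lesion
progressions (only an SLD rule, plus the independent death hazard),
missed visits, measurement-error heavy tails, or — importantly — any
dependence of post-progression survival on pre-progression dynamics under
the null model. Passing tests on these cohorts therefore demonstrate that
the *pipeline* behaves correctly under known mechanisms, not that real
NSCLC data satisfy those mechanisms.

A structural consequence worth knowing: under the strict null
post-progression model, the forward-alignment CP against OS is bounded
near 0.55–0.60 no matter how informative the kinetics are, because OS is
PFS plus an independent component that carries most of the variance, and
PFS itself is quantised to the scan grid. Forward CPs in the 0.6–0.7
range reported for real NSCLC comparator arms are therefore evidence that
real OS retains more kinetics-linked structure than the strict null allows — the qualitative
forward/reverse contrast (forward intervals excluding 0.5, reverse
intervals straddling it) emerges from the generator, but the full
magnitude of the forward association does not. The linked post-progression
model exists precisely so users can explore departures from the null.

## Problem sizes in the tests

The test-suite simulations use cohorts of 100–400 patients, 10–20 seeded
replicates for recovery and pattern checks, 200 replicates for bootstrap
coverage, and 1,000 bootstrap/trial resamples where a 1,000-sample scheme
is part of the emulated analysis; these sizes were chosen so the full
suite exercises every stage end-to-end at desk scale.

## Known limitations

* The estimator is a first-order (Laplace) approximation with diagonal
  random effects; no covariances, no covariate models, no SAEM.
* Reverse-alignment fits inherit the non-closure approximation described
  above.
* CP is apparent (in-sample) concordance, as in the emulated analysis;
  no censoring-weighted c-index is provided.
* The OS-HR "predictions" from GR/TTG ratios are scale proxies, not
  calibrated surrogacy estimates.
* Landmark analysis at a fixed forward time — the other standard remedy
  for time-dependent bias — is out of scope.
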
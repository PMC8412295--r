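---
title: "Repeated-measures dose finding with nTTP and early efficacy: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Repeated-measures dose finding with nTTP and early efficacy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rmdose)
```

This vignette is the package's account of the science it implements: the
toxicity score, the Bayesian models, the decision rules, the simulation
machinery, and — importantly — the choices we made where the design was
genuinely open, with the reasoning behind each.

## The toxicity endpoint

A patient-cycle toxicity profile is a vector of maximum observed grades
$G_l \in \{0,\dots,4\}$, one per monitored toxicity type.  Given
elicited severity weights $w_{lh}$ (non-negative, non-decreasing in
grade, zero at grade 0), the normalized total toxicity profile is

$$\mathrm{nTTP} = \frac{1}{v}\sqrt{\sum_{l=1}^L w_{l,G_l}^2},$$

the Euclidean norm of the realized weights divided by a normalization
constant $v$.  `weight_matrix()` enforces
$v \ge \sqrt{\sum_l \max_h w_{lh}^2}$, which is exactly the condition
under which every possible profile scores in $[0,1]$.  With the default
three-type matrix (renal and neurological weights $0, 0.5, 0.75, 1,
1.5$; hematological $0, 0, 0, 0.5, 1$) and $v = 2.5$, the worst profile
scores $\sqrt{5.5}/2.5 \approx 0.938$.

We deliberately use the Euclidean-norm form rather than a plain sum of
squared weights: only the norm form respects the $[0,1]$ normalization
claim under $v = 2.5$ (the maximal sum of squares is $5.5 > 2.5$), and
only the norm form reproduces the analytic scenario means that anchor
the test suite.  Grades are accepted with their CTCAE meaning (an
integer 0–4), never as 1-based column indices; a profile of grades
$(1,2,0)$ therefore scores $\sqrt{0.5^2+0.75^2}/2.5 = 0.361$.

The DLT rule is per-type and configurable: a profile is dose limiting
when any type reaches its minimal dose-limiting grade (defaults: 3 for
renal and neurological, 4 for hematological; `NA` disables a type).

## The longitudinal toxicity model

nTTP scores $y_{ij}$ for patient $i$ in cycle $j$ follow a
random-intercept linear mixed model

$$y_{ij} = \beta_0 + \beta_1 x_i + \beta_2 t_j + \gamma_i +
\varepsilon_{ij}, \qquad \beta_1 > 0,$$

with $\gamma_i \sim N(0, \sigma_\gamma^2)$ capturing within-patient
correlation and $\varepsilon_{ij} \sim N(0, \sigma_\varepsilon^2)$.
The positivity constraint on the dose effect encodes the monotone
dose-toxicity assumption.  Patients may contribute unequal numbers of
cycles; post-DLT dropout simply truncates a patient's rows, and the DLT
cycle itself is retained.  The response is modeled on its raw scale
with Gaussian error — adequate in the bulk of the $[0,1]$ range, a
known approximation near the boundaries.

**Priors** (all overridable through `parm()` blocks): Normal(0, 1000)
on $\beta_0$, $\beta_1$, $\beta_2$; Inverse-Gamma(0.001, 0.001) on both
variances.  The `gamma` block (Normal(0, 100) by default) supplies the
prior centre of the random intercepts; their spread is the hierarchical
$\sigma_\gamma^2$, so the block's variance is not used by the conjugate
hierarchy — it is retained for interface compatibility with the usual
control-list idiom.

**Sampling.**  All full conditionals are conjugate, so the sampler is a
bespoke Gibbs scan — no external MCMC engine.  Two numerical choices
matter:

* The fixed effects $(\beta_0, \beta_1, \beta_2)$ are drawn *as one
  block* from their joint Gaussian conditional: $\beta_1$ from its
  truncated-to-$(0,\infty)$ Gaussian marginal (inverse-CDF sampling,
  switching to Robert's exponential-rejection method when the
  truncation is more than five standard deviations into the tail), then
  $(\beta_0, \beta_2)$ from their exact conditional given $\beta_1$.
  With data on only a few dose levels the intercept and dose effect are
  nearly collinear, and a one-at-a-time scan mixes an order of
  magnitude more slowly; the block draw makes retained draws
  near-independent, which is what lets short default chains (2000
  iterations, 500 burn-in, thin 1, 1 chain) deliver stable posterior
  summaries.
* The warm start is deterministic — variances at 1, random intercepts
  at 0 — so a fixed seed reproduces a fit exactly.

With a single dose level in the data, $\beta_1$ is unidentified and its
truncated vague prior dominates; this is why the *designs* below never
rely on the model until at least two dose levels carry data.

## The joint toxicity-efficacy model

A single early-efficacy outcome per patient, $E_i \in (0,1)$, is linked
to toxicity through the shared random intercept:

$$E_i = \alpha_0 + \alpha_1 x_i + \alpha_2 x_i^2 + \nu\gamma_i +
\epsilon_{ei}, \qquad \epsilon_{ei} \sim N(0, \sigma_e^2).$$

The quadratic dose term admits non-monotone dose-efficacy shapes; the
loading $\nu$ measures the toxicity-efficacy association (a
compound-symmetric joint covariance).  Given $\gamma$, the block
$(\alpha_0, \alpha_1, \alpha_2, \nu)$ is a conjugate Gaussian
regression and is drawn jointly; the $\gamma_i$ conditional pools the
patient's toxicity residuals, the efficacy residual and the prior.  The
*predicted efficacy* of a dose is the posterior mean of
$\alpha_0 + \alpha_1 x + \alpha_2 x^2$ (random effect excluded).

## Decision rules

**Toxicity-only design.**  The Bayesian risk of dose $x$ is the
posterior expectation of the absolute loss
$|\pi_Y(x,\theta,t_1) - \pi_1|$, where $\pi_Y(x,\theta,t_1)$ is the
population cycle-1 mean nTTP and $\pi_1$ the elicited target.  We
average the loss over draws (the risk proper) rather than taking the
distance of the posterior mean; the cruder point-estimate reading is
available via `bayes_risk(method = "point_estimate")` for cross-checks
— the two rank doses identically whenever the posterior spread is
comparable across doses.  The rule set: 3+3 start-up until two dose
levels carry data, then risk minimization over doses no more than one
level above the highest tried, ties broken toward the lower dose.  The
start-up is the canonical table (0/3 escalate, 1/3 expand, ≤1/6
escalate, ≥2 de-escalate or stop at the lowest dose) — the specific 3+3
variant is a documented choice, as several circulate.

**Dual-endpoint design.**  Dose $x$ is *allowable* when
$P\{\pi_Y(x,\theta,t_1) < c_1 \mid O\} > p_1$ and
$P\{\pi_Y(x,\theta,t'_{1+}) < c_2 \mid O\} > p_2$.  For these two
conditions to be well defined we code the cycle covariate 0 for cycle 1
and 1 for all later cycles in every dual-design fit, so the late-cycle
quantity is the model's aggregate mean over cycles beyond the first —
our reading of an aggregate that the methodology leaves only loosely
specified.  (The toxicity-only design keeps the natural coding
$t_j = j$, which is what reproduces constant per-cycle increments in
its posterior surface.)  Stage 1 (first half of the sample) escalates
by risk minimization restricted to doses passing the cycle-1 condition
alone at cutoff `ps1` — the late-cycle condition needs the joint fit,
and a separate stage-1 cutoff mirrors the simulation interface.  While
only one dose level has data, stage 1 reuses the 3+3 start-up, since
the mixed model cannot yet inform escalation.  Stage 2 refits the joint
model at every cohort (the refit schedule is unstated in the
methodology; per-cohort refitting is the most adaptive choice) and
randomizes the next cohort among allowable doses with probability
$\exp\{\hat E_a\}/\sum_{x \in A}\exp\{\hat E_x\}$.  Stage 3 declares
efficacious every allowable dose within $\delta$ of the best predicted
efficacy and recommends the lowest.  An empty allowable set terminates
the trial at any stage; in the start-up phase a de-escalation below the
lowest dose also terminates, the 3+3's own stopping rule.

Defaults: $\delta = 0.1$ (order of the efficacy scale; a tuning
parameter with no canonical value), `stage1_fraction = 0.5`, cutoffs
and bounds as supplied by the user — these are tuning parameters meant
to be calibrated by simulation, not constants of the method.

## Scenario generation

The parametric toxicity generator is a proportional-odds model per
type: $\mathrm{logit}(c_j) = \lambda_j + \zeta_l\,\mathrm{dose} +
\psi\,\mathrm{cycle}$, $j = 0,\dots,3$, with grade probabilities by
differencing and grade 4 as $1 - c_3$.  Dose enters as the integer
level $1..K$ (no unit rescaling), cycle as the integer index.  Toxicity
types are independent, in generation and in the analytic truth; a
user-supplied 4-D probability array (dose × cycle × type × grade)
bypasses the model entirely when historical data exist.  Scenario truth
is computed analytically: the cycle-1 DLT probability as one minus the
product of per-type sub-DLT probabilities, and the mean nTTP by
exhaustive enumeration over all $5^L$ grade combinations (125 for three
types) — a sampling estimator agrees within Monte-Carlo error, which
the test suite checks.

Efficacy outcomes are drawn from beta distributions matched by moments
to the per-dose mean and a common SD (validity requires
$\sigma^2 < \mu(1-\mu)$), so samples stay strictly inside $(0,1)$.  The
flat-efficacy study scenario fixes mean 0.5 at all six doses with
SD 0.2 — the conventional default spread for this generator — and
$\delta = 0.1$; both were fixed before any operating characteristics
were computed and not revisited.

**What the generator does *not* emulate:** correlated toxicity types,
time-varying dose within a patient, accrual patterns other than the
one-cycle cohort gap, informative dropout other than DLT, or
non-Gaussian nTTP error.  Passing tests therefore certify the
implementation under these idealized conditions, not performance on
real trial data.

## Trial simulation

Cohorts are enrolled one cycle apart: when cohort $c$ is about to
enrol, cohort $b < c$ contributes its first $\min(c-b, J)$ cycles,
truncated at DLT dropout.  Each patient's full $J$-cycle trajectory is
generated at enrollment and revealed as time passes, so a fixed seed
reproduces a trial bit-for-bit; in a batch, every trial receives its
own seed drawn from the master seed, making trials independent and
individually reproducible.  Efficacy is observed once a patient has
completed cycle 1 — with the one-cycle gap, that is every previously
enrolled patient.  At the end of a toxicity-only trial the final MTD is
the risk-minimizing dose *among the doses actually tried* (an untried
recommendation would be clinically meaningless); the dual design ends
with the stage-3 selection.  Operating characteristics report per-dose
allocation (share of patients) and recommendation (share of trials),
with early terminations kept as their own category so that
recommendation and termination shares sum to one.

## Problem sizes and tolerances

The test suite and the acceptance script choose sizes that make the
checks sharp but quick: analytic truth is exact (enumeration, not
sampling); the example-trial posterior uses the default 2000/500 chain,
whose block updates give near-iid draws (across-seed spread of the
cycle-1 means well inside the 0.03 Monte-Carlo tolerance used for
comparisons); recommendation stability is judged over 20 seeded refits;
parameter recovery uses 200 patients × 3 cycles (toxicity model) and
120 patients (joint model) over 20 seeds with a 3-posterior-SD
criterion; the flat-efficacy operating characteristics use 100
simulated trials with 600/200 chains in the acceptance script and a
25-trial reduced batch in the test suite, compared within 3 binomial
standard errors of the replicate count actually used.  Recommendation
percentages for that scenario are reported among non-terminated trials,
the denominator under which the design's concentration on the lowest
doses is defined.

## Known limitations

* The Gaussian response model can place posterior mass outside $[0,1]$
  at extrapolated doses; the decision rules are unaffected (they
  compare means and tail probabilities), but the surface should not be
  read as a probability.
* $\nu$ and $\sigma_\gamma$ are weakly identified when the random
  intercepts are small; recovery checks use a 3-posterior-SD criterion
  for that reason.
* The 3+3 start-up's stopping rule can terminate a trial whose lowest
  dose is in truth acceptable when early DLT draws are unlucky; this is
  a property of the start-up, visible in the flat-efficacy scenario's
  termination share.
* Intra-patient dose adjustment and user-defined decision rules are out
  of scope.
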
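---
title: "Estimating and ranking local determinants of health literacy with MRP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating and ranking local determinants of health literacy with MRP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hlmrp)
```

## The estimation problem

Local public-health teams need to know which socio-demographic factors
are most strongly associated with low health literacy *in their own
population*, but no single dataset contains both current local
demographics and measured literacy outcomes. `hlmrp` addresses this with
a three-part pipeline:

1. **Multilevel regression with post-stratification (MRP).** A Bayesian
   multilevel logistic model is fitted to a national source survey in
   which individuals took literacy, numeracy and ICT assessments, each
   outcome dichotomised at an expert-set threshold ("not health
   literate" = 1). Cell-level predicted probabilities are then averaged
   over the *target* population's joint covariate distribution.
2. **Counterfactual average treatment effects (MRP-ATE).** For every
   non-reference covariate level, the difference between two
   counterfactual post-stratified prevalences: everyone assigned that
   level versus everyone assigned the reference level, holding the joint
   distribution of the remaining covariates fixed.
3. **Probabilistic priority ranking.** Per posterior draw, contrasts are
   ranked by absolute ATE; cumulative rank probabilities, rankograms and
   SUCRA summarise which determinants are most likely to matter most.

## Model

For individual $i$ with binary outcome $y_i$ (1 = below the
health-literacy threshold),

$$y_i \sim \text{Bernoulli}(\pi_i), \qquad
\pi_i = \text{logit}^{-1}\Big(\beta_0 + \sum_x \beta^x_{\gamma_x[i]} +
u_{j[i]}\Big),$$

where $x$ ranges over ten categorical covariates (age group, sex,
ethnicity, English as first language, UK born, qualification level,
gross income, occupational class, working status, home ownership),
$\gamma_x[i]$ is individual $i$'s level of covariate $x$, and the
deprivation quintile effect is partially pooled,
$u_j \sim \mathcal N(\mu, \sigma^2)$. Reference levels are pinned at
zero (the presentation convention of effect tables: one row per omitted
non-reference level), not sum-to-zero coded.

Priors are weakly informative by default: $\mathcal N(0, 2.5^2)$ for the
intercept and fixed effects, $\mathcal N(0, 2.5^2)$ for $\mu$, and
half-normal with scale 1 for $\sigma$. These regularise without
dominating at sample sizes in the thousands. `prior_spec(flat = TRUE)`
switches to effectively flat priors (sd 100) for users who want
maximum-likelihood-like behaviour; we default to the weakly informative
choice because genuinely flat priors on a logistic scale place most
prior mass on implausibly extreme probabilities and do not help with
sparse cells.

Post-stratification averages cell predictions over the target frame:
$$\hat\pi^{\text{mrp}} = \sum_{c \in \mathcal S} w_c \, \hat\pi_c,$$
with $\mathcal S$ the set of all covariate combinations and $w_c$ each
cell's share of the target population. With the default schema (eight
binary covariates, two three-level covariates, five deprivation
quintiles) $|\mathcal S| = 2^8 \times 3 \times 3 \times 5 = 11{,}520$.
The schema is fully configurable, so a user whose covariate coding
implies a different cell count simply declares different levels.

## Posterior computation

Fitting uses a Pólya-Gamma data-augmentation Gibbs sampler implemented
in C++: given latent $\omega_i \sim \text{PG}(n_i, z_i'\theta)$, the
full conditional of the coefficient vector is Gaussian, so the sampler
alternates exact conditional draws with no tuning parameters. Records
are first aggregated to binomial sufficient statistics per unique
covariate pattern. Three implementation details matter:

* **PG sampling.** Exact alternating-series rejection (Devroye) for unit
  shape, summed for integer shapes up to 60; beyond that a
  moment-matched normal approximation (relative error $O(1/b)$) is used.
  The sampler's mean and variance are unit-tested against the closed
  forms $\mathbb E = \tfrac{b}{2z}\tanh(z/2)$ and
  $\mathbb V = \tfrac{b(\sinh z - z)}{4 z^3 \cosh^2(z/2)}$.
* **Collapsed group mean.** The likelihood constrains only
  $\beta_0 + u_j$, so conditioning the $\theta$ update on $\mu$ leaves a
  weakly identified direction that mixes very slowly. We therefore
  integrate $\mu$ out of the $u$ prior
  ($u \sim \mathcal N(0, \sigma^2 I + s_\mu^2 \mathbf 1\mathbf 1')$,
  Sherman–Morrison for the precision) and draw the whole coefficient
  vector from its exact joint Gaussian conditional; $\mu$ is then
  regenerated conjugately for reporting. This took the worst split
  R-hat on desk-scale fits from ~1.3–1.6 to ~1.01.
* **Group sd.** The half-normal prior on $\sigma$ is not conjugate; a
  univariate slice sampler (step-out and shrink) updates it.

All randomness flows through R's RNG, so a fit is a pure function of
(data, settings, seed). Split R-hat and Geyer initial-positive-sequence
effective sample sizes are reported per parameter, with a warning above
the 1.01 threshold. Defaults are 4 chains × 1000 warmup × 1000 draws;
the desk-scale `"test"` profile (2 × 500 × 500) is what the test suite
and the analysis scripts use, and a `"smoke"` profile (2 × 250 × 250)
drives the byte-identity determinism checks. The suite's replicate
calibration study uses 20 source surveys of n = 4000; the
cross-implementation checks use one n = 4000 fit against `lme4::glmer`
and one n = 1500 three-covariate fit against the same model in JAGS.

## Building the target frame from heterogeneous sources

The target population's joint distribution is not observed in one
dataset. The frame is assembled from three blocks:

* the covariates observed in the target-area residents microdata (age,
  sex, ethnicity, working status, home ownership), whose joint is
  estimated directly as (optionally weighted) relative cell frequencies;
* the remaining covariates (qualification, English, UK born, occupation,
  income), whose joint is estimated from auxiliary national microdata
  and then **raked** (iterative proportional fitting) to the target
  area's known margins — IPF preserves the auxiliary data's odds-ratio
  structure while matching every margin;
* the deprivation quintile margin, from a small-area table of
  deprivation deciles and populations, pooling deciles $\{2q-1, 2q\}$
  into quintile $q$.

The blocks are combined under **mutual independence** — cell weight =
product of block probabilities. This is the frame-construction
assumption of the pipeline: nothing in the available sources identifies
cross-block dependence (e.g. between home ownership and income), so the
frame is exact within blocks and independent across them. Users with
richer target data can instead supply any set of blocks that partitions
the schema.

Numerical choices for raking: margins are cycled in declared schema
order; convergence is max absolute margin deviation ≤ 1e-10 after a
full cycle, with a 1000-cycle cap. Structural zeros in the seed are
preserved, never jittered, and a target that puts mass where the seed
margin is zero raises an infeasibility error rather than inventing
population members. A practical corollary, surfaced by testing: if the
auxiliary microdata are very sparse (a few hundred records over 72
cells), empirical zeros can make the margins unattainable and raking
correctly fails — the generator defaults (n = 3000) avoid this regime,
and real analyses should too.

## Counterfactual effects and ranking

`counterfactual_frame()` moves, within every stratum of the non-focal
covariates, all of the stratum's weight onto the focal level — so the
non-focal joint is exactly conserved (tested to 1e-12). The MRP-ATE for
level $\ell$ versus reference $r$ of a covariate is, per posterior draw,

$$\text{MRP-ATE} = \hat\pi^{\text{mrp}}_{T=\ell} -
\hat\pi^{\text{mrp}}_{T=r},$$

i.e. both arms are counterfactual ("everyone assigned $\ell$" vs
"everyone assigned $r$"); treated-vs-observed (ATT) and stochastic
interventions are deliberately out of scope. These are *predictive
comparisons* — summaries of the fitted model's structure over the
target population — not identified causal effects. Negative values mean
improvement (lower probability of not being health literate).

Summaries are posterior means with equal-tailed 95% intervals
(empirical 2.5%/97.5% quantiles, linear-interpolation rule,
`stats::quantile` type 7); reporting is rounded to 3 decimals with full
precision retained internally, because independently rounded SUCRA and
expected-rank columns are not mutually consistent under their exact
linear identity.

Ranking uses the **absolute** ATE (the sign of a contrast is an artifact
of which level is the reference), with ties broken by item declaration
order — a measure-zero event for continuous draws. With cumulative rank
probabilities $P_{ir} = \sum_{k \le r} p(R_i = k)$ over $n$ items,

$$\text{SUCRA}_i = \frac{1}{n-1}\sum_{r=1}^{n-1} P_{ir}, \qquad
\mathbb E[\text{rank}_i] = n - \sum_{r=1}^{n-1} P_{ir}
= n - (n-1)\,\text{SUCRA}_i.$$

The default ranked set is every non-reference (variable, level) pair —
16 items under the default schema. The reported rankogram keeps the
first four rank positions and items with cumulative probability ≥ 0.25
there; the unfiltered table is always exported alongside.

## The synthetic-data generator

Because the real target-area microdata are licence-restricted, the
package generates every input from a known multilevel logistic process,
so the whole pipeline is testable end to end:

* **Source survey** (default n = 4000): covariates drawn independently
  from level probabilities typical of a national adult skills survey
  (predominantly UK-born, white, English-first-language), with an
  optional pairwise log-odds tilt to induce associations. Outcomes are
  Bernoulli draws from the ground-truth linear predictor. The three
  assessments sit on nested subsamples (ICT ⊂ numeracy ⊂ literacy,
  fractions 1 / 0.75 / 0.4 of one random permutation, sizes rounded),
  mirroring a survey design that administers the intensive modules to
  planned subsets; the nesting is an assumption and is configurable.
* **Target microdata** (default n = 3000) over the residents-survey
  block, drawn from a joint with young, diverse, largely renting
  margins and mild working/ownership/age tilts.
* **Auxiliary microdata** (default n = 3000) over the remaining block,
  drawn from national-style margins with English/UK-born association,
  plus the target-area margins that raking must reproduce — chosen to
  be far from the auxiliary margins so raking is a real adjustment.
* **Small-area table**: 164 areas with deprivation deciles concentrated
  in deciles 2–4 (a deprived inner-city profile) and Poisson
  populations (mean 2200).

The default ground-truth effects encode the qualitative structure the
analysis is designed to detect: qualification level dominates literacy
and numeracy (−1.2 and −0.8 logits), age dominates ICT (+1.3), English
as first language matters mainly for literacy (−1.0), and working
status carries a true zero effect for literacy — a built-in negative
control. Quintile effects are fixed (mean ≈ 0, spread matching
σ ≈ 0.2–0.3) so analytic targets are computable by enumeration.

What the generator does **not** emulate: instrument content,
interviewer or mode effects, nonresponse, survey weights, and real
cross-covariate dependence beyond the configured tilts. Passing tests
therefore demonstrate that the *method* is implemented correctly and is
calibrated under its own assumptions — not that those assumptions hold
in any particular real survey.

## What the calibration study shows — and a note on shrinkage

On 20 replicate source surveys (n = 4000, test MCMC profile), the 95%
posterior intervals of the identified coefficients (fixed effects and
intercept-plus-quintile sums) cover the truth at ≈ 95–98%, the null
covariate's ATE interval covers zero in ≥ 90% of replicates, and its
SUCRA falls below every ≥ 0.5-logit covariate in ≥ 95%.

Posterior-mean MRP-ATEs recover the analytic enumeration targets within
Monte-Carlo error for all **fixed-effect** contrasts. The four
deprivation-quintile contrasts do not — and should not: partial pooling
deliberately shrinks quintile effects toward their common mean, so
posterior quintile ATEs are biased toward zero deviation relative to
the generator truth. This is the intended "borrowed strength" of the
multilevel prior (most visible for quintiles that are rare in the
target area), and the suite asserts it directionally: posterior
deviations from the quintile mean are smaller in magnitude than, and
strongly correlated with, the true deviations. Users who want unshrunk
quintile contrasts can refit with the deprivation variable as fixed
effects by editing the schema/`imd_variable` choice.

## Degenerate inputs and error behaviour

Errors are classed conditions, raised early with the failing stage and
input named: single-class outcomes (separation), unknown levels
(schema mismatch), overlapping or incomplete frame blocks, infeasible
raking targets, zero total population, and misaligned
prediction/frame cell orders. Determinism is part of the contract: two
pipeline runs from the same config and seed produce byte-identical CSV
outputs (the manifest records seeds, settings and diagnostics, and no
timestamps, precisely so that it too is reproducible).

## Known limitations

* Cross-block independence of the frame is an assumption, not an
  estimate; it is exactly what richer target microdata would relax.
* Effects are predictive comparisons; no confounder selection,
  mediation, or identification argument is made.
* No interaction terms and a single grouped covariate; outcomes are
  fitted independently with no shared parameters.
* The MRP-ATE intervals ignore uncertainty in the frame weights
  (microdata sampling error and raking), as is conventional.
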
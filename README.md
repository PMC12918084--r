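# hlmrp

Estimating and ranking the local-population determinants of health
literacy with **multilevel regression and post-stratification (MRP)**,
counterfactual average treatment effects, and SUCRA-based priority
ranking.

## The problem

Local public-health teams want to know which socio-demographic factors
matter most for low health literacy *in their own area*. The catch: the
surveys that measure literacy, numeracy and ICT skills are national and
dated, while the datasets that describe the local population carry no
literacy outcomes. `hlmrp` bridges the two:

1. **Multilevel regression** — a Bayesian hierarchical logistic model is
   fitted to a national source survey. For individual *i*,
   `y_i ~ Bernoulli(logit⁻¹(β₀ + Σ_x β^x_{γ_x[i]} + u_{j[i]}))`, with
   ten categorical covariates as reference-coded fixed effects and the
   deprivation quintile as a partially pooled group effect
   `u_j ~ N(μ, σ²)`. Outcome 1 codes *not* meeting the health-literacy
   threshold.
2. **Post-stratification** — cell predictions are averaged over the
   target population's cell weights, `π̂ᵐʳᵖ = Σ_c w_c π̂_c`, over the
   11,520 cells of the default 11-covariate schema. The frame is built
   from heterogeneous sources: a local residents-survey joint, an
   auxiliary national joint **raked** (iterative proportional fitting)
   to local margins, and a small-area deprivation table pooled to
   quintiles, combined under block independence.
3. **MRP-ATE** — for each non-reference covariate level, the difference
   of two counterfactual post-stratified prevalences (everyone assigned
   the level vs everyone assigned the reference), per posterior draw.
4. **Priority ranking** — contrasts ranked per draw by |ATE|; cumulative
   rank probabilities `P_ir = Σ_{k≤r} p(R_i = k)`, rankograms, and
   `SUCRA_i = Σ_{r<n} P_ir / (n−1)` with
   `E[rank_i] = n − (n−1)·SUCRA_i`.

Because the real local microdata are licence-restricted, the package
ships a synthetic-data generator that emulates every input from a known
multilevel logistic process, so the whole pipeline is testable and
reproducible end to end. The multilevel model is sampled by a compiled
Pólya-Gamma data-augmentation Gibbs sampler (no tuning parameters,
exact conditional updates; a desk-scale fit takes a few seconds).

## Worked example

```r
library(hlmrp)

cfg <- pipeline_config("synthetic", seed = 2026,
                       n_source = 4000, n_target = 3000, n_lfs = 3000,
                       mcmc = mcmc_profile("test", seed = 2026))
bundle <- run_pipeline(cfg)
print(bundle)
#> MRP report bundle:
#>   outcomes: literacy, numeracy, ict
#>   contrasts per outcome: 16
#>   post-stratified prevalence:
#>     literacy  0.147 [0.113, 0.185]
#>     numeracy  0.293 [0.247, 0.343]
#>     ict       0.228 [0.175, 0.292]
```

The post-stratified prevalences are the model's estimates of the share
of the *target* population below each skills threshold — note they
differ substantially from the source survey's crude prevalences (0.10,
0.22, 0.27 under the same seed), which is the point of reweighting to
local demographics.

Largest literacy effects (change in probability of not being health
literate if everyone were assigned the level, vs its reference):

```r
top <- subset(bundle$ate, outcome == "literacy")
head(top[order(-abs(top$mean)), c("variable", "level", "mean_r", "lower95_r", "upper95_r")], 5)
#>       variable       level mean_r lower95_r upper95_r
#>  qualification level2_plus -0.137    -0.176    -0.104
#>        english         yes -0.120    -0.172    -0.073
#>            job       lower  0.088     0.061     0.121
#>         income       ge10k -0.070    -0.116    -0.028
#>            age         45+  0.063     0.036     0.092
```

Holding a level-2+ qualification lowers the estimated probability of
low literacy by 0.137 (95% CrI 0.104–0.176); English as first language
is next. For ICT the ranking flips — age dominates:

```r
su <- subset(bundle$sucra, outcome == "ict")
head(su[order(-su$sucra), c("variable", "level", "sucra_pct", "expected_rank_r")], 4)
#>       variable       level sucra_pct expected_rank_r
#>            age         45+        99               1
#>  qualification level2_plus        93               2
#>            job       lower        79               4
#>         income       other        76               5
```

A SUCRA of 99% means being 45+ is almost certain to be the top-ranked
ICT determinant by absolute effect size. These recovered orderings
match the generator's ground truth (qualification dominates literacy
and numeracy, age dominates ICT), which is exactly what the test suite
verifies quantitatively.

## Analysis workflow

The `analysis/` scripts run the same pipeline step by step, writing
tables under `results/`:

```sh
Rscript analysis/01_simulate.R   # synthetic inputs + ground truth
Rscript analysis/02_frame.R      # frame build + source-vs-target comparison
Rscript analysis/03_fit.R        # per-outcome multilevel fits (draws persisted)
Rscript analysis/04_effects.R    # post-stratification + MRP-ATE tables
Rscript analysis/05_ranking.R    # rankograms + SUCRA
Rscript analysis/06_report.R     # figures (forest, rankogram, dumbbell)
```

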
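# primecause

Causal repetition-priming effects in between-subjects word-fragment-completion
(WFC) experiments, under the potential-outcomes framework.

## The problem

Having studied a word (e.g. *gazette*) makes it easier to later complete a
fragment cue (`_aze__e`) into that word — repetition priming. Calling that
effect *causal* requires comparing two outcomes for the same person: success
had they studied the word, and success had they not. Only one of the two is
ever observed, so priming experiments randomize subjects into a studied arm
(`Z = 1`) and a non-studied arm (`Z = 0`) and compare arms. This package
gives that familiar practice its formal footing and the estimators, tests
and diagnostics that go with it. It is aimed at cognitive psychologists and
biostatisticians analysing (or planning) between-subjects priming studies.

For a subject–word pair, the individual causal priming effect is
`Y(Z=1) − Y(Z=0)`, the difference of the two potential outcomes; its average
over `N` subjects and `M` words is the **average priming effect (APE)** —
the estimand, unobservable directly. The observable estimator is the
**difference in priming effect (DPE)**: with `K` subjects per arm,

    DPE = p̂₁ − p̂₀,      p̂_z = (1/KM) Σ_i Σ_j Y_ij(Z=z)

With perfectly matched arms DPE equals the sample APE exactly; under
randomization it is unbiased. Significance uses the pooled two-proportion
z statistic (no continuity correction),

    z = DPE / sqrt( p̂ (1−p̂) (1/N₁ + 1/N₀) )

with `p̂` the pooled success proportion (`z²` equals the Pearson chi-square
of the 2×2 table), and the 100(1−α)% Wald interval uses the *unpooled*
variances. The package also provides:

* a **multinomial processing tree (MPT)** bridge: with storage probability
  `B`, stored/unstored accuracies `C`/`D` and baseline `A`, the treated-arm
  probability is `p₁ = BC + D(1−B)`, `p₀ = A`, and the priming effect
  decomposes as `p₁ − p₀ = B(C−D) + (D−A)` — the storage effect plus a
  baseline shift, reducing to `B(C−D)` when `A = D`;
* **covariate adjustment** by trial-level logistic regression
  (`logit P(Y=1) = β₀ + β_z z + β_w w`), with the conventional
  `exp(β_z)/(1+exp(β_z))` transform and a g-computation marginal risk
  difference comparable to the DPE;
* **propensity-score matching** for exposures that cannot be randomized
  (e.g. medication), and the matched-strata contrast
  `DPE_exposed − DPE_unexposed`;
* an **inclusion/exclusion** (process-dissociation) contrast `p_i − p_e`
  estimating conscious recollection of Phase-1 items in three-phase designs;
* a **potential-outcomes simulator** that realises *both* counterfactual
  outcomes per subject–word pair under randomized, matched or confounded
  assignment, so the APE is exactly computable and every estimator is
  testable by identity or parameter recovery.

## Worked example

```r
library(primecause)

cfg <- sim_config(seed = 7)        # 22 subjects/arm, 24 words, tau = 0.5
sim <- simulate_experiment(cfg)

true_ape(sim$potential)            # the estimand, knowable only in simulation
#> [1] 0.09090909

estimate_dpe(sim$trials)
#> Priming effect (dpe): 0.0625
#>   p1_hat = 0.2898 (n1 = 528)   p0_hat = 0.2273 (n0 = 528)
#>   per-word effects for 24 words

out <- test_priming(sim$trials)
out$test
#> Pooled two-proportion z test (two_sided)
#>   DPE = 0.0625   z = 2.319   p = 0.02037   pooled p = 0.2585
out$ci
#> 95% Wald CI for the priming effect: (0.0098, 0.1152)
```

The estimand (`0.091`) sits inside the interval; the observed DPE (`0.0625`)
differs from it by sampling error in a single 44-subject experiment. The
pooled z test rejects no-priming at the 5% level.

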
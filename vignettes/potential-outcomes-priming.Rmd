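---
title: "Potential-outcomes methods for priming experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Potential-outcomes methods for priming experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(primecause)
```

## The estimand and the estimator

A word-fragment-completion (WFC) trial exposes a subject to a fragment cue
and scores the completion as correct or not. The causal effect of having
studied the target word is, per subject-word pair, the difference between
the two potential outcomes $Y(Z{=}1) - Y(Z{=}0)$ — observable for at most
one value of $Z$ per pair. The estimand this package targets is the
**average priming effect (APE)**, the mean of those differences over $N$
subjects and $M$ words; the estimator is the **difference in priming
effect (DPE)** between the studied and non-studied arms,
$\widehat{DPE} = \hat p_1 - \hat p_0$, pooling subject-word trials within
each arm.

Two classical design arguments connect the two. Under *perfect matching* —
every treated subject paired with a control who would respond identically
under either assignment — DPE equals the sample APE as an algebraic
identity. Under *randomization*, the arms are exchangeable and DPE is
unbiased for the APE. Both arguments are executable here because the
simulator realises both potential outcomes: the matched identity is tested
exactly, and unbiasedness as a Monte-Carlo property.

Two estimators are exposed because they genuinely differ under imbalance:
`estimate_dpe()` pools trials (each word weighted by its trial count) and
`estimate_per_word_epe()` averages word-level DPEs with equal weight. They
coincide exactly when per-word arm sizes are balanced; the test suite pins
the distinction with a hand-counted unbalanced fixture.

## Inference

`pooled_ztest()` implements the pooled two-proportion statistic
$z = \widehat{DPE}\big/\sqrt{\hat p(1-\hat p)(1/N_1 + 1/N_0)}$ with no
continuity correction; its square is the Pearson chi-square of the 2x2
table and the two-sided p-values coincide (held to 1e-10 over random
tables, with `stats::chisq.test()` as the independent route).
`wald_ci()` uses the *unpooled* variances. The asymmetry — pooled variance
in the test, unpooled in the interval — is the conventional pairing and is
kept deliberately; "fixing" it would break agreement with published
intervals.

Sidedness: the scientific alternative in priming studies is one-sided
(priming helps), but published z and interval values are two-sided
conventions, so `two_sided` is the default and `one_sided_greater` a flag.

Trials are pooled as independent units; there is no clustering correction
for repeated trials within subject, matching standard practice for these
designs. Consequently the nominal test size is exact only when trials are
exchangeable — the calibration experiment below uses exactly that regime,
and the limitation is restated there.

## Reconstructing published inference from summaries

For the packaged between-subjects study only condition-level summaries
(DPE, z, group sizes) were printed numerically; the underlying proportions
appeared in a figure. `solve_pooled_proportion()` therefore inverts the
pooled statistic: with equal arms, $\hat p(1-\hat p) = (DPE/z)^2\,n/2$, a
quadratic whose roots sum to one. The sub-0.5 root is the default because
WFC accuracies in this literature sit below one half; the other root is
reported and selectable. Arm proportions follow as
$\hat p \pm DPE/2$ (exact for equal arms). The recomputed z is then a
round-trip consistency check, while the Wald endpoints are a genuine
independent recomputation — the interval formula uses unpooled variances
the inversion never touched.

Printed values are compared after half-away-from-zero rounding at the
printed precision (R's `round()` is half-even, which disagrees with
printed tables at ties). Two of the four endpoints land within 0.001 of
the printed digits rather than on them — the printed inputs are themselves
rounded to 3 and 2 decimals, and that input rounding propagates; the
report flags these as "within 0.001" rather than asserting them. The
printed second-test conditional DPEs are carried as reference values only:
recomputing their tests needs the first-test failure counts, which were
never published numerically. The conditional estimator is instead pinned
to an exact manual-counting oracle on an eight-row fixture.

## The simulator

No generative model is prescribed by the framework itself, so the
simulator adopts the simplest structure exhibiting the heterogeneity the
estimators must survive: a logistic random-intercept model
$$\operatorname{logit} P(Y_{ij}(z)=1) = \mu + a_i + b_j + \gamma w_i +
\tau z,$$
with subject ability $a_i \sim N(0, \sigma_s^2)$, word difficulty
$b_j \sim N(0, \sigma_w^2)$ and a standard-normal subject covariate
$w_i$. Defaults mirror the canonical experiment: 22 subjects per arm, 24
words, $\mu = -1.1$ (baseline accuracy near 0.25, the reconstructed
non-studied-arm value), $\tau = 0.5$ (a DPE near 0.10 on the probability
scale, the magnitude the reconstruction gives), $\sigma_s = \sigma_w =
0.5$ (moderate heterogeneity: subject and word effects move accuracies by
roughly $\pm 0.1$–$0.2$), $\gamma = 0$.

Design choices worth recording:

* **Both potential outcomes are realised.** By default they share one
  uniform draw per subject-word pair (monotone coupling: studying never
  hurts when $\tau \ge 0$); an independent-draw mode exists because
  monotonicity is an assumption, not a consequence of the framework.
  Consistency $y = z y_1 + (1-z) y_0$ holds by construction and is
  asserted, not assumed, in tests.
* **Assignment mechanisms.** `randomized` draws an exact half split;
  `matched` clones each treated subject into a control sharing ability,
  covariate and all per-word uniforms, making DPE = APE an exact identity;
  `confounded` lets treatment uptake follow
  $P(z{=}1\,|\,w) = \operatorname{logit}^{-1}(\text{strength}\cdot w)$,
  reproducing the chance-imbalance scenario covariate adjustment exists
  for (arm sizes then vary binomially around $K$).
* **RNG contract.** One root seed; per-subject and per-word sub-streams are
  derived deterministically from it, with a fixed draw layout per subject.
  Growing $K$ or $M$ therefore leaves existing units' draws unchanged
  (asserted in tests), and same-cue versus different-cue two-test modes
  differ only in cue labels, never in outcomes.
* **Carryover.** The two-test generator adds a single log-odds bonus
  `carryover` to second-test trials of attempted words. Word-level
  learning and mechanism-level learning are deliberately conflated in this
  one knob: the framework's motivation for between-subjects designs does
  not distinguish them, and a single generator parameter keeps the
  conditional second-test estimator testable without claiming a richer
  carryover theory.
* **Inclusion/exclusion.** The three-phase generator uses the standard
  independence model of process dissociation — recollection $r$
  independent of familiarity $f$ — so the Phase-1 contrast has the closed
  form $p_i - p_e = r$ and parameter recovery is a sharp test. Phase-2
  items are called old with fixed probability 0.9 (recent, well-learned
  items; the contrast never uses them), distractors with probability $f$.

What the simulator does *not* emulate: reaction times, semantic structure
between words, response criteria shifting over a session, and
patient-population submodels. Passing tests therefore certify the
estimators' statistical behaviour under controlled heterogeneity, not
robustness to every feature of real data.

## Calibration and recovery experiments

The suite's stochastic checks use these problem sizes, chosen as the
smallest designs that make the bands sharp:

* **Test size and coverage** — 10,000 replicates of a 50-per-arm, 24-word
  null experiment with $\tau = 0$, $\mu = 0$ and all heterogeneity off, so
  trials are i.i.d. Bernoulli(0.5) and the pooled test's assumptions hold
  exactly; the rejection rate must fall inside the exact binomial 99% band
  around 0.05 and Wald coverage of the true (zero) effect inside the band
  around 0.95. With random intercepts switched on the test is
  anticonservative — trials within a subject are correlated — which is the
  documented cost of the no-clustering convention, not a defect of the
  implementation.
* **Unbiasedness** — 1,000 replicates at the default (heterogeneous)
  design: the mean of DPE minus the replicate's true APE must sit within
  3 Monte-Carlo SEs of zero.
* **Parameter recovery** — storage effect $B(C-D)$ from MPT data with
  $A = D$ at 10^4 trials per arm, and recollection from the
  inclusion/exclusion contrast at 10^4 Phase-1 trials per group, each
  within 3 binomial SEs.
* **Adjustment under confounding** — 500 replicates with $\gamma = 1$ and
  confounding strength 1: the g-computation estimate from the logistic fit
  must beat the raw DPE in median absolute error against the replicate's
  true APE.

## Covariate adjustment and matching

`fit_logistic_adjustment()` fits the trial-level logistic model by maximum
likelihood (`stats::glm`, deviance tolerance 1e-8, 100 iterations). The
conventional transform $e^{\beta_z}/(1+e^{\beta_z})$ is reported verbatim
as `transformed_effect` because it is how adjusted priming effects are
commonly quoted; note it is *not* a risk difference, so the fit also
reports `marginal_effect`, the g-computation average of fitted risk
differences, which is on the DPE scale and is what the confounding
experiment scores. Separation is detected as a divergent non-intercept
coefficient (|beta| > 15) or non-convergence; the intercept is excluded
because its magnitude tracks covariate location, not degeneracy.
Rank-deficient designs are an error, not a silent drop.

`propensity_match()` estimates scores by logistic regression and matches
greedily: exposed subjects in descending score order, nearest available
control by absolute score distance, all ties broken lexicographically by
subject id — a fully deterministic rule, so matching needs no seed and is
invariant to row order (both asserted). Without replacement is the
default; a caliper refuses distant pairs and counts the exposed subject
unmatched. Matching covariates default to all provided columns, since the
scenario motivating PSM gives no basis for excluding any measured
pre-treatment variable.

## MPT bridge

Only the forward map is implemented. From $(A, B, C, D)$ the arm
probabilities are $p_1 = BC + D(1-B)$, $p_0 = A$, and the priming effect
decomposes exactly as $B(C-D) + (D-A)$. Recovering all four parameters
from the two observable proportions is not identifiable (two observables,
four unknowns), so estimation targets the reduced $A = D$ form — the
observable difference then *is* the storage effect estimate — and
`storage_sensitivity()` tabulates the bias, exactly the baseline gap
$D - A$, when the reduction fails. No threshold for "close enough to
$A = D$" is claimed.

## Known limitations

* No cluster-robust variance or multiplicity correction across words; the
  inference module matches the conventional analysis exactly, including
  its small sins.
* Binary treatment only; graded, categorical or time-varying word-study
  exposures are out of scope.
* Post-treatment variables must not be adjusted for; the package offers no
  principal-stratification machinery, only the warning.
* The interchange file schema is this package's own convention; no
  community standard exists for trial-level priming data.
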
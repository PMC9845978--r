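---
title: "Testing macroevolutionary trait syndromes with phylosyndrome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing macroevolutionary trait syndromes with phylosyndrome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylosyndrome)
```

## The problem

Many comparative questions about organismal strategy reduce to: do two
binary traits co-occur across a clade more (or less) often than shared
ancestry alone would predict? The motivating application is larval
protective coloration in Lepidoptera — whether particular colours
(scored from an 11-name vocabulary, up to three salient colours per
species), two-colour composites, repeated pattern elements (stripe,
band, spot, stipple, blotch) and host-plant ecology (diet breadth,
tissue type, growth form) form evolutionary syndromes. The package
covers the full workflow: binary trait coding with composite expansion
and rarity filtering, phylogenetic logistic regression, false discovery
rate control within hypothesis families, an observer-resampling
consensus rule, and a synthetic-data generator that makes every stage
testable without any external data.

## Trait coding

Each species' colour set of size $k \le 3$ expands into $k + k(k-1)/2$
binary traits: the singles plus every unordered two-colour combination,
never three-colour combinations. A species scored yellow, black and
white therefore carries six colour traits. Pair columns are named by the
lexicographically ordered join (`black/yellow`), so column identity is
stable across observers and bootstrap replicates, and a pair column
always equals the AND of its two component columns. Colour traits seen
in fewer than five species (strictly fewer — a column sum of exactly
five survives) are excluded before modelling; patterns and ecology
columns are exempt by default because the rarity concern is specific to
the combinatorial colour space, with a `scope = "all"` switch for
sensitivity checks. Ecology categories are one-hot expanded so that
every model is binary–binary; growth form is a non-exclusive set (a
species feeding on forbs and woody hosts gets a 1 in both columns).
Species missing from the ecology table are dropped from ecology models
only, never globally, which maximizes the tips available to each model.

## The regression model

For a binary tip trait $y$ with design matrix $X$ (intercept plus one
predictor in the pipeline), the model is

$$\operatorname{logit} P(y_i = 1) = x_i^\top \beta$$

with working covariance
$V(\alpha) = D_\mu^{1/2}\, R(\alpha)\, D_\mu^{1/2}$, where
$D_\mu = \operatorname{diag}\{\mu_i(1-\mu_i)\}$ and $R(\alpha)$ is a
correlation matrix that decays with patristic distance $d_{ij}$ on the
height-normalized tree. $\alpha \ge 0$ is the phylogenetic signal
parameter in units of inverse tree height: $\alpha = 0$ is perfect
correlation, large $\alpha$ is independence.

Coefficients solve penalized quasi-score equations

$$\tilde X^\top R^{-1} \tilde r \;+\; X^\top\{h \circ (\tfrac12 - \mu)\} = 0,$$

with $\tilde X = D_\mu^{1/2} X$, $\tilde r = D_\mu^{-1/2}(y - \mu)$,
working information $J = \tilde X^\top R^{-1} \tilde X$ and generalized
leverages $h_i = [\tilde X J^{-1} \tilde X^\top R^{-1}]_{ii}$. The
second term is the exact gradient of $\tfrac12 \log\det J$ — a
Firth-type (Jeffreys) penalty that keeps estimates finite under
separation (frequent with rare colour traits) and reduces small-sample
bias. When $R = I$ these equations are exactly Jeffreys-penalized
ordinary logistic regression, which is the package's independence-limit
oracle check. Standard errors come from $J^{-1}$ at the solution and
p-values are two-sided Wald, because positive and negative associations
are both of scientific interest.

### Two correlation families

`phyloglm_control(corr_form = ...)` offers two one-parameter families:

* `"exponential"`: $R_{ij} = e^{-\alpha d_{ij}}$, the exact binary-scale
  correlation of a stationary symmetric two-state switching process.
* `"arcsine"` (default):
  $R_{ij} = \tfrac{2}{\pi} \arcsin(e^{-\alpha d_{ij}})$, the
  binary-scale correlation induced by a latent liability process with
  exponentially decaying correlation, evaluated at balanced prevalence.

The families differ in shape, not limits. Thresholding a continuous
liability attenuates correlation non-uniformly: near zero distance the
binary correlation falls off like a square root, while at long range it
is proportional to the latent correlation. A pure exponential fitted to
such data is dominated by the many short-distance pairs, lands on too
fast a decay rate, and underestimates the long-range dependence that
controls the variance of clade-level contrasts — which makes Wald tests
anti-conservative. The arcsine family has the square-root initial drop
built in, so the estimated $\alpha$ retains realistic long-range
dependence and the tests stay calibrated for threshold-like traits.
Discrete characters that truly evolve by state switching are better
served by the exponential family; both are exposed, and the calibration
experiments in the test suite use the default.

### Estimating the signal parameter

$\alpha$ maximizes a penalized Gaussian working log-likelihood of the
Pearson residuals,

$$\mathrm{pl}(\alpha) = -\tfrac12 \tilde r^\top R^{-1} \tilde r
  - \tfrac12 \log\det R - \tfrac12 \textstyle\sum_i \log w_i
  - \tfrac12 \log\det J,$$

profiled over $\beta$ (the $-\tfrac12\log\det J$ term plays the role of
a REML adjustment for the estimated coefficients; the $+\tfrac12$
Jeffreys penalty applies only inside the $\beta$ equations). The search
is a coarse log-spaced grid over $[\alpha_{\min}, \alpha_{\max}]$
(default $[10^{-3}, 10^3]$, 15 points) followed by golden-section
refinement in the bracketing interval; grid values whose coefficient
solve does not converge are excluded from the profile, and the scan
starts at the independence end with warm starts because solves are most
stable there. A fit whose $\hat\alpha$ lands at a search bound reports
`alpha_at_bound` rather than clamping silently. Initialization is
deterministic (the ordinary Firth solution), so fits are reproducible
without seeds.

Numerical safeguards: the Newton solves are damped by step-halving on
the score norm and bail out early when the score stalls (reported as
non-convergence); $R(\alpha)$ is inverted by Cholesky with an
escalating diagonal ridge and, as a last resort, a pseudo-inverse;
coincident tips (zero patristic distance) receive a terminal-branch
jitter of $10^{-8}$ times the tree height so the correlation matrix
stays non-singular. Trees are height-normalized by default so that
$\alpha$ has the same units on every tree.

### A working taxonomy of signal strength

On a unit-height tree, the correlation half-life is $\ln 2 / \alpha$.
We call signal *strong* when the half-life is of order the tree height
($\alpha \lesssim 0.7$), *moderate* when it is roughly a third to a
half of the height ($\alpha \approx 1.4$–$2$), and *weak* beyond
$\alpha \approx 3.5$. The package's parameter-recovery experiment uses
$\alpha_{\mathrm{true}} = 2$ with a predictor evolved by a two-state
Markov process — the standard design for recovery experiments in this
model family, where both traits evolve by tractable processes and the
effective information about the slope grows with the number of
independent state switches. A predictor that is one single clade block
is the hardest case: the slope then rests on essentially one deep
contrast, its sampling distribution on the log-odds scale is strongly
right-skewed for *any* estimator (we verified that ordinary maximum
likelihood on the same data is several times more biased), and no
amount of modelling recovers information that a single contrast does
not contain. The clade-block predictor therefore remains the generator
default for pipeline-level tests — it is the realistic shape of host-use
evolution — while the recovery experiment, whose purpose is to measure
estimator bias rather than design difficulty, uses the switching
predictor.

## The association pipeline

`run_full_analysis()` implements the full design:

1. **Trait universe.** The two observers' scores are pooled by union and
   the rarity filter is applied once; the resulting columns are frozen
   so every bootstrap replicate fits the same model list. (A
   `refilter_per_replicate` flag offers the alternative.)
2. **Models.** Every colour trait is regressed on every pattern trait,
   and every colour and pattern trait on every ecology column, coloration
   being the response (`direction = "reversed"` swaps this for
   sensitivity analysis; `pairs` restricts the list). Pairs named in the
   configuration's literature-derived list form the *a priori* family;
   the rest are *exploratory*.
3. **FDR.** Within each family (and within each replicate), p-values
   are Benjamini–Hochberg adjusted over whatever models ran there.
4. **Observer bootstrap.** Each of B replicates (study default 1000)
   draws one observer per species uniformly at random, rebuilds the
   trait matrix on the frozen columns and refits everything. A replicate
   counts as significant for a pair only when the adjusted p-value is
   below the level **and** the coefficient sign matches the pooled-data
   sign — supported associations carry a sign, so support must not
   accumulate across contradictory directions.
5. **Consensus.** Support is the significant fraction among converged
   replicates (`replicates_used` is reported; a pair with under 50%
   convergence is flagged unreliable). An association is supported when
   support reaches the consensus threshold, 0.90 by default, compared
   with `>=` so that exactly 90% qualifies.

Randomness is controlled by a master seed that spawns one sub-seed per
replicate, so any replicate can be reproduced independently and the
full edge list is byte-identical across runs with the same seed.

Because a bootstrap analysis fits the same tree thousands of times, the
pipeline profiles $\alpha$ on the fixed grid only (no golden-section
refinement) and precomputes the correlation inverses once per tree,
shared across all models and replicates. The discretization of
$\hat\alpha$ is immaterial at the level of significance calls, and the
sharing is what makes a 1000-replicate run tractable. Standalone
`fit_phyloglm()` calls always refine continuously.

## The synthetic-data generator

`simulate_study()` emulates the study design end to end: a Yule or
birth–death tree conditioned on the tip count and scaled to unit
height; a binary ecology predictor that is either one clade (30–70% of
tips, the shape of conserved host use) or a two-state Markov process; a
response colour trait generated by a latent-threshold scheme — draw
$z \sim \mathcal N(0, R_{\exp}(\alpha_{\mathrm{true}}))$ and set
$y_i = 1$ iff $\Phi(z_i) < \operatorname{logit}^{-1}(\beta_0 + \beta_1
x_i)$ — plus any number of null traits; and two observers who each
toggle every trait independently with the configured disagreement
probability (colour additions respect the three-colour cap by random
eviction). The threshold construction gives *exact* marginal
frequencies under the regression model with a correlation that decays
with distance; it is deliberately not the same joint law as either
working correlation family, so parameter-recovery results demonstrate
robustness to that mismatch rather than self-confirmation. An exact
switching-process generator (`predictor_model = "mk_switch"`) is
included for pure-signal recovery checks where the fitted exponential
family matches the generating process.

What the generator does *not* emulate: polymorphism (one morph per
species), correlated observer errors (flips are independent across
observers and traits), non-ultrametric trees, and the empirical trait
frequencies of any particular dataset. Passing the simulation suite
therefore shows that the machinery recovers known truth under idealized
scoring noise, not that any biological conclusion from real data is
correct.

## Validation problem sizes

The test suite validates at desk scale: oracle equivalence on 200-tip
star trees; coefficient recovery and Wald calibration on 300-tip trees
over 200 replicates; consensus-rule calibration on fifty 150-tip null
datasets with twenty models each at B = 100; power and end-to-end
separation of a planted log-odds-2 association on 300-tip trees at
B = 100 across 20–25 seeded runs. The study-scale configuration
(thousands of tips, B = 1000) uses identical code paths.

## Known limitations

* The signal parameter is profiled, and its sampling uncertainty is not
  propagated into the Wald intervals; p-values are asymptotic.
* Working correlations are one-parameter families; real traits whose
  dependence mixes processes (e.g. rate variation across clades) will
  be approximated.
* With a predictor confined to one clade, slope estimates are
  intrinsically noisy and right-skewed at any sample size — the package
  reports this regime honestly rather than fixing it, and the bootstrap
  consensus rule is the intended guard against over-reading single
  fits.
* The fitter is not a numerical clone of any published implementation;
  its correctness is established against internal oracles (ordinary
  Firth regression in the independence limit, brute-force
  Benjamini–Hochberg, graph-based patristic distances, simulation truth).
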
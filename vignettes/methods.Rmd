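---
title: "Models and methods for paired discrete choice experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for paired discrete choice experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ruraldce)
```

This vignette documents the models the package implements, the numerical
choices behind them, and what the synthetic-data machinery does and does
not emulate. The running example is the rural-job experiment the package
ships as its reference condition: six job attributes — monthly salary
(four levels, 9,056 / 11,320 / 13,584 / 15,848 ETB, coded linearly in
ETB/month) and five binary attributes (housing, drug and equipment
supply, mandatory service years before study leave, management support,
workload), each dummy-coded against the less attractive reference level —
presented as 24 paired job comparisons split into 3 blocks, with each
respondent answering 2 blocks (16 tasks).

## Random utility and the paired-choice likelihood

Alternative $j$ in task $t$ has utility $U_{jt} = x_{jt}'\beta +
\varepsilon_{jt}$ with i.i.d. standard Gumbel errors, so in a paired task
the probability of choosing A is $\mathrm{logistic}\{(x_A - x_B)'\beta\}$.
All estimators therefore work on the per-task difference vector
$d_t = x_{A,t} - x_{B,t}$; the encoded column order (salary,
house_superior, drug_adequate, serve_oneyear, management_support,
workload_normal) is a single package-wide constant shared by the design
matrix, every estimator and all post-estimation, so coefficients can
never be silently reordered.

## Design construction

The original experiment used an orthogonal main-effects fractional
factorial; only its criteria — orthogonality, level balance, minimum
within-task overlap, utility balance — are recoverable, not its
algorithm. `build_paired_design()` therefore runs a seeded random-swap
search over profile pairings: starting from random pairs drawn from the
128-profile factorial, single-profile replacement moves are accepted only
when they strictly decrease a weighted penalty with one term per
criterion (mean absolute deviation of level frequencies from uniform;
mean absolute off-diagonal correlation between standardised encoded
columns; mean fraction of attributes identical within a task; mean
$|P(A) - 1/2|$ under a prior coefficient vector). Strict-decrease
acceptance makes the penalty trace non-increasing by construction, and
the (schema, seed) pair fully determines the result; equal-penalty
candidates are resolved by keeping the incumbent, and the final task
list is put in a canonical lexicographic order before blocking so the
output does not depend on the search path. The default prior is the zero
vector — no pilot estimates are assumed — under which every task is
utility-balanced at exactly $P(A) = 1/2$. Blocks are formed by a greedy
assignment that keeps each block's encoded column sums close to
proportional, then shuffled within block with the same seed. With the
default 2,000 search iterations the emitted 24-task design typically has
perfectly balanced binary attributes (24/24), salary counts within
$\pm 1$ of 12, and a maximum inter-column correlation below 0.1.

Whether the original 48 generated scenarios were pruned from a larger
candidate set is unknown; the package generates the 24 pairs directly,
which satisfies the same stated criteria.

## Synthetic respondents

The data-generating processes mirror the three estimators: identical
coefficients (`clogit`), independent normal random coefficients per
respondent (`mixl` — only per-attribute standard deviations are reported
for the reference study, so no correlation structure is assumed), and a
finite mixture with fixed class shares (`latent_class`). The shipped
presets use the study's published values: mixed-logit means/SDs for the
six attributes (salary fixed), and the three-class structure with shares
0.298/0.417/0.285. Covariates emulate the published sample margins: sex
Bernoulli(0.75 male) and integer ages from a rounded normal with mean 24
and SD 1.3 truncated to 21–28. Class membership is independent of
covariates by default, because the true dependence in the study is
unobservable; interaction DGPs instead shift a named coefficient
additively for a covariate dummy (the direction reported for the
young × service-year effect, with configurable magnitude since only the
direction was published). Gumbel noise is drawn by inverse CDF,
$-\log(-\log U)$, so simulations are bit-reproducible across platforms
given the seed, and one global seed is expanded into per-stage child
seeds by the documented rule in `child_seed()`.

What the generator does **not** emulate: response styles, attribute
non-attendance, straight-lining, item nonresponse, or any covariate–class
dependence. Passing recovery tests on these data therefore shows the
estimators are correct for the assumed random-utility process — not that
real respondents behave this way.

## Estimation

**Conditional logit.** Newton–Raphson from $\beta = 0$ with analytic
gradient and Hessian and step-halving; convergence when the gradient
max-norm falls below $10^{-6}$; covariance from the inverse observed
information, with respondent-clustered sandwich errors available.
Complete separation (the binary-logit MLE at infinity) is detected by a
runaway fitted utility difference and flagged on the result rather than
raised. The implementation is cross-checked in the test suite against an
independent conditional-logit implementation to four decimals.

**Panel mixed logit.** The simulated likelihood averages, per
respondent, the product of paired-choice probabilities across that
respondent's 16 tasks over $R$ coefficient draws before taking logs —
the panel estimator, which is what justifies respondent-level
heterogeneity with repeated choices. Draws are Halton sequences with one
prime base per random coefficient (2, 3, 5, 7, 11), burn-in 50,
inverse-normal transformed and partitioned across respondents;
random-shift scrambling is available behind a flag but off by default so
results are exactly reproducible. These details are the package's own
choices — the reference study reports only that 2,000 Halton draws were
used. Standard deviations enter unconstrained and are reported as
absolute values; salary is fixed (non-random) by default, matching the
absence of a published salary SD and keeping WTA ratios stable. The
optimiser is BFGS on the analytic gradient with the salary direction
internally rescaled (per 1,000 ETB) for conditioning; standard errors
come from a central-difference Hessian of the simulated log-likelihood.
Monte-Carlo noise in the likelihood is checked in the tests by doubling
$R$ and by comparison with a brute-force pseudo-random oracle.

**Latent class.** EM with seeded restarts: the E-step computes posterior
class probabilities from current shares and per-class panel likelihoods;
the M-step refits one weighted conditional logit per class (warm-started
Newton run to a $10^{-8}$ gradient norm, so the M-step truly maximises
and the mixture log-likelihood is provably non-decreasing — asserted on
every fixture in the tests). Restarts initialise classes at the pooled
estimate plus noise. A restart whose smallest share collapses below
`share_floor` is abandoned; the default floor is 0.05, in line with
mixture-modelling practice (the R reference mixture implementation uses
the same 5% minimum prior), because near-empty classes of a percent or
two are uninterpretable likelihood artifacts whose spurious
log-likelihood gain routinely exceeds the AIC penalty and destabilises
class selection; the floor is configurable down to effectively zero for
users who want them. Labels are deterministic — classes sorted by
descending salary coefficient, ties by share — so class numbering is
reproducible across runs. `select_classes()` fits each candidate $C$ and
chooses the AIC minimiser ($\mathrm{AIC} = 2k - 2\ell$,
$k = 6C + (C-1)$) among non-degenerate fits, propagating convergence
flags for the rest.

**Interactions.** Attribute × dummy columns (male; young = age ≤ 24) are
appended to the difference matrix and the conditional logit refitted;
rank-deficient interaction sets are rejected naming the collinear
columns.

Classical (inverse-information) standard errors are the default
everywhere because that matches the reported model family; whether the
original analysis clustered by respondent is unstated, so clustering is
available but never asserted as "the" published variant.

## Post-estimation

**Willingness to accept** is the coefficient ratio
$\mathrm{WTA}_a = \beta_a / \beta_{\text{salary}}$ in ETB/month —
invariant to rescaling all utilities — with delta-method or Krinsky–Robb
(10,000 seeded multivariate-normal draws, percentile bounds) intervals.
Ratios are refused when $|\beta_{\text{salary}}|$ is below a tolerance,
where they are numerically meaningless.

**Relative importance** per class takes each attribute's utility range —
$|\beta| \times 6{,}792$ ETB for salary (the span of its levels),
$|\beta|$ for a binary attribute — and normalises by the class maximum, so
exactly one attribute per class scores 1. The pooled table weights the
per-class *scores* by the class shares (the published description —
"adjusted by the class share" — does not say whether scores or raw ranges
are pooled; score-pooling is the default because it keeps every class on
the same normalised scale, and range-pooling is available via
`pooling = "ranges"`).

**Uptake-rate change** for a single attribute move is computed from a
paired comparison of the policy job against the otherwise identical base
job: $P = \mathrm{logistic}(\beta'\Delta x)$ and
$\Delta\% = 100 (P - 0.5)/0.5$ percentage points. This formula, applied
to the published mixed-logit coefficient means, reproduces the study's
printed prediction table (26.21 / 49.05 / 66.69 for the three salary
moves, and the five non-salary rows within 1%, the slack being rounding
of the printed coefficients) — which is why it, and plugging in the means
rather than integrating over the random coefficients, are the defaults; a
simulation-averaged probability is available via `simulate = TRUE`.
Intervals are Krinsky–Robb by default (the published table does not state
its interval method, so intervals are treated as illustrative, not as
replication targets).

The published coefficient tables themselves are shipped as
`reference_mixl()` and `reference_lcm()`. Because the study published
standard errors but not covariance matrices, these objects carry a
diagonal covariance approximation and say so; every *point* statistic
computed from them is exact.

## Numerical and testing choices

Tolerances: gradient max-norm $10^{-6}$ (conditional logit), EM absolute
log-likelihood improvement $10^{-7}$, BFGS relative tolerance $10^{-10}$.
Degenerate inputs are handled explicitly: zero mixing SDs reduce the
simulated likelihood to the conditional logit exactly; a single latent
class reproduces the conditional logit to $10^{-6}$; a zero design prior
gives exact utility balance; separation and degenerate mixtures are
flagged, not raised.

The test suite runs everything at deliberately chosen sizes: the full
study scale (352 respondents × 16 tasks) for conditional-logit and
mixed-logit recovery with 200 Halton draws rather than 2,000 (the
simulated likelihood is insensitive to the increase well below one
standard error, which the suite checks directly), and 2,000 respondents
for latent-class share recovery and AIC class selection, where the
study's own 352 would confound estimator correctness with small-sample
noise. Recovery is asserted within three standard errors of the
generating values; class shares within an absolute 0.05 band, roughly
three standard errors of a share estimate at that size.

## Known limitations

Two alternatives per task only, and no opt-out alternative; independent
(uncorrelated) random coefficients; constant-only class membership (no
covariates in the membership model); no WTP-space estimation, scale
heterogeneity or Bayesian variants. Published reference intervals are
approximations as described above. The uptake-change formula is tied to
the paired-comparison framing; it is not a market-share forecast against
an outside option.
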
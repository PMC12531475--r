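---
title: "Agreement analysis for binary ratings: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Agreement analysis for binary ratings: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agreebin)
```

This vignette is the package's account of the statistics it implements:
the measures, the chance models, how uncertainty is quantified, how the
sample-size calculators are built, what the simulators emulate, and where
the limits are.

## Data model

An agreement study yields binary assessments (1 = positive/abnormal,
0 = negative/normal) of $N$ patients by $R$ observers, possibly on several
occasions. `agreebin` stores them tidily — one row per assessment with
columns `patient`, `rater`, `occasion`, `rating` — and validates at entry:
values outside $\{0, 1, \mathrm{NA}\}$, duplicated patients, or duplicated
(patient, rater, occasion) triples are errors; patients with fewer than two
non-missing ratings are flagged at construction and rejected (by name) when
an analysis needs them. Analyses are *available-case*: every formula runs
off the per-patient sufficient statistics $(m_{i1}, R_i)$ — the number of
positive ratings and the number of ratings of patient $i$ — so observers
need not rate every patient, except where noted.

For intra-observer designs, replicate assessments are assumed
*interchangeable* (exchangeable within observer). `select_occasion()`
reduces replicates to one per observer, by first occasion or by a seeded
random draw; under interchangeability the rule is immaterial in
distribution, and the test suite checks exactly that on simulated data.

## Measures of agreement

For one observer pair, with cell counts $n_{11}, n_{12}, n_{21}, n_{22}$:

* proportion of agreement $p_o = (n_{11} + n_{22})/N$;
* specific positive agreement $p_{pos} = 2n_{11}/(2n_{11}+n_{12}+n_{21})$
  and its negative mirror — conditional views that matter when one category
  is rare and $p_o$ is dominated by the frequent one;
* Jaccard $p_J = n_{11}/(n_{11}+n_{12}+n_{21})$, linked by
  $p_J = p_{pos}/(2-p_{pos})$;
* Goodman–Kruskal $\lambda = 2p_{pos}-1$ and the Rogot–Goldberg mean
  $(p_{pos}+p_{neg})/2$.

Two identities are enforced by property tests: the Jaccard link above, and
the marginal-weighted decomposition
$p_o = \tfrac{p_{1.}+p_{.1}}{2} p_{pos} + \tfrac{p_{2.}+p_{.2}}{2} p_{neg}$.

### Chance correction

$\kappa = (p_o - p_e)/(1 - p_e)$ under three chance models: a fair coin
($p_e = 1/2$; G-index/PABAK), observer-specific marginals
($p_e = p_{1.}p_{.1} + p_{2.}p_{.2}$; Cohen), and pooled marginals
($p_e = \bar p_1^2 + \bar p_2^2$ with $\bar p_j$ the averaged marginal;
Scott/intraclass). Pooling the marginals always yields the largest $p_e$,
so $\kappa_2 \ge \kappa_3$ and $\kappa_1 \ge \kappa_3$ on every table;
$\kappa_1 \ge \kappa_2$ only when the observer-marginals chance agreement
is at least $1/2$ — with marginals straddling 50% the order can reverse,
which is itself diagnostic of discordant rating styles. Krippendorff's
alpha applies a finite-sample correction to the pooled-marginals chance
disagreement, $q_e^{(\alpha)} = \frac{NR}{NR-1} q_e^{(3)}$; the
implementation is proven (by a dual-route test against an independently
coded coincidence-matrix oracle) to equal the classical alpha, including
with missing ratings. Gwet's AC1 is $(p_o - q_e)/(1 - q_e)$ with $q_e$ the
pooled-marginals chance *disagreement*; it is reported because it is
widely requested, with the caveat that comparing agreement to expected
disagreement is conceptually debatable.

### More than two observers

All measures generalize by averaging over the $R(R-1)/2$ observer pairs.
The proportion of agreement becomes the mean fraction of agreeing pairs
per patient, which the package computes from $(m_{i1}, R_i)$ and verifies
against explicit pair enumeration. Specific agreement admits two
generalizations: the *pooled* form (ratio of mean numerator to mean
denominator; e.g. $p_{pos} = \sum_i m_{i1}(m_{i1}-1) / \sum_i
m_{i1}(R_i-1)$), which preserves the Jaccard identity and has an analytic
standard error, and the *mean-of-pairs* form, directly interpretable but
without either property. Pooled is the default; the two coincide exactly
when all pairs share the same positive rate. Chance models extend
likewise: the observer-marginals $p_e$ subtracts a between-observer
dispersion term and requires a complete matrix (with missing data the
pooled model is the honest choice and the error message says so); the
pooled model uses the ratings-weighted prevalence
$\bar p_j = \sum_i m_{ij} / \sum_i R_i$, which also covers unequal $R_i$.
The resulting kappas are Randolph's kappa ($\kappa_1$), Hubert/Conger's
kappa ($\kappa_2$) and Fleiss' kappa ($\kappa_3$); every multi-observer
formula reduces to its pair version at $R = 2$ (tested).

## The worked CTG example

Five obstetricians classified 20 cardiotocographs. The raw matrix of that
classic example was never printed; what is available are the per-observer
positive counts (6, 6, 9, 7, 12) and the ten pairwise agreement
proportions. For binary data those summaries determine each pairwise 2×2
table *uniquely* — `reconstruct_pair_tables()` solves
$n_{11} = (N p_o - N + n_a + n_b)/2$ and validates parity and range — and
`build_ctg_fixture()` finds, by deterministic backtracking over
per-patient rating patterns, a 20×5 matrix consistent with all fifteen
constraints. Every point estimate in the package depends on the data only
through these statistics, so the fixture reproduces them exactly
(`po_multi` 0.73; pooled $p_{pos}$ 0.6625, $p_J$ 0.4953; $\kappa_{1,2,3}$
0.46, 0.445, 0.4375; dropping the deviant fifth observer raises
everything). Multi-observer *standard errors* additionally depend on the
per-patient counts, which the summaries do not pin down completely; they
are fixture-dependent, a caveat repeated in `build_ctg_fixture()`'s
documentation. In practice the reconstruction reproduces the reference
intervals to ±0.01.

One printed reference value resists reproduction: the four-observer
$\kappa_2$ is exactly $409/549 = 0.74499$ from the formulas, which rounds
to 0.74, not the printed 0.75 (a double-rounding artifact; the same source
prints the neighbouring $\kappa_1$ as both 0.76 and 0.77). The package
returns the exact value.

## Inference

Patients are the independent sampling units. For a pair of observers the
delta method on the multinomial cells gives closed forms: the binomial
variance for $p_o$; the Fleiss–Cohen–Everitt large-sample variance for
Cohen's kappa; the Bloch–Kraemer variance for the intraclass kappa; a
4-fold linear map for the uniform-chance kappa; and the multinomial
gradient for $p_{pos}$/$p_{neg}$. For $R \ge 2$ observers every
coefficient is linearized in the per-patient statistics: writing the
estimator as a smooth function of means of per-patient quantities, the
influence contribution of patient $i$ is the gradient-weighted deviation,
and $\widehat{\mathrm{var}} = \sum_i (\mathrm{IF}_i -
\overline{\mathrm{IF}})^2 / (N(N-1))$. A delete-one jackknife is available
as a cross-check (`se_multi(..., method = "jackknife")`); the two differ
by $O(1/N)$. Mean-of-pairs specific agreement is *not* smooth in the
sufficient statistics and has no analytic standard error: asking for one
is an error that points to the bootstrap.

Intervals are Wald, $\hat\theta \pm z_{1-\alpha/2}\,\mathrm{se}$, truncated
to the coefficient's range with a `clamped` flag (reference tables print
1.00 uppers; the flag preserves the information that truncation happened).
Three refinements:

* **Continuity correction** (pairs, $p_o$ only): the per-patient agreement
  indicator is Bernoulli, and at small $N$ its discreteness degrades the
  Wald interval; the Yates correction widens it by $1/2N$ per side.
* **Bootstrap**: patients resampled with replacement, percentile interval,
  seed mandatory, undefined replicates dropped and counted (more than 50%
  undefined is an error). Agrees with the delta method within 15% on
  $N = 200$ matrices in the test suite.
* **Fisher-z**: symmetric interval on the $\tanh^{-1}$ scale. Near the
  boundary the clamped Wald interval *overcovers* grossly (0.999 observed
  at $\kappa_3 = 0.9$, $N = 30$, against 0.937 for Fisher-z); the
  variance-stabilized interval is the better default for agreement above
  about 0.9.

A seeded simulation in the test suite confirms that the Wald/delta
interval for Cohen's kappa holds its nominal level (coverage in
[0.92, 0.97] at $N = 100$, $\kappa = 0.5$).

## Sample-size planning

Both calculators target the mean pairwise proportion of agreement for $R$
observers, assuming (as is standard at the design stage) a common
prevalence $\pi$ of positive results. The estimator is a mean of
per-patient agreement fractions $a_i$, so everything reduces to a
planning value for $\mathrm{var}(a)$ given the two design inputs
$(\pi, p_o)$ — equivalently the implied pairwise kappa
$\kappa = 1 - (1-p_o)/(2\pi(1-\pi))$, which also defines the feasible
region ($p_o > 1 - 2\pi(1-\pi)$). The inputs fix the mean of $a$ but not
its distribution, so a model for the per-patient positive count is needed;
`plan_variance()` offers three, a genuinely open design choice:

* `worst_case` — the distribution maximizing $\mathrm{var}(a)$ subject to
  the matched agreement level: mass only on unanimous and maximally split
  patients, variance $(1-p_o)(p_o - a_{\min}(R))$. Assumption-light and
  conservative; the default for precision (CI-width) planning, where an
  optimistic variance means an underpowered study. For $R = 3$ *every*
  model coincides with it ($a_i$ is two-valued), and for $R = 2$ all three
  models give the binomial $p_o(1-p_o)$.
* `latent_class` — patients have a true status; observers err
  independently with a common rate $\varepsilon$ solved from
  $\varepsilon(1-\varepsilon) = (1-p_o)/2$, and the class weight is solved
  from $\pi$. A natural data-generating alternative; the default for power
  planning.
* `beta_binomial` — beta-mixed counts with ICC $\kappa$; lighter-tailed
  than the latent class, provided for sensitivity analysis.

The criteria are then solved by integer search: smallest $N$ with
$2 z_{1-\alpha/2}\sqrt{V_1/N} \le w$ (precision), or with
$\Phi\!\big((\rho_A-\rho_0)\sqrt{N/V_A} - z_{1-\alpha}\big) \ge 1-\beta$
(one-sided power, variance under the alternative). Minimality and
monotonicity in $R$ are property-tested, and seeded simulations of the
planning models at the five-observer cells confirm the achieved width and
power within Monte-Carlo error.

Known limit: for reference inputs ($\pi = 0.35$, $p_o = 0.80$, $w = 0.10$;
$\rho_0 = 0.80, \rho_A = 0.85$), the power-mode table
(192, 140, 110, 91, 77, 67 for $R = 3..8$) matches the published planning
table for this scenario within ±2 patients, and the precision-mode table
(144, 144, 123, 123, 115, 115) matches it at $R = 3, 4$ exactly and at
$R = 5$ within 2; at $R = 6$–8 the published precision figures
(111, 106, 95) fall between the worst-case bound and every constructive
model we examined and could not be reproduced by any single
common-correlation construction (the $R=3$ cell is model-forced, which
pins the criterion constant). The calculators therefore report their own
model-derived minima rather than imitating those cells.

## Simulators

`simulate_ratings()` is the common-correlation generator: patient-level
success probabilities drawn from a beta distribution with mean $\pi$ and
ICC $\rho$ (degenerate endpoints handled exactly), observers conditionally
independent. It emulates exchangeable observers with a shared difficulty
gradient across patients — the regime in which $\kappa_3$ *is* an
intraclass correlation — and the suite verifies parameter recovery (bias
below 0.02 at $N = 1000$, $R = 5$) and the implied pairwise agreement
$1 - 2\pi(1-\pi)(1-\rho)$. `simulate_rater_shift()` adds observer-specific
cutpoints on a shared latent Gaussian trait, generating the
heterogeneous-marginals regime that separates $\kappa_2$ from $\kappa_3$
(and can push $\kappa_2$ above $\kappa_1$ when marginals straddle 50%).
`simulate_intra_rater()` produces exchangeable replicates for
repeatability designs. All require a seed, restore the session RNG state,
and attach their generating spec as an attribute (the CLI writes it as a
JSON sidecar).

What the simulators do *not* emulate — and hence what passing tests do not
establish about real data: patient-by-observer interactions (a tracing
systematically misread by one observer only), drift over occasions,
informative missingness, and correlated errors between observers who
trained together. Real designs with those features need richer models than
any coefficient here fits.

## Numerical conventions

All counts are integers and every coefficient is a single division of
exactly representable integers (or sums of such ratios), so identities
hold to machine precision and are tested at $10^{-12}$ without a rational
arithmetic layer. Undefined coefficients (empty category, $p_e = 1$)
return `NA` with a machine-readable reason rather than 0 or `NaN`, and
propagate through derived quantities, standard errors and the tidy output
(`note` column). Presentation rounds to two decimals by default
(`print(fit, digits = )`, CLI `--precision`); machine formats always carry
full precision. Quantiles use exact `qnorm` values. Bootstrap and
occasion-selection seeds are mandatory, making every stochastic path
reproducible; seeded runs are asserted byte-identical in the CLI tests.
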
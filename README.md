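# agreebin

Agreement analysis for binary ratings: how closely do several observers (or
one observer on several occasions) agree when classifying patients on a
two-level scale such as normal/abnormal?

Clinical agreement studies routinely involve more than two raters, yet most
software stops at Cohen's kappa for a pair and reports no standard errors.
`agreebin` is aimed at biostatisticians and clinical researchers who need
the full toolbox for a binary scale:

* **Observed agreement** — the proportion of agreement
  `po = p11 + p22` for a pair, and for `R` observers the mean over all
  `R(R-1)/2` pairs, `po = mean_i [m1(m1-1) + m2(m2-1)] / (R_i(R_i-1))`,
  where `m1` of patient *i*'s `R_i` ratings are positive. Missing ratings
  are handled available-case via the per-patient `R_i`.
* **Specific agreement** — agreement conditional on a category:
  `ppos = 2 n11 / (2 n11 + n12 + n21)` (Dice / Sørensen / F1),
  `pneg` analogously, and the Jaccard coefficient
  `pJ = n11 / (n11 + n12 + n21) = ppos / (2 - ppos)`. Two multi-observer
  generalizations are provided: the pooled ratio-of-means (keeps the
  algebraic identities and an analytic standard error) and the unweighted
  mean over pairs.
* **Chance-corrected agreement** — `kappa = (po - pe)/(1 - pe)` under three
  chance models: a fair coin (G-index/PABAK; Randolph's kappa for many
  raters), observer-specific marginals (Cohen's kappa; Hubert/Conger for
  many raters), and pooled marginals (Scott's pi / Fleiss' kappa), plus
  Krippendorff's alpha (finite-sample-corrected) and Gwet's AC1.
* **Inference** — delta-method standard errors (closed forms for a pair,
  per-patient influence functions for `R >= 2`), Wald intervals with
  truncation flags, Yates continuity correction, patient-resampling
  bootstrap, and Fisher-z intervals for agreement near 1.
* **Design** — minimum numbers of patients for a target confidence-interval
  width or for a one-sided test of agreement, given the number of observers
  and the anticipated prevalence.
* **Simulation** — seeded generators of rating matrices with known
  prevalence and intraclass correlation (common-correlation/beta mixing,
  rater-specific cutpoints, intra-rater replicates).

Coefficients whose denominator vanishes (e.g. `ppos` when no one ever rated
positive) come back as an explicit *undefined* value with a reason — never
silently as 0.

## Worked example

The package ships a classic teaching example: five obstetricians (A–E)
classified 20 cardiotocographs as normal or abnormal. The published study
reported the per-observer positive counts (6, 6, 9, 7, 12) and all ten
pairwise agreement proportions; `ctg_fixture()` returns a rating matrix
reconstructed from those summaries by constraint search
(`build_ctg_fixture()`), which pins every statistic below exactly.

Observers A and C cross-classify as (n11, n12, n21, n22) = (6, 0, 3, 11):

```r
library(agreebin)
agreement(pair_table(6, 0, 3, 11, raters = c("A", "C")))
#> Agreement analysis: 20 patients, 2 raters
#> 95% confidence intervals (wald)
#>    coefficient    estimate    se lower upper level method     clamped
#>  1 po                 0.85  0.08  0.69     1  0.95 wald_delta TRUE
#>  2 kappa1             0.7   0.16  0.39     1  0.95 wald_delta TRUE
#>  3 kappa2             0.69  0.16  0.38     1  0.95 wald_delta FALSE
#>  4 kappa3             0.68  0.17  0.35     1  0.95 wald_delta TRUE
#>  5 ppos               0.8   0.11  0.58     1  0.95 wald_delta TRUE
#>  6 pneg               0.88  0.07  0.75     1  0.95 wald_delta TRUE
#>  ...
```

A and C agree on 85% of tracings; positive (abnormal) agreement is lower
(0.80) than negative (0.88); correcting for chance under the
observer-marginals model leaves kappa2 = 0.69 with a wide interval
(0.38–1.00) — twenty patients say little about population-level agreement.
`clamped = TRUE` marks bounds truncated at the natural range.

All five observers:

```r
agreement(ctg_fixture(), coefficients = c("po", "kappa2", "kappa3", "ppos", "pneg"))
#> Agreement analysis: 20 patients, 5 raters
#>   coefficient estimate    se lower upper level method     clamped
#> 1 po              0.73  0.05  0.63  0.83  0.95 wald_delta FALSE
#> 2 kappa2          0.45  0.12  0.21  0.68  0.95 wald_delta FALSE
#> 3 kappa3          0.44  0.12  0.2   0.68  0.95 wald_delta FALSE
#> 4 ppos            0.66  0.1   0.46  0.86  0.95 wald_delta FALSE
#> 5 pneg            0.78  0.05  0.68  0.87  0.95 wald_delta FALSE
```

An average pair of obstetricians agrees on 73% of tracings; after
accounting for each observer's rating style, about 45% of the
classification variability reflects real differences between patients
(kappa2 = 0.45, CI 0.21–0.68).

Planning a follow-up study to *test* H0: agreement <= 0.80 against an
alternative of 0.85 (one-sided alpha 0.05, power 0.80, 35% expected
abnormal):

```r
design_table(3:8, "power", prevalence = 0.35, rho0 = 0.80, rhoA = 0.85)
#>   n_raters     n achieved_power
#> 1        3   192          0.801
#> 2        4   140          0.802
#> 3        5   110          0.802
#> 4        6    91          0.803
#> 5        7    77          0.801
#> 6        8    67          0.800
```

With six observers, 91 patients suffice. `design_table(..., "ci_width")`
gives the precision-based analogue.

A command-line interface covering the same workflow (subcommands `agree`,
`design`, `simulate`, `fixture`) is installed at `inst/cli/agreebin`:

```sh
Rscript inst/cli/agreebin agree --pair-table '6 0 3 11' --coef po,kappa2
```

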
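#' Agreement coefficients for two observers
#'
#' Point estimates computed from a 2x2 [pair_table()]:
#'
#' * `po_pair()` — proportion of agreement (simple matching / Rand
#'   coefficient), `(n11 + n22) / N`.
#' * `ppos_pair()`, `pneg_pair()` — proportions of specific positive and
#'   negative agreement (Dice/Sorensen/F1 for the positive category),
#'   `2 n11 / (2 n11 + n12 + n21)` and `2 n22 / (2 n22 + n12 + n21)`.
#' * `jaccard_pair()` — Jaccard/Tanimoto coefficient
#'   `n11 / (n11 + n12 + n21)`; algebraically `ppos / (2 - ppos)`.
#' * `lambda_index()` — Goodman-Kruskal lambda, `2 ppos - 1`.
#' * `rogot_goldberg()` — mean of `ppos` and `pneg`.
#'
#' Coefficients with a zero denominator (a category never used by either
#' observer) are undefined; see [is_undefined()].
#'
#' @param t A [pair_table()].
#' @return A numeric scalar, or `NA` with a `reason` attribute when
#'   undefined.
#' @examples
#' t <- pair_table(6, 0, 3, 11)
#' po_pair(t)        # 0.85
#' ppos_pair(t)      # 0.80
#' jaccard_pair(t)   # 2/3
#' @export
po_pair <- function(t) {
  stopifnot(inherits(t, "pair_table"))
  (t$n11 + t$n22) / t$n
}

#' @rdname po_pair
#' @export
ppos_pair <- function(t) {
  stopifnot(inherits(t, "pair_table"))
  den <- 2 * t$n11 + t$n12 + t$n21
  if (den == 0) {
    return(undefined_coef("no positive rating by either observer"))
  }
  2 * t$n11 / den
}

#' @rdname po_pair
#' @export
pneg_pair <- function(t) {
  stopifnot(inherits(t, "pair_table"))
  den <- 2 * t$n22 + t$n12 + t$n21
  if (den == 0) {
    return(undefined_coef("no negative rating by either observer"))
  }
  2 * t$n22 / den
}

#' @rdname po_pair
#' @export
jaccard_pair <- function(t) {
  stopifnot(inherits(t, "pair_table"))
  den <- t$n11 + t$n12 + t$n21
  if (den == 0) {
    return(undefined_coef("no positive rating by either observer"))
  }
  t$n11 / den
}

#' @rdname po_pair
#' @export
lambda_index <- function(t) {
  pp <- ppos_pair(t)
  if (is_undefined(pp)) return(pp)
  2 * pp - 1
}

#' @rdname po_pair
#' @export
rogot_goldberg <- function(t) {
  pp <- ppos_pair(t)
  pn <- pneg_pair(t)
  if (is_undefined(pp)) return(pp)
  if (is_undefined(pn)) return(pn)
  (pp + pn) / 2
}

chance_models <- c("uniform", "rater_marginals", "pooled_marginals")

# accept def1/def2/def3 and kappa1/2/3 shorthands
match_chance <- function(chance) {
  chance <- tolower(chance[[1]])
  alias <- c(def1 = "uniform", def2 = "rater_marginals",
             def3 = "pooled_marginals",
             "1" = "uniform", "2" = "rater_marginals", "3" = "pooled_marginals")
  if (chance %in% names(alias)) chance <- alias[[chance]]
  match.arg(chance, chance_models)
}

#' Chance agreement for two observers
#'
#' The proportion of agreement expected if both observers classified at
#' random, under one of three classical chance models:
#'
#' * `"uniform"` (definition 1): both observers toss a fair coin;
#'   `pe = 0.5`. Leads to the G-index / PABAK / Brennan-Prediger kappa.
#' * `"rater_marginals"` (definition 2): each observer tosses their own
#'   biased coin with success probability equal to their observed positive
#'   rate; `pe = p1. p.1 + p2. p.2`. Leads to Cohen's kappa.
#' * `"pooled_marginals"` (definition 3): both observers share a coin with
#'   the average positive rate; `pe = ((p1. + p.1)/2)^2 + ((p2. + p.2)/2)^2`.
#'   Leads to Scott's pi / the intraclass kappa.
#'
#' @param t A [pair_table()].
#' @param chance Chance model; `"def1"`, `"def2"`, `"def3"` are accepted
#'   shorthands.
#' @return The chance agreement proportion.
#' @examples
#' chance_agreement(pair_table(6, 0, 3, 11), "rater_marginals")  # 0.52
#' @export
chance_agreement <- function(t, chance = c("rater_marginals", "uniform",
                                           "pooled_marginals")) {
  stopifnot(inherits(t, "pair_table"))
  chance <- match_chance(chance)
  p <- pair_proportions(t)
  switch(chance,
    uniform = 0.5,
    rater_marginals = p$p1. * p$p.1 + p$p2. * p$p.2,
    pooled_marginals = ((p$p1. + p$p.1) / 2)^2 + ((p$p2. + p$p.2) / 2)^2
  )
}

#' Chance-corrected agreement (kappa) for two observers
#'
#' `kappa = (po - pe) / (1 - pe)`, with `pe` given by
#' [chance_agreement()]. The three chance models yield the G-index/PABAK
#' (`uniform`; equal to `2 po - 1`), Cohen's kappa (`rater_marginals`) and
#' Scott's pi / intraclass kappa (`pooled_marginals`). On any table the
#' ordering `kappa1 >= kappa2 >= kappa3` holds.
#'
#' @inheritParams chance_agreement
#' @return A numeric scalar, or undefined (see [is_undefined()]) when
#'   `pe = 1` (all ratings in one category under the pooled model).
#' @examples
#' kappa_pair(pair_table(6, 0, 3, 11), "def2")  # 0.6875, Cohen's kappa
#' @export
kappa_pair <- function(t, chance = c("rater_marginals", "uniform",
                                     "pooled_marginals")) {
  pe <- chance_agreement(t, chance)
  if (pe >= 1) {
    return(undefined_coef(
      "chance agreement is 1: all ratings fall in a single category"))
  }
  (po_pair(t) - pe) / (1 - pe)
}

#' Krippendorff's alpha for two observers
#'
#' Chance correction built on the pooled-marginals model but with a finite
#' sample (Bessel-type) correction of the expected disagreement,
#' `qe = (NR / (NR - 1)) * 2 * ((p1. + p.1)/2) * ((p2. + p.2)/2)` with
#' `R = 2` ratings per patient; `alpha = 1 - qo / qe`. This equals the
#' classical coincidence-matrix formulation of alpha for binary data and
#' converges to Scott's pi as the number of patients grows.
#'
#' @param t A [pair_table()].
#' @return A numeric scalar, or undefined when every rating falls in one
#'   category.
#' @export
kripp_alpha_pair <- function(t) {
  stopifnot(inherits(t, "pair_table"))
  n1 <- 2 * t$n11 + t$n12 + t$n21   # pairable positive ratings
  n2 <- 2 * t$n22 + t$n12 + t$n21
  if (n1 == 0 || n2 == 0) {
    return(undefined_coef("expected disagreement is 0: one category unused"))
  }
  # qo = (n12 + n21)/N and qe = n1*n2 / (N * (2N - 1)), so
  1 - (2 * t$n - 1) * (t$n12 + t$n21) / (n1 * n2)
}

#' @rdname gwet_ac1
#' @export
ac1_pair <- function(t) {
  stopifnot(inherits(t, "pair_table"))
  qe <- 1 - chance_agreement(t, "pooled_marginals")
  if (qe >= 1) return(undefined_coef("chance disagreement is 1"))
  (po_pair(t) - qe) / (1 - qe)
}
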
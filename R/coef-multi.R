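# Multi-observer agreement coefficients. All formulas run off the
# per-patient sufficient statistics (m_pos, n_rated) from category_counts();
# pairwise-mean identities are checked against explicit pair enumeration in
# the test suite.

# shared entry: validated counts for analysis
multi_counts <- function(x, require_complete = FALSE, caller = "this statistic") {
  x <- as_ratings(x)
  cc <- category_counts(x, warn = FALSE)
  under <- cc$patient[cc$n_rated < 2]
  if (length(under)) {
    abort(paste0("patient(s) with fewer than two non-missing ratings: ",
                 paste(under, collapse = ", "),
                 ". Drop or complete them before computing ", caller, "."))
  }
  if (require_complete) {
    w <- ratings_wide(x)
    if (anyNA(w) || length(unique(cc$n_rated)) > 1L) {
      abort(paste0(caller, " requires a complete matrix (every observer ",
                   "rates every patient); with missing ratings use the ",
                   "pooled-marginals chance model instead."))
    }
  }
  list(ratings = x, counts = cc)
}

#' Mean pairwise proportion of agreement for two or more observers
#'
#' The average, over all distinct observer pairs, of the pairwise proportion
#' of agreement. Computed from the per-patient counts: with `m1` positive and
#' `m2` negative among `R_i` ratings for patient `i`,
#' `po = mean_i [m1(m1-1) + m2(m2-1)] / (R_i (R_i - 1))`, which equals the
#' explicit mean over pair tables when every observer rates every patient,
#' and extends it to per-patient numbers of ratings otherwise
#' (available-case analysis).
#'
#' @param x A [ratings] object, or anything [as_ratings()] accepts.
#' @return A numeric scalar.
#' @examples
#' po_multi(ctg_fixture())  # 0.73
#' @export
po_multi <- function(x) {
  cc <- multi_counts(x, caller = "the proportion of agreement")$counts
  mean((cc$m_pos * (cc$m_pos - 1) + cc$m_neg * (cc$m_neg - 1)) /
         (cc$n_rated * (cc$n_rated - 1)))
}

#' Specific agreement for two or more observers
#'
#' Two generalizations of the specific (positive or negative) agreement:
#'
#' * `approach = "pooled"` (default): the ratio of the mean numerator to the
#'   mean denominator across pairs. For the positive category this is
#'   `sum(m1 (m1 - 1)) / sum(m1 (R_i - 1))`. It preserves the identity
#'   `pJ = ppos / (2 - ppos)` and admits an analytic standard error, at the
#'   price of weighting observer pairs by how often they use the category.
#' * `approach = "mean_of_pairs"`: the unweighted mean of the pairwise
#'   indices; directly interpretable, but the Jaccard identity no longer
#'   holds and no analytic standard error exists (use [bootstrap_ci()]).
#'
#' Both approaches coincide when all pairs share the same positive rate, and
#' reduce to [ppos_pair()]/[pneg_pair()] for two observers.
#' `jaccard_multi()` generalizes the Jaccard coefficient the same way.
#'
#' @param x A [ratings] object, or anything [as_ratings()] accepts.
#' @param category `"pos"` or `"neg"`.
#' @param approach `"pooled"` or `"mean_of_pairs"`.
#' @return A numeric scalar, or undefined (see [is_undefined()]) when the
#'   category is never used.
#' @examples
#' specific_multi(ctg_fixture(), "pos")                 # 0.66
#' specific_multi(ctg_fixture(), "pos", "mean_of_pairs") # 0.69
#' @export
specific_multi <- function(x, category = c("pos", "neg"),
                           approach = c("pooled", "mean_of_pairs")) {
  category <- match.arg(category)
  approach <- match.arg(approach)
  if (approach == "pooled") {
    cc <- multi_counts(x, caller = "pooled specific agreement")$counts
    m <- if (category == "pos") cc$m_pos else cc$m_neg
    den <- sum(m * (cc$n_rated - 1))
    if (den == 0) {
      lab <- switch(category, pos = "positive", neg = "negative")
      return(undefined_coef(paste0("no ", lab, " ratings")))
    }
    sum(m * (m - 1)) / den
  } else {
    mean_of_pairs(x, switch(category, pos = ppos_pair, neg = pneg_pair),
                  paste0("specific ", category, " agreement"))
  }
}

#' @rdname specific_multi
#' @export
jaccard_multi <- function(x, approach = c("pooled", "mean_of_pairs")) {
  approach <- match.arg(approach)
  if (approach == "pooled") {
    pp <- specific_multi(x, "pos", "pooled")
    if (is_undefined(pp)) return(pp)
    pp / (2 - pp)
  } else {
    mean_of_pairs(x, jaccard_pair, "the Jaccard coefficient")
  }
}

# unweighted mean of a pairwise index over all observer pairs
mean_of_pairs <- function(x, pair_fun, what) {
  mc <- multi_counts(x, require_complete = TRUE, caller = what)
  w <- ratings_wide(mc$ratings)
  raters <- colnames(w)
  pairs <- utils::combn(raters, 2, simplify = FALSE)
  vals <- purrr::map_dbl(pairs, function(p) {
    v <- pair_fun(crosstab(mc$ratings, p[1], p[2]))
    if (is_undefined(v)) NA_real_ else v
  })
  if (anyNA(vals)) {
    bad <- purrr::map_chr(pairs[is.na(vals)], paste, collapse = ",")
    return(undefined_coef(paste0(what, " is undefined for pair(s): ",
                                 paste(bad, collapse = "; "))))
  }
  mean(vals)
}

#' Chance agreement for two or more observers
#'
#' Extends the three chance models of [chance_agreement()] to `R` observers.
#' Under `"rater_marginals"` (definition 2; requires a complete matrix),
#' `pe = sum_j pj^2 - (1/(R(R-1))) sum_j sum_r (pj(r) - pj)^2` with `pj(r)`
#' the proportion of patients observer `r` assigned to category `j` and `pj`
#' the mean over observers. Under `"pooled_marginals"` (definition 3),
#' `pe = mean_i (m_i1 p1 + m_i2 p2) / R_i` with pooled prevalences
#' `pj = sum_i m_ij / sum_i R_i`, which allows per-patient numbers of
#' ratings. Both reduce to the two-observer formulas for `R = 2`.
#'
#' @inheritParams po_multi
#' @inheritParams chance_agreement
#' @return The chance agreement proportion.
#' @export
chance_multi <- function(x, chance = c("rater_marginals", "uniform",
                                       "pooled_marginals")) {
  chance <- match_chance(chance)
  if (chance == "uniform") return(0.5)
  if (chance == "rater_marginals") {
    mc <- multi_counts(x, require_complete = TRUE,
                       caller = "the rater-marginals chance model")
    w <- ratings_wide(mc$ratings)
    r <- ncol(w)
    p1r <- colMeans(w)
    p1 <- mean(p1r)
    disp <- sum((p1r - p1)^2) + sum(((1 - p1r) - (1 - p1))^2)
    p1^2 + (1 - p1)^2 - disp / (r * (r - 1))
  } else {
    cc <- multi_counts(x, caller = "the pooled-marginals chance model")$counts
    p1 <- sum(cc$m_pos) / sum(cc$n_rated)
    mean((cc$m_pos * p1 + cc$m_neg * (1 - p1)) / cc$n_rated)
  }
}

#' Chance-corrected agreement (kappa) for two or more observers
#'
#' `kappa = (po - pe) / (1 - pe)` with [po_multi()] and [chance_multi()];
#' equivalently the ratio of mean pairwise excess agreement to mean pairwise
#' chance disagreement. The three chance models yield Randolph's kappa /
#' kappa-BP (`uniform`), Hubert/Conger's kappa (`rater_marginals`) and
#' Fleiss' kappa (`pooled_marginals`); note that Fleiss' kappa generalizes
#' Scott's pi, not Cohen's kappa.
#'
#' @inheritParams chance_multi
#' @return A numeric scalar, or undefined when `pe = 1`.
#' @examples
#' kappa_multi(ctg_fixture(), "def2")  # Conger's kappa, 0.45
#' @export
kappa_multi <- function(x, chance = c("rater_marginals", "uniform",
                                      "pooled_marginals")) {
  pe <- chance_multi(x, chance)
  if (pe >= 1) {
    return(undefined_coef(
      "chance agreement is 1: all ratings fall in a single category"))
  }
  (po_multi(x) - pe) / (1 - pe)
}

#' Gwet's AC1 coefficient
#'
#' `AC1 = (po - qe) / (1 - qe)`, where `qe` is the proportion of
#' disagreement expected by chance under the pooled-marginals model
#' (`qe = 2 p1 p2`). The comparison of observed agreement with expected
#' disagreement makes AC1 less sensitive to prevalence than kappa, though
#' that construction has been criticized as conceptually mismatched.
#' `ac1_pair()` is the two-observer version.
#'
#' @inheritParams po_multi
#' @param t A [pair_table()] (for `ac1_pair()`).
#' @return A numeric scalar, or undefined when `qe = 1`.
#' @export
gwet_ac1 <- function(x) {
  qe <- 1 - chance_multi(x, "pooled_marginals")
  if (qe >= 1) return(undefined_coef("chance disagreement is 1"))
  (po_multi(x) - qe) / (1 - qe)
}

#' Krippendorff's alpha for two or more observers
#'
#' The classical coincidence-matrix alpha for binary data, allowing
#' per-patient numbers of ratings (available-case): with `c_j = sum_i m_ij`
#' pairable ratings in category `j` and `n.. = sum_i R_i`,
#' `alpha = 1 - (n.. - 1) * sum_i [m_i1 m_i2 / (R_i - 1)] / (c1 c2)`.
#' Patients with a single rating cannot form coincidence pairs and are
#' excluded, as in the canonical definition. For two complete observers this
#' equals [kripp_alpha_pair()], and it approaches Fleiss' kappa as the
#' number of patients grows.
#'
#' @inheritParams po_multi
#' @return A numeric scalar, or undefined when one category is never used.
#' @export
kripp_alpha <- function(x) {
  x <- as_ratings(x)
  cc <- category_counts(x, warn = FALSE)
  cc <- cc[cc$n_rated >= 2, , drop = FALSE]
  if (nrow(cc) == 0) abort("no patient has two or more ratings.")
  c1 <- sum(cc$m_pos)
  c2 <- sum(cc$m_neg)
  if (c1 == 0 || c2 == 0) {
    return(undefined_coef("expected disagreement is 0: one category unused"))
  }
  ntot <- sum(cc$n_rated)
  dobs <- sum(cc$m_pos * cc$m_neg / (cc$n_rated - 1))
  1 - (ntot - 1) * dobs / (c1 * c2)
}
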
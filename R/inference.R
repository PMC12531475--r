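# Standard errors (delta method / influence functions), Wald-type intervals,
# continuity correction, bootstrap, Fisher-z.

#' Delta-method standard errors for two-observer coefficients
#'
#' Large-sample standard errors treating the four cell counts as
#' multinomial:
#'
#' * `se_po_pair()` — binomial form `sqrt(po (1 - po) / N)`.
#' * `se_kappa_pair()` — under the uniform chance model the kappa is a
#'   linear map of `po` (`var = 4 var(po)`); under rater marginals the
#'   Fleiss-Cohen-Everitt large-sample variance of Cohen's kappa; under
#'   pooled marginals the Bloch-Kraemer variance of the intraclass kappa.
#' * `se_specific_pair()` — multinomial delta method for the specific
#'   agreement proportions.
#'
#' @param t A [pair_table()].
#' @param chance Chance model, as in [kappa_pair()].
#' @param category `"pos"` or `"neg"`.
#' @return A non-negative numeric scalar (undefined propagates as in
#'   [is_undefined()]).
#' @examples
#' se_po_pair(pair_table(6, 0, 3, 11))  # 0.0798
#' @export
se_po_pair <- function(t) {
  stopifnot(inherits(t, "pair_table"))
  po <- po_pair(t)
  sqrt(po * (1 - po) / t$n)
}

#' @rdname se_po_pair
#' @export
se_kappa_pair <- function(t, chance = c("rater_marginals", "uniform",
                                        "pooled_marginals")) {
  stopifnot(inherits(t, "pair_table"))
  chance <- match_chance(chance)
  k <- kappa_pair(t, chance)
  if (is_undefined(k)) return(k)
  p <- pair_proportions(t)
  n <- t$n
  if (chance == "uniform") {
    return(2 * se_po_pair(t))
  }
  if (chance == "rater_marginals") {
    pe <- chance_agreement(t, chance)
    a <- p$p11 * (1 - (p$p1. + p$p.1) * (1 - k))^2 +
      p$p22 * (1 - (p$p2. + p$p.2) * (1 - k))^2
    b <- (1 - k)^2 * (p$p12 * (p$p.1 + p$p2.)^2 + p$p21 * (p$p.2 + p$p1.)^2)
    cc <- (k - pe * (1 - k))^2
    v <- (a + b - cc) / (n * (1 - pe)^2)
    return(sqrt(max(v, 0)))
  }
  # pooled marginals: intraclass kappa, common prevalence (p1. + p.1)/2
  pi1 <- (p$p1. + p$p.1) / 2
  v <- (1 - k) / n *
    ((1 - k) * (1 - 2 * k) + k * (2 - k) / (2 * pi1 * (1 - pi1)))
  sqrt(max(v, 0))
}

#' @rdname se_po_pair
#' @export
se_specific_pair <- function(t, category = c("pos", "neg")) {
  stopifnot(inherits(t, "pair_table"))
  category <- match.arg(category)
  val <- if (category == "pos") ppos_pair(t) else pneg_pair(t)
  if (is_undefined(val)) return(val)
  p <- pair_proportions(t)
  # gradient of 2*paa / (2*paa + p12 + p21) wrt the multinomial cells
  paa <- if (category == "pos") p$p11 else p$p22
  den <- 2 * paa + p$p12 + p$p21
  g_aa <- 2 * (p$p12 + p$p21) / den^2
  g_off <- -2 * paa / den^2
  gsq <- g_aa^2 * paa + g_off^2 * (p$p12 + p$p21)
  gbar <- g_aa * paa + g_off * (p$p12 + p$p21)  # zero analytically
  sqrt(max((gsq - gbar^2) / t$n, 0))
}

#' Wald-type confidence interval
#'
#' `estimate +/- z(1 - alpha/2) * se`, truncated to the coefficient's
#' natural range. Truncation is recorded in the `clamped` column: published
#' agreement tables routinely print an upper bound of 1.00.
#'
#' @param estimate,se Point estimate and its standard error.
#' @param level Confidence level (default 0.95).
#' @param bounds Natural range to clamp to, e.g. `c(0, 1)` for proportions
#'   and `c(-1, 1)` for kappas; `NULL` for none.
#' @return A one-row tibble: `estimate`, `se`, `lower`, `upper`, `level`,
#'   `method`, `clamped`.
#' @examples
#' wald_ci(0.85, 0.0798)
#' @export
wald_ci <- function(estimate, se, level = 0.95, bounds = c(0, 1)) {
  stopifnot(se >= 0 || is.na(se), level > 0, level < 1)
  z <- qnorm(1 - (1 - level) / 2)
  lo <- estimate - z * se
  hi <- estimate + z * se
  clamped <- FALSE
  if (!is.null(bounds)) {
    clamped <- isTRUE(lo < bounds[1]) || isTRUE(hi > bounds[2])
    lo <- max(lo, bounds[1])
    hi <- min(hi, bounds[2])
  }
  tibble::tibble(estimate = as_coef(estimate), se = se, lower = lo,
                 upper = hi, level = level, method = "wald_delta",
                 clamped = clamped)
}

#' Continuity-corrected interval for the pairwise proportion of agreement
#'
#' With two observers the per-patient agreement indicator is Bernoulli, and
#' its discreteness degrades the Wald interval at small `N`. Yates'
#' correction widens the interval by `1 / (2N)` on each side before
#' clamping.
#'
#' @param t A [pair_table()].
#' @param level Confidence level.
#' @return A one-row tibble as in [wald_ci()].
#' @export
continuity_corrected_ci <- function(t, level = 0.95) {
  stopifnot(inherits(t, "pair_table"))
  po <- po_pair(t)
  se <- se_po_pair(t)
  z <- qnorm(1 - (1 - level) / 2)
  lo <- po - z * se - 1 / (2 * t$n)
  hi <- po + z * se + 1 / (2 * t$n)
  clamped <- lo < 0 || hi > 1
  tibble::tibble(estimate = po, se = se, lower = max(lo, 0),
                 upper = min(hi, 1), level = level,
                 method = "wald_delta_cc", clamped = clamped)
}

#' Fisher-z (variance-stabilizing) confidence interval
#'
#' Transforms the estimate with `atanh`, builds a symmetric interval on the
#' z scale with the delta-mapped standard error `se / (1 - estimate^2)`, and
#' back-transforms. The bounds lie strictly inside (-1, 1) without clamping,
#' which helps when agreement is close to 1 and the Wald interval would be
#' truncated.
#'
#' @inheritParams wald_ci
#' @return A one-row tibble as in [wald_ci()].
#' @export
fisher_z_ci <- function(estimate, se, level = 0.95) {
  if (abs(estimate) >= 1) {
    abort("Fisher-z interval requires |estimate| < 1.")
  }
  z <- qnorm(1 - (1 - level) / 2)
  zest <- atanh(estimate)
  zse <- se / (1 - estimate^2)
  tibble::tibble(estimate = as_coef(estimate), se = se,
                 lower = tanh(zest - z * zse), upper = tanh(zest + z * zse),
                 level = level, method = "fisher_z", clamped = FALSE)
}

# ---- multi-observer standard errors -----------------------------------

# influence contributions per patient for a multi-observer coefficient;
# variance of the estimator is sum((IF - mean)^2) / (N (N - 1))
influence_values <- function(x, coefficient) {
  mc <- multi_counts(x, caller = coefficient)
  cc <- mc$counts
  n <- nrow(cc)
  a <- (cc$m_pos * (cc$m_pos - 1) + cc$m_neg * (cc$m_neg - 1)) /
    (cc$n_rated * (cc$n_rated - 1))
  po <- mean(a)
  if (coefficient == "po") return(a - po)
  if (coefficient == "kappa1") return(2 * (a - po))
  if (coefficient %in% c("kappa3", "ac1")) {
    p1 <- sum(cc$m_pos) / sum(cc$n_rated)
    pe <- p1^2 + (1 - p1)^2
    # prevalence influence: p1 is a ratio of per-patient sums
    rbar <- mean(cc$n_rated)
    if_p1 <- (cc$m_pos - p1 * cc$n_rated) / rbar
    if_pe <- (4 * p1 - 2) * if_p1
    if (coefficient == "kappa3") {
      if (pe >= 1) abort("kappa is undefined: chance agreement is 1.")
      return((a - po) / (1 - pe) + (po - 1) * if_pe / (1 - pe)^2)
    }
    if (pe <= 0) abort("AC1 is undefined: chance disagreement is 1.")
    return((a - po) / pe + (1 - po) * if_pe / pe^2)
  }
  if (coefficient == "kappa2") {
    w <- ratings_wide(mc$ratings)
    if (anyNA(w)) {
      abort("the rater-marginals chance model requires a complete matrix.")
    }
    r <- ncol(w)
    p1r <- colMeans(w)
    p1 <- mean(p1r)
    pe <- p1^2 + (1 - p1)^2 - 2 * sum((p1r - p1)^2) / (r * (r - 1))
    if (pe >= 1) abort("kappa is undefined: chance agreement is 1.")
    dpe <- (4 * p1 - 2) / r - (4 / (r * (r - 1))) * (p1r - p1)
    if_pe <- as.numeric(sweep(w, 2, p1r) %*% dpe)
    return((a - po) / (1 - pe) + (po - 1) * if_pe / (1 - pe)^2)
  }
  if (coefficient %in% c("ppos", "pneg", "jaccard")) {
    m <- if (coefficient == "pneg") cc$m_neg else cc$m_pos
    u <- m * (m - 1)
    v <- m * (cc$n_rated - 1)
    if (sum(v) == 0) abort("specific agreement is undefined: category unused.")
    ratio <- sum(u) / sum(v)
    if_ratio <- ((u - mean(u)) - ratio * (v - mean(v))) / mean(v)
    if (coefficient == "jaccard") {
      # pJ = ppos / (2 - ppos): derivative 2 / (2 - ppos)^2
      return(if_ratio * 2 / (2 - ratio)^2)
    }
    return(if_ratio)
  }
  abort(paste0("no analytic standard error for '", coefficient, "'."))
}

#' Standard errors for multi-observer coefficients
#'
#' Delta-method standard errors obtained by linearizing each coefficient in
#' the per-patient sufficient statistics (influence functions): patients are
#' the independent sampling units, so the variance of the estimator is the
#' empirical variance of the per-patient influence contributions divided by
#' `N`. `method = "jackknife"` instead deletes one patient at a time; the
#' two agree closely and the jackknife also covers coefficients without a
#' closed-form linearization (e.g. Krippendorff's alpha).
#'
#' Mean-of-pairs specific agreement has no analytic standard error (the
#' unweighted mean of ratios does not linearize in the per-patient counts);
#' use [bootstrap_ci()].
#'
#' @param x A [ratings] object, or anything [as_ratings()] accepts.
#' @param coefficient One of `"po"`, `"kappa1"`, `"kappa2"`, `"kappa3"`,
#'   `"ppos"`, `"pneg"`, `"jaccard"`, `"ac1"`, `"alpha"`.
#' @param method `"influence"` (analytic linearization, default) or
#'   `"jackknife"`.
#' @return A non-negative numeric scalar.
#' @examples
#' se_multi(ctg_fixture(), "po")
#' @export
se_multi <- function(x, coefficient = c("po", "kappa1", "kappa2", "kappa3",
                                        "ppos", "pneg", "jaccard", "ac1",
                                        "alpha"),
                     method = c("influence", "jackknife")) {
  coefficient <- match.arg(coefficient)
  method <- match.arg(method)
  x <- as_ratings(x)
  if (method == "influence" && coefficient != "alpha") {
    IF <- influence_values(x, coefficient)
    n <- length(IF)
    return(sqrt(sum((IF - mean(IF))^2) / (n * (n - 1))))
  }
  jackknife_se(x, multi_estimator(coefficient))
}

multi_estimator <- function(coefficient) {
  switch(coefficient,
    po = po_multi,
    kappa1 = function(x) kappa_multi(x, "uniform"),
    kappa2 = function(x) kappa_multi(x, "rater_marginals"),
    kappa3 = function(x) kappa_multi(x, "pooled_marginals"),
    ppos = function(x) specific_multi(x, "pos"),
    pneg = function(x) specific_multi(x, "neg"),
    jaccard = jaccard_multi,
    ac1 = gwet_ac1,
    alpha = kripp_alpha,
    abort(paste0("unknown coefficient '", coefficient, "'."))
  )
}

jackknife_se <- function(x, stat) {
  x <- as_ratings(x)
  pats <- unique(x$patient)
  n <- length(pats)
  vals <- purrr::map_dbl(pats, function(p) {
    v <- stat(new_ratings(x[x$patient != p, ]))
    if (is_undefined(v)) NA_real_ else v
  })
  if (anyNA(vals)) abort("jackknife replicate undefined; use bootstrap_ci().")
  sqrt((n - 1) / n * sum((vals - mean(vals))^2))
}

#' Nonparametric bootstrap confidence interval
#'
#' Resamples patients (the independent units) with replacement, recomputes
#' the statistic on each resample, and returns the percentile interval.
#' Replicates on which the statistic is undefined (e.g. a category vanished
#' from the resample) are dropped and counted; more than 50% undefined is an
#' error.
#'
#' @param x A [ratings] object, or anything [as_ratings()] accepts.
#' @param statistic A coefficient name accepted by [se_multi()], or a
#'   function `ratings -> numeric`.
#' @param B Number of bootstrap resamples (at least 200; default 2000).
#' @param seed Integer seed (required: resampling must be reproducible).
#' @param level Confidence level.
#' @return A one-row tibble as in [wald_ci()] (`se` is the bootstrap
#'   standard deviation; `method` is `"bootstrap_percentile"`), with an
#'   attribute `n_undefined`.
#' @examples
#' bootstrap_ci(ctg_fixture(), "po", B = 200, seed = 1)
#' @export
bootstrap_ci <- function(x, statistic, B = 2000, seed, level = 0.95) {
  stopifnot(B >= 200)
  if (missing(seed) || is.null(seed)) {
    abort("bootstrap_ci() requires a `seed` for reproducibility.")
  }
  x <- as_ratings(x)
  stat <- if (is.function(statistic)) statistic else {
    multi_estimator(match.arg(statistic, c("po", "kappa1", "kappa2", "kappa3",
                                           "ppos", "pneg", "jaccard", "ac1",
                                           "alpha")))
  }
  est <- stat(x)
  if (is_undefined(est)) {
    abort(paste0("statistic undefined on the observed data: ",
                 undefined_reason(est)))
  }
  rows_by_patient <- split(seq_len(nrow(x)), x$patient)
  n <- length(rows_by_patient)
  reps <- with_seed(seed, {
    purrr::map_dbl(seq_len(B), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      rows <- unlist(rows_by_patient[idx], use.names = FALSE)
      boot <- x[rows, ]
      # resampled patients must stay distinct units
      boot$patient <- rep(sprintf("b%04d", seq_along(idx)),
                          lengths(rows_by_patient)[idx])
      v <- tryCatch(stat(new_ratings(boot)), error = function(e) NA_real_)
      if (is_undefined(v)) NA_real_ else v
    })
  })
  n_undef <- sum(is.na(reps))
  if (n_undef > B / 2) {
    abort(paste0("statistic undefined on ", n_undef, " of ", B,
                 " bootstrap replicates."))
  }
  reps <- reps[!is.na(reps)]
  alpha <- 1 - level
  qs <- stats::quantile(reps, c(alpha / 2, 1 - alpha / 2), names = FALSE,
                        type = 6)
  out <- tibble::tibble(estimate = as_coef(est), se = stats::sd(reps),
                        lower = qs[1], upper = qs[2], level = level,
                        method = "bootstrap_percentile", clamped = FALSE)
  attr(out, "n_undefined") <- n_undef
  out
}
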
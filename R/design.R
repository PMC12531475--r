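# Sample-size planning for agreement studies: how many patients are needed,
# for a given number of observers, to estimate (or test) the mean pairwise
# proportion of agreement. Only two quantities are assumed known at the
# planning stage: the expected proportion of positive test results (common
# to all observers) and the target agreement level.

agree_values <- function(n_raters) {
  m <- 0:n_raters
  (m * (m - 1) + (n_raters - m) * (n_raters - m - 1)) /
    (n_raters * (n_raters - 1))
}

#' Planning variance of the proportion of agreement
#'
#' At the planning stage the estimator of the mean pairwise proportion of
#' agreement is the average over patients of the per-patient agreement
#' statistic `a_i` (the fraction of agreeing observer pairs), so its
#' variance for a study with `N` patients is `Var(a) / N`. `plan_variance()`
#' returns `Var(a)` for one patient under a chosen distribution of the
#' per-patient positive count, each matching the anticipated prevalence
#' `pi` and target pairwise agreement `po` (equivalently the implied
#' pairwise kappa `1 - (1 - po) / (2 pi (1 - pi))`):
#'
#' * `"worst_case"`: the distribution maximizing `Var(a)` subject to the
#'   matched agreement level (mass only on unanimous patients and on
#'   maximally split patients), giving `(1 - po)(po - a_min(R))`. A
#'   conservative, assumption-light choice for precision planning.
#' * `"latent_class"`: patients have a true status with prevalence adjusted
#'   to match `pi`, and observers misclassify it independently with a
#'   common error rate solved from `po` (`eps(1 - eps) = (1 - po)/2`).
#' * `"beta_binomial"`: the per-patient positive count is beta-binomial
#'   with mean `pi` and intraclass correlation equal to the implied kappa.
#'
#' For two observers every choice reduces to the binomial variance
#' `po (1 - po)`, and for three observers all three coincide (the
#' per-patient statistic takes only two values).
#'
#' @param n_raters Number of observers (`R >= 2`).
#' @param prevalence Anticipated proportion of positive test results,
#'   common to all observers.
#' @param agreement Target pairwise proportion of agreement.
#' @param dist Planning distribution (see above).
#' @return A list: `variance` (of `a` for one patient), `implied_kappa`,
#'   `dist` (tibble with columns `m`, `prob`, when a distribution is
#'   constructed), `n_raters`, `model`.
#' @examples
#' plan_variance(5, 0.35, 0.80, "worst_case")
#' @export
plan_variance <- function(n_raters, prevalence, agreement,
                          dist = c("worst_case", "latent_class",
                                   "beta_binomial")) {
  dist <- match.arg(dist)
  r <- n_raters
  stopifnot(r >= 2, r == round(r))
  if (prevalence <= 0 || prevalence >= 1) {
    abort("`prevalence` must lie strictly between 0 and 1.")
  }
  lower <- 1 - 2 * prevalence * (1 - prevalence)
  if (agreement <= lower || agreement > 1) {
    abort(paste0("target agreement must lie in (", signif(lower, 4), ", 1] ",
                 "for prevalence ", prevalence,
                 " (the implied kappa must be positive)."))
  }
  kap <- 1 - (1 - agreement) / (2 * prevalence * (1 - prevalence))
  a <- agree_values(r)
  m <- 0:r
  pm <- NULL
  if (dist == "worst_case") {
    amin <- min(a)
    s <- (agreement - amin) / (1 - amin)   # unanimous mass
    v <- (1 - agreement) * (agreement - amin)
    # explicit three-point distribution (for simulation), when prevalence
    # allows allocating the unanimous mass between m = 0 and m = R
    for (mid in unique(c(floor(r / 2), ceiling(r / 2)))) {
      pr <- (r * prevalence - mid * (1 - s)) / r
      if (pr >= -1e-12 && pr <= s + 1e-12) {
        pr <- min(max(pr, 0), s)
        pm <- numeric(r + 1)
        pm[1] <- s - pr
        pm[mid + 1] <- pm[mid + 1] + 1 - s
        pm[r + 1] <- pm[r + 1] + pr
        break
      }
    }
  } else if (dist == "latent_class") {
    eps <- (1 - sqrt(2 * agreement - 1)) / 2
    eta <- (prevalence - eps) / (1 - 2 * eps)
    if (is.nan(eta) || eta < 0 || eta > 1) {
      abort("prevalence incompatible with the latent-class construction at this agreement level.")
    }
    pm <- eta * dbinom(m, r, 1 - eps) + (1 - eta) * dbinom(m, r, eps)
    v <- sum(pm * a^2) - sum(pm * a)^2
  } else {
    if (kap >= 1) {
      v <- 0
      pm <- numeric(r + 1)
      pm[1] <- 1 - prevalence
      pm[r + 1] <- prevalence
    } else {
      theta <- 1 / kap - 1
      sh1 <- prevalence * theta
      sh2 <- (1 - prevalence) * theta
      pm <- choose(r, m) * beta(sh1 + m, sh2 + r - m) / beta(sh1, sh2)
      v <- sum(pm * a^2) - sum(pm * a)^2
    }
  }
  list(variance = v, implied_kappa = kap,
       dist = if (!is.null(pm)) tibble::tibble(m = m, prob = pm),
       n_raters = r, model = dist)
}

#' Minimum number of patients for a target confidence-interval width
#'
#' Finds, by integer search, the smallest `N` such that the anticipated
#' two-sided Wald interval for the mean pairwise proportion of agreement has
#' width `2 z(1 - alpha/2) sqrt(Var(a)/N)` at most `width`. The default
#' planning variance is the conservative `"worst_case"` bound of
#' [plan_variance()].
#'
#' @inheritParams plan_variance
#' @param width Maximal confidence-interval width (full width, e.g. 0.10
#'   for an interval like (0.75, 0.85)).
#' @param level Confidence level.
#' @return A one-row tibble: `n_raters`, `n`, `achieved_width`.
#' @examples
#' n_for_ci_width(5, prevalence = 0.35, agreement = 0.80, width = 0.10)
#' @export
n_for_ci_width <- function(n_raters, prevalence, agreement, width = 0.10,
                           level = 0.95,
                           dist = c("worst_case", "latent_class",
                                    "beta_binomial")) {
  if (width <= 0 || width >= 1) abort("`width` must lie in (0, 1).")
  pv <- plan_variance(n_raters, prevalence, agreement, dist)
  z <- qnorm(1 - (1 - level) / 2)
  wfun <- function(n) 2 * z * sqrt(pv$variance / n)
  n <- 4
  while (wfun(n) > width) n <- n + 1
  tibble::tibble(n_raters = n_raters, n = as.integer(n),
                 achieved_width = wfun(n))
}

#' Minimum number of patients to test an agreement hypothesis
#'
#' Sample size for the one-sided test of `H0: rho <= rho0` against
#' `H1: rho = rhoA > rho0` on the mean pairwise proportion of agreement:
#' the smallest `N` with
#' `pnorm((rhoA - rho0) / sqrt(Var_A(a)/N) - z(1 - alpha)) >= power`,
#' where `Var_A(a)` is the planning variance under the alternative. The
#' default planning distribution is the latent-class model, the natural
#' data-generating alternative.
#'
#' @inheritParams plan_variance
#' @param rho0,rhoA Agreement level under the null and the alternative.
#' @param alpha One-sided type-I error.
#' @param power Target power `1 - beta`.
#' @return A one-row tibble: `n_raters`, `n`, `achieved_power`.
#' @examples
#' n_for_power(5, prevalence = 0.35, rho0 = 0.80, rhoA = 0.85)
#' @export
n_for_power <- function(n_raters, prevalence, rho0, rhoA, alpha = 0.05,
                        power = 0.80,
                        dist = c("latent_class", "worst_case",
                                 "beta_binomial")) {
  if (rhoA <= rho0) abort("`rhoA` must exceed `rho0`.")
  stopifnot(alpha > 0, alpha < 1, power > 0, power < 1)
  pv <- plan_variance(n_raters, prevalence, rhoA, match.arg(dist))
  za <- qnorm(1 - alpha)
  pw <- function(n) pnorm((rhoA - rho0) * sqrt(n / pv$variance) - za)
  n <- 4
  while (pw(n) < power) n <- n + 1
  tibble::tibble(n_raters = n_raters, n = as.integer(n),
                 achieved_power = pw(n))
}

#' Sample-size table over a range of observer counts
#'
#' One row per number of observers, in either planning mode.
#'
#' @inheritParams plan_variance
#' @inheritParams n_for_ci_width
#' @inheritParams n_for_power
#' @param n_raters Integer vector of observer counts, e.g. `3:8`.
#' @param mode `"ci_width"` or `"power"`.
#' @param dist Planning distribution; defaults to `"worst_case"` for
#'   `mode = "ci_width"` and `"latent_class"` for `mode = "power"` (see
#'   [plan_variance()]).
#' @return A tibble of class `agree_design` with columns `n_raters`, `n`
#'   and the achieved width or power.
#' @examples
#' design_table(3:8, mode = "ci_width", prevalence = 0.35, agreement = 0.80)
#' @export
design_table <- function(n_raters = 3:8, mode = c("ci_width", "power"),
                         prevalence, agreement = NULL, width = 0.10,
                         level = 0.95, rho0 = NULL, rhoA = NULL,
                         alpha = 0.05, power = 0.80, dist = NULL) {
  mode <- match.arg(mode)
  rows <- purrr::map(n_raters, function(r) {
    if (mode == "ci_width") {
      if (is.null(agreement)) abort("ci_width mode needs `agreement`.")
      n_for_ci_width(r, prevalence, agreement, width, level,
                     dist = dist %||% "worst_case")
    } else {
      if (is.null(rho0) || is.null(rhoA)) {
        abort("power mode needs `rho0` and `rhoA`.")
      }
      n_for_power(r, prevalence, rho0, rhoA, alpha, power,
                  dist = dist %||% "latent_class")
    }
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("agree_design", class(out))
  attr(out, "mode") <- mode
  out
}

#' @export
autoplot.agree_design <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$n_raters, y = .data$n)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "number of observers", y = "minimum number of patients",
                  title = switch(attr(object, "mode"),
                                 ci_width = "Precision-based sample size",
                                 power = "Power-based sample size")) +
    ggplot2::theme_minimal()
}
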
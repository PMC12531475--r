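#' Agreement analysis for a pair table or a ratings object
#'
#' One-stop front-end: computes the requested agreement coefficients with
#' standard errors and confidence intervals, and returns a fitted object
#' with [tidy()], [glance()] and [ggplot2::autoplot()] methods.
#'
#' For a [pair_table()] the closed-form delta-method standard errors are
#' used; for a [ratings] object (two or more observers) the
#' influence-function standard errors of [se_multi()]. `ci = "bootstrap"`
#' resamples patients and requires a ratings object (expand a pair table
#' with [as_ratings()]) and a seed.
#'
#' @param x A [pair_table()], a [ratings] object, or a data frame accepted
#'   by [as_ratings()].
#' @param coefficients Character vector among `"po"`, `"ppos"`, `"pneg"`,
#'   `"jaccard"`, `"lambda"` (pair only), `"rogot_goldberg"` (pair only),
#'   `"kappa1"`, `"kappa2"`, `"kappa3"`, `"ac1"`, `"alpha"`, or `"all"`.
#' @param approach Generalization used for multi-observer specific
#'   agreement: `"pooled"` (default) or `"mean_of_pairs"` (no analytic
#'   standard error; combine with `ci = "bootstrap"` or `ci = "none"`).
#' @param ci `"wald"` (default), `"wald_cc"` (continuity-corrected, pairwise
#'   `po` only), `"bootstrap"`, `"fisher_z"` or `"none"`.
#' @param level Confidence level.
#' @param B,seed Bootstrap replicates and seed (see [bootstrap_ci()]).
#' @return An object of class `agree_fit`.
#' @examples
#' agreement(pair_table(6, 0, 3, 11))
#' agreement(ctg_fixture(), coefficients = c("po", "kappa2"))
#' @export
agreement <- function(x, coefficients = "all",
                      approach = c("pooled", "mean_of_pairs"),
                      ci = c("wald", "wald_cc", "bootstrap", "fisher_z",
                             "none"),
                      level = 0.95, B = 2000, seed = NULL) {
  approach <- match.arg(approach)
  ci <- match.arg(ci)
  is_pair <- inherits(x, "pair_table")
  all_coefs <- if (is_pair) {
    c("po", "kappa1", "kappa2", "kappa3", "ppos", "pneg", "jaccard",
      "lambda", "rogot_goldberg", "ac1", "alpha")
  } else {
    c("po", "kappa1", "kappa2", "kappa3", "ppos", "pneg", "jaccard",
      "ac1", "alpha")
  }
  coefficients <- if (identical(coefficients, "all")) all_coefs else {
    unknown <- setdiff(coefficients, all_coefs)
    if (length(unknown)) {
      abort(paste0("unknown or unavailable coefficient(s): ",
                   paste(unknown, collapse = ", ")))
    }
    coefficients
  }
  if (length(coefficients) == 0) abort("no coefficient selected.")
  rows <- purrr::map(coefficients, function(coef) {
    if (is_pair) agree_row_pair(x, coef, ci, level, B, seed)
    else agree_row_multi(x, coef, approach, ci, level, B, seed)
  })
  est <- dplyr::bind_rows(rows)
  out <- list(estimates = est, data = x, level = level, ci = ci,
              approach = approach)
  if (!is_pair) {
    xr <- as_ratings(x)
    out$n_patients <- dplyr::n_distinct(xr$patient)
    out$n_raters <- dplyr::n_distinct(xr$rater)
  } else {
    out$n_patients <- x$n
    out$n_raters <- 2L
  }
  structure(out, class = "agree_fit")
}

coef_bounds <- function(coef) {
  if (coef %in% c("kappa1", "kappa2", "kappa3", "ac1", "alpha", "lambda")) {
    c(-1, 1)
  } else {
    c(0, 1)
  }
}

pair_estimator <- function(coef) {
  switch(coef,
    po = po_pair, ppos = ppos_pair, pneg = pneg_pair, jaccard = jaccard_pair,
    lambda = lambda_index, rogot_goldberg = rogot_goldberg,
    kappa1 = function(t) kappa_pair(t, "uniform"),
    kappa2 = function(t) kappa_pair(t, "rater_marginals"),
    kappa3 = function(t) kappa_pair(t, "pooled_marginals"),
    ac1 = ac1_pair, alpha = kripp_alpha_pair)
}

pair_se <- function(t, coef) {
  switch(coef,
    po = se_po_pair(t),
    ppos = se_specific_pair(t, "pos"),
    pneg = se_specific_pair(t, "neg"),
    kappa1 = se_kappa_pair(t, "uniform"),
    kappa2 = se_kappa_pair(t, "rater_marginals"),
    kappa3 = se_kappa_pair(t, "pooled_marginals"),
    # remaining pair coefficients: smooth maps of the cells; jackknife
    jackknife_se(as_ratings(t), function(x) {
      w <- ratings_wide(x)
      pair_estimator(coef)(pair_table(
        sum(w[, 1] == 1 & w[, 2] == 1), sum(w[, 1] == 1 & w[, 2] == 0),
        sum(w[, 1] == 0 & w[, 2] == 1), sum(w[, 1] == 0 & w[, 2] == 0)))
    }))
}

agree_row_pair <- function(t, coef, ci, level, B, seed) {
  val <- pair_estimator(coef)(t)
  if (is_undefined(val)) {
    return(tibble::tibble(coefficient = coef, estimate = NA_real_,
                          se = NA_real_, lower = NA_real_, upper = NA_real_,
                          level = level, method = "undefined",
                          clamped = FALSE, note = undefined_reason(val)))
  }
  if (ci == "none") {
    return(tibble::tibble(coefficient = coef, estimate = as_coef(val),
                          se = NA_real_, lower = NA_real_, upper = NA_real_,
                          level = level, method = "point", clamped = FALSE,
                          note = NA_character_))
  }
  if (ci == "bootstrap") {
    row <- bootstrap_ci(as_ratings(t), function(x) {
      w <- ratings_wide(x)
      pair_estimator(coef)(pair_table(
        sum(w[, 1] == 1 & w[, 2] == 1), sum(w[, 1] == 1 & w[, 2] == 0),
        sum(w[, 1] == 0 & w[, 2] == 1), sum(w[, 1] == 0 & w[, 2] == 0)))
    }, B = B, seed = seed, level = level)
    return(dplyr::relocate(dplyr::mutate(row, coefficient = coef, note = NA_character_), "coefficient"))
  }
  if (ci == "wald_cc") {
    if (coef != "po") {
      abort("the continuity-corrected interval applies to the pairwise proportion of agreement only.")
    }
    row <- continuity_corrected_ci(t, level)
    return(dplyr::relocate(dplyr::mutate(row, coefficient = coef, note = NA_character_), "coefficient"))
  }
  se <- pair_se(t, coef)
  row <- if (ci == "fisher_z") fisher_z_ci(val, se, level)
  else wald_ci(val, se, level, coef_bounds(coef))
  dplyr::relocate(dplyr::mutate(row, coefficient = coef, note = NA_character_), "coefficient")
}

agree_row_multi <- function(x, coef, approach, ci, level, B, seed) {
  est_fun <- if (approach == "mean_of_pairs" &&
                 coef %in% c("ppos", "pneg", "jaccard")) {
    switch(coef,
      ppos = function(d) specific_multi(d, "pos", "mean_of_pairs"),
      pneg = function(d) specific_multi(d, "neg", "mean_of_pairs"),
      jaccard = function(d) jaccard_multi(d, "mean_of_pairs"))
  } else {
    multi_estimator(coef)
  }
  val <- tryCatch(est_fun(x), error = function(e) undefined_coef(conditionMessage(e)))
  if (is_undefined(val)) {
    return(tibble::tibble(coefficient = coef, estimate = NA_real_,
                          se = NA_real_, lower = NA_real_, upper = NA_real_,
                          level = level, method = "undefined",
                          clamped = FALSE, note = undefined_reason(val)))
  }
  if (ci == "none") {
    return(tibble::tibble(coefficient = coef, estimate = as_coef(val),
                          se = NA_real_, lower = NA_real_, upper = NA_real_,
                          level = level, method = "point", clamped = FALSE,
                          note = NA_character_))
  }
  if (ci == "bootstrap") {
    row <- bootstrap_ci(x, est_fun, B = B, seed = seed, level = level)
    return(dplyr::relocate(dplyr::mutate(row, coefficient = coef, note = NA_character_), "coefficient"))
  }
  if (ci == "wald_cc") {
    abort("the continuity-corrected interval applies to a pair table only.")
  }
  if (approach == "mean_of_pairs" && coef %in% c("ppos", "pneg", "jaccard")) {
    abort(paste0("no analytic standard error exists for mean-of-pairs ",
                 "specific agreement; use ci = \"bootstrap\" or ci = \"none\"."))
  }
  se <- se_multi(x, coef)
  row <- if (ci == "fisher_z") fisher_z_ci(val, se, level)
  else wald_ci(val, se, level, coef_bounds(coef))
  dplyr::relocate(dplyr::mutate(row, coefficient = coef, note = NA_character_), "coefficient")
}

#' @export
print.agree_fit <- function(x, digits = 2, ...) {
  cat("Agreement analysis: ", x$n_patients, " patients, ", x$n_raters,
      " raters\n", sep = "")
  if (x$ci != "none") {
    cat(100 * x$level, "% confidence intervals (", x$ci, ")\n", sep = "")
  }
  est <- x$estimates
  shown <- dplyr::mutate(est, dplyr::across(
    dplyr::all_of(c("estimate", "se", "lower", "upper")),
    ~ round(.x, digits)))
  print(shown, n = Inf)
  invisible(x)
}

#' Tidiers for agreement fits
#'
#' `tidy()` returns one row per coefficient (`coefficient`, `estimate`,
#' `se`, `lower`, `upper`, `level`, `method`, `clamped`, `note`); `glance()`
#' a one-row summary of the design.
#'
#' @param x An `agree_fit` from [agreement()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.agree_fit <- function(x, ...) {
  x$estimates
}

#' @rdname tidy.agree_fit
#' @export
glance.agree_fit <- function(x, ...) {
  po <- x$estimates$estimate[x$estimates$coefficient == "po"]
  tibble::tibble(n_patients = x$n_patients, n_raters = x$n_raters,
                 n_coefficients = nrow(x$estimates),
                 po = if (length(po)) po[1] else NA_real_,
                 level = x$level, ci = x$ci)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Plot an agreement fit
#'
#' Point estimates with confidence intervals, one row per coefficient.
#'
#' @param object An `agree_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.agree_fit <- function(object, ...) {
  d <- object$estimates
  d$coefficient <- factor(d$coefficient, levels = rev(d$coefficient))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate, y = .data$coefficient)) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$lower,
                                          xmax = .data$upper)) +
    ggplot2::labs(x = "estimate", y = NULL,
                  title = paste0("Agreement coefficients (",
                                 100 * object$level, "% CI)")) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
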
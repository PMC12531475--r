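# Simulators of binary rating matrices with known agreement structure.

beta_shapes <- function(prevalence, icc) {
  stopifnot(prevalence > 0, prevalence < 1, icc >= 0, icc <= 1)
  if (icc == 0 || icc == 1) return(NULL)  # handled analytically
  theta <- 1 / icc - 1
  c(prevalence * theta, (1 - prevalence) * theta)
}

draw_propensities <- function(n, prevalence, icc) {
  if (icc == 0) return(rep(prevalence, n))
  if (icc == 1) return(as.numeric(runif(n) < prevalence))
  sh <- beta_shapes(prevalence, icc)
  rbeta(n, sh[1], sh[2])
}

#' Simulate exchangeable binary ratings (common-correlation model)
#'
#' Each patient receives a latent success probability drawn from a beta
#' distribution with mean `prevalence` and intraclass correlation `icc`
#' (the degenerate endpoints `icc = 0` and `icc = 1` are handled exactly);
#' observers then rate conditionally independently. Under this model the
#' expected pairwise proportion of agreement is
#' `1 - 2 prevalence (1 - prevalence) (1 - icc)` and the intraclass kappa
#' estimates `icc`, which makes the generator the reference truth for
#' parameter-recovery and coverage studies.
#'
#' @param n_patients,n_raters Dimensions of the rating matrix.
#' @param prevalence Marginal probability of a positive rating.
#' @param icc Intraclass correlation in `[0, 1]`.
#' @param seed Integer seed (required: simulations must be reproducible).
#' @return A [ratings] object with a `sim_spec` attribute recording the
#'   generating parameters.
#' @examples
#' r <- simulate_ratings(50, 3, prevalence = 0.35, icc = 0.5, seed = 1)
#' kappa_multi(r, "def3")
#' @export
simulate_ratings <- function(n_patients, n_raters, prevalence, icc, seed) {
  if (missing(seed) || is.null(seed)) abort("`seed` is required.")
  stopifnot(n_patients >= 1, n_raters >= 1)
  m <- with_seed(seed, {
    p <- draw_propensities(n_patients, prevalence, icc)
    matrix(rbinom(n_patients * n_raters, 1, rep(p, n_raters)),
           n_patients, n_raters)
  })
  dimnames(m) <- list(sprintf("P%04d", seq_len(n_patients)),
                      sprintf("R%d", seq_len(n_raters)))
  out <- as_ratings(tibble::as_tibble(m, rownames = "patient"),
                    format = "wide")
  attr(out, "sim_spec") <- list(model = "common_correlation",
                                n_patients = n_patients, n_raters = n_raters,
                                prevalence = prevalence, icc = icc,
                                seed = seed)
  out
}

#' Simulate raters with different positive rates (rating-style shift)
#'
#' Latent-threshold construction for observers with systematically
#' different rating styles: each patient has a standard normal latent trait
#' shared with correlation `icc`, and observer `r` declares a positive when
#' their noisy copy exceeds their own cutpoint `qnorm(1 - marginals[r])`.
#' Equal cutpoints recover an exchangeable model (so the rater-marginals
#' and pooled-marginals kappas nearly coincide); heterogeneous marginals
#' open a gap between them, the situation the rater-marginals chance model
#' is designed for.
#'
#' @param n_patients Number of patients.
#' @param marginals Numeric vector of per-observer positive rates.
#' @param icc Correlation of the latent trait between observers.
#' @param seed Integer seed (required).
#' @return A [ratings] object with a `sim_spec` attribute.
#' @export
simulate_rater_shift <- function(n_patients, marginals, icc, seed) {
  if (missing(seed) || is.null(seed)) abort("`seed` is required.")
  stopifnot(all(marginals > 0), all(marginals < 1), icc >= 0, icc <= 1)
  r <- length(marginals)
  m <- with_seed(seed, {
    trait <- rnorm(n_patients)
    z <- sqrt(icc) * matrix(trait, n_patients, r) +
      sqrt(1 - icc) * matrix(rnorm(n_patients * r), n_patients, r)
    cut <- qnorm(1 - marginals)
    1L * sweep(z, 2, cut, `>`)
  })
  dimnames(m) <- list(sprintf("P%04d", seq_len(n_patients)),
                      names(marginals) %||% sprintf("R%d", seq_len(r)))
  out <- as_ratings(tibble::as_tibble(m, rownames = "patient"),
                    format = "wide")
  attr(out, "sim_spec") <- list(model = "rater_shift",
                                n_patients = n_patients, marginals = marginals,
                                icc = icc, seed = seed)
  out
}

#' Simulate replicate assessments by a single observer
#'
#' Intra-observer (repeatability) design: one observer assesses each
#' patient on several occasions under identical conditions. Replicates are
#' exchangeable within patient (interchangeable-ratings assumption), so
#' permuting occasion labels leaves every agreement coefficient's
#' distribution unchanged, and [select_occasion()] with either rule yields
#' equal-in-distribution inter-occasion statistics.
#'
#' @param n_patients Number of patients.
#' @param occasions Number of replicate assessments (`>= 2`).
#' @param prevalence Marginal probability of a positive rating.
#' @param icc Within-patient correlation of replicates (the repeatability).
#' @param seed Integer seed (required).
#' @return A [ratings] object with rater `"A"` and occasions
#'   `1:occasions`, and a `sim_spec` attribute.
#' @export
simulate_intra_rater <- function(n_patients, occasions, prevalence, icc,
                                 seed) {
  if (missing(seed) || is.null(seed)) abort("`seed` is required.")
  stopifnot(occasions >= 2)
  m <- with_seed(seed, {
    p <- draw_propensities(n_patients, prevalence, icc)
    matrix(rbinom(n_patients * occasions, 1, rep(p, occasions)),
           n_patients, occasions)
  })
  out <- tibble::tibble(
    patient = rep(sprintf("P%04d", seq_len(n_patients)), occasions),
    rater = "A",
    occasion = rep(seq_len(occasions), each = n_patients),
    rating = as.integer(m)
  )
  out <- new_ratings(out[order(out$patient, out$occasion), ])
  attr(out, "sim_spec") <- list(model = "intra_rater",
                                n_patients = n_patients,
                                occasions = occasions,
                                prevalence = prevalence, icc = icc,
                                seed = seed)
  out
}
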
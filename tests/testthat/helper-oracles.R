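# Independent oracles and small generators used across the test files.

# canonical coincidence-matrix Krippendorff alpha for a binary wide matrix
# (units in rows); written directly from the textbook definition, kept
# independent of the package's closed-form implementation
alpha_coincidence_oracle <- function(w) {
  m1 <- rowSums(w == 1, na.rm = TRUE)
  m2 <- rowSums(w == 0, na.rm = TRUE)
  mu <- m1 + m2
  keep <- mu >= 2
  m1 <- m1[keep]; m2 <- m2[keep]; mu <- mu[keep]
  o11 <- sum(m1 * (m1 - 1) / (mu - 1))
  o22 <- sum(m2 * (m2 - 1) / (mu - 1))
  o12 <- sum(m1 * m2 / (mu - 1))  # ordered (1,2); (2,1) identical
  ntot <- sum(mu)
  n1 <- o11 + o12
  n2 <- o22 + o12
  do <- (o12 + o12) / ntot
  de <- 2 * n1 * n2 / (ntot * (ntot - 1))
  1 - do / de
}

# mean over all explicit pair tables of a pairwise statistic (complete data)
mean_pairs_oracle <- function(x, pair_fun) {
  w <- agreebin:::ratings_wide(as_ratings(x))
  pairs <- combn(colnames(w), 2, simplify = FALSE)
  mean(vapply(pairs, function(p) {
    pair_fun(crosstab(x, p[1], p[2]))
  }, numeric(1)))
}

# brute-force recovery of n11 from (na, nb, po, n): enumerate and check
solve_n11_oracle <- function(na, nb, po, n) {
  hits <- integer(0)
  for (n11 in 0:min(na, nb)) {
    n22 <- n - na - nb + n11
    if (n22 < 0) next
    if (isTRUE(all.equal((n11 + n22) / n, po))) hits <- c(hits, n11)
  }
  stopifnot(length(hits) == 1L)
  hits
}

# random valid pair table with all cells possibly zero but N fixed
random_pair_table <- function(n = 50) {
  p <- as.numeric(rmultinom(1, n, prob = runif(4, 0.05, 1)))
  pair_table(p[1], p[2], p[3], p[4])
}

# random complete rating matrix as a ratings object
random_ratings <- function(n_patients, n_raters, prevalence = 0.4) {
  m <- matrix(rbinom(n_patients * n_raters, 1, prevalence),
              n_patients, n_raters,
              dimnames = list(sprintf("p%03d", 1:n_patients),
                              sprintf("R%d", 1:n_raters)))
  as_ratings(tibble::as_tibble(m, rownames = "patient"), format = "wide")
}

expect_coef_equal <- function(x, expected, tol = 1e-12) {
  expect_equal(as.numeric(x), expected, tolerance = tol)
}
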
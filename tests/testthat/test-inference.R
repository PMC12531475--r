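ac <- pair_table(6, 0, 3, 11)

test_that("pairwise delta-method intervals reproduce the published table", {
  po_row <- wald_ci(po_pair(ac), se_po_pair(ac))
  expect_equal(se_po_pair(ac), sqrt(0.85 * 0.15 / 20), tolerance = 1e-12)
  expect_equal(round(po_row$lower, 2), 0.69)
  expect_equal(po_row$upper, 1)           # clamped
  expect_true(po_row$clamped)

  k1 <- wald_ci(kappa_pair(ac, "def1"), se_kappa_pair(ac, "def1"),
                bounds = c(-1, 1))
  expect_equal(round(k1$lower, 2), 0.39)
  expect_equal(k1$upper, 1)

  k2 <- wald_ci(kappa_pair(ac, "def2"), se_kappa_pair(ac, "def2"),
                bounds = c(-1, 1))
  expect_equal(round(k2$lower, 2), 0.38)
  expect_equal(round(k2$upper, 2), 1.00)

  k3 <- wald_ci(kappa_pair(ac, "def3"), se_kappa_pair(ac, "def3"),
                bounds = c(-1, 1))
  expect_equal(round(k3$lower, 2), 0.35)

  pp <- wald_ci(ppos_pair(ac), se_specific_pair(ac, "pos"))
  expect_equal(round(pp$lower, 2), 0.58)
  pn <- wald_ci(pneg_pair(ac), se_specific_pair(ac, "neg"))
  expect_equal(round(pn$lower, 2), 0.75)
})

test_that("standard errors scale and degenerate correctly", {
  expect_equal(se_po_pair(pair_table(5, 0, 0, 15)), 0)
  expect_equal(se_po_pair(pair_table(0, 2, 3, 0)), 0)  # po = 0 boundary
  doubled <- pair_table(12, 0, 6, 22)
  expect_equal(se_po_pair(doubled), se_po_pair(ac) / sqrt(2),
               tolerance = 1e-12)
  # undefined coefficients propagate through their standard errors
  expect_true(is_undefined(se_kappa_pair(pair_table(4, 0, 0, 0), "def3")))
  expect_true(is_undefined(se_specific_pair(pair_table(0, 0, 0, 4), "pos")))
})

test_that("wald_ci clamps, degenerates and narrows with level", {
  r <- wald_ci(0.85, 0.0798)
  expect_equal(round(c(r$lower, r$upper), 2), c(0.69, 1.00))
  z <- wald_ci(0.5, 0)
  expect_equal(c(z$lower, z$upper), c(0.5, 0.5))
  narrow <- wald_ci(0.6, 0.1, level = 0.90)
  wide <- wald_ci(0.6, 0.1, level = 0.95)
  expect_lt(narrow$upper - narrow$lower, wide$upper - wide$lower)
})

test_that("continuity correction widens the po interval by 1/(2N)", {
  cc <- continuity_corrected_ci(ac)
  plain <- wald_ci(po_pair(ac), se_po_pair(ac))
  expect_equal(cc$lower, max(plain$estimate - qnorm(0.975) * plain$se -
                               1 / 40, 0), tolerance = 1e-12)
  expect_true(cc$lower <= plain$lower && cc$upper >= plain$upper)
  # negligible at large N
  big <- pair_table(400, 50, 50, 500)
  d <- wald_ci(po_pair(big), se_po_pair(big))$lower -
    continuity_corrected_ci(big)$lower
  expect_lt(abs(d), 1e-3 + 1 / 2000)
})

test_that("fisher-z intervals stay inside the open interval", {
  sym <- fisher_z_ci(0, 0.2)
  expect_equal(sym$lower, -sym$upper, tolerance = 1e-12)
  hi <- fisher_z_ci(0.95, 0.1)
  expect_lt(hi$upper, 1)
  expect_error(fisher_z_ci(1, 0.1), "< 1")
})

test_that("multi-observer influence intervals reproduce the published A-E row", {
  x <- ctg_fixture()
  tab4 <- list(po = c(0.63, 0.83), kappa1 = c(0.26, 0.66),
               kappa2 = c(0.22, 0.67), kappa3 = c(0.20, 0.67),
               ppos = c(0.47, 0.86), pneg = c(0.68, 0.87))
  for (coef in names(tab4)) {
    est <- agreebin:::multi_estimator(coef)(x)
    ci <- wald_ci(est, se_multi(x, coef), bounds = agreebin:::coef_bounds(coef))
    expect_lt(abs(ci$lower - tab4[[coef]][1]), 0.02)
    expect_lt(abs(ci$upper - tab4[[coef]][2]), 0.02)
  }
})

test_that("influence and jackknife standard errors agree", {
  x <- ctg_fixture()
  # linearization and delete-one jackknife differ by O(1/N); at N = 20 a
  # few percent is expected
  for (coef in c("po", "kappa2", "kappa3", "ppos", "ac1")) {
    expect_equal(se_multi(x, coef), se_multi(x, coef, "jackknife"),
                 tolerance = 0.06)
  }
  # homogeneous matrix: no sampling variability
  same <- as_ratings(tibble::tibble(patient = paste0("p", 1:6),
                                    A = rep(1:0, 3), B = rep(1:0, 3),
                                    C = rep(1:0, 3)))
  expect_equal(se_multi(same, "po"), 0)
})

test_that("bootstrap percentile intervals are seeded and sane", {
  x <- ctg_fixture()
  b1 <- bootstrap_ci(x, "po", B = 400, seed = 12)
  b2 <- bootstrap_ci(x, "po", B = 400, seed = 12)
  expect_identical(b1, b2)
  expect_error(bootstrap_ci(x, "po", B = 400), "seed")
  expect_error(bootstrap_ci(x, "po", B = 100, seed = 1), "B >= 200")
  # degenerate all-agree matrix: interval collapses at 1
  same <- as_ratings(tibble::tibble(patient = paste0("p", 1:8),
                                    A = rep(1:0, 4), B = rep(1:0, 4)))
  b <- bootstrap_ci(same, "po", B = 200, seed = 3)
  expect_equal(c(b$lower, b$upper), c(1, 1))
})

test_that("bootstrap agrees with the delta method on larger matrices", {
  set.seed(5)
  for (r in c(2, 5)) {
    x <- random_ratings(200, r)
    for (coef in c("po", "kappa3")) {
      bse <- bootstrap_ci(x, coef, B = 1000, seed = 99)$se
      dse <- se_multi(x, coef)
      expect_lt(abs(bse - dse) / dse, 0.15)
    }
  }
})

test_that("mean-of-pairs specific agreement refuses an analytic interval", {
  x <- ctg_fixture()
  expect_error(
    agreement(x, coefficients = "ppos", approach = "mean_of_pairs",
              ci = "wald"),
    "bootstrap")
  fit <- agreement(x, coefficients = "ppos", approach = "mean_of_pairs",
                   ci = "bootstrap", B = 200, seed = 2)
  expect_equal(tidy(fit)$estimate, 0.69, tolerance = 0.005)
})

test_that("wald coverage for Cohen's kappa near 0.5 is close to nominal", {
  # two raters, N = 100, true kappa2 = 0.5 under a common-correlation model
  pi <- 0.35; rho <- 0.5
  p11 <- pi^2 + rho * pi * (1 - pi)
  p12 <- pi * (1 - pi) * (1 - rho)
  p22 <- (1 - pi)^2 + rho * pi * (1 - pi)
  probs <- c(p11, p12, p12, p22)
  set.seed(2024)
  hits <- 0L; B <- 2000L
  for (b in seq_len(B)) {
    cells <- as.numeric(rmultinom(1, 100, probs))
    t <- pair_table(cells[1], cells[2], cells[3], cells[4])
    k <- kappa_pair(t, "def2")
    if (is_undefined(k)) next
    ci <- wald_ci(k, se_kappa_pair(t, "def2"), bounds = c(-1, 1))
    if (ci$lower <= rho && rho <= ci$upper) hits <- hits + 1L
  }
  expect_gte(hits / B, 0.92)
  expect_lte(hits / B, 0.97)
})

test_that("fisher-z improves on wald when agreement is extreme", {
  # high intraclass kappa, small sample: wald clips at 1, fisher-z does not
  pi <- 0.35; rho <- 0.9; n <- 30
  p11 <- pi^2 + rho * pi * (1 - pi)
  p12 <- pi * (1 - pi) * (1 - rho)
  p22 <- (1 - pi)^2 + rho * pi * (1 - pi)
  probs <- c(p11, p12, p12, p22)
  set.seed(31)
  hit_w <- 0L; hit_f <- 0L; used <- 0L
  for (b in 1:1000) {
    cells <- as.numeric(rmultinom(1, n, probs))
    t <- pair_table(cells[1], cells[2], cells[3], cells[4])
    k <- kappa_pair(t, "def3")
    if (is_undefined(k) || abs(k) >= 1) next
    se <- se_kappa_pair(t, "def3")
    used <- used + 1L
    w <- wald_ci(k, se, bounds = c(-1, 1))
    f <- fisher_z_ci(k, se)
    if (w$lower <= rho && rho <= w$upper) hit_w <- hit_w + 1L
    if (f$lower <= rho && rho <= f$upper) hit_f <- hit_f + 1L
  }
  # clamping makes the wald interval grossly overcover (~0.999 here); the
  # fisher-z interval stays inside (-1, 1) and lands far closer to nominal
  expect_lt(abs(hit_f / used - 0.95), abs(hit_w / used - 0.95))
})
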
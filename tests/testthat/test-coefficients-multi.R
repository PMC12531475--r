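ctg <- ctg_fixture()
ctg_ad <- agreebin:::new_ratings(dplyr::filter(tibble::as_tibble(ctg),
                                               rater != "E"))

test_that("multi-observer point estimates reproduce the worked example", {
  expect_equal(po_multi(ctg), 0.73)
  expect_equal(po_multi(ctg_ad), 53 / 60)                     # 0.88
  expect_equal(specific_multi(ctg, "pos"), 0.6625)            # 0.66
  expect_equal(jaccard_multi(ctg), 106 / 214)                 # 0.50
  expect_equal(round(specific_multi(ctg, "pos", "mean_of_pairs"), 2), 0.69)
  expect_equal(round(jaccard_multi(ctg, "mean_of_pairs"), 2), 0.56)
  expect_equal(specific_multi(ctg, "neg"), 0.775)             # 0.78
  expect_equal(specific_multi(ctg_ad, "pos"), 70 / 84)        # 0.83
  expect_equal(jaccard_multi(ctg_ad), 35 / 49)                # 0.71
  expect_equal(kappa_multi(ctg, "def1"), 0.46)
  expect_equal(kappa_multi(ctg, "def2"), 0.2165 / 0.4865)     # 0.45
  expect_equal(kappa_multi(ctg, "def3"), 0.21 / 0.48)         # 0.44
  expect_equal(kappa_multi(ctg_ad, "def1"), 2 * 53 / 60 - 1)  # 0.77
  # Conger's kappa for A-D is exactly 409/549 = 0.74499 (the published
  # table prints 0.75, a double-rounding artifact)
  expect_equal(kappa_multi(ctg_ad, "def2"), 409 / 549, tolerance = 1e-12)
  expect_equal(round(kappa_multi(ctg_ad, "def3"), 2), 0.74)
})

test_that("chance agreement formulas match their direct evaluation", {
  # rater marginals (0.30, 0.30, 0.45, 0.35, 0.60), overall prevalence 0.40
  expect_equal(chance_multi(ctg, "def2"), 0.5135)
  expect_equal(chance_multi(ctg, "def3"), 0.52)
  expect_equal(chance_multi(ctg, "def1"), 0.5)
  # equal per-rater marginals collapse definition 2 onto definition 3
  m <- matrix(c(1, 0, 1, 0, 1, 0, 1, 0, 0, 1, 1, 0), 4, 3)
  x <- as_ratings(tibble::as_tibble(`dimnames<-`(m,
         list(paste0("p", 1:4), c("A", "B", "C"))), rownames = "patient"))
  expect_equal(chance_multi(x, "def2"), chance_multi(x, "def3"),
               tolerance = 1e-12)
})

test_that("gwet's AC1 follows from observed agreement and chance disagreement", {
  qe <- 1 - chance_multi(ctg, "def3")
  expect_equal(gwet_ac1(ctg), (0.73 - qe) / (1 - qe))
  all_agree <- as_ratings(tibble::tibble(patient = c("a", "b"),
                                         A = c(1, 0), B = c(1, 0)))
  expect_equal(gwet_ac1(all_agree), 1)
})

test_that("all multi-observer formulas reduce to the pair case at R = 2", {
  set.seed(33)
  for (i in 1:20) {
    x <- random_ratings(25, 2)
    t <- crosstab(x, "R1", "R2")
    expect_equal(po_multi(x), po_pair(t), tolerance = 1e-12)
    for (ch in c("def1", "def2", "def3")) {
      expect_equal(chance_multi(x, ch), chance_agreement(t, ch),
                   tolerance = 1e-12)
      k <- kappa_pair(t, ch)
      if (!is_undefined(k)) {
        expect_equal(kappa_multi(x, ch), as.numeric(k), tolerance = 1e-12)
      }
    }
    pp <- ppos_pair(t)
    if (!is_undefined(pp)) {
      expect_equal(specific_multi(x, "pos"), as.numeric(pp),
                   tolerance = 1e-12)
      expect_equal(specific_multi(x, "pos", "mean_of_pairs"),
                   as.numeric(pp), tolerance = 1e-12)
    }
    a <- kripp_alpha_pair(t)
    if (!is_undefined(a)) {
      expect_equal(kripp_alpha(x), as.numeric(a), tolerance = 1e-12)
      expect_equal(gwet_ac1(x), as.numeric(ac1_pair(t)), tolerance = 1e-12)
    }
  }
})

test_that("sufficient-statistic formulas equal explicit pair enumeration", {
  set.seed(44)
  for (r in c(3, 5)) {
    for (i in 1:10) {
      x <- random_ratings(20, r)
      expect_equal(po_multi(x), mean_pairs_oracle(x, po_pair),
                   tolerance = 1e-12)
      # pooled specific agreement: ratio of mean numerator to mean denominator
      w <- agreebin:::ratings_wide(x)
      pairs <- combn(r, 2, simplify = FALSE)
      num <- mean(vapply(pairs, function(p) {
        mean(w[, p[1]] == 1 & w[, p[2]] == 1)
      }, numeric(1)))
      den <- mean(vapply(pairs, function(p) {
        (mean(w[, p[1]] == 1) + mean(w[, p[2]] == 1)) / 2
      }, numeric(1)))
      if (den > 0) {
        expect_equal(specific_multi(x, "pos"), num / den, tolerance = 1e-12)
      }
      # definition-2 chance: mean over pairs of the pairwise chance agreement
      expect_equal(chance_multi(x, "def2"),
                   mean_pairs_oracle(x, function(t) {
                     chance_agreement(t, "def2")
                   }), tolerance = 1e-12)
    }
  }
})

test_that("pooled Jaccard keeps its identity; mean-of-pairs need not", {
  set.seed(91)
  for (i in 1:20) {
    x <- random_ratings(15, 4)
    pp <- specific_multi(x, "pos")
    if (is_undefined(pp)) next
    expect_equal(jaccard_multi(x), pp / (2 - pp), tolerance = 1e-12)
  }
})

test_that("coefficients are invariant to rater and patient permutations", {
  set.seed(77)
  x <- random_ratings(18, 4)
  d <- tibble::as_tibble(x)
  perm <- agreebin:::new_ratings(d[sample(nrow(d)), ])
  relab <- dplyr::mutate(d, rater = c(R1 = "Z", R2 = "Y", R3 = "X",
                                      R4 = "W")[rater])
  relab <- agreebin:::new_ratings(relab)
  for (f in list(po_multi, function(z) kappa_multi(z, "def2"),
                 function(z) kappa_multi(z, "def3"), gwet_ac1, kripp_alpha,
                 function(z) specific_multi(z, "pos"))) {
    expect_equal(f(perm), f(x), tolerance = 1e-12)
    expect_equal(f(relab), f(x), tolerance = 1e-12)
  }
})

test_that("dropping the deviant rater E raises agreement across the board", {
  expect_gt(po_multi(ctg_ad), po_multi(ctg))
  expect_gt(specific_multi(ctg_ad, "pos"), specific_multi(ctg, "pos"))
  for (ch in c("def1", "def2", "def3")) {
    expect_gt(kappa_multi(ctg_ad, ch), kappa_multi(ctg, ch))
  }
})

test_that("multi-observer alpha matches the coincidence oracle with missing data", {
  set.seed(60)
  x <- random_ratings(30, 4)
  w <- agreebin:::ratings_wide(x)
  w[sample(length(w), 15)] <- NA
  x <- suppressWarnings(as_ratings(tibble::as_tibble(w, rownames = "patient")))
  expect_equal(kripp_alpha(x), alpha_coincidence_oracle(w), tolerance = 1e-12)
  # alpha stays within 0.02 of the pooled-marginals kappa on the fixture
  expect_lt(abs(kripp_alpha(ctg) - kappa_multi(ctg, "def3")), 0.02)
  # and the gap closes as the sample grows
  big <- simulate_ratings(4000, 4, prevalence = 0.4, icc = 0.5, seed = 8)
  expect_lt(abs(kripp_alpha(big) - kappa_multi(big, "def3")), 1e-3)
})

test_that("variable numbers of ratings per patient are handled", {
  df <- tibble::tibble(patient = c("a", "b", "c", "d"),
                       R1 = c(1, 0, 1, 0), R2 = c(1, 0, 0, NA),
                       R3 = c(NA, 0, 1, 1))
  x <- suppressWarnings(as_ratings(df))
  cc <- category_counts(x)
  expect_equal(sort(cc$n_rated), c(2, 2, 3, 3))
  man <- mean(c(1, 1, (2 * 1 + 0) / 6, 0))  # per-patient agreement fractions
  expect_equal(po_multi(x), man)
  # definition 2 needs a complete matrix
  expect_error(chance_multi(x, "def2"), "complete")
  expect_error(kappa_multi(x, "def2"), "complete")
  # definition 3 pools prevalence over ratings
  p1 <- sum(cc$m_pos) / sum(cc$n_rated)
  expect_equal(chance_multi(x, "def3"),
               mean((cc$m_pos * p1 + cc$m_neg * (1 - p1)) / cc$n_rated))
  # patients with a single rating abort the analysis with their names
  one <- tibble::tibble(patient = c("a", "b"), R1 = c(1, 1), R2 = c(0, NA))
  expect_error(po_multi(suppressWarnings(as_ratings(one))), "b")
})
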
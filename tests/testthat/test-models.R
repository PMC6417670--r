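test_that("pooled_theta is the pooled frequency and rejects degenerate nulls", {
  expect_equal(pooled_theta(10, 2000), 0.005)
  expect_equal(pooled_theta(c(10, 3), c(2000, 30)), c(0.005, 0.1))
  expect_error(pooled_theta(0, 100), class = "diffclone_degenerate_error")
  expect_error(pooled_theta(100, 100), class = "diffclone_degenerate_error")
})

test_that("beta shapes follow the mean/concentration reparameterisation", {
  expect_equal(unlist(beta_shape_from_moments(0.2, 10)), c(beta1 = 2, beta2 = 8))
  expect_equal(unlist(beta_shape_from_moments(0.001, 100)),
               c(beta1 = 0.1, beta2 = 99.9))
  expect_equal(unlist(beta_shape_from_moments(0.5, 2)), c(beta1 = 1, beta2 = 1))
  # flooring keeps shapes positive
  expect_equal(beta_shape_from_moments(1e-9, 1e-3)$beta1, 1e-8)
  expect_error(beta_shape_from_moments(0.5, 0),
               class = "diffclone_calibration_error")
  expect_error(beta_shape_from_moments(1.2, 5), class = "diffclone_domain_error")
})

test_that("beta-binomial mass is exact for the uniform prior and empty support", {
  for (n in c(1, 10, 117)) {
    expect_equal(betabinomial_logpmf(0:n, n, 1, 1), rep(log(1 / (n + 1)), n + 1),
                 tolerance = 1e-12)
  }
  expect_equal(betabinomial_logpmf(0, 0, 2.5, 7), 0)
  expect_error(betabinomial_logpmf(11, 10, 1, 1), class = "diffclone_domain_error")
})

test_that("beta-binomial mass normalises and matches quadrature", {
  for (shape_pair in list(c(1e-3, 1), c(0.5, 2), c(1, 1), c(40, 2.5),
                          c(1e3, 1e4), c(1e6, 1e6))) {
    lp <- betabinomial_logpmf(0:400, 400, shape_pair[[1]], shape_pair[[2]])
    expect_lt(abs(sum(exp(lp)) - 1), 1e-9)
  }
  expect_equal(exp(betabinomial_logpmf(7, 50, 2.5, 40)),
               oracle_bb_pmf_quadrature(7, 50, 2.5, 40), tolerance = 1e-6)
  # and against the recurrence-built mass across the support
  pm <- oracle_bb_pmf(60, 0.3, 17)
  expect_equal(exp(betabinomial_logpmf(0:60, 60, 0.3, 17)), pm,
               tolerance = 1e-10)
})

test_that("binomial p-values equal direct pmf summation on small supports", {
  for (n in c(10, 50, 200)) {
    cases <- expand.grid(k_a = c(0, 1, floor(n / 10), floor(n / 3)),
                         k_b = c(0, 2, floor(n / 8), floor(n / 2)))
    cases <- cases[cases$k_a + cases$k_b >= 1, ]
    for (alt in c("two_sided", "expansion_in_B", "contraction_in_B")) {
      got <- binomial_pvalue(cases$k_a, cases$k_b, n, n, alternative = alt)
      want <- mapply(oracle_binom_pvalue, cases$k_a, cases$k_b, n, n,
                     MoreArgs = list(alternative = alt))
      expect_equal(got, unname(want), tolerance = 1e-12)
      expect_true(all(got >= 0 & got <= 1))
    }
  }
  # unequal depths as well
  got <- binomial_pvalue(3, 17, 150, 900)
  expect_equal(got, oracle_binom_pvalue(3, 17, 150, 900), tolerance = 1e-12)
})

test_that("beta-binomial p-values equal direct summation under every rule", {
  dm <- dispersion_model(a = 1, b = 0.5)
  for (n in c(20, 80, 200)) {
    cases <- expand.grid(k_a = c(0, 1, floor(n / 6)), k_b = c(0, 3, floor(n / 4)))
    cases <- cases[cases$k_a + cases$k_b >= 1, ]
    for (i in seq_len(nrow(cases))) {
      k_a <- cases$k_a[[i]]; k_b <- cases$k_b[[i]]
      v <- predict_variance(dm, k_a + k_b)
      for (alt in c("two_sided", "expansion_in_B", "contraction_in_B")) {
        expect_equal(
          betabinomial_pvalue(k_a, k_b, n, n, dm, alternative = alt),
          oracle_bb_pvalue(k_a, k_b, n, n, v, alternative = alt),
          tolerance = 1e-9)
      }
      expect_equal(
        betabinomial_pvalue(k_a, k_b, n, n, dm, two_sided_rule = "min_likelihood"),
        oracle_bb_pvalue(k_a, k_b, n, n, v, two_sided_rule = "min_likelihood"),
        tolerance = 1e-9)
      expect_equal(
        betabinomial_pvalue(k_a, k_b, n, n, dm, alternative = "expansion_in_B",
                            statistic = "B"),
        oracle_bb_pvalue(k_a, k_b, n, n, v, alternative = "expansion_in_B",
                         statistic = "B"),
        tolerance = 1e-9)
    }
  }
})

test_that("large-support shortcuts agree with full enumeration", {
  dm <- dispersion_model(a = 1, b = 0.5)
  n <- 1e5
  v <- predict_variance(dm, 32)
  # min-likelihood rule via unimodal interval search vs whole-support sum
  expect_equal(
    betabinomial_pvalue(2, 30, n, n, dm, two_sided_rule = "min_likelihood"),
    oracle_bb_pvalue(2, 30, n, n, v, two_sided_rule = "min_likelihood"),
    tolerance = 1e-10)
  expect_equal(
    betabinomial_pvalue(2, 30, n, n, dm),
    oracle_bb_pvalue(2, 30, n, n, v),
    tolerance = 1e-10)
  # binomial binary-search boundaries vs whole-support sum
  expect_equal(binomial_pvalue(2, 30, n, n),
               oracle_binom_pvalue(2, 30, n, n), tolerance = 1e-12)
  expect_equal(binomial_pvalue(400, 60, n, n),
               oracle_binom_pvalue(400, 60, n, n), tolerance = 1e-12)
})

test_that("one-sided tails are complementary and monotone in k_A", {
  dm <- dispersion_model(a = 2, b = 1)
  n <- 5000
  for (k_total in c(6, 40, 200)) {
    k_as <- 0:k_total
    exp_p <- betabinomial_pvalue(k_as, k_total - k_as, n, n, dm,
                                 alternative = "expansion_in_B")
    con_p <- betabinomial_pvalue(k_as, k_total - k_as, n, n, dm,
                                 alternative = "contraction_in_B")
    mu <- k_total / (2 * n)
    v <- predict_variance(dm, k_total)
    pm <- exp(betabinomial_logpmf(k_as, n, mu * v, (1 - mu) * v))
    expect_equal(exp_p + con_p, 1 + pm, tolerance = 1e-12)
    expect_true(all(diff(exp_p) >= -1e-12))

    bin_exp <- binomial_pvalue(k_as, k_total - k_as, n, n,
                               alternative = "expansion_in_B")
    expect_true(all(diff(bin_exp) >= -1e-12))
  }
})

test_that("the beta-binomial approaches the binomial at high concentration", {
  huge <- dispersion_model(a = 1e4, b = 0)   # v = 1e8 for every k_total
  n <- 2000
  k_a <- 12; k_b <- 40
  theta <- (k_a + k_b) / (2 * n)
  # pointwise mass convergence
  lp <- betabinomial_logpmf(0:n, n, theta * 1e8, (1 - theta) * 1e8)
  expect_lt(max(abs(exp(lp) - dbinom(0:n, n, theta))), 1e-6)
  # the expansion tail converges to the binomial lower tail on sample A
  expect_equal(
    betabinomial_pvalue(k_a, k_b, n, n, huge, alternative = "expansion_in_B"),
    pbinom(k_a, n, theta), tolerance = 1e-4)
})

test_that("degenerate and invalid inputs are rejected", {
  dm <- dispersion_model(a = 1, b = 1)
  expect_error(binomial_pvalue(0, 0, 100, 100),
               class = "diffclone_degenerate_error")
  expect_error(betabinomial_pvalue(0, 0, 100, 100, dm),
               class = "diffclone_degenerate_error")
  expect_error(betabinomial_pvalue(1, 1, 100, 100, list(a = 1, b = 1)),
               class = "diffclone_state_error")
  # k_A = 0 one-sided expansion is the single mass term at zero
  v <- predict_variance(dm, 5)
  mu <- 5 / 200
  expect_equal(betabinomial_pvalue(0, 5, 100, 100, dm,
                                   alternative = "expansion_in_B"),
               exp(betabinomial_logpmf(0, 100, mu * v, (1 - mu) * v)),
               tolerance = 1e-12)
})
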
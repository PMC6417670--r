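test_that("Zipf profiles are normalised power laws", {
  p <- simulate_repertoire(2, zipf_exponent = 1)
  expect_equal(p$frequency, c(2 / 3, 1 / 3))
  for (args in list(c(100, 0.8), c(5000, 1.2), c(10, 3))) {
    prof <- simulate_repertoire(args[[1]], args[[2]])
    expect_lt(abs(sum(prof$frequency) - 1), 1e-12)
    expect_true(all(prof$frequency > 0))
  }
  prof <- simulate_repertoire(1e4, 1.2)
  expect_equal(prof$frequency[[1]], 1 / sum(seq_len(1e4)^(-1.2)))
})

test_that("calibration panels are valid profiles", {
  panel <- simulate_calibration_panel(n_clones = 1000, freq_min = 1e-5,
                                      freq_max = 1e-4)
  expect_lt(abs(sum(panel$frequency) - 1), 1e-12)
  expect_equal(nrow(panel), 1001L)
  expect_error(simulate_calibration_panel(n_clones = 1e5, freq_min = 1e-4,
                                          freq_max = 1e-3),
               class = "diffclone_parameter_error")
})

test_that("multinomial draws have the right totals, moments and determinism", {
  single <- structure(tibble::tibble(rearrangement = "only", frequency = 1),
                      class = c("repertoire_profile", class(tibble::tibble())))
  s <- draw_sample(single, 500, seed = 1)
  expect_equal(s$templates, 500L)

  prof <- simulate_repertoire(50, 1.0)
  s1 <- draw_sample(prof, 2e4, seed = 7)
  s2 <- draw_sample(prof, 2e4, seed = 7)
  s3 <- draw_sample(prof, 2e4, seed = 8)
  expect_identical(s1$templates, s2$templates)
  expect_false(identical(s1$templates, s3$templates))
  expect_equal(total_templates(s1), 2e4)

  # empirical mean of a clone's count matches its binomial expectation
  withr::with_seed(12, {
    target <- prof$rearrangement[[30]]
    f <- prof$frequency[[30]]
    n <- 1e4
    counts <- vapply(1:300, function(i) {
      s <- draw_sample(prof, n)
      k <- s$templates[s$rearrangement == target]
      if (length(k) == 0L) 0L else k
    }, integer(1))
    se <- sqrt(n * f * (1 - f) / 300)
    expect_lt(abs(mean(counts) - n * f), 3 * se)
  })
})

test_that("frequency perturbation is mean-preserving, normalised and seeded", {
  prof <- simulate_repertoire(500, 1.1)
  # near-zero target dispersion: output equals input almost exactly
  still <- perturb_frequencies(prof, 1e-6, 0, 2e5, seed = 3)
  expect_lt(max(abs(still$frequency - prof$frequency) / prof$frequency), 1e-3)

  moved <- perturb_frequencies(prof, 2, 1, 2e5, seed = 3)
  expect_lt(abs(sum(moved$frequency) - 1), 1e-12)
  again <- perturb_frequencies(prof, 2, 1, 2e5, seed = 3)
  expect_identical(moved$frequency, again$frequency)
  # repeated perturbation keeps the simplex constraint
  twice <- perturb_frequencies(moved, 2, 1, 2e5, seed = 4)
  expect_lt(abs(sum(twice$frequency) - 1), 1e-12)
})

test_that("the injected drift reproduces the target residual-variance curve", {
  # one clone, many replicate pairs: the measured mean squared count
  # difference minus the sampling part recovers the target dispersion
  withr::with_seed(31, {
    f <- 2e-4; n <- 1e6; a0 <- 2; b0 <- 1
    prof <- structure(tibble::tibble(rearrangement = c("x", "rest"),
                                     frequency = c(f, 1 - f)),
                      class = c("repertoire_profile", class(tibble::tibble())))
    reps <- 4000
    d <- vapply(seq_len(reps), function(i) {
      fa <- perturb_frequencies(prof, a0, b0, 2 * n, share = 0.5)$frequency[[1]]
      fb <- perturb_frequencies(prof, a0, b0, 2 * n, share = 0.5)$frequency[[1]]
      rbinom(1, n, fa) - rbinom(1, n, fb)
    }, numeric(1))
    target <- (b0 * log(f * 2 * n) + a0)^2
    resid <- mean(d^2) - 2 * n * f * (1 - f)
    # MC standard error of mean(d^2) is ~ sqrt(2/reps) * E[d^2]
    expect_lt(abs(resid - target), 4 * sqrt(2 / reps) * (2 * n * f + target))
  })
})

test_that("profile mixtures interpolate frequencies over the clone union", {
  p <- simulate_repertoire(100, 1.2, prefix = "dnrA")
  q <- simulate_repertoire(150, 1.2, prefix = "dnrB")
  expect_equal(mix_profiles(p, q, 1)$frequency[match(p$rearrangement,
               mix_profiles(p, q, 1)$rearrangement)], p$frequency)
  m0 <- mix_profiles(p, q, 0)
  expect_equal(nrow(m0), 150L)
  m <- mix_profiles(p, q, 0.05)
  expect_lt(abs(sum(m$frequency) - 1), 1e-12)
  # a clone private to p carries ratio * its frequency
  expect_equal(m$frequency[m$rearrangement == "dnrA000001"],
               0.05 * p$frequency[[1]])
  # fold change across two mixtures is the ratio of mixing proportions
  m2 <- mix_profiles(p, q, 0.5)
  expect_equal(m2$frequency[m2$rearrangement == "dnrA000001"] /
                 m$frequency[m$rearrangement == "dnrA000001"], 10)
})

test_that("estimate_fpr is reproducible and rejects empty tested sets", {
  prof <- simulate_repertoire(400, 1.1)
  f1 <- estimate_fpr(prof, 5000, diffab_config(), 3, seed = 17)
  f2 <- estimate_fpr(prof, 5000, diffab_config(), 3, seed = 17)
  expect_equal(f1$fpr, f2$fpr)
  expect_equal(f1$n_tested, f2$n_tested)
  tiny <- simulate_repertoire(10, 1.0)
  expect_error(estimate_fpr(tiny, 2, diffab_config(), 1, seed = 1),
               class = "diffclone_undefined_fpr_error")
})

test_that("paired cohorts are reproducible and carry the join invariants", {
  panel <- simulate_calibration_panel(n_clones = 500, freq_max = 5e-5)
  pairs <- simulate_paired_cohort(panel, 3, 5e4, drift = list(a = 2, b = 1),
                                  seed = 23)
  pairs2 <- simulate_paired_cohort(panel, 3, 5e4, drift = list(a = 2, b = 1),
                                   seed = 23)
  expect_identical(pairs[[2]]$k_A, pairs2[[2]]$k_A)
  for (p in pairs) {
    expect_equal(sum(p$k_A), p$n_A[[1]])
    expect_equal(sum(p$k_B), p$n_B[[1]])
  }
})
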
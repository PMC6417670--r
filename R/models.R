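# Exact tests of clone-frequency change between two samples.
#
# Null model: a clone has one frequency theta in both samples, estimated by
# pooling, theta = (k_A + k_B) / (n_A + n_B). The binomial test asks whether
# the count in sample B is within pure sampling variance of Binomial(n_B,
# theta); the beta-binomial test widens the null by placing a beta prior on
# theta with mean mu = theta and concentration v supplied per clone by a
# calibrated dispersion model, so normal time-dependent biological drift is
# absorbed into the null.

# relative tie tolerance for the minimum-likelihood two-sided rule, the
# same convention stats::fisher.test uses
TWO_SIDED_REL_TOL <- 1e-7

#' Pooled null frequency of a clone
#'
#' The common frequency under the null hypothesis that a clone has the same
#' frequency in both samples: `theta = (k_A + k_B) / (n_A + n_B)`.
#'
#' @param k_total Pooled clone count `k_A + k_B` (vectorised).
#' @param n_total Pooled sample total `n_A + n_B`.
#' @return Numeric vector of pooled frequencies, each in (0, 1).
#' @export
pooled_theta <- function(k_total, n_total) {
  if (!is_count(k_total) || !is_count(n_total)) {
    stop_domain("k_total and n_total must be non-negative integers",
                "diffclone_domain_error")
  }
  if (any(k_total < 1) || any(k_total >= n_total)) {
    stop_domain(
      "degenerate null: need 1 <= k_total < n_total (filter untestable clones first)",
      "diffclone_degenerate_error")
  }
  k_total / n_total
}

#' Beta shape parameters from mean and concentration
#'
#' Reparameterises the beta prior on clone frequency by its mean `mu` and
#' the calibrated dispersion quantity `v`: `beta1 = mu * v`,
#' `beta2 = (1 - mu) * v`. Shapes are floored at `epsilon` because the
#' calibrated `v(k) = (b log k + a)^2` can be arbitrarily small near its
#' root.
#'
#' @param mu Mean frequency in (0, 1) (vectorised).
#' @param v Positive dispersion value(s); larger `v` means a tighter prior.
#' @param epsilon Floor applied to each shape (default `1e-8`).
#' @return A tibble with columns `beta1`, `beta2`.
#' @export
beta_shape_from_moments <- function(mu, v, epsilon = 1e-8) {
  if (any(!is.finite(mu)) || any(mu <= 0) || any(mu >= 1)) {
    stop_domain("mu must lie strictly in (0, 1)", "diffclone_domain_error")
  }
  if (any(!is.finite(v)) || any(v <= 0)) {
    stop_domain("dispersion v must be positive", "diffclone_calibration_error")
  }
  tibble::tibble(beta1 = pmax(mu * v, epsilon),
                 beta2 = pmax((1 - mu) * v, epsilon))
}

#' Beta-binomial log probability mass
#'
#' `log P(K = k)` for the beta-binomial distribution on `0..n` with beta
#' shapes `(beta1, beta2)`: the binomial likelihood marginalised over a
#' `Beta(beta1, beta2)` prior on the success probability, computed through
#' log-gamma so it is stable for shapes spanning many orders of magnitude.
#'
#' @param k Count(s), `0 <= k <= n`.
#' @param n Number of trials (support size).
#' @param beta1,beta2 Positive beta shape parameters.
#' @return Log-probabilities, same length as `k`.
#' @export
betabinomial_logpmf <- function(k, n, beta1, beta2) {
  if (any(k < 0) || any(k > n) || any(k != floor(k))) {
    stop_domain("k must be an integer in [0, n]", "diffclone_domain_error")
  }
  if (any(beta1 <= 0) || any(beta2 <= 0)) {
    stop_domain("beta shapes must be positive", "diffclone_domain_error")
  }
  lchoose(n, k) + lbeta(k + beta1, n - k + beta2) - lbeta(beta1, beta2)
}

#' Exact binomial p-value for clone frequency change
#'
#' Tests the count in sample B against `Binomial(n_B, theta)` with `theta`
#' pooled across both samples. One-sided alternatives are exact tail sums;
#' the two-sided p-value uses the minimum-likelihood rule (total mass of
#' all outcomes no more probable than the observed one, the convention that
#' makes this test agree with the two-sided Fisher exact test).
#'
#' All arguments are vectorised over clones.
#'
#' @param k_a,k_b Clone template counts in samples A and B.
#' @param n_a,n_b Total template counts of samples A and B.
#' @param alternative `"two_sided"` (default), `"expansion_in_B"`
#'   (`P(K >= k_B)`), or `"contraction_in_B"` (`P(K <= k_B)`).
#' @return Numeric vector of p-values in `[0, 1]`.
#' @export
binomial_pvalue <- function(k_a, k_b, n_a, n_b,
                            alternative = c("two_sided", "expansion_in_B",
                                            "contraction_in_B")) {
  alternative <- match.arg(alternative)
  theta <- pooled_theta(k_a + k_b, n_a + n_b)
  m <- max(length(k_a), length(k_b), length(n_a), length(n_b))
  k_b <- rep_len(k_b, m); n_b <- rep_len(n_b, m); theta <- rep_len(theta, m)
  switch(alternative,
    expansion_in_B   = pbinom(k_b - 1, n_b, theta, lower.tail = FALSE),
    contraction_in_B = pbinom(k_b, n_b, theta),
    two_sided        = binom_two_sided(k_b, n_b, theta)
  )
}

# vectorised minimum-likelihood two-sided binomial p-value.
# The binomial pmf is unimodal, so the acceptance set {k : pmf(k) <=
# pmf(obs)(1 + tol)} is a left tail [0, a] plus a right tail [b, n]; both
# boundaries are located by vectorised binary search on the monotone flanks
# and the tails evaluated with pbinom, keeping the cost O(log n) per clone.
binom_two_sided <- function(kobs, n, theta) {
  m <- length(kobs)
  lthr <- dbinom(kobs, n, theta, log = TRUE) + log1p(TWO_SIDED_REL_TOL)
  mode <- pmin(floor((n + 1) * theta), n)
  lp <- function(k) {
    out <- rep(-Inf, length(k))
    ok <- k >= 0 & k <= n
    out[ok] <- dbinom(k[ok], n[ok], theta[ok], log = TRUE)
    out
  }
  all_accept <- lp(mode) <= lthr
  # left boundary a = max{k <= mode : lpmf(k) <= lthr}, -1 if none
  lo <- rep(-1, m); hi <- mode
  while (any(hi - lo > 1)) {
    mid <- (lo + hi) %/% 2
    take <- hi - lo > 1
    ok <- lp(mid) <= lthr
    lo <- ifelse(take & ok, mid, lo)
    hi <- ifelse(take & !ok, mid, hi)
  }
  a <- lo
  # right boundary b = min{k >= mode : lpmf(k) <= lthr}, n + 1 if none
  lo <- mode; hi <- n + 1
  while (any(hi - lo > 1)) {
    mid <- (lo + hi) %/% 2
    take <- hi - lo > 1
    ok <- lp(mid) <= lthr
    hi <- ifelse(take & ok, mid, hi)
    lo <- ifelse(take & !ok, mid, lo)
  }
  b <- hi
  p <- pbinom(a, n, theta) + pbinom(b - 1, n, theta, lower.tail = FALSE)
  p[all_accept] <- 1
  pmin(p, 1)
}

#' Exact beta-binomial p-value for clone frequency change
#'
#' The overdispersed analogue of [binomial_pvalue()]. For each clone the
#' pooled frequency `mu = k_total / n_total` and the calibrated dispersion
#' `v = predict_variance(dispersion, k_total)` define beta shapes
#' `(mu v, (1 - mu) v)`; the test statistic is by default the count in
#' sample A on support `n_A`, so expansion in B corresponds to the lower
#' tail `sum_{k = 0}^{k_A} P(K = k)` of the beta-binomial mass. Tail sums
#' are accumulated from log-space mass terms; for large supports the
#' two-sided rule exploits unimodality of the mass function rather than
#' enumerating the whole support.
#'
#' Two different two-sided rules are provided. The default, `"depletion"`,
#' doubles the smaller of the two one-sided depletion probabilities
#' `P(K_A <= k_A)` on support `n_A` and `P(K_B <= k_B)` on support `n_B`
#' (capped at 1); it is exactly symmetric in the two samples, and under a
#' strongly overdispersed calibrated prior it only ever rejects when one
#' sample's count is *improbably low* given the pooled frequency — the
#' well-behaved tail of a mass-near-zero beta-binomial. The alternative
#' `"min_likelihood"` rule (sum of all point masses no more probable than
#' the observed count, the Fisher-style convention used for the binomial
#' test) is available but degenerates when the beta shape `mu * v` falls
#' below 1: the mass function is then monotone decreasing, the rule
#' collapses to the upper tail `P(K >= k_obs)`, and perfectly ordinary
#' small-count observations (a clone seen a handful of times in A and
#' absent from B) are assigned tiny p-values, defeating the conservatism
#' the overdispersed null exists to provide.
#'
#' @inheritParams binomial_pvalue
#' @param dispersion A fitted [dispersion_model()] supplying `v(k_total)`.
#' @param statistic Which sample's count is the one-sided test statistic:
#'   `"A"` (default, support `n_A`) or `"B"` (support `n_B`, tail
#'   directions mirrored so `"expansion_in_B"` keeps its meaning).
#' @param two_sided_rule `"depletion"` (default) or `"min_likelihood"`,
#'   see Details.
#' @param epsilon Floor for the beta shapes (default `1e-8`).
#' @return Numeric vector of p-values in `[0, 1]`.
#' @export
betabinomial_pvalue <- function(k_a, k_b, n_a, n_b, dispersion,
                                alternative = c("two_sided", "expansion_in_B",
                                                "contraction_in_B"),
                                statistic = c("A", "B"),
                                two_sided_rule = c("depletion", "min_likelihood"),
                                epsilon = 1e-8) {
  alternative <- match.arg(alternative)
  statistic <- match.arg(statistic)
  two_sided_rule <- match.arg(two_sided_rule)
  check_fitted(dispersion)
  k_total <- k_a + k_b
  theta <- pooled_theta(k_total, n_a + n_b)
  v <- predict_variance(dispersion, k_total)
  shapes <- beta_shape_from_moments(theta, v, epsilon = epsilon)

  m <- max(length(k_a), length(k_b), length(n_a), length(n_b))
  k_a <- rep_len(k_a, m); k_b <- rep_len(k_b, m)
  n_a <- rep_len(n_a, m); n_b <- rep_len(n_b, m)

  if (statistic == "A") {
    obs <- k_a; size <- n_a
    lower_is_expansion <- TRUE
  } else {
    obs <- k_b; size <- n_b
    lower_is_expansion <- FALSE
  }

  vapply(seq_len(m), function(i) {
    b1 <- shapes$beta1[[i]]; b2 <- shapes$beta2[[i]]
    switch(alternative,
      two_sided = if (two_sided_rule == "depletion") {
        min(1, 2 * min(bb_lower_tail(k_a[[i]], n_a[[i]], b1, b2),
                       bb_lower_tail(k_b[[i]], n_b[[i]], b1, b2)))
      } else {
        bb_two_sided(obs[[i]], size[[i]], b1, b2)
      },
      expansion_in_B = if (lower_is_expansion) {
        bb_lower_tail(obs[[i]], size[[i]], b1, b2)
      } else {
        bb_upper_tail(obs[[i]], size[[i]], b1, b2)
      },
      contraction_in_B = if (lower_is_expansion) {
        bb_upper_tail(obs[[i]], size[[i]], b1, b2)
      } else {
        bb_lower_tail(obs[[i]], size[[i]], b1, b2)
      }
    )
  }, numeric(1))
}

# P(K <= kobs): log-space mass terms combined by log-sum-exp
bb_lower_tail <- function(kobs, n, b1, b2) {
  min(1, exp(logsumexp(betabinomial_logpmf(0:kobs, n, b1, b2))))
}

# P(K >= kobs) via the complement of the strictly-lower tail, so that
# lower + upper = 1 + pmf(kobs) holds to machine precision
bb_upper_tail <- function(kobs, n, b1, b2) {
  if (kobs == 0) return(1)
  below <- exp(logsumexp(betabinomial_logpmf(0:(kobs - 1), n, b1, b2)))
  max(0, min(1, 1 - below))
}

# minimum-likelihood two-sided beta-binomial p-value.
# Small supports are enumerated exactly. Large supports use the shape of
# the mass function: for beta1, beta2 >= 1 it is log-concave (ratio
# pmf(k+1)/pmf(k) decreasing), for beta1 <= 1 <= beta2 monotone decreasing,
# for beta2 <= 1 <= beta1 monotone increasing; in each case the rejection
# set {pmf > pmf(obs)} is one contiguous interval around the mode, found by
# binary search and summed directly, p = 1 - rejected mass. Only the
# U-shaped case (both shapes < 1) falls back to full enumeration.
bb_two_sided <- function(kobs, n, b1, b2) {
  if (n <= 4096) {
    lp <- betabinomial_logpmf(0:n, n, b1, b2)
    lthr <- lp[[kobs + 1]] + log1p(TWO_SIDED_REL_TOL)
    return(min(1, sum(exp(lp[lp <= lthr]))))
  }
  lpf <- function(k) betabinomial_logpmf(k, n, b1, b2)
  lthr <- lpf(kobs) + log1p(TWO_SIDED_REL_TOL)

  if (b1 < 1 && b2 < 1) {
    lp <- lpf(0:n)
    return(min(1, sum(exp(lp[lp <= lthr]))))
  }
  mode <- bb_mode(n, b1, b2)
  if (lpf(mode) <= lthr) return(1)

  a <- -1                                   # left accept boundary
  if (mode > 0) {
    lo <- -1; hi <- mode                    # lpf increasing on [0, mode]
    while (hi - lo > 1) {
      mid <- (lo + hi) %/% 2
      if (lpf(mid) <= lthr) lo <- mid else hi <- mid
    }
    a <- lo
  }
  b <- n + 1                                # right accept boundary
  if (mode < n) {
    lo <- mode; hi <- n + 1                 # lpf decreasing on [mode, n]
    while (hi - lo > 1) {
      mid <- (lo + hi) %/% 2
      if (lpf(mid) <= lthr) hi <- mid else lo <- mid
    }
    b <- hi
  }
  rejected <- sum(exp(lpf(seq.int(a + 1, b - 1))))
  max(0, min(1, 1 - rejected))
}

# mode of the beta-binomial mass for the unimodal / monotone regimes
bb_mode <- function(n, b1, b2) {
  if (b1 <= 1 && b2 >= 1) return(0)
  if (b2 <= 1 && b1 >= 1) return(n)
  # interior mode: last k with pmf(k+1)/pmf(k) >= 1; the log ratio is
  # decreasing in k when both shapes exceed 1
  lr <- function(k) {
    log(n - k) + log(k + b1) - log(k + 1) - log(n - k - 1 + b2)
  }
  if (lr(0) < 0) return(0)
  if (lr(n - 1) >= 0) return(n)
  lo <- 0; hi <- n - 1
  while (hi - lo > 1) {
    mid <- (lo + hi) %/% 2
    if (lr(mid) >= 0) lo <- mid else hi <- mid
  }
  lo + 1
}
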
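# Brute-force oracles, kept independent of the implementation paths they
# check: direct-space summation over the whole support, beta-binomial mass
# built from the term ratio recurrence (no lbeta/lchoose), and quadrature
# over the beta prior.

# full beta-binomial pmf on 0..n from the recurrence
# u(k+1)/u(k) = (n-k)(k+b1) / ((k+1)(n-k-1+b2)), normalised at the end
oracle_bb_pmf <- function(n, b1, b2) {
  if (n == 0) return(1)
  k <- 0:(n - 1)
  lr <- log(n - k) + log(k + b1) - log(k + 1) - log(n - k - 1 + b2)
  lu <- c(0, cumsum(lr))
  lu <- lu - max(lu)
  u <- exp(lu)
  u / sum(u)
}

# direct-summation beta-binomial p-value under every rule the package offers
oracle_bb_pvalue <- function(k_a, k_b, n_a, n_b, v,
                             alternative = "two_sided",
                             statistic = "A",
                             two_sided_rule = "depletion",
                             epsilon = 1e-8) {
  mu <- (k_a + k_b) / (n_a + n_b)
  b1 <- max(mu * v, epsilon)
  b2 <- max((1 - mu) * v, epsilon)
  if (alternative == "two_sided" && two_sided_rule == "depletion") {
    pa <- sum(oracle_bb_pmf(n_a, b1, b2)[seq_len(k_a + 1)])
    pb <- sum(oracle_bb_pmf(n_b, b1, b2)[seq_len(k_b + 1)])
    return(min(1, 2 * min(pa, pb)))
  }
  if (statistic == "A") {
    obs <- k_a; pm <- oracle_bb_pmf(n_a, b1, b2); lower_is_expansion <- TRUE
  } else {
    obs <- k_b; pm <- oracle_bb_pmf(n_b, b1, b2); lower_is_expansion <- FALSE
  }
  lower <- sum(pm[seq_len(obs + 1)])
  upper <- sum(pm[(obs + 1):length(pm)])
  switch(alternative,
    two_sided = min(1, sum(pm[pm <= pm[[obs + 1]] * (1 + 1e-7)])),
    expansion_in_B = if (lower_is_expansion) lower else upper,
    contraction_in_B = if (lower_is_expansion) upper else lower
  )
}

# direct-summation binomial p-value
oracle_binom_pvalue <- function(k_a, k_b, n_a, n_b,
                                alternative = "two_sided") {
  theta <- (k_a + k_b) / (n_a + n_b)
  pm <- dbinom(0:n_b, n_b, theta)
  switch(alternative,
    expansion_in_B = sum(pm[(k_b + 1):(n_b + 1)]),
    contraction_in_B = sum(pm[seq_len(k_b + 1)]),
    two_sided = min(1, sum(pm[pm <= pm[[k_b + 1]] * (1 + 1e-7)]))
  )
}

# quadrature oracle for a single beta-binomial mass term
oracle_bb_pmf_quadrature <- function(k, n, b1, b2) {
  integrand <- function(th) dbinom(k, n, th) * dbeta(th, b1, b2)
  stats::integrate(integrand, 0, 1, rel.tol = 1e-10,
                   subdivisions = 2000L)$value
}

# a tiny repertoire tibble from named counts
toy_repertoire <- function(counts, id = "toy") {
  diffclone:::new_repertoire(
    dplyr::arrange(tibble::tibble(rearrangement = names(counts),
                                  templates = as.integer(counts)),
                   rearrangement),
    id)
}

# write a clone-table TSV and return its path
write_clone_tsv <- function(lines, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- tempfile(tmpdir = dir, fileext = ".tsv")
  writeLines(lines, path)
  path
}
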
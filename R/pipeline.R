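# End-to-end differential abundance: filter, test, BH-correct, classify,
# annotate against a reference repertoire.

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH adjusted p-values: sort ascending, `q_(i) = min_{j >= i}
#' min(1, p_(j) * m / j)`, returned in input order. Clones significant at
#' FDR `t` are exactly those with adjusted value below `t`.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values, same length and order as the input.
#' @export
benjamini_hochberg <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop_domain("p-values must lie in [0, 1]", "diffclone_domain_error")
  }
  m <- length(p_values)
  o <- order(p_values)
  q <- pmin(1, p_values[o] * m / seq_len(m))
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- q
  out
}

#' Configuration for a differential-abundance run
#'
#' Defaults reproduce the reference analysis settings with zero arguments:
#' two-sided testing, clones with pooled count below 5 excluded before any
#' test, significance at BH-adjusted FDR below 0.01.
#'
#' @param model `"binomial"` (pure sampling null) or `"beta_binomial"`
#'   (calibrated overdispersed null; requires `dispersion`).
#' @param dispersion A fitted [dispersion_model()], required when
#'   `model = "beta_binomial"`.
#' @param fdr_threshold Significance threshold on the BH-adjusted value
#'   (default 0.01).
#' @param min_total Minimum pooled count `k_A + k_B` for a clone to be
#'   tested (default 5); clones below it are reported `not_tested` and do
#'   not enter the multiplicity correction.
#' @param alternative Test alternative (default `"two_sided"`); one-sided
#'   modes are intended for power studies.
#' @param statistic Beta-binomial one-sided test statistic convention,
#'   `"A"` or `"B"`; see [betabinomial_pvalue()].
#' @param two_sided_rule Two-sided rule for the beta-binomial model,
#'   `"depletion"` (default) or `"min_likelihood"`; see
#'   [betabinomial_pvalue()].
#' @return A `diffab_config` list.
#' @export
diffab_config <- function(model = c("binomial", "beta_binomial"),
                          dispersion = NULL,
                          fdr_threshold = 0.01,
                          min_total = 5,
                          alternative = c("two_sided", "expansion_in_B",
                                          "contraction_in_B"),
                          statistic = c("A", "B"),
                          two_sided_rule = c("depletion", "min_likelihood")) {
  model <- match.arg(model)
  alternative <- match.arg(alternative)
  statistic <- match.arg(statistic)
  two_sided_rule <- match.arg(two_sided_rule)
  if (model == "beta_binomial") {
    if (is.null(dispersion)) {
      stop_domain("beta_binomial model requires a fitted dispersion model",
                  "diffclone_config_error")
    }
    check_fitted(dispersion)
  }
  stopifnot(is.numeric(fdr_threshold), fdr_threshold > 0, fdr_threshold <= 1,
            is.numeric(min_total), min_total >= 1)
  structure(
    list(model = model, dispersion = dispersion,
         fdr_threshold = fdr_threshold, min_total = min_total,
         alternative = alternative, statistic = statistic,
         two_sided_rule = two_sided_rule),
    class = "diffab_config"
  )
}

#' Differential clone abundance between two samples
#'
#' Joins two repertoires, excludes clones with pooled count below
#' `min_total` (they are reported but never tested), computes the
#' configured exact p-value for every remaining clone, applies the
#' Benjamini-Hochberg correction across exactly the tested set, and
#' classifies each tested clone as `expanded` / `contracted` (adjusted FDR
#' below threshold, direction by frequency change) or `not_significant`.
#'
#' The fold change `freq_B / freq_A` is a display quantity only (it plays
#' no role in testing); zero counts enter it with a half-template
#' pseudocount `0.5 / n`.
#'
#' @param a,b `tcr_repertoire` tibbles: sample A (earlier) and sample B
#'   (later).
#' @param config A [diffab_config()].
#' @return A tibble of class `diffab_result`, one row per clone in the
#'   union of the two samples, columns `rearrangement, k_A, n_A, k_B, n_B,
#'   freq_A, freq_B, fold_change, p_value, fdr, classification`; the
#'   configuration is attached as attribute `config`.
#' @examples
#' prof <- simulate_repertoire(200, zipf_exponent = 1.1)
#' a <- draw_sample(prof, 5000, seed = 1)
#' b <- draw_sample(prof, 5000, seed = 2)
#' res <- run_diffab(a, b, diffab_config())
#' table(res$classification)
#' @export
run_diffab <- function(a, b, config = diffab_config()) {
  stopifnot(inherits(config, "diffab_config"))
  obs <- join_samples(a, b)
  tested <- obs$k_total >= config$min_total & obs$k_total < obs$n_total

  p <- rep(NA_real_, nrow(obs))
  if (any(tested)) {
    t_obs <- obs[tested, , drop = FALSE]
    p[tested] <- switch(config$model,
      binomial = binomial_pvalue(t_obs$k_A, t_obs$k_B, t_obs$n_A, t_obs$n_B,
                                 alternative = config$alternative),
      beta_binomial = betabinomial_pvalue(
        t_obs$k_A, t_obs$k_B, t_obs$n_A, t_obs$n_B,
        dispersion = config$dispersion,
        alternative = config$alternative,
        statistic = config$statistic,
        two_sided_rule = config$two_sided_rule)
    )
  }
  fdr <- rep(NA_real_, nrow(obs))
  fdr[tested] <- benjamini_hochberg(p[tested])

  freq_a <- obs$k_A / obs$n_A
  freq_b <- obs$k_B / obs$n_B
  fold <- (pmax(obs$k_B, 0.5) / obs$n_B) / (pmax(obs$k_A, 0.5) / obs$n_A)

  cls <- rep("not_tested", nrow(obs))
  sig <- tested & !is.na(fdr) & fdr < config$fdr_threshold
  cls[tested] <- "not_significant"
  cls[sig & freq_b > freq_a] <- "expanded"
  cls[sig & freq_b < freq_a] <- "contracted"

  out <- obs |>
    dplyr::mutate(
      freq_A = freq_a, freq_B = freq_b, fold_change = fold,
      p_value = p, fdr = fdr,
      classification = factor(cls, levels = classification_levels)
    ) |>
    dplyr::select(dplyr::all_of(results_columns))
  structure(out,
            class = c("diffab_result", class(tibble::tibble())),
            config = config,
            sample_ids = c(A = sample_id(a), B = sample_id(b)))
}

#' Annotate differential-abundance results against a reference repertoire
#'
#' Flags each clone by presence in a reference sample (typically a
#' pre-treatment tumour repertoire, so expanded blood clones found there
#' are tumour-infiltrating lymphocyte clones) and summarises the overlap of
#' the expanded set.
#'
#' @param records A `diffab_result` tibble from [run_diffab()].
#' @param reference A `tcr_repertoire` tibble to test membership against.
#' @return A list with `records` (the input plus a logical `in_reference`
#'   column) and `summary`, a one-row tibble with `n_expanded`,
#'   `n_expanded_in_reference` and `pct_expanded_in_reference` (`NA` when
#'   nothing is expanded, never 0 by convention).
#' @export
annotate_overlap <- function(records, reference) {
  in_ref <- records$rearrangement %in% reference$rearrangement
  records$in_reference <- in_ref
  expanded <- records$classification == "expanded"
  n_exp <- sum(expanded, na.rm = TRUE)
  n_exp_ref <- sum(expanded & in_ref, na.rm = TRUE)
  pct <- if (n_exp > 0) 100 * n_exp_ref / n_exp else NA_real_
  list(
    records = records,
    summary = tibble::tibble(
      n_expanded = n_exp,
      n_expanded_in_reference = n_exp_ref,
      pct_expanded_in_reference = pct
    )
  )
}

#' @method glance diffab_result
#' @export
glance.diffab_result <- function(x, ...) {
  cfg <- attr(x, "config")
  tibble::tibble(
    model = cfg$model,
    alternative = cfg$alternative,
    n_clones = nrow(x),
    n_tested = sum(x$classification != "not_tested"),
    n_expanded = sum(x$classification == "expanded"),
    n_contracted = sum(x$classification == "contracted"),
    fdr_threshold = cfg$fdr_threshold,
    min_total = cfg$min_total
  )
}

#' @method tidy dispersion_model
#' @export
tidy.dispersion_model <- function(x, ...) {
  tibble::tibble(term = c("a", "b"), estimate = c(x$a, x$b))
}

#' @method glance dispersion_model
#' @export
glance.dispersion_model <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r_squared,
    n_bins = x$provenance$n_bins %||% NA_integer_,
    n_clones = x$provenance$n_clones %||% NA_integer_
  )
}
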
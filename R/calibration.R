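# Calibration of time-dependent dispersion from paired same-subject samples.
#
# Counts of the same clone in two samples drawn weeks apart vary more than
# multinomial sampling allows. The excess is summarised per pooled count
# k_total = k_A + k_B as the residual variance: the variance of the count
# difference minus the variance expected from sampling alone, and the
# dispersion model fits sqrt(residual variance) = b * log(k_total) + a, so
# the predicted dispersion v(k) = (b log k + a)^2 is non-negative by
# construction.

classification_levels <- c("expanded", "contracted", "not_significant",
                           "not_tested")

#' Per-k_total variance table from paired same-subject samples
#'
#' Groups paired clone observations by their exact pooled count `k_total`
#' and contrasts the observed variability of the count difference with the
#' variance expected under pure sampling. Under the null that a clone has
#' one frequency in both samples, `K_A | k_total ~ Binomial(k_total, p)`
#' with `p = n_A / (n_A + n_B)`, so
#' `Var(k_A - k_B | k_total) = 4 k_total p (1 - p)`; `p` is averaged over
#' the pairs contributing to a bin.
#'
#' Three estimators of the observed variability are available:
#' * `"msd"` (default): the mean squared difference
#'   `mean((k_A - k_B)^2)`, the consistent estimator of
#'   `Var(k_A - k_B | k_total)` given that the difference has null mean
#'   (approximately) zero;
#' * `"var_abs"`: the sample variance of `|k_A - k_B|`. Note that
#'   `Var(|X|) < Var(X)` (by roughly `1 - 2/pi` for near-normal `X`), so
#'   this estimator is conservative: residuals clamp to zero on null data
#'   but underestimate genuine overdispersion;
#' * `"var_signed"`: the sample variance of `k_A - k_B`.
#'
#' @param pairs A tibble of paired observations from [join_samples()], or a
#'   list of such tibbles (one per same-subject sample pair), pooled.
#' @param min_obs_per_bin Drop bins with fewer contributing clones
#'   (default 5).
#' @param observed Variability estimator, see above.
#' @return A tibble with columns `k_total`, `n_obs`, `observed_var`,
#'   `expected_binomial_var`, `residual_var` (clamped at 0), sorted by
#'   `k_total`.
#' @export
variance_by_total <- function(pairs, min_obs_per_bin = 5,
                              observed = c("msd", "var_abs", "var_signed")) {
  observed <- match.arg(observed)
  if (inherits(pairs, "data.frame")) pairs <- list(pairs)
  tab <- dplyr::bind_rows(pairs)
  if (any(tab$k_total < 1)) {
    stop_domain("every paired observation must have k_total >= 1",
                "diffclone_calibration_error")
  }
  est <- switch(observed,
    msd        = function(d) mean(d^2),
    var_abs    = function(d) if (length(d) < 2L) NA_real_ else var(abs(d)),
    var_signed = function(d) if (length(d) < 2L) NA_real_ else var(d)
  )
  out <- tab |>
    dplyr::mutate(diff = .data$k_A - .data$k_B,
                  p_a = .data$n_A / .data$n_total) |>
    dplyr::group_by(.data$k_total) |>
    dplyr::summarise(
      n_obs = dplyr::n(),
      observed_var = est(.data$diff),
      p_bar = mean(.data$p_a),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_obs >= min_obs_per_bin, !is.na(.data$observed_var)) |>
    dplyr::mutate(
      expected_binomial_var = 4 * .data$k_total * .data$p_bar * (1 - .data$p_bar),
      residual_var = pmax(.data$observed_var - .data$expected_binomial_var, 0)
    ) |>
    dplyr::select("k_total", "n_obs", "observed_var",
                  "expected_binomial_var", "residual_var") |>
    dplyr::arrange(.data$k_total)
  if (nrow(out) == 0L) {
    stop_domain("no k_total bin met min_obs_per_bin; not enough calibration data",
                "diffclone_calibration_error")
  }
  out
}

#' Construct a dispersion model
#'
#' The dispersion model maps a clone's pooled count to the beta prior
#' concentration used by [betabinomial_pvalue()]:
#' `v(k_total) = (b * log(k_total) + a)^2` with the natural logarithm.
#' Usually produced by [fit_dispersion()]; this constructor builds one from
#' known coefficients (e.g. for simulation studies).
#'
#' @param a Intercept of the fitted square-root-scale line.
#' @param b Slope against `log(k_total)`.
#' @param r_squared Optional goodness of fit of the squared-form prediction.
#' @param provenance Optional list of training metadata.
#' @return An object of class `dispersion_model`.
#' @export
dispersion_model <- function(a, b, r_squared = NA_real_, provenance = list()) {
  stopifnot(is.numeric(a), is.numeric(b), length(a) == 1L, length(b) == 1L,
            is.finite(a), is.finite(b))
  structure(
    list(a = a, b = b, log_base = "natural", fitted = TRUE,
         r_squared = r_squared, provenance = provenance),
    class = "dispersion_model"
  )
}

check_fitted <- function(model) {
  if (!inherits(model, "dispersion_model") || !isTRUE(model$fitted)) {
    stop_domain("dispersion model is not fitted", "diffclone_state_error")
  }
  invisible(model)
}

#' Fit the dispersion model to a variance table
#'
#' Fits `sqrt(residual_var) = b * log(k_total) + a` by least squares over
#' the bins with positive residual variance. The square-root scale makes
#' the model exactly linear in `log(k_total)` (no nonlinear optimisation,
#' no local minima); since the squared form is invariant to flipping the
#' sign of both coefficients, the fit is normalised to `b >= 0`.
#'
#' The fit proceeds in two stages. Stage one regresses
#' `sqrt(residual_var)` on `log(k_total)` (weighted least squares over the
#' positive-residual bins): on this scale the model is exactly linear, so
#' there is no initialisation or local-minimum concern. Stage two refines
#' the coefficients by iteratively reweighted Gauss-Newton least squares on
#' the *variance* scale, where the per-bin residual-variance estimate is an
#' unbiased mean and the fit is therefore free of the square-root
#' transformation's small-sample (Jensen/truncation) bias; zero-residual
#' bins also contribute. Weights approximate the inverse sampling variance
#' of a bin's mean squared difference, `n_obs / (k_total + v + 1)^2`.
#'
#' Bins with very small pooled counts are excluded from the fit
#' (`min_k_total`, default 20): given `k_total = s`, the squared count
#' difference is bounded by `s^2`, so when the dispersion curve approaches
#' the sampling variance the bin estimator is censored from above and
#' systematically underestimates the curve. Such clones are still tested
#' downstream — the model is evaluated there by extrapolation, exactly as
#' a single fitted curve is applied across all counts in practice.
#'
#' @param table Output of [variance_by_total()].
#' @param weight_by_n_obs Weight bins by their number of contributing
#'   clones (default `TRUE`), so well-populated bins dominate.
#' @param min_k_total Exclude bins with `k_total` below this from the fit
#'   (default 20); see Details.
#' @param refine Run the variance-scale Gauss-Newton refinement after the
#'   square-root-scale initialisation (default `TRUE`).
#' @return A `dispersion_model` carrying the coefficients, the R-squared of
#'   the squared-form prediction against `residual_var`, and training
#'   provenance (bins used, `k_total` range, clone counts).
#' @export
fit_dispersion <- function(table, weight_by_n_obs = TRUE, min_k_total = 20,
                           refine = TRUE) {
  use <- table[table$k_total >= min_k_total, , drop = FALSE]
  pos <- use[use$residual_var > 0, , drop = FALSE]
  if (nrow(pos) < 3L) {
    stop_domain(
      "under-determined fit: need at least 3 bins with positive residual variance",
      "diffclone_calibration_error")
  }
  w_pos <- if (weight_by_n_obs) pos$n_obs else rep(1, nrow(pos))
  dat <- data.frame(y = sqrt(pos$residual_var), x = log(pos$k_total))
  fit <- lm(y ~ x, data = dat, weights = w_pos)
  a <- unname(coef(fit)[[1L]])
  b <- unname(coef(fit)[[2L]])

  if (refine && nrow(use) >= 3L) {
    kk <- use$k_total; rv <- use$residual_var
    nn <- if (weight_by_n_obs) use$n_obs else rep(1, nrow(use))
    L <- log(kk)
    for (it in seq_len(8L)) {
      g <- a + b * L
      w <- nn / (kk + g^2 + 1)^2
      X <- cbind(2 * g, 2 * L * g)
      r <- rv - g^2
      upd <- tryCatch(solve(crossprod(X, w * X), crossprod(X, w * r)),
                      error = function(e) NULL)
      if (is.null(upd) || any(!is.finite(upd))) break
      a <- a + upd[[1L]]
      b <- b + upd[[2L]]
    }
  }
  if (b < 0) { a <- -a; b <- -b }   # the square is sign-invariant

  w <- if (weight_by_n_obs) use$n_obs else rep(1, nrow(use))
  pred <- (b * log(use$k_total) + a)^2
  ss_res <- sum(w * (use$residual_var - pred)^2)
  ss_tot <- sum(w * (use$residual_var - weighted.mean(use$residual_var, w))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  dispersion_model(
    a = a, b = b, r_squared = r2,
    provenance = list(
      n_bins = nrow(use),
      k_total_range = range(use$k_total),
      n_clones = sum(use$n_obs),
      weighted = weight_by_n_obs,
      min_k_total = min_k_total,
      refined = refine,
      table = use
    )
  )
}

#' Predict the dispersion for a pooled count
#'
#' Evaluates `v(k_total) = (b * log(k_total) + a)^2` (natural log), floored
#' at `epsilon` so downstream beta shapes stay positive even at the root of
#' the fitted line.
#'
#' @param model A fitted [dispersion_model()].
#' @param k_total Pooled clone count(s), integer `>= 1`.
#' @param epsilon Floor (default `1e-8`).
#' @return Numeric vector of dispersion values `v >= epsilon`.
#' @export
predict_variance <- function(model, k_total, epsilon = 1e-8) {
  check_fitted(model)
  if (any(k_total < 1)) {
    stop_domain("k_total must be >= 1", "diffclone_domain_error")
  }
  pmax((model$b * log(k_total) + model$a)^2, epsilon)
}

#' @export
predict.dispersion_model <- function(object, k_total, ...) {
  predict_variance(object, k_total)
}

#' @export
print.dispersion_model <- function(x, ...) {
  cat("Dispersion model: v(k_total) = (b * log(k_total) + a)^2\n")
  cat(sprintf("  a = %.6g, b = %.6g (natural log)\n", x$a, x$b))
  if (!is.na(x$r_squared)) cat(sprintf("  R-squared = %.3f\n", x$r_squared))
  if (!is.null(x$provenance$n_bins)) {
    cat(sprintf("  trained on %d bins (k_total %d..%d, %d clones)\n",
                x$provenance$n_bins, x$provenance$k_total_range[[1L]],
                x$provenance$k_total_range[[2L]], x$provenance$n_clones))
  }
  invisible(x)
}

#' Serialise a dispersion model to JSON
#'
#' @param model A fitted [dispersion_model()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_dispersion <- function(model, path) {
  check_fitted(model)
  prov <- model$provenance
  prov$table <- NULL   # keep the document small; the table is training data
  jsonlite::write_json(
    list(a = model$a, b = model$b, log_base = model$log_base,
         r_squared = model$r_squared, provenance = prov),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a dispersion model from JSON
#'
#' @param path Path written by [write_dispersion()].
#' @return A `dispersion_model`.
#' @export
read_dispersion <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$a) || is.null(doc$b)) {
    stop_domain("dispersion JSON lacks coefficients a/b", "diffclone_format_error")
  }
  dispersion_model(a = doc$a, b = doc$b,
                   r_squared = doc$r_squared %||% NA_real_,
                   provenance = doc$provenance %||% list())
}
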
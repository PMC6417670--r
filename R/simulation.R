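# Synthetic repertoires and Monte-Carlo characterisation of the tests.
#
# A repertoire profile is a heavy-tailed (Zipf-like) clone frequency
# distribution standing in for a donor's genomic-DNA pool; sequencing a
# sample is a multinomial draw of templates from it. Technical replicates
# are two draws from one profile (a pure-sampling null); time-separated
# samples are emulated by resampling each clone's frequency from a beta
# distribution before the second draw, which inflates the count variance
# with total count exactly in the functional form the calibration fits.

#' Simulate a Zipf-like clone frequency profile
#'
#' Clone `i` of `n_clones` receives unnormalised mass `i^(-zipf_exponent)`;
#' frequencies are the normalised masses. Deterministic given its
#' parameters.
#'
#' @param n_clones Number of clones (`>= 2`).
#' @param zipf_exponent Power-law exponent of the rank-frequency curve
#'   (default 1.2; values just above 1 give the heavy tail typical of
#'   blood TCR repertoires).
#' @param prefix Clone-identifier prefix, so profiles built with different
#'   prefixes share no clones (two "donors").
#' @param seed Stored for provenance; the construction itself is
#'   deterministic.
#' @return A tibble of class `repertoire_profile` with columns
#'   `rearrangement`, `frequency` (summing to 1).
#' @export
simulate_repertoire <- function(n_clones, zipf_exponent = 1.2,
                                prefix = "clone", seed = NULL) {
  stopifnot(n_clones >= 2)
  mass <- seq_len(n_clones)^(-zipf_exponent)
  structure(
    tibble::tibble(
      rearrangement = sprintf("%s%06d", prefix, seq_len(n_clones)),
      frequency = mass / sum(mass)
    ),
    class = c("repertoire_profile", class(tibble::tibble())),
    zipf_exponent = zipf_exponent, seed = seed
  )
}

#' Simulate a calibration-panel frequency profile
#'
#' A deterministic profile designed for dispersion-calibration studies:
#' `n_clones` clone frequencies evenly spaced between `freq_min` and
#' `freq_max` (uniform in frequency, so every pooled-count bin in the
#' working range is densely and evenly populated), plus one "filler" clone
#' absorbing the remaining probability mass so frequencies sum to 1. Unlike
#' the Zipf profile of [simulate_repertoire()], whose steep rank-frequency
#' curve leaves mid- and high-count bins nearly empty, the panel gives the
#' per-`k_total` variance table well-populated bins across the range where
#' the dispersion curve is identifiable.
#'
#' @param n_clones Number of panel clones (default 10000).
#' @param freq_min,freq_max Frequency range of the panel (defaults
#'   `5e-6` and `1.9e-4`; with the default sequencing depth of 1e6
#'   templates per sample this spans pooled counts of roughly 20-380).
#' @param prefix Clone-identifier prefix.
#' @return A `repertoire_profile` tibble; the filler clone is named
#'   `<prefix>_filler`.
#' @export
simulate_calibration_panel <- function(n_clones = 10000, freq_min = 5e-6,
                                       freq_max = 1.9e-4, prefix = "panel") {
  stopifnot(n_clones >= 2, freq_min > 0, freq_max > freq_min)
  f <- seq(freq_min, freq_max, length.out = n_clones)
  filler <- 1 - sum(f)
  if (filler <= 0) {
    stop_domain("panel frequencies exceed 1; reduce n_clones or freq_max",
                "diffclone_parameter_error")
  }
  structure(
    tibble::tibble(
      rearrangement = c(sprintf("%s%06d", prefix, seq_len(n_clones)),
                        paste0(prefix, "_filler")),
      frequency = c(f, filler)
    ),
    class = c("repertoire_profile", class(tibble::tibble()))
  )
}

#' Draw a sequencing sample from a frequency profile
#'
#' One multinomial draw of `n_templates` templates from the profile's
#' frequencies; clones receiving zero templates are omitted, as in a real
#' clone table.
#'
#' @param profile A `repertoire_profile`.
#' @param n_templates Sequencing depth (total templates).
#' @param seed Optional integer seed; the same seed reproduces the draw
#'   exactly and the caller's RNG state is left untouched.
#' @param sample_id Label for the resulting sample.
#' @return A `tcr_repertoire` tibble.
#' @export
draw_sample <- function(profile, n_templates, seed = NULL,
                        sample_id = "synthetic") {
  stopifnot(n_templates >= 1)
  counts <- with_seed_or_not(seed,
    as.integer(rmultinom(1, size = n_templates, prob = profile$frequency)))
  keep <- counts > 0L
  new_repertoire(
    tibble::tibble(rearrangement = profile$rearrangement[keep],
                   templates = counts[keep]) |>
      dplyr::arrange(.data$rearrangement),
    sample_id)
}

#' Perturb clone frequencies with count-calibrated biological noise
#'
#' Emulates normal time-dependent drift of clone frequencies between two
#' blood draws. Each clone's frequency is resampled from a beta
#' distribution with mean equal to its current frequency, with the beta
#' concentration chosen per clone so that the *residual count variance*
#' measured by [variance_by_total()] on pairs drawn before/after the
#' perturbation follows the target curve
#' `v_t(k) = (dispersion_b * log(k) + dispersion_a)^2` at the clone's
#' expected pooled count `k`. (The frequency-noise variance that produces a
#' residual count variance `v_t` at per-sample depth `n` is `v_t / n^2`,
#' hence concentration `c = n^2 f (1 - f) / v_t - 1`.) This makes the
#' calibration exactly well-specified: fitting the dispersion model on
#' perturbed pairs recovers `(dispersion_a, dispersion_b)`.
#'
#' @param profile A `repertoire_profile`.
#' @param dispersion_a,dispersion_b Coefficients of the target residual
#'   standard-deviation line `b * log(k_total) + a`.
#' @param pair_templates Expected pooled sequencing depth `n_A + n_B` of
#'   the sample pair the perturbed profile will be compared across.
#' @param seed Optional integer seed.
#' @param share Fraction of the target residual variance this perturbation
#'   contributes (default 1). When *both* samples of a pair are drawn from
#'   independently perturbed profiles, use `share = 0.5` for each so the
#'   pair's total drift variance matches the target curve; the symmetric
#'   construction keeps the count difference conditionally mean-zero given
#'   `k_total`, which is what the calibration estimator assumes.
#' @param epsilon Floor for the target dispersion (default `1e-8`).
#' @return A new `repertoire_profile` with the same clones, frequencies
#'   renormalised to 1.
#' @export
perturb_frequencies <- function(profile, dispersion_a, dispersion_b,
                                pair_templates, seed = NULL, share = 1,
                                epsilon = 1e-8) {
  stopifnot(pair_templates >= 2, share > 0, share <= 1)
  f <- profile$frequency
  n_s <- pair_templates / 2
  k_bar <- pmax(f * pair_templates, 2)   # clones below the test filter anyway
  v_t <- pmax(share * (dispersion_b * log(k_bar) + dispersion_a)^2, epsilon)
  conc <- n_s^2 * f * (1 - f) / v_t - 1
  if (any(!is.finite(conc))) {
    stop_domain("non-finite beta concentration; check dispersion coefficients",
                "diffclone_parameter_error")
  }
  conc <- pmin(pmax(conc, epsilon), 1e14)
  new_f <- with_seed_or_not(seed, rbeta(length(f), f * conc, (1 - f) * conc))
  new_f <- pmax(new_f, 1e-15)
  out <- profile
  out$frequency <- new_f / sum(new_f)
  out
}

#' Mix two repertoire profiles at a fixed ratio
#'
#' Pointwise mixture over the union of clones:
#' `freq = ratio * P + (1 - ratio) * Q`. Comparing mixtures built at ratios
#' `r1` and `r2` gives every clone private to `P` an expected frequency
#' fold change of `r2 / r1` — the dilution design used to estimate
#' statistical power with known truth.
#'
#' @param p,q `repertoire_profile` tibbles.
#' @param ratio Mixing proportion of `p`, in `[0, 1]`.
#' @return A `repertoire_profile` over the union of clones.
#' @export
mix_profiles <- function(p, q, ratio) {
  stopifnot(ratio >= 0, ratio <= 1)
  mixed <- dplyr::full_join(
    tibble::tibble(rearrangement = p$rearrangement, f_p = p$frequency),
    tibble::tibble(rearrangement = q$rearrangement, f_q = q$frequency),
    by = "rearrangement"
  ) |>
    dplyr::mutate(
      frequency = ratio * dplyr::coalesce(.data$f_p, 0) +
        (1 - ratio) * dplyr::coalesce(.data$f_q, 0)
    ) |>
    dplyr::filter(.data$frequency > 0) |>
    dplyr::select("rearrangement", "frequency") |>
    dplyr::arrange(.data$rearrangement)
  structure(mixed,
            class = c("repertoire_profile", class(tibble::tibble())),
            mixture_ratio = ratio)
}

#' Simulate a cohort of paired same-subject samples
#'
#' Builds the training input for dispersion calibration: `n_pairs`
#' independent sample pairs drawn from one latent profile, each sample's
#' frequencies first drifted with [perturb_frequencies()] (`share = 0.5`
#' per side, so the pair's count-difference drift variance follows the
#' target curve `(drift$b * log(k_total) + drift$a)^2`). With
#' `drift = NULL` the pairs are pure technical replicates.
#'
#' @param profile A `repertoire_profile` (e.g.
#'   [simulate_calibration_panel()]).
#' @param n_pairs Number of sample pairs.
#' @param n_templates Depth of each sample.
#' @param drift `list(a =, b =)` residual-dispersion coefficients, or
#'   `NULL` for technical replicates.
#' @param seed Integer seed.
#' @return A list of `n_pairs` paired-observation tibbles (see
#'   [join_samples()]), ready for [variance_by_total()].
#' @export
simulate_paired_cohort <- function(profile, n_pairs, n_templates,
                                   drift = NULL, seed = NULL) {
  stopifnot(n_pairs >= 1)
  purrr::map(seq_len(n_pairs), function(i) {
    prof_a <- profile
    prof_b <- profile
    if (!is.null(drift)) {
      prof_a <- perturb_frequencies(profile, drift$a, drift$b,
                                    pair_templates = 2 * n_templates,
                                    seed = child_seed(seed, 4L * i),
                                    share = 0.5)
      prof_b <- perturb_frequencies(profile, drift$a, drift$b,
                                    pair_templates = 2 * n_templates,
                                    seed = child_seed(seed, 4L * i + 3L),
                                    share = 0.5)
    }
    join_samples(
      draw_sample(prof_a, n_templates, seed = child_seed(seed, 4L * i + 1L),
                  sample_id = sprintf("subj%02dA", i)),
      draw_sample(prof_b, n_templates, seed = child_seed(seed, 4L * i + 2L),
                  sample_id = sprintf("subj%02dB", i))
    )
  })
}

#' Monte-Carlo false-positive rate of a differential-abundance test
#'
#' Draws `n_replicate_pairs` pairs of samples whose clones all share the
#' same true frequencies — so every significant call is a false positive —
#' runs [run_diffab()] on each pair, and reports the pooled false-positive
#' rate over tested clones. With `perturb = NULL` the two draws come from
#' the identical profile (technical replicates); supplying
#' `perturb = list(a =, b =)` resamples the second draw's frequencies with
#' [perturb_frequencies()], emulating two blood draws weeks apart (still a
#' null: no clone responds to anything, frequencies only drift).
#'
#' @param profile A `repertoire_profile`.
#' @param n_templates Depth of each sample.
#' @param config A [diffab_config()].
#' @param n_replicate_pairs Number of independent sample pairs.
#' @param seed Integer seed; pair `i` uses a seed derived from it.
#' @param perturb Optional `list(a =, b =)` of drift coefficients.
#' @return A one-row tibble: `n_pairs`, `n_tested`, `n_significant`,
#'   `mean_significant_per_pair`, `fpr` (pooled significant / tested) and
#'   `fpr_se` (standard error of the per-pair rates). Per-pair counts are
#'   attached as attribute `pairs`.
#' @export
estimate_fpr <- function(profile, n_templates, config, n_replicate_pairs,
                         seed = NULL, perturb = NULL) {
  stopifnot(n_replicate_pairs >= 1)
  per_pair <- purrr::map(seq_len(n_replicate_pairs), function(i) {
    prof_a <- profile
    prof_b <- profile
    if (!is.null(perturb)) {
      # drift both draws away from the latent profile, half the target
      # variance each, so their difference carries the full drift variance
      prof_a <- perturb_frequencies(profile, perturb$a, perturb$b,
                                    pair_templates = 2 * n_templates,
                                    seed = child_seed(seed, 4L * i),
                                    share = 0.5)
      prof_b <- perturb_frequencies(profile, perturb$a, perturb$b,
                                    pair_templates = 2 * n_templates,
                                    seed = child_seed(seed, 4L * i + 3L),
                                    share = 0.5)
    }
    a <- draw_sample(prof_a, n_templates, seed = child_seed(seed, 4L * i + 1L),
                     sample_id = paste0("rep", i, "A"))
    b <- draw_sample(prof_b, n_templates, seed = child_seed(seed, 4L * i + 2L),
                     sample_id = paste0("rep", i, "B"))
    res <- run_diffab(a, b, config)
    tibble::tibble(
      pair = i,
      n_tested = sum(res$classification != "not_tested"),
      n_significant = sum(res$classification %in% c("expanded", "contracted"))
    )
  }) |> dplyr::bind_rows()

  if (sum(per_pair$n_tested) == 0L) {
    stop_domain("no clone passed the min_total filter; FPR undefined",
                "diffclone_undefined_fpr_error")
  }
  rates <- per_pair$n_significant / pmax(per_pair$n_tested, 1L)
  out <- tibble::tibble(
    n_pairs = n_replicate_pairs,
    n_tested = sum(per_pair$n_tested),
    n_significant = sum(per_pair$n_significant),
    mean_significant_per_pair = mean(per_pair$n_significant),
    fpr = sum(per_pair$n_significant) / sum(per_pair$n_tested),
    fpr_se = if (n_replicate_pairs > 1) {
      stats::sd(rates) / sqrt(n_replicate_pairs)
    } else {
      sqrt(out_rate_var(rates[[1L]], per_pair$n_tested[[1L]]))
    }
  )
  attr(out, "pairs") <- per_pair
  out
}

out_rate_var <- function(rate, n) rate * (1 - rate) / max(n, 1)

#' Monte-Carlo power surface from a dilution design
#'
#' Estimates the probability of detecting a clone as significantly expanded
#' as a function of its baseline frequency and its expected fold change,
#' using mixtures of two disjoint repertoires at fixed ratios. The baseline
#' comparison sample is the mixture at `ratios[1]`; each `r` in `ratios` is
#' compared against it, giving clones private to `profile_a` an expected
#' fold change `r / ratios[1]` (a ratio equal to the baseline estimates the
#' null/false-positive level, "fold change 1"). Power in a cell is the
#' fraction of (private clone, replicate) pairs classified `expanded`.
#'
#' @param profile_a,profile_b `repertoire_profile` tibbles with disjoint
#'   clones (build them with different `prefix`es).
#' @param ratios Mixing proportions of `profile_a`; the first is the
#'   baseline.
#' @param n_templates Depth of each drawn sample.
#' @param config A [diffab_config()].
#' @param n_reps Replicate sample pairs per ratio.
#' @param seed Integer seed.
#' @param freq_breaks Baseline-frequency bin edges (default half-decade
#'   bins from 1e-5 to 1e-1).
#' @return A tibble of class `power_grid`: `fold_change`, `freq_lo`,
#'   `freq_hi`, `freq_mid` (geometric midpoint), `n_eval`, `n_detected`,
#'   `power`, `se` (binomial Monte-Carlo standard error).
#' @export
estimate_power <- function(profile_a, profile_b, ratios, n_templates,
                           config, n_reps, seed = NULL,
                           freq_breaks = 10^seq(-5, -1, by = 0.5)) {
  stopifnot(length(ratios) >= 1, all(ratios >= 0), all(ratios <= 1),
            n_reps >= 1)
  base_ratio <- ratios[[1L]]
  private_a <- setdiff(profile_a$rearrangement, profile_b$rearrangement)
  baseline_freq <- base_ratio *
    profile_a$frequency[match(private_a, profile_a$rearrangement)]
  bin <- cut(baseline_freq, breaks = freq_breaks, include.lowest = TRUE)
  track <- tibble::tibble(rearrangement = private_a,
                          baseline_freq = baseline_freq, bin = bin) |>
    dplyr::filter(!is.na(bin))
  mix_base <- mix_profiles(profile_a, profile_b, base_ratio)

  cells <- purrr::imap(ratios, function(r2, j) {
    fold <- r2 / base_ratio
    mix_b <- mix_profiles(profile_a, profile_b, r2)
    det <- purrr::map(seq_len(n_reps), function(rep) {
      s <- child_seed(seed, (j - 1L) * n_reps * 2L + rep * 2L)
      a <- draw_sample(mix_base, n_templates, seed = s, sample_id = "mixA")
      b <- draw_sample(mix_b, n_templates, seed = child_seed(s, 1L),
                       sample_id = "mixB")
      res <- run_diffab(a, b, config)
      hits <- res$rearrangement[res$classification == "expanded"]
      tibble::tibble(rearrangement = track$rearrangement,
                     detected = track$rearrangement %in% hits)
    }) |> dplyr::bind_rows()
    det |>
      dplyr::left_join(track, by = "rearrangement") |>
      dplyr::group_by(.data$bin) |>
      dplyr::summarise(n_eval = dplyr::n(),
                       n_detected = sum(.data$detected), .groups = "drop") |>
      dplyr::mutate(fold_change = fold)
  }) |> dplyr::bind_rows()

  edges <- tibble::tibble(
    bin = cut(sqrt(freq_breaks[-1] * freq_breaks[-length(freq_breaks)]),
              breaks = freq_breaks, include.lowest = TRUE),
    freq_lo = freq_breaks[-length(freq_breaks)],
    freq_hi = freq_breaks[-1],
    freq_mid = sqrt(freq_breaks[-1] * freq_breaks[-length(freq_breaks)])
  )
  out <- cells |>
    dplyr::left_join(edges, by = "bin") |>
    dplyr::mutate(power = .data$n_detected / .data$n_eval,
                  # Monte-Carlo SE with an add-one shrunk proportion so
                  # cells at 0 or 1 keep a non-degenerate uncertainty
                  p_shrunk = (.data$n_detected + 1) / (.data$n_eval + 2),
                  se = sqrt(.data$p_shrunk * (1 - .data$p_shrunk) / .data$n_eval)) |>
    dplyr::select("fold_change", "freq_lo", "freq_hi", "freq_mid",
                  "n_eval", "n_detected", "power", "se") |>
    dplyr::arrange(.data$fold_change, .data$freq_mid)
  structure(out,
            class = c("power_grid", class(tibble::tibble())),
            n_reps = n_reps, seed = seed, ratios = ratios,
            n_templates = n_templates)
}
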
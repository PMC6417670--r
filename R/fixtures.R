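#' Generate a deterministic set of small synthetic datasets
#'
#' Writes a self-contained fixture set used by the documentation, tests and
#' CLI examples: a pair of technical replicates (two draws from one
#' profile), a pair of "two-week" samples (second draw after biological
#' frequency drift), a mixture-dilution series for power studies, and a
#' small synthetic "tumour" reference repertoire overlapping the donor's
#' largest clones. All files are headered TSV clone tables readable with
#' `read_repertoire(..., dialect = "immunoseq")`. The same seed always
#' reproduces byte-identical files.
#'
#' @param out_dir Writable output directory (created if missing).
#' @param seed Integer seed.
#' @param n_clones Clones per donor profile (default 2000).
#' @param n_templates Templates per sample (default 20000).
#' @param drift Residual-dispersion coefficients `list(a =, b =)` used for
#'   the two-week pair (defaults `a = 2`, `b = 1`).
#' @return Named character vector of the written file paths, invisibly.
#' @export
make_fixtures <- function(out_dir, seed = 20190314, n_clones = 2000,
                          n_templates = 20000, drift = list(a = 2, b = 1)) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  donor1 <- simulate_repertoire(n_clones, zipf_exponent = 1.2, prefix = "dnrA")
  donor2 <- simulate_repertoire(n_clones, zipf_exponent = 1.2, prefix = "dnrB")

  paths <- c(
    technical_A = "technical_replicate_A.tsv",
    technical_B = "technical_replicate_B.tsv",
    twoweek_A   = "twoweek_A.tsv",
    twoweek_B   = "twoweek_B.tsv",
    mixture_100 = "mixture_ratio_100.tsv",
    mixture_50  = "mixture_ratio_50.tsv",
    mixture_10  = "mixture_ratio_10.tsv",
    mixture_5   = "mixture_ratio_5.tsv",
    tumor       = "tumor_synthetic.tsv"
  )
  paths <- setNames(file.path(out_dir, paths), names(paths))

  write_repertoire(draw_sample(donor1, n_templates, seed = child_seed(seed, 1)),
                   paths[["technical_A"]])
  write_repertoire(draw_sample(donor1, n_templates, seed = child_seed(seed, 2)),
                   paths[["technical_B"]])

  drifted_a <- perturb_frequencies(donor1, drift$a, drift$b,
                                   pair_templates = 2 * n_templates,
                                   seed = child_seed(seed, 3), share = 0.5)
  drifted_b <- perturb_frequencies(donor1, drift$a, drift$b,
                                   pair_templates = 2 * n_templates,
                                   seed = child_seed(seed, 11), share = 0.5)
  write_repertoire(draw_sample(drifted_a, n_templates, seed = child_seed(seed, 4)),
                   paths[["twoweek_A"]])
  write_repertoire(draw_sample(drifted_b, n_templates, seed = child_seed(seed, 5)),
                   paths[["twoweek_B"]])

  ratios <- c(mixture_100 = 1, mixture_50 = 0.5, mixture_10 = 0.1,
              mixture_5 = 0.05)
  for (i in seq_along(ratios)) {
    mx <- mix_profiles(donor1, donor2, ratios[[i]])
    write_repertoire(draw_sample(mx, n_templates, seed = child_seed(seed, 5 + i)),
                     paths[[names(ratios)[[i]]]])
  }

  # synthetic tumour reference: the donor's top clones plus private ones
  tumor_clones <- head(donor1$rearrangement, 150)
  tumor <- with_seed_or_not(child_seed(seed, 10), tibble::tibble(
    rearrangement = c(tumor_clones, sprintf("tumor%04d", 1:50)),
    templates = as.integer(pmax(1, rbinom(200, 500, 0.05)))
  ))
  write_repertoire(new_repertoire(dplyr::arrange(tumor, .data$rearrangement),
                                  "tumor_synthetic"),
                   paths[["tumor"]])
  invisible(paths)
}
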
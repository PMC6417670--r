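---
title: "Detecting differentially abundant T-cell clones: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting differentially abundant T-cell clones}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diffclone)
```

## The problem

Immunosequencing of TCR-beta CDR3 rearrangements reports, for each blood
sample, a table of clones and template counts. Comparing two samples from
the same subject — before and after a vaccine or therapy, or simply weeks
apart — raises the question of which clones genuinely changed frequency.
Two noise sources stand between the counts and that answer: multinomial
sampling of a few hundred thousand templates from a very diverse
repertoire, and ordinary biological drift of clone frequencies over time.
A test that models only the first source mistakes the second for signal;
this package implements both the sampling-only (binomial) test and a
beta-binomial test whose extra dispersion is calibrated from paired
same-subject samples, together with the simulation machinery needed to
characterise their false-positive rates and power.

## The binomial test

For clone $i$ with counts $k_{iA}, k_{iB}$ in samples of $n_A, n_B$ total
templates, the null hypothesis is a single frequency
$\theta = (k_{iA}+k_{iB})/(n_A+n_B)$ in both samples; the count in sample
B is then $K \sim \mathrm{Binomial}(n_B, \theta)$ and the test asks
whether $k_{iB}$ is an ordinary draw from it:

$$P(k \mid \theta, n) = \binom{n}{k}\,\theta^k (1-\theta)^{n-k}.$$

One-sided p-values are exact tail sums. The two-sided p-value uses the
minimum-likelihood rule — the total mass of all outcomes no more probable
than the observed one (with the conventional $1+10^{-7}$ tie tolerance) —
which is the rule under which this unconditional binomial test tracks
Fisher's exact test. One caveat is inherited from the construction: the
statistic is sample B's count on support $n_B$, so unlike Fisher's
conditional test the binomial test is not exactly symmetric under swapping
the two samples, and under symmetric frequency drift its significant calls
lean towards depletions (a clone collapsing to near zero produces a more
extreme lower tail than the matching upper-tail excursion). The
beta-binomial two-sided rule below is exactly swap-symmetric.

Large supports never enumerate the full mass function: the binomial mass is
unimodal, so the acceptance region's two boundaries are located by binary
search on the monotone flanks ($O(\log n)$ per clone) and the tails
evaluated with `pbinom`.

## The beta-binomial test

Biological drift is modelled by a beta prior on the clone frequency. With
mean $\mu$ (the pooled frequency) and a dispersion quantity $v$, the shape
parameters are

$$\beta_1 = \mu v, \qquad \beta_2 = (1-\mu)\,v,$$

and the marginal null for a count on $n$ trials is the beta-binomial mass,
computed through log-gamma and floored at $\varepsilon = 10^{-8}$ per
shape, because the calibrated $v(k) = (b\log k + a)^2$ can pass
arbitrarily close to zero at the root of the fitted line.

The per-clone dispersion comes from a calibrated **dispersion model**
$v(k_{\mathrm{total}}) = (b \log k_{\mathrm{total}} + a)^2$ (natural
logarithm, one fixed convention shared by fit and prediction), evaluated
at the clone's pooled count. Note the units asymmetry taken over from the
method as published: $v$ is estimated on the *count-residual-variance*
scale but consumed as a beta *concentration*. Since typical fitted values
are tens while a frequency-faithful concentration would be of order
$k/\mathrm{CV}^2$, the prior is much wider than the drift that trained it
— the test is deliberately, strongly conservative at small and moderate
counts, which is the behaviour that gives it its specificity. Two
consequences are worth spelling out:

* $v \to \infty$ is the binomial limit. A dispersion model trained on
  *technical replicates* fits residual variances near zero, i.e. small
  $v$ — the **wide-prior limit, not the binomial limit**. Such a model is
  even more conservative than the drift-trained one (both call
  essentially nothing on replicate data, as the tests verify); no
  calibration on null data can make the beta-binomial collapse onto the
  binomial.
* when $\beta_1 = \mu v < 1$ — true for essentially every clone at
  realistic coefficients — the mass function is monotone decreasing with
  most mass at zero. A minimum-likelihood two-sided rule then degenerates
  into the upper tail $P(K \ge k_{\mathrm{obs}})$ and assigns tiny
  p-values to perfectly ordinary events such as a clone seen five times
  in one sample and absent from the other; in simulation this inverts the
  model's entire purpose (it calls *more* clones than the binomial on
  drifting pairs). The package therefore defines the beta-binomial
  two-sided p-value by the **depletion rule**:
  $$p = \min\!\Big(1,\; 2 \min\big(P(K_A \le k_{iA}\mid n_A),\;
  P(K_B \le k_{iB}\mid n_B)\big)\Big),$$
  doubled lower tails of the two per-sample statistics. This is built
  from the same one-sided sums as the published construction ("from 0 to
  $k_{iA}$"), is exactly symmetric in the samples, and only rejects when
  one sample's count is improbably *low* given the pooled frequency —
  the well-behaved tail of a mass-near-zero beta-binomial. The
  minimum-likelihood rule remains available
  (`betabinomial_pvalue(..., two_sided_rule = "min_likelihood")`) and is
  verified against brute-force enumeration, it is simply not the default.

One-sided tests use sample A's count on support $n_A$ by default
(expansion in B = lower tail of $k_{iA}$); `statistic = "B"` mirrors the
convention. Tail sums accumulate log-space mass terms; the
minimum-likelihood path exploits unimodality (interval around the mode by
binary search) instead of enumerating large supports.

## Calibrating the dispersion model

Training data are pairs of samples drawn from the same subject a fixed
interval apart. `variance_by_total()` groups the paired observations by
exact pooled count $k_{\mathrm{total}}$ and, per bin, contrasts the
observed variability of the count difference $D = k_{iA}-k_{iB}$ with the
sampling expectation. Under the null, conditionally on
$k_{\mathrm{total}}$, $K_A \sim \mathrm{Binomial}(k_{\mathrm{total}}, p)$
with $p = n_A/(n_A+n_B)$, so the sampling variance of $D$ is
$4\,k_{\mathrm{total}}\,p(1-p)$ (with $p$ averaged over the pairs
contributing to the bin). The published description of this quantity
("$np(1-p)$ where $n$ is equal to $k_{iA}$ and $p$ is the frequency of
observing a given pair") is not implementable as written; this standard
conditional form is used instead.

The default estimator of the observed variability is the **mean squared
difference** $\widehat{E}[D^2]$, which is the consistent estimator of
$\mathrm{Var}(D \mid k_{\mathrm{total}})$ because $D$ has null conditional
mean zero. The sample variance of the *absolute* difference $|D|$
(`observed = "var_abs"`) is also offered but is not the default:
$\mathrm{Var}(|D|) \approx (1-2/\pi)\,\mathrm{Var}(D)$ for near-normal
$D$, so subtracting the signed-difference sampling variance from it
produces residuals that clamp to zero on null data yet systematically
underestimate genuine overdispersion. A signed-difference sample variance
(`"var_signed"`) completes the set.

`fit_dispersion()` then fits $\sqrt{\text{residual variance}} =
b\log k + a$ in two stages: a weighted linear fit on the square-root scale
(exactly linear, so no initialisation or local-minimum concerns), refined
by iteratively-reweighted Gauss-Newton least squares on the variance
scale, where the bin estimator is an unbiased mean and the square-root
transformation's small-sample (Jensen and positive-truncation) bias
disappears; zero-residual bins also inform the refined fit. Weights
approximate inverse sampling variance, $n_{\mathrm{obs}}/(k+v+1)^2$. Bins
with $k_{\mathrm{total}}$ below `min_k_total` (default 20) are excluded
from the fit: given $k_{\mathrm{total}} = s$ the squared difference is
bounded by $s^2$, so where the dispersion curve is comparable to the
sampling variance the bin estimator is censored from above and biased
low. Clones at such counts are still tested — the single fitted curve is
extrapolated there, exactly as one curve is applied across all counts in
practice. The sign convention $b \ge 0$ resolves the $(a,b) \to (-a,-b)$
invariance of the squared form. Bins are pooled across all provided pairs
(a pooled cohort fit, the default reading of a multi-donor training set);
per-pair fits are available by calling the chain on single pairs.

## The synthetic-data generator

`simulate_repertoire()` builds a Zipf-like profile (clone $i$ gets mass
$i^{-s}$, default exponent 1.2), standing in for a donor's gDNA pool;
`draw_sample()` is one multinomial draw of templates from it — two draws
from one profile are a technical replicate pair, a pure-sampling null.

`perturb_frequencies()` emulates time-dependent drift: each clone's
frequency is resampled from a beta distribution with mean equal to its
current frequency. The coefficients `(dispersion_a, dispersion_b)`
parameterise the **target residual count-variance curve**
$v_t(k) = (b\log k + a)^2$, and the per-clone concentration is derived as
$c = n_s^2 f(1-f)/v_t - 1$ (the frequency-noise variance that produces a
residual count variance $v_t$ at per-sample depth $n_s$). Deriving $c$
rather than using $v_t$ directly as the concentration is what makes the
calibration exactly well-specified, so that the closed loop — perturb,
sample, bin, fit — recovers the generating coefficients; that recovery is
the package's central correctness check on the whole calibration chain.
Cohort pairs perturb *both* samples independently with `share = 0.5`
each: the count difference then keeps conditional mean zero given
$k_{\mathrm{total}}$ (which the variance-table estimator assumes), while
the pair's total drift variance still matches the target curve.

Recovery is evaluated on `simulate_calibration_panel()`: frequencies
evenly spaced (uniform in frequency) plus one filler clone, so that every
pooled-count bin in the identifiable range is densely and evenly
populated. A Zipf profile is the realistic choice for false-positive-rate
and power studies, but its steep rank-frequency curve leaves mid- and
high-count bins nearly empty, and exact-count binning then starves the
fit; the panel is the designed experiment for the estimator, the Zipf
profile the stress test for the pipeline.

What the generator does **not** emulate: V/J-gene usage or sequence
generation, PCR amplification bias, the fine shape of real donors'
clone-size distributions, sharing of clones between donors, or genuine
antigen-driven responses. Passing tests therefore demonstrate the
statistical machinery under its own assumptions, not assay-level realism.

## The pipeline

`run_diffab()` joins two samples over the union of clone keys
(zero-filling), excludes clones with $k_{\mathrm{total}} < 5$ *before*
testing (`min_total`; the exclusion is part of the multiplicity strategy,
so the Benjamini-Hochberg correction runs across exactly the tested set),
computes the configured model's p-value per clone, adjusts, and classifies
clones with adjusted FDR below 0.01 as `expanded` or `contracted` by the
direction of the frequency change. All thresholds are configuration with
these defaults. The reported fold change $(k_B/n_B)/(k_A/n_A)$ is a
display-only quantity and uses a half-template pseudocount
($\max(k, 0.5)/n$) for zero counts; it never enters testing.
`annotate_overlap()` flags clones present in a reference repertoire
(e.g. a pre-treatment tumour sample) and reports the percentage of
expanded clones found there, `NA` — not zero — when nothing is expanded.

## Study designs and scales

The packaged studies use sizes chosen to make Monte-Carlo uncertainty
small relative to the effects being demonstrated while keeping a full run
in the tens of seconds on one CPU:

* false-positive rate: $10^4$-clone Zipf profile, $10^5$ templates per
  sample; 100 technical-replicate pairs (binomial) and 25 pairs per model
  on drifting pairs, drift curve $a = 2$, $b = 1$ — chosen so that the
  drift standard deviation is a few counts at small $k_{\mathrm{total}}$
  (clearly super-binomial) and a small fraction of $k$ at large counts,
  the qualitative shape of a $( b\log k + a)^2$ residual curve;
* dispersion recovery: $10^4$-clone calibration panel, depth $10^6$,
  50 pairs, bins with at least 50 clones, fit from
  $k_{\mathrm{total}} \ge 30$;
* power: mixtures of two disjoint $10^4$-clone Zipf profiles at ratios
  0.05/0.1/0.25/0.5/1 against the 0.05 baseline (expected fold changes
  1-20 for donor-A-private clones), 15 replicate pairs per ratio,
  binomial model — the mixtures are pure-sampling data, so the
  sampling-only model is the calibrated one for this design and the power
  surface is a property of the testing pipeline, not of a particular
  dispersion fit.

## Numerical choices

* tail sums accumulate log-space mass terms (log-sum-exp); upper tails are
  complements of strictly-lower tails so that the identity
  $p_{\mathrm{lower}} + p_{\mathrm{upper}} = 1 + \mathrm{pmf(obs)}$ holds
  to machine precision;
* two-sided ties use the relative tolerance $1+10^{-7}$;
* beta shapes and predicted dispersions are floored at $10^{-8}$;
* the minimum-likelihood rejection interval is found by binary search on
  monotone flanks (regimes: log-concave for both shapes $\ge 1$, monotone
  when exactly one shape is $\le 1$, full enumeration for the U-shaped
  both-below-1 case and for supports up to 4096);
* degenerate nulls ($k_{\mathrm{total}} = 0$ or
  $k_{\mathrm{total}} = n_{\mathrm{total}}$) are refused with a distinct
  error class — callers filter first.

## Known limitations

* The count-variance-as-concentration convention is inherited as
  published; it makes the test conservative by construction and its
  sensitivity is confined to frequent clones with large fold changes, as
  the power surface shows.
* The binomial two-sided test is only approximately swap-symmetric (see
  above); the beta-binomial depletion rule is exactly symmetric.
* Dispersion is a function of pooled count only — no subject-, interval-
  or covariate-specific dispersion.
* Exact-count binning with a minimum-occupancy filter discards sparse
  high-count bins rather than smoothing them; fitted curves extrapolate
  there.

## A minimal session

```{r example, eval = FALSE}
# calibrate from paired same-subject samples
pairs <- list(
  join_samples(read_repertoire("subj1_week0.tsv"),
               read_repertoire("subj1_week2.tsv")),
  join_samples(read_repertoire("subj2_week0.tsv"),
               read_repertoire("subj2_week2.tsv"))
)
disp <- fit_dispersion(variance_by_total(pairs))

# test a pre/post pair and annotate against a tumour sample
res <- run_diffab(read_repertoire("pre.tsv"), read_repertoire("post.tsv"),
                  diffab_config(model = "beta_binomial", dispersion = disp))
annotate_overlap(res, read_repertoire("tumor.tsv"))$summary
```
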
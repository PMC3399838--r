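---
title: "Genome-bin infinitesimal models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome-bin infinitesimal models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genobin)
```

## The model

A quantitative trait under a polygenic architecture is, in regression
terms, `y_j = b0 + sum_k a_k Z_jk + e_j` with one coded genotype
`Z_jk` per marker. With hundreds of thousands of markers the model is
both too large and too collinear to fit marker-by-marker. genobin takes
the view of the marker-based infinitesimal model: treat the genetic
effect as a function of genome position and approximate the integral of
that function by a finite sum over *bins* — contiguous genome intervals.
Each bin contributes one covariate and one effect, so the model
dimension is the number of bins `m`, not the number of markers `p`.

Genotypes are coded AA = +1, Aa = 0, aa = -1. In an F2 population this
coding has `Var(Z) = 1/2` and, for two loci at recombination fraction
`r`, `Cov(Z_h, Z_l) = (1 - 2r)/2`; both facts are exercised directly by
the test suite against Monte-Carlo simulation. Two covariate
constructions are available:

* **Unweighted bin average** (`bin_average()`): the mean of the coded
  genotypes of the `p_k` markers in bin `k`. Its F2 variance is
  `theoretical_bin_variance()`:
  `(1/p^2) * (p/2 + 2 * sum_{h<l} (1 - 2 r_hl)/2)`, which is 1/2 under
  complete linkage and decays to `1/(2p)` for unlinked markers. Because
  the power to detect a bin scales with this variance, the unweighted
  model needs high within-bin LD (line crosses: F2, BC, DH) and
  reasonably homogeneous effect directions within a bin.

* **Adaptive weighted score** (`single_marker_scan()` +
  `compute_weights()` + `weighted_bin_score()`): each marker first gets
  a least-squares estimate `b_h` from a one-marker-at-a-time regression;
  within each bin the weights `w_h = b_h / mean(|b|)` are signed and
  normalized to unit mean absolute value, and the score is the weighted
  genotype mean. The signs re-align markers whose effects point in
  opposite directions, which rescues binning in populations with low or
  no LD where the unweighted average cancels to noise. The scan is
  deliberately simple regression, not within-bin multiple regression:
  the weights only need to carry relative sign and magnitude, and a
  multivariable scan would reintroduce the dimensionality problem the
  bins exist to remove.

Bin effects are estimated by the Lasso (glmnet backend) minimizing
`(1/2n) * RSS + lambda * sum|gamma|` with an unpenalized intercept.
Covariates enter unstandardized so that the stated objective is the one
actually minimized and a fitted `lambda` is comparable across runs. Bins
with nonzero estimates are tested with an approximate Wald statistic
`W = gamma^2 * SSX / sigma2` and reported as `LOD = W / (2 ln 10)`
with LOD >= 3 as the conventional significance line; bins shrunk exactly
to zero carry no test because the penalty forces their estimation error
to zero. The marginal (single-covariate) variance approximation is a
reconstruction choice: it is the only single-covariate form consistent
with interpreting the per-bin test as an F/Wald test, it is exact when
bin covariates are mutually independent, and it is anti-conservative
when neighbouring bins are correlated — the null-calibration test in the
suite therefore uses unlinked bins.

Predictive value is measured by k-fold cross-validation
(`kfold_cv()`, default k = 10, balanced folds differing by at most one,
seeded): `MSE = mean((y - yhat_oof)^2)` over out-of-fold predictions,
and `predictability()` converts it to `R^2 = 1 - MSE / var(y)`, the
proportion of phenotypic variance predicted out of sample (clipped at 0
when MSE exceeds the phenotypic variance). `scan_bin_sizes()` repeats
this over a grid of bin sizes with a shared fold partition so the
MSE comparison between sizes and modes is paired.

## Tunable parameters

* `bin_size` / `unit` (cM, bp, log10 bp, or a marker count): the key
  resolution/power trade-off. Small bins keep mapping resolution but
  overfit when `m >> n`; large bins stabilize estimation but merge
  distinct QTL. There is usually an interior optimum, which is exactly
  what `scan_bin_sizes()` locates; it also reports a one-standard-error
  band because adjacent sizes are often statistically indistinguishable.
* `lambda`: `"cv"` selects the penalty by seeded k-fold cross-validation
  on a fixed 50-point grid spanning four decades down from the smallest
  all-zero `lambda` (ties toward the larger, more parsimonious value);
  `"pretune"` in `scan_bin_sizes()` selects it once per (size, mode) on
  the full data and holds it fixed across the outer folds — the
  classical predetermined-penalty protocol, cheaper and mildly
  optimistic; a numeric value fixes it, with 0 giving OLS.
* `weights` (`"fold"` or `"whole"`): whether the adaptive scan runs
  inside each training fold (default; no information from the held-out
  fold reaches the covariates) or once on the whole sample. Whole-sample
  weighting is offered as a compatibility switch because it is common
  practice, but it leaks the test fold into the weights and its
  cross-validated R^2 should be read as optimistic.
* MAF threshold (default 0.05) and marker-mean imputation are the only
  QC steps; covariate pre-adjustment (`adjust_covariates()`) regresses
  the trait on treatment-coded co-factors and carries the residuals
  forward, so downstream variances are on the adjusted scale.

## The simulator

`simulate_f2()` generates F2 genotypes gamete by gamete as a Markov walk
along each chromosome: Bernoulli(1/2) at the first marker, then a flip
with the Haldane recombination fraction of each inter-marker distance.
Haldane's map function was chosen because it assumes no interference,
which is what makes the walk Markov; it also fixes the inter-locus
covariance `(1 - 2r)/2` used by `theoretical_bin_variance()`, and the
two are cross-checked against each other by simulation in the tests.

`design_preset()` provides four architectures on a single large
chromosome (heritabilities below follow
`h2 = var_main / (var_main + var_epi + sigma2_e)`):

| design | genome | markers | QTL | genetic variance | notes |
|---|---|---|---|---|---|
| I | 2400 cM | 120,001 (0.02 cM) | 20 oligogenic | 64.12 main + 26.52 epistatic | error variance 10/20/40/100 -> h2 0.64/0.58/0.49/0.34 |
| II | 2400 cM | 120,001 | 20 clusters x 500 small QTL (+/- 5 cM) | 81.94 | error 10/20/50/100 -> h2 0.89/0.80/0.62/0.45 |
| III | 2400 cM | 120,001 | 1000 uniform, first half +, second half - | 81.94 | same error levels |
| IV | 12,000,000 cM | 120,001 (100 cM) | the 20 QTL of design I, no epistasis | 64.12 | no LD; default n = 1000 |

Individual QTL effects in the oligogenic designs are not uniquely
determined by the aggregate variances, so the presets use a documented
palette of variance shares — one major QTL at 15% of phenotypic variance
down to a tail of minor ones near 1%, alternating in sign — rescaled
analytically (through the F2 covariance matrix of the QTL positions) so
the additive variance is exactly 64.12 in expectation; design III draws
seeded normal magnitudes and rescales to 81.94 the same way. Epistatic
pairs in design I are 20 pairs of well-separated loci with equal
|effect| chosen so `sum(g^2)/4 = 26.52` (each product of unlinked F2
indicators has variance 1/4); the realized epistatic variance is
reported empirically rather than asserted. `scale` shrinks the marker
panel (and the QTL count of the polygenic designs) for fast experiments
while preserving genome length, spacing structure and variance targets.

What the simulator does **not** emulate: crossover interference,
outbred/pedigreed populations (RIL, half-sib designs), allele-frequency
spectra other than F2 1:2:1, genotyping error, and linked epistatic
pairs. Tests that pass on these simulations therefore demonstrate the
internal consistency of the method under its own assumptions, not its
behaviour on, say, outbred cattle panels, where LD structure is
irregular and the adaptive weights inherit estimation noise from much
smaller effective effect sizes.

## Numerical choices and degenerate inputs

* Bins are half-open `[start, start + size)` anchored at position 0 per
  chromosome; the final bin is truncated at the chromosome end (the last
  marker's position) and closed there, so bin widths may be unequal but
  every marker belongs to exactly one bin. A small epsilon in the
  position/width quotient keeps markers sitting exactly on a boundary
  (up to floating-point representation) in the right-hand bin.
  Anchoring at 0 rather than at the first marker is a convention; it
  makes partitions at different sizes nest.
* Empty bins are retained in the partition (stable indexing across a
  bin-size scan) but excluded from the design matrix, as are
  all-constant covariates (with a warning).
* Weights in a bin whose mean absolute scan estimate is below 1e-12 are
  set to zero rather than divided out.
* `sigma2 = RSS / (n - df)` uses the Lasso active-set size plus one as
  `df`, the standard degrees-of-freedom estimate for the Lasso; when the
  active set reaches `n` the residual variance is reported `NA` with a
  warning rather than a misleading number.
* QTL are anchored to the nearest marker, ties toward the lower index.
* At `lambda = 0` the coordinate-descent path is run with a deep
  warm-start grid and a very tight convergence threshold; the solution
  agrees with a direct normal-equations solve to better than 1e-6
  relative (tested), so OLS is not special-cased.

## Problem sizes used in the packaged checks

The packaged tests run the full pipeline on scaled-down designs chosen
to keep Monte-Carlo error well below the effects being demonstrated:
the no-LD contrast uses design IV at scale 0.02 (2400 markers,
n = 500, 50 replicates), the bin-size optimum uses design I at scale
0.02 (2400 markers at 1 cM, n = 300, the seven classical sizes 1-100 cM,
50 replicates), and the F2 theory checks use n = 20,000 individuals.
Theory-level quantities (bin counts, heritability algebra, MSE-to-R^2
identities, the complete-linkage variance limit) are checked exactly.

## Worked example

```{r example, eval = FALSE}
library(genobin)

design <- design_preset("I", scale = 0.02, n = 300)
ds <- simulate_dataset(design, seed = 1)

profile <- scan_bin_sizes(ds$genotypes, ds$map, ds$phenotypes,
                          sizes = c(1, 2, 5, 10, 20, 40, 100), unit = "cM",
                          modes = "unweighted", k = 10, seed = 1)
autoplot(profile)
attr(profile, "best")

part <- make_bins(ds$map, attr(profile, "best")$bin_size, "cM")
feats <- bin_average(ds$genotypes, part)
fit <- fit_bins(feats, ds$phenotypes, lambda = "cv", seed = 1)
wald_lod(fit, feats, ds$phenotypes) |> dplyr::filter(significant)
```

## Known limitations

* Adjacent bin sizes at the fine end of a scan differ by less than the
  between-fold standard error of the MSE, so the argmin of a single
  10-fold partition is unstable there; read the optimum from profiles
  averaged over replicates or use the reported one-standard-error band,
  not a lone argmin.
* The Wald variance approximation ignores between-bin correlation, so
  per-bin LOD scores in dense, highly correlated partitions are
  anti-conservative; treat them as a ranking, not calibrated p-values.
* Whole-sample adaptive weighting (`weights = "whole"`) double-uses the
  data; it is provided for comparability, not recommended.
* Bin-by-bin epistasis is not modelled; epistatic variance in the
  simulations goes to the residual, exactly as the additive analysis
  would experience it in practice.
* The simulator is F2-only by design; applying the unweighted model to
  low-LD material is expected to fail (that failure is itself one of the
  packaged checks) and the adaptive model is the supported route there.
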
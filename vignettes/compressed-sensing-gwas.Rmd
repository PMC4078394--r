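---
title: "Sparse marker selection in GWAS as a compressed-sensing problem"
author: "csgwas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse marker selection in GWAS as a compressed-sensing problem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csgwas)
```

## The problem and the model

A genome-wide association study regresses a quantitative phenotype on far
more genotyped markers than it has subjects. The model is the standard
additive one,

$$y = A x + e,$$

with $y \in \mathbb{R}^n$ the phenotype, $A \in \mathbb{R}^{n \times p}$ the
matrix of standardized minor-allele dosages (each column centered and scaled
to unit variance), $x$ a vector of partial regression coefficients of which
only $s \ll p$ are nonzero, and $e$ Gaussian residual noise. The narrow-sense
heritability $h^2$ is the variance of the breeding values $Ax$ when the
phenotypic variance is one, so the residual variance is $\sigma_E^2 = 1 -
h^2$.

Compressed-sensing theory treats $A$ as a sensing matrix and asks when the
support of $x$ — which markers matter, as opposed to how large their effects
are — can be recovered by convex optimization. The answer is organized by two
ratios: the undersampling $\delta = n/p$ and the sparsity $\rho = s/n$. For
noiseless Gaussian-like designs there is a curve $\rho_{L1}(\delta)$ below
which L1 minimization recovers the support with probability approaching one
and above which it fails; with noise the sharp transition becomes a rapid
crossover at smaller $\rho$. Standardized genotype matrices of unlinked
markers behave like such designs: their column covariance approaches the
identity (isotropy; `isotropy_deviation()`) and, once rare alleles are
pruned, no single entry is extreme (bounded coherence; `coherence()`).

## The estimator

The package solves the lasso

$$\hat{x}(\lambda) = \arg\min_x \; \frac{1}{2n}\lVert y - Ax \rVert_2^2 +
\lambda \lVert x \rVert_1$$

by cyclic coordinate descent with the soft-threshold update
$\hat{x}_j \leftarrow S(\hat{x}_j + A_j'r/n,\, \lambda)$, where $r$ is the
current residual and $S(z,\lambda) = \mathrm{sign}(z)(|z|-\lambda)_+$. The
$1/(2n)$ normalization is the one under which this update is exact for
columns with $\lVert A_j \rVert^2 = n$, which is what the package's
population-variance (1/n) standardization guarantees; the same convention
makes the penalty scale of $\lambda$ comparable across sample sizes.

The path runs down a 100-point logarithmic grid from $\lambda_{max} =
\lVert A'y \rVert_\infty / n$ (where the solution is exactly zero) to a
noise-dependent floor

$$\lambda_{min} = \frac{\sigma_E^*}{n}\,\mathrm{median}\,
\lVert A'e \rVert_\infty, \qquad \sigma_E^* = \sqrt{\sigma_E^2 + 1/n},$$

estimated from 1000 Monte-Carlo draws of i.i.d. standard-normal noise
vectors. Each grid point is warm-started at the previous solution.
Convergence at a penalty is declared when the fractional change of the
objective over one sweep falls below $10^{-4}$ (denominator guarded at
$10^{-12}$); a sweep cap of 10,000 flags rather than raises on failure. The
selected support is exactly the nonzero set at the terminal penalty — no
post-hoc magnitude threshold.

Two solver modes produce the same solutions at the stated tolerance: plain
cyclic sweeps over all $p$ coordinates, and an active-set mode that iterates
over an ever-active set and, between inner loops, screens all coordinates
for Karush–Kuhn–Tucker violations with a single BLAS-level gradient
evaluation; it terminates only when no coordinate violates the optimality
conditions. The active-set mode is the default and is what makes
genome-sized paths affordable. Coordinates are visited in fixed index order
1..p; no random permutation, so runs are exactly reproducible.

$\sigma_E^2$ is an input: the true value in simulations, an external
estimate (e.g. from genomic relatedness) on real data. In the noiseless case
$\sigma_E^* = \sqrt{1/n}$, a deliberately conservative floor: it leaves a
small residual shrinkage bias, visible as a nonzero NE asymptote deep in the
recovery phase. Ten-fold cross-validation of the terminal penalty
(`cv_lambda()`) is provided as a data-driven alternative but is an order of
magnitude more expensive and is not used by the default pipeline.

## Simulated study conditions

`simulate_genotypes()` draws dosages per marker as Binomial(2, MAF) across
subjects, standardizes, and places markers at 10-kb spacing on one synthetic
chromosome. Defaults emulate a post-QC common-variant panel: independent
columns with MAF uniform on (0.05, 0.5). Linked markers are available as
contiguous blocks sharing one MAF, each block member copying a latent block
dosage per entry with probability $\sqrt{r}$, which gives within-block
pairwise correlation $\approx r$ — the simplest structure that reproduces
near-diagonal LD bands. What this generator does *not* emulate: realistic
recombination-driven LD decay, allele-frequency-dependent LD, population
structure, relatedness, and missingness patterns of real arrays. Passing
tests therefore certify the method's behavior on an idealized sensing
matrix, which is exactly the regime the theory addresses; they do not
certify performance on structured real cohorts.

Coefficient ensembles (`ensemble_spec()`): equal magnitudes with signs in
$\{-1, 1\}$, or a hyperexponential rank curve $\exp(-i/\tau_1) +
\exp(-i/\tau_2)$, $i = 1..s$, with $(\tau_1, \tau_2) = (0.05s, p)$ or
$(0.2s, p)$ — a few large effects with a long weak tail. The curve is
interpreted as the deterministic ordered-magnitude profile (matching how
such effect-size spectra are usually displayed) rather than as i.i.d. draws
from the mixture density truncated to the top $s$; the decay constants were
arbitrary in origin, and either reading is defensible. Exactly
$\lfloor s/2 \rfloor$ coefficients are flipped negative, removing
sign-imbalance variance at small $s$. Supports are placed uniformly at
random or within a MAF window.

`simulate_phenotype()` rescales the breeding values so their empirical (1/n)
variance equals $h^2$ *exactly* per realization, then adds
$N(0, 1 - h^2)$ residuals; $y$ is not rescaled afterward. Exact rescaling
makes the realized noise level — and hence $\lambda_{min}$ — reproducible
replicate by replicate. The coefficient vector that relates $y$ to $A$ after
rescaling is $c\,x$ with $c = \sqrt{h^2/\widehat{\mathrm{Var}}(Ax)}$; it is
returned by the simulator and is the ground truth for error metrics.

Every stochastic operation takes an explicit seed; replicate $r$ of an
experiment derives an independent substream from (seed, $r$), so whole
phase-plane surfaces are bit-for-bit reproducible.

## Measures of selection

With the truth in hand: the normalized coefficient error
$NE = \lVert x - \hat{x} \rVert_2 / \lVert x \rVert_2$, the false positive
rate, and the positive predictive value (with $FDR = 1 - PPV$). Observable
without the truth: the median P-value of the selected markers
($\mu_{P\text{-}value}$), where each P-value comes from the two-tailed
$t$-test of a univariate regression of $y$ on that marker ($n-2$ degrees of
freedom). Under the null these P-values are uniform, so a selection that
behaves like noise has a median near 0.5; across the transition to good
recovery the median collapses toward zero. Characteristically it first
*rises* with sample size in the poor-recovery region — the relaxing penalty
admits more noise markers — and then falls sharply; the transition detector
therefore uses the last sustained downward crossing.

Proximity-based variants serve real-data comparisons where exact truth is
unavailable: `adjusted_ppv()` credits a selection within an inclusive 500-kb
same-chromosome window of a reference marker (1-based positions;
$|\Delta bp| \le 500{,}000$), and `adjusted_mu_pvalue()` is the median of
the P-values strictly below a significance threshold, divided by the
threshold. Empty selections are reported as missing, never zero — an empty
selection is a failure to select, not a perfect one. `null_adjusted_ppv()`
gives the chance baseline by scoring randomly drawn marker sets of the same
size.

## Phase-plane exploration and transition detection

`run_experiment()` ties the pieces together at one design point (subsample
subjects, re-standardize within the subsample, draw a model, simulate,
solve, score; aggregate replicates by the median — robust at 3–5
replicates). `sweep_rho()`, `sweep_n()` and `sweep_plane()` organize scans;
`theoretical_boundary()` evaluates $\rho_{L1}(\delta)$ from its variational
Gaussian-integral form, maximized numerically over the threshold parameter
(the curve is validated in the tests by Monte-Carlo recovery contours on
small designs, which land within $\pm 0.1$ in $\rho$ of the curve at
$\delta \in \{0.2, 0.5, 0.8\}$).

Verbal transition criteria are formalized as:

* **NE criterion.** Along a $\rho$ scan at fixed $n$: the largest $\rho$
  with median $NE < 0.5$, linearly interpolated between the bracketing grid
  points; censored at the scan edge when every point is below. Along an $n$
  scan: the interpolated sample size at which median NE first drops
  below 0.5.
* **Median-P criterion.** The smallest scanned $n$ from which the median
  P-value, normalized by its maximum over the scan, stays below 0.05.
* **Convergence of the selection measures.** Either the absolute
  good-recovery corner (PPV > 0.95, FPR < 0.001, normalized median-P below
  0.05, sustained), or — when the asymptote itself is not presumed — the
  plateau rule: PPV within 0.05 of its value at the largest scanned $n$ and
  normalized median-P below 0.05, both sustained.

The integer design at a grid point is $n = \mathrm{round}(\delta p)$,
$s = \max(1, \mathrm{round}(\rho n))$, with the stored coordinates
recomputed from the integers.

A marker that is polymorphic in the subject pool can be monomorphic inside
a small subsample; subsample re-standardization maps such columns to exact
zeros (excluding them from that replicate without reindexing), which matters
only for rare-allele spectra.

## Problem sizes used by the shipped analyses

The acceptance analysis and the full-scale tests use $p = 8027$ independent
markers with MAF $\sim U(0.05, 0.5)$ and 3 replicates per grid point: the
sparsity sweeps at $n = 4000$ (noiseless grid $\rho \in [0.2, 0.5]$, noisy
grid $\rho \in [0.01, 0.08]$), the noiseless sample-size scan at $s = 125$
over $n = 250..2500$ in steps of 250, and the noisy scan over
$n = 1000..8000$ in steps of 1000. These sizes resolve each transition to
about one grid step. When a design point analyzes the full pool the
analyzed matrix is the same in every replicate, so the Monte-Carlo penalty
floor is computed once per point; otherwise it is recomputed per analyzed
subsample.

## Known limitations

* The theoretical $\lambda_{min}$ is conservative in the noiseless case;
  the NE asymptote is small but nonzero, and the empirically detected NE
  transitions sit slightly below (earlier than) where smoother criteria
  would place them.
* With heavy noise the NE criterion and the selection-measure criteria
  genuinely diverge: accurate selection occurs well before accurate
  magnitude fitting, so NE-based critical ratios are far more pessimistic
  than PPV- or median-P-based ones. The observable median-P diagnostic is
  the recommended instrument on real data.
* LD is modeled only as exchangeable within-block correlation; real LD
  decay, structure and admixture are out of scope, as are covariates,
  dominance, epistasis, and binary traits.
* Cross-validation folds reuse the full-matrix standardization rather than
  re-standardizing per training fold; at the sample sizes involved the
  difference is $O(1/\sqrt{n})$.
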
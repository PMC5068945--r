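---
title: "Marker scans with a genomic relationship matrix: models, downdates, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marker scans with a genomic relationship matrix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grmgwas)
```

## The model

All of `grmgwas` revolves around the single-marker mixed model

$$ y_i = x_{ij}\,\beta_j + g_i + e_i, \qquad
   \mathbf g \sim N(\mathbf 0,\; \mathbf G\,\sigma_g^2), \qquad
   e_i \sim N(0, \sigma_e^2), $$

where $x_{ij}$ is the centered allele dosage of individual $i$ at marker
$j$, and $\mathbf G = \mathbf X\mathbf X'$ is the genomic relationship
matrix built from all $p$ centered marker columns, optionally scaled by
$1/(p\bar d)$ with $\bar d$ the mean diagonal of $\mathbf X\mathbf X'/p$ so
that its mean diagonal is exactly one. Phenotypes are mean-centered; there
is no further fixed-effect structure in the likelihood. The phenotypic
covariance is $\mathbf V = \mathbf G\sigma_g^2 + \mathbf I\sigma_e^2$, the
GLS estimator is $\hat\beta_j = \mathbf x_j'\mathbf V^{-1}\mathbf y /
\mathbf x_j'\mathbf V^{-1}\mathbf x_j$, and genomic BLUP is
$\hat{\mathbf g} = \sigma_g^2\,\mathbf G\mathbf V^{-1}(\mathbf y -
\mathbf x_j\hat\beta_j)$. Genomic heritability is
$h_g^2 = \sigma_g^2/(\sigma_g^2+\sigma_e^2)$.

## One inversion, many covariance matrices

Testing marker $j$ as a fixed effect while leaving its column inside
$\mathbf G$ means the marker enters the model twice, once through the mean
and once through the covariance. The clean alternative — rebuild and invert
$\mathbf V_{[-j]} = \mathbf V - c\,\mathbf x_j\mathbf x_j'$ for every $j$,
with $c = \sigma_g^2 \cdot \text{scale}_c$ — looks like $p$ inversions, but
the Sherman–Morrison–Woodbury identity collapses it to one:

$$ \mathbf V_{[-j]}^{-1} = \mathbf V^{-1} +
   \frac{c\,\mathbf t_j\mathbf t_j'}{1 - c\,\mathbf x_j'\mathbf t_j},
   \qquad \mathbf t_j = \mathbf V^{-1}\mathbf x_j, $$

with an $m$-column analogue for blocks of markers and for eigenvector
contributions (`rank1_downdate_inv()`, `lowrank_downdate_inv()`,
`eig_downdate_then_marker()`, and `downdate_grm_inv()` for
$\mathbf G^{-1}$ itself). The scalar (or matrix) capacitance
$1 - c\,\mathbf x_j'\mathbf V^{-1}\mathbf x_j$ must stay positive for the
downdated matrix to remain positive definite; the implementation refuses the
downdate when the capacitance falls below $10^{-10}$ relative to
$\mathbf x'\mathbf V^{-1}\mathbf x$, rather than returning a near-singular
inverse. The scaling constant of the GRM is frozen at build time and marker
downdates subtract $\text{scale}_c\,\mathbf x_j\mathbf x_j'$ without
recomputing $\bar d$ — this is precisely what makes the next section's
invariance exact for the scaled matrix as well.

## The marker-out invariance, and its perimeter

With variance components held fixed, the GLS estimate of $\beta_j$ is the
same whether computed with $\mathbf V$ or with $\mathbf V_{[-j]}$, and the
BLUP of $\mathbf g$ is likewise unchanged; the same holds for a block of
$m$ markers tested jointly. The test suite checks this to $10^{-8}$ over a
hundred seeded instances (raw and scaled GRMs, several heritabilities), and
`gls_scan(..., drop_tested = TRUE)` exposes the downdated route so the
identity can be demonstrated on any data set. What is *not* invariant is the
sampling variance: treating the marker as fixed-and-removed, the correct
variance is

$$ \operatorname{Var}(\hat\beta_{j,\text{out}}) =
   (\mathbf x_j'\mathbf V^{-1}\mathbf x_j)^{-1} - c, $$

which `markerout_variance()` computes both in this closed form and as the
explicit sandwich $s_j^{-2}\,\mathbf x_j'\mathbf V^{-1}\mathbf
V_{[-j]}\mathbf V^{-1}\mathbf x_j$; the scan reports the corrected standard
error (`se_markerout`) alongside the naive one rather than replacing it.

During development we found the invariance is broader than the marker case:
if the covariance is modified by *any* term $\mathbf W\mathbf B\mathbf W'$
lying in the span of the fixed design $\mathbf W$, then
$(\mathbf W'\mathbf V_\ast^{-1}\mathbf W)^{-1} =
(\mathbf W'\mathbf V^{-1}\mathbf W)^{-1} - \mathbf B$ and the GLS point
estimate is unchanged. Removing fitted eigenvectors of $\mathbf G$ from the
covariance is exactly such a modification, so at fixed variance components
`pc_adjusted_scan()`'s two modes (`keep_G`, `remove_from_G`) return
identical marker estimates *and* identical marker standard errors (the
$\mathbf B$ correction sits in the PC block). Eigenvector removal matters
through a different channel: the variance partition itself. Discounting a
dominant structure axis from $\mathbf G$ typically moves genomic variance
into the residual — on a simulated two-stratum panel whose trait is
confounded with the leading axis, refitting after removing the top
eigenvector collapses $\hat h^2$ toward zero — and once
$(\sigma_g^2,\sigma_e^2)$ are re-estimated on the edited matrix the two
modes genuinely differ. The command-line `gwas --pc-mode remove` therefore
re-estimates variance components on the edited $\mathbf G$ by default.

## Variance components on the spectrum

With $\mathbf G = \mathbf U\boldsymbol\Lambda\mathbf U'$ and
$\tilde{\mathbf y} = \mathbf U'\mathbf y$, the log-likelihood separates into
$n$ univariate terms with variances $\lambda_i\sigma_g^2 + \sigma_e^2$, so
each evaluation is $O(n)$ after one decomposition (`grm_loglik()`, verified
against the dense multivariate-normal density). `fit_ml()` concentrates the
total variance out — for fixed $h^2$, $\hat\sigma^2_{tot} = \frac1n\sum_i
\tilde y_i^2 / w_i$ with $w_i = h^2\lambda_i + 1 - h^2$ — and maximizes the
resulting one-dimensional profile with Brent's method on
$h^2 \in [10^{-6}, 1-10^{-6}]$ (tolerance $10^{-8}$), evaluating the
boundary values explicitly. A one-dimensional bounded search has no
convergence ambiguity to monitor, which matters when the fit is repeated
once per removed marker or eigenvector.

Two numerical choices deserve emphasis:

* **The contrast space.** Column-centering the markers puts the unit vector
  in the null space of $\mathbf G$, and mean-centering $\mathbf y$ makes the
  data exactly orthogonal to it. A direction with zero eigenvalue *and* zero
  data component contributes $-\tfrac12\log\sigma_e^2$ and nothing else, so
  the full $n$-dimensional likelihood is unbounded as $\sigma_e^2 \to 0$:
  left in, the maximizer is dragged toward the $h^2 = 1$ boundary and the
  heritability estimator is badly biased upward.
  `fit_ml()` drops such data-free, variance-free directions and fits on the
  remaining contrasts — the same accounting REML applies to an estimated
  mean. Directions with zero eigenvalue but nonzero data are kept; they
  inform $\sigma_e^2$.
* **Standard errors** come from the observed information: a central
  finite-difference Hessian of the log-likelihood in
  $(\sigma_g^2, \sigma_e^2)$ with step $10^{-4}$ of each estimate, reported
  as `NA` at boundary optima where the quadratic approximation fails.

So calibrated, the estimator recovers its target: over 50 simulated
replicates ($n = 300$, $p = 1000$, $h^2 = 0.5$) the mean $\hat h^2$ is
within 0.05 of truth, and with no genomic signal ($\sigma_g^2 = 0$,
$n = 500$) $\hat h^2$ falls below 0.1 in at least 90% of replicates — both
assertions live in the test suite and are recomputed on every run.

## Scan statistics and conventions

* OLS residual variance uses $n-1$ degrees of freedom (centered data, one
  slope, no intercept); OLS $p$-values are two-sided Student-$t$, GLS
  statistics are referred to the standard normal, matching their
  large-sample justification.
* GLS $R^2$ is computed on the whitened scale: `whiten_gls()` forms
  $\mathbf V^{-1/2}$ from the spectral square root, after which OLS on the
  transformed data reproduces GLS estimates and standard errors exactly
  (tested to $10^{-10}$), and the per-marker fraction of corrected sum of
  squares is well defined on a common footing with OLS.
* Bonferroni significance uses $\alpha/p_{\text{tested}}$ with
  $\alpha = 0.05$ by default; monomorphic markers are excluded from both the
  scan and the family size, but kept in $\mathbf X$ (all-zero centered
  columns) so the GRM is reproducible.
* The single-marker variance descriptor is $2q(1-q)\beta^2$ for diploid
  0/1/2 coding and $q(1-q)\beta^2$ for binary/inbred coding, with $q$ taken
  from the original (uncentered) dosage means; it assumes linkage
  equilibrium and is a screening metric, not a variance decomposition.
* The mixed-model-equation route (`mme_solve()`) requires an invertible
  $\mathbf G$; since centered-marker GRMs never are, it is the right tool
  for externally supplied full-rank matrices, and the GLS/BLUP "strong-arm"
  route (one factorization of the always-invertible $\mathbf V$) is the
  default elsewhere. The two agree to $10^{-8}$ wherever both apply.

## The simulator: what it emulates and what it does not

`simulate_genotypes()` draws base allele frequencies $q_j \sim
\text{Uniform}(0.1, 0.9)$ and, for each of $K$ subpopulations, jitters them
by $\text{Uniform}(-\delta/2, +\delta/2)$ (clipped to $[0.02, 0.98]$),
then samples dosages $\text{Binomial}(2, q_{jk})$ or, for binary/DArT-like
markers, $\text{Bernoulli}(q_{jk})$. Two subpopulations with $\delta
\approx 0.3$ reproduce the two-cluster geometry of structured breeding
panels (the first MDS axis separates the groups by more than four
within-group standard deviations); many subpopulations with small $\delta$
give diffuse, family-like structure. Phenotypes follow the generative model
exactly, with $\mathbf g$ drawn through the spectral factor of the supplied
GRM. Defaults ($n = 200$, $p = 500$, $h^2 = 0.5$, unit phenotypic
variance) describe a modest breeding panel.

The simulator deliberately omits linkage disequilibrium, a realistic
site-frequency spectrum, calibrated $F_{ST}$, selection, and missingness
patterns. Passing tests therefore certify the linear-algebraic and
likelihood machinery under the model's own assumptions — not robustness to
LD-induced redundancy among markers or to ascertainment, which real panels
exhibit. Every stochastic entry point takes an explicit seed, uses the
Mersenne-Twister/Inversion generators, and restores the caller's RNG state.

## Multidimensional scaling

`classical_mds()` is the Torgerson construction: double-center the squared
distances, take the top-$K$ spectral configuration, report eigenvalues as
fractions of the positive-eigenvalue total (negative eigenvalues flag
non-Euclidean distortion and are excluded from the denominator; a requested
dimension with non-positive eigenvalue is zeroed with a warning).
`nonmetric_mds()` minimizes Kruskal's stress-1 by SMACOF majorization with
pool-adjacent-violators isotonic regression (`stats::isoreg`) for the
disparities, initialized from the classical solution plus three seeded
random restarts, tolerance $10^{-7}$ on the stress decrease, at most 300
iterations per start, best configuration kept. Stress is non-increasing
along each run by construction of the Guttman transform; the nesting
property $\text{stress}(K{+}1) \le \text{stress}(K)$ is asserted in tests
with best-of-restarts. The STRESS reported for the classical fit uses the
configuration distances directly (no monotone transform), so the
conventional 5–10% adequacy rule can be applied to both variants; which
variant produced a number is recorded in the result's `method` field.

## Problem sizes and degenerate inputs

The test suite runs entirely on simulated data at desk scale: invariance
properties on 100 instances of $n = 40$–$60$, $p = 150$–$300$; recovery
experiments at $n = 300$–$500$; oracle comparisons on $8$–$25$-dimensional
random positive-definite matrices. These sizes were chosen so the full
suite completes in well under a minute while the properties being checked
(exact identities, parameter recovery) are scale-free or already stable at
these sizes.

Degenerate inputs are errors, not silent repairs: double centering, dosages
outside the declared coding, all-missing marker columns, phenotype/genotype
ID mismatches, non-PSD matrices offered as GRMs, downdates that would break
positive definiteness, $\mathbf G \propto \mathbf I$ (heritability
unidentifiable), and zero-variance phenotypes. Missing genotypes are
mean-imputed per marker before centering under the default policy, with a
strict `fail` mode available; imputation is a pragmatic default for GRM
construction, not a claim about the best treatment of missingness.

## Known limitations

Single-trait, single-variance-component models only; no fixed-effect
designs beyond the implicit mean; no REML with general $\mathbf X$; no
binary-trait link functions; no LD-aware (leave-one-chromosome-out)
schemes, since the data model carries no map positions; $p$-values are
large-sample. The eigenvector basis within tied eigenvalue blocks is
whatever the decomposition returns — every downstream quantity used
(projections, sums of outer products) is invariant to that choice, so no
canonicalization is attempted.
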
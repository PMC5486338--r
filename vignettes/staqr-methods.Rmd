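---
title: "Structured additive quantile regression for childhood hemoglobin: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structured additive quantile regression: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Childhood anemia is conventionally analysed by dichotomising hemoglobin
(Hb < 11 g/dL in under-fives) and fitting a logistic-type mean model.
That discards information twice: the cut is arbitrary, and a mean model
cannot tell whether a covariate acts differently in the lower tail of the
Hb distribution — which is exactly where anemic children live.  Quantile
regression models the conditional $\theta$-quantile of Hb directly.  The
quantile levels of substantive interest are tied to anemia prevalence:
if 37% of children fall below the 11 g/dL cut-off, the $\theta = 0.37$
conditional quantile describes the Hb level of the marginal anemic child,
and lower levels ($0.15$, $0.21$) describe the more severely affected.
`prevalence_to_theta()` maps an observed prevalence to its quantile level.

## The model

For child $i$ with categorical covariates $x_i$, continuous covariates
$u_{ki}$ and district $d_i$, the structured additive quantile model is

$$Q_{y_i}(\theta \mid \cdot) \;=\; \eta_{\theta i} \;=\;
  x_i'\beta_\theta \;+\; \sum_k f_{\theta k}(u_{ki}) \;+\;
  f_{\theta}^{(sp)}(d_i),$$

estimated by minimising the check loss
$\rho_\theta(u) = u\{\theta - I(u < 0)\}$, or equivalently by maximising
an asymmetric Laplace (AL) likelihood with density
$f(y) = \theta(1-\theta)\sigma^{-1}
  \exp\{-\rho_\theta((y-\eta)/\sigma)\}$,
whose $\theta$-quantile is exactly $\eta$.

Priors follow standard structured additive regression practice:

* fixed effects $\beta_\theta$: diffuse $N(0, 10^6)$;
* each smooth $f_{\theta k}$: a second-order random walk (RW2) on the
  sorted unique covariate values, i.e. a Gaussian Markov random field
  with structure matrix $K = D_2^\top D_2$ penalising squared second
  differences, variance $\tau_k^2 \sim IG(1, 0.005)$;
* the spatial effect: an intrinsic CAR (Besag) GMRF with
  $K = \operatorname{diag}(d) - A$ over the binary district adjacency,
  variance $\tau_{sp}^2 \sim IG(1, 0.005)$;
* the AL scale: $\sigma \sim IG(0.001, 0.001)$.

The three DHS covariates carrying smooths are integer-valued (months /
years), so the observed unique values are treated as an equispaced RW2
grid; no knot selection is involved.

## Estimation: a Gibbs sampler on the AL scale mixture

The AL distribution admits the normal–exponential mixture
$y_i = \eta_i + \xi z_i + \sqrt{\omega^2 \sigma z_i}\,\varepsilon_i$ with
$z_i \sim \text{Exp}(\text{mean } \sigma)$,
$\xi = (1-2\theta)/\{\theta(1-\theta)\}$,
$\omega^2 = 2/\{\theta(1-\theta)\}$.  Conditional on $z$, the model is
Gaussian and every block has a closed-form full conditional:

* $z_i$ is generalised inverse Gaussian $GIG(1/2, a, b_i)$ with
  $a = 1/\{2\theta(1-\theta)\sigma\}$ and
  $b_i = (y_i - \eta_i)^2/(\omega^2\sigma)$, sampled through the
  inverse-Gaussian reciprocal identity ($1/z \sim$ inverse Gaussian);
  the degenerate $b_i \to 0$ case falls back to a Gamma(1/2) draw;
* $\beta$ and every $f$ block are multivariate normal with precision
  (data precision + $K/\tau^2$); because each observation maps to exactly
  one grid point, the data part of every block precision is diagonal and
  the updates are cheap dense Cholesky solves on small matrices;
* $\tau^2$ and $\sigma$ are inverse gamma.

The inner loop is implemented in C++ (RcppArmadillo), as is usual for
MCMC regression packages.  With a Gaussian likelihood the same skeleton
performs conjugate mean-regression updates, so the Model-1 DIC is
computed by literally the same machinery as the quantile models.

**Identifiability.**  The RW2 null space contains constants and linear
trends; the ICAR null space contains component-wise constants.  At every
iteration each structured block is re-centred to sum to zero and the
removed mean is absorbed into the intercept.  Only the constant is
removed: the linear trend inside a smooth is identified by the data and
deliberately left in the smooth (no separate linear fixed effect is
included for smoothed covariates), which is the standard convention and
is what lets a monotone effect such as child age live entirely in
$f(\text{child age})$.  Multi-component spatial graphs would additionally
need per-component intercepts; the package centres globally and all
shipped analyses use connected graphs.

**Numerical safeguards.**  Latent scales are clamped to
$[10^{-12}, 10^{12}]$; a failed Cholesky factorisation is retried with a
small ridge and a non-finite draw aborts the chain with a diagnostic
rather than propagating.  Defaults are 12000 iterations, 2000 burn-in,
thinning 5; the package's own validation fits use 2000–6000 iterations,
which the sampler's fast mixing (independence-like z updates, block
Gaussian moves) makes sufficient for posterior means and medians.

## The frequentist oracle

`fit_linear_qr()` solves linear quantile regression exactly: an
iteratively reweighted least-squares pass on the smoothed check loss
produces a warm start, after which the solution is polished to a vertex
of the underlying linear programme — a basis of $p$ interpolated
observations — and simplex-type pivots are applied until the
subgradient condition $-\theta \le g_j \le 1-\theta$ certifies
optimality (degenerate bases are flagged).  Intercept-only fits
therefore return exact order statistics.  The sampler is validated
against this oracle, not against another Bayesian implementation, so the
two routes are fully independent.

## DIC

For every fit the deviance is $D = -2\sum_i \log f(y_i)$ under the
model's own likelihood.  `compute_dic()` reports
$\bar D$ (average over stored draws), $D(\hat\eta, \hat\sigma)$ at the
posterior means, $p_D = \bar D - D(\hat\eta,\hat\sigma)$ and
$DIC = \bar D + p_D$.  `dic_identity()` is the arithmetic complement
$DIC = D + 2 p_D$ used to check reported comparison tables for internal
consistency.  Comparing an AL-likelihood DIC with a Gaussian one follows
the established usage for this model ladder; it is meaningful exactly
because both deviances are on the same $-2\log f$ scale.

## The synthetic data generator

The restricted survey micro-data cannot be shipped, so
`generate_dataset()` draws child records whose structure mirrors the
survey extract the models were designed for:

* $n = 3248$ children by default; child age uniform on 0–59 months,
  mother's age at birth uniform on 15–49 years, breastfeeding duration
  uniform on 0–36 months; ten categorical covariates with the survey's
  published marginal frequencies; districts uniform over a 30-node
  (5 × 6) rook lattice standing in for the administrative map.
* True categorical effects of ±0.1–0.4 g/dL with the published signs
  (fever, wasting, underweight, maternal anemia, illiteracy and low BMI
  harmful; male sex, vitamin A and wealth protective).
* Smooth truths are fixed piecewise polynomials with the documented
  shapes: child age increasing and concave; mother's age negative before
  20, positive through the twenties, dipping near 35 and rising again;
  breastfeeding declining to ~10 months then an inverse U peaking near
  25 months.  All are centred to mean zero over their grids.
* The spatial truth is the smoothest non-constant eigenvector of the
  ICAR structure matrix scaled to sd 0.2 g/dL — a deterministic,
  spatially clustered field on any graph.

**Noise calibration (done once, at design time).**  The default noise is
a two-component normal mixture
$0.9\,N(0.240, 0.957^2) + 0.1\,N(-2.159, 2.124^2)$ whose parameters were
solved, jointly with the variance contributed by the true effects, to
meet four targets: marginal mean 11.25 g/dL, marginal sd 1.41 g/dL,
37% of children below 11 g/dL, and a lower tail heavy enough that an AL
fit at $\theta = 0.37$ attains a per-observation log score on a par with
(slightly above) a Gaussian fit — the relationship the survey's own
model-comparison table exhibits.  The last target matters: with a
mildly skewed but thin-tailed noise the Gaussian mean model would win
every DIC comparison for reasons that have nothing to do with the
spatial or nonlinear structure.  A `"gaussian"` noise option
(sd 1.339) and an `"asymmetric-laplace"` option
($\sigma = 0.427$, so the marginal variance matches) are provided; the
AL option puts the $\theta$-design-quantile of the noise at exactly
zero, making the true quantile surface equal to the structural
predictor — that is what the parameter-recovery tests use.

**What the generator does not emulate.**  Survey design (weights,
stratification, clustering), the real administrative adjacency,
joint dependence among categorical covariates (they are drawn
independently), altitude adjustment, and measurement rounding of Hb.
Passing recovery tests on these data therefore demonstrates that the
estimation machinery works, not that the substantive survey findings
are reproduced.

The separate `table1_fixture()` reconstructs the published
cross-tabulation exactly from its printed counts; since only each
variable's two-way margin with anemia status is published, variables are
laid out independently within the anemic and non-anemic row blocks, and
a variable whose published total falls short of the block size is `NA`
on the remaining rows.

## Problem sizes used in the shipped validation

The test-suite fits are deliberately moderate: sampler-vs-oracle checks
use $n = 3000$ with 6000 iterations; Model-5 parameter recovery uses ten
replicates of $n = 4000$ (AL noise) with 6000 iterations; the DIC
ladder selection uses ten replicates of the full five-model ladder at
$n = 3248$ with 3000 iterations.  Recovery is summarised by the median
across replicates of the Pearson correlation between posterior-mean and
true curves (the median is used because a single replicate's
correlation is itself a noisy statistic), together with the pooled
coverage of the 95% credible intervals over all fixed effects and
replicates.

## Known limitations and conventions

* Anemia category bounds use half-open intervals
  $[0,7)$, $[7,10)$, $[10,11)$, $[11,\infty)$; Hb is recorded to
  0.1 g/dL, so this is observationally identical to the conventional
  7–9.9 / 10–10.9 labels.
* Cross-tabulation chi-squares are classical Pearson statistics; the
  published survey table embeds complex-survey corrections that are
  deliberately not reproduced (e.g. the raw chi-square for child sex is
  far from the published p-value), and a few published row percentages
  are inconsistent with their own counts — counts are treated as
  authoritative.  Display percentages are rounded half-up to one
  decimal.
* Separate fits are run per quantile level; no quantile-crossing
  adjustment is applied across levels, matching how per-level results
  are usually reported.
* Each model-ladder comparison is emitted per quantile level.
* An unstructured child-level random effect (`re()`) is supported but
  excluded from the default ladder, whose top model combines fixed,
  smooth and spatial terms only.
* The exact QR solver flags, but does not enumerate, non-unique vertex
  solutions (degenerate dual bases).
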
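---
title: "Latent-variable modelling of seasonal cheese profiles with block-missing data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent-variable modelling of seasonal cheese profiles with block-missing data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pecomics)
```

## The model

Profiles are modelled by probabilistic principal component analysis: each
sample $x \in \mathbb{R}^p$ (here $p = 81$: 73 %FAME variables and 8
minerals) is

$$x = W z + \mu + \varepsilon, \qquad z \sim N(0, I_q), \qquad
\varepsilon \sim N(0, \sigma^2 I_p),$$

so the marginal is $x \sim N(\mu,\, W W^\top + \sigma^2 I)$. The point of
the probabilistic formulation is missing data: a sample observed only on a
coordinate subset $o$ still has a tractable marginal
$N(\mu_o,\, W_o W_o^\top + \sigma^2 I)$, so mineral-only *partial* samples
contribute to the likelihood, and any sample's latent posterior
$p(z \mid x_o)$ and conditional reconstruction $E[x_{\text{miss}} \mid
x_o] = \mu_{\text{miss}} + W_{\text{miss}}\, E[z \mid x_o]$ are available
in closed form. On complete data the maximum-likelihood solution coincides
with the classical PCA eigendecomposition, which the test suite checks
directly.

### EM over arbitrary masks

`fit_ppca()` maximises the observed-data likelihood by EM, treating both
the latent scores and the missing coordinates as latent variables. The
E-step computes, per missingness pattern (the study design has only two:
fully observed, and mineral-only), the posterior moments of $z$ and the
conditional moments of the missing block; the M-step updates $(\mu, W)$ by
one joint weighted regression and $\sigma^2$ in closed form. Because the
M-step is exact, the observed-data log-likelihood is non-decreasing at
every iteration; the fitter records the trace and the tests assert
monotonicity to $10^{-8}$. Samples sharing a mask are processed as one
matrix block, so the two-pattern design costs two sets of matrix products
per iteration regardless of sample count.

Numerical choices:

- **Initialisation** is deterministic: eigendecomposition of the
  mean-imputed covariance, with $\sigma^2_0$ the mean of the trailing
  eigenvalues. On complete data this *is* the ML solution, so EM starts at
  the optimum and simply verifies stationarity. A random initialisation is
  available behind a seed.
- **Convergence** is declared at a relative log-likelihood change below
  `tol` (default $10^{-8}$; the Monte-Carlo drivers use $10^{-7}$ with a
  2000-iteration cap). Non-convergence returns the model with
  `converged = FALSE` plus a warning rather than an error, since a
  near-converged model is still usable inside a validation sweep.
- **Canonical orientation**: after convergence $W$ is rotated by its SVD so
  $W^\top W$ is diagonal with descending entries (ordered principal axes),
  and each component's sign is fixed so its largest-magnitude loading is
  positive. Scores, loadings and boundaries are therefore reproducible
  across runs.
- $\sigma^2$ is floored at $10^{-12}$ so exactly collinear (noise-free)
  data cannot produce a degenerate likelihood.
- **Explained variance** per component is $d_k^2 / \operatorname{tr}(S)$,
  with $d_k$ the singular values of $W$ and $\operatorname{tr}(S)$ the
  total per-variable variance of the observed fitting data. The fractions
  are descending and sum to at most 1; the noise floor $\sigma^2$ absorbs
  the rest.
- Fully missing rows are excluded from fitting (they carry no likelihood
  information) but score at the prior mean and reconstruct to $\mu$.

## Classification and comparators

`fit_lda()`/`classify_lda()` implement the centroid form of linear
discriminant analysis in score space: equal priors, pooled within-class
covariance, assignment by minimal Mahalanobis distance, deterministic
tie-break by class order. Equal priors (rather than empirical frequencies)
match the balanced design and give the equal-distance linear boundaries
exported by `lda_boundaries_2d()` for the 2-PC view. By default the
validation driver classifies on *all* retained components; the
2-component restriction is a visualisation view, available behind
`lda_components = "two"`. The model-order sweep makes the all-components
reading the operative one — the order is selected by validation %CC, which
would be meaningless if classification ignored components beyond the
second.

The PLS comparators (`fit_pls()`, `fit_plsda()`) use NIPALS with deflation
of both blocks, one-hot $\{0,1\}$ class coding with argmax decoding, and
internal autoscaling from calibration statistics. They see only the
8-variable mineral block, the study's fully observed predictor set, so
their latent-variable count is bounded by 8. At a saturated number of
latent variables the coefficients equal ordinary least squares, which is
the oracle the tests compare against; no claim is made of equivalence to
any specific published PLS variant beyond that limit.

## Preprocessing

"Unit variance" preprocessing is implemented as full autoscaling
(centre by the mean, divide by the SD with the $n-1$ denominator), computed
over observed cells only. Centring is included even though PPCA estimates
$\mu$ regardless, because autoscaling is the chemometrics norm and makes
the scale-heterogeneous variables commensurable. The scaler is fitted on
each Monte-Carlo calibration set and applied to the corresponding
validation samples, never the reverse, so no validation information leaks
into the preprocessing; a test asserts this by perturbing validation
values and checking the scaler is unchanged.

## The validation protocols

**Classification (hybrid cross + external).** Per iteration and month,
`round(0.85 n)` of the complete samples (at least one left out) are drawn
into calibration; the rest are the internal cross-validation pool. The
partial samples are divided once per run: about a third per month (at
least one) form a fixed external pool that is never calibrated on across
all iterations; the others join every calibration set. On the default
design this reproduces per-month calibration cells (10, 2), (10, 2),
(8, 4) and validation cells (2, 1), (2, 1), (1, 2), a 36/9 calibration/
validation split whose partial fractions (22% of calibration, 44% of
validation) sit inside the protocol's 15–35% and 30–65% bands for every
seed. %CC is reported over all validation samples, with internal/external
breakdowns alongside. The same per-iteration splits are reused across
model orders, so order comparisons use common random draws.

**Imputation (Monte-Carlo CV).** Per iteration, `round(0.2 n)` complete
samples per month (at least one) lose their %FAME block; the model is
fitted on the remainder (PPCA also uses the partial samples; PLSR only the
complete ones, since its response block must be observed) and predicts the
held-out %FAME from the minerals. Residuals are pooled within an
iteration; the curves report per-iteration RMSECV and $R^2$ (in percent,
with total deviations taken about the calibration %FAME means) averaged
over iterations. Metrics are computed on the autoscaled scale, where
RMSECV ≈ 1 means errors as large as a variable's natural spread, and are
also exported on the original measurement scale since it is not obvious
which scale a given published error value refers to. Truly partial samples
have no %FAME ground truth, so imputation metrics use only held-out
complete samples; classification correctness, by contrast, uses the known
month labels of all validation samples.

Selected order: argmax of mean %CC or $R^2$, argmin of RMSECV, ties toward
the smaller order.

## Tukey comparisons from summary statistics

Macro-composition parameters are compared across months directly from
published per-month mean ± SD with `tukey_from_summary()`: pooled
within-group variance from the SDs, studentized-range statistic with the
Tukey–Kramer harmonic-mean correction for unequal $n$, p-values from
`ptukey` with $\sum(n_i - 1)$ error degrees of freedom. Per-month $n$ is
taken as 15 (45 samples over 3 balanced months) — an assumption, since the
published table reports only mean ± SD. `assign_letters()` builds the
compact letter display from the maximal mutually-non-significant cliques,
lettered in order of descending group means. Under these inputs the fat
and protein parameters separate April from June sharply while ash,
moisture and the proteolysis indices show no significant pair; a few
published letter pairs (NaCl, pH, the January–June fat contrast) are not
reproducible from the printed summary statistics at any plausible $n$ and
are not asserted.

## What the generator emulates — and what it does not

`generate_dataset()` draws exactly the structure the analysis assumes:
$x = \mu + W_{\text{true}}(z_0 + \delta_{\text{month}}) + \varepsilon$
with $z_0 \sim N(0, I_{q_{\text{true}}})$, isotropic noise, and the block
missing design (per-month complete/partial counts 12/3, 12/3, 9/6).
Defaults, chosen once as the package's study conditions:

- $q_{\text{true}} = 5$ with geometrically decaying axis scales
  $2.2 \times 0.7^{k-1}$ — five genuine components, so the model orders a
  practitioner would select (5–7) are sensible, and all five axes are
  strong enough at $n = 2000$ samples for the loading subspace to be
  re-estimated to a few hundredths of a radian.
- noise SD 1 against per-variable signal SDs of roughly 3, giving a
  5-component model that explains ~85% of the total variance with PC1/PC2
  around 48%/24%.
- class separation injected in latent space ($\pm 1.5$ prior-SD units on
  the first two axes: January and April positive on axis 1, June negative;
  April positive on axis 2, January negative) so the 2-PC score geometry
  shows three separated month clusters.
- mineral loadings on axes 1–2 oriented by a fixed sign pattern with
  deterministic magnitudes: S, P, Ca tracking April; K, Zn tracking
  January; Na tracking June; Fe weakly winter-leaning; Mg near-inert. A
  test estimates class-conditional mineral means at large $n$ and checks
  the implied month maxima. The magnitudes (`mineral_strength = 0.35`
  relative to the axis scales) keep the mineral block informative but
  subordinate: the 73-variable FAME block carries most of the class
  signal, so the full-profile PPCA+LDA route outperforms the mineral-only
  PLS-DA comparator — the regime the comparison is about.
- heterogeneous per-variable scales (log-normal row factors on
  $W_{\text{true}}$ and $\mu$), so unit-variance preprocessing is
  consequential; the noise stays isotropic, keeping the generator exactly
  inside the PPCA model class.
- a shared within-class covariance across months (the homoscedastic
  assumption LDA makes); the study gives no information about
  between-season covariance differences, so none are simulated.

What passing tests on this generator show is that the *pipeline* is
correct: estimators match their closed-form/brute-force oracles, the
protocol bookkeeping is exact, and recovery behaves as theory predicts
when the model is well-specified. They do not show that real cheese
profiles satisfy the model: real %FAME data are compositional
(non-negative, closing to ~100%), skewed, and chemically correlated in
ways no low-rank Gaussian captures, and real headline numbers (e.g. a
98% classification accuracy or $R^2 > 99$%) depend on that private data's
signal-to-noise ratio, which the defaults make no attempt to match.

## Problem sizes used in the tests and acceptance run

The suite exercises the full 45 × 81 design with 20 Monte-Carlo
iterations for the protocol checks, $n = 2000$ for parameter recovery,
$n \approx 10^3$–$10^4$ per-class draws for distributional checks, and
tiny (6 × 3) instances for the direct-likelihood oracle. These sizes keep
every oracle comparison sharp while the whole suite runs in a couple of
minutes on one core.

## Known limitations

- No compositional treatment of %FAME (no closure constraint or log-ratio
  transforms); the generator and model treat variables as unconstrained
  Gaussians.
- PPCA assumes isotropic residual noise after autoscaling; strongly
  heteroscedastic residuals would call for factor analysis instead.
- The CLD letters use a greedy maximal-clique enumeration that is exact
  for the 3-group case used here but exponential in the number of groups.
- `fit_ppca` is an O(patterns × p × q) per-iteration pure-R implementation;
  it is fast for block patterns but slows when every row has a distinct
  random mask and hundreds of EM iterations are needed.
- Monte-Carlo iterations are seed-indexed and sequential; there is no
  parallel execution.
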
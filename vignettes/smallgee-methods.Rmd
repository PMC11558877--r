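---
title: "Small-sample GEE for binary outcomes: models, corrections, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Small-sample GEE for binary outcomes: models, corrections, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smallgee)
```

## The marginal model

For cluster $i = 1,\dots,K$ with $n_i$ binary observations, the mean
model is $\operatorname{logit}\mu_{it} = x_{it}^\top\beta$ with working
covariance $V_i = \phi A_i^{1/2} R_i(\alpha) A_i^{1/2}$,
$A_i = \operatorname{diag}(\mu_{it}(1-\mu_{it}))$. Coefficients solve the
estimating equation $U(\beta)=\sum_i D_i^\top V_i^{-1}(Y_i-\mu_i)=0$,
$D_i = \partial\mu_i/\partial\beta^\top = A_iX_i$ for the logit link.
Only the marginal mean is modeled; $R(\alpha)$ is a working assumption
and neither the point estimates nor the robust covariances require it to
be correct. Only the logit link and binary outcomes are supported: the
Firth-type penalized equation below is developed for this case, and all
derivative formulas use the logistic variance function.

Fitting is Fisher scoring: $\beta \leftarrow \beta + \Phi^{-1}U$ with
$\Phi = \sum_i D_i^\top V_i^{-1}D_i$, and after every coefficient update
the nuisance parameters are refreshed from Pearson residuals
$e_{it} = \hat\varepsilon_{it}/\sqrt{\mu_{it}(1-\mu_{it})}$:

* scale: $\hat\phi = \sum e_{it}^2/(\sum n_i - p)$, or fixed at 1;
* exchangeable: $\hat\alpha = \sum_i\sum_{t<t'} e_{it}e_{it'} /
  \{\hat\phi\,(\sum_i n_i(n_i-1)/2 - p)\}$;
* AR(1): lag-one cross-products over adjacent occasion positions,
  divided by $\hat\phi\,(m - p)$ where $m$ counts the adjacent pairs
  actually available (equal to $\sum_i(n_i-1)$ without occasion gaps;
  under gaps only true lag-one pairs enter, which keeps the estimator
  honest for unbalanced visit schedules);
* unstructured: each occasion pair $(t,t')$ separately, denominator
  $\hat\phi\,(K_{tt'} - p)$ with $K_{tt'}$ the number of clusters
  observed at both occasions.

These are the classical moment estimators with a $p$
degrees-of-freedom correction throughout; the convention was confirmed
by reproducing the published wheeze-study grid to three decimals (see
the acceptance tests). Moment estimates outside the admissible range
(exchangeable: $(-1/(n_{\max}-1),\,1)$; AR(1): $(-1,1)$) are clamped to
0.99 of the violated boundary with a warning rather than aborting —
with very few clusters the raw estimate can legitimately stray, and a
clamped interior value keeps every $R_i$ positive definite.

Starting values come from ordinary logistic regression (GEE, BCGEE) or
Firth logistic regression (PGEE) treating observations as independent.
Convergence is declared when the maximum absolute coefficient update
falls below `tol` ($10^{-5}$ by default, at most `maxitr` = 50
iterations); the max-abs metric was chosen over a relative one because
coefficients on the logit scale have a natural unit. Step-halving (up
to 10 halvings) rejects any update that inflates the sup-norm of the
(penalized) score, which stabilizes near-separated small samples. If a
coefficient passes 50 in absolute value the fit warns that the data may
be separated and suggests PGEE. Non-convergence is a warning plus a
flag on the returned object, never an error, so grid summaries can
record it per combination.

## Bias-corrected GEE

The second-order bias of the GEE estimator is
$$b_r = \sum_s \kappa^{rs}\sum_{u,v}\Big[\kappa_{su,v} -
\tfrac12\sum_{k,\ell}\kappa^{k\ell}\kappa_{sv\ell}\kappa_{u,k}\Big]\kappa^{uv},$$
with $\kappa_{rs}=\mathrm E[\partial U_r/\partial\beta_s]$,
$\kappa_{r,s}=\mathrm E[U_rU_s]$,
$\kappa_{rsu}=\mathrm E[\partial^2U_r/\partial\beta_s\partial\beta_u]$,
$\kappa_{rs,u}=\mathrm E[(\partial U_r/\partial\beta_s)U_u]$, and
$\kappa^{rs}$ the inverse of $[\kappa_{rs}]$. The corrected estimate is
the one-step subtraction $\hat\beta_{\mathrm{BC}} = \hat\beta - b$.

The cumulants are defined as expectations, so plug-in rules are needed.
The package evaluates:

* $\kappa_{rs}$ and $\kappa_{rsu}$ analytically with $Y$ replaced by
  $\hat\mu$ (residual terms have zero mean; under the canonical link
  $[\kappa_{rs}] = -\Phi$ exactly);
* $\kappa_{r,s}$ and $\kappa_{u,k}$ empirically as
  $\sum_i (D_i^\top V_i^{-1}\hat\varepsilon_i)_r
  (D_i^\top V_i^{-1}\hat\varepsilon_i)_s$ — the sandwich meat. Using
  observed residual cross-products here, instead of a model-based
  $\mathrm{Cov}(Y_i)$, is what keeps the correction valid when the
  working correlation is misspecified;
* $\kappa_{rs,u}$ empirically with the derivative factor centered at
  its model-based mean,
  $\sum_i \{(\partial G_{i,r}/\partial\beta_s)\hat\varepsilon_i\}\,
  (G_{i,u}\hat\varepsilon_i)$ with $G_i = D_i^\top V_i^{-1}$: for
  independent clusters the cross-cluster terms of the defining
  expectation vanish because $\mathrm E[U^{(i)}]=0$, so only the
  zero-mean part of the derivative contributes.

$\alpha$ and $\phi$ are held fixed while differentiating $U$, the
standard simplification in this literature. $\kappa_{rs}^{(u)} =
\partial\kappa_{rs}/\partial\beta_u$ is computed (it is the negative of
the information derivatives used by the penalty below) and retained for
cross-checking, though the bias contraction above does not use it.

Two conventions around the one-step correction deserve note. First, the
correction is applied once, not iterated — the corrected estimate is an
explicit functional of the converged fit. Second, after subtracting
$b$, the per-cluster quantities and $\Phi$ feeding the covariance
estimators are re-evaluated at $\hat\beta_{\mathrm{BC}}$ **with
$\hat\phi,\hat\alpha$ kept at their converged values from the
uncorrected fit**. The sandwich-type estimators are invariant to $\phi$
so this choice is invisible for them, but the Morel estimator is not;
keeping the converged nuisance values is both internally consistent
with the one-step reading (the nuisance estimators belong to the solved
equation) and reproduces the published wheeze results exactly, whereas
re-estimating $\phi$ at the corrected coefficients does not.

The bias contraction is implemented as vectorized matrix products; the
test suite checks it against a literal five-index loop, against a
hand-reduced scalar ($p=1$) case, and against central finite
differences of the estimating function on a $K=5$, $n_i=2$ problem, and
verifies the $O(1/K)$ scaling law by replicating clusters.

## Penalized GEE

The penalized equation adds $g_r = \tfrac12\,
\mathrm{tr}[\Phi^{-1}\partial\Phi/\partial\beta_r]$ to each score
component. With $R$ and $\phi$ fixed, $\beta$ enters
$\Phi = \phi^{-1}\sum_i X_i^\top A_i^{1/2} R_i^{-1} A_i^{1/2} X_i$ only
through $A_i$, with $\partial A_i/\partial\beta_r =
\operatorname{diag}(\mu''\,x_{\cdot r})$, $\mu'' = \mu(1-\mu)(1-2\mu)$;
the product rule over both $A^{1/2}$ factors gives
$\partial\Phi/\partial\beta_r$ in closed form. For clusters of size one
with independence and $\phi=1$ the penalty collapses to the classical
Firth modified score $X^\top\{h\,(\tfrac12-\mu)\}$ with $h$ the weighted
hat diagonal, which the tests verify, along with finite-difference
checks of $\partial\Phi/\partial\beta_r$ and finiteness under complete
separation.

Two open choices were resolved as follows: the Newton step uses $\Phi$
as the Jacobian (Fisher-scoring convention for Firth-type equations;
$\partial g/\partial\beta$ is omitted and step-halving guards the
iteration), and $\phi$ is profiled on unpenalized Pearson residuals —
the penalty modifies the score, not the residual variance model.

## The covariance menu

All estimators share the bread $\Phi^{-1}\{\cdot\}\Phi^{-1}$ and differ
in the meat. With $H_{ij} = D_i\Phi^{-1}D_j^\top V_j^{-1}$ (cluster
leverage; $\sum_i \operatorname{tr} H_{ii} = p$):

| method | meat |
|---|---|
| SA | $\sum_i g_i g_i^\top$, $g_i = D_i^\top V_i^{-1}\hat\varepsilon_i$ |
| MK | $K/(K-p)$ times SA |
| KC | residuals pre-multiplied by $(I-H_{ii})^{-1/2}$ |
| MD | residuals pre-multiplied by $(I-H_{ii})^{-1}$ |
| FG | $g_i$ scaled by $F_i = \operatorname{diag}\{1-\min(\delta,[N_i]_{ss})\}^{-1/2}$, $N_i = D_i^\top V_i^{-1}D_i\Phi^{-1}$ |
| PA | pooled middle matrix $\frac1K\sum_j A_j^{-1/2}\hat\varepsilon_j\hat\varepsilon_j^\top A_j^{-1/2}$ re-inserted per cluster |
| GS | $K/(K-p)$ times PA |
| MB | $\Psi + \gamma_1\gamma_2\Phi$, $\Psi$ from centered $d_i = D_i^\top V_i^{-1}\hat\varepsilon_i$ |
| WL / WB | PA-style pooling of MD- / KC-inflated residuals |
| FW | the average of KC and MD |
| FZ | MD-style bread around $\hat\varepsilon_i\hat\varepsilon_i^\top - \sum_{j\ne i}H_{ij}\hat\varepsilon_j\hat\varepsilon_j^\top H_{ij}^\top$ |

Numerical and interpretive choices:

* $(I-H_{ii})^{-1/2}$ is the principal matrix square root via
  eigendecomposition; $I-H_{ii}$ is nonsymmetric, so complex pairs can
  occur in principle, and an imaginary remainder above $10^{-8}$ is an
  error rather than silently truncated. This preserves the
  $(S\varepsilon)(S\varepsilon)^\top$ structure of the KC/WB middle
  factor.
* The Fay–Graubard truncation $\delta$ defaults to 0.75 (the value
  recommended in the original proposal) and is exposed as an argument.
* In FZ, the leading inflation matrix is read as $(I - H_{ii})$ — the
  only dimensionally consistent reading.
* In MB, $\Psi$ carries the literal factor
  $(\sum n_i - 1)/(\sum n_i - p)\cdot K/(K-1)$, $\gamma_1 =
  \min(0.5,\,p/(K-p))$, $\gamma_2 = \max(1,\,
  \operatorname{tr}(\Phi^{-1}\Psi)/p)$, and $d_i$ uses the working
  $V_i$ (not its independence version) when a non-trivial structure is
  fitted.
* The pooled middle matrix of PA/GS/WL/WB is accumulated on the pooled
  occasion grid and the per-cluster submatrix re-selected, which equals
  the printed balanced-data formula exactly and extends it to unequal
  cluster sizes.
* FZ is not guaranteed positive semidefinite; a negative diagonal
  entry yields `NaN` standard errors with a warning. Negatives within
  numerical roundoff of zero (relative $10^{-12}$) are treated as zero.
* For BCGEE and PGEE fits every estimator is evaluated at that method's
  own coefficients and residuals, so each method column of a grid has
  its own twelve standard errors.

Degenerate-case anchors: for clusters of size one with independence and
fixed scale, SA, KC and MD coincide with the HC0, HC2 and HC3
heteroskedasticity-robust estimators for logistic scores, which the
tests verify against an independently coded per-observation
implementation.

## The synthetic-data generator

`simulate_binary_clusters()` draws each cluster by thresholding a
latent multivariate normal: for occasions $s,t$ with marginals
$\mu_s,\mu_t$ and target binary-scale correlation $\rho_{st}$
(exchangeable $\rho$ or AR(1) $\rho^{|s-t|}$), the latent correlation
$r_{st}$ solves $\Phi_2(z_s, z_t; r) = \mu_s\mu_t +
\rho_{st}\sqrt{\mu_s(1-\mu_s)\mu_t(1-\mu_t)}$, $z = \Phi^{-1}(\mu)$.
This construction was chosen over odds-ratio-based ones because it
controls the marginals exactly — logit $\mu_{it} = x_{it}^\top\beta$
holds by construction — and targets precisely the binary-scale
correlation that the moment estimator $\hat\alpha$ measures. The
bivariate normal probability is computed by one-dimensional quadrature
of $\phi(z)\,\Phi\{(z_t - rz)/\sqrt{1-r^2}\}$ (`stats::integrate`,
relative tolerance $10^{-12}$), and $r$ by bisection to $10^{-10}$;
solved pairs are cached. Targets outside the Fréchet-compatible range
for the implied margins raise an error that reports the attainable
interval. Output is fully determined by the seed through R's default
Mersenne–Twister stream.

Default study conditions mirror the package's intended regime:
clusters of size 4 (the wheeze design's four annual visits), a
cluster-level binary covariate, within-cluster correlation 0.3 — a
moderate value typical of repeated binary health outcomes — and
simulation sizes $K=500$ with 200 replicates for consistency checks and
$K=20$ with 500 replicates for the small-sample regime, $K=20$ being
the smallest size at which the published simulation literature on these
corrections operates. `wheeze_like_fixture()` emulates the wheeze
schema (16 children × 4 ages, city and maternal-smoking covariates,
AR(1) correlation 0.3, wheeze risk declining with age) for pipeline
tests.

What the generator does **not** emulate: covariate-dependent or
time-varying correlation, informative cluster sizes, missing-data
mechanisms (dropout), and overdispersion beyond the binary variance
($\phi$ is 1 in truth). Passing recovery tests therefore demonstrate
correctness of the estimating machinery under a clean exchangeable/AR(1)
truth, not robustness to those real-data features.

## Data handling

Long-format data are split by cluster identifier; when an occasion
variable is supplied, rows are sorted by it within cluster (occasion
labels are categorical positions, not numeric times — a gap of two
visits contributes $\alpha^2$ under AR(1) via positions, and
unstructured estimation aligns clusters on the pooled label set) and
duplicates within a cluster are an error. Without an occasion variable,
cluster rows must be contiguous and file order is kept. Rows with
missing values in the outcome or any model term are dropped with a
logged count — complete-case analysis is the minimal defensible default
for an estimating-equation method, and the count is surfaced so the
user can judge. Design matrices use standard treatment coding with the
lowest-sorted factor level as reference; rank-deficient designs are
rejected at construction.

## Known limitations

Binary outcomes and the logit link only. No covariance-inflation
adjustments, no degrees-of-freedom–adjusted $t$ inference (Wald tests
use the standard normal), no QIC or other selection criteria, no
weights or offsets, no user-supplied fixed correlation matrices, and no
m-dependent structures beyond AR(1). The FZ estimator can be indefinite
by construction; its `NaN` standard errors are a feature, not a bug.
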
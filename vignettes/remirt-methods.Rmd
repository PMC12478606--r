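---
title: "Regularized variational estimation for multi-group DIF detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regularized variational estimation for multi-group DIF detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

When item response data are pooled across studies or demographic groups,
some items may function differently in different groups even for
respondents with the same underlying trait level — differential item
functioning (DIF). Ignoring DIF contaminates any score comparison across
groups; testing items one at a time is laborious and needs pre-specified
"anchor" items that are assumed clean. **remirt** fits a regularized
explanatory multidimensional item response model that estimates all
group-specific item effects jointly and uses a Lasso penalty to decide,
in one pass, which items show DIF. Items whose DIF parameters are shrunk
to zero act as the anchors, so no prior knowledge of clean items is
required.

## Model

For person $i$ in group $g$ with latent trait vector
$\theta_i \in \mathbb{R}^K$, the probability of endorsing binary item $j$
is

$$
P(Y_{ij}=1 \mid \theta_i) = \operatorname{logit}^{-1}\!\big(
(a_j + \gamma_{gj})^\top \theta_i + b_j + \beta_{gj}\big),
$$

where $a_j$ and $b_j$ are the item's slope vector and intercept,
restricted to the dimensions given by a binary Q-matrix (each item loads
only on its designated dimensions), and $\gamma_{gj}, \beta_{gj}$ are the
group's slope and intercept offsets against the reference group
($\gamma_{1j} = 0$, $\beta_{1j} = 0$). Nonzero $\beta$ is uniform DIF;
nonzero $\gamma$ is non-uniform DIF. Group trait distributions are
$\theta_i \sim N(\mu_g, \Sigma_g)$; differences in $\mu_g, \Sigma_g$ are
*impact*, which is estimated, not penalized.

We use the slope–intercept convention above throughout (simulator,
estimators, predictions). A difficulty-style parameterization is obtained
by negating $b_j$ and $\beta_{gj}$.

### Identification

The latent scale is pinned by the reference group: $\mu_1 = 0$ and
$\operatorname{diag}(\Sigma_1) = 1$ (a correlation matrix; we deliberately
fix only the diagonal, the weakest sufficient constraint). Impact would
still be confounded with DIF if most items had DIF in the same direction;
the Lasso resolves this by preferring sparse DIF patterns, which makes
clean items the implicit anchors. When more than half the items share
same-signed DIF this assumption genuinely fails — that is a property of
the model, not the algorithm.

The estimated criterion is the penalized marginal log-likelihood
$\ell(\Theta) - N\lambda \sum_{g \ge 2, j}
(\|\gamma_{gj}\|_1 + |\beta_{gj}|)$. The factor $N$ on the penalty keeps
the tuning parameter on a per-observation scale.

## Estimation

### Gaussian variational EM (GVEM)

The marginal likelihood involves a $K$-dimensional integral per person.
GVEM replaces each person's posterior by a Gaussian
$q_i = N(\mu^*_i, \Sigma^*_i)$ and each logistic log-likelihood term by
its quadratic lower bound with local parameter $\xi_{ij}$ (curvature
$\eta(\xi) = \tanh(\xi/2)/(4\xi)$, tight at $\xi_{ij} = |x_{ij}|$). All
updates are then closed-form:

* E-step: $\Sigma^{*-1}_i = \Sigma_g^{-1} + 2\sum_j \eta(\xi_{ij})
  \tilde a_{gj} \tilde a_{gj}^\top$ and the matching linear solve for
  $\mu^*_i$;
* $\xi$-step: $\xi_{ij}^2 = E_q[x_{ij}^2]$;
* M-step: intercepts and on-support slopes by small linear systems,
  $\mu_g$ and $\Sigma_g$ by weighted moments;
* DIF step: the bound is exactly quadratic in each DIF coordinate, so the
  penalized coordinate update is an exact soft-threshold
  ($\text{ST}(cx + d, N\lambda)/c$ with positive curvature $c$),
  visited group by group, item by item, intercept before slopes;
* identification step: rescale so $\operatorname{diag}(\Sigma_1) = 1$,
  transforming the variational state along with the parameters so the
  bound is unchanged.

Each step maximizes the same bound, so in unpenalized runs the bound is
monotonically nondecreasing — the test suite asserts this exactly (slack
1e-8) on every recorded trace. During penalized runs the monotone
quantity is the bound minus the penalty; because the L1 penalty is not
invariant under the identification rescaling (the bound is), the
recorded penalized objective can dip by the small rescaling drift, which
vanishes as the scale converges — the suite bounds these dips at 1e-4.
Convergence is declared when
no parameter entry moves more than `tol` ($10^{-4}$ by default) between
iterations.

The full path algorithm is: deterministic starting values ($A = Q$,
intercepts at clipped logits of the observed proportions, everything else
neutral), one unpenalized EM run shared as a warm start, then for every
$\lambda$ a penalized run followed by a *debiasing* run — unpenalized,
with the zero pattern found by the penalized run held fixed — because
Lasso shrinkage biases the surviving coefficients and the information
criteria should compare debiased models. The warm-start run estimates
all DIF parameters without a penalty and is therefore not identified; it
is capped at `warm_iter` (300) iterations since it only supplies starting
values and can otherwise drift slowly along a likelihood ridge.

Degenerate items (all 0 or all 1) are kept: their starting intercepts are
clipped to $\pm 3$ and the quadratic bound keeps all updates finite; a
warning is emitted.

### Importance-weighted refinement (IW-GVEMM)

GVEM's slopes are biased when latent dimensions are strongly correlated.
The refinement draws $M$ samples per person from the converged
variational distributions (once per dataset — the same draws are reused
for every $\lambda$, making the whole path deterministic given the seed)
and maximizes the importance-weighted bound
$\sum_i \log \frac{1}{M} \sum_m w_{im}$, a tighter bound that approaches
the true marginal log-likelihood as $M \to \infty$. We default to
$M = 10$; in our checks this already recovers quadrature-accurate
estimates.

The IW objective has no closed-form updates. We optimize with Adam over
an unconstrained parameterization: covariances through Cholesky factors
with log-diagonals, and the reference correlation matrix through
tanh-transformed canonical partial correlations, so positive definiteness
and the identification constraints hold *by construction* at every step.
Penalized DIF coordinates take a proximal step instead,
$\text{ST}(x - s\,\hat m, s N \lambda)$, using the coordinate's own Adam
step size $s$; this produces exact zeros. Gradients are analytic
(logistic score terms, Gaussian natural terms, and the chain rule through
both covariance transforms) and are verified against central finite
differences in the tests.

Per $\lambda$, optimization runs from the shared GVEM starting state
(penalized phase, learning rate 0.1), then a debias phase with the zero
pattern fixed. The debias phase restarts the optimizer at the penalized
optimum, where a fresh adaptive optimizer with a large step briefly
overshoots and takes hundreds of iterations to settle; we therefore use a
smaller debias step (0.05 by default), which settles on the optimum
several times faster. The base rate also decays gently
($\mathrm{lr}_t = \mathrm{lr}_0/(1 + 0.002\,t)$): with a constant step,
Adam on a deterministic objective can enter a persistent small limit
cycle that defeats a parameter-stability stopping rule, and the decay
damps it without freezing the run. Both rates, the decay, the
moment constants (0.9/0.999), the stopping rule (no parameter moves more
than `adam_tol` for `adam_window` consecutive steps), and the iteration
cap are configurable via `remirt_control()`.

## Choosing the tuning parameter

Each debiased fit is scored by
$-2\,\text{bound} + a_N \cdot \text{df}$, where df is the number of
surviving DIF parameters, the bound is the fit's own variational bound
(GVEM) or importance-weighted bound (IW-GVEMM) — never a mixture across
methods — and $a_N = \log N$ (BIC) or $a_N = c \log N \log\log N$ (GIC).
BIC tends to keep too many DIF parameters; GIC with $c = 1$ (the default)
is more conservative. Ties are broken toward the larger $\lambda$, and
when the largest grid value is selected the grid is extended by factors
of 1.5 until the selection is interior.

The default grid is 8 log-spaced values in $[0.0025, 0.04]$. The scale
comes from the update itself: the soft threshold on a DIF coordinate in
parameter units is roughly $G\lambda / (2\bar\eta)$ with $\bar\eta
\approx 0.1$, so this range runs from below the sampling noise of a DIF
estimate (no shrinkage) to order-one shrinkage for typical designs;
anything larger is reached by grid extension. Two diagnostics help choose
$c$: `scree_dif()` traces the selected model size against $c$ (elbows
suggest reasonable values; the curve is nonincreasing), and `fit_rmse()`
compares Monte-Carlo model-implied response proportions with observed
proportions per group and item.

## The simulator

`sim_remirt()` emulates a standard three-group DIF study: one reference
and two focal groups (low/high DIF), between-item structure (`J_per_dim`
items loading solely on each of `K` dimensions), latent traits
$N(0, R(\rho))$ with compound-symmetric correlation $\rho$ for all groups
(no impact by default; an `impact` override exists), reference slopes
drawn from Uniform(1, 2.5) and intercepts from Uniform(−1, 1), and a
fraction `dif_proportion` of each dimension's items receiving DIF —
intercept-only (uniform) or intercept-and-slope (non-uniform) of
magnitude 0.5 (low focal group) and 1.0 (high). With `balanced = TRUE`
the DIF signs alternate deterministically over the DIF item list so
positive and negative effects cancel on average, which keeps DIF
separable from impact even at high DIF rates. The generating
distributions and magnitudes are configurable stand-ins chosen from
typical two-parameter-logistic ranges. The DIF effect size `wabc()` (the
area between reference and focal item response curves, weighted by the
focal trait density) quantifies each generated effect;
`evaluate_detection()` scores a fit's flags against the truth as
true/false positive rates per focal group and in total.

What the simulator does *not* emulate: polytomous responses, missing
data, within-item multidimensionality, guessing, or covariate-driven
(continuous) DIF. Passing operating-characteristic tests on these
designs therefore says nothing about such data.

## Numerical choices and scales used in the test suite

* Quadrature references (`marginal_loglik_gh`, `fit_mml_gh`) use product
  Gauss–Hermite rules and exist for $K \le 3$ only; they are accuracy
  references, never part of the estimators. The ML reference fitter
  rejects optimizer excursions where the quadrature sum degenerates
  (a true binary log-likelihood cannot be positive).
* The compiled kernels evaluate the logistic terms with a
  polynomial exponential and an arctanh-series `log1p` (two-lane SSE2
  with a scalar fallback), accurate to ~1e-9 absolute — far below any
  statistical tolerance used anywhere; an R reference engine
  (`engine = "r"`) computes the same quantities with base R and the test
  suite pins the two together at 1e-8.
* Singular per-item slope systems get a 1e-8 ridge; negative computed
  $\xi^2$ (roundoff) is clamped to zero with a warning.
* The operating-characteristic checks run the Study-style design (three
  groups, $K = 2$, 20 items, $\rho = 0.8$, 20% balanced uniform DIF,
  $n = 1000$ and 250 per group) with 20 replications, and the
  estimation-accuracy check uses $K = 1$, $J = 5$, $n = 2000$ per group;
  these sizes give stable averages while keeping the default suite quick.

## Known limitations

* Binary responses only; ordinal items must be dichotomized first.
* No missing-data handling: the readers reject missing cells loudly.
* DIF is detected against a designated reference group; a different
  reference can flag a different item set. This is inherent to the
  dummy-coded parameterization.
* When DIF is one-directional and affects most items, DIF and impact are
  not separable (see Identification above).
* No standard errors on the debiased estimates; the Lasso's selection
  event makes naive standard errors misleading.
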
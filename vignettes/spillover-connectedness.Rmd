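---
title: "Measuring healthcare-expenditure spillovers: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring healthcare-expenditure spillovers: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spillnet)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the tunable parameters and why their
defaults are what they are, what the synthetic world does and does not
emulate, and the numerical choices a maintainer should know about.

## 1. The measurement model

### TVP-VAR with forgetting factors

Let $y_t$ be the $N$-vector of weekly disease-group expenditures. The
measurement model is a VAR($p$) whose coefficients and innovation
covariance drift:

$$y_t = (I_N \otimes x_t')\,\beta_t + \epsilon_t, \qquad
  \beta_t = \beta_{t-1} + u_t, \qquad
  \epsilon_t \sim (0, \Sigma_t),$$

with $x_t = (1, y_{t-1}', \ldots, y_{t-p}')'$. Instead of specifying a
state-noise covariance, the Kalman filter *forgets*: the one-step
prediction covariance is inflated as $P_{t|t-1} = P_{t-1|t-1}/\kappa_1$,
and the innovation covariance is an exponentially weighted moving average
of one-step prediction errors,
$\Sigma_t = \kappa_2 \Sigma_{t-1} + (1-\kappa_2)\, e_t e_t'$.
The filter is deterministic given the data; with
$\kappa_1 = \kappa_2 = 1$ it is exact recursive least squares.

**Assumptions.** Conditional linearity; Gaussian-like innovations (the
filter is the linear-optimal update regardless, but the inference
interpretation is Gaussian); smooth parameter drift (a random walk state —
abrupt breaks are tracked with a lag governed by $\kappa_1$); weak
stationarity of the observed series, screened beforehand with the
Phillips–Perron test.

**Parameters.**

| parameter | default | units / range | why |
|---|---|---|---|
| $p$ | 1 (or BIC over 1..4) | lags | weekly data, parsimony at $N=18$ ($k = Np+1$ per equation) |
| $\kappa_1$ | 0.99 | (0,1] | effective window $\approx 1/(1-\kappa_1) = 100$ weeks: slow structural drift |
| $\kappa_2$ | 0.96 | (0,1] | covariance adapts faster than coefficients; the customary pairing with 0.99 |
| prior | OLS on first 10% | — | data-driven scale for $P_0 = \hat\Sigma_0 \otimes (X_0'X_0)^{-1}$ |
| $H$ | 10 | weeks | horizon at which the FEVD has essentially converged for stationary weekly dynamics; reported with all outputs |

The `"diffuse"` prior is implemented as an *exact information start*:
least squares on the smallest full-rank leading block, identity
innovation covariance, filtering from the next observation. A literal
"huge $P_0$" start loses 5–10 digits to floating-point cancellation in
the covariance update and cannot meet a $10^{-6}$ recursive-least-squares
equivalence; the information start is exact to machine precision.

### Generalized FEVD and the index family

For MA coefficients $\Psi_h$ and covariance $\Sigma$, the generalized
share of $i$'s $H$-step forecast-error variance due to shocks in $j$ is

$$\theta_{ij} = \frac{\sigma_{jj}^{-1} \sum_{h=0}^{H-1}
  (e_i'\Psi_h \Sigma e_j)^2}{\sum_{h=0}^{H-1} e_i'\Psi_h \Sigma \Psi_h' e_i},$$

row-normalized to $\tilde\phi_{ij}$ (generalized shocks are correlated, so
raw rows do not sum to one). The decomposition needs no shock ordering,
which is what makes the directional indices well-defined. The index
family (TCI, TO/FROM, NTDCI, NPDCI) is computed exactly as in the README;
three conventions are switchable and default as follows:

- TCI denominator $N$ (not $N-1$);
- NPDCI in percent of row-normalized shares *without* an extra $1/N$
  factor, so that $\mathrm{NTDCI}_i = \sum_j \mathrm{NPDCI}_{ij}$ holds
  exactly;
- the static table is the element-wise *mean of the per-period normalized
  FEVD matrices* with indices recomputed from the mean (the time-varying
  analogue of a full-sample table); a full-sample OLS static mode exists
  for oracle tests.

A zero NTDCI is classified as sign-breaking ("in-between"): purity is
strict sign uniformity over every period.

## 2. Preprocessing

- **Deflation**: nominal expenditure / population, rescaled to base-period
  prices (base year index = 100 convention).
- **Phillips–Perron screening**: first-order autoregression with
  Bartlett/Newey–West long-run variance; automatic bandwidth
  $\lfloor 4 (T/100)^{2/9} \rfloor$; constant-only deterministics by
  default; 5% decision from MacKinnon response-surface critical values.
  The source study reports neither bandwidth nor deterministics, so these
  defaults are flagged as assumptions, not reconstructions.
- **Weekly→monthly**: a week belongs to the month containing its start
  date; monthly value = arithmetic mean of member weeks. Weekly bins are
  consecutive 7-day intervals anchored at the study start (the only
  convention that reproduces 822 bins for the printed 2000-01-01 to
  2015-09-30 window); the trailing partial week is kept by default and a
  flag drops it.
- **Hodrick–Prescott filter**: trend minimizes
  $\sum (y-\tau)^2 + \lambda \sum (\Delta^2 \tau)^2$, solved through the
  sparse pentadiagonal normal equations $(I + \lambda D'D)\tau = y$.
  $\lambda = 14400$ for monthly series (the conventional monthly choice);
  weekly series are not filtered by default — only the monthly regression
  variables are. Which regression variable is HP-filtered vs differenced
  is recipe-driven (`default_recipe()`): index cycles and level covariates
  take HP cycles, the Baumol cost variable enters as its first difference
  ("growth") scaled by $10^{-2}$ to match conventional table scaling.

## 3. Robust determinants regression

OLS influence diagnostics motivate robustness: externally studentized
residuals, DFFITS and COVRATIO are computed in closed form from the hat
matrix and verified in tests against literal leave-one-out refits. Flag
thresholds (configurable, textbook defaults, the source study reports
none): $|RStudent| > 2$, $|DFFITS| > 2\sqrt{k/n}$,
$|COVRATIO - 1| > 3k/n$.

MM-estimation: stage 1 is an S-estimate with a bisquare $\rho$ tuned for
50% breakdown ($c \approx 1.5476$, found by solving
$E\,\rho_c(Z) = 0.5$ numerically), initialized from 500 seeded elemental
subsamples with two concentration steps each and full refinement of the
best candidate; stage 2 is an M-step with a bisquare $\psi$ tuned for 95%
Gaussian efficiency ($c \approx 4.685$), holding the S-scale fixed.
Standard errors use the MM asymptotic covariance
$\hat\sigma^2 \frac{n}{n-k}\,\overline{\psi^2}/(\overline{\psi'})^2
(X'X)^{-1}$; z-statistics are normal-referenced with 1/5/10% stars,
matching the reporting convention of determinants tables. Data that are
exactly linear for more than half the sample drive the S-scale to zero
(the exact-fit property); the estimator then returns the exact-fit
coefficients with zero scale and undefined z-statistics rather than
failing.

Effect classification follows the sign/significance rules: *convex*
demographic effect = significantly negative young-dependency and
significantly positive old-dependency coefficients, *concave* the
reverse; *pro-/counter-cyclical* = significantly positive/negative
leading-index coefficient.

## 4. The synthetic world

The generator stands in for restricted claims data and government
statistics. It emulates:

- a weekly panel of $N$ stationary series from a VAR with known
  coefficients and innovation covariance (Gaussian innovations; burn-in
  200 periods; every coefficient stack validated for companion spectral
  radius < 1, with the offending period named otherwise);
- a defaults world chosen once for realism: own-lag 0.30, cross-lags
  0.035/0.005 (below/above the diagonal) so that low-index series are net
  transmitters — a symmetric stack would make every pairwise net index
  identically zero, a world with no directional structure at all;
  equicorrelated innovations (0.6) give the high total connectedness that
  expenditure panels display; intercept 100 for expenditure-like levels;
- an optional time-varying truth: a deterministic half-cosine drift
  between two stationary stacks (smooth, checkable ground-truth path) or
  an abrupt mid-sample switch for tracking tests;
- monthly covariates = smooth trend + AR(1) cycle, with the demographic
  transition built in (young dependency trending down 0.55→0.33, old
  trending up 0.14→0.33 over the window — Taiwan-like magnitudes), a
  persistent business-cycle index, a slowly rising medical price index,
  a primary-care share around 0.7, and a Baumol variable assembled from
  simulated wage growth, productivity growth and healthcare labor share
  by the definitional formula (wage − productivity)/labor share.

It does **not** emulate: claims-level structure (no ICD coding or CCS
grouping of records), seasonality, heavy-tailed or heteroskedastic
innovations, measurement revisions, or any cross-equation link between
the covariates and the expenditure panel. A green recovery test therefore
establishes that the estimation machinery inverts the stated generating
process — not that the pipeline would recover the truth under real-data
pathologies.

## 5. Numerical choices and caveats

- All filter covariance updates use the expanded Joseph form and are
  symmetrized; negative eigenvalues (never observed in tests at sane
  settings) are clipped to zero with a warning.
- Per-period coefficient-uncertainty matrices are not stored by default:
  at $N=18, p=1$ the state covariance is $342\times342$, about 770 MB
  over 822 weeks. The final-period matrix is kept;
  `store_uncertainty = TRUE` retains the full path.
- Under default forgetting, coefficient noise inflates estimated
  connectedness: with an effective window of ~100 weeks, a *diagonal*
  (zero-spillover) truth yields a spurious static TCI of about 7 at
  $N=4$ and 35 at $N=18$; in the $\kappa = 1$ limit the same experiment
  gives < 5. Dynamic TCI levels should therefore be read relative to a
  same-configuration baseline, not as absolute zero-anchored shares.
  Across replicate panels the time-averaged TCI of the default filter is
  unbiased for the true-parameter TCI within Monte-Carlo error (the
  acceptance suite measures this with replicate-based standard errors).
- The M-scale is solved by the standard fixed-point iteration on
  $s^2$; the S-stage subsampling is seeded, making the whole regression
  grid bit-reproducible.
- Monte-Carlo tests use per-coefficient 3-SE bands where a single
  comparison is made and Bonferroni-style 4-SE bands for simultaneous
  coefficient panels; seeds are fixed and stated in the tests.
- HP reconstruction (`trend + cycle = input`) is exact up to one ulp
  (the cycle is defined as the subtraction); tests assert at 1e-14.

## 6. Known limitations

- No stochastic-volatility or MCMC TVP-VAR; no rolling-window variant
  (deliberately — the forgetting-factor filter is the point).
- No seasonal adjustment and no unit-root tests besides Phillips–Perron.
- Monthly aggregation of weekly indices ignores aggregation bias unless
  homotheticity-type assumptions hold; testing them is out of scope.
- MM z-statistics are asymptotic; at the monthly sample size (~189) their
  size is verified by simulation to be near nominal, but small-sample
  refinements (bootstrap) are not provided.
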
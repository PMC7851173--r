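---
title: "Covariate-driven CTCRW movement modelling and vessel-encounter risk"
author: "ctcrwrisk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Covariate-driven CTCRW movement modelling and vessel-encounter risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctcrwrisk)
```

## The model

Positions of a satellite-tagged animal are modelled as the time integral of
an Ornstein–Uhlenbeck velocity process,

$$ dv = -\beta\, v\, dt + \sigma\, dW, \qquad x(t) = \int_0^t v(s)\, ds, $$

run independently in the two planar coordinates. $\sigma$ (km h$^{-3/2}$)
sets the overall variability of velocity and $\beta$ (h$^{-1}$) the rate at
which velocity decorrelates; the derived quantities

$$ p = 3/\beta \quad\text{(persistence, hours)}, \qquad
   \nu = \frac{\sqrt{\pi}\,\sigma}{2\sqrt{\beta}} \quad\text{(long-term
   velocity, km/h)} $$

summarize the behavioural continuum: low $\nu$ and low $p$ indicate
area-restricted search (ARS, a foraging proxy), high values indicate
transit. $\nu$ is the mean of the stationary speed distribution, which is
Rayleigh with scale $\sigma/\sqrt{2\beta}$ — this closed form is one of the
package's test oracles.

The extension fitted here lets both parameters vary along the track as
lognormal latent variables driven by environmental covariates:

$$ \log\sigma_t \sim N(A_0 + A X_t,\ \varepsilon_1), \qquad
   \log\beta_t \sim N(B_0 + B X_t,\ \varepsilon_2), $$

with $X_t$ the standardized covariates attributed to the interval ending at
relocation $t$. Because the process is conditionally linear-Gaussian, the
likelihood of the observed positions given $(\sigma_t, \beta_t)$ is computed
exactly by a Kalman filter over the 4-dimensional state $(x, v_x, y, v_y)$,
using the exact OU-integrated transition over each (irregular) interval —
no time regularization is needed. Observation error uses the Argos error
ellipse: a fix of semi-major $M$, semi-minor $m$ and orientation $c$
(clockwise from north) contributes a bivariate normal error with axis
standard deviations $M/\sqrt2$ and $m/\sqrt2$.

## Fitting

`fit_ctcrw()` is a two-stage fit. Stage 1 maximizes the constant-parameter
Kalman likelihood and smooths the states (Rauch–Tung–Striebel), producing
estimated true locations. Covariates are extracted at those locations as the
mean within a 3 km radius — twice the nominal error of the best Argos
classes — and standardized; missing values become 0, the mean of a
standardized variable. Stage 2 maximizes the marginal likelihood

$$ \int L_K(\sigma, \beta)\; N(\log\sigma \mid A_0 + AX, \varepsilon_1)\;
   N(\log\beta \mid B_0 + BX, \varepsilon_2)\; d\log\sigma\, d\log\beta $$

by the Laplace approximation with automatic differentiation (TMB), declaring
the states and the latent $\log\sigma_t, \log\beta_t$ jointly as random
effects; the approximation is exact in the Gaussian state dimensions.
The package also implements the marginal-form Laplace directly in R
(`laplace_marginal_nll()`): an inner BFGS finds the mode of the
$2(n-1)$-dimensional latent vector over the *state-integrated* Kalman
likelihood, and a finite-difference curvature supplies the determinant term.
The two factorizations are distinct approximations of the same integral;
on a 3-interval toy the marginal form agrees with 6-dimensional
Gauss–Hermite quadrature to about 0.02%, while the joint form used for
fitting is a few percent off on such tiny diffuse problems and far sharper
at realistic track lengths. The pure-R form is the validation path and the
TMB form the fitting path; tests tie both to quadrature and to a dense
multivariate-normal oracle.

Standard errors are Wald (inverse Hessian of the outer objective), and
p-values are two-sided Wald tests — the convention assumed for per-animal
coefficient reports in this literature.

### Fixed and reduced parameters

* $\varepsilon_2$ is **fixed at 0.01**: estimating it yields tiny values
  with enormous standard errors, so it is pinned rather than estimated.
* If no covariate effect on $\log\beta_t$ is significant at 0.05, the model
  is refitted with a single scalar $\log\beta$.
* If that scalar estimate exceeds **4 on the log scale**, the model is
  refitted with $\log\beta$ fixed at 4. At $\log\beta = 4$ persistence is
  $3/e^4 \approx 0.055$ h, i.e. velocity decorrelates between consecutive
  Argos fixes: the data carry no autocorrelation information and the
  likelihood is flat along a ridge where $\beta$ and $\sigma$ grow together
  at fixed diffusion rate $\sigma^2/\beta^2$. The cap is interpreted on the
  log scale because that is the scale of the reported coefficient tables
  and because $3/e^4$ matches the documented ~0.05 h persistence bound.
* $\varepsilon_1 \to 0$ collapses are tolerated (they parallel the
  small-variance estimates with huge SEs seen in per-animal reports); when
  the outer Hessian is not positive definite the fit is retried once from a
  more dispersed start.

### Numerical choices

Time is in hours and distance in kilometres throughout, so $\sigma$ is
numerically of order 1–10. The initial state is diffuse in position
(variance $10^6$ km$^2$, centred on the first fix) and stationary in
velocity. The OU-integrated position variance involves the expression
$dt - 2(1-e^{-\beta dt})/\beta + (1-e^{-2\beta dt})/(2\beta)$, a triple
cancellation that destroys double precision when $\beta\,dt$ is small (very
persistent tracks push the optimizer there); below $\beta dt = 0.01$ the
implementation switches to the series
$\sigma^2 dt^3 (1/3 - \beta dt/4 + 7(\beta dt)^2/60)$ and uses `expm1`
elsewhere. Outer optimization is `nlminb` with gradient from AD
(tolerance $10^{-10}$); the pure-R inner optimizer is BFGS at
$10^{-10}$ relative tolerance. Observation variances are floored at
$10^{-8}$ km$^2$ inside `fit_ctcrw()` so simulated noise-free fixes cannot
make the objective singular. Duplicate timestamps are dropped (first kept)
because the continuous-time transition requires strictly positive steps.

### Interval attribution

The latent pair $(\sigma_t, \beta_t)$ governing the interval that ends at
relocation $t$ uses, by default, the covariates extracted at relocation $t$
(`attribution = "end"`); `"start"` is available and is what the simulation
tests use, since the generator draws each interval's parameters from the
covariates at the interval's starting position. With covariate fields that
are smooth on the scale of a step the two conventions differ negligibly.

### Standardization

By default each track is standardized by its own extracted series, matching
per-individual fits. `stats =` accepts fixed constants — e.g. a synthetic
stack's global raster constants — which is what the parameter-recovery tests
use, so that the recovered slope is on the same scale as the generating one.

## Covariate layers

* **DAHCC** — distance to areas of high spring chlorophyll-a. Cells at or
  above the 95th percentile of the spring-mean chlorophyll distribution form
  the high-concentration set; every marine cell gets the log of the distance
  to the nearest high-set cell centre. The distance is floored at half a
  cell width before the log so the high set itself has a finite value (the
  source convention does not state the handling of zero distances). A raster
  distance transform replaces polygonization — equivalent at cell
  resolution.
* **SST thermal gradient** — the SST field is median-filtered (3 × 3 by
  default, suppressing impulse noise) and the gradient magnitude computed by
  central differences (one-sided on edges), in °C km$^{-1}$. This implements
  the documented essence of contextual median-filter gradient estimation;
  full multi-scale front classification is out of scope.
* Covariates are screened for collinearity with
  `flag_correlated_covariates()` (flag at $|r| \ge 0.5$).

## Behavioural layers and risk mapping

`classify_states()` labels each relocation by its quadrant relative to the
*pooled* medians of $\sigma_t$ and $p_t$ across all animals (values equal to
a median count as below — a deterministic tie rule). `predict_nu_raster()`
evaluates the fitted response on a 1-km grid, using the median
back-transform $\exp(\mu)$ — with $\varepsilon_2 = 0.01$ the mean/median
distinction is negligible for $\beta$, and for $\sigma$ the choice is
documented here. Spatial predictions are averaged only across individuals
with **more than 200 locations**; shorter tracks give unstable prediction
curves.

Vessel density `VD` counts, per month, the daily number of unique vessels
crossing each 8-km cell — a vessel crosses every cell traversed by straight
segments between consecutive fixes (switchable to fix containment only) —
divided by the number of days with data in that month, then averages months.
The 1-km $\nu$ grid is aggregated to 8 km by the mean before any risk
algebra. Then

$$ RPEW_i = \frac{N_i / \nu_i}{\sum_j N_j/\nu_j}, \qquad
   RPVEW_i = \frac{Pw_i\, Pt_i\, Pv_i}{\sum_j Pw_j\, Pt_j\, Pv_j}, $$

with $Pw \propto N$, $Pt \propto 1/\nu$, $Pv \propto VD$. Overlap between
the whale field ($N \cdot 1/\nu$) and $VD$ is quantified by Schoener's
$D = 1 - \tfrac12\sum|p_i - q_i|$ and Warren's
$I = 1 - \tfrac12\sum(\sqrt{p_i} - \sqrt{q_i})^2$ after min–max rescaling
and sum-normalization; when layer minima are zero the rescale is a no-op
after normalization (a property the tests document).

## The synthetic-data generator

`make_covariate_stack()`, `simulate_track()`, `simulate_vessels()` and
`make_density_raster()` generate every input the pipeline needs. Chosen
study conditions: 500 relocations per track at 0.5–2.5 h spacing;
$A_0 = 1.5$, active DAHCC slope $0.6$ (mid-range of significant per-animal
velocity–productivity slopes), $\varepsilon_1 = 0.2$, single
$\log\beta = 0.7$ ($\beta \approx 2$ h$^{-1}$, persistence 1.5 h —
consistent with three quarters of locations below 1.6 h persistence);
an Argos class mixture dominated by the poorer classes with ellipse axes
from 250 m (class 3) to 5 km (class B); tracks start near a
high-chlorophyll patch, emulating tag deployment on foraging grounds where
the covariate actually varies. Ellipse noise is drawn from the same
bivariate-normal construction the observation model assumes, so generator
and model are self-consistent by design. Boundary crossings reflect.

What the generator does **not** emulate: coastline geometry and land
masking, temporal gaps and Argos duty cycling, covariate measurement error,
inter-individual heterogeneity, and true discrete behavioural switching — passing
tests show the estimator recovers its own generating process under realistic
noise, not that the model is correct for real whales.

Parameter-recovery checks run 50 seeded replicates of the single-covariate
design, fitting the generating structure (covariate on $\sigma$, scalar
$\beta$), and require the active slope to fall within 2 standard errors of
truth in at least 90% of replicates, with 95% Wald coverage between 0.85
and 1. Recovery is assessed under the generating model deliberately: the
*full* covariate-$\beta$ model, with $\varepsilon_2$ pinned, has a second
likelihood ridge on which the $\sigma$- and $\beta$-slopes grow together
(only their difference — the diffusion response — is well identified), and
Wald tests on that ridge spuriously retain the covariate-$\beta$ model in
roughly 8% of replicates with extreme compensating slopes. Per-animal
coefficient tables in this literature show the same signature (paired
$\sigma$/$\beta$ slopes of several units with small SEs), so the ridge is a
property of the model at these conditions, not of this implementation;
coverage under a model-selection step is post-selection inference and is
not expected to satisfy nominal bounds. The automatic reduction and cap
rules are exercised by their own dedicated tests.

## Known limitations

* The joint (states-included) Laplace used for fitting is biased on very
  short tracks; the pure-R marginal form is preferable there and both are
  exposed.
* $\varepsilon_1$ frequently collapses to ~0 with an enormous SE on tracks
  where per-interval velocity information is weak; slope inference is
  unaffected in the recovery tests, but $\varepsilon_1$ itself should not be
  interpreted.
* The vessel "crossing" rule interpolates straight segments between fixes;
  with sparse fixes this understates path curvature.
* GeoTIFF I/O is not provided; rasters exchange as ESRI ASCII grids and CSV
  cell tables.

## Problem sizes used by the test-suite

Unit tests use tracks of 40–150 relocations and rasters up to 200 × 200
cells; the recovery study uses 50 tracks of 500 relocations; quadrature
validation uses a 3-interval toy with 7–8 Gauss–Hermite nodes per latent
dimension; Monte-Carlo oracles use $10^5$–$10^6$ draws. These sizes were
chosen so each oracle's sampling error is far below the tolerance it
guards.
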
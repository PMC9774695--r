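---
title: "Joint modelling of sensor trajectories and cow survival: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint modelling of sensor trajectories and cow survival}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A dairy cow only becomes profitable from her second lactation onward, so an
early, per-cow forecast of survival to the second and third calving is
directly actionable for breeding and culling decisions. Automatic milking
systems record daily milk yield (MY, kg), body weight (BW, kg) and
rumination time (RUM, min) through the first lactation. `herdsurv`
implements a multivariate joint model that couples these three longitudinal
trajectories to the time-to-culling process and delivers dynamically
updated, individualized survival probabilities.

## The model

For cow $i$ and outcome $k \in \{\mathrm{MY}, \mathrm{BW}, \mathrm{RUM}\}$
observed at days in milk $t \in [5, 305]$:

$$y_{ik}(t) = \beta_{0k} + \boldsymbol\beta_{1k}^\top ns_k(t) +
\beta_{2k}\,\mathrm{AFC}_i + \beta_{3k}\,\mathrm{SEAS}_i(t) +
b_{i0k} + \mathbf b_{i1k}^\top ns_k(t) + \varepsilon_{ik}(t),$$

with $\varepsilon_{ik}(t) \sim N(0, \sigma_k^2)$ i.i.d. across days.
$ns_k(\cdot)$ is a natural cubic spline of DIM: one interior knot at the
median observed DIM for RUM (basis dimension 2), three knots at the DIM
quartiles for MY and BW (dimension 4), boundary knots at the observed DIM
range, linear continuation beyond. AFC (age at first calving) is coded
low/medium/high by the herd quartiles (interquartile range inclusive);
SEAS is warm for April–October. The stacked random-effects vector

$$\mathbf b_i = (b_{i0,1}, \mathbf b_{i1,1}, \dots, b_{i0,3},
\mathbf b_{i1,3})^\top \sim N(\mathbf 0, \mathbf D), \qquad q = \dim
\mathbf b_i = 5 + 5 + 3 = 13,$$

has a fully unstructured covariance $\mathbf D$, which is what ties the
three outcomes together. One random coefficient accompanies every spline
column, so each cow can reshape — not just shift — her curves.

The culling hazard couples to the *slopes* of the noiseless trajectories
$m_{ik}(t)$:

$$h_i(t) = h_0(t)\,\exp\{\gamma_1\,\mathrm{AFC}_i +
\alpha_1 m'_{i1}(t) + \alpha_2 m'_{i2}(t) + \alpha_3 m'_{i3}(t)\},$$

so a cow whose rumination curve is falling (negative $m'_{i3}$) with
$\alpha_3 < 0$ has an elevated hazard: the model reads disturbances such
as disease out of the raw series without any feature engineering. AFC and
SEAS are (piecewise) constant in time, so only the spline part contributes
to $m'_{ik}$; the SEAS step has zero derivative almost everywhere and is
excluded from the slope by convention. A current-value association
($\alpha_k m_{ik}(t)$, `association = "value"`) is also implemented, since
it is the natural alternative a user may want to compare against.

The baseline $h_0(t)$ is piecewise-constant on 6 intervals cut at the
event-time sextiles of the training data, with a Gaussian random-walk
smoothing prior (SD 1) on the log rates. This keeps every cumulative-hazard
integral semi-closed-form (a sum of per-interval Gauss–Legendre panels,
split additionally at the spline knots so the integrand is analytic on each
panel and the 15-point rule is exact to machine precision) and makes the
null-association survival function available in closed form for testing.

## Estimation

Sampling is Metropolis-within-Gibbs, with outcomes internally z-scored on
the training data for conditioning:

* $\boldsymbol\beta_k$ and each $\mathbf b_i$ are proposed from their
  *exact* Gaussian conditionals given the longitudinal data (and the
  $N(\mathbf 0, \mathbf D)$ prior for $\mathbf b_i$) and accepted with a
  Metropolis–Hastings ratio containing only the survival likelihood. This
  is an exact independence-MH step: when the association is null it reduces
  to the conjugate Gibbs update, and in practice it accepts at 95%+ and
  mixes nearly as i.i.d., which is why desk-scale chains can be short.
* $\sigma_k^2$ (inverse-gamma) and $\mathbf D$ (inverse-Wishart) are
  conjugate.
* $\boldsymbol\alpha$, $\boldsymbol\gamma$ and the log baseline rates use
  adaptive random-walk Metropolis targeted to 20–40% acceptance; the
  $\boldsymbol\alpha$ proposal is preconditioned per component by the
  running posterior spread, since the three association coefficients live
  on very different natural scales (per kg/day of MY slope vs per min/day
  of RUM slope).

Priors: $\boldsymbol\beta_k \sim N(0, 10^4)$ on the standardized scale,
$\sigma_k^2 \sim \mathrm{InvGamma}(0.01, 0.01)$,
$\mathbf D \sim \mathrm{InvWishart}(q + 2, \mathbf I)$,
$\alpha_k, \gamma_j \sim N(0, 10)$ *on the natural per-unit-slope scale*
(weakly informative for coefficients of the magnitude seen in practice,
0.005–1.5), and a diffuse prior on the first log baseline rate. The
association design columns carry the outcome scale factor so that the
sampled $\alpha_k$ is already natural — putting the $N(0,10)$ prior on a
standardized-slope coefficient instead would be unintentionally severe for
rumination, whose natural slope unit is tiny relative to its sensor SD.

Defaults are 2 chains of 1500 warm-up + 1500 kept iterations, sized for
herds up to a few hundred cows; an observation-thinning option (`step = 3`
keeps every third day) cuts the dominant longitudinal cost with little
information loss, because adjacent daily residuals are independent given
the smooth trajectory. Split-$\hat R$ is recorded for all association and
AFC parameters and a fit carries a warning when any exceeds 1.1.

## Dynamic prediction

For a new cow with data $\mathcal Y_i(v)$ through day $v$,
$\pi_i(u \mid v) = \Pr\{T_i \ge u \mid T_i > v, \mathcal Y_i(v)\}$ is
computed by Monte Carlo over the retained posterior draws: for each draw,
one random-effects vector is proposed from the Gaussian longitudinal
conditional and MH-corrected by the survival-to-$v$ factor
$\exp\{-H_i(0, v)\}$ (the proposal cancels everything else exactly), then
$\exp\{-H_i(v, u)\}$ is averaged across draws (500 by default). Credible
bands are the 2.5/97.5 percentiles of the per-draw curves. The default
evaluation grid is every 7 days from $v$ to $t_2$. A cow is called *culled
at $t_j$* when $\pi_i(t_j \mid v) \le c$ with $c = 0.5$ (the boundary
counts as culled).

## Evaluation protocol

Accuracy is measured by repeated 3-fold cross-validation (3 repeats, hence
9 fits), per scenario: observation windows $v \in \{60, 150, 240\}$ DIM
crossed with horizons $t_1$ (mean calving interval, rounded to days) and
$t_2 = 2 t_1$. Spline knots and AFC quartiles are recomputed on each
training fold so held-out cows never leak into them; the fold-partition
seed is independent of the MCMC seed. Only test cows alive at 240 DIM are
evaluated, whatever the window.

*Discrimination* is the time-dependent AUC over comparable pairs — one cow
with an observed culling in $(v, t_j]$ against one cow known alive at
$t_j$, ties counting one half; cows censored inside the window form no
pairs. It is exactly 0.5-calibrated for outcome-independent scores and is
reported as missing when a fold has no event in the window.
*Calibration* is a censoring-aware expected squared prediction error: cows
observed beyond $t_j$ contribute $(1-\pi_i)^2$, cows culled before it
$\pi_i^2$, and cows censored before it both terms weighted by the model's
own conditional survival $\pi_i(t_j \mid T_i)$; with no censoring it is the
Brier score, pinning the 0.25 coin-flip anchor. Scenario means over the 9
runs get $t$-based 95% confidence intervals
($\bar x \pm t_{0.975, m-1}\, s/\sqrt m$ over the $m$ non-missing values) —
an SD-width band would not be an interval for the mean — and significance
means excluding 0.50 (AUC, above) or 0.25 (PE, below). Variance homogeneity
of each metric across farms is Levene's classic $W$ (ANOVA on absolute
deviations from group means).

## The synthetic-herd generator

Because the farm data behind this class of model are private, the package
ships a generator whose draws have *exactly* the generative structure the
model assumes: spline-shaped mean curves (milk yield peaking near 60 DIM at
roughly 32 kg, body weight dipping post-calving then recovering toward 600
kg, rumination near 470 min/day), cow effects from an unstructured
13-dimensional covariance with SDs in the range seen on commercial farms,
AFC bands and a first-calving calendar spread over a year to exercise the
season step, and culling times drawn by inverse-transform sampling from the
slope-coupled hazard (daily 5-point Gauss–Legendre accumulation, root
refinement to $10^{-9}$, integer-day ceiling — culling dates derive from
the last milk recording). Default truths: $\sigma = (2.5, 12, 55)$,
$\boldsymbol\alpha = (0, 0.1, -0.6)$, $\gamma = (0.3, 0.6)$, and a rising
piecewise-constant baseline giving about 8–12% culled before $t_1$ and
25–30% before $t_2$, inside the ranges spanned by commercial herds. These
defaults are illustrative calibrations, not estimates. Administrative
censoring comes from a common dataset end date, so per-cow censoring times
vary with calving date as in real data.

Recording errors are injected as upward spikes at least
`outlier_magnitude` (default 4) herd SDs above the mean, because a
downward milk-yield error cannot exceed three herd SDs (the mean-to-SD
ratio is about 2.8) and would be undetectable by the cleaning rule — and
negative sensor values would be rejected as corrupt files rather than
cleanable outliers. Sensor noise is truncated at zero (negligible at the
defaults). The generator emulates the *model's* world: it does not produce
autocorrelated residuals, disease episodes, missing-not-at-random gaps,
multi-lactation carry-over or herd-management interventions, so passing
tests demonstrate correctness of the machinery and recoverability under
the stated assumptions — not performance on real farms.

## Data processing rules

Cleaning follows a fixed order: 2-hourly rumination slots are summed to
daily minutes (a day with any of the 12 slots missing is missing); values
outside 3 herd SDs of the herd mean (computed once, on the raw data) are
removed unless a cow accumulates 30 or more such days for that outcome, in
which case all are kept as genuine abnormal behaviour (the boundary case
of exactly 30 counts as abnormal, applied per outcome); cows culled before
50 DIM are dropped; records outside 5–305 DIM are dropped; and a cow is
dropped when any outcome retains fewer than 90% of the days in
$[5, \min(T, 305)]$ — cleaning runs before the completeness check, so
removed outliers count against completeness. Cleaning never alters a
value; it only removes rows or drops cows, and every rule reports exact
counts. AFC quartiles are computed on the post-filter herd when a farm is
processed as a whole, and on the training fold during cross-validation.

## Numerical and design choices

* **Basis parameterization.** Any valid natural-spline basis spans the
  same function space, so fitted curves — not raw coefficients — are the
  comparable quantities across software; the basis is the B-spline
  construction with the natural constraints projected out, and the
  intercept is carried by $\beta_{0k}$.
* **Quadrature.** 15-point Gauss–Legendre per panel, panels split at
  baseline jumps (and at spline knots in the definitional path); the
  event-time grid treats integer days as continuous, and no tie handling
  is needed.
* **Degenerate inputs.** Zero-SD outcomes with non-constant data, empty
  post-filter herds, cows missing an outcome entirely, duplicate cow-days,
  physically impossible values (negative sensors, rumination beyond 1440
  min/day, slots beyond 120 min) all raise early, named errors. Linear
  predictors beyond $\pm 50$ trip an overflow guard (an error in the
  definitional API, a rejected proposal inside the sampler).
* **Problem sizes.** The shipped analysis and the test suite run at desk
  scale by choice: herds of 100–200 cows, every-3rd-day thinning for
  fits, single chains of 300–800 kept draws for recovery and
  cross-validation studies, 500 Monte-Carlo draws per prediction. The
  near-i.i.d. random-effects update makes these short chains effective;
  the package defaults (2 × 1500 + 1500) remain appropriate for a real
  analysis.
* **Serialization.** Fits persist as `params.parquet` (one row per kept
  draw) plus `spec.json` carrying knots, standardization, baseline cuts,
  priors and seeds, so predictions from a reloaded fit are identical.

## Known limitations

Residuals are assumed Gaussian and independent across days; real AMS
series are autocorrelated and occasionally heteroscedastic. The hazard is
proportional given the slopes, with no competing risks (sold vs died) and
no cure fraction. The slope association reads instantaneous derivatives,
so a transient dip contributes only while it lasts. Extrapolation of
trajectories beyond 305 DIM is linear by construction of the natural
basis; survival predictions to $t_2 \approx 820$ days lean on that
constant late slope. Finally, all empirical performance statements in this
package are about herds generated under the model's own assumptions.
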
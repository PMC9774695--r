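# herdsurv

Early, per-cow predictions of survival to the second and third calving,
from nothing more than the daily sensor streams a first-lactation cow
already generates on an automatic milking system: milk yield (kg/day),
body weight (kg) and rumination time (min/day). The package is aimed at
quantitative dairy scientists and biostatisticians who want a fully
reproducible joint-modelling pipeline — from raw sensor files to
cross-validated accuracy — and, because such farm data are private, it
ships a synthetic-herd generator with exactly the generative structure the
model assumes, so every stage can be exercised and audited end to end.

## The model

Three linear mixed models on natural cubic splines of days in milk (DIM),

y_ik(t) = β₀k + β₁kᵀ ns_k(t) + β₂k AFC_i + β₃k SEAS_i(t) + b_i0k + b_i1kᵀ ns_k(t) + ε_ik(t),

share a 13-dimensional multivariate-normal random-effects vector
b_i ~ N(0, D) (unstructured D; one random coefficient per spline column:
5 + 5 + 3 for MY, BW, RUM). The culling hazard couples to the *slopes* of
the smoothed trajectories,

h_i(t) = h₀(t) · exp{ γ₁ AFC_i + α₁ m′_i1(t) + α₂ m′_i2(t) + α₃ m′_i3(t) },

so e.g. a falling rumination curve raises the culling risk when α₃ < 0.
Estimation is Metropolis-within-Gibbs (fixed and random effects proposed
from their exact longitudinal-conjugate Gaussians and accepted against the
survival likelihood; variances and D conjugate; association, AFC and
baseline parameters by adaptive random-walk Metropolis). Survival of a new
cow with data to day v is predicted as
π_i(u|v) = Pr(T_i ≥ u | T_i > v, data), Monte-Carlo averaged over
posterior draws with the cow's random effects drawn conditionally on her
own trajectories and her survival to v; the call "culled at horizon t_j"
is made when π_i(t_j|v) ≤ 0.5. Accuracy is judged by repeated 3-fold
cross-validation with a time-dependent AUC (discrimination) and a
censoring-aware expected prediction error (calibration), against the
random-guessing anchors 0.50 and 0.25. The methods vignette
(`vignettes/joint-modelling-methods.Rmd`) derives all of this in detail.

## Worked example

```r
library(herdsurv)

cfg  <- default_config(n_cows = 120, seed = 20260919, outlier_rate = 0.01)
herd <- generate_herd(cfg)            # synthetic farm, truths known
pp   <- preprocess_herd(herd)         # 3-SD rule, T<50, 5-305 DIM, 90% filter
fit  <- fit_joint_model(thin_observations(pp$herd, 3),
                        mcmc = mcmc_control(chains = 1, burnin = 600, iter = 800),
                        seed = 42)
print(fit)
```

```
Multivariate joint model fit (slope association)
  cows: 119  posterior draws: 800
              mean     sd   q2.5  q97.5
alpha.MY    -0.265  1.076 -2.215  1.882
alpha.BW     0.124  0.243 -0.301  0.630
alpha.RUM   -0.524  0.193 -0.942 -0.091
gamma.medium 0.001  0.413 -0.669  0.949
gamma.high   0.660  0.405 -0.100  1.543
```

The generating truths were α = (0, 0.1, −0.6) and γ = (0.3, 0.6): the
negative rumination-slope association is recovered (posterior mean −0.52,
95% credible interval excluding zero) and every coefficient lies within
about one posterior SD of its truth. Dynamic prediction then contrasts
individual cows — here the herd's steepest vs flattest late-lactation
rumination decline, predicted from 240 days of data:

```r
pred <- predict_survival(fit, cow_data, v = 240, seed = 1240)
classify(pred, fit$t1)   # horizon t1 = second calving (410 d)
```

```
steep RUM-decline cow: pi(t1) = 0.870 -> alive,  pi(t2) = 0.472 -> culled
flat  RUM-decline cow: pi(t1) = 0.980 -> alive,  pi(t2) = 0.892 -> alive
```

## Analysis workflow

The `analysis/` scripts run the whole study in order, writing tables under
`results/`:

| script | what it does |
|---|---|
| `01_simulate_herd.R`     | simulate the 120-cow study herd (writes `results/herd/`) |
| `02_preprocess.R`        | cleaning rules + exact per-rule accounting |
| `03_fit_joint_model.R`   | joint fit; association-recovery table (`association_recovery.csv`) |
| `04_dynamic_predictions.R` | per-cow survival curves and culled/alive calls |
| `05_cross_validation.R`  | 3×3-fold CV on two farms, all six (v, horizon) scenarios; AUC/PE summaries (`summary.csv`), Levene homogeneity (`levene.csv`) |

On the shipped configuration the cross-validated prediction error is
significantly below 0.25 in all twelve farm × scenario cells, mean AUC
ranges from about 0.46 to 0.70 and tends to improve with longer
observation windows and the nearer horizon, and Levene's tests find the
metrics mostly homogeneous across the two farms — the behaviour expected
of a well-calibrated model whose discriminative signal is honest but
modest.

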
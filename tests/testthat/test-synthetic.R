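test_that("random effects have the configured covariance structure", {
  cfg <- default_config(n_cows = 5000, seed = 1,
                        D_true = diag(13), sigma_true = c(1, 1, 1))
  b <- simulate_random_effects(cfg, seed = 42)
  expect_equal(dim(b), c(5000L, 13L))
  expect_lt(max(abs(cov(b) - diag(13))), 0.1)
  # degenerate covariance: all draws exactly zero
  cfg0 <- default_config(n_cows = 10, seed = 1, D_true = matrix(0, 13, 13))
  expect_true(all(simulate_random_effects(cfg0, seed = 1) == 0))
  # determinism under a fixed seed
  expect_identical(simulate_random_effects(cfg, seed = 9),
                   simulate_random_effects(cfg, seed = 9))
  # invalid covariance is refused
  bad <- diag(13); bad[1, 2] <- bad[2, 1] <- 2
  expect_error(default_config(n_cows = 5, seed = 1, D_true = bad),
               "positive semi-definite")
})

test_that("trajectories reduce to the fixed-effect curve without noise", {
  cfg <- default_config(n_cows = 2, seed = 1,
                        sigma_true = c(MY = 0, BW = 0, RUM = 0))
  cov2 <- data.frame(cow_id = c("a", "b"), afc_cat = c("low", "low"),
                     calving1_date = as.Date("2015-01-01"))
  tr <- simulate_trajectories(cfg, matrix(0, 2, 13), cov2, seed = 1)
  grid <- cfg$obs_grid
  spec <- cfg$specs$MY
  beta <- cfg$beta_true$MY
  warm <- as.numeric(format(as.Date("2015-01-01") + grid, "%m") %in%
                       sprintf("%02d", 4:10))
  expected <- beta[1] + as.numeric(ns_basis(grid, spec) %*% beta[2:5]) +
    beta[8] * warm
  expect_equal(tr$data$my_kg[tr$data$cow_id == "a"], expected,
               tolerance = 1e-12)
})

test_that("AFC category shifts the mean curve by a constant offset", {
  cfg <- default_config(n_cows = 2, seed = 1)
  cov2 <- data.frame(cow_id = c("hi", "lo"), afc_cat = c("high", "low"),
                     calving1_date = as.Date("2015-02-01"))
  tr <- simulate_trajectories(cfg, matrix(0, 2, 13), cov2, seed = 1)
  for (k in c("MY", "BW", "RUM")) {
    m <- tr$means
    diffs <- m[[k]][m$cow_id == "hi"] - m[[k]][m$cow_id == "lo"]
    p <- 1 + cfg$specs[[k]]$dim
    expect_equal(diffs, rep(cfg$beta_true[[k]][p + 2], length(diffs)),
                 tolerance = 1e-12)
  }
})

test_that("pooled residuals reproduce the configured noise level", {
  cfg <- default_config(n_cows = 500, seed = 3)
  cov_n <- data.frame(cow_id = sprintf("c%03d", 1:500),
                      afc_cat = sample(c("low", "medium", "high"), 500,
                                       replace = TRUE),
                      calving1_date = as.Date("2015-06-01"))
  b <- simulate_random_effects(cfg, seed = 4)
  tr <- simulate_trajectories(cfg, b, cov_n, seed = 5)
  expect_lt(abs(sd(tr$data$my_kg - tr$means$MY) / cfg$sigma_true[["MY"]] - 1),
            0.02)
  expect_lt(abs(sd(tr$data$rum_min - tr$means$RUM) /
                  cfg$sigma_true[["RUM"]] - 1), 0.02)
})

test_that("null-association event times are exponential with the baseline rate", {
  lam <- 1 / 150
  cfg <- default_config(n_cows = 1, seed = 1,
                        alpha_true = c(MY = 0, BW = 0, RUM = 0),
                        gamma_true = c(medium = 0, high = 0),
                        baseline_hazard = rep(lam, 6),
                        censor_day = 1500)
  set.seed(10)
  cov1 <- data.frame(cow_id = "x", afc_cat = "medium")
  draws <- replicate(1500, simulate_event_time(cfg, rep(0, 13), cov1)$T_exact)
  expect_lt(sum(is.na(draws)), 3)  # censoring beyond 10 mean lifetimes
  expect_lt(abs(mean(draws, na.rm = TRUE) / (1 / lam) - 1), 0.05)
})

test_that("all records are censored when the horizon precedes every event", {
  cfg <- default_config(n_cows = 1, seed = 1,
                        baseline_hazard = rep(1e-8, 6))
  set.seed(2)
  cov1 <- data.frame(cow_id = "x", afc_cat = "low")
  recs <- replicate(20, simulate_event_time(cfg, rep(0, 13), cov1),
                    simplify = FALSE)
  expect_true(all(vapply(recs, `[[`, 0L, "event") == 0L))
  expect_true(all(vapply(recs, `[[`, 0L, "T") == 900L))
})

test_that("the returned event time solves the inverse-transform identity", {
  cfg <- default_config(n_cows = 1, seed = 1)
  set.seed(33)
  b <- simulate_random_effects(cfg)[1, ]
  cov1 <- data.frame(cow_id = "x", afc_cat = "high")
  rec <- simulate_event_time(cfg, b, cov1)
  expect_equal(rec$event, 1L)
  # brute-force cumulative hazard by fine trapezoid, split at the baseline
  # rate jumps so no panel straddles a discontinuity
  cuts <- seq(0, cfg$censor_day, length.out = 7)
  edges <- sort(unique(c(0, cuts[cuts < rec$T_exact], rec$T_exact)))
  gamma_lp <- cfg$gamma_true[["high"]]
  H <- 0
  for (s in seq_len(length(edges) - 1)) {
    tg <- seq(edges[s], edges[s + 1], length.out = 10000)
    lp <- gamma_lp + herdsurv:::slope_lp(cfg, b, tg) +
      herdsurv:::baseline_log_h0(cfg, (edges[s] + edges[s + 1]) / 2)
    h <- exp(lp)
    H <- H + sum((h[-1] + h[-length(h)]) / 2 * diff(tg))
  }
  expect_lt(abs(H - rec$E), 1e-6)
  expect_equal(rec$T, as.integer(ceiling(rec$T_exact)))
})

test_that("hazard overflow is caught with the cow named", {
  cfg <- default_config(n_cows = 1, seed = 1,
                        alpha_true = c(MY = 0, BW = 0, RUM = 500))
  b <- rep(0, 13); b[12] <- 400  # huge rumination spline slope
  expect_error(
    simulate_event_time(cfg, b, data.frame(cow_id = "bad", afc_cat = "low")),
    "overflow.*bad")
})

test_that("outlier injection matches the configured rate and is logged", {
  cfg <- default_config(n_cows = 100, seed = 5, outlier_rate = 0.01,
                        miss_rate = 0, baseline_hazard = rep(1e-8, 6))
  herd <- generate_herd(cfg)
  n_days <- nrow(herd$sensor)
  expect_equal(n_days, 100 * 301)
  counts <- table(factor(herd$outlier_log$outcome,
                         levels = c("MY", "BW", "RUM")))
  for (k in c("MY", "BW", "RUM")) {
    # binomial 99% band around 301 = 30100 * 0.01
    expect_gt(counts[[k]], 301 - 2.576 * sqrt(301 * 0.99))
    expect_lt(counts[[k]], 301 + 2.576 * sqrt(301 * 0.99))
  }
  # rate zero leaves the dataset untouched
  cfg0 <- default_config(n_cows = 10, seed = 5, outlier_rate = 0)
  h0 <- generate_herd(cfg0)
  h00 <- inject_outliers(h0, cfg0, seed = 1)
  expect_identical(h0$sensor, h00$sensor)
  expect_equal(nrow(h00$outlier_log), 0L)
})

test_that("herd generation is deterministic and respects its contract", {
  cfg <- default_config(n_cows = 3, seed = 17)
  h1 <- generate_herd(cfg)
  h2 <- generate_herd(cfg)
  expect_identical(h1$sensor, h2$sensor)
  expect_identical(h1$cows, h2$cows)
  expect_lte(nrow(h1$sensor), 3 * 301)
  expect_true(all(h1$truth$survival$T >= 1))
  expect_true(all(h1$truth$survival$event %in% 0:1))
  # byte-identical files under the same seed
  d1 <- file.path(tempdir(), "herdA"); d2 <- file.path(tempdir(), "herdB")
  write_herd(h1, d1); write_herd(generate_herd(cfg), d2)
  for (f in c("sensor.csv", "cows.csv", "truth.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  expect_error(default_config(n_cows = 0, seed = 1), "positive")
})

test_that("steeper rumination decline shortens survival under negative alpha", {
  cfg <- default_config(n_cows = 400, seed = 23,
                        alpha_true = c(MY = 0, BW = 0, RUM = -2.5))
  herd <- generate_herd(cfg)
  b <- herd$truth$b
  spec <- cfg$specs$RUM
  # end-of-lactation RUM slope per cow (natural scale)
  sl <- as.numeric(ns_basis_deriv(280, spec) %*%
                     (cfg$beta_true$RUM[2:3] + t(b[, 12:13])))
  T <- herd$truth$survival$T
  # steeper decline (more negative slope) -> higher hazard -> culled earlier,
  # so slope and survival time are positively rank-correlated
  expect_gt(cor(sl, T, method = "spearman"), 0.15)
})

test_that("with null association the survival curve matches the closed form", {
  cfg <- default_config(n_cows = 2000, seed = 31,
                        alpha_true = c(MY = 0, BW = 0, RUM = 0),
                        gamma_true = c(medium = 0, high = 0),
                        censor_day = 1000)
  set.seed(77)
  b <- simulate_random_effects(cfg)
  cov1 <- data.frame(cow_id = "x", afc_cat = "low")
  Tx <- vapply(seq_len(2000), function(i) {
    r <- simulate_event_time(cfg, b[i, ], cov1)
    if (is.na(r$T_exact)) Inf else r$T_exact
  }, 0)
  cuts <- seq(0, cfg$censor_day, length.out = 7)
  Hfun <- function(t) {
    full <- pmax(pmin(t, cuts[-1]) - cuts[-7], 0)
    sum(full * cfg$baseline_hazard)
  }
  tg <- seq(10, 990, by = 10)
  S_emp <- vapply(tg, function(t) mean(Tx > t), 0)
  S_th <- exp(-vapply(tg, Hfun, 0))
  expect_lt(max(abs(S_emp - S_th)), 0.03)
})
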
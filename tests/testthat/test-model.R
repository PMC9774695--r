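make_params <- function(alpha = c(0, 0.1, -0.6), gamma = c(0.3, 0.6),
                        log_h0 = log(rep(3e-4, 6)),
                        cuts = seq(0, 900, length.out = 7),
                        association = "slope") {
  cfg <- default_config(n_cows = 1, seed = 1)
  jm_params(specs = cfg$specs, beta = cfg$beta_true,
            sigma = unname(cfg$sigma_true), D = cfg$D_true,
            gamma = gamma, alpha = alpha, log_h0 = log_h0, cuts = cuts,
            association = association)
}

test_that("trajectory value and slope follow the mixed-model structure", {
  p <- make_params()
  cov0 <- list(afc_cat = "low", calving1_date = NULL)
  t <- c(10, 60, 150, 280)
  tr <- trajectory_value_and_slope(p, rep(0, 13), cov0, t, "MY")
  beta <- p$beta$MY
  expect_equal(tr$m, beta[1] + as.numeric(ns_basis(t, p$specs$MY) %*%
                                            beta[2:5]), tolerance = 1e-12)
  # analytic slope vs central finite differences
  h <- 1e-4
  set.seed(4)
  b <- rnorm(13, 0, 0.5)
  covw <- list(afc_cat = "high", calving1_date = as.Date("2015-01-10"))
  for (k in c("MY", "BW", "RUM")) {
    tt <- c(20.3, 77.7, 201.1)
    fd <- (trajectory_value_and_slope(p, b, cov0, tt + h, k)$m -
             trajectory_value_and_slope(p, b, cov0, tt - h, k)$m) / (2 * h)
    expect_lt(max(abs(fd - trajectory_value_and_slope(p, b, cov0, tt,
                                                      k)$m_slope)), 1e-6)
  }
  # AFC shifts the value but never the slope
  tr_low <- trajectory_value_and_slope(p, b, cov0, t, "BW")
  tr_high <- trajectory_value_and_slope(
    p, b, list(afc_cat = "high", calving1_date = NULL), t, "BW")
  expect_false(isTRUE(all.equal(tr_low$m, tr_high$m)))
  expect_equal(tr_low$m_slope, tr_high$m_slope, tolerance = 1e-12)
})

test_that("hazard is the baseline under null association and log-linear in it", {
  p0 <- make_params(alpha = c(0, 0, 0), gamma = c(0, 0))
  cov0 <- list(afc_cat = "high")
  t <- c(50, 200, 500, 880)
  expect_equal(hazard(t, p0, rep(0, 13), cov0), rep(3e-4, 4),
               tolerance = 1e-12)
  # adding delta to one association term multiplies the hazard by exp(delta)
  p1 <- make_params(alpha = c(0, 0, -0.6))
  p2 <- make_params(alpha = c(0, 0, -0.6 + 0.25))
  b <- rep(0, 13)
  sl <- trajectory_value_and_slope(p1, b, cov0, t, "RUM")$m_slope
  expect_equal(hazard(t, p2, b, cov0) / hazard(t, p1, b, cov0),
               exp(0.25 * sl), tolerance = 1e-10)
  # alpha3 < 0: a more negative rumination slope raises the hazard
  b_steep <- rep(0, 13); b_steep[12:13] <- c(-150, -150)
  sl_flat <- trajectory_value_and_slope(p1, b, cov0, 200, "RUM")$m_slope
  sl_steep <- trajectory_value_and_slope(p1, b_steep, cov0, 200, "RUM")$m_slope
  expect_lt(sl_steep, sl_flat)
  expect_gt(hazard(200, p1, b_steep, cov0), hazard(200, p1, b, cov0))
  # overflow guard
  p_big <- make_params(alpha = c(0, 0, 500))
  expect_error(hazard(200, p_big, b_steep, list(afc_cat = "low",
                                                cow_id = "c9")),
               "overflow")
})

test_that("cumulative hazard quadrature matches brute-force integration", {
  p <- make_params(log_h0 = log(c(1, 2, 3, 4, 5, 6) * 1e-4))
  set.seed(8)
  b <- as.numeric(rmvn(1, rep(0, 13), 0.25 * p$D))
  cov0 <- list(afc_cat = "medium")
  expect_equal(cumulative_hazard(100, 100, p, b, cov0), 0)
  # constant hazard: closed form h * (u - v)
  p_const <- make_params(alpha = c(0, 0, 0), gamma = c(0, 0),
                         log_h0 = log(rep(2e-4, 6)))
  expect_equal(cumulative_hazard(30, 530, p_const, b, cov0), 2e-4 * 500,
               tolerance = 1e-10)
  # Gauss-Legendre vs 10^4-point trapezoid split at the baseline jumps
  H <- cumulative_hazard(10, 700, p, b, cov0)
  brk <- c(p$cuts, 80, 155, 230, 5, 305)
  edges <- sort(unique(c(10, 700, brk[brk > 10 & brk < 700])))
  H_trap <- 0
  for (s in seq_len(length(edges) - 1)) {
    tg <- seq(edges[s], edges[s + 1], length.out = 32769)
    hh <- hazard(tg, p, b, cov0)
    H_trap <- H_trap + sum((hh[-1] + hh[-length(hh)]) / 2 * diff(tg))
  }
  expect_lt(abs(H - H_trap) / H_trap, 1e-5)
  expect_error(cumulative_hazard(100, 50, p, b, cov0), ">= v")
})

test_that("log posterior: longitudinal maximum coincides with least squares", {
  hh <- cached_herd(30, 41)
  herd <- thin_observations(hh$herd, 7L)
  des <- build_design(herd)
  p0 <- make_params()
  n <- des$n
  b0 <- matrix(0, n, 13)
  p0$specs <- des$specs  # the same basis must underlie X and the model
  for (k in c("MY", "RUM")) {
    raw <- des$raw[[k]]
    spec <- des$specs[[k]]
    amed <- des$W[raw$cow_idx, 1]; ahigh <- des$W[raw$cow_idx, 2]
    X <- cbind(1, ns_basis(raw$t, spec), amed, ahigh, raw$warm)
    ols <- qr.solve(X, raw$y)
    pk <- ncol(X)
    ll_k <- function(beta_k) {
      p <- p0
      p$beta[[k]] <- c(beta_k, p0$beta[[k]][-seq_len(pk)])
      log_posterior(p, b0, des, include = "longitudinal")
    }
    # the longitudinal log-likelihood is exactly quadratic in beta, so the
    # central difference is the exact gradient: it must vanish at OLS
    h <- 1e-3
    grad <- vapply(seq_len(pk), function(j) {
      e <- numeric(pk); e[j] <- h
      (ll_k(ols + e) - ll_k(ols - e)) / (2 * h)
    }, 0)
    expect_lt(max(abs(grad)), 1e-5)
    # and OLS dominates perturbed coefficients
    set.seed(2)
    for (r in 1:3)
      expect_gte(ll_k(ols), ll_k(ols + rnorm(pk, 0, 0.05)))
  }
})

test_that("log posterior survival term responds exactly to baseline shifts", {
  hh <- cached_herd(30, 41)
  herd <- thin_observations(hh$herd, 7L)
  des <- build_design(herd)
  p <- make_params(cuts = des$cuts,
                   log_h0 = log(rep(3e-4, des$n_int)))
  set.seed(5)
  b <- rmvn(des$n, rep(0, 13), 0.1 * p$D)
  s0 <- log_posterior(p, b, des, include = "survival")
  cshift <- 0.37
  p2 <- p; p2$log_h0 <- p$log_h0 + cshift
  s1 <- log_posterior(p2, b, des, include = "survival")
  Hsum <- sum(vapply(seq_len(des$n), function(i)
    cumulative_hazard(0, des$survival$T[i], p, b[i, ],
                      des$covariates[i, ]), 0))
  d <- sum(des$survival$event)
  expect_equal(s1 - s0, d * cshift - (exp(cshift) - 1) * Hsum,
               tolerance = 1e-8)
  # finite at the generating values, and component attribution works
  expect_true(is.finite(log_posterior(p, b, des)))
  pbad <- p; pbad$log_h0[1] <- 800
  expect_error(log_posterior(pbad, b, des, include = "survival"),
               "survival")
})

test_that("log posterior is invariant to permuting the cow order", {
  hh <- cached_herd(30, 41)
  herd <- thin_observations(hh$herd, 7L)
  set.seed(9)
  perm <- sample(nrow(herd$cows))
  herd2 <- herd
  herd2$cows <- herd$cows[perm, ]
  herd2$survival <- herd$survival[perm, ]
  des1 <- build_design(herd)
  des2 <- build_design(herd2)
  p <- make_params(cuts = des1$cuts, log_h0 = log(rep(3e-4, des1$n_int)))
  b <- rmvn(des1$n, rep(0, 13), 0.1 * p$D)
  b2 <- b[match(des2$cow_id, des1$cow_id), ]
  l1 <- log_posterior(p, b, des1, include = c("longitudinal", "survival",
                                              "ranef"))
  l2 <- log_posterior(p, b2, des2, include = c("longitudinal", "survival",
                                               "ranef"))
  expect_equal(l1, l2, tolerance = 1e-9)
})
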
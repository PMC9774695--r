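test_that("the design matches the data layout and the stacked dimension", {
  hh <- cached_herd(40, 13)
  herd <- hh$herd
  des <- build_design(herd)
  expect_s3_class(des, "jm_design")
  expect_equal(des$q, 13L)  # (1+4) + (1+4) + (1+2) random coefficients
  for (k in c("MY", "BW", "RUM")) {
    col <- herdsurv:::sensor_cols[[k]]
    expect_equal(des$long[[k]]$N, sum(!is.na(herd$sensor[[col]])))
  }
  # reference AFC category contributes no dummy
  low <- which(des$covariates$afc_cat == "low")
  expect_true(all(des$W[low, ] == 0))
  expect_equal(ncol(des$W), 2L)
  # a cow without observations for an outcome is refused by name
  broken <- herd
  cid <- broken$cows$cow_id[1]
  broken$sensor$rum_min[broken$sensor$cow_id == cid] <- NA
  expect_error(build_design(broken), paste0(cid, ".*RUM"))
})

test_that("sampler survival likelihood agrees with the definitional model", {
  fit <- cached_fit()
  hh <- cached_herd(80, 7, thin = 3)
  des <- build_design(hh$herd)
  pp <- herdsurv:::draw_params(fit, 25L)
  b_std <- fit$b_draws[dim(fit$b_draws)[1], , ]
  # internal (cached linear predictor) path
  nd <- des$node
  an <- numeric(length(nd$t)); ae <- numeric(des$n)
  for (k in seq_along(des$specs)) {
    blk <- des$blocks[[k]]
    an <- an + pp$alpha[k] *
      (as.numeric(des$XA[[k]] %*% pp$beta[[k]]) +
         rowSums(des$ZA[[k]] * b_std[nd$cow, blk, drop = FALSE]))
    ae <- ae + pp$alpha[k] *
      (as.numeric(des$XAe[[k]] %*% pp$beta[[k]]) +
         rowSums(des$ZAe[[k]] * b_std[, blk, drop = FALSE]))
  }
  gw <- as.numeric(des$W %*% pp$gamma)
  sc <- herdsurv:::surv_eval(des, an, ae, gw, pp$logh0)
  # definitional path on the natural scale
  kn <- names(des$specs)
  s_k <- vapply(des$scale, `[[`, 0, "scale")
  beta_nat <- Map(function(k, i) herdsurv:::std_to_nat_beta(
    pp$beta[[k]], des$scale[[k]], des$specs[[k]]), kn, seq_along(kn))
  names(beta_nat) <- kn
  S <- diag(rep(s_k, times = vapply(des$specs, function(s) 1 + s$dim, 0)))
  b_nat <- b_std %*% S
  params <- jm_params(des$specs, beta_nat, sigma = pp$sigma * s_k,
                      D = S %*% pp$D %*% S, gamma = pp$gamma,
                      alpha = pp$alpha, log_h0 = pp$logh0, cuts = des$cuts)
  ll_def <- log_posterior(params, b_nat, des, include = "survival")
  expect_equal(sc$ll, ll_def, tolerance = 1e-5)
})

test_that("fits are reproducible under a fixed seed", {
  hh <- cached_herd(40, 13)
  herd <- thin_observations(hh$herd, 7L)
  mc <- mcmc_control(chains = 2, burnin = 40, iter = 40)
  f1 <- fit_joint_model(herd, mcmc = mc, seed = 77)
  f2 <- fit_joint_model(herd, mcmc = mc, seed = 77)
  expect_identical(f1$draws, f2$draws)
  f3 <- fit_joint_model(herd, mcmc = mc, seed = 78)
  expect_false(identical(f1$draws, f3$draws))
  # draw bookkeeping: kept iterations x chains
  expect_equal(nrow(f1$draws), 80L)
  expect_true(all(c("alpha.RUM", "gamma.high") %in%
                    names(f1$diagnostics$rhat)))
})

test_that("with survival switched off the fit matches a linear mixed model", {
  cfg <- default_config(n_cows = 60, seed = 51, baseline_hazard = rep(1e-9, 6),
                        calving_span = 1)
  herd <- thin_observations(preprocess_herd(generate_herd(cfg))$herd, 5L)
  expect_true(all(herd$survival$event == 0))
  expect_equal(length(unique(herd$survival$T)), 1L)  # common censoring day
  des <- build_design(herd)
  fit <- fit_mcmc(des, mcmc_control(chains = 1, burnin = 250, iter = 500),
                  seed = 3, fix = list(alpha = 0, gamma = 0, logh0 = -30))
  # univariate oracle: REML=FALSE mixed model on the standardized outcome
  k <- "MY"
  raw <- des$raw[[k]]
  sc <- des$scale[[k]]
  B <- ns_basis(raw$t, des$specs[[k]])
  df <- data.frame(y = (raw$y - sc$center) / sc$scale,
                   B1 = B[, 1], B2 = B[, 2], B3 = B[, 3], B4 = B[, 4],
                   amed = des$W[raw$cow_idx, 1],
                   ahigh = des$W[raw$cow_idx, 2],
                   warm = raw$warm, cow = raw$cow_idx)
  lf <- lme4::lmer(
    y ~ B1 + B2 + B3 + B4 + amed + ahigh + warm +
      (1 + B1 + B2 + B3 + B4 | cow),
    data = df, REML = FALSE,
    control = lme4::lmerControl(check.conv.grad = "ignore",
                                check.conv.hess = "ignore"))
  beta_hat <- unname(lme4::fixef(lf))
  post <- unname(colMeans(fit$draws[, grep("^beta\\.MY\\.",
                                           colnames(fit$draws))]))
  # order: intercept, spline 1-4, AFC medium, AFC high, SEAS warm.
  # the univariate oracle ignores the cross-outcome coupling the joint fit
  # estimates, so agreement is judged on the oracle's own standard errors
  se <- sqrt(diag(as.matrix(vcov(lf))))
  expect_lt(max(abs(post - beta_hat) / se), 1.2)
  sig_post <- mean(fit$draws[, "sigma.MY"])
  expect_lt(abs(sig_post / sigma(lf) - 1), 0.05)
})

test_that("posterior hazards are positive with monotone cumulative hazard", {
  fit <- cached_fit()
  hh <- cached_herd(80, 7, thin = 3)
  des <- build_design(hh$herd)
  kn <- names(des$specs)
  s_k <- vapply(des$scale, `[[`, 0, "scale")
  S <- diag(rep(s_k, times = vapply(des$specs, function(s) 1 + s$dim, 0)))
  cov0 <- list(afc_cat = "medium")
  set.seed(12)
  for (d in sample(fit$n_draws, 5)) {
    pp <- herdsurv:::draw_params(fit, d)
    beta_nat <- setNames(lapply(kn, function(k) herdsurv:::std_to_nat_beta(
      pp$beta[[k]], des$scale[[k]], des$specs[[k]])), kn)
    params <- jm_params(des$specs, beta_nat, sigma = pp$sigma * s_k,
                        D = S %*% pp$D %*% S, gamma = pp$gamma,
                        alpha = pp$alpha, log_h0 = pp$logh0,
                        cuts = des$cuts)
    b <- as.numeric(rmvn(1, rep(0, 13), params$D * 0.2))
    tg <- seq(5, 800, by = 45)
    expect_true(all(hazard(tg, params, b, cov0) > 0))
    H <- vapply(tg, function(u) cumulative_hazard(5, u, params, b, cov0), 0)
    expect_true(all(diff(H) >= 0))
  }
})

test_that("a negative rumination association is recovered in sign", {
  cfg <- default_config(n_cows = 150, seed = 61)   # alpha3 = -0.6
  herd <- thin_observations(preprocess_herd(generate_herd(cfg))$herd, 3L)
  fit <- fit_joint_model(herd,
                         mcmc = mcmc_control(chains = 1, burnin = 350,
                                             iter = 450), seed = 8)
  a3 <- association_draws(fit)[, "alpha.RUM"]
  expect_gt(mean(a3 < 0), 0.9)
})
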
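# shared fixtures, generated in code and cached for the session

small_herd_cache <- new.env()

# a preprocessed mid-size herd with default truths (daily data)
cached_herd <- function(n_cows = 80, seed = 7, thin = NULL) {
  key <- paste0("h", n_cows, "_", seed, "_", thin %||% 0)
  if (is.null(small_herd_cache[[key]])) {
    cfg <- default_config(n_cows = n_cows, seed = seed)
    pp <- preprocess_herd(generate_herd(cfg))
    herd <- pp$herd
    if (!is.null(thin)) herd <- thin_observations(herd, thin)
    small_herd_cache[[key]] <- list(cfg = cfg, herd = herd, report = pp$report)
  }
  small_herd_cache[[key]]
}

# a short-chain fit on the cached herd, shared by prediction tests
cached_fit <- function() {
  if (is.null(small_herd_cache$fit)) {
    hh <- cached_herd(80, 7, thin = 3)
    small_herd_cache$fit <- fit_joint_model(
      hh$herd, mcmc = mcmc_control(chains = 1, burnin = 250, iter = 350),
      seed = 99)
  }
  small_herd_cache$fit
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# hand-constructed fit with repeated identical posterior draws: gives exact
# control of the parameters the prediction machinery sees
fake_fit <- function(specs, beta_std, sigma_std, D_std, alpha, gamma,
                     logh0, cuts, scale, n_draws = 200,
                     association = "slope", t1 = 410, t2 = 820) {
  q <- sum(vapply(specs, function(s) 1L + s$dim, 0L))
  li <- lower.tri(matrix(0, q, q), diag = TRUE)
  kn <- names(specs)
  row <- c(unlist(beta_std), sigma_std, D_std[li], alpha, gamma, logh0, 0)
  cn <- c(
    unlist(lapply(kn, function(k)
      paste0("beta.", k, ".", seq_along(beta_std[[k]])))),
    paste0("sigma.", kn), paste0("D.", seq_len(sum(li))),
    paste0("alpha.", kn), c("gamma.medium", "gamma.high"),
    paste0("logh0.", seq_along(logh0)), "surv_loglik")
  draws <- matrix(rep(row, each = n_draws), n_draws,
                  dimnames = list(NULL, cn))
  fit <- structure(list(
    draws = draws, n_draws = n_draws, scale = scale, specs = specs,
    cuts = cuts, association = association,
    blocks = herdsurv:::re_blocks(specs), q = q, t1 = t1, t2 = t2
  ), class = "jm_fit")
  fit$col_idx <- herdsurv:::param_cols(draws, kn)
  fit
}

# one-outcome reduction: intercept + linear time trend (natural spline with
# no interior knots is linear), random effects of dimension 2
reduced_fit <- function(sigma_std, alpha, D_std = diag(2), n_draws = 200,
                        logh0 = log(rep(3e-4, 3))) {
  specs <- list(MY = spline_spec(numeric(0), c(5, 305)))
  fake_fit(specs,
           beta_std = list(MY = c(0, 0.5, 0, 0, 0)),
           sigma_std = sigma_std, D_std = D_std, alpha = alpha,
           gamma = c(0, 0), logh0 = logh0,
           cuts = c(0, 300, 600, 900),
           scale = list(MY = list(center = 0, scale = 1)),
           n_draws = n_draws)
}

reduced_cow <- function(b_true, sigma, days = 5:60, seed = 1) {
  set.seed(seed)
  specs <- spline_spec(numeric(0), c(5, 305))
  B <- ns_basis(days, specs)
  m <- 0 + B %*% 0.5 + b_true[1] + B %*% b_true[2]
  list(sensor = data.frame(cow_id = "c1", dim = days,
                           my_kg = as.numeric(m) + rnorm(length(days), 0,
                                                         sigma),
                           bw_kg = NA, rum_min = NA),
       afc_cat = "low", calving1_date = NULL, cow_id = "c1")
}

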
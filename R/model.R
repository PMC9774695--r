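#' Joint-model parameter set
#'
#' Collects, on the natural measurement scale, every parameter of the joint
#' model: per-outcome fixed effects `beta` (intercept, spline coefficients,
#' AFC medium, AFC high, SEAS warm), residual SDs `sigma`, the unstructured
#' covariance `D` of the stacked random effects, AFC log-hazard coefficients
#' `gamma` (medium, high vs low), association coefficients `alpha` (per unit
#' slope/day of MY, BW, RUM under the slope association), and a
#' piecewise-constant baseline hazard with log-rates `log_h0` on the
#' intervals defined by `cuts`.
#'
#' @param specs named list of [spline_spec()] for MY, BW, RUM
#' @param beta named list of fixed-effect vectors
#' @param sigma residual SDs (length 3, positive)
#' @param D q x q random-effects covariance, q = sum over outcomes of
#'   (1 + spline dimension)
#' @param gamma length-2 AFC log-hazard coefficients
#' @param alpha length-3 association coefficients
#' @param log_h0 log baseline rates (events/day), one per interval
#' @param cuts interval boundaries, `length(log_h0) + 1` increasing values
#'   starting at 0; the last rate extends beyond `max(cuts)`
#' @param association `"slope"` (hazard depends on trajectory derivatives) or
#'   `"value"` (on current trajectory values)
#' @return object of class `jm_params`
#' @export
jm_params <- function(specs, beta, sigma, D, gamma, alpha, log_h0, cuts,
                      association = c("slope", "value")) {
  association <- match.arg(association)
  stopifnot(all(sigma > 0), all(is.finite(log_h0)),
            length(cuts) == length(log_h0) + 1, !is.unsorted(cuts),
            cuts[1] == 0)
  q <- sum(vapply(specs, function(s) 1L + s$dim, 0L))
  D <- (D + t(D)) / 2
  if (nrow(D) != q) stop("D has dimension ", nrow(D), ", expected ", q)
  if (min(eigen(D, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop("D must be positive definite")
  structure(list(specs = specs, beta = beta, sigma = sigma, D = D,
                 gamma = gamma, alpha = alpha, log_h0 = log_h0, cuts = cuts,
                 association = association),
            class = "jm_params")
}

afc_dummies <- function(afc_cat) {
  c(medium = as.numeric(afc_cat == "medium"),
    high = as.numeric(afc_cat == "high"))
}

log_h0_at <- function(params, t) {
  idx <- pmax(pmin(findInterval(t, params$cuts, rightmost.closed = FALSE),
                   length(params$log_h0)), 1L)
  params$log_h0[idx]
}

#' Trajectory value and slope for one cow
#'
#' Evaluates the noiseless trajectory `m_ik(t)` of outcome `k` and its
#' analytic derivative. AFC and SEAS are (piecewise) constant in time, so
#' only the spline part contributes to the slope.
#'
#' @param params a [jm_params()]
#' @param b_i stacked random-effect vector for the cow
#' @param covariates list/row with `afc_cat` and optionally `calving1_date`
#'   (needed to resolve SEAS; without it the cold season is assumed)
#' @param t evaluation times (DIM / days post first calving)
#' @param k outcome name ("MY", "BW", "RUM") or index
#' @return list `m`, `m_slope` (vectors along `t`)
#' @export
trajectory_value_and_slope <- function(params, b_i, covariates, t, k) {
  if (is.numeric(k)) k <- names(params$specs)[k]
  spec <- params$specs[[k]]
  blocks <- re_blocks(params$specs)
  bk <- b_i[blocks[[match(k, names(params$specs))]]]
  beta <- params$beta[[k]]
  p <- 1 + spec$dim
  warm <- if (!is.null(covariates$calving1_date) &&
              !is.na(covariates$calving1_date)) {
    as.numeric(is_warm(as.Date(covariates$calving1_date) + t))
  } else rep(0, length(t))
  ad <- afc_dummies(covariates$afc_cat)
  B <- ns_basis(t, spec)
  m <- beta[1] + as.numeric(B %*% beta[2:p]) +
    beta[p + 1] * ad[["medium"]] + beta[p + 2] * ad[["high"]] +
    beta[p + 3] * warm + bk[1] + as.numeric(B %*% bk[-1])
  slope <- as.numeric(ns_basis_deriv(t, spec) %*% (beta[2:p] + bk[-1]))
  list(m = m, m_slope = slope)
}

#' Culling hazard for one cow
#'
#' `h_i(t) = h0(t) exp(gamma' AFC_i + sum_k alpha_k a_ik(t))` where `a_ik` is
#' the trajectory slope (default association) or the trajectory value.
#'
#' @inheritParams trajectory_value_and_slope
#' @param t times (days post first calving), vectorized
#' @return hazard rates (events/day)
#' @export
hazard <- function(t, params, b_i, covariates) {
  ad <- afc_dummies(covariates$afc_cat)
  lp <- rep(sum(params$gamma * ad), length(t))
  for (k in names(params$specs)) {
    tr <- trajectory_value_and_slope(params, b_i, covariates, t, k)
    a <- if (params$association == "slope") tr$m_slope else tr$m
    lp <- lp + params$alpha[[match(k, names(params$specs))]] * a
  }
  if (any(abs(lp) > 50))
    stop("hazard overflow: |linear predictor| > 50 for cow ",
         covariates$cow_id %||% "?")
  exp(log_h0_at(params, t) + lp)
}

#' Cumulative hazard by Gauss-Legendre quadrature
#'
#' Integrates the hazard over `[v, u]` with a fixed-order Gauss-Legendre rule
#' on each baseline-hazard interval intersected with `[v, u]`, so the
#' piecewise-constant baseline never straddles a quadrature panel.
#'
#' @inheritParams hazard
#' @param v,u integration limits, `0 <= v <= u`
#' @param quad_points nodes per panel (default 15)
#' @return the cumulative hazard `H_i(v, u)`
#' @export
cumulative_hazard <- function(v, u, params, b_i, covariates,
                              quad_points = 15) {
  if (u < v) stop("u must be >= v")
  if (u == v) return(0)
  # panels split at the baseline-rate jumps and at the spline knots, so the
  # integrand is analytic on every panel
  kinks <- unlist(lapply(params$specs, function(s)
    c(s$interior_knots, s$boundary_knots)))
  brk <- c(params$cuts, kinks)
  edges <- sort(unique(c(v, u, brk[brk > v & brk < u])))
  total <- 0
  for (s in seq_len(length(edges) - 1)) {
    gl <- gauss_legendre(quad_points, edges[s], edges[s + 1])
    total <- total + sum(gl$weights * hazard(gl$nodes, params, b_i, covariates))
  }
  total
}

#' Log posterior of the joint model
#'
#' Definitional (unoptimized) evaluation used for testing and diagnostics:
#' Gaussian longitudinal log-likelihood, survival log-likelihood
#' `sum_i [d_i log h_i(T_i) - H_i(0, T_i)]`, the random-effects density
#' `sum_i log N(b_i; 0, D)` and the log-priors. Components can be switched
#' off to isolate terms.
#'
#' @param params a [jm_params()] (natural scale)
#' @param b_all n x q matrix of random effects (cow order of `design`)
#' @param design a [build_design()] object
#' @param include character subset of
#'   `c("longitudinal", "survival", "ranef", "prior")`
#' @return scalar log posterior (up to additive constants in the priors)
#' @export
log_posterior <- function(params, b_all, design,
                          include = c("longitudinal", "survival", "ranef",
                                      "prior")) {
  total <- 0
  comp <- function(x, label) {
    if (!is.finite(x)) stop("non-finite log-posterior component: ", label)
    x
  }
  n <- design$n
  if ("longitudinal" %in% include) {
    ll <- 0
    for (k in names(params$specs)) {
      raw <- design$raw[[k]]
      for (i in seq_len(n)) {
        rows <- raw$cow_idx == i
        if (!any(rows)) next
        tr <- trajectory_value_and_slope(
          params, b_all[i, ], design$covariates[i, ], raw$t[rows], k)
        ll <- ll + sum(dnorm(raw$y[rows], tr$m,
                             params$sigma[[match(k, names(params$specs))]],
                             log = TRUE))
      }
    }
    total <- total + comp(ll, "longitudinal")
  }
  if ("survival" %in% include) {
    ll <- 0
    for (i in seq_len(n)) {
      cov_i <- design$covariates[i, ]
      Ti <- design$survival$T[i]
      if (design$survival$event[i] == 1)
        ll <- ll + log(hazard(Ti, params, b_all[i, ], cov_i))
      ll <- ll - cumulative_hazard(0, Ti, params, b_all[i, ], cov_i)
    }
    total <- total + comp(ll, "survival")
  }
  if ("ranef" %in% include) {
    Dinv <- chol2inv(chol(params$D))
    ld <- determinant(params$D, logarithm = TRUE)$modulus
    ll <- -0.5 * n * (ld + ncol(b_all) * log(2 * pi)) -
      0.5 * sum((b_all %*% Dinv) * b_all)
    total <- total + comp(as.numeric(ll), "ranef")
  }
  if ("prior" %in% include) {
    pr <- design$priors
    lp <- 0
    for (k in names(params$specs)) {
      bstd <- nat_to_std_beta(params$beta[[k]], design$scale[[k]],
                              params$specs[[k]])
      lp <- lp + sum(dnorm(bstd, 0, sqrt(pr$beta_var), log = TRUE))
      s2 <- (params$sigma[[match(k, names(params$specs))]] /
               design$scale[[k]]$scale)^2
      lp <- lp + (-(pr$sigma_a + 1) * log(s2) - pr$sigma_b / s2)
    }
    lp <- lp + sum(dnorm(params$alpha, 0, sqrt(pr$assoc_var), log = TRUE)) +
      sum(dnorm(params$gamma, 0, sqrt(pr$assoc_var), log = TRUE))
    lp <- lp + dnorm(params$log_h0[1], 0, 10, log = TRUE) +
      sum(dnorm(diff(params$log_h0), 0, pr$h0_rw_sd, log = TRUE))
    # inverse-Wishart prior on standardized-scale D
    Sd <- diag(1 / rep(vapply(design$scale, `[[`, 0, "scale"),
                       times = vapply(params$specs, function(s) 1 + s$dim, 0)))
    Dstd <- Sd %*% params$D %*% Sd
    q <- nrow(Dstd)
    Dinv <- chol2inv(chol(Dstd))
    lp <- lp - 0.5 * (pr$d_nu + q + 1) *
      as.numeric(determinant(Dstd, logarithm = TRUE)$modulus) -
      0.5 * sum(diag(Dinv))
    total <- total + comp(lp, "prior")
  }
  total
}

# natural-scale beta -> standardized-scale beta for one outcome
nat_to_std_beta <- function(beta, scale_k, spec) {
  p <- 1 + spec$dim
  out <- beta / scale_k$scale
  out[1] <- (beta[1] - scale_k$center) / scale_k$scale
  out
}
std_to_nat_beta <- function(beta, scale_k, spec) {
  out <- beta * scale_k$scale
  out[1] <- beta[1] * scale_k$scale + scale_k$center
  out
}
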
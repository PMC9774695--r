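#' Model design for the multivariate joint model
#'
#' Turns a preprocessed herd into the matrices the sampler consumes: per
#' outcome a fixed design (intercept, natural spline of DIM, AFC dummies,
#' SEAS dummy) and random design (intercept, spline), internally z-scored per
#' outcome for sampler conditioning; a survival design with AFC dummies; a
#' piecewise-constant baseline-hazard grid with intervals cut at event-time
#' quantiles of the training data; and a per-cow Gauss-Legendre rule for the
#' cumulative hazard, with panels never straddling a baseline interval.
#'
#' @param herd preprocessed `herd_dataset` (from [preprocess_herd()])
#' @param specs optional named list of [spline_spec()]; defaults to
#'   [make_knots()] on the pooled observed DIM values per outcome
#' @param association hazard association: trajectory `"slope"` (default) or
#'   current `"value"`
#' @param n_intervals baseline-hazard intervals (default 6)
#' @param quad_points Gauss-Legendre nodes per panel (default 15)
#' @param priors optional overrides: `beta_var`, `sigma_a`, `sigma_b`,
#'   `d_nu`, `assoc_var`, `h0_rw_sd`
#' @return object of class `jm_design`
#' @export
build_design <- function(herd, specs = NULL,
                         association = c("slope", "value"),
                         n_intervals = 6, quad_points = 15, priors = list()) {
  association <- match.arg(association)
  sensor <- herd$sensor
  cows <- herd$cows
  survival <- herd$survival
  survival <- survival[match(cows$cow_id, survival$cow_id), , drop = FALSE]
  n <- nrow(cows)
  ci_all <- match(sensor$cow_id, cows$cow_id)
  if (is.null(specs)) {
    specs <- list()
    for (k in names(sensor_cols)) {
      col <- sensor_cols[[k]]
      specs[[k]] <- make_knots(sensor$dim[!is.na(sensor[[col]])], k)
    }
  }
  warm_all <- if (!is.null(sensor$season)) {
    as.numeric(sensor$season == "warm")
  } else as.numeric(is_warm(as.Date(sensor$date)))
  amed <- as.numeric(cows$afc_cat == "medium")
  ahigh <- as.numeric(cows$afc_cat == "high")
  covariates <- data.frame(cow_id = cows$cow_id, afc_cat = cows$afc_cat,
                           calving1_date = cows$calving1_date %||%
                             as.Date(NA))
  long <- list(); raw <- list(); scale <- list()
  for (k in names(specs)) {
    col <- sensor_cols[[k]]
    rows <- !is.na(sensor[[col]])
    t <- sensor$dim[rows]
    yv <- sensor[[col]][rows]
    ci <- ci_all[rows]
    cnt <- tabulate(ci, n)
    if (any(cnt == 0))
      stop("cow ", cows$cow_id[which(cnt == 0)[1]],
           " has no observations for outcome ", k)
    center <- mean(yv); scl <- sd(yv)
    y <- (yv - center) / scl
    B <- ns_basis(t, specs[[k]])
    X <- cbind(1, B, amed[ci], ahigh[ci], warm_all[rows])
    Z <- cbind(1, B)
    qk <- ncol(Z); pk <- ncol(X)
    ZZ <- Z[, rep(seq_len(qk), times = qk)] * Z[, rep(seq_len(qk), each = qk)]
    ZX <- Z[, rep(seq_len(qk), times = pk)] * X[, rep(seq_len(pk), each = qk)]
    long[[k]] <- list(
      XtX = crossprod(X), Xty = as.numeric(crossprod(X, y)),
      yty = sum(y^2), N = length(y), p = pk, q = qk,
      ZtZ = rowsum(ZZ, ci), Zty = rowsum(Z * y, ci), ZtX = rowsum(ZX, ci)
    )
    raw[[k]] <- list(t = t, y = yv, cow_idx = ci, warm = warm_all[rows])
    scale[[k]] <- list(center = center, scale = scl)
  }
  q <- sum(vapply(long, `[[`, 0L, "q"))
  Tvec <- as.numeric(survival$T)
  event <- as.integer(survival$event)
  eT <- Tvec[event == 1]
  inner <- if (length(unique(eT)) >= 2 * n_intervals) {
    quantile(eT, seq_len(n_intervals - 1) / n_intervals, type = 7)
  } else {
    quantile(Tvec, seq_len(n_intervals - 1) / n_intervals, type = 7)
  }
  cuts <- sort(unique(c(0, as.numeric(inner), max(Tvec))))
  cuts <- cuts[cuts <= max(Tvec)]
  n_int <- length(cuts) - 1L
  gl01 <- gauss_legendre(quad_points, 0, 1)
  node_t <- node_w <- numeric(0); node_cow <- node_int <- integer(0)
  for (i in seq_len(n)) {
    edges <- sort(unique(c(0, cuts[cuts > 0 & cuts < Tvec[i]], Tvec[i])))
    for (s in seq_len(length(edges) - 1)) {
      a <- edges[s]; bseg <- edges[s + 1]
      node_t <- c(node_t, a + (bseg - a) * gl01$nodes)
      node_w <- c(node_w, (bseg - a) * gl01$weights)
      mid <- (a + bseg) / 2
      j <- max(1L, min(findInterval(mid, cuts), n_int))
      node_cow <- c(node_cow, rep(i, quad_points))
      node_int <- c(node_int, rep(j, quad_points))
    }
  }
  int_T <- pmax(1L, pmin(findInterval(Tvec, cuts,
                                      rightmost.closed = TRUE), n_int))
  # association designs carry the outcome's scale factor, so that the alpha
  # sampled against the standardized coefficients is already on the natural
  # per-unit scale (per kg/day or min/day of slope)
  XA <- ZA <- XAe <- ZAe <- list()
  for (k in names(specs)) {
    spec <- specs[[k]]
    pk <- long[[k]]$p
    s_k <- scale[[k]]$scale
    if (association == "slope") {
      Bd <- s_k * ns_basis_deriv(node_t, spec)
      Bde <- s_k * ns_basis_deriv(Tvec, spec)
      XA[[k]] <- cbind(0, Bd, 0, 0, 0)
      ZA[[k]] <- cbind(0, Bd)
      XAe[[k]] <- cbind(0, Bde, 0, 0, 0)
      ZAe[[k]] <- cbind(0, Bde)
    } else {
      # current-value association; the centering offset alpha_k * center_k
      # is constant over cows and time and is absorbed by the baseline
      B <- ns_basis(node_t, spec)
      Be <- ns_basis(Tvec, spec)
      node_dates <- covariates$calving1_date[node_cow] + node_t
      warm_n <- as.numeric(is_warm(node_dates))
      warm_e <- as.numeric(is_warm(covariates$calving1_date + Tvec))
      warm_n[is.na(warm_n)] <- 0; warm_e[is.na(warm_e)] <- 0
      XA[[k]] <- s_k * cbind(1, B, amed[node_cow], ahigh[node_cow], warm_n)
      ZA[[k]] <- s_k * cbind(1, B)
      XAe[[k]] <- s_k * cbind(1, Be, amed, ahigh, warm_e)
      ZAe[[k]] <- s_k * cbind(1, Be)
    }
  }
  pr <- list(beta_var = 1e4, sigma_a = 0.01, sigma_b = 0.01, d_nu = q + 2,
             assoc_var = 10, h0_rw_sd = 1)
  pr[names(priors)] <- priors
  structure(list(
    n = n, q = q, cow_id = cows$cow_id, covariates = covariates,
    specs = specs, scale = scale, long = long, raw = raw,
    survival = list(T = Tvec, event = event, int_T = int_T),
    W = cbind(medium = amed, high = ahigh),
    cuts = cuts, n_int = n_int,
    node = list(t = node_t, w = node_w, cow = node_cow, int = node_int,
                ends = cumsum(tabulate(node_cow, n))),
    XA = XA, ZA = ZA, XAe = XAe, ZAe = ZAe,
    association = association, priors = pr,
    blocks = re_blocks(specs),
    t1 = herd$t1, t2 = herd$t2, quartiles = herd$quartiles
  ), class = "jm_design")
}

#' MCMC settings
#'
#' @param chains number of chains (run sequentially with derived seeds)
#' @param burnin adaptation/warm-up iterations discarded per chain
#' @param iter kept iterations per chain (before thinning)
#' @param thin keep every `thin`-th draw
#' @param b_thin keep every `b_thin`-th random-effects draw
#' @return list of settings
#' @export
mcmc_control <- function(chains = 2L, burnin = 1500L, iter = 1500L,
                         thin = 1L, b_thin = 25L) {
  list(chains = as.integer(chains), burnin = as.integer(burnin),
       iter = as.integer(iter), thin = as.integer(thin),
       b_thin = as.integer(b_thin))
}

# per-cow sums over contiguous cow-major node runs (faster than rowsum)
groupsum <- function(x, ends) {
  cs <- cumsum(x)
  c(cs[ends[1]], diff(cs[ends]))
}

# survival log-likelihood from the association linear predictor caches
surv_eval <- function(des, assoc_node, assoc_event, gw, logh0) {
  nd <- des$node
  lp <- assoc_node + gw[nd$cow] + logh0[nd$int]
  lpe <- assoc_event + gw + logh0[des$survival$int_T]
  Lam <- groupsum(nd$w * exp(pmin(lp, 50)), nd$ends)
  ll_i <- des$survival$event * lpe - Lam
  bad <- abs(assoc_node) > 50
  if (any(bad)) ll_i[groupsum(as.numeric(bad), nd$ends) > 0] <- -Inf
  list(ll_i = ll_i, ll = sum(ll_i), Lambda = Lam, lpe = lpe)
}

run_chain <- function(des, burnin, iter, thin, b_thin, seed, fix = list()) {
  set.seed(seed)
  n <- des$n; q <- des$q; K <- length(des$specs)
  kn <- names(des$specs)
  pr <- des$priors
  blocks <- des$blocks
  nd <- des$node
  Tvec <- des$survival$T; event <- des$survival$event
  long_ZtZ <- lapply(des$long, `[[`, "ZtZ")
  long_Zty <- lapply(des$long, `[[`, "Zty")
  long_ZtX <- lapply(des$long, `[[`, "ZtX")
  ## initial values: per-outcome OLS, crude occurrence/exposure baseline
  beta <- list(); sigma2 <- numeric(K)
  for (k in seq_len(K)) {
    L <- des$long[[k]]
    bhat <- solve(L$XtX + diag(1e-8, L$p), L$Xty)
    beta[[k]] <- as.numeric(bhat)
    sigma2[k] <- max((L$yty - sum(bhat * L$Xty)) / L$N, 1e-4)
  }
  b <- matrix(0, n, q)
  D <- diag(0.5, q); Dinv <- diag(2, q)
  alpha <- rep(0, K); gamma <- c(0, 0)
  risk <- vapply(seq_len(des$n_int), function(j) {
    sum(pmax(pmin(Tvec, des$cuts[j + 1]) - des$cuts[j], 0))
  }, 0)
  dj <- tabulate(des$survival$int_T[event == 1], des$n_int)
  logh0 <- log((dj + 0.5) / (risk + 1))
  # optionally hold survival parameters at fixed values (used to isolate the
  # longitudinal submodel, e.g. against a standalone mixed-model fit)
  if (!is.null(fix$alpha)) alpha <- rep(fix$alpha, length.out = K)
  if (!is.null(fix$gamma)) gamma <- rep(fix$gamma, length.out = 2)
  if (!is.null(fix$logh0)) logh0 <- rep(fix$logh0, length.out = des$n_int)
  gw <- as.numeric(des$W %*% gamma)
  ## association caches: etaX/etaZ per outcome at nodes and event times
  etaX <- etaZ <- etaXe <- etaZe <- list()
  for (k in seq_len(K)) {
    blk <- blocks[[k]]
    etaX[[k]] <- as.numeric(des$XA[[k]] %*% beta[[k]])
    etaZ[[k]] <- as.numeric(assoc_ranef(des$ZA[[k]],
                                        b[, blk, drop = FALSE], nd$cow))
    etaXe[[k]] <- as.numeric(des$XAe[[k]] %*% beta[[k]])
    etaZe[[k]] <- rowSums(des$ZAe[[k]] * b[, blk, drop = FALSE])
  }
  assoc_sum <- function(a) {
    an <- numeric(length(nd$t)); ae <- numeric(n)
    for (k in seq_len(K)) {
      an <- an + a[k] * (etaX[[k]] + etaZ[[k]])
      ae <- ae + a[k] * (etaXe[[k]] + etaZe[[k]])
    }
    list(node = an, event = ae)
  }
  as_c <- assoc_sum(alpha)
  sc <- surv_eval(des, as_c$node, as_c$event, gw, logh0)
  ls_alpha <- log(1); ls_gamma <- log(0.2); ls_h <- rep(log(0.3), des$n_int)
  alpha_prec <- vapply(seq_len(K), function(k) {
    spread <- max(sd(etaX[[k]]), 1e-3)
    1 / (spread * sqrt(max(sum(event), 1)))
  }, 0)
  alpha_hist <- matrix(NA_real_, 200, K); ah_i <- 0L
  acc <- c(beta = 0, b = 0, alpha = 0, gamma = 0, h0 = 0)
  att <- c(beta = 0, b = 0, alpha = 0, gamma = 0, h0 = 0)
  win_acc <- c(alpha = 0, gamma = 0); win_att <- c(alpha = 0, gamma = 0)
  win_h_acc <- win_h_att <- rep(0, des$n_int)
  total <- burnin + iter
  kept <- floor(iter / thin)
  p_all <- sum(vapply(des$long, `[[`, 0L, "p"))
  nvech <- q * (q + 1) / 2
  draws <- matrix(NA_real_, kept, p_all + K + nvech + K + 2 + des$n_int + 1)
  b_keep <- array(NA_real_, c(max(1, floor(iter / b_thin)), n, q))
  li <- lower.tri(matrix(0, q, q), diag = TRUE)
  kept_i <- 0L; bkept_i <- 0L
  h0_prior <- function(lh) {
    dnorm(lh[1], 0, 10, log = TRUE) +
      sum(dnorm(diff(lh), 0, pr$h0_rw_sd, log = TRUE))
  }
  for (it in seq_len(total)) {
    adapting <- it <= burnin
    ## --- beta_k: conjugate longitudinal proposal, survival MH correction
    for (k in seq_len(K)) {
      L <- des$long[[k]]
      qk <- L$q; pk <- L$p
      bk <- b[, blocks[[k]], drop = FALSE]
      BBm <- bk[, rep(seq_len(qk), times = pk), drop = FALSE]
      v <- colSums(matrix(colSums(L$ZtX * BBm), qk, pk))
      Vinv <- L$XtX / sigma2[k] + diag(1 / pr$beta_var, pk)
      ch <- chol(Vinv)
      m <- backsolve(ch, backsolve(ch, (L$Xty - v) / sigma2[k],
                                   transpose = TRUE))
      prop <- as.numeric(m + backsolve(ch, rnorm(pk)))
      att["beta"] <- att["beta"] + 1
      if (alpha[k] == 0) {
        accept <- TRUE
        sc_p <- sc; an_p <- as_c$node; ae_p <- as_c$event
      } else {
        eX <- as.numeric(des$XA[[k]] %*% prop)
        eXe <- as.numeric(des$XAe[[k]] %*% prop)
        an_p <- as_c$node + alpha[k] * (eX - etaX[[k]])
        ae_p <- as_c$event + alpha[k] * (eXe - etaXe[[k]])
        sc_p <- surv_eval(des, an_p, ae_p, gw, logh0)
        accept <- log(runif(1)) < sc_p$ll - sc$ll
      }
      if (accept) {
        beta[[k]] <- prop
        etaX[[k]] <- as.numeric(des$XA[[k]] %*% prop)
        etaXe[[k]] <- as.numeric(des$XAe[[k]] %*% prop)
        as_c$node <- an_p; as_c$event <- ae_p; sc <- sc_p
        acc["beta"] <- acc["beta"] + 1
      }
    }
    ## --- sigma2_k: conjugate inverse-gamma
    for (k in seq_len(K)) {
      L <- des$long[[k]]
      qk <- L$q; pk <- L$p
      bk <- b[, blocks[[k]], drop = FALSE]
      BBm <- bk[, rep(seq_len(qk), times = pk), drop = FALSE]
      v <- colSums(matrix(colSums(L$ZtX * BBm), qk, pk))
      BBq <- bk[, rep(seq_len(qk), times = qk), drop = FALSE] *
        bk[, rep(seq_len(qk), each = qk), drop = FALSE]
      SS <- L$yty - 2 * sum(beta[[k]] * L$Xty) +
        sum(beta[[k]] * (L$XtX %*% beta[[k]])) -
        2 * sum(bk * L$Zty) + 2 * sum(v * beta[[k]]) + sum(L$ZtZ * BBq)
      sigma2[k] <- 1 / rgamma(1, pr$sigma_a + L$N / 2,
                              pr$sigma_b + max(SS, 1e-12) / 2)
    }
    ## --- b_i: conjugate longitudinal proposal + survival MH, all cows
    z <- matrix(rnorm(n * q), n, q)
    bprop <- propose_ranef(Dinv, sigma2, long_ZtZ, long_Zty, long_ZtX,
                           beta, blocks, z)
    an_p <- as_c$node; ae_p <- as_c$event
    eZp <- eZep <- list()
    for (k in seq_len(K)) {
      blk <- blocks[[k]]
      bpk <- bprop[, blk, drop = FALSE]
      eZp[[k]] <- as.numeric(assoc_ranef(des$ZA[[k]], bpk, nd$cow))
      eZep[[k]] <- rowSums(des$ZAe[[k]] * bpk)
      an_p <- an_p + alpha[k] * (eZp[[k]] - etaZ[[k]])
      ae_p <- ae_p + alpha[k] * (eZep[[k]] - etaZe[[k]])
    }
    sc_p <- surv_eval(des, an_p, ae_p, gw, logh0)
    accept_i <- log(runif(n)) < sc_p$ll_i - sc$ll_i
    att["b"] <- att["b"] + n
    acc["b"] <- acc["b"] + sum(accept_i)
    if (any(accept_i)) {
      b[accept_i, ] <- bprop[accept_i, ]
      mask <- accept_i[nd$cow]
      for (k in seq_len(K)) {
        etaZ[[k]][mask] <- eZp[[k]][mask]
        etaZe[[k]][accept_i] <- eZep[[k]][accept_i]
      }
      as_c$node[mask] <- an_p[mask]
      as_c$event[accept_i] <- ae_p[accept_i]
      sc$ll_i[accept_i] <- sc_p$ll_i[accept_i]
      sc$Lambda[accept_i] <- sc_p$Lambda[accept_i]
      sc$lpe[accept_i] <- sc_p$lpe[accept_i]
      sc$ll <- sum(sc$ll_i)
    }
    ## --- D: conjugate inverse-Wishart
    D <- rinvwishart(pr$d_nu + n, diag(q) + crossprod(b))
    Dinv <- chol2inv(chol(D))
    ## --- alpha: adaptive random-walk Metropolis (joint)
    if (is.null(fix$alpha)) {
    aprop <- alpha + exp(ls_alpha) * alpha_prec * rnorm(K)
    asp <- assoc_sum(aprop)
    sc_p <- surv_eval(des, asp$node, asp$event, gw, logh0)
    lr <- sc_p$ll - sc$ll +
      sum(dnorm(aprop, 0, sqrt(pr$assoc_var), log = TRUE)) -
      sum(dnorm(alpha, 0, sqrt(pr$assoc_var), log = TRUE))
    att["alpha"] <- att["alpha"] + 1; win_att["alpha"] <- win_att["alpha"] + 1
    if (log(runif(1)) < lr) {
      alpha <- aprop; as_c <- asp; sc <- sc_p
      acc["alpha"] <- acc["alpha"] + 1; win_acc["alpha"] <- win_acc["alpha"] + 1
    }
    }
    ## --- gamma: RWM via the time-constant factorization
    if (is.null(fix$gamma)) {
    Lam_tilde <- sc$Lambda * exp(-gw)
    lpe_nog <- sc$lpe - gw
    for (rep_g in 1:2) {
      gprop <- gamma + exp(ls_gamma) * rnorm(2)
      gwp <- as.numeric(des$W %*% gprop)
      ll_cur <- sum(event * gw) - sum(exp(gw) * Lam_tilde) +
        sum(dnorm(gamma, 0, sqrt(pr$assoc_var), log = TRUE))
      ll_p <- sum(event * gwp) - sum(exp(gwp) * Lam_tilde) +
        sum(dnorm(gprop, 0, sqrt(pr$assoc_var), log = TRUE))
      att["gamma"] <- att["gamma"] + 1; win_att["gamma"] <- win_att["gamma"] + 1
      if (log(runif(1)) < ll_p - ll_cur) {
        gamma <- gprop; gw <- gwp
        acc["gamma"] <- acc["gamma"] + 1
        win_acc["gamma"] <- win_acc["gamma"] + 1
      }
    }
    sc$Lambda <- Lam_tilde * exp(gw)
    sc$lpe <- lpe_nog + gw
    sc$ll_i <- event * sc$lpe - sc$Lambda
    sc$ll <- sum(sc$ll_i)
    }
    ## --- log h0: componentwise MH on the occurrence/exposure factorization
    if (is.null(fix$logh0)) {
    lp_noh <- as_c$node + gw[nd$cow]
    wexp <- nd$w * exp(pmin(lp_noh, 50))
    Fj <- as.numeric(rowsum(wexp, nd$int))
    jj <- sort(unique(nd$int))
    Fall <- numeric(des$n_int); Fall[jj] <- Fj
    for (j in seq_len(des$n_int)) {
      lhp <- logh0
      lhp[j] <- logh0[j] + exp(ls_h[j]) * rnorm(1)
      dll <- dj[j] * (lhp[j] - logh0[j]) -
        Fall[j] * (exp(lhp[j]) - exp(logh0[j])) +
        h0_prior(lhp) - h0_prior(logh0)
      att["h0"] <- att["h0"] + 1; win_h_att[j] <- win_h_att[j] + 1
      if (log(runif(1)) < dll) {
        logh0 <- lhp
        acc["h0"] <- acc["h0"] + 1; win_h_acc[j] <- win_h_acc[j] + 1
      }
    }
    }
    sc <- surv_eval(des, as_c$node, as_c$event, gw, logh0)
    if (adapting) {
      ah_i <- ah_i %% 200L + 1L
      alpha_hist[ah_i, ] <- alpha
    }
    ## --- adaptation (burn-in only), targeting 20-40% acceptance
    if (adapting && it %% 25 == 0) {
      if (it >= 100) {
        sds <- apply(alpha_hist, 2, sd, na.rm = TRUE)
        ok <- is.finite(sds) & sds > 0
        alpha_prec[ok] <- sds[ok]
      }
      tune <- function(ls, rate) {
        if (rate > 0.4) ls + 0.25 else if (rate < 0.2) ls - 0.25 else ls
      }
      if (win_att["alpha"] > 0)
        ls_alpha <- tune(ls_alpha, win_acc["alpha"] / win_att["alpha"])
      if (win_att["gamma"] > 0)
        ls_gamma <- tune(ls_gamma, win_acc["gamma"] / win_att["gamma"])
      for (j in seq_len(des$n_int)) {
        if (win_h_att[j] > 0)
          ls_h[j] <- tune(ls_h[j], win_h_acc[j] / win_h_att[j])
      }
      win_acc[] <- 0; win_att[] <- 0; win_h_acc[] <- 0; win_h_att[] <- 0
    }
    ## --- storage
    if (it > burnin) {
      post <- it - burnin
      if (post %% thin == 0) {
        kept_i <- kept_i + 1L
        draws[kept_i, ] <- c(unlist(beta), sqrt(sigma2), D[li],
                             alpha, gamma, logh0, sc$ll)
      }
      if (post %% b_thin == 0 && bkept_i < dim(b_keep)[1]) {
        bkept_i <- bkept_i + 1L
        b_keep[bkept_i, , ] <- b
      }
    }
  }
  cn <- c(
    unlist(lapply(kn, function(k)
      paste0("beta.", k, ".", seq_len(des$long[[k]]$p)))),
    paste0("sigma.", kn),
    paste0("D.", seq_len(nvech)),
    paste0("alpha.", kn),
    c("gamma.medium", "gamma.high"),
    paste0("logh0.", seq_len(des$n_int)),
    "surv_loglik"
  )
  colnames(draws) <- cn
  list(draws = draws[seq_len(kept_i), , drop = FALSE],
       b_keep = b_keep[seq_len(max(bkept_i, 1)), , , drop = FALSE],
       accept = acc / pmax(att, 1))
}

#' Fit the Bayesian multivariate joint model
#'
#' Metropolis-within-Gibbs sampler: per-outcome fixed effects and per-cow
#' random effects are proposed from their exact longitudinal-conjugate
#' Gaussian conditionals and accepted against the survival likelihood
#' (an exact independence Metropolis-Hastings step that reduces to a Gibbs
#' update when the association is null); residual variances and the
#' random-effects covariance are conjugate (inverse-gamma, inverse-Wishart);
#' association, AFC and log baseline-rate parameters use adaptive random-walk
#' Metropolis targeted to 20-40% acceptance. Outcomes are standardized
#' internally; association coefficients are reported back on the natural
#' per-unit-slope scale.
#'
#' @param design a [build_design()] object
#' @param mcmc a [mcmc_control()]
#' @param seed integer seed; chains use seeds derived from it
#' @return object of class `jm_fit`: `draws` (kept posterior draws, all
#'   chains stacked, standardized scale), `b_draws`, `scale`, `specs`,
#'   `cuts`, `diagnostics` (acceptance rates and split-Rhat for the
#'   association and AFC parameters), and the settings
#' @export
fit_mcmc <- function(design, mcmc = mcmc_control(), seed = 1L,
                     fix = list()) {
  chains <- lapply(seq_len(mcmc$chains), function(c) {
    run_chain(design, mcmc$burnin, mcmc$iter, mcmc$thin, mcmc$b_thin,
              derive_seed(seed, c), fix = fix)
  })
  draws <- do.call(rbind, lapply(chains, `[[`, "draws"))
  acc <- Reduce(`+`, lapply(chains, `[[`, "accept")) / mcmc$chains
  mon <- grep("^(alpha|gamma)", colnames(draws), value = TRUE)
  rhat <- vapply(mon, function(cn) split_rhat(draws[, cn], mcmc$chains), 0)
  warn <- character(0)
  if (any(rhat > 1.1, na.rm = TRUE))
    warn <- paste0("split-Rhat > 1.1 for: ",
                   paste(mon[which(rhat > 1.1)], collapse = ", "))
  fit <- structure(list(
    draws = draws,
    b_draws = chains[[1]]$b_keep,
    n_draws = nrow(draws),
    scale = design$scale,
    specs = design$specs,
    cuts = design$cuts,
    association = design$association,
    priors = design$priors,
    blocks = design$blocks,
    q = design$q,
    cow_id = design$cow_id,
    t1 = design$t1, t2 = design$t2,
    quartiles = design$quartiles,
    diagnostics = list(accept = acc, rhat = rhat, warnings = warn),
    mcmc = mcmc, seed = seed
  ), class = "jm_fit")
  fit$col_idx <- param_cols(draws, names(design$specs))
  fit
}

#' Natural-scale association and AFC coefficient draws
#'
#' @param fit a `jm_fit`
#' @return matrix of draws: `alpha.MY`, `alpha.BW`, `alpha.RUM` on the
#'   per-unit-slope natural scale, plus `gamma.medium`, `gamma.high`
#' @export
association_draws <- function(fit) {
  kn <- names(fit$specs)
  fit$draws[, c(paste0("alpha.", kn), "gamma.medium", "gamma.high"),
            drop = FALSE]
}

#' @export
print.jm_fit <- function(x, ...) {
  cat("Multivariate joint model fit (", x$association, " association)\n",
      sep = "")
  cat("  cows:", length(x$cow_id), " posterior draws:", x$n_draws, "\n")
  a <- association_draws(x)
  s <- t(apply(a, 2, function(v) c(mean = mean(v), sd = sd(v),
                                   q2.5 = unname(quantile(v, 0.025)),
                                   q97.5 = unname(quantile(v, 0.975)))))
  print(round(s, 4))
  if (length(x$diagnostics$warnings))
    cat("  warning:", x$diagnostics$warnings, "\n")
  invisible(x)
}

#' One-call convenience: design + fit
#'
#' @inheritParams build_design
#' @inheritParams fit_mcmc
#' @return a `jm_fit`
#' @export
fit_joint_model <- function(herd, specs = NULL, association = "slope",
                            mcmc = mcmc_control(), seed = 1L, ...) {
  design <- build_design(herd, specs = specs, association = association, ...)
  fit_mcmc(design, mcmc = mcmc, seed = seed)
}

# column-index map into the draws matrix, computed once per fit
param_cols <- function(draws, kn) {
  cn <- colnames(draws)
  list(
    beta = setNames(lapply(kn, function(k)
      grep(paste0("^beta\\.", k, "\\."), cn)), kn),
    sigma = match(paste0("sigma.", kn), cn),
    D = grep("^D\\.", cn),
    alpha = match(paste0("alpha.", kn), cn),
    gamma = match(c("gamma.medium", "gamma.high"), cn),
    logh0 = grep("^logh0\\.", cn)
  )
}

# reconstruct standardized-scale parameter pieces for draw d
draw_params <- function(fit, d) {
  ci <- fit$col_idx
  dr <- fit$draws[d, ]
  q <- fit$q
  li <- lower.tri(matrix(0, q, q), diag = TRUE)
  D <- matrix(0, q, q)
  D[li] <- dr[ci$D]
  D <- D + t(D) - diag(diag(D))
  list(beta = lapply(ci$beta, function(ix) unname(dr[ix])),
       sigma = unname(dr[ci$sigma]),
       D = D,
       alpha = unname(dr[ci$alpha]),
       gamma = unname(dr[ci$gamma]),
       logh0 = unname(dr[ci$logh0]))
}
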
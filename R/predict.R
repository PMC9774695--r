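#' Dynamic individualized survival prediction
#'
#' For a new cow with sensor data up to day `v` of her first lactation, the
#' probability of surviving to day `u > v` is
#' `pi(u|v) = Pr(T >= u | T > v, data to v, training fit)`, computed by
#' Monte-Carlo: for each retained posterior draw of the model parameters, a
#' random-effects vector is drawn from its conditional distribution given the
#' cow's observed trajectories and her survival to `v`, and the conditional
#' survival `exp(-H(v, u))` is averaged over draws. Predictions update as
#' more days of data accrue.
#'
#' @name dynamic_prediction
NULL

# standardized per-outcome design matrices for one cow's data up to v
cow_design <- function(fit, cow_data, v) {
  sensor <- cow_data$sensor
  sensor <- sensor[sensor$dim >= 5 & sensor$dim <= v, , drop = FALSE]
  kn <- names(fit$specs)
  out <- list()
  warm <- if (!is.null(sensor$season)) as.numeric(sensor$season == "warm")
          else if (!is.null(sensor$date)) as.numeric(is_warm(as.Date(sensor$date)))
          else rep(0, nrow(sensor))
  ad <- afc_dummies(cow_data$afc_cat)
  for (k in kn) {
    col <- sensor_cols[[k]]
    rows <- !is.na(sensor[[col]])
    if (!any(rows))
      stop("cow ", cow_data$cow_id %||% "?", " has no ", k,
           " observations in [5, ", v, "]; univariate fallback is not ",
           "supported")
    t <- sensor$dim[rows]
    y <- (sensor[[col]][rows] - fit$scale[[k]]$center) / fit$scale[[k]]$scale
    B <- ns_basis(t, fit$specs[[k]])
    out[[k]] <- list(
      X = cbind(1, B, ad[["medium"]], ad[["high"]], warm[rows]),
      Z = cbind(1, B), y = y
    )
  }
  out
}

# quadrature layout over [v, u_max]: panels split at baseline cuts and grid
# points; returns node times/weights, per-node baseline interval, panel ids
# and the panel index reaching each grid point
pred_quad <- function(fit, v, u_grid, quad_points = 15) {
  u_max <- max(u_grid)
  edges <- sort(unique(c(v, u_grid,
                         fit$cuts[fit$cuts > v & fit$cuts < u_max])))
  gl01 <- gauss_legendre(quad_points, 0, 1)
  nseg <- length(edges) - 1
  node_t <- as.numeric(vapply(seq_len(nseg), function(s) {
    edges[s] + (edges[s + 1] - edges[s]) * gl01$nodes
  }, numeric(quad_points)))
  node_w <- as.numeric(vapply(seq_len(nseg), function(s) {
    (edges[s + 1] - edges[s]) * gl01$weights
  }, numeric(quad_points)))
  n_int <- length(fit$cuts) - 1
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  seg_int <- pmax(1L, pmin(findInterval(mids, fit$cuts), n_int))
  node_int <- rep(seg_int, each = quad_points)
  node_seg <- rep(seq_len(nseg), each = quad_points)
  grid_seg <- findInterval(u_grid, edges) - 1L  # panels fully before u
  grid_seg[u_grid <= v] <- 0L
  grid_seg <- pmin(grid_seg, nseg)
  list(t = node_t, w = node_w, int = node_int, seg = node_seg,
       nseg = nseg, grid_seg = grid_seg)
}

# association design at arbitrary times for one cow (standardized scale,
# matching build_design's scaling convention)
pred_assoc_design <- function(fit, qd, cow_data) {
  kn <- names(fit$specs)
  XA <- ZA <- list()
  ad <- afc_dummies(cow_data$afc_cat)
  for (k in kn) {
    spec <- fit$specs[[k]]
    s_k <- fit$scale[[k]]$scale
    if (fit$association == "slope") {
      Bd <- s_k * ns_basis_deriv(qd$t, spec)
      XA[[k]] <- cbind(0, Bd, 0, 0, 0)
      ZA[[k]] <- cbind(0, Bd)
    } else {
      B <- ns_basis(qd$t, spec)
      warm <- if (!is.null(cow_data$calving1_date) &&
                  !is.na(cow_data$calving1_date)) {
        as.numeric(is_warm(as.Date(cow_data$calving1_date) + qd$t))
      } else rep(0, length(qd$t))
      XA[[k]] <- s_k * cbind(1, B, ad[["medium"]], ad[["high"]], warm)
      ZA[[k]] <- s_k * cbind(1, B)
    }
  }
  list(XA = XA, ZA = ZA)
}

#' Conditional random-effects draws for a new cow
#'
#' For each retained posterior draw, proposes the random-effects vector from
#' its exact Gaussian conditional given the longitudinal data (and the
#' multivariate-normal prior) and corrects by Metropolis-Hastings for the
#' survival-to-`v` factor `exp(-H(0, v))`, carrying the chain across
#' posterior draws.
#'
#' @param fit a `jm_fit`
#' @param cow_data list with `sensor` (the cow's rows), `afc_cat`,
#'   optionally `calving1_date`, `cow_id`
#' @param v observation window (DIM)
#' @param n_draws Monte-Carlo draws (default 500, capped at the posterior
#'   sample size)
#' @param seed integer seed
#' @return list `b` (n_draws x q), `draw_idx` (posterior draws used),
#'   `accept` (MH acceptance rate)
#' @export
sample_conditional_random_effects <- function(fit, cow_data, v,
                                              n_draws = 500, seed = 1L) {
  set.seed(seed)
  n_draws <- min(n_draws, fit$n_draws)
  draw_idx <- round(seq(1, fit$n_draws, length.out = n_draws))
  cd <- cow_design(fit, cow_data, v)
  qd <- pred_quad(fit, 0, v)
  adn <- pred_assoc_design(fit, qd, cow_data)
  kn <- names(fit$specs)
  q <- fit$q
  blocks <- fit$blocks
  w_afc <- afc_dummies(cow_data$afc_cat)
  H0v <- function(p, b) {
    lp <- p$logh0[qd$int] + sum(p$gamma * w_afc)
    for (k in seq_along(kn)) {
      lp <- lp + p$alpha[k] *
        (as.numeric(adn$XA[[k]] %*% p$beta[[k]]) +
           as.numeric(adn$ZA[[k]] %*% b[blocks[[k]]]))
    }
    sum(qd$w * exp(pmin(lp, 50)))
  }
  b_cur <- rep(0, q)
  H_cur <- Inf
  out <- matrix(NA_real_, n_draws, q)
  acc <- 0
  for (d in seq_len(n_draws)) {
    p <- draw_params(fit, draw_idx[d])
    Dinv <- chol2inv(chol(p$D))
    P <- Dinv
    rhs <- numeric(q)
    for (k in seq_along(kn)) {
      blk <- blocks[[k]]
      s2 <- p$sigma[k]^2
      P[blk, blk] <- P[blk, blk] + crossprod(cd[[k]]$Z) / s2
      rhs[blk] <- crossprod(cd[[k]]$Z,
                            cd[[k]]$y - cd[[k]]$X %*% p$beta[[k]]) / s2
    }
    ch <- chol(P)
    m <- backsolve(ch, backsolve(ch, rhs, transpose = TRUE))
    bprop <- as.numeric(m + backsolve(ch, rnorm(q)))
    H_prop <- H0v(p, bprop)
    # H_cur must be re-evaluated under the current draw's parameters
    H_cur_d <- if (d == 1) Inf else H0v(p, b_cur)
    if (log(runif(1)) < H_cur_d - H_prop) {
      b_cur <- bprop
      acc <- acc + 1
    }
    out[d, ] <- b_cur
  }
  list(b = out, draw_idx = draw_idx, accept = acc / n_draws)
}

#' Predict the survival curve of a new cow
#'
#' @inheritParams sample_conditional_random_effects
#' @param u_grid evaluation days post first calving (defaults to every 7
#'   days from `v` to the herd's `t2`); must satisfy `u >= v`
#' @return object of class `survival_prediction`: `curve` (data.frame with
#'   `u`, `pi`, `lo`, `hi` — posterior mean and pointwise 95% credible
#'   bounds), `S` (per-draw survival matrix), `v`, `cow_id`
#' @export
predict_survival <- function(fit, cow_data, v, u_grid = NULL, n_draws = 500,
                             seed = 1L) {
  if (is.null(u_grid))
    u_grid <- sort(unique(c(seq(v, fit$t2, by = 7), fit$t1, fit$t2)))
  if (any(u_grid < v)) stop("all u_grid values must be >= v")
  u_grid <- sort(unique(u_grid))
  cs <- sample_conditional_random_effects(fit, cow_data, v, n_draws, seed)
  nD <- nrow(cs$b)
  qd <- pred_quad(fit, v, u_grid)
  adn <- pred_assoc_design(fit, qd, cow_data)
  kn <- names(fit$specs)
  blocks <- fit$blocks
  w_afc <- afc_dummies(cow_data$afc_cat)
  N <- length(qd$t)
  ci <- fit$col_idx
  dr <- fit$draws[cs$draw_idx, , drop = FALSE]
  lp <- t(dr[, ci$logh0, drop = FALSE])[qd$int, , drop = FALSE]  # N x nD
  lp <- sweep(lp, 2, as.numeric(dr[, ci$gamma, drop = FALSE] %*% w_afc), `+`)
  for (k in seq_along(kn)) {
    contrib <- adn$XA[[k]] %*% t(dr[, ci$beta[[k]], drop = FALSE]) +
      adn$ZA[[k]] %*% t(cs$b[, blocks[[k]], drop = FALSE])
    lp <- lp + sweep(contrib, 2, dr[, ci$alpha[k]], `*`)
  }
  wexp <- exp(pmin(lp, 50)) * qd$w
  seg_int <- rowsum(wexp, qd$seg)                 # nseg x nD
  Hcum <- apply(seg_int, 2, cumsum)
  Hcum <- rbind(0, Hcum)
  S <- exp(-Hcum[qd$grid_seg + 1L, , drop = FALSE])  # n_u x nD
  pi_hat <- rowMeans(S)
  qs <- t(apply(S, 1, quantile, probs = c(0.025, 0.975)))
  structure(list(
    curve = data.frame(u = u_grid, pi = pi_hat, lo = qs[, 1], hi = qs[, 2]),
    S = t(S), u_grid = u_grid, v = v,
    cow_id = cow_data$cow_id %||% NA_character_,
    n_draws = nD, accept = cs$accept
  ), class = "survival_prediction")
}

#' Classify a cow as culled or alive at a horizon
#'
#' A cow is predicted culled at horizon `t_j` when her predicted survival
#' probability does not exceed the threshold: `pi(t_j|v) <= c`.
#'
#' @param prediction a [predict_survival()] result
#' @param horizon the horizon `t_j` (must be in the prediction grid)
#' @param c threshold in (0, 1), default 0.5
#' @return `"culled"` or `"alive"`
#' @export
classify <- function(prediction, horizon, c = 0.5) {
  stopifnot(c > 0, c < 1)
  i <- match(horizon, prediction$curve$u)
  if (is.na(i)) stop("horizon ", horizon, " is not in the prediction grid")
  if (prediction$curve$pi[i] <= c) "culled" else "alive"
}

#' @export
print.survival_prediction <- function(x, ...) {
  cat("Dynamic survival prediction for cow", x$cow_id, "from v =", x$v,
      "DIM (", x$n_draws, "draws )\n")
  print(head(x$curve, 12), row.names = FALSE)
  invisible(x)
}
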
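#' Synthetic herd generator
#'
#' Generates herds with exactly the statistical structure assumed by the joint
#' model: each cow carries a multivariate-normal random-effects vector shared
#' between three spline-shaped sensor trajectories (milk yield, body weight,
#' rumination time) and a proportional-hazards culling process whose log-hazard
#' is linear in the slopes of the noiseless trajectories. Used as ground truth
#' for parameter-recovery and end-to-end tests of the pipeline.
#'
#' @name synthetic_herd
NULL

# Default mean lactation-shaped curves (natural units), projected onto the
# spline basis to obtain default fixed effects.
default_mean_curve <- function(outcome) {
  switch(outcome,
    MY  = function(t) 15 * t^0.25 * exp(-0.004 * t),          # kg/day
    BW  = function(t) 575 - 45 * exp(-t / 55) + 0.12 * t,     # kg
    RUM = function(t) 440 + 40 * (1 - exp(-t / 50))           # min/day
  )
}

project_curve <- function(f, spec, grid) {
  X <- cbind(1, ns_basis(grid, spec))
  as.numeric(qr.solve(X, f(grid)))
}

#' Default synthetic-herd configuration
#'
#' Builds a complete [synthetic_config()] whose trajectory, variance and
#' hazard parameters emulate a commercial Holstein herd on an automatic
#' milking system: mean milk yield around 28 kg/day peaking near 60 DIM, body
#' weight dipping post-calving then recovering, rumination close to 470
#' min/day, cow-level random intercepts and spline slopes with magnitudes in
#' the range seen on such farms, and a rising piecewise-constant baseline
#' culling hazard giving roughly 10% culled before the second calving and 27%
#' before the third. The slope-association defaults are
#' `alpha = (0, 0.1, -0.6)` (per kg/day, kg/day, min/day).
#'
#' @param n_cows herd size
#' @param seed integer seed (mandatory)
#' @param ... overrides for any [synthetic_config()] field
#' @return a `synthetic_config`
#' @export
default_config <- function(n_cows = 150, seed = 1L, ...) {
  grid <- 5:305
  specs <- list(
    MY  = spline_spec(c(80, 155, 230), c(5, 305)),
    BW  = spline_spec(c(80, 155, 230), c(5, 305)),
    RUM = spline_spec(155, c(5, 305))
  )
  beta_true <- list(
    # order: intercept, spline coefs, AFC medium, AFC high, SEAS warm
    MY  = c(project_curve(default_mean_curve("MY"), specs$MY, grid),
            -0.3, 1.2, -0.8),
    BW  = c(project_curve(default_mean_curve("BW"), specs$BW, grid),
            -4, 25, -2),
    RUM = c(project_curve(default_mean_curve("RUM"), specs$RUM, grid),
            -20, -25, -9)
  )
  sds <- c(4.6, 7.5, 6.6, 11, 10,    # MY: intercept + 4 spline
           48, 43, 45, 74, 45,      # BW
           129, 150, 100)           # RUM: intercept + 2 spline
  q <- length(sds)
  R <- matrix(0.1, q, q)
  blocks <- list(1:5, 6:10, 11:13)
  for (bl in blocks) R[bl, bl] <- 0.2
  diag(R) <- 1
  D_true <- diag(sds) %*% R %*% diag(sds)
  args <- list(
    n_cows = n_cows,
    obs_grid = grid,
    specs = specs,
    beta_true = beta_true,
    sigma_true = c(MY = 2.5, BW = 12, RUM = 55),
    D_true = D_true,
    gamma_true = c(medium = 0.3, high = 0.6),
    alpha_true = c(MY = 0, BW = 0.1, RUM = -0.6),
    baseline_hazard = c(1.2e-4, 1.8e-4, 2.4e-4, 3.2e-4, 4e-4, 5e-4),
    censor_day = 900,
    calving_interval = 410,
    afc_probs = c(low = 0.25, medium = 0.5, high = 0.25),
    afc_bands = rbind(low = c(640, 699), medium = c(700, 779),
                      high = c(780, 880)),
    calving_start = as.Date("2015-01-01"),
    calving_span = 365,
    miss_rate = 0.02,
    outlier_rate = 0,
    outlier_magnitude = 4,
    seed = seed
  )
  over <- list(...)
  args[names(over)] <- over
  do.call(synthetic_config, args)
}

#' Synthetic-herd configuration
#'
#' Validates and assembles the true parameter values of the generating model.
#' `baseline_hazard` holds piecewise-constant rates (events/day) on 6 equal
#' intervals over `[0, censor_day]`; the last rate extends beyond `censor_day`
#' when a cow's administrative follow-up is longer.
#'
#' @param n_cows,obs_grid,specs,beta_true,sigma_true,D_true,gamma_true
#'   see [default_config()]
#' @param alpha_true slope-association coefficients (MY, BW, RUM)
#' @param baseline_hazard 6 piecewise-constant rates (events/day)
#' @param censor_day administrative follow-up (days post first calving)
#' @param calving_interval mean calving interval (days); horizons are
#'   `t1 = calving_interval`, `t2 = 2 * calving_interval`
#' @param afc_probs,afc_bands AFC category probabilities and age bands (days)
#' @param calving_start,calving_span first-calving calendar window
#' @param miss_rate daily probability a sensor record is missing
#' @param outlier_rate,outlier_magnitude recording-error injection parameters
#' @param seed integer seed
#' @return a `synthetic_config`
#' @export
synthetic_config <- function(n_cows, obs_grid, specs, beta_true, sigma_true,
                             D_true, gamma_true, alpha_true, baseline_hazard,
                             censor_day, calving_interval, afc_probs,
                             afc_bands, calving_start, calving_span,
                             miss_rate = 0, outlier_rate = 0,
                             outlier_magnitude = 4, seed) {
  if (n_cows <= 0) stop("n_cows must be positive")
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  stopifnot(all(sigma_true >= 0), all(baseline_hazard >= 0),
            outlier_rate >= 0, outlier_rate < 1, censor_day > max(obs_grid))
  if (abs(sum(afc_probs) - 1) > 1e-8) stop("afc_probs must sum to 1")
  D_true <- (D_true + t(D_true)) / 2
  ev <- eigen(D_true, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1))
    stop("D_true is not positive semi-definite")
  q_expected <- sum(vapply(specs, function(s) 1L + s$dim, 0L))
  if (nrow(D_true) != q_expected)
    stop("D_true dimension ", nrow(D_true), " does not match the random ",
         "design (", q_expected, ")")
  for (k in names(specs)) {
    if (length(beta_true[[k]]) != 1 + specs[[k]]$dim + 3)
      stop("beta_true[", k, "] has the wrong length for its spline basis")
  }
  cfg <- as.list(environment())
  cfg$ev <- cfg$q_expected <- NULL
  cfg$q <- q_expected
  class(cfg) <- "synthetic_config"
  cfg
}

# offsets of each outcome's random-effect block in the stacked vector
re_blocks <- function(specs) {
  sizes <- vapply(specs, function(s) 1L + s$dim, 0L)
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  Map(function(s, e) s:e, starts, ends)
}

#' Draw cow-level random effects
#'
#' Independent multivariate-normal draws `b_i ~ N(0, D_true)`, stacked as
#' (intercept, spline coefficients) per outcome in the order MY, BW, RUM.
#'
#' @param config a `synthetic_config`
#' @param seed optional seed; `NULL` uses the current RNG state
#' @return `n_cows` x q matrix
#' @export
simulate_random_effects <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rmvn(config$n_cows, rep(0, nrow(config$D_true)), config$D_true)
}

# month-based binary season: April through October is warm
is_warm <- function(dates) {
  m <- as.integer(format(dates, "%m"))
  m >= 4L & m <= 10L
}

#' Simulate sensor trajectories
#'
#' Evaluates the noiseless trajectory means `m_ik(t)` on the observation grid
#' and adds independent Gaussian daily noise per outcome.
#'
#' @param config a `synthetic_config`
#' @param b matrix of random effects ([simulate_random_effects()])
#' @param covariates data.frame with columns `cow_id`, `afc_cat`,
#'   `calving1_date`
#' @param seed optional seed for the noise
#' @return list with `data` (long cow-day table of noisy observations) and
#'   `means` (the noiseless `m_ik(t)`)
#' @export
simulate_trajectories <- function(config, b, covariates, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(covariates)
  if (nrow(b) != n) stop("b and covariates disagree on the number of cows")
  grid <- config$obs_grid
  ng <- length(grid)
  blocks <- re_blocks(config$specs)
  afc_med <- as.numeric(covariates$afc_cat == "medium")
  afc_high <- as.numeric(covariates$afc_cat == "high")
  dates <- rep(covariates$calving1_date, each = ng) + rep(grid, n)
  warm <- as.numeric(is_warm(dates))
  out <- data.frame(
    cow_id = rep(covariates$cow_id, each = ng),
    dim = rep(grid, n),
    date = dates
  )
  means <- out[, c("cow_id", "dim")]
  for (k in names(config$specs)) {
    spec <- config$specs[[k]]
    B <- ns_basis(grid, spec)
    beta <- config$beta_true[[k]]
    p <- 1 + spec$dim
    fixed_t <- beta[1] + B %*% beta[2:p]                     # ng x 1
    bk <- b[, blocks[[k]], drop = FALSE]
    rand <- rep(bk[, 1], each = ng) +
      as.numeric(B %*% t(bk[, -1, drop = FALSE]))            # cow-major
    cov_eff <- rep(beta[p + 1] * afc_med + beta[p + 2] * afc_high, each = ng)
    m <- rep(as.numeric(fixed_t), n) + rand + cov_eff + beta[p + 3] * warm
    means[[k]] <- m
    # sensor readings cannot be negative; truncation is negligible at the
    # default parameter values
    out[[k]] <- pmax(m + rnorm(n * ng, 0, config$sigma_true[[k]]), 0)
  }
  names(out)[names(out) %in% names(config$specs)] <-
    paste0(tolower(names(config$specs)), c("_kg", "_kg", "_min"))
  list(data = out, means = means)
}

# per-cow slope of the noiseless trajectory sum weighted by alpha, evaluated
# at arbitrary times; SEAS and AFC are time-invariant (zero slope)
slope_lp <- function(config, b_i, t) {
  blocks <- re_blocks(config$specs)
  lp <- numeric(length(t))
  for (j in seq_along(config$specs)) {
    k <- names(config$specs)[j]
    spec <- config$specs[[k]]
    p <- 1 + spec$dim
    coef <- config$beta_true[[k]][2:p] + b_i[blocks[[j]]][-1]
    lp <- lp + config$alpha_true[[j]] * as.numeric(ns_basis_deriv(t, spec) %*% coef)
  }
  lp
}

baseline_log_h0 <- function(config, t) {
  cuts <- seq(0, config$censor_day, length.out = 7)
  idx <- pmin(findInterval(t, cuts, rightmost.closed = TRUE), 6L)
  log(config$baseline_hazard[pmax(idx, 1L)])
}

#' Simulate a culling time by inverse-transform sampling
#'
#' Draws `E ~ Exp(1)` and solves `H_i(T*) = E` for the cumulative hazard of
#' the slope-association model, accumulating per-day 5-point Gauss-Legendre
#' integrals and refining the crossing day by root finding. Times beyond the
#' censoring horizon are administratively censored.
#'
#' @param config a `synthetic_config`
#' @param b_i random-effect vector for one cow
#' @param covariates one-row data.frame (`afc_cat`)
#' @param censor_day per-cow follow-up horizon; defaults to
#'   `config$censor_day`
#' @param seed optional seed
#' @param cow_id label used in numerical-guard errors
#' @return list with `T` (integer days), `event` (1 culled, 0 censored),
#'   `T_exact` and `E` (for oracle checks; `NA` when censored)
#' @export
simulate_event_time <- function(config, b_i, covariates,
                                censor_day = config$censor_day, seed = NULL,
                                cow_id = covariates$cow_id %||% "?") {
  if (!is.null(seed)) set.seed(seed)
  E <- rexp(1)
  gamma_lp <- switch(as.character(covariates$afc_cat),
                     low = 0,
                     medium = config$gamma_true[["medium"]],
                     high = config$gamma_true[["high"]])
  C <- censor_day
  gl <- gauss_legendre(5, 0, 1)
  days <- seq_len(ceiling(C))
  node_t <- as.numeric(outer(gl$nodes, days - 1, `+`))   # 5 x C, day-major
  lp <- gamma_lp + slope_lp(config, b_i, node_t) + baseline_log_h0(config, node_t)
  if (max(abs(lp - baseline_log_h0(config, node_t))) > 50)
    stop("hazard overflow (|linear predictor| > 50) for cow ", cow_id)
  h <- exp(lp)
  day_int <- as.numeric(gl$weights %*% matrix(h, nrow = 5))
  H <- cumsum(day_int)
  if (H[length(H)] < E || E > -log(.Machine$double.xmin)) {
    return(list(T = as.integer(floor(C)), event = 0L, T_exact = NA_real_,
                E = E))
  }
  d <- which(H >= E)[1]
  H_lo <- if (d == 1) 0 else H[d - 1]
  part <- function(t) {
    # integral over (d-1, t), t in (d-1, d]
    g <- gauss_legendre(5, d - 1, t)
    lp2 <- gamma_lp + slope_lp(config, b_i, g$nodes) +
      baseline_log_h0(config, g$nodes)
    sum(g$weights * exp(lp2))
  }
  root <- uniroot(function(t) H_lo + part(t) - E, c(d - 1, d),
                  tol = 1e-9, extendInt = "no")$root
  if (root > C) {
    return(list(T = as.integer(floor(C)), event = 0L, T_exact = NA_real_,
                E = E))
  }
  list(T = as.integer(ceiling(root)), event = 1L, T_exact = root, E = E)
}

#' Inject recording-error outliers
#'
#' Displaces randomly selected cow-days by at least `outlier_magnitude` herd
#' standard deviations (random sign), emulating sensor recording errors that
#' the cleaning rules must remove. Injected positions are returned for test
#' oracles.
#'
#' @param herd a `herd_dataset`
#' @param config a `synthetic_config` (uses `outlier_rate`,
#'   `outlier_magnitude`)
#' @param seed optional seed
#' @return the herd with displaced values and an `outlier_log` element
#' @export
inject_outliers <- function(herd, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rate <- config$outlier_rate
  if (rate == 0) {
    herd$outlier_log <- data.frame(cow_id = character(), dim = integer(),
                                   outcome = character())
    return(herd)
  }
  sensor <- herd$sensor
  cols <- c(MY = "my_kg", BW = "bw_kg", RUM = "rum_min")
  logs <- list()
  for (k in names(cols)) {
    col <- cols[[k]]
    ok <- !is.na(sensor[[col]])
    hit <- ok & runif(nrow(sensor)) < rate
    if (any(hit)) {
      s <- sd(sensor[[col]], na.rm = TRUE)
      mu <- mean(sensor[[col]], na.rm = TRUE)
      shift <- (config$outlier_magnitude + abs(rnorm(sum(hit), 0, 0.5))) * s
      # recording errors are upward spikes anchored at max(value, herd mean):
      # they are always displaced by at least `outlier_magnitude` SDs AND end
      # up beyond the 3-SD band, while staying physically non-negative
      # (downward errors on milk yield could not exceed 3 herd SDs at all)
      val <- pmax(sensor[[col]][hit], mu) + shift
      # rumination is capped at 24 h/day; the cap still lies far outside
      # the 3-SD band so capped errors remain detectable
      if (k == "RUM") val <- pmin(val, 1440)
      sensor[[col]][hit] <- val
      logs[[k]] <- data.frame(cow_id = sensor$cow_id[hit],
                              dim = sensor$dim[hit], outcome = k)
    }
  }
  herd$sensor <- sensor
  herd$outlier_log <- if (length(logs)) do.call(rbind, logs) else
    data.frame(cow_id = character(), dim = integer(), outcome = character())
  rownames(herd$outlier_log) <- NULL
  herd
}

#' Generate a complete synthetic herd
#'
#' Orchestrates the simulators: draws AFC categories and ages, first-calving
#' dates across a calendar year (so the warm/cold season step is exercised),
#' shared random effects, culling times coupled to the trajectory slopes, and
#' sensor observations up to culling (or 305 DIM) with random missing days.
#' Sensor recording stops at culling, and cows are censored at the common
#' dataset end date.
#'
#' @param config a `synthetic_config`
#' @return object of class `herd_dataset`: `sensor` (long cow-day table),
#'   `cows` (one row per cow with dates), `end_date`, `t1`, `t2`, and `truth`
#'   (random effects, survival records and the configuration)
#' @export
generate_herd <- function(config) {
  set.seed(config$seed)
  n <- config$n_cows
  cow_id <- sprintf("cow%04d", seq_len(n))
  cat_names <- names(config$afc_probs)
  afc_cat <- sample(cat_names, n, replace = TRUE, prob = config$afc_probs)
  bands <- config$afc_bands[afc_cat, , drop = FALSE]
  afc_days <- as.integer(round(runif(n, bands[, 1], bands[, 2])))
  calving1 <- config$calving_start +
    as.integer(floor(runif(n, 0, config$calving_span)))
  birth <- calving1 - afc_days
  covariates <- data.frame(cow_id = cow_id, afc_cat = afc_cat,
                           afc_days = afc_days, calving1_date = calving1)
  end_date <- max(calving1) + config$censor_day
  b <- simulate_random_effects(config)
  surv <- vector("list", n)
  for (i in seq_len(n)) {
    surv[[i]] <- simulate_event_time(
      config, b[i, ], covariates[i, ],
      censor_day = as.numeric(end_date - calving1[i]), cow_id = cow_id[i])
  }
  Tvec <- vapply(surv, `[[`, 0L, "T")
  event <- vapply(surv, `[[`, 0L, "event")
  traj <- simulate_trajectories(config, b, covariates)
  sensor <- traj$data
  keep <- sensor$dim <= rep(pmin(Tvec, 305L), each = length(config$obs_grid))
  sensor <- sensor[keep, , drop = FALSE]
  if (config$miss_rate > 0) {
    sensor <- sensor[runif(nrow(sensor)) >= config$miss_rate, , drop = FALSE]
  }
  rownames(sensor) <- NULL
  cows <- data.frame(
    cow_id = cow_id,
    birth_date = birth,
    calving1_date = calving1,
    culling_date = as.Date(ifelse(event == 1, calving1 + Tvec, NA),
                           origin = "1970-01-01"),
    afc_days = afc_days
  )
  herd <- list(
    sensor = sensor,
    cows = cows,
    end_date = end_date,
    t1 = as.integer(round(config$calving_interval)),
    t2 = 2L * as.integer(round(config$calving_interval)),
    truth = list(b = b, survival = data.frame(cow_id = cow_id, T = Tvec,
                                              event = event),
                 afc_cat = afc_cat, config = config),
    config = config
  )
  class(herd) <- "herd_dataset"
  herd <- inject_outliers(herd, config)
  herd
}

#' @export
print.herd_dataset <- function(x, ...) {
  cat("Synthetic/processed herd:", nrow(x$cows), "cows,",
      nrow(x$sensor), "sensor cow-days\n")
  cat("  horizons t1 =", x$t1, ", t2 =", x$t2,
      "days post first calving\n")
  if (!is.null(x$truth))
    cat("  culled:", sum(x$truth$survival$event), "of", nrow(x$cows), "\n")
  invisible(x)
}

#' Write a herd to CSV + JSON files
#'
#' Emits `sensor.csv` (cow_id, date, dim, my_kg, bw_kg, rum_min), `cows.csv`
#' (cow_id, birth_date, calving1_date, culling_date empty when censored,
#' afc_days) and `truth.json` with the true parameters for test oracles.
#'
#' @param herd a `herd_dataset`
#' @param dir output directory (created if absent)
#' @return `dir`, invisibly
#' @export
write_herd <- function(herd, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sensor <- herd$sensor
  sensor$date <- format(sensor$date, "%Y-%m-%d")
  write.csv(sensor[, c("cow_id", "date", "dim", "my_kg", "bw_kg", "rum_min")],
            file.path(dir, "sensor.csv"), row.names = FALSE, na = "")
  cows <- herd$cows
  for (col in c("birth_date", "calving1_date", "culling_date"))
    cows[[col]] <- ifelse(is.na(cows[[col]]), "",
                          format(cows[[col]], "%Y-%m-%d"))
  write.csv(cows, file.path(dir, "cows.csv"), row.names = FALSE, na = "")
  cfg <- herd$config
  truth <- list(
    end_date = format(herd$end_date, "%Y-%m-%d"),
    t1 = herd$t1, t2 = herd$t2,
    beta_true = cfg$beta_true,
    sigma_true = as.list(cfg$sigma_true),
    D_true = cfg$D_true,
    gamma_true = as.list(cfg$gamma_true),
    alpha_true = as.list(cfg$alpha_true),
    baseline_hazard = cfg$baseline_hazard,
    censor_day = cfg$censor_day,
    seed = cfg$seed,
    b = herd$truth$b,
    survival = herd$truth$survival
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"), digits = NA,
                       auto_unbox = TRUE, dataframe = "columns")
  invisible(dir)
}
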
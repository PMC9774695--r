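#' Accuracy protocol: repeated cross-validation, AUC and prediction error
#'
#' The predictive accuracy of the joint model is measured per scenario — an
#' observation window `v` in {60, 150, 240} DIM crossed with a horizon `t_j`
#' (the average second or third calving) — by repeated 3-fold
#' cross-validation (3 repeats, 9 fits in total). Discrimination is the
#' time-dependent AUC over comparable pairs; calibration is a
#' censoring-aware expected squared prediction error that reduces to the
#' Brier score when no cow is censored before the horizon. Metric means over
#' the 9 runs are compared against the random-guessing anchors (0.50 for
#' AUC, 0.25 for PE) with t-based 95% confidence intervals, and variance
#' homogeneity across herds is checked with Levene's test.
#'
#' @name evaluation
NULL

#' Censoring-aware expected prediction error
#'
#' Average squared distance between survival status at `t_j` and the
#' predicted survival probability. Cows observed beyond the horizon
#' contribute `(1 - pi)^2`; cows culled before it contribute `pi^2`; cows
#' censored before the horizon contribute both terms weighted by the model's
#' own conditional survival `pi(t_j | T_i)`. With no censoring before `t_j`
#' this is the Brier score, so a constant prediction of 0.5 scores 0.25.
#'
#' @param T observed times (days post first calving)
#' @param event 1 culled, 0 censored
#' @param pi predicted survival probabilities `pi(t_j | v)`
#' @param t_j the horizon
#' @param pi_cond conditional survival `pi(t_j | T_i)` for cows censored
#'   before `t_j` (ignored, may be `NA`, elsewhere)
#' @return the prediction error, in `[0, 1]`
#' @export
prediction_error <- function(T, event, pi, t_j, pi_cond = NULL) {
  n <- length(T)
  if (n == 0) stop("empty test set")
  stopifnot(length(event) == n, length(pi) == n)
  alive <- T > t_j
  culled <- event == 1 & T <= t_j
  cens <- event == 0 & T <= t_j
  contrib <- numeric(n)
  contrib[alive] <- (1 - pi[alive])^2
  contrib[culled] <- pi[culled]^2
  if (any(cens)) {
    if (is.null(pi_cond) || any(is.na(pi_cond[cens])))
      stop("pi_cond required for cows censored before the horizon")
    w <- pi_cond[cens]
    contrib[cens] <- w * (1 - pi[cens])^2 + (1 - w) * pi[cens]^2
  }
  mean(contrib)
}

#' Time-dependent AUC over comparable pairs
#'
#' Concordance between predicted survival probabilities and outcome classes
#' in the window `(v, t_j]`: over all pairs of one cow with an observed
#' culling in the window and one cow known alive at `t_j`, the fraction in
#' which the culled cow has the lower predicted survival (ties count 1/2).
#' Cows censored inside the window are not comparable and are excluded.
#' Returns `NA` when the window contains no culling event (the metric is
#' then not estimable).
#'
#' @inheritParams prediction_error
#' @param v start of the window (the observation time)
#' @return AUC in `[0, 1]`, or `NA_real_`
#' @export
time_dependent_auc <- function(T, event, pi, v, t_j) {
  cases <- event == 1 & T > v & T <= t_j
  controls <- T > t_j
  if (!any(cases) || !any(controls)) return(NA_real_)
  pc <- pi[cases]; ps <- pi[controls]
  cmp <- outer(pc, ps, function(a, b) (a < b) + 0.5 * (a == b))
  mean(cmp)
}

#' t-based confidence interval against a performance anchor
#'
#' 95% CI `mean +/- t(0.975, m-1) * SD / sqrt(m)` over the non-missing CV
#' metric values; significance means the interval excludes the anchor on the
#' stated side (above 0.50 for AUC, below 0.25 for PE).
#'
#' @param values metric values (typically 9 = 3 folds x 3 repeats)
#' @param null anchor value (0.5 or 0.25)
#' @param direction `"greater"` or `"less"` — the side that counts as better
#'   than guessing
#' @return list `mean`, `sd`, `ci_low`, `ci_high`, `m`, `significant`
#'   (`NA` when fewer than 2 values)
#' @export
significance_ci <- function(values, null, direction = c("greater", "less")) {
  direction <- match.arg(direction)
  x <- values[!is.na(values)]
  m <- length(x)
  if (m < 2)
    return(list(mean = if (m) mean(x) else NA_real_, sd = NA_real_,
                ci_low = NA_real_, ci_high = NA_real_, m = m,
                significant = NA))
  mu <- mean(x); s <- sd(x)
  half <- qt(0.975, m - 1) * s / sqrt(m)
  ci <- c(mu - half, mu + half)
  sig <- if (direction == "greater") ci[1] > null else ci[2] < null
  list(mean = mu, sd = s, ci_low = ci[1], ci_high = ci[2], m = m,
       significant = sig)
}

#' Levene's test of variance homogeneity across groups
#'
#' Classic Levene W: a one-way ANOVA F statistic on the absolute deviations
#' from the group means.
#'
#' @param values numeric metric values
#' @param groups group labels (e.g., herd), at least 2 groups of 2
#' @return list `W`, `p`, `df`
#' @export
levene_test <- function(values, groups) {
  groups <- factor(groups)
  keep <- !is.na(values)
  values <- values[keep]; groups <- droplevels(groups[keep])
  if (nlevels(groups) < 2 || any(table(groups) < 2))
    stop("Levene's test needs at least 2 groups with at least 2 values each")
  dev <- abs(values - ave(values, groups, FUN = mean))
  if (all(dev == 0))
    return(list(W = 0, p = 1,
                df = c(nlevels(groups) - 1,
                       length(values) - nlevels(groups))))
  a <- anova(lm(dev ~ groups))
  list(W = a$`F value`[1], p = a$`Pr(>F)`[1], df = a$Df)
}

# restrict a preprocessed herd to a cow subset, recomputing AFC categories
# from the reference (training) cows' quartiles
subset_herd <- function(herd, cow_ids, afc_ref_ids = cow_ids) {
  out <- herd
  out$sensor <- herd$sensor[herd$sensor$cow_id %in% cow_ids, , drop = FALSE]
  out$cows <- herd$cows[herd$cows$cow_id %in% cow_ids, , drop = FALSE]
  out$survival <- herd$survival[herd$survival$cow_id %in% cow_ids, ,
                                drop = FALSE]
  ref <- herd$cows[herd$cows$cow_id %in% afc_ref_ids, , drop = FALSE]
  q <- quantile(ref$afc_days, c(0.25, 0.5, 0.75), type = 7)
  out$cows$afc_cat <- categorize_afc(out$cows$afc_days, as.numeric(q))
  out$afc_quartiles <- as.numeric(q)
  out
}

one_cow_data <- function(herd, cid) {
  i <- match(cid, herd$cows$cow_id)
  list(sensor = herd$sensor[herd$sensor$cow_id == cid, , drop = FALSE],
       afc_cat = herd$cows$afc_cat[i],
       calving1_date = herd$cows$calving1_date[i],
       cow_id = cid)
}

#' Repeated 3-fold cross-validation of the full pipeline
#'
#' Cows are randomly partitioned into near-equal folds; each fold in turn is
#' held out, the joint model is refit on the remainder (with spline knots
#' and AFC quartiles recomputed on the training cows only), and survival is
#' predicted for the held-out cows that survived at least 240 DIM, for every
#' observation window in `v_list` and both horizons. The fold-partition seed
#' is independent of the MCMC seed.
#'
#' @param herd preprocessed `herd_dataset`
#' @param folds,repeats CV layout (defaults 3 x 3)
#' @param v_list observation windows (DIM)
#' @param mcmc a [mcmc_control()] for the per-fold fits
#' @param n_draws Monte-Carlo draws per prediction
#' @param obs_thin observation-thinning step for the training fits (1 = use
#'   all days)
#' @param seed partition seed; MCMC and prediction seeds are derived
#' @param association passed to [build_design()]
#' @return data.frame of fold metrics: `v`, `horizon`, `t_j`, `repeat_id`,
#'   `fold`, `auc`, `pe`, `n_test`, `n_events_in_horizon`
#' @export
repeated_kfold_cv <- function(herd, folds = 3, repeats = 3,
                              v_list = c(60, 150, 240),
                              mcmc = mcmc_control(), n_draws = 500,
                              obs_thin = 1L, seed = 1L,
                              association = "slope") {
  n <- nrow(herd$cows)
  if (n < 30) stop("need at least 30 cows for cross-validation")
  horizons <- c(t1 = herd$t1, t2 = herd$t2)
  res <- list()
  for (r in seq_len(repeats)) {
    set.seed(derive_seed(seed, r))
    fold_of <- sample(rep(seq_len(folds), length.out = n))
    for (f in seq_len(folds)) {
      train_ids <- herd$cows$cow_id[fold_of != f]
      test_ids <- herd$cows$cow_id[fold_of == f]
      train <- subset_herd(herd, train_ids)
      if (obs_thin > 1) train <- thin_observations(train, obs_thin)
      fit <- fit_joint_model(train, association = association, mcmc = mcmc,
                             seed = derive_seed(seed, 100 + 10 * r + f))
      test <- subset_herd(herd, test_ids, afc_ref_ids = train_ids)
      sv <- test$survival
      ok <- sv$T > 240 | (sv$T == 240 & sv$event == 0)
      eligible <- sv$cow_id[ok]
      for (v in v_list) {
        if (length(eligible) == 0) {
          for (j in seq_along(horizons)) {
            res[[length(res) + 1]] <- data.frame(
              v = v, horizon = names(horizons)[j], t_j = horizons[j],
              repeat_id = r, fold = f, auc = NA_real_, pe = NA_real_,
              n_test = 0L, n_events_in_horizon = 0L)
          }
          next
        }
        Tt <- sv$T[match(eligible, sv$cow_id)]
        ev <- sv$event[match(eligible, sv$cow_id)]
        pi_t <- matrix(NA_real_, length(eligible), length(horizons))
        pi_cond <- matrix(NA_real_, length(eligible), length(horizons))
        for (ii in seq_along(eligible)) {
          cid <- eligible[ii]
          u_grid <- sort(unique(c(v, horizons, Tt[ii])))
          u_grid <- u_grid[u_grid >= v]
          pred <- predict_survival(
            fit, one_cow_data(test, cid), v = v, u_grid = u_grid,
            n_draws = n_draws,
            seed = derive_seed(seed, 1000 + ii + 31 * v))
          Sbar <- colMeans(pred$S)
          for (j in seq_along(horizons)) {
            pi_t[ii, j] <- Sbar[match(horizons[j], pred$u_grid)]
            if (ev[ii] == 0 && Tt[ii] <= horizons[j]) {
              iT <- match(Tt[ii], pred$u_grid)
              ij <- match(horizons[j], pred$u_grid)
              pi_cond[ii, j] <- if (!is.na(iT) && Sbar[iT] > 0)
                Sbar[ij] / Sbar[iT] else NA_real_
            }
          }
        }
        for (j in seq_along(horizons)) {
          tj <- horizons[j]
          nev <- sum(ev == 1 & Tt > v & Tt <= tj)
          auc <- time_dependent_auc(Tt, ev, pi_t[, j], v, tj)
          pe <- prediction_error(Tt, ev, pi_t[, j], tj, pi_cond[, j])
          res[[length(res) + 1]] <- data.frame(
            v = v, horizon = names(horizons)[j], t_j = tj, repeat_id = r,
            fold = f, auc = auc, pe = pe, n_test = length(eligible),
            n_events_in_horizon = nev)
        }
      }
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Summarize fold metrics per scenario
#'
#' @param metrics a [repeated_kfold_cv()] result (possibly from several
#'   herds, with an extra `herd` column)
#' @return data.frame with one row per scenario: means, SDs, 95% CIs and
#'   significance flags against the 0.50 (AUC) and 0.25 (PE) anchors
#' @export
summarize_evaluation <- function(metrics) {
  sc <- unique(metrics[, c("v", "horizon", "t_j")])
  rows <- lapply(seq_len(nrow(sc)), function(i) {
    m <- metrics[metrics$v == sc$v[i] & metrics$horizon == sc$horizon[i], ]
    a <- significance_ci(m$auc, 0.5, "greater")
    p <- significance_ci(m$pe, 0.25, "less")
    data.frame(
      v = sc$v[i], horizon = sc$horizon[i], t_j = sc$t_j[i],
      n_runs = nrow(m),
      auc_mean = a$mean, auc_sd = a$sd, auc_ci_low = a$ci_low,
      auc_ci_high = a$ci_high, auc_gt_0.5 = a$significant,
      pe_mean = p$mean, pe_sd = p$sd, pe_ci_low = p$ci_low,
      pe_ci_high = p$ci_high, pe_lt_0.25 = p$significant
    )
  })
  out <- do.call(rbind, rows)
  out[order(out$v, out$t_j), ]
}
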
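test_that("2-hourly rumination slots aggregate to daily minutes", {
  slots <- data.frame(
    cow_id = rep("a", 12), date = as.Date("2015-03-01"),
    minutes = rep(40, 12))
  out <- aggregate_rumination(slots)
  expect_equal(out$rum_min, 480)
  # 11 slots present: day is missing
  out11 <- aggregate_rumination(slots[-1, ])
  expect_true(is.na(out11$rum_min))
  # all-zero slots are a valid (zero-minute) day
  slots0 <- transform(slots, minutes = 0)
  expect_equal(aggregate_rumination(slots0)$rum_min, 0)
  # slot values above 120 minutes are physically impossible
  slots$minutes[1] <- 130
  expect_error(aggregate_rumination(slots), "120")
})

make_sensor <- function(values, cow = "c1", outcome = "my_kg") {
  out <- data.frame(cow_id = cow, dim = seq_along(values),
                    date = as.Date("2015-01-01") + seq_along(values),
                    my_kg = 30, bw_kg = 500, rum_min = 450)
  out[[outcome]] <- values
  out
}

test_that("3-SD outliers are removed unless a cow has 30 or more such days", {
  # herd mean 30, SD 5 (forced via herd_stats)
  stats <- herd_quartiles(make_sensor(rep(30, 10)))
  stats$outcome$MY <- list(mean = 30, sd = 5)
  # 10 outlying days at 46 -> removed
  v <- rep(30, 100); v[1:10] <- 46
  r <- remove_outliers(make_sensor(v), stats)
  expect_equal(sum(is.na(r$sensor$my_kg)), 10)
  expect_equal(nrow(r$removed), 10)
  expect_false(any(r$report$kept[r$report$outcome == "MY"]))
  # 31 outlying days -> kept as genuine abnormal behaviour
  v31 <- rep(30, 100); v31[1:31] <- 46
  r31 <- remove_outliers(make_sensor(v31), stats)
  expect_equal(sum(is.na(r31$sensor$my_kg)), 0)
  expect_true(all(r31$report$kept[r31$report$outcome == "MY"]))
  # exactly 30 also triggers the keep-all exception (boundary decision)
  v30 <- rep(30, 100); v30[1:30] <- 46
  expect_equal(sum(is.na(remove_outliers(make_sensor(v30),
                                         stats)$sensor$my_kg)), 0)
  # everything within 3 SD: unchanged
  r0 <- remove_outliers(make_sensor(rep(32, 50)), stats)
  expect_equal(sum(is.na(r0$sensor$my_kg)), 0)
})

test_that("outlier cleaning is idempotent and never alters values", {
  hh <- cached_herd(40, 13)
  raw <- generate_herd(default_config(n_cows = 40, seed = 13,
                                      outlier_rate = 0.005))
  st <- herd_quartiles(raw$sensor)
  once <- remove_outliers(raw$sensor, st)
  twice <- remove_outliers(once$sensor, st)
  expect_identical(once$sensor, twice$sensor)
  kept <- !is.na(once$sensor$my_kg)
  expect_identical(once$sensor$my_kg[kept], raw$sensor$my_kg[kept])
})

test_that("survival time and censoring follow the date arithmetic", {
  r <- compute_survival(as.Date("2015-01-01"), as.Date("2015-12-31"),
                        as.Date("2016-06-01"))
  expect_equal(r$T, 364L)
  expect_equal(r$event, 1L)
  r2 <- compute_survival(as.Date("2015-01-01"), as.Date(NA),
                         as.Date("2016-01-01"))
  expect_equal(r2$T, 365L)
  expect_equal(r2$event, 0L)
  expect_error(compute_survival(as.Date("2015-01-01"), as.Date("2015-01-01"),
                                as.Date("2016-01-01")), "at least 1")
  expect_error(compute_survival(as.Date("2015-01-01"), as.Date("2014-12-01"),
                                as.Date("2016-01-01")), "precedes")
})

test_that("AFC categories use inclusive interquartile boundaries", {
  q <- c(700, 730, 760)
  expect_equal(categorize_afc(c(650, 700, 730, 760, 800), q),
               c("low", "medium", "medium", "medium", "high"))
})

test_that("season is warm from April through October inclusive", {
  expect_equal(assign_season(as.Date("2015-06-15")), "warm")
  expect_equal(assign_season(as.Date("2015-12-15")), "cold")
  expect_equal(assign_season(as.Date("2015-04-01")), "warm")
  expect_equal(assign_season(as.Date("2015-10-31")), "warm")
  expect_equal(assign_season(as.Date("2015-11-01")), "cold")
  expect_equal(assign_season(as.Date("2015-03-31")), "cold")
})

test_that("cow filters drop early cullings and incomplete recorders", {
  mk <- function(cow, days) {
    data.frame(cow_id = cow, dim = days,
               date = as.Date("2015-01-01") + days,
               my_kg = 30, bw_kg = 500, rum_min = 450)
  }
  sensor <- rbind(
    mk("early", 5:44),          # culled DIM 45
    mk("full", 5:305),          # complete
    mk("ok93", sort(sample(5:305, 280))),   # 280/301 = 93%
    mk("low83", sort(sample(5:305, 250)))   # 250/301 = 83%
  )
  surv <- data.frame(cow_id = c("early", "full", "ok93", "low83"),
                     T = c(45L, 400L, 400L, 400L), event = c(1L, 0L, 0L, 0L))
  f <- apply_cow_filters(sensor, surv)
  expect_setequal(f$survival$cow_id, c("full", "ok93"))
  expect_equal(f$report$culled_before_50, 1L)
  expect_equal(f$report$incomplete_cows, 1L)
  expect_true(all(f$sensor$dim >= 5 & f$sensor$dim <= 305))
  # for a culled cow the completeness denominator is min(T, 305) - 4
  sensor2 <- rbind(mk("cut", 5:95), mk("ref", 5:305))
  surv2 <- data.frame(cow_id = c("cut", "ref"), T = c(100L, 400L),
                      event = c(1L, 0L))
  f2 <- apply_cow_filters(sensor2, surv2)   # 91/96 = 94.8%
  expect_true("cut" %in% f2$survival$cow_id)
})

test_that("horizons come from the mean calving interval or the config", {
  expect_equal(estimate_horizons(c(414, 414)), list(t1 = 414L, t2 = 828L))
  expect_equal(estimate_horizons(rep(400, 5)), list(t1 = 400L, t2 = 800L))
  expect_equal(estimate_horizons(config = list(t1 = 420, t2 = 840)),
               list(t1 = 420L, t2 = 840L))
  expect_error(estimate_horizons(), "no calving intervals")
})

test_that("injected recording errors are removed by the cleaning round-trip", {
  cfg <- default_config(n_cows = 60, seed = 19, outlier_rate = 0.01,
                        miss_rate = 0)
  herd <- generate_herd(cfg)
  pp <- preprocess_herd(herd)
  inj <- herd$outlier_log
  # restrict to cows with < 30 injected days per outcome and still retained
  per <- table(inj$cow_id, inj$outcome)
  ok_cows <- rownames(per)[apply(per, 1, max) < 30]
  inj <- inj[inj$cow_id %in% intersect(ok_cows, pp$herd$cows$cow_id), ]
  rem <- pp$report$removed_positions
  key <- function(d) paste(d$cow_id, d$dim, d$outcome)
  hit <- key(inj) %in% key(rem)
  expect_gte(mean(hit), 0.99)
})
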
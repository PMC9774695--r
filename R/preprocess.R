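#' Data cleaning and filtering for AMS sensor records
#'
#' Implements the processing rules that turn raw sensor files into the
#' modelling dataset: daily aggregation of 2-hourly rumination slots, the
#' 3-standard-deviation outlier rule with the 30-day "abnormal behaviour"
#' exception, survival-time computation with administrative censoring, AFC
#' quartile categories, the warm/cold season coding, removal of cows culled
#' before 50 DIM, restriction to the 5-305 DIM window, and the 90% daily
#' completeness filter. Cleaning never alters values; it only removes rows or
#' drops cows, and every rule reports its counts in a cleaning report.
#'
#' @name preprocessing
NULL

sensor_cols <- c(MY = "my_kg", BW = "bw_kg", RUM = "rum_min")

#' Aggregate 2-hourly rumination slots into daily minutes
#'
#' Each day has 12 two-hour slots; a day is the sum of its slots and is
#' treated as missing when any slot is absent (an incomplete day would
#' understate rumination time).
#'
#' @param two_hourly data.frame with columns `cow_id`, `date`, `minutes`
#'   (one row per recorded slot; at most 12 per cow-day)
#' @return data.frame `cow_id`, `date`, `rum_min` (`NA` for incomplete days)
#' @export
aggregate_rumination <- function(two_hourly) {
  if (any(two_hourly$minutes < 0 | two_hourly$minutes > 120, na.rm = TRUE))
    stop("rumination slot values must be within [0, 120] minutes")
  key <- interaction(two_hourly$cow_id, two_hourly$date, drop = TRUE)
  n_slots <- tapply(two_hourly$minutes, key, function(x) sum(!is.na(x)))
  total <- tapply(two_hourly$minutes, key, sum, na.rm = TRUE)
  first <- !duplicated(key)
  out <- data.frame(
    cow_id = two_hourly$cow_id[first],
    date = two_hourly$date[first],
    rum_min = as.numeric(total[match(key[first], names(total))])
  )
  complete <- n_slots[match(key[first], names(n_slots))] == 12
  out$rum_min[!complete] <- NA_real_
  out[order(out$cow_id, out$date), , drop = FALSE]
}

#' Herd-level statistics for cleaning and coding
#'
#' Per-outcome herd means and SDs over all cow-days (computed once, on the
#' raw data), AFC quartiles for the low/medium/high coding and DIM quartiles
#' for spline-knot placement.
#'
#' @param sensor long cow-day sensor table
#' @param cows per-cow table with `afc_days`
#' @return object of class `herd_quartiles`
#' @export
herd_quartiles <- function(sensor, cows = NULL) {
  stats <- lapply(sensor_cols, function(col) {
    x <- sensor[[col]]
    list(mean = mean(x, na.rm = TRUE), sd = sd(x, na.rm = TRUE))
  })
  afc_q <- if (!is.null(cows) && nrow(cows) > 0) {
    unname(quantile(cows$afc_days, c(0.25, 0.5, 0.75), type = 7,
                    na.rm = TRUE))
  } else c(NA_real_, NA_real_, NA_real_)
  dim_q <- unname(quantile(sensor$dim, c(0.25, 0.5, 0.75), type = 7))
  out <- list(outcome = stats, afc_quartiles = afc_q, dim_quartiles = dim_q)
  class(out) <- "herd_quartiles"
  out
}

#' Remove outlying sensor days
#'
#' Days where a sensor value falls outside 3 herd SDs of the herd mean are
#' treated as recording errors and removed — unless a cow accumulates 30 or
#' more such days for that outcome, in which case all are kept as genuine
#' abnormal behaviour (e.g., disease). Herd mean and SD are computed once on
#' the input data (single pass).
#'
#' @param sensor long cow-day sensor table
#' @param herd_stats a [herd_quartiles()]; computed from `sensor` if missing
#' @param keep_all_at days-per-cow threshold at which outliers are kept
#'   (default 30)
#' @return list `sensor` (values set to `NA` where removed), `report`
#'   (per-cow-outcome outlier-day counts, and whether they were kept),
#'   `removed` (cow/dim/outcome rows actually removed)
#' @export
remove_outliers <- function(sensor, herd_stats = NULL, keep_all_at = 30L) {
  if (is.null(herd_stats)) herd_stats <- herd_quartiles(sensor)
  removed <- list()
  report <- list()
  for (k in names(sensor_cols)) {
    col <- sensor_cols[[k]]
    st <- herd_stats$outcome[[k]]
    x <- sensor[[col]]
    if (st$sd == 0 && length(unique(x[!is.na(x)])) > 1)
      stop("herd SD is zero for ", k, " but the data are not constant")
    if (is.na(st$sd) || st$sd == 0) next
    out_flag <- !is.na(x) & abs(x - st$mean) > 3 * st$sd
    per_cow <- tapply(out_flag, sensor$cow_id, sum)
    keep_cows <- names(per_cow)[per_cow >= keep_all_at]
    drop <- out_flag & !(sensor$cow_id %in% keep_cows)
    removed[[k]] <- data.frame(cow_id = sensor$cow_id[drop],
                               dim = sensor$dim[drop],
                               outcome = rep(k, sum(drop)))
    flagged <- names(per_cow)[per_cow > 0]
    report[[k]] <- data.frame(
      outcome = rep(k, length(flagged)),
      cow_id = flagged,
      outlier_days = as.integer(per_cow[flagged]),
      kept = flagged %in% keep_cows
    )
    sensor[[col]][drop] <- NA_real_
  }
  removed <- if (length(removed)) do.call(rbind, removed) else
    data.frame(cow_id = character(), dim = integer(), outcome = character())
  report <- if (length(report)) do.call(rbind, report) else
    data.frame(outcome = character(), cow_id = character(),
               outlier_days = integer(), kept = logical())
  rownames(removed) <- rownames(report) <- NULL
  list(sensor = sensor, report = report, removed = removed)
}

#' Survival time from calving, culling and dataset end dates
#'
#' @param calving1 first-calving date
#' @param culling culling date or `NA` (still on farm)
#' @param end_date final date of the dataset
#' @return list `T` (days), `event` (1 culled, 0 censored)
#' @export
compute_survival <- function(calving1, culling, end_date) {
  if (is.na(calving1) || calving1 > end_date)
    stop("first calving must precede the dataset end date")
  if (!is.na(culling)) {
    if (culling < calving1) stop("culling date precedes first calving")
    T <- as.integer(culling - calving1)
    if (T < 1) stop("survival time must be at least 1 day")
    list(T = T, event = 1L)
  } else {
    T <- as.integer(end_date - calving1)
    if (T < 1) stop("survival time must be at least 1 day")
    list(T = T, event = 0L)
  }
}

#' AFC category from herd quartiles
#'
#' 'low' below the first quartile, 'medium' within the interquartile range
#' (boundaries inclusive), 'high' above the third quartile.
#'
#' @param afc_days age at first calving (days)
#' @param quartiles a [herd_quartiles()] (or numeric Q1/Q2/Q3 vector)
#' @return character vector of categories
#' @export
categorize_afc <- function(afc_days, quartiles) {
  q <- if (inherits(quartiles, "herd_quartiles")) quartiles$afc_quartiles
       else quartiles
  ifelse(afc_days < q[1], "low", ifelse(afc_days > q[3], "high", "medium"))
}

#' Season of a date
#'
#' @param date Date vector
#' @return "warm" for April-October (inclusive), "cold" otherwise
#' @export
assign_season <- function(date) {
  ifelse(is_warm(as.Date(date)), "warm", "cold")
}

#' Cow-level filters
#'
#' Applies, in order: removal of cows culled before 50 DIM; restriction of
#' sensor rows to 5-305 DIM; removal of cows with less than 90% daily
#' observations for any outcome, the denominator being the number of days in
#' `[5, min(T, 305)]`.
#'
#' @param sensor long cow-day sensor table (already outlier-cleaned)
#' @param survival data.frame `cow_id`, `T`, `event`
#' @return list `sensor`, `survival` (filtered), `report` (counts per rule,
#'   per-cow completeness)
#' @export
apply_cow_filters <- function(sensor, survival) {
  n0 <- nrow(survival)
  early <- survival$T < 50
  survival <- survival[!early, , drop = FALSE]
  sensor <- sensor[sensor$cow_id %in% survival$cow_id, , drop = FALSE]
  in_window <- sensor$dim >= 5 & sensor$dim <= 305
  rows_out_of_window <- sum(!in_window)
  sensor <- sensor[in_window, , drop = FALSE]
  denom <- pmin(survival$T, 305L) - 4L
  comp <- matrix(NA_real_, nrow(survival), length(sensor_cols),
                 dimnames = list(survival$cow_id, names(sensor_cols)))
  for (k in names(sensor_cols)) {
    col <- sensor_cols[[k]]
    days <- tapply(!is.na(sensor[[col]]), sensor$cow_id, sum)
    comp[, k] <- as.numeric(days[survival$cow_id]) / denom
  }
  comp[is.na(comp)] <- 0
  incomplete <- apply(comp, 1, min) < 0.90
  survival <- survival[!incomplete, , drop = FALSE]
  sensor <- sensor[sensor$cow_id %in% survival$cow_id, , drop = FALSE]
  if (nrow(survival) == 0)
    stop("no cows remain after filtering (rules: T<50 removed ", sum(early),
         ", <90% completeness removed ", sum(incomplete), ")")
  rownames(sensor) <- rownames(survival) <- NULL
  report <- list(
    input_cows = n0,
    culled_before_50 = sum(early),
    rows_outside_5_305 = rows_out_of_window,
    incomplete_cows = sum(incomplete),
    retained_cows = nrow(survival),
    completeness = comp
  )
  list(sensor = sensor, survival = survival, report = report)
}

#' Thin sensor observations to a coarser grid
#'
#' Keeps every `step`-th DIM, reducing the dominant cost of fitting daily
#' data. Applied after preprocessing (the completeness filter judges the
#' original daily records).
#'
#' @param herd a preprocessed `herd_dataset`
#' @param step keep DIM values with `dim %% step == offset`
#' @param offset grid offset (default chosen so DIM 5 is kept with step 3)
#' @return the herd with a thinned sensor table
#' @export
thin_observations <- function(herd, step = 3L, offset = 5L %% step) {
  herd$sensor <- herd$sensor[herd$sensor$dim %% step == offset, ,
                             drop = FALSE]
  herd
}

#' Prediction horizons from calving intervals
#'
#' `t1` is the mean calving interval rounded to whole days; `t2 = 2 * t1`.
#'
#' @param intervals observed calving intervals (days), or `NULL`
#' @param config optional list with explicit `t1`, `t2` overrides
#' @return list `t1`, `t2`
#' @export
estimate_horizons <- function(intervals = NULL, config = NULL) {
  if (!is.null(config) && !is.null(config$t1)) {
    t2 <- config$t2 %||% (2L * as.integer(config$t1))
    return(list(t1 = as.integer(config$t1), t2 = as.integer(t2)))
  }
  if (is.null(intervals) || !length(intervals))
    stop("no calving intervals observed and no configured horizons")
  t1 <- as.integer(round(mean(intervals)))
  list(t1 = t1, t2 = 2L * t1)
}

#' Preprocess a raw herd into the modelling dataset
#'
#' Runs the full cleaning pipeline in the fixed order: rumination aggregation
#' (if 2-hourly), survival computation, 3-SD outlier cleaning, cow filters,
#' AFC categorisation and season coding. Returns a `herd_dataset` plus the
#' cleaning report.
#'
#' @param herd a `herd_dataset` (e.g., from [generate_herd()] or
#'   [read_herd()])
#' @param horizons optional list `t1`, `t2` overriding the herd's
#' @return list `herd` (cleaned, with `afc_cat` on `cows`), `report`
#' @export
preprocess_herd <- function(herd, horizons = NULL) {
  sensor <- herd$sensor
  cows <- herd$cows
  surv_list <- Map(compute_survival, cows$calving1_date, cows$culling_date,
                   MoreArgs = list(end_date = herd$end_date))
  survival <- data.frame(
    cow_id = cows$cow_id,
    T = vapply(surv_list, `[[`, 0L, "T"),
    event = vapply(surv_list, `[[`, 0L, "event")
  )
  raw_stats <- herd_quartiles(sensor, cows)
  cleaned <- remove_outliers(sensor, raw_stats)
  filtered <- apply_cow_filters(cleaned$sensor, survival)
  cows <- cows[cows$cow_id %in% filtered$survival$cow_id, , drop = FALSE]
  post_stats <- herd_quartiles(filtered$sensor, cows)
  cows$afc_cat <- categorize_afc(cows$afc_days, post_stats)
  filtered$sensor$season <- assign_season(filtered$sensor$date)
  hz <- if (!is.null(horizons)) estimate_horizons(config = horizons)
        else list(t1 = herd$t1, t2 = herd$t2)
  out <- list(
    sensor = filtered$sensor,
    cows = cows,
    survival = filtered$survival,
    end_date = herd$end_date,
    t1 = hz$t1, t2 = hz$t2,
    quartiles = post_stats,
    truth = herd$truth
  )
  class(out) <- "herd_dataset"
  report <- list(
    outliers = cleaned$report,
    outlier_rows_removed = nrow(cleaned$removed),
    removed_positions = cleaned$removed,
    filters = filtered$report
  )
  list(herd = out, report = report)
}
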
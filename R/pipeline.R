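#' File formats, configuration and the pipeline driver
#'
#' CSV dialects: `sensor.csv` holds one row per cow-day (`cow_id`, `date`
#' ISO-8601, `dim`, `my_kg`, `bw_kg`, `rum_min`; empty fields are missing
#' days) and `cows.csv` one row per cow (`cow_id`, `birth_date`,
#' `calving1_date`, `culling_date` empty when the cow is still on farm,
#' `afc_days`). DIM counts days from the first calving (calving day 0; the
#' first modelled day is DIM 5). Pipeline settings travel in a YAML file
#' with explicit seeds for the simulation, the fold partition and the MCMC.
#'
#' @name cli_io
NULL

#' Read a sensor CSV
#'
#' @param path file with columns `cow_id`, `date`, `dim`, `my_kg`, `bw_kg`,
#'   `rum_min`
#' @return validated data.frame with `Date` dates
#' @export
read_sensor_csv <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("cow_id", "date", "dim", "my_kg", "bw_kg", "rum_min")
  miss <- setdiff(req, names(x))
  if (length(miss)) stop("sensor file missing column(s): ",
                         paste(miss, collapse = ", "))
  d <- as.Date(x$date, format = "%Y-%m-%d")
  if (any(is.na(d) & !is.na(x$date) & nzchar(x$date)))
    stop("unparseable date in sensor file (expected ISO-8601): ",
         x$date[which(is.na(d) & nzchar(x$date))[1]])
  x$date <- d
  dup <- duplicated(x[, c("cow_id", "dim")])
  if (any(dup))
    stop("duplicated cow-day: cow ", x$cow_id[which(dup)[1]], " DIM ",
         x$dim[which(dup)[1]])
  for (col in c("my_kg", "bw_kg", "rum_min")) {
    if (any(x[[col]] < 0, na.rm = TRUE))
      stop("negative ", col, " value")
  }
  if (any(x$rum_min > 1440, na.rm = TRUE))
    stop("rumination above 1440 min/day is physically impossible")
  x
}

#' Read a cow table CSV
#'
#' @param path file with columns `cow_id`, `birth_date`, `calving1_date`,
#'   `culling_date` (empty if censored), `afc_days`
#' @return validated data.frame
#' @export
read_cows_csv <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("cow_id", "calving1_date", "culling_date", "afc_days")
  miss <- setdiff(req, names(x))
  if (length(miss)) stop("cow file missing column(s): ",
                         paste(miss, collapse = ", "))
  for (col in intersect(c("birth_date", "calving1_date", "culling_date"),
                        names(x))) {
    raw <- x[[col]]
    d <- as.Date(raw, format = "%Y-%m-%d")
    if (any(is.na(d) & !is.na(raw) & nzchar(raw)))
      stop("unparseable ", col, " (expected ISO-8601)")
    x[[col]] <- d
  }
  if (anyDuplicated(x$cow_id)) stop("duplicated cow_id in cow file")
  x
}

#' Read a herd directory written by [write_herd()]
#'
#' @param dir directory with `sensor.csv`, `cows.csv` and (optionally)
#'   `truth.json`
#' @param end_date dataset end date; taken from `truth.json` when absent
#' @param t1,t2 horizons; taken from `truth.json` when absent
#' @return a `herd_dataset`
#' @export
read_herd <- function(dir, end_date = NULL, t1 = NULL, t2 = NULL) {
  sensor <- read_sensor_csv(file.path(dir, "sensor.csv"))
  cows <- read_cows_csv(file.path(dir, "cows.csv"))
  truth <- NULL
  tf <- file.path(dir, "truth.json")
  if (file.exists(tf)) truth <- jsonlite::read_json(tf, simplifyVector = TRUE)
  end_date <- end_date %||% as.Date(truth$end_date)
  if (is.null(end_date) || is.na(end_date))
    stop("end_date must be given or present in truth.json")
  structure(list(
    sensor = sensor, cows = cows, end_date = as.Date(end_date),
    t1 = as.integer(t1 %||% truth$t1 %||% NA),
    t2 = as.integer(t2 %||% truth$t2 %||% NA),
    truth = truth
  ), class = "herd_dataset")
}

#' Pipeline configuration
#'
#' Reads (or validates) the YAML pipeline settings; all seeds must be
#' explicit so every stage is reproducible.
#'
#' @param x path to a YAML file, or a list
#' @return validated config list
#' @export
pipeline_config <- function(x) {
  cfg <- if (is.character(x)) yaml::read_yaml(x) else x
  defaults <- list(
    simulate = list(enabled = FALSE, n_cows = 150),
    horizons = NULL,
    association = "slope",
    mcmc = list(chains = 2, burnin = 1500, iter = 1500, thin = 1),
    evaluation = list(folds = 3, repeats = 3, v = c(60, 150, 240),
                      threshold = 0.5, n_draws = 500, obs_thin = 1),
    seeds = list()
  )
  for (nm in names(defaults)) {
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
    else if (is.list(defaults[[nm]])) {
      missing_sub <- setdiff(names(defaults[[nm]]), names(cfg[[nm]]))
      cfg[[nm]][missing_sub] <- defaults[[nm]][missing_sub]
    }
  }
  need_seeds <- c("partition", "mcmc",
                  if (isTRUE(cfg$simulate$enabled)) "simulation")
  miss <- setdiff(need_seeds, names(cfg$seeds))
  if (length(miss))
    stop("config must set explicit seeds: ", paste(miss, collapse = ", "))
  v <- cfg$evaluation$v
  if (!all(v %in% 5:305)) stop("observation windows v must lie in 5..305")
  cth <- cfg$evaluation$threshold
  if (cth <= 0 || cth >= 1) stop("threshold c must be in (0, 1)")
  cfg
}

log_stage <- function(...) message("[herdsurv] ", ...)

#' Run the full pipeline
#'
#' Optionally simulates a herd, then preprocesses, cross-validates the joint
#' model over the configured scenarios and writes `fold_metrics.csv`,
#' `summary.csv` and `cleaning_report.json` under the output directory.
#'
#' @param config a [pipeline_config()] (or path/list coercible to one)
#' @param out_dir output directory
#' @return list with `herd`, `report`, `metrics`, `summary` (invisibly)
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (isTRUE(cfg$simulate$enabled)) {
    log_stage("simulating herd: n_cows=", cfg$simulate$n_cows,
              " seed=", cfg$seeds$simulation)
    over <- cfg$simulate[setdiff(names(cfg$simulate),
                                 c("enabled", "n_cows"))]
    sim_cfg <- do.call(default_config,
                       c(list(n_cows = cfg$simulate$n_cows,
                              seed = cfg$seeds$simulation), over))
    herd_dir <- file.path(out_dir, "herd")
    write_herd(generate_herd(sim_cfg), herd_dir)
    cfg$paths$herd <- herd_dir
  }
  log_stage("reading herd from ", cfg$paths$herd)
  herd <- read_herd(cfg$paths$herd)
  log_stage("preprocessing ", nrow(herd$cows), " cows")
  pp <- preprocess_herd(herd, horizons = cfg$horizons)
  rep_out <- pp$report
  rep_out$filters$completeness <- NULL
  jsonlite::write_json(
    list(outlier_rows_removed = rep_out$outlier_rows_removed,
         filters = rep_out$filters),
    file.path(out_dir, "cleaning_report.json"), auto_unbox = TRUE,
    digits = NA)
  log_stage("cross-validating: ", cfg$evaluation$repeats, "x",
            cfg$evaluation$folds, " folds, v = ",
            paste(cfg$evaluation$v, collapse = ","))
  mc <- do.call(mcmc_control, cfg$mcmc)
  metrics <- repeated_kfold_cv(
    pp$herd, folds = cfg$evaluation$folds, repeats = cfg$evaluation$repeats,
    v_list = cfg$evaluation$v, mcmc = mc,
    n_draws = cfg$evaluation$n_draws, obs_thin = cfg$evaluation$obs_thin,
    seed = cfg$seeds$partition, association = cfg$association)
  summary <- summarize_evaluation(metrics)
  write.csv(metrics, file.path(out_dir, "fold_metrics.csv"),
            row.names = FALSE)
  write.csv(summary, file.path(out_dir, "summary.csv"), row.names = FALSE)
  log_stage("done; artifacts in ", out_dir)
  invisible(list(herd = pp$herd, report = pp$report, metrics = metrics,
                 summary = summary))
}
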
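#' Serialize a joint-model fit to a directory
#'
#' Writes `params.parquet` (posterior draws, one row per draw),
#' `spec.json` (spline knots, standardization, baseline cuts, priors,
#' seeds, MCMC settings) and `diagnostics.json`. Training-cow random-effect
#' draws are not serialized; predictions for new cows do not need them.
#' Requires the `arrow` package.
#'
#' @param fit a `jm_fit`
#' @param dir output directory
#' @return `dir`, invisibly
#' @export
write_fit <- function(fit, dir) {
  if (!requireNamespace("arrow", quietly = TRUE))
    stop("write_fit requires the 'arrow' package")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  arrow::write_parquet(as.data.frame(fit$draws),
                       file.path(dir, "params.parquet"))
  spec <- list(
    specs = lapply(fit$specs, spec_to_list),
    scale = fit$scale,
    cuts = fit$cuts,
    association = fit$association,
    priors = fit$priors,
    q = fit$q,
    cow_id = fit$cow_id,
    t1 = fit$t1, t2 = fit$t2,
    mcmc = fit$mcmc, seed = fit$seed
  )
  jsonlite::write_json(spec, file.path(dir, "spec.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(fit$diagnostics, file.path(dir, "diagnostics.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load a joint-model fit written by [write_fit()]
#'
#' @param dir directory with `params.parquet` and `spec.json`
#' @return a `jm_fit` (without training random-effect draws)
#' @export
read_fit <- function(dir) {
  if (!requireNamespace("arrow", quietly = TRUE))
    stop("read_fit requires the 'arrow' package")
  draws <- as.matrix(arrow::read_parquet(file.path(dir, "params.parquet")))
  spec <- jsonlite::read_json(file.path(dir, "spec.json"),
                              simplifyVector = TRUE)
  specs <- lapply(spec$specs, spec_from_list)
  scale <- lapply(spec$scale, function(s)
    list(center = s$center, scale = s$scale))
  fit <- structure(list(
    draws = draws, b_draws = NULL, n_draws = nrow(draws),
    scale = scale, specs = specs, cuts = as.numeric(spec$cuts),
    association = spec$association, priors = spec$priors,
    blocks = re_blocks(specs), q = spec$q, cow_id = spec$cow_id,
    t1 = spec$t1, t2 = spec$t2, quartiles = NULL,
    diagnostics = jsonlite::read_json(file.path(dir, "diagnostics.json"),
                                      simplifyVector = TRUE),
    mcmc = spec$mcmc, seed = spec$seed
  ), class = "jm_fit")
  fit$col_idx <- param_cols(draws, names(specs))
  fit
}
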
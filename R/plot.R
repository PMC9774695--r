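#' Plot a dynamic survival prediction
#'
#' Mirrors the decision-support view a farmer would see: the cow's observed
#' sensor trajectories up to the observation day `v` (one panel per outcome)
#' and the predicted survival curve with its 95% credible band beyond `v`.
#' Requires ggplot2.
#'
#' @param prediction a [predict_survival()] result
#' @param cow_data the cow data used for the prediction (for the sensor
#'   panels); optional
#' @return a ggplot object
#' @export
plot_prediction <- function(prediction, cow_data = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_prediction requires the 'ggplot2' package")
  cv <- prediction$curve
  p_surv <- ggplot2::ggplot(cv, ggplot2::aes(x = u, y = pi)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = lo, ymax = hi),
                         fill = "grey80") +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = prediction$v, linetype = "dotted") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "days post first calving",
                  y = expression(pi(u ~ "|" ~ v)),
                  title = paste0("Predicted survival from v = ",
                                 prediction$v, " DIM")) +
    ggplot2::theme_minimal()
  if (is.null(cow_data)) return(p_surv)
  sensor <- cow_data$sensor
  sensor <- sensor[sensor$dim <= prediction$v, ]
  long <- do.call(rbind, lapply(names(sensor_cols), function(k) {
    data.frame(dim = sensor$dim, outcome = k,
               value = sensor[[sensor_cols[[k]]]])
  }))
  p_sens <- ggplot2::ggplot(long[!is.na(long$value), ],
                            ggplot2::aes(x = dim, y = value)) +
    ggplot2::geom_point(size = 0.3, colour = "firebrick", alpha = 0.6) +
    ggplot2::geom_smooth(method = "loess", formula = y ~ x, se = FALSE,
                         linewidth = 0.5, colour = "black") +
    ggplot2::facet_wrap(~outcome, scales = "free_y", nrow = 1) +
    ggplot2::labs(x = "days in milk", y = NULL) +
    ggplot2::theme_minimal()
  if (requireNamespace("patchwork", quietly = TRUE)) {
    p_sens / p_surv
  } else {
    p_surv
  }
}
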
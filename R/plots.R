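#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point labs
#' @export
ggplot2::autoplot

#' Plot a simulated trial series
#'
#' Predicted peak displacement (the model's absolute error) against trial,
#' colored by trial mode.
#'
#' @param object An `adapt_series` from [simulate_model()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.adapt_series <- function(object, ...) {
  ggplot(object, aes(x = .data$trial, y = .data$abs_error,
                     color = .data$mode)) +
    geom_line(aes(group = 1), color = "grey60") +
    geom_point(size = 0.8) +
    labs(x = "trial", y = "predicted peak displacement",
         color = "trial mode")
}

#' Plot a generalization curve with its half-Gaussian fit
#'
#' @param composite An [composite_exp2()] result.
#' @param which `"deadaptation"` or `"reexposure"`.
#' @return A ggplot object.
#' @export
plot_generalization <- function(composite,
                                which = c("deadaptation", "reexposure")) {
  which <- match.arg(which)
  col <- paste0(sub("deadaptation", "deadaptation_error_cm",
                    sub("reexposure", "reexposure_error_cm", which)))
  fit <- composite$fits[[which]]
  grid <- tibble::tibble(rel = seq(0, 180, by = 1))
  grid$y <- fit$offset + fit$amplitude * exp(-grid$rel^2 / (2 * fit$width_deg^2))
  ggplot(composite$curve,
         aes(x = .data$relative_orientation_deg, y = .data[[col]])) +
    geom_line(data = grid, aes(x = .data$rel, y = .data$y),
              color = "red") +
    geom_point() +
    labs(x = "relative orientation (deg)", y = "error (cm)",
         title = sprintf("%s generalization", which))
}

#' Plot observed series against a model fit
#'
#' @param observed Observed series (`NA` on clamp trials).
#' @param fit An [fit_model()] result.
#' @param schedule The schedule the series lives on.
#' @return A ggplot object.
#' @export
plot_fit <- function(observed, fit, schedule) {
  spec <- par_spec(fit$model_kind, "gain" %in% names(fit$estimate))
  mdl <- par_to_model(fit$model_kind, fit$estimate, spec, fit$compliance)
  sim <- simulate_model(schedule, mdl$params, compliance = mdl$compliance)
  df <- tibble::tibble(trial = sim$trial, observed = as.numeric(observed),
                       fitted = sim$abs_error)
  ggplot(df, aes(x = .data$trial)) +
    geom_point(aes(y = .data$observed), size = 0.6, color = "black",
               na.rm = TRUE) +
    geom_line(aes(y = .data$fitted), color = "red") +
    labs(x = "trial", y = "peak displacement",
         title = sprintf("%s fit (R^2 = %.3f)", fit$model_kind, fit$r_squared))
}
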